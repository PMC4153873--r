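test_that("sample-size specifications parse per the documented grammar", {
  expect_equal(parse_sizes("15 14 15 16", 4), c(15L, 14L, 15L, 16L))
  expect_equal(parse_sizes("15", 4), rep(15L, 4))
  expect_error(parse_sizes("15 14", 4), "expected 1 or 4")
  expect_error(parse_sizes("15 x 15 16", 4), "whole numbers")
  expect_error(parse_sizes("15 1 15 16", 4), "at least 2")
  expect_error(parse_sizes("", 4), "empty")
})

test_that("variable-name validation rejects spaces and duplicates, warns on long names", {
  expect_silent(validate_names("Arginine"))
  expect_error(validate_names(c("ok", "total cholesterol")),
               "space in variable name")
  expect_error(validate_names(c("V1", "V2", "V1")), "duplicate")
  expect_warning(out <- validate_names("Triacylglycerol"),
                 "exceeds 10 characters")
  expect_equal(out$sanitized_name, "Triacylglycerol")  # no silent truncation
})

test_that("a generated raw workbook reads back to the generator's exact moments", {
  cfg <- fixture_config(seed = 301)
  path <- tempfile(fileext = ".xlsx")
  fx <- make_raw_workbook(cfg, path)
  wb <- read_workbook(path, "S1", factor_name = "group")
  expect_length(wb$sheets, 1)
  b <- wb$sheets[[1]]
  expect_equal(b$mode, "raw")
  expect_equal(b$responses, paste0("V", 1:6))
  for (v in b$responses) {
    rs <- summarize_raw(b$data$group, b$data[[v]], variable = v)
    truth <- fx$truth[fx$truth$response == v, ]
    expect_equal(rs$groups$label, truth$label)
    expect_equal(rs$groups$mean, truth$sample_mean, tolerance = 1e-10)
    expect_equal(rs$groups$sd, truth$sample_sd, tolerance = 1e-10)
    expect_equal(rs$groups$n, truth$n)
  }
})

test_that("tables not anchored at the top-left cell are still located", {
  cfg <- fixture_config(seed = 302, n_responses = 2)
  path <- tempfile(fileext = ".xlsx")
  make_raw_workbook(cfg, path, start_row = 4, start_col = 3)
  wb <- read_workbook(path, "S1", factor_name = "group")
  expect_equal(wb$sheets[[1]]$responses, c("V1", "V2"))
  expect_equal(nrow(wb$sheets[[1]]$data), sum(cfg$n))
})

test_that("multi-sheet workbooks preserve sheet order and yield one bundle per sheet", {
  cfg <- fixture_config(seed = 303, n_responses = 2, n_sheets = 3)
  path <- tempfile(fileext = ".xlsx")
  make_raw_workbook(cfg, path, scenario = "S2")
  wb <- read_workbook(path, "S2", factor_name = "group")
  expect_equal(names(wb$sheets), paste0("Data", 1:3))
  expect_true(all(vapply(wb$sheets, function(b) b$mode, "") == "raw"))
})

test_that("summary workbooks parse the (label, mean, dispersion) layout with sizes attached", {
  cfg <- fixture_config(seed = 304, n_responses = 2, n = 15,
                        levels = paste0("L", 1:4))
  path <- tempfile(fileext = ".xlsx")
  fx <- make_summary_workbook(cfg, path, dispersion_kind = "SEM")
  wb <- read_workbook(path, "S3", dispersion_kind = "SEM",
                      sizes_spec = "15")
  b <- wb$sheets[[1]]
  expect_equal(b$mode, "summary")
  expect_length(b$summaries, 2)
  rs <- b$summaries[[1]]
  expect_equal(rs$variable, "Var1")
  expect_equal(rs$groups$label, paste0("L", 1:4))
  expect_equal(rs$groups$n, rep(15, 4))
  truth <- fx$truth[fx$truth$response == "Var1", ]
  expect_equal(rs$groups$mean, truth$sample_mean, tolerance = 1e-10)
  expect_equal(rs$groups$sd, truth$sample_sd, tolerance = 1e-10)

  # unbalanced positional sizes follow source order
  wb2 <- read_workbook(path, "S3", dispersion_kind = "SEM",
                       sizes_spec = "15 14 15 16")
  expect_equal(wb2$sheets[[1]]$summaries[[1]]$groups$n, c(15, 14, 15, 16))
})

test_that("CSV input works for raw data with empty fields as missing", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("group,V1", "A,1", "A,2", "A,", "B,2", "B,3", "B,4"), path)
  wb <- read_workbook(path, "S1", factor_name = "group")
  rs <- summarize_raw(wb$sheets[[1]]$data$group, wb$sheets[[1]]$data$V1)
  expect_equal(rs$groups$n, c(2, 3))
  expect_equal(rs$groups$mean, c(1.5, 3))
})

test_that("reading the same file twice yields identical bundles", {
  cfg <- fixture_config(seed = 305, n_responses = 1)
  path <- tempfile(fileext = ".xlsx")
  make_raw_workbook(cfg, path)
  expect_identical(read_workbook(path, "S1", factor_name = "group"),
                   read_workbook(path, "S1", factor_name = "group"))
})

test_that("input validation errors carry actionable context", {
  cfg <- fixture_config(seed = 306, n_responses = 1)
  path <- tempfile(fileext = ".xlsx")
  make_raw_workbook(cfg, path)
  expect_error(read_workbook(path, "S1", factor_name = "Group"),
               "case-sensitive")
  expect_error(read_workbook(path, "S1"), "factor_name")
  expect_error(read_workbook(tempfile(fileext = ".txt"), "S1"), "not found")
  bad <- tempfile(fileext = ".txt")
  writeLines("x", bad)
  expect_error(read_workbook(bad, "S1"), "unsupported file extension")

  # single data column: no response left once the factor is taken
  one_col <- tempfile(fileext = ".csv")
  writeLines(c("group", "A", "A", "B", "B"), one_col)
  expect_error(read_workbook(one_col, "S1", factor_name = "group"),
               "at least one response")

  # summary without sizes
  spath <- tempfile(fileext = ".xlsx")
  make_summary_workbook(fixture_config(seed = 307, n_responses = 1), spath)
  expect_error(read_workbook(spath, "S3"), "sizes_spec")
})

test_that("two disjoint data blocks in one sheet are an error, not a guess", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("group,V1", "A,1", "A,2", "", "other,V9", "B,3", "B,4"), path)
  expect_error(read_workbook(path, "S1", factor_name = "group"),
               "disjoint data block")
})

test_that("display precision is inferred from the source text", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("Group,Var1,Var1_SEM", "L1,110,4", "L2,115,5", "L3,149.5,6.25"),
             path)
  wb <- read_workbook(path, "S3", dispersion_kind = "SEM", sizes_spec = "6")
  rs <- wb$sheets[[1]]$summaries[[1]]
  expect_equal(rs$groups$digits[1], 1L)     # max over the column: 149.5
  expect_equal(rs$groups$sem_digits[1], 2L) # 6.25
})
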