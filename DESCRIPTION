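Package: aovtab
Title: Publication-Ready One-Way ANOVA Tables with Post-Hoc Letter Displays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: One-way analysis of variance computed from raw observations or
    from published summary statistics (per-group sample size, mean, and SD or
    SEM), followed by all-pairwise multiple comparisons (Fisher LSD with
    optional Bonferroni/Holm p-value adjustment, Tukey-Kramer,
    Student-Newman-Keuls, and Duncan multiple range tests), compact letter
    displays built by the insert-and-absorb algorithm, and rendering of the
    results as publication-ready RTF tables in the two formats common in
    life-science journals (per-group SEM and pooled SEM). Reads single- and
    multi-sheet spreadsheet workbooks or CSV files, generates synthetic toy
    workbooks for testing, and ships a command-line pipeline that turns a
    workbook into one finished table per dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    readxl,
    digest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
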