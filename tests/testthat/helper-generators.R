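# Shared generators and independent oracles for the test suite.

# Random summary row: k groups with positive SDs; balanced or unbalanced.
random_summary <- function(k = 3L, balanced = TRUE, n_range = c(4L, 12L)) {
  n <- if (balanced) rep(sample(n_range[1]:n_range[2], 1), k)
       else sample(n_range[1]:n_range[2], k, replace = TRUE)
  response_summary("y", paste0("g", seq_len(k)), n,
                   mean = rnorm(k, 10, 2),
                   dispersion = runif(k, 0.5, 2),
                   dispersion_kind = "SD")
}

# Random raw dataset consistent with the one-way model.
random_raw <- function(k = 3L, n = 8L, effects = rnorm(k, 0, 1), sigma = 1) {
  n <- rep_len(n, k)
  fac <- rep(paste0("g", seq_len(k)), times = n)
  y <- rep(effects, times = n) + rnorm(sum(n), 0, sigma)
  list(fac = fac, y = y)
}

# Definitional brute-force p-value adjustments, written independently of
# the implementation (and of stats::p.adjust).
brute_bonferroni <- function(p) pmin(1, length(p) * p)
brute_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Random symmetric significance relation on k groups.
random_relation <- function(k) {
  rel <- matrix(FALSE, k, k)
  up <- which(upper.tri(rel))
  rel[up] <- sample(c(TRUE, FALSE), length(up), replace = TRUE)
  rel[lower.tri(rel)] <- t(rel)[lower.tri(rel)]
  rel
}

# Relation from an integer bitmask over the C(k,2) upper-triangle pairs,
# for exhaustive enumeration at small k.
relation_from_mask <- function(k, mask) {
  rel <- matrix(FALSE, k, k)
  up <- which(upper.tri(rel))
  bits <- as.logical(bitwAnd(mask, 2^(seq_along(up) - 1)))
  rel[up] <- bits
  rel[lower.tri(rel)] <- t(rel)[lower.tri(rel)]
  rel
}

# CLD soundness: sharing a letter must mirror non-significance exactly.
cld_sound <- function(display, relation) {
  k <- length(display$labels)
  shares <- function(i, j) {
    a <- strsplit(display$letters[i], "")[[1]]
    b <- strsplit(display$letters[j], "")[[1]]
    length(intersect(a, b)) > 0
  }
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (relation[i, j] && shares(i, j)) return(FALSE)
    if (!relation[i, j] && !shares(i, j)) return(FALSE)
  }
  TRUE
}

# No letter class absorbed in another.
cld_absorbed <- function(display) {
  cl <- display$partition
  for (a in seq_along(cl)) for (b in seq_along(cl)) {
    if (a != b && all(cl[[a]] %in% cl[[b]])) return(FALSE)
  }
  TRUE
}

# Significant pair set (sorted label pairs) of an mcp_result.
sig_pairs <- function(mcp) {
  cmp <- mcp$comparisons[mcp$comparisons$significant, , drop = FALSE]
  if (nrow(cmp) == 0) return(character(0))
  sort(apply(cmp[, c("label_i", "label_j")], 1,
             function(r) paste(sort(r), collapse = "|")))
}
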