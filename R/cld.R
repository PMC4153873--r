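#' Compact letter display by insert-and-absorb
#'
#' Converts a symmetric pairwise significance relation into superscript
#' letter strings so that two groups share a letter if and only if they are
#' NOT significantly different. The constructive algorithm starts from one
#' class containing all groups; each significant pair (i, j) is "inserted" by
#' duplicating every class containing both, deleting i from one copy and j
#' from the other; after every insertion any class that is a subset of
#' another is "absorbed" (deleted). Pairs are processed in a fixed
#' lexicographic position order, so output is deterministic; any processing
#' order yields a valid display.
#'
#' Letter naming is a presentation choice with no statistical content:
#' classes are ordered by the best `ranks` value among their members (by
#' default input position; the table pipeline passes descending-mean ranks so
#' that 'a' attaches to the class containing the largest mean). Downstream
#' comparisons should use the induced partition (see
#' [letters_to_partition()]), which is invariant to letter renaming.
#'
#' @param labels Group labels in presentation order.
#' @param relation Symmetric logical matrix with `FALSE` diagonal;
#'   `relation[i, j]` is `TRUE` when groups i and j differ significantly.
#' @param ranks Optional numeric vector, one per group, smaller = earlier
#'   letter; defaults to input position.
#' @return An object of class `letter_display`: list with `labels`,
#'   `letters` (character vector, letters within each string sorted), and
#'   `partition` (list of character vectors of labels, one per letter class).
#' @examples
#' rel <- matrix(FALSE, 3, 3)
#' rel[1, 3] <- rel[3, 1] <- rel[2, 3] <- rel[3, 2] <- TRUE
#' insert_absorb(c("0", "4", "8"), rel)$letters  # "a" "a" "b"
#' @export
insert_absorb <- function(labels, relation, ranks = seq_along(labels)) {
  labels <- as.character(labels)
  k <- length(labels)
  relation <- as.matrix(relation)
  if (!is.logical(relation)) storage.mode(relation) <- "logical"
  if (nrow(relation) != k || ncol(relation) != k)
    stop("relation must be a ", k, " x ", k, " matrix")
  if (anyNA(relation)) stop("relation must not contain NA")
  if (!isTRUE(all(relation == t(relation)))) stop("relation must be symmetric")
  if (any(diag(relation))) stop("relation diagonal must be FALSE")
  if (length(ranks) != k) stop("ranks must have one entry per group")

  classes <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    if (!relation[i, j]) next
    out <- list()
    for (cl in classes) {
      if (i %in% cl && j %in% cl) {
        out <- c(out, list(setdiff(cl, i), setdiff(cl, j)))
      } else {
        out <- c(out, list(cl))
      }
    }
    out <- Filter(length, out)
    # absorb: drop classes contained in another (duplicates keep one copy)
    keep <- rep(TRUE, length(out))
    for (a in seq_along(out)) for (b in seq_along(out)) {
      if (a == b || !keep[a] || !keep[b]) next
      if (all(out[[a]] %in% out[[b]]) &&
          (length(out[[a]]) < length(out[[b]]) || a > b)) keep[a] <- FALSE
    }
    classes <- out[keep]
  }
  # order classes: best (smallest) member rank, ties by larger class then
  # by member positions, for full determinism
  key1 <- vapply(classes, function(cl) min(ranks[cl]), numeric(1))
  key2 <- -vapply(classes, length, numeric(1))
  key3 <- vapply(classes, function(cl) paste(sort(cl), collapse = ","), "")
  classes <- classes[order(key1, key2, key3)]

  lab <- vapply(seq_along(classes), letter_name, "")
  letters_out <- vapply(seq_len(k), function(g) {
    paste(sort(lab[vapply(classes, function(cl) g %in% cl, logical(1))]),
          collapse = "")
  }, "")
  structure(list(
    labels = labels,
    letters = letters_out,
    partition = lapply(classes, function(cl) labels[cl])
  ), class = "letter_display")
}

# a..z, then aa, ab, ... for pathological displays with > 26 classes
letter_name <- function(i) {
  if (i <= 26L) return(letters[i])
  paste0(letter_name((i - 1L) %/% 26L), letters[(i - 1L) %% 26L + 1L])
}

#' Canonical partition of a letter display
#'
#' The set of letter classes as sets of group labels, independent of which
#' letter names each class. Two displays that differ only by renaming or
#' reordering letters map to the identical canonical partition, which makes
#' this the right object for comparing displays (published tables are not
#' consistent about which class gets 'a').
#'
#' @param display A `letter_display` from [insert_absorb()].
#' @return List of character vectors (sorted labels), sorted canonically;
#'   classes are unique.
#' @export
letters_to_partition <- function(display) {
  stopifnot(inherits(display, "letter_display"))
  canonical_partition(display$partition)
}

# Shared canonical form: sort labels within classes, dedupe, sort classes.
canonical_partition <- function(classes) {
  cl <- lapply(classes, function(x) sort(as.character(x)))
  keys <- vapply(cl, paste, "", collapse = "\r")
  cl <- cl[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  cl[order(keys)]
}

#' Compare two partitions up to letter renaming
#'
#' @param a,b Partitions (lists of label vectors) or `letter_display`
#'   objects.
#' @return `TRUE` when both induce the same set of classes.
#' @export
same_partition <- function(a, b) {
  if (inherits(a, "letter_display")) a <- a$partition
  if (inherits(b, "letter_display")) b <- b$partition
  identical(canonical_partition(a), canonical_partition(b))
}

#' @export
print.letter_display <- function(x, ...) {
  cat("Letter display:\n")
  print(data.frame(label = x$labels, letters = x$letters), row.names = FALSE)
  invisible(x)
}
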