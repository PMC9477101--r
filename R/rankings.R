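# Ranking and paired-comparison-pattern algebra.
#
# A complete ranking of J items induces J(J-1)/2 signed pairwise decisions
# y_jk in {+1, -1} over canonical pairs (j, k), j < k in item-label order.
# Exactly J! of the 2^(J(J-1)/2) conceivable patterns are transitive, and
# those are precisely the patterns derivable from rankings.

.wt_cache <- new.env(parent = emptyenv())

# all permutations of 1..J in lexicographic order
perms_lex <- function(J) {
  if (J == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_lex(J - 1L)
  nsub <- nrow(sub)
  out <- matrix(0L, nsub * J, J)
  for (first in seq_len(J)) {
    rest <- setdiff(seq_len(J), first)
    rows <- (first - 1L) * nsub + seq_len(nsub)
    out[rows, 1L] <- first
    out[rows, -1L] <- matrix(rest[sub], nsub, J - 1L)
  }
  out
}

# cached enumeration of the J! transitive patterns plus derived design pieces:
#   perm  J! x J permutations (rows are orderings, lexicographic)
#   Y     J! x J(J-1)/2 signed pairwise indicators
#   X     J! x J per-item aggregated scores (row sums of signed indicators)
pattern_space <- function(J) {
  J <- as.integer(J)
  if (is.na(J) || J < 2L || J > 7L) {
    stop("number of items must be between 2 and 7; the pattern space grows as J! ",
         "and is enumerated exactly")
  }
  key <- paste0("J", J)
  hit <- .wt_cache[[key]]
  if (!is.null(hit)) return(hit)
  perm <- perms_lex(J)
  np <- nrow(perm)
  pos <- matrix(0L, np, J)
  pos[cbind(rep(seq_len(np), J), c(perm))] <- rep(seq_len(J), each = np)
  pr <- pc_pairs(J)
  m <- nrow(pr)
  Y <- matrix(0L, np, m)
  for (q in seq_len(m)) {
    Y[, q] <- ifelse(pos[, pr[q, 1L]] < pos[, pr[q, 2L]], 1L, -1L)
  }
  B <- matrix(0, J, m)
  B[cbind(pr[, 1L], seq_len(m))] <- 1
  B[cbind(pr[, 2L], seq_len(m))] <- -1
  X <- Y %*% t(B)
  res <- list(J = J, perm = perm, Y = Y, X = X, pairs = pr, B = B)
  assign(key, res, envir = .wt_cache)
  res
}

pair_names <- function(labels) {
  pr <- pc_pairs(length(labels))
  paste0(labels[pr[, 1L]], ":", labels[pr[, 2L]])
}

#' Enumerate all transitive paired-comparison patterns
#'
#' Returns the `J!` patterns derivable from complete rankings of `J` items,
#' one row per pattern, in a stable order: lexicographic by the generating
#' ranking (in item-label order). Columns follow the canonical pair order
#' (1,2), (1,3), ..., (1,J), (2,3), ..., (J-1,J).
#'
#' @param items an [item_set], a character vector of labels, or an integer
#'   number of items `J` (2 to 7).
#' @return An integer matrix of +1/-1 with `factorial(J)` rows; the attribute
#'   `"orderings"` holds the generating ranking (label indices) for each row.
#' @examples
#' nrow(enumerate_patterns(5)) # 120
#' @export
enumerate_patterns <- function(items) {
  if (is.numeric(items) && length(items) == 1L) {
    J <- as.integer(items)
    labels <- letters[seq_len(min(J, 26L))]
  } else {
    items <- as_item_set(items)
    J <- n_items(items)
    labels <- items$labels
  }
  sp <- pattern_space(J)
  Y <- sp$Y
  colnames(Y) <- pair_names(labels)
  attr(Y, "orderings") <- sp$perm
  Y
}

#' Convert a complete ranking to its paired-comparison pattern
#'
#' @param ranking a character vector giving the ordering of item labels,
#'   position 1 = highest on the judged attribute.
#' @param items an [item_set] (or character vector of labels).
#' @return Integer vector of +1/-1 over the canonical pairs: +1 when the
#'   row item precedes (is preferred to) the column item.
#' @examples
#' it <- item_set(letters[1:5])
#' ranking_to_pattern(letters[1:5], it) # all +1
#' @export
ranking_to_pattern <- function(ranking, items) {
  items <- as_item_set(items)
  J <- n_items(items)
  ranking <- as.character(ranking)
  idx <- match(ranking, items$labels)
  if (anyNA(idx)) stop("unknown item label '", ranking[which(is.na(idx))[1L]], "'")
  if (anyDuplicated(idx)) {
    stop("duplicate item label '", ranking[duplicated(idx)][1L], "' in ranking")
  }
  if (length(ranking) != J) {
    stop("incomplete ranking: expected ", J, " items, got ", length(ranking))
  }
  pos <- integer(J)
  pos[idx] <- seq_len(J)
  pr <- pc_pairs(J)
  y <- ifelse(pos[pr[, 1L]] < pos[pr[, 2L]], 1L, -1L)
  names(y) <- pair_names(items$labels)
  y
}

#' Recover the ranking generating a transitive pattern
#'
#' Inverse of [ranking_to_pattern()]. Intransitive patterns (containing a
#' preference cycle) cannot arise from rankings and raise an error naming a
#' violating triple.
#'
#' @param pattern a +1/-1 vector over the canonical pairs.
#' @param items an [item_set] (or character vector of labels).
#' @return Character vector: the unique complete ranking inducing `pattern`.
#' @export
pattern_to_ranking <- function(pattern, items) {
  items <- as_item_set(items)
  J <- n_items(items)
  m <- J * (J - 1L) / 2L
  pattern <- as.integer(pattern)
  if (length(pattern) != m || !all(pattern %in% c(-1L, 1L))) {
    stop("pattern must be a vector of +1/-1 of length J(J-1)/2 = ", m)
  }
  x <- drop(item_scores(pattern))
  if (!identical(sort(x), seq(-(J - 1), J - 1, by = 2))) {
    trip <- find_cycle_triple(pattern, J)
    stop("intransitive pattern: cycle ", items$labels[trip[1L]], " > ",
         items$labels[trip[2L]], " > ", items$labels[trip[3L]], " > ",
         items$labels[trip[1L]])
  }
  items$labels[order(x, decreasing = TRUE)]
}

# signed preference of item a over item b implied by a pattern
pattern_pref <- function(pattern, a, b, J) {
  pr <- pc_pairs(J)
  if (a < b) q <- which(pr[, 1L] == a & pr[, 2L] == b) else q <- which(pr[, 1L] == b & pr[, 2L] == a)
  s <- pattern[q]
  if (a < b) s else -s
}

find_cycle_triple <- function(pattern, J) {
  for (i in seq_len(J - 2L)) for (j in (i + 1L):(J - 1L)) for (k in (j + 1L):J) {
    sij <- pattern_pref(pattern, i, j, J)
    sjk <- pattern_pref(pattern, j, k, J)
    ski <- pattern_pref(pattern, k, i, J)
    if (sij == 1L && sjk == 1L && ski == 1L) return(c(i, j, k))
    if (sij == -1L && sjk == -1L && ski == -1L) return(c(i, k, j))
  }
  stop("no violating triple found (pattern is transitive)")
}

#' Per-item aggregated design scores of a pattern
#'
#' For each item, the signed sum of its pairwise indicators: +1 for each item
#' it beats, -1 for each item it loses to. For a pattern derived from a
#' complete ranking the scores are the arithmetic sequence
#' `J-1, J-3, ..., -(J-1)` in ranking order, and they always sum to zero.
#' These are the per-item columns of the loglinear pattern-model design.
#'
#' @param pattern a +1/-1 vector over the canonical pairs, or a matrix with
#'   one pattern per row.
#' @return A numeric vector of length `J` (or a matrix with `J` columns).
#' @examples
#' it <- item_set(letters[1:5])
#' item_scores(ranking_to_pattern(letters[1:5], it)) # 4 2 0 -2 -4
#' @export
item_scores <- function(pattern) {
  Y <- if (is.matrix(pattern)) pattern else matrix(pattern, nrow = 1L)
  m <- ncol(Y)
  J <- as.integer((1 + sqrt(1 + 8 * m)) / 2)
  if (J * (J - 1L) / 2L != m) stop("pattern length is not of the form J(J-1)/2")
  sp_B <- pattern_space(J)$B
  X <- Y %*% t(sp_B)
  if (!is.matrix(pattern)) drop(X) else X
}

# --- rankings tables ------------------------------------------------------

ranking_cols <- function(J) paste0("pos", seq_len(J))

# validate a rankings data.frame and return the n x J matrix of label indices
as_ordering_matrix <- function(rankings, items) {
  items <- as_item_set(items)
  J <- n_items(items)
  cols <- ranking_cols(J)
  if (!is.data.frame(rankings)) stop("'rankings' must be a data.frame")
  miss <- setdiff(c("subject_id", cols), names(rankings))
  if (length(miss)) {
    stop("rankings table is missing column(s): ", paste(miss, collapse = ", "))
  }
  M <- as.matrix(rankings[cols])
  idx <- matrix(match(M, items$labels), nrow(M), J)
  if (anyNA(idx)) {
    bad <- which(is.na(idx), arr.ind = TRUE)[1L, ]
    stop("row ", bad[1L], ": unknown item label '", M[bad[1L], bad[2L]], "'")
  }
  if (nrow(idx)) {
    dup <- vapply(seq_len(nrow(idx)), function(r) anyDuplicated(idx[r, ]) > 0L, logical(1L))
    if (any(dup)) {
      r <- which(dup)[1L]
      lab <- M[r, ][duplicated(idx[r, ])][1L]
      stop("row ", r, ": duplicate item label '", lab, "' in ranking")
    }
  }
  rownames(idx) <- as.character(rankings$subject_id)
  idx
}

# lexicographic rank (1-based) of each permutation row in the enumeration
perm_rank_rows <- function(P) {
  J <- ncol(P)
  n <- nrow(P)
  if (n == 0L) return(integer(0))
  r <- rep(1, n)
  for (i in seq_len(J - 1L)) {
    cnt <- rep(0, n)
    for (j in (i + 1L):J) cnt <- cnt + (P[, j] < P[, i])
    r <- r + cnt * factorial(J - i)
  }
  as.integer(r)
}

# pattern index (into the enumeration order) for each row of a rankings table
pattern_index <- function(rankings, items) {
  idx <- as_ordering_matrix(rankings, items)
  perm_rank_rows(idx)
}

#' Tabulate rankings into a pattern count table
#'
#' Counts subjects per transitive pattern: the `J!`-cell multinomial the
#' loglinear pattern model is fitted to. Unobserved patterns get count 0.
#'
#' @param rankings a data.frame with columns `subject_id`, `pos1`, ...,
#'   `posJ` (cells are item labels; position 1 = highest on the attribute).
#' @param items an [item_set].
#' @return An object of class `pattern_table`: list with `counts` (length
#'   `J!`, enumeration order), `n`, and `items`.
#' @export
tabulate_patterns <- function(rankings, items) {
  items <- as_item_set(items)
  J <- n_items(items)
  pidx <- pattern_index(rankings, items)
  counts <- tabulate(pidx, nbins = factorial(J))
  pattern_table(counts, items)
}

#' Construct a pattern count table directly
#'
#' @param counts non-negative numeric vector of length `J!` in the
#'   enumeration order of [enumerate_patterns()].
#' @param items an [item_set].
#' @return An object of class `pattern_table`.
#' @export
pattern_table <- function(counts, items) {
  items <- as_item_set(items)
  J <- n_items(items)
  counts <- as.numeric(counts)
  if (length(counts) != factorial(J)) {
    stop("'counts' must have length J! = ", factorial(J))
  }
  if (any(counts < 0) || anyNA(counts)) stop("'counts' must be non-negative")
  structure(list(counts = counts, n = sum(counts), items = items),
            class = "pattern_table")
}

#' @export
print.pattern_table <- function(x, ...) {
  cat("Pattern table over", length(x$counts), "transitive patterns,",
      "n =", x$n, "\n")
  obs <- sum(x$counts > 0)
  cat(" ", obs, "patterns observed\n")
  invisible(x)
}

#' Proportion of rankings matching the intended order
#'
#' @param rankings a rankings data.frame (see [tabulate_patterns()]).
#' @param items an [item_set] with a non-`NULL` `intended_order`.
#' @return Proportion in `[0, 1]`.
#' @export
correct_ranking_rate <- function(rankings, items) {
  items <- as_item_set(items)
  if (is.null(items$intended_order)) {
    stop("'items' has no intended_order; cannot score rankings as correct")
  }
  idx <- as_ordering_matrix(rankings, items)
  if (nrow(idx) == 0L) return(NaN)
  target <- match(items$intended_order, items$labels)
  mean(apply(idx, 1L, function(r) all(r == target)))
}

#' Per-subject expanded design of the loglinear pattern model
#'
#' Stacks one copy of the `J!`-row pattern design (intercept plus the per-item
#' aggregated scores) per subject, as used by the Poisson loglinear
#' formulation of the pattern model where each subject contributes a block.
#'
#' @param items an [item_set].
#' @param n_subjects number of subjects.
#' @return A numeric matrix with `n_subjects * factorial(J)` rows and
#'   `1 + J` columns (`intercept`, one score column per item).
#' @export
expanded_design <- function(items, n_subjects) {
  items <- as_item_set(items)
  sp <- pattern_space(n_items(items))
  D <- cbind(intercept = 1, sp$X)
  colnames(D) <- c("intercept", paste0("x_", items$labels))
  D[rep(seq_len(nrow(D)), times = n_subjects), , drop = FALSE]
}

#' Design structure of the loglinear pattern model
#'
#' One row per transitive pattern: the generating ranking, the signed pairwise
#' indicators, and the per-item aggregated scores.
#'
#' @param items an [item_set].
#' @return A data.frame with `factorial(J)` rows.
#' @export
pattern_design <- function(items) {
  items <- as_item_set(items)
  J <- n_items(items)
  sp <- pattern_space(J)
  rank_str <- apply(sp$perm, 1L, function(r) paste(items$labels[r], collapse = " "))
  Y <- sp$Y
  colnames(Y) <- paste0("y_", gsub(":", "", pair_names(items$labels)))
  X <- sp$X
  colnames(X) <- paste0("x_", items$labels)
  data.frame(ranking = rank_str, Y, intercept = 1, X,
             check.names = FALSE, stringsAsFactors = FALSE)
}

# --- delimited-text I/O ---------------------------------------------------

#' Read a rankings table from delimited text
#'
#' Expects a header `subject_id,pos1,...,posJ`; cells are item labels.
#' Validation is strict: unknown or duplicated labels are reported with the
#' offending row number.
#'
#' @param path file path.
#' @param items an [item_set].
#' @param sep field delimiter (default comma).
#' @return A validated rankings data.frame.
#' @export
read_rankings <- function(path, items, sep = ",") {
  items <- as_item_set(items)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = TRUE,
                          fileEncoding = "UTF-8")
  as_ordering_matrix(df, items) # validates; errors carry row numbers
  df
}

#' Write a rankings table to delimited text
#'
#' @param rankings a rankings data.frame.
#' @param path file path.
#' @param sep field delimiter.
#' @export
write_rankings <- function(rankings, path, sep = ",") {
  utils::write.table(rankings, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
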