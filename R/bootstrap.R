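# Nonparametric bootstrap of the full tree pipeline: resample subjects with
# replacement, regrow and prune a tree per resample, and summarize how often
# each covariate is selected for a split and where the cutpoints fall.

#' Bootstrap configuration
#'
#' @param B number of resamples (the study-scale default is 1000; smaller
#'   values are useful for smoke tests).
#' @param seed master seed; per-resample seeds are spawned from it so that
#'   increasing `B` never alters earlier resamples.
#' @param tree a [tree_config()] applied identically to every resample.
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(B = 1000L, seed = NULL, tree = tree_config()) {
  stopifnot(B >= 1)
  structure(list(B = as.integer(B), seed = seed, tree = tree),
            class = "bootstrap_config")
}

# covariates appearing in >= 1 split of a (pruned) tree, with cutpoints
collect_splits <- function(tree) {
  rules <- list()
  rec <- function(node) {
    if (is.null(node$kids)) return(invisible(NULL))
    rules[[length(rules) + 1L]] <<- node$split
    rec(node$kids[[1L]])
    rec(node$kids[[2L]])
  }
  rec(tree$root)
  rules
}

#' Bootstrap stability of an LLBT partition tree
#'
#' Grows and prunes a tree on `B` subject-level resamples (with replacement,
#' size `n`; each subject's ranking and covariates move together) and records,
#' per covariate, the fraction of resamples in which it appears in at least
#' one split of the pruned tree, together with all observed cutpoints
#' (numeric/ordinal splits).
#'
#' @inheritParams grow_tree
#' @param config a [bootstrap_config()].
#' @return An object of class `stability_summary`: list with `selection`
#'   (named proportions), `cutpoints` (named list of numeric vectors), `B`,
#'   `seed`, `n`.
#' @export
bootstrap_trees <- function(rankings, covariates, items, kinds,
                            config = bootstrap_config(), levels = list(),
                            groups = NULL) {
  items <- as_item_set(items)
  n <- nrow(rankings)
  B <- config$B
  seeds <- with_fixed_seed(config$seed %||% 0L,
                           sample.int(.Machine$integer.max, B, replace = TRUE))
  cov_names <- setdiff(names(covariates), "subject_id")
  hits <- stats::setNames(numeric(length(cov_names)), cov_names)
  cutpoints <- stats::setNames(vector("list", length(cov_names)), cov_names)
  crow <- match(as.character(rankings$subject_id),
                as.character(covariates$subject_id))
  n_single <- 0L
  for (b in seq_len(B)) {
    idx <- with_fixed_seed(seeds[b], sample.int(n, n, replace = TRUE))
    # handle the resample as a weighted dataset (multiplicity = case weight):
    # duplicated subjects then cannot inflate the score-fluctuation tests
    mult <- tabulate(idx, nbins = n)
    use <- which(mult > 0)
    rk <- rankings[use, , drop = FALSE]
    cvv <- covariates[crow[use], , drop = FALSE]
    cvv$subject_id <- rk$subject_id
    grp <- groups
    if (!is.null(groups)) {
      gv <- groups$values
      if (!is.null(names(gv))) gv <- gv[as.character(rankings$subject_id)]
      grp <- if (length(unique(gv[use])) < 2L) NULL else
        group_spec(stats::setNames(gv[use], as.character(rk$subject_id)),
                   reference = if (groups$reference %in% gv[use])
                     groups$reference else NULL)
    }
    tree <- grow_tree(rk, cvv, items, kinds, config$tree, levels = levels,
                      groups = grp, weights = mult[use])
    rules <- collect_splits(tree)
    if (!length(rules)) n_single <- n_single + 1L
    seen <- unique(vapply(rules, function(r) r$covariate, character(1)))
    hits[seen] <- hits[seen] + 1
    for (r in rules) {
      if (r$kind != "nominal") {
        cutpoints[[r$covariate]] <- c(cutpoints[[r$covariate]], r$cutpoint)
      }
    }
  }
  structure(list(selection = hits / B, cutpoints = cutpoints, B = B,
                 seed = config$seed, n = n, n_single_node = n_single),
            class = "stability_summary")
}

#' @export
print.stability_summary <- function(x, ...) {
  cat("Bootstrap stability over", x$B, "resamples (n =", x$n, ")\n")
  df <- data.frame(covariate = names(x$selection),
                   selection_probability = unname(x$selection),
                   n_cutpoints = vapply(x$cutpoints, length, integer(1)),
                   mean_cutpoint = vapply(x$cutpoints, function(v)
                     if (length(v)) mean(v) else NA_real_, numeric(1)))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Summarize the cutpoint distribution of one covariate
#'
#' @param summary a `stability_summary`.
#' @param name covariate name.
#' @param breaks number of histogram bins over the sample range.
#' @return A list with `covariate`, `n_samples`, `mean`, `hist` (a
#'   `data.frame` of bin midpoints and frequencies), and `empty = TRUE` when
#'   the covariate was never selected.
#' @export
summarize_cutpoints <- function(summary, name, breaks = 10L) {
  if (!name %in% names(summary$cutpoints)) stop("unknown covariate '", name, "'")
  v <- summary$cutpoints[[name]]
  if (!length(v)) {
    return(list(covariate = name, n_samples = 0L, mean = NULL, hist = NULL,
                empty = TRUE))
  }
  if (length(unique(v)) == 1L) {
    h <- data.frame(mid = v[1L], count = length(v))
  } else {
    hh <- graphics::hist(v, breaks = breaks, plot = FALSE)
    h <- data.frame(mid = hh$mids, count = hh$counts)
  }
  list(covariate = name, n_samples = length(v), mean = mean(v), hist = h,
       empty = FALSE)
}

#' Write a stability summary to CSV and JSON
#'
#' The CSV carries one row per covariate (`covariate, selection_probability,
#' n_cutpoints, mean_cutpoint`); the JSON additionally carries the raw
#' cutpoint samples.
#'
#' @param summary a `stability_summary`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @export
write_stability <- function(summary, csv_path = NULL, json_path = NULL) {
  df <- data.frame(covariate = names(summary$selection),
                   selection_probability = unname(summary$selection),
                   n_cutpoints = vapply(summary$cutpoints, length, integer(1)),
                   mean_cutpoint = vapply(summary$cutpoints, function(v)
                     if (length(v)) mean(v) else NA_real_, numeric(1)))
  if (!is.null(csv_path)) {
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(B = summary$B, n = summary$n,
                              selection = as.list(summary$selection),
                              cutpoints = summary$cutpoints),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(df)
}
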