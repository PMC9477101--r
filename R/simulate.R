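# Synthetic ranking studies.
#
# A simulation design pairs covariate distributions with leaf rules mapping
# covariate conditions to worth vectors. Rankings are drawn from the EXACT
# pattern distribution of the loglinear Bradley-Terry model (enumeration plus
# a categorical draw), not from a sequential Plackett-Luce scheme: the two
# ranking laws differ for J >= 3, and recovery tests are only meaningful when
# the generator and the estimator share one law.

#' Declare a covariate's sampling distribution
#'
#' @param name covariate name.
#' @param kind `"numeric"`, `"ordinal"` or `"nominal"`.
#' @param mean,sd numeric covariates: natural-scale mean and sd. With
#'   `lognormal = TRUE` these are the natural-scale moments of a lognormal
#'   (converted internally to meanlog/sdlog).
#' @param lognormal sample from a lognormal instead of a normal.
#' @param round round numeric draws to integers.
#' @param min,max truncation bounds (rejection sampling after rounding).
#' @param levels ordinal/nominal: the category values, in order.
#' @param probs ordinal/nominal: category probabilities (sum to 1).
#' @return An object of class `covariate_spec`.
#' @export
covariate_spec <- function(name, kind = c("numeric", "ordinal", "nominal"),
                           mean = NULL, sd = NULL, lognormal = FALSE,
                           round = FALSE, min = -Inf, max = Inf,
                           levels = NULL, probs = NULL) {
  kind <- match.arg(kind)
  if (kind == "numeric") {
    if (is.null(mean) || is.null(sd)) stop("numeric spec '", name, "' needs mean and sd")
    if (sd <= 0) stop("numeric spec '", name, "': sd must be > 0")
    if (lognormal && mean <= 0) stop("lognormal spec '", name, "': mean must be > 0")
  } else {
    if (is.null(levels) || is.null(probs)) {
      stop(kind, " spec '", name, "' needs levels and probs")
    }
    if (length(levels) != length(probs)) stop("levels/probs length mismatch in '", name, "'")
    if (any(probs < 0) || abs(sum(probs) - 1) > 1e-6) {
      stop("probs of '", name, "' must be non-negative and sum to 1")
    }
    probs <- probs / sum(probs)
  }
  structure(list(name = name, kind = kind, mean = mean, sd = sd,
                 lognormal = lognormal, round = round, min = min, max = max,
                 levels = levels, probs = probs),
            class = "covariate_spec")
}

#' Shifted-binomial probabilities for a Likert scale
#'
#' Convenience for emulating a 1..K Likert item with a given mean: the
#' response is `1 + Binomial(K - 1, p)` with `p = (mean - 1) / (K - 1)`,
#' which reproduces the target mean and a realistic unimodal spread.
#'
#' @param mean target mean on the 1..K scale.
#' @param K number of scale points.
#' @return Probability vector over `1:K`.
#' @export
likert_probs <- function(mean, K) {
  p <- (mean - 1) / (K - 1)
  if (p <= 0 || p >= 1) stop("mean must lie strictly inside the 1..K scale")
  stats::dbinom(0:(K - 1), K - 1, p)
}

sample_one_covariate <- function(spec, n) {
  if (spec$kind == "numeric") {
    out <- numeric(0)
    pars <- if (spec$lognormal) {
      m <- spec$mean; s <- spec$sd
      list(meanlog = log(m^2 / sqrt(m^2 + s^2)),
           sdlog = sqrt(log(1 + s^2 / m^2)))
    } else NULL
    guard <- 0L
    while (length(out) < n) {
      guard <- guard + 1L
      if (guard > 1000L) stop("truncation bounds of '", spec$name, "' reject nearly all draws")
      z <- if (spec$lognormal) {
        stats::rlnorm(n, pars$meanlog, pars$sdlog)
      } else {
        stats::rnorm(n, spec$mean, spec$sd)
      }
      if (spec$round) z <- round(z)
      z <- z[z >= spec$min & z <= spec$max]
      out <- c(out, z)
    }
    out[seq_len(n)]
  } else {
    idx <- sample.int(length(spec$levels), n, replace = TRUE, prob = spec$probs)
    spec$levels[idx]
  }
}

#' Declare a leaf of a simulation design
#'
#' @param when list of predicates, each
#'   `list(covariate = <name>, op = <"<="|"<"|">"|">="|"=="|"in">, value = )`;
#'   their conjunction defines the leaf. `list()` matches everyone (one-leaf
#'   designs).
#' @param worth worth vector of the leaf (positive, sums to 1).
#' @param group_worth optional named list of worth vectors per focal group;
#'   groups not listed fall back to `worth`.
#' @return An object of class `leaf_spec`.
#' @export
leaf_spec <- function(when = list(), worth, group_worth = NULL) {
  worth <- as.numeric(worth)
  if (any(worth <= 0) || abs(sum(worth) - 1) > 1e-8) {
    stop("leaf worth must be strictly positive and sum to 1")
  }
  for (pr in when) {
    if (!all(c("covariate", "op", "value") %in% names(pr)) ||
        !pr$op %in% c("<=", "<", ">", ">=", "==", "in")) {
      stop("each predicate needs fields covariate, op (<=, <, >, >=, ==, in), value")
    }
  }
  if (!is.null(group_worth)) {
    for (g in names(group_worth)) {
      gw <- as.numeric(group_worth[[g]])
      if (length(gw) != length(worth) || any(gw <= 0) || abs(sum(gw) - 1) > 1e-8) {
        stop("group worth '", g, "' must match length and lie on the simplex")
      }
    }
  }
  structure(list(when = when, worth = worth, group_worth = group_worth),
            class = "leaf_spec")
}

#' Assemble a simulation design
#'
#' @param items an [item_set].
#' @param covariates list of [covariate_spec()]s.
#' @param leaves list of [leaf_spec()]s. Their conditions must be mutually
#'   exclusive and exhaustive over the sampled covariate space (validated on
#'   the sampled subjects before any ranking is drawn).
#' @param n number of subjects.
#' @param seed default seed used by [simulate_study()].
#' @param group optional focal-group spec:
#'   `list(name = , levels = , probs = , reference = )`.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(items, covariates, leaves, n, seed = NULL, group = NULL) {
  items <- as_item_set(items)
  if (!length(leaves)) stop("a design needs at least one leaf")
  if (n < 1) stop("'n' must be >= 1")
  cn <- vapply(covariates, function(s) s$name, character(1))
  if (anyDuplicated(cn)) stop("duplicate covariate names in design")
  J <- n_items(items)
  for (lf in leaves) {
    if (!inherits(lf, "leaf_spec")) stop("'leaves' must be leaf_spec objects")
    if (length(lf$worth) != J) stop("leaf worth length must equal the number of items")
    for (pr in lf$when) {
      if (!pr$covariate %in% cn) stop("leaf condition references undeclared covariate '",
                                      pr$covariate, "'")
    }
  }
  if (!is.null(group)) {
    if (is.null(group$name) || is.null(group$levels) || is.null(group$probs)) {
      stop("group spec needs name, levels, probs")
    }
    if (abs(sum(group$probs) - 1) > 1e-8) stop("group probs must sum to 1")
    group$reference <- group$reference %||% group$levels[[1L]]
  }
  structure(list(items = items, covariates = covariates, leaves = leaves,
                 n = as.integer(n), seed = seed, group = group),
            class = "sim_design")
}

eval_predicate <- function(pr, x) {
  switch(pr$op,
         "<=" = x <= pr$value,
         "<"  = x < pr$value,
         ">"  = x > pr$value,
         ">=" = x >= pr$value,
         "==" = x == pr$value,
         "in" = x %in% pr$value)
}

leaf_membership <- function(design, covdf) {
  n <- nrow(covdf)
  M <- vapply(design$leaves, function(lf) {
    ok <- rep(TRUE, n)
    for (pr in lf$when) ok <- ok & eval_predicate(pr, covdf[[pr$covariate]])
    ok
  }, logical(n))
  M <- matrix(M, nrow = n)
  hits <- rowSums(M)
  if (any(hits != 1L)) {
    bad <- which(hits != 1L)[1L]
    stop("leaf conditions are not mutually exclusive and exhaustive: subject ",
         bad, " matches ", hits[bad], " leaves")
  }
  max.col(M, ties.method = "first")
}

#' Sample the covariate table of a design
#'
#' @param design a [sim_design()].
#' @param seed seed (default: the design's).
#' @return data.frame with `subject_id` and one column per covariate spec.
#' @export
sample_covariates <- function(design, seed = design$seed) {
  if (!is.null(seed)) set.seed(seed)
  cols <- lapply(design$covariates, sample_one_covariate, n = design$n)
  names(cols) <- vapply(design$covariates, function(s) s$name, character(1))
  cbind(data.frame(subject_id = seq_len(design$n)),
        as.data.frame(cols, stringsAsFactors = FALSE))
}

#' Sample rankings from a worth vector
#'
#' Draws transitive patterns from the exact pattern distribution implied by
#' `worth` (probability proportional to `exp(sum_j lambda_j x_j)`), then
#' converts each to a ranking. Ties or incomplete rankings cannot occur.
#'
#' @param worth worth vector on the simplex (length `J`, 2 <= J <= 7).
#' @param n number of rankings.
#' @param items an [item_set] (default: letters).
#' @return A rankings data.frame (`subject_id`, `pos1`, ..., `posJ`).
#' @export
sample_ranking <- function(worth, n = 1L, items = NULL) {
  J <- length(worth)
  items <- as_item_set(items %||% letters[seq_len(J)])
  if (n_items(items) != J) stop("items do not match the worth vector length")
  lambda <- lambda_from_worth(worth)
  p <- pattern_distribution(lambda)
  sp <- pattern_space(J)
  idx <- sample.int(length(p), n, replace = TRUE, prob = p)
  ord <- sp$perm[idx, , drop = FALSE]
  M <- matrix(items$labels[ord], n, J)
  colnames(M) <- ranking_cols(J)
  cbind(data.frame(subject_id = seq_len(n)),
        as.data.frame(M, stringsAsFactors = FALSE))
}

#' Simulate a full ranking study
#'
#' Samples covariates, routes every subject to exactly one leaf (validated
#' before any ranking is drawn), and draws each subject's ranking from the
#' leaf's worth vector (per focal group when the design declares one).
#'
#' @param design a [sim_design()].
#' @param seed seed (default: the design's).
#' @return List with `rankings`, `covariates` (sharing `subject_id`), `leaf`
#'   (leaf index per subject) and `groups` (a [group_spec()] or `NULL`).
#' @export
simulate_study <- function(design, seed = design$seed) {
  if (!is.null(seed)) set.seed(seed)
  covdf <- sample_covariates(design, seed = NULL)
  leaf <- leaf_membership(design, covdf)
  n <- design$n
  grp <- NULL
  gval <- NULL
  if (!is.null(design$group)) {
    gi <- sample.int(length(design$group$levels), n, replace = TRUE,
                     prob = design$group$probs)
    gval <- as.character(design$group$levels[gi])
    grp <- group_spec(gval, reference = as.character(design$group$reference))
  }
  J <- n_items(design$items)
  sp <- pattern_space(J)
  ordmat <- matrix(NA_character_, n, J)
  cells <- if (is.null(gval)) leaf else paste(leaf, gval)
  for (cell in unique(cells)) {
    rows <- which(cells == cell)
    lf <- design$leaves[[leaf[rows[1L]]]]
    w <- lf$worth
    if (!is.null(gval) && !is.null(lf$group_worth)) {
      gw <- lf$group_worth[[gval[rows[1L]]]]
      if (!is.null(gw)) w <- gw
    }
    p <- pattern_distribution(lambda_from_worth(w))
    idx <- sample.int(length(p), length(rows), replace = TRUE, prob = p)
    ordmat[rows, ] <- matrix(design$items$labels[sp$perm[idx, , drop = FALSE]],
                             length(rows), J)
  }
  colnames(ordmat) <- ranking_cols(J)
  rankings <- cbind(data.frame(subject_id = seq_len(n)),
                    as.data.frame(ordmat, stringsAsFactors = FALSE))
  list(rankings = rankings, covariates = covdf, leaf = leaf, groups = grp)
}

#' Default study-emulation design
#'
#' A ready-made [sim_design()] shaped like a large classroom ranking study:
#' five items ranked on visual abstraction; covariates age (rounded normal,
#' mean 15.35, sd 2.96, truncated at 13), task time (lognormal, mean 23.01 s,
#' sd 10.26 s), gender (52% female), art grade (1..6 Likert-type, mean 1.96),
#' five 1..5 self-rated art-skill items and five 1..4 self-rated visual-skill
#' items (shifted-binomial marginals); and four leaves defined by task time
#' and interest in visual puzzles (IP), each with its own worth vector.
#'
#' @param n number of subjects (default 987).
#' @param seed default seed for [simulate_study()].
#' @return A [sim_design()].
#' @export
study_design <- function(n = 987L, seed = NULL) {
  items <- item_set(letters[1:5], attribute = "abstraction",
                    intended_order = letters[1:5])
  lik5 <- function(name, mean) {
    covariate_spec(name, "ordinal", levels = 1:5, probs = likert_probs(mean, 5))
  }
  lik4 <- function(name, mean) {
    covariate_spec(name, "ordinal", levels = 1:4, probs = likert_probs(mean, 4))
  }
  covs <- list(
    covariate_spec("age", "numeric", mean = 15.35, sd = 2.96, round = TRUE,
                   min = 13),
    covariate_spec("game_time", "numeric", mean = 23.01, sd = 10.26,
                   lognormal = TRUE),
    covariate_spec("gender", "nominal", levels = c("female", "male"),
                   probs = c(0.52, 0.48)),
    covariate_spec("art_grade", "ordinal", levels = 1:6,
                   probs = likert_probs(1.96, 6)),
    lik5("S1", 3.63), lik5("S2", 3.70), lik5("S3", 3.33), lik5("S4", 3.70),
    lik5("S5", 3.26),
    lik4("PM", 2.57), lik4("SO", 3.20), lik4("LM", 2.70), lik4("IM", 2.05),
    lik4("IP", 2.74)
  )
  fast <- list(covariate = "game_time", op = "<=", value = 20)
  slow <- list(covariate = "game_time", op = ">", value = 20)
  leaves <- list(
    leaf_spec(list(fast, list(covariate = "IP", op = "<=", value = 2)),
              worth = c(0.415, 0.241, 0.143, 0.120, 0.081)),
    leaf_spec(list(fast, list(covariate = "IP", op = ">", value = 2)),
              worth = c(0.318, 0.237, 0.184, 0.144, 0.117)),
    leaf_spec(list(slow, list(covariate = "IP", op = "<=", value = 1)),
              worth = c(0.280, 0.233, 0.230, 0.158, 0.099)),
    leaf_spec(list(slow, list(covariate = "IP", op = ">", value = 1)),
              worth = c(0.403, 0.223, 0.184, 0.116, 0.074))
  )
  sim_design(items, covs, leaves, n = n, seed = seed)
}

#' Covariate kinds of a design
#'
#' Named vector of kinds suitable for [grow_tree()] on the output of
#' [simulate_study()].
#'
#' @param design a [sim_design()].
#' @return Named character vector.
#' @export
design_kinds <- function(design) {
  stats::setNames(vapply(design$covariates, function(s) s$kind, character(1)),
                  vapply(design$covariates, function(s) s$name, character(1)))
}
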