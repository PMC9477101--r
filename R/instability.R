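# Parameter-instability (score-fluctuation) tests.
#
# Subjects are ordered by a candidate covariate; cumulative sums of their
# decorrelated model score contributions fluctuate like a Brownian bridge when
# the node model is stable. For numeric/ordinal covariates the statistic is
# supLM: the supremum over admissible split fractions t in [trim, 1-trim] of
# ||W(t)||^2 / (t (1 - t)). For nominal covariates the within-category score
# aggregates give a chi-square statistic with (C-1) * k degrees of freedom.
#
# p-values for supLM use the limiting distribution of the supremum of the
# squared normalized k-dimensional Brownian bridge, evaluated by Monte Carlo
# once per (k, trim) pair (fixed internal seed, cached), with an exponential
# tail extrapolation above the 98th percentile so that very small p-values
# vary smoothly.

#' Declare a subject covariate
#'
#' @param name covariate name.
#' @param values vector of values, one per subject (aligned with the rankings
#'   table row order, or named by subject id).
#' @param kind one of `"numeric"`, `"ordinal"`, `"nominal"`. Kinds are always
#'   declared, never inferred: Likert-type columns are ordinal.
#' @param levels for ordinal covariates, the level order (default: sorted
#'   unique values); for nominal, the category set.
#' @return An object of class `covariate`.
#' @export
covariate <- function(name, values, kind = c("numeric", "ordinal", "nominal"),
                      levels = NULL) {
  kind <- match.arg(kind)
  if (kind == "numeric") {
    values <- as.numeric(values)
    code <- values
    levels <- NULL
  } else {
    if (is.null(levels)) levels <- sort(unique(values[!is.na(values)]))
    code <- match(values, levels)
    if (any(is.na(code) & !is.na(values))) {
      stop("covariate '", name, "': value outside declared levels")
    }
  }
  structure(list(name = name, kind = kind, values = values, code = code,
                 levels = levels),
            class = "covariate")
}

subset_covariate <- function(cv, idx) {
  cv$values <- cv$values[idx]
  cv$code <- cv$code[idx]
  cv
}

# numeric representation of a covariate value for split rules / summaries
covariate_numeric_level <- function(cv, code) {
  if (cv$kind == "numeric") return(code)
  lv <- suppressWarnings(as.numeric(cv$levels))
  if (!anyNA(lv)) lv[code] else code
}

# ---- null distribution of the supLM functional ----------------------------

with_fixed_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

suplm_null_sample <- function(k, trim, R = 10000L, grid = 200L) {
  key <- sprintf("supLM_k%d_t%.3f", k, trim)
  hit <- .wt_cache[[key]]
  if (!is.null(hit)) return(hit)
  tt <- seq_len(grid) / grid
  keep <- tt >= trim & tt <= 1 - trim & tt < 1
  if (!any(keep)) keep <- which.min(abs(tt - 0.5))
  denom <- tt * (1 - tt)
  seed <- 77000L + 97L * k + as.integer(round(1000 * trim))
  sup <- with_fixed_seed(seed, {
    out <- numeric(R)
    for (r in seq_len(R)) {
      Z <- matrix(stats::rnorm(grid * k), grid, k)
      C <- apply(Z, 2L, cumsum) / sqrt(grid)
      B <- C - tt %o% C[grid, ]
      lm <- rowSums(B * B) / denom
      out[r] <- max(lm[keep])
    }
    sort(out)
  })
  assign(key, sup, envir = .wt_cache)
  sup
}

suplm_pvalue <- function(stat, k, trim) {
  # the reference distribution is tabulated on a 0.05 grid of trimming
  # fractions (the functional depends on trim only mildly); the statistic
  # itself always uses the exact trim
  trim <- max(0.05, min(0.45, round(trim / 0.05) * 0.05))
  null <- suplm_null_sample(k, trim)
  R <- length(null)
  u <- null[ceiling(0.98 * R)]
  if (stat <= u) return(mean(null >= stat))
  excess <- null[null > u] - u
  scale <- mean(excess)
  min(0.02 * exp(-(stat - u) / scale), 0.02)
}

# ---- the tests -------------------------------------------------------------

#' Test parameter instability of a node model along one covariate
#'
#' @param scores per-subject score matrix (rows = subjects, centered at the
#'   node maximum-likelihood estimate, e.g. from [loglik_and_scores()]).
#' @param cov a [covariate()] whose values align with the rows of `scores`.
#' @param minsize minimum admissible child size; also sets the trimming
#'   fraction `trim = max(0.1, minsize / n)`.
#' @param order_ties optional vector (e.g. subject ids) used to break ties in
#'   the covariate ordering deterministically.
#' @param weights optional non-negative case weights (e.g. bootstrap
#'   multiplicities). Partial sums use `w_i * s_i`, the information estimate
#'   uses `w_i^2 * s_i * s_i'`, and the Brownian time of the fluctuation
#'   process is the cumulative share of squared weights, so duplicated
#'   subjects do not inflate the statistic.
#' @return An object of class `instability_result` with fields `covariate`,
#'   `statistic`, `p_value`, `p_adjusted` (initialized to `p_value`; filled
#'   in by the tree via Bonferroni), `test` (`"supLM"` or `"chisq"`), `flag`.
#' @export
instability_test <- function(scores, cov, minsize, order_ties = NULL,
                             weights = NULL) {
  S <- as.matrix(scores)
  n <- nrow(S)
  w <- weights %||% rep(1, n)
  if (length(w) != n || any(w < 0)) stop("'weights' must be non-negative, one per row")
  W_tot <- sum(w)
  if (W_tot < 2 * minsize) stop("need at least 2 * minsize subjects")
  if (length(cov$code) != n) stop("covariate length does not match score rows")
  res <- function(stat, p, test, flag = NA_character_) {
    structure(list(covariate = cov$name, statistic = stat, p_value = p,
                   p_adjusted = p, test = test, flag = flag),
              class = "instability_result")
  }
  vals <- cov$code
  if (length(unique(vals[w > 0])) < 2L) {
    return(res(0, 1, if (cov$kind == "nominal") "chisq" else "supLM",
               "no variation"))
  }
  # decorrelate by the outer-product-of-gradients information estimate
  Sw <- S * w
  A <- crossprod(Sw)
  eg <- eigen(A, symmetric = TRUE)
  tol <- max(eg$values) * 1e-8
  pos <- eg$values > tol
  k_eff <- sum(pos)
  Ahalf_inv <- eg$vectors[, pos, drop = FALSE] %*%
    diag(1 / sqrt(eg$values[pos]), k_eff)
  P <- Sw %*% Ahalf_inv # partial sums of P are the normalized process
  w2_share <- w^2 / sum(w^2)

  if (cov$kind == "nominal") {
    cats <- unique(vals[!is.na(vals)])
    if (length(cats) < 2L) return(res(0, 1, "chisq", "no variation"))
    stat <- 0
    for (cc in cats) {
      rows <- vals == cc
      g <- colSums(P[rows, , drop = FALSE])
      stat <- stat + sum(g^2) / sum(w2_share[rows])
    }
    df <- (length(cats) - 1L) * k_eff
    return(res(stat, stats::pchisq(stat, df, lower.tail = FALSE), "chisq"))
  }

  trim <- max(0.1, minsize / W_tot)
  ord <- if (is.null(order_ties)) order(vals) else order(vals, order_ties)
  v <- vals[ord]
  CS <- apply(P[ord, , drop = FALSE], 2L, cumsum)
  tau <- cumsum(w2_share[ord])
  cw <- cumsum(w[ord])
  i <- seq_len(n - 1L)
  admissible <- cw[i] >= minsize & (W_tot - cw[i]) >= minsize &
    tau[i] >= trim & tau[i] <= 1 - trim & v[i] < v[i + 1L]
  if (!any(admissible)) return(res(0, 1, "supLM", "no admissible split"))
  lm <- rowSums(CS[i, , drop = FALSE]^2) / (tau[i] * (1 - tau[i]))
  stat <- max(lm[admissible])
  res(stat, suplm_pvalue(stat, k_eff, trim), "supLM")
}

#' @export
print.instability_result <- function(x, ...) {
  cat(sprintf("instability of '%s': %s = %.3f, p = %.4g (adjusted %.4g)%s\n",
              x$covariate, x$test, x$statistic, x$p_value, x$p_adjusted,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Select the splitting covariate
#'
#' Returns the name of the covariate with the smallest Bonferroni-adjusted
#' p-value if it is below `alpha`, otherwise `NULL`. Ties are broken by
#' declaration order (the order of `results`).
#'
#' @param results list of `instability_result`s (with `p_adjusted` filled in).
#' @param alpha significance level.
#' @return Covariate name or `NULL`.
#' @export
select_split_variable <- function(results, alpha = 0.05) {
  if (!length(results)) stop("'results' must be non-empty")
  padj <- vapply(results, function(r) r$p_adjusted, numeric(1))
  best <- which.min(padj) # which.min takes the first on ties
  if (padj[best] < alpha) results[[best]]$covariate else NULL
}

# apply Bonferroni across candidate covariates within a node
adjust_instability <- function(results) {
  m <- length(results)
  lapply(results, function(r) {
    r$p_adjusted <- min(1, r$p_value * m)
    r
  })
}
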