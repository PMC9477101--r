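# Loglinear Bradley-Terry pattern model.
#
# The probability of preferring item j over item k is pi_j / (pi_j + pi_k),
# with worth parameters pi on the simplex. On the pattern level the model is
# an exponential family over the J! transitive patterns:
#   p(y) = exp(sum_j lambda_j x_j(y)) / Z(lambda),
# where x(y) are the per-item aggregated scores and pi_j propto exp(2 lambda_j).
# The fit maximizes the J!-cell multinomial likelihood by damped Newton on the
# J-1 free coordinates (sum-to-zero constraint on lambda); the Poisson
# loglinear formulation with a log link is equivalent and is used as an
# independent oracle in the test suite.

#' Transform item parameters to worth parameters
#'
#' `pi_j = exp(2 lambda_j) / sum_k exp(2 lambda_k)`. Invariant under adding a
#' constant to all `lambda`; guarded against overflow by max-subtraction.
#'
#' @param lambda numeric vector of item parameters.
#' @return Worth vector on the open simplex (sums to 1).
#' @export
worth_from_lambda <- function(lambda) {
  nms <- names(lambda)
  lambda <- as.numeric(lambda)
  if (anyNA(lambda) || any(!is.finite(lambda))) stop("'lambda' must be finite")
  w <- exp(2 * (lambda - max(lambda)))
  p <- w / sum(w)
  names(p) <- nms
  p
}

#' Transform worth parameters back to item parameters
#'
#' Inverse of [worth_from_lambda()]: `lambda_j = log(pi_j) / 2`, recentred so
#' that `sum(lambda) = 0`.
#'
#' @param pi worth vector on the open simplex.
#' @return Item parameter vector with `sum(lambda) = 0`.
#' @export
lambda_from_worth <- function(pi) {
  pi <- as.numeric(pi)
  if (anyNA(pi) || any(pi <= 0)) stop("worth parameters must be strictly positive")
  if (abs(sum(pi) - 1) > 1e-8) stop("worth parameters must sum to 1")
  l <- log(pi) / 2
  l - mean(l)
}

#' Pairwise preference probability
#'
#' Probability that item `j` is preferred to item `k`:
#' `pi_j / (pi_j + pi_k)`.
#'
#' @param pi worth vector (optionally named by item label).
#' @param j,k item labels (if `pi` is named) or indices; must differ.
#' @return A probability.
#' @export
preference_prob <- function(pi, j, k) {
  resolve <- function(a) {
    if (is.character(a)) {
      i <- match(a, names(pi))
      if (is.na(i)) stop("unknown item '", a, "'")
      i
    } else as.integer(a)
  }
  ji <- resolve(j); ki <- resolve(k)
  if (ji == ki) stop("'j' and 'k' must be different items")
  pi[[ji]] / (pi[[ji]] + pi[[ki]])
}

#' Probability distribution over all transitive patterns
#'
#' @param lambda item parameter vector (length `J`, 2 <= J <= 7).
#' @return Numeric vector of length `J!` (enumeration order of
#'   [enumerate_patterns()]) summing to 1.
#' @export
pattern_distribution <- function(lambda) {
  J <- length(lambda)
  sp <- pattern_space(J)
  eta <- drop(sp$X %*% lambda)
  w <- exp(eta - max(eta))
  w / sum(w)
}

#' Probability of a single paired-comparison pattern
#'
#' `p(y) = exp(sum_j lambda_j x_j(y)) / Z(lambda)`, normalized over the `J!`
#' transitive patterns. The expected pattern frequency in a sample of `n`
#' subjects is `n * p(y)`.
#'
#' @param lambda item parameter vector.
#' @param pattern a +1/-1 vector over the canonical pairs.
#' @return A probability.
#' @export
pattern_probability <- function(lambda, pattern) {
  J <- length(lambda)
  x <- item_scores(as.integer(pattern))
  if (length(x) != J) stop("pattern does not match the number of items")
  sp <- pattern_space(J)
  eta <- drop(sp$X %*% lambda)
  M <- max(eta)
  exp(sum(lambda * x) - M - log(sum(exp(eta - M))))
}

# free-coordinate sufficient statistics: u = x_{1..J-1} - x_J
free_stats <- function(X) {
  J <- ncol(X)
  X[, -J, drop = FALSE] - X[, J]
}

# damped Newton maximizer of the multinomial pattern loglikelihood
# (optionally ridge-penalized on lambda, used after separation is detected)
llbt_newton <- function(counts, sp, penalty = 0, theta0 = NULL,
                        tol = 1e-10, maxit = 200L) {
  J <- sp$J
  U <- free_stats(sp$X)
  n <- sum(counts)
  ubar <- colSums(counts * U) / n
  theta <- theta0 %||% numeric(J - 1L)
  Pen <- diag(J - 1L) + 1 # ||lambda||^2 = theta' (I + 11') theta
  obj <- function(th) {
    eta <- drop(U %*% th)
    M <- max(eta)
    n * sum(th * ubar) - n * (M + log(sum(exp(eta - M)))) -
      penalty * drop(crossprod(th, Pen %*% th))
  }
  converged <- FALSE
  separated <- FALSE
  f <- obj(theta)
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    eta <- drop(U %*% theta)
    eta <- eta - max(eta)
    w <- exp(eta)
    p <- w / sum(w)
    Eu <- colSums(p * U)
    g <- n * (ubar - Eu) - 2 * penalty * drop(Pen %*% theta)
    H <- n * (crossprod(U, p * U) - tcrossprod(Eu)) + 2 * penalty * Pen
    if (max(abs(g)) / max(1, n) < tol) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) { # singular information: degenerate counts
      separated <- TRUE
      break
    }
    alpha <- 1
    repeat {
      thn <- theta + alpha * step
      fn <- obj(thn)
      if (is.finite(fn) && fn >= f) break
      alpha <- alpha / 2
      if (alpha < 1e-10) { thn <- theta; fn <- f; break }
    }
    theta <- thn
    f <- fn
    lam <- c(theta, -sum(theta))
    if (penalty == 0 && max(abs(lam)) > 15) {
      separated <- TRUE
      break
    }
  }
  lambda <- c(theta, -sum(theta))
  eta <- drop(sp$X %*% lambda)
  M <- max(eta)
  logZ <- M + log(sum(exp(eta - M)))
  p <- exp(eta - logZ)
  pos <- counts > 0
  loglik <- sum(counts[pos] * log(p[pos]))
  Eu <- colSums(p * free_stats(sp$X))
  H <- n * (crossprod(free_stats(sp$X), p * free_stats(sp$X)) - tcrossprod(Eu)) +
    2 * penalty * Pen
  cov_theta <- tryCatch(solve(H), error = function(e) matrix(NA_real_, J - 1L, J - 1L))
  list(theta = theta, lambda = lambda, p = p, logZ = logZ, loglik = loglik,
       cov_theta = cov_theta, converged = converged, separated = separated,
       iterations = it)
}

# cov of full lambda from cov of free coordinates (lambda = A theta)
cov_lambda_full <- function(cov_theta) {
  k <- nrow(cov_theta)
  A <- rbind(diag(k), rep(-1, k))
  A %*% cov_theta %*% t(A)
}

#' Fit the loglinear Bradley-Terry pattern model
#'
#' Maximum-likelihood estimation of the item parameters from a pattern count
#' table, by damped Newton iteration on the concave `J!`-cell multinomial
#' loglikelihood (sum-to-zero identifiability constraint). Degenerate tables
#' in which some item is always first or last push `lambda` to infinity
#' (separation); this is detected when any `|lambda|` exceeds 15 during
#' iteration, a warning is raised, and a ridge-penalized fit
#' (penalty `1e-4 * ||lambda||^2`) is returned with `separated = TRUE`.
#'
#' @param table a [pattern_table()] (or a rankings data.frame together with
#'   `items`).
#' @param items required when `table` is a rankings data.frame.
#' @param tol convergence tolerance on the per-subject gradient max-norm (default 1e-10).
#' @param maxit maximum Newton iterations.
#' @return An object of class `llbt_fit` with elements `lambda`, `pi`,
#'   `cov_lambda`, `loglik`, `aic`, `npar`, `n`, `converged`, `separated`,
#'   `normalization` (log of the pattern-space normalizing constant).
#' @export
fit_llbt <- function(table, items = NULL, tol = 1e-10, maxit = 200L) {
  if (is.data.frame(table)) {
    if (is.null(items)) stop("'items' is required when fitting from a rankings table")
    table <- tabulate_patterns(table, items)
  }
  if (!inherits(table, "pattern_table")) stop("'table' must be a pattern_table")
  if (table$n < 1) stop("pattern table is empty: total count must be >= 1")
  items <- table$items
  J <- n_items(items)
  sp <- pattern_space(J)
  res <- llbt_newton(table$counts, sp, penalty = 0, tol = tol, maxit = maxit)
  penalty <- 0
  if (res$separated) {
    warning("separation detected (some item is always preferred or always ",
            "dominated); returning a ridge-penalized fit (penalty 1e-4 * ||lambda||^2)")
    penalty <- 1e-4
    res <- llbt_newton(table$counts, sp, penalty = penalty, tol = tol,
                       maxit = maxit)
    res$separated <- TRUE
  }
  lambda <- res$lambda
  names(lambda) <- items$labels
  pi <- worth_from_lambda(lambda)
  npar <- J - 1L
  structure(list(items = items, lambda = lambda, pi = pi,
                 cov_theta = res$cov_theta,
                 cov_lambda = cov_lambda_full(res$cov_theta),
                 loglik = res$loglik, n = table$n, npar = npar,
                 aic = -2 * res$loglik + 2 * npar,
                 converged = res$converged, separated = res$separated,
                 penalty = penalty, normalization = res$logZ,
                 iterations = res$iterations,
                 group_terms = NULL, group_pi = NULL, group_fits = NULL,
                 reference_group = NULL),
            class = "llbt_fit")
}

#' @export
print.llbt_fit <- function(x, ...) {
  cat("Loglinear Bradley-Terry pattern model fit\n")
  cat("  n =", x$n, " items:", paste(x$items$labels, collapse = ", "), "\n")
  cat("  logLik =", format(x$loglik, digits = 7),
      " AIC =", format(x$aic, digits = 7),
      " parameters =", x$npar, "\n")
  if (x$separated) cat("  NOTE: separation detected; ridge-penalized fit\n")
  if (!x$converged) cat("  WARNING: did not converge\n")
  if (is.null(x$group_pi)) {
    tab <- rbind(lambda = x$lambda, worth = x$pi)
    print(round(tab, 4))
  } else {
    cat("  focal groups (reference:", x$reference_group, ")\n")
    print(round(x$group_pi, 4))
  }
  invisible(x)
}

#' Fit the pattern model with a focal grouping variable
#'
#' Extension in which every subgroup keeps its own item parameters: the
#' reference group carries `lambda_j`, each other group adds an interaction
#' offset `lambda_js` (fixed at 0 in the reference group). Because the
#' interaction is saturated, the joint maximum-likelihood fit factorizes into
#' independent per-group fits; the total loglikelihood is their sum.
#'
#' @param tables_by_group named list of [pattern_table()]s, one per group.
#' @param reference label of the reference group (default: first listed).
#' @return An `llbt_fit` whose `lambda`/`pi` are the reference group's, with
#'   `group_terms` (interaction offsets), `group_pi` (worth per group) and
#'   `group_fits` populated. `npar = G * (J - 1)`.
#' @export
fit_llbt_grouped <- function(tables_by_group, reference = NULL) {
  if (!is.list(tables_by_group) || length(tables_by_group) < 2L ||
      is.null(names(tables_by_group)) || any(!nzchar(names(tables_by_group)))) {
    stop("'tables_by_group' must be a named list of at least two pattern tables")
  }
  glabs <- names(tables_by_group)
  reference <- reference %||% glabs[1L]
  if (!reference %in% glabs) stop("reference group '", reference, "' not found")
  for (g in glabs) {
    tb <- tables_by_group[[g]]
    if (!inherits(tb, "pattern_table")) stop("group '", g, "' is not a pattern_table")
    if (tb$n < 1) stop("group '", g, "' is empty")
  }
  items <- tables_by_group[[1L]]$items
  J <- n_items(items)
  fits <- lapply(tables_by_group, fit_llbt)
  ref_fit <- fits[[reference]]
  lambda <- ref_fit$lambda
  group_terms <- lapply(fits, function(f) f$lambda - lambda)
  group_pi <- vapply(fits, function(f) f$pi, numeric(J))
  rownames(group_pi) <- items$labels
  loglik <- sum(vapply(fits, function(f) f$loglik, numeric(1)))
  n <- sum(vapply(fits, function(f) f$n, numeric(1)))
  npar <- length(fits) * (J - 1L)
  structure(list(items = items, lambda = lambda, pi = ref_fit$pi,
                 cov_theta = ref_fit$cov_theta,
                 cov_lambda = ref_fit$cov_lambda,
                 loglik = loglik, n = n, npar = npar,
                 aic = -2 * loglik + 2 * npar,
                 converged = all(vapply(fits, function(f) f$converged, logical(1))),
                 separated = any(vapply(fits, function(f) f$separated, logical(1))),
                 penalty = max(vapply(fits, function(f) f$penalty, numeric(1))),
                 normalization = ref_fit$normalization,
                 iterations = NA_integer_,
                 group_terms = group_terms, group_pi = group_pi,
                 group_fits = fits, reference_group = reference),
            class = "llbt_fit")
}

# per-subject score contributions (full J columns, rank J-1):
# x(y_i) - E_lambda[x]
llbt_score_rows <- function(lambda, pidx) {
  J <- length(lambda)
  sp <- pattern_space(J)
  p <- pattern_distribution(lambda)
  Ex <- colSums(p * sp$X)
  sweep(sp$X[pidx, , drop = FALSE], 2L, Ex)
}

#' Loglikelihood and per-subject score contributions
#'
#' Expands a pattern table into one row per subject (patterns in enumeration
#' order) and returns each subject's score contribution
#' `x(y) - E_lambda[x]`, the gradient ingredient used by the parameter
#' instability tests. At the maximum-likelihood estimate the column sums of
#' the score matrix are zero.
#'
#' @param fit an `llbt_fit` (ungrouped).
#' @param table a [pattern_table()] over the same items.
#' @return List with `loglik` (total, matching `fit$loglik` when `table` is
#'   the fitted table) and `scores` (an `n x J` matrix).
#' @export
loglik_and_scores <- function(fit, table) {
  if (!inherits(fit, "llbt_fit")) stop("'fit' must be an llbt_fit")
  if (!is.null(fit$group_pi)) {
    stop("per-subject scores for grouped fits require group membership; ",
         "supply tables per group")
  }
  if (!inherits(table, "pattern_table")) stop("'table' must be a pattern_table")
  J <- n_items(fit$items)
  if (length(table$counts) != factorial(J)) stop("dimension mismatch between fit and table")
  counts <- table$counts
  if (any(counts != round(counts))) stop("per-subject expansion needs integer counts")
  pidx <- rep(seq_along(counts), times = counts)
  S <- llbt_score_rows(fit$lambda, pidx)
  colnames(S) <- fit$items$labels
  p <- pattern_distribution(fit$lambda)
  pos <- counts > 0
  list(loglik = sum(counts[pos] * log(p[pos])), scores = S)
}

#' Confidence intervals for worth parameters
#'
#' Delta-method intervals computed on the logit scale of each worth parameter
#' and mapped back, so bounds always lie in (0, 1) and contain the point
#' estimate.
#'
#' @param fit an `llbt_fit` (converged).
#' @param level confidence level (default 0.95).
#' @return A data.frame with columns `item`, `worth`, `lower`, `upper` (plus
#'   `group` for grouped fits).
#' @export
worth_ci <- function(fit, level = 0.95) {
  if (!inherits(fit, "llbt_fit")) stop("'fit' must be an llbt_fit")
  if (!fit$converged) stop("fit did not converge; confidence intervals unavailable")
  if (!is.null(fit$group_fits)) {
    out <- lapply(names(fit$group_fits), function(g) {
      ci <- worth_ci(fit$group_fits[[g]], level)
      cbind(group = g, ci)
    })
    return(do.call(rbind, out))
  }
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)")
  pi <- fit$pi
  J <- length(pi)
  z <- stats::qnorm(1 - (1 - level) / 2)
  lower <- upper <- numeric(J)
  for (j in seq_len(J)) {
    # d logit(pi_j) / d lambda = 2 (e_j - pi) / (1 - pi_j)
    h <- 2 * ((seq_len(J) == j) - pi) / (1 - pi[j])
    v <- drop(t(h) %*% fit$cov_lambda %*% h)
    se <- sqrt(pmax(v, 0))
    lower[j] <- stats::plogis(stats::qlogis(pi[j]) - z * se)
    upper[j] <- stats::plogis(stats::qlogis(pi[j]) + z * se)
  }
  data.frame(item = fit$items$labels, worth = unname(pi),
             lower = lower, upper = upper, stringsAsFactors = FALSE)
}
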