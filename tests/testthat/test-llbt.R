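# Loglinear Bradley-Terry pattern model: transforms, probabilities, fitting.

test_that("worth transform and its inverse behave as documented", {
  expect_equal(worth_from_lambda(rep(0, 5)), rep(0.2, 5))
  expect_equal(worth_from_lambda(c(log(2) / 2, 0)), c(2 / 3, 1 / 3))
  l <- c(0.4, -0.1, 0.3, -0.6)
  expect_equal(worth_from_lambda(l), worth_from_lambda(l + 3.7))
  expect_error(worth_from_lambda(c(0, Inf)), "finite")

  expect_equal(lambda_from_worth(rep(0.2, 5)), rep(0, 5))
  # published subgroup worths round-trip through the transform
  pi <- c(0.415, 0.241, 0.143, 0.120, 0.081)
  expect_equal(worth_from_lambda(lambda_from_worth(pi)), pi, tolerance = 1e-12)
  expect_error(lambda_from_worth(c(0.5, 0.4)), "sum to 1")
  expect_error(lambda_from_worth(c(1.2, -0.2)), "positive")
})

test_that("preference probabilities follow pi_j / (pi_j + pi_k)", {
  expect_equal(preference_prob(c(0.5, 0.5), 1, 2), 0.5)
  expect_equal(preference_prob(c(2 / 3, 1 / 3), 1, 2), 2 / 3)
  pi <- c(a = 0.415, b = 0.241, c = 0.143, d = 0.120, e = 0.081)
  expect_equal(preference_prob(pi, "a", "e"), 0.415 / (0.415 + 0.081),
               tolerance = 1e-12)
  expect_equal(preference_prob(pi, "a", "e") + preference_prob(pi, "e", "a"), 1)
  expect_error(preference_prob(pi, "a", "a"), "different")
})

test_that("pattern probabilities match hand enumeration and normalize", {
  l0 <- rep(0, 5)
  p <- pattern_distribution(l0)
  expect_equal(p, rep(1 / 120, 120))
  lambda <- c(0.5, 0, -0.5)
  p3 <- pattern_distribution(lambda)
  expect_equal(sum(p3), 1, tolerance = 1e-12)
  expect_equal(p3, hand_pattern_probs_3(lambda), tolerance = 1e-12)
  Y <- enumerate_patterns(3)
  for (r in seq_len(6)) {
    expect_equal(pattern_probability(lambda, unclass(Y)[r, ]), p3[r],
                 tolerance = 1e-12)
  }
})

test_that("marginal pairwise preference from patterns is monotone in lambda", {
  # summing pattern probabilities over patterns with y_jk = +1 must order
  # pairs consistently with lambda_j - lambda_k (J = 3, exhaustive)
  lambda <- c(0.8, 0.1, -0.9)
  Y <- unclass(enumerate_patterns(3))
  p <- pattern_distribution(lambda)
  marg <- vapply(1:3, function(q) sum(p[Y[, q] == 1]), numeric(1))
  gaps <- c(lambda[1] - lambda[2], lambda[1] - lambda[3], lambda[2] - lambda[3])
  expect_equal(order(marg), order(gaps))
  expect_true(all(marg > 0.5)) # all gaps positive here
})

test_that("the fit matches the Poisson loglinear oracle on random tables", {
  set.seed(202)
  for (rep in 1:6) {
    J <- sample(3:5, 1)
    counts <- as.numeric(stats::rmultinom(1, 250,
                                          prob = rexp(factorial(J)) + 0.05))
    it <- item_set(letters[seq_len(J)])
    tb <- pattern_table(counts, it)
    fit <- fit_llbt(tb)
    # independent IRLS route: Poisson GLM with log link on the J!-cell table
    sp <- worthtree:::pattern_space(J)
    U <- sp$X[, -J, drop = FALSE] - sp$X[, J]
    gfit <- stats::glm(counts ~ U, family = stats::poisson(),
                       control = stats::glm.control(epsilon = 1e-13))
    th <- stats::coef(gfit)[-1]
    lam <- unname(c(th, -sum(th)))
    expect_equal(unname(fit$lambda), lam, tolerance = 1e-7)
    expect_equal(fit$pi, worth_from_lambda(fit$lambda), tolerance = 1e-12)
    expect_equal(sum(fit$pi), 1, tolerance = 1e-10)
    expect_equal(fit$aic, -2 * fit$loglik + 2 * (J - 1))
  }
})

test_that("the fit is self-consistent at exact expected counts", {
  lam_star <- c(0.4, 0.2, 0, -0.2, -0.4)
  counts <- 500 * pattern_distribution(lam_star)
  fit <- fit_llbt(pattern_table(counts, items5))
  expect_equal(unname(fit$lambda), lam_star, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("uniform counts give uniform worths", {
  fit <- fit_llbt(pattern_table(rep(2, 120), items5))
  expect_equal(unname(fit$pi), rep(0.2, 5), tolerance = 1e-8)
})

test_that("separation is flagged and handled by a penalized fit", {
  rk <- make_rankings(matrix(rep(letters[1:5], each = 40), 40))
  expect_warning(fit <- fit_llbt(tabulate_patterns(rk, items5)), "separation")
  expect_true(fit$separated)
  expect_equal(fit$penalty, 1e-4)
  expect_true(all(fit$pi > 0))
  expect_equal(sum(fit$pi), 1, tolerance = 1e-10)
  expect_true(fit$pi[1] > 0.999) # near-degenerate, like always-first items
})

test_that("worth intervals are valid, symmetric under symmetry, and shrink", {
  fit_u <- fit_llbt(pattern_table(rep(5, 120), items5))
  ci <- worth_ci(fit_u, 0.95)
  expect_true(all(ci$lower > 0 & ci$upper < 1))
  expect_true(all(ci$lower < ci$worth & ci$worth < ci$upper))
  expect_equal(diff(range(ci$upper - ci$lower)), 0, tolerance = 1e-10)

  ci50 <- worth_ci(fit_u, 0.5)
  expect_true(all(ci50$lower > ci$lower & ci50$upper < ci$upper))

  # width shrinks like n^(-1/2) at fixed lambda*
  lam_star <- lambda_from_worth(c(0.4, 0.25, 0.15, 0.12, 0.08))
  p_star <- pattern_distribution(lam_star)
  widths <- vapply(c(500, 2000, 8000), function(n) {
    f <- fit_llbt(pattern_table(n * p_star, items5))
    ci <- worth_ci(f)
    ci$upper[1] - ci$lower[1]
  }, numeric(1))
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.1)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.1)
  expect_error(worth_ci(structure(list(converged = FALSE), class = "llbt_fit")),
               "converge")
})

test_that("grouped fits keep the reference at zero offset and add logliks", {
  set.seed(9)
  tb1 <- tabulate_patterns(sample_ranking(c(0.4, 0.25, 0.15, 0.12, 0.08), 400),
                           items5)
  tb2 <- tabulate_patterns(sample_ranking(c(0.08, 0.12, 0.15, 0.25, 0.4), 400),
                           items5)
  fg <- fit_llbt_grouped(list(novice = tb1, expert = tb2))
  expect_equal(fg$reference_group, "novice")
  expect_equal(unname(fg$group_terms$novice), rep(0, 5))
  expect_equal(fg$loglik, fit_llbt(tb1)$loglik + fit_llbt(tb2)$loglik,
               tolerance = 1e-9)
  expect_equal(fg$npar, 8)
  expect_equal(fg$aic, -2 * fg$loglik + 2 * 8)
  expect_equal(colnames(fg$group_pi), c("novice", "expert"))
  expect_equal(unname(colSums(fg$group_pi)), c(1, 1), tolerance = 1e-10)

  # identical tables => zero interaction offsets
  fg0 <- fit_llbt_grouped(list(g1 = tb1, g2 = tb1))
  expect_equal(unname(fg0$group_terms$g2), rep(0, 5), tolerance = 1e-6)

  # distinct truths recovered per group
  expect_lt(max(abs(fg$group_pi[, "novice"] - c(0.4, 0.25, 0.15, 0.12, 0.08))),
            0.05)
  expect_lt(max(abs(fg$group_pi[, "expert"] - c(0.08, 0.12, 0.15, 0.25, 0.4))),
            0.05)
  expect_error(fit_llbt_grouped(list(a = tb1)), "at least two")
  expect_error(
    fit_llbt_grouped(list(a = tb1, b = pattern_table(rep(0, 120), items5))),
    "empty")
})

test_that("per-subject scores sum to zero at the MLE and match the design", {
  set.seed(31)
  tb <- tabulate_patterns(sample_ranking(c(0.35, 0.3, 0.2, 0.1, 0.05), 500),
                          items5)
  fit <- fit_llbt(tb)
  ls <- loglik_and_scores(fit, tb)
  expect_equal(ls$loglik, fit$loglik, tolerance = 1e-9)
  expect_lt(max(abs(colSums(ls$scores))), 1e-6)
  expect_equal(nrow(ls$scores), 500)

  # at lambda = 0 the expected scores vanish, so the identity-ranking subject
  # scores exactly its design row
  fit0 <- fit_llbt(pattern_table(rep(1, 120), items5))
  tb1 <- tabulate_patterns(make_rankings(list(letters[1:5])), items5)
  s <- loglik_and_scores(fit0, tb1)$scores
  expect_equal(unname(s[1, ]), c(4, 2, 0, -2, -4), tolerance = 1e-7)
})

test_that("parameter recovery from sampled rankings is accurate at n = 2000", {
  set.seed(88)
  pi_star <- c(0.4, 0.25, 0.15, 0.12, 0.08)
  hits <- replicate(20, {
    rk <- sample_ranking(pi_star, 2000)
    f <- fit_llbt(tabulate_patterns(rk, items5))
    max(abs(f$pi - pi_star)) < 0.03
  })
  expect_gte(mean(hits), 0.95)
})

test_that("fit records survive a JSON round trip", {
  set.seed(14)
  tb <- tabulate_patterns(sample_ranking(c(0.4, 0.25, 0.15, 0.12, 0.08), 300),
                          items5)
  fit <- fit_llbt(tb)
  path <- tempfile(fileext = ".json")
  fit_to_json(fit, path)
  back <- fit_from_json(path)
  expect_equal(back$lambda, fit$lambda, tolerance = 1e-12)
  expect_equal(back$pi, fit$pi, tolerance = 1e-12)
  expect_equal(back$loglik, fit$loglik, tolerance = 1e-12)
  expect_equal(back$aic, fit$aic, tolerance = 1e-12)
  expect_equal(back$n, fit$n)
  expect_equal(back$cov_lambda, unname(fit$cov_lambda), tolerance = 1e-12)
})
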