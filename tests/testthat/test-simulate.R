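# Synthetic-data generator: covariate marginals, the exact ranking law,
# leaf routing, and the bundled study-emulation design.

test_that("covariate samples follow their declared marginals", {
  # law of large numbers on an untruncated age spec
  plain_age <- covariate_spec("age", "numeric", mean = 15.35, sd = 2.96)
  d0 <- sim_design(items5, list(plain_age),
                   list(leaf_spec(list(), rep(0.2, 5))), n = 10000, seed = 60)
  expect_lt(abs(mean(sample_covariates(d0)$age) - 15.35), 0.1)

  des <- study_design(n = 10000, seed = 61)
  cv <- sample_covariates(des)
  expect_equal(nrow(cv), 10000)
  # the bundled design rounds then truncates at 13 (continuous-scale cut at
  # 12.5), which lifts the mean to the truncated-normal expectation
  a <- (12.5 - 15.35) / 2.96
  e_trunc <- 15.35 + 2.96 * stats::dnorm(a) / (1 - stats::pnorm(a))
  expect_lt(abs(mean(cv$age) - e_trunc), 0.1)
  expect_true(all(cv$age >= 13))
  expect_lt(abs(mean(cv$game_time) - 23.01), 0.5)
  expect_lt(abs(mean(cv$gender == "female") - 0.52), 0.02)
  for (v in c("S1", "S2", "S3", "S4", "S5")) {
    expect_true(all(cv[[v]] %in% 1:5))
  }
  # a uniform 4-level ordinal spec hits each level at 0.25 +/- 0.02
  sp <- covariate_spec("u", "ordinal", levels = 1:4, probs = rep(0.25, 4))
  d2 <- sim_design(items5, list(sp), list(leaf_spec(list(), rep(0.2, 5))),
                   n = 10000, seed = 3)
  u <- sample_covariates(d2)$u
  expect_true(all(abs(table(u) / 10000 - 0.25) < 0.02))
  # reproducibility
  expect_identical(sample_covariates(des, seed = 61), cv)
})

test_that("likert_probs reproduces the target mean", {
  for (m in c(2.05, 2.74, 3.63)) {
    p <- likert_probs(m, if (m > 3) 5 else 4)
    K <- length(p)
    expect_equal(sum(p * seq_len(K)), m, tolerance = 1e-12)
  }
  expect_error(likert_probs(5, 5), "inside")
})

test_that("rankings are drawn from the exact pattern law", {
  set.seed(71)
  # J = 3, exhaustive cells: total-variation distance and chi-square GOF
  w3 <- c(0.5, 0.3, 0.2)
  rk <- sample_ranking(w3, 50000, items3)
  counts <- tabulate_patterns(rk, items3)$counts
  p <- pattern_distribution(lambda_from_worth(w3))
  tv <- 0.5 * sum(abs(counts / 50000 - p))
  expect_lt(tv, 0.02)
  expect_gt(stats::chisq.test(counts, p = p)$p.value, 0.01)

  # a dominant item heads the modal ranking
  w <- c(0.9, 0.05, 0.03, 0.01, 0.01)
  rk5 <- sample_ranking(w / sum(w), 2000, items5)
  expect_gt(mean(rk5$pos1 == "a"), 0.8)

  # J = 2 reduces to the pairwise preference probability
  rk2 <- sample_ranking(c(2 / 3, 1 / 3), 20000, item_set(c("a", "b")))
  expect_equal(mean(rk2$pos1 == "a"), 2 / 3, tolerance = 0.015)

  # never ties or incomplete rankings
  expect_true(all(apply(as.matrix(rk5[paste0("pos", 1:5)]), 1,
                        function(r) length(unique(r)) == 5)))
})

test_that("a one-leaf design round-trips through the estimator", {
  d <- homogeneous_design(2000, worth = c(0.415, 0.241, 0.143, 0.120, 0.081))
  sim <- simulate_study(d, seed = 81)
  f <- fit_llbt(tabulate_patterns(sim$rankings, items5))
  expect_lt(max(abs(f$pi - d$leaves[[1]]$worth)), 0.03)
})

test_that("leaf routing is validated and exhaustive", {
  # overlapping leaves are rejected before any ranking is drawn
  bad <- sim_design(items5,
                    list(covariate_spec("age", "numeric", mean = 15, sd = 3)),
                    list(leaf_spec(list(list(covariate = "age", op = "<=",
                                             value = 20)), rep(0.2, 5)),
                         leaf_spec(list(), rep(0.2, 5))),
                    n = 50, seed = 4)
  expect_error(simulate_study(bad), "mutually exclusive and exhaustive")
  # gaps are rejected too
  gap <- sim_design(items5,
                    list(covariate_spec("age", "numeric", mean = 15, sd = 3)),
                    list(leaf_spec(list(list(covariate = "age", op = "<=",
                                             value = 10)), rep(0.2, 5))),
                    n = 50, seed = 4)
  expect_error(simulate_study(gap), "matches 0 leaves")
  expect_error(leaf_spec(list(), c(0.5, 0.6)), "sum to 1")
  expect_error(
    sim_design(items5, list(), list(leaf_spec(list(list(covariate = "zz",
                                                        op = "<=", value = 1)),
                                              rep(0.2, 5))), n = 10),
    "undeclared covariate")
})

test_that("subjects within a leaf route correctly and share the leaf law", {
  des <- planted_design(400)
  sim <- simulate_study(des, seed = 91)
  expect_identical(sim$leaf, ifelse(sim$covariates$age <= 15, 1L, 2L))
  expect_equal(sim$rankings$subject_id, sim$covariates$subject_id)
  # same seed gives an identical study
  sim2 <- simulate_study(des, seed = 91)
  expect_identical(sim, sim2)
})

test_that("the bundled study design matches its documented shape", {
  des <- study_design(n = 987)
  expect_equal(des$n, 987L)
  expect_equal(n_items(des$items), 5)
  expect_equal(length(des$leaves), 4)
  kinds <- design_kinds(des)
  expect_equal(unname(kinds[c("age", "gender", "IP")]),
               c("numeric", "nominal", "ordinal"))
  sim <- simulate_study(des, seed = 101)
  expect_equal(nrow(sim$rankings), 987)
  # the per-subject expanded model design has n * J! rows
  expect_equal(nrow(expanded_design(des$items, nrow(sim$rankings))), 118440)
  # leaf shares roughly match the time/IP marginals they are built from
  expect_gt(min(table(sim$leaf)), 20)
})

test_that("designs survive a YAML round trip", {
  des <- study_design(n = 200, seed = 10)
  path <- tempfile(fileext = ".yaml")
  design_to_yaml(des, path)
  back <- design_from_yaml(path)
  expect_equal(back$n, des$n)
  expect_equal(back$items$labels, des$items$labels)
  expect_equal(length(back$leaves), length(des$leaves))
  expect_equal(back$leaves[[2]]$worth, des$leaves[[2]]$worth)
  expect_equal(design_kinds(back), design_kinds(des))
  s1 <- simulate_study(des, seed = 12)
  s2 <- simulate_study(back, seed = 12)
  expect_identical(s1$rankings, s2$rankings)
})
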