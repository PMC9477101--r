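# Shared fixtures and independent oracles for the test suite.

items5 <- item_set(letters[1:5], attribute = "abstraction",
                   intended_order = letters[1:5])
items3 <- item_set(letters[1:3])

# build a rankings data.frame from a list/matrix of orderings
make_rankings <- function(orderings, items = items5) {
  M <- if (is.matrix(orderings)) orderings else do.call(rbind, orderings)
  colnames(M) <- paste0("pos", seq_len(ncol(M)))
  cbind(data.frame(subject_id = seq_len(nrow(M))),
        as.data.frame(M, stringsAsFactors = FALSE))
}

# brute-force multinomial MLE oracle: direct numerical maximization of the
# J!-cell loglikelihood over the free item parameters (BFGS with numeric
# gradients, restarted once from its own solution for polish)
brute_mle <- function(counts, J) {
  Y <- enumerate_patterns(J)
  X <- item_scores(unclass(Y))
  negll <- function(theta) {
    lambda <- c(theta, -sum(theta))
    eta <- X %*% lambda
    M <- max(eta)
    -(sum(counts * eta) - sum(counts) * (M + log(sum(exp(eta - M)))))
  }
  o <- stats::optim(numeric(J - 1), negll, method = "BFGS",
                    control = list(reltol = 1e-15, maxit = 2000))
  o <- stats::optim(o$par, negll, method = "BFGS",
                    control = list(reltol = 1e-15, maxit = 2000))
  lambda <- c(o$par, -sum(o$par))
  list(lambda = lambda, pi = worth_from_lambda(lambda), loglik = -o$value)
}

# hand enumeration of pattern probabilities for J = 3: weight of each of the
# 6 orderings is exp(sum_{j<k} y_jk (lambda_j - lambda_k))
hand_pattern_probs_3 <- function(lambda) {
  orders <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  w <- vapply(orders, function(o) {
    pos <- integer(3)
    pos[o] <- 1:3
    s <- 0
    for (j in 1:2) for (k in (j + 1):3) {
      y <- if (pos[j] < pos[k]) 1 else -1
      s <- s + y * (lambda[j] - lambda[k])
    }
    exp(s)
  }, numeric(1))
  w / sum(w)
}

# standard planted-split fixture: one age <= 15 split with the steep and
# flat worth regimes of a large classroom study, plus four decoy covariates
planted_design <- function(n = 1000,
                           steep = c(0.933, 0.061, 0.005, 4.10e-4, 2.00e-5),
                           flat = c(0.593, 0.228, 0.106, 0.053, 0.018)) {
  steep <- steep / sum(steep)
  flat <- flat / sum(flat)
  sim_design(
    items5,
    covariates = list(
      covariate_spec("age", "numeric", mean = 15.35, sd = 2.96, round = TRUE,
                     min = 13),
      covariate_spec("game_time", "numeric", mean = 23.01, sd = 10.26,
                     lognormal = TRUE),
      covariate_spec("gender", "nominal", levels = c("female", "male"),
                     probs = c(0.52, 0.48)),
      covariate_spec("IP", "ordinal", levels = 1:4,
                     probs = likert_probs(2.74, 4)),
      covariate_spec("LM", "ordinal", levels = 1:4,
                     probs = likert_probs(2.70, 4))
    ),
    leaves = list(
      leaf_spec(list(list(covariate = "age", op = "<=", value = 15)), steep),
      leaf_spec(list(list(covariate = "age", op = ">", value = 15)), flat)
    ),
    n = n
  )
}

# same covariates, a single homogeneous leaf
homogeneous_design <- function(n = 800,
                               worth = c(0.40, 0.25, 0.15, 0.12, 0.08)) {
  d <- planted_design(n)
  d$leaves <- list(leaf_spec(list(), worth / sum(worth)))
  d
}

planted_kinds <- c(age = "numeric", game_time = "numeric", gender = "nominal",
                   IP = "ordinal", LM = "ordinal")
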