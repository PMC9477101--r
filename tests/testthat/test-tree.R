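# Recursive partitioning: growth, cutpoint search, pruning, prediction.

test_that("a planted age split is recovered at the root with its cutpoint", {
  des <- planted_design(1000)
  ok <- 0L
  for (s in 1:10) {
    sim <- simulate_study(des, seed = 1000 + s)
    tree <- grow_tree(sim$rankings, sim$covariates, items5, planted_kinds,
                      tree_config(alpha = 0.05, minsize = 40))
    rs <- tree$root$split
    if (!is.null(rs) && rs$covariate == "age" && abs(rs$cutpoint - 15) <= 1) {
      ok <- ok + 1L
    }
    # partition invariants at every level
    nodes <- worthtree:::tree_nodes(tree)
    for (nd in nodes) {
      if (!is.null(nd$kids)) {
        expect_setequal(c(nd$kids[[1]]$subjects, nd$kids[[2]]$subjects),
                        nd$subjects)
        expect_equal(nd$kids[[1]]$n + nd$kids[[2]]$n, nd$n)
      }
      expect_equal(sum(nd$fit$pi), 1, tolerance = 1e-10)
    }
  }
  expect_gte(ok, 9L)
})

test_that("homogeneous data almost always yields a single node", {
  des <- homogeneous_design(800)
  single <- 0L
  for (s in 1:10) {
    sim <- simulate_study(des, seed = 2000 + s)
    tree <- grow_tree(sim$rankings, sim$covariates, items5, planted_kinds,
                      tree_config())
    if (is.null(tree$root$split)) single <- single + 1L
  }
  expect_gte(single, 9L)
})

test_that("tiny nodes are never split and forced cutpoints are unique", {
  des <- homogeneous_design(60)
  sim <- simulate_study(des, seed = 3)
  tree <- grow_tree(sim$rankings, sim$covariates, items5, planted_kinds,
                    tree_config(minsize = 40))
  expect_null(tree$root$split)
  expect_equal(tree$root$stop_reason, "node too small")

  # n = 2 * minsize with two distinct values: only one admissible cutpoint
  set.seed(4)
  rk <- sample_ranking(c(0.4, 0.25, 0.15, 0.12, 0.08), 20)
  cv <- covariate("z", rep(c(1, 2), each = 10), "numeric")
  rule <- search_cutpoint(rk, cv, items5, minsize = 10)
  expect_equal(rule$cutpoint, 1)
  expect_error(search_cutpoint(rk, covariate("z", rep(1, 20), "numeric"),
                               items5, minsize = 10),
               "unsplittable")

  # two-level nominal covariate: the single binary partition
  cvn <- covariate("g", rep(c("x", "y"), each = 10), "nominal")
  rule_n <- search_cutpoint(rk, cvn, items5, minsize = 10)
  expect_setequal(rule_n$left_levels, "x")
})

test_that("planted cutpoints are located within one observation gap", {
  steep <- c(0.933, 0.061, 0.005, 4.1e-4, 2e-5); steep <- steep / sum(steep)
  flat <- c(0.593, 0.228, 0.106, 0.053, 0.018); flat <- flat / sum(flat)
  set.seed(66)
  hits <- replicate(25, {
    z <- round(rnorm(500, 15.35, 2.96))
    rk <- make_rankings(rbind(
      as.matrix(sample_ranking(steep, sum(z <= 15))[, -1]),
      as.matrix(sample_ranking(flat, sum(z > 15))[, -1])))
    zz <- c(z[z <= 15], z[z > 15])
    rule <- search_cutpoint(rk, covariate("z", zz, "numeric"), items5, 40)
    # ages are integers, so one inter-observation gap equals 1
    rule$covariate == "z" && abs(rule$cutpoint - 15) <= 1
  })
  expect_gte(mean(hits), 0.9)
})

test_that("AIC pruning is idempotent, monotone, and spares true splits", {
  des <- planted_design(1000)
  sim <- simulate_study(des, seed = 5)
  grown <- grow_tree(sim$rankings, sim$covariates, items5, planted_kinds,
                     tree_config(prune = "none"))
  pruned <- prune_aic(grown)
  expect_lte(worthtree:::subtree_aic(pruned$root),
             worthtree:::subtree_aic(grown$root))
  pruned2 <- prune_aic(pruned)
  expect_equal(node_table(pruned2), node_table(pruned))
  # the true split survives
  expect_equal(pruned$root$split$covariate, "age")

  # an overgrown tree on homogeneous data collapses toward the root
  desh <- homogeneous_design(600)
  simh <- simulate_study(desh, seed = 6)
  loose <- grow_tree(simh$rankings, simh$covariates, items5, planted_kinds,
                     tree_config(alpha = 0.5, prune = "none"))
  tight <- prune_aic(loose)
  expect_lte(nrow(node_table(tight)), nrow(node_table(loose)))
  expect_lte(worthtree:::subtree_aic(tight$root),
             worthtree:::subtree_aic(loose$root))

  # single-node tree is unchanged
  one <- grow_tree(simh$rankings, simh$covariates, items5, planted_kinds,
                   tree_config(alpha = 1e-9))
  expect_null(one$root$split)
  expect_equal(node_table(prune_aic(one)), node_table(one))
})

test_that("prediction routes by the <= convention and errors on missing", {
  des <- planted_design(1000)
  sim <- simulate_study(des, seed = 8)
  tree <- grow_tree(sim$rankings, sim$covariates, items5, planted_kinds,
                    tree_config())
  expect_equal(tree$root$split$covariate, "age")
  cut <- tree$root$split$cutpoint
  nd <- data.frame(age = c(cut, cut + 1, 13, 25), game_time = 20,
                   gender = "male", IP = 2, LM = 2)
  pr <- predict_node(tree, nd)
  expect_equal(pr$node[1], tree$root$kids[[1]]$id) # exactly at cut -> left
  expect_equal(pr$node[2], tree$root$kids[[2]]$id)
  expect_false(pr$node[3] == pr$node[4])
  expect_equal(unname(rowSums(pr$worth)), rep(1, 4), tolerance = 1e-10)
  expect_error(predict_node(tree, data.frame(game_time = 10)), "age")

  # single-node tree returns root worths for any input
  desh <- homogeneous_design(300)
  simh <- simulate_study(desh, seed = 9)
  one <- grow_tree(simh$rankings, simh$covariates, items5, planted_kinds,
                   tree_config(alpha = 1e-9))
  pr1 <- predict_node(one, data.frame(whatever = 1))
  expect_equal(pr1$node, one$root$id)
  expect_equal(unname(pr1$worth[1, ]), unname(one$root$fit$pi))
})

test_that("a focal group is modeled in every node and never split on", {
  steep <- c(0.933, 0.061, 0.005, 4.1e-4, 2e-5); steep <- steep / sum(steep)
  flat <- c(0.593, 0.228, 0.106, 0.053, 0.018); flat <- flat / sum(flat)
  des <- planted_design(600)
  des$leaves <- list(
    leaf_spec(list(list(covariate = "age", op = "<=", value = 15)),
              flat, group_worth = list(expert = steep)),
    leaf_spec(list(list(covariate = "age", op = ">", value = 15)),
              flat, group_worth = list(expert = steep)))
  des$group <- list(name = "expertise", levels = c("novice", "expert"),
                    probs = c(0.5, 0.5), reference = "novice")
  des <- sim_design(des$items, des$covariates, des$leaves, n = 600,
                    group = des$group)
  sim <- simulate_study(des, seed = 17)
  tree <- grow_tree(sim$rankings, sim$covariates, items5, planted_kinds,
                    tree_config(), groups = sim$groups)
  for (nd in worthtree:::tree_nodes(tree)) {
    if (!is.null(nd$split)) expect_false(nd$split$covariate == "expertise")
    expect_false(is.null(nd$fit$group_pi))
  }
  # worth differences live in the group dimension, not in splits
  gp <- tree$root$fit$group_pi
  expect_lt(max(abs(gp[, "novice"] - flat)), 0.08)
  expect_lt(max(abs(gp[, "expert"] - steep)), 0.08)
})

test_that("subjects with missing covariates are dropped and counted", {
  des <- homogeneous_design(300)
  sim <- simulate_study(des, seed = 21)
  sim$covariates$age[c(5, 10)] <- NA
  tree <- grow_tree(sim$rankings, sim$covariates, items5, planted_kinds,
                    tree_config())
  expect_equal(tree$dropped_missing, 2)
  expect_equal(tree$n, 298)
})
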