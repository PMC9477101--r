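# Model-based recursive partitioning of LLBT fits over subject covariates.
#
# At each node: fit the pattern model, test every candidate covariate for
# parameter instability (Bonferroni-adjusted within the node), split on the
# most unstable covariate at the cutpoint maximizing the children's combined
# loglikelihood, and recurse until no covariate is significant, the node is
# too small, or the depth limit is reached. An optional focal grouping
# variable is modeled inside every node and never used for splitting.

#' Tree-growing configuration
#'
#' @param alpha significance level for the instability tests (default 0.05).
#' @param minsize minimum subjects per node (default 40, the value used for
#'   large classroom samples; small expert/novice panels would use e.g. 4).
#' @param max_depth maximum tree depth (root = depth 0).
#' @param prune `"aic"` (post-prune splits that do not lower the combined
#'   AIC) or `"none"`.
#' @param bonferroni adjust instability p-values across candidate covariates.
#' @param seed optional seed recorded with the tree.
#' @return An object of class `tree_config`.
#' @export
tree_config <- function(alpha = 0.05, minsize = 40L, max_depth = 10L,
                        prune = c("aic", "none"), bonferroni = TRUE,
                        seed = NULL) {
  prune <- match.arg(prune)
  stopifnot(alpha > 0, alpha < 1, minsize >= 1, max_depth >= 0)
  structure(list(alpha = alpha, minsize = as.integer(minsize),
                 max_depth = as.integer(max_depth), prune = prune,
                 bonferroni = isTRUE(bonferroni), seed = seed),
            class = "tree_config")
}

#' Declare a focal grouping variable
#'
#' The focal group (e.g. expert vs. novice) is modeled inside every tree node
#' via group-specific item parameters and is never a splitting candidate.
#'
#' @param values group label per subject (aligned with the rankings rows, or
#'   named by subject id).
#' @param reference reference group label (default: first level).
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(values, reference = NULL) {
  values <- as.character(values)
  labs <- unique(values)
  if (length(labs) < 2L) stop("a focal group needs at least two levels")
  reference <- reference %||% labs[1L]
  if (!reference %in% labs) stop("reference group '", reference, "' not among labels")
  structure(list(values = values, reference = reference, labels = labs),
            class = "group_spec")
}

# build covariate objects from a data.frame + declared kinds
build_covariates <- function(covariates, kinds, levels = list()) {
  if (!is.data.frame(covariates)) stop("'covariates' must be a data.frame")
  if (!"subject_id" %in% names(covariates)) {
    stop("covariates table needs a 'subject_id' column")
  }
  vars <- setdiff(names(covariates), "subject_id")
  if (is.null(kinds)) stop("covariate kinds must be declared (named vector), never inferred")
  miss <- setdiff(vars, names(kinds))
  if (length(miss)) stop("no kind declared for covariate(s): ", paste(miss, collapse = ", "))
  lapply(vars, function(v) {
    covariate(v, covariates[[v]], kinds[[v]], levels = levels[[v]])
  })
}

# fit a node, optionally grouped
node_fit <- function(pidx, gidx, glabs, items, w = NULL) {
  J <- n_items(items)
  w <- w %||% rep(1, length(pidx))
  counts_of <- function(ii) {
    cnt <- numeric(factorial(J))
    if (length(ii)) {
      agg <- rowsum(w[ii], pidx[ii])
      cnt[as.integer(rownames(agg))] <- agg
    }
    pattern_table(cnt, items)
  }
  all_idx <- seq_along(pidx)
  if (is.null(gidx)) {
    fit <- suppressWarnings(fit_llbt(counts_of(all_idx)))
  } else {
    tabs <- lapply(glabs, function(g) counts_of(which(gidx == g)))
    names(tabs) <- glabs
    present <- vapply(tabs, function(t) t$n >= 1, logical(1))
    if (sum(present) < 2L) {
      fit <- suppressWarnings(fit_llbt(counts_of(all_idx)))
    } else {
      fit <- suppressWarnings(fit_llbt_grouped(tabs[present],
                                               reference = if (present[[1L]]) glabs[1L] else names(tabs[present])[1L]))
    }
  }
  fit
}

# per-subject scores at the node MLE; grouped fits get block-diagonal columns
node_scores <- function(fit, pidx, gidx) {
  if (is.null(fit$group_fits)) {
    return(llbt_score_rows(fit$lambda, pidx))
  }
  glabs <- names(fit$group_fits)
  J <- n_items(fit$items)
  S <- matrix(0, length(pidx), J * length(glabs))
  for (gi in seq_along(glabs)) {
    rows <- which(gidx == glabs[gi])
    if (!length(rows)) next
    S[rows, (gi - 1L) * J + seq_len(J)] <-
      llbt_score_rows(fit$group_fits[[gi]]$lambda, pidx[rows])
  }
  S
}

# ---- cutpoint search -------------------------------------------------------

all_binary_partitions <- function(levels) {
  C <- length(levels)
  out <- list()
  for (mask in seq_len(2^(C - 1L) - 1L)) {
    left <- levels[as.logical(bitwAnd(mask, 2^(seq_len(C) - 1L)))]
    out[[length(out) + 1L]] <- left
  }
  out
}

# maximize sum of children logliks; pidx = pattern indices, cv = covariate
# (already subset to the node). Returns NULL when unsplittable.
best_cut <- function(pidx, cv, minsize, items, theta0 = NULL, w = NULL) {
  n <- length(pidx)
  w <- w %||% rep(1, n)
  W_tot <- sum(w)
  J <- n_items(items)
  nb <- factorial(J)
  sp <- pattern_space(J)
  child_ll <- function(rows) {
    cnt <- numeric(nb)
    agg <- rowsum(w[rows], pidx[rows])
    cnt[as.integer(rownames(agg))] <- agg
    llbt_newton(cnt, sp, theta0 = theta0)$loglik
  }
  if (cv$kind == "nominal") {
    lev_present <- unique(cv$values[!is.na(cv$values)])
    if (length(lev_present) > 10L) stop("nominal covariate '", cv$name, "' has more than 10 levels")
    if (length(lev_present) < 2L) return(NULL)
    best <- NULL
    for (left in all_binary_partitions(lev_present)) {
      rows <- which(cv$values %in% left)
      if (sum(w[rows]) < minsize || W_tot - sum(w[rows]) < minsize) next
      ll <- child_ll(rows) + child_ll(setdiff(seq_len(n), rows))
      if (is.null(best) || ll > best$loglik) {
        best <- list(covariate = cv$name, kind = "nominal",
                     left_levels = left, cutpoint = NA_real_, loglik = ll)
      }
    }
    return(best)
  }
  ord <- order(cv$code)
  v <- cv$code[ord]
  cw <- cumsum(w[ord])
  cand <- which(v[-n] < v[-1L])
  cand <- cand[cw[cand] >= minsize & (W_tot - cw[cand]) >= minsize]
  if (!length(cand)) return(NULL)
  best <- NULL
  for (i in cand) {
    rows <- ord[seq_len(i)]
    ll <- child_ll(rows) + child_ll(ord[(i + 1L):n])
    if (is.null(best) || ll > best$loglik) {
      # report the cutpoint as the left child's maximum observed value,
      # so rules print as e.g. "age <= 15"
      best <- list(covariate = cv$name, kind = cv$kind,
                   cutpoint = covariate_numeric_level(cv, v[i]),
                   cut_code = v[i], levels = cv$levels,
                   left_levels = NULL, loglik = ll)
    }
  }
  best
}

#' Search the best cutpoint for a covariate
#'
#' Among admissible binary splits (each child at least `minsize` subjects),
#' returns the rule maximizing the sum of the two children's pattern-model
#' loglikelihoods. Numeric/ordinal rules are reported as
#' `value <= cutpoint -> left`, with the cutpoint the left child's largest
#' observed value; nominal rules are a category subset.
#'
#' @param rankings rankings data.frame.
#' @param cov a [covariate()] aligned with the rankings rows.
#' @param items an [item_set].
#' @param minsize minimum child size.
#' @return A list describing the split rule (fields `covariate`, `kind`,
#'   `cutpoint` or `left_levels`, `loglik`).
#' @export
search_cutpoint <- function(rankings, cov, items, minsize) {
  items <- as_item_set(items)
  pidx <- pattern_index(rankings, items)
  rule <- best_cut(pidx, cov, minsize, items)
  if (is.null(rule)) stop("node unsplittable: no admissible cutpoint for '", cov$name, "'")
  rule
}

rule_goes_left <- function(rule, value, code) {
  if (rule$kind == "nominal") value %in% rule$left_levels
  else code <= rule$cut_code
}

rule_label <- function(rule) {
  if (rule$kind == "nominal") {
    paste0(rule$covariate, " in {", paste(rule$left_levels, collapse = ","), "}")
  } else {
    paste0(rule$covariate, " <= ", format(rule$cutpoint, digits = 6))
  }
}

# ---- growing ---------------------------------------------------------------

#' Grow a loglinear Bradley-Terry partition tree
#'
#' @param rankings rankings data.frame (`subject_id`, `pos1`, ..., `posJ`).
#' @param covariates data.frame with `subject_id` plus one column per
#'   candidate covariate. Subjects with any missing covariate value are
#'   dropped at tree entry (count recorded in the result).
#' @param items an [item_set].
#' @param kinds named character vector declaring each covariate's kind
#'   (`"numeric"`, `"ordinal"`, `"nominal"`).
#' @param config a [tree_config()].
#' @param levels named list of level orders for ordinal/nominal covariates.
#' @param groups optional [group_spec()] (focal variable; modeled in every
#'   node, never split on).
#' @param weights optional non-negative case weights, one per ranking row
#'   (e.g. bootstrap multiplicities); node sizes, fits and instability tests
#'   are all weighted.
#' @return An object of class `llbt_tree`.
#' @export
grow_tree <- function(rankings, covariates, items, kinds,
                      config = tree_config(), levels = list(), groups = NULL,
                      weights = NULL) {
  items <- as_item_set(items)
  sid <- as.character(rankings$subject_id)
  crow <- match(sid, as.character(covariates$subject_id))
  if (anyNA(crow)) {
    stop("subject '", sid[which(is.na(crow))[1L]], "' has no covariate row")
  }
  covariates <- covariates[crow, , drop = FALSE]
  covs <- build_covariates(covariates, kinds, levels)
  wts <- weights %||% rep(1, nrow(rankings))
  if (length(wts) != nrow(rankings) || any(wts < 0)) {
    stop("'weights' must be non-negative, one per ranking row")
  }
  keep <- !Reduce(`|`, lapply(covs, function(cv) is.na(cv$values)),
                  rep(FALSE, nrow(rankings)))
  dropped <- sum(!keep)
  rankings <- rankings[keep, , drop = FALSE]
  covs <- lapply(covs, subset_covariate, idx = which(keep))
  sid <- sid[keep]
  wts <- wts[keep]
  pidx <- pattern_index(rankings, items)
  gidx <- NULL
  glabs <- NULL
  if (!is.null(groups)) {
    if (!inherits(groups, "group_spec")) stop("'groups' must be a group_spec")
    gvals <- groups$values
    if (!is.null(names(gvals))) gvals <- gvals[sid]
    else gvals <- gvals[which(keep)]
    if (length(gvals) != length(sid) || anyNA(gvals)) {
      stop("every subject must be mapped to a focal group")
    }
    gidx <- as.character(gvals)
    glabs <- c(groups$reference, setdiff(groups$labels, groups$reference))
  }

  id_counter <- new.env(parent = emptyenv())
  id_counter$next_id <- 1L

  build <- function(rows, depth) {
    id <- id_counter$next_id
    id_counter$next_id <- id + 1L
    fit <- node_fit(pidx[rows], if (is.null(gidx)) NULL else gidx[rows],
                    glabs, items, w = wts[rows])
    node <- list(id = id, depth = depth, n = sum(wts[rows]),
                 subjects = sid[rows],
                 fit = fit, instability = NULL, split = NULL, kids = NULL,
                 stop_reason = NULL)
    if (!fit$converged) {
      node$stop_reason <- "fit did not converge"
      return(node)
    }
    if (sum(wts[rows]) < 2 * config$minsize) {
      node$stop_reason <- "node too small"
      return(node)
    }
    if (depth >= config$max_depth) {
      node$stop_reason <- "depth limit"
      return(node)
    }
    S <- node_scores(fit, pidx[rows], if (is.null(gidx)) NULL else gidx[rows])
    tests <- lapply(covs, function(cv) {
      instability_test(S, subset_covariate(cv, rows), config$minsize,
                       order_ties = sid[rows], weights = wts[rows])
    })
    if (config$bonferroni) tests <- adjust_instability(tests)
    node$instability <- tests
    pick <- select_split_variable(tests, config$alpha)
    if (is.null(pick)) {
      node$stop_reason <- "no significant instability"
      return(node)
    }
    cv <- covs[[match(pick, vapply(covs, function(c) c$name, character(1)))]]
    rule <- best_cut(pidx[rows], subset_covariate(cv, rows), config$minsize,
                     items, theta0 = fit$lambda[-length(fit$lambda)],
                     w = wts[rows])
    if (is.null(rule)) {
      node$stop_reason <- "node unsplittable"
      return(node)
    }
    goleft <- rule_goes_left(rule, cv$values[rows], cv$code[rows])
    node$split <- rule
    node$kids <- list(build(rows[goleft], depth + 1L),
                      build(rows[!goleft], depth + 1L))
    node
  }

  root <- build(seq_along(pidx), 0L)
  tree <- structure(list(root = root, items = items, config = config,
                         covariates = vapply(covs, function(c) c$name, character(1)),
                         kinds = kinds, n = length(pidx),
                         dropped_missing = dropped,
                         groups = if (is.null(groups)) NULL else groups),
                    class = "llbt_tree")
  if (config$prune == "aic") tree <- prune_aic(tree)
  tree
}

# ---- pruning ---------------------------------------------------------------

subtree_aic <- function(node) {
  if (is.null(node$kids)) return(node$fit$aic)
  sum(vapply(node$kids, subtree_aic, numeric(1)))
}

prune_node <- function(node) {
  if (is.null(node$kids)) return(node)
  node$kids <- lapply(node$kids, prune_node)
  if (subtree_aic(node) >= node$fit$aic) {
    node$kids <- NULL
    node$split <- NULL
    node$stop_reason <- "pruned (AIC)"
  }
  node
}

#' AIC post-pruning
#'
#' Bottom-up: a split whose descendants' combined AIC (`-2 * sum(loglik) +
#' 2 * sum(parameters)` over the terminal nodes below) is not lower than the
#' node's own AIC is collapsed. Idempotent; never increases the tree's total
#' AIC.
#'
#' @param tree an `llbt_tree`.
#' @return The pruned tree.
#' @export
prune_aic <- function(tree) {
  tree$root <- prune_node(tree$root)
  tree
}

# ---- prediction and summaries ---------------------------------------------

#' Route new subjects to terminal nodes
#'
#' Routing follows the `<=` (left) / `>` (right) convention; a value exactly
#' at a cutpoint goes left.
#'
#' @param tree an `llbt_tree`.
#' @param newdata data.frame with one row per subject and a column for every
#'   covariate used in the tree's split rules.
#' @return A list with `node` (terminal node id per row) and `worth` (matrix
#'   of that node's worth vector per row; for grouped fits, the reference
#'   group's unless `group` is given).
#' @param group optional focal-group label per row (grouped trees).
#' @export
predict_node <- function(tree, newdata, group = NULL) {
  n <- nrow(newdata)
  ids <- integer(n)
  J <- n_items(tree$items)
  W <- matrix(NA_real_, n, J, dimnames = list(NULL, tree$items$labels))
  for (r in seq_len(n)) {
    node <- tree$root
    while (!is.null(node$kids)) {
      rule <- node$split
      if (!rule$covariate %in% names(newdata)) {
        stop("missing covariate '", rule$covariate, "' in newdata")
      }
      value <- newdata[[rule$covariate]][r]
      if (is.na(value)) stop("missing value for covariate '", rule$covariate, "'")
      left <- if (rule$kind == "nominal") {
        value %in% rule$left_levels
      } else if (rule$kind == "ordinal") {
        code <- match(value, rule$levels)
        if (is.na(code)) stop("value '", value, "' outside declared levels of '",
                              rule$covariate, "'")
        code <= rule$cut_code
      } else {
        as.numeric(value) <= rule$cutpoint
      }
      node <- node$kids[[if (left) 1L else 2L]]
    }
    ids[r] <- node$id
    pi <- node$fit$pi
    if (!is.null(node$fit$group_pi) && !is.null(group)) {
      g <- as.character(group[r])
      if (g %in% colnames(node$fit$group_pi)) pi <- node$fit$group_pi[, g]
    }
    W[r, ] <- pi
  }
  list(node = ids, worth = W)
}

# flatten nodes in preorder
tree_nodes <- function(tree) {
  out <- list()
  rec <- function(node, path) {
    node$path <- path
    out[[length(out) + 1L]] <<- node
    if (!is.null(node$kids)) {
      lab <- node$split
      rec(node$kids[[1L]], c(path, rule_label(lab)))
      neg <- if (lab$kind == "nominal") {
        paste0(lab$covariate, " not in {", paste(lab$left_levels, collapse = ","), "}")
      } else paste0(lab$covariate, " > ", format(lab$cutpoint, digits = 6))
      rec(node$kids[[2L]], c(path, neg))
    }
  }
  rec(tree$root, character(0))
  out
}

#' Terminal-node worth table
#'
#' One row per terminal node: node id, size, the path of split rules leading
#' to it, and the worth parameter of every item (for grouped fits, of the
#' reference group).
#'
#' @param tree an `llbt_tree`.
#' @return A data.frame.
#' @export
node_table <- function(tree) {
  nodes <- Filter(function(nd) is.null(nd$kids), tree_nodes(tree))
  W <- t(vapply(nodes, function(nd) nd$fit$pi, numeric(n_items(tree$items))))
  colnames(W) <- tree$items$labels
  data.frame(node = vapply(nodes, function(nd) nd$id, integer(1)),
             n = vapply(nodes, function(nd) nd$n, numeric(1)),
             path = vapply(nodes, function(nd)
               if (length(nd$path)) paste(nd$path, collapse = ", ") else "<root>",
               character(1)),
             W, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @export
print.llbt_tree <- function(x, ...) {
  nt <- sum(vapply(tree_nodes(x), function(nd) is.null(nd$kids), logical(1)))
  cat("LLBT partition tree: n =", x$n, "subjects,", nt, "terminal node(s)")
  if (x$dropped_missing > 0) cat(" (", x$dropped_missing, "dropped for missing covariates)")
  cat("\n")
  rec <- function(node, indent) {
    pre <- paste(rep("|  ", indent), collapse = "")
    if (is.null(node$kids)) {
      cat(pre, "[", node$id, "] n=", node$n, "  worth: ",
          paste(sprintf("%s=%s", names(node$fit$pi), format_worth(node$fit$pi)),
                collapse = " "), "\n", sep = "")
    } else {
      cat(pre, "[", node$id, "] split: ", rule_label(node$split), "\n", sep = "")
      rec(node$kids[[1L]], indent + 1L)
      rec(node$kids[[2L]], indent + 1L)
    }
  }
  rec(x$root, 0L)
  invisible(x)
}
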