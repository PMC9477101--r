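# Serialization: JSON fit/tree records, DOT tree rendering, YAML designs.

#' Format worth parameters for display
#'
#' Three significant figures, switching to scientific notation below 1e-3
#' (near-degenerate worths stay readable).
#'
#' @param x numeric vector of worths.
#' @return Character vector.
#' @export
format_worth <- function(x) {
  ifelse(x < 1e-3, sprintf("%.2e", x), sprintf("%.3g", x))
}

#' Serialize a model fit to JSON
#'
#' Stable key names; round-trippable through [fit_from_json()].
#'
#' @param fit an `llbt_fit`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @param level confidence level for the embedded worth intervals.
#' @return The JSON string (invisibly when written to `path`).
#' @export
fit_to_json <- function(fit, path = NULL, level = 0.95) {
  ci <- if (fit$converged) worth_ci(fit, level) else NULL
  rec <- list(
    schema_version = 1L,
    items = list(labels = fit$items$labels, attribute = fit$items$attribute,
                 intended_order = fit$items$intended_order),
    lambda = as.list(fit$lambda),
    pi = as.list(fit$pi),
    worth_ci = ci,
    ci_level = if (is.null(ci)) NULL else level,
    cov_lambda = fit$cov_lambda,
    loglik = fit$loglik, aic = fit$aic, npar = fit$npar, n = fit$n,
    converged = fit$converged, separated = fit$separated,
    penalty = fit$penalty, normalization = fit$normalization,
    reference_group = fit$reference_group,
    group_pi = if (is.null(fit$group_pi)) NULL else
      lapply(as.data.frame(fit$group_pi), identity),
    group_terms = if (is.null(fit$group_terms)) NULL else
      lapply(fit$group_terms, as.list)
  )
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Rebuild a model fit from its JSON record
#'
#' @param json a JSON string or a file path produced by [fit_to_json()].
#' @return An `llbt_fit` (covariances restored; group fits are not).
#' @export
fit_from_json <- function(json) {
  rec <- if (file.exists(json)) jsonlite::read_json(json, simplifyVector = TRUE)
         else jsonlite::fromJSON(json, simplifyVector = TRUE)
  items <- item_set(rec$items$labels, rec$items$attribute %||% "",
                    rec$items$intended_order)
  lambda <- unlist(rec$lambda)
  gp <- NULL
  if (!is.null(rec$group_pi)) {
    gp <- do.call(cbind, rec$group_pi)
    rownames(gp) <- items$labels
  }
  structure(list(items = items, lambda = lambda, pi = unlist(rec$pi),
                 cov_theta = NULL,
                 cov_lambda = matrix(unlist(rec$cov_lambda),
                                     length(lambda), length(lambda)),
                 loglik = rec$loglik, n = rec$n, npar = rec$npar,
                 aic = rec$aic, converged = rec$converged,
                 separated = rec$separated, penalty = rec$penalty,
                 normalization = rec$normalization,
                 iterations = NA_integer_,
                 group_terms = rec$group_terms, group_pi = gp,
                 group_fits = NULL,
                 reference_group = rec$reference_group),
            class = "llbt_fit")
}

#' Serialize a partition tree to JSON
#'
#' Versioned schema: `schema_version`, items, configuration, and a flat node
#' array (id, depth, n, terminal flag, split rule, worth parameters with
#' intervals, instability p-values, loglik, AIC).
#'
#' @param tree an `llbt_tree`.
#' @param path optional file path.
#' @return The JSON string (invisibly when written to `path`).
#' @export
tree_to_json <- function(tree, path = NULL) {
  nodes <- lapply(tree_nodes(tree), function(nd) {
    ci <- if (nd$fit$converged) worth_ci(nd$fit) else NULL
    list(id = nd$id, depth = nd$depth, n = nd$n,
         terminal = is.null(nd$kids),
         split = if (is.null(nd$split)) NULL else list(
           covariate = nd$split$covariate, kind = nd$split$kind,
           cutpoint = nd$split$cutpoint,
           left_levels = nd$split$left_levels,
           label = rule_label(nd$split)),
         stop_reason = nd$stop_reason,
         worth = as.list(nd$fit$pi),
         worth_ci = ci,
         loglik = nd$fit$loglik, aic = nd$fit$aic,
         converged = nd$fit$converged, separated = nd$fit$separated,
         instability = if (is.null(nd$instability)) NULL else
           lapply(nd$instability, function(r)
             list(covariate = r$covariate, statistic = r$statistic,
                  p_value = r$p_value, p_adjusted = r$p_adjusted,
                  test = r$test)))
  })
  rec <- list(schema_version = 1L,
              items = list(labels = tree$items$labels,
                           attribute = tree$items$attribute,
                           intended_order = tree$items$intended_order),
              config = list(alpha = tree$config$alpha,
                            minsize = tree$config$minsize,
                            max_depth = tree$config$max_depth,
                            prune = tree$config$prune,
                            bonferroni = tree$config$bonferroni),
              n = tree$n, dropped_missing = tree$dropped_missing,
              nodes = nodes)
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Render a partition tree as DOT (graphviz)
#'
#' Terminal nodes show per-item worths, optionally on a log10 scale (useful
#' when worths span several orders of magnitude).
#'
#' @param tree an `llbt_tree`.
#' @param path optional file path.
#' @param log_worth display `log10(worth)` instead of raw worths.
#' @return The DOT source (invisibly when written to `path`).
#' @export
tree_to_dot <- function(tree, path = NULL, log_worth = FALSE) {
  nodes <- tree_nodes(tree)
  lines <- c("digraph llbt_tree {", "  node [shape=box, fontname=\"Helvetica\"];")
  for (nd in nodes) {
    if (is.null(nd$kids)) {
      w <- nd$fit$pi
      vals <- if (log_worth) sprintf("%.2f", log10(w)) else format_worth(w)
      lab <- paste0("node ", nd$id, "\\nn = ", nd$n, "\\n",
                    paste(paste0(names(w), if (log_worth) ": log10 pi = " else ": pi = ",
                                 vals), collapse = "\\n"))
      lines <- c(lines, sprintf("  n%d [label=\"%s\", style=filled, fillcolor=lightgrey];",
                                nd$id, lab))
    } else {
      lines <- c(lines, sprintf("  n%d [label=\"node %d\\nn = %d\\n%s\"];",
                                nd$id, nd$id, nd$n, rule_label(nd$split)))
      kl <- nd$kids[[1L]]$id
      kr <- nd$kids[[2L]]$id
      lines <- c(lines,
                 sprintf("  n%d -> n%d [label=\"yes\"];", nd$id, kl),
                 sprintf("  n%d -> n%d [label=\"no\"];", nd$id, kr))
    }
  }
  lines <- c(lines, "}")
  dot <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(dot, path)
    return(invisible(dot))
  }
  dot
}

# ---- design configs --------------------------------------------------------

#' Write a simulation design to YAML
#'
#' @param design a [sim_design()].
#' @param path file path.
#' @export
design_to_yaml <- function(design, path) {
  rec <- list(
    items = list(labels = design$items$labels,
                 attribute = design$items$attribute,
                 intended_order = design$items$intended_order),
    n = design$n,
    seed = design$seed,
    covariates = lapply(design$covariates, function(s) {
      out <- list(name = s$name, kind = s$kind)
      if (s$kind == "numeric") {
        out <- c(out, list(mean = s$mean, sd = s$sd, lognormal = s$lognormal,
                           round = s$round))
        if (is.finite(s$min)) out$min <- s$min
        if (is.finite(s$max)) out$max <- s$max
      } else {
        out <- c(out, list(levels = s$levels, probs = s$probs))
      }
      out
    }),
    group = design$group,
    leaves = lapply(design$leaves, function(lf) {
      list(when = lf$when, worth = lf$worth, group_worth = lf$group_worth)
    })
  )
  yaml::write_yaml(rec, path, precision = 15L)
  invisible(path)
}

#' Read a simulation design from YAML
#'
#' @param path file path written by [design_to_yaml()] (or hand-authored with
#'   the same structure).
#' @return A validated [sim_design()].
#' @export
design_from_yaml <- function(path) {
  rec <- yaml::read_yaml(path)
  items <- item_set(rec$items$labels, rec$items$attribute %||% "",
                    rec$items$intended_order)
  covs <- lapply(rec$covariates, function(s) {
    if (s$kind == "numeric") {
      covariate_spec(s$name, "numeric", mean = s$mean, sd = s$sd,
                     lognormal = isTRUE(s$lognormal), round = isTRUE(s$round),
                     min = s$min %||% -Inf, max = s$max %||% Inf)
    } else {
      covariate_spec(s$name, s$kind, levels = unlist(s$levels),
                     probs = unlist(s$probs))
    }
  })
  leaves <- lapply(rec$leaves, function(lf) {
    leaf_spec(lf$when %||% list(), unlist(lf$worth),
              group_worth = if (is.null(lf$group_worth)) NULL
                            else lapply(lf$group_worth, unlist))
  })
  sim_design(items, covs, leaves, n = rec$n, seed = rec$seed,
             group = rec$group)
}

#' Read a covariates table from delimited text
#'
#' Kinds are taken from the caller, never inferred from the file.
#'
#' @param path file path with header `subject_id,<covariate>,...`.
#' @param kinds named character vector of covariate kinds; numeric and
#'   ordinal columns are converted to numeric when possible.
#' @param sep field delimiter.
#' @return A data.frame.
#' @export
read_covariates <- function(path, kinds, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", fileEncoding = "UTF-8")
  if (!"subject_id" %in% names(df)) stop("covariates file needs a 'subject_id' column")
  for (v in setdiff(names(df), "subject_id")) {
    if (!v %in% names(kinds)) stop("no kind declared for covariate '", v, "'")
    if (kinds[[v]] %in% c("numeric", "ordinal")) {
      num <- suppressWarnings(as.numeric(df[[v]]))
      if (kinds[[v]] == "numeric" && anyNA(num) && !all(is.na(num) == (df[[v]] == ""))) {
        stop("covariate '", v, "' declared numeric but contains non-numeric values")
      }
      if (!anyNA(num) || kinds[[v]] == "numeric") df[[v]] <- num
    }
  }
  df
}

#' Write a covariates table
#'
#' @param covariates data.frame.
#' @param path file path.
#' @param sep field delimiter.
#' @export
write_covariates <- function(covariates, path, sep = ",") {
  utils::write.table(covariates, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
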