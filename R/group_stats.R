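# Shapiro-Wilk wrapper that survives degenerate samples: a constant
# sample cannot be tested and is routed to the nonparametric branch.
sw_gate <- function(x, label, alpha, path) {
  if (length(unique(x)) == 1L) {
    path[[length(path) + 1L]] <- data.frame(
      gate = paste0("shapiro_", label), p = NA_real_,
      outcome = "degenerate (constant sample): treated as non-normal")
    return(list(pass = FALSE, path = path))
  }
  p <- stats::shapiro.test(x)$p.value
  pass <- p >= alpha
  path[[length(path) + 1L]] <- data.frame(
    gate = paste0("shapiro_", label), p = p,
    outcome = if (pass) "normal" else "non-normal")
  list(pass = pass, path = path)
}

new_test_result <- function(test_name, statistic, p_value, path, alpha_gate,
                            comparisons = NULL) {
  structure(list(test_name = test_name,
                 statistic = unname(statistic),
                 p_value = unname(p_value),
                 decision_path = do.call(rbind, path),
                 alpha_gate = alpha_gate,
                 comparisons = comparisons),
            class = "xv_test_result")
}

#' @export
print.xv_test_result <- function(x, ...) {
  cat(sprintf("<xv_test_result> %s: statistic %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  cat("decision path:\n")
  print(x$decision_path, row.names = FALSE)
  if (!is.null(x$comparisons)) {
    cat("comparisons:\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}

#' Two-group comparison with normality- and variance-gated routing
#'
#' The decision tree used throughout the analyses: Shapiro-Wilk on each
#' sample; when both pass at `alpha_gate` the parametric branch runs a
#' two-sided F-test on the variances to decide between the pooled t-test
#' and Welch's correction; when either sample fails, the two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test is used (exact for small
#' tie-free samples, normal approximation with tie correction otherwise).
#' Every gate and its p-value is recorded in `decision_path`. Both
#' samples must pass the normality gate for the parametric branch; if
#' both samples have zero variance the F gate is undefined (the samples
#' are already routed nonparametrically by the degenerate-sample rule).
#'
#' @param a,b Numeric samples, each of length >= 3.
#' @param alpha_gate Gate significance level (default 0.05).
#' @return An `xv_test_result`: `test_name` (one of `"t"`, `"welch_t"`,
#'   `"mann_whitney"`), `statistic`, `p_value`, `decision_path`,
#'   `alpha_gate`.
#' @examples
#' set.seed(1)
#' compare_two(rnorm(20), rnorm(20, 1))
#' @export
compare_two <- function(a, b, alpha_gate = 0.05) {
  if (length(a) < 3 || length(b) < 3)
    xv_stop("xv_sample_too_small", "each sample needs n >= 3")
  path <- list()
  ga <- sw_gate(a, "a", alpha_gate, path); path <- ga$path
  gb <- sw_gate(b, "b", alpha_gate, path); path <- gb$path
  if (ga$pass && gb$pass) {
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      path[[length(path) + 1L]] <- data.frame(
        gate = "f_variance", p = NA_real_,
        outcome = "both variances zero: pooled t by convention")
      welch <- FALSE
    } else {
      pf <- stats::var.test(a, b)$p.value
      welch <- pf < alpha_gate
      path[[length(path) + 1L]] <- data.frame(
        gate = "f_variance", p = pf,
        outcome = if (welch) "unequal variances: Welch" else "pooled t")
    }
    ht <- stats::t.test(a, b, var.equal = !welch)
    new_test_result(if (welch) "welch_t" else "t",
                    ht$statistic, ht$p.value, path, alpha_gate)
  } else {
    n_large <- length(a) > 20 || length(b) > 20
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, exact = !n_large, correct = TRUE))
    new_test_result("mann_whitney", ht$statistic, ht$p.value, path,
                    alpha_gate)
  }
}

#' Multi-group comparison with normality-gated routing
#'
#' Shapiro-Wilk on each group: when every group passes, a one-way ANOVA
#' is run, followed by Dunnett many-to-one comparisons of each group
#' against the control (single-step adjusted p-values from the
#' equi-correlated multivariate t distribution); when any group fails,
#' the Kruskal-Wallis test is used instead. The multivariate-t quantile
#' integration is run under a fixed internal stream so results are
#' reproducible; the caller's random-number state is left untouched.
#'
#' @param groups Named list of >= 3 numeric samples, each n >= 3.
#' @param control_index Index (or name) of the control group for the
#'   Dunnett comparisons (default 1).
#' @param alpha_gate Gate significance level (default 0.05).
#' @return An `xv_test_result` with `test_name` `"anova_dunnett"` or
#'   `"kruskal_wallis"`; on the Dunnett branch, `statistic`/`p_value` are
#'   the ANOVA F and p, and `comparisons` holds one row per non-control
#'   group with the adjusted p-value.
#' @export
compare_many <- function(groups, control_index = 1, alpha_gate = 0.05) {
  if (length(groups) < 3)
    xv_stop("xv_too_few_groups", "need at least 3 groups")
  if (any(lengths(groups) < 3))
    xv_stop("xv_sample_too_small", "each group needs n >= 3")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  if (is.character(control_index))
    control_index <- match(control_index, names(groups))
  if (is.na(control_index) || control_index < 1 ||
      control_index > length(groups))
    xv_stop("xv_bad_control", "control_index does not name a group")
  path <- list()
  all_pass <- TRUE
  for (k in seq_along(groups)) {
    g <- sw_gate(groups[[k]], names(groups)[k], alpha_gate, path)
    path <- g$path
    all_pass <- all_pass && g$pass
  }
  if (all_pass) {
    lv <- c(names(groups)[control_index],
            names(groups)[-control_index])
    dat <- data.frame(y = unlist(groups, use.names = FALSE),
                      g = factor(rep(names(groups), lengths(groups)),
                                 levels = lv))
    fit <- stats::aov(y ~ g, data = dat)
    an <- summary(fit)[[1]]
    dn <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    sm <- with_fixed_rng(1234L, summary(dn))
    comps <- data.frame(
      comparison = names(sm$test$coefficients),
      estimate = unname(sm$test$coefficients),
      statistic = unname(sm$test$tstat),
      p_adjusted = unname(as.numeric(sm$test$pvalues)))
    new_test_result("anova_dunnett", an[["F value"]][1],
                    an[["Pr(>F)"]][1], path, alpha_gate, comps)
  } else {
    ht <- stats::kruskal.test(groups)
    new_test_result("kruskal_wallis", ht$statistic, ht$p.value, path,
                    alpha_gate)
  }
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's state.
with_fixed_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
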