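design_factor_names <- c("n_waves", "class_size", "n_classrooms",
                         "prop_treatment", "icc", "effect_label")

# design factors present in a summary table with >= 2 observed levels
active_factors <- function(summaries) {
  present <- intersect(design_factor_names, names(summaries))
  present[vapply(present, function(f) length(unique(summaries[[f]])) > 1L,
                 logical(1))]
}

check_balanced_factorial <- function(summaries, factors) {
  if (!length(factors)) stop("no design factor varies in the summary table")
  cells <- interaction(summaries[factors], drop = FALSE, sep = " / ")
  counts <- table(cells)
  if (any(counts == 0L)) {
    miss <- names(counts)[counts == 0L]
    stop("incomplete factorial: missing cell(s) ",
         paste(utils::head(miss, 5L), collapse = "; "),
         if (length(miss) > 5L) sprintf(" (and %d more)", length(miss) - 5L))
  }
  if (length(unique(counts)) != 1L) {
    stop("unbalanced factorial: cell counts range from ", min(counts),
         " to ", max(counts), "; rebalance the input instead")
  }
  invisible(counts)
}

#' Factorial ANOVA of a condition-level outcome with eta-squared
#'
#' Decomposes a Monte Carlo outcome (power, convergence rate or singularity
#' rate) over the design factors of a complete balanced factorial of
#' condition summaries, reporting `eta^2 = SS_term / SS_total` per term.
#' All design factors are treated as categorical.  On a balanced complete
#' design the sequential decomposition used here coincides with Type-II/III,
#' so the result is invariant to factor ordering.
#'
#' @param summaries A grid results table ([run_grid()] output or equivalent)
#'   forming a complete balanced factorial in its varying design factors.
#' @param outcome Column to analyse: `"power"`, `"convergence_rate"` or
#'   `"singularity_rate"`.
#' @param include_two_way Include all pairwise factor interactions.  Default
#'   follows the reporting convention of this package's reference analysis:
#'   two-way terms for power, main effects only otherwise.
#' @return A data frame with one row per model term plus the residual:
#'   `term`, `df`, `sum_sq`, `F`, `p`, `eta_squared`.  The `eta_squared`
#'   column sums to 1 (including the residual row).
#' @export
anova_eta2 <- function(summaries,
                       outcome = c("power", "convergence_rate",
                                   "singularity_rate"),
                       include_two_way = NULL) {
  outcome <- match.arg(outcome)
  if (!outcome %in% names(summaries)) {
    stop("summaries has no column '", outcome, "'")
  }
  if (is.null(include_two_way)) include_two_way <- outcome == "power"
  factors <- active_factors(summaries)
  check_balanced_factorial(summaries, factors)

  d <- summaries
  for (f in factors) d[[f]] <- factor(d[[f]])
  d$.y <- d[[outcome]]
  rhs <- paste(factors, collapse = " + ")
  if (include_two_way && length(factors) > 1L) {
    rhs <- sprintf("(%s)^2", rhs)
  }
  fit <- stats::aov(stats::as.formula(paste(".y ~", rhs)), data = d)
  tab <- summary(fit)[[1L]]
  term <- trimws(rownames(tab))
  ss <- tab[["Sum Sq"]]
  ss_total <- sum(ss)
  # a constant outcome leaves only rounding noise in the sums of squares
  degenerate <- ss_total <= 1e-20 * max(1, sum(d$.y^2))
  eta <- if (degenerate) rep(0, length(ss)) else ss / ss_total
  # a saturated model (zero residual df) has no F or p columns
  fval <- if (is.null(tab[["F value"]])) rep(NA_real_, length(ss)) else
    tab[["F value"]]
  pval <- if (is.null(tab[["Pr(>F)"]])) rep(NA_real_, length(ss)) else
    tab[["Pr(>F)"]]
  out <- data.frame(term = term, df = tab[["Df"]], sum_sq = ss,
                    F = fval, p = pval,
                    eta_squared = eta, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Tukey HSD post-hoc comparisons for one design factor
#'
#' All pairwise comparisons of the levels of a design factor on a
#' condition-level outcome, using the studentized range distribution with
#' the residual mean square of the main-effects ANOVA over all varying
#' design factors.  Family-wise error is controlled at `alpha`.
#'
#' @inheritParams anova_eta2
#' @param factor_name The design factor to compare (must have >= 2 levels).
#' @param alpha Family-wise error rate.
#' @return A data frame with one row per level pair: `factor`,
#'   `level_pair` (higher level first, as `"b-a"`), `mean_difference`,
#'   `lwr`, `upr`, `adjusted_p`, `significant`.
#' @export
tukey_hsd <- function(summaries, factor_name,
                      outcome = c("power", "convergence_rate",
                                  "singularity_rate"),
                      alpha = 0.05) {
  outcome <- match.arg(outcome)
  factors <- active_factors(summaries)
  if (!factor_name %in% names(summaries)) {
    stop("summaries has no column '", factor_name, "'")
  }
  if (length(unique(summaries[[factor_name]])) < 2L) {
    stop("factor '", factor_name, "' has fewer than two levels")
  }
  factors <- union(factors, factor_name)
  check_balanced_factorial(summaries, factors)

  d <- summaries
  for (f in factors) d[[f]] <- factor(d[[f]])
  d$.y <- d[[outcome]]
  fit <- stats::aov(stats::as.formula(
    paste(".y ~", paste(factors, collapse = " + "))), data = d)
  tk <- stats::TukeyHSD(fit, which = factor_name, conf.level = 1 - alpha)
  tab <- tk[[factor_name]]
  padj <- tab[, "p adj"]
  # zero residual mean square makes the studentized range 0/0 (constant
  # outcome) or infinite (exact group separation); resolve by the size of
  # the observed mean difference
  scale2 <- 1e-20 * max(1, sum(d$.y^2))
  if (sum(stats::residuals(fit)^2) <= scale2) {
    padj <- ifelse(abs(tab[, "diff"]) <= sqrt(scale2), 1, 0)
  }
  out <- data.frame(factor = factor_name,
                    level_pair = rownames(tab),
                    mean_difference = tab[, "diff"],
                    lwr = tab[, "lwr"], upr = tab[, "upr"],
                    adjusted_p = padj,
                    significant = padj < alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Percentage of conditions meeting a predicate, by design slice
#'
#' Summarizes how often a condition-level outcome satisfies a predicate
#' (e.g. power below 0.8: "underpowered") within each combination of the
#' requested slicing factors.  Slices defined by the cross of observed
#' factor levels that contain no conditions are reported with `NA`
#' percentage rather than zero.
#'
#' @inheritParams anova_eta2
#' @param outcome Name of the outcome column.
#' @param predicate Either a function mapping the outcome vector to a
#'   logical vector, or a numeric threshold used with `direction`.
#' @param direction When `predicate` is a threshold: `"below"` counts
#'   `outcome < predicate`, `"above"` counts `outcome > predicate`.
#' @param slice_factors Character vector of design factor columns to slice
#'   by; empty for a single overall percentage.
#' @return A data frame with the slice factors, `n` (conditions in slice)
#'   and `percent` (0-100).
#' @export
threshold_percentages <- function(summaries, outcome, predicate,
                                  direction = c("below", "above"),
                                  slice_factors = character(0)) {
  if (!outcome %in% names(summaries)) {
    stop("summaries has no column '", outcome, "'")
  }
  if (is.function(predicate)) {
    hit <- predicate(summaries[[outcome]])
  } else {
    direction <- match.arg(direction)
    hit <- if (direction == "below") summaries[[outcome]] < predicate
    else summaries[[outcome]] > predicate
  }
  if (!length(slice_factors)) {
    return(data.frame(n = length(hit), percent = 100 * mean(hit)))
  }
  missing <- setdiff(slice_factors, names(summaries))
  if (length(missing)) {
    stop("summaries has no column(s): ", paste(missing, collapse = ", "))
  }
  d <- summaries[slice_factors]
  d$.hit <- as.numeric(hit)
  agg_n <- stats::aggregate(d$.hit, by = d[slice_factors], FUN = length)
  agg_p <- stats::aggregate(d$.hit, by = d[slice_factors], FUN = mean)
  obs <- agg_n[slice_factors]
  obs$n <- agg_n$x
  obs$percent <- 100 * agg_p$x
  full <- expand.grid(lapply(summaries[slice_factors], function(x)
    sort(unique(x))), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- merge(full, obs, by = slice_factors, all.x = TRUE, sort = TRUE)
  out$n[is.na(out$n)] <- 0L
  out
}
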