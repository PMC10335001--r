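#' Population parameters for the three-level generative model
#'
#' Bundles the eight fixed-effect coefficients and the five variance and
#' covariance parameters of the three-level (occasion within student within
#' classroom) longitudinal model
#' \deqn{Y_{tij} = \gamma_{000} + \gamma_{001}Trt_j + \gamma_{010}Apt_{ij}
#'   + \gamma_{100}Time_{tij} + \gamma_{011}Trt_jApt_{ij}
#'   + \gamma_{101}Trt_jTime_{tij} + \gamma_{110}Apt_{ij}Time_{tij}
#'   + \gamma_{111}Trt_jApt_{ij}Time_{tij}
#'   + u_{00j} + r_{0ij} + r_{1ij}Time_{tij} + e_{tij}}
#' with \eqn{u_{00j} \sim N(0, \tau_{\beta 00})} per classroom,
#' \eqn{(r_{0ij}, r_{1ij}) \sim N_2(0, T_\pi)} per student and
#' \eqn{e_{tij} \sim N(0, \sigma^2)} per occasion.
#'
#' Defaults are the reference study conditions used throughout the package:
#' a small treatment main effect, a strong aptitude effect, moderate growth,
#' and an IQ-like aptitude scale (mean 0, SD 15).  `gamma101` (the
#' treatment-by-time coefficient) and `tau_beta00` (the classroom intercept
#' variance) are condition-dependent and default to `NA`; use
#' [resolve_params()] to fill them from a design condition.
#'
#' @param gamma000,gamma001,gamma010,gamma011,gamma100,gamma101,gamma110,gamma111
#'   Fixed-effect coefficients, ordered intercept, treatment, aptitude, time,
#'   treatment:aptitude, treatment:time, aptitude:time,
#'   treatment:aptitude:time.
#' @param sigma2_e Occasion-level residual variance (>= 0; zero only for
#'   degenerate noise-free data used to check exact recovery).
#' @param tau_pi00,tau_pi01,tau_pi11 Student-level intercept variance,
#'   intercept-slope covariance and time-slope variance; the implied 2x2
#'   matrix must be positive semi-definite.
#' @param tau_beta00 Classroom-level intercept variance (>= 0, or `NA` until
#'   resolved from an ICC).
#' @param aptitude_mean,aptitude_sd Mean and standard deviation of the
#'   per-student aptitude/skill covariate.
#'
#' @return An object of class `"pop_params"` (a named list).
#' @seealso [resolve_params()], [simulate_dataset()]
#' @export
#' @examples
#' p <- pop_params()
#' p$gamma110
pop_params <- function(gamma000 = 0, gamma001 = 0.1, gamma010 = 0.5,
                       gamma011 = 0.3, gamma100 = 0.1, gamma101 = NA_real_,
                       gamma110 = 0.5, gamma111 = 0.1,
                       sigma2_e = 1.0, tau_pi00 = 0.2, tau_pi01 = 0.05,
                       tau_pi11 = 0.1, tau_beta00 = NA_real_,
                       aptitude_mean = 0, aptitude_sd = 15) {
  p <- list(gamma000 = gamma000, gamma001 = gamma001, gamma010 = gamma010,
            gamma011 = gamma011, gamma100 = gamma100, gamma101 = gamma101,
            gamma110 = gamma110, gamma111 = gamma111,
            sigma2_e = sigma2_e, tau_pi00 = tau_pi00, tau_pi01 = tau_pi01,
            tau_pi11 = tau_pi11, tau_beta00 = tau_beta00,
            aptitude_mean = aptitude_mean, aptitude_sd = aptitude_sd)
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L, logical(1))
  if (!all(num)) {
    stop("all population parameters must be single numeric values: ",
         paste(names(p)[!num], collapse = ", "))
  }
  if (sigma2_e < 0) stop("sigma2_e must be >= 0")
  if (tau_pi00 < 0 || tau_pi11 < 0) {
    stop("tau_pi00 and tau_pi11 must be >= 0")
  }
  if (tau_pi00 * tau_pi11 - tau_pi01^2 < -1e-12) {
    stop("student random-effect matrix T_pi is not positive semi-definite")
  }
  if (!is.na(tau_beta00) && tau_beta00 < 0) stop("tau_beta00 must be >= 0")
  if (aptitude_sd <= 0) stop("aptitude_sd must be > 0")
  structure(p, class = "pop_params")
}

#' @export
print.pop_params <- function(x, ...) {
  cat("Three-level population parameters\n")
  cat("  fixed effects:\n")
  fe <- unlist(x[1:8])
  print(fe)
  cat("  variance components: sigma2_e =", x$sigma2_e,
      " tau_pi = [", x$tau_pi00, x$tau_pi01, ";", x$tau_pi01, x$tau_pi11, "]",
      " tau_beta00 =", x$tau_beta00, "\n")
  cat("  aptitude ~ N(", x$aptitude_mean, ",", x$aptitude_sd, "^2 )\n")
  invisible(x)
}

#' Convert an intraclass correlation to the classroom intercept variance
#'
#' The classroom-level (level-3) ICC of the model is
#' \eqn{ICC = \tau_{\beta 00} / (\sigma^2 + \tau_{\pi 00} + \tau_{\beta 00})},
#' the share of outcome variance at time 0 attributable to classrooms.
#' Inverting for the classroom intercept variance gives
#' \eqn{\tau_{\beta 00} = ICC (\sigma^2 + \tau_{\pi 00}) / (1 - ICC)}.
#'
#' @param icc Intraclass correlation, in `[0, 1)`.  Vectorized.
#' @param sigma2_e Occasion-level residual variance (> 0).
#' @param tau_pi00 Student-level intercept variance (>= 0).
#' @return The implied classroom intercept variance `tau_beta00`.
#' @seealso [icc_from_tau_beta00()] for the inverse.
#' @export
#' @examples
#' icc_to_tau_beta00(0.2, 1.0, 0.2)  # 0.3
icc_to_tau_beta00 <- function(icc, sigma2_e = 1.0, tau_pi00 = 0.2) {
  if (any(!is.finite(icc)) || any(icc < 0) || any(icc >= 1)) {
    stop("icc must lie in [0, 1)")
  }
  if (sigma2_e <= 0) stop("sigma2_e must be > 0")
  if (tau_pi00 < 0) stop("tau_pi00 must be >= 0")
  icc * (sigma2_e + tau_pi00) / (1 - icc)
}

#' Intraclass correlation implied by a classroom intercept variance
#'
#' Inverse of [icc_to_tau_beta00()]:
#' \eqn{ICC = \tau_{\beta 00} / (\sigma^2 + \tau_{\pi 00} + \tau_{\beta 00})}.
#'
#' @param tau_beta00 Classroom intercept variance (>= 0). Vectorized.
#' @inheritParams icc_to_tau_beta00
#' @return The implied ICC.
#' @export
icc_from_tau_beta00 <- function(tau_beta00, sigma2_e = 1.0, tau_pi00 = 0.2) {
  if (any(tau_beta00 < 0)) stop("tau_beta00 must be >= 0")
  if (sigma2_e <= 0) stop("sigma2_e must be > 0")
  if (tau_pi00 < 0) stop("tau_pi00 must be >= 0")
  tau_beta00 / (sigma2_e + tau_pi00 + tau_beta00)
}

#' Map an effect-size label to the treatment-by-time coefficient
#'
#' The size of the slopes difference is controlled through the
#' treatment-by-time coefficient `gamma101`.  With the three-way coefficient
#' held at `gamma111 = 0.1` and aptitude conditioned at -1, the
#' treatment-minus-control difference in time slopes is
#' `gamma101 - gamma111`, so labels map as small -> 0.2 (difference 0.1),
#' medium -> 0.4 (difference 0.3) and large -> 0.6 (difference 0.5).
#'
#' @param effect_label `"small"`, `"medium"` or `"large"`. Vectorized.
#' @return The corresponding `gamma101` value(s).
#' @export
#' @examples
#' effect_to_gamma101(c("small", "large"))
effect_to_gamma101 <- function(effect_label) {
  map <- c(small = 0.2, medium = 0.4, large = 0.6)
  if (!is.character(effect_label) && !is.factor(effect_label)) {
    stop("effect_label must be a character vector")
  }
  lab <- as.character(effect_label)
  bad <- !(lab %in% names(map))
  if (any(bad)) {
    stop("unknown effect_label: ", paste(unique(lab[bad]), collapse = ", "),
         " (expected small, medium or large)")
  }
  unname(map[lab])
}

#' Centered, unit-spaced wave codings
#'
#' Measurement waves are coded as equally spaced time scores with spacing one
#' and mean zero: three waves give (-1, 0, 1), four give
#' (-1.5, -0.5, 0.5, 1.5), five give (-2, -1, 0, 1, 2).
#'
#' @param n_waves Number of waves (integer >= 2).
#' @return Numeric vector of length `n_waves`.
#' @export
wave_times <- function(n_waves) {
  if (length(n_waves) != 1L || !is.finite(n_waves) ||
      n_waves != round(n_waves) || n_waves < 2) {
    stop("n_waves must be a single integer >= 2")
  }
  t <- seq_len(n_waves) - 1
  t - mean(t)
}

#' Factor levels of the reference factorial design
#'
#' The full design crosses 3 wave counts x 3 class sizes x 4 classroom
#' counts x 2 treatment proportions x 3 ICCs x 3 effect sizes = 648
#' conditions.
#'
#' @return Named list of factor levels, in the order used by [build_grid()].
#' @export
default_factor_levels <- function() {
  list(n_waves        = c(3L, 4L, 5L),
       class_size     = c(10L, 20L, 30L),
       n_classrooms   = c(20L, 30L, 40L, 50L),
       prop_treatment = c(0.5, 0.3),
       icc            = c(0.086, 0.113, 0.2),
       effect_label   = c("small", "medium", "large"))
}

#' Enumerate the factorial design grid
#'
#' Builds the Cartesian product of the supplied factor levels as a data frame
#' of design conditions.  Enumeration order is deterministic: nested loops
#' with `n_waves` outermost and `effect_label` innermost (i.e. `effect_label`
#' varies fastest, then `icc`, `prop_treatment`, `n_classrooms`,
#' `class_size`, `n_waves`), and `condition_index` runs 1..N in that order.
#'
#' @param factor_levels Named list with elements `n_waves`, `class_size`,
#'   `n_classrooms`, `prop_treatment`, `icc`, `effect_label`, each a
#'   non-empty vector of levels.  Defaults to [default_factor_levels()].
#' @return A data frame of class `"design_grid"` with one row per condition
#'   and columns `condition_index` plus the six design factors.
#' @export
#' @examples
#' nrow(build_grid())  # 648
build_grid <- function(factor_levels = default_factor_levels()) {
  needed <- names(default_factor_levels())
  missing <- setdiff(needed, names(factor_levels))
  if (length(missing)) {
    stop("factor_levels is missing: ", paste(missing, collapse = ", "))
  }
  lens <- vapply(factor_levels[needed], length, integer(1))
  if (any(lens == 0L)) {
    stop("every factor needs at least one level; empty: ",
         paste(needed[lens == 0L], collapse = ", "))
  }
  if (any(factor_levels$n_waves < 2)) stop("n_waves levels must be >= 2")
  if (any(factor_levels$class_size < 1) || any(factor_levels$n_classrooms < 1)) {
    stop("class_size and n_classrooms levels must be >= 1")
  }
  pt <- factor_levels$prop_treatment
  if (any(pt <= 0 | pt >= 1)) stop("prop_treatment levels must be in (0, 1)")
  if (any(factor_levels$icc < 0 | factor_levels$icc >= 1)) {
    stop("icc levels must be in [0, 1)")
  }
  effect_to_gamma101(factor_levels$effect_label)  # validates labels

  # expand.grid varies its first argument fastest -> list factors from
  # innermost to outermost, then restore the documented column order
  g <- expand.grid(effect_label   = factor_levels$effect_label,
                   icc            = factor_levels$icc,
                   prop_treatment = factor_levels$prop_treatment,
                   n_classrooms   = factor_levels$n_classrooms,
                   class_size     = factor_levels$class_size,
                   n_waves        = factor_levels$n_waves,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, rev(names(g))]
  g <- cbind(condition_index = seq_len(nrow(g)), g)
  rownames(g) <- NULL
  class(g) <- c("design_grid", "data.frame")
  g
}

#' Resolve condition-dependent population parameters
#'
#' Returns a copy of `base` with `gamma101` set from the condition's effect
#' size label and `tau_beta00` set from its ICC (using the base residual and
#' student intercept variances); all other parameters are unchanged.
#' Resolving an already-resolved parameter set with the same condition is
#' idempotent.
#'
#' @param condition A single design condition: one row of a grid from
#'   [build_grid()], or a list with at least `icc` and `effect_label`.
#' @param base Base [pop_params()] holding the condition-independent values.
#' @return A fully resolved `"pop_params"` object.
#' @export
resolve_params <- function(condition, base = pop_params()) {
  condition <- as_condition(condition)
  p <- unclass(base)
  p$gamma101 <- effect_to_gamma101(condition$effect_label)
  p$tau_beta00 <- icc_to_tau_beta00(condition$icc, p$sigma2_e, p$tau_pi00)
  do.call(pop_params, p)
}

# normalize a one-row grid slice / list into a plain condition list
as_condition <- function(condition) {
  if (is.data.frame(condition)) {
    if (nrow(condition) != 1L) {
      stop("condition must be a single design condition (one row)")
    }
    condition <- as.list(condition)
  }
  if (!is.list(condition)) stop("condition must be a list or one-row data frame")
  for (f in c("icc", "effect_label")) {
    if (is.null(condition[[f]])) stop("condition is missing '", f, "'")
  }
  condition
}
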