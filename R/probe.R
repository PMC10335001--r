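# fixed-effect positions in the canonical coefficient ordering
.fe <- c(intercept = 1L, treatment = 2L, aptitude = 3L, time = 4L,
         trt_apt = 5L, trt_time = 6L, apt_time = 7L, trt_apt_time = 8L)

new_probe <- function(kind, estimate, se, df, alpha, conditioning,
                      mode = NULL) {
  if (!is.finite(se) || se <= 0) stop("computed standard error is not positive")
  t <- estimate / se
  p <- if (is.infinite(df)) 2 * stats::pnorm(-abs(t)) else
    2 * stats::pt(-abs(t), df)
  structure(list(kind = kind, estimate = estimate, se = se, t = t, df = df,
                 p = p, significant = p < alpha, alpha = alpha,
                 conditioning = conditioning, mode = mode),
            class = "sdt_probe")
}

check_converged <- function(fit) {
  if (!isTRUE(fit$converged)) {
    stop("model did not converge; probing refused (diagnostics: ",
         paste(fit$diagnostics$messages, collapse = "; "), ")")
  }
}

probe_df <- function(fit, df_policy) {
  df_policy <- match.arg(df_policy, c("normal", "residual"))
  if (df_policy == "normal") Inf else fit$n_obs - 8 - 1
}

#' Omnibus test of the three-way cross-level interaction
#'
#' Tests the treatment-by-aptitude-by-time coefficient against zero with the
#' critical ratio `t = estimate / SE`, the standard omnibus check that an
#' aptitude-by-treatment interaction on growth exists at all.
#'
#' @param fit A converged `"sdt_fit"` from [fit_lmm()].
#' @param alpha Two-sided significance level.
#' @param df_policy `"normal"` (default) refers the ratio to the standard
#'   normal; `"residual"` uses a t reference with `n_obs - 9` degrees of
#'   freedom, the single-level regression convention.  At the sample sizes
#'   this package simulates the two are practically identical.
#' @return An `"sdt_probe"` with the estimate, standard error, t, df, p and
#'   significance flag.
#' @export
omnibus_interaction_test <- function(fit, alpha = 0.05,
                                     df_policy = "normal") {
  check_converged(fit)
  i <- .fe[["trt_apt_time"]]
  new_probe("omnibus",
            estimate = unname(fit$beta_hat[i]),
            se = sqrt(fit$vcov_beta[i, i]),
            df = probe_df(fit, df_policy), alpha = alpha,
            conditioning = list())
}

#' Simple slope of time at given moderator values
#'
#' The conditional (simple) slope of the outcome on time at aptitude `a` and
#' treatment arm `w` is the compound coefficient
#' `gamma100 + gamma101 w + gamma110 a + gamma111 a w`; its standard error
#' comes from the corresponding rows and columns of the fixed-effect
#' covariance matrix (delta method with a linear combination).
#'
#' @param fit A converged `"sdt_fit"`.
#' @param aptitude_value Conditioning value for aptitude (raw units).
#' @param treatment_value 0 (control) or 1 (treatment).
#' @inheritParams omnibus_interaction_test
#' @return An `"sdt_probe"`.
#' @export
simple_slope <- function(fit, aptitude_value, treatment_value,
                         alpha = 0.05, df_policy = "normal") {
  check_converged(fit)
  if (!treatment_value %in% c(0, 1)) stop("treatment_value must be 0 or 1")
  a <- aptitude_value; w <- treatment_value
  cvec <- numeric(8)
  cvec[.fe[["time"]]] <- 1
  cvec[.fe[["trt_time"]]] <- w
  cvec[.fe[["apt_time"]]] <- a
  cvec[.fe[["trt_apt_time"]]] <- a * w
  new_probe("simple_slope",
            estimate = sum(cvec * fit$beta_hat),
            se = sqrt(drop(cvec %*% fit$vcov_beta %*% cvec)),
            df = probe_df(fit, df_policy), alpha = alpha,
            conditioning = list(aptitude = a, treatment = w))
}

#' Slopes difference test for the treatment-control growth contrast
#'
#' Tests whether the time slopes of the treatment and control arms differ at
#' a low conditioning value of aptitude.  At aptitude `a`, the
#' treatment-minus-control difference in simple slopes is
#' `gamma101 + a * gamma111`; at the default `a = -1` this is
#' `gamma101 - gamma111`.
#'
#' Two variance conventions are provided:
#' \describe{
#'   \item{`"as_printed"` (default)}{the test exactly as published for this
#'     setting: `t = (g101 - g111) / sqrt(var(g101) + var(g111) +
#'     2 cov(g101, g111))`, with the covariance term *added*.}
#'   \item{`"delta_method"`}{the general conditional-contrast variance:
#'     `estimate = g101 + a g111`, `se^2 = var(g101) + a^2 var(g111) +
#'     2 a cov(g101, g111)`; at `a = -1` the covariance term enters with the
#'     opposite sign to `"as_printed"`.}
#' }
#' The two agree exactly when the estimated covariance is zero, which it
#' nearly is when aptitude is centered; both are exposed rather than
#' guessing which convention a given published analysis used.
#'
#' @param fit A converged `"sdt_fit"`.
#' @param aptitude_value Conditioning value of aptitude, default -1
#'   ("low"); used by the `"delta_method"` mode (the `"as_printed"` formula
#'   is fixed at the `a = -1` contrast).
#' @param mode `"as_printed"` or `"delta_method"`.
#' @inheritParams omnibus_interaction_test
#' @return An `"sdt_probe"`; `$significant` is `p < alpha` (two-sided).
#' @export
slopes_difference_test <- function(fit, aptitude_value = -1,
                                   mode = c("as_printed", "delta_method"),
                                   alpha = 0.05, df_policy = "normal") {
  check_converged(fit)
  mode <- match.arg(mode)
  i <- .fe[["trt_time"]]; j <- .fe[["trt_apt_time"]]
  b <- fit$beta_hat; V <- fit$vcov_beta
  if (mode == "as_printed") {
    estimate <- unname(b[i] - b[j])
    var_est <- V[i, i] + V[j, j] + 2 * V[i, j]
  } else {
    a <- aptitude_value
    estimate <- unname(b[i] + a * b[j])
    var_est <- V[i, i] + a^2 * V[j, j] + 2 * a * V[i, j]
  }
  if (!is.finite(var_est) || var_est < 0) {
    stop("computed variance of the slopes difference is negative")
  }
  new_probe("slopes_difference", estimate = estimate, se = sqrt(var_est),
            df = probe_df(fit, df_policy), alpha = alpha,
            conditioning = list(aptitude = aptitude_value,
                                treatment = c(0, 1)),
            mode = mode)
}

#' @export
print.sdt_probe <- function(x, ...) {
  cat(sprintf("%s test: estimate = %.5g, se = %.5g, t = %.4g, df = %s, p = %.4g%s\n",
              x$kind, x$estimate, x$se, x$t,
              if (is.infinite(x$df)) "Inf" else format(x$df),
              x$p, if (isTRUE(x$significant)) " *" else ""))
  if (length(x$conditioning)) {
    cat("  conditioning:",
        paste(names(x$conditioning),
              vapply(x$conditioning, function(v) paste(v, collapse = "/"),
                     character(1)),
              sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}
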