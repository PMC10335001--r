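#' Fit the three-level analysis model by REML
#'
#' Fits the analysis model matching the generative structure: fixed effects
#' `y ~ treatment * aptitude * time`, a random intercept and time slope per
#' student (with free covariance) and a random intercept per classroom.
#' Estimation is restricted maximum likelihood via [lme4::lmer()], which
#' profiles the residual variance and optimizes over the Cholesky factor of
#' the relative covariance matrices, so boundary (singular) solutions are
#' returned rather than failing.
#'
#' Convergence is judged by the package's own criterion, not lme4's
#' warnings: the optimizer must report success and the Newton-scaled
#' gradient of the profiled deviance, `max |H^-1 g|`, must not exceed
#' `grad_tol`.  Singularity is judged by [is_singular_fit()] at tolerance
#' `singular_tol`.
#'
#' @param dataset A long-format dataset (see [simulate_dataset()],
#'   [read_dataset()]); must contain at least two classrooms per arm and at
#'   least two waves.
#' @param reml Use REML (default) rather than ML.
#' @param grad_tol Convergence tolerance on the scaled gradient (default
#'   2e-3, the convention of the mixed-model software family this package
#'   targets).
#' @param singular_tol Boundary tolerance passed to [is_singular_fit()].
#' @param keep_model Keep the underlying `merMod` object in the result
#'   (`$model`); off by default to keep Monte Carlo replications light.
#'
#' @return An object of class `"sdt_fit"` with elements `beta_hat` (named,
#'   ordered intercept, treatment, aptitude, time, treatment:aptitude,
#'   treatment:time, aptitude:time, treatment:aptitude:time), `vcov_beta`
#'   (8x8), `sigma2_hat`, `tau_pi00_hat`, `tau_pi01_hat`, `tau_pi11_hat`,
#'   `tau_beta00_hat`, `reml_criterion` (-2 restricted log-likelihood),
#'   `converged`, `singular`, `n_obs`, `n_students`, `n_classrooms` and a
#'   `diagnostics` list (optimizer, status code, scaled gradient norm,
#'   function evaluations, messages).
#' @export
fit_lmm <- function(dataset, reml = TRUE, grad_tol = 2e-3,
                    singular_tol = 1e-4, keep_model = FALSE) {
  validate_dataset(dataset)
  d <- data.frame(y = dataset$y,
                  treatment = dataset$treatment,
                  aptitude = dataset$aptitude,
                  time = dataset$time,
                  .student = factor(paste(dataset$classroom, dataset$student,
                                          sep = ":")),
                  .classroom = factor(dataset$classroom))
  arm_counts <- table(tapply(d$treatment, d$.classroom, `[`, 1L))
  if (length(arm_counts) < 2L || any(arm_counts < 2L)) {
    stop("estimation requires at least two classrooms in each arm")
  }

  # Degenerate input: if the fixed part interpolates the outcome exactly
  # (all generating variances zero), the mixed-model likelihood is flat in
  # the confounded directions and GLS coefficients are not unique.  The
  # unique exact solution is ordinary least squares with all variance
  # components at the boundary; return that directly.
  ols <- stats::lm(y ~ treatment * aptitude * time, data = d)
  rss <- sum(stats::residuals(ols)^2)
  if (rss <= 1e-10 * max(1, sum(d$y^2)) && ols$rank == 8L) {
    V0 <- matrix(0, 8L, 8L, dimnames = list(names(stats::coef(ols)),
                                            names(stats::coef(ols))))
    res <- structure(list(
      beta_hat = stats::coef(ols), vcov_beta = V0,
      sigma2_hat = rss / stats::df.residual(ols),
      tau_pi00_hat = 0, tau_pi01_hat = 0, tau_pi11_hat = 0,
      tau_beta00_hat = 0, reml_criterion = -Inf,
      converged = TRUE, singular = TRUE,
      n_obs = nrow(d), n_students = nlevels(d$.student),
      n_classrooms = nlevels(d$.classroom),
      diagnostics = list(optimizer = "ols-degenerate", conv_code = 0L,
                         grad_norm = 0, feval = 0L,
                         messages = "outcome is an exact linear function of the fixed part")
    ), class = "sdt_fit")
    return(res)
  }

  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            check.conv.hess = "ignore",
                            calc.derivs = TRUE)
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(y ~ treatment * aptitude * time +
                 (time | .student) + (1 | .classroom),
               data = d, REML = reml, control = ctrl),
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    },
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    })

  beta <- lme4::fixef(fit)
  if (length(beta) != 8L) {
    stop("rank-deficient fixed-effect design: estimated ", length(beta),
         " of 8 coefficients")
  }
  V <- as.matrix(stats::vcov(fit))
  dimnames(V) <- list(names(beta), names(beta))

  vc <- lme4::VarCorr(fit)
  Tpi <- matrix(vc$.student, 2L, 2L)
  sigma2 <- stats::sigma(fit)^2

  opt <- fit@optinfo
  grad_norm <- Inf
  if (!is.null(opt$derivs)) {
    grad_norm <- tryCatch(
      max(abs(solve(opt$derivs$Hessian, opt$derivs$gradient))),
      error = function(e) Inf)
  }
  converged <- identical(as.integer(opt$conv$opt), 0L) &&
    is.finite(grad_norm) && grad_norm <= grad_tol

  res <- structure(list(
    beta_hat = beta,
    vcov_beta = V,
    sigma2_hat = sigma2,
    tau_pi00_hat = Tpi[1L, 1L],
    tau_pi01_hat = Tpi[1L, 2L],
    tau_pi11_hat = Tpi[2L, 2L],
    tau_beta00_hat = as.numeric(vc$.classroom[1L, 1L]),
    reml_criterion = if (reml) lme4::REMLcrit(fit) else
      -2 * as.numeric(stats::logLik(fit)),
    converged = converged,
    singular = NA,
    n_obs = nrow(d),
    n_students = nlevels(d$.student),
    n_classrooms = nlevels(d$.classroom),
    diagnostics = list(optimizer = opt$optimizer,
                       conv_code = as.integer(opt$conv$opt),
                       grad_norm = grad_norm,
                       feval = opt$feval,
                       messages = msgs)
  ), class = "sdt_fit")
  res$singular <- is_singular_fit(res, tol = singular_tol)
  if (keep_model) res$model <- fit
  res
}

#' Is a mixed-model fit on the boundary of the variance parameter space?
#'
#' A fit is flagged singular when any random-effect standard deviation is at
#' (or numerically indistinguishable from) zero relative to the residual
#' scale, or when the student intercept-slope correlation is at +/-1.
#' Concretely, with `s = sqrt(sigma2_hat)`, the checks are
#' `sqrt(tau_pi00)/s <= tol`, conditional slope SD
#' `sqrt(tau_pi11 (1 - rho^2))/s <= tol`, `sqrt(tau_beta00)/s <= tol`, or
#' `|rho| >= 1 - tol` -- equivalently, a zero on the diagonal of the scaled
#' Cholesky factor the optimizer works on.
#'
#' @param fit An `"sdt_fit"` object (or any list carrying `sigma2_hat`,
#'   `tau_pi00_hat`, `tau_pi01_hat`, `tau_pi11_hat`, `tau_beta00_hat`).
#' @param tol Boundary tolerance (default 1e-4).
#' @return `TRUE` if the fit is singular.
#' @export
is_singular_fit <- function(fit, tol = 1e-4) {
  s2 <- fit$sigma2_hat
  if (!is.finite(s2) || s2 <= 0) return(TRUE)
  t00 <- max(fit$tau_pi00_hat, 0)
  t11 <- max(fit$tau_pi11_hat, 0)
  tb <- max(fit$tau_beta00_hat, 0)
  d1 <- sqrt(t00 / s2)
  if (t00 > 0) {
    cond <- max(0, t11 - fit$tau_pi01_hat^2 / t00)
  } else {
    cond <- t11
  }
  d2 <- sqrt(cond / s2)
  d3 <- sqrt(tb / s2)
  rho <- if (t00 > 0 && t11 > 0) fit$tau_pi01_hat / sqrt(t00 * t11) else 0
  min(d1, d2, d3) <= tol || abs(rho) >= 1 - tol
}

#' @export
print.sdt_fit <- function(x, ...) {
  cat("Three-level REML fit (", x$n_obs, " occasions, ", x$n_students,
      " students, ", x$n_classrooms, " classrooms)\n", sep = "")
  cat("  -2 restricted logLik:", format(x$reml_criterion), "\n")
  cat("  converged:", x$converged, " singular:", x$singular, "\n")
  cat("  fixed effects:\n")
  print(round(x$beta_hat, 4))
  cat("  variance components: sigma2 =", signif(x$sigma2_hat, 4),
      " tau_pi00 =", signif(x$tau_pi00_hat, 4),
      " tau_pi01 =", signif(x$tau_pi01_hat, 4),
      " tau_pi11 =", signif(x$tau_pi11_hat, 4),
      " tau_beta00 =", signif(x$tau_beta00_hat, 4), "\n")
  invisible(x)
}

#' Serialize a fit summary to JSON
#'
#' Writes estimates, the fixed-effect covariance matrix, variance
#' components, flags and optimizer diagnostics as a structured JSON file.
#'
#' @param fit An `"sdt_fit"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  out <- unclass(fit)
  out$model <- NULL
  out$beta_hat <- as.list(fit$beta_hat)
  out$vcov_beta <- unname(apply(fit$vcov_beta, 1L, as.vector, simplify = FALSE))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
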