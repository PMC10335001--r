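# shared fixtures and an independent REML oracle for the test suite

# a small design condition; override fields as needed
small_condition <- function(n_waves = 3L, class_size = 4L, n_classrooms = 6L,
                            prop_treatment = 0.5, icc = 0.113,
                            effect_label = "small", condition_index = 1L) {
  list(condition_index = condition_index, n_waves = n_waves,
       class_size = class_size, n_classrooms = n_classrooms,
       prop_treatment = prop_treatment, icc = icc,
       effect_label = effect_label)
}

# hand-built fit object for exercising the probe statistics without lme4
stub_fit <- function(beta = rep(0, 8), vcov = diag(8) * 0.01,
                     converged = TRUE, sigma2 = 1, tau_pi00 = 0.2,
                     tau_pi01 = 0.05, tau_pi11 = 0.1, tau_beta00 = 0.3,
                     n_obs = 600L) {
  names(beta) <- c("(Intercept)", "treatment", "aptitude", "time",
                   "treatment:aptitude", "treatment:time", "aptitude:time",
                   "treatment:aptitude:time")
  structure(list(beta_hat = beta, vcov_beta = vcov, sigma2_hat = sigma2,
                 tau_pi00_hat = tau_pi00, tau_pi01_hat = tau_pi01,
                 tau_pi11_hat = tau_pi11, tau_beta00_hat = tau_beta00,
                 converged = converged, singular = FALSE, n_obs = n_obs,
                 diagnostics = list(messages = character(0))),
            class = "sdt_fit")
}

# Independent dense evaluation of -2 x restricted log-likelihood for the
# three-level model.  Builds V = Z G Z' + sigma2 I explicitly and uses the
# textbook REML expression; deliberately shares no code with fit_lmm().
oracle_neg2_reml <- function(dataset, sigma2, tau_pi00, tau_pi01, tau_pi11,
                             tau_beta00) {
  d <- as.data.frame(dataset)
  X <- stats::model.matrix(~ treatment * aptitude * time, d)
  n <- nrow(X); p <- ncol(X)
  skey <- paste(d$classroom, d$student)
  sid <- match(skey, unique(skey))
  cid <- match(d$classroom, unique(d$classroom))
  ns <- max(sid); nc <- max(cid)
  Z <- matrix(0, n, 2L * ns + nc)
  for (i in seq_len(n)) {
    Z[i, 2L * sid[i] - 1L] <- 1
    Z[i, 2L * sid[i]] <- d$time[i]
    Z[i, 2L * ns + cid[i]] <- 1
  }
  G <- matrix(0, 2L * ns + nc, 2L * ns + nc)
  for (s in seq_len(ns)) {
    G[2L * s - 1L, 2L * s - 1L] <- tau_pi00
    G[2L * s, 2L * s] <- tau_pi11
    G[2L * s - 1L, 2L * s] <- tau_pi01
    G[2L * s, 2L * s - 1L] <- tau_pi01
  }
  for (j in seq_len(nc)) G[2L * ns + j, 2L * ns + j] <- tau_beta00
  V <- Z %*% G %*% t(Z) + sigma2 * diag(n)
  cV <- chol(V)
  Vi <- chol2inv(cV)
  XtViX <- t(X) %*% Vi %*% X
  b <- solve(XtViX, t(X) %*% Vi %*% d$y)
  r <- d$y - X %*% b
  as.numeric((n - p) * log(2 * pi) + 2 * sum(log(diag(cV))) +
               determinant(XtViX, logarithm = TRUE)$modulus +
               t(r) %*% Vi %*% r)
}

# minimize the oracle over all five variance parameters from several starts
oracle_best_neg2_reml <- function(dataset, starts) {
  obj <- function(th) {
    # th = (log sigma2, log t00, z(corr), log t11, log taub)
    s2 <- exp(th[1]); t00 <- exp(th[2]); t11 <- exp(th[4]); tb <- exp(th[5])
    rho <- tanh(th[3])
    oracle_neg2_reml(dataset, s2, t00, rho * sqrt(t00 * t11), t11, tb)
  }
  best <- Inf
  for (st in starts) {
    o <- tryCatch(stats::optim(st, obj, method = "Nelder-Mead",
                               control = list(maxit = 2000,
                                              reltol = 1e-10)),
                  error = function(e) NULL)
    if (!is.null(o) && o$value < best) best <- o$value
  }
  best
}

# fixed-effect truth vector in the model's coefficient order
true_beta <- function(params) {
  unlist(params[c("gamma000", "gamma001", "gamma010", "gamma100",
                  "gamma011", "gamma101", "gamma110", "gamma111")])
}
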