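#' Reproducible random stream for a (condition, replication) pair
#'
#' Streams are derived hierarchically from a single master seed with the
#' L'Ecuyer-CMRG generator: the master seed initializes a base stream,
#' [parallel::nextRNGStream()] is applied `condition_index` times to reach
#' the condition's stream, and [parallel::nextRNGSubStream()] is applied
#' `replication_index` times to reach the replication's substream.  Distinct
#' (condition, replication) pairs therefore get statistically independent,
#' reproducible streams, independent of execution order or worker count.
#'
#' @param master_seed Non-negative integer master seed.
#' @param condition_index Condition position in the grid (>= 0).
#' @param replication_index Replication number (>= 0).
#' @return A `.Random.seed` state vector usable as the `stream` argument of
#'   [simulate_dataset()].  The caller's RNG state is left untouched.
#' @export
seed_stream <- function(master_seed, condition_index = 0L,
                        replication_index = 0L) {
  for (v in c(master_seed, condition_index, replication_index)) {
    if (length(v) != 1L || !is.finite(v) || v < 0 || v != round(v)) {
      stop("seed_stream arguments must be single non-negative integers")
    }
  }
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master_seed), kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", globalenv(), inherits = FALSE)
  for (i in seq_len(condition_index)) s <- parallel::nextRNGStream(s)
  for (i in seq_len(replication_index)) s <- parallel::nextRNGSubStream(s)
  s
}

#' Monte Carlo evaluation of one design condition
#'
#' Replicates simulate -> fit -> slopes difference test for a single design
#' condition and aggregates power, convergence rate, singular-fit rate and
#' estimate accuracy.  Replication `r` uses the stream
#' `seed_stream(master_seed, condition_index, r)`, so results do not depend
#' on how conditions are scheduled.
#'
#' A replication whose fit or probe raises an error is recorded as failed
#' and never aborts the condition.  Non-converged fits yield no test
#' statistic.  Singular fits still yield a test (singularity is a warning,
#' not a failure) and count toward both power and the singularity rate.
#'
#' @param condition One design condition (a row of [build_grid()] output).
#'   Its `condition_index` (0 if absent) enters the seed derivation.
#' @param base_params Condition-independent [pop_params()].
#' @param n_reps Number of Monte Carlo replications (>= 1).
#' @param master_seed Master seed for [seed_stream()].
#' @param alpha Two-sided significance level for the probe.
#' @param df_policy,probe_mode,aptitude_value Passed to
#'   [slopes_difference_test()].
#' @param denominator Power denominator policy: `"all"` (default) counts
#'   non-converged and failed replications as non-significant over all
#'   `n_reps`; `"converged"` divides by the number of converged fits.  Both
#'   rates are always reported (`power_all`, `power_converged`); `power`
#'   echoes the selected policy.
#' @param grad_tol,singular_tol Passed to [fit_lmm()].
#' @param keep_replications Attach the per-replication audit table (p-value,
#'   convergence/singularity/failure flags) as attribute `"replications"`.
#' @param fit_fun,probe_fun Optional overrides taking `(dataset)` and
#'   `(fit)` respectively; intended for testing the aggregation logic with
#'   stub fitters.  `probe_fun` must return a list with at least `p`.
#'
#' @return A one-row data frame of class `"condition_summary"`: the design
#'   factors, `n_reps`, `master_seed`, `power`, `power_all`,
#'   `power_converged`, `convergence_rate`, `singularity_rate`, `n_failed`,
#'   the mean fixed-effect estimates across converged fits (`mean_*`) and
#'   their relative bias (`relbias_*`) for coefficients with non-zero truth.
#' @export
run_condition <- function(condition, base_params = pop_params(),
                          n_reps = 1000L, master_seed = 1L, alpha = 0.05,
                          df_policy = "normal",
                          probe_mode = c("as_printed", "delta_method"),
                          aptitude_value = -1,
                          denominator = c("all", "converged"),
                          grad_tol = 2e-3, singular_tol = 1e-4,
                          keep_replications = FALSE,
                          fit_fun = NULL, probe_fun = NULL) {
  condition <- as_condition(condition)
  probe_mode <- match.arg(probe_mode)
  denominator <- match.arg(denominator)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  cond_index <- if (is.null(condition$condition_index)) 0L else
    as.integer(condition$condition_index)
  params <- resolve_params(condition, base_params)

  if (is.null(fit_fun)) {
    fit_fun <- function(d) fit_lmm(d, grad_tol = grad_tol,
                                   singular_tol = singular_tol)
  }
  if (is.null(probe_fun)) {
    probe_fun <- function(f) slopes_difference_test(
      f, aptitude_value = aptitude_value, mode = probe_mode,
      alpha = alpha, df_policy = df_policy)
  }

  failed <- logical(n_reps)
  converged <- logical(n_reps)
  singular <- rep(NA, n_reps)
  pval <- rep(NA_real_, n_reps)
  betas <- matrix(NA_real_, n_reps, 8L)

  s <- seed_stream(master_seed, cond_index, 0L)
  for (r in seq_len(n_reps)) {
    s <- parallel::nextRNGSubStream(s)
    dataset <- simulate_dataset(condition, params, stream = s)
    fit <- tryCatch(fit_fun(dataset), error = function(e) e)
    if (inherits(fit, "error")) {
      failed[r] <- TRUE
      next
    }
    converged[r] <- isTRUE(fit$converged)
    singular[r] <- isTRUE(fit$singular)
    if (!is.null(fit$beta_hat) && converged[r]) betas[r, ] <- fit$beta_hat
    if (converged[r]) {
      pr <- tryCatch(probe_fun(fit), error = function(e) e)
      if (inherits(pr, "error")) {
        failed[r] <- TRUE
        converged[r] <- FALSE
      } else {
        pval[r] <- pr$p
      }
    }
  }

  sig <- !is.na(pval) & pval < alpha
  n_conv <- sum(converged)
  power_all <- sum(sig) / n_reps
  power_conv <- if (n_conv > 0) sum(sig) / n_conv else NA_real_
  # truth in the model's coefficient order (time precedes treatment:aptitude)
  truth <- unlist(params[c("gamma000", "gamma001", "gamma010", "gamma100",
                           "gamma011", "gamma101", "gamma110", "gamma111")])
  mean_est <- colMeans(betas[converged, , drop = FALSE])
  relbias <- ifelse(truth != 0, (mean_est - truth) / truth, NA_real_)

  out <- data.frame(condition_index = cond_index,
                    n_waves = condition$n_waves,
                    class_size = condition$class_size,
                    n_classrooms = condition$n_classrooms,
                    prop_treatment = condition$prop_treatment,
                    icc = condition$icc,
                    effect_label = condition$effect_label,
                    n_reps = as.integer(n_reps),
                    master_seed = as.integer(master_seed),
                    power = if (denominator == "all") power_all else power_conv,
                    power_all = power_all,
                    power_converged = power_conv,
                    convergence_rate = n_conv / n_reps,
                    singularity_rate = sum(singular, na.rm = TRUE) / n_reps,
                    n_failed = sum(failed),
                    stringsAsFactors = FALSE)
  out[paste0("mean_", names(truth))] <- as.list(mean_est)
  out[paste0("relbias_", names(truth))] <- as.list(relbias)
  if (keep_replications) {
    attr(out, "replications") <- data.frame(
      replication = seq_len(n_reps), p = pval, significant = sig,
      converged = converged, singular = singular, failed = failed)
  }
  class(out) <- c("condition_summary", "data.frame")
  out
}

#' Monte Carlo sweep over a design grid
#'
#' Runs [run_condition()] for every row of a design grid, optionally in
#' parallel and with per-condition checkpointing.  Because every
#' replication's stream is derived from `(master_seed, condition_index,
#' replication)`, serial and parallel executions with the same master seed
#' produce identical tables.
#'
#' @param grid A `"design_grid"` from [build_grid()].
#' @param ... Arguments passed on to [run_condition()] (`base_params`,
#'   `n_reps`, `master_seed`, `alpha`, ...).
#' @param n_workers Number of in-process workers (forked via
#'   [parallel::mclapply()] when > 1).
#' @param checkpoint Optional CSV path.  Completed condition rows are
#'   appended as the run progresses and are not recomputed when the run is
#'   restarted with the same path; a checkpoint whose columns or run
#'   settings (master seed, replication count) do not match the request is
#'   refused.
#' @param verbose Print per-condition progress lines.
#' @return A data frame of class `"grid_results"`, one
#'   [run_condition()] summary row per condition, in grid order.
#' @export
run_grid <- function(grid = build_grid(), ..., n_workers = 1L,
                     checkpoint = NULL, verbose = FALSE) {
  if (!is.data.frame(grid) || nrow(grid) == 0L) {
    stop("grid must be a non-empty design grid")
  }
  args <- list(...)
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- read_checkpoint(checkpoint, args)
    if (verbose) message("resuming: ", nrow(done), " conditions from checkpoint")
  }
  todo <- setdiff(grid$condition_index, done$condition_index)
  rows_todo <- which(grid$condition_index %in% todo)

  worker <- function(i) {
    res <- do.call(run_condition, c(list(condition = grid[i, ]), args))
    if (verbose) {
      message(sprintf("condition %d: power=%.3f conv=%.3f sing=%.3f",
                      res$condition_index, res$power, res$convergence_rate,
                      res$singularity_rate))
    }
    res
  }

  new_rows <- list()
  if (length(rows_todo)) {
    if (n_workers > 1L) {
      new_rows <- parallel::mclapply(rows_todo, worker,
                                     mc.cores = n_workers,
                                     mc.set.seed = FALSE,
                                     mc.preschedule = TRUE)
      errs <- vapply(new_rows, inherits, logical(1), "try-error")
      if (any(errs)) stop("condition failed: ", new_rows[[which(errs)[1]]])
      if (!is.null(checkpoint)) {
        for (res in new_rows) append_checkpoint(checkpoint, res)
      }
    } else {
      for (k in seq_along(rows_todo)) {
        res <- worker(rows_todo[k])
        if (!is.null(checkpoint)) append_checkpoint(checkpoint, res)
        new_rows[[k]] <- res
      }
    }
  }

  out <- do.call(rbind, c(list(done), new_rows))
  out <- out[order(out$condition_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("grid_results", "data.frame")
  out
}

summary_columns <- function() {
  c("condition_index", "n_waves", "class_size", "n_classrooms",
    "prop_treatment", "icc", "effect_label", "n_reps", "master_seed",
    "power", "power_all", "power_converged", "convergence_rate",
    "singularity_rate", "n_failed")
}

append_checkpoint <- function(path, row) {
  utils::write.table(row, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = !file.exists(path),
                     append = file.exists(path))
}

read_checkpoint <- function(path, args) {
  done <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                   comment.char = "#"),
                   error = function(e) NULL)
  if (is.null(done) || !all(summary_columns() %in% names(done)) ||
      anyNA(done$condition_index)) {
    stop("refusing to resume from corrupt checkpoint: ", path)
  }
  want_seed <- if (is.null(args$master_seed)) 1L else args$master_seed
  want_reps <- if (is.null(args$n_reps)) 1000L else args$n_reps
  if (nrow(done) && (any(done$master_seed != want_seed) ||
                     any(done$n_reps != want_reps))) {
    stop("checkpoint ", path, " was written with different run settings ",
         "(master_seed/n_reps); refusing to resume")
  }
  done
}
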