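#' Run configuration for the simulation pipeline
#'
#' Collects everything a reproducible run needs: the factor levels of the
#' design grid, the base population parameters, the replication count,
#' master seed, significance level and the probing/aggregation policies.
#' Defaults reproduce the package's reference study design exactly (648
#' conditions, 1000 replications).
#'
#' @param factor_levels Named list of grid factor levels
#'   (see [default_factor_levels()]).
#' @param base_params Condition-independent [pop_params()].
#' @param n_reps Replications per condition (>= 1).
#' @param master_seed Non-negative integer master seed.
#' @param alpha Two-sided significance level, in (0, 1).
#' @param df_policy `"normal"` or `"residual"` (see
#'   [slopes_difference_test()]).
#' @param probe_mode `"as_printed"` or `"delta_method"`.
#' @param denominator `"all"` or `"converged"` (see [run_condition()]).
#' @param aptitude_value Conditioning value of aptitude for the probe.
#' @param n_workers Worker count for [run_grid()].
#' @param output_dir Directory for files written by the `cmd_*` entry
#'   points.
#' @param audit Write per-replication audit output where supported.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(factor_levels = default_factor_levels(),
                       base_params = pop_params(),
                       n_reps = 1000L, master_seed = 1L, alpha = 0.05,
                       df_policy = c("normal", "residual"),
                       probe_mode = c("as_printed", "delta_method"),
                       denominator = c("all", "converged"),
                       aptitude_value = -1, n_workers = 1L,
                       output_dir = ".", audit = FALSE) {
  df_policy <- match.arg(df_policy)
  probe_mode <- match.arg(probe_mode)
  denominator <- match.arg(denominator)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (master_seed < 0 || master_seed != round(master_seed)) {
    stop("master_seed must be a non-negative integer")
  }
  if (!inherits(base_params, "pop_params")) {
    base_params <- do.call(pop_params, as.list(base_params))
  }
  build_grid(factor_levels)  # validates the levels
  structure(list(factor_levels = factor_levels, base_params = base_params,
                 n_reps = as.integer(n_reps),
                 master_seed = as.integer(master_seed), alpha = alpha,
                 df_policy = df_policy, probe_mode = probe_mode,
                 denominator = denominator, aptitude_value = aptitude_value,
                 n_workers = as.integer(n_workers), output_dir = output_dir,
                 audit = isTRUE(audit)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' The on-disk format is a human-editable YAML file mirroring the
#' [run_config()] arguments; missing keys take the defaults, so an empty
#' file reproduces the reference design.
#'
#' @param path File path.
#' @param config A `"run_config"` object.
#' @return `load_config()` returns a validated `"run_config"`;
#'   `save_config()` returns `path` invisibly.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$factor_levels)) {
    defaults <- default_factor_levels()
    fl <- defaults
    for (nm in names(raw$factor_levels)) {
      if (!nm %in% names(defaults)) stop("unknown factor: ", nm)
      fl[[nm]] <- unlist(raw$factor_levels[[nm]])
    }
    int_cols <- c("n_waves", "class_size", "n_classrooms")
    fl[int_cols] <- lapply(fl[int_cols], as.integer)
    raw$factor_levels <- fl
  }
  if (!is.null(raw$base_params)) {
    raw$base_params <- do.call(pop_params, lapply(raw$base_params, as.numeric))
  }
  do.call(run_config, raw)
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  out$base_params <- lapply(unclass(out$base_params), function(x)
    if (is.na(x)) NULL else x)
  out$base_params <- Filter(Negate(is.null), out$base_params)
  out$factor_levels <- lapply(out$factor_levels, as.vector)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Short digest identifying a run configuration
#'
#' A deterministic 31-bit hash of the canonical serialization of the
#' configuration, embedded in output files so that results can be matched
#' to the settings that produced them.
#'
#' @param config A `"run_config"` object.
#' @return An 8-character hexadecimal string.
#' @export
config_digest <- function(config) {
  stopifnot(inherits(config, "run_config"))
  keep <- setdiff(names(config), "output_dir")  # where, not what
  txt <- paste(deparse(lapply(unclass(config)[keep], unclass)), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 7
  m <- 2147483647
  for (b in bytes) h <- (h * 31 + b) %% m
  sprintf("%08x", h)
}
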