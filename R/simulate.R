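#' Randomly assign classrooms to the treatment arm
#'
#' The number of treated classrooms is deterministic given the design:
#' `round(prop_treatment * n_classrooms)` with half-up rounding.  Only the
#' identity of the treated classrooms is random, drawn uniformly without
#' replacement from the current (or supplied) random stream.
#'
#' @param n_classrooms Number of classrooms (>= 2).
#' @param prop_treatment Proportion assigned to treatment, in (0, 1).
#' @param stream Optional RNG state vector (see [seed_stream()]); when
#'   `NULL` the current RNG state is used and advanced.
#' @return Integer 0/1 vector of length `n_classrooms`.
#' @export
assign_treatment <- function(n_classrooms, prop_treatment, stream = NULL) {
  if (n_classrooms < 2) stop("n_classrooms must be >= 2")
  if (prop_treatment <= 0 || prop_treatment >= 1) {
    stop("prop_treatment must be in (0, 1)")
  }
  n_treated <- floor(n_classrooms * prop_treatment + 0.5)
  if (n_treated == 0L || n_treated == n_classrooms) {
    stop("invalid design: ", n_treated, " of ", n_classrooms,
         " classrooms treated leaves an empty arm")
  }
  with_stream(stream, {
    trt <- integer(n_classrooms)
    trt[sample.int(n_classrooms, n_treated)] <- 1L
    trt
  })
}

#' Simulate a long-format dataset from the three-level model
#'
#' Generates one dataset for a design condition under the generative model in
#' [pop_params()]: outcome = fixed part + classroom intercept deviation +
#' student intercept and time-slope deviations + occasion residual.  Aptitude
#' is drawn per student from `N(aptitude_mean, aptitude_sd^2)`; treatment is
#' assigned per classroom via [assign_treatment()].
#'
#' Draws consume the random stream in a fixed, documented order so that a
#' dataset is a pure function of (condition, params, stream): treatment
#' assignment, classroom intercept deviations, student aptitudes, student
#' random effects, occasion residuals.
#'
#' @param condition One design condition (one row of [build_grid()] output or
#'   a list with `n_waves`, `class_size`, `n_classrooms`, `prop_treatment`,
#'   `icc`, `effect_label`).
#' @param params Fully resolved [pop_params()]; defaults to
#'   `resolve_params(condition)`.
#' @param stream Optional RNG state from [seed_stream()]; `NULL` uses the
#'   current RNG state.
#' @return A data frame of class `"long_dataset"` with columns `classroom`,
#'   `student`, `wave`, `time`, `treatment`, `aptitude`, `y`; one row per
#'   occasion, `n_waves * class_size * n_classrooms` rows in total.
#'   Student ids are globally unique.
#' @export
#' @examples
#' cond <- build_grid()[1, ]
#' d <- simulate_dataset(cond, stream = seed_stream(1))
#' nrow(d)  # 3 * 10 * 20
simulate_dataset <- function(condition, params = NULL, stream = NULL) {
  condition <- as_condition(condition)
  for (f in c("n_waves", "class_size", "n_classrooms", "prop_treatment")) {
    if (is.null(condition[[f]])) stop("condition is missing '", f, "'")
  }
  if (is.null(params)) params <- resolve_params(condition)
  if (!inherits(params, "pop_params")) stop("params must be a pop_params object")
  if (is.na(params$gamma101) || is.na(params$tau_beta00)) {
    stop("params are not fully resolved (gamma101 or tau_beta00 is NA); ",
         "see resolve_params()")
  }

  W <- as.integer(condition$n_waves)
  cs <- as.integer(condition$class_size)
  J <- as.integer(condition$n_classrooms)
  tv <- wave_times(W)
  n_students <- cs * J
  n <- W * n_students

  with_stream(stream, {
    trt_cl <- assign_treatment(J, condition$prop_treatment)
    u00 <- stats::rnorm(J, 0, sqrt(params$tau_beta00))
    apt_st <- stats::rnorm(n_students, params$aptitude_mean, params$aptitude_sd)
    L <- tpi_chol(params$tau_pi00, params$tau_pi01, params$tau_pi11)
    re_st <- matrix(stats::rnorm(2L * n_students), n_students, 2L) %*% t(L)
    e <- stats::rnorm(n, 0, sqrt(params$sigma2_e))

    classroom <- rep(seq_len(J), each = W * cs)
    student <- rep(seq_len(n_students), each = W)
    wave <- rep(seq_len(W), times = n_students)
    time <- rep(tv, times = n_students)
    treatment <- trt_cl[classroom]
    aptitude <- apt_st[student]

    y <- params$gamma000 +
      params$gamma001 * treatment +
      params$gamma010 * aptitude +
      params$gamma100 * time +
      params$gamma011 * treatment * aptitude +
      params$gamma101 * treatment * time +
      params$gamma110 * aptitude * time +
      params$gamma111 * treatment * aptitude * time +
      u00[classroom] + re_st[student, 1L] + re_st[student, 2L] * time + e

    d <- data.frame(classroom = classroom, student = student, wave = wave,
                    time = time, treatment = treatment, aptitude = aptitude,
                    y = y)
    class(d) <- c("long_dataset", "data.frame")
    attr(d, "condition") <- condition
    d
  })
}

# lower Cholesky factor of the 2x2 student random-effect matrix,
# tolerating positive semi-definite (boundary) inputs
tpi_chol <- function(t00, t01, t11) {
  if (t00 > 0) {
    l11 <- sqrt(t00)
    l21 <- t01 / l11
    l22 <- sqrt(max(0, t11 - l21^2))
  } else {
    if (abs(t01) > 1e-12) stop("T_pi is not positive semi-definite")
    l11 <- 0; l21 <- 0; l22 <- sqrt(t11)
  }
  matrix(c(l11, l21, 0, l22), 2L, 2L)
}

dataset_columns <- c("classroom", "student", "wave", "time",
                     "treatment", "aptitude", "y")

#' Validate a long-format dataset
#'
#' Checks the structural invariants expected by [fit_lmm()]: the seven
#' canonical columns, treatment constant within classroom, aptitude constant
#' within student, and a balanced panel (every student observed at the same
#' set of at least two time points).
#'
#' @param dataset A data frame.
#' @return The dataset, invisibly, with class `"long_dataset"`.
#' @export
validate_dataset <- function(dataset) {
  if (!is.data.frame(dataset)) stop("dataset must be a data frame")
  missing <- setdiff(dataset_columns, names(dataset))
  if (length(missing)) {
    stop("dataset is missing column(s): ", paste(missing, collapse = ", "))
  }
  d <- dataset
  bad <- which(!stats::complete.cases(d[dataset_columns]))
  if (length(bad)) stop("dataset has missing values, first at row ", bad[1])
  if (!all(d$treatment %in% c(0, 1))) stop("treatment must be coded 0/1")

  key <- paste(d$classroom, d$student)
  if (any(tapply(d$treatment, d$classroom, function(x) length(unique(x)) > 1))) {
    off <- names(which(tapply(d$treatment, d$classroom,
                              function(x) length(unique(x)) > 1)))[1]
    row <- which(d$classroom == off)[1]
    stop("treatment varies within classroom ", off, " (see row ", row, ")")
  }
  if (any(tapply(d$aptitude, key, function(x) length(unique(x)) > 1))) {
    off <- names(which(tapply(d$aptitude, key,
                              function(x) length(unique(x)) > 1)))[1]
    stop("aptitude varies within student ", off)
  }
  times <- tapply(d$time, key, function(x) paste(sort(x), collapse = ","))
  if (length(unique(times)) != 1L) {
    stop("students are observed at differing sets of time points ",
         "(unbalanced panel)")
  }
  if (length(unique(d$time)) < 2L) stop("at least two distinct waves required")
  if (!inherits(dataset, "long_dataset")) {
    class(dataset) <- c("long_dataset", class(dataset))
  }
  invisible(dataset)
}

#' Write / read a long-format dataset as plain-text CSV
#'
#' `write_dataset()` writes the seven canonical columns with a header row;
#' reals are written with 17 significant digits so the write/read round trip
#' is bitwise exact for doubles.  `read_dataset()` parses and validates the
#' file, reporting the offending row on structural violations.
#'
#' @param dataset A `"long_dataset"` (or compatible data frame).
#' @param path File path.
#' @return `read_dataset()` returns a validated `"long_dataset"`;
#'   `write_dataset()` returns `path` invisibly.
#' @export
write_dataset <- function(dataset, path) {
  validate_dataset(dataset)
  d <- dataset[dataset_columns]
  out <- data.frame(classroom = as.integer(d$classroom),
                    student = as.integer(d$student),
                    wave = as.integer(d$wave),
                    time = sprintf("%.17g", d$time),
                    treatment = as.integer(d$treatment),
                    aptitude = sprintf("%.17g", d$aptitude),
                    y = sprintf("%.17g", d$y))
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(dataset_columns, names(d))
  if (length(missing)) {
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  validate_dataset(d)
  d <- d[dataset_columns]
  class(d) <- c("long_dataset", "data.frame")
  d
}

# Evaluate an expression under a specific RNG state, restoring the caller's
# state afterwards.  `stream` is a .Random.seed vector (e.g. from
# seed_stream()); NULL means "use and advance the current state".
with_stream <- function(stream, expr) {
  if (is.null(stream)) return(eval.parent(substitute(expr)))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", stream, envir = globalenv())
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  eval.parent(substitute(expr))
}
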