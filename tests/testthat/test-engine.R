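test_that("seed streams are reproducible and pair-distinct", {
  expect_identical(seed_stream(5, 3, 7), seed_stream(5, 3, 7))
  expect_false(identical(seed_stream(5, 3, 7), seed_stream(5, 3, 8)))
  expect_false(identical(seed_stream(5, 3, 7), seed_stream(5, 4, 7)))
  expect_false(identical(seed_stream(5, 3, 7), seed_stream(6, 3, 7)))
  expect_error(seed_stream(-1), "non-negative")
  expect_error(seed_stream(1, 2.5), "non-negative")
})

test_that("seed_stream leaves the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(seed_stream(1, 2, 3))
  expect_identical(.Random.seed, before)
})

test_that("power aggregation counts significant replications correctly", {
  cond <- small_condition(condition_index = 1L)
  always <- run_condition(cond, n_reps = 5, master_seed = 1,
                          fit_fun = function(d) list(converged = TRUE,
                                                     singular = FALSE),
                          probe_fun = function(f) list(p = 0.01))
  expect_equal(always$power, 1)
  expect_equal(always$convergence_rate, 1)

  seq_probe <- local({
    i <- 0
    function(f) {
      i <<- i + 1
      list(p = c(0.01, 0.20, 0.04, 0.90)[i])
    }
  })
  half <- run_condition(cond, n_reps = 4, master_seed = 1,
                        fit_fun = function(d) list(converged = TRUE,
                                                   singular = FALSE),
                        probe_fun = seq_probe)
  expect_equal(half$power, 0.5)
})

test_that("failed and non-converged replications follow the denominator policy", {
  cond <- small_condition(condition_index = 1L)
  flaky_fit <- local({
    i <- 0
    function(d) {
      i <<- i + 1
      if (i == 2) stop("synthetic failure")
      list(converged = i != 3, singular = i == 4)
    }
  })
  res <- run_condition(cond, n_reps = 4, master_seed = 1,
                       fit_fun = flaky_fit,
                       probe_fun = function(f) list(p = 0.01))
  # rep 2 fails, rep 3 does not converge, reps 1 and 4 are significant
  expect_equal(res$n_failed, 1L)
  expect_equal(res$convergence_rate, 0.5)
  expect_equal(res$singularity_rate, 0.25)
  expect_equal(res$power_all, 0.5)
  expect_equal(res$power_converged, 1)
})

test_that("grid runs are a pure function of the master seed", {
  g <- build_grid(list(n_waves = 3L, class_size = 4L, n_classrooms = 8L,
                       prop_treatment = 0.5, icc = c(0.086, 0.2),
                       effect_label = "small"))
  r1 <- run_grid(g, n_reps = 3, master_seed = 21)
  r2 <- run_grid(g, n_reps = 3, master_seed = 21)
  r3 <- run_grid(g, n_reps = 3, master_seed = 22)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  # a different master seed changes the simulated data, visible in the
  # continuous estimate means even when the coarse power rates coincide
  expect_false(identical(r1$mean_gamma100, r3$mean_gamma100))
  expect_equal(nrow(r1), 2L)
})

test_that("single condition, single replication gives degenerate rates", {
  g <- build_grid(list(n_waves = 3L, class_size = 4L, n_classrooms = 8L,
                       prop_treatment = 0.5, icc = 0.2,
                       effect_label = "large"))
  r <- run_grid(g, n_reps = 1, master_seed = 2)
  expect_equal(nrow(r), 1L)
  expect_true(all(unlist(r[c("power_all", "convergence_rate",
                             "singularity_rate")]) %in% c(0, 1)))
})

test_that("interrupted grid runs resume from the checkpoint unchanged", {
  g <- build_grid(list(n_waves = 3L, class_size = 4L, n_classrooms = 8L,
                       prop_treatment = 0.5, icc = c(0.086, 0.113, 0.2),
                       effect_label = "small"))
  ck <- withr::local_tempfile(fileext = ".csv")
  full <- run_grid(g, n_reps = 2, master_seed = 31)
  # simulate an interrupted run: first condition only, then resume
  run_grid(g[1, ], n_reps = 2, master_seed = 31, checkpoint = ck)
  resumed <- run_grid(g, n_reps = 2, master_seed = 31, checkpoint = ck)
  expect_equal(as.data.frame(resumed), as.data.frame(full),
               ignore_attr = TRUE)
})

test_that("corrupt or incompatible checkpoints are refused", {
  ck <- withr::local_tempfile(fileext = ".csv")
  writeLines("not,a,checkpoint\n1,2", ck)
  g <- build_grid(list(n_waves = 3L, class_size = 4L, n_classrooms = 8L,
                       prop_treatment = 0.5, icc = 0.2,
                       effect_label = "small"))
  expect_error(run_grid(g, n_reps = 2, master_seed = 1, checkpoint = ck),
               "corrupt checkpoint")

  ck2 <- withr::local_tempfile(fileext = ".csv")
  run_grid(g, n_reps = 2, master_seed = 1, checkpoint = ck2)
  expect_error(run_grid(g, n_reps = 2, master_seed = 2, checkpoint = ck2),
               "different run settings")
})

test_that("replication audit tables reconcile with the summary counts", {
  cond <- small_condition(n_waves = 3L, class_size = 4L, n_classrooms = 8L,
                          icc = 0.2, effect_label = "large",
                          condition_index = 2L)
  res <- run_condition(cond, n_reps = 6, master_seed = 77,
                       keep_replications = TRUE)
  reps <- attr(res, "replications")
  expect_equal(nrow(reps), 6L)
  expect_equal(sum(reps$significant), res$power_all * 6)
  expect_equal(sum(reps$converged), res$convergence_rate * 6)
  expect_equal(sum(reps$significant) +
                 sum(!reps$significant & !reps$failed) + sum(reps$failed),
               6L)
})
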