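test_that("treatment assignment has deterministic counts and random identity", {
  s <- seed_stream(1)
  expect_equal(sum(assign_treatment(20, 0.5, s)), 10L)
  expect_equal(sum(assign_treatment(20, 0.3, s)), 6L)
  expect_identical(assign_treatment(20, 0.5, s), assign_treatment(20, 0.5, s))
  expect_error(assign_treatment(4, 0.1), "empty arm")
  expect_error(assign_treatment(20, 1.5), "prop_treatment")
})

test_that("simulated datasets satisfy the long-format invariants", {
  cond <- small_condition(n_waves = 4L, class_size = 5L, n_classrooms = 6L,
                          prop_treatment = 0.5)
  d <- simulate_dataset(cond, stream = seed_stream(3, 1, 1))
  expect_s3_class(d, "long_dataset")
  expect_equal(nrow(d), 4 * 5 * 6)
  expect_equal(sum(tapply(d$treatment, d$classroom, `[`, 1)), 3)
  expect_true(all(tapply(d$treatment, d$classroom,
                         function(x) length(unique(x))) == 1))
  expect_true(all(tapply(d$aptitude, d$student,
                         function(x) length(unique(x))) == 1))
  for (tt in split(d$time, d$student)) expect_equal(tt, wave_times(4))
  expect_silent(validate_dataset(d))
})

test_that("datasets are a pure function of (condition, params, stream)", {
  cond <- small_condition()
  d1 <- simulate_dataset(cond, stream = seed_stream(7, 2, 5))
  d2 <- simulate_dataset(cond, stream = seed_stream(7, 2, 5))
  d3 <- simulate_dataset(cond, stream = seed_stream(7, 2, 6))
  expect_identical(d1$y, d2$y)
  expect_false(identical(d1$y, d3$y))
})

test_that("with all variance components zero the outcome is the fixed part", {
  cond <- small_condition(icc = 0, effect_label = "small")
  p <- pop_params(gamma101 = 0.2, sigma2_e = 0, tau_pi00 = 0, tau_pi01 = 0,
                  tau_pi11 = 0, tau_beta00 = 0)
  d <- simulate_dataset(cond, p, stream = seed_stream(11))
  fixed <- p$gamma000 + p$gamma001 * d$treatment + p$gamma010 * d$aptitude +
    p$gamma100 * d$time + p$gamma011 * d$treatment * d$aptitude +
    p$gamma101 * d$treatment * d$time + p$gamma110 * d$aptitude * d$time +
    p$gamma111 * d$treatment * d$aptitude * d$time
  expect_equal(d$y, fixed, tolerance = 1e-12)
})

test_that("empirical moments match the generative model", {
  # 10,000 students; checks are 3-4 Monte Carlo SEs wide
  cond <- small_condition(n_waves = 3L, class_size = 50L, n_classrooms = 200L,
                          icc = 0.2, effect_label = "small",
                          condition_index = 1L)
  p <- resolve_params(cond)
  d <- simulate_dataset(cond, p, stream = seed_stream(13, 1, 1))

  st <- !duplicated(d$student)
  expect_lt(abs(mean(d$aptitude[st])), 0.45)        # 3 * 15/sqrt(1e4)
  expect_lt(abs(stats::sd(d$aptitude[st]) - 15), 0.45)

  fixed <- p$gamma000 + p$gamma001 * d$treatment + p$gamma010 * d$aptitude +
    p$gamma100 * d$time + p$gamma011 * d$treatment * d$aptitude +
    p$gamma101 * d$treatment * d$time + p$gamma110 * d$aptitude * d$time +
    p$gamma111 * d$treatment * d$aptitude * d$time
  resid <- d$y - fixed
  at0 <- d$time == 0
  # var at time 0 = sigma2 + tau_pi00 + tau_beta00 = 1.5; the 3-SE band
  # accounts for the shared classroom effects (200 classrooms)
  expect_lt(abs(stats::var(resid[at0]) - 1.5), 0.12)
  # mean of y for treated students at time 0, net of aptitude terms,
  # equals gamma000 + gamma001.  Students share classroom deviations, so
  # var(mean) = (sigma2 + tau_pi00)/n_students + tau_beta00/J_treated
  # = 1.3/5000 + 0.3/100; the band is 3 SE
  trt0 <- at0 & d$treatment == 1
  net <- d$y[trt0] - (p$gamma010 + p$gamma011) * d$aptitude[trt0]
  expect_lt(abs(mean(net) - (p$gamma000 + p$gamma001)),
            3 * sqrt(1.3 / 5000 + 0.3 / 100))
})

test_that("write/read round-trips a dataset exactly", {
  d <- simulate_dataset(small_condition(), stream = seed_stream(17))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, path)
  d2 <- read_dataset(path)
  expect_equal(as.data.frame(d2), as.data.frame(d)[names(d2)],
               tolerance = 0, ignore_attr = TRUE)
})

test_that("dataset validation reports structural violations", {
  d <- simulate_dataset(small_condition(), stream = seed_stream(19))
  expect_error(validate_dataset(d[setdiff(names(d), "aptitude")]),
               "missing column.*aptitude")
  bad <- d
  bad$treatment[1] <- 1 - bad$treatment[1]
  expect_error(validate_dataset(bad), "treatment varies within classroom")
  bad2 <- d
  bad2$aptitude[2] <- bad2$aptitude[2] + 1
  expect_error(validate_dataset(bad2), "aptitude varies within student")
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, path)
  txt <- readLines(path)
  writeLines(gsub("aptitude", "apt", txt[1]), path)
  cat(txt[-1], file = path, sep = "\n", append = TRUE)
  expect_error(read_dataset(path), "missing column")
})

test_that("the reference lowest-power condition yields 600 occasion rows", {
  cond <- small_condition(n_waves = 3L, class_size = 10L, n_classrooms = 20L)
  d <- simulate_dataset(cond, stream = seed_stream(23))
  expect_equal(nrow(d), 600L)
})
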