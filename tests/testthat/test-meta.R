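# condition-summary-like table over a toy factorial, with outcome set by a
# supplied function of the factor levels
toy_summaries <- function(f, n_waves = c(3, 4), effect_label = c("small",
                                                                 "large")) {
  g <- expand.grid(n_waves = n_waves, effect_label = effect_label,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$power <- mapply(f, g$n_waves, g$effect_label)
  g
}

test_that("a constant outcome yields zero eta-squared everywhere", {
  s <- toy_summaries(function(w, e) 0.7)
  an <- anova_eta2(s, "power", include_two_way = FALSE)
  expect_true(all(an$eta_squared == 0))
})

test_that("eta-squared attributes all variance to the splitting factor", {
  # outcome split along effect_label only: (0, 0) vs (1, 1)
  s <- toy_summaries(function(w, e) if (e == "small") 0 else 1)
  an <- anova_eta2(s, "power", include_two_way = FALSE)
  expect_equal(an$eta_squared[an$term == "effect_label"], 1)
  expect_equal(an$eta_squared[an$term == "n_waves"], 0)
  expect_equal(sum(an$eta_squared), 1)
})

test_that("the decomposition is invariant to factor ordering and affine scale", {
  s <- toy_summaries(function(w, e) 0.2 * w + (e == "large") * 0.3 +
                       0.01 * w * (e == "large"),
                     n_waves = c(3, 4, 5))
  an1 <- anova_eta2(s, "power", include_two_way = TRUE)
  an2 <- anova_eta2(s[rev(seq_len(nrow(s))),
                      c("effect_label", "n_waves", "power")],
                    "power", include_two_way = TRUE)
  m1 <- an1$eta_squared[match(sort(an1$term), an1$term)]
  m2 <- an2$eta_squared[match(sort(an1$term),
                              gsub("effect_label:n_waves",
                                   "n_waves:effect_label", an2$term))]
  expect_equal(m1, m2, tolerance = 1e-10)

  s2 <- s
  s2$power <- 100 * s$power - 7
  an3 <- anova_eta2(s2, "power", include_two_way = TRUE)
  expect_equal(an3$eta_squared, an1$eta_squared, tolerance = 1e-10)
})

test_that("a saturated decomposition reports terms without F statistics", {
  # one observation per cell and a full interaction model: no residual df
  s <- toy_summaries(function(w, e) 0.1 * w + (e == "large"))
  an <- anova_eta2(s, "power", include_two_way = TRUE)
  expect_true(all(is.na(an$F)))
  expect_equal(sum(an$eta_squared), 1)
})

test_that("incomplete or unbalanced factorials are rejected by name", {
  s <- toy_summaries(function(w, e) 0.5)
  expect_error(anova_eta2(s[-1, ], "power"), "missing cell")
  expect_error(anova_eta2(rbind(s, s[1, ]), "power"), "unbalanced")
})

test_that("Tukey HSD flags only the shifted group", {
  # three wave levels, four replicate conditions each; one level shifted by
  # many residual SDs
  set.seed(202)
  s <- expand.grid(n_waves = c(3, 4, 5), effect_label = c("a", "b", "c", "d"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  s$power <- rnorm(nrow(s), 0, 0.01) + ifelse(s$n_waves == 5, 1, 0)
  tk <- tukey_hsd(s, "n_waves", "power")
  expect_equal(nrow(tk), 3L)
  sig <- tk$significant[order(tk$level_pair)]
  names(sig) <- sort(tk$level_pair)
  expect_false(sig[["4-3"]])
  expect_true(sig[["5-3"]])
  expect_true(sig[["5-4"]])
})

test_that("Tukey HSD is conservative and collapses to the t-test for 2 levels", {
  set.seed(203)
  s <- expand.grid(n_waves = c(3, 4), effect_label = letters[1:6],
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  s$power <- rnorm(nrow(s))
  tk <- tukey_hsd(s, "n_waves", "power")
  fit <- stats::aov(power ~ factor(n_waves) + factor(effect_label), data = s)
  p_unadj <- summary(fit)[[1]][["Pr(>F)"]][1]
  expect_equal(tk$adjusted_p, p_unadj, tolerance = 1e-10)

  sflat <- s
  sflat$power <- rep(0.4, nrow(s))
  tkflat <- tukey_hsd(sflat, "n_waves", "power")
  expect_true(all(tkflat$adjusted_p > 0.99 | is.na(tkflat$adjusted_p)))
})

test_that("threshold percentages count and slice correctly", {
  s <- expand.grid(n_waves = c(3, 4, 5), class_size = c(10, 20),
                   effect_label = c("small", "large"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  s$power <- 0.9
  all_ok <- threshold_percentages(s, "power", 0.8, "below")
  expect_equal(all_ok$percent, 0)

  s$power[1:3] <- 0.5  # 3 of 12 below
  overall <- threshold_percentages(s, "power", 0.8, "below")
  expect_equal(overall$percent, 25)

  by_eff <- threshold_percentages(s, "power", 0.8, "below",
                                  slice_factors = "effect_label")
  expect_equal(sort(by_eff$percent), c(0, 50))

  fn <- threshold_percentages(s, "power", function(x) x > 0.8,
                              slice_factors = "effect_label")
  expect_equal(sort(fn$percent), c(50, 100))

  # a slice with no conditions is reported as missing, not zero
  s2 <- s[!(s$n_waves == 5 & s$effect_label == "large"), ]
  sliced <- threshold_percentages(s2, "power", 0.8, "below",
                                  slice_factors = c("n_waves",
                                                    "effect_label"))
  empty <- sliced[sliced$n_waves == 5 & sliced$effect_label == "large", ]
  expect_true(is.na(empty$percent))
  expect_equal(empty$n, 0L)
})
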