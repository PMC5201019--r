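test_that("noiseless synthetic curves reproduce the truth at the frame times", {
  lib <- tiny_library()
  ref <- library_curve(lib, 100, 0.06)
  sy <- generate_synthetic_curve(list(F0 = 100, K_dep = 0.06), noise = 0,
                                 seed = 7, truth_curve = ref, duration = 10)
  expect_equal(sy$curve$value, curve_value(ref, sy$curve$time))
  expect_equal(sy$curve$time[1], 0.035)
  expect_equal(diff(sy$curve$time)[1], 1 / 30)
})

test_that("synthetic generation is reproducible from its seed", {
  lib <- tiny_library()
  ref <- library_curve(lib, 100, 0.06)
  g <- function(seed) generate_synthetic_curve(
    list(F0 = 100, K_dep = 0.06), noise = 0.02, seed = seed,
    truth_curve = ref, duration = 10)$curve$value
  expect_identical(g(11), g(11))
  expect_false(identical(g(11), g(12)))
})

test_that("frame rate and first-frame delay reshape the apparent curve", {
  lib <- tiny_library()
  ref <- library_curve(lib, 100, 0.02)
  fast <- generate_synthetic_curve(list(F0 = 100, K_dep = 0.02), noise = 0,
                                   seed = 1, truth_curve = ref, duration = 10,
                                   fps = 30, first_frame = 0.035)
  slow <- generate_synthetic_curve(list(F0 = 100, K_dep = 0.02), noise = 0,
                                   seed = 1, truth_curve = ref, duration = 10,
                                   fps = 4.25, first_frame = 0.235)
  tt <- seq(0.5, 8, by = 0.5)
  vf <- curve_value(fast$curve, tt)
  vs <- curve_value(slow$curve, tt)
  # same underlying data, but the delayed, renormalized series looks slower
  expect_true(all(vs > vf))
  expect_gt(max(vs - vf), 0.05)
  expect_error(generate_synthetic_curve(list(F0 = 100, K_dep = 0.02),
                                        noise = 0, seed = 1, truth_curve = ref,
                                        first_frame = 99), "outside")
})

test_that("parameters are recovered from noisy synthetic cohorts", {
  lib <- tiny_library()
  tab <- parameter_recovery_study(lib, data.frame(F0 = 100, K_dep = 0.06),
                                  noise_levels = c(0, 0.02), n_per = 12,
                                  seed = 3)
  # noise-free on-grid truth: exact recovery
  expect_equal(tab$mae_F[tab$noise == 0], 0)
  expect_equal(tab$mae_K[tab$noise == 0], 0)
  expect_equal(tab$frac_within_step_F[tab$noise == 0], 1)
  # errors do not decrease with noise
  expect_true(all(diff(tab$mae_F) >= 0))
  expect_true(all(diff(tab$mae_K) >= 0))
})

test_that("stabilized and control cohorts separate significantly", {
  lib <- tiny_library()
  fits <- function(F0, K_dep, seeds) lapply(seeds, function(s) {
    sy <- generate_synthetic_curve(list(F0 = F0, K_dep = K_dep), noise = 0.02,
                                   seed = s, duration = 10,
                                   truth_curve = library_curve(lib, F0, K_dep))
    fit_curve(sy$curve, lib, tiny_fitgrid(), k = 0)
  })
  ctrl <- fits(80, 0.06, 1:10)
  jasp <- fits(140, 0.02, 11:20)
  cs <- cohort_stats(ctrl, jasp)
  expect_lt(cs$t_test$ratio$p_value, 0.01)
  expect_lt(cs$t_test$K_dep$p_value, 0.01)
  expect_gt(mean(sapply(ctrl, `[[`, "ratio")),
            mean(sapply(jasp, `[[`, "ratio")))
})

test_that("perturbing one parameter leaves the other's fit in place", {
  lib <- tiny_library()
  fit_noiseless <- function(F0, K_dep) {
    sy <- generate_synthetic_curve(list(F0 = F0, K_dep = K_dep), noise = 0,
                                   seed = 1, duration = 10,
                                   truth_curve = library_curve(lib, F0, K_dep))
    fit_curve(sy$curve, lib, tiny_fitgrid(), k = 0)
  }
  # F0 changes: fitted ratio moves, fitted K_dep stays within one step
  fa <- fit_noiseless(60, 0.06); fb <- fit_noiseless(140, 0.06)
  expect_gt(abs(fa$ratio - fb$ratio), 1)
  expect_lte(abs(fa$K_dep - fb$K_dep), 0.02)
  # K_dep changes: fitted F stays within one step
  fc <- fit_noiseless(100, 0.02); fd <- fit_noiseless(100, 0.10)
  expect_lte(abs(fc$F - fd$F), 20)
  expect_gt(abs(fc$K_dep - fd$K_dep), 0.05)
})
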