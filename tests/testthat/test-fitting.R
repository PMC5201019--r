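test_that("the fit grid is dense early, sparse late, and starts at t_norm", {
  fg <- fit_grid()
  tt <- as.numeric(fg)
  expect_equal(tt[1], 0.035)
  expect_true(all(diff(tt) > 0))
  expect_equal(max(tt), 25)
  expect_true(all(abs(diff(tt[tt > 0.05 & tt <= 3]) - 0.05) < 1e-9))
  expect_true(all(abs(diff(tt[tt >= 3.2]) - 0.2) < 1e-9))
  expect_error(fit_grid(fine = 0.3), "smaller")
})

test_that("resampling interpolates linearly and truncates to the support", {
  fg <- fit_grid(end = 10)
  # a curve sampled at video rate, resampled onto 0.05-s points
  tt <- c(seq(0.035, 10, by = 1 / 30), 10)
  cur <- new_curve(tt, 1 / (1 + tt), 0.035)
  rs <- resample_to_fit_grid(cur, fg)
  expect_equal(rs$time, as.numeric(fg))
  i <- findInterval(0.5, tt)
  lin <- approx(tt[i + 0:1], cur$value[i + 0:1], 0.5)$y
  expect_equal(curve_value(rs, 0.5), lin)
  # already on the grid: unchanged
  on <- new_curve(as.numeric(fg), seq_along(fg) * 0.01, 0.035)
  expect_equal(resample_to_fit_grid(on, fg)$value, on$value)
  # short curve: grid truncated and flagged
  stt <- seq(0.035, 5, by = 0.05)
  short <- new_curve(stt, rep(1, length(stt)), 0.035)
  rs2 <- resample_to_fit_grid(short, fit_grid(end = 25))
  expect_lte(max(rs2$time), max(stt))
  expect_equal(rs2$meta$truncated_at, max(stt))
  # shorter than the fine segment: rejected
  expect_error(resample_to_fit_grid(new_curve(c(0.035, 2), c(1, 0.5), 0.035),
                                    fg), "fine")
})

test_that("rmsd matches hand-computed values", {
  a <- new_curve(1:4, c(1, 0.8, 0.6, 0.5), 0.035)
  expect_equal(rmsd(a, a), 0)
  b <- new_curve(1:4, a$value + 0.07, 0.035)
  expect_equal(rmsd(a, b), 0.07)
  d <- new_curve(1:4, c(0.9, 0.9, 0.5, 0.4), 0.035)
  expect_equal(rmsd(a, d), sqrt(mean(c(0.1, -0.1, 0.1, 0.1)^2)))
  expect_error(rmsd(a, new_curve(1:3, c(1, 2, 3), 0.035)), "grids|lengths")
})

test_that("every library cell fits itself exactly", {
  lib <- tiny_library()
  fg <- tiny_fitgrid()
  for (j in seq_len(n_scenarios(lib))) {
    ft <- fit_curve(library_curve(lib, lib$F[j], lib$K_dep[j]), lib, fg, k = 2)
    expect_equal(ft$F, lib$F[j])
    expect_equal(ft$K_dep, lib$K_dep[j])
    expect_equal(ft$rmsd, 0)
    expect_true(all(ft$rmsd <= ft$alternatives$rmsd))
  }
})

test_that("a forward simulation at off-grid truth fits within one grid step", {
  lib <- tiny_library()
  p <- sim_params(D = 3, F0 = 92, K_dep = 0.053, t_post = 10)
  cur <- normalize_curve(simulate_photoactivation(p, tiny_grid(), tiny_roi()))
  ft <- fit_curve(cur, lib, tiny_fitgrid())
  expect_lte(abs(ft$F - 92), 20)
  expect_lte(abs(ft$K_dep - 0.053), 0.02)
  expect_equal(ft$ratio, (200 - ft$F) / ft$F)
})

test_that("filament stabilization shows up as low ratio and low K_dep", {
  lib <- tiny_library()
  p <- sim_params(D = 3, F0 = 140, K_dep = 0.02, t_post = 10)
  cur <- normalize_curve(simulate_photoactivation(p, tiny_grid(), tiny_roi()))
  ft <- fit_curve(cur, lib, tiny_fitgrid())
  expect_equal(ft$F, 140)
  expect_equal(ft$K_dep, 0.02)
  expect_lt(ft$ratio, 0.5)
})

test_that("immobile-fraction subtraction isolates the mobile component", {
  # constructed curve: immobile plateau p over a fast mobile decay
  tt <- seq(0.035, 5, by = 0.01)
  p <- 0.4
  mob <- exp(-3 * (tt - 0.035))
  cur <- new_curve(tt, p + (1 - p) * mob, 0.035)
  cor <- subtract_immobile_fraction(cur)
  expect_equal(cor$meta$immobile_fraction, curve_value(cur, 2.5))
  expect_equal(curve_value(cor, 0.035), 1)
  expect_lt(curve_value(cor, 2.5), 0.01)  # decays to ~0 by t_ref
  # a pure-diffusion-like curve with no plateau barely changes early on
  mob2 <- new_curve(tt, mob + 1e-4, 0.035)
  cor2 <- subtract_immobile_fraction(mob2)
  early <- tt <= 1.5
  expect_lt(max(abs(cor2$value[early] - mob2$value[early])), 0.01)
  # degenerate: plateau at the normalization level
  expect_error(subtract_immobile_fraction(new_curve(tt, rep(1, length(tt)),
                                                    0.035)), "mobile")
  expect_error(subtract_immobile_fraction(new_curve(c(0.035, 1), c(1, 0.5),
                                                    0.035)), "reference")
})

test_that("simulated filament signal, corrected, matches pure diffusion early on", {
  lib <- tiny_library()
  wt <- library_curve(lib, 100, 0.02)      # 50% filaments, slow turnover
  cor <- subtract_immobile_fraction(wt)
  dif <- simulate_diffusion_only(3, tiny_grid(), tiny_roi(), t_post = 3)
  tt <- seq(0.035, 1.5, by = 0.05)
  expect_lt(max(abs(curve_value(cor, tt) - curve_value(dif, tt))), 0.06)
})

test_that("the diffusion coefficient is recovered from diffusion-only decay", {
  target <- simulate_diffusion_only(4, tiny_grid(), tiny_roi(), t_post = 2)
  ft <- fit_diffusion(target, c(2, 3, 4, 5), tiny_grid(), tiny_roi())
  expect_equal(ft$D, 4)
  expect_equal(nrow(ft$table), 4)
  expect_true(all(ft$rmsd <= ft$table$rmsd))
})

test_that("cohort statistics match hand-computed formulas", {
  mk <- function(F, K) structure(list(F = F, K_dep = K, ratio = (200 - F) / F,
                                      rmsd = 0), class = "maap_fit")
  a <- lapply(c(60, 80, 100), function(f) mk(f, 0.04))
  b <- lapply(c(100, 120, 140), function(f) mk(f, 0.08))
  # identical groups: p = 1
  same <- cohort_stats(a, a)
  expect_equal(same$t_test$ratio$p_value, 1)
  # hand-computed Welch t for K_dep is degenerate (zero variance): use ratio
  ga <- sapply(a, `[[`, "ratio"); gb <- sapply(b, `[[`, "ratio")
  se <- sqrt(var(ga) / 3 + var(gb) / 3)
  t_hand <- (mean(ga) - mean(gb)) / se
  df_hand <- se^4 / ((var(ga) / 3)^2 / 2 + (var(gb) / 3)^2 / 2)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  cs <- cohort_stats(a, b)
  expect_equal(cs$t_test$ratio$statistic, t_hand)
  expect_equal(cs$t_test$ratio$p_value, p_hand)
  # pooled-variance option reproduces the classical formula
  sp2 <- (2 * var(ga) + 2 * var(gb)) / 4
  t_pooled <- (mean(ga) - mean(gb)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(cohort_stats(a, b, pooled = TRUE)$t_test$ratio$statistic,
               t_pooled)
  # perfectly linear K_dep-ratio pairs give r = 1
  lin <- lapply(1:4, function(i) mk(200 / (1 + i * 0.5), 0.01 * i))
  expect_equal(unname(cohort_stats(lin, lin)$correlation["A"]), 1)
  # percentile summary covers the box-and-whisker quantiles
  expect_true(all(c("p5", "p25", "p50", "p75", "p95") %in% names(cs$summary)))
  expect_error(cohort_stats(a[1], b), "at least 2")
})

test_that("decay curves round-trip through the text format", {
  tt <- seq(0.035, 4, by = 0.1)
  cur <- new_curve(tt, exp(-tt), 0.035, meta = list(label = "x"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_decay_curve(cur, path, comment = "unit test")
  back <- read_decay_curve(path)
  expect_identical(back$time, cur$time)
  expect_identical(back$value, cur$value)
  # whitespace-delimited input without header, out-of-order rows
  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "1.0 0.5", "0.035 1.0", "2.0 0.25"), path2)
  cur2 <- read_decay_curve(path2)
  expect_equal(cur2$time, c(0.035, 1, 2))
  # renormalization at t_norm for data normalized elsewhere
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,int", "0.035,4", "1,2"), path3)
  cur3 <- read_decay_curve(path3, renormalize = TRUE)
  expect_equal(cur3$value, c(1, 0.5))
  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_decay_curve(empty), "no data")
})

test_that("renormalizing to a delayed first frame slows the apparent decay", {
  lib <- tiny_library()
  cur <- library_curve(lib, 100, 0.06)
  tt <- seq(0.3, 3, by = 0.1)
  v035 <- curve_value(cur, tt)
  v235 <- curve_value(cur, tt) / curve_value(cur, 0.235)
  expect_true(all(v235 > v035))
  expect_gt(v235[tt == 1] - v035[tt == 1], 0.03)
})
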