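test_that("steady-state polymerization rate follows detailed balance", {
  expect_equal(steady_state_polymerization_rate(100, 100, 0.06), 0.06)
  expect_equal(steady_state_polymerization_rate(0, 200, 0.1), 0)
  expect_equal(steady_state_polymerization_rate(150, 50, 0.1), 0.3)
  expect_error(steady_state_polymerization_rate(100, 0, 0.1), "positive")
})

test_that("simulation parameters are validated", {
  p <- sim_params(F0 = 150, K_dep = 0.1)
  expect_equal(p$G0, 50)
  expect_equal(p$k_pol, 0.3)
  expect_error(sim_params(F0 = 200), "F0")
  expect_error(sim_params(F0 = -1), "F0")
  expect_error(sim_params(D = -3), "D")
  expect_error(sim_params(K_dep = -0.1), "K_dep")
})

test_that("total photoactivated actin is conserved after the pulse", {
  p <- sim_params(D = 3, F0 = 100, K_dep = 0.06, t_post = 5)
  sim <- simulate_photoactivation(p, tiny_grid(), tiny_roi())
  post <- sim$total_pa[sim$times >= 0]
  expect_lt(diff(range(post)) / post[1], 1e-3)   # contract: 0.1%
  expect_lt(diff(range(post)) / post[1], 1e-10)  # in practice: exact
  expect_true(all(sim$roi_raw >= 0))
})

test_that("immobile-only system keeps its normalized ROI signal at 1", {
  p <- sim_params(D = 3, F0 = 199.9, K_dep = 0, t_post = 2)
  sim <- simulate_photoactivation(p, tiny_grid(), tiny_roi())
  cur <- normalize_curve(sim)
  expect_true(all(cur$value > 0.999))
})

test_that("with D = 0 the simulation matches the two-state exchange ODE", {
  p <- sim_params(D = 0, F0 = 120, K_dep = 0.1, t_post = 4)
  sim <- simulate_photoactivation(p, tiny_grid(), tiny_roi(),
                                  snapshot_times = c(0, 1.5, 4))
  # total PA in each voxel is frozen; ROI curve is constant
  v0 <- stats::approx(sim$times, sim$roi_raw, 0)$y
  post <- sim$roi_raw[sim$times >= 0]
  expect_lt(max(abs(post - v0)), 1e-4 * v0)
  # independent closed form: G(t) = Geq + (G0 - Geq) exp(-(kp+kd) t)
  s0 <- sim$snapshots[[1]]
  for (sn in sim$snapshots[-1]) {
    dt <- sn$time - s0$time
    rate <- p$k_pol + p$K_dep
    Geq <- (p$K_dep / rate) * (s0$G + s0$F)
    expect_lt(max(abs(Geq + (s0$G - Geq) * exp(-rate * dt) - sn$G)), 1e-10)
  }
  # after the saturating pulse, ROI voxels carry the steady-state G:F split
  # (the laser leaves a ~1e-3 dark residue by design)
  ridx <- roi_interior_index(tiny_grid(), tiny_roi())
  expect_lt(max(abs(s0$G[ridx] - p$G0)), 2e-3 * p$G0)
  expect_lt(max(abs(s0$F[ridx] - p$F0)), 2e-3 * p$F0)
})

test_that("half-cell and full-cell simulations agree", {
  p <- sim_params(D = 3, F0 = 100, K_dep = 0.06, t_post = 2)
  gh <- tiny_grid()
  gf <- voxelize(tiny_geometry(), c(0.5, 0.5, 0.25), half_cell = FALSE)
  tt <- seq(0.035, 2, by = 0.05)
  ch <- normalize_curve(simulate_photoactivation(p, gh, tiny_roi()))
  cf <- normalize_curve(simulate_photoactivation(p, gf, tiny_roi()))
  expect_lt(max(abs(curve_value(ch, tt) - curve_value(cf, tt))), 1e-9)
})

test_that("early free-diffusion retention matches the analytic disc solution", {
  # flat slab, near-instantaneous activation of a 1-um-radius disc
  slab <- voxelize(make_round_cell(8, 1, 1), c(0.1, 0.1, 0.5),
                   half_cell = TRUE)
  p <- sim_params(D = 3, F0 = 0, K_dep = 0, t_post = 0.05, t_pulse = 1e-3,
                  laser_rate = log(1e3) / 1e-3, dt_pulse = 5e-4)
  sim <- simulate_photoactivation(p, slab, roi_spec(c(0, 0), 1))
  ret <- stats::approx(sim$times, sim$roi_raw, 0.035)$y /
    stats::approx(sim$times, sim$roi_raw, 0)$y
  expect_equal(ret, disc_retention(3, 0.035), tolerance = 0.02)
})

test_that("decay curves respond monotonically to the kinetic parameters", {
  lib <- tiny_library()
  tt <- lib$times
  pick <- function(F, K) lib$curves[, lib$F == F & lib$K_dep == K]
  # faster depolymerization: lower curve everywhere
  expect_true(all(pick(100, 0.10) <= pick(100, 0.02) + 1e-6))
  # larger G fraction (smaller F): lower curve while diffusion dominates
  early <- tt <= 2
  expect_true(all(pick(60, 0.06)[early] <= pick(140, 0.06)[early] + 1e-6))
  # normalized decay curves are non-increasing (tolerance 1e-3)
  expect_true(all(apply(lib$curves, 2, function(v) all(diff(v) <= 1e-3))))
})

test_that("mesh refinement changes the ROI curve by less than 1% pointwise", {
  p <- sim_params(D = 3, F0 = 100, K_dep = 0.06, t_post = 3)
  tt <- seq(0.035, 3, by = 0.05)
  val <- function(sp) {
    g <- voxelize(tiny_geometry(), sp, half_cell = TRUE)
    curve_value(normalize_curve(simulate_photoactivation(p, g, tiny_roi())), tt)
  }
  expect_lt(max(abs(val(c(0.25, 0.25, 0.125)) - val(c(0.125, 0.125, 0.0625)))),
            0.01)
})

test_that("normalization fixes the curve to 1 at t_norm, interpolating as needed", {
  cur <- normalize_curve(c(0.01, 0.035, 1, 2), c(5, 5, 5, 5))
  expect_true(all(cur$value == 1))
  cur2 <- normalize_curve(c(0.035, 1), c(4, 2))
  expect_equal(cur2$value, c(1, 0.5))
  # t_norm between samples: linear interpolation of the normalizer
  cur3 <- normalize_curve(c(0.03, 0.04, 1), c(6, 2, 1), t_norm = 0.035)
  expect_equal(cur3$time[1], 0.035)
  expect_equal(cur3$value[1], 1)
  expect_equal(cur3$value[2], 2 / 4)  # normalizer is (6+2)/2 = 4
  expect_error(normalize_curve(c(0.035, 1), c(0, 1)), "positive")
  expect_error(normalize_curve(c(0.1, 1), c(2, 1), t_norm = 0.035), "range")
})

test_that("ROI mean over stored fields equals direct summation", {
  grd <- tiny_grid()
  ridx <- roi_interior_index(grd, tiny_roi())
  n <- grd$n
  # uniform, zero-outside-ROI, and checkerboard fields
  chk <- rep_len(c(1, 2), n)
  zro <- numeric(n); zro[-ridx] <- 7
  fields <- list(
    list(time = 0, G = rep(3, n), F = rep(2, n)),
    list(time = 1, G = zro, F = numeric(n)),
    list(time = 2, G = chk, F = chk)
  )
  ts <- roi_mean_timeseries(fields, grd, tiny_roi())
  expect_equal(ts$roi_mean[1], 5)
  expect_equal(ts$roi_mean[2], 0)
  expect_equal(ts$roi_mean[3], mean(2 * chk[ridx]))
  expect_error(roi_mean_timeseries(list(), grd, tiny_roi()), "no fields")
})

test_that("delay loss is zero at zero delay and grows with the delay", {
  loss <- delay_loss(3, c(0, 0.02, 0.05, 0.1), tiny_grid(), tiny_roi())
  expect_equal(unname(loss[1]), 0)
  expect_true(all(diff(loss) > 0))
  expect_true(all(loss >= 0 & loss < 1))
})
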