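# Synthetic experiments: simulated decay curves with a known ground truth,
# sampled and degraded like camera data, for closed-loop validation of the
# fitting pipeline.

#' Generate a synthetic experimental decay curve
#'
#' Forward-simulates (or reuses) a noise-free truth curve, samples it at the
#' camera frame times, adds independent Gaussian noise per frame, and
#' normalizes to the first recorded frame -- exactly the processing applied
#' to real image series. The Gaussian noise standard deviation is `noise`
#' times the (pre-noise) first-frame intensity; the noise model is
#' deliberately minimal and is recorded in the curve metadata.
#'
#' @param truth list with elements `F0` (uM), `K_dep` (1/s) and optionally
#'   `D` (um^2/s, default 3)
#' @param grid,roi simulation domain (ignored when `truth_curve` is given)
#' @param fps camera frame rate (frames/s)
#' @param first_frame time of the first recorded frame after the pulse (s)
#' @param duration recording duration (s)
#' @param noise relative noise level (s.d. / first-frame intensity)
#' @param seed integer seed; identical seeds reproduce identical curves
#' @param truth_curve optional precomputed noise-free `maap_curve` for this
#'   truth (e.g. a library curve), reused across replicates
#' @param A_tot total actin (uM)
#' @return an object of class `maap_synth`: `curve` (a `maap_curve`
#'   normalized at `first_frame`), `truth`, `acquisition`, `seed`
#' @export
generate_synthetic_curve <- function(truth, grid = NULL, roi = NULL,
                                     fps = 30, first_frame = 0.035,
                                     duration = 25, noise = 0.02,
                                     seed = 1L, truth_curve = NULL,
                                     A_tot = 200) {
  stopifnot(fps > 0, noise >= 0, first_frame >= 0)
  if (is.null(truth_curve)) {
    p <- sim_params(D = truth$D %||% 3, A_tot = A_tot, F0 = truth$F0,
                    K_dep = truth$K_dep, t_post = duration + 1 / fps)
    sim <- simulate_photoactivation(p, grid, roi)
    truth_curve <- normalize_curve(sim, t_norm = min(first_frame, 0.035))
  }
  if (first_frame < min(truth_curve$time) ||
      first_frame > max(truth_curve$time))
    stop("first frame lies outside the simulated time range")
  frames <- seq(first_frame, min(duration, max(truth_curve$time)),
                by = 1 / fps)
  if (length(frames) < 2) stop("acquisition window contains fewer than 2 frames")
  ideal <- curve_value(truth_curve, frames)
  rng <- local({ set.seed(seed); stats::rnorm(length(frames), 0, 1) })
  vals <- ideal + noise * ideal[1] * rng
  vals <- vals / vals[1]
  curve <- new_curve(frames, vals, first_frame,
                     meta = list(truth = truth, noise = noise, fps = fps,
                                 seed = seed, noise_model = "additive Gaussian"))
  structure(list(curve = curve, truth = truth,
                 acquisition = list(fps = fps, first_frame = first_frame,
                                    duration = duration),
                 noise = noise, seed = seed),
            class = "maap_synth")
}

#' @export
print.maap_synth <- function(x, ...) {
  cat(sprintf(
    "<maap_synth> truth F = %g uM, K_dep = %g /s; %g frames/s from %g s, noise %g%%, seed %d\n",
    x$truth$F0, x$truth$K_dep, x$acquisition$fps, x$acquisition$first_frame,
    100 * x$noise, x$seed))
  invisible(x)
}

#' Parameter-recovery study on synthetic data
#'
#' For each ground-truth condition and noise level, generates `n_per`
#' synthetic curves (with per-curve seeds derived deterministically from
#' `seed`), fits each against the library, and tabulates recovery quality:
#' median absolute error, bias, and the fraction of fits landing within one
#' grid step of the truth, per parameter.
#'
#' @param library a `maap_library` to fit against; its grid also defines the
#'   "one grid step" tolerance
#' @param truths data.frame with columns `F0` and `K_dep` (on-grid truths
#'   reuse the library curve as the noise-free reference; off-grid truths
#'   require `grid`/`roi` to simulate)
#' @param noise_levels relative noise levels to test
#' @param n_per number of replicate curves per condition
#' @param seed master seed
#' @param fps,first_frame,duration acquisition model
#' @param grid,roi simulation domain for off-grid truths
#' @param fitgrid a [fit_grid()] used for the fits
#' @return data.frame with one row per (truth, noise level): median absolute
#'   errors, biases, and `frac_within_step` per parameter, plus `n`
#' @export
parameter_recovery_study <- function(library, truths, noise_levels = 0.02,
                                     n_per = 50, seed = 1L, fps = 30,
                                     first_frame = 0.035, duration = NULL,
                                     grid = NULL, roi = NULL,
                                     fitgrid = NULL) {
  stopifnot(inherits(library, "maap_library"), is.data.frame(truths))
  duration <- duration %||% max(library$times)
  fitgrid <- fitgrid %||% fit_grid(end = min(25, max(library$times)),
                                   t_norm = library$meta$t_norm)
  stepF <- min(diff(sort(unique(library$F))))
  stepK <- min(diff(sort(unique(library$K_dep))))
  out <- list()
  for (i in seq_len(nrow(truths))) {
    tr <- list(F0 = truths$F0[i], K_dep = truths$K_dep[i],
               D = library$spec$D)
    on_grid <- any(library$F == tr$F0 & library$K_dep == tr$K_dep)
    ref <- if (on_grid) library_curve(library, tr$F0, tr$K_dep) else NULL
    if (is.null(ref) && is.null(grid))
      stop("off-grid truth requires a simulation grid")
    for (nz in noise_levels) {
      errF <- errK <- numeric(n_per)
      for (r in seq_len(n_per)) {
        sub_seed <- (seed * 10000L + i * 1000L + round(1e4 * nz) + r) %% .Machine$integer.max
        sy <- generate_synthetic_curve(tr, grid, roi, fps = fps,
                                       first_frame = first_frame,
                                       duration = duration, noise = nz,
                                       seed = sub_seed, truth_curve = ref,
                                       A_tot = library$spec$A_tot)
        ft <- fit_curve(sy$curve, library, fitgrid, k = 0)
        errF[r] <- ft$F - tr$F0
        errK[r] <- ft$K_dep - tr$K_dep
      }
      out[[length(out) + 1L]] <- data.frame(
        F0 = tr$F0, K_dep = tr$K_dep, noise = nz, n = n_per,
        mae_F = stats::median(abs(errF)), bias_F = mean(errF),
        frac_within_step_F = mean(abs(errF) <= stepF + 1e-9),
        mae_K = stats::median(abs(errK)), bias_K = mean(errK),
        frac_within_step_K = mean(abs(errK) <= stepK + 1e-9))
    }
  }
  do.call(rbind, out)
}
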