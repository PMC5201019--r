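#' Simulation parameters
#'
#' Bundles the kinetic and protocol parameters of a photoactivation
#' simulation. Units are fixed throughout the package: micrometres, seconds
#' and micromolar.
#'
#' The cytoplasm is assumed to be at steady state: the bulk F- and G-actin
#' concentrations `F0` and `G0 = A_tot - F0` are constant during the
#' experiment, so the pseudo-first-order polymerization rate is tied to the
#' depolymerization rate by detailed balance,
#' `k_pol = K_dep * F0 / G0` (see
#' [steady_state_polymerization_rate()]). Photoactivation converts dark actin
#' to its photoactivated ('PA') form without changing any rate: PA-G diffuses
#' with coefficient `D`, PA-F is immobile, and the two exchange with rates
#' `(k_pol, K_dep)`.
#'
#' @param D G-actin diffusion coefficient (um^2/s)
#' @param A_tot total actin concentration (uM)
#' @param F0 F-actin concentration (uM), `0 <= F0 < A_tot`
#' @param K_dep F-actin depolymerization rate (1/s)
#' @param t_pulse duration of the activation pulse (s)
#' @param laser_rate first-order dark-to-PA conversion rate inside the ROI
#'   during the pulse (1/s). The default converts >99.9% of the resident
#'   fluorophores within the 65-ms pulse, i.e. the region is driven to
#'   essentially complete activation.
#' @param t_post simulated time after the pulse (s)
#' @param t_norm normalization time: decay curves are divided by their value
#'   this long after the pulse, mimicking the first recorded frame (s)
#' @param dt_pulse solver time step during the pulse (s)
#' @return an object of class `maap_params`
#' @export
sim_params <- function(D = 3, A_tot = 200, F0 = 100, K_dep = 0.06,
                       t_pulse = 0.065, laser_rate = log(1e3) / 0.065,
                       t_post = 25, t_norm = 0.035, dt_pulse = 1e-3) {
  if (D < 0) stop("D must be >= 0")
  if (A_tot <= 0) stop("A_tot must be positive")
  if (F0 < 0 || F0 >= A_tot) stop("F0 must satisfy 0 <= F0 < A_tot")
  if (K_dep < 0) stop("K_dep must be >= 0")
  if (t_pulse <= 0 || t_post <= 0) stop("t_pulse and t_post must be positive")
  if (t_norm >= t_post) stop("t_norm must fall inside the recorded decay")
  G0 <- A_tot - F0
  structure(
    list(D = D, A_tot = A_tot, F0 = F0, G0 = G0, K_dep = K_dep,
         k_pol = steady_state_polymerization_rate(F0, G0, K_dep),
         t_pulse = t_pulse, laser_rate = laser_rate, t_post = t_post,
         t_norm = t_norm, dt_pulse = dt_pulse),
    class = "maap_params"
  )
}

#' Polymerization rate at steady state
#'
#' With constant bulk pools, the polymerization flux `k_pol * G0` must equal
#' the depolymerization flux `K_dep * F0`, giving
#' `k_pol = K_dep * F0 / G0`. With these rates the spatially uniform
#' `(G0, F0)` state is stationary, so the dark pools never need to be
#' simulated explicitly.
#'
#' @param F0 F-actin concentration (uM)
#' @param G0 G-actin concentration (uM), must be positive
#' @param K_dep depolymerization rate (1/s)
#' @return pseudo-first-order polymerization rate (1/s)
#' @examples
#' steady_state_polymerization_rate(100, 100, 0.06)  # 0.06
#' steady_state_polymerization_rate(150, 50, 0.1)    # 0.3
#' @export
steady_state_polymerization_rate <- function(F0, G0, K_dep) {
  if (any(G0 <= 0)) stop("G0 must be positive")
  if (any(F0 < 0) || any(K_dep < 0)) stop("F0 and K_dep must be >= 0")
  K_dep * F0 / G0
}

#' @export
print.maap_params <- function(x, ...) {
  cat(sprintf(
    "<maap_params> D = %g um^2/s, A_tot = %g uM (F = %g, G = %g), K_dep = %g /s, k_pol = %.4g /s\n",
    x$D, x$A_tot, x$F0, x$G0, x$K_dep, x$k_pol))
  cat(sprintf("  pulse %g ms (laser %0.3g /s), decay %g s, normalized at %g s\n",
              1e3 * x$t_pulse, x$laser_rate, x$t_post, x$t_norm))
  invisible(x)
}
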