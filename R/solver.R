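# Sparse finite-volume diffusion operator and cached implicit stepper.
#
# The diffusion equation is discretized with the standard 7-point stencil on
# the interior voxels of a maap_grid. Omitting couplings to exterior voxels
# realizes the zero-flux (closed-cell) boundary condition exactly, and makes
# the operator symmetric with zero column sums, so backward-Euler steps
# conserve total mass to linear-solver precision. Cholesky factorizations of
# (I + dt * D * L) are cached per grid (keyed by dt * D), which makes library
# sweeps over many kinetic parameter combinations at a fixed diffusion
# coefficient essentially free of refactorization cost.

# Unit-coefficient Laplacian (positive semi-definite), built lazily per grid.
#' @noRd
grid_laplacian <- function(grid) {
  if (!is.null(grid$cache$L)) return(grid$cache$L)
  mask <- grid$mask
  d <- grid$dims
  n <- grid$n
  idx <- array(0L, d)
  idx[mask] <- seq_len(n)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diagv <- numeric(n)
  for (ax in 1:3) {
    h2 <- grid$spacing[ax]^2
    m1 <- slice_drop_last(mask, ax); m2 <- slice_drop_first(mask, ax)
    both <- m1 & m2
    if (!any(both)) next
    i1 <- slice_drop_last(idx, ax)[both]
    i2 <- slice_drop_first(idx, ax)[both]
    ii <- c(ii, i1, i2); jj <- c(jj, i2, i1)
    xx <- c(xx, rep(-1 / h2, 2 * length(i1)))
    diagv <- diagv + (tabulate(i1, n) + tabulate(i2, n)) / h2
  }
  L <- Matrix::forceSymmetric(
    Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                         x = c(xx, diagv), dims = c(n, n)))
  grid$cache$L <- L
  L
}

#' @noRd
slice_drop_last <- function(a, ax) {
  d <- dim(a)
  switch(ax, a[-d[1], , , drop = FALSE], a[, -d[2], , drop = FALSE],
         a[, , -d[3], drop = FALSE])
}

#' @noRd
slice_drop_first <- function(a, ax) {
  switch(ax, a[-1, , , drop = FALSE], a[, -1, , drop = FALSE],
         a[, , -1, drop = FALSE])
}

# Cholesky factor of (I + theta * L), theta = dt * D, cached on the grid.
#' @noRd
diffusion_factor <- function(grid, theta) {
  key <- sprintf("chol_%.12g", theta)
  f <- grid$cache[[key]]
  if (is.null(f)) {
    L <- grid_laplacian(grid)
    A <- Matrix::Diagonal(grid$n) + theta * L
    f <- Matrix::Cholesky(methods::as(A, "symmetricMatrix"),
                          LDL = FALSE, super = TRUE)
    grid$cache[[key]] <- f
  }
  f
}

# One backward-Euler diffusion step: solve (I + dt D L) u_new = u.
#' @noRd
diffusion_step <- function(grid, u, theta) {
  as.numeric(Matrix::solve(diffusion_factor(grid, theta), u,
                           system = "A"))
}

# Piecewise-constant time-step ladder for the decay phase: fine stepping
# while the G-actin front leaves the ROI, coarser once the dynamics are slow.
# Quantized (few distinct dt values) so each factorization is reused.
#' @noRd
decay_schedule <- function(t_post, dt0 = 1e-3) {
  seg <- rbind(c(0.1, dt0), c(0.5, 5e-3), c(3, 2e-2), c(Inf, 5e-2))
  dts <- numeric(0)
  t <- 0
  for (s in seq_len(nrow(seg))) {
    hi <- min(seg[s, 1], t_post)
    if (hi <= t) next
    dt <- seg[s, 2]
    k <- ceiling(round((hi - t) / dt, 9))
    dts <- c(dts, rep(dt, k))
    t <- t + k * dt
    if (t >= t_post - 1e-12) break
  }
  dts
}
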