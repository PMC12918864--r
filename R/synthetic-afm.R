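## Hertz prefactor in pN when E_r is in Pa and R, delta in nm:
## F[N] = (4/3) E_r sqrt(R[m]) delta[m]^{3/2}  ->  1e-6 scale in pN/nm units.
hertz_prefactor <- function(E_r, R) (4 / 3) * E_r * sqrt(R) * 1e-6

## Indentation delta solving  C*delta^{3/2} + k*delta = k*(z - z0)
## (cantilever compliance d = F/k removed from the piezo travel).
## Vectorized safeguarded Newton; residual is convex and increasing in delta,
## so iteration from delta = z - z0 converges monotonically. tol in nm.
solve_indentation <- function(dz, C, k, tol = 1e-6, max_iter = 200L) {
  delta <- pmax(dz, 0)
  for (i in seq_len(max_iter)) {
    f <- C * delta^1.5 + k * delta - k * dz
    fp <- 1.5 * C * sqrt(delta) + k
    step <- f / fp
    delta <- pmax(delta - step, 0)
    if (max(abs(step)) < tol) break
  }
  delta
}

#' Simulate an AFM approach force curve (Hertz forward model)
#'
#' Generates an approach segment on a uniform piezo grid: baseline
#' `slope * z + noise` before contact, plus for `z >= z0` the Hertzian force
#' of a rigid sphere indenting an elastic half-space,
#' `F = (4/3) E_r sqrt(R) delta^{3/2}`, with the indentation solved
#' self-consistently against cantilever deflection (`delta = (z - z0) - F/k`).
#'
#' @param E_r Reduced Young's modulus (Pa, > 0).
#' @param z0 True contact point (nm, inside `z_range`).
#' @param R Probe radius (nm; default 3660, a 7.32 um bead).
#' @param k Cantilever spring constant (pN/nm; default 30).
#' @param baseline_slope Baseline tilt (pN/nm; default 0).
#' @param noise_sd Additive force noise sd (pN; default 0).
#' @param n_points Samples on the grid (default 1024).
#' @param z_range Length-2 z interval (nm; default `c(0, 4000)`).
#' @param seed Integer seed.
#' @return A `force_curve` object (see [force_curve()]) with attribute
#'   `truth = list(E_r, z0, baseline_slope, noise_sd)`.
#' @export
simulate_force_curve <- function(E_r, z0, R = 3660, k = 30,
                                 baseline_slope = 0, noise_sd = 0,
                                 n_points = 1024L, z_range = c(0, 4000),
                                 seed = 1L) {
  stopifnot(E_r > 0, R > 0, k > 0, n_points >= 8L)
  if (z0 <= z_range[1L] || z0 >= z_range[2L])
    stop("simulate_force_curve: z0 must lie strictly inside z_range")
  set.seed(seed)
  z <- seq(z_range[1L], z_range[2L], length.out = n_points)
  force <- baseline_slope * z
  if (noise_sd > 0) force <- force + stats::rnorm(n_points, sd = noise_sd)
  contact <- z >= z0
  if (any(contact)) {
    delta <- solve_indentation(z[contact] - z0, hertz_prefactor(E_r, R), k)
    force[contact] <- force[contact] + hertz_force(E_r, R, delta)
  }
  fc <- force_curve(z = z, force = force, k = k, R = R)
  attr(fc, "truth") <- list(E_r = E_r, z0 = z0,
                            baseline_slope = baseline_slope,
                            noise_sd = noise_sd)
  fc
}

#' Write a force curve as TSV
#'
#' Dialect: `#`-prefixed metadata lines (`k_pN_per_nm`, `R_nm`) followed by
#' a header and tab-separated `z_nm`, `force_pN` columns.
#'
#' @param curve A `force_curve`.
#' @param path Output path.
#' @export
write_force_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# k_pN_per_nm\t%.10g", curve$k),
               sprintf("# R_nm\t%.10g", curve$R),
               "z_nm\tforce_pN"), con)
  utils::write.table(data.frame(z = sprintf("%.10g", curve$z),
                                f = sprintf("%.10g", curve$force)),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
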