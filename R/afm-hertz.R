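#' Construct a force curve
#'
#' Approach segment of an AFM force-distance measurement with cantilever
#' deflection already converted to force (`F = k d`).
#'
#' @param z Piezo extension (nm), strictly monotone increasing toward the
#'   sample.
#' @param force Force (pN).
#' @param k Cantilever spring constant (pN/nm).
#' @param R Probe radius (nm).
#' @param trigger Maximum force used for fitting (pN; default 1e4 = 10 nN).
#' @return A `force_curve` object.
#' @export
force_curve <- function(z, force, k, R, trigger = 1e4) {
  z <- as.numeric(z); force <- as.numeric(force)
  if (length(z) != length(force)) stop("force_curve: z and force lengths differ")
  if (any(!is.finite(z)) || any(!is.finite(force)))
    stop("force_curve: non-finite values")
  if (any(diff(z) <= 0)) stop("force_curve: z must be strictly increasing")
  if (k <= 0 || R <= 0) stop("force_curve: k and R must be positive")
  structure(list(z = z, force = force, k = k, R = R, trigger = trigger),
            class = "force_curve")
}

#' Read a force curve TSV
#'
#' Dialect: `#`-prefixed metadata lines carrying `k_pN_per_nm` and `R_nm`,
#' then a `z_nm<TAB>force_pN` header and two tab-separated numeric columns.
#' Metadata missing from the header may be supplied via `k` / `R`.
#'
#' @param path File path.
#' @param k,R Overrides for the spring constant (pN/nm) and probe radius
#'   (nm) when absent from the file header.
#' @param trigger Trigger force (pN).
#' @return A `force_curve`.
#' @export
read_force_curve <- function(path, k = NULL, R = NULL, trigger = 1e4) {
  if (!file.exists(path)) stop("read_force_curve: no such file: ", path)
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- lines[meta_idx]
  get_meta <- function(key) {
    hit <- grep(paste0("\\b", key, "\\b"), meta, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    as.numeric(sub(".*\\t", "", hit[1L]))
  }
  k <- if (!is.null(k)) k else get_meta("k_pN_per_nm")
  R <- if (!is.null(R)) R else get_meta("R_nm")
  if (is.null(k) || is.na(k)) stop("read_force_curve: spring constant k missing (header k_pN_per_nm or k=)")
  if (is.null(R) || is.na(R)) stop("read_force_curve: probe radius R missing (header R_nm or R=)")
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  header <- grepl("^z_nm", body[1L])
  data_lines <- if (header) body[-1L] else body
  data_lines <- data_lines[nzchar(data_lines)]
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("read_force_curve: malformed row at data line ", bad[1L])
  z <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  f <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(z) || anyNA(f))
    stop("read_force_curve: non-numeric value at data line ",
         which(is.na(z) | is.na(f))[1L])
  force_curve(z = z, force = f, k = k, R = R, trigger = trigger)
}

#' Hertz force of a sphere indenting an elastic half-space
#'
#' `F = (4/3) E_r sqrt(R) delta^{3/2}` with consistent units
#' (E_r in Pa, R and delta in nm, F in pN).
#'
#' @param E_r Reduced Young's modulus (Pa).
#' @param R Sphere radius (nm).
#' @param delta Indentation depth (nm, >= 0).
#' @return Force in pN.
#' @examples
#' hertz_force(1000, 3660, 1000)  # ~2550 pN
#' @export
hertz_force <- function(E_r, R, delta) {
  if (any(delta < 0)) stop("hertz_force: negative indentation")
  hertz_prefactor(E_r, R) * delta^1.5
}

#' Line-intersection estimate of the contact point
#'
#' Fits a least-squares line to the flat, undeformed baseline (first
#' `baseline_frac` of points by z) and another to the in-contact region
#' (last `contact_frac` of points); the estimated contact point is the z of
#' their intersection, clamped to the curve range. Near-parallel lines fall
#' back to the first point exceeding the baseline by 3 baseline-noise sds
#' and raise a `degenerate` flag.
#'
#' @param curve A `force_curve`.
#' @param baseline_frac,contact_frac Fractions of the curve used for the two
#'   line fits (each region must keep >= 3 points; sum <= 1).
#' @return List with `z0`, `baseline` (intercept, slope), `flags`.
#' @export
estimate_contact_point <- function(curve, baseline_frac = 0.4,
                                   contact_frac = 0.2) {
  stopifnot(inherits(curve, "force_curve"))
  if (baseline_frac + contact_frac > 1)
    stop("estimate_contact_point: baseline_frac + contact_frac > 1")
  n <- length(curve$z)
  n_b <- floor(n * baseline_frac); n_c <- floor(n * contact_frac)
  if (n_b < 3L || n_c < 3L)
    stop("estimate_contact_point: each region needs >= 3 points")
  zb <- curve$z[seq_len(n_b)]; fb <- curve$force[seq_len(n_b)]
  zc <- curve$z[(n - n_c + 1L):n]; fc <- curve$force[(n - n_c + 1L):n]
  c1 <- stats::lm.fit(cbind(1, zb), fb)$coefficients
  c2 <- stats::lm.fit(cbind(1, zc), fc)$coefficients
  flags <- character(0)
  dslope <- c2[2L] - c1[2L]
  noise_sd <- stats::sd(fb - (c1[1L] + c1[2L] * zb))
  scale_slope <- max(abs(c1[2L]), abs(c2[2L]), 1e-12)
  if (abs(dslope) < 1e-8 * scale_slope || abs(dslope) < 1e-15) {
    flags <- c(flags, "degenerate")
    resid <- curve$force - (c1[1L] + c1[2L] * curve$z)
    hit <- which(resid > 3 * max(noise_sd, .Machine$double.eps))
    z0 <- if (length(hit)) curve$z[hit[1L]] else curve$z[n]
  } else {
    z0 <- unname((c1[1L] - c2[1L]) / dslope)
  }
  if (z0 <= curve$z[1L] || z0 >= curve$z[n]) {
    flags <- c(flags, "boundary-contact")
    z0 <- min(max(z0, curve$z[1L]), curve$z[n])
  }
  list(z0 = z0, baseline = unname(c1), baseline_noise_sd = noise_sd,
       flags = flags)
}

## Baseline-corrected Hertz fit at one candidate contact sample.
## E_r by closed-form least squares of F against (4/3)sqrt(R) delta^{3/2};
## delta includes the cantilever-compliance correction delta = (z-z0) - F/k.
fit_at_candidate <- function(z, f_corr, idx, k, R, trigger) {
  z0 <- z[idx]
  sel <- which(z >= z0 & f_corr <= trigger)
  if (length(sel) < 3L) return(NULL)
  delta <- (z[sel] - z0) - f_corr[sel] / k
  keep <- delta >= 0
  if (sum(keep) < 3L) return(NULL)
  x <- (4 / 3) * sqrt(R) * 1e-6 * delta[keep]^1.5   # pN per Pa
  y <- f_corr[sel][keep]
  E_r <- sum(x * y) / sum(x * x)
  resid <- y - E_r * x
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  list(E_r = E_r, z0 = z0, idx = idx, rss = rss,
       r2 = if (tss > 0) 1 - rss / tss else 1, n_fit = length(y))
}

#' Refine the contact point by iterative candidate testing
#'
#' Tests every sample within `window` points of the initial estimate: each
#' candidate contact point gets a baseline-subtracted Hertz fit (closed-form
#' least squares of force against `delta^{3/2}`, indentation corrected for
#' cantilever compliance, fit range contact to trigger force) and the
#' candidate with minimal residual sum of squares wins.
#'
#' With `recenter = TRUE` (default) the window is re-centered on the best
#' candidate and the search repeated whenever the optimum sits at the window
#' edge, so a poor initial estimate still walks to the interior minimum; the
#' final fit keeps a `boundary-window` flag only if the walk hits the curve
#' ends.
#'
#' @param curve A `force_curve`.
#' @param z0_est Initial contact-point estimate (nm).
#' @param window Candidate half-width in samples (default 25).
#' @param baseline Length-2 (intercept, slope) baseline to subtract; fitted
#'   from the first 40% of points when `NULL`.
#' @param recenter Re-center and repeat while the optimum is at the window
#'   edge.
#' @return A `hertz_fit` list: `E_r` (Pa), `z0` (nm), `rss`, `r2`, `n_fit`,
#'   `flags`.
#' @export
refine_contact_point <- function(curve, z0_est, window = 25L,
                                 baseline = NULL, recenter = TRUE) {
  stopifnot(inherits(curve, "force_curve"), window >= 1L)
  z <- curve$z
  if (z0_est < z[1L] || z0_est > z[length(z)])
    stop("refine_contact_point: z0_est outside curve range")
  if (is.null(baseline)) {
    n_b <- max(3L, floor(length(z) * 0.4))
    baseline <- unname(stats::lm.fit(cbind(1, z[seq_len(n_b)]),
                                     curve$force[seq_len(n_b)])$coefficients)
  }
  f_corr <- curve$force - (baseline[1L] + baseline[2L] * z)
  centre <- which.min(abs(z - z0_est))
  flags <- character(0)
  fit <- NULL; cand <- integer(0); fits <- list(); best <- NA_integer_
  for (pass in seq_len(if (recenter) 50L else 1L)) {
    cand <- max(1L, centre - window):min(length(z) - 3L, centre + window)
    fits <- lapply(cand, function(i)
      fit_at_candidate(z, f_corr, i, curve$k, curve$R, curve$trigger))
    ok <- !vapply(fits, is.null, TRUE)
    fits <- fits[ok]; cand <- cand[ok]
    pos <- if (length(fits)) vapply(fits, function(f) f$E_r > 0, TRUE) else logical(0)
    if (!length(fits) || !any(pos)) {
      return(structure(list(E_r = NA_real_, z0 = NA_real_, rss = NA_real_,
                            r2 = NA_real_, n_fit = 0L,
                            flags = "negative-modulus"),
                       class = "hertz_fit"))
    }
    fits <- fits[pos]; cand <- cand[pos]
    best <- which.min(vapply(fits, `[[`, 0, "rss"))
    fit <- fits[[best]]
    at_edge <- cand[best] == min(cand) || cand[best] == max(cand)
    at_curve_end <- cand[best] <= 1L || cand[best] >= length(z) - 3L
    if (!at_edge || at_curve_end || cand[best] == centre) break
    centre <- cand[best]
  }
  if (cand[best] == min(cand) || cand[best] == max(cand))
    flags <- c(flags, "boundary-window")
  if (is.finite(fit$r2) && fit$r2 < 0.8) flags <- c(flags, "poor-fit")
  structure(list(E_r = fit$E_r, z0 = fit$z0, rss = fit$rss, r2 = fit$r2,
                 n_fit = fit$n_fit, flags = flags,
                 candidate_rss = vapply(fits, `[[`, 0, "rss")),
            class = "hertz_fit")
}

#' Analyze one force curve (two-stage contact detection + Hertz fit)
#'
#' Composition of [estimate_contact_point()] and [refine_contact_point()];
#' QC flags from both stages propagate into the returned fit.
#'
#' @param curve A `force_curve`.
#' @param baseline_frac,contact_frac See [estimate_contact_point()].
#' @param window See [refine_contact_point()].
#' @return A `hertz_fit`.
#' @export
analyze_curve <- function(curve, baseline_frac = 0.4, contact_frac = 0.2,
                          window = 25L) {
  est <- estimate_contact_point(curve, baseline_frac, contact_frac)
  fit <- refine_contact_point(curve, est$z0, window = window,
                              baseline = est$baseline)
  fit$flags <- union(est$flags, fit$flags)
  fit$z0_initial <- est$z0
  fit
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("Hertz fit: E_r = %.4g Pa, z0 = %.5g nm, r2 = %.4f (n = %d)\n",
              x$E_r, x$z0, x$r2, x$n_fit))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a batch of force-curve files
#'
#' @param paths Character vector of force-curve TSV paths.
#' @param ... Passed to [analyze_curve()] / [read_force_curve()].
#' @param k,R,trigger Metadata overrides.
#' @return Data.frame: `file`, `E_r_Pa`, `z0_nm`, `rss`, `r2`, `flags`.
#' @export
analyze_curve_batch <- function(paths, k = NULL, R = NULL, trigger = 1e4, ...) {
  rows <- lapply(paths, function(p) {
    fit <- analyze_curve(read_force_curve(p, k = k, R = R, trigger = trigger), ...)
    data.frame(file = basename(p), E_r_Pa = fit$E_r, z0_nm = fit$z0,
               rss = fit$rss, r2 = fit$r2,
               flags = paste(fit$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare two groups of fitted moduli
#'
#' Welch and Brown--Forsythe comparison of two groups of reduced Young's
#' moduli, plus the fraction of group B exceeding the maximum of group A
#' (the screen's "above the stiffest control cell" statistic).
#'
#' @param moduli_a,moduli_b Numeric vectors of unflagged `E_r` values (Pa).
#' @return A `group_comparison` with an extra `exceedance_b` field.
#' @export
compare_modulus_groups <- function(moduli_a, moduli_b) {
  moduli_a <- moduli_a[is.finite(moduli_a)]
  moduli_b <- moduli_b[is.finite(moduli_b)]
  if (length(moduli_a) < 2L || length(moduli_b) < 2L)
    stop("compare_modulus_groups: need >= 2 unflagged fits per group")
  cmp <- compare_groups(moduli_a, moduli_b)
  cmp$exceedance_b <- mean(moduli_b > max(moduli_a))
  cmp
}

#' Convert reduced modulus to Young's modulus
#'
#' `E = E_r (1 - nu^2)` for a rigid probe.
#' @param E_r Reduced modulus (Pa).
#' @param nu Poisson ratio (default 0.5, incompressible cell).
#' @return Young's modulus (Pa).
#' @export
young_from_reduced <- function(E_r, nu = 0.5) E_r * (1 - nu^2)
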