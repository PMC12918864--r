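#' Ridged-device geometry
#'
#' Layout of the diagonal-ridge sorting channel used to window ridge
#' interactions and bin outlet destinations. Distances are in micrometres.
#' The y axis points toward the stiff outlets: positive deflection sorts a
#' cell toward outlet 5.
#'
#' @param n_ridges Number of diagonal ridges (device default 14).
#' @param x_first Along-flow position of the first ridge centerline at
#'   `y = y_ref`.
#' @param spacing Centerline spacing between consecutive ridges.
#' @param angle_deg Ridge angle to the flow axis (degrees).
#' @param width Interaction window full width `w` (ridge width plus roughly
#'   one cell diameter).
#' @param y_extent Length-2 channel y interval.
#' @param outlet_breaks Four strictly increasing interior y boundaries
#'   partitioning `y_extent` into outlets 1..5 (default: equal fifths).
#' @param y_ref Reference y for the centerline anchors.
#' @return A `ridge_geometry` list.
#' @export
ridge_geometry <- function(n_ridges = 14L, x_first = 150, spacing = 150,
                           angle_deg = 30, width = 40,
                           y_extent = c(-300, 300), outlet_breaks = NULL,
                           y_ref = 0) {
  stopifnot(n_ridges >= 1L, width > 0, spacing > 0,
            y_extent[2L] > y_extent[1L])
  if (is.null(outlet_breaks))
    outlet_breaks <- y_extent[1L] + diff(y_extent) * (1:4) / 5
  if (length(outlet_breaks) != 4L || is.unsorted(outlet_breaks, strictly = TRUE))
    stop("ridge_geometry: outlet_breaks must be 4 strictly increasing values")
  structure(list(
    n_ridges = as.integer(n_ridges),
    ridge_x = x_first + spacing * (seq_len(n_ridges) - 1L),
    angle_deg = angle_deg, tan_theta = tan(angle_deg * pi / 180),
    width = width, y_extent = y_extent, outlet_breaks = outlet_breaks,
    y_ref = y_ref
  ), class = "ridge_geometry")
}

#' Per-ridge deflection model for the track simulator
#'
#' Each simulated cell carries a latent stiffness score `s ~ N(0, 1)`. Under
#' ridge `i` the cell gains a y deflection drawn
#' `N(mean + stiffness_gain * s, sd)` and dwells
#' `max(0, N(dwell_mean, dwell_sd))` seconds.
#'
#' @param mean Baseline mean deflection per ridge (um).
#' @param sd Deflection sd per ridge (um).
#' @param stiffness_gain Deflection gained per unit latent stiffness (um).
#' @param dwell_mean,dwell_sd Dwell time distribution under a ridge (s).
#' @return A `deflection_model` list.
#' @export
deflection_model <- function(mean = 0, sd = 0, stiffness_gain = 0,
                             dwell_mean = 0.01, dwell_sd = 0) {
  stopifnot(sd >= 0, dwell_mean >= 0, dwell_sd >= 0)
  structure(list(mean = mean, sd = sd, stiffness_gain = stiffness_gain,
                 dwell_mean = dwell_mean, dwell_sd = dwell_sd),
            class = "deflection_model")
}

#' Simulate cell tracks through the ridged sorting device
#'
#' Cells advance at constant free-flow speed along the flow axis, and under
#' each ridge window dwell a drawn time while gaining a drawn y deflection;
#' positions are sampled at the camera frame rate with isotropic Gaussian
#' noise. The generative path is built in the along-flow coordinate
#' `u = x - (y - y_ref) tan(theta)`, so the interaction windows match the
#' analysis windowing rule exactly.
#'
#' @param geometry [ridge_geometry()].
#' @param n_cells Number of tracks.
#' @param model [deflection_model()].
#' @param fps Frame rate (frames/s; cameras in this assay run 2500--3000).
#' @param pos_noise Position noise sd (um) on both axes.
#' @param speed Free-flow speed (um/s).
#' @param y_start Starting y (um); recycled over cells.
#' @param seed Integer seed.
#' @return A list with `tracks` (data.frame `TRACK_ID,FRAME,POSITION_X,
#'   POSITION_Y`) and `truth` (list with per-cell `stiffness`, and
#'   `deflections` / `dwells` matrices of cell x ridge ground truth).
#' @export
simulate_tracks <- function(geometry, n_cells, model = deflection_model(),
                            fps = 2500, pos_noise = 0, speed = 20000,
                            y_start = 0, seed = 1L) {
  stopifnot(inherits(geometry, "ridge_geometry"), fps > 0, n_cells >= 1L,
            speed > 0, pos_noise >= 0)
  set.seed(seed)
  nr <- geometry$n_ridges
  w <- geometry$width
  stiff <- stats::rnorm(n_cells)
  defl <- matrix(stats::rnorm(n_cells * nr,
                              mean = model$mean + model$stiffness_gain * stiff,
                              sd = model$sd),
                 nrow = n_cells)
  dwell <- matrix(pmax(0, stats::rnorm(n_cells * nr, mean = model$dwell_mean,
                                       sd = model$dwell_sd)),
                  nrow = n_cells)
  y0 <- rep_len(y_start, n_cells)
  u_end <- geometry$ridge_x[nr] + w / 2 + geometry$width  # short run-out
  res <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    # breakpoints of the piecewise-linear (t, u, y) path
    t_b <- 0; u_b <- 0; y_b <- y0[i]
    for (r in seq_len(nr)) {
      win_in <- geometry$ridge_x[r] - w / 2
      gap <- win_in - u_b[length(u_b)]
      if (gap > 0) {                      # free flight to the window
        t_b <- c(t_b, t_b[length(t_b)] + gap / speed)
        u_b <- c(u_b, win_in)
        y_b <- c(y_b, y_b[length(y_b)])
      }
      tau <- max(dwell[i, r], w / speed) # crossing the window takes >= w/speed
      # y ramps over the middle of the dwell so frames near the window edges
      # see the full deflection regardless of the sampling phase
      t0 <- t_b[length(t_b)]; ylast <- y_b[length(y_b)]
      t_b <- c(t_b, t0 + 0.4 * tau, t0 + 0.6 * tau, t0 + tau)
      u_b <- c(u_b, win_in + 0.4 * w, win_in + 0.6 * w, win_in + w)
      y_b <- c(y_b, ylast, ylast + defl[i, r], ylast + defl[i, r])
      dwell[i, r] <- tau
    }
    gap <- u_end - u_b[length(u_b)]
    t_b <- c(t_b, t_b[length(t_b)] + gap / speed)
    u_b <- c(u_b, u_end)
    y_b <- c(y_b, y_b[length(y_b)])
    tf <- seq(0, t_b[length(t_b)], by = 1 / fps)
    u <- stats::approx(t_b, u_b, xout = tf)$y
    y <- stats::approx(t_b, y_b, xout = tf)$y
    x <- u + (y - geometry$y_ref) * geometry$tan_theta
    if (pos_noise > 0) {
      x <- x + stats::rnorm(length(x), sd = pos_noise)
      y <- y + stats::rnorm(length(y), sd = pos_noise)
    }
    res[[i]] <- data.frame(TRACK_ID = i, FRAME = seq_along(tf) - 1L,
                           POSITION_X = x, POSITION_Y = y)
  }
  list(tracks = do.call(rbind, res),
       truth = list(stiffness = stiff, deflections = defl, dwells = dwell))
}

#' Write a track table CSV
#' @param tracks Data.frame with `TRACK_ID,FRAME,POSITION_X,POSITION_Y`.
#' @param path Output path.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks[, c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
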