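#' Read a TrackMate-style track table
#'
#' CSV with columns `TRACK_ID,FRAME,POSITION_X,POSITION_Y` (x, y in um,
#' integer frames from 0). Frames are sorted within track; duplicate
#' (track, frame) pairs are rejected.
#'
#' @param path CSV path.
#' @return Data.frame sorted by track then frame.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("read_tracks: no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y")
  if (!all(need %in% names(d)))
    stop("read_tracks: expected columns ", paste(need, collapse = ","))
  if (any(d$FRAME != as.integer(d$FRAME)))
    stop("read_tracks: non-integer FRAME at line ",
         which(d$FRAME != as.integer(d$FRAME))[1L] + 1L)
  bad <- which(!is.finite(d$POSITION_X) | !is.finite(d$POSITION_Y))
  if (length(bad))
    stop("read_tracks: malformed position at line ", bad[1L] + 1L)
  d$FRAME <- as.integer(d$FRAME)
  d <- d[order(d$TRACK_ID, d$FRAME), need]
  if (anyDuplicated(d[, c("TRACK_ID", "FRAME")]))
    stop("read_tracks: duplicate (TRACK_ID, FRAME) pair")
  rownames(d) <- NULL
  d
}

#' Per-ridge interaction windows of one track
#'
#' For ridge `i`, the interaction window is the maximal contiguous frame run
#' where the cell's signed along-flow distance to the inclined ridge
#' centerline, `x - [x0_i + (y - y_ref) tan(theta)]`, has magnitude at most
#' `w/2`. Tracks that never enter a window get an empty interval for that
#' ridge.
#'
#' @param track Data.frame of one track (`FRAME,POSITION_X,POSITION_Y`,
#'   sorted by frame).
#' @param geometry [ridge_geometry()].
#' @return List of length `n_ridges`; each element an integer vector of row
#'   indices into `track` (possibly empty).
#' @export
ridge_windows <- function(track, geometry) {
  stopifnot(inherits(geometry, "ridge_geometry"))
  if (nrow(track) < 2L) stop("ridge_windows: track needs >= 2 frames")
  x <- track$POSITION_X; y <- track$POSITION_Y
  half <- geometry$width / 2
  lapply(seq_len(geometry$n_ridges), function(r) {
    d <- x - (geometry$ridge_x[r] + (y - geometry$y_ref) * geometry$tan_theta)
    inside <- abs(d) <= half
    if (!any(inside)) return(integer(0))
    runs <- rle(inside)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    true_runs <- which(runs$values)
    best <- true_runs[which.max(runs$lengths[true_runs])]
    starts[best]:ends[best]
  })
}

#' Per-ridge and cumulative trajectory metrics for one track
#'
#' Deflection under ridge `i` is `y(last window frame) - y(first window
#' frame)`; interaction time is the window length in frames divided by the
#' frame rate. The cumulative statistics sum the first `n_cumulative` ridges
#' (missing windows contribute 0). The predicted outlet is the outlet bin of
#' the track's final y position.
#'
#' @param track One track's data.frame (sorted by frame).
#' @param geometry [ridge_geometry()].
#' @param fps Frame rate (frames/s).
#' @param n_cumulative Ridges entering the cumulative sums (default 5).
#' @return A one-row data.frame: `track_id`, `cum_deflection`, `cum_time`,
#'   `n_ridges_hit`, `outlet`, plus attribute `per_ridge` (deflection and
#'   time per ridge). Tracks with < 2 frames return `NULL`.
#' @export
track_metrics <- function(track, geometry, fps, n_cumulative = 5L) {
  stopifnot(fps > 0)
  if (nrow(track) < 2L) return(NULL)
  wins <- ridge_windows(track, geometry)
  defl <- vapply(wins, function(w)
    if (length(w) >= 1L) track$POSITION_Y[w[length(w)]] - track$POSITION_Y[w[1L]]
    else NA_real_, 0)
  tau <- vapply(wins, function(w) length(w) / fps, 0)
  first <- seq_len(min(n_cumulative, geometry$n_ridges))
  cum_defl <- sum(defl[first], na.rm = TRUE)
  cum_time <- sum(tau[first])
  outlet <- findInterval(track$POSITION_Y[nrow(track)],
                         geometry$outlet_breaks) + 1L
  out <- data.frame(track_id = track$TRACK_ID[1L],
                    cum_deflection = cum_defl, cum_time = cum_time,
                    n_ridges_hit = sum(!is.na(defl)), outlet = outlet)
  attr(out, "per_ridge") <- data.frame(ridge = seq_along(defl),
                                       deflection = defl, time = tau)
  out
}

#' Metrics for every track in a table
#'
#' @param tracks Track table (`TRACK_ID,FRAME,POSITION_X,POSITION_Y`).
#' @param geometry [ridge_geometry()].
#' @param fps Frame rate.
#' @param n_cumulative Ridges entering the cumulative sums.
#' @return Data.frame with one row per track having >= 2 frames.
#' @export
all_track_metrics <- function(tracks, geometry, fps, n_cumulative = 5L) {
  rows <- lapply(split(tracks, tracks$TRACK_ID), track_metrics,
                 geometry = geometry, fps = fps, n_cumulative = n_cumulative)
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Compare two groups of track metrics
#'
#' Welch and Brown--Forsythe tests on cumulative deflection and cumulative
#' interaction time between two track populations.
#'
#' @param metrics_a,metrics_b Data.frames from [all_track_metrics()]
#'   (>= 2 tracks each).
#' @return A list with `deflection` and `time`, each a `group_comparison`.
#' @export
summarize_track_groups <- function(metrics_a, metrics_b) {
  if (nrow(metrics_a) < 2L || nrow(metrics_b) < 2L)
    stop("summarize_track_groups: need >= 2 tracks per group")
  list(deflection = compare_groups(metrics_a$cum_deflection,
                                   metrics_b$cum_deflection),
       time = compare_groups(metrics_a$cum_time, metrics_b$cum_time))
}

#' Fraction of tracks reaching each outlet
#'
#' @param metrics Data.frame from [all_track_metrics()] (>= 1 track).
#' @return Named numeric vector of length 5 summing to 1.
#' @export
outlet_fractions <- function(metrics) {
  if (nrow(metrics) < 1L) stop("outlet_fractions: no tracks")
  tab <- tabulate(metrics$outlet, nbins = 5L)
  stats::setNames(tab / sum(tab), paste0("outlet", 1:5))
}
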