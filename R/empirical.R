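#' Read a head-marker motion-capture series from TSV/CSV
#'
#' Expects long format with columns `time_s, agent_id, group_id, marker,
#' x, y, z`, where `marker` is `"L"` or `"R"` for the left/right head
#' marker, `z` is the vertical axis and `(x, y)` the horizontal plane.
#' The time grid must be uniform (nominally 120 Hz); short runs of
#' missing frames are filled by linear interpolation.
#'
#' @param path Path to a `.tsv`/`.csv` file (separator inferred from the
#'   extension; tab otherwise).
#' @param max_gap_frames Longest run of missing frames that may be
#'   interpolated; longer gaps are an error.
#' @param grid_tol Relative tolerance on the uniformity of the time grid.
#' @return A data.frame of class `marker_series` (sorted, gap-free), with
#'   attributes `rate_hz` and `n_interpolated`.
#' @export
read_marker_series <- function(path, max_gap_frames = 5L, grid_tol = 1e-3) {
  if (!file.exists(path)) {
    stop("read_marker_series(): file not found: ", path, call. = FALSE)
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time_s", "agent_id", "group_id", "marker", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("read_marker_series(): missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!all(df$marker %in% c("L", "R"))) {
    stop("read_marker_series(): 'marker' must be 'L' or 'R'", call. = FALSE)
  }
  times <- sort(unique(df$time_s))
  if (length(times) < 2L) {
    stop("read_marker_series(): need at least 2 frames", call. = FALSE)
  }
  dtv <- diff(times)
  dt <- stats::median(dtv)
  if (any(abs(dtv / dt - round(dtv / dt)) > grid_tol)) {
    stop("read_marker_series(): time grid is not uniform", call. = FALSE)
  }
  full_times <- seq(times[1], times[length(times)], by = dt)
  df <- df[order(df$agent_id, df$marker, df$time_s), ]
  keys <- unique(df[, c("agent_id", "group_id", "marker")])
  n_interp <- 0L
  pieces <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- df$agent_id == keys$agent_id[i] & df$marker == keys$marker[i]
    sub <- df[sel, ]
    idx <- round((sub$time_s - full_times[1]) / dt) + 1L
    missing_idx <- setdiff(seq_along(full_times), idx)
    if (length(missing_idx)) {
      runs <- rle(diff(missing_idx) == 1L)
      longest <- if (length(missing_idx) == 1L) 1L else
        max(c(1L, runs$lengths[runs$values] + 1L))
      if (longest > max_gap_frames) {
        stop("read_marker_series(): gap of ", longest,
             " frames exceeds max_gap_frames for agent ", keys$agent_id[i],
             " marker ", keys$marker[i], call. = FALSE)
      }
      n_interp <- n_interp + length(missing_idx)
    }
    out <- data.frame(time_s = full_times,
                      agent_id = keys$agent_id[i],
                      group_id = keys$group_id[i],
                      marker = keys$marker[i])
    for (col in c("x", "y", "z")) {
      out[[col]] <- stats::approx(sub$time_s, sub[[col]], xout = full_times,
                                  rule = 2)$y
    }
    pieces[[i]] <- out
  }
  res <- do.call(rbind, pieces)
  res <- res[order(res$time_s, res$agent_id, res$marker), ]
  rownames(res) <- NULL
  structure(res, class = c("marker_series", "data.frame"),
            rate_hz = 1 / dt, n_interpolated = n_interp)
}

#' Write a marker series to TSV/CSV (schema of [read_marker_series()])
#'
#' @param markers A `marker_series` (or compatible data.frame).
#' @param path Output path; `.csv` gets commas, anything else tabs.
#' @return `path`, invisibly.
#' @export
write_marker_series <- function(markers, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(as.data.frame(markers), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Position and gaze azimuth from a pair of head markers
#'
#' The agent position is the horizontal midpoint of the left and right
#' markers. The gaze azimuth is the direction of the right-to-left marker
#' vector rotated by `rotation` (default -90 degrees), so that a person
#' whose left marker sits at (-w, 0) and right marker at (+w, 0) faces
#' the +y direction. Frames with coincident markers have no defined gaze;
#' they are flagged and their gaze is interpolated from neighbouring
#' frames.
#'
#' @param markers A `marker_series` from [read_marker_series()] (or a
#'   data.frame in the same schema).
#' @param rotation Rotation applied to the right-to-left vector, in
#'   radians; use `+pi/2` if the marker labels follow the opposite
#'   handedness.
#' @return A data.frame with columns `time_s, agent_id, group_id, x, y,
#'   delta_rad, z` (z = vertical midpoint, kept for phase estimation) and
#'   attribute `n_flagged` (frames with coincident markers).
#' @export
estimate_position_gaze <- function(markers, rotation = -pi / 2) {
  df <- as.data.frame(markers)
  left <- df[df$marker == "L", ]
  right <- df[df$marker == "R", ]
  key <- function(d) paste(d$agent_id, format(d$time_s, digits = 15))
  right <- right[match(key(left), key(right)), ]
  if (anyNA(right$x)) {
    stop("estimate_position_gaze(): left/right marker rows do not pair up",
         call. = FALSE)
  }
  vx <- left$x - right$x
  vy <- left$y - right$y
  coincident <- vx == 0 & vy == 0
  gaze <- rep(NA_real_, length(vx))
  gaze[!coincident] <- wrap_angle(atan2(vy[!coincident], vx[!coincident]) +
                                    rotation)
  out <- data.frame(time_s = left$time_s,
                    agent_id = left$agent_id,
                    group_id = left$group_id,
                    x = (left$x + right$x) / 2,
                    y = (left$y + right$y) / 2,
                    delta_rad = gaze,
                    z = (left$z + right$z) / 2)
  if (any(coincident)) {
    for (ag in unique(out$agent_id[coincident])) {
      sel <- out$agent_id == ag
      g <- out$delta_rad[sel]
      ok <- which(!is.na(g))
      if (!length(ok)) {
        stop("estimate_position_gaze(): all frames coincident for agent ", ag,
             call. = FALSE)
      }
      # interpolate the unit gaze vector, not the wrapped angle
      gx <- stats::approx(ok, cos(g[ok]), xout = seq_along(g), rule = 2)$y
      gy <- stats::approx(ok, sin(g[ok]), xout = seq_along(g), rule = 2)$y
      out$delta_rad[sel] <- atan2(gy, gx)
    }
  }
  structure(out, n_flagged = sum(coincident))
}

#' Analytic signal via the FFT
#'
#' Discrete analytic signal `x + i * H(x)` of a real series, computed by
#' zeroing negative frequencies and doubling positive ones in the DFT.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Oscillation phase from a vertical head-position series
#'
#' Estimates the bounce phase: the vertical velocity is obtained by
#' central differences at the native sampling rate, and the phase is the
#' argument of its analytic signal (velocity plus i times its Hilbert
#' transform). In spontaneous dance the vertical head velocity tends to
#' lock to the tactus-level beat, so this phase is the empirical
#' counterpart of the model's oscillation phase. The first and last
#' `edge_trim` seconds are unreliable (finite-window Hilbert transform)
#' and flagged.
#'
#' An optional band-pass (Gaussian transfer function around
#' `band_hz`) can be applied to the velocity before the analytic signal;
#' it is off by default.
#'
#' @param z Numeric vector: vertical position, uniformly sampled.
#' @param rate_hz Sampling rate (Hz).
#' @param edge_trim Seconds flagged as edge-unreliable at each end.
#' @param band_hz Optional length-2 numeric `c(lo, hi)` band in Hz; if
#'   supplied, frequencies outside the band are attenuated to zero before
#'   phase extraction.
#' @return A data.frame with columns `theta_rad` (wrapped phase) and
#'   `edge` (logical flag); same number of rows as `length(z)`.
#' @examples
#' t <- seq(0, 10, by = 1 / 120)
#' z <- (1 - cos(4 * pi * t)) / (4 * pi) # velocity = sin(4 pi t)
#' ph <- estimate_phase_hilbert(z, 120)
#' @export
estimate_phase_hilbert <- function(z, rate_hz, edge_trim = 0.5,
                                   band_hz = NULL) {
  n <- length(z)
  if (n < 2 * rate_hz) {
    stop("estimate_phase_hilbert(): need at least 2 s of data", call. = FALSE)
  }
  if (any(!is.finite(z))) {
    stop("estimate_phase_hilbert(): non-finite values in input", call. = FALSE)
  }
  dt <- 1 / rate_hz
  v <- numeric(n)
  v[2:(n - 1)] <- (z[3:n] - z[1:(n - 2)]) / (2 * dt)
  v[1] <- (z[2] - z[1]) / dt
  v[n] <- (z[n] - z[n - 1]) / dt
  if (all(v == 0)) {
    stop("estimate_phase_hilbert(): constant signal, phase undefined",
         call. = FALSE)
  }
  v <- v - mean(v)
  if (!is.null(band_hz)) {
    if (length(band_hz) != 2L || band_hz[1] >= band_hz[2]) {
      stop("estimate_phase_hilbert(): 'band_hz' must be c(lo, hi)",
           call. = FALSE)
    }
    freqs <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / (n * dt)
    keep <- abs(freqs) >= band_hz[1] & abs(freqs) <= band_hz[2]
    v <- Re(stats::fft(stats::fft(v) * keep, inverse = TRUE) / n)
  }
  a <- analytic_signal(v)
  theta <- Arg(a)
  edge_n <- ceiling(edge_trim * rate_hz)
  edge <- seq_len(n) <= edge_n | seq_len(n) > n - edge_n
  data.frame(theta_rad = theta, edge = edge)
}

#' Convert a marker series to the model state schema
#'
#' Full empirical ingestion: pairs the head markers into per-agent
#' position and gaze, estimates the bounce phase from the vertical
#' midpoint via the analytic signal, and returns rows in the simulator's
#' state CSV schema (with `omega_rad_s` and `phi_rad` set to `NA`, since
#' neither is observable from markers alone).
#'
#' @param markers A `marker_series` from [read_marker_series()].
#' @param rotation Gaze convention passed to [estimate_position_gaze()].
#' @param edge_trim Seconds trimmed from both ends (Hilbert end effects);
#'   trimmed frames are dropped from the output.
#' @param band_hz Optional band-pass, see [estimate_phase_hilbert()].
#' @return A data.frame in the state CSV schema: `time_s, agent_id,
#'   group_id, x, y, theta_rad, delta_rad, omega_rad_s, phi_rad`.
#' @export
ingest_markers <- function(markers, rotation = -pi / 2, edge_trim = 0.5,
                           band_hz = NULL) {
  pg <- estimate_position_gaze(markers, rotation = rotation)
  rate <- attr(markers, "rate_hz")
  if (is.null(rate)) {
    tms <- sort(unique(pg$time_s))
    rate <- 1 / stats::median(diff(tms))
  }
  pg <- pg[order(pg$agent_id, pg$time_s), ]
  pg$theta_rad <- NA_real_
  pg$edge <- FALSE
  for (ag in unique(pg$agent_id)) {
    sel <- pg$agent_id == ag
    ph <- estimate_phase_hilbert(pg$z[sel], rate, edge_trim = edge_trim,
                                 band_hz = band_hz)
    pg$theta_rad[sel] <- ph$theta_rad
    pg$edge[sel] <- ph$edge
  }
  pg <- pg[!pg$edge, ]
  out <- data.frame(time_s = pg$time_s, agent_id = pg$agent_id,
                    group_id = pg$group_id, x = pg$x, y = pg$y,
                    theta_rad = pg$theta_rad, delta_rad = pg$delta_rad,
                    omega_rad_s = NA_real_, phi_rad = NA_real_)
  out <- out[order(out$time_s, out$agent_id), ]
  rownames(out) <- NULL
  out
}
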