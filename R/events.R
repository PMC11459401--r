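#' Construct a gaze recording
#'
#' One trial's timestamped gaze-sample stream in screen pixels. Samples are
#' clipped to the screen and must have strictly increasing timestamps.
#'
#' @param samples data frame with columns `t_ms`, `x_px`, `y_px`.
#' @param geometry a [screen_geometry()].
#' @param participant_id identifier string.
#' @param trial_index zero-based trial (= stimulus image) index.
#' @return An object of class `gaze_recording`.
#' @export
gaze_recording <- function(samples, geometry, participant_id = "p0",
                           trial_index = 0L) {
  stopifnot(is.data.frame(samples))
  need <- c("t_ms", "x_px", "y_px")
  if (!all(need %in% names(samples))) {
    stop("samples must have columns t_ms, x_px, y_px")
  }
  if (nrow(samples) < 2) stop("a gaze recording needs at least 2 samples")
  if (any(diff(samples$t_ms) <= 0)) {
    stop("sample timestamps must be strictly increasing")
  }
  samples$x_px <- pmin(pmax(samples$x_px, 0), geometry$width_px)
  samples$y_px <- pmin(pmax(samples$y_px, 0), geometry$height_px)
  structure(
    list(
      participant_id = as.character(participant_id),
      trial_index = as.integer(trial_index),
      samples = samples[, need],
      geometry = geometry
    ),
    class = "gaze_recording"
  )
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf(
    "<gaze_recording> %s trial %d: %d samples over %.0f ms\n",
    x$participant_id, x$trial_index, nrow(x$samples),
    diff(range(x$samples$t_ms))
  ))
  invisible(x)
}

#' Per-sample angular gaze velocity
#'
#' Converts gaze positions to angular coordinates about the screen centre and
#' differentiates: central differences on interior samples, one-sided at the
#' ends. Units are degrees per second.
#'
#' @param recording a [gaze_recording()].
#' @param median_filter logical; apply a 3-sample running-median prefilter to
#'   the pixel positions before differentiation (suppresses single-sample
#'   tracker glitches).
#' @return Numeric vector of angular speeds, one per sample.
#' @export
compute_velocity <- function(recording, median_filter = FALSE) {
  s <- recording$samples
  n <- nrow(s)
  if (n < 3) stop("velocity needs at least 3 samples")
  t <- s$t_ms
  if (any(diff(t) == 0)) stop("duplicate timestamps in recording")
  x <- s$x_px
  y <- s$y_px
  if (median_filter && n >= 3) {
    x <- stats::runmed(x, 3, endrule = "keep")
    y <- stats::runmed(y, 3, endrule = "keep")
  }
  th <- angular_position(x, y, recording$geometry)
  v <- numeric(n)
  i <- 2:(n - 1)
  v[i] <- sqrt((th[i + 1, 1] - th[i - 1, 1])^2 + (th[i + 1, 2] - th[i - 1, 2])^2) /
    (t[i + 1] - t[i - 1]) * 1000
  v[1] <- sqrt(sum((th[2, ] - th[1, ])^2)) / (t[2] - t[1]) * 1000
  v[n] <- sqrt(sum((th[n, ] - th[n - 1, ])^2)) / (t[n] - t[n - 1]) * 1000
  v
}

#' I-VT fixation/saccade event detection
#'
#' Velocity-threshold classification: samples slower than
#' `velocity_threshold_dps` form fixation candidates, faster samples saccade
#' candidates. Saccade candidates whose displacement is below
#' `min_saccade_amplitude_deg` are reclassified as fixational (so their
#' flanking fixations merge); adjacent fixations closer than 0.5 degrees and
#' separated by less than `merge_gap_ms` are merged; fixations shorter than
#' `min_fixation_ms` are discarded. Recording gaps longer than `merge_gap_ms`
#' (blinks/dropouts) always split events. The returned events are time-ordered,
#' non-overlapping and alternate fixation/saccade.
#'
#' Saccade spans run from the last sample of the preceding fixation to the
#' first sample of the following one, so kept events partition the recording's
#' time span up to discarded fixation spans.
#'
#' @param recording a [gaze_recording()].
#' @param velocity_threshold_dps I-VT threshold, deg/s.
#' @param min_fixation_ms minimum fixation duration, ms.
#' @param min_saccade_amplitude_deg minimum saccade amplitude, deg.
#' @param merge_gap_ms maximum gap bridged when merging fixations, ms.
#' @param median_filter passed to [compute_velocity()].
#' @return A data frame of class `event_table`, one row per event, with
#'   columns `kind`, `start_ms`, `end_ms`, `duration_ms`, `cx_px`, `cy_px`,
#'   `amp_deg`, `amp_h_deg`, `amp_v_deg`, `mean_v_dps`, `peak_v_dps`,
#'   `dir_x`, `dir_y`. The recording's geometry is attached as attribute
#'   `geometry`.
#' @export
detect_events <- function(recording,
                          velocity_threshold_dps = 30,
                          min_fixation_ms = 60,
                          min_saccade_amplitude_deg = 0.5,
                          merge_gap_ms = 75,
                          median_filter = FALSE) {
  stopifnot(velocity_threshold_dps > 0, min_fixation_ms > 0,
            min_saccade_amplitude_deg > 0, merge_gap_ms > 0)
  s <- recording$samples
  n <- nrow(s)
  if (n == 0) stop("empty recording")
  v <- compute_velocity(recording, median_filter = median_filter)
  t <- s$t_ms
  th <- angular_position(s$x_px, s$y_px, recording$geometry)

  is_sac <- v >= velocity_threshold_dps
  # segment boundaries: change of class or a recording gap starts a new one
  gap <- c(FALSE, diff(t) > merge_gap_ms)
  new_seg <- c(TRUE, (is_sac[-1] != is_sac[-n])) | gap
  i0 <- which(new_seg)
  i1 <- c(i0[-1] - 1L, n)
  sac <- is_sac[i0]

  # reclassify sub-amplitude saccade candidates as fixational
  a <- pmax(1L, i0 - 1L)
  b <- pmin(n, i1 + 1L)
  amp0 <- sqrt((th[b, 1] - th[a, 1])^2 + (th[b, 2] - th[a, 2])^2)
  sac[sac & amp0 < min_saccade_amplitude_deg] <- FALSE

  merge_contiguous <- function(i0, i1, sac) {
    if (length(i0) >= 2) {
      same <- sac[-1] == sac[-length(sac)] &
        (t[i0[-1]] - t[i1[-length(i1)]]) <= merge_gap_ms
      grp <- cumsum(c(TRUE, !same))
      i0 <- i0[!duplicated(grp)]
      i1 <- rev(rev(i1)[!duplicated(rev(grp))])
      sac <- sac[!duplicated(grp)]
    }
    list(i0 = i0, i1 = i1, sac = sac)
  }
  sg <- merge_contiguous(i0, i1, sac)

  # merge adjacent fixations that are close in space and time (e.g. around a
  # dropped saccade or a short gap)
  repeat {
    done <- TRUE
    if (length(sg$i0) >= 2) {
      for (j in seq_len(length(sg$i0) - 1)) {
        if (sg$sac[j] || sg$sac[j + 1]) next
        gap_ms <- t[sg$i0[j + 1]] - t[sg$i1[j]]
        c1 <- colMeans(th[sg$i0[j]:sg$i1[j], , drop = FALSE])
        c2 <- colMeans(th[sg$i0[j + 1]:sg$i1[j + 1], , drop = FALSE])
        if (gap_ms < merge_gap_ms && sqrt(sum((c1 - c2)^2)) < 0.5) {
          sg$i1[j] <- sg$i1[j + 1]
          sg$i0 <- sg$i0[-(j + 1)]
          sg$i1 <- sg$i1[-(j + 1)]
          sg$sac <- sg$sac[-(j + 1)]
          done <- FALSE
          break
        }
      }
    }
    if (done) break
  }

  # discard short fixations, then collapse saccade runs created by the drops
  keep <- sg$sac | (t[sg$i1] - t[sg$i0] >= min_fixation_ms)
  sg <- lapply(sg, `[`, keep)
  sg <- merge_contiguous(sg$i0, sg$i1, sg$sac)
  # leading/trailing saccades have no flanking fixation pair
  while (length(sg$sac) > 0 && sg$sac[1]) sg <- lapply(sg, `[`, -1)
  while (length(sg$sac) > 0 && sg$sac[length(sg$sac)]) {
    sg <- lapply(sg, `[`, -length(sg$sac))
  }

  m <- length(sg$i0)
  kind <- ifelse(sg$sac, "saccade", "fixation")
  start_ms <- end_ms <- cx <- cy <- amp <- amph <- ampv <-
    mv <- pv <- dx <- dy <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    j0 <- sg$i0[j]
    j1 <- sg$i1[j]
    if (!sg$sac[j]) {
      start_ms[j] <- t[j0]
      end_ms[j] <- t[j1]
      cx[j] <- mean(s$x_px[j0:j1])
      cy[j] <- mean(s$y_px[j0:j1])
    } else {
      a <- max(1L, j0 - 1L)
      b <- min(n, j1 + 1L)
      start_ms[j] <- t[a]
      end_ms[j] <- t[b]
      dth <- th[b, ] - th[a, ]
      amp[j] <- sqrt(sum(dth^2))
      amph[j] <- abs(dth[1])
      ampv[j] <- abs(dth[2])
      mv[j] <- mean(v[j0:j1])
      pv[j] <- max(v[j0:j1])
      if (amp[j] > 0) {
        dx[j] <- dth[1] / amp[j]
        dy[j] <- dth[2] / amp[j]
      }
    }
  }
  ev <- data.frame(
    kind = kind, start_ms = start_ms, end_ms = end_ms,
    duration_ms = end_ms - start_ms, cx_px = cx, cy_px = cy,
    amp_deg = amp, amp_h_deg = amph, amp_v_deg = ampv,
    mean_v_dps = mv, peak_v_dps = pv, dir_x = dx, dir_y = dy,
    stringsAsFactors = FALSE
  )
  structure(ev, geometry = recording$geometry, class = c("event_table", "data.frame"))
}

#' Write detected events to CSV
#'
#' @param events an `event_table` from [detect_events()].
#' @param path output file path.
#' @export
write_events_csv <- function(events, path) {
  out <- data.frame(
    kind = events$kind, start_ms = events$start_ms, end_ms = events$end_ms,
    cx = events$cx_px, cy = events$cy_px, amp_deg = events$amp_deg,
    amp_h_deg = events$amp_h_deg, amp_v_deg = events$amp_v_deg,
    mean_v = events$mean_v_dps, peak_v = events$peak_v_dps
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
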