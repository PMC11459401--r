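# Feature extraction: the three feature families computed per trial --
# 14 complex eye-movement (CEM) metrics, gaze-heatmap Shannon entropy, and
# per-AOI total fixation durations -- and the participant x 260 table.

cem_metric_names <- c(
  "fix_count", "fix_dur_mean_ms", "sacc_amp_deg", "sacc_amp_h_deg",
  "sacc_amp_v_deg", "sacc_vel_mean_dps", "sacc_vel_peak_dps",
  "vel_waveform_q", "scanpath_len_deg", "hull_area_deg2", "roi_count",
  "inflection_count", "amp_dur_slope", "main_seq_slope"
)

# Shoelace area of a polygon given as an n x 2 matrix.
polygon_area <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

ls_slope <- function(x, y) {
  vx <- sum((x - mean(x))^2)
  if (vx == 0) return(NA_real_)
  sum((x - mean(x)) * (y - mean(y))) / vx
}

#' Complex eye-movement pattern metrics
#'
#' The 14 per-trial CEM indicators, in this fixed order:
#' (1) fixation count; (2) mean fixation duration, ms; (3) mean vectorial
#' saccade amplitude, deg; (4) mean absolute horizontal amplitude; (5) mean
#' absolute vertical amplitude; (6) mean of per-saccade mean velocities;
#' (7) mean of per-saccade peak velocities; (8) velocity waveform indicator
#' (mean peak-to-mean velocity ratio, the saccadic "q factor"); (9) scanpath
#' length: summed angular distance between consecutive fixation centroids,
#' deg; (10) convex-hull area of the fixation centroids, deg^2;
#' (11) regions-of-interest count: occupied cells when centroids are binned
#' on an `roi_grid` screen grid; (12) inflection count: consecutive
#' scanpath-direction pairs whose heading change is at least 90 degrees;
#' (13) amplitude-duration slope: least-squares slope of saccade duration
#' (ms) on amplitude (deg); (14) main-sequence slope: least-squares slope of
#' log10 peak velocity on log10 amplitude.
#'
#' Metrics that need at least two saccades (12-14) or two distinct
#' amplitudes (14) return `NA` when the trial cannot support them; an empty
#' event table returns an all-`NA` vector with a warning.
#'
#' @param events an `event_table` from [detect_events()] (geometry attached).
#' @param geometry optional [screen_geometry()] override; defaults to the
#'   `geometry` attribute of `events`.
#' @param roi_grid integer 2-vector, the screen binning used by metric 11.
#' @return Named numeric 14-vector.
#' @export
cem_features <- function(events, geometry = NULL, roi_grid = c(8L, 8L)) {
  geometry <- geometry %||% attr(events, "geometry")
  out <- stats::setNames(rep(NA_real_, 14), cem_metric_names)
  if (nrow(events) == 0) {
    warning("empty event list: all CEM metrics missing")
    return(out)
  }
  fx <- events[events$kind == "fixation", , drop = FALSE]
  sc <- events[events$kind == "saccade", , drop = FALSE]
  out["fix_count"] <- nrow(fx)
  if (nrow(fx) > 0) out["fix_dur_mean_ms"] <- mean(fx$duration_ms)
  if (nrow(sc) > 0) {
    out["sacc_amp_deg"] <- mean(sc$amp_deg)
    out["sacc_amp_h_deg"] <- mean(sc$amp_h_deg)
    out["sacc_amp_v_deg"] <- mean(sc$amp_v_deg)
    out["sacc_vel_mean_dps"] <- mean(sc$mean_v_dps)
    out["sacc_vel_peak_dps"] <- mean(sc$peak_v_dps)
    out["vel_waveform_q"] <- mean(sc$peak_v_dps / sc$mean_v_dps)
  }
  if (nrow(fx) >= 1) {
    th <- angular_position(fx$cx_px, fx$cy_px, geometry)
    if (nrow(fx) >= 2) {
      d <- diff(th)
      step <- sqrt(rowSums(d^2))
      out["scanpath_len_deg"] <- sum(step)
      # inflections: heading change >= 90 deg between consecutive scanpath legs
      if (nrow(fx) >= 3) {
        dots <- rowSums(d[-nrow(d), , drop = FALSE] * d[-1, , drop = FALSE])
        out["inflection_count"] <- sum(dots <= 1e-9)
      }
    }
    hull <- grDevices::chull(th)
    out["hull_area_deg2"] <- if (length(hull) >= 3) {
      polygon_area(th[hull, , drop = FALSE])
    } else 0
    ix <- pmin(pmax(floor(fx$cx_px / geometry$width_px * roi_grid[1]), 0),
               roi_grid[1] - 1)
    iy <- pmin(pmax(floor(fx$cy_px / geometry$height_px * roi_grid[2]), 0),
               roi_grid[2] - 1)
    out["roi_count"] <- length(unique(ix * roi_grid[2] + iy))
  }
  if (nrow(sc) >= 2) {
    out["amp_dur_slope"] <- ls_slope(sc$amp_deg, sc$duration_ms)
    pos <- sc$amp_deg > 0 & sc$peak_v_dps > 0
    if (sum(pos) >= 2) {
      out["main_seq_slope"] <- ls_slope(log10(sc$amp_deg[pos]),
                                        log10(sc$peak_v_dps[pos]))
    }
  }
  out
}

#' Fixation-duration heatmap
#'
#' Deposits each fixation's duration into the grid cell containing its
#' centroid, then applies separable Gaussian smoothing with reflective
#' boundaries (so total mass is conserved).
#'
#' @param fixations an `event_table` (saccade rows ignored) with pixel
#'   centroids.
#' @param geometry a [screen_geometry()].
#' @param grid integer 2-vector `(nx, ny)`; default 64 x 36 (screen aspect).
#' @param smoothing_sigma_px Gaussian sigma in pixels (0 disables
#'   smoothing).
#' @return `ny` x `nx` nonnegative matrix (rows = screen y).
#' @export
duration_heatmap <- function(fixations, geometry = NULL,
                             grid = c(64L, 36L), smoothing_sigma_px = 30) {
  geometry <- geometry %||% attr(fixations, "geometry")
  if (any(grid < 2)) stop("grid dimensions must be >= 2")
  nx <- grid[1]
  ny <- grid[2]
  m <- matrix(0, nrow = ny, ncol = nx)
  fx <- fixations[fixations$kind == "fixation", , drop = FALSE]
  if (nrow(fx) == 0) return(m)
  ix <- pmin(pmax(floor(fx$cx_px / geometry$width_px * nx), 0), nx - 1) + 1
  iy <- pmin(pmax(floor(fx$cy_px / geometry$height_px * ny), 0), ny - 1) + 1
  for (k in seq_len(nrow(fx))) {
    m[iy[k], ix[k]] <- m[iy[k], ix[k]] + fx$duration_ms[k]
  }
  if (smoothing_sigma_px > 0) {
    sig_x <- smoothing_sigma_px / (geometry$width_px / nx)
    sig_y <- smoothing_sigma_px / (geometry$height_px / ny)
    m <- blur_reflect(m, sig_y, sig_x)
  }
  m
}

# Separable Gaussian blur with reflective padding; conserves total mass.
blur_reflect <- function(m, sig_r, sig_c) {
  k1 <- function(sig) {
    r <- max(1L, ceiling(3 * sig))
    k <- stats::dnorm(-r:r, sd = sig)
    k / sum(k)
  }
  conv_rows <- function(m, k) {
    r <- (length(k) - 1L) / 2L
    n <- nrow(m)
    if (r >= n) stop("smoothing kernel wider than heatmap; reduce sigma")
    idx <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
    pad <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * pad[(j - 1) + seq_len(n), , drop = FALSE]
    }
    out
  }
  if (sig_r > 0) m <- conv_rows(m, k1(sig_r))
  if (sig_c > 0) m <- t(conv_rows(t(m), k1(sig_c)))
  m
}

#' Shannon entropy of a heatmap
#'
#' Normalizes the matrix to a probability distribution and returns
#' `-sum(p * log2(p))` over nonzero cells. Spatially dispersed gaze yields
#' high entropy, tightly focused gaze low entropy.
#'
#' @param heatmap nonnegative matrix with positive total mass.
#' @return entropy in bits, in `[0, log2(length(heatmap))]`.
#' @export
shannon_entropy <- function(heatmap) {
  if (any(heatmap < 0)) stop("heatmap must be nonnegative")
  tot <- sum(heatmap)
  if (tot <= 0) stop("all-zero heatmap: no gaze mass")
  p <- heatmap[heatmap > 0] / tot
  -sum(p * log2(p))
}

#' Per-trial feature bundle
#'
#' Runs event detection and all three feature families on one recording.
#'
#' @param recording a [gaze_recording()].
#' @param schema AOI schema for the trial's stimulus (default
#'   [default_aoi_schema()] at the recording's trial index).
#' @param heatmap_grid,heatmap_sigma_px passed to [duration_heatmap()].
#' @param ... detector parameters passed to [detect_events()].
#' @return List of class `trial_features`: `participant_id`, `trial_index`,
#'   `cem` (named 14-vector), `entropy_bits`, `aoi_dwell_ms` (named vector).
#' @export
trial_features <- function(recording, schema = NULL,
                           heatmap_grid = c(64L, 36L), heatmap_sigma_px = 30,
                           ...) {
  if (is.null(schema)) {
    schema <- default_aoi_schema(recording$trial_index, recording$geometry)
  }
  ev <- detect_events(recording, ...)
  hm <- duration_heatmap(ev, recording$geometry, grid = heatmap_grid,
                         smoothing_sigma_px = heatmap_sigma_px)
  ent <- if (sum(hm) > 0) shannon_entropy(hm) else NA_real_
  structure(
    list(participant_id = recording$participant_id,
         trial_index = recording$trial_index,
         cem = cem_features(ev, recording$geometry),
         entropy_bits = ent,
         aoi_dwell_ms = aoi_dwell(ev, schema)),
    class = "trial_features"
  )
}

#' Assemble the participant feature table
#'
#' Pivots per-trial features into one row per participant with
#' `n_trials * (14 + 1 + n_regions)` named columns (260 under the default
#' 10-trial protocol and 11-region schema). Column order is CEM by trial,
#' then entropy by trial, then AOI dwell by trial; names encode provenance
#' as `family_t<trial>_<metric>`. Participants missing any trial are
#' excluded with a warning (mirroring exclusion for missing eye-movement
#' data). Missing metric values are imputed by the column median; the
#' imputation mask is retained as attribute `missing_mask` and per-column
#' provenance as attribute `provenance`.
#'
#' @param per_trial list of [trial_features()] objects covering every
#'   participant and trial.
#' @param protocol a [stimulus_protocol()].
#' @return Data frame of class `feature_table`, rownames = participant ids.
#' @export
assemble_feature_table <- function(per_trial, protocol = stimulus_protocol()) {
  pids <- vapply(per_trial, `[[`, "", "participant_id")
  trials <- vapply(per_trial, `[[`, 0L, "trial_index")
  n_trials <- protocol$n_trials
  complete <- names(which(table(pids) == n_trials))
  incomplete <- setdiff(unique(pids), complete)
  if (length(incomplete)) {
    warning(sprintf("excluding %d participant(s) with missing trials: %s",
                    length(incomplete), paste(incomplete, collapse = ", ")))
  }
  complete <- unique(pids)[unique(pids) %in% complete] # keep original order
  region_names <- names(per_trial[[1]]$aoi_dwell_ms)
  tcols <- function(fam, metrics) {
    unlist(lapply(seq_len(n_trials) - 1L, function(j) {
      sprintf("%s_t%02d_%s", fam, j, metrics)
    }))
  }
  cols <- c(tcols("cem", cem_metric_names),
            tcols("ent", "entropy_bits"),
            tcols("aoi", region_names))
  mat <- matrix(NA_real_, nrow = length(complete), ncol = length(cols),
                dimnames = list(complete, cols))
  for (tf in per_trial) {
    if (!tf$participant_id %in% complete) next
    j <- tf$trial_index
    mat[tf$participant_id, sprintf("cem_t%02d_%s", j, cem_metric_names)] <- tf$cem
    mat[tf$participant_id, sprintf("ent_t%02d_entropy_bits", j)] <- tf$entropy_bits
    mat[tf$participant_id, sprintf("aoi_t%02d_%s", j, region_names)] <- tf$aoi_dwell_ms
  }
  mask <- is.na(mat)
  for (j in seq_len(ncol(mat))) {
    if (any(mask[, j])) {
      med <- stats::median(mat[, j], na.rm = TRUE)
      if (is.na(med)) med <- 0
      mat[mask[, j], j] <- med
    }
  }
  prov <- data.frame(
    column = cols,
    family = rep(c("cem", "entropy", "aoi"),
                 times = c(14 * n_trials, n_trials,
                           length(region_names) * n_trials)),
    trial = c(rep(seq_len(n_trials) - 1L, each = 14),
              seq_len(n_trials) - 1L,
              rep(seq_len(n_trials) - 1L, each = length(region_names))),
    metric = c(rep(cem_metric_names, times = n_trials),
               rep("entropy_bits", n_trials),
               rep(region_names, times = n_trials))
  )
  out <- as.data.frame(mat)
  attr(out, "missing_mask") <- mask
  attr(out, "provenance") <- prov
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Extract the full feature table from a cohort
#'
#' Convenience wrapper: runs [trial_features()] on every recording and
#' assembles the participant x feature table.
#'
#' @param cohort a `gaze_cohort` from [generate_cohort()], or a list with
#'   `recordings` and `protocol`.
#' @param schemas optional list of AOI schemas indexed by `image_index + 1`;
#'   default schemas are built per trial.
#' @param ... passed to [trial_features()].
#' @return A `feature_table`.
#' @export
extract_features <- function(cohort, schemas = NULL, ...) {
  per_trial <- lapply(cohort$recordings, function(rec) {
    schema <- if (!is.null(schemas)) schemas[[rec$trial_index + 1L]] else NULL
    trial_features(rec, schema = schema, ...)
  })
  assemble_feature_table(per_trial, cohort$protocol)
}
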