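#' Synthetic-cohort generator configuration
#'
#' Tunable knobs of the trait-conditioned gaze generator. The trait-to-gaze
#' coupling map is a synthetic convention (no generative model exists for the
#' real study population): each of the five traits perturbs a designated gaze
#' parameter monotonically, with effect sizes scaled by the cohort's
#' `coupling_strength`.
#'
#' \describe{
#'   \item{TYa (intensity)}{more off-face exploration and larger target
#'     spread: longer scanpaths, larger hull areas, more background dwell.}
#'   \item{SYa (flexibility)}{shorter fixations and a higher probability of
#'     switching area of interest between fixations.}
#'   \item{Yy (balance)}{left/right face dwell balance: high Yy looks at both
#'     faces equally, low Yy is biased to one side.}
#'   \item{SYi (persistence)}{stronger preference for the eye regions.}
#'   \item{TYi (convergence)}{longer fixations and lower gaze dispersion.}
#' }
#'
#' @param fix_dur_base_ms baseline mean fixation duration (Gamma mean), ms.
#' @param fix_dur_shape Gamma shape of fixation durations.
#' @param switch_base baseline probability of changing AOI after a fixation.
#' @param spread_base_px baseline s.d. of fixation targets around region
#'   anchors, px.
#' @param bg_base probability of an off-face (background) fixation target.
#' @param jitter_px s.d. of per-sample Gaussian measurement jitter, px.
#' @param ms_c,ms_b main-sequence coefficients: peak velocity (deg/s) =
#'   `ms_c * amplitude^ms_b`.
#' @param ms_noise_sd s.d. of multiplicative log-normal noise on peak
#'   velocity.
#' @param min_refix_deg minimum distance between consecutive fixation
#'   targets, deg (keeps every generated saccade above the detector floor).
#' @param inventory_noise half-width of the bounded integer noise added to
#'   inventory scores.
#' @param masking_low_frac fraction of participants whose masking score falls
#'   below the exclusion threshold of 5.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(fix_dur_base_ms = 280, fix_dur_shape = 8,
                         switch_base = 0.65, spread_base_px = 45,
                         bg_base = 0.25, jitter_px = 3,
                         ms_c = 90, ms_b = 0.5, ms_noise_sd = 0.05,
                         min_refix_deg = 1.2,
                         inventory_noise = 0L, masking_low_frac = 0.07) {
  structure(as.list(environment()), class = "synth_config")
}

# Admissible inventory score maxima per trait (minima are 0).
trait_score_max <- c(TYa = 20L, SYa = 22L, Yy = 10L, SYi = 21L, TYi = 22L)

#' Trait names in canonical order
#' @return character vector `c("TYa","SYa","Yy","SYi","TYi")`.
#' @export
trait_names <- function() names(trait_score_max)

#' Build a participant profile
#'
#' Maps a participant's latent trait intensities to the gaze parameters used
#' by [generate_trial()]. The mapping is deterministic given the latent
#' vector, the coupling strength and the generator configuration; at
#' `coupling_strength = 0` every participant receives the baseline
#' parameters, so gaze behaviour is statistically independent of the traits.
#'
#' @param participant_id identifier.
#' @param latent_traits named 5-vector in `[0,1]` (order TYa, SYa, Yy, SYi,
#'   TYi).
#' @param coupling_strength real in `[0,1]`.
#' @param config a [synth_config()].
#' @return An object of class `participant_profile` with a `gaze_params`
#'   list.
#' @export
participant_profile <- function(participant_id, latent_traits,
                                coupling_strength = 1,
                                config = synth_config()) {
  if (length(latent_traits) != 5 || any(latent_traits < 0 | latent_traits > 1)) {
    stop("latent_traits must be a 5-vector in [0,1]")
  }
  if (coupling_strength < 0 || coupling_strength > 1) {
    stop("coupling_strength must lie in [0,1]")
  }
  lt <- stats::setNames(as.numeric(latent_traits), trait_names())
  cc <- coupling_strength
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  gp <- list(
    fix_dur_mean_ms = config$fix_dur_base_ms *
      exp(cc * (0.45 * (lt["TYi"] - 0.5) - 0.75 * (lt["SYa"] - 0.5))),
    switch_prob = clamp(config$switch_base + cc * 0.8 * (lt["SYa"] - 0.5), 0.1, 0.95),
    bg_prob = clamp(config$bg_base + cc * 0.55 * (lt["TYa"] - 0.5), 0.02, 0.6),
    spread_px = config$spread_base_px *
      exp(cc * (0.4 * (lt["TYa"] - 0.5) - 1.3 * (lt["TYi"] - 0.5))),
    left_bias = clamp(0.5 + cc * 0.5 * (1 - lt["Yy"]), 0.5, 0.95),
    eye_weight = exp(cc * 4.0 * (lt["SYi"] - 0.5)),
    ms_c = config$ms_c * exp(-cc * 1.1 * (lt["TYi"] - 0.5)),
    ms_b = config$ms_b + cc * 0.24 * (lt["TYa"] - 0.5)
  )
  gp <- lapply(gp, unname)
  structure(
    list(participant_id = as.character(participant_id),
         latent_traits = lt,
         coupling_strength = cc,
         gaze_params = gp,
         config = config),
    class = "participant_profile"
  )
}

# Draw a fixation target inside a region polygon: anchor at the polygon
# centroid plus isotropic Gaussian spread, rejection-sampled into the
# polygon (falls back to the centroid).
draw_target <- function(polygon, spread_px) {
  cx <- mean(polygon[, 1])
  cy <- mean(polygon[, 2])
  if (spread_px <= 0) return(c(cx, cy))
  for (i in 1:30) {
    p <- c(cx, cy) + stats::rnorm(2, 0, spread_px)
    if (point_in_polygon(p[1], p[2], polygon)) return(p)
  }
  c(cx, cy)
}

# Pick the next target region given the profile's AOI biases: face side by
# the left/right balance bias, then a region within that side weighted by
# the eye preference, with an off-face (background) escape probability.
pick_region <- function(schema, profile, cur_side) {
  gp <- profile$gaze_params
  side <- if (stats::runif(1) < gp$left_bias) "face_L" else "face_R"
  if (stats::runif(1) < gp$bg_prob) {
    return(list(region = "background", side = side))
  }
  cand <- c(side,
            paste0(side, c("_eye_L", "_eye_R", "_nose", "_mouth")))
  w <- c(0.8, 1.5 * gp$eye_weight, 1.5 * gp$eye_weight, 1.0, 1.0)
  list(region = cand[sample.int(length(cand), 1, prob = w)], side = side)
}

# Minimum-jerk displacement profile on s in [0,1]; velocity is single-peaked
# with peak 1.875 * amplitude / duration.
min_jerk <- function(s) 10 * s^3 - 15 * s^4 + 6 * s^5

#' Generate one synthetic gaze trial
#'
#' Simulates a 5 s free-viewing trial as a fixation/saccade alternation: the
#' first fixation starts at the screen centre (the inter-trial cross),
#' fixation durations are Gamma-distributed, fixation targets follow a
#' Markov walk over the trial's AOI schema biased by the participant's gaze
#' parameters, and saccades follow the configured main sequence
#' (peak velocity = `ms_c * amplitude^ms_b`, rendered as minimum-jerk
#' position ramps so the velocity waveform has a single peak). Gaussian
#' sample jitter is added on top.
#'
#' @param profile a [participant_profile()].
#' @param image_index zero-based stimulus index in `[0, n_trials)`.
#' @param geometry a [screen_geometry()].
#' @param protocol a [stimulus_protocol()].
#' @param seed integer seed; identical arguments reproduce the trial exactly.
#' @param schema AOI schema for the stimulus; default
#'   [default_aoi_schema()] at `image_index`.
#' @param jitter_px,ms_noise_sd overrides of the corresponding
#'   [synth_config()] noise levels (set both to 0 for a noiseless trial).
#' @param force_region if non-`NULL`, every fixation target is drawn from
#'   this named region (degenerate single-AOI generator, used for testing).
#' @return A [gaze_recording()] with attribute `ground_truth`: a list with
#'   data frames `fixations` (`x_px`, `y_px`, `start_ms`, `end_ms`) and
#'   `saccades` (`amp_deg`, `peak_v_dps`, `duration_ms`).
#' @export
generate_trial <- function(profile, image_index, geometry = screen_geometry(),
                           protocol = stimulus_protocol(), seed = 1L,
                           schema = NULL,
                           jitter_px = NULL, ms_noise_sd = NULL,
                           force_region = NULL) {
  if (image_index < 0 || image_index >= protocol$n_trials) {
    stop("image_index out of range [0, n_trials)")
  }
  cfg <- profile$config
  gp <- profile$gaze_params
  jitter_px <- jitter_px %||% cfg$jitter_px
  ms_noise_sd <- ms_noise_sd %||% cfg$ms_noise_sd
  if (is.null(schema)) schema <- default_aoi_schema(image_index, geometry)

  dur_ms <- protocol$trial_duration_s * 1000
  hz <- geometry$sampling_rate_hz
  n_samp <- round(dur_ms / 1000 * hz)
  t_ms <- (seq_len(n_samp) - 1) / hz * 1000

  res <- with_seed(seed, {
    shape <- cfg$fix_dur_shape
    scale <- gp$fix_dur_mean_ms / shape
    centre <- c(geometry$width_px / 2, geometry$height_px / 2)
    cur_pos <- centre
    cur_region <- "background"
    cur_side <- if (stats::runif(1) < gp$left_bias) "face_L" else "face_R"
    cur_t <- 0
    fixs <- list()
    sacs <- list()
    segs <- list() # rendering segments: fixation or saccade
    repeat {
      d <- min(max(stats::rgamma(1, shape = shape, scale = scale), 80), 1200)
      if (cur_t + d + 250 > dur_ms) {
        fixs[[length(fixs) + 1]] <- c(cur_pos, cur_t, dur_ms)
        segs[[length(segs) + 1]] <- list(kind = "f", t0 = cur_t, t1 = dur_ms,
                                         p0 = cur_pos)
        break
      }
      # choose the next fixation target, at least min_refix_deg away
      nxt <- NULL
      for (try in 1:40) {
        if (!is.null(force_region)) {
          rn <- force_region
          new_side <- cur_side
        } else if (stats::runif(1) < gp$switch_prob || length(fixs) == 0) {
          pk <- pick_region(schema, profile, cur_side)
          rn <- pk$region
          new_side <- pk$side
        } else {
          rn <- cur_region
          new_side <- cur_side
        }
        cand <- draw_target(schema$regions[[rn]]$polygon, gp$spread_px)
        th0 <- angular_position(cur_pos[1], cur_pos[2], geometry)
        th1 <- angular_position(cand[1], cand[2], geometry)
        amp <- sqrt(sum((th1 - th0)^2))
        if (amp >= cfg$min_refix_deg) {
          nxt <- cand
          nxt_region <- rn
          nxt_side <- new_side
          break
        }
      }
      if (is.null(nxt)) { # degenerate schema/force_region: stay put
        fixs[[length(fixs) + 1]] <- c(cur_pos, cur_t, dur_ms)
        segs[[length(segs) + 1]] <- list(kind = "f", t0 = cur_t, t1 = dur_ms,
                                         p0 = cur_pos)
        break
      }
      vp <- gp$ms_c * amp^gp$ms_b *
        exp(if (ms_noise_sd > 0) stats::rnorm(1, 0, ms_noise_sd) else 0)
      sd_ms <- 1.875 * amp / vp * 1000
      if (cur_t + d + sd_ms + 160 > dur_ms) {
        fixs[[length(fixs) + 1]] <- c(cur_pos, cur_t, dur_ms)
        segs[[length(segs) + 1]] <- list(kind = "f", t0 = cur_t, t1 = dur_ms,
                                         p0 = cur_pos)
        break
      }
      fixs[[length(fixs) + 1]] <- c(cur_pos, cur_t, cur_t + d)
      segs[[length(segs) + 1]] <- list(kind = "f", t0 = cur_t, t1 = cur_t + d,
                                       p0 = cur_pos)
      sacs[[length(sacs) + 1]] <- c(amp, vp, sd_ms)
      segs[[length(segs) + 1]] <- list(kind = "s", t0 = cur_t + d,
                                       t1 = cur_t + d + sd_ms,
                                       p0 = cur_pos, p1 = nxt)
      cur_t <- cur_t + d + sd_ms
      cur_pos <- nxt
      cur_region <- nxt_region
      cur_side <- nxt_side
    }

    # render the piecewise trajectory at the sampling grid
    x <- numeric(n_samp)
    y <- numeric(n_samp)
    si <- 1
    for (k in seq_len(n_samp)) {
      tt <- t_ms[k]
      while (si < length(segs) && tt >= segs[[si]]$t1) si <- si + 1
      sg <- segs[[si]]
      if (sg$kind == "f" || sg$t1 == sg$t0) {
        x[k] <- sg$p0[1]
        y[k] <- sg$p0[2]
      } else {
        s <- min(max((tt - sg$t0) / (sg$t1 - sg$t0), 0), 1)
        f <- min_jerk(s)
        x[k] <- sg$p0[1] + f * (sg$p1[1] - sg$p0[1])
        y[k] <- sg$p0[2] + f * (sg$p1[2] - sg$p0[2])
      }
    }
    if (jitter_px > 0) {
      x <- x + stats::rnorm(n_samp, 0, jitter_px)
      y <- y + stats::rnorm(n_samp, 0, jitter_px)
    }
    list(x = x, y = y, fixs = fixs, sacs = sacs)
  })

  rec <- gaze_recording(
    data.frame(t_ms = t_ms, x_px = res$x, y_px = res$y),
    geometry,
    participant_id = profile$participant_id,
    trial_index = image_index
  )
  fx <- do.call(rbind, res$fixs)
  sc <- if (length(res$sacs)) do.call(rbind, res$sacs) else
    matrix(numeric(0), ncol = 3)
  attr(rec, "ground_truth") <- list(
    fixations = stats::setNames(as.data.frame(fx),
                                c("x_px", "y_px", "start_ms", "end_ms")),
    saccades = stats::setNames(as.data.frame(sc),
                               c("amp_deg", "peak_v_dps", "duration_ms"))
  )
  rec
}

#' Generate a synthetic inventory record
#'
#' Each trait score is `round(latent * score_max)` plus bounded integer
#' noise, clipped to the trait's admissible range. The masking (validity)
#' score is drawn so a configurable fraction of participants falls below the
#' exclusion threshold of 5.
#'
#' @param profile a [participant_profile()].
#' @param seed integer seed.
#' @param noise half-width of the integer noise (0 disables it).
#' @param masking_low_frac probability of a masking score below 5.
#' @return One-row data frame: `participant_id`, the five trait scores and
#'   `masking`.
#' @export
generate_inventory <- function(profile, seed = 1L,
                               noise = profile$config$inventory_noise,
                               masking_low_frac = profile$config$masking_low_frac) {
  with_seed(seed, {
    sc <- integer(5)
    for (i in 1:5) {
      hi <- trait_score_max[[i]]
      base <- round(profile$latent_traits[[i]] * hi)
      eps <- if (noise > 0) sample(seq(-noise, noise), 1) else 0L
      sc[i] <- as.integer(min(max(base + eps, 0L), hi))
    }
    masking <- if (stats::runif(1) < masking_low_frac) sample(0:4, 1) else sample(5:10, 1)
    out <- data.frame(participant_id = profile$participant_id,
                      TYa = sc[1], SYa = sc[2], Yy = sc[3], SYi = sc[4],
                      TYi = sc[5], masking = masking)
    out
  })
}

#' Generate a trait-conditioned synthetic cohort
#'
#' Draws latent trait intensities so the three label levels of every trait
#' are (approximately) balanced, derives per-participant gaze parameters via
#' [participant_profile()], and simulates the full session (one recording
#' per stimulus image) plus the inventory record for each participant.
#' Identical arguments and seed reproduce the cohort exactly.
#'
#' @param n_participants number of participants (>= 2).
#' @param coupling_strength real in `[0,1]`; 0 makes gaze behaviour
#'   independent of the traits, 1 applies the full coupling map of
#'   [synth_config()].
#' @param geometry a [screen_geometry()].
#' @param protocol a [stimulus_protocol()].
#' @param seed integer master seed; all per-trial seeds are derived from it.
#' @param config a [synth_config()].
#' @return A list of class `gaze_cohort`: `recordings` (list of
#'   `n_participants * n_trials` [gaze_recording()]s), `inventory` (data
#'   frame), `profiles` (list of [participant_profile()]s).
#' @export
generate_cohort <- function(n_participants, coupling_strength = 1,
                            geometry = screen_geometry(),
                            protocol = stimulus_protocol(),
                            seed = 1L, config = synth_config()) {
  if (n_participants < 2) stop("n_participants must be >= 2")
  if (coupling_strength < 0 || coupling_strength > 1) {
    stop("coupling_strength must lie in [0,1]")
  }
  bounds <- trait_level_bounds()
  # levels are allocated in (near-)equal thirds per trait and shuffled, so
  # every trait's three classes are balanced by construction
  latents <- with_seed(derive_seed(seed, 1), {
    lev_mat <- vapply(1:5, function(k) {
      sample(rep(1:3, length.out = n_participants))
    }, integer(n_participants))
    lev_mat <- matrix(lev_mat, nrow = n_participants)
    lapply(seq_len(n_participants), function(i) {
      vapply(1:5, function(k) {
        b <- bounds[[trait_names()[k]]]
        sc <- sample(b[lev_mat[i, k], "lo"]:b[lev_mat[i, k], "hi"], 1)
        sc / trait_score_max[[k]]
      }, numeric(1))
    })
  })
  profiles <- vector("list", n_participants)
  inv <- vector("list", n_participants)
  recordings <- vector("list", n_participants * protocol$n_trials)
  r <- 1L
  for (i in seq_len(n_participants)) {
    pid <- sprintf("p%03d", i)
    profiles[[i]] <- participant_profile(pid, latents[[i]], coupling_strength,
                                         config)
    inv[[i]] <- generate_inventory(profiles[[i]], derive_seed(seed, 2, i))
    for (j in seq_len(protocol$n_trials) - 1L) {
      recordings[[r]] <- generate_trial(profiles[[i]], j, geometry, protocol,
                                        seed = derive_seed(seed, 3, i, j))
      r <- r + 1L
    }
  }
  structure(
    list(recordings = recordings,
         inventory = do.call(rbind, inv),
         profiles = profiles,
         geometry = geometry, protocol = protocol,
         coupling_strength = coupling_strength, seed = seed),
    class = "gaze_cohort"
  )
}

#' @export
print.gaze_cohort <- function(x, ...) {
  cat(sprintf(
    "<gaze_cohort> %d participants x %d trials (coupling %.2f, seed %d)\n",
    nrow(x$inventory), x$protocol$n_trials, x$coupling_strength, x$seed
  ))
  invisible(x)
}
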