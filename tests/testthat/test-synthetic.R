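test_that("a cohort has n_participants x n_trials recordings and is reproducible", {
  prot <- stimulus_protocol()
  c1 <- generate_cohort(4, 0, protocol = prot, seed = 1)
  expect_length(c1$recordings, 40L)
  expect_equal(nrow(c1$inventory), 4L)
  c2 <- generate_cohort(4, 0, protocol = prot, seed = 1)
  expect_identical(c1$recordings, c2$recordings)
  expect_identical(c1$inventory, c2$inventory)
  # different seed changes the data
  c3 <- generate_cohort(4, 0, protocol = prot, seed = 2)
  expect_false(identical(c1$recordings[[1]]$samples, c3$recordings[[1]]$samples))
})

test_that("cohort arguments are validated", {
  expect_error(generate_cohort(1, 0.5, seed = 1), ">= 2")
  expect_error(generate_cohort(4, 1.2, seed = 1), "\\[0,1\\]")
  expect_error(generate_cohort(4, -0.1, seed = 1), "\\[0,1\\]")
  expect_error(participant_profile("p", c(0.2, 0.3, 1.4, 0, 0)), "\\[0,1\\]")
})

test_that("trials start at the screen centre and cover the protocol duration", {
  prof <- default_profile()
  g <- test_geometry()
  prot <- stimulus_protocol()
  rec <- generate_trial(prof, 0, g, prot, seed = 3)
  first <- rec$samples[1, ]
  d0 <- pixels_to_degrees(first$x_px - g$width_px / 2,
                          first$y_px - g$height_px / 2, g)$deg
  expect_lt(d0, 2) # the inter-trial cross pins the first sample to centre
  expect_equal(nrow(rec$samples), round(prot$trial_duration_s * g$sampling_rate_hz))
  expect_equal(max(rec$samples$t_ms) - min(rec$samples$t_ms),
               (nrow(rec$samples) - 1) / 90 * 1000, tolerance = 1e-9)
  expect_error(generate_trial(prof, 10, g, prot, seed = 1), "out of range")
})

test_that("a degenerate single-AOI generator keeps all fixations in that AOI", {
  prof <- default_profile()
  g <- test_geometry()
  schema <- default_aoi_schema(0, g)
  rec <- generate_trial(prof, 0, g, seed = 5, jitter_px = 0, ms_noise_sd = 0,
                        force_region = "face_L_nose")
  gt <- attr(rec, "ground_truth")$fixations
  # all fixation targets after the initial central cross land in the polygon
  inside <- point_in_polygon(gt$x_px[-1], gt$y_px[-1],
                             schema$regions$face_L_nose$polygon)
  expect_true(all(inside))
})

test_that("ground-truth saccades recover the configured main sequence exactly", {
  cfg <- synth_config(ms_b = 0.5, ms_noise_sd = 0)
  prof <- default_profile(config = cfg)
  amp <- numeric(0)
  vp <- numeric(0)
  for (seed in 1:5) {
    gt <- attr(generate_trial(prof, 0, seed = seed, jitter_px = 0,
                              ms_noise_sd = 0), "ground_truth")$saccades
    amp <- c(amp, gt$amp_deg)
    vp <- c(vp, gt$peak_v_dps)
  }
  slope <- oracle_slope(log10(amp), log10(vp))
  expect_equal(slope, 0.5, tolerance = 1e-6)
  expect_equal(exp(mean(log(vp / amp^0.5))), prof$gaze_params$ms_c,
               tolerance = 1e-9)
})

test_that("inventory scores map latent traits through the Table ranges", {
  cfg <- synth_config()
  p1 <- participant_profile("a", c(1, 1, 1, 1, 1), 0, cfg)
  inv <- generate_inventory(p1, seed = 1, noise = 0)
  expect_identical(c(inv$TYa, inv$SYa, inv$Yy, inv$SYi, inv$TYi),
                   c(20L, 22L, 10L, 21L, 22L))
  p0 <- participant_profile("b", rep(0, 5), 0, cfg)
  inv0 <- generate_inventory(p0, seed = 1, noise = 0)
  expect_true(all(c(inv0$TYa, inv0$SYa, inv0$Yy, inv0$SYi, inv0$TYi) == 0L))
  expect_true(all(as.character(discretize_score("TYa", 0)) == "low"))
  # latent Yy = 0.6 -> score 6 -> medium
  pm <- participant_profile("c", c(0, 0, 0.6, 0, 0), 0, cfg)
  invm <- generate_inventory(pm, seed = 1, noise = 0)
  expect_identical(invm$Yy, 6L)
  expect_identical(as.character(discretize_score("Yy", invm$Yy)), "medium")
  # bounded noise stays inside the admissible range
  invn <- generate_inventory(p1, seed = 2, noise = 2)
  expect_true(invn$TYa <= 20 && invn$SYa <= 22 && invn$Yy <= 10)
})

test_that("coupling maps traits monotonically onto their gaze parameters", {
  cfg <- synth_config()
  gp_at <- function(trait_idx, value) {
    lt <- rep(0.5, 5)
    lt[trait_idx] <- value
    participant_profile("p", lt, 1, cfg)$gaze_params
  }
  lo <- lapply(1:5, gp_at, value = 0.1)
  hi <- lapply(1:5, gp_at, value = 0.9)
  # TYa: more off-face exploration, steeper main sequence
  expect_gt(hi[[1]]$bg_prob, lo[[1]]$bg_prob)
  expect_gt(hi[[1]]$ms_b, lo[[1]]$ms_b)
  # SYa: shorter fixations, more switching
  expect_lt(hi[[2]]$fix_dur_mean_ms, lo[[2]]$fix_dur_mean_ms)
  expect_gt(hi[[2]]$switch_prob, lo[[2]]$switch_prob)
  # Yy: better left/right balance
  expect_lt(hi[[3]]$left_bias, lo[[3]]$left_bias)
  # SYi: stronger eye preference
  expect_gt(hi[[4]]$eye_weight, lo[[4]]$eye_weight)
  # TYi: longer fixations, slower saccades, lower dispersion
  expect_gt(hi[[5]]$fix_dur_mean_ms, lo[[5]]$fix_dur_mean_ms)
  expect_lt(hi[[5]]$ms_c, lo[[5]]$ms_c)
  expect_lt(hi[[5]]$spread_px, lo[[5]]$spread_px)
  # coupling 0 erases every trait effect
  z1 <- participant_profile("p", c(0.9, 0.1, 0.8, 0.2, 0.7), 0, cfg)$gaze_params
  z2 <- participant_profile("p", rep(0.5, 5), 0, cfg)$gaze_params
  expect_equal(z1, z2)
})

test_that("the masking-score mixture exercises the exclusion path", {
  cfg <- synth_config()
  prof <- default_profile(config = cfg)
  masks <- vapply(1:400, function(s) {
    generate_inventory(prof, seed = s)$masking
  }, numeric(1))
  frac_low <- mean(masks < 5)
  expect_gt(frac_low, 0.02)
  expect_lt(frac_low, 0.15)
  expect_true(all(masks >= 0 & masks <= 10))
})
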