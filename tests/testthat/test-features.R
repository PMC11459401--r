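test_that("CEM fixation metrics come out exactly on constructed events", {
  ev <- make_events(fix = data.frame(x = seq(400, 560, 40), y = 500,
                                     dur = rep(200, 5)))
  cem <- cem_features(ev)
  expect_equal(unname(cem["fix_count"]), 5)
  expect_equal(unname(cem["fix_dur_mean_ms"]), 200)
  expect_true(is.na(cem["sacc_amp_deg"])) # no saccades -> flagged missing
  expect_true(is.na(cem["main_seq_slope"]))
})

test_that("a 10x10 degree square path has known scanpath, hull and inflections", {
  g <- test_geometry()
  pitch <- pixel_pitch_cm(g)
  px_of <- function(deg_x, deg_y) {
    c(g$width_px / 2 + tan(deg_x * pi / 180) * g$viewing_distance_cm / pitch,
      g$height_px / 2 + tan(deg_y * pi / 180) * g$viewing_distance_cm / pitch)
  }
  corners <- rbind(px_of(-5, -5), px_of(5, -5), px_of(5, 5), px_of(-5, 5))
  ev <- make_events(fix = data.frame(x = corners[, 1], y = corners[, 2],
                                     dur = 250))
  cem <- cem_features(ev)
  expect_equal(unname(cem["scanpath_len_deg"]), 30, tolerance = 1e-9)
  expect_equal(unname(cem["hull_area_deg2"]), 100, tolerance = 1e-9)
  expect_equal(unname(cem["inflection_count"]), 2)
})

test_that("slope metrics recover exact synthetic regression coefficients", {
  amp <- c(2, 4, 6, 9, 13)
  ev <- make_events(sacc = data.frame(amp = amp, peak = 100 * amp^0.55,
                                      dur = 2.2 * amp + 21))
  cem <- cem_features(ev)
  expect_equal(unname(cem["main_seq_slope"]), 0.55, tolerance = 1e-6)
  expect_equal(unname(cem["amp_dur_slope"]), 2.2, tolerance = 1e-6)
})

test_that("all 14 CEM metrics match brute-force recomputation on random trials", {
  prof <- default_profile()
  g <- test_geometry()
  for (seed in 1:20) {
    rec <- generate_trial(prof, seed %% 10, g, seed = seed)
    ev <- detect_events(rec)
    a <- unname(cem_features(ev, g))
    b <- oracle_cem(ev, g)
    same_na <- is.na(a) == is.na(b)
    expect_true(all(same_na))
    idx <- !is.na(a)
    expect_equal(a[idx], b[idx], tolerance = 1e-9)
  }
})

test_that("hull area is zero for collinear centroids and rotation invariant", {
  # points on the horizontal line through the screen centre are collinear in
  # angular space too
  ev <- make_events(fix = data.frame(x = c(400, 500, 600), y = 540, dur = 100))
  expect_equal(unname(cem_features(ev)["hull_area_deg2"]), 0)

  g <- test_geometry()
  set.seed(7)
  # rotation about the screen centre in angular space: compare hull of
  # rotated angular coordinates via the oracle
  pts <- cbind(runif(8, -8, 8), runif(8, -5, 5))
  a0 <- oracle_hull_area(pts)
  th <- 0.73
  rot <- pts %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(oracle_hull_area(rot), a0, tolerance = 1e-6)
})

test_that("scanpath length translates and scales as a length should", {
  base <- data.frame(x = c(500, 700, 650, 900), y = c(300, 350, 500, 620),
                     dur = 100)
  len0 <- unname(cem_features(make_events(fix = base))["scanpath_len_deg"])
  shifted <- base
  shifted$x <- shifted$x + 60
  shifted$y <- shifted$y + 40
  len1 <- unname(cem_features(make_events(fix = shifted))["scanpath_len_deg"])
  expect_equal(len1, len0, tolerance = 0.02)
  # doubling angular separations about the centre doubles the length
  g <- test_geometry()
  pitch <- pixel_pitch_cm(g)
  to_ang <- function(px, py) {
    cbind(atan((px - g$width_px / 2) * pitch / 70),
          atan((py - g$height_px / 2) * pitch / 70)) * 180 / pi
  }
  ang <- to_ang(base$x, base$y)
  back <- function(a) {
    data.frame(x = g$width_px / 2 + tan(a[, 1] * pi / 180) * 70 / pitch,
               y = g$height_px / 2 + tan(a[, 2] * pi / 180) * 70 / pitch,
               dur = 100)
  }
  len2 <- unname(cem_features(make_events(fix = back(ang * 2)))["scanpath_len_deg"])
  expect_equal(len2, 2 * len0, tolerance = 1e-9)
})

test_that("heatmap deposits durations and conserves mass under smoothing", {
  g <- test_geometry()
  ev <- make_events(fix = data.frame(x = 431, y = 207, dur = 300))
  m0 <- duration_heatmap(ev, g, smoothing_sigma_px = 0)
  expect_equal(sum(m0 > 0), 1L)
  expect_equal(max(m0), 300)

  ev2 <- make_events(fix = data.frame(x = c(100, 1800), y = c(100, 900),
                                      dur = c(250, 250)))
  m2 <- duration_heatmap(ev2, g, smoothing_sigma_px = 0)
  expect_equal(sort(m2[m2 > 0]), c(250, 250))

  m3 <- duration_heatmap(ev2, g, smoothing_sigma_px = 45)
  expect_equal(sum(m3), 500, tolerance = 1e-9) # reflective boundary conserves mass
  expect_true(all(m3 >= 0))
  expect_equal(duration_heatmap(make_events(fix = data.frame(x = numeric(0),
                                                             y = numeric(0),
                                                             dur = numeric(0))[0, ]),
                                g)[1, 1], 0)
})

test_that("Shannon entropy hits its analytic limits and splitting increases it", {
  expect_equal(shannon_entropy(matrix(1, 16, 16)), 8) # log2(256)
  m <- matrix(0, 4, 4)
  m[2, 3] <- 7
  expect_equal(shannon_entropy(m), 0)
  m2 <- matrix(0, 4, 4)
  m2[1, 1] <- 0.5
  m2[4, 4] <- 0.5
  expect_equal(shannon_entropy(m2), 1)
  expect_error(shannon_entropy(matrix(0, 3, 3)), "zero")
  # splitting one cell's mass equally into two strictly increases entropy
  m3 <- matrix(0, 4, 4)
  m3[1, 1] <- 4
  m3[2, 2] <- 4
  m4 <- m3
  m4[2, 2] <- 2
  m4[3, 3] <- 2
  expect_gt(shannon_entropy(m4), shannon_entropy(m3))
  # bounds
  set.seed(3)
  r <- matrix(rexp(64), 8, 8)
  h <- shannon_entropy(r)
  expect_gte(h, 0)
  expect_lte(h, log2(64))
})

test_that("AOI dwell credits nested regions and the background remainder", {
  g <- test_geometry()
  schema <- default_aoi_schema(0, g)
  nose <- schema$regions$face_L_nose$polygon
  cx <- mean(nose[, 1])
  cy <- mean(nose[, 2])
  ev <- make_events(fix = data.frame(x = c(cx, 30), y = c(cy, 30),
                                     dur = c(400, 150)))
  d <- aoi_dwell(ev, schema)
  expect_equal(unname(d["face_L_nose"]), 400)
  expect_equal(unname(d["face_L"]), 400) # nested: the face accrues too
  expect_equal(unname(d["background"]), 150) # off-face only
  expect_equal(unname(d["face_R"]), 0)
  # disjoint top-level regions partition the total fixation duration
  expect_equal(unname(d["face_L"] + d["face_R"] + d["background"]), 550)

  none <- aoi_dwell(ev[0, ], schema)
  expect_true(all(none == 0))
})

test_that("dwell partition holds on random synthetic trials", {
  prof <- default_profile()
  g <- test_geometry()
  schema <- default_aoi_schema(0, g)
  for (seed in c(3, 14, 25)) {
    ev <- detect_events(generate_trial(prof, 0, g, seed = seed))
    d <- aoi_dwell(ev, schema)
    expect_equal(unname(d["face_L"] + d["face_R"] + d["background"]),
                 sum(ev$duration_ms[ev$kind == "fixation"]), tolerance = 1e-9)
  }
})

test_that("point-in-polygon counts boundaries inside and rejects bad input", {
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  expect_true(point_in_polygon(5, 5, sq))
  expect_true(point_in_polygon(0, 5, sq))   # edge
  expect_true(point_in_polygon(10, 10, sq)) # vertex
  expect_false(point_in_polygon(10.001, 5, sq))
  expect_false(point_in_polygon(-1, -1, sq))
  expect_error(point_in_polygon(1, 1, cbind(c(0, 1), c(0, 1))), "n >= 3")
})

test_that("feature table has 26 columns per trial and parsable provenance", {
  prot1 <- stimulus_protocol(n_trials = 1)
  coh <- generate_cohort(3, 0.5, protocol = prot1, seed = 2)
  ft <- extract_features(coh)
  expect_identical(ncol(ft), 26L)
  prov <- attr(ft, "provenance")
  expect_identical(nrow(prov), 26L)
  expect_identical(as.integer(table(prov$family)[c("cem", "entropy", "aoi")]),
                   c(14L, 1L, 11L))
})

test_that("identical recordings give identical feature rows; missing trials excluded", {
  prot <- stimulus_protocol(n_trials = 2)
  prof <- default_profile()
  g <- test_geometry()
  tf <- list()
  for (pid in c("pa", "pb")) {
    for (j in 0:1) {
      rec <- generate_trial(prof, j, g, stimulus_protocol(n_trials = 2),
                            seed = 100 + j)
      rec$participant_id <- pid
      tf[[length(tf) + 1]] <- trial_features(rec)
      tf[[length(tf)]]$participant_id <- pid
    }
  }
  # a third participant missing trial 1
  rec <- generate_trial(prof, 0, g, stimulus_protocol(n_trials = 2), seed = 55)
  rec$participant_id <- "pc"
  tfc <- trial_features(rec)
  tfc$participant_id <- "pc"
  expect_warning(ft <- assemble_feature_table(c(tf, list(tfc)), prot),
                 "missing trials")
  expect_identical(rownames(ft), c("pa", "pb"))
  expect_equal(unname(as.matrix(ft)[1, ]), unname(as.matrix(ft)[2, ]))
})
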