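# Independent brute-force oracles and shared fixtures. The oracles use plain
# loops and share no code with the package implementations they check.

# Finite-difference angular velocity: straightforward loop re-implementation.
oracle_velocity <- function(rec) {
  s <- rec$samples
  g <- rec$geometry
  pitch <- g$diagonal_cm / sqrt(g$width_px^2 + g$height_px^2)
  ang <- function(x, y) {
    c(atan((x - g$width_px / 2) * pitch / g$viewing_distance_cm),
      atan((y - g$height_px / 2) * pitch / g$viewing_distance_cm)) * 180 / pi
  }
  n <- nrow(s)
  v <- numeric(n)
  for (i in seq_len(n)) {
    if (i == 1) {
      p1 <- ang(s$x_px[1], s$y_px[1]); p2 <- ang(s$x_px[2], s$y_px[2])
      v[i] <- sqrt(sum((p2 - p1)^2)) / (s$t_ms[2] - s$t_ms[1]) * 1000
    } else if (i == n) {
      p1 <- ang(s$x_px[n - 1], s$y_px[n - 1]); p2 <- ang(s$x_px[n], s$y_px[n])
      v[i] <- sqrt(sum((p2 - p1)^2)) / (s$t_ms[n] - s$t_ms[n - 1]) * 1000
    } else {
      p1 <- ang(s$x_px[i - 1], s$y_px[i - 1]); p2 <- ang(s$x_px[i + 1], s$y_px[i + 1])
      v[i] <- sqrt(sum((p2 - p1)^2)) / (s$t_ms[i + 1] - s$t_ms[i - 1]) * 1000
    }
  }
  v
}

# Naive recomputation of the 14 CEM metrics from an event table.
oracle_cem <- function(ev, geometry, roi_grid = c(8, 8)) {
  pitch <- geometry$diagonal_cm / sqrt(geometry$width_px^2 + geometry$height_px^2)
  ang <- function(x, y) {
    c(atan((x - geometry$width_px / 2) * pitch / geometry$viewing_distance_cm),
      atan((y - geometry$height_px / 2) * pitch / geometry$viewing_distance_cm)) * 180 / pi
  }
  fx <- ev[ev$kind == "fixation", ]
  sc <- ev[ev$kind == "saccade", ]
  out <- rep(NA_real_, 14)
  out[1] <- nrow(fx)
  if (nrow(fx) > 0) out[2] <- sum(fx$duration_ms) / nrow(fx)
  if (nrow(sc) > 0) {
    out[3] <- sum(sc$amp_deg) / nrow(sc)
    out[4] <- sum(sc$amp_h_deg) / nrow(sc)
    out[5] <- sum(sc$amp_v_deg) / nrow(sc)
    out[6] <- sum(sc$mean_v_dps) / nrow(sc)
    out[7] <- sum(sc$peak_v_dps) / nrow(sc)
    q <- 0
    for (i in seq_len(nrow(sc))) q <- q + sc$peak_v_dps[i] / sc$mean_v_dps[i]
    out[8] <- q / nrow(sc)
  }
  if (nrow(fx) >= 1) {
    pts <- matrix(0, nrow(fx), 2)
    for (i in seq_len(nrow(fx))) pts[i, ] <- ang(fx$cx_px[i], fx$cy_px[i])
    if (nrow(fx) >= 2) {
      len <- 0
      for (i in 2:nrow(fx)) len <- len + sqrt(sum((pts[i, ] - pts[i - 1, ])^2))
      out[9] <- len
      if (nrow(fx) >= 3) {
        infl <- 0
        for (i in 2:(nrow(fx) - 1)) {
          d1 <- pts[i, ] - pts[i - 1, ]
          d2 <- pts[i + 1, ] - pts[i, ]
          if (sum(d1 * d2) <= 1e-9) infl <- infl + 1
        }
        out[12] <- infl
      }
    }
    # convex hull area by testing all point triples is infeasible; use the
    # monotone-chain hull written here independently
    out[10] <- oracle_hull_area(pts)
    cells <- character(0)
    for (i in seq_len(nrow(fx))) {
      ix <- min(max(floor(fx$cx_px[i] / geometry$width_px * roi_grid[1]), 0),
                roi_grid[1] - 1)
      iy <- min(max(floor(fx$cy_px[i] / geometry$height_px * roi_grid[2]), 0),
                roi_grid[2] - 1)
      cells <- union(cells, paste(ix, iy))
    }
    out[11] <- length(cells)
  }
  if (nrow(sc) >= 2) {
    out[13] <- oracle_slope(sc$amp_deg, sc$duration_ms)
    if (all(sc$amp_deg > 0) && all(sc$peak_v_dps > 0) &&
        length(unique(sc$amp_deg)) >= 2) {
      out[14] <- oracle_slope(log10(sc$amp_deg), log10(sc$peak_v_dps))
    }
  }
  out
}

oracle_slope <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0
  den <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    den <- den + (x[i] - mx)^2
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Monotone-chain convex hull + shoelace, written independently.
oracle_hull_area <- function(pts) {
  pts <- unique(pts[order(pts[, 1], pts[, 2]), , drop = FALSE])
  n <- nrow(pts)
  if (n < 3) return(0)
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(pts[h[length(h) - 1], ], pts[h[length(h)], ], pts[i, ]) <= 0) {
        h <- h[-length(h)]
      }
      h <- c(h, i)
    }
    h[-length(h)]
  }
  hull <- c(build(seq_len(n)), build(rev(seq_len(n))))
  hp <- pts[hull, , drop = FALSE]
  m <- nrow(hp)
  if (m < 3) return(0)
  area <- 0
  for (i in seq_len(m)) {
    j <- if (i == m) 1 else i + 1
    area <- area + hp[i, 1] * hp[j, 2] - hp[j, 1] * hp[i, 2]
  }
  abs(area) / 2
}

# Exact Friedman p-value by enumerating all within-block orderings of the
# treatment scores (permutation null of the rank statistic).
oracle_friedman_perm_p <- function(m) {
  k <- ncol(m)
  n <- nrow(m)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  stat <- function(mat) {
    r <- t(apply(mat, 1, rank))
    rb <- colMeans(r)
    s <- 12 * n / (k * (k + 1)) * sum((rb - (k + 1) / 2)^2)
    ties <- sum(apply(mat, 1, function(row) {
      tt <- table(row)
      sum(tt^3 - tt)
    }))
    corr <- 1 - ties / (n * k * (k^2 - 1))
    if (corr > 0) s / corr else 0
  }
  obs <- stat(m)
  pk <- perms(seq_len(k))
  idx <- rep(1L, n)
  total <- length(pk)^n
  count <- 0
  for (code in seq_len(total) - 1) {
    digits <- integer(n)
    c0 <- code
    for (b in seq_len(n)) {
      digits[b] <- c0 %% length(pk)
      c0 <- c0 %/% length(pk)
    }
    mm <- m
    for (b in seq_len(n)) mm[b, ] <- m[b, pk[[digits[b] + 1]]]
    if (stat(mm) >= obs - 1e-12) count <- count + 1
  }
  count / total
}

# Small shared fixtures -------------------------------------------------

test_geometry <- function() screen_geometry()

# A two-fixation noiseless stream: hold at A, jump, hold at B.
two_fixation_recording <- function(geometry = test_geometry(),
                                   a = c(500, 500), b = c(1400, 600),
                                   hold_ms = 1000, dt = 1000 / 90) {
  n1 <- round(hold_ms / dt)
  t <- seq(0, by = dt, length.out = 2 * n1)
  x <- c(rep(a[1], n1), rep(b[1], n1))
  y <- c(rep(a[2], n1), rep(b[2], n1))
  gaze_recording(data.frame(t_ms = t, x_px = x, y_px = y), geometry)
}

default_profile <- function(latent = rep(0.5, 5), coupling = 1,
                            config = synth_config()) {
  participant_profile("pX", latent, coupling, config)
}

# Build an event table directly (bypassing detection) for metric tests.
make_events <- function(fix = NULL, sacc = NULL, geometry = test_geometry()) {
  rows <- list()
  tt <- 0
  if (!is.null(fix)) {
    for (i in seq_len(nrow(fix))) {
      rows[[length(rows) + 1]] <- data.frame(
        kind = "fixation", start_ms = tt, end_ms = tt + fix$dur[i],
        duration_ms = fix$dur[i], cx_px = fix$x[i], cy_px = fix$y[i],
        amp_deg = NA_real_, amp_h_deg = NA_real_, amp_v_deg = NA_real_,
        mean_v_dps = NA_real_, peak_v_dps = NA_real_,
        dir_x = NA_real_, dir_y = NA_real_)
      tt <- tt + fix$dur[i] + 20
    }
  }
  if (!is.null(sacc)) {
    for (i in seq_len(nrow(sacc))) {
      rows[[length(rows) + 1]] <- data.frame(
        kind = "saccade", start_ms = tt, end_ms = tt + sacc$dur[i],
        duration_ms = sacc$dur[i], cx_px = NA_real_, cy_px = NA_real_,
        amp_deg = sacc$amp[i],
        amp_h_deg = sacc$amp[i], amp_v_deg = 0,
        mean_v_dps = sacc$peak[i] / 1.6, peak_v_dps = sacc$peak[i],
        dir_x = 1, dir_y = 0)
      tt <- tt + sacc$dur[i] + 20
    }
  }
  if (length(rows) == 0) {
    ev <- data.frame(kind = character(), start_ms = numeric(),
                     end_ms = numeric(), duration_ms = numeric(),
                     cx_px = numeric(), cy_px = numeric(),
                     amp_deg = numeric(), amp_h_deg = numeric(),
                     amp_v_deg = numeric(), mean_v_dps = numeric(),
                     peak_v_dps = numeric(), dir_x = numeric(),
                     dir_y = numeric())
  } else {
    ev <- do.call(rbind, rows)
  }
  attr(ev, "geometry") <- geometry
  class(ev) <- c("event_table", "data.frame")
  ev
}
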