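ptab <- function(...) {
  df <- data.frame(...)
  class(df) <- c("particle_table", "data.frame")
  df
}

base_rec <- function(frame, x, y, area = 25, perimeter = 20,
                     orientation = 0, length = 5, width = 5) {
  data.frame(frame = frame, cm_x = x, cm_y = y, perimeter = perimeter,
             area = area, orientation = orientation, length = length,
             width = width, touches_border = FALSE)
}

test_that("normalize_features divides by the median absolute value", {
  tab <- ptab(rbind(base_rec(1, 10, 10, area = 10),
                    base_rec(1, 20, 20, area = 30)))
  out <- normalize_features(tab)
  expect_equal(out$area, c(0.5, 1.5))  # median |area| = 20
  expect_equal(attr(out, "scales")[["area"]], 20)
  expect_equal(out$raw_cm_x, c(10, 20))
})

test_that("constant characteristics normalize to 1 and the map is idempotent", {
  tab <- ptab(rbind(base_rec(1, 8, 6), base_rec(2, 9, 7)))
  out <- normalize_features(tab)
  expect_true(all(out$area == 1))
  out2 <- normalize_features(out)
  for (f in c("cm_x", "cm_y", "area", "perimeter", "length", "width"))
    expect_equal(out2[[f]], out[[f]], tolerance = 1e-12)
  expect_error(normalize_features(ptab(base_rec(1, 1, 1)[0, ])),
               "empty")
})

test_that("cost is the weighted L1 feature distance", {
  i <- base_rec(1, 10, 10)
  j <- base_rec(2, 13, 14)
  w <- feature_weights(cm_x = 1, cm_y = 1, perimeter = 1, area = 1,
                       orientation = 1, length = 1, width = 1)
  E <- cost_matrix(i, j, w = w, gate = 40)
  expect_equal(E$costs[1, 1], 7)  # |dx| + |dy| = 3 + 4

  expect_equal(cost_matrix(i, i, w = w)$costs[1, 1], 0)
})

test_that("orientation differences wrap on the 180-degree circle", {
  i <- base_rec(1, 10, 10, orientation = -89)
  j <- base_rec(2, 10, 10, orientation = 89)
  w <- feature_weights(cm_x = 0, cm_y = 0, perimeter = 0, area = 0,
                       orientation = 1, length = 0, width = 0)
  expect_equal(cost_matrix(i, j, w = w)$costs[1, 1], 2)
})

test_that("displacement beyond the gate is inadmissible", {
  i <- base_rec(1, 0, 0)
  j <- base_rec(2, 50, 0)
  E <- cost_matrix(i, j, gate = 30)
  expect_true(is.infinite(E$costs[1, 1]))
  expect_equal(nrow(associate(E)$matches), 0)
})

test_that("empty frames give empty associations", {
  e <- ptab(base_rec(1, 1, 1)[0, ])
  E <- cost_matrix(e, base_rec(2, 1, 1))
  expect_equal(dim(E$costs), c(0, 1))
  res <- associate(E)
  expect_equal(nrow(res$matches), 0)
  expect_equal(res$appeared, 1)
})

test_that("association resolves the classic crossing cost matrix", {
  res <- associate(matrix(c(5, 2, 2, 5), 2, byrow = TRUE))
  expect_equal(res$total_cost, 4)
  m <- res$matches[order(res$matches[, "i"]), ]
  expect_equal(unname(m[, "j"]), c(2, 1))
})

test_that("a 1x1 and a 2x1 matrix match the obvious cardinalities", {
  r1 <- associate(matrix(3, 1, 1))
  expect_equal(nrow(r1$matches), 1)

  r2 <- associate(matrix(c(1, 2), 2, 1))
  expect_equal(nrow(r2$matches), 1)
  expect_length(r2$disappeared, 1)
  expect_length(r2$appeared, 0)
  expect_equal(unname(r2$matches[1, ]), c(1, 1))  # cheaper row wins
})

test_that("assignment cost equals brute force on random matrices", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(2:5, 1)
    a <- matrix(stats::runif(n * n, 0, 100), n)
    expect_equal(associate(a)$total_cost, brute_force_lap(a),
                 tolerance = 1e-9)
  }
})

test_that("no particle is ever assigned twice", {
  set.seed(31)
  for (rep in 1:20) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    a <- matrix(stats::runif(n1 * n2, 0, 10), n1, n2)
    a[stats::runif(n1 * n2) < 0.3] <- Inf
    res <- associate(a)
    expect_true(!anyDuplicated(res$matches[, "i"]))
    expect_true(!anyDuplicated(res$matches[, "j"]))
    expect_setequal(c(res$matches[, "i"], res$disappeared),
                    seq_len(n1))
    expect_setequal(c(res$matches[, "j"], res$appeared), seq_len(n2))
  }
})

make_line_table <- function(frames, x0 = 10, step = 10, drop = integer()) {
  recs <- do.call(rbind, lapply(setdiff(seq_len(frames), drop),
                                function(t)
                                  base_rec(t, x0 + step * (t - 1), 50)))
  ptab(recs)
}

test_that("a particle present in all frames gives one full track", {
  tab <- make_line_table(30)
  ts <- track_particles(tab, n_frames = 30)
  expect_equal(length(unique(ts$tracks$track_id)), 1)
  expect_equal(sum(!ts$tracks$gap), 30)
})

test_that("a one-frame dropout is closed with a gap marker", {
  tab <- make_line_table(20, drop = 10)
  ts <- track_particles(tab, n_frames = 20, max_gap = 1)
  expect_equal(length(unique(ts$tracks$track_id)), 1)
  expect_equal(sum(ts$tracks$gap), 1)
  expect_equal(ts$tracks$frame[ts$tracks$gap], 10)
  expect_equal(sum(!ts$tracks$gap), 19)
})

test_that("a dropout longer than max_gap splits the track", {
  tab <- make_line_table(20, drop = c(10, 11))
  ts <- track_particles(tab, n_frames = 20, max_gap = 1,
                        min_track_len = 5)
  expect_equal(length(unique(ts$tracks$track_id)), 2)
})

test_that("spurious short detections produce no track", {
  # a single-frame detection far from the moving particle
  tab <- ptab(rbind(make_line_table(10), base_rec(4, 400, 400)))
  ts <- track_particles(tab, n_frames = 10, min_track_len = 5)
  expect_equal(length(unique(ts$tracks$track_id)), 1)
})

test_that("velocities convert displacement to um/s at the optics scale", {
  # 10 px/frame at 94.2 nm/px, 30 fps -> 28.26 um/s
  tab <- make_line_table(10)
  ts <- track_particles(tab, n_frames = 10)
  res <- track_velocities(ts, optical_config())
  expect_equal(res$n_vectors, 9)
  expect_equal(res$mean_velocity, 28.26, tolerance = 1e-12)

  # displacement (3, 4) px -> 5 px -> 14.13 um/s
  tab2 <- ptab(rbind(base_rec(1, 10, 10), base_rec(2, 13, 14),
                     base_rec(3, 16, 18), base_rec(4, 19, 22),
                     base_rec(5, 22, 26)))
  res2 <- track_velocities(track_particles(tab2, n_frames = 5,
                                           min_track_len = 5))
  expect_equal(res2$mean_velocity, 14.13, tolerance = 1e-12)
})

test_that("a stationary track has zero speed", {
  tab <- make_line_table(8, step = 0)
  res <- track_velocities(track_particles(tab, n_frames = 8))
  expect_equal(res$mean_velocity, 0)
})

test_that("a speed step across a closed gap uses the elapsed time", {
  tab <- make_line_table(11, drop = 6)
  res <- track_velocities(track_particles(tab, n_frames = 11))
  # all steps 10 px / frame; the bridged step is 20 px over 2 frames
  expect_equal(unique(round(res$velocities$speed_um_s, 10)), 28.26)
  expect_equal(res$n_vectors, 9)
})

test_that("empty track sets yield an empty flagged result", {
  ts <- track_particles(ptab(base_rec(1, 1, 1)[0, ]), n_frames = 5)
  res <- track_velocities(ts)
  expect_equal(res$n_vectors, 0)
  expect_true(is.na(res$mean_velocity))
  expect_equal(res$qc_flag, "ok")
})

test_that("crowded samples raise the too_crowded flag", {
  # 16 parallel movers > 15 threshold
  recs <- do.call(rbind, lapply(1:16, function(i)
    do.call(rbind, lapply(1:6, function(t)
      base_rec(t, 10 + 5 * (t - 1), 30 * i)))))
  ts <- track_particles(ptab(recs), n_frames = 6)
  res <- track_velocities(ts)
  expect_equal(res$mean_bacteria_per_image, 16)
  expect_equal(res$qc_flag, "too_crowded")
})
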