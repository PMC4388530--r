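# Shared fixtures: all scenes are generated in code at test time.

# Two bacteria with distinct areas whose paths cross mid-series with a
# few frames' offset in arrival, so the bodies pass ~35 px apart and
# both stay inside the frame for all 30 frames.
crossing_scene_spec <- function(seed = 5) {
  scene_spec(width_px = 520, height_px = 480, n_frames = 30,
             bacteria = list(
               bacterium_spec(c(90, 240), speed = 40, heading = 0,
                              length = 3.0, width = 0.9),
               bacterium_spec(c(250, 30), speed = 40, heading = 90,
                              length = 1.5, width = 0.7)),
             rng_seed = seed)
}

# Run the pipeline on a scene and return truth mean speed, recovered
# mean speed and the result object.
recover_scene <- function(spec) {
  sc <- render_scene(spec)
  res <- suppressMessages(run_pipeline(sc$frames))
  list(truth_mean = mean(sc$truth$speed_um_s),
       recovered_mean = res$mean_velocity,
       result = res, truth = sc$truth)
}

# Assign each recovered track to the ground-truth bacterium with the
# smallest maximum per-frame deviation; returns a data frame with the
# assignment and that deviation (px).
match_tracks_to_truth <- function(result, truth) {
  ts <- attr(result, "tracks")$tracks
  ids <- unique(ts$track_id)
  do.call(rbind, lapply(ids, function(id) {
    tr <- ts[ts$track_id == id & !ts$gap, ]
    dev <- vapply(unique(truth$bacterium_id), function(b) {
      m <- merge(tr, truth[truth$bacterium_id == b, ], by = "frame")
      if (nrow(m) == 0) return(Inf)
      max(sqrt((m$x_px.x - m$x_px.y)^2 + (m$y_px.x - m$y_px.y)^2))
    }, numeric(1))
    data.frame(track_id = id,
               bacterium_id = unique(truth$bacterium_id)[which.min(dev)],
               max_dev_px = min(dev))
  }))
}

# All permutations of 1..n (for brute-force assignment oracles).
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, p + (p >= k))))
}

# Brute-force minimal assignment cost over all permutations (square
# matrix, finite entries).
brute_force_lap <- function(a) {
  n <- nrow(a)
  pm <- permutations_of(n)
  min(apply(pm, 1, function(p) sum(a[cbind(seq_len(n), p)])))
}

# Brute-force feature computation on a pixel mask by direct looping,
# independent of measure_features' vectorized path.
brute_force_moments <- function(px) {
  xs <- px[, "col"] - 1; ys <- px[, "row"] - 1
  n <- nrow(px)
  cmx <- sum(xs) / n; cmy <- sum(ys) / n
  m20 <- 0; m02 <- 0; m11 <- 0
  for (k in seq_len(n)) {
    m20 <- m20 + (xs[k] - cmx)^2
    m02 <- m02 + (ys[k] - cmy)^2
    m11 <- m11 + (xs[k] - cmx) * (ys[k] - cmy)
  }
  list(cm_x = cmx, cm_y = cmy, mu20 = m20 / n, mu02 = m02 / n,
       mu11 = m11 / n)
}

# Random connected pixel blob grown from a seed pixel.
random_blob <- function(n_px, seed) {
  set.seed(seed)
  px <- matrix(c(10L, 10L), 1, 2,
               dimnames = list(NULL, c("row", "col")))
  while (nrow(px) < n_px) {
    base <- px[sample(nrow(px), 1), ]
    step <- rbind(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))[sample(4, 1), ]
    cand <- base + step
    if (!any(px[, 1] == cand[1] & px[, 2] == cand[2]))
      px <- rbind(px, cand)
  }
  px
}
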