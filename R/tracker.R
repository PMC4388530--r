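# Frame-to-frame association and track building.
#
# Particles detected in consecutive frames are linked by minimising the
# total weighted L1 distance between their seven characteristics over a
# one-to-one assignment (optimal linear assignment, not greedy nearest
# neighbour: a global optimum is what prevents double assignments when
# two cells cross). Unmatched particles become disappearances and
# appearances; short interruptions are closed by re-linking across a
# bounded gap, and tracks too short to be trustworthy are dropped.

FEATURE_NAMES <- c("cm_x", "cm_y", "perimeter", "area", "orientation",
                   "length", "width")

#' Per-characteristic association weights
#'
#' The association cost between two particles is
#' `sum_c w_c * |f_c(i) - f_c(j)|` over the seven characteristics,
#' evaluated on normalized features. The defaults weight the two
#' centroid terms 1.0 and the five shape terms 0.2 each: over one frame
#' at 30 fps position is by far the most informative cue, while shape
#' disambiguates crossing cells.
#'
#' @param cm_x,cm_y,perimeter,area,orientation,length,width
#'   non-negative weights; at least one must be positive.
#' @return A named numeric vector of class `feature_weights`.
#' @export
feature_weights <- function(cm_x = 1, cm_y = 1, perimeter = 0.2,
                            area = 0.2, orientation = 0.2,
                            length = 0.2, width = 0.2) {
  w <- c(cm_x = cm_x, cm_y = cm_y, perimeter = perimeter, area = area,
         orientation = orientation, length = length, width = width)
  stopifnot(all(w >= 0), any(w > 0))
  structure(w, class = c("feature_weights", "numeric"))
}

#' Normalize particle characteristics for weighting
#'
#' Divides each characteristic by its series-wide robust scale — the
#' median absolute value, floored at 1 — so that characteristics with
#' different units become commensurate before weighting. Applying the
#' normalization twice is idempotent (the rescaled columns have median
#' absolute value 1). The raw centroids are preserved in `raw_cm_x` /
#' `raw_cm_y` because displacement gating operates in pixels.
#'
#' @param table a non-empty `particle_table` from [analyze_frames()].
#' @return The normalized table, with the scales attached as
#'   `attr(, "scales")`.
#' @export
normalize_features <- function(table) {
  if (nrow(table) == 0) stop("cannot normalize an empty particle table")
  if (!("raw_cm_x" %in% names(table))) {
    table$raw_cm_x <- table$cm_x
    table$raw_cm_y <- table$cm_y
  }
  scales <- vapply(FEATURE_NAMES,
                   function(f) max(stats::median(abs(table[[f]])), 1),
                   numeric(1))
  for (f in FEATURE_NAMES) table[[f]] <- table[[f]] / scales[[f]]
  attr(table, "scales") <- scales
  table
}

# angular distance on orientations, which live on a 180-degree circle
orientation_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Association cost matrix between two frames
#'
#' Entry `(i, j)` is the weighted sum of absolute characteristic
#' differences between particle `i` of the earlier frame and particle
#' `j` of the later frame. Orientation differences are taken on the
#' 180-degree circle (a cell at -89 degrees is close to one at +89).
#' Pairs whose raw centroid displacement exceeds `gate` pixels are
#' inadmissible (`Inf` cost): no plausible cell moves that far in one
#' frame interval.
#'
#' @param frame_t,frame_t1 rows of a (normally [normalize_features()]d)
#'   particle table for two consecutive frames.
#' @param w a [feature_weights()] vector.
#' @param gate maximum admissible centroid displacement in raw pixels.
#'   The default 40 px corresponds to about 113 um/s at the canonical
#'   optics — above any plausible swimming speed.
#' @return A `cost_matrix` object: list of `costs` (matrix, `Inf` where
#'   inadmissible) and `gate`. Either frame empty gives a 0-row/col
#'   matrix.
#' @export
cost_matrix <- function(frame_t, frame_t1, w = feature_weights(),
                        gate = 40) {
  n1 <- nrow(frame_t); n2 <- nrow(frame_t1)
  costs <- matrix(0, n1, n2)
  if (n1 > 0 && n2 > 0) {
    for (f in FEATURE_NAMES) {
      d <- if (f == "orientation")
        outer(frame_t[[f]], frame_t1[[f]], orientation_dist)
      else
        abs(outer(frame_t[[f]], frame_t1[[f]], `-`))
      costs <- costs + w[[f]] * d
    }
    rx <- if ("raw_cm_x" %in% names(frame_t)) "raw_cm_x" else "cm_x"
    ry <- if ("raw_cm_y" %in% names(frame_t)) "raw_cm_y" else "cm_y"
    disp <- sqrt(outer(frame_t[[rx]], frame_t1[[rx]], `-`)^2 +
                   outer(frame_t[[ry]], frame_t1[[ry]], `-`)^2)
    costs[disp > gate] <- Inf
  }
  structure(list(costs = costs, gate = gate), class = "cost_matrix")
}

# O(n^3) Hungarian algorithm (shortest augmenting paths with
# potentials) for a square cost matrix with finite entries.
# Returns the column assigned to each row.
solve_lap <- function(a) {
  n <- nrow(a)
  stopifnot(ncol(a) == n, all(is.finite(a)))
  u <- numeric(n)
  v <- numeric(n + 1)
  p <- integer(n + 1)      # p[j]: row assigned to column j (0 = none)
  way <- integer(n)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- logical(n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- a[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          if (j <= n) v[j] <- v[j] - delta
        } else if (j <= n) {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assign_col <- integer(n)
  assign_col[p[seq_len(n)]] <- seq_len(n)
  assign_col
}

#' Optimal one-to-one association between two frames
#'
#' Solves the linear assignment problem on the admissible entries of a
#' cost matrix: the returned matching has minimal total cost among all
#' matchings of maximal size, so no particle is ever assigned twice and
#' crossings resolve globally. Rows with no admissible partner are
#' reported as disappearances, columns as appearances.
#'
#' @param E a [cost_matrix()] or a plain numeric matrix (entries may be
#'   `Inf` for inadmissible pairs).
#' @return A list: `matches` (2-column matrix `i`, `j`), `disappeared`
#'   (row indices), `appeared` (column indices), `total_cost`.
#' @export
associate <- function(E) {
  costs <- if (inherits(E, "cost_matrix")) E$costs else as.matrix(E)
  n1 <- nrow(costs); n2 <- ncol(costs)
  empty <- list(matches = cbind(i = integer(), j = integer()),
                disappeared = seq_len(n1), appeared = seq_len(n2),
                total_cost = 0)
  if (n1 == 0 || n2 == 0) return(empty)
  big <- max(1, costs[is.finite(costs)], na.rm = TRUE) * n1 * n2 + 1e6
  n <- max(n1, n2)
  a <- matrix(big, n, n)
  fin <- costs
  fin[!is.finite(fin)] <- big
  a[seq_len(n1), seq_len(n2)] <- fin
  col_of <- solve_lap(a)
  keep <- which(seq_len(n) <= n1 & col_of <= n2)
  keep <- keep[is.finite(costs[cbind(keep, col_of[keep])])]
  matches <- cbind(i = keep, j = col_of[keep])
  list(matches = matches,
       disappeared = setdiff(seq_len(n1), matches[, "i"]),
       appeared = setdiff(seq_len(n2), matches[, "j"]),
       total_cost = sum(costs[matches]))
}

#' Assemble tracks from per-pair assignments
#'
#' Chains the frame-to-frame matches into tracks. A track whose particle
#' is missed for up to `max_gap` consecutive frames is re-linked to an
#' unexplained "appeared" particle using the same weighted cost and the
#' same displacement gate scaled by the elapsed frame count; competing
#' re-links are resolved by another optimal assignment. Tracks with
#' fewer than `min_track_len` detections are removed as spurious.
#'
#' @param assignments list of [associate()] results for frame pairs
#'   `(1,2), (2,3), ...`.
#' @param tables list of per-frame particle-table subsets (normalized),
#'   `length(assignments) + 1` entries, in frame order.
#' @param max_gap maximum number of consecutive missed frames that can
#'   be closed (default 1).
#' @param min_track_len minimum number of detections for a track to be
#'   kept (default 5).
#' @param w,gate cost weights and per-frame displacement gate used for
#'   gap closing.
#' @return A `track_set`: list with `tracks` (data frame `track_id`,
#'   `frame`, `x_px`, `y_px`, `gap`; gap rows carry `NA` coordinates),
#'   `n_frames`, and `particles_per_frame`.
#' @export
build_tracks <- function(assignments, tables, max_gap = 1,
                         min_track_len = 5, w = feature_weights(),
                         gate = 40) {
  n_frames <- length(tables)
  stopifnot(length(assignments) == n_frames - 1)

  tracks <- list()    # each: list(frames =, idx =) detection lists
  owner <- lapply(tables, function(tb)
    rep(NA_integer_, if (is.null(tb)) 0 else nrow(tb)))
  open <- list()      # tracks awaiting gap closure: id + last frame

  new_track <- function(t, i) {
    tracks[[length(tracks) + 1]] <<- list(frames = t, idx = i)
    owner[[t]][i] <<- length(tracks)
  }
  extend <- function(id, t, i) {
    tracks[[id]]$frames <<- c(tracks[[id]]$frames, t)
    tracks[[id]]$idx <<- c(tracks[[id]]$idx, i)
    owner[[t]][i] <<- id
  }

  if (nrow(tables[[1]]) > 0)
    for (i in seq_len(nrow(tables[[1]]))) new_track(1L, i)

  for (t in seq_len(n_frames - 1)) {
    as_t <- assignments[[t]]
    # continue matched tracks
    if (nrow(as_t$matches) > 0)
      for (k in seq_len(nrow(as_t$matches))) {
        id <- owner[[t]][as_t$matches[k, "i"]]
        extend(id, t + 1L, as_t$matches[k, "j"])
      }
    # tracks interrupted at frame t move to the open pool
    for (i in as_t$disappeared) {
      id <- owner[[t]][i]
      open[[length(open) + 1]] <- list(id = id, last = t)
    }
    appeared <- as_t$appeared
    # drop open tracks whose gap can no longer be closed
    if (length(open) > 0) {
      alive <- vapply(open, function(o) (t + 1L) - o$last - 1L <= max_gap,
                      TRUE)
      open <- open[alive]
    }
    # gap closing: open tracks vs appeared particles at frame t+1
    if (length(open) > 0 && length(appeared) > 0) {
      oc <- matrix(Inf, length(open), length(appeared))
      for (oi in seq_along(open)) {
        o <- open[[oi]]
        last_det <- tables[[o$last]][tracks[[o$id]]$idx[
          length(tracks[[o$id]]$idx)], , drop = FALSE]
        span <- (t + 1L) - o$last      # elapsed frame intervals
        cm <- cost_matrix(last_det,
                          tables[[t + 1L]][appeared, , drop = FALSE],
                          w = w, gate = gate * span)
        oc[oi, ] <- cm$costs[1, ]
      }
      res <- associate(oc)
      if (nrow(res$matches) > 0)
        for (k in seq_len(nrow(res$matches))) {
          o <- open[[res$matches[k, "i"]]]
          extend(o$id, t + 1L, appeared[res$matches[k, "j"]])
        }
      closed <- if (nrow(res$matches) > 0) res$matches[, "i"] else
        integer()
      open <- open[setdiff(seq_along(open), closed)]
      appeared <- appeared[setdiff(seq_along(appeared),
                                   res$matches[, "j"])]
    }
    # remaining appearances start new tracks
    for (j in appeared) new_track(t + 1L, j)
  }

  keep <- which(vapply(tracks, function(tr) length(tr$frames), 0L) >=
                  min_track_len)
  rows <- lapply(seq_along(keep), function(k) {
    tr <- tracks[[keep[k]]]
    det <- data.frame(track_id = k, frame = tr$frames,
                      x_px = vapply(seq_along(tr$frames), function(q) {
                        tb <- tables[[tr$frames[q]]]
                        if ("raw_cm_x" %in% names(tb))
                          tb$raw_cm_x[tr$idx[q]] else tb$cm_x[tr$idx[q]]
                      }, 0),
                      y_px = vapply(seq_along(tr$frames), function(q) {
                        tb <- tables[[tr$frames[q]]]
                        if ("raw_cm_y" %in% names(tb))
                          tb$raw_cm_y[tr$idx[q]] else tb$cm_y[tr$idx[q]]
                      }, 0),
                      gap = FALSE)
    gaps <- setdiff(seq(min(tr$frames), max(tr$frames)), tr$frames)
    if (length(gaps) > 0)
      det <- rbind(det, data.frame(track_id = k, frame = gaps,
                                   x_px = NA_real_, y_px = NA_real_,
                                   gap = TRUE))
    det[order(det$frame), ]
  })
  df <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(track_id = integer(), frame = integer(),
               x_px = numeric(), y_px = numeric(), gap = logical())
  rownames(df) <- NULL
  structure(list(tracks = df, n_frames = n_frames,
                 particles_per_frame =
                   vapply(tables, nrow, 0L)),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks over %d frames (mean %.1f particles/frame)\n",
              length(unique(x$tracks$track_id)), x$n_frames,
              mean(x$particles_per_frame)))
  invisible(x)
}

#' Detect and link particles in one call
#'
#' Convenience wrapper: splits a particle table by frame, normalizes the
#' characteristics, associates every consecutive frame pair and builds
#' tracks.
#'
#' @param table a `particle_table` from [analyze_frames()].
#' @param n_frames total number of frames in the series (frames with no
#'   detections are represented as empty).
#' @param w,gate,max_gap,min_track_len see [cost_matrix()] and
#'   [build_tracks()].
#' @return A `track_set`.
#' @export
track_particles <- function(table, n_frames, w = feature_weights(),
                            gate = 40, max_gap = 1, min_track_len = 5) {
  if (nrow(table) > 0) table <- normalize_features(table)
  tables <- lapply(seq_len(n_frames), function(t)
    table[table$frame == t, , drop = FALSE])
  assignments <- lapply(seq_len(n_frames - 1), function(t)
    associate(cost_matrix(tables[[t]], tables[[t + 1]], w = w,
                          gate = gate)))
  build_tracks(assignments, tables, max_gap = max_gap,
               min_track_len = min_track_len, w = w, gate = gate)
}

#' Convert tracks to velocities and sample-level summary
#'
#' Every consecutive pair of detections within a track yields one
#' velocity vector: the Euclidean centroid displacement in pixels,
#' scaled to micrometres and divided by the elapsed time. A step that
#' bridges a closed gap of `g` frames spans `(g + 1) / fps` seconds, so
#' its speed uses the straight-line distance over that time.
#'
#' Quality control: when the mean number of detected particles per
#' frame exceeds 15 the association becomes unreliable (too many
#' near-identical candidates within the gate) and the result is flagged
#' `too_crowded`; such samples should be diluted further.
#'
#' @param tracks a `track_set`.
#' @param optics an [optical_config()] supplying `pixel_size_nm` and
#'   `fps`.
#' @return A `sample_result`: list with `velocities` (data frame
#'   `track_id`, `from_frame`, `speed_um_s`), `mean_velocity`, `sem`,
#'   `n_vectors`, `mean_bacteria_per_image`, `qc_flag` ("ok" or
#'   "too_crowded").
#' @export
track_velocities <- function(tracks, optics = optical_config()) {
  stopifnot(inherits(tracks, "track_set"),
            optics$pixel_size_nm > 0, optics$fps > 0)
  px_um <- optics$pixel_size_nm / 1000
  df <- tracks$tracks[!tracks$tracks$gap, , drop = FALSE]
  vel <- do.call(rbind, lapply(split(df, df$track_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 2) return(NULL)
    dist_px <- sqrt(diff(tr$x_px)^2 + diff(tr$y_px)^2)
    dt <- diff(tr$frame) / optics$fps
    data.frame(track_id = tr$track_id[1],
               from_frame = tr$frame[-nrow(tr)],
               speed_um_s = dist_px * px_um / dt)
  }))
  if (is.null(vel))
    vel <- data.frame(track_id = integer(), from_frame = integer(),
                      speed_um_s = numeric())
  n <- nrow(vel)
  mb <- mean(tracks$particles_per_frame)
  structure(list(velocities = vel,
                 mean_velocity = if (n > 0) mean(vel$speed_um_s) else
                   NA_real_,
                 sem = if (n > 1)
                   stats::sd(vel$speed_um_s) / sqrt(n) else NA_real_,
                 n_vectors = n,
                 mean_bacteria_per_image = mb,
                 qc_flag = if (mb > 15) "too_crowded" else "ok"),
            class = "sample_result")
}

#' @export
print.sample_result <- function(x, ...) {
  cat(sprintf(
    "<sample_result> mean %.2f um/s (SEM %.2f), n = %d vectors, %.1f bacteria/image [%s]\n",
    x$mean_velocity, x$sem, x$n_vectors, x$mean_bacteria_per_image,
    x$qc_flag))
  invisible(x)
}
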