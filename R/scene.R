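# Synthetic microscopy scenes with known bacterial kinematics.
#
# Coordinate convention (used package-wide): pixel (0, 0) is the top-left
# pixel centre, x increases rightwards (columns), y increases downwards
# (rows). Positions are floats in pixel units; a pixel covers the unit
# square centred on its integer coordinate. Frame indices are 1-based.

#' Describe one swimming bacterium
#'
#' A bacterium is rendered as a solid anti-aliased ellipse whose major
#' axis is aligned with its current heading. Each inter-frame step the
#' cell advances `speed / fps` micrometres along its heading, and the
#' heading is perturbed by a zero-mean Gaussian turn.
#'
#' @param start_xy numeric length-2, initial centroid in pixels (x, y).
#' @param speed swimming speed in micrometres per second (>= 0).
#' @param heading initial heading in degrees; 0 points along +x, 90
#'   along +y (downwards on screen).
#' @param heading_sd_per_step standard deviation of the random turn
#'   applied at each step, in degrees.
#' @param length,width full body axes in micrometres; `length >= width > 0`.
#'   Bodies narrower than 0.4 um are below the optical detection limit
#'   of the canonical setup and will generally not be recovered.
#' @param intensity peak body brightness, 0-255.
#' @return A `bacterium_spec` object.
#' @export
bacterium_spec <- function(start_xy, speed, heading,
                           heading_sd_per_step = 0,
                           length = 2.5, width = 0.8,
                           intensity = 200) {
  stopifnot(base::length(start_xy) == 2, is.finite(start_xy),
            speed >= 0, is.finite(heading),
            heading_sd_per_step >= 0,
            width > 0, length >= width,
            intensity >= 0, intensity <= 255)
  structure(list(start_xy = as.numeric(start_xy), speed = speed,
                 heading = heading,
                 heading_sd_per_step = heading_sd_per_step,
                 length = length, width = width,
                 intensity = intensity),
            class = "bacterium_spec")
}

#' Describe one static debris particle
#'
#' Debris models undissolved medium particles: it is rendered as a disc
#' at the same position in every frame, so a correct differencing stage
#' must suppress it completely.
#'
#' @param center_xy numeric length-2, centre in pixels (x, y).
#' @param radius disc radius in micrometres (> 0).
#' @param intensity brightness, 0-255.
#' @return A `debris_spec` object.
#' @export
debris_spec <- function(center_xy, radius, intensity = 180) {
  stopifnot(length(center_xy) == 2, is.finite(center_xy), radius > 0,
            intensity >= 0, intensity <= 255)
  structure(list(center_xy = as.numeric(center_xy), radius = radius,
                 intensity = intensity),
            class = "debris_spec")
}

#' Describe a synthetic scene
#'
#' Defaults mirror the canonical acquisition geometry: 1280 x 960 px,
#' 30 frames at 30 fps (one second of video), 94.2 nm pixel pitch.
#'
#' @param width_px,height_px image size in pixels (>= 1).
#' @param n_frames number of frames (>= 1).
#' @param fps frame rate, frames per second.
#' @param pixel_size_nm physical pixel edge length in nanometres.
#' @param background_level constant background intensity, 0-255.
#' @param noise_sd standard deviation of i.i.d. Gaussian pixel noise
#'   added to every frame (>= 0; 0 disables noise).
#' @param bacteria list of [bacterium_spec()] objects.
#' @param debris list of [debris_spec()] objects.
#' @param rng_seed integer seed; rendering is fully deterministic given
#'   the spec.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(width_px = 1280, height_px = 960, n_frames = 30,
                       fps = 30, pixel_size_nm = 94.2,
                       background_level = 20, noise_sd = 0,
                       bacteria = list(), debris = list(),
                       rng_seed = 1L) {
  stopifnot(width_px >= 1, height_px >= 1, n_frames >= 1, fps > 0,
            pixel_size_nm > 0,
            background_level >= 0, background_level <= 255,
            noise_sd >= 0)
  stopifnot(all(vapply(bacteria, inherits, TRUE, "bacterium_spec")),
            all(vapply(debris, inherits, TRUE, "debris_spec")))
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 n_frames = as.integer(n_frames), fps = fps,
                 pixel_size_nm = pixel_size_nm,
                 background_level = background_level,
                 noise_sd = noise_sd,
                 bacteria = bacteria, debris = debris,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_spec")
}

# Add an anti-aliased filled ellipse to an intensity matrix (in place
# value, returned). Coverage per pixel estimated on a 4x4 subpixel grid;
# the ellipse blends above the background and overlapping bodies take
# the pointwise maximum so they never overshoot their peak intensity.
render_ellipse <- function(img, cx, cy, a, b, theta_deg, intensity, bg) {
  h <- nrow(img); w <- ncol(img)
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  r <- a + 1
  x0 <- max(0, floor(cx - r)); x1 <- min(w - 1, ceiling(cx + r))
  y0 <- max(0, floor(cy - r)); y1 <- min(h - 1, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  off <- ((1:4) - 0.5) / 4 - 0.5
  cov <- matrix(0, length(ys), length(xs))
  for (oy in off) {
    dy <- ys + oy - cy
    for (ox in off) {
      dx <- xs + ox - cx
      u <- (outer(dy, dx, function(Y, X) X * ct + Y * st)) / a
      v <- (outer(dy, dx, function(Y, X) -X * st + Y * ct)) / b
      cov <- cov + (u * u + v * v <= 1)
    }
  }
  cov <- cov / 16
  sub <- img[ys + 1, xs + 1, drop = FALSE]
  img[ys + 1, xs + 1] <- pmax(sub, bg + cov * (intensity - bg))
  img
}

#' Render a synthetic frame series with ground truth
#'
#' Advances every bacterium by `speed / fps` micrometres per step with
#' Gaussian heading perturbation, rasterizes bodies as anti-aliased
#' ellipses over a constant background, renders debris identically in
#' every frame, then adds Gaussian noise (if `noise_sd > 0`) and
#' quantizes to 8 bits. The RNG is seeded from `spec$rng_seed`, so the
#' same spec always yields bit-identical frames.
#'
#' @param spec a [scene_spec()].
#' @return A list with components:
#'   \describe{
#'     \item{frames}{a [frame_stack()] of 8-bit integer matrices.}
#'     \item{truth}{a data frame with one row per bacterium per frame
#'       while its centroid lies inside the image: `frame`,
#'       `bacterium_id`, `x_px`, `y_px`, `speed_um_s`. The speed is the
#'       true per-step speed, which for this motion model equals the
#'       spec speed of the cell. Once a centroid leaves the image the
#'       bacterium stops producing rows (its exit frame is the last
#'       row + 1).}
#'   }
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  w <- spec$width_px; h <- spec$height_px
  px_um <- spec$pixel_size_nm / 1000
  for (b in spec$bacteria) {
    if (b$start_xy[1] < 0 || b$start_xy[1] >= w ||
        b$start_xy[2] < 0 || b$start_xy[2] >= h)
      stop("bacterium starts outside the image area")
  }
  set.seed(spec$rng_seed)

  nb <- length(spec$bacteria)
  # pre-compute trajectories so truth and rendering share positions
  pos <- vector("list", nb)
  for (i in seq_len(nb)) {
    b <- spec$bacteria[[i]]
    step_px <- b$speed / spec$fps / px_um
    xy <- matrix(NA_real_, spec$n_frames, 2)
    hd <- numeric(spec$n_frames)
    xy[1, ] <- b$start_xy; hd[1] <- b$heading
    for (t in seq_len(spec$n_frames - 1)) {
      turn <- if (b$heading_sd_per_step > 0)
        stats::rnorm(1, 0, b$heading_sd_per_step) else 0
      hd[t + 1] <- hd[t] + turn
      th <- hd[t + 1] * pi / 180
      xy[t + 1, ] <- xy[t, ] + step_px * c(cos(th), sin(th))
    }
    pos[[i]] <- list(xy = xy, hd = hd)
  }

  frames <- vector("list", spec$n_frames)
  for (t in seq_len(spec$n_frames)) {
    img <- matrix(spec$background_level, h, w)
    for (d in spec$debris) {
      r_px <- d$radius / px_um
      img <- render_ellipse(img, d$center_xy[1], d$center_xy[2],
                            r_px, r_px, 0, d$intensity,
                            spec$background_level)
    }
    for (i in seq_len(nb)) {
      b <- spec$bacteria[[i]]
      img <- render_ellipse(img,
                            pos[[i]]$xy[t, 1], pos[[i]]$xy[t, 2],
                            b$length / 2 / px_um, b$width / 2 / px_um,
                            pos[[i]]$hd[t], b$intensity,
                            spec$background_level)
    }
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    frames[[t]] <- round(pmin(pmax(img, 0), 255))
    storage.mode(frames[[t]]) <- "integer"
  }

  truth <- do.call(rbind, lapply(seq_len(nb), function(i) {
    xy <- pos[[i]]$xy
    inside <- xy[, 1] >= 0 & xy[, 1] < w & xy[, 2] >= 0 & xy[, 2] < h
    # rows stop at the first exit even if the walk would re-enter
    last <- if (all(inside)) spec$n_frames else which(!inside)[1] - 1
    if (last < 1) return(NULL)
    data.frame(frame = seq_len(last), bacterium_id = i,
               x_px = xy[seq_len(last), 1], y_px = xy[seq_len(last), 2],
               speed_um_s = spec$bacteria[[i]]$speed)
  }))
  if (is.null(truth))
    truth <- data.frame(frame = integer(), bacterium_id = integer(),
                        x_px = numeric(), y_px = numeric(),
                        speed_um_s = numeric())

  list(frames = frame_stack(frames, fps = spec$fps,
                            pixel_size_nm = spec$pixel_size_nm),
       truth = truth)
}

#' Draw a randomized scene specification
#'
#' Convenience generator for validation studies: `n_bacteria` cells with
#' speeds drawn uniformly from `speed_range`, uniform random headings,
#' and start positions chosen so that the straight-line path over the
#' whole series stays `margin` pixels inside the image (curved paths can
#' still clip the margin, not the frame, for moderate
#' `heading_sd_per_step`). The default count sits in the 5-10 band that
#' gives the tracker its best operating regime.
#'
#' @param n_bacteria number of cells.
#' @param speed_range length-2 numeric, um/s.
#' @param width_px,height_px,n_frames,fps,pixel_size_nm,background_level,noise_sd
#'   passed to [scene_spec()].
#' @param heading_sd_per_step degrees, per-step turn SD for every cell.
#' @param margin minimum straight-path distance from the border, px.
#' @param seed integer seed (also becomes the scene's `rng_seed`).
#' @return A `scene_spec`.
#' @export
random_scene_spec <- function(n_bacteria = 5, speed_range = c(40, 60),
                              width_px = 1024, height_px = 768,
                              n_frames = 30, fps = 30,
                              pixel_size_nm = 94.2,
                              background_level = 20, noise_sd = 0,
                              heading_sd_per_step = 5, margin = 60,
                              seed = 1L) {
  set.seed(seed)
  px_um <- pixel_size_nm / 1000
  bacteria <- vector("list", n_bacteria)
  for (i in seq_len(n_bacteria)) {
    repeat {
      speed <- stats::runif(1, speed_range[1], speed_range[2])
      heading <- stats::runif(1, 0, 360)
      travel <- speed * (n_frames - 1) / fps / px_um
      dir <- c(cos(heading * pi / 180), sin(heading * pi / 180))
      mid <- c(stats::runif(1, margin, width_px - margin),
               stats::runif(1, margin, height_px - margin))
      p0 <- mid - dir * travel / 2
      p1 <- mid + dir * travel / 2
      ok <- all(c(p0, p1) >= margin) &&
        p0[1] <= width_px - margin && p1[1] <= width_px - margin &&
        p0[2] <= height_px - margin && p1[2] <= height_px - margin
      if (ok) break
    }
    bacteria[[i]] <- bacterium_spec(p0, speed, heading,
                                    heading_sd_per_step =
                                      heading_sd_per_step,
                                    length = stats::runif(1, 2.0, 3.0),
                                    width = stats::runif(1, 0.7, 0.9),
                                    intensity = 200)
  }
  scene_spec(width_px = width_px, height_px = height_px,
             n_frames = n_frames, fps = fps,
             pixel_size_nm = pixel_size_nm,
             background_level = background_level, noise_sd = noise_sd,
             bacteria = bacteria, rng_seed = seed)
}

#' Write a frame stack as a PNG series
#'
#' One 8-bit grayscale PNG per frame with zero-padded, lexically
#' sortable names (`frame_0001.png`, ...). The round trip through
#' [read_series()] is lossless.
#'
#' @param stack a [frame_stack()].
#' @param directory output directory, created if missing.
#' @return Invisibly, the vector of files written.
#' @export
write_series <- function(stack, directory) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory)
  n <- length(stack$frames)
  files <- file.path(directory,
                     sprintf("frame_%04d.png", seq_len(n)))
  for (i in seq_len(n))
    png::writePNG(stack$frames[[i]] / 255, files[i])
  invisible(files)
}

#' Write ground-truth tracks as CSV
#'
#' @param truth the `truth` data frame from [render_scene()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
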