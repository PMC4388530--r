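# Particle detection and feature measurement on sum-difference images.

#' Detect bright connected components
#'
#' Thresholds a normalized sum-difference image and extracts
#' 8-connected components (diagonal-touching pixels belong to the same
#' cell body). Components smaller than `min_area` are discarded as
#' speckle; components touching the image border are retained and
#' flagged, since cells entering or leaving the field of view are still
#' trackable.
#'
#' Labelling uses `EBImage::bwlabel()` (4-connected) followed by a
#' union-find merge across diagonal neighbours to obtain 8-connectivity.
#'
#' @param B a normalized [sum_diff_image].
#' @param threshold intensity cut in (0, 255); pixels `>= threshold` are
#'   foreground. `NULL` (default) selects the threshold by Otsu's
#'   method on the image histogram.
#' @param min_area minimum component area in px^2. The default 14 is
#'   the area of a disc of diameter 0.4 um at 94.2 nm/px — the optical
#'   detection limit of the canonical setup.
#' @return A list of components, each a list with `pixels` (2-column
#'   matrix of 1-based row/col indices) and `touches_border` (logical).
#'   An image with no foreground yields an empty list.
#' @export
detect_particles <- function(B, threshold = NULL, min_area = 14) {
  stopifnot(inherits(B, "sum_diff_image"))
  if (!B$normalized) stop("detect_particles expects a normalized image")
  v <- B$values
  if (max(v) == 0) return(list())
  if (is.null(threshold)) threshold <- otsu_threshold(v)
  stopifnot(threshold > 0, threshold < 255)
  mask <- v >= threshold
  if (!any(mask)) return(list())

  lab <- EBImage::bwlabel(mask * 1L)
  lab <- merge_diagonal_labels(lab)

  idx <- which(lab > 0)
  h <- nrow(v)
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  groups <- split(seq_along(idx), lab[idx])
  comps <- lapply(groups, function(g) {
    r <- rows[g]; c <- cols[g]
    list(pixels = cbind(row = r, col = c),
         touches_border = any(r == 1L | r == h | c == 1L |
                                c == ncol(v)))
  })
  comps <- comps[vapply(comps, function(cp) nrow(cp$pixels), 0L) >=
                   min_area]
  unname(comps)
}

# Otsu's threshold on an 8-bit image, returned on the 0-255 scale.
otsu_threshold <- function(v) {
  th <- EBImage::otsu(EBImage::Image(t(v) / 255),
                      range = c(0, 1), levels = 256) * 255
  min(max(th, 1), 254)
}

# Merge 4-connected labels that touch diagonally (union-find).
merge_diagonal_labels <- function(lab) {
  nl <- max(lab)
  if (nl < 2) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w, drop = FALSE]; b1 <- lab[-1, -1, drop = FALSE]
  a2 <- lab[-1, -w, drop = FALSE]; b2 <- lab[-h, -1, drop = FALSE]
  pr <- rbind(cbind(as.vector(a1), as.vector(b1)),
              cbind(as.vector(a2), as.vector(b2)))
  pr <- pr[pr[, 1] > 0 & pr[, 2] > 0 & pr[, 1] != pr[, 2], ,
           drop = FALSE]
  if (nrow(pr) == 0) return(lab)
  parent <- seq_len(nl)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pr))) {
    ra <- find(pr[k, 1]); rb <- find(pr[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nl), find, 1L)
  lab[lab > 0] <- root[lab[lab > 0]]
  lab
}

#' Measure the seven particle characteristics of one component
#'
#' Computes, from the pixel membership alone: area (pixel count),
#' centre of mass (unweighted centroid of pixel centres, 0-based pixel
#' coordinates), orientation (angle of the principal axis from the
#' second central moments, degrees in `[-90, 90)` measured from +x
#' towards +y), length and width (full extents of the pixel centres
#' projected on the major/minor principal axes, plus one pixel), and
#' perimeter (crack-boundary length: the count of exposed pixel edges).
#'
#' @param component one element of the list returned by
#'   [detect_particles()].
#' @param frame_index 1-based frame the component was detected in.
#' @return A one-row data frame: `frame`, `cm_x`, `cm_y`, `perimeter`,
#'   `area`, `orientation`, `length`, `width`, `touches_border`.
#' @export
measure_features <- function(component, frame_index) {
  px <- component$pixels
  if (is.null(px) || nrow(px) == 0) stop("empty component mask")
  x <- px[, "col"] - 1; y <- px[, "row"] - 1
  n <- nrow(px)
  cmx <- mean(x); cmy <- mean(y)
  dx <- x - cmx; dy <- y - cmy
  mu20 <- mean(dx * dx); mu02 <- mean(dy * dy); mu11 <- mean(dx * dy)
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  if (theta >= 90) theta <- theta - 180
  th <- theta * pi / 180
  p1 <- dx * cos(th) + dy * sin(th)
  p2 <- -dx * sin(th) + dy * cos(th)
  len <- diff(range(p1)) + 1
  wid <- diff(range(p2)) + 1
  if (len < wid) {  # ensure length is the larger extent
    tmp <- len; len <- wid; wid <- tmp
    theta <- if (theta >= 0) theta - 90 else theta + 90
  }
  # crack perimeter: 4*area minus twice the number of 4-adjacent pairs
  r0 <- min(px[, "row"]); c0 <- min(px[, "col"])
  m <- matrix(FALSE, max(px[, "row"]) - r0 + 1, max(px[, "col"]) - c0 + 1)
  m[cbind(px[, "row"] - r0 + 1, px[, "col"] - c0 + 1)] <- TRUE
  adj <- 0
  if (nrow(m) > 1) adj <- adj + sum(m[-1, , drop = FALSE] &
                                      m[-nrow(m), , drop = FALSE])
  if (ncol(m) > 1) adj <- adj + sum(m[, -1, drop = FALSE] &
                                      m[, -ncol(m), drop = FALSE])
  perim <- 4 * n - 2 * adj
  data.frame(frame = frame_index, cm_x = cmx, cm_y = cmy,
             perimeter = perim, area = n, orientation = theta,
             length = len, width = wid,
             touches_border = isTRUE(component$touches_border))
}

#' Build a particle table from normalized sum-difference images
#'
#' Runs [detect_particles()] and [measure_features()] on every image
#' and collects the records into one table, sorted by
#' `(frame, cm_y, cm_x)` for reproducibility.
#'
#' @param diffs list of normalized [sum_diff_image] objects (as from
#'   [sum_difference_stack()]).
#' @param threshold,min_area passed to [detect_particles()].
#' @return A `particle_table` data frame (possibly zero rows) with the
#'   columns of [measure_features()].
#' @export
analyze_frames <- function(diffs, threshold = NULL, min_area = 14) {
  recs <- lapply(diffs, function(B) {
    comps <- detect_particles(B, threshold = threshold,
                              min_area = min_area)
    if (length(comps) == 0) return(NULL)
    do.call(rbind, lapply(comps, measure_features,
                          frame_index = B$source_index))
  })
  tab <- do.call(rbind, recs)
  if (is.null(tab))
    tab <- data.frame(frame = integer(), cm_x = numeric(),
                      cm_y = numeric(), perimeter = numeric(),
                      area = numeric(), orientation = numeric(),
                      length = numeric(), width = numeric(),
                      touches_border = logical())
  tab <- tab[order(tab$frame, tab$cm_y, tab$cm_x), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("particle_table", "data.frame")
  tab
}
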