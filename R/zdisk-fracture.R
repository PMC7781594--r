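# Z-disk disorder ("fracture area") metric.
#
# Pipeline: segment dark transverse Z-disk ridges from a calibrated
# electron micrograph, fit each ridge path with an orthogonal
# (total-least-squares) line, and average the per-segment mean squared
# orthogonal residuals weighted by each segment's angular deviation from
# the common Z-disk orientation. Output is in nm^2; larger values mean
# more Z-disk disorder.

#' Segment Z-disk ridge paths from an electron micrograph
#'
#' Isolates dark, thin, near-vertical (transverse) ridges: the image is
#' inverted and Gaussian-smoothed, a ridge response is computed as the
#' magnitude of the most negative Hessian eigenvalue, the response is
#' thresholded at a quantile, thinned to one ridge point per image row,
#' and points are linked across rows into connected paths. Paths shorter
#' than `min_length_nm` or oriented outside `orientation_gate_deg` of
#' the dominant transverse direction are discarded.
#'
#' @param img a calibrated [micrograph].
#' @param sigma_px Gaussian smoothing scale, px.
#' @param threshold_quantile ridge-response threshold quantile in (0, 1).
#' @param min_length_nm minimum path extent, nm.
#' @param orientation_gate_deg keep segments within this axial angle of
#'   the dominant transverse orientation.
#' @param max_gap_px maximum row-to-row column jump when linking ridge
#'   points into a path.
#' @param side_offset_nm flank sampling distance for the ridge-vs-edge
#'   test: a Z-disk line must be darker than both flanks at this offset
#'   (A-band edges are darker on one side only and are rejected).
#' @return list of `zdisk_segment` objects (coordinates only; see
#'   [fit_segment_line()]), possibly empty (with a warning) when no
#'   ridge passes the filters.
#' @export
segment_zdisks <- function(img, sigma_px = 2, threshold_quantile = 0.90,
                           min_length_nm = 500, orientation_gate_deg = 30,
                           max_gap_px = 3, side_offset_nm = 120) {
  stopifnot(inherits(img, "micrograph"))
  px <- img$pixels
  inv <- max(px) - px
  sm <- blur_gaussian(inv, sigma_px)

  # Hessian via central differences; ridge strength = -min eigenvalue
  nr <- nrow(sm); nc <- ncol(sm)
  if (nr < 5 || nc < 5) stop("image too small to segment")
  dxx <- sm * 0; dyy <- sm * 0; dxy <- sm * 0
  dyy[2:(nr - 1), ] <- sm[3:nr, ] - 2 * sm[2:(nr - 1), ] + sm[1:(nr - 2), ]
  dxx[, 2:(nc - 1)] <- sm[, 3:nc] - 2 * sm[, 2:(nc - 1)] + sm[, 1:(nc - 2)]
  dxy[2:(nr - 1), 2:(nc - 1)] <-
    (sm[3:nr, 3:nc] - sm[3:nr, 1:(nc - 2)] -
     sm[1:(nr - 2), 3:nc] + sm[1:(nr - 2), 1:(nc - 2)]) / 4
  tr <- dxx + dyy
  det_ <- dxx * dyy - dxy^2
  disc <- sqrt(pmax((tr / 2)^2 - det_, 0))
  lmin <- tr / 2 - disc
  ridge <- pmax(-lmin, 0)  # first arg keeps the matrix dims

  pos <- ridge[ridge > 0]
  if (length(pos) == 0) {
    warning("no ridge response in image; returning empty segment list")
    return(list())
  }
  thr <- stats::quantile(pos, threshold_quantile)
  mask <- ridge >= thr

  # thin: one ridge point per row per ridge (column-wise local maxima of
  # the response within the mask); near-vertical ridges cross every row
  pts <- which(local_maxima_rowwise(ridge, mask), arr.ind = TRUE)
  if (nrow(pts) == 0) {
    warning("no ridge points after thinning; returning empty segment list")
    return(list())
  }

  # per-point ridge-vs-edge test: a Z-disk line is darker (higher on the
  # inverted image) than BOTH flanks; an intensity step (A-band edge,
  # frame boundary) is darker on one side only and is rejected here,
  # before linking, so edge points cannot be chained into a path
  nmpp <- img$nm_per_px
  off <- max(2L, round(side_offset_nm / nmpp))
  margin <- 0.02 * diff(range(sm))
  jl <- pmax(1L, pts[, 2] - off)
  jr <- pmin(nc, pts[, 2] + off)
  on_v <- sm[pts]
  keep <- on_v > sm[cbind(pts[, 1], jl)] + margin &
          on_v > sm[cbind(pts[, 1], jr)] + margin
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) == 0) {
    warning("no point passes the ridge-vs-edge test; returning empty segment list")
    return(list())
  }

  # link points across adjacent rows into paths
  paths <- link_ridge_points(pts, max_gap_px = max_gap_px)
  paths <- paths[vapply(paths, nrow, integer(1)) >= 5L]
  if (length(paths) == 0) {
    warning("no linked ridge path long enough; returning empty segment list")
    return(list())
  }

  segs <- lapply(paths, function(p) {
    coords_px <- cbind(x = as.numeric(p[, 2]), y = as.numeric(p[, 1]))
    coords_px <- refine_normal_subpixel(coords_px, sm)
    coords <- cbind(x_nm = (coords_px[, 1] - 0.5) * nmpp,
                    y_nm = (coords_px[, 2] - 0.5) * nmpp)
    zdisk_segment(coords)
  })

  # length gate
  lens <- vapply(segs, segment_extent_nm, numeric(1))
  segs <- segs[lens >= min_length_nm]
  if (length(segs) == 0) {
    warning("no segment passes the length gate; returning empty segment list")
    return(list())
  }
  # orientation gate against the dominant (length-weighted) axial angle
  angs <- vapply(segs, function(s) tls_angle_deg(s$coords_nm), numeric(1))
  lens <- vapply(segs, segment_extent_nm, numeric(1))
  dom <- axial_mean_deg(angs, lens)
  dev <- abs(axial_diff_deg(angs, dom))
  segs <- segs[dev <= orientation_gate_deg]
  if (length(segs) == 0)
    warning("no segment passes the orientation gate; returning empty segment list")
  segs
}

# Sub-pixel ridge localization: for each path point, sample the smoothed
# inverted intensity along the local normal (from the path's TLS
# direction) and take the vertex of a least-squares parabola. This is
# orientation-correct, so tilted (e.g. rotated) ridges are localized
# without bias. coords_px: columns x (col), y (row), in pixel units.
refine_normal_subpixel <- function(coords_px, sm, half_window = 3L) {
  d <- tls_direction(coords_px)            # unit tangent (x, y)
  nrm <- c(-d[2], d[1])                    # unit normal
  ts <- seq(-half_window, half_window)
  nr <- nrow(sm); nc <- ncol(sm)
  out <- coords_px
  X <- cbind(1, ts, ts^2)
  XtXi <- solve(crossprod(X))
  for (i in seq_len(nrow(coords_px))) {
    xs <- coords_px[i, 1] + ts * nrm[1]
    ys <- coords_px[i, 2] + ts * nrm[2]
    if (any(xs < 1) || any(xs > nc) || any(ys < 1) || any(ys > nr)) next
    v <- bilinear_sample(sm, xs, ys)
    beta <- XtXi %*% crossprod(X, v)
    if (beta[3] >= 0) next                 # not a peak
    tstar <- -beta[2] / (2 * beta[3])
    tstar <- min(max(tstar, -half_window), half_window)
    out[i, 1] <- coords_px[i, 1] + tstar * nrm[1]
    out[i, 2] <- coords_px[i, 2] + tstar * nrm[2]
  }
  out
}

bilinear_sample <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  j0 <- pmin(pmax(floor(x), 1L), nc - 1L)
  i0 <- pmin(pmax(floor(y), 1L), nr - 1L)
  fx <- x - j0; fy <- y - i0
  id <- function(i, j) (j - 1L) * nr + i
  (1 - fy) * ((1 - fx) * m[id(i0, j0)] + fx * m[id(i0, j0 + 1L)]) +
    fy * ((1 - fx) * m[id(i0 + 1L, j0)] + fx * m[id(i0 + 1L, j0 + 1L)])
}

# Row-wise local maxima: within each row, TRUE where masked response is a
# strict local maximum along the row (plateaus keep their first column).
local_maxima_rowwise <- function(mat, mask) {
  nc <- ncol(mat)
  left <- cbind(-Inf, mat[, -nc, drop = FALSE])
  right <- cbind(mat[, -1, drop = FALSE], -Inf)
  out <- mask & mat > left & mat >= right
  out
}

# Greedy row-by-row linking of (row, col) ridge points into paths.
link_ridge_points <- function(pts, max_gap_px = 3) {
  ord <- order(pts[, 1], pts[, 2])
  pts <- pts[ord, , drop = FALSE]
  rows <- pts[, 1]
  paths <- list()          # list of integer vectors of point indices
  open_tail <- integer(0)  # index of last point of each open path
  open_id <- integer(0)
  path_pts <- list()
  urows <- unique(rows)
  for (r in urows) {
    idx <- which(rows == r)
    cols <- pts[idx, 2]
    used_open <- rep(FALSE, length(open_tail))
    assigned <- rep(0L, length(idx))
    if (length(open_tail)) {
      tail_rows <- pts[open_tail, 1]
      tail_cols <- pts[open_tail, 2]
      alive <- (r - tail_rows) <= max_gap_px
      for (k in seq_along(idx)) {
        cand <- which(alive & !used_open &
                      abs(tail_cols - cols[k]) <= max_gap_px)
        if (length(cand)) {
          j <- cand[which.min(abs(tail_cols[cand] - cols[k]))]
          assigned[k] <- j
          used_open[j] <- TRUE
        }
      }
    }
    for (k in seq_along(idx)) {
      if (assigned[k] > 0L) {
        pid <- open_id[assigned[k]]
        path_pts[[pid]] <- c(path_pts[[pid]], idx[k])
        open_tail[assigned[k]] <- idx[k]
      } else {
        path_pts[[length(path_pts) + 1L]] <- idx[k]
        open_tail <- c(open_tail, idx[k])
        open_id <- c(open_id, length(path_pts))
      }
    }
    # drop dead paths from the open set
    alive <- (r - pts[open_tail, 1]) <= max_gap_px
    open_tail <- open_tail[alive]
    open_id <- open_id[alive]
  }
  lapply(path_pts, function(ii) pts[ii, , drop = FALSE])
}

#' Construct a Z-disk segment
#'
#' @param coords_nm two-column matrix of (x, y) coordinates in nm.
#' @return object of class `zdisk_segment` (line unfitted).
#' @export
zdisk_segment <- function(coords_nm) {
  coords_nm <- as.matrix(coords_nm)
  if (nrow(coords_nm) < 2) stop("a segment needs at least 2 coordinates")
  structure(list(coords_nm = coords_nm, line = NULL, angle_deg = NA_real_,
                 residuals_nm = NULL, length_nm = NA_real_),
            class = "zdisk_segment")
}

# Axial TLS angle of a coordinate set, degrees from image vertical,
# in (-90, 90].
tls_angle_deg <- function(coords) {
  d <- tls_direction(coords)
  a <- atan2(d[1], d[2]) * 180 / pi   # x over y: 0 deg = vertical
  wrap_axial_deg(a)
}

tls_direction <- function(coords) {
  cc <- sweep(coords, 2, colMeans(coords))
  sv <- svd(cc, nu = 0, nv = 2)
  sv$v[, 1]
}

wrap_axial_deg <- function(a) {
  a <- (a + 90) %% 180 - 90
  ifelse(a == -90, 90, a)
}

# Length-weighted axial circular mean (period 180 deg).
axial_mean_deg <- function(angles_deg, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(angles_deg))
  th2 <- angles_deg * pi / 90  # doubled angle in radians
  m <- atan2(sum(weights * sin(th2)), sum(weights * cos(th2))) / 2 * 180 / pi
  wrap_axial_deg(m)
}

# Axial angular difference wrapped into [-90, 90).
axial_diff_deg <- function(a, b) {
  d <- (a - b + 90) %% 180 - 90
  d
}

segment_extent_nm <- function(seg) {
  coords <- seg$coords_nm
  d <- tls_direction(coords)
  proj <- as.vector(sweep(coords, 2, colMeans(coords)) %*% d)
  diff(range(proj))
}

#' Fit the orthogonal-regression line of a Z-disk segment
#'
#' Total-least-squares fit: the first principal direction of the
#' coordinate scatter through the centroid. Residuals are signed
#' orthogonal distances to the line; the angle is axial (period 180
#' degrees) relative to the image vertical.
#'
#' @param seg a `zdisk_segment`.
#' @return the segment with `line`, `angle_deg`, `residuals_nm` and
#'   `length_nm` filled.
#' @export
fit_segment_line <- function(seg) {
  stopifnot(inherits(seg, "zdisk_segment"))
  coords <- seg$coords_nm
  if (nrow(unique(coords)) < 2) stop("degenerate fit: all coordinates identical")
  centroid <- colMeans(coords)
  d <- tls_direction(coords)
  normal <- c(-d[2], d[1])
  centered <- sweep(coords, 2, centroid)
  res <- as.vector(centered %*% normal)
  proj <- as.vector(centered %*% d)
  seg$line <- list(direction = d, centroid = centroid)
  seg$angle_deg <- tls_angle_deg(coords)
  seg$residuals_nm <- res
  seg$length_nm <- diff(range(proj))
  seg
}

#' Fracture area of a set of fitted Z-disk segments
#'
#' The per-segment mean squared orthogonal residual is weighted by that
#' segment's axial angular deviation from the length-weighted mean
#' Z-disk orientation, `w_i = 1 + |dtheta_i| / theta_ref`, and the
#' weighted contributions are averaged with length weights:
#' `FA = sum(L_i * MSR_i * w_i) / sum(L_i)` (nm^2). Straight, mutually
#' parallel Z-disks score 0; waviness and angular scatter both increase
#' the score.
#'
#' @param segments list of fitted `zdisk_segment`s (see
#'   [fit_segment_line()]).
#' @param theta_ref angular scale of the weight, degrees.
#' @return object of class `fracture_result`: `fracture_area_nm2`,
#'   `reference_angle_deg`, `per_segment` data.frame, `n_segments`.
#' @export
fracture_area <- function(segments, theta_ref = 45) {
  if (length(segments) == 0) stop("no Z-disks to score")
  fitted <- vapply(segments, function(s)
    inherits(s, "zdisk_segment") && !is.null(s$residuals_nm), logical(1))
  if (!all(fitted)) stop("all segments must be fitted (see fit_segment_line)")
  if (theta_ref <= 0) stop("theta_ref must be > 0")
  ang <- vapply(segments, function(s) s$angle_deg, numeric(1))
  len <- vapply(segments, function(s) s$length_nm, numeric(1))
  msr <- vapply(segments, function(s) mean(s$residuals_nm^2), numeric(1))
  ref <- axial_mean_deg(ang, len)
  dth <- axial_diff_deg(ang, ref)
  w <- 1 + abs(dth) / theta_ref
  contrib <- msr * w
  fa <- sum(len * contrib) / sum(len)
  structure(list(
    fracture_area_nm2 = fa,
    reference_angle_deg = ref,
    per_segment = data.frame(segment = seq_along(segments),
                             msr_nm2 = msr, dtheta_deg = dth,
                             weight = w, contribution_nm2 = contrib,
                             length_nm = len),
    n_segments = length(segments)
  ), class = "fracture_result")
}

#' @export
print.fracture_result <- function(x, ...) {
  cat(sprintf("<fracture_result: %.3g nm^2 over %d segments, ref angle %.2f deg>\n",
              x$fracture_area_nm2, x$n_segments, x$reference_angle_deg))
  invisible(x)
}

#' Score an electron micrograph for Z-disk disorder
#'
#' Composition of [segment_zdisks()], [fit_segment_line()] and
#' [fracture_area()], with an optional exclusion list for semi-automatic
#' curation.
#'
#' @param img a calibrated [micrograph].
#' @param theta_ref angular weight scale, degrees.
#' @param exclude integer ids of segments to drop before scoring.
#' @param ... passed to [segment_zdisks()].
#' @return a `fracture_result`; its `excluded` attribute records the
#'   curated-out segment ids.
#' @export
score_image <- function(img, theta_ref = 45, exclude = NULL, ...) {
  segs <- segment_zdisks(img, ...)
  if (length(segs) == 0) stop("no Z-disks to score")
  if (!is.null(exclude)) {
    keep <- setdiff(seq_along(segs), exclude)
    if (length(keep) == 0) stop("no Z-disks to score after exclusion")
    segs <- segs[keep]
  }
  segs <- lapply(segs, fit_segment_line)
  res <- fracture_area(segs, theta_ref = theta_ref)
  attr(res, "excluded") <- exclude
  res
}
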