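# Minimal raster toolbox used by the segmentation and detection code.
# No image-processing package is assumed; everything operates on plain
# numeric matrices indexed [row, col] with row 1 at the top.

#' Gaussian blur of a matrix
#'
#' Separable Gaussian convolution with edge replication. Kernel is
#' truncated at 3 sigma.
#'
#' @param mat numeric matrix.
#' @param sigma standard deviation in pixels; `sigma <= 0` returns the
#'   input unchanged.
#' @return blurred matrix, same dimensions.
#' @keywords internal
blur_gaussian <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  mat <- conv_rows(mat, k)
  t(conv_rows(t(mat), k))
}

# 1-D convolution of every row with kernel k, replicate padding.
conv_rows <- function(mat, k) {
  r <- (length(k) - 1L) / 2L
  nc <- ncol(mat)
  pad <- cbind(mat[, rep(1L, r), drop = FALSE], mat,
               mat[, rep(nc, r), drop = FALSE])
  out <- matrix(0, nrow(mat), nc)
  for (j in seq_along(k)) {
    out <- out + k[j] * pad[, j:(j + nc - 1L), drop = FALSE]
  }
  out
}

#' Connected-component labeling of a logical mask
#'
#' Two-pass run-length labeling with union-find; 8-connectivity.
#'
#' @param mask logical matrix.
#' @return integer matrix of the same shape; 0 = background, components
#'   numbered from 1 in arbitrary order.
#' @keywords internal
label_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  prev_runs <- NULL  # matrix: start col, end col, label
  next_lab <- 0L
  for (i in seq_len(nr)) {
    row <- mask[i, ]
    if (!any(row)) { prev_runs <- NULL; next }
    d <- diff(c(FALSE, row, FALSE))
    starts <- which(d == 1L); ends <- which(d == -1L) - 1L
    cur <- matrix(0L, length(starts), 3L)
    for (ri in seq_along(starts)) {
      s <- starts[ri]; e <- ends[ri]
      l <- 0L
      if (!is.null(prev_runs)) {
        # 8-connectivity: previous-row run overlapping [s-1, e+1]
        hit <- prev_runs[, 1L] <= e + 1L & prev_runs[, 2L] >= s - 1L
        for (pi in which(hit)) {
          pl <- find(prev_runs[pi, 3L])
          if (l == 0L) l <- pl else if (pl != l) parent[pl] <- find(l)
        }
      }
      if (l == 0L) {
        next_lab <- next_lab + 1L
        parent[next_lab] <- next_lab
        l <- next_lab
      }
      lab[i, s:e] <- l
      cur[ri, ] <- c(s, e, l)
    }
    prev_runs <- cur
  }
  if (next_lab == 0L) return(lab)
  roots <- vapply(seq_len(next_lab), find, integer(1))
  remap <- match(roots, unique(roots))
  idx <- lab > 0L
  lab[idx] <- remap[lab[idx]]
  lab
}

#' Rotate a micrograph with bilinear resampling
#'
#' Rotates around the image centre onto a canvas large enough to hold
#' the whole rotated frame; uncovered pixels are filled with the median
#' intensity. Used mainly for rotation-invariance checks of image
#' metrics.
#'
#' @param img a [micrograph].
#' @param angle_deg rotation angle, degrees (counter-clockwise).
#' @return a rotated [micrograph] with the same calibration.
#' @export
rotate_micrograph <- function(img, angle_deg) {
  src <- img$pixels
  nr <- nrow(src); nc <- ncol(src)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  # output canvas bounding the rotated frame
  w2 <- abs(nc * ct) + abs(nr * st)
  h2 <- abs(nc * st) + abs(nr * ct)
  nr2 <- ceiling(h2); nc2 <- ceiling(w2)
  fill <- stats::median(src)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  cy2 <- (nr2 + 1) / 2; cx2 <- (nc2 + 1) / 2
  ii <- matrix(seq_len(nr2), nr2, nc2)
  jj <- matrix(seq_len(nc2), nr2, nc2, byrow = TRUE)
  # inverse map: output pixel -> source coordinates
  xs <- ct * (jj - cx2) + st * (ii - cy2) + cx
  ys <- -st * (jj - cx2) + ct * (ii - cy2) + cy
  j0 <- floor(xs); i0 <- floor(ys)
  fx <- xs - j0; fy <- ys - i0
  out <- matrix(fill, nr2, nc2)
  ok <- j0 >= 1 & j0 <= nc - 1 & i0 >= 1 & i0 <= nr - 1
  id <- function(i, j) (j - 1L) * nr + i
  v00 <- src[id(i0[ok], j0[ok])]
  v01 <- src[id(i0[ok], j0[ok] + 1L)]
  v10 <- src[id(i0[ok] + 1L, j0[ok])]
  v11 <- src[id(i0[ok] + 1L, j0[ok] + 1L)]
  out[ok] <- (1 - fy[ok]) * ((1 - fx[ok]) * v00 + fx[ok] * v01) +
             fy[ok] * ((1 - fx[ok]) * v10 + fx[ok] * v11)
  micrograph(pmax(out, 0), img$nm_per_px, img$modality)
}

# Local maxima of mat restricted to mask: pixel >= all 8 neighbours and
# strictly greater than at least one. Returns logical matrix.
local_maxima <- function(mat, mask = NULL) {
  nr <- nrow(mat); nc <- ncol(mat)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mat
  ge <- matrix(TRUE, nr, nc)
  gt <- matrix(FALSE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    nb <- pad[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj]
    ge <- ge & (mat >= nb)
    gt <- gt | (mat > nb)
  }
  out <- ge & gt
  if (!is.null(mask)) out <- out & mask
  out
}
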