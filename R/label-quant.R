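# Immunogold / immunofluorescence label quantification.

#' Detect immunogold particles in an IEM micrograph
#'
#' Dark-blob detection on the inverted, background-subtracted image:
#' light Gaussian smoothing, contrast thresholding, connected-component
#' labeling, and splitting of fused aggregates when separable intensity
#' maxima exist. Blobs with estimated diameter below `min_diameter_nm`
#' (default 8 nm, the inclusion rule for silver-enhanced nanogold) are
#' excluded. Detection is invariant to multiplying the image by a
#' positive constant.
#'
#' @param img a calibrated [micrograph] (modality `"IEM"`).
#' @param min_diameter_nm minimum particle diameter, nm.
#' @param min_contrast minimum blob contrast as a fraction of the image
#'   dynamic range (the "appropriate electron density" rule; a declared
#'   convention).
#' @param sigma_px detection smoothing scale, px.
#' @param split_min_sep_nm minimum separation of intensity maxima for an
#'   aggregate to be split into individual detections, nm.
#' @return a `particle_set`: data.frame `x_nm, y_nm, diameter_nm, fused`
#'   with attribute `nm_per_px`.
#' @export
detect_particles <- function(img, min_diameter_nm = 8, min_contrast = 0.3,
                             sigma_px = 1, split_min_sep_nm = NULL) {
  stopifnot(inherits(img, "micrograph"))
  px <- img$pixels
  rng <- diff(range(px))
  if (rng == 0) return(empty_particle_set(img$nm_per_px))
  inv <- (max(px) - px) / rng          # 0 = background, 1 = darkest
  bg <- stats::median(inv)
  resp <- blur_gaussian(inv - bg, sigma_px)
  mask <- resp > min_contrast
  if (!any(mask)) return(empty_particle_set(img$nm_per_px))
  lab <- label_mask(mask)
  nmpp <- img$nm_per_px
  if (is.null(split_min_sep_nm)) split_min_sep_nm <- min_diameter_nm
  maxima <- which(local_maxima(resp, mask), arr.ind = TRUE)
  max_lab <- lab[maxima]

  # diameter from the unsmoothed image: pixels of the blob darker than
  # half the blob's own raw depth (half-max area), which is unbiased by
  # the detection smoothing
  raw_diameter <- function(idx) {
    depth <- max(inv[idx])
    area <- sum(inv[idx] > depth / 2) * nmpp^2
    2 * sqrt(area / pi)
  }
  out <- list()
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l, arr.ind = TRUE)
    mx <- maxima[max_lab == l, , drop = FALSE]
    # cluster maxima: merge maxima closer than the separability gate
    centers <- cluster_maxima(mx, resp, split_min_sep_nm / nmpp)
    n_sub <- max(1L, nrow(centers))
    if (n_sub == 1L) {
      wt <- resp[idx]
      cx <- sum(idx[, 2] * wt) / sum(wt)
      cy <- sum(idx[, 1] * wt) / sum(wt)
      out[[length(out) + 1L]] <- data.frame(
        x_nm = (cx - 0.5) * nmpp, y_nm = (cy - 0.5) * nmpp,
        diameter_nm = raw_diameter(idx), fused = FALSE)
    } else {
      # fused aggregate with recognizable individual particles: assign
      # pixels to the nearest maximum
      d2 <- outer(idx[, 1], centers[, 1], "-")^2 +
            outer(idx[, 2], centers[, 2], "-")^2
      assign <- max.col(-d2)
      for (s in seq_len(n_sub)) {
        sub <- idx[assign == s, , drop = FALSE]
        if (nrow(sub) == 0) next
        wt <- resp[sub]
        cx <- sum(sub[, 2] * wt) / sum(wt)
        cy <- sum(sub[, 1] * wt) / sum(wt)
        out[[length(out) + 1L]] <- data.frame(
          x_nm = (cx - 0.5) * nmpp, y_nm = (cy - 0.5) * nmpp,
          diameter_nm = raw_diameter(sub), fused = TRUE)
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[res$diameter_nm >= min_diameter_nm, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "nm_per_px") <- nmpp
  class(res) <- c("particle_set", "data.frame")
  res
}

empty_particle_set <- function(nm_per_px) {
  res <- data.frame(x_nm = numeric(), y_nm = numeric(),
                    diameter_nm = numeric(), fused = logical())
  attr(res, "nm_per_px") <- nm_per_px
  class(res) <- c("particle_set", "data.frame")
  res
}

# Merge local maxima closer than min_sep_px; keep the strongest of each
# cluster. Returns a matrix with columns row, col.
cluster_maxima <- function(mx, resp, min_sep_px) {
  if (nrow(mx) <= 1) return(mx)
  ord <- order(resp[mx], decreasing = TRUE)
  mx <- mx[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(mx))
  for (i in seq_len(nrow(mx) - 1L)) {
    if (!keep[i]) next
    d <- sqrt((mx[, 1] - mx[i, 1])^2 + (mx[, 2] - mx[i, 2])^2)
    drop <- which(d < min_sep_px & seq_len(nrow(mx)) > i)
    keep[drop] <- FALSE
  }
  mx[keep, , drop = FALSE]
}

#' Restrict particles to the sarcomeric I-band region of interest
#'
#' Keeps particles whose axial (x) distance to the nearest Z-disk is at
#' most half the I-band width plus `margin_nm` (the I-band including the
#' Z-disk, +/- 20 nm by default); everything else is marked
#' background-excluded. The operation is idempotent.
#'
#' @param particles a `particle_set`.
#' @param zdisk_x_nm numeric vector of Z-disk axial centers, nm.
#' @param sl_um sarcomere length, um.
#' @param aband_length_nm A-band length, nm.
#' @param margin_nm ROI margin, nm.
#' @return the particle set with an added logical column `included` and
#'   character column `reason` (`""` or `"outside-iband-roi"`).
#' @export
apply_iband_roi <- function(particles, zdisk_x_nm, sl_um,
                            aband_length_nm = 1600, margin_nm = 20) {
  if (missing(zdisk_x_nm) || is.null(zdisk_x_nm) || length(zdisk_x_nm) == 0)
    stop("Z-disk geometry is required")
  ihalf <- (sl_um * 1000 - aband_length_nm) / 2
  if (ihalf < 0) stop("A-band longer than the sarcomere")
  lim <- ihalf + margin_nm
  if (nrow(particles) == 0) {
    particles$included <- logical(0); particles$reason <- character(0)
    return(particles)
  }
  dmin <- vapply(particles$x_nm,
                 function(x) min(abs(x - zdisk_x_nm)), numeric(1))
  particles$included <- dmin <= lim
  particles$reason <- ifelse(particles$included, "", "outside-iband-roi")
  particles
}

#' Epitope-to-Z-disk distances
#'
#' Per particle, the Euclidean distance to the nearest point of any
#' Z-disk centerline (or the axial distance when Z-disks are given as
#' straight positions). Optionally fits a two-component Gaussian mixture
#' to flag bimodal (partial-recoil) distributions; the fit is reported
#' only, never used to filter.
#'
#' @param particles a `particle_set` (rows with `included == FALSE` are
#'   ignored if the column exists).
#' @param zdisks either a numeric vector of Z-disk axial positions (nm)
#'   or a list of two-column centerline matrices (x_nm, y_nm).
#' @param mixture fit the two-component mixture? (default TRUE when
#'   >= 10 distances).
#' @return an `epitope_distance_set`: list with `distances_nm`,
#'   `mean_nm`, `sem_nm`, and `mixture` (NULL or list with `means`,
#'   `weights`, `sds`).
#' @export
epitope_distances <- function(particles, zdisks, mixture = NULL) {
  if (nrow(particles) == 0) stop("need at least one particle")
  if ("included" %in% names(particles))
    particles <- particles[particles$included, , drop = FALSE]
  if (nrow(particles) == 0) stop("no included particles")
  if (is.numeric(zdisks)) {
    d <- vapply(particles$x_nm, function(x) min(abs(x - zdisks)), numeric(1))
  } else {
    all_pts <- do.call(rbind, zdisks)
    d <- vapply(seq_len(nrow(particles)), function(i) {
      dx <- all_pts[, 1] - particles$x_nm[i]
      dy <- all_pts[, 2] - particles$y_nm[i]
      sqrt(min(dx^2 + dy^2))
    }, numeric(1))
  }
  if (is.null(mixture)) mixture <- length(d) >= 10
  mix <- if (mixture) fit_gaussian_mixture2(d) else NULL
  structure(list(distances_nm = d, mean_nm = mean(d),
                 sem_nm = stats::sd(d) / sqrt(length(d)), mixture = mix),
            class = "epitope_distance_set")
}

#' Two-component 1-D Gaussian mixture by EM
#'
#' Initialized at the 10th/90th percentiles; at most `max_iter`
#' iterations or a log-likelihood change below `tol`.
#'
#' @param x numeric data.
#' @param max_iter,tol EM controls.
#' @return list `means`, `sds`, `weights`, `loglik`, `iterations`
#'   (components ordered by mean).
#' @export
fit_gaussian_mixture2 <- function(x, max_iter = 200, tol = 1e-8) {
  stopifnot(length(x) >= 4)
  mu <- stats::quantile(x, c(0.1, 0.9), names = FALSE)
  if (diff(mu) == 0) mu <- mu + c(-1, 1) * max(1e-6, stats::sd(x) / 10)
  s <- rep(max(stats::sd(x) / 2, 1e-6), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], s[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    w <- c(mean(g), mean(1 - g))
    mu[1] <- sum(g * x) / sum(g)
    mu[2] <- sum((1 - g) * x) / sum(1 - g)
    s[1] <- sqrt(sum(g * (x - mu[1])^2) / sum(g))
    s[2] <- sqrt(sum((1 - g) * (x - mu[2])^2) / sum(1 - g))
    s <- pmax(s, 1e-8)
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ord <- order(mu)
  list(means = mu[ord], sds = s[ord], weights = w[ord],
       loglik = ll, iterations = it)
}

#' Gold-particle counts per sarcomere
#'
#' @param particles a `particle_set` (ROI-included rows only are
#'   counted if an `included` column exists).
#' @param boundaries data.frame with columns `start_nm`, `end_nm`
#'   delimiting each sarcomere along the fiber axis; must not overlap.
#' @return list `counts`, `mean`, `sem`.
#' @export
particles_per_sarcomere <- function(particles, boundaries) {
  stopifnot(is.data.frame(boundaries),
            all(c("start_nm", "end_nm") %in% names(boundaries)))
  if (nrow(boundaries) == 0) stop("need at least one sarcomere boundary pair")
  b <- boundaries[order(boundaries$start_nm), ]
  if (any(b$end_nm <= b$start_nm)) stop("invalid boundary pair")
  if (nrow(b) > 1 && any(b$start_nm[-1] < b$end_nm[-nrow(b)]))
    stop("overlapping sarcomere boundaries")
  x <- particles$x_nm
  if ("included" %in% names(particles)) x <- x[particles$included]
  counts <- vapply(seq_len(nrow(b)), function(i)
    sum(x >= b$start_nm[i] & x < b$end_nm[i]), numeric(1))
  list(counts = counts, mean = mean(counts),
       sem = stats::sd(counts) / sqrt(length(counts)))
}

#' Percent ratio of two group means
#'
#' `100 * a / b`; used to express one genotype's label abundance or
#' staining intensity as a percentage of a reference group.
#'
#' @param a,b group means (b > 0).
#' @return percent scalar.
#' @export
group_ratio_percent <- function(a, b) {
  if (b <= 0) stop("reference mean must be > 0")
  100 * a / b
}

#' Thick-filament end-to-end lengths from HaloTag label positions
#'
#' HaloTag epitopes mark the A-band edges; labels on the two flanks of
#' an A-band are paired and the axial end-to-end distance returned. In
#' `"per-filament"` mode labels pair only when their transverse (y)
#' positions agree within `transverse_gate_nm`; in
#' `"perpendicular-line"` mode each left label pairs with the
#' transversely nearest right label regardless of the gate (grouping
#' along a line perpendicular to the fiber axis).
#'
#' @param particles a `particle_set` of HaloTag labels.
#' @param aband_centers_nm axial positions of A-band (M-line) centers, nm.
#' @param sl_um sarcomere length, um (pairing search window is half the
#'   SL on each side of the center).
#' @param mode `"per-filament"` or `"perpendicular-line"`.
#' @param transverse_gate_nm transverse matching gate, nm.
#' @return a `filament_length_set`: list `lengths_nm`, `pairing_mode`,
#'   `mean_nm`, `sem_nm`; empty (with a warning) when one flank has no
#'   labels.
#' @export
thick_filament_lengths <- function(particles, aband_centers_nm, sl_um,
                                   mode = c("per-filament", "perpendicular-line"),
                                   transverse_gate_nm = 20) {
  mode <- match.arg(mode)
  if ("included" %in% names(particles))
    particles <- particles[particles$included, , drop = FALSE]
  half <- sl_um * 1000 / 2
  lengths <- numeric(0)
  any_side <- FALSE
  for (cx in aband_centers_nm) {
    sel <- abs(particles$x_nm - cx) < half
    p <- particles[sel, , drop = FALSE]
    left <- p[p$x_nm < cx, , drop = FALSE]
    right <- p[p$x_nm >= cx, , drop = FALSE]
    if (nrow(left) == 0 || nrow(right) == 0) next
    any_side <- TRUE
    used <- rep(FALSE, nrow(right))
    for (i in order(left$y_nm)) {
      dy <- abs(right$y_nm - left$y_nm[i])
      dy[used] <- Inf
      j <- which.min(dy)
      if (!is.finite(dy[j])) next
      if (mode == "per-filament" && dy[j] > transverse_gate_nm) next
      used[j] <- TRUE
      lengths <- c(lengths, right$x_nm[j] - left$x_nm[i])
    }
  }
  if (!any_side || length(lengths) == 0) {
    warning("no label pairs straddle an A-band; returning empty set")
    return(structure(list(lengths_nm = numeric(0), pairing_mode = mode,
                          mean_nm = NA_real_, sem_nm = NA_real_),
                     class = "filament_length_set"))
  }
  structure(list(lengths_nm = lengths, pairing_mode = mode,
                 mean_nm = mean(lengths),
                 sem_nm = stats::sd(lengths) / sqrt(length(lengths))),
            class = "filament_length_set")
}

#' HaloTag/ACTN2 immunofluorescence intensity ratio
#'
#' Per sarcomere, the integrated background-subtracted HaloTag intensity
#' divided by the integrated ACTN2 intensity. Background defaults to the
#' per-channel median of pixels outside all sarcomere strips.
#'
#' @param halotag,actn2 co-registered [micrograph]s of identical shape.
#' @param boundaries data.frame `start_nm`, `end_nm` of sarcomere strips
#'   along the fiber axis.
#' @param background optional numeric length-2 vector of (halotag,
#'   actn2) background levels overriding the default estimate.
#' @param background_region optional `c(start_nm, end_nm)` of a
#'   user-defined off-sarcomere region whose per-channel median is used
#'   as background; when neither this nor `background` is given, the
#'   10th percentile of each channel is used (robust to band bleed-in).
#' @return an `if_ratio_result`: list with `per_sarcomere` data.frame
#'   (`halotag`, `actn2`, `ratio`), `mean`, `sem`. Sarcomeres whose
#'   ACTN2 integral does not exceed background are dropped with a
#'   warning.
#' @export
if_intensity_ratio <- function(halotag, actn2, boundaries, background = NULL,
                               background_region = NULL) {
  stopifnot(inherits(halotag, "micrograph"), inherits(actn2, "micrograph"))
  if (!identical(dim(halotag$pixels), dim(actn2$pixels)))
    stop("channels must be co-registered with the same shape")
  nmpp <- halotag$nm_per_px
  nc <- ncol(halotag$pixels)
  x_cols <- (seq_len(nc) - 0.5) * nmpp
  col_sets <- lapply(seq_len(nrow(boundaries)), function(i) {
    which(x_cols >= boundaries$start_nm[i] & x_cols < boundaries$end_nm[i])
  })
  if (is.null(background)) {
    if (!is.null(background_region)) {
      off <- x_cols >= background_region[1] & x_cols < background_region[2]
      if (!any(off)) stop("background region contains no pixels")
      background <- c(stats::median(halotag$pixels[, off]),
                      stats::median(actn2$pixels[, off]))
    } else {
      background <- c(stats::quantile(halotag$pixels, 0.1, names = FALSE),
                      stats::quantile(actn2$pixels, 0.1, names = FALSE))
    }
  }
  rows <- lapply(col_sets, function(cols) {
    if (length(cols) == 0) return(NULL)
    h <- sum(halotag$pixels[, cols] - background[1])
    a <- sum(actn2$pixels[, cols] - background[2])
    data.frame(halotag = max(h, 0), actn2 = a)
  })
  per <- do.call(rbind, rows)
  ok <- per$actn2 > 0
  if (any(!ok)) warning(sum(!ok), " sarcomere(s) dropped: ACTN2 at or below background")
  per <- per[ok, , drop = FALSE]
  per$ratio <- per$halotag / per$actn2
  structure(list(per_sarcomere = per, mean = mean(per$ratio),
                 sem = stats::sd(per$ratio) / sqrt(nrow(per))),
            class = "if_ratio_result")
}
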