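#' Preprocess a density image for domain identification
#'
#' Gaussian smoothing (radius 5 px) followed by CLAHE contrast
#' enhancement (tile size 120 px), then rescaling to `[0, 1]` -- the
#' same conditioning applied to electron-tomography density maps before
#' picking domain centers.  Images smaller than one CLAHE tile fall
#' back to single-tile (global) histogram equalisation with a warning.
#'
#' @param img an `srev_image`.
#' @param blur_sigma Gaussian filter radius in px.
#' @param clahe_block CLAHE tile size in px.
#' @return the preprocessed `srev_image` (values in `[0, 1]`).
#' @export
preprocess_density <- function(img, blur_sigma = 5, clahe_block = 120) {
  stopifnot(inherits(img, "srev_image"))
  m <- img$data
  rng <- range(m)
  if (diff(rng) > 0) m <- (m - rng[1]) / diff(rng)
  sm <- EBImage::gblur(EBImage::Image(m), sigma = blur_sigma)
  nx <- round(nrow(m) / clahe_block)
  ny <- round(ncol(m) / clahe_block)
  if (nx < 2 || ny < 2) {
    warning("image smaller than the CLAHE tile; using single-tile equalisation")
    eq <- EBImage::imageData(
      EBImage::equalize(sm, range = range(EBImage::imageData(sm))))
  } else {
    # CLAHE needs dimensions divisible by the tile counts: pad with edge
    # replication, equalise, crop back
    sm <- EBImage::imageData(sm)
    px <- nx * ceiling(nrow(sm) / nx) - nrow(sm)
    py <- ny * ceiling(ncol(sm) / ny) - ncol(sm)
    padded <- rbind(sm, sm[rep(nrow(sm), px), , drop = FALSE])
    padded <- cbind(padded, padded[, rep(ncol(padded), py), drop = FALSE])
    eq <- EBImage::imageData(EBImage::clahe(EBImage::Image(padded),
                                            nx = nx, ny = ny))
    eq <- eq[seq_len(nrow(sm)), seq_len(ncol(sm)), drop = FALSE]
  }
  m <- eq
  rng <- range(m)
  if (diff(rng) > 0) m <- (m - rng[1]) / diff(rng)
  out <- img
  out$data <- m
  out$normalized <- TRUE
  out
}

#' Find packing-domain centers as density maxima
#'
#' Local maxima of the (preprocessed) density above a relative
#' threshold, with non-maximum suppression inside `min_separation` px.
#'
#' @param img an `srev_image` (preprocessed; see [preprocess_density()]).
#' @param min_separation suppression radius in px.
#' @param threshold relative intensity floor (fraction of the image max).
#' @return integer matrix with columns `x`, `y` (pixel indices); zero
#'   rows when the image is flat.
#' @export
find_domain_centers <- function(img, min_separation = 10, threshold = 0.1) {
  stopifnot(inherits(img, "srev_image"))
  m <- img$data
  if (max(m) <= min(m))
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  brush <- EBImage::makeBrush(2 * min_separation + 1, shape = "disc")
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(m), brush))
  cand <- which(m >= dil & m >= threshold * max(m), arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  # greedy suppression by intensity for plateau duplicates
  ord <- order(m[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  kept <- matrix(0L, 0, 2)
  for (k in seq_len(nrow(cand))) {
    p <- cand[k, ]
    if (nrow(kept) == 0 ||
        min((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2) > min_separation^2)
      kept <- rbind(kept, p)
  }
  dimnames(kept) <- list(NULL, c("x", "y"))
  kept
}

# radial-bin index (1 px wide) for every offset in a (2R+1)^2 box,
# shared by the mass-scaling and radial-CVC curves
radial_bins <- function(R) {
  off <- seq(-R, R)
  d <- sqrt(outer(off^2, off^2, "+"))
  pmin(floor(d) + 1L, R + 1L)  # bin R+1 collects corners beyond R
}

# per-pixel radial cumulative mass around (cx, cy), truncated at the border
radial_mass <- function(m, cx, cy, R) {
  Re <- min(R, cx - 1, nrow(m) - cx, cy - 1, ncol(m) - cy)
  if (Re < 3) return(NULL)
  bins <- radial_bins(Re)
  sub <- m[(cx - Re):(cx + Re), (cy - Re):(cy + Re)]
  per_bin <- rowsum(as.vector(sub), as.vector(bins))[, 1]
  list(cum = cumsum(per_bin[seq_len(Re)]),      # mass within r = 1..Re px
       ann = per_bin[seq_len(Re)],              # annulus mass
       ann_px = rowsum(rep(1, length(bins)), as.vector(bins))[seq_len(Re), 1],
       R = Re)
}

#' Mass-scaling curve around a domain center
#'
#' For every pixel `p` of an 11 x 11 window around the center, the
#' cumulative mass `M_p(r)` within radius `r` is computed; the returned
#' curve is the average of the `M_p` weighted by the density at `p`.
#'
#' @param img an `srev_image` (raw density recommended).
#' @param center length-2 pixel coordinates of the domain center.
#' @param window window edge in px (odd, default 11).
#' @param r_max largest radius in nm.
#' @return curve table with `mid` (r, nm), `value` (M), `n` (window
#'   pixels contributing); truncated at the available radius near
#'   borders.
#' @export
mass_scaling_curve <- function(img, center, window = 11, r_max = 150) {
  stopifnot(inherits(img, "srev_image"), length(center) == 2)
  m <- img$data
  R <- floor(r_max / img$pixel)
  h <- (window - 1) %/% 2
  xs <- max(1, center[1] - h):min(nrow(m), center[1] + h)
  ys <- max(1, center[2] - h):min(ncol(m), center[2] + h)
  acc <- NULL
  wsum <- 0
  n_used <- 0
  Rmin <- R
  curves <- list()
  weights <- numeric(0)
  for (x in xs) for (y in ys) {
    rm <- radial_mass(m, x, y, R)
    if (is.null(rm)) next
    curves[[length(curves) + 1L]] <- rm$cum
    weights <- c(weights, m[x, y])
    Rmin <- min(Rmin, rm$R)
  }
  if (length(curves) == 0 || Rmin < 3)
    stop("domain center too close to the border for a mass-scaling curve")
  if (sum(weights) <= 0) weights <- rep(1, length(curves))
  Mw <- Reduce(`+`, Map(function(cv, w) w * cv[seq_len(Rmin)],
                        curves, weights)) / sum(weights)
  curve_table(seq_len(Rmin) * img$pixel, Mw, rep(length(curves), Rmin))
}

#' Radial CVC profile around a domain center
#'
#' Annulus-averaged density converted to a volume fraction using the
#' slab thickness and the nucleosome volume.  For normalised images the
#' absolute scale is arbitrary but minima locations are unaffected.
#'
#' @inheritParams mass_scaling_curve
#' @return curve table with `mid` (r, nm), `value` (CVC), `n`
#'   (annulus pixel counts).
#' @export
radial_cvc_curve <- function(img, center, r_max = 150) {
  stopifnot(inherits(img, "srev_image"), length(center) == 2)
  R <- floor(r_max / img$pixel)
  rm <- radial_mass(img$data, center[1], center[2], R)
  if (is.null(rm))
    stop("domain center too close to the border for a radial CVC curve")
  v_bead <- (4 / 3) * pi * img$ro^3
  cvc <- rm$ann * v_bead / (rm$ann_px * img$pixel^2 * img$thickness)
  curve_table(seq_len(rm$R) * img$pixel, cvc, rm$ann_px)
}

#' Domain radius from mass-scaling stopping criteria
#'
#' The radius `Rd` is the smallest `r` at which any of three criteria
#' fires: (i) the mass-scaling curve deviates from the power law
#' `M(r) ~ r^D` fitted on the inner region by more than `dev_tol`;
#' (ii) the sliding-window local exponent of `M(r)` reaches 3;
#' (iii) the radial CVC has a strict local minimum followed by an
#' increase.  Domains where no criterion fires before the curve ends
#' have no defined radius (`NA`).
#'
#' @param M a mass-scaling curve table.
#' @param cvc a radial CVC curve table.
#' @param inner_window radial fit window (nm) anchoring criterion (i).
#' @param dev_tol relative deviation threshold of criterion (i).
#' @param exponent_window bins of the centered log-log finite difference
#'   used for the local exponent of criterion (ii).
#' @param min_r smallest radius (nm) a criterion may fire at, shielding
#'   the core oscillations.
#' @return `Rd` in nm, or `NA` if no criterion fires.
#' @export
domain_radius <- function(M, cvc, inner_window = c(20, 60), dev_tol = 0.05,
                          exponent_window = 5, min_r = 20) {
  fired <- numeric(0)
  ok <- M$value > 0 & is.finite(M$value)
  # (i) deviation from the inner power law -- only meaningful when the
  # inner region itself obeys one (fit residuals within the tolerance)
  inner <- ok & M$mid >= inner_window[1] & M$mid <= inner_window[2]
  if (sum(inner) >= 3) {
    fit <- lm(log(M$value[inner]) ~ log(M$mid[inner]))
    pred <- exp(coef(fit)[1] + coef(fit)[2] * log(M$mid))
    if (max(abs(M$value[inner] / pred[inner] - 1)) <= dev_tol) {
      beyond <- which(ok & M$mid > inner_window[2] &
                      abs(M$value / pred - 1) > dev_tol)
      if (length(beyond)) fired <- c(fired, M$mid[beyond[1]])
    }
  }
  # (ii) local exponent reaches 3
  h <- (exponent_window - 1) %/% 2
  n <- nrow(M)
  if (n >= exponent_window) {
    ks <- (h + 1):(n - h)
    slope <- (log(M$value[ks + h]) - log(M$value[ks - h])) /
      (log(M$mid[ks + h]) - log(M$mid[ks - h]))
    hit <- which(is.finite(slope) & slope >= 3 & M$mid[ks] >= min_r)
    if (length(hit)) fired <- c(fired, M$mid[ks[hit[1]]])
  }
  # (iii) radial CVC local minimum followed by a material increase
  # (a >= 5 % rise within the next 10 bins guards against discretisation
  # ripples in the near-empty tail)
  v <- cvc$value
  if (length(v) >= 3) {
    ks <- 2:(length(v) - 1)
    cand <- ks[v[ks] < v[ks - 1] & v[ks + 1] > v[ks] & cvc$mid[ks] >= min_r]
    for (k in cand) {
      ahead <- v[(k + 1):min(k + 10, length(v))]
      if (max(ahead) > 1.05 * v[k]) {
        fired <- c(fired, cvc$mid[k])
        break
      }
    }
  }
  if (length(fired) == 0) return(NA_real_)
  min(fired)
}

#' Identify packing domains in a slab density image
#'
#' Full pipeline: [preprocess_density()], [find_domain_centers()] on the
#' preprocessed image, then [mass_scaling_curve()], [radial_cvc_curve()]
#' and [domain_radius()] on the raw density for each center.  Centers
#' whose radius is undefined are dropped.
#'
#' @param img a raw (unpreprocessed) `srev_image`.
#' @param min_separation,threshold passed to [find_domain_centers()].
#' @param r_max largest probed radius in nm.
#' @param ... passed to [domain_radius()].
#' @return data.frame of class `srev_domains` with columns `x`, `y`
#'   (px), `x_nm`, `y_nm`, `radius_nm`, `peak_density`.
#' @export
find_domains <- function(img, min_separation = 10, threshold = 0.1,
                         r_max = 150, ...) {
  proc <- preprocess_density(img)
  centers <- find_domain_centers(proc, min_separation, threshold)
  out <- data.frame(x = integer(0), y = integer(0), x_nm = numeric(0),
                    y_nm = numeric(0), radius_nm = numeric(0),
                    peak_density = numeric(0))
  for (k in seq_len(nrow(centers))) {
    ctr <- centers[k, ]
    rd <- tryCatch({
      M <- mass_scaling_curve(img, ctr, r_max = r_max)
      cvc <- radial_cvc_curve(img, ctr, r_max = r_max)
      domain_radius(M, cvc, ...)
    }, error = function(e) NA_real_)
    if (is.na(rd)) next
    out <- rbind(out, data.frame(
      x = ctr[1], y = ctr[2],
      x_nm = img$origin[1] + (ctr[1] - 0.5) * img$pixel,
      y_nm = img$origin[2] + (ctr[2] - 0.5) * img$pixel,
      radius_nm = rd, peak_density = proc$data[ctr[1], ctr[2]]))
  }
  class(out) <- c("srev_domains", "data.frame")
  out
}

#' Pooled statistics of domain sets
#'
#' @param domain_sets list of `srev_domains` (one per configuration).
#' @return list with `radii` (pooled, nm), `mean_radius`, `counts`
#'   (domains per configuration) and `mean_count`.
#' @export
domain_stats <- function(domain_sets) {
  stopifnot(length(domain_sets) >= 1)
  radii <- unlist(lapply(domain_sets, function(d) d$radius_nm))
  counts <- vapply(domain_sets, nrow, integer(1))
  list(radii = radii,
       mean_radius = if (length(radii)) mean(radii) else NA_real_,
       counts = counts, mean_count = mean(counts))
}
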