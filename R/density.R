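#' Coordination numbers
#'
#' Number of other beads within a coordination radius of each bead
#' (default 11.5 nm): 0 for an isolated nucleosome, up to 12 for one
#' immersed in a densely packed domain.
#'
#' @param chain an `srev_chain`.
#' @param radius coordination radius in nm.
#' @return integer vector, one count per bead.
#' @export
coordination_numbers <- function(chain, radius = 11.5) {
  stopifnot(inherits(chain, "srev_chain"), radius > 0)
  coordination_cpp(chain$positions, radius)
}

#' Chromatin volume concentration on a cubic probing grid
#'
#' Local volume fraction in a `grid x grid x grid` array of cubic
#' probing volumes of edge `cube_edge` nm centered on `center`: each
#' cube's CVC is the number of bead centers it contains times the bead
#' volume `4/3 pi ro^3`, divided by the cube volume.
#'
#' @param chain an `srev_chain`.
#' @param cube_edge probing-cube edge in nm (default 120).
#' @param grid cubes per axis (default 6).
#' @param center grid center (nm).
#' @return numeric vector of `grid^3` per-cube volume fractions.
#' @export
cvc_grid <- function(chain, cube_edge = 120, grid = 6L, center = c(0, 0, 0)) {
  stopifnot(inherits(chain, "srev_chain"), cube_edge > 0, grid >= 1)
  half <- grid * cube_edge / 2
  if (half * sqrt(3) > chain$rc)
    warning("probing grid extends beyond the confinement sphere; ",
            "outer cubes are partly unreachable")
  p <- sweep(chain$positions, 2, center)
  idx <- floor((p + half) / cube_edge)
  inside <- rowSums(idx >= 0 & idx < grid) == 3L
  idx <- idx[inside, , drop = FALSE]
  flat <- idx[, 1] + grid * (idx[, 2] + grid * idx[, 3]) + 1
  counts <- tabulate(flat, nbins = grid^3)
  counts * (4 / 3) * pi * chain$ro^3 / cube_edge^3
}

#' Pair correlation function g(r)
#'
#' Standard radial distribution estimate normalised by the overall
#' number density `N / (4/3 pi rc^3)`.  Reference beads are restricted
#' to an interior sphere of radius `rc - r_max` about the confinement
#' center so shell normalisation needs no boundary correction.
#'
#' @param chain an `srev_chain`.
#' @param dr radial bin width in nm.
#' @param r_max largest distance in nm (must satisfy `r_max < rc`).
#' @return curve table with `mid` (r, nm), `value` (g), `n` (pair counts).
#' @export
pair_correlation <- function(chain, dr = 2, r_max = 130) {
  stopifnot(inherits(chain, "srev_chain"), dr > 0, r_max < chain$rc)
  pos <- chain$positions
  n <- nrow(pos)
  r2 <- rowSums(pos^2)
  refs <- which(r2 <= (chain$rc - r_max)^2)
  if (length(refs) == 0) stop("no beads in the interior reference region")
  hist <- dist_hist_cpp(pos, refs - 1L, dr, r_max)
  edges <- seq(0, by = dr, length.out = length(hist) + 1)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  shell <- (4 / 3) * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  density <- n / ((4 / 3) * pi * chain$rc^3)
  g <- hist / (length(refs) * shell * density)
  curve_table(mid, g, hist)
}

#' Cumulative pair correlation G(r)
#'
#' Trapezoidal cumulative integral `G(r) = int_0^r 4 pi r'^2 g(r') dr'`,
#' the expected number of neighbours within `r` divided by the overall
#' number density.  Over intermediate scales `G(r)` follows a power law
#' `r^D` with packing parameter `D < 3`.
#'
#' @param g a `g(r)` curve table from [pair_correlation()].
#' @return curve table with `mid` (r, nm), `value` (G), `n`.
#' @export
cumulative_G <- function(g) {
  stopifnot(is.data.frame(g), all(c("mid", "value", "n") %in% names(g)))
  x <- c(0, g$mid)
  y <- c(0, 4 * pi * g$mid^2 * g$value)
  G <- cumsum(c(0, diff(x) * (head(y, -1) + tail(y, -1)) / 2))[-1]
  curve_table(g$mid, G, g$n)
}

#' Packing parameter D
#'
#' Log-log least-squares slope of `G(r)` over a radial window, by
#' default 40-120 nm, the regime where `G(r)` is essentially a perfect
#' power law `r^D`.
#'
#' @param G a `G(r)` curve table from [cumulative_G()].
#' @param window radial fit window in nm.
#' @return the packing parameter D.
#' @export
fit_packing_D <- function(G, window = c(40, 120)) fit_loglog(G, window)

#' Per-configuration packing parameter and local volume fraction
#'
#' Both quantities are measured in the same sphere (default radius
#' 240 nm) centered on the configuration's center of mass: `D_i` is
#' [fit_packing_D()] applied to the configuration's own `G(r)`
#' restricted to beads in the sphere, and `phi_i` is the bead volume
#' fraction of the sphere, `n_inside * (ro / radius)^3`.
#'
#' @param chain an `srev_chain`.
#' @param radius sphere radius in nm.
#' @param dr,r_max radial binning of the underlying `g(r)`.
#' @param window radial fit window in nm.
#' @param min_beads smallest usable bead count inside the sphere;
#'   configurations below it are skipped (`NULL` return) with a message.
#' @return list with `D` and `phi`, or `NULL` if the sphere is too empty.
#' @export
local_D_phi <- function(chain, radius = 240, dr = 2, r_max = 130,
                        window = c(40, 120), min_beads = 200L) {
  stopifnot(inherits(chain, "srev_chain"), radius > r_max)
  com <- colMeans(chain$positions)
  p <- sweep(chain$positions, 2, com)
  d2 <- rowSums(p^2)
  inside <- d2 <= radius^2
  n_in <- sum(inside)
  if (n_in < min_beads) {
    message(sprintf("local_D_phi: only %d beads in the %g nm sphere; skipped",
                    n_in, radius))
    return(NULL)
  }
  sub <- p[inside, , drop = FALSE]
  refs <- which(rowSums(sub^2) <= (radius - r_max)^2)
  if (length(refs) < 10) {
    message("local_D_phi: too few interior reference beads; skipped")
    return(NULL)
  }
  hist <- dist_hist_cpp(sub, refs - 1L, dr, r_max)
  edges <- seq(0, by = dr, length.out = length(hist) + 1)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  shell <- (4 / 3) * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  density <- n_in / ((4 / 3) * pi * radius^3)
  g <- curve_table(mid, hist / (length(refs) * shell * density), hist)
  list(D = fit_packing_D(cumulative_G(g), window),
       phi = n_in * (chain$ro / radius)^3)
}

# Gaussian mass deposition weights for one axis: integral of N(center,
# sigma) over each pixel, restricted to a +/- 4 sigma index window.
axis_weights <- function(edges, center, sigma) {
  i0 <- max(1L, findInterval(center - 4 * sigma, edges))
  i1 <- min(length(edges) - 1L, findInterval(center + 4 * sigma, edges) + 1L)
  if (i1 < i0) return(NULL)
  w <- diff(pnorm(edges[i0:(i1 + 1L)], mean = center, sd = sigma))
  list(idx = i0:i1, w = w)
}

#' Render a 2D slab density image
#'
#' Beads within a slab of given thickness about the configuration's
#' center-of-mass plane deposit unit mass as an isotropic Gaussian
#' (default `sigma = ro`) integrated over each pixel, mirroring how
#' electron-tomography density maps are produced from a physical
#' section.  By default the image is normalised to its highest value.
#'
#' @param chain an `srev_chain`.
#' @param thickness slab thickness in nm (default 100).
#' @param pixel pixel size in nm.
#' @param sigma Gaussian deposition width in nm.
#' @param half_width half extent of the image in nm (default `rc`).
#' @param center_z slab mid-plane (nm); default the chain's COM z.
#' @param normalize divide by the maximum pixel value.
#' @return object of class `srev_image`: `data` (matrix, x rows by y
#'   columns), `pixel` (nm), `thickness`, `origin` (lower edges, nm),
#'   `normalized`.
#' @export
render_slab_density <- function(chain, thickness = 100, pixel = 2,
                                sigma = chain$ro, half_width = chain$rc,
                                center_z = NULL, normalize = TRUE) {
  stopifnot(inherits(chain, "srev_chain"), thickness > 0, pixel > 0)
  if (is.null(center_z)) center_z <- mean(chain$positions[, 3])
  npx <- ceiling(2 * half_width / pixel)
  edges <- seq(-half_width, by = pixel, length.out = npx + 1)
  img <- matrix(0, npx, npx)
  keep <- abs(chain$positions[, 3] - center_z) <= thickness / 2
  pos <- chain$positions[keep, , drop = FALSE]
  for (b in seq_len(nrow(pos))) {
    wx <- axis_weights(edges, pos[b, 1], sigma)
    wy <- axis_weights(edges, pos[b, 2], sigma)
    if (is.null(wx) || is.null(wy)) next
    img[wx$idx, wy$idx] <- img[wx$idx, wy$idx] + outer(wx$w, wy$w)
  }
  if (normalize && max(img) > 0) img <- img / max(img)
  structure(list(data = img, pixel = pixel, thickness = thickness,
                 origin = c(-half_width, -half_width),
                 normalized = normalize, ro = chain$ro, sigma = sigma),
            class = "srev_image")
}

#' Render a 3D density volume
#'
#' Gaussian mass deposition as in [render_slab_density()] but on a 3D
#' voxel grid covering the whole configuration; total deposited mass
#' equals the bead count to within the clipped Gaussian tails.
#'
#' @param chain an `srev_chain`.
#' @param voxel voxel edge in nm.
#' @param sigma Gaussian deposition width in nm.
#' @param half_width half extent of the grid in nm; the default pads
#'   `rc` by `4 sigma` so no mass is clipped.
#' @return object of class `srev_volume`: `data` (3D array), `voxel`,
#'   `origin`.
#' @export
render_volume <- function(chain, voxel = 4, sigma = chain$ro,
                          half_width = chain$rc + 4 * sigma) {
  stopifnot(inherits(chain, "srev_chain"), voxel > 0)
  npx <- ceiling(2 * half_width / voxel)
  edges <- seq(-half_width, by = voxel, length.out = npx + 1)
  vol <- array(0, dim = c(npx, npx, npx))
  pos <- chain$positions
  for (b in seq_len(nrow(pos))) {
    wx <- axis_weights(edges, pos[b, 1], sigma)
    wy <- axis_weights(edges, pos[b, 2], sigma)
    wz <- axis_weights(edges, pos[b, 3], sigma)
    if (is.null(wx) || is.null(wy) || is.null(wz)) next
    vol[wx$idx, wy$idx, wz$idx] <- vol[wx$idx, wy$idx, wz$idx] +
      outer(wx$w, wy$w) %o% wz$w
  }
  structure(list(data = vol, voxel = voxel, origin = rep(-half_width, 3),
                 sigma = sigma, ro = chain$ro),
            class = "srev_volume")
}

#' @export
print.srev_image <- function(x, ...) {
  cat(sprintf("density image: %d x %d px, %g nm/px, slab %g nm%s\n",
              nrow(x$data), ncol(x$data), x$pixel, x$thickness,
              if (isTRUE(x$normalized)) ", normalized" else ""))
  invisible(x)
}
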