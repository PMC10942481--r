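# fixtures built in code, shared across test files

# bare chain from a position matrix (bonds = consecutive rows)
make_chain <- function(pos, ro = 4.9, rc = 650, alpha = NA_real_,
                       rest = NULL) {
  chain <- structure(list(positions = pos, rest_lengths = NULL, ro = ro,
                          rc = rc, alpha = alpha, relaxed = TRUE,
                          relax_iterations = NA_integer_),
                     class = "srev_chain")
  chain$rest_lengths <- if (is.null(rest))
    pmax(bond_lengths(chain), 2 * ro) else rest
  chain
}

# FCC cluster at contact distance a = 2 ro: central bead + 12 nearest
# neighbours (coordination 12)
fcc_cluster <- function(ro = 4.9) {
  a <- 2 * ro / sqrt(2)  # half the cubic lattice constant
  nn <- rbind(c(1,1,0), c(1,-1,0), c(-1,1,0), c(-1,-1,0),
              c(1,0,1), c(1,0,-1), c(-1,0,1), c(-1,0,-1),
              c(0,1,1), c(0,1,-1), c(0,-1,1), c(0,-1,-1))
  rbind(c(0, 0, 0), nn * a)
}

# uniform random beads in a sphere (ideal-gas fixture)
uniform_sphere_chain <- function(n, rc, ro = 4.9, seed = 1) {
  set.seed(seed)
  pos <- matrix(rnorm(3 * ceiling(n * 2.2)), ncol = 3)
  pos <- pos / sqrt(rowSums(pos^2)) * rc * runif(nrow(pos))^(1/3)
  make_chain(pos[seq_len(n), ], ro = ro, rc = rc)
}

# genomic map with uniform bp spacing (clean abscissa for scaling oracles)
uniform_map <- function(n, spacing = 185) {
  structure(list(linker_bp = rep(spacing - 147L, n - 1),
                 qualifies = rep(TRUE, n - 1),
                 s = 1 + spacing * (0:(n - 1)), bp_per_bead = 147L,
                 total_bp = spacing * n), class = "srev_genomic_map")
}

# synthetic image of k Gaussian blobs on a quiet background
blob_image <- function(centers_px, sigma_px, size = 240, pixel = 2,
                       thickness = 100, ro = 4.9) {
  m <- matrix(0, size, size)
  xs <- seq_len(size)
  for (k in seq_len(nrow(centers_px))) {
    gx <- dnorm(xs, centers_px[k, 1], sigma_px)
    gy <- dnorm(xs, centers_px[k, 2], sigma_px)
    m <- m + outer(gx, gy)
  }
  structure(list(data = m / max(m), pixel = pixel, thickness = thickness,
                 origin = c(0, 0), normalized = TRUE, ro = ro, sigma = ro),
            class = "srev_image")
}

# synthetic image of parabolic density domes: density rho0 (1 - (r/R0)^2)
# inside radius R0 (px), zero outside.  The core mass scaling is an exact
# power law M ~ r^2, so the domain-radius criteria are well posed.
dome_image <- function(centers_px, R0_px, size = 240, pixel = 2,
                       thickness = 100, ro = 4.9) {
  m <- matrix(0, size, size)
  xs <- seq_len(size)
  for (k in seq_len(nrow(centers_px))) {
    d2 <- outer((xs - centers_px[k, 1])^2, (xs - centers_px[k, 2])^2, "+")
    m <- m + pmax(0, 1 - d2 / R0_px[k]^2)
  }
  structure(list(data = m / max(m), pixel = pixel, thickness = thickness,
                 origin = c(0, 0), normalized = TRUE, ro = ro, sigma = ro),
            class = "srev_image")
}

# ideal random-flight chain fixture: returns disabled, no excluded
# volume, no confinement.  The genomic abscissa is uniform (185 bp per
# step) so scaling exponents are probed against step count, free of the
# correlation between a bond's length and its own linker contribution.
# A modest jump cutoff keeps the step variance well behaved.
random_flight <- function(n = 20000, seed = 5) {
  w <- generate_walk(walk_params(1.15, n, rc = 1e9, seed = seed,
                                 u_max = 5),
                     returns_enabled = FALSE, confine = FALSE)
  chain <- make_chain(w$positions * 10, rc = 1e9)
  list(chain = chain, map = uniform_map(n))
}

# small relaxed SR-EV chain cached across tests (lazy, built once)
cached_chain <- local({
  cache <- new.env(parent = emptyenv())
  function(alpha = 1.15, n_beads = 2000, phi = 0.16, seed = 42) {
    key <- paste(alpha, n_beads, phi, seed, sep = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <- sr_ev_chain(alpha, n_beads = n_beads,
                                  rc = rc_for_phi(phi, n_beads), seed = seed)
    cache[[key]]
  }
})
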