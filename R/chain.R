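#' Relaxation settings for excluded-volume resolution
#'
#' The expanded chain is relaxed by overdamped descent on a soft-core
#' energy: pair repulsion `k_repulsion * (2 ro - r)^2` below contact,
#' harmonic bonds `k_bond * (r - r0)^2` with `r0` the bond's initial
#' length (floored at `2 ro`), and reflecting spherical confinement at
#' `rc`.  The loop terminates the moment no overlapping pair remains.
#'
#' @param k_repulsion soft-core stiffness (energy / nm^2).
#' @param k_bond bond stiffness; moderate relative to `k_repulsion` so
#'   that crowding can stretch linkers.
#' @param gamma descent step (mobility x timestep, nm^2 / energy).
#' @param max_iter iteration budget before a non-convergence error.
#' @param temperature optional thermal noise level; the default 0 keeps
#'   relaxation deterministic and strictly energy-decreasing.
#' @param perturbation jitter amplitude (nm) applied to co-located beads
#'   when a walk is expanded (see [expand_overlaps()]).
#' @param contact_margin fractional inflation of the repulsion range
#'   beyond the contact diameter `2 ro`.  A purely contact-ranged soft
#'   core has zero force at contact, so bond tension could hold pairs at
#'   an infinitesimal overlap forever; the small margin keeps a
#'   restoring force alive at `2 ro` and lets the loop reach exactly
#'   zero overlaps.
#' @param method `"fire"` (damped inertial molecular dynamics with FIRE
#'   adaptive time-stepping; fast, the production default) or
#'   `"descent"` (plain overdamped gradient descent; strictly
#'   energy-decreasing at temperature 0, used to audit the descent
#'   contract).  `gamma` is the initial timestep for `"fire"` and the
#'   descent step otherwise.
#' @return an object of class `srev_relax_config`.
#' @export
relax_config <- function(k_repulsion = 1, k_bond = 0.05, gamma = 0.1,
                         max_iter = 20000L, temperature = 0,
                         perturbation = 0.5, contact_margin = 0.1,
                         method = c("fire", "descent")) {
  method <- match.arg(method)
  stopifnot(k_repulsion > 0, k_bond > 0, gamma > 0, max_iter > 0,
            temperature >= 0, perturbation > 0, contact_margin >= 0)
  structure(list(k_repulsion = k_repulsion, k_bond = k_bond, gamma = gamma,
                 max_iter = as.integer(max_iter), temperature = temperature,
                 perturbation = perturbation, contact_margin = contact_margin,
                 method = method),
            class = "srev_relax_config")
}

#' Expand a walk into a linear bead chain
#'
#' Every visit of the walk (origin plus each step endpoint) becomes one
#' bead, in walk order, so revisited sites turn into clusters of
#' coincident beads on a single linear bond path.  Beads sharing a site
#' are displaced onto consecutive shells of a close-packed (FCC) ball
#' around the site, randomly rotated per site and jittered by small
#' random offsets (`<= perturbation` nm).  This seeds every cluster
#' overlap-free inside the volume it must come to occupy, so the
#' subsequent relaxation only has to resolve inter-cluster overlaps.
#' Bond rest lengths are the traversed step lengths (nm), floored at
#' the bead diameter.
#'
#' @param walk an `srev_walk`.
#' @param ro non-overlap (bead) radius in nm.
#' @param perturbation jitter amplitude in nm.
#' @return an unrelaxed chain of class `srev_chain` with fields
#'   `positions` (nm), `rest_lengths` (per bond, nm), `ro`, `rc`,
#'   `relaxed` flag and provenance (`alpha`, walk params).
#' @export
expand_overlaps <- function(walk, ro = 4.9, perturbation = 0.5) {
  stopifnot(inherits(walk, "srev_walk"))
  unit <- walk$params$unit_length
  pos <- walk$positions * unit
  # the walk is confined around its running center of mass, which
  # drifts; recenter so the relaxation sphere (origin, radius rc)
  # coincides with the configuration
  pos <- sweep(pos, 2, colMeans(pos))
  site <- walk$site_id + 1L
  mult <- walk$site_multiplicity[site]
  multi <- mult > 1L
  n_multi <- sum(multi)
  if (n_multi > 0) {
    # rank of each bead among the visits to its site (0-based)
    ord <- order(site)
    counts <- tabulate(site)
    rank0 <- integer(length(site))
    rank0[ord] <- sequence(counts[counts > 0]) - 1L
    k <- rank0[multi]
    dir <- fcc_ball(max(k) + 1L, 2 * ro * 1.02)[k + 1L, , drop = FALSE]
    # random per-site rotation (Rodrigues), indexed to each bead's site
    smax <- length(walk$site_multiplicity)
    theta <- runif(smax, 0, 2 * pi)[site[multi]]
    ax <- matrix(rnorm(3L * smax), ncol = 3L)
    ax <- (ax / sqrt(rowSums(ax^2)))[site[multi], , drop = FALSE]
    kd <- rowSums(ax * dir)
    kx <- cbind(ax[, 2] * dir[, 3] - ax[, 3] * dir[, 2],
                ax[, 3] * dir[, 1] - ax[, 1] * dir[, 3],
                ax[, 1] * dir[, 2] - ax[, 2] * dir[, 1])
    rot <- dir * cos(theta) + kx * sin(theta) + ax * kd * (1 - cos(theta))
    pos[multi, ] <- pos[multi, , drop = FALSE] + rot +
      matrix(runif(3L * n_multi, -perturbation, perturbation), ncol = 3L)
  }
  rest <- pmax(walk$step_lengths * unit, 2 * ro)
  structure(list(positions = pos, rest_lengths = rest, ro = ro,
                 rc = walk$params$rc, alpha = walk$params$alpha,
                 params = walk$params, relaxed = FALSE,
                 relax_iterations = NA_integer_),
            class = "srev_chain")
}

# first n points of an FCC lattice (nearest-neighbour spacing `nn`),
# sorted by distance from the origin; point 1 is the origin
fcc_ball <- function(n, nn) {
  r <- 1L
  repeat {
    g <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
    g <- g[rowSums(g) %% 2 == 0, , drop = FALSE]
    if (nrow(g) >= n) break
    r <- r + 1L
  }
  g <- g[order(rowSums(g^2)), , drop = FALSE]
  unname(g[seq_len(n), , drop = FALSE] * (nn / sqrt(2)))
}

#' Count excluded-volume overlaps
#'
#' Number of unordered bead pairs closer than `2 ro` between centers,
#' found with a linked-cell neighbor search.
#'
#' @param chain an `srev_chain`.
#' @return integer overlap count.
#' @export
count_overlaps <- function(chain) {
  stopifnot(inherits(chain, "srev_chain"))
  count_overlaps_cpp(chain$positions, chain$ro)
}

#' Relax a chain to zero overlaps
#'
#' Overdamped low-temperature descent under the energy described in
#' [relax_config()]; bond topology is untouched and the loop stops as
#' soon as all overlaps are resolved.
#'
#' @param chain an `srev_chain` (typically from [expand_overlaps()]).
#' @param config an `srev_relax_config`.
#' @return the relaxed chain; `relax_iterations` and `energy_trace`
#'   record the descent.  Errors if overlaps remain after `max_iter`.
#' @export
relax_chain <- function(chain, config = relax_config()) {
  stopifnot(inherits(chain, "srev_chain"),
            inherits(config, "srev_relax_config"))
  res <- relax_cpp(chain$positions, chain$rest_lengths, chain$ro, chain$rc,
                   config$k_repulsion, config$k_bond, config$gamma,
                   config$max_iter, config$temperature, config$contact_margin,
                   if (identical(config$method, "descent")) 1L else 0L)
  if (!res$converged)
    stop(sprintf("relaxation did not converge: %d overlaps after %d iterations",
                 as.integer(res$overlaps), res$iterations))
  chain$positions <- res$positions
  chain$relaxed <- TRUE
  chain$relax_iterations <- res$iterations
  chain$energy_trace <- res$energy_trace
  chain
}

#' Chain potential energy
#'
#' Soft-core pair energy plus harmonic bond energy of the current
#' configuration; the quantity minimised by [relax_chain()].
#'
#' @param chain an `srev_chain`.
#' @param config an `srev_relax_config` supplying the stiffnesses.
#' @return scalar energy.
#' @export
chain_energy <- function(chain, config = relax_config()) {
  chain_energy_cpp(chain$positions, chain$rest_lengths, chain$ro,
                   config$k_repulsion, config$k_bond)
}

#' Bond lengths of a chain
#' @param chain an `srev_chain`.
#' @return numeric vector of the `N - 1` consecutive bead distances (nm).
#' @export
bond_lengths <- function(chain) {
  p <- chain$positions
  sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
}

#' Radius of gyration
#' @param chain an `srev_chain`.
#' @return scalar radius of gyration (nm).
#' @export
radius_of_gyration <- function(chain) {
  p <- chain$positions
  com <- colMeans(p)
  sqrt(mean(rowSums(sweep(p, 2, com)^2)))
}

#' Overall bead volume fraction
#'
#' `phi = N (ro / rc)^3`: the fraction of the confinement sphere volume
#' occupied by `n_beads` beads of radius `ro`.
#'
#' @param n_beads number of beads.
#' @param ro bead radius (nm).
#' @param rc confinement radius (nm).
#' @return volume fraction.
#' @seealso [beads_for_phi()]
#' @export
volume_fraction <- function(n_beads, ro = 4.9, rc = 650) {
  stopifnot(n_beads >= 0, ro > 0, rc > 0)
  n_beads * (ro / rc)^3
}

#' Bead count realising a target volume fraction
#' @param phi target volume fraction.
#' @param rc confinement radius (nm).
#' @param ro bead radius (nm).
#' @return `round(phi * (rc / ro)^3)`.
#' @export
beads_for_phi <- function(phi, rc = 650, ro = 4.9) {
  as.integer(round(phi * (rc / ro)^3))
}

#' Confinement radius realising a target volume fraction
#'
#' Inverse of [beads_for_phi()]; used to scale ensembles down while
#' preserving `phi`.
#'
#' @param phi target volume fraction.
#' @param n_beads bead count.
#' @param ro bead radius (nm).
#' @return confinement radius in nm.
#' @export
rc_for_phi <- function(phi, n_beads, ro = 4.9) {
  ro * (n_beads / phi)^(1 / 3)
}

#' Generate one SR-EV configuration
#'
#' Convenience pipeline: [generate_walk()] then [expand_overlaps()] then
#' [relax_chain()].  Specify the system size either as `n_beads` or as a
#' volume fraction `phi` (converted with [beads_for_phi()]).
#'
#' @param alpha folding parameter.
#' @param phi overall volume fraction (used when `n_beads` is `NULL`).
#' @param n_beads bead count override.
#' @param rc confinement radius (nm).
#' @param seed RNG seed (walk and jitter).
#' @param ro bead radius (nm).
#' @param config relaxation settings.
#' @param ... passed to [walk_params()].
#' @return a relaxed `srev_chain`.
#' @export
sr_ev_chain <- function(alpha, phi = NULL, n_beads = NULL, rc = 650,
                        seed = 1L, ro = 4.9, config = relax_config(), ...) {
  if (is.null(n_beads)) {
    if (is.null(phi)) stop("give either phi or n_beads")
    n_beads <- beads_for_phi(phi, rc, ro)
  }
  walk <- generate_walk(walk_params(alpha, n_beads, rc = rc, seed = seed, ...))
  chain <- expand_overlaps(walk, ro = ro, perturbation = config$perturbation)
  relax_chain(chain, config)
}

#' @export
print.srev_chain <- function(x, ...) {
  cat(sprintf(
    "SR-EV chain: %d beads, alpha = %.3f, rc = %g nm, ro = %g nm, %s\n",
    nrow(x$positions), x$alpha, x$rc, x$ro,
    if (isTRUE(x$relaxed)) sprintf("relaxed (%d iterations)", x$relax_iterations)
    else "unrelaxed"))
  invisible(x)
}
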