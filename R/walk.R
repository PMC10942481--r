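#' Parameters for a self-returning random walk
#'
#' The SRRW takes, at each step, either a return over the most recent
#' un-returned forward step -- with probability `U0^(-alpha)/alpha`
#' where `U0` is that step's length -- or a forward jump of length drawn
#' from the heavy-tailed density `(alpha+1) * U^-(alpha+2)`, `U > 1`,
#' in a uniformly random direction.  Lengths are measured in unit
#' lengths (one unit = `unit_length` nm = one nucleosome diameter).
#'
#' @param alpha folding parameter (> 1).  Smaller values give more and
#'   longer returns and heavier jump tails.
#' @param n_beads target number of beads; the walk takes `n_beads - 1`
#'   steps and every visit (including revisits) becomes one bead.
#' @param rc global confinement radius in nm.  Forward jumps ending
#'   farther than `rc` from the running center of mass of the
#'   already-generated nodes are rejected and resampled.
#' @param unit_length minimum jump length in nm (default 10, the
#'   nucleosome diameter).
#' @param u_max local jump cutoff in unit lengths; the jump-length law is
#'   truncated at `u_max` by rejection resampling.
#' @param seed RNG seed used by [generate_walk()].
#' @return an object of class `srev_walk_params`.
#' @seealso [generate_walk()]
#' @export
walk_params <- function(alpha, n_beads, rc = 650, unit_length = 10,
                        u_max = 100, seed = 1L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L)
  if (alpha <= 1) stop("alpha must be > 1 (return probability <= 1/alpha)")
  if (n_beads < 2) stop("n_beads must be >= 2")
  if (rc <= unit_length) stop("rc must exceed the unit length")
  if (u_max <= 1) stop("u_max must be > 1")
  structure(list(alpha = alpha, n_beads = as.integer(n_beads), rc = rc,
                 unit_length = unit_length, u_max = u_max,
                 seed = as.integer(seed)),
            class = "srev_walk_params")
}

#' Return probability of the SRRW
#'
#' Probability that the walk reverses its last un-returned forward step
#' of length `u0` (in unit lengths): `u0^(-alpha) / alpha`.
#'
#' @param u0 backbone step length(s) in unit lengths, `>= 1`.
#' @param alpha folding parameter, `> 1`.
#' @return probabilities in `(0, 1/alpha]`.
#' @export
return_probability <- function(u0, alpha) {
  if (any(u0 < 1)) stop("u0 must be >= 1")
  if (alpha <= 1) stop("alpha must be > 1")
  u0^(-alpha) / alpha
}

#' Sample forward-jump lengths
#'
#' Draws from the jump-length density `(alpha+1) * U^-(alpha+2)` for
#' `U > 1`, truncated to `[1, u_max]` by rejection resampling.  The
#' untruncated inverse CDF is `U = (1 - u)^(-1/(alpha+1))`.
#'
#' @param n number of draws.
#' @param alpha folding parameter, `> 1`.
#' @param u_max local cutoff in unit lengths (`Inf` disables truncation).
#' @return numeric vector of lengths in unit lengths.
#' @seealso [jump_length_quantile()], [jump_length_cdf()]
#' @export
sample_jump_length <- function(n, alpha, u_max = 100) {
  if (alpha <= 1) stop("alpha must be > 1")
  if (u_max <= 1) stop("u_max must be > 1")
  out <- numeric(0)
  while (length(out) < n) {
    u <- jump_length_quantile(runif(n - length(out)), alpha)
    out <- c(out, u[u <= u_max])
  }
  out
}

#' Quantile function of the untruncated jump-length law
#' @param p probabilities in `[0, 1)`.
#' @param alpha folding parameter.
#' @return jump lengths `(1 - p)^(-1/(alpha+1))`.
#' @export
jump_length_quantile <- function(p, alpha) (1 - p)^(-1 / (alpha + 1))

#' CDF of the jump-length law, optionally truncated
#' @param q lengths in unit lengths.
#' @param alpha folding parameter.
#' @param u_max truncation point (`Inf` for the untruncated law).
#' @return cumulative probabilities.
#' @export
jump_length_cdf <- function(q, alpha, u_max = Inf) {
  p <- ifelse(q < 1, 0, 1 - pmin(q, u_max)^(-(alpha + 1)))
  if (is.finite(u_max)) p <- p / (1 - u_max^(-(alpha + 1)))
  pmin(p, 1)
}

#' Generate a self-returning random walk
#'
#' Runs the SRRW under the return rules: at each step, with probability
#' [return_probability()] of the top-of-stack backbone step the walk
#' exactly reverses that step (stack pop); otherwise it takes a forward
#' jump with length from [sample_jump_length()] and uniform random
#' direction (stack push).  Forward jumps ending outside the confinement
#' sphere of radius `rc` around the running center of mass of the
#' already-generated nodes are rejected and fully resampled.  Returns
#' are always accepted.  Deterministic given `params$seed`.
#'
#' @param params a [walk_params()] object.
#' @param returns_enabled set `FALSE` to disable returns entirely
#'   (plain random flight; used by scaling oracles).
#' @param confine set `FALSE` to disable the global cutoff.
#' @param max_retries rejection budget per forward step.
#' @return an object of class `srev_walk` with elements
#'   `positions` (n_beads x 3, unit lengths), `is_return` (per step),
#'   `step_lengths` (per step, unit lengths), `site_id` (per bead,
#'   0-based distinct-site label matched by stack identity),
#'   `site_multiplicity` (visits per distinct site) and `params`.
#' @export
generate_walk <- function(params, returns_enabled = TRUE, confine = TRUE,
                          max_retries = 10000L) {
  stopifnot(inherits(params, "srev_walk_params"))
  set.seed(params$seed)
  raw <- srrw_generate_cpp(params$n_beads - 1L, params$alpha,
                           params$rc / params$unit_length, params$u_max,
                           returns_enabled, confine, max_retries)
  structure(list(positions = raw$positions,
                 is_return = raw$is_return,
                 step_lengths = raw$step_lengths,
                 site_id = raw$site_id,
                 site_multiplicity = tabulate(raw$site_id + 1L, raw$n_sites),
                 params = params),
            class = "srev_walk")
}

#' Fraction of return steps in a walk
#'
#' @param walk an `srev_walk`.
#' @return `count(return steps) / count(all steps)`, in `[0, 1)`.
#' @export
return_fraction <- function(walk) {
  stopifnot(inherits(walk, "srev_walk"))
  if (length(walk$is_return) < 1) stop("walk has no steps")
  mean(walk$is_return)
}

#' @export
print.srev_walk <- function(x, ...) {
  cat(sprintf("SRRW: %d beads, alpha = %.3f, rc = %g nm, %.1f%% returns\n",
              nrow(x$positions), x$params$alpha, x$params$rc,
              100 * mean(x$is_return)))
  invisible(x)
}
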