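#' Per-configuration pair statistics vs genomic distance
#'
#' Stratified pair subsampling: for every log-spaced bin of genomic
#' separation `s`, up to `pairs_per_bin` bead pairs are drawn at random
#' (uniform bead, uniform side, uniform partner within the bin) and
#' their squared 3D distance and contact status (`< cutoff` nm)
#' accumulated.  Unbiased per bin and far cheaper than full pair
#' enumeration at large `N`.
#'
#' @param chain an `srev_chain`.
#' @param map the matching `srev_genomic_map`.
#' @param edges genomic-distance bin edges in bp (see [log_bins()]).
#' @param pairs_per_bin pairs sampled per bin.
#' @param cutoff contact cutoff in nm.
#' @return list with per-bin `sum_r2`, `n`, `n_contact`.
#' @export
pair_curve_stats <- function(chain, map, edges, pairs_per_bin = 2000L,
                             cutoff = 35) {
  stopifnot(inherits(chain, "srev_chain"), inherits(map, "srev_genomic_map"))
  curve_pairs_cpp(chain$positions, as.numeric(map$s), as.numeric(edges),
                  as.integer(pairs_per_bin), cutoff)
}

# shared driver for the two ensemble curves
ensemble_pair_curves <- function(chains, maps, edges, pairs_per_bin, cutoff,
                                 seed = NULL) {
  if (inherits(chains, "srev_chain")) {
    chains <- list(chains)
    maps <- list(maps)
  }
  stopifnot(length(chains) == length(maps), length(chains) >= 1)
  if (!is.null(seed)) set.seed(seed)
  nb <- length(edges) - 1
  sum_r2 <- n <- n_contact <- numeric(nb)
  for (k in seq_along(chains)) {
    st <- pair_curve_stats(chains[[k]], maps[[k]], edges, pairs_per_bin, cutoff)
    sum_r2 <- sum_r2 + st$sum_r2
    n <- n + st$n
    n_contact <- n_contact + st$n_contact
  }
  mid <- sqrt(edges[-1] * edges[-length(edges)])
  list(mid = mid, sum_r2 = sum_r2, n = n, n_contact = n_contact)
}

#' Ensemble end-to-end distance vs genomic distance
#'
#' Root mean squared 3D distance between bead pairs as a function of
#' their genomic separation, pooled over an ensemble of configurations.
#' Empty bins are reported as `NA`.
#'
#' @param chains a single `srev_chain` or a list of them.
#' @param maps the matching genomic map(s).
#' @param edges genomic bin edges in bp.
#' @param pairs_per_bin pairs sampled per bin per configuration.
#' @param seed optional seed for the pair subsampling.
#' @return curve table with `mid` (bp), `value` (`sqrt(<R^2(s)>)`, nm), `n`.
#' @export
end_to_end_curve <- function(chains, maps,
                             edges = log_bins(300, 3e7, 20),
                             pairs_per_bin = 2000L, seed = NULL) {
  acc <- ensemble_pair_curves(chains, maps, edges, pairs_per_bin,
                              cutoff = 0, seed = seed)
  curve_table(acc$mid, ifelse(acc$n > 0, sqrt(acc$sum_r2 / acc$n), NA_real_),
              acc$n)
}

#' Ensemble contact probability vs genomic distance
#'
#' Fraction of sampled bead pairs at genomic separation `s` whose 3D
#' distance is below `cutoff` (default 35 nm), pooled over the ensemble.
#'
#' @inheritParams end_to_end_curve
#' @param cutoff contact cutoff in nm.
#' @return curve table with `mid` (bp), `value` (`<Cp(s)>`), `n`.
#' @export
contact_curve <- function(chains, maps, cutoff = 35,
                          edges = log_bins(300, 3e7, 20),
                          pairs_per_bin = 2000L, seed = NULL) {
  stopifnot(cutoff > 0)
  acc <- ensemble_pair_curves(chains, maps, edges, pairs_per_bin,
                              cutoff = cutoff, seed = seed)
  curve_table(acc$mid, ifelse(acc$n > 0, acc$n_contact / acc$n, NA_real_),
              acc$n)
}

#' Flory exponent from an end-to-end curve
#'
#' Log-log slope of `sqrt(<R^2(s)>)` against `s` over a genomic window.
#' The intra-domain regime is `[1e3, 4e4]` bp and the inter-domain
#' regime `[4e4, 1e6]` bp, with the transition near `s ~ 4e4` bp.
#'
#' @param curve an end-to-end curve table.
#' @param window genomic fit window in bp.
#' @return the Flory exponent nu.
#' @export
fit_flory <- function(curve, window = c(1e3, 4e4)) fit_loglog(curve, window)

#' Contact-probability scaling exponent
#'
#' Log-log slope `S` of `<Cp(s)>` over a genomic window.  Intra-domain
#' windows give `S > -1`; inter-domain windows fluctuate around `-1`.
#'
#' @param curve a contact curve table.
#' @param window genomic fit window in bp.
#' @return the slope `S`.
#' @export
contact_slope <- function(curve, window = c(4e4, 1e6)) fit_loglog(curve, window)

#' Standard genomic fit windows
#' @return named list with `intra` (`[1e3, 4e4]` bp) and `inter`
#'   (`[4e4, 1e6]` bp) windows.
#' @export
genomic_windows <- function() list(intra = c(1e3, 4e4), inter = c(4e4, 1e6))
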