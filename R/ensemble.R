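#' Ensemble run configuration
#'
#' Describes a set of simulation conditions (alpha x phi), a replicate
#' count and the seeding scheme.  Per-replicate seeds are
#' `base_seed + 1000 * condition_index + replicate`, so any replicate
#' can be regenerated in isolation.  `n_beads` defaults to
#' [beads_for_phi()] for each condition but accepts explicit overrides
#' (e.g. a published bead count whose rounding convention differs).
#'
#' @param conditions data.frame with columns `alpha` and `phi`, and
#'   optionally `n_beads` overrides.
#' @param replicates configurations per condition (default 1000, the
#'   full production ensemble size; scale down for desk use).
#' @param rc confinement radius in nm.  Use `rescale_rc = TRUE` to
#'   instead derive `rc` per condition from `n_beads` so that `phi` is
#'   preserved at reduced system sizes.
#' @param n_beads single bead-count override applied to all conditions
#'   (used together with `rescale_rc`).
#' @param rescale_rc derive `rc` from `n_beads` and `phi` per condition.
#' @param ro bead radius (nm).
#' @param base_seed base RNG seed.
#' @param relax relaxation settings ([relax_config()]).
#' @return object of class `srev_run_config`.
#' @export
run_config <- function(conditions, replicates = 1000L, rc = 650,
                       n_beads = NULL, rescale_rc = FALSE, ro = 4.9,
                       base_seed = 1L, relax = relax_config()) {
  stopifnot(is.data.frame(conditions), nrow(conditions) >= 1,
            all(c("alpha", "phi") %in% names(conditions)), replicates >= 1)
  if (!is.null(n_beads)) conditions$n_beads <- as.integer(n_beads)
  if (is.null(conditions$n_beads))
    conditions$n_beads <- beads_for_phi(conditions$phi, rc, ro)
  conditions$rc <- if (rescale_rc)
    rc_for_phi(conditions$phi, conditions$n_beads, ro) else rc
  structure(list(conditions = conditions,
                 replicates = as.integer(replicates), ro = ro,
                 base_seed = as.integer(base_seed), relax = relax),
            class = "srev_run_config")
}

#' Apply a function over every configuration of an ensemble
#'
#' Streams through `conditions x replicates`: for each slot a walk is
#' generated, expanded and relaxed, genomic coordinates are assigned,
#' and `fun(chain, map, condition, replicate)` is called; only its
#' return value is retained, so arbitrarily large ensembles run in
#' bounded memory.  Failed replicates are skipped with a warning; the
#' run errors if more than 5 % fail.
#'
#' @param config an `srev_run_config`.
#' @param fun function of `(chain, map, condition, replicate)`.
#' @return list of lists: `result[[condition]][[replicate]]`.
#' @export
ensemble_apply <- function(config, fun) {
  stopifnot(inherits(config, "srev_run_config"))
  cond <- config$conditions
  out <- vector("list", nrow(cond))
  failed <- 0L
  total <- nrow(cond) * config$replicates
  for (ci in seq_len(nrow(cond))) {
    out[[ci]] <- vector("list", config$replicates)
    for (rep in seq_len(config$replicates)) {
      seed <- config$base_seed + 1000L * ci + rep
      res <- tryCatch({
        chain <- sr_ev_chain(cond$alpha[ci], n_beads = cond$n_beads[ci],
                             rc = cond$rc[ci], seed = seed, ro = config$ro,
                             config = config$relax)
        fun(chain, assign_linkers(chain), cond[ci, ], rep)
      }, error = function(e) {
        warning(sprintf("condition %d replicate %d failed: %s",
                        ci, rep, conditionMessage(e)))
        failed <<- failed + 1L
        NULL
      })
      out[[ci]][[rep]] <- res
    }
  }
  if (failed > 0.05 * total)
    stop(sprintf("%d of %d replicates failed", failed, total))
  out
}

#' Run an ensemble and collect summary tables
#'
#' Generates every configuration of the run, optionally keeps the
#' chains, and returns a per-replicate summary table (bead count, seed,
#' relaxation iterations, mean linker bp, total bp, radius of
#' gyration).  Fully reproducible from the config.
#'
#' @param config an `srev_run_config`.
#' @param keep_chains retain the chains (and maps) in the result; turn
#'   off for large runs.
#' @param out_dir optional directory: chains are saved as
#'   `chain_<condition>_<replicate>.rds` and the summary as
#'   `summary.csv`.
#' @return list with `summary` (data.frame) and, when kept, `chains`
#'   and `maps` (nested lists).
#' @export
run_ensemble <- function(config, keep_chains = TRUE, out_dir = NULL) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- list()
  chains <- list()
  maps <- list()
  res <- ensemble_apply(config, function(chain, map, condition, rep) {
    row <- data.frame(alpha = condition$alpha, phi = condition$phi,
                      replicate = rep, n_beads = nrow(chain$positions),
                      rc = condition$rc,
                      seed = config$base_seed +
                        1000L * as.integer(rownames(condition)) + rep,
                      relax_iterations = chain$relax_iterations,
                      mean_linker_bp = mean_linker(map),
                      total_bp = map$total_bp,
                      rg = radius_of_gyration(chain))
    if (!is.null(out_dir))
      saveRDS(list(chain = chain, map = map),
              file.path(out_dir, sprintf("chain_a%.2f_phi%.2f_r%03d.rds",
                                         condition$alpha, condition$phi, rep)))
    list(row = row, chain = if (keep_chains) chain,
         map = if (keep_chains) map)
  })
  for (ci in seq_along(res)) {
    chains[[ci]] <- lapply(res[[ci]], `[[`, "chain")
    maps[[ci]] <- lapply(res[[ci]], `[[`, "map")
    rows <- c(rows, lapply(res[[ci]], `[[`, "row"))
  }
  summary <- do.call(rbind, rows)
  if (!is.null(out_dir))
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  out <- list(summary = summary, config = config)
  if (keep_chains) {
    out$chains <- chains
    out$maps <- maps
  }
  out
}
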