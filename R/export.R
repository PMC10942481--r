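#' Export a chain to a coordinate file
#'
#' Supported formats: `"xyz"` (N + comment header, one `C x y z` line
#' per bead, nm), `"pdb"` (one pseudo-atom per bead, sequential residue
#' numbers, nm scaled to Angstrom), `"csv"` (positions in nm plus
#' per-bond linker bp when a genomic map is given; round-trips with
#' [read_chain_csv()]).
#'
#' @param chain an `srev_chain`.
#' @param file output path.
#' @param map optional `srev_genomic_map` (adds linker bp to CSV).
#' @param format one of `"xyz"`, `"pdb"`, `"csv"`.
#' @return `file`, invisibly.
#' @export
export_chain <- function(chain, file, map = NULL,
                         format = c("xyz", "pdb", "csv")) {
  stopifnot(inherits(chain, "srev_chain"))
  format <- tryCatch(match.arg(format),
                     error = function(e)
                       stop("unknown format; supported: xyz, pdb, csv"))
  pos <- chain$positions
  n <- nrow(pos)
  if (format == "xyz") {
    header <- sprintf("SR-EV chain alpha=%g rc=%g ro=%g (nm)",
                      chain$alpha, chain$rc, chain$ro)
    writeLines(c(as.character(n), header,
                 sprintf("C %.4f %.4f %.4f", pos[, 1], pos[, 2], pos[, 3])),
               file)
  } else if (format == "pdb") {
    # nm -> Angstrom x10; one CA pseudo-atom per nucleosome
    bio3d::write.pdb(file = file, xyz = as.vector(t(pos)) * 10,
                     resno = seq_len(n), resid = rep("NUC", n),
                     eleno = seq_len(n), elety = rep("CA", n),
                     chain = rep("A", n))
  } else {
    df <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3])
    if (!is.null(map)) df$linker_bp <- c(map$linker_bp, NA)
    write.csv(df, file, row.names = FALSE)
  }
  invisible(file)
}

#' Read a chain written by `export_chain(format = "csv")`
#'
#' @param file CSV path.
#' @param ro,rc,alpha chain metadata not stored in the CSV.
#' @return an `srev_chain` (marked relaxed; rest lengths are the stored
#'   bond lengths).
#' @export
read_chain_csv <- function(file, ro = 4.9, rc = 650, alpha = NA_real_) {
  df <- read.csv(file)
  pos <- as.matrix(df[, c("x", "y", "z")])
  dimnames(pos) <- NULL
  chain <- structure(list(positions = pos, rest_lengths = NULL, ro = ro,
                          rc = rc, alpha = alpha, relaxed = TRUE,
                          relax_iterations = NA_integer_),
                     class = "srev_chain")
  chain$rest_lengths <- pmax(bond_lengths(chain), 2 * ro)
  chain
}

#' Read an XYZ file written by `export_chain(format = "xyz")`
#' @inheritParams read_chain_csv
#' @return an `srev_chain`.
#' @export
read_chain_xyz <- function(file, ro = 4.9, rc = 650, alpha = NA_real_) {
  lines <- readLines(file)
  n <- as.integer(lines[1])
  parts <- do.call(rbind, strsplit(trimws(lines[3:(n + 2)]), "\\s+"))
  pos <- matrix(as.numeric(parts[, 2:4]), ncol = 3)
  chain <- structure(list(positions = pos, rest_lengths = NULL, ro = ro,
                          rc = rc, alpha = alpha, relaxed = TRUE,
                          relax_iterations = NA_integer_),
                     class = "srev_chain")
  chain$rest_lengths <- pmax(bond_lengths(chain), 2 * ro)
  chain
}
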