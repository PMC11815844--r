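# Kyte-Doolittle hydropathy scale (original publication values)
.kd_scale <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L ||
      !nzchar(sequence)) {
    stop("`sequence` must be a single non-empty string")
  }
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(aa), names(.kd_scale))
  if (length(bad)) {
    stop("invalid residue(s): ", paste(bad, collapse = ", "))
  }
  aa
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of the Kyte-Doolittle hydropathy values over the
#' residues of a one-letter sequence. Negative scores mean hydrophilic,
#' positive hydrophobic; values lie in [-4.5, 4.5]. Report rounded to
#' two decimals for presentation.
#'
#' @param sequence One-letter amino-acid string (20 standard residues).
#' @return The GRAVY score (unrounded).
#' @export
#' @examples
#' gravy("RRRRRRRRR")          # -4.5, nona-arginine
#' round(gravy("PLIYLRLLRGQWC"), 2)
gravy <- function(sequence) {
  mean(.kd_scale[check_sequence(sequence)])
}

#' Formal net charge at neutral pH
#'
#' Integer formal-charge model: +1 per K/R, -1 per D/E, histidine
#' neutral. Zwitterionic termini (+1 amino, -1 carboxyl) cancel, so
#' including them does not change the total; fractional pKa-based
#' charges are deliberately out of scope.
#'
#' @param sequence One-letter amino-acid string.
#' @param include_termini Include the (mutually cancelling) zwitterionic
#'   termini.
#' @return Integer net charge in elementary-charge units.
#' @export
#' @examples
#' net_charge("RRRRRRRRR") # +9
net_charge <- function(sequence, include_termini = TRUE) {
  aa <- check_sequence(sequence)
  q <- sum(aa %in% c("K", "R")) - sum(aa %in% c("D", "E"))
  if (include_termini) q <- q + 1L - 1L
  as.integer(q)
}

#' Registry of the study peptides
#'
#' Bundled records of the five cell-penetrating peptides (one
#' representative per class plus two reference entries), with declared
#' descriptor values and recomputed GRAVY / net charge for
#' cross-checking. The K-FGF entry declares length 17 but carries a
#' 16-residue sequence; the printed sequence is stored as-is and the
#' mismatch flagged in `length_matches` rather than guessed around.
#'
#' @return Data frame with one row per peptide: `name`,
#'   `declared_length`, `sequence`, `declared_type`,
#'   `declared_net_charge`, `declared_gravy`, `net_charge`, `gravy`
#'   (recomputed, 2 dp), `length_matches`.
#' @export
#' @examples
#' peptide_registry()[, c("name", "net_charge", "gravy")]
peptide_registry <- function() {
  reg <- data.frame(
    name = c("Arg9", "MAP", "TP10", "TP2", "K-FGF"),
    declared_length = c(9L, 18L, 21L, 13L, 17L),
    sequence = c("RRRRRRRRR", "KLALKLALKALKAALKLA",
                 "AGYLLGKINLKALAALAKKIL", "PLIYLRLLRGQWC",
                 "AAVALLPAVLLALLAP"),
    declared_type = c("cationic", "amphipathic", "amphipathic",
                      "hydrophobic", "hydrophobic"),
    declared_net_charge = c(9L, 5L, 4L, 2L, 0L),
    declared_gravy = c(-4.5, 0.99, 0.93, 0.42, 2.42)
  )
  reg$net_charge <- vapply(reg$sequence, net_charge, integer(1),
                           USE.NAMES = FALSE)
  reg$gravy <- round(vapply(reg$sequence, gravy, numeric(1),
                            USE.NAMES = FALSE), 2)
  reg$length_matches <- nchar(reg$sequence) == reg$declared_length
  reg
}

#' Descriptor table for arbitrary peptides
#'
#' @param peptides Named character vector of sequences, or a data frame
#'   with `name` and `sequence` (e.g. from [read_fasta_peptides()]).
#' @return Data frame with `name`, `sequence`, `length`, `net_charge`,
#'   `gravy` (2 dp).
#' @export
peptide_descriptors <- function(peptides) {
  if (is.data.frame(peptides)) {
    nm <- peptides$name
    sq <- peptides$sequence
  } else {
    nm <- names(peptides) %||% paste0("peptide", seq_along(peptides))
    sq <- unname(peptides)
  }
  data.frame(
    name = nm, sequence = sq, length = nchar(sq),
    net_charge = vapply(sq, net_charge, integer(1), USE.NAMES = FALSE),
    gravy = round(vapply(sq, gravy, numeric(1), USE.NAMES = FALSE), 2)
  )
}
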