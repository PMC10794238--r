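#' @keywords internal
"_PACKAGE"

## Canonical one-letter alphabet used throughout; the gap symbol is "-".
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP <- "-"

## Ambiguous / non-standard codes normalized to gap on input.
AMBIGUOUS_CODES <- c("B", "Z", "X", "U", "O", "J", "*", ".")

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "tcsevol")
  if (!nzchar(path)) {
    # during in-source development (pkgload) extdata sits under inst/
    path <- system.file("inst", "extdata", file, package = "tcsevol")
  }
  if (!nzchar(path)) stop("packaged table not found: ", file)
  path
}

#' Packaged background amino-acid frequencies
#'
#' Average amino-acid composition of proteins in a large non-redundant
#' database, used as the reference distribution \eqn{q^a} for the
#' relative-entropy conservation \eqn{C_i} and the coupling coefficients
#' \eqn{k_i^a}. The shipped table is a documented stand-in and is
#' renormalized to sum exactly to 1.
#'
#' @return Named numeric vector of length 20 over [AA_ALPHABET] order.
#' @export
background_frequencies <- function() {
  tab <- utils::read.delim(.extdata("background_frequencies.tsv"),
                           comment.char = "#", stringsAsFactors = FALSE)
  q <- tab$freq[match(AA_ALPHABET, tab$aa)]
  if (anyNA(q)) stop("background table is missing amino acids")
  q <- q / sum(q)
  stats::setNames(q, AA_ALPHABET)
}

#' Packaged hydrophobicity classification
#'
#' @return Character vector of the amino acids classified as hydrophobic.
#' @export
hydrophobic_residues <- function() {
  tab <- utils::read.delim(.extdata("hydrophobicity.tsv"),
                           comment.char = "#", stringsAsFactors = FALSE)
  sort(tab$aa[tab$hydrophobic == 1])
}

#' Miyazawa-Jernigan contact-energy model
#'
#' Loads the packaged 20x20 residue-residue contact-energy table
#' (Miyazawa-Jernigan statistical potential, RT units; attractive contacts
#' are negative). Stored as the upper half plus diagonal and completed by
#' symmetry.
#'
#' @param path Optional path to an alternative three-column
#'   (aa1, aa2, energy) table.
#' @return An object of class `energy_model`: list with `table` (symmetric
#'   20x20 named matrix) and `provenance`.
#' @export
mj_energy_model <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("mj1996_contact_energies.tsv")
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  m <- matrix(NA_real_, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (r in seq_len(nrow(tab))) {
    m[tab$aa1[r], tab$aa2[r]] <- tab$energy[r]
    m[tab$aa2[r], tab$aa1[r]] <- tab$energy[r]
  }
  if (anyNA(m)) stop("contact-energy table incomplete: all 210 independent ",
                     "entries are required")
  structure(list(table = m, provenance = basename(path)),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> 20x20 contact energies (", x$provenance, ")\n",
      sep = "")
  cat("  range [", min(x$table), ", ", max(x$table), "] RT\n", sep = "")
  invisible(x)
}
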