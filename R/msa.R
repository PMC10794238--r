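## Paired HK/RR alignment: reading, writing, filtering, indexing.

#' Construct a paired alignment object
#'
#' Container for an aligned set of concatenated HK(DHp)/RR(Rec) sequence
#' pairs. Columns are indexed 0-based half-open internally; `domain_ranges`
#' must be disjoint and cover all columns.
#'
#' @param seqs Character matrix (sequences x columns) over the 20 amino
#'   acids plus the gap symbol `-`.
#' @param ids Character vector of sequence identifiers.
#' @param domain_ranges Named list of integer pairs `c(start, end)`
#'   (0-based, half-open) partitioning the columns.
#' @param removed_columns Integer vector of original column indices removed
#'   by filtering (0-based).
#' @param ambiguous_count Number of ambiguous residue codes normalized to
#'   gap on input.
#' @return Object of class `paired_alignment`.
#' @export
paired_alignment <- function(seqs, ids, domain_ranges,
                             removed_columns = integer(),
                             ambiguous_count = 0L) {
  stopifnot(is.matrix(seqs), is.character(seqs))
  if (nrow(seqs) == 0L) stop("empty alignment")
  if (length(ids) != nrow(seqs)) stop("ids/sequence count mismatch")
  bad <- !(seqs %in% c(AA_ALPHABET, GAP))
  if (any(bad)) stop("alignment contains non-canonical symbols: ",
                     paste(unique(seqs[bad]), collapse = ", "))
  .check_domain_ranges(domain_ranges, ncol(seqs))
  structure(list(seqs = seqs, ids = as.character(ids),
                 column_count = ncol(seqs),
                 domain_ranges = domain_ranges,
                 removed_columns = as.integer(removed_columns),
                 ambiguous_count = as.integer(ambiguous_count)),
            class = "paired_alignment")
}

.check_domain_ranges <- function(domain_ranges, n_col) {
  if (length(domain_ranges) == 0L) stop("domain_ranges must be non-empty")
  cov <- integer(0)
  for (r in domain_ranges) {
    if (length(r) != 2L || r[1] < 0 || r[2] > n_col || r[1] >= r[2])
      stop("domain range out of bounds or empty")
    cov <- c(cov, seq.int(r[1], r[2] - 1L))
  }
  if (anyDuplicated(cov)) stop("domain ranges overlap")
  if (!setequal(cov, 0:(n_col - 1L)))
    stop("domain ranges must cover all ", n_col, " columns")
  invisible(TRUE)
}

#' @export
print.paired_alignment <- function(x, ...) {
  rng <- vapply(names(x$domain_ranges), function(d)
    sprintf("%s=[%d,%d)", d, x$domain_ranges[[d]][1],
            x$domain_ranges[[d]][2]), "")
  cat("<paired_alignment> ", nrow(x$seqs), " sequences x ",
      x$column_count, " columns (", paste(rng, collapse = ", "), ")\n",
      sep = "")
  if (length(x$removed_columns))
    cat("  filtered columns:", length(x$removed_columns), "\n")
  invisible(x)
}

#' Columns belonging to one domain
#'
#' @param aln A `paired_alignment`.
#' @param domain Domain name (e.g. "DHp", "Rec").
#' @return 1-based column indices of the domain within the alignment.
#' @export
domain_columns <- function(aln, domain) {
  r <- aln$domain_ranges[[domain]]
  if (is.null(r)) stop("unknown domain: ", domain)
  seq.int(r[1] + 1L, r[2])
}

#' Read a paired alignment from aligned FASTA
#'
#' All records must have identical aligned length. Lower-case letters are
#' upper-cased; ambiguous or non-standard residue codes (B, Z, X, U, O, J,
#' `*`, `.`) are normalized to the gap symbol and counted.
#'
#' @param path Aligned-FASTA file.
#' @param domain_ranges Named list of 0-based half-open column intervals
#'   (e.g. `list(DHp = c(0, 62), Rec = c(62, 172))`).
#' @return A [paired_alignment()].
#' @export
read_paired_alignment <- function(path, domain_ranges) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("alignment-format error: ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("input error: empty alignment file")
  w <- Biostrings::width(set)
  if (length(unique(w)) != 1L)
    stop("alignment-format error: ragged alignment (lengths ",
         paste(sort(unique(w)), collapse = ", "), ")")
  chars <- toupper(as.character(set))
  m <- matrix(unlist(strsplit(chars, ""), use.names = FALSE),
              nrow = length(set), byrow = TRUE)
  amb <- m %in% AMBIGUOUS_CODES
  n_amb <- sum(amb)
  m[amb] <- GAP
  if (n_amb > 0)
    message("normalized ", n_amb, " ambiguous residue codes to gap")
  paired_alignment(m, names(set) %||% paste0("seq", seq_len(nrow(m))),
                   domain_ranges, ambiguous_count = n_amb)
}

#' Write a paired alignment to aligned FASTA
#'
#' @param aln A `paired_alignment`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_paired_alignment <- function(aln, path) {
  seqs <- apply(aln$seqs, 1L, paste0, collapse = "")
  set <- Biostrings::BStringSet(stats::setNames(seqs, aln$ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Filter a paired alignment by gap content
#'
#' Sequences whose overall gap fraction exceeds `max_seq_gap_frac` are
#' removed first; then, on the surviving sequences, columns whose gap
#' fraction exceeds `max_col_gap_frac` are removed. Domain ranges are
#' re-indexed to the retained columns and the original indices of dropped
#' columns recorded.
#'
#' @param aln A `paired_alignment`.
#' @param max_seq_gap_frac Maximum tolerated per-sequence gap fraction
#'   (default 0.2).
#' @param max_col_gap_frac Maximum tolerated per-column gap fraction
#'   (default 0.5).
#' @param drop_columns Optional extra 0-based original column indices to
#'   drop unconditionally (e.g. columns gapped in the reference complex
#'   structure).
#' @return Filtered `paired_alignment`.
#' @export
filter_alignment <- function(aln, max_seq_gap_frac = 0.2,
                             max_col_gap_frac = 0.5,
                             drop_columns = integer()) {
  stopifnot(max_seq_gap_frac >= 0, max_seq_gap_frac <= 1,
            max_col_gap_frac >= 0, max_col_gap_frac <= 1)
  gaps <- aln$seqs == GAP
  seq_frac <- rowMeans(gaps)
  keep_seq <- seq_frac <= max_seq_gap_frac
  if (!any(keep_seq)) stop("empty-alignment error: all sequences removed")
  sub <- aln$seqs[keep_seq, , drop = FALSE]
  col_frac <- colMeans(sub == GAP)
  keep_col <- col_frac <= max_col_gap_frac
  keep_col[drop_columns + 1L] <- FALSE
  if (!any(keep_col)) stop("empty-alignment error: all columns removed")

  # original 0-based index of each current column
  orig <- .original_columns(aln)
  removed <- sort(c(aln$removed_columns, orig[!keep_col]))

  new_ranges <- list()
  for (d in names(aln$domain_ranges)) {
    r <- aln$domain_ranges[[d]]
    in_dom <- seq_len(aln$column_count) - 1L >= r[1] &
      seq_len(aln$column_count) - 1L < r[2]
    n_kept <- sum(keep_col & in_dom)
    start <- if (length(new_ranges))
      new_ranges[[length(new_ranges)]][2] else 0L
    if (n_kept > 0L) new_ranges[[d]] <- c(start, start + n_kept)
  }
  paired_alignment(sub[, keep_col, drop = FALSE], aln$ids[keep_seq],
                   new_ranges, removed_columns = removed,
                   ambiguous_count = aln$ambiguous_count)
}

## Original (pre-filter) 0-based indices of the current columns.
.original_columns <- function(aln) {
  total <- aln$column_count + length(aln$removed_columns)
  setdiff(0:(total - 1L), aln$removed_columns)
}

#' Tabulate filter decisions
#'
#' Companion report for [filter_alignment()]: per-sequence and per-column
#' gap fractions with the kept/dropped flag, computed with the same
#' sequence-first ordering.
#'
#' @inheritParams filter_alignment
#' @return List of two data frames, `sequences` and `columns`.
#' @export
filter_report <- function(aln, max_seq_gap_frac = 0.2,
                          max_col_gap_frac = 0.5) {
  gaps <- aln$seqs == GAP
  seq_frac <- rowMeans(gaps)
  keep_seq <- seq_frac <= max_seq_gap_frac
  col_frac <- colMeans(gaps[keep_seq, , drop = FALSE])
  list(
    sequences = data.frame(id = aln$ids, gap_fraction = seq_frac,
                           kept = keep_seq),
    columns = data.frame(column = .original_columns(aln),
                         gap_fraction = col_frac,
                         kept = col_frac <= max_col_gap_frac)
  )
}
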