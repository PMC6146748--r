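#' Alignment parameters for the seed-and-extend aligner
#'
#' The internal nucleotide aligner seeds exact k-mer matches on both strands,
#' clusters seed diagonals, and extends each candidate diagonal with banded
#' affine-gap Smith-Waterman, returning the best-scoring local alignment.
#' A gap of length k costs `|gap_open| + k * |gap_extend|`. The band half-width
#' is `max(16, band_frac * query length)`.
#'
#' @param kmer exact-seed length (<= 16), default 15.
#' @param band_frac band half-width as a fraction of query length, default 0.2.
#' @param match,mismatch,gap_open,gap_extend alignment scores (defaults
#'   +2 / -3 / -5 / -2).
#' @param max_diagonals number of seed-diagonal clusters extended per strand.
#' @return list of class `alignment_params`.
#' @export
alignment_params <- function(kmer = 15L, band_frac = 0.2, match = 2L,
                             mismatch = -3L, gap_open = -5L, gap_extend = -2L,
                             max_diagonals = 8L) {
  abort_if(kmer < 4 || kmer > 16, "kmer must be in [4, 16]")
  abort_if(band_frac <= 0, "band_frac must be positive")
  structure(list(kmer = as.integer(kmer), band_frac = band_frac,
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 max_diagonals = as.integer(max_diagonals)),
            class = "alignment_params")
}

# batch best-local-alignment of queries against a subject (character);
# returns a data.frame with identity (%) and query coverage per query
align_batch <- function(queries, subject, params = alignment_params()) {
  r <- .cpp_align_batch(as.character(queries), subject,
                        params$kmer, params$band_frac, params$match,
                        params$mismatch, -params$gap_open,
                        -params$gap_extend, params$max_diagonals)
  qlen <- nchar(as.character(queries))
  data.frame(
    found = r$found, score = r$score,
    identity = ifelse(r$found, 100 * r$matches / r$columns, NA_real_),
    columns = r$columns,
    q_aligned = r$q_end - r$q_start,
    coverage = ifelse(r$found, (r$q_end - r$q_start) / qlen, NA_real_),
    q_start = r$q_start, q_end = r$q_end,
    s_start = r$s_start, s_end = r$s_end,
    strand = r$strand, stringsAsFactors = FALSE
  )
}

#' Align one fragment against a subject genome
#'
#' Searches both strands; seeds exact k-mers and extends with banded
#' affine-gap dynamic programming. Absence of any seeded, positive-scoring
#' extension is a valid result (`NULL`).
#'
#' @param fragment character or DNAString fragment.
#' @param subject subject genome (DNAStringSet or character contigs; contigs
#'   are joined with an N spacer so no alignment crosses a contig boundary).
#' @param params [alignment_params()].
#' @return a one-row data.frame (identity %, coverage, strand, score,
#'   0-based half-open coordinates) or `NULL` when nothing aligns.
#' @export
align_fragment <- function(fragment, subject, params = alignment_params()) {
  subject <- concat_subject(as_contigs(subject))
  res <- align_batch(as.character(fragment)[1], subject, params)
  if (!res$found[1]) return(NULL)
  res[1, setdiff(names(res), "found")]
}
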