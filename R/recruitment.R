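#' Read-recruitment parameters
#'
#' Defaults follow the recruitment convention for MAG abundance estimation:
#' ten million randomly sampled singleton reads mapped per MAG with a cutoff
#' of 95% identity over a minimum of 50 aligned bases. Identity is
#' matches / aligned columns, so gap columns count against identity.
#'
#' @param min_identity identity cutoff as a fraction (default 0.95).
#' @param min_aligned minimum alignment length in columns (default 50).
#' @param subsample_n reads subsampled per dataset (default 1e7).
#' @param mode `"independent"` maps reads onto each MAG separately (a read may
#'   count for several MAGs); `"competitive"` assigns each read to its single
#'   best-scoring MAG (ties to the lexicographically smaller id).
#' @param denominator RPKG denominator: `"mapped"` (total bases of reads
#'   recruited to at least one MAG in the dataset) or `"sampled"` (total bases
#'   of the subsampled read set).
#' @param align [alignment_params()] for the read aligner.
#' @return list of class `recruitment_params`.
#' @export
recruitment_params <- function(min_identity = 0.95, min_aligned = 50L,
                               subsample_n = 1e7,
                               mode = c("independent", "competitive"),
                               denominator = c("mapped", "sampled"),
                               align = alignment_params(max_diagonals = 4L)) {
  abort_if(min_identity <= 0 || min_identity > 1,
           "min_identity must be in (0, 1]")
  abort_if(min_aligned < 1, "min_aligned must be >= 1")
  structure(list(min_identity = min_identity,
                 min_aligned = as.integer(min_aligned),
                 subsample_n = subsample_n, mode = match.arg(mode),
                 denominator = match.arg(denominator), align = align),
            class = "recruitment_params")
}

#' Uniform subsample of a read set without replacement
#'
#' @param reads DNAStringSet.
#' @param n sample size; `n >= length(reads)` returns all reads.
#' @param seed integer seed.
#' @return DNAStringSet in original relative order.
#' @export
subsample_reads <- function(reads, n, seed = 1L) {
  abort_if(n < 0, "n must be >= 0")
  if (n >= length(reads)) return(reads)
  idx <- with_seed(seed, sort(sample.int(length(reads), n)))
  reads[idx]
}

#' Recruit reads onto one MAG
#'
#' A read is recruited iff its best local alignment to the MAG (either strand)
#' spans at least `min_aligned` columns at identity >= `min_identity`. Each
#' read is counted at most once.
#'
#' @param reads DNAStringSet.
#' @param mag genome (DNAStringSet or character contigs).
#' @param params [recruitment_params()].
#' @param details return the per-read alignment table as well.
#' @return list with `count` (recruited reads), `bases` (total length of
#'   recruited reads), `recruited` (logical per read) and, with
#'   `details = TRUE`, the alignment table.
#' @export
recruit_reads <- function(reads, mag, params = recruitment_params(),
                          details = FALSE) {
  abort_if(length(reads) == 0, "empty read set")
  subj <- concat_subject(as_contigs(mag))
  aln <- align_batch(reads, subj, params$align)
  recruited <- aln$found & !is.na(aln$identity) &
    aln$columns >= params$min_aligned &
    aln$identity >= 100 * params$min_identity
  out <- list(count = sum(recruited),
              bases = sum(Biostrings::width(reads)[recruited]),
              recruited = recruited)
  if (details) out$alignments <- aln
  out
}

#' Reads per kilobase of genome per gigabase of mapped reads
#'
#' `rpkg = count / (mag_length / 1e3) / (mapped_bases / 1e9)`. A zero mapped
#' total yields 0 with a warning.
#'
#' @param count recruited read count.
#' @param mapped_bases total mapped bases in the dataset (denominator basis).
#' @param mag_length MAG length in bases.
#' @return RPKG value.
#' @examples
#' compute_rpkg(1000, 0.5e9, 2e6)  # 1.0
#' @export
compute_rpkg <- function(count, mapped_bases, mag_length) {
  abort_if(any(mag_length <= 0), "mag_length must be positive")
  abort_if(any(mapped_bases < 0) || any(count < 0), "negative input")
  n <- max(length(count), length(mapped_bases), length(mag_length))
  count <- rep_len(count, n)
  mapped_bases <- rep_len(mapped_bases, n)
  mag_length <- rep_len(mag_length, n)
  zero <- mapped_bases == 0
  if (any(zero)) warning("mapped base total is 0; RPKG set to 0")
  out <- numeric(n)
  out[!zero] <- count[!zero] / (mag_length[!zero] / 1e3) /
    (mapped_bases[!zero] / 1e9)
  out
}

#' Abundance profile of a MAG set across read datasets
#'
#' For every dataset: subsample, recruit each read against every MAG with the
#' identity/length cutoffs, and normalise counts to RPKG with a per-dataset
#' denominator shared across MAGs.
#'
#' @param read_sets named list of DNAStringSet, one per dataset.
#' @param mags named list of genomes.
#' @param params [recruitment_params()].
#' @param seed global seed; per-dataset subsampling seeds are derived from it.
#' @return data.frame of class `abundance_profile`: dataset, mag, reads,
#'   bases, mag_length, mapped_bases, rpkg.
#' @export
profile_community <- function(read_sets, mags, params = recruitment_params(),
                              seed = 1L) {
  abort_if(length(read_sets) == 0 || length(mags) == 0,
           "need at least one dataset and one MAG")
  abort_if(is.null(names(read_sets)) || anyDuplicated(names(read_sets)) > 0,
           "dataset id collision")
  abort_if(is.null(names(mags)) || anyDuplicated(names(mags)) > 0,
           "duplicate MAG ids")
  mag_ids <- sort(names(mags))
  mag_len <- vapply(mags, function(g) sum(nchar(as_contigs(g))), numeric(1))
  rows <- list()
  for (ds in names(read_sets)) {
    reads <- subsample_reads(read_sets[[ds]], params$subsample_n,
                             seed = derive_seed(seed, paste0("subsample:", ds)))
    rlen <- Biostrings::width(reads)
    rec <- lapply(mag_ids, function(m) recruit_reads(reads, mags[[m]], params,
                                                     details = TRUE))
    names(rec) <- mag_ids
    if (params$mode == "competitive") {
      # each read kept only for its best-scoring MAG; ties -> smaller id
      score <- vapply(rec, function(r)
        ifelse(r$alignments$found, r$alignments$score, -Inf),
        numeric(length(reads)))
      if (length(reads) == 1) score <- matrix(score, nrow = 1)
      best <- max.col(replace(score, !is.finite(score), -1e18),
                      ties.method = "first")
      for (k in seq_along(mag_ids)) {
        keep <- rec[[k]]$recruited & (best == k)
        rec[[k]]$recruited <- keep
        rec[[k]]$count <- sum(keep)
        rec[[k]]$bases <- sum(rlen[keep])
      }
    }
    any_recruited <- Reduce(`|`, lapply(rec, `[[`, "recruited"))
    mapped_bases <- if (params$denominator == "mapped")
      sum(rlen[any_recruited]) else sum(rlen)
    counts <- vapply(rec, `[[`, numeric(1), "count")
    rows[[ds]] <- data.frame(
      dataset = ds, mag = mag_ids, reads = counts,
      bases = vapply(rec, `[[`, numeric(1), "bases"),
      mag_length = mag_len[mag_ids], mapped_bases = mapped_bases,
      rpkg = compute_rpkg(counts, mapped_bases, mag_len[mag_ids]),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("abundance_profile", "data.frame")
  out
}
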