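#' Parameters for fragment-based genome comparison
#'
#' The query genome is cut into consecutive non-overlapping fragments
#' (default 1020 b) and every fragment is locally aligned against the subject.
#' A fragment qualifies for the ANI mean when its best alignment has identity
#' >= `qual_identity` over >= `qual_coverage` of the fragment; conserved DNA
#' counts query bases lying in alignments at >= `condna_identity` identity.
#' The species decision uses the `ani_threshold`/`condna_threshold` pair
#' (95/69 by convention).
#'
#' @param fragment_length fragment size in bases (>= 100), default 1020.
#' @param min_fragment terminal remainders shorter than this are dropped.
#' @param qual_identity,qual_coverage fragment qualification thresholds.
#' @param condna_identity identity floor for the conserved-DNA numerator.
#' @param ani_threshold,condna_threshold species-decision thresholds (%).
#' @param align [alignment_params()].
#' @return list of class `ani_params`.
#' @export
ani_params <- function(fragment_length = 1020L, min_fragment = 100L,
                       qual_identity = 30, qual_coverage = 0.7,
                       condna_identity = 90, ani_threshold = 95,
                       condna_threshold = 69, align = alignment_params()) {
  abort_if(fragment_length < 100, "fragment_length must be >= 100")
  structure(list(fragment_length = as.integer(fragment_length),
                 min_fragment = as.integer(min_fragment),
                 qual_identity = qual_identity, qual_coverage = qual_coverage,
                 condna_identity = condna_identity,
                 ani_threshold = ani_threshold,
                 condna_threshold = condna_threshold, align = align),
            class = "ani_params")
}

#' Cut a genome into consecutive non-overlapping fragments
#'
#' Fragmentation happens within contigs only — no fragment spans a contig
#' boundary. A terminal remainder shorter than `min_fragment` (default 100 b)
#' is dropped.
#'
#' @param genome DNAStringSet or character vector of contigs.
#' @param fragment_length window size in bases (>= 100).
#' @param min_fragment minimum retained remainder length.
#' @return data.frame: contig, start, end (0-based half-open), seq.
#' @examples
#' g <- generate_genome(2500, seed = 1)
#' nrow(fragment_genome(g, 1020))  # 1020 + 1020 + 460
#' @export
fragment_genome <- function(genome, fragment_length = 1020L,
                            min_fragment = 100L) {
  abort_if(fragment_length < 100, "fragment_length must be >= 100")
  contigs <- as_contigs(genome)
  out <- lapply(names(contigs), function(id) {
    L <- nchar(contigs[[id]])
    starts <- seq.int(0L, L - 1L, by = fragment_length)
    ends <- pmin(starts + fragment_length, L)
    keep <- (ends - starts) >= min_fragment
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) return(NULL)
    data.frame(contig = id, start = starts, end = ends,
               seq = substring(contigs[[id]], starts + 1L, ends),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  abort_if(is.null(out) || nrow(out) == 0, "no fragment passes min_fragment")
  out
}

#' Fragment-based comparison of two genomes (ANI + conserved DNA)
#'
#' Computes both directional statistics of the species-delineation scheme in
#' one pass: ANI is the unweighted mean identity over qualifying fragments
#' (identity >= 30% over >= 70% of the fragment), and conserved DNA is the
#' percentage of fragmented query bases lying in alignments at >= 90%
#' identity. When no fragment qualifies, ANI is reported as 0 with flag
#' `no_homology`.
#'
#' @param query,subject genomes (DNAStringSet or character contig vectors).
#' @param params [ani_params()].
#' @param query_id,subject_id labels for the result.
#' @return object of class `ani_result`: list with `ani`, `condna`,
#'   `n_fragments`, `n_qualifying`, `decision`, `flags` and the per-fragment
#'   alignment table.
#' @export
compare_genomes <- function(query, subject, params = ani_params(),
                            query_id = "query", subject_id = "subject") {
  qc <- as_contigs(query, id = query_id)
  sc <- as_contigs(subject, id = subject_id)
  frags <- fragment_genome(qc, params$fragment_length, params$min_fragment)
  subj <- concat_subject(sc)
  aln <- align_batch(frags$seq, subj, params$align)
  flen <- nchar(frags$seq)
  qualifying <- aln$found & !is.na(aln$identity) &
    aln$identity >= params$qual_identity &
    aln$coverage >= params$qual_coverage
  n_qual <- sum(qualifying)
  flags <- character()
  if (n_qual == 0) {
    ani <- 0
    flags <- c(flags, "no_homology")
  } else {
    ani <- mean(aln$identity[qualifying])
  }
  conserved <- aln$found & !is.na(aln$identity) &
    aln$identity >= params$condna_identity
  condna <- 100 * sum(aln$q_aligned[conserved]) / sum(flen)
  condna <- min(condna, 100)
  cls <- classify_pair(ani, condna,
                       ani_threshold = params$ani_threshold,
                       condna_threshold = params$condna_threshold)
  structure(list(query = query_id, subject = subject_id,
                 ani = ani, condna = condna,
                 n_fragments = nrow(frags), n_qualifying = n_qual,
                 decision = cls$code, flags = union(flags, cls$flags),
                 fragments = cbind(frags[, c("contig", "start", "end")], aln)),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("ANI %s vs %s: %.4f%% (conDNA %.4f%%), %d/%d fragments qualify, decision %d%s\n",
              x$query, x$subject, x$ani, x$condna, x$n_qualifying,
              x$n_fragments, x$decision,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Average nucleotide identity between two genomes
#'
#' @inheritParams compare_genomes
#' @return an `ani_result` (see [compare_genomes()]).
#' @export
compute_ani <- function(query, subject, params = ani_params(),
                        query_id = "query", subject_id = "subject") {
  compare_genomes(query, subject, params, query_id, subject_id)
}

#' Conserved-DNA fraction of a query genome relative to a subject
#'
#' @inheritParams compare_genomes
#' @return conserved DNA as a percentage of the fragmented query length.
#' @export
compute_conserved_dna <- function(query, subject, params = ani_params()) {
  compare_genomes(query, subject, params)$condna
}

#' Species-delineation decision from an (ANI, conDNA) pair
#'
#' Three-way decision matrix: ANI >= 95 and conDNA >= 69 is the same species
#' (code 1); ANI >= 95 with conDNA < 69 might be the same species (code -1);
#' ANI < 95 with conDNA < 69 is a different species (code 0). The remaining
#' quadrant (ANI < 95, conDNA >= 69) is not covered by the published rule and
#' maps to 0 with flag `unspecified_quadrant`.
#'
#' @param ani ANI in percent, `[0, 100]`.
#' @param condna conserved DNA in percent, `[0, 100]`.
#' @param ani_threshold,condna_threshold decision thresholds (95 and 69).
#' @return list with integer `code` (1, -1 or 0) and character `flags`.
#' @examples
#' classify_pair(96, 75)$code  # 1: same species
#' classify_pair(96, 60)$code  # -1: might be same species
#' classify_pair(90, 50)$code  # 0: different species
#' @export
classify_pair <- function(ani, condna, ani_threshold = 95,
                          condna_threshold = 69) {
  abort_if(!is.finite(ani) || ani < 0 || ani > 100,
           "ani must be in [0, 100]")
  abort_if(!is.finite(condna) || condna < 0 || condna > 100,
           "condna must be in [0, 100]")
  flags <- character()
  if (ani >= ani_threshold) {
    code <- if (condna >= condna_threshold) 1L else -1L
  } else {
    code <- 0L
    if (condna >= condna_threshold) flags <- "unspecified_quadrant"
  }
  list(code = code, flags = flags)
}

#' All-against-all ANI, conserved-DNA and decision matrices
#'
#' Fragment-based ANI is directional, so every ordered pair is computed.
#' Diagonals are fixed at (100, 100, 1).
#'
#' @param genomes named list of genomes (>= 2, unique ids).
#' @param params [ani_params()].
#' @return list of three square matrices: `ani`, `condna`, `decision`
#'   (rows = query, columns = subject).
#' @export
pairwise_matrices <- function(genomes, params = ani_params()) {
  abort_if(length(genomes) < 2, "need at least 2 genomes")
  ids <- names(genomes)
  abort_if(is.null(ids) || anyDuplicated(ids) > 0, "duplicate genome ids")
  n <- length(ids)
  ani <- matrix(100, n, n, dimnames = list(ids, ids))
  condna <- matrix(100, n, n, dimnames = list(ids, ids))
  decision <- matrix(1L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    r <- compare_genomes(genomes[[i]], genomes[[j]], params,
                         query_id = ids[i], subject_id = ids[j])
    ani[i, j] <- r$ani
    condna[i, j] <- r$condna
    decision[i, j] <- r$decision
  }
  list(ani = ani, condna = condna, decision = decision)
}
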