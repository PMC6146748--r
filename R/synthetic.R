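#' Generate a random genome with a target GC content
#'
#' Bases are drawn i.i.d. with `P(G) + P(C) = gc` (G and C equiprobable, A and
#' T equiprobable), so the realised GC fraction is binomial around the target.
#' Deterministic for a fixed seed; the caller's RNG state is not disturbed.
#'
#' @param length genome length in bases (positive integer).
#' @param gc target GC fraction in `[0, 1]`.
#' @param id sequence id used as the FASTA record name.
#' @param seed integer seed.
#' @return a [Biostrings::DNAStringSet] with one record named `id`.
#' @examples
#' g <- generate_genome(1000, gc = 0.5, id = "mock", seed = 1)
#' @export
generate_genome <- function(length, gc = 0.5, id = "genome", seed = 1L) {
  abort_if(!is.numeric(length) || length < 1 || length != round(length),
           "length must be a positive integer")
  abort_if(!is.numeric(gc) || gc < 0 || gc > 1, "gc must be in [0, 1]")
  seq <- with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
  })
  out <- Biostrings::DNAStringSet(seq)
  names(out) <- id
  out
}

#' Mutate a genome at given substitution and indel rates
#'
#' Each site is substituted independently with probability `sub_rate`, always
#' to one of the three alternative bases (uniformly, no transition bias).
#' Indel events are seeded per site with probability `indel_rate`; event
#' lengths are geometric with mean `indel_mean` and insertions/deletions are
#' equiprobable, keeping expected length drift near zero. With
#' `indel_rate = 0` coordinates are preserved (the per-site alignment is the
#' identity), which is what makes direct per-site divergence oracles possible.
#'
#' @param genome a [Biostrings::DNAStringSet] or character vector of contigs.
#' @param sub_rate substitutions per site in `[0, 1)`.
#' @param indel_rate indel events per site in `[0, 1)`.
#' @param seed integer seed.
#' @param indel_mean mean indel length (geometric), default 2.
#' @param id id for the mutant genome.
#' @return list with `genome` (DNAStringSet) and `truth`, a record holding the
#'   rates and the realised substitution/indel counts.
#' @export
mutate_genome <- function(genome, sub_rate, indel_rate = 0, seed = 1L,
                          indel_mean = 2, id = "mutant") {
  abort_if(!is.numeric(sub_rate) || sub_rate < 0 || sub_rate >= 1,
           "sub_rate must be in [0, 1)")
  abort_if(!is.numeric(indel_rate) || indel_rate < 0 || indel_rate >= 1,
           "indel_rate must be in [0, 1)")
  contigs <- as_contigs(genome)
  res <- with_seed(seed, {
    realized_subs <- 0L
    realized_indels <- 0L
    mutated <- vapply(contigs, function(s) {
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      L <- length(chars)
      if (sub_rate > 0) {
        hit <- which(runif(L) < sub_rate)
        if (length(hit)) {
          code <- match(chars[hit], DNA_BASES)
          shift <- sample.int(3, length(hit), replace = TRUE)
          chars[hit] <- DNA_BASES[(code - 1L + shift) %% 4L + 1L]
          realized_subs <<- realized_subs + length(hit)
        }
      }
      if (indel_rate > 0) {
        sites <- which(runif(length(chars)) < indel_rate)
        if (length(sites)) {
          lens <- rgeom(length(sites), prob = 1 / indel_mean) + 1L
          is_ins <- runif(length(sites)) < 0.5
          # apply right-to-left so earlier coordinates stay valid
          ord <- order(sites, decreasing = TRUE)
          for (m in ord) {
            p <- sites[m]
            if (is_ins[m]) {
              ins <- sample(DNA_BASES, lens[m], replace = TRUE)
              chars <- append(chars, ins, after = p)
            } else {
              drop <- p:min(p + lens[m] - 1L, length(chars))
              chars <- chars[-drop]
            }
          }
          realized_indels <<- realized_indels + length(sites)
        }
      }
      paste(chars, collapse = "")
    }, character(1))
    list(mutated = mutated, subs = realized_subs, indels = realized_indels)
  })
  mut <- Biostrings::DNAStringSet(unname(res$mutated))
  names(mut) <- if (length(mut) == 1) id else paste0(id, "_", seq_along(mut))
  list(
    genome = mut,
    truth = list(parent_id = names(contigs)[1], child_id = id,
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 realized_subs = res$subs, realized_indels = res$indels)
  )
}

#' Simulate a shotgun read set from a community with known composition
#'
#' The source genome of each read is drawn with probability proportional to
#' `weight * genome length` (a copy-number weight times target size, so that
#' length-normalised abundance such as RPKG recovers the weights). Start
#' positions and strands are uniform and each base is flipped to one of the
#' other three with probability `error_rate`. Every read is tagged with its
#' source in the returned truth table.
#'
#' @param genomes named list of genomes (each a DNAStringSet or character
#'   vector of contigs); names are the community member ids.
#' @param weights named non-negative copy-number weights, names matching
#'   `genomes`.
#' @param n_reads number of reads to simulate.
#' @param read_length read length in bases; must not exceed the shortest
#'   contig of any member.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return list with `reads` (DNAStringSet named `read_00001`, ...) and
#'   `truth` (data.frame: read, source, contig, start (0-based), strand).
#' @export
simulate_reads <- function(genomes, weights, n_reads, read_length = 150L,
                           error_rate = 0, seed = 1L) {
  abort_if(length(genomes) == 0, "empty community")
  abort_if(is.null(names(genomes)) || anyDuplicated(names(genomes)) > 0,
           "genomes must be uniquely named")
  abort_if(!all(names(weights) %in% names(genomes)),
           "weights name a genome that is not supplied: ",
           paste(setdiff(names(weights), names(genomes)), collapse = ", "))
  abort_if(any(weights < 0) || sum(weights) <= 0,
           "weights must be non-negative and sum > 0")
  contigs <- lapply(genomes, as_contigs)
  lens <- lapply(contigs, nchar)
  abort_if(read_length > min(unlist(lens)),
           "read_length exceeds the shortest contig")
  if (n_reads == 0) {
    return(list(reads = Biostrings::DNAStringSet(),
                truth = data.frame(read = character(), source = character(),
                                   contig = character(), start = integer(),
                                   strand = character())))
  }
  members <- names(weights)
  glen <- vapply(lens[members], sum, numeric(1))
  with_seed(seed, {
    src <- sample(members, n_reads, replace = TRUE, prob = weights * glen)
    seqs <- character(n_reads)
    contig_id <- character(n_reads)
    start0 <- integer(n_reads)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    for (m in members) {
      sel <- which(src == m)
      if (!length(sel)) next
      cl <- lens[[m]]
      ok <- cl >= read_length
      ci <- if (sum(ok) == 1) rep(which(ok), length(sel))
            else sample(which(ok), length(sel), replace = TRUE,
                        prob = (cl[ok] - read_length + 1))
      st <- vapply(ci, function(i)
        sample.int(cl[i] - read_length + 1L, 1L), integer(1))
      seqs[sel] <- substring(contigs[[m]][ci], st, st + read_length - 1L)
      contig_id[sel] <- names(contigs[[m]])[ci]
      start0[sel] <- st - 1L
    }
    neg <- strand == "-"
    if (any(neg)) seqs[neg] <- revcomp_chr(seqs[neg])
    if (error_rate > 0) {
      flat <- which(runif(n_reads * read_length) < error_rate)
      if (length(flat)) {
        ri <- (flat - 1L) %/% read_length + 1L
        pos <- (flat - 1L) %% read_length + 1L
        shift <- sample.int(3, length(flat), replace = TRUE)
        for (m in seq_along(flat)) {
          b <- substr(seqs[ri[m]], pos[m], pos[m])
          code <- match(b, DNA_BASES)
          substr(seqs[ri[m]], pos[m], pos[m]) <-
            DNA_BASES[(code - 1L + shift[m]) %% 4L + 1L]
        }
      }
    }
    ids <- sprintf("read_%06d", seq_len(n_reads))
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- ids
    list(reads = reads,
         truth = data.frame(read = ids, source = src, contig = contig_id,
                            start = start0, strand = strand,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic proteome with controlled acidic-residue enrichment
#'
#' Residues are i.i.d. with `P(Asp) + P(Glu) = acidic_enrichment` (split
#' equally) and the remaining mass uniform over the other 18 standard amino
#' acids. Raising the enrichment acid-shifts the proteome's isoelectric-point
#' distribution, emulating the acidic proteomes of "salt-in" halophiles.
#'
#' @param n_proteins number of proteins (>= 1).
#' @param length_range integer vector `c(min, max)` protein length in residues.
#' @param acidic_enrichment target Asp+Glu residue fraction in `[0, 1]`.
#' @param seed integer seed.
#' @param id proteome id used to name records.
#' @return a [Biostrings::AAStringSet].
#' @export
generate_proteome <- function(n_proteins, length_range = c(100L, 400L),
                              acidic_enrichment = 0.12, seed = 1L,
                              id = "proteome") {
  abort_if(n_proteins < 1, "n_proteins must be >= 1")
  abort_if(acidic_enrichment < 0 || acidic_enrichment > 1,
           "acidic_enrichment must be in [0, 1]")
  abort_if(length(length_range) != 2 || length_range[1] < 1 ||
             length_range[2] < length_range[1], "bad length_range")
  prob <- rep((1 - acidic_enrichment) / 18, 20)
  names(prob) <- AA_ALPHABET
  prob[c("D", "E")] <- acidic_enrichment / 2
  with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n_proteins, replace = TRUE)
    flat <- sample(AA_ALPHABET, sum(lens), replace = TRUE, prob = prob)
    ends <- cumsum(lens)
    seqs <- vapply(seq_len(n_proteins), function(i)
      paste(flat[(ends[i] - lens[i] + 1L):ends[i]], collapse = ""),
      character(1))
    out <- Biostrings::AAStringSet(seqs)
    names(out) <- sprintf("%s_p%04d", id, seq_len(n_proteins))
    out
  })
}

#' Generate a gene-to-KO annotation table with planned pathway completeness
#'
#' For every (genome, pathway) cell of the plan, `floor(fraction * n_required)`
#' of the pathway's required KEGG Orthology ids are included, chosen uniformly
#' at random, emulating the annotation tables produced by KEGG annotation
#' servers. The returned truth records the realised KO subset per cell so
#' downstream completeness calls can be checked exactly.
#'
#' @param plan data.frame with columns `genome`, `pathway`, `fraction`.
#' @param defs pathway definitions from [load_pathway_defs()].
#' @param seed integer seed.
#' @param background_kos optional extra (non-pathway) KOs added per genome.
#' @return list with `table` (data.frame: genome, gene, ko) and `truth`
#'   (plan plus `n_included` and the included KO ids).
#' @export
generate_annotation_table <- function(plan, defs, seed = 1L,
                                      background_kos = 0L) {
  abort_if(!all(c("genome", "pathway", "fraction") %in% names(plan)),
           "plan needs columns genome, pathway, fraction")
  unknown <- setdiff(unique(plan$pathway), names(defs))
  abort_if(length(unknown) > 0,
           "unknown pathway id: ", paste(unknown, collapse = ", "))
  abort_if(any(plan$fraction < 0 | plan$fraction > 1),
           "fractions must be in [0, 1]")
  with_seed(seed, {
    rows <- list()
    included <- character(nrow(plan))
    n_included <- integer(nrow(plan))
    for (i in seq_len(nrow(plan))) {
      req <- defs[[plan$pathway[i]]]$required
      n <- floor(plan$fraction[i] * length(req) + 1e-9)
      kos <- if (n > 0) sort(sample(req, n)) else character()
      n_included[i] <- n
      included[i] <- paste(kos, collapse = ",")
      if (n > 0)
        rows[[length(rows) + 1L]] <-
          data.frame(genome = plan$genome[i], ko = kos,
                     stringsAsFactors = FALSE)
    }
    if (background_kos > 0) {
      for (g in unique(plan$genome)) {
        kos <- sprintf("K%05d", sample(70000:79999, background_kos))
        rows[[length(rows) + 1L]] <-
          data.frame(genome = g, ko = kos, stringsAsFactors = FALSE)
      }
    }
    tab <- if (length(rows)) do.call(rbind, rows)
           else data.frame(genome = character(), ko = character())
    if (nrow(tab))
      tab$gene <- paste0(tab$genome, sprintf("_g%05d", seq_len(nrow(tab))))
    else tab$gene <- character()
    tab <- tab[, c("genome", "gene", "ko")]
    truth <- plan
    truth$n_included <- n_included
    truth$included_kos <- included
    list(table = tab, truth = truth)
  })
}

#' Write simulated reads as FASTQ
#'
#' Constant quality "I" (Phred 40, offset 33); the simulator does not model
#' quality-score error profiles.
#'
#' @param reads DNAStringSet of reads.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  qual <- Biostrings::PhredQuality(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = qual)
  invisible(path)
}
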