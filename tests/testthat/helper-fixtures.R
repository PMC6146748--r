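# shared fixture builders; everything is generated in code at test time

small_community <- function(n_genomes = 3, length = 8000, seed = 1) {
  ids <- paste0("mag", seq_len(n_genomes))
  genomes <- lapply(seq_len(n_genomes), function(i)
    generate_genome(length, gc = 0.45 + 0.05 * (i %% 3), id = ids[i],
                    seed = seed * 100 + i))
  names(genomes) <- ids
  genomes
}

# a read taken from `genome` with `n_mismatch` substitutions spread over the
# interior so the ends stay matching (the local alignment then spans the read)
read_with_mismatches <- function(genome, start, len, n_mismatch, seed = 1) {
  s <- substring(as.character(genome)[1], start, start + len - 1)
  if (n_mismatch == 0) return(s)
  pos <- round(seq(len * 0.15, len * 0.85, length.out = n_mismatch))
  withr::with_seed(seed, {
    for (p in pos) {
      b <- substr(s, p, p)
      alt <- setdiff(c("A", "C", "G", "T"), b)
      substr(s, p, p) <- sample(alt, 1)
    }
  })
  s
}

# independent net-charge evaluation used as the pI oracle: a literal
# transcription of the Henderson-Hasselbalch sum, separate from the package's
# vectorised implementation
oracle_charge <- function(seq, pH) {
  n <- table(strsplit(seq, "")[[1]])
  g <- function(a) if (a %in% names(n)) as.numeric(n[[a]]) else 0
  pka_b <- c(nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
  pka_a <- c(cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
  cnt_b <- c(nterm = 1, K = g("K"), R = g("R"), H = g("H"))
  cnt_a <- c(cterm = 1, D = g("D"), E = g("E"), C = g("C"), Y = g("Y"))
  sum(cnt_b / (1 + 10^(pH - pka_b))) - sum(cnt_a / (1 + 10^(pka_a - pH)))
}

revcomp_chr_for_tests <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

random_protein <- function(len, seed) {
  withr::with_seed(seed, paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                      len, replace = TRUE), collapse = ""))
}
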