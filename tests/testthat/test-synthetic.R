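test_that("genome generation is seed-deterministic and respects gc", {
  g1 <- generate_genome(1000, gc = 0.5, seed = 1)
  g2 <- generate_genome(1000, gc = 0.5, seed = 1)
  expect_identical(as.character(g1), as.character(g2))
  expect_false(identical(as.character(generate_genome(1000, 0.5, seed = 2)),
                         as.character(g1)))

  gc1 <- generate_genome(10, gc = 1, seed = 3)
  expect_true(grepl("^[GC]+$", as.character(gc1)))

  # binomial oracle: observed GC within 3 standard errors of the target
  L <- 100000; gc <- 0.4
  g <- as.character(generate_genome(L, gc, seed = 4))
  obs <- nchar(gsub("[AT]", "", g)) / L
  se <- sqrt(gc * (1 - gc) / L)
  expect_lt(abs(obs - gc), 3 * se)

  expect_error(generate_genome(0, 0.5), "positive")
  expect_error(generate_genome(100, 1.2), "gc")
})

test_that("mutation realises the requested substitution rate", {
  g <- generate_genome(100000, 0.5, seed = 5)

  m0 <- mutate_genome(g, sub_rate = 0, indel_rate = 0, seed = 6)
  expect_identical(as.character(m0$genome)[[1]], as.character(g)[[1]])
  expect_equal(m0$truth$realized_subs, 0)

  m <- mutate_genome(g, sub_rate = 0.05, indel_rate = 0, seed = 7)
  expect_equal(unname(nchar(as.character(m$genome))),
               unname(nchar(as.character(g))))
  sd3 <- 3 * sqrt(100000 * 0.05 * 0.95)
  expect_lt(abs(m$truth$realized_subs - 5000), sd3)
  # coordinate preservation: realised subs equal per-site differences
  a <- strsplit(as.character(g)[[1]], "")[[1]]
  b <- strsplit(as.character(m$genome)[[1]], "")[[1]]
  expect_identical(sum(a != b), as.integer(m$truth$realized_subs))

  m2 <- mutate_genome(g, sub_rate = 0.05, indel_rate = 0, seed = 7)
  expect_identical(as.character(m$genome), as.character(m2$genome))

  mi <- mutate_genome(g, sub_rate = 0, indel_rate = 0.001, seed = 8)
  expect_gt(mi$truth$realized_indels, 0)
  expect_error(mutate_genome(g, sub_rate = 1), "sub_rate")
})

test_that("read simulation tags every read with its true source", {
  genomes <- small_community(2, length = 5000, seed = 2)

  sim0 <- simulate_reads(genomes, c(mag1 = 1, mag2 = 1), n_reads = 0)
  expect_equal(length(sim0$reads), 0)
  expect_equal(nrow(sim0$truth), 0)

  sim <- simulate_reads(genomes["mag1"], c(mag1 = 1), 200, read_length = 100,
                        error_rate = 0, seed = 9)
  expect_equal(length(sim$reads), nrow(sim$truth))
  g1 <- as.character(genomes$mag1)[[1]]
  hit <- vapply(seq_len(200), function(i) {
    r <- as.character(sim$reads[[i]])
    grepl(r, g1, fixed = TRUE) ||
      grepl(revcomp_chr_for_tests(r), g1, fixed = TRUE)
  }, logical(1))
  expect_true(all(hit))
  # truth coordinates locate the read exactly
  fwd <- sim$truth$strand == "+"
  recovered <- substring(g1, sim$truth$start + 1, sim$truth$start + 100)
  expect_identical(recovered[fwd],
                   unname(as.character(sim$reads)[fwd]))

  # binomial oracle on source proportions at weights 3:1, equal lengths
  simw <- simulate_reads(genomes, c(mag1 = 3, mag2 = 1), 100000,
                         read_length = 100, seed = 10)
  n1 <- sum(simw$truth$source == "mag1")
  expect_lt(abs(n1 - 75000), 3 * sqrt(100000 * 0.75 * 0.25))

  expect_error(simulate_reads(genomes, c(mag1 = 1), 10, read_length = 6000),
               "read_length")
  expect_error(simulate_reads(list(), numeric(), 10), "empty")
})

test_that("proteome generation hits the acidic-enrichment target", {
  p0 <- generate_proteome(20, c(50, 100), acidic_enrichment = 0, seed = 11)
  expect_false(any(grepl("[DE]", as.character(p0))))

  p1 <- generate_proteome(50, c(200, 300), 0.3, seed = 12)
  p1b <- generate_proteome(50, c(200, 300), 0.3, seed = 12)
  expect_identical(as.character(p1), as.character(p1b))
  total <- sum(nchar(as.character(p1)))
  nde <- sum(nchar(gsub("[^DE]", "", paste(as.character(p1), collapse = ""))))
  expect_lt(abs(nde / total - 0.3), 3 * sqrt(0.3 * 0.7 / total))
  lens <- nchar(as.character(p1))
  expect_true(all(lens >= 200 & lens <= 300))

  expect_error(generate_proteome(0, c(10, 20), 0.1), "n_proteins")
})

test_that("annotation tables realise the planned completeness fractions", {
  defs <- load_pathway_defs()
  plan <- data.frame(genome = c("g1", "g1", "g2"),
                     pathway = c("emp_glycolysis", "pta_ack", "emp_glycolysis"),
                     fraction = c(1, 0, 0.5))
  ann <- generate_annotation_table(plan, defs, seed = 13)
  n_req <- length(defs$emp_glycolysis$required)
  g1 <- ann$table[ann$table$genome == "g1", ]
  expect_setequal(intersect(g1$ko, defs$emp_glycolysis$required),
                  defs$emp_glycolysis$required)
  expect_false(any(defs$pta_ack$required %in% g1$ko))
  g2 <- ann$table[ann$table$genome == "g2", ]
  expect_equal(sum(defs$emp_glycolysis$required %in% g2$ko),
               floor(0.5 * n_req))
  expect_false(anyDuplicated(ann$table$gene) > 0)
  expect_error(generate_annotation_table(
    data.frame(genome = "g", pathway = "nope", fraction = 1), defs),
    "unknown pathway")
})

test_that("fastq round trip preserves reads", {
  genomes <- small_community(1, length = 2000, seed = 3)
  sim <- simulate_reads(genomes, c(mag1 = 1), 25, read_length = 80, seed = 14)
  fp <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim$reads, fp)
  back <- read_fastq(fp)
  expect_identical(as.character(back), as.character(sim$reads))
})
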