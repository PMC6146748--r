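test_that("subsampling is uniform, without replacement and deterministic", {
  genomes <- small_community(1, length = 3000, seed = 5)
  sim <- simulate_reads(genomes, c(mag1 = 1), 100, read_length = 60, seed = 1)
  expect_equal(length(subsample_reads(sim$reads, 0)), 0)
  expect_identical(as.character(subsample_reads(sim$reads, 500)),
                   as.character(sim$reads))
  s1 <- subsample_reads(sim$reads, 30, seed = 2)
  s2 <- subsample_reads(sim$reads, 30, seed = 2)
  expect_identical(as.character(s1), as.character(s2))
  expect_equal(length(s1), 30)
  expect_false(anyDuplicated(names(s1)) > 0)
})

test_that("recruitment applies the identity and length cutoffs per read", {
  g <- generate_genome(5000, 0.5, seed = 6)
  perfect <- substring(as.character(g), 1001, 1150)
  ten_mm <- read_with_mismatches(g, 2001, 150, 10, seed = 1) # identity 93.3%
  four_mm <- read_with_mismatches(g, 3001, 150, 4, seed = 2) # identity 97.3%
  short40 <- substring(as.character(g), 4001, 4040)
  reads <- Biostrings::DNAStringSet(c(perfect, ten_mm, four_mm, short40))
  names(reads) <- paste0("r", 1:4)
  rec <- recruit_reads(reads, g, recruitment_params(), details = TRUE)
  expect_identical(rec$recruited, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(rec$count, 2)
  expect_equal(rec$alignments$identity[1], 100)
  expect_lt(rec$alignments$identity[2], 95)
  # the 40-b read aligns perfectly but is below the 50-column floor
  expect_equal(rec$alignments$columns[4], 40)
})

test_that("rpkg normalisation is the documented ratio", {
  expect_equal(compute_rpkg(1000, 0.5e9, 2e6), 1.0)
  expect_equal(compute_rpkg(0, 1e9, 1e6), 0)
  # doubling depth leaves rpkg unchanged
  expect_equal(compute_rpkg(500, 2.5e8, 3e6),
               compute_rpkg(1000, 5e8, 3e6))
  expect_warning(r0 <- compute_rpkg(5, 0, 1e6), "0")
  expect_equal(r0, 0)
  expect_error(compute_rpkg(10, 1e9, 0), "mag_length")
})

test_that("raising cutoffs never increases recruited counts", {
  g <- generate_genome(20000, 0.5, seed = 7)
  sim <- simulate_reads(list(g1 = g), c(g1 = 1), 400, read_length = 150,
                        error_rate = 0.03, seed = 8)
  counts <- vapply(c(0.90, 0.95, 0.99), function(mi)
    recruit_reads(sim$reads, g, recruitment_params(min_identity = mi))$count,
    numeric(1))
  expect_true(all(diff(counts) <= 0))
  counts_len <- vapply(c(50L, 100L, 140L), function(ml)
    recruit_reads(sim$reads, g,
                  recruitment_params(min_aligned = ml))$count, numeric(1))
  expect_true(all(diff(counts_len) <= 0))
})

test_that("independent mode isolates MAGs; competitive assigns reads once", {
  genomes <- small_community(3, length = 6000, seed = 9)
  sim <- simulate_reads(genomes, c(mag1 = 2, mag2 = 1, mag3 = 1), 300,
                        read_length = 120, seed = 10)
  p <- recruitment_params(subsample_n = 1e7)
  prof_all <- profile_community(list(d = sim$reads), genomes, p, seed = 1)
  prof_two <- profile_community(list(d = sim$reads), genomes[1:2], p, seed = 1)
  for (m in c("mag1", "mag2"))
    expect_equal(prof_all$reads[prof_all$mag == m],
                 prof_two$reads[prof_two$mag == m])

  pc <- recruitment_params(mode = "competitive")
  prof_c <- profile_community(list(d = sim$reads), genomes, pc, seed = 1)
  expect_lte(sum(prof_c$reads), length(sim$reads))
  # independent mode recruits at least as much per MAG
  expect_true(all(prof_all$reads >= prof_c$reads))
})

test_that("profile recovers relative abundance and rejects id collisions", {
  genomes <- small_community(2, length = 6000, seed = 11)
  sim <- simulate_reads(genomes, c(mag1 = 4, mag2 = 1), 2000,
                        read_length = 150, seed = 12)
  prof <- profile_community(list(d = sim$reads), genomes,
                            recruitment_params(), seed = 2)
  ratio <- prof$rpkg[prof$mag == "mag1"] / prof$rpkg[prof$mag == "mag2"]
  expect_lt(abs(ratio - 4) / 4, 0.15)
  # a MAG absent from the community recruits nothing at 95%/50 b
  absent <- generate_genome(6000, 0.5, "magX", seed = 13)
  prof2 <- profile_community(list(d = sim$reads),
                             c(genomes, list(magX = absent)),
                             recruitment_params(), seed = 2)
  expect_equal(prof2$reads[prof2$mag == "magX"], 0)
  expect_error(profile_community(setNames(list(sim$reads, sim$reads),
                                          c("d", "d")), genomes),
               "collision")
})
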