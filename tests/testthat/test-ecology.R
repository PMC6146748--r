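test_that("quality tiers follow the completeness/contamination thresholds", {
  expect_equal(quality_tier(92, 4), "near_complete")
  expect_equal(quality_tier(50, 9.9), "medium")
  expect_equal(quality_tier(49.9, 2), "fail")
  expect_equal(quality_tier(95, 5.0), "medium")   # strict < 5 boundary
  expect_equal(quality_tier(95, 5.0, contamination_inclusive = TRUE),
               "near_complete")
  expect_equal(quality_tier(60, 10.0), "fail")    # strict < 10 boundary
  expect_error(quality_tier(-1, 2), "completeness")
  expect_error(quality_tier(80, -2), "contamination")

  # tier nesting: near_complete always satisfies the medium thresholds
  set.seed(1)
  comp <- runif(200, 0, 100); cont <- runif(200, 0, 15)
  tier <- quality_tier(comp, cont)
  nc <- tier == "near_complete"
  expect_true(all(comp[nc] >= 50 & cont[nc] < 10))

  tab <- tier_quality_table(data.frame(mag = c("a", "b"),
                                       completeness = c(91, 55),
                                       contamination = c(1, 3)))
  expect_equal(tab$tier, c("near_complete", "medium"))
})

make_profile <- function(high, moderate, mags = names(high)) {
  rbind(data.frame(dataset = "H1", mag = mags, rpkg = unname(high)),
        data.frame(dataset = "M1", mag = mags, rpkg = unname(moderate)))
}
groups2 <- c(H1 = "high", M1 = "moderate")

test_that("salinity scores reproduce the hand-ranked example", {
  prof <- make_profile(c(A = 10, B = 5, C = 1), c(A = 1, B = 5, C = 10))
  s <- salinity_preference_scores(prof, groups2)
  s <- s[order(s$mag), ]
  expect_equal(s$pos_rank_score, c(3L, 2L, 1L))
  expect_equal(s$neg_rank_score, c(-1L, -2L, -3L))
  expect_equal(s$salinity_score, c(2L, 0L, -2L))
})

test_that("salinity scores are permutations, zero-sum and scale-invariant", {
  for (seed in 1:5) {
    set.seed(seed)
    M <- sample(3:40, 1)
    mags <- sprintf("m%02d", seq_len(M))
    prof <- rbind(
      data.frame(dataset = "H1", mag = mags, rpkg = runif(M) * 100),
      data.frame(dataset = "H2", mag = mags, rpkg = runif(M) * 10),
      data.frame(dataset = "M1", mag = mags, rpkg = runif(M) * 50))
    g <- c(H1 = "high", H2 = "high", M1 = "moderate")
    s <- salinity_preference_scores(prof, g)
    expect_setequal(s$pos_rank_score, seq_len(M))
    expect_setequal(s$neg_rank_score, -seq_len(M))
    expect_equal(sum(s$salinity_score), 0)
    # positive rescaling within one group changes nothing (rank-based)
    prof2 <- prof
    hi <- prof2$dataset %in% c("H1", "H2")
    prof2$rpkg[hi] <- prof2$rpkg[hi] * 37.5
    expect_identical(salinity_preference_scores(prof2, g)$salinity_score,
                     s$salinity_score)
  }
})

test_that("salinity scoring validates groups and breaks ties by id", {
  prof <- make_profile(c(A = 1, B = 1), c(A = 1, B = 1))
  s <- salinity_preference_scores(prof, groups2)
  s <- s[order(s$mag), ]
  expect_equal(s$pos_rank_score, c(2L, 1L))  # tie -> ascending id order
  expect_equal(s$neg_rank_score, c(-2L, -1L))
  expect_error(salinity_preference_scores(prof, c(H1 = "high")), "missing")
  expect_error(salinity_preference_scores(prof, c(H1 = "high", M1 = "high")),
               "non-empty")
})

test_that("top-n ordering is by rpkg with deterministic ties", {
  prof <- rbind(data.frame(dataset = "d", mag = c("b", "a", "c"),
                           rpkg = c(5, 5, 9)))
  expect_equal(top_n_abundant(prof, "d", 10), c("c", "a", "b"))
  expect_equal(top_n_abundant(prof, "d", 1), "c")
  expect_error(top_n_abundant(prof, "nope", 1), "unknown dataset")
  expect_error(top_n_abundant(prof, "d", 0), "n must")
})

test_that("species aggregation merges by connected components", {
  mags <- c("A", "B", "C")
  prof <- rbind(data.frame(dataset = "d1", mag = mags, rpkg = c(4, 6, 10)),
                data.frame(dataset = "d2", mag = mags, rpkg = c(1, 3, 7)))
  dec_all0 <- matrix(0L, 3, 3, dimnames = list(mags, mags)); diag(dec_all0) <- 1L
  agg0 <- aggregate_species(prof, dec_all0)
  expect_equal(nrow(agg0), 6)
  expect_equal(agg0$rpkg[agg0$cluster == "A" & agg0$dataset == "d1"], 4)

  # A-B same species: mean(4, 6) = 5
  dec <- dec_all0; dec["A", "B"] <- dec["B", "A"] <- 1L
  agg <- aggregate_species(prof, dec)
  expect_equal(agg$rpkg[agg$cluster == "A;B" & agg$dataset == "d1"], 5)
  expect_equal(agg$n_members[agg$cluster == "A;B"], c(2L, 2L))

  # transitive chain A-B (1), B-C (-1), A-C (0) -> one cluster
  dec2 <- dec_all0
  dec2["A", "B"] <- dec2["B", "A"] <- 1L
  dec2["B", "C"] <- dec2["C", "B"] <- -1L
  agg2 <- aggregate_species(prof, dec2)
  expect_setequal(unique(agg2$cluster), "A;B;C")
  expect_equal(agg2$rpkg[agg2$dataset == "d1"], mean(c(4, 6, 10)))
  expect_error(aggregate_species(prof, dec2, mags = c("A", "Z")), "cover")
})

test_that("phylogeny eligibility needs 8 distinct markers of >= 80 aa", {
  panel <- ribosomal_panel()
  t8 <- data.frame(mag = "m1", marker = panel[1:8], length_aa = 80)
  expect_true(phylogeny_eligibility(t8)$eligible)
  t7 <- data.frame(mag = "m2", marker = panel[1:7], length_aa = 200)
  expect_false(phylogeny_eligibility(t7)$eligible)
  # 9 markers but two below 80 aa -> 7 valid -> not eligible
  t9 <- data.frame(mag = "m3", marker = panel[1:9],
                   length_aa = c(rep(100, 7), 79, 79))
  expect_false(phylogeny_eligibility(t9)$eligible)
  # duplicated marker counts once
  tdup <- data.frame(mag = "m4", marker = panel[c(1:7, 7)], length_aa = 100)
  e <- phylogeny_eligibility(tdup)
  expect_equal(e$n_markers, 7L)
  expect_false(e$eligible)
  expect_error(phylogeny_eligibility(
    data.frame(mag = "m", marker = "rpL99", length_aa = 100)), "unknown marker")
})
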