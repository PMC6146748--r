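test_that("packaged definitions load, validate and round-trip", {
  defs <- load_pathway_defs()
  expect_true(all(c("codh_acs_bacterial", "codh_acs_archaeal", "wl_eastern",
                    "emp_glycolysis", "pfor", "pta_ack", "nrfA", "prk")
                  %in% names(defs)))
  expect_equal(defs$codh_acs_bacterial$required, "K14138")
  expect_equal(defs$codh_acs_archaeal$required, "K00193")
  expect_equal(defs$nrfA$required, "K03385")
  expect_equal(defs$prk$required, "K00855")
  for (d in defs) {
    expect_true(length(d$required) > 0)
    expect_equal(length(intersect(d$required, d$optional)), 0)
  }
  fp <- withr::local_tempfile(fileext = ".yaml")
  write_pathway_defs(defs, fp)
  defs2 <- load_pathway_defs(fp)
  expect_equal(defs2, defs)
})

test_that("malformed configurations are rejected", {
  bad_ko <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("pathways:", "  - id: x", "    required: [K123]"), bad_ko)
  expect_error(load_pathway_defs(bad_ko), "malformed KO")

  overlap <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("pathways:",
               "  - id: x",
               "    required: [K00001]",
               "    optional: [K00001]"), overlap)
  expect_error(load_pathway_defs(overlap), "overlap")

  dup <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("pathways:",
               "  - id: x",
               "    required: [K00001]",
               "  - id: x",
               "    required: [K00002]"), dup)
  expect_error(load_pathway_defs(dup), "duplicate")
})

test_that("pathway scoring is presence-based with exact completeness", {
  defs <- load_pathway_defs()
  req <- defs$emp_glycolysis$required
  full <- data.frame(genome = "g", gene = paste0("g_", seq_along(req)),
                     ko = req)
  call <- score_pathway(full, defs$emp_glycolysis)
  expect_equal(call$completeness, 1)
  expect_true(call$present)
  expect_equal(length(call$missing), 0)

  empty <- data.frame(genome = "g", gene = "g_1", ko = "K99999")
  call0 <- score_pathway(empty, defs$emp_glycolysis)
  expect_equal(call0$completeness, 0)
  expect_false(call0$present)
  expect_setequal(call0$missing, req)

  # duplicate KO rows change nothing (multiplicity ignored)
  dup <- rbind(full, full)
  dup$gene <- paste0("g_", seq_len(nrow(dup)))
  expect_equal(score_pathway(dup, defs$emp_glycolysis)$completeness, 1)
})

test_that("planned completeness is recovered exactly from generated tables", {
  defs <- load_pathway_defs()
  plan <- expand.grid(genome = c("g1", "g2", "g3"),
                      pathway = c("emp_glycolysis", "wl_eastern", "pfor"),
                      stringsAsFactors = FALSE)
  set.seed(30)
  plan$fraction <- sample(c(0, 0.25, 0.5, 0.75, 1), nrow(plan), replace = TRUE)
  ann <- generate_annotation_table(plan, defs, seed = 31)
  for (i in seq_len(nrow(plan))) {
    def <- defs[[plan$pathway[i]]]
    got <- score_pathway(ann$table, def, genome = plan$genome[i])$completeness
    expect_equal(got, floor(plan$fraction[i] * length(def$required)) /
                   length(def$required))
  }
})

test_that("marker screening applies the product-length floor", {
  ann <- data.frame(
    genome = c("g1", "g2", "g3", "g4"),
    gene = paste0("gene", 1:4),
    ko = c("K14138", "K14138", "K14138", "K00625"),
    length_aa = c(510, 480, NA, 600))
  expect_warning(hits <- screen_marker(ann, "K14138", min_length = 500),
                 "length data")
  expect_equal(hits, "g1")
  # no length screen: all carriers qualify
  all_hits <- screen_marker(ann, "K14138")
  expect_equal(all_hits, c("g1", "g2", "g3"))
  expect_true(all(hits %in% all_hits))  # screened set is a subset
  expect_equal(screen_marker(ann, "K99999"), character())
  expect_error(screen_marker(ann, "acsB"), "malformed")
})

test_that("function summaries are monotone in annotation supersets", {
  defs <- load_pathway_defs()[c("emp_glycolysis", "pta_ack", "prk")]
  base <- data.frame(genome = "g",
                     gene = paste0("a", 1:3),
                     ko = defs$emp_glycolysis$required[1:3])
  more <- rbind(base, data.frame(genome = "g", gene = paste0("b", 1:3),
                                 ko = c(defs$emp_glycolysis$required[4:6])))
  s1 <- summarize_functions(base, defs)
  s2 <- summarize_functions(more, defs)
  expect_true(all(s2$completeness >= s1$completeness))
  expect_equal(unname(s2$present["g", "emp_glycolysis"]), TRUE)
  # adding an unrelated KO changes no calls
  extra <- rbind(more, data.frame(genome = "g", gene = "z", ko = "K77777"))
  expect_equal(summarize_functions(extra, defs)$present, s2$present)
})
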