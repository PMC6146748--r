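pkg_version <- function() as.character(utils::packageVersion("halomag"))

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", ...)
  writeLines(msg, con)
  message(msg)
}

#' Validate a pipeline run configuration
#'
#' A run configuration (R list or YAML file) names the inputs and parameters
#' of a full post-binning analysis:
#' \describe{
#'   \item{genomes}{named list of MAG FASTA paths.}
#'   \item{reads}{manifest: named list of `list(path=, group=)` per dataset;
#'     `group` is "high" or "moderate" salinity.}
#'   \item{proteomes}{named list of protein FASTA paths (optional).}
#'   \item{annotations}{gene-to-KO TSV (optional).}
#'   \item{quality}{bin quality TSV: mag, completeness, contamination.}
#'   \item{outdir, seed}{output directory and global seed.}
#'   \item{params}{optional overrides: `min_identity` (0.95), `min_aligned`
#'     (50), `subsample_n` (1e7), `fragment_length` (1020), `bin_width` (0.2),
#'     `top_n` (10), `ani_threshold` (95), `condna_threshold` (69).}
#' }
#' Defaults reproduce the standard study parameters (95%/50 b recruitment,
#' 1e7-read subsample, 1020-b fragments, 95/69 decision thresholds, 0.2 pI
#' bins).
#'
#' @param config list or YAML path.
#' @return the validated config with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  abort_if(!is.list(config), "config must be a list or YAML path")
  for (field in c("genomes", "reads", "quality", "outdir"))
    abort_if(is.null(config[[field]]), "config is missing '", field, "'")
  if (is.null(config$seed)) config$seed <- 1L
  defaults <- list(min_identity = 0.95, min_aligned = 50L, subsample_n = 1e7,
                   fragment_length = 1020L, bin_width = 0.2, top_n = 10L,
                   ani_threshold = 95, condna_threshold = 69)
  config$params <- utils::modifyList(defaults,
                                     if (is.null(config$params)) list()
                                     else config$params)
  paths <- c(unlist(config$genomes),
             vapply(config$reads, `[[`, character(1), "path"),
             unlist(config$proteomes), config$annotations, config$quality)
  missing <- paths[!file.exists(paths)]
  abort_if(length(missing) > 0,
           "missing input file(s): ", paste(missing, collapse = ", "))
  grp <- vapply(config$reads, `[[`, character(1), "group")
  abort_if(!all(grp %in% c("high", "moderate")),
           "dataset group must be 'high' or 'moderate'")
  config
}

#' Run the full post-binning pipeline
#'
#' Executes quality tiering, read subsampling/recruitment and RPKG
#' normalisation, salinity-preference scoring, ANI/conserved-DNA matrices over
#' the union of top-n abundant MAGs, same-species abundance averaging, pI
#' profiling, and the pathway presence matrix; writes every table plus a run
#' log recording the tool version, all parameters and all seeds. Rerunning
#' with the same config yields byte-identical tables.
#'
#' @param config list or YAML path (see [validate_config()]).
#' @return (invisibly) a list with every computed object.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  p <- config$params
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(config$outdir, "run_log.txt"), open = "wt")
  on.exit(close(logf))
  hdr <- sprintf("halomag %s | seed %d | %s", pkg_version(), config$seed,
                 paste(names(p), unlist(p), sep = "=", collapse = " "))
  log_line(logf, "run_pipeline start: ", hdr)
  stage <- function(name, expr) {
    log_line(logf, "stage ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  quality <- stage("quality_tiering", {
    q <- read_table_checked(config$quality,
                            required = c("mag", "completeness", "contamination"),
                            numeric_cols = c("completeness", "contamination"))
    tier_quality_table(q)
  })
  write_tsv(quality, file.path(config$outdir, "quality_tiers.tsv"), hdr)

  mags <- stage("load_genomes",
                lapply(config$genomes, read_fasta, type = "dna"))

  profile <- stage("recruitment", {
    read_sets <- lapply(config$reads, function(r) {
      if (grepl("\\.f(ast)?q(\\.gz)?$", r$path)) read_fastq(r$path)
      else read_fasta(r$path, type = "dna")
    })
    rp <- recruitment_params(min_identity = p$min_identity,
                             min_aligned = p$min_aligned,
                             subsample_n = p$subsample_n)
    profile_community(read_sets, mags, rp, seed = config$seed)
  })
  write_tsv(as.data.frame(profile),
            file.path(config$outdir, "abundance_profile.tsv"), hdr)

  groups <- vapply(config$reads, `[[`, character(1), "group")
  scores <- stage("salinity_scores",
                  salinity_preference_scores(profile, groups))
  write_tsv(scores, file.path(config$outdir, "salinity_scores.tsv"), hdr)

  top <- stage("top_n", {
    sort(unique(unlist(lapply(unique(profile$dataset), function(ds)
      top_n_abundant(profile, ds, p$top_n)))))
  })

  matrices <- stage("ani_matrices", {
    ap <- ani_params(fragment_length = p$fragment_length,
                     ani_threshold = p$ani_threshold,
                     condna_threshold = p$condna_threshold)
    if (length(top) >= 2) pairwise_matrices(mags[top], ap) else NULL
  })
  if (!is.null(matrices)) {
    write_matrix_tsv(matrices$ani,
                     file.path(config$outdir, "ani_matrix.tsv"), hdr)
    write_matrix_tsv(matrices$condna,
                     file.path(config$outdir, "condna_matrix.tsv"), hdr)
    write_matrix_tsv(matrices$decision,
                     file.path(config$outdir, "decision_matrix.tsv"), hdr)
  }

  species <- stage("species_averaging", {
    if (is.null(matrices)) NULL
    else aggregate_species(profile, matrices$decision, top)
  })
  if (!is.null(species))
    write_tsv(species, file.path(config$outdir, "species_abundance.tsv"), hdr)

  profiles_pi <- stage("pi_profiles", {
    if (is.null(config$proteomes)) NULL
    else lapply(names(config$proteomes), function(id) {
      prot <- read_fasta(config$proteomes[[id]], type = "protein")
      pi_profile(prot, bin_width = p$bin_width, id = id)
    })
  })
  if (!is.null(profiles_pi)) {
    tab <- do.call(rbind, lapply(profiles_pi, function(pr)
      data.frame(proteome = pr$id,
                 bin_left = sprintf("%.1f", pr$breaks[-length(pr$breaks)]),
                 count = pr$counts,
                 median_pi = sprintf("%.4f", pr$median_pi),
                 acidic_fraction = sprintf("%.4f", pr$acidic_fraction))))
    write_tsv(tab, file.path(config$outdir, "pi_profiles.tsv"), hdr)
  }

  pathway_summary <- stage("pathways", {
    if (is.null(config$annotations)) NULL
    else {
      ann <- read_table_checked(config$annotations,
                                required = c("genome", "gene", "ko"),
                                numeric_cols = "length_aa")
      summarize_functions(ann, load_pathway_defs(config$pathway_defs))
    }
  })
  if (!is.null(pathway_summary)) {
    m <- pathway_summary$present
    write_tsv(data.frame(genome = rownames(m), m, check.names = FALSE),
              file.path(config$outdir, "pathway_presence.tsv"), hdr)
  }

  log_line(logf, "run_pipeline done")
  invisible(list(config = config, quality = quality, profile = profile,
                 scores = scores, top = top, matrices = matrices,
                 species = species, pi_profiles = profiles_pi,
                 pathways = pathway_summary))
}

#' Write a small self-contained synthetic demo dataset and its run config
#'
#' Generates four MAGs (two of them a same-species pair at ~2% divergence),
#' two read datasets with different community compositions (one "high", one
#' "moderate" salinity), two proteomes (one acid-shifted, one neutral), an
#' annotation table with planned pathway completeness, and a bin quality
#' table; writes everything under `dir` with a `config.yaml` ready for
#' [run_pipeline()].
#'
#' @param dir output directory.
#' @param seed global seed.
#' @param genome_length MAG length in bases (default 20 kb, desk scale).
#' @param n_reads reads per dataset.
#' @return path of the written config file.
#' @export
write_demo_data <- function(dir, seed = 1L, genome_length = 20000L,
                            n_reads = 2000L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- c("magA", "magB", "magC", "magD")
  gA <- generate_genome(genome_length, 0.45, "magA",
                        derive_seed(seed, "genome:magA"))
  gB <- mutate_genome(gA, sub_rate = 0.02, seed = derive_seed(seed, "mut:magB"),
                      id = "magB")$genome
  gC <- generate_genome(genome_length, 0.55, "magC",
                        derive_seed(seed, "genome:magC"))
  gD <- generate_genome(genome_length, 0.50, "magD",
                        derive_seed(seed, "genome:magD"))
  genomes <- list(magA = gA, magB = gB, magC = gC, magD = gD)
  genome_paths <- list()
  for (id in ids) {
    fp <- file.path(dir, paste0(id, ".fasta"))
    write_fasta(genomes[[id]], fp)
    genome_paths[[id]] <- fp
  }
  # two communities with opposite preferences for magA/magB vs magC
  comm <- list(
    highSed = c(magA = 6, magB = 3, magC = 1, magD = 2),
    modSed = c(magA = 1, magB = 1, magC = 6, magD = 2)
  )
  reads_cfg <- list()
  for (ds in names(comm)) {
    sim <- simulate_reads(genomes, comm[[ds]], n_reads, read_length = 150L,
                          error_rate = 0.005,
                          seed = derive_seed(seed, paste0("reads:", ds)))
    fp <- file.path(dir, paste0(ds, ".fastq"))
    write_fastq(sim$reads, fp)
    reads_cfg[[ds]] <- list(path = fp,
                            group = if (ds == "highSed") "high" else "moderate")
  }
  prot_cfg <- list()
  for (cfg in list(list(id = "magA", enr = 0.40), list(id = "magC", enr = 0.10))) {
    prot <- generate_proteome(150, c(120L, 350L), cfg$enr,
                              seed = derive_seed(seed, paste0("prot:", cfg$id)),
                              id = cfg$id)
    fp <- file.path(dir, paste0(cfg$id, "_proteins.fasta"))
    write_fasta(prot, fp)
    prot_cfg[[cfg$id]] <- fp
  }
  defs <- load_pathway_defs()
  plan <- expand.grid(genome = ids, pathway = c("codh_acs_bacterial",
                                                "emp_glycolysis", "pta_ack"),
                      stringsAsFactors = FALSE)
  plan$fraction <- rep(c(1, 1, 0, 0.5), 3)
  ann <- generate_annotation_table(plan, defs,
                                   seed = derive_seed(seed, "annotations"))
  ann$table$length_aa <- 520L
  ann_path <- file.path(dir, "annotations.tsv")
  write_tsv(ann$table, ann_path)
  quality <- data.frame(mag = ids,
                        completeness = c(95, 88, 72, 45),
                        contamination = c(2.1, 4.0, 8.5, 3.0))
  q_path <- file.path(dir, "quality.tsv")
  write_tsv(quality, q_path)
  config <- list(genomes = genome_paths, reads = reads_cfg,
                 proteomes = prot_cfg, annotations = ann_path,
                 quality = q_path, outdir = file.path(dir, "results"),
                 seed = seed,
                 params = list(subsample_n = n_reads, top_n = 3L))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  cfg_path
}
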