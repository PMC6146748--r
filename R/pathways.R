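#' Load pathway/marker definitions
#'
#' Pathway definitions map a pathway id to a set of required KEGG Orthology
#' (KO) ids, optional KO ids, and the fraction of required KOs needed for a
#' "present" call. The packaged defaults cover the Wood-Ljungdahl screen
#' (bacterial-type acsB/K14138 and archaeal-type cdhC/K00193 CODH/ACS, the
#' eastern THF branch), EMP glycolysis, PFOR, acetate interconversion
#' (pta + ack), nrfA (K03385) and PRK (K00855). KO memberships are editable
#' configuration, not hard-coded constants.
#'
#' @param path YAML config; default: the packaged definitions.
#' @return named list of `pathway_def` lists (id, name, required, optional,
#'   presence_threshold).
#' @export
load_pathway_defs <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pathway_defs.yaml", package = "halomag")
  abort_if(!file.exists(path), "no such file: ", path)
  raw <- yaml::read_yaml(path)
  abort_if(is.null(raw$pathways), "config must hold a 'pathways' list")
  defs <- lapply(raw$pathways, function(p) {
    abort_if(is.null(p$id) || is.null(p$required) || length(p$required) == 0,
             "each pathway needs an id and a non-empty required KO set")
    required <- as.character(unlist(p$required))
    optional <- as.character(unlist(p$optional))
    kos <- c(required, optional)
    bad <- kos[!grepl("^K[0-9]{5}$", kos)]
    abort_if(length(bad) > 0,
             "malformed KO id in '", p$id, "': ", paste(bad, collapse = ", "))
    abort_if(length(intersect(required, optional)) > 0,
             "required and optional KO sets overlap in '", p$id, "'")
    thr <- if (is.null(p$presence_threshold)) 1.0 else p$presence_threshold
    abort_if(thr <= 0 || thr > 1, "presence_threshold must be in (0, 1]")
    structure(list(id = p$id,
                   name = if (is.null(p$name)) p$id else p$name,
                   required = required, optional = optional,
                   presence_threshold = thr),
              class = "pathway_def")
  })
  ids <- vapply(defs, `[[`, character(1), "id")
  abort_if(anyDuplicated(ids) > 0, "duplicate pathway id: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  setNames(defs, ids)
}

#' Write pathway definitions back to YAML
#'
#' Round-trips with [load_pathway_defs()].
#' @param defs definitions from [load_pathway_defs()].
#' @param path output path.
#' @export
write_pathway_defs <- function(defs, path) {
  yaml::write_yaml(list(pathways = lapply(unname(defs), function(d)
    list(id = d$id, name = d$name, required = as.list(d$required),
         optional = as.list(d$optional),
         presence_threshold = d$presence_threshold))), path)
  invisible(path)
}

# annotation rows for one genome -> distinct KO set
annotated_kos <- function(annotations, genome) {
  unique(annotations$ko[annotations$genome == genome])
}

#' Pathway completeness and presence for one genome
#'
#' Completeness = |required KOs annotated| / |required|; KO multiplicity is
#' ignored (the calls are presence-based). Present iff completeness reaches
#' the definition's presence threshold.
#'
#' @param annotations data.frame with columns `genome`, `gene`, `ko` (and
#'   optionally `length_aa`).
#' @param def one `pathway_def`.
#' @param genome genome id; default: the single genome in the table.
#' @return list of class `pathway_call`: genome, pathway, completeness,
#'   present, missing KOs.
#' @export
score_pathway <- function(annotations, def, genome = NULL) {
  abort_if(!all(c("genome", "ko") %in% names(annotations)),
           "annotation table needs columns genome, ko")
  if (is.null(genome)) {
    gs <- unique(annotations$genome)
    abort_if(length(gs) != 1, "specify `genome` for a multi-genome table")
    genome <- gs
  }
  kos <- annotated_kos(annotations, genome)
  hit <- intersect(def$required, kos)
  completeness <- length(hit) / length(def$required)
  structure(list(genome = genome, pathway = def$id,
                 completeness = completeness,
                 present = completeness >= def$presence_threshold - 1e-12,
                 missing = setdiff(def$required, kos)),
            class = "pathway_call")
}

#' Screen genomes for a marker KO with an optional product-length filter
#'
#' A genome qualifies iff it has at least one gene annotated with the KO whose
#' product length reaches `min_length` residues. With a positive `min_length`,
#' genes lacking length data are excluded from the screen with a warning.
#' The canonical use is the acsB (K14138) scan at 500 aa.
#'
#' @param annotations data.frame: genome, gene, ko, optionally `length_aa`.
#' @param ko KO id to screen for.
#' @param min_length minimum product length in residues (0 disables).
#' @return sorted character vector of qualifying genome ids.
#' @export
screen_marker <- function(annotations, ko, min_length = 0L) {
  abort_if(min_length < 0, "min_length must be >= 0")
  abort_if(!grepl("^K[0-9]{5}$", ko), "malformed KO id: ", ko)
  hits <- annotations[annotations$ko == ko, , drop = FALSE]
  if (min_length > 0) {
    if (!"length_aa" %in% names(hits)) {
      warning("no length_aa column; all hits excluded from length screen")
      return(character())
    }
    nolen <- is.na(hits$length_aa)
    if (any(nolen))
      warning(sum(nolen), " hit(s) lack length data and were excluded")
    hits <- hits[!nolen & hits$length_aa >= min_length, , drop = FALSE]
  }
  sort(unique(hits$genome))
}

#' Genome-by-pathway presence matrix
#'
#' @param annotations annotation table covering one or more genomes.
#' @param defs pathway definitions.
#' @return list: `present` (logical genome x pathway matrix), `completeness`
#'   (numeric matrix), `genome_totals`, `pathway_totals`.
#' @export
summarize_functions <- function(annotations, defs) {
  abort_if(length(defs) == 0, "need at least one pathway definition")
  genomes <- sort(unique(annotations$genome))
  abort_if(length(genomes) == 0, "annotation table holds no genomes")
  pw <- names(defs)
  present <- matrix(FALSE, length(genomes), length(pw),
                    dimnames = list(genomes, pw))
  completeness <- matrix(0, length(genomes), length(pw),
                         dimnames = list(genomes, pw))
  for (g in genomes) for (p in pw) {
    call <- score_pathway(annotations, defs[[p]], genome = g)
    present[g, p] <- call$present
    completeness[g, p] <- call$completeness
  }
  list(present = present, completeness = completeness,
       genome_totals = rowSums(present), pathway_totals = colSums(present))
}
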