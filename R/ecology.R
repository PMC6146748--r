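#' MAG quality tier from completeness and contamination
#'
#' Near-complete: completeness >= 90% and contamination < 5%. Medium:
#' completeness >= 50% and contamination < 10%. Everything else fails.
#' Contamination boundaries are strict (`<`) by default, in line with the
#' MIMAG-style wording; set `contamination_inclusive = TRUE` for `<=`.
#'
#' @param completeness percent in `[0, 100]` (vectorised).
#' @param contamination percent >= 0 (vectorised).
#' @param contamination_inclusive use `<=` instead of `<` at the 5/10 bounds.
#' @return character vector: "near_complete", "medium" or "fail".
#' @examples
#' quality_tier(92, 4)    # near_complete
#' quality_tier(50, 9.9)  # medium
#' quality_tier(95, 5.0)  # medium (strict < 5 boundary)
#' @export
quality_tier <- function(completeness, contamination,
                         contamination_inclusive = FALSE) {
  abort_if(any(!is.finite(completeness)) || any(!is.finite(contamination)),
           "inputs must be finite")
  abort_if(any(completeness < 0) || any(completeness > 100),
           "completeness must be in [0, 100]")
  abort_if(any(contamination < 0), "contamination must be >= 0")
  lt <- if (contamination_inclusive) `<=` else `<`
  ifelse(completeness >= 90 & lt(contamination, 5), "near_complete",
         ifelse(completeness >= 50 & lt(contamination, 10), "medium", "fail"))
}

#' Annotate a bin quality table with tiers
#'
#' @param quality data.frame with columns `mag`, `completeness`,
#'   `contamination`.
#' @param ... passed to [quality_tier()].
#' @return the table with a `tier` column appended.
#' @export
tier_quality_table <- function(quality, ...) {
  abort_if(!all(c("mag", "completeness", "contamination") %in% names(quality)),
           "quality table needs columns mag, completeness, contamination")
  quality$tier <- quality_tier(quality$completeness, quality$contamination, ...)
  quality
}

# deterministic rank used everywhere: largest value first, ties broken by
# ascending id
rank_desc <- function(values, ids) {
  order(order(-values, ids))
}

#' Rank-based salinity-preference scores
#'
#' Per MAG, RPKG is summed over the high-salinity datasets and over the
#' moderate-salinity datasets. A positive score (M down to 1 over M MAGs) is
#' assigned by ranking the high-salinity sums (largest sum gets +M) and a
#' negative score by ranking the moderate-salinity sums (largest gets -M);
#' the salinity preference score is their sum, placing MAGs recruiting
#' preferentially from high salinity on the positive end, moderate salinity on
#' the negative end, and those without preference in the middle. Ranking ties
#' are broken by ascending MAG id.
#'
#' @param profile an `abundance_profile` (or data.frame with dataset, mag,
#'   rpkg).
#' @param groups named character vector mapping every dataset id to
#'   `"high"` or `"moderate"`.
#' @return data.frame sorted by decreasing salinity_score: mag, high_sum,
#'   moderate_sum, pos_rank_score, neg_rank_score, salinity_score.
#' @export
salinity_preference_scores <- function(profile, groups) {
  datasets <- unique(profile$dataset)
  missing <- setdiff(datasets, names(groups))
  abort_if(length(missing) > 0,
           "dataset missing a salinity group label: ",
           paste(missing, collapse = ", "))
  abort_if(!all(groups %in% c("high", "moderate")),
           "groups must be 'high' or 'moderate'")
  abort_if(!any(groups[datasets] == "high") ||
             !any(groups[datasets] == "moderate"),
           "both salinity groups must be non-empty")
  mags <- sort(unique(profile$mag))
  M <- length(mags)
  sum_group <- function(g) {
    sub <- profile[profile$dataset %in% datasets[groups[datasets] == g], ]
    s <- tapply(sub$rpkg, factor(sub$mag, levels = mags), sum, default = 0)
    as.numeric(s)
  }
  high_sum <- sum_group("high")
  moderate_sum <- sum_group("moderate")
  pos <- M - rank_desc(high_sum, mags) + 1L
  neg <- -(M - rank_desc(moderate_sum, mags) + 1L)
  out <- data.frame(mag = mags, high_sum = high_sum,
                    moderate_sum = moderate_sum,
                    pos_rank_score = as.integer(pos),
                    neg_rank_score = as.integer(neg),
                    salinity_score = as.integer(pos + neg),
                    stringsAsFactors = FALSE)
  out[order(-out$salinity_score, out$mag), , drop = FALSE]
}

#' Top-n abundant MAGs in one dataset
#'
#' @param profile an `abundance_profile`.
#' @param dataset dataset id.
#' @param n number of MAGs (>= 1); fewer available means all are returned.
#' @return character vector of MAG ids, by descending RPKG (ties by id).
#' @export
top_n_abundant <- function(profile, dataset, n = 10L) {
  abort_if(n < 1, "n must be >= 1")
  abort_if(!dataset %in% profile$dataset, "unknown dataset: ", dataset)
  sub <- profile[profile$dataset == dataset, ]
  sub <- sub[order(-sub$rpkg, sub$mag), ]
  head(sub$mag, n)
}

#' Average abundance over same-species MAG clusters
#'
#' MAGs whose pairwise decision code marks them as the same species (code 1)
#' or likely the same species (code -1) are merged into clusters by connected
#' components, and RPKG is averaged arithmetically per cluster and dataset.
#'
#' @param profile an `abundance_profile`.
#' @param decision square decision matrix (from [pairwise_matrices()]).
#' @param mags MAG subset to aggregate (default: all matrix rows).
#' @param same_species_codes decision codes treated as joining (default
#'   `c(1, -1)`).
#' @return data.frame: cluster (member ids joined by ";"), dataset, rpkg
#'   (mean over members), n_members.
#' @export
aggregate_species <- function(profile, decision, mags = rownames(decision),
                              same_species_codes = c(1L, -1L)) {
  abort_if(is.null(rownames(decision)) ||
             !all(mags %in% rownames(decision)) ||
             !all(mags %in% colnames(decision)),
           "decision matrix does not cover the MAG subset")
  abort_if(!all(mags %in% profile$mag),
           "profile does not cover the MAG subset")
  mags <- sort(unique(mags))
  n <- length(mags)
  # union-find over pairs flagged as (likely) same species
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (decision[mags[i], mags[j]] %in% same_species_codes) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  labels <- vapply(split(mags, comp), paste, character(1), collapse = ";")
  cluster_of <- setNames(labels[as.character(comp)], mags)
  sub <- profile[profile$mag %in% mags, ]
  sub$cluster <- cluster_of[sub$mag]
  agg <- stats::aggregate(rpkg ~ cluster + dataset, data = sub, FUN = mean)
  sizes <- vapply(strsplit(agg$cluster, ";", fixed = TRUE), length, integer(1))
  agg$n_members <- sizes
  agg[order(agg$cluster, agg$dataset), , drop = FALSE]
}

#' The 16-ribosomal-protein marker panel
#'
#' Standard concatenated-ribosomal-protein panel used for MAG phylogeny.
#' @return character vector of 16 marker names.
#' @export
ribosomal_panel <- function() {
  c("rpL2", "rpL3", "rpL4", "rpL5", "rpL6", "rpL14", "rpL15", "rpL16",
    "rpL18", "rpL22", "rpL24", "rpS3", "rpS8", "rpS10", "rpS17", "rpS19")
}

#' Phylogeny eligibility from ribosomal-protein markers
#'
#' Only markers of at least `min_length` residues (default 80 aa) are
#' considered; a MAG is eligible for the concatenated ribosomal-protein tree
#' iff it encodes at least `min_markers` (default 8) of the 16-protein panel.
#' Duplicate copies of a marker count once — the rule concerns presence.
#'
#' @param markers data.frame with columns `mag`, `marker`, `length_aa`.
#' @param panel marker panel (default [ribosomal_panel()]).
#' @param min_length minimum marker length in residues.
#' @param min_markers minimum number of distinct qualifying markers.
#' @return data.frame: mag, n_markers, eligible.
#' @export
phylogeny_eligibility <- function(markers, panel = ribosomal_panel(),
                                  min_length = 80L, min_markers = 8L) {
  abort_if(!all(c("mag", "marker", "length_aa") %in% names(markers)),
           "markers table needs columns mag, marker, length_aa")
  unknown <- setdiff(unique(markers$marker), panel)
  abort_if(length(unknown) > 0,
           "unknown marker id: ", paste(unknown, collapse = ", "))
  ok <- markers[markers$length_aa >= min_length, ]
  counts <- tapply(ok$marker, ok$mag, function(x) length(unique(x)))
  mags <- sort(unique(markers$mag))
  n <- ifelse(is.na(counts[mags]), 0L, as.integer(counts[mags]))
  data.frame(mag = mags, n_markers = n, eligible = n >= min_markers,
             row.names = NULL, stringsAsFactors = FALSE)
}
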