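#' Load a pKa set for isoelectric-point prediction
#'
#' The package ships an editable table of pKa values for the nine ionizable
#' groups (N- and C-terminus plus the Lys, Arg, His, Asp, Glu, Cys, Tyr side
#' chains). Cys and Tyr are treated as (weakly) acidic; terminal groups are
#' counted once per protein.
#'
#' @param path optional TSV with columns group, pka, type ("acidic"/"basic");
#'   default: the packaged set.
#' @return list of class `pka_set` with named numeric vectors `acidic` and
#'   `basic`.
#' @export
load_pka_set <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pka_default.tsv", package = "halomag")
  df <- read_table_checked(path, required = c("group", "pka", "type"),
                           numeric_cols = "pka")
  abort_if(any(df$pka <= 0 | df$pka >= 14), "pKa values must be in (0, 14)")
  abort_if(!all(df$type %in% c("acidic", "basic")), "type must be acidic/basic")
  structure(list(
    acidic = setNames(df$pka[df$type == "acidic"],
                      df$group[df$type == "acidic"]),
    basic = setNames(df$pka[df$type == "basic"], df$group[df$type == "basic"])
  ), class = "pka_set")
}

# counts of ionizable groups for a set of sequences; rows = proteins
ionizable_counts <- function(seqs) {
  aa <- Biostrings::AAStringSet(toupper(as.character(seqs)))
  freq <- Biostrings::alphabetFrequency(aa)
  letters_present <- colnames(freq)[colSums(freq) > 0]
  bad <- setdiff(letters_present, AA_ALPHABET)
  list(freq = freq, bad = bad)
}

#' Net charge of a protein at a given pH (Henderson-Hasselbalch)
#'
#' `charge = sum_basic n / (1 + 10^(pH - pKa)) - sum_acidic n / (1 + 10^(pKa - pH))`
#' over the ionizable groups; strictly decreasing in pH whenever any ionizable
#' group is present, which guarantees a unique isoelectric point.
#'
#' @param counts named non-negative counts of ionizable groups; names among
#'   `nterm`, `cterm`, `K`, `R`, `H`, `D`, `E`, `C`, `Y`. Groups absent from
#'   the vector count 0.
#' @param pH pH value(s) in `[0, 14]` (vectorised).
#' @param pka a `pka_set` from [load_pka_set()].
#' @return net charge in elementary charges, one value per pH.
#' @export
net_charge <- function(counts, pH, pka = load_pka_set()) {
  abort_if(any(counts < 0), "counts must be non-negative")
  abort_if(any(pH < 0 | pH > 14), "pH must be in [0, 14]")
  cnt <- function(g) if (g %in% names(counts)) counts[[g]] else 0
  pos <- Reduce(`+`, lapply(names(pka$basic), function(g)
    cnt(g) / (1 + 10^(pH - pka$basic[[g]]))))
  negv <- Reduce(`+`, lapply(names(pka$acidic), function(g)
    cnt(g) / (1 + 10^(pka$acidic[[g]] - pH))))
  unname(pos - negv)
}

# vectorised bisection on the ionizable-count matrix; returns pI per row
pi_from_counts <- function(freq, pka, tolerance = 1e-4, max_iter = 200L) {
  n <- nrow(freq)
  col0 <- function(g) if (g %in% colnames(freq)) freq[, g] else rep(0, n)
  side_counts <- lapply(setNames(nm = c("K", "R", "H", "D", "E", "C", "Y")),
                        col0)
  charge_at <- function(pH) {
    z <- rep(0, n)
    for (g in names(pka$basic)) {
      ng <- if (g == "nterm") rep(1, n) else side_counts[[g]]
      z <- z + ng / (1 + 10^(pH - pka$basic[[g]]))
    }
    for (g in names(pka$acidic)) {
      ng <- if (g == "cterm") rep(1, n) else side_counts[[g]]
      z <- z - ng / (1 + 10^(pka$acidic[[g]] - pH))
    }
    z
  }
  lo <- rep(0, n); hi <- rep(14, n)
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    z <- charge_at(mid)
    if (all(abs(z) < tolerance)) break
    pos <- z > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  # returned unrounded: the convergence guarantee is |net charge| < tolerance
  # at the returned pH; output tables format to 4 decimals
  (lo + hi) / 2
}

#' Predicted isoelectric point of a protein
#'
#' Bisection on `[0, 14]` of the net-charge function until the absolute charge
#' falls below `tolerance`; the root is unique because the charge is strictly
#' decreasing in pH. The returned value satisfies
#' `|net_charge(counts, pI)| < tolerance` (output tables format pI to 4
#' decimals).
#'
#' @param sequence protein sequence(s): character vector or AAStringSet over
#'   the 20 standard residues.
#' @param pka a `pka_set`.
#' @param tolerance charge tolerance at the root (default 1e-4).
#' @param on_invalid "error" (default) rejects sequences with non-standard
#'   letters (B, Z, X, ...); "skip" drops the offending residues with a
#'   warning.
#' @return numeric vector of pI values.
#' @examples
#' compute_pi(strrep("D", 20)) < 4
#' @export
compute_pi <- function(sequence, pka = load_pka_set(), tolerance = 1e-4,
                       on_invalid = c("error", "skip")) {
  on_invalid <- match.arg(on_invalid)
  seqs <- as.character(sequence)
  abort_if(length(seqs) == 0 || any(nchar(seqs) == 0),
           "sequences must be non-empty")
  ic <- ionizable_counts(seqs)
  if (length(ic$bad) > 0) {
    if (on_invalid == "error")
      stop("non-standard residue letter(s): ", paste(ic$bad, collapse = ", "),
           call. = FALSE)
    warning("skipping non-standard residues: ",
            paste(ic$bad, collapse = ", "))
  }
  pi_from_counts(ic$freq, pka, tolerance)
}

#' Isoelectric-point histogram of a proteome
#'
#' Histogram of predicted pI values over half-open bins `[left, right)` of
#' width `bin_width` (default 0.2) spanning `[0, 14]`; the median pI and the
#' acidic fraction (share of proteins with pI < 5.5) are computed from the
#' unbinned values.
#'
#' @param proteome AAStringSet or character vector of protein sequences (or a
#'   numeric vector of precomputed pI values).
#' @param bin_width bin width; must divide the `[0, 14]` span.
#' @param pka a `pka_set`.
#' @param id proteome label.
#' @param acidic_cutoff pI below which a protein counts as acidic (5.5).
#' @return object of class `pi_profile`: list with `id`, `breaks`, `counts`,
#'   `n_proteins`, `median_pi`, `acidic_fraction`, `pi` (per-protein values).
#' @export
pi_profile <- function(proteome, bin_width = 0.2, pka = load_pka_set(),
                       id = "proteome", acidic_cutoff = 5.5) {
  nbins <- 14 / bin_width
  abort_if(abs(nbins - round(nbins)) > 1e-9,
           "bin_width must divide the [0, 14] span")
  pi <- if (is.numeric(proteome)) proteome else compute_pi(proteome, pka = pka)
  abort_if(length(pi) == 0, "empty proteome")
  breaks <- seq(0, 14, by = bin_width)
  idx <- pmin(floor(pi / bin_width) + 1L, length(breaks) - 1L)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  structure(list(id = id, breaks = breaks, counts = counts,
                 n_proteins = length(pi), median_pi = median(pi),
                 acidic_fraction = mean(pi < acidic_cutoff),
                 acidic_cutoff = acidic_cutoff, pi = pi),
            class = "pi_profile")
}

#' @export
print.pi_profile <- function(x, ...) {
  cat(sprintf("pI profile '%s': %d proteins, median pI %.2f, %.1f%% with pI < %.1f\n",
              x$id, x$n_proteins, x$median_pi, 100 * x$acidic_fraction,
              x$acidic_cutoff))
  invisible(x)
}

#' Detect a pronounced acidic peak in a pI profile
#'
#' Operational criterion for an acid-shifted ("salt-in") proteome: the modal
#' histogram bin centre lies below `mode_cutoff` AND at least
#' `fraction_cutoff` of proteins have pI below the acidic cutoff. Both
#' quantities are reported alongside the call; ties for the modal bin resolve
#' to the most acidic bin.
#'
#' @param profile a `pi_profile`.
#' @param mode_cutoff maximum modal bin centre (default 5.5).
#' @param fraction_cutoff minimum acidic protein fraction (default 0.5).
#' @return list: `acidic` (logical), `modal_center`, `acidic_fraction`,
#'   thresholds used.
#' @export
acidic_peak <- function(profile, mode_cutoff = 5.5, fraction_cutoff = 0.5) {
  abort_if(!inherits(profile, "pi_profile"), "need a pi_profile")
  centers <- profile$breaks[-length(profile$breaks)] + diff(profile$breaks) / 2
  modal <- centers[which.max(profile$counts)]
  list(acidic = (modal < mode_cutoff) &&
         (profile$acidic_fraction >= fraction_cutoff),
       modal_center = modal, acidic_fraction = profile$acidic_fraction,
       mode_cutoff = mode_cutoff, fraction_cutoff = fraction_cutoff)
}
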