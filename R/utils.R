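# internal helpers: seeded RNG isolation, seed derivation, assertions

# evaluate expr with a private RNG stream; the caller's .Random.seed is
# untouched, so generators never leak global random state
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a stage seed from a global seed
#'
#' One global seed drives the whole pipeline; per-stage seeds are derived by
#' hashing the stage name so stages can be rerun in isolation and adding a
#' stage never perturbs another stage's stream.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(length(stage) == 1, is.character(stage))
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

abort_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

DNA_BASES <- c("A", "C", "G", "T")

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# normalise a genome argument (character vector, DNAString(Set)) to an
# uppercase named character vector of contigs
as_contigs <- function(x, id = NULL) {
  if (inherits(x, "DNAStringSet") || inherits(x, "DNAString") ||
      inherits(x, "BStringSet")) {
    x <- as.character(x)
  }
  abort_if(!is.character(x) || length(x) == 0,
           "genome must be a character vector or DNAStringSet")
  x <- toupper(x)
  abort_if(any(nchar(x) == 0), "genome contains an empty contig")
  if (is.null(names(x)))
    names(x) <- paste0(if (is.null(id)) "contig" else id, "_", seq_along(x))
  x
}

# join contigs with an N spacer so no k-mer seed and no profitable local
# extension crosses a contig boundary
concat_subject <- function(contigs, spacer = 100) {
  paste(contigs, collapse = strrep("N", spacer))
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
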