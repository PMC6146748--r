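#' Read a FASTA file with validation
#'
#' Wraps Biostrings parsing with the checks the pipeline relies on: record
#' order and ids preserved (id = first whitespace-delimited token of the
#' header), sequences uppercased, duplicate ids and empty files rejected, and
#' non-IUPAC characters refused beyond a configurable tolerance.
#'
#' @param path FASTA path.
#' @param type "dna" or "protein".
#' @param max_other maximum tolerated fraction of letters outside the core
#'   alphabet (IUPAC ambiguity codes for DNA); default 0 beyond N.
#' @return a [Biostrings::DNAStringSet] or [Biostrings::AAStringSet].
#' @export
read_fasta <- function(path, type = c("dna", "protein"), max_other = 0) {
  type <- match.arg(type)
  abort_if(!file.exists(path), "no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  abort_if(length(raw) == 0, "empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  abort_if(length(dup) > 0,
           "duplicate FASTA id: ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(raw))
  if (type == "dna") {
    core <- c(DNA_BASES, "N")
    iupac <- c(core, "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U")
    letters_seen <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
    bad <- setdiff(letters_seen, iupac)
    abort_if(length(bad) > 0,
             "non-IUPAC characters in ", path, ": ",
             paste(bad, collapse = ", "))
    n_other <- sum(vapply(seqs, function(s)
      nchar(gsub(paste0("[", paste(core, collapse = ""), "]"), "", s)),
      numeric(1)))
    frac <- n_other / sum(nchar(seqs))
    abort_if(frac > max_other,
             sprintf("ambiguity codes exceed tolerance (%.3g > %.3g)",
                     frac, max_other))
    out <- Biostrings::DNAStringSet(seqs)
  } else {
    bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]),
                   c(AA_ALPHABET, "X", "B", "Z", "U", "*"))
    abort_if(length(bad) > 0,
             "unexpected protein characters in ", path, ": ",
             paste(bad, collapse = ", "))
    out <- Biostrings::AAStringSet(seqs)
  }
  names(out) <- ids
  out
}

#' Write sequences as FASTA
#' @param x an XStringSet.
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ read set
#' @param path FASTQ path.
#' @return DNAStringSet (qualities are ignored; the analyses are
#'   identity-threshold based).
#' @export
read_fastq <- function(path) {
  abort_if(!file.exists(path), "no such file: ", path)
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Read a tab-separated table with a required schema
#'
#' One header line; `#`-prefixed comment lines and blank lines are ignored;
#' unknown columns are preserved. Declared numeric columns are coerced with
#' row-numbered error messages.
#'
#' @param path TSV path.
#' @param required character vector of required column names.
#' @param numeric_cols columns that must parse as numbers.
#' @return data.frame.
#' @export
read_table_checked <- function(path, required = character(),
                               numeric_cols = character()) {
  abort_if(!file.exists(path), "no such file: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   blank.lines.skip = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing <- setdiff(required, names(df))
  abort_if(length(missing) > 0,
           "missing required column(s) in ", path, ": ",
           paste(missing, collapse = ", "))
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    abort_if(length(bad) > 0,
             sprintf("column '%s' of %s not numeric at data row %s",
                     col, path, paste(bad, collapse = ", ")))
    df[[col]] <- v
  }
  df
}

#' Write a table as TSV with a provenance comment header
#'
#' @param df data.frame.
#' @param path output path.
#' @param comment optional character vector written as `# ` lines before the
#'   header (tool version and parameters, per the run-log convention).
#' @export
write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# square matrix <-> labelled TSV (row label in first column "id")
write_matrix_tsv <- function(m, path, comment = NULL) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, comment = comment)
}

read_matrix_tsv <- function(path) {
  df <- read_table_checked(path, required = "id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  storage.mode(m) <- "double"
  m
}
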