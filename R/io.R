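# File I/O: FASTA via Biostrings, TSV with provenance headers.

provenance_header <- function(params = list()) {
  ver <- tryCatch(as.character(utils::packageVersion("topolabel")),
                  error = function(e) "dev")
  p <- if (length(params)) {
    paste(vapply(names(params), function(k) paste0(k, "=", params[[k]]),
                 character(1)), collapse = "; ")
  } else ""
  h <- paste0("# topolabel ", ver, "; coordinates 1-based inclusive")
  if (nzchar(p)) h <- c(h, paste0("# ", p))
  h
}

#' Write a TSV with a provenance header
#'
#' Tab-separated, `#` comment lines, UTF-8, `.` decimal separator. The
#' header records the package version and any parameters supplied.
#'
#' @param df A `data.frame`.
#' @param path Output file.
#' @param params Optional named list recorded in the header (seeds,
#'   thresholds, ...).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, params = list()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by this package
#' @param path Input file; `#` lines are ignored.
#' @return `data.frame`.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read protein sequences from FASTA
#'
#' Parsing is done by `Biostrings::readAAStringSet()`; a light structural
#' pre-scan reports malformed records with their line number, and duplicate
#' ids are rejected. The record id is the first whitespace-delimited token of
#' the header; the remainder becomes the description. Sequences are
#' upper-cased.
#'
#' @param path FASTA file.
#' @return Protein `data.frame` (see [protein_set()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  meaningful <- which(nzchar(trimws(lines)) & !grepl("^[;#]", lines))
  if (length(meaningful) == 0L) {
    return(protein_set(character(0), character(0)))
  }
  if (!startsWith(lines[meaningful[1]], ">")) {
    stop("malformed FASTA: sequence line before first header at line ",
         meaningful[1])
  }
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  desc <- trimws(substring(headers, nchar(ids) + 1L))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  protein_set(ids, as.character(seqs), desc)
}

#' Write protein sequences to FASTA
#' @param db Protein `data.frame` (see [protein_set()]).
#' @param path Output file.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path, width = 60L) {
  validate_proteins(db)
  hdr <- ifelse(nzchar(db$description),
                paste(db$id, db$description), db$id)
  x <- Biostrings::AAStringSet(db$sequence)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}
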