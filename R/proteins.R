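# Protein sequence containers and validation.

.SEQ_LETTERS <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                  "R","S","T","V","W","Y","X")

#' Build a protein set
#'
#' Proteins are held in a plain `data.frame` with columns `id`, `sequence`
#' and `description`. Sequences are upper-cased and restricted to the 20
#' canonical one-letter codes plus `X` (treated as a uniform-emission
#' wildcard by the topology model).
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Character vector of sequences.
#' @param description Optional character vector of free-text descriptions.
#' @return `data.frame` with columns `id`, `sequence`, `description`.
#' @export
protein_set <- function(id, sequence, description = "") {
  stopifnot(length(id) == length(sequence))
  db <- data.frame(id = as.character(id),
                   sequence = toupper(as.character(sequence)),
                   description = rep_len(as.character(description), length(id)),
                   stringsAsFactors = FALSE)
  validate_proteins(db)
  db
}

#' Validate a protein set
#'
#' @param db `data.frame` as returned by [protein_set()].
#' @return `db`, invisibly, after checking ids are unique and sequences are
#'   non-empty strings over the allowed alphabet.
#' @export
validate_proteins <- function(db) {
  stopifnot(is.data.frame(db), all(c("id", "sequence") %in% names(db)))
  if (anyDuplicated(db$id)) {
    stop("duplicate protein id(s): ",
         paste(unique(db$id[duplicated(db$id)]), collapse = ", "))
  }
  if (any(!nzchar(db$sequence))) {
    stop("empty sequence for protein(s): ",
         paste(db$id[!nzchar(db$sequence)], collapse = ", "))
  }
  ok <- !grepl(paste0("[^", paste(.SEQ_LETTERS, collapse = ""), "]"), db$sequence)
  if (any(!ok)) {
    stop("illegal characters in sequence(s): ", paste(db$id[!ok], collapse = ", "))
  }
  invisible(db)
}
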