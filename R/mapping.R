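# Map modified-peptide observations onto protein sequences, aggregate labeled
# positions with replicate provenance, apply the >=3-replicate filter,
# classify proteins and validate against reference topologies.

.OBS_COLUMNS <- c("peptide", "modification", "mod_offset", "experiment_id",
                  "replicate_id", "cell_line", "protein_hint", "score")

#' Build a modified-peptide observation table
#'
#' One row per MS identification of a peptide carrying a labeled lysine (or
#' labeled protein N-terminus, `mod_offset` 1), with experiment, biological
#' replicate and cell line provenance.
#'
#' @param peptide,modification,mod_offset,experiment_id,replicate_id,cell_line,protein_hint,score
#'   Column vectors (recycled where scalar); `mod_offset` is the 1-based
#'   position of the modified residue within the peptide.
#' @return Observation `data.frame`.
#' @export
observation_table <- function(peptide, modification = "thioacyl", mod_offset,
                              experiment_id = "", replicate_id, cell_line = "",
                              protein_hint = "", score = NA_real_) {
  n <- length(peptide)
  data.frame(peptide = toupper(as.character(peptide)),
             modification = rep_len(as.character(modification), n),
             mod_offset = as.integer(rep_len(mod_offset, n)),
             experiment_id = rep_len(as.character(experiment_id), n),
             replicate_id = rep_len(as.character(replicate_id), n),
             cell_line = rep_len(as.character(cell_line), n),
             protein_hint = rep_len(as.character(protein_hint), n),
             score = rep_len(as.numeric(score), n),
             stringsAsFactors = FALSE)
}

#' Read an observation TSV
#' @param path File with header columns `peptide, modification, mod_offset,
#'   experiment_id, replicate_id, cell_line, protein_hint, score`.
#' @return Observation `data.frame`.
#' @export
read_observations <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("peptide", "mod_offset", "replicate_id")
  if (!all(need %in% names(tab))) {
    stop("observation TSV must have columns: ", paste(need, collapse = ", "))
  }
  for (col in .OBS_COLUMNS) if (is.null(tab[[col]])) tab[[col]] <- ""
  tab$mod_offset <- as.integer(tab$mod_offset)
  tab[.OBS_COLUMNS]
}

#' Write an observation TSV
#' @param observations Observation `data.frame`.
#' @param path Output file.
#' @param params Optional named list recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path, params = list()) {
  write_tsv(observations[.OBS_COLUMNS], path, params = params)
  invisible(path)
}

# best ungapped alignment windows of pep in seq with identity >= min_identity;
# returns start offsets of the best-identity location(s) (ties -> earliest)
.best_windows <- function(pep_chars, seq_chars, min_identity) {
  np <- length(pep_chars); ns <- length(seq_chars)
  if (np > ns) return(integer(0))
  n_start <- ns - np + 1L
  ident <- vapply(seq_len(n_start), function(s) {
    sum(pep_chars == seq_chars[s:(s + np - 1L)])
  }, numeric(1)) / np
  best <- max(ident)
  if (best < min_identity) return(integer(0))
  which(ident == best)[1L]
}

#' Map modified-peptide observations onto a protein database
#'
#' Each peptide is first located by exact substring search in every database
#' protein; a peptide matching a protein at multiple offsets maps to all of
#' them and is flagged ambiguous, as is a peptide matching several proteins.
#' When no exact match exists anywhere, an ungapped sliding alignment per
#' protein accepts the best window with identity at least `min_identity`
#' (default 0.95, the conventional 95 percent identity filter). Observations
#' landing on the same (protein, position) are merged, accumulating counts
#' and replicate/cell-line sets.
#'
#' Observations whose peptide contains illegal characters, or whose modified
#' residue is neither a lysine nor the peptide N-terminus, are rejected; the
#' rejects are returned in the `"rejected"` attribute.
#'
#' @param observations Observation `data.frame` (see [observation_table()]).
#' @param database Protein `data.frame` (see [protein_set()]).
#' @param min_identity Identity threshold for the fallback sliding alignment.
#' @return `mapped_positions` `data.frame`: `protein_id`, `position`
#'   (1-based), `residue`, `observation_count`, `n_replicates`, `ambiguous`,
#'   plus list columns `replicates` and `cell_lines`.
#' @export
map_peptides <- function(observations, database, min_identity = 0.95) {
  validate_proteins(database)
  stopifnot(min_identity > 0, min_identity <= 1)
  empty <- data.frame(protein_id = character(0), position = integer(0),
                      residue = character(0), observation_count = integer(0),
                      n_replicates = integer(0), ambiguous = logical(0))
  empty$replicates <- list(); empty$cell_lines <- list()
  class(empty) <- c("mapped_positions", "data.frame")
  if (nrow(observations) == 0L) return(empty)

  legal <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", observations$peptide)
  off_ok <- observations$mod_offset >= 1L &
    observations$mod_offset <= nchar(observations$peptide)
  res_at <- substring(observations$peptide, observations$mod_offset,
                      observations$mod_offset)
  chem_ok <- off_ok & (res_at == "K" | observations$mod_offset == 1L)
  keep <- legal & chem_ok
  rejected <- observations[!keep, , drop = FALSE]
  if (nrow(rejected)) {
    message("map_peptides: rejected ", nrow(rejected),
            " observation(s) with illegal peptides or modification offsets")
  }
  observations <- observations[keep, , drop = FALSE]
  if (nrow(observations) == 0L) {
    attr(empty, "rejected") <- rejected
    return(empty)
  }

  seq_chars <- lapply(database$sequence, function(s) strsplit(s, "")[[1]])
  # locate each distinct peptide once: list of (protein index, match start)
  peps <- unique(observations$peptide)
  loc <- lapply(peps, function(pep) {
    hits_i <- integer(0); hits_s <- integer(0)
    for (j in seq_along(database$id)) {
      m <- gregexpr(pep, database$sequence[j], fixed = TRUE)[[1]]
      if (m[1] != -1L) {
        hits_i <- c(hits_i, rep(j, length(m)))
        hits_s <- c(hits_s, as.integer(m))
      }
    }
    if (length(hits_i) == 0L) {
      pc <- strsplit(pep, "")[[1]]
      for (j in seq_along(database$id)) {
        s <- .best_windows(pc, seq_chars[[j]], min_identity)
        if (length(s)) {
          hits_i <- c(hits_i, j); hits_s <- c(hits_s, s)
        }
      }
    }
    list(protein = hits_i, start = hits_s,
         ambiguous = length(hits_i) > 1L)
  })
  names(loc) <- peps

  acc <- new.env(parent = emptyenv())
  n_mapped_events <- 0L
  for (r in seq_len(nrow(observations))) {
    ob <- observations[r, ]
    hit <- loc[[ob$peptide]]
    if (length(hit$protein) == 0L) next
    for (h in seq_along(hit$protein)) {
      j <- hit$protein[h]
      pos <- hit$start[h] + ob$mod_offset - 1L
      key <- paste0(database$id[j], "\r", pos)
      cur <- acc[[key]]
      if (is.null(cur)) {
        cur <- list(protein_id = database$id[j], position = pos,
                    residue = substring(database$sequence[j], pos, pos),
                    observation_count = 0L, replicates = character(0),
                    cell_lines = character(0), ambiguous = FALSE)
      }
      cur$observation_count <- cur$observation_count + 1L
      cur$replicates <- union(cur$replicates, ob$replicate_id)
      cur$cell_lines <- union(cur$cell_lines, ob$cell_line)
      cur$ambiguous <- cur$ambiguous || hit$ambiguous
      acc[[key]] <- cur
      n_mapped_events <- n_mapped_events + 1L
    }
  }
  items <- as.list(acc)
  if (length(items) == 0L) {
    attr(empty, "rejected") <- rejected
    return(empty)
  }
  out <- data.frame(
    protein_id = vapply(items, `[[`, character(1), "protein_id"),
    position = vapply(items, `[[`, integer(1), "position"),
    residue = vapply(items, `[[`, character(1), "residue"),
    observation_count = vapply(items, `[[`, integer(1), "observation_count"),
    n_replicates = vapply(items, function(x) length(x$replicates), integer(1)),
    ambiguous = vapply(items, `[[`, logical(1), "ambiguous"),
    stringsAsFactors = FALSE
  )
  out$replicates <- lapply(items, function(x) sort(x$replicates))
  out$cell_lines <- lapply(items, function(x) sort(x$cell_lines))
  out <- out[order(out$protein_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mapped_positions", "data.frame")
  attr(out, "rejected") <- rejected
  attr(out, "n_mapped_events") <- n_mapped_events
  out
}

#' Keep positions supported by enough biological replicates
#'
#' Retains exactly the mapped positions identified in at least
#' `min_replicates` distinct biological replicates (default 3, the
#' at-least-three-independent-experiments rule). Order-preserving and
#' idempotent.
#'
#' @param positions `mapped_positions` from [map_peptides()].
#' @param min_replicates Minimum number of distinct replicate ids.
#' @return Filtered `mapped_positions`.
#' @export
filter_by_replicates <- function(positions, min_replicates = 3L) {
  stopifnot(min_replicates >= 1L)
  keep <- vapply(positions$replicates, length, integer(1)) >= min_replicates
  out <- positions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify database proteins as transmembrane or soluble
#'
#' A protein is a TMP iff its unconstrained topology prediction contains at
#' least one membrane segment.
#'
#' @param database Protein `data.frame`.
#' @param model A `topology_hmm`.
#' @return Named character vector, `"TMP"` or `"soluble"` per protein id.
#' @export
classify_proteins <- function(database, model) {
  if (nrow(database) == 0L) return(stats::setNames(character(0), character(0)))
  out <- vapply(seq_len(nrow(database)), function(i) {
    pred <- predict_topology(model, database[i, , drop = FALSE])
    if (any(pred$topology$segments$label == "M")) "TMP" else "soluble"
  }, character(1))
  stats::setNames(out, database$id)
}

#' Validate mapped positions against reference topologies
#'
#' A position is comparable iff its protein has a reference topology covering
#' that residue; it is confirmed extracellular iff the reference label there
#' is `O`.
#'
#' @param positions `mapped_positions`.
#' @param references List of `topology` objects.
#' @return A `validation_report`: totals, percent confirmed (absent when no
#'   position is comparable) and per-position verdicts.
#' @export
validate_against_reference <- function(positions, references) {
  refs <- list()
  for (t in references) refs[[t$protein_id]] <- t
  n <- nrow(positions)
  comparable <- logical(n); confirmed <- logical(n)
  ref_label <- character(n)
  for (i in seq_len(n)) {
    ref <- refs[[positions$protein_id[i]]]
    pos <- positions$position[i]
    if (is.null(ref)) { ref_label[i] <- NA_character_; next }
    if (pos > topology_length(ref)) {
      message("validate_against_reference: position ", pos, " beyond reference",
              " length for ", positions$protein_id[i], "; not comparable")
      ref_label[i] <- NA_character_
      next
    }
    comparable[i] <- TRUE
    lab <- substring(topology_labels(ref), pos, pos)
    ref_label[i] <- lab
    confirmed[i] <- lab == "O"
  }
  n_comp <- sum(comparable)
  structure(list(
    n_positions_total = n,
    n_positions_comparable = n_comp,
    n_confirmed_extracellular = sum(confirmed),
    percent_confirmed = if (n_comp > 0) 100 * sum(confirmed) / n_comp else NULL,
    verdicts = data.frame(protein_id = positions$protein_id,
                          position = positions$position,
                          comparable = comparable,
                          reference_label = ref_label,
                          confirmed = confirmed,
                          stringsAsFactors = FALSE)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation against reference topologies:\n",
      x$n_positions_total, "positions,", x$n_positions_comparable,
      "comparable,", x$n_confirmed_extracellular, "confirmed extracellular")
  if (is.null(x$percent_confirmed)) {
    cat(" (percent confirmed undefined: no comparable positions)\n")
  } else {
    cat(sprintf(" (%.1f%% confirmed)\n", x$percent_confirmed))
  }
  invisible(x)
}

#' Export filtered positions as extracellular constraints
#'
#' Every labeled lysine position becomes a constraint with label `O` — the
#' labeling chemistry only reaches the extracellular side.
#'
#' @param positions `mapped_positions`.
#' @param source Source string recorded per constraint.
#' @return Constraint `data.frame` (see [constraint_table()]).
#' @export
positions_to_constraints <- function(positions, source = "surface-labeling") {
  constraint_table(positions$protein_id, positions$position,
                   label = "O", source = source)
}

#' Write mapped positions as TSV (list columns collapsed with commas)
#' @param positions `mapped_positions`.
#' @param path Output file.
#' @param params Optional provenance parameters.
#' @return `path`, invisibly.
#' @export
write_mapped_positions <- function(positions, path, params = list()) {
  flat <- positions
  flat$replicates <- vapply(positions$replicates, paste, character(1),
                            collapse = ",")
  flat$cell_lines <- vapply(positions$cell_lines, paste, character(1),
                            collapse = ",")
  class(flat) <- "data.frame"
  write_tsv(flat, path, params = params)
  invisible(path)
}

#' Read mapped positions written by [write_mapped_positions()]
#' @param path Input file.
#' @return `mapped_positions` `data.frame`.
#' @export
read_mapped_positions <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  tab$replicates <- strsplit(as.character(tab$replicates), ",", fixed = TRUE)
  tab$cell_lines <- strsplit(as.character(tab$cell_lines), ",", fixed = TRUE)
  tab$position <- as.integer(tab$position)
  class(tab) <- c("mapped_positions", "data.frame")
  tab
}
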