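# Per-residue I/M/O topology annotations as alternating segments, plus the
# positional constraints consumed by the constrained decoder.

#' Construct a topology annotation
#'
#' A topology assigns every residue of a protein to inside (`I`, cytosolic),
#' membrane helix (`M`) or outside (`O`, extracellular/lumenal), as an
#' ordered list of segments tiling `[1, L]`. Segments must alternate
#' loop/helix with every `M` flanked by one `I` and one `O` side, so a valid
#' topology is either a single loop segment or the pattern
#' loop, M, loop, M, ... with loop labels alternating between I and O.
#'
#' @param protein_id Protein identifier.
#' @param start,end Integer vectors of 1-based inclusive segment bounds.
#' @param label Character vector over `{I, M, O}`.
#' @param min_helix,max_helix Allowed membrane-helix length range.
#' @return A `topology` object.
#' @export
topology <- function(protein_id, start, end, label,
                     min_helix = 15L, max_helix = 25L) {
  seg <- data.frame(start = as.integer(start), end = as.integer(end),
                    label = as.character(label), stringsAsFactors = FALSE)
  obj <- structure(list(protein_id = as.character(protein_id), segments = seg),
                   class = "topology")
  validate_topology(obj, min_helix = min_helix, max_helix = max_helix)
  obj
}

#' Validate a topology annotation
#'
#' @param top A `topology` object.
#' @param min_helix,max_helix Allowed membrane-helix length range.
#' @return `top`, invisibly; errors name the protein and offending segment.
#' @export
validate_topology <- function(top, min_helix = 15L, max_helix = 25L) {
  stopifnot(inherits(top, "topology"))
  seg <- top$segments
  id <- top$protein_id
  if (nrow(seg) == 0L) stop("topology of ", id, " has no segments")
  if (!all(seg$label %in% c("I", "M", "O"))) {
    stop("topology of ", id, ": labels must be I, M or O")
  }
  if (seg$start[1] != 1L) stop("topology of ", id, " does not start at residue 1")
  if (any(seg$end < seg$start)) {
    k <- which(seg$end < seg$start)[1]
    stop("topology of ", id, ": segment ", k, " has end < start")
  }
  if (nrow(seg) > 1L) {
    gaps <- seg$start[-1L] != seg$end[-nrow(seg)] + 1L
    if (any(gaps)) {
      k <- which(gaps)[1]
      stop("topology of ", id, ": segments ", k, " and ", k + 1L,
           " do not tile (gap or overlap)")
    }
    if (any(seg$label[-1L] == seg$label[-nrow(seg)])) {
      stop("topology of ", id, ": consecutive segments share a label")
    }
  }
  is_m <- seg$label == "M"
  if (any(is_m)) {
    for (k in which(is_m)) {
      if (k == 1L || k == nrow(seg)) {
        stop("topology of ", id, ": M segment ", k, " at protein terminus")
      }
      flank <- sort(c(seg$label[k - 1L], seg$label[k + 1L]))
      if (!identical(flank, c("I", "O"))) {
        stop("topology of ", id, ": M segment ", k,
             " not flanked by one I and one O side")
      }
      len <- seg$end[k] - seg$start[k] + 1L
      if (len < min_helix || len > max_helix) {
        stop("topology of ", id, ": M segment ", k, " length ", len,
             " outside [", min_helix, ", ", max_helix, "]")
      }
    }
  }
  invisible(top)
}

#' @export
print.topology <- function(x, ...) {
  cat("topology of", x$protein_id, "(", topology_length(x), "aa,",
      sum(x$segments$label == "M"), "TM helices )\n")
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Protein length covered by a topology
#' @param top A `topology` object.
#' @return Integer length.
#' @export
topology_length <- function(top) top$segments$end[nrow(top$segments)]

#' Per-residue label string of a topology
#' @param top A `topology` object.
#' @return String of `I`/`M`/`O`, one character per residue.
#' @export
topology_labels <- function(top) {
  seg <- top$segments
  paste(rep(seg$label, seg$end - seg$start + 1L), collapse = "")
}

#' Build a topology from a per-residue label string
#' @param protein_id Protein identifier.
#' @param labels String of `I`/`M`/`O`.
#' @param ... Passed to [topology()] (helix length bounds).
#' @return A `topology` object.
#' @export
topology_from_labels <- function(protein_id, labels, ...) {
  r <- rle(strsplit(labels, "")[[1]])
  end <- cumsum(r$lengths)
  start <- c(1L, end[-length(end)] + 1L)
  topology(protein_id, start, end, r$values, ...)
}

#' Read topology annotations
#'
#' Auto-detects the format: a segment TSV with header columns
#' `protein_id, start, end, label` (1-based inclusive), or a FASTA-like file
#' of per-residue `I`/`M`/`O` label strings under `>id` headers.
#'
#' @param path Input file.
#' @param ... Passed to [topology()] (helix length bounds).
#' @return Named list of `topology` objects.
#' @export
read_topology <- function(path, ...) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0L) return(list())
  if (startsWith(body[1], ">")) {
    db <- read_fasta_labels(path)
    tops <- lapply(names(db), function(id) topology_from_labels(id, db[[id]], ...))
  } else {
    tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    need <- c("protein_id", "start", "end", "label")
    if (!all(need %in% names(tab))) {
      stop("segment TSV must have columns: ", paste(need, collapse = ", "))
    }
    tops <- lapply(split(tab, tab$protein_id), function(d) {
      d <- d[order(d$start), , drop = FALSE]
      topology(d$protein_id[1], d$start, d$end, d$label, ...)
    })
  }
  names(tops) <- vapply(tops, function(t) t$protein_id, character(1))
  tops
}

# FASTA-like reader for label strings (not protein sequences)
read_fasta_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  out <- list(); cur <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      cur <- strsplit(sub("^>", "", ln), "\\s+")[[1]][1]
      if (cur %in% names(out)) stop("duplicate id '", cur, "' at line ", i)
      out[[cur]] <- ""
    } else {
      if (is.null(cur)) stop("sequence line before first header at line ", i)
      out[[cur]] <- paste0(out[[cur]], gsub("\\s", "", ln))
    }
  }
  out
}

#' Write topology annotations
#'
#' @param tops List of `topology` objects.
#' @param path Output file.
#' @param format `"segments"` for the segment TSV, `"labels"` for the
#'   FASTA-like label-string format.
#' @param params Optional named list recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_topology <- function(tops, path, format = c("segments", "labels"),
                           params = list()) {
  format <- match.arg(format)
  if (inherits(tops, "topology")) tops <- list(tops)
  if (format == "segments") {
    tab <- do.call(rbind, lapply(tops, function(t) {
      cbind(data.frame(protein_id = t$protein_id, stringsAsFactors = FALSE),
            t$segments)
    }))
    write_tsv(tab, path, params = params)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(provenance_header(params), con)
    for (t in tops) writeLines(c(paste0(">", t$protein_id), topology_labels(t)), con)
  }
  invisible(path)
}

#' Build a constraint table
#'
#' A topology constraint pins one residue of one protein to a loop label
#' (`I` or `O`); the labeling chemistry only localizes loop residues, so `M`
#' is never a constraint label.
#'
#' @param protein_id,position,label,source Vectors of equal length (recycled
#'   where scalar); `position` 1-based.
#' @return `data.frame` with columns `protein_id`, `position`, `label`,
#'   `source`.
#' @export
constraint_table <- function(protein_id, position, label = "O", source = "") {
  n <- max(length(protein_id), length(position))
  out <- data.frame(protein_id = rep_len(as.character(protein_id), n),
                    position = rep_len(as.integer(position), n),
                    label = rep_len(as.character(label), n),
                    source = rep_len(as.character(source), n),
                    stringsAsFactors = FALSE)
  if (!all(out$label %in% c("I", "O"))) {
    stop("constraint labels must be I or O (never M)")
  }
  if (any(out$position < 1L)) stop("constraint positions must be >= 1")
  out
}

#' Read a constraint TSV
#' @param path File with header `protein_id, position, label, source`.
#' @return Constraint `data.frame` (see [constraint_table()]).
#' @export
read_constraints <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "label")
  if (!all(need %in% names(tab))) {
    stop("constraint TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(tab$source)) tab$source <- ""
  constraint_table(tab$protein_id, tab$position, tab$label, tab$source)
}

#' Write a constraint TSV
#' @param constraints Constraint `data.frame`.
#' @param path Output file.
#' @param params Optional named list recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_constraints <- function(constraints, path, params = list()) {
  write_tsv(constraints[c("protein_id", "position", "label", "source")],
            path, params = params)
  invisible(path)
}
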