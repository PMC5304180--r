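# Sequence-context characterization of labeled lysines: positional
# entropy/information logos around the central K, and a random-labeling null
# for the length distribution of identified extracellular segments.

#' Extract aligned sequence windows around labeled lysines
#'
#' Windows `[pos - w, pos + w]` centered on each mapped lysine, padded with
#' `-` where the window runs outside the protein. Positions whose residue is
#' not K are skipped (with a message).
#'
#' @param database Protein `data.frame`.
#' @param positions `mapped_positions` (or any `data.frame` with
#'   `protein_id` and `position`).
#' @param w Half-window width in residues (default 10, i.e. the surrounding
#'   20 amino acids).
#' @return A `context_set`: character vector of `2w + 1`-mers with the
#'   window width in attribute `w`.
#' @export
extract_contexts <- function(database, positions, w = 10L) {
  w <- as.integer(w)
  stopifnot(w >= 0L)
  seqs <- stats::setNames(database$sequence, database$id)
  windows <- character(0)
  skipped <- 0L
  for (i in seq_len(nrow(positions))) {
    id <- positions$protein_id[i]
    pos <- positions$position[i]
    s <- seqs[[id]]
    if (is.null(s) || pos < 1L || pos > nchar(s)) { skipped <- skipped + 1L; next }
    if (substring(s, pos, pos) != "K") { skipped <- skipped + 1L; next }
    lo <- pos - w; hi <- pos + w
    core <- substring(s, max(lo, 1L), min(hi, nchar(s)))
    pad_l <- strrep("-", max(0L, 1L - lo))
    pad_r <- strrep("-", max(0L, hi - nchar(s)))
    windows <- c(windows, paste0(pad_l, core, pad_r))
  }
  if (skipped > 0L) {
    message("extract_contexts: skipped ", skipped,
            " position(s) that are not lysines in their protein")
  }
  structure(windows, w = w, class = "context_set")
}

#' Per-column Shannon entropy and information content of a context set
#'
#' For each window column, the Shannon entropy (bits) of the observed
#' amino-acid frequencies (pads excluded; no pseudocounts, matching standard
#' sequence-logo practice) and the information content
#' `log2(20) - H` (logo height convention). Offsets are reported relative to
#' the central lysine.
#'
#' @param contexts A `context_set` from [extract_contexts()].
#' @return `data.frame` with columns `offset` (`-w..w`), `n` (residues
#'   counted), `entropy` (bits; `NA` for all-pad columns) and `information`.
#' @export
positional_entropy <- function(contexts) {
  stopifnot(inherits(contexts, "context_set"))
  if (length(contexts) == 0L) stop("empty context set")
  w <- attr(contexts, "w")
  width <- 2L * w + 1L
  mat <- do.call(rbind, strsplit(unclass(contexts), ""))
  out <- data.frame(offset = seq_len(width) - w - 1L, n = NA_integer_,
                    entropy = NA_real_, information = NA_real_)
  for (j in seq_len(width)) {
    col <- mat[, j]
    col <- col[col %in% .AA20]
    out$n[j] <- length(col)
    if (length(col) == 0L) next
    q <- as.numeric(table(col)) / length(col)
    H <- -sum(q * log2(q))
    out$entropy[j] <- H
    out$information[j] <- log2(20) - H
  }
  out
}

#' Position-by-residue sequence-logo matrix
#'
#' Standard information-scaled logo: each cell is the column's residue
#' frequency times the column's information content.
#'
#' @param contexts A `context_set`.
#' @return Numeric matrix, rows `-w..w` offsets, columns the 20 amino acids.
#' @export
logo_matrix <- function(contexts) {
  stopifnot(inherits(contexts, "context_set"))
  w <- attr(contexts, "w")
  width <- 2L * w + 1L
  mat <- do.call(rbind, strsplit(unclass(contexts), ""))
  ent <- positional_entropy(contexts)
  out <- matrix(0, nrow = width, ncol = 20,
                dimnames = list(ent$offset, .AA20))
  for (j in seq_len(width)) {
    col <- mat[, j]
    col <- col[col %in% .AA20]
    if (length(col) == 0L) next
    q <- table(factor(col, levels = .AA20)) / length(col)
    out[j, ] <- as.numeric(q) * ent$information[j]
  }
  out
}

# extracellular segments of a topology with their lysine positions
.o_segments_with_k <- function(top, sequence) {
  seg <- top$segments
  seg <- seg[seg$label == "O", , drop = FALSE]
  aa <- strsplit(sequence, "")[[1]]
  lapply(seq_len(nrow(seg)), function(k) {
    rng <- seg$start[k]:seg$end[k]
    list(length = length(rng), lysines = rng[aa[rng] == "K"])
  })
}

#' Random-labeling null for identified extracellular segment lengths
#'
#' Compares the length distribution of extracellular segments identified by
#' labeled lysines with the lengths that would be identified if the same
#' number of lysines had been labeled uniformly at random among all
#' extracellular lysines. The two-sample Kolmogorov-Smirnov statistic is
#' computed between the observed lengths and the pooled null draws, and a
#' resampling p-value is the fraction of resamples whose own statistic
#' against the pooled null is at least the observed one.
#'
#' @param references Named list of `topology` objects.
#' @param proteins Protein `data.frame` providing the sequences.
#' @param labeled `data.frame` with `protein_id` and `position` of labeled
#'   lysines; positions not on O segments are skipped with a message.
#' @param n_resamples Number of null resamples (default 199).
#' @return A `length_null` object: `observed` and pooled `null` lengths,
#'   `statistic`, `p_value`, per-resample statistics.
#' @export
segment_length_null <- function(references, proteins, labeled,
                                n_resamples = 199L) {
  if (nrow(labeled) == 0L) stop("zero labeled positions")
  seqs <- stats::setNames(proteins$sequence, proteins$id)
  # global pools: one entry per (protein, O segment)
  seg_len <- integer(0)      # segment length
  seg_of_k <- integer(0)     # segment index of each extracellular lysine
  k_key <- character(0)      # protein:position key of each extracellular lysine
  for (id in names(references)) {
    s <- seqs[[id]]
    if (is.null(s)) next
    for (seg in .o_segments_with_k(references[[id]], s)) {
      seg_len <- c(seg_len, seg$length)
      si <- length(seg_len)
      if (length(seg$lysines)) {
        seg_of_k <- c(seg_of_k, rep(si, length(seg$lysines)))
        k_key <- c(k_key, paste0(id, ":", seg$lysines))
      }
    }
  }
  if (length(k_key) == 0L) stop("references contain no extracellular lysines")
  lab_key <- unique(paste0(labeled$protein_id, ":", labeled$position))
  hit <- lab_key %in% k_key
  if (any(!hit)) {
    message("segment_length_null: skipped ", sum(!hit),
            " labeled position(s) not on extracellular segments")
  }
  lab_idx <- match(lab_key[hit], k_key)
  if (length(lab_idx) == 0L) stop("no labeled positions on extracellular segments")
  observed <- seg_len[unique(seg_of_k[lab_idx])]
  n_lab <- length(lab_idx)
  draws <- lapply(seq_len(n_resamples), function(r) {
    idx <- sample.int(length(k_key), n_lab)
    seg_len[unique(seg_of_k[idx])]
  })
  pooled <- unlist(draws)
  ks <- function(x) {
    if (length(x) == 0L) return(NA_real_)
    unname(suppressWarnings(stats::ks.test(x, pooled)$statistic))
  }
  d_obs <- ks(observed)
  d_res <- vapply(draws, ks, numeric(1))
  structure(list(observed = observed, null = pooled,
                 statistic = d_obs,
                 p_value = mean(d_res >= d_obs, na.rm = TRUE),
                 resample_stats = d_res,
                 n_resamples = n_resamples, n_labeled = n_lab),
            class = "length_null")
}

#' @export
print.length_null <- function(x, ...) {
  cat("extracellular segment length null:", length(x$observed),
      "identified segments vs", x$n_resamples, "random-labeling resamples\n",
      sprintf("KS statistic %.4f, resampling p = %.4f\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' Write a logo matrix as TSV
#' @param mat Matrix from [logo_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_logo_matrix <- function(mat, path) {
  df <- data.frame(offset = rownames(mat), mat, check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}
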