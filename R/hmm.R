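# Duration-constrained hidden-state model of membrane topology with hard
# positional constraints, posterior decoding, a reliability score and a
# topology-correctness comparator.
#
# Macro states: I (cytosolic loop), O (extracellular loop), M_io (helix
# traversed inside->outside), M_oi (outside->inside). Splitting M by
# traversal direction enforces I/O alternation structurally. Helix duration
# bounds [min_len, max_len] are realized by chained sub-states: a helix must
# run through at least min_len sub-states and may not exceed max_len.

.AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
           "R","S","T","V","W","Y")

#' Construct a topology HMM specification
#'
#' Usually obtained from [train_topology_hmm()]; the constructor validates
#' the parameter set.
#'
#' @param emissions 4 x 20 matrix, rows `I`, `O`, `M_io`, `M_oi`, columns the
#'   20 amino acids; every row sums to 1.
#' @param start Length-2 probability vector over the N-terminal side,
#'   names `I`, `O`.
#' @param loop_cont Named vector `c(I =, O =)` of loop self-continuation
#'   probabilities.
#' @param helix_cont Named vector `c(io =, oi =)` of helix continuation
#'   probabilities beyond the minimum duration.
#' @param min_len,max_len Helix duration bounds (residues).
#' @return A `topology_hmm` object.
#' @export
topology_hmm <- function(emissions, start, loop_cont, helix_cont,
                         min_len = 15L, max_len = 25L) {
  emissions <- as.matrix(emissions)
  stopifnot(identical(rownames(emissions), c("I", "O", "M_io", "M_oi")),
            identical(colnames(emissions), .AA20))
  if (any(emissions < 0) || any(abs(rowSums(emissions) - 1) > 1e-12)) {
    stop("every emission row must be a probability vector summing to 1")
  }
  stopifnot(all(c("I", "O") %in% names(start)),
            all(c("I", "O") %in% names(loop_cont)),
            all(c("io", "oi") %in% names(helix_cont)))
  if (abs(sum(start[c("I", "O")]) - 1) > 1e-12 || any(start < 0)) {
    stop("start must be a probability distribution over {I, O}")
  }
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (min_len < 1L || min_len > max_len) stop("need 1 <= min_len <= max_len")
  structure(list(emissions = emissions,
                 start = start[c("I", "O")],
                 loop_cont = loop_cont[c("I", "O")],
                 helix_cont = helix_cont[c("io", "oi")],
                 min_len = min_len, max_len = max_len),
            class = "topology_hmm")
}

#' @export
print.topology_hmm <- function(x, ...) {
  cat("topology HMM: helix duration", x$min_len, "-", x$max_len,
      "| start P(I) =", signif(x$start[["I"]], 4),
      "| loop continuation I/O =", signif(x$loop_cont[["I"]], 4), "/",
      signif(x$loop_cont[["O"]], 4), "\n")
  invisible(x)
}

# ---- sub-state graph -------------------------------------------------------

# state order: 1 = I, 2 = O, 3..(2+max) = M_io chain, then M_oi chain
.hmm_states <- function(model) {
  mx <- model$max_len
  macro <- c("I", "O", rep("M", 2L * mx))
  list(n = 2L + 2L * mx,
       macro = macro,
       emis_row = c("I", "O", rep("M_io", mx), rep("M_oi", mx)),
       end_ok = macro %in% c("I", "O"))
}

.hmm_edges <- function(model) {
  mn <- model$min_len; mx <- model$max_len
  pI <- model$loop_cont[["I"]]; pO <- model$loop_cont[["O"]]
  qio <- model$helix_cont[["io"]]; qoi <- model$helix_cont[["oi"]]
  io1 <- 3L; oi1 <- 3L + mx
  from <- integer(0); to <- integer(0); p <- numeric(0)
  add <- function(f, t, pr) {
    if (pr > 0) {
      from <<- c(from, f); to <<- c(to, t); p <<- c(p, pr)
    }
  }
  add(1L, 1L, pI); add(1L, io1, 1 - pI)
  add(2L, 2L, pO); add(2L, oi1, 1 - pO)
  for (k in seq_len(mx)) {
    sio <- io1 + k - 1L; soi <- oi1 + k - 1L
    if (k < mn) {
      add(sio, sio + 1L, 1); add(soi, soi + 1L, 1)
    } else if (k < mx) {
      add(sio, sio + 1L, qio); add(sio, 2L, 1 - qio)
      add(soi, soi + 1L, qoi); add(soi, 1L, 1 - qoi)
    } else {
      add(sio, 2L, 1); add(soi, 1L, 1)
    }
  }
  ord <- order(from, to)
  list(from = from[ord], to = to[ord], logp = log(p[ord]))
}

.hmm_logstart <- function(model) {
  st <- .hmm_states(model)
  out <- rep(-Inf, st$n)
  out[1L] <- log(model$start[["I"]])
  out[2L] <- log(model$start[["O"]])
  out
}

# n_states x L matrix of log emission likelihoods, with constraint masking.
# X emits uniformly (1/20) under every state.
.hmm_logemit <- function(model, sequence, constraints = NULL) {
  st <- .hmm_states(model)
  aa <- strsplit(sequence, "")[[1]]
  idx <- match(aa, .AA20)
  logE <- log(model$emissions)            # 4 x 20
  L <- length(aa)
  out <- matrix(log(1 / 20), nrow = st$n, ncol = L)
  known <- !is.na(idx)
  rows <- match(st$emis_row, rownames(logE))
  out[, known] <- logE[rows, idx[known], drop = FALSE]
  if (!is.null(constraints) && nrow(constraints) > 0L) {
    for (r in seq_len(nrow(constraints))) {
      pos <- constraints$position[r]
      lab <- constraints$label[r]
      out[st$macro != lab, pos] <- -Inf
    }
  }
  out
}

# ---- training --------------------------------------------------------------

#' Train the topology HMM on annotated proteins
#'
#' Supervised maximum-likelihood estimation. Emission tables are additively
#' smoothed relative residue frequencies under each macro label, with
#' membrane helices split by traversal direction (the side of the preceding
#' loop). Loop self-continuation and helix continuation probabilities are
#' maximum-likelihood estimates from segment lengths; the N-terminal start
#' distribution comes from the first-segment labels.
#'
#' @param proteins Protein `data.frame` (see [protein_set()]).
#' @param annotations List of `topology` objects matching the proteins by
#'   `protein_id`.
#' @param pseudocount Positive additive smoothing count for emissions and the
#'   start distribution.
#' @param min_helix,max_helix Helix duration bounds adopted by the model.
#' @return A `topology_hmm` object.
#' @export
train_topology_hmm <- function(proteins, annotations, pseudocount = 1,
                               min_helix = 15L, max_helix = 25L) {
  stopifnot(pseudocount > 0)
  if (length(annotations) == 0L) stop("empty training set")
  validate_proteins(proteins)
  counts <- matrix(0, nrow = 4, ncol = 20,
                   dimnames = list(c("I", "O", "M_io", "M_oi"), .AA20))
  start_counts <- c(I = 0, O = 0)
  loop_stay <- c(I = 0, O = 0); loop_exit <- c(I = 0, O = 0)
  helix_len <- list(io = integer(0), oi = integer(0))
  for (top in annotations) {
    validate_topology(top, min_helix = min_helix, max_helix = max_helix)
    i <- match(top$protein_id, proteins$id)
    if (is.na(i)) stop("no protein sequence for annotation of ", top$protein_id)
    seq <- proteins$sequence[i]
    if (nchar(seq) != topology_length(top)) {
      stop("annotation/protein length mismatch for ", top$protein_id, ": ",
           topology_length(top), " vs ", nchar(seq))
    }
    seg <- top$segments
    aa <- strsplit(seq, "")[[1]]
    start_counts[seg$label[1]] <- start_counts[seg$label[1]] + 1
    for (k in seq_len(nrow(seg))) {
      lab <- seg$label[k]
      len <- seg$end[k] - seg$start[k] + 1L
      state <- if (lab == "M") {
        if (seg$label[k - 1L] == "I") "M_io" else "M_oi"
      } else lab
      res <- aa[seg$start[k]:seg$end[k]]
      tab <- table(factor(res[res %in% .AA20], levels = .AA20))
      counts[state, ] <- counts[state, ] + as.numeric(tab)
      if (lab %in% c("I", "O")) {
        loop_stay[lab] <- loop_stay[lab] + (len - 1L)
        if (k < nrow(seg)) loop_exit[lab] <- loop_exit[lab] + 1L
      } else {
        dir <- if (state == "M_io") "io" else "oi"
        helix_len[[dir]] <- c(helix_len[[dir]], len)
      }
    }
  }
  emissions <- (counts + pseudocount) / (rowSums(counts) + 20 * pseudocount)
  start <- (start_counts + pseudocount) / (sum(start_counts) + 2 * pseudocount)
  loop_cont <- vapply(c(I = "I", O = "O"), function(l) {
    d <- loop_stay[[l]] + loop_exit[[l]]
    p <- if (d == 0) 0.98 else loop_stay[[l]] / d
    min(max(p, 1e-4), 1 - 1e-4)
  }, numeric(1))
  helix_cont <- vapply(c(io = "io", oi = "oi"), function(d) {
    len <- helix_len[[d]]
    den <- sum(len - min_helix) + sum(len < max_helix)
    q <- if (den == 0) 0.5 else sum(len - min_helix) / den
    min(max(q, 1e-4), 1 - 1e-4)
  }, numeric(1))
  topology_hmm(emissions, start, loop_cont, helix_cont,
               min_len = min_helix, max_len = max_helix)
}

# ---- prediction ------------------------------------------------------------

.check_constraints <- function(constraints, id, L) {
  if (is.null(constraints) || nrow(constraints) == 0L) return(NULL)
  if ("protein_id" %in% names(constraints)) {
    constraints <- constraints[constraints$protein_id == id, , drop = FALSE]
  }
  if (nrow(constraints) == 0L) return(NULL)
  if (!all(constraints$label %in% c("I", "O"))) {
    stop("constraint labels must be I or O")
  }
  if (any(constraints$position < 1L | constraints$position > L)) {
    stop("constraint position outside [1, ", L, "] for ", id)
  }
  constraints <- unique(constraints[c("position", "label")])
  dup <- duplicated(constraints$position)
  if (any(dup)) {
    stop("contradictory duplicate constraints at position(s) ",
         paste(unique(constraints$position[dup]), collapse = ", "),
         " for ", id)
  }
  constraints
}

#' Predict membrane topology, optionally under positional constraints
#'
#' Viterbi decoding over the duration-constrained sub-state graph. At every
#' constrained position, states whose macro label differs from the constraint
#' label are masked (probability zero) — constraints are hard. Per-residue
#' posteriors come from forward-backward under the same masking; the
#' reliability score is the mean posterior probability of the predicted
#' macro label. If the constraints admit no positive-probability path, the
#' `conflict` flag is set and the unconstrained prediction is returned.
#'
#' @param model A `topology_hmm`.
#' @param protein One-row protein `data.frame` (see [protein_set()]), or a
#'   plain sequence string (then `id` names it).
#' @param constraints Optional constraint `data.frame`
#'   (see [constraint_table()]); rows for other proteins are ignored.
#' @param id Identifier used when `protein` is a bare sequence string.
#' @return A `topology_prediction` object: `topology`, `posterior`
#'   (3 x L matrix, rows `I`/`M`/`O`), `per_residue_posterior`,
#'   `reliability`, `constrained`, `conflict`, `logprob`.
#' @export
predict_topology <- function(model, protein, constraints = NULL,
                             id = "protein") {
  stopifnot(inherits(model, "topology_hmm"))
  if (is.data.frame(protein)) {
    stopifnot(nrow(protein) == 1L)
    id <- protein$id
    sequence <- protein$sequence
  } else {
    sequence <- toupper(protein)
  }
  if (!nzchar(sequence)) stop("empty sequence for ", id)
  L <- nchar(sequence)
  cons <- .check_constraints(constraints, id, L)
  st <- .hmm_states(model)
  edges <- .hmm_edges(model)
  logstart <- .hmm_logstart(model)
  decode <- function(cns) {
    le <- .hmm_logemit(model, sequence, cns)
    vit <- dp_viterbi(logstart, edges$from, edges$to, edges$logp, le, st$end_ok)
    if (!is.finite(vit$logprob)) return(NULL)
    fb <- dp_forward_backward(logstart, edges$from, edges$to, edges$logp,
                              le, st$end_ok)
    list(vit = vit, fb = fb)
  }
  res <- decode(cons)
  conflict <- FALSE
  if (is.null(res)) {
    conflict <- TRUE
    res <- decode(NULL)
    if (is.null(res)) stop("no admissible state path for ", id)
  }
  macro_path <- st$macro[res$vit$path]
  post3 <- rbind(I = colSums(res$fb$posterior[st$macro == "I", , drop = FALSE]),
                 M = colSums(res$fb$posterior[st$macro == "M", , drop = FALSE]),
                 O = colSums(res$fb$posterior[st$macro == "O", , drop = FALSE]))
  prp <- post3[cbind(match(macro_path, rownames(post3)), seq_len(L))]
  top <- topology_from_labels(id, paste(macro_path, collapse = ""),
                              min_helix = model$min_len,
                              max_helix = model$max_len)
  structure(list(topology = top,
                 posterior = post3,
                 per_residue_posterior = prp,
                 reliability = mean(prp),
                 constrained = !is.null(cons),
                 conflict = conflict,
                 logprob = res$vit$logprob),
            class = "topology_prediction")
}

#' @export
print.topology_prediction <- function(x, ...) {
  cat("topology prediction for", x$topology$protein_id, "|",
      sum(x$topology$segments$label == "M"), "TM helices | reliability",
      round(x$reliability, 4),
      if (x$constrained) "| constrained" else "",
      if (x$conflict) "| CONFLICT (unconstrained fallback)" else "", "\n")
  invisible(x)
}

#' Reliability of a topology prediction
#'
#' The mean, over residues, of the posterior probability of the predicted
#' macro label — a per-prediction confidence score whose ordering tracks the
#' probability that the prediction is correct.
#'
#' @param result A `topology_prediction`.
#' @return Scalar in `[0, 1]`.
#' @export
reliability_score <- function(result) {
  stopifnot(inherits(result, "topology_prediction"))
  if (length(result$per_residue_posterior) == 0L) stop("posteriors not populated")
  mean(result$per_residue_posterior)
}

#' Compare a predicted topology with a reference
#'
#' A prediction is correct iff it has the same number of membrane segments
#' as the reference, the i-th predicted M segment overlaps the i-th reference
#' M segment by at least `min_overlap` residues, and the N-terminal side
#' (I or O) matches.
#'
#' @param predicted,reference `topology` objects of the same protein length.
#' @param min_overlap Minimum helix overlap in residues (default 5).
#' @return `TRUE` or `FALSE`.
#' @export
compare_topology <- function(predicted, reference, min_overlap = 5L) {
  stopifnot(inherits(predicted, "topology"), inherits(reference, "topology"))
  if (topology_length(predicted) != topology_length(reference)) {
    stop("length mismatch: ", topology_length(predicted), " vs ",
         topology_length(reference))
  }
  pm <- predicted$segments[predicted$segments$label == "M", , drop = FALSE]
  rm_ <- reference$segments[reference$segments$label == "M", , drop = FALSE]
  if (nrow(pm) != nrow(rm_)) return(FALSE)
  if (predicted$segments$label[1] != reference$segments$label[1]) return(FALSE)
  if (nrow(pm) > 0L) {
    ov <- pmin(pm$end, rm_$end) - pmax(pm$start, rm_$start) + 1L
    if (any(ov < min_overlap)) return(FALSE)
  }
  TRUE
}

# ---- serialization ---------------------------------------------------------

#' Write a topology HMM to structured text
#'
#' Key/value lines plus the emission table, numbers at full double precision
#' so that a write/read round trip is exact.
#'
#' @param model A `topology_hmm`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_topology_hmm <- function(model, path) {
  stopifnot(inherits(model, "topology_hmm"))
  g <- function(x) sprintf("%.17g", x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    provenance_header(),
    paste0("min_len\t", model$min_len),
    paste0("max_len\t", model$max_len),
    paste0("start_I\t", g(model$start[["I"]])),
    paste0("start_O\t", g(model$start[["O"]])),
    paste0("loop_cont_I\t", g(model$loop_cont[["I"]])),
    paste0("loop_cont_O\t", g(model$loop_cont[["O"]])),
    paste0("helix_cont_io\t", g(model$helix_cont[["io"]])),
    paste0("helix_cont_oi\t", g(model$helix_cont[["oi"]])),
    paste0("emissions\tstate\t", paste(.AA20, collapse = "\t"))
  ), con)
  for (r in rownames(model$emissions)) {
    writeLines(paste(c("emissions", r, g(model$emissions[r, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a topology HMM written by [write_topology_hmm()]
#' @param path Input file.
#' @return A `topology_hmm`.
#' @export
read_topology_hmm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kv <- list()
  emis <- matrix(NA_real_, 4, 20, dimnames = list(c("I", "O", "M_io", "M_oi"),
                                                  .AA20))
  for (p in parts) {
    if (p[1] == "emissions") {
      if (p[2] == "state") next
      emis[p[2], ] <- as.numeric(p[-(1:2)])
    } else {
      kv[[p[1]]] <- as.numeric(p[2])
    }
  }
  topology_hmm(emis,
               start = c(I = kv$start_I, O = kv$start_O),
               loop_cont = c(I = kv$loop_cont_I, O = kv$loop_cont_O),
               helix_cont = c(io = kv$helix_cont_io, oi = kv$helix_cont_oi),
               min_len = kv$min_len, max_len = kv$max_len)
}
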