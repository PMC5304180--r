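# Constraint-corruption benchmark: sample extracellular-lysine constraints at
# given coverage, corrupt a fraction into false positives, run constrained
# prediction, and compute accuracy and reliability-coverage statistics over
# repeated randomizations.

#' Build benchmark entries from proteins and reference topologies
#'
#' Derives, per protein, the extracellular-lysine pool (K residues inside O
#' segments) and the intracellular pool (K inside I segments) used for
#' constraint sampling and corruption.
#'
#' @param proteins Protein `data.frame`.
#' @param annotations Named list of `topology` objects.
#' @return List of `benchmark_entry` objects.
#' @export
benchmark_entries <- function(proteins, annotations) {
  validate_proteins(proteins)
  lapply(seq_len(nrow(proteins)), function(i) {
    id <- proteins$id[i]
    ann <- annotations[[id]]
    if (is.null(ann)) stop("no reference topology for ", id)
    labels <- strsplit(topology_labels(ann), "")[[1]]
    aa <- strsplit(proteins$sequence[i], "")[[1]]
    if (length(labels) != length(aa)) {
      stop("reference/protein length mismatch for ", id)
    }
    structure(list(protein = proteins[i, , drop = FALSE],
                   reference = ann,
                   extracellular_lysines = which(aa == "K" & labels == "O"),
                   intracellular_lysines = which(aa == "K" & labels == "I")),
              class = "benchmark_entry")
  })
}

# round-half-up sample-size rule
.round_half_up <- function(x) floor(x + 0.5)

#' Sample extracellular-lysine constraints at a coverage fraction
#'
#' Uniform sample without replacement of `round(p * n)` positions from the
#' entry's extracellular-lysine pool, each emitted as a constraint with label
#' `O`. Uses the current RNG state.
#'
#' @param entry A `benchmark_entry`.
#' @param p Coverage fraction in `[0, 1]`.
#' @return Constraint `data.frame`.
#' @export
sample_constraints <- function(entry, p) {
  stopifnot(p >= 0, p <= 1)
  pool <- entry$extracellular_lysines
  k <- .round_half_up(p * length(pool))
  if (k == 0L) {
    return(constraint_table(character(0), integer(0)))
  }
  pos <- sort(pool[sample.int(length(pool), k)])
  constraint_table(entry$protein$id, pos, label = "O", source = "sampled")
}

#' Corrupt a fraction of constraints into false positives
#'
#' Removes `round(f * n)` constraints uniformly at random and replaces them
#' with distinct intracellular-lysine positions still labelled `O` (false
#' positives), so the total constraint count is unchanged — unless the
#' intracellular pool is exhausted, in which case as many as available are
#' used (with a message).
#'
#' @param constraints Constraint `data.frame` of label-O positions of `entry`.
#' @param entry The `benchmark_entry` the constraints belong to.
#' @param f Corruption fraction in `[0, 1]`.
#' @return Constraint `data.frame` of the same size (see above).
#' @export
corrupt_constraints <- function(constraints, entry, f) {
  stopifnot(f >= 0, f <= 1)
  n <- nrow(constraints)
  k <- .round_half_up(f * n)
  if (k == 0L) return(constraints)
  pool <- setdiff(entry$intracellular_lysines, constraints$position)
  if (length(pool) < k) {
    message("corrupt_constraints: intracellular pool exhausted for ",
            entry$protein$id, " (", length(pool), " < ", k, ")")
    k <- length(pool)
  }
  if (k == 0L) return(constraints)
  drop <- sample.int(n, k)
  fake <- if (length(pool) == 1L) pool else pool[sample.int(length(pool), k)]
  kept <- constraints[-drop, , drop = FALSE]
  out <- rbind(kept,
               constraint_table(entry$protein$id, fake, label = "O",
                                source = "corrupted"))
  out[order(out$position), , drop = FALSE]
}

#' Simulation configuration
#'
#' @param fractions Coverage fractions `p`; default `c(0, .25, .5, .75, 1)`.
#' @param corruption_fractions False-positive fractions `f`; default
#'   `c(0, .04, .08, .12, .16)`.
#' @param n_randomizations Randomizations per `(p, f)` cell (default 50).
#' @param seed Base seed; per-(cell, randomization, protein) RNG streams are
#'   derived from it, so results do not depend on evaluation order.
#' @param min_overlap Helix-overlap threshold for [compare_topology()].
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(fractions = c(0, 0.25, 0.50, 0.75, 1.00),
                              corruption_fractions = c(0, 0.04, 0.08, 0.12, 0.16),
                              n_randomizations = 50L, seed = 1L,
                              min_overlap = 5L) {
  stopifnot(all(fractions >= 0 & fractions <= 1),
            all(corruption_fractions >= 0 & corruption_fractions <= 1),
            n_randomizations >= 1L)
  structure(list(fractions = fractions,
                 corruption_fractions = corruption_fractions,
                 n_randomizations = as.integer(n_randomizations),
                 seed = as.integer(seed),
                 min_overlap = as.integer(min_overlap)),
            class = "simulation_config")
}

# order-independent sub-seed derivation; stepwise modular LCG keeps every
# intermediate below 2^53 and the result below 2^31
.stream_seed <- function(seed, ...) {
  s <- seed %% 2147483647
  for (x in c(...)) s <- (s * 69069 + x + 1) %% 2147483647
  as.integer(s)
}

#' Run the constraint-corruption benchmark simulation
#'
#' For every `(p, f)` cell and randomization: sample constraints per protein,
#' corrupt them, predict under the corrupted constraints and score
#' correctness with [compare_topology()]. Accuracy is the percent of
#' proteins with correctly predicted topology; means and standard deviations
#' are taken over randomizations. Reliability-coverage curves are computed
#' per cell, both on the final randomization and averaged over all
#' randomizations.
#'
#' @param benchmark List of `benchmark_entry` objects.
#' @param model A `topology_hmm`.
#' @param config A [simulation_config()].
#' @return A `simulation_result`: `records` (tidy per-protein-per-rep
#'   `data.frame`), `summary` (per-cell accuracy mean/sd), `curves`
#'   (reliability-coverage per cell).
#' @export
run_simulation <- function(benchmark, model, config) {
  stopifnot(length(benchmark) > 0L, inherits(model, "topology_hmm"),
            inherits(config, "simulation_config"))
  n_prot <- length(benchmark)
  # unconstrained predictions are deterministic; compute once and reuse for
  # every empty constraint set
  uncon <- lapply(benchmark, function(e) predict_topology(model, e$protein))
  uncon_ok <- vapply(seq_len(n_prot), function(i) {
    compare_topology(uncon[[i]]$topology, benchmark[[i]]$reference,
                     min_overlap = config$min_overlap)
  }, logical(1))
  n_total <- length(config$fractions) * length(config$corruption_fractions) *
    config$n_randomizations * n_prot
  col_p <- numeric(n_total); col_f <- numeric(n_total)
  col_rep <- integer(n_total); col_id <- character(n_total)
  col_ok <- logical(n_total); col_rel <- numeric(n_total)
  col_conf <- logical(n_total); col_nc <- integer(n_total)
  row <- 0L
  for (ip in seq_along(config$fractions)) {
    p <- config$fractions[ip]
    for (jf in seq_along(config$corruption_fractions)) {
      f <- config$corruption_fractions[jf]
      for (r in seq_len(config$n_randomizations)) {
        for (i in seq_len(n_prot)) {
          entry <- benchmark[[i]]
          set.seed(.stream_seed(config$seed, ip, jf, r, i))
          cons <- sample_constraints(entry, p)
          cons <- corrupt_constraints(cons, entry, f)
          if (nrow(cons) == 0L) {
            pred <- uncon[[i]]
            ok <- uncon_ok[i]
          } else {
            pred <- predict_topology(model, entry$protein, cons)
            ok <- compare_topology(pred$topology, entry$reference,
                                   min_overlap = config$min_overlap)
          }
          row <- row + 1L
          col_p[row] <- p; col_f[row] <- f; col_rep[row] <- r
          col_id[row] <- entry$protein$id; col_ok[row] <- ok
          col_rel[row] <- pred$reliability; col_conf[row] <- pred$conflict
          col_nc[row] <- nrow(cons)
        }
      }
    }
  }
  records <- data.frame(p = col_p, f = col_f, rep = col_rep,
                        protein_id = col_id, correct = col_ok,
                        reliability = col_rel, conflict = col_conf,
                        n_constraints = col_nc, stringsAsFactors = FALSE)
  acc_rep <- stats::aggregate(correct ~ p + f + rep, data = records,
                              FUN = function(x) 100 * mean(x))
  summary <- do.call(rbind, lapply(split(acc_rep, acc_rep[c("p", "f")], drop = TRUE),
    function(d) data.frame(p = d$p[1], f = d$f[1],
                           accuracy_mean = mean(d$correct),
                           accuracy_sd = stats::sd(d$correct))))
  summary$accuracy_sd[is.na(summary$accuracy_sd)] <- 0
  summary <- summary[order(summary$p, summary$f), , drop = FALSE]
  rownames(summary) <- NULL
  curves <- do.call(rbind, lapply(split(records, records[c("p", "f")], drop = TRUE),
    function(d) {
      last <- reliability_coverage(d[d$rep == max(d$rep), , drop = FALSE])
      per_rep <- lapply(split(d, d$rep), reliability_coverage)
      mean_acc <- rowMeans(vapply(per_rep, `[[`, numeric(nrow(last)), "accuracy"))
      data.frame(p = d$p[1], f = d$f[1], coverage = last$coverage,
                 accuracy_last = last$accuracy, accuracy_mean = mean_acc)
    }))
  rownames(curves) <- NULL
  structure(list(records = records, summary = summary, curves = curves,
                 config = config),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("constraint-corruption simulation:",
      length(unique(x$records$protein_id)), "proteins,",
      x$config$n_randomizations, "randomizations per cell\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Reliability-coverage curve
#'
#' Sorts predictions by decreasing reliability (ties broken by protein id)
#' and reports, for each coverage level `100 k / N`, the percent correct
#' among the `k` most reliable predictions. The value at 100 percent
#' coverage equals the overall accuracy.
#'
#' @param records `data.frame` with columns `reliability`, `correct` and
#'   `protein_id`.
#' @return `data.frame` with columns `coverage` and `accuracy` (percent).
#' @export
reliability_coverage <- function(records) {
  n <- nrow(records)
  if (n == 0L) {
    return(data.frame(coverage = numeric(0), accuracy = numeric(0)))
  }
  ord <- order(-records$reliability, records$protein_id)
  correct <- records$correct[ord]
  k <- seq_len(n)
  data.frame(coverage = 100 * k / n,
             accuracy = 100 * cumsum(correct) / k)
}

#' Write simulation results as tidy TSV files
#'
#' Emits `records.tsv` (p, f, rep, protein_id, correct, reliability),
#' `summary.tsv` (p, f, accuracy_mean, accuracy_sd) and `curves.tsv`
#' (p, f, coverage, accuracy on the final randomization and averaged).
#'
#' @param result A `simulation_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  params <- list(seed = result$config$seed,
                 n_randomizations = result$config$n_randomizations,
                 min_overlap = result$config$min_overlap)
  write_tsv(result$records, file.path(dir, "records.tsv"), params = params)
  write_tsv(result$summary, file.path(dir, "summary.tsv"), params = params)
  write_tsv(result$curves, file.path(dir, "curves.tsv"), params = params)
  invisible(dir)
}
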