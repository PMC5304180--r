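# Training estimators, constrained decoding, reliability, comparator.

test_that("emission training matches the additive-smoothing closed form", {
  db <- protein_set("P1", "KKKK")
  ann <- list(topology_from_labels("P1", "IIII"))
  m <- train_topology_hmm(db, ann, pseudocount = 1)
  expect_equal(m$emissions["I", "K"], (4 + 1) / (4 + 20))
  # labels absent from training fall back to the uniform pseudocount row
  expect_equal(unname(m$emissions["O", ]), rep(1 / 20, 20))
  expect_equal(unname(m$emissions["M_io", ]), rep(1 / 20, 20))
})

test_that("training counts are additive over disjoint training sets", {
  cfg1 <- synthetic_config(n_proteins = 6L, seed = 31L)
  cfg2 <- synthetic_config(n_proteins = 6L, seed = 32L)
  g1 <- generate_proteins(cfg1)
  g2 <- generate_proteins(cfg2)
  g2$proteins$id <- sub("SYN", "ALT", g2$proteins$id)
  g2$annotations <- lapply(g2$annotations, function(t) {
    t$protein_id <- sub("SYN", "ALT", t$protein_id); t
  })
  names(g2$annotations) <- sub("SYN", "ALT", names(g2$annotations))
  # independent oracle: direct tally of residues under each macro label
  tally <- function(gen) {
    counts <- matrix(0, 4, 20, dimnames = list(c("I", "O", "M_io", "M_oi"),
                                               topolabel:::.AA20))
    for (id in gen$proteins$id) {
      aa <- strsplit(gen$proteins$sequence[gen$proteins$id == id], "")[[1]]
      seg <- gen$annotations[[id]]$segments
      for (k in seq_len(nrow(seg))) {
        state <- if (seg$label[k] == "M") {
          if (seg$label[k - 1] == "I") "M_io" else "M_oi"
        } else seg$label[k]
        tab <- table(factor(aa[seg$start[k]:seg$end[k]],
                            levels = topolabel:::.AA20))
        counts[state, ] <- counts[state, ] + as.numeric(tab)
      }
    }
    counts
  }
  pc <- 0.5
  m12 <- train_topology_hmm(rbind(g1$proteins, g2$proteins),
                            c(g1$annotations, g2$annotations), pseudocount = pc)
  csum <- tally(g1) + tally(g2)
  expected <- (csum + pc) / (rowSums(csum) + 20 * pc)
  expect_equal(m12$emissions, expected, tolerance = 1e-12)
})

test_that("training rejects mismatched or empty input", {
  db <- protein_set("P1", "KKKK")
  expect_error(train_topology_hmm(db, list(), 1), "empty training set")
  expect_error(
    train_topology_hmm(db, list(topology_from_labels("P1", "IIIII")), 1),
    "length mismatch.*P1")
  expect_error(
    train_topology_hmm(db, list(topology_from_labels("P9", "IIII")), 1),
    "P9")
})

test_that("constrained Viterbi equals exhaustive path enumeration on short sequences", {
  toy <- make_toy_model()
  st <- topolabel:::.hmm_states(toy)
  ed <- topolabel:::.hmm_edges(toy)
  ls <- topolabel:::.hmm_logstart(toy)
  run_dp <- function(seq, cons) {
    le <- topolabel:::.hmm_logemit(toy, seq, cons)
    topolabel:::dp_viterbi(ls, ed$from, ed$to, ed$logp, le, st$end_ok)$logprob
  }
  # unconstrained: every sequence over {K, L} up to length 8
  for (L in 1:8) {
    for (seq in all_strings(c("K", "L"), L)) {
      expect_equal(run_dp(seq, NULL), oracle_best_logprob(toy, seq),
                   tolerance = 1e-10)
    }
  }
  # constrained: randomized single and paired constraints
  set.seed(99)
  for (i in 1:40) {
    L <- sample(3:8, 1)
    seq <- paste(sample(c("K", "L"), L, replace = TRUE), collapse = "")
    k <- sample(1:2, 1)
    cons <- data.frame(position = sample(L, k),
                       label = sample(c("I", "O"), k, replace = TRUE))
    expect_equal(run_dp(seq, cons), oracle_best_logprob(toy, seq, cons),
                 tolerance = 1e-10)
  }
})

test_that("posteriors normalize and decoded topologies satisfy the invariants", {
  model <- synth_model()
  bench <- synth_benchmark()$entries
  set.seed(5)
  for (e in bench[sample(length(bench), 8)]) {
    cons <- sample_constraints(e, 0.5)
    pred <- predict_topology(model, e$protein, cons)
    expect_true(all(abs(colSums(pred$posterior) - 1) < 1e-9))
    expect_true(all(pred$posterior >= 0 & pred$posterior <= 1 + 1e-12))
    # decoded topology passes the alternation/tiling validator
    expect_silent(validate_topology(pred$topology))
    expect_identical(topology_length(pred$topology), nchar(e$protein$sequence))
  }
})

test_that("decoded labels honour every constraint when no conflict is flagged", {
  model <- synth_model()
  bench <- synth_benchmark()$entries
  set.seed(17)
  n_checked <- 0L
  for (e in bench) {
    cons <- sample_constraints(e, 0.75)
    if (nrow(cons) == 0L) next
    pred <- predict_topology(model, e$protein, cons)
    if (pred$conflict) next
    labs <- strsplit(topology_labels(pred$topology), "")[[1]]
    expect_identical(labs[cons$position], cons$label)
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 10L)
})

test_that("fully constraining to a valid annotation forces that topology", {
  model <- synth_model()
  gen <- synth_benchmark()$gen
  id <- gen$proteins$id[1]
  labs <- strsplit(topology_labels(gen$annotations[[id]]), "")[[1]]
  loop <- which(labs != "M")
  cons <- data.frame(protein_id = id, position = loop, label = labs[loop])
  pred <- predict_topology(model, gen$proteins[1, , drop = FALSE], cons)
  expect_false(pred$conflict)
  got <- strsplit(topology_labels(pred$topology), "")[[1]]
  expect_identical(got[loop], labs[loop])
})

test_that("contradictory constraints error; infeasible ones set the conflict flag", {
  model <- synth_model()
  gen <- synth_benchmark()$gen
  pr <- gen$proteins[1, , drop = FALSE]
  expect_error(
    predict_topology(model, pr, data.frame(position = c(5L, 5L),
                                           label = c("I", "O"))),
    "contradictory")
  # adjacent I and O with no room for a helix in between is unsatisfiable
  pred <- predict_topology(model, pr, data.frame(position = c(10L, 11L),
                                                 label = c("I", "O")))
  expect_true(pred$conflict)
  # the fallback is the unconstrained prediction
  expect_identical(topology_labels(pred$topology),
                   topology_labels(predict_topology(model, pr)$topology))
})

test_that("a hydrophobic stretch between charged flanks decodes as one helix", {
  model <- synth_model()
  seq <- paste0("KKKKK", strrep("L", 21), "SSSSS")
  pred <- predict_topology(model, seq, id = "TOY")
  seg <- pred$topology$segments
  m <- seg[seg$label == "M", ]
  expect_identical(nrow(m), 1L)
  # the helix overlaps the poly-L stretch
  expect_gt(min(m$end, 26) - max(m$start, 6) + 1, 10)
})

test_that("reliability is the mean predicted-label posterior and conditioning cannot lower it", {
  model <- synth_model()
  gen <- synth_benchmark()$gen
  pred <- predict_topology(model, gen$proteins[2, , drop = FALSE])
  expect_equal(reliability_score(pred), mean(pred$per_residue_posterior))
  fake <- pred
  fake$per_residue_posterior <- c(0.5, 1.0)
  expect_equal(reliability_score(fake), 0.75)
  fake$per_residue_posterior <- rep(1, 10)
  expect_equal(reliability_score(fake), 1)
  # constraining to the prediction's own labels cannot lower reliability
  set.seed(23)
  for (i in 1:6) {
    pr <- gen$proteins[i, , drop = FALSE]
    p0 <- predict_topology(model, pr)
    labs <- strsplit(topology_labels(p0$topology), "")[[1]]
    loop <- which(labs != "M")
    pos <- sample(loop, min(5, length(loop)))
    p1 <- predict_topology(model, pr,
                           data.frame(position = pos, label = labs[pos]))
    expect_gte(p1$reliability, p0$reliability - 1e-12)
  }
})

test_that("prediction is deterministic for identical inputs", {
  model <- synth_model()
  e <- synth_benchmark()$entries[[3]]
  set.seed(1); cons <- sample_constraints(e, 0.5)
  a <- predict_topology(model, e$protein, cons)
  b <- predict_topology(model, e$protein, cons)
  expect_identical(topology_labels(a$topology), topology_labels(b$topology))
  expect_identical(a$reliability, b$reliability)
  expect_identical(a$logprob, b$logprob)
})

test_that("topology comparison checks helix count, pairwise overlap and orientation", {
  ref <- topology_from_labels("P", paste0(strrep("I", 9), strrep("M", 21),
                                          strrep("O", 10)))
  expect_true(compare_topology(ref, ref))
  # every loop label swapped: orientation differs
  flip <- topology_from_labels("P", chartr("IO", "OI", topology_labels(ref)))
  expect_false(compare_topology(flip, ref))
  # shifted helix with >= min_overlap residues of overlap still counts
  shift <- topology_from_labels("P", paste0(strrep("I", 12), strrep("M", 21),
                                            strrep("O", 7)))
  expect_true(compare_topology(shift, ref, min_overlap = 5))
  expect_false(compare_topology(shift, ref, min_overlap = 19))
  # differing helix count fails
  noM <- topology_from_labels("P", strrep("I", 40))
  expect_false(compare_topology(noM, ref))
  expect_error(compare_topology(topology_from_labels("P", "II"), ref),
               "length mismatch")
})

test_that("interval overlap arithmetic matches the comparator decision", {
  # reference helix [10, 30], prediction [13, 33]: overlap 18 >= 5
  ref <- topology("P", c(1, 10, 31), c(9, 30, 40), c("I", "M", "O"))
  prd <- topology("P", c(1, 13, 34), c(12, 33, 40), c("I", "M", "O"))
  expect_true(compare_topology(prd, ref, min_overlap = 5))
  expect_true(compare_topology(prd, ref, min_overlap = 18))
  expect_false(compare_topology(prd, ref, min_overlap = 19))
})

test_that("model serialization round-trips exactly", {
  model <- synth_model()
  path <- withr::local_tempfile(fileext = ".hmm")
  write_topology_hmm(model, path)
  back <- read_topology_hmm(path)
  expect_identical(back$emissions, model$emissions)
  expect_identical(back$start, model$start)
  expect_identical(back$loop_cont, model$loop_cont)
  expect_identical(back$helix_cont, model$helix_cont)
  expect_identical(back$min_len, model$min_len)
  expect_identical(back$max_len, model$max_len)
})
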