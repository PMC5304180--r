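# Shared fixtures: a reduced-alphabet toy model for exhaustive checks, and a
# synthetic-trained model reused across test files.

# toy model over {K, L} with short helix durations so exhaustive path
# enumeration stays tractable
make_toy_model <- function(min_len = 2L, max_len = 3L) {
  emis <- matrix(0, 4, 20, dimnames = list(c("I", "O", "M_io", "M_oi"),
                                           topolabel:::.AA20))
  emis["I", c("K", "L")] <- c(0.8, 0.2)
  emis["O", c("K", "L")] <- c(0.5, 0.5)
  emis["M_io", c("K", "L")] <- c(0.1, 0.9)
  emis["M_oi", c("K", "L")] <- c(0.2, 0.8)
  topology_hmm(emis, start = c(I = 0.6, O = 0.4),
               loop_cont = c(I = 0.7, O = 0.8),
               helix_cont = c(io = 0.5, oi = 0.4),
               min_len = min_len, max_len = max_len)
}

# one trained model + a disjoint evaluation benchmark, built once per session
synth_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_proteins = 40L, seed = 2024L)
      gen <- generate_proteins(cfg)
      cache <<- train_topology_hmm(gen$proteins, gen$annotations)
    }
    cache
  }
})

# "protein:position" keys of all extracellular lysines of a generated set
ext_lysine_keys <- function(gen) {
  out <- character(0)
  for (id in gen$proteins$id) {
    aa <- strsplit(gen$proteins$sequence[gen$proteins$id == id], "")[[1]]
    labels <- strsplit(topology_labels(gen$annotations[[id]]), "")[[1]]
    k <- which(aa == "K" & labels == "O")
    if (length(k)) out <- c(out, paste0(id, ":", k))
  }
  out
}

synth_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_proteins = 30L, seed = 515L)
      gen <- generate_proteins(cfg)
      cache <<- list(gen = gen,
                     entries = benchmark_entries(gen$proteins, gen$annotations))
    }
    cache
  }
})
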