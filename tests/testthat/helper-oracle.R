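# Independent brute-force oracle: exhaustively enumerates every
# constraint-consistent state path through the sub-state graph and returns the
# maximum path log-probability. Shares only the model definition with the DP
# implementation, not the dynamic program itself.

oracle_best_logprob <- function(model, sequence, constraints = NULL) {
  st <- topolabel:::.hmm_states(model)
  ed <- topolabel:::.hmm_edges(model)
  ls <- topolabel:::.hmm_logstart(model)
  le <- topolabel:::.hmm_logemit(model, sequence, constraints)
  L <- ncol(le)
  succ <- split(data.frame(to = ed$to, lp = ed$logp), ed$from)
  best <- -Inf
  rec <- function(s, t, lp) {
    lp <- lp + le[s, t]
    if (!is.finite(lp)) return()
    if (t == L) {
      if (st$end_ok[s] && lp > best) best <<- lp
      return()
    }
    sc <- succ[[as.character(s)]]
    if (is.null(sc)) return()
    for (k in seq_len(nrow(sc))) rec(sc$to[k], t + 1L, lp + sc$lp[k])
  }
  for (s in seq_len(st$n)) if (is.finite(ls[s])) rec(s, 1L, ls[s])
  best
}

# all strings of the given length over an alphabet
all_strings <- function(alphabet, len) {
  if (len == 0L) return(character(0))
  grid <- do.call(expand.grid, rep(list(alphabet), len))
  apply(grid, 1, paste, collapse = "")
}
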