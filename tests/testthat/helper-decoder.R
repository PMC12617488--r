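random_model <- function(n_neurons, n_bins, n_corr = 2, seed = 1) {
  set.seed(seed)
  ns <- n_bins * n_corr
  P <- matrix(runif(n_neurons * ns, 0.02, 0.98), n_neurons, ns)
  states <- expand.grid(bin = seq_len(n_bins) - 1L,
                        corridor = c("A", "B")[seq_len(n_corr)],
                        stringsAsFactors = FALSE)
  structure(list(P = P, states = states, T_jk = rep(10, ns),
                 usable = rep(TRUE, ns), pseudocount = 0.5),
            class = "decoder_model")
}

brute_posterior <- function(model, svec) {
  pr <- apply(model$P, 2, function(p) prod(ifelse(svec == 1, p, 1 - p)))
  pr / sum(pr)
}

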