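# Independent oracles used across test files.

# brute-force union-find over chain contact pairs
uf_components <- function(n_chains, pairs) {
  parent <- seq_len(n_chains)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(pairs)) for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n_chains), find, integer(1))
  sort(as.integer(table(roots)), decreasing = TRUE)
}

# standard truth spectrum parameters used by several fixtures
truth_params <- function(D_G = 1.5, tau_G = 0.1, D_L = 30, tau_L = 180,
                         r_L = 2, p_L = 0.4, ...) {
  spectrum_params(intensity = 1, D_G = D_G, tau_G = tau_G, D_L = D_L,
                  tau_L = tau_L, r_L = r_L, p_L = p_L, ...)
}
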