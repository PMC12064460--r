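# Shared fixtures built in code.

anxiety_bank <- load_item_bank("anxiety_sv")
depressive_bank <- load_item_bank("depressive_sv")

# Small deterministic two-item bank for enumeration oracles.
toy_bank <- function(n = 2L) {
  item_bank(anxiety_bank$items[seq_len(n), , drop = FALSE], name = "toy")
}

# Scalar re-implementation of the GRM category probabilities, used as an
# independent oracle against the vectorized package code.
oracle_grm_prob <- function(a, b, theta) {
  pstar <- c(1, 1 / (1 + exp(-a * (theta - b))), 0)
  pstar[1:5] - pstar[2:6]
}
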