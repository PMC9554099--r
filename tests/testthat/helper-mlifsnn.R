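# Shared helpers: tiny deterministic networks and an exact rational oracle
# for the shift multiplier.

tiny_net <- function(n_in = 3, n_hidden = 4, n_out = 2, seed = 1, ...) {
  build_network(n_in, n_hidden, n_out, seed = seed, ...)
}

# Exact value of the shift-multiplier circuit, computed independently on
# integer raw values (no floating shifts): a's fraction bits gate integer
# divisions of b's raw magnitude.
shift_mul_oracle <- function(a, b) {
  a_frac <- floor(abs(a) * 65536) %% 65536
  b_raw <- min(floor(abs(b) * 65536), 8388607)
  acc <- 0
  for (i in 1:16) {
    bit <- floor(a_frac / 2^(16 - i)) %% 2
    acc <- acc + bit * floor(b_raw / 2^i)
  }
  sign(b) * min(acc, 8388607) / 65536
}

# One labeled pattern set small enough for fast training smoke tests.
fixture_patterns <- function() make_classification_fixture()
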