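# Standard atomic weights, rounded to 3 decimals; fixed table so that
# molecular weights are reproducible across environments.
ATOMIC_MASSES <- c(
  H  = 1.008,
  B  = 10.811,
  C  = 12.011,
  N  = 14.007,
  O  = 15.999,
  F  = 18.998,
  P  = 30.974,
  S  = 32.065,
  Cl = 35.453,
  Br = 79.904,
  I  = 126.904
)

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_OK <- c("B", "C", "N", "O", "P", "S")

# Default valence candidates per element; the smallest candidate that is
# >= the (rounded-up) bond-order sum is used for implicit-H assignment.
DEFAULT_VALENCES <- list(
  B = 3, C = 4, N = 3, O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1, H = 0
)
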