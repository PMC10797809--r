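# Independent oracles for Dempster combination, kept deliberately naive so
# they share no code path with the package implementation.

# Oracle 1: enumerate every tuple of label choices across sources; tuples in
# which all sources name the same label contribute their product to that
# label's agreement mass, all other tuples contribute to the conflict.
oracle_enumerate <- function(M) {
  l <- nrow(M)
  phi <- ncol(M)
  tuples <- as.matrix(expand.grid(rep(list(seq_len(phi)), l)))
  agree <- numeric(phi)
  conflict <- 0
  for (t in seq_len(nrow(tuples))) {
    idx <- tuples[t, ]
    prod_t <- prod(M[cbind(seq_len(l), idx)])
    if (all(idx == idx[1])) {
      agree[idx[1]] <- agree[idx[1]] + prod_t
    } else {
      conflict <- conflict + prod_t
    }
  }
  list(k = conflict, masses = agree / sum(agree))
}

# Oracle 2: sequential pairwise combination, normalizing at each step.
oracle_sequential <- function(M) {
  acc <- M[1, ]
  for (s in 2:nrow(M)) {
    p <- acc * M[s, ]
    acc <- p / sum(p)
  }
  k_seq <- 1 - sum(apply(M, 2, prod))
  list(k = k_seq, masses = acc)
}

# Random valid BPA matrix: l sources over phi labels, occasionally with
# exact zeros (the paradox-inducing case).
random_mass_matrix <- function(l, phi, zero_prob = 0.2) {
  M <- matrix(rgamma(l * phi, shape = 1), l, phi)
  zeros <- matrix(runif(l * phi) < zero_prob, l, phi)
  keep <- rowSums(!zeros) > 0
  zeros[!keep, 1] <- FALSE       # keep at least one positive mass per row
  M[zeros] <- 0
  M <- M / rowSums(M)
  colnames(M) <- paste0("A", seq_len(phi))
  M
}

# Bare pixel array (attributes dropped) for bitwise image comparisons.
pix <- function(img) array(as.integer(img), dim(img))

expect_masses_equal <- function(object, expected, tol = 1e-12) {
  expect_equal(unname(as.numeric(object)), unname(as.numeric(expected)),
               tolerance = tol)
}
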