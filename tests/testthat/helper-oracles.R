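# Independent oracles and small builders shared across tests.
# The oracles deliberately use explicit per-component loops so they share no
# code path with the package's array-based implementations.

# Buckley weight extraction evaluated symbol by symbol:
# r_i = (c_i1 x ... x c_in)^(1/n), w_i = r_i x (sum r)^(-1),
# crisp_i = (L_i + M_i + U_i) / sum_j (L_j + M_j + U_j)
oracle_buckley <- function(entries) {
  n <- length(entries)
  r <- vector("list", n)
  for (i in seq_len(n)) {
    prod <- c(1, 1, 1)
    for (j in seq_len(n)) {
      e <- entries[[i]][[j]]
      prod <- c(prod[1] * e[1], prod[2] * e[2], prod[3] * e[3])
    }
    r[[i]] <- c(prod[1]^(1 / n), prod[2]^(1 / n), prod[3]^(1 / n))
  }
  s <- c(0, 0, 0)
  for (i in seq_len(n)) s <- s + r[[i]]
  inv <- c(1 / s[3], 1 / s[2], 1 / s[1])
  w <- lapply(r, function(x) c(x[1] * inv[1], x[2] * inv[2], x[3] * inv[3]))
  comp <- numeric(n)
  for (i in seq_len(n)) comp[i] <- w[[i]][1] + w[[i]][2] + w[[i]][3]
  list(r = r, w = w, crisp = comp / sum(comp))
}

# random reciprocal linguistic matrix over the importance scale
random_term_matrix <- function(n, labels = paste0("X", seq_len(n))) {
  base <- c("E", "SI", "FI", "HI", "VI", "EI")
  codes <- c(base, paste0("1/", setdiff(base, "E")))
  m <- matrix("E", n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      m[i, j] <- sample(codes, 1)
      m[j, i] <- if (m[i, j] == "E") "E"
      else if (startsWith(m[i, j], "1/")) sub("^1/", "", m[i, j])
      else paste0("1/", m[i, j])
    }
  }
  m
}

# pairwise_matrix from a list of linguistic rows
pcm_rows <- function(rows, labels, source = "test") {
  m <- do.call(rbind, rows)
  rownames(m) <- colnames(m) <- labels
  pairwise_matrix(m, labels = labels, source = source)
}

# entries of a pairwise_matrix as the nested-list form the oracle expects
pcm_as_lists <- function(m) {
  n <- length(m$labels)
  lapply(seq_len(n), function(i) {
    lapply(seq_len(n), function(j) as.numeric(m$entries[i, j, ]))
  })
}

study_subs <- c("C11", "C12", "C21", "C22", "C31", "C32", "C41", "C42")

# absolute-tolerance comparison for published (truncated-print) values
expect_near <- function(object, expected, tol = 0.01) {
  expect_lte(max(abs(object - expected)), tol)
}
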