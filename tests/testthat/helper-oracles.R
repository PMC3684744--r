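# Brute-force LMG oracle: average sequential R2 increments over all p!
# orderings, with R2 from plain lm fits. Kept independent of the package's
# subset-weighted implementation.
lmg_bruteforce <- function(X, y, groups) {
  p <- length(groups)
  r2_of <- function(cols) {
    if (!length(cols)) return(0)
    summary(stats::lm(y ~ X[, cols, drop = FALSE]))$r.squared
  }
  perms <- gtools_permutations(p)
  contrib <- numeric(p)
  for (r in seq_len(nrow(perms))) {
    prev <- 0; cols <- integer(0)
    for (j in perms[r, ]) {
      cols <- c(cols, groups[[j]])
      cur <- r2_of(cols)
      contrib[j] <- contrib[j] + (cur - prev)
      prev <- cur
    }
  }
  contrib / nrow(perms)
}

# all permutations of 1..p without external packages
gtools_permutations <- function(p) {
  if (p == 1) return(matrix(1))
  sub <- gtools_permutations(p - 1)
  out <- matrix(0L, nrow = p * nrow(sub), ncol = p)
  row <- 1
  for (k in seq_len(p)) {
    for (r in seq_len(nrow(sub))) {
      rest <- setdiff(seq_len(p), k)[sub[r, ]]
      out[row, ] <- c(k, rest)
      row <- row + 1
    }
  }
  out
}

fit_from_matrix <- function(X, y) {
  d <- tibble::as_tibble(as.data.frame(X))
  d$y <- y
  fit_dispersal_glm(d, model_terms(linear = colnames(X)), response = "y")
}

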