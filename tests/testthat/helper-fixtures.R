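# shared fixtures built in code

path_adjacency <- function(n, names = paste0("M", seq_len(n))) {
  A <- matrix(0L, n, n, dimnames = list(names, names))
  if (n > 1) {
    A[cbind(1:(n - 1), 2:n)] <- 1L
    A <- A + t(A)
  }
  A
}

# undirected Erdos-Renyi-style adjacency with reproducible seed
random_adjacency <- function(p, prob, seed) {
  set.seed(seed)
  A <- matrix(0L, p, p, dimnames = list(paste0("V", 1:p), paste0("V", 1:p)))
  up <- upper.tri(A)
  A[up] <- as.integer(runif(sum(up)) < prob)
  A + t(A)
}

# exact correlation matrix of a Markov marker chain
chain_corr <- function(thetas, eps = rep(0, length(thetas) + 1),
                       names = paste0("M", seq_len(length(thetas) + 1))) {
  p <- length(thetas) + 1
  R <- diag(p)
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    r <- prod(1 - 2 * thetas[i:(j - 1)]) * (1 - 2 * eps[i]) * (1 - 2 * eps[j])
    R[i, j] <- R[j, i] <- r
  }
  dimnames(R) <- list(names, names)
  R
}

# per-test RNG isolation
local_rng <- function(seed, env = parent.frame()) {
  withr::local_seed(seed, .local_envir = env)
}
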