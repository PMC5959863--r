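# Independent oracles, deliberately written without reusing package internals.

# Dense multivariate-normal log density via Cholesky.
dmvnorm_log <- function(x, mean, V) {
  R <- chol(V)
  z <- backsolve(R, x - mean, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
}

# Brownian covariance by explicit path enumeration over the edge matrix:
# shared root-to-MRCA length = summed lengths of edges common to both
# root-to-tip paths.
brute_bm_cov <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent_edge <- function(node) which(tree$edge[, 2] == node)
  path_edges <- function(tip) {
    out <- integer(0); node <- tip
    while (node != root) {
      e <- parent_edge(node)
      out <- c(out, e)
      node <- tree$edge[e, 1]
    }
    out
  }
  paths <- lapply(seq_len(ntip), path_edges)
  C <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) for (j in seq_len(ntip)) {
    C[i, j] <- sum(tree$edge.length[intersect(paths[[i]], paths[[j]])])
  }
  C
}

# Random positive-definite matrix.
rand_pd <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  crossprod(A) + diag(p) * 0.1
}

# Named trait vectors from a simulate_bm_traits data.frame.
trait_vec <- function(d, col) stats::setNames(d[[col]], d$species)
trait_mat <- function(d) {
  m <- rbind(x = d$x, y = d$y)
  colnames(m) <- d$species
  m
}
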