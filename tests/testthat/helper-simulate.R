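# Shared fixtures, built in code.

# Planted-cluster Likert battery: `sizes` symptoms per factor, common
# loading, 5-level discretization at the generator's default cut-points.
sim_likert <- function(n, sizes, loading = 0.85, seed = 1,
                       n_noise = 0, thresholds = c(-1.5, -0.5, 0.5, 1.5)) {
  set.seed(seed)
  K <- length(sizes)
  f <- matrix(rnorm(n * K), n, K)
  cont <- do.call(cbind, lapply(seq_len(K), function(k) {
    vapply(seq_len(sizes[k]), function(j) {
      loading * f[, k] + rnorm(n, 0, sqrt(1 - loading^2))
    }, numeric(n))
  }))
  if (n_noise > 0) cont <- cbind(cont, matrix(rnorm(n * n_noise), n))
  lik <- matrix(cut(cont, c(-Inf, thresholds, Inf), labels = FALSE),
                n, ncol(cont))
  colnames(lik) <- sprintf("s%02d", seq_len(ncol(lik)))
  truth <- setNames(c(rep(seq_len(K), sizes), rep(0L, n_noise)),
                    colnames(lik))
  list(likert = lik, truth = truth, factors = f)
}

# Independent oracle: adjusted Rand index straight from the
# contingency-table formula, coded separately from the package's version.
ari_oracle <- function(p1, p2) {
  tab <- table(p1, p2)
  n <- sum(tab)
  sum_nij <- sum(tab * (tab - 1) / 2)
  sum_a <- sum(rowSums(tab) * (rowSums(tab) - 1) / 2)
  sum_b <- sum(colSums(tab) * (colSums(tab) - 1) / 2)
  ex <- sum_a * sum_b / (n * (n - 1) / 2)
  mx <- (sum_a + sum_b) / 2
  (sum_nij - ex) / (mx - ex)
}

# Independent oracle: all directed paths from `from` to `to` given an edge
# list (data frame from/to with weights), breadth-first.
paths_oracle <- function(edges, from, to) {
  out <- list()
  queue <- list(list(node = from, prod = 1, path = from))
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    if (cur$node == to && length(cur$path) > 1) {
      out[[length(out) + 1]] <- cur
      next
    }
    nxt <- edges[edges$from == cur$node, , drop = FALSE]
    for (i in seq_len(nrow(nxt))) {
      queue[[length(queue) + 1]] <- list(
        node = nxt$to[i], prod = cur$prod * nxt$weight[i],
        path = c(cur$path, nxt$to[i]))
    }
  }
  out
}

# Independent oracle for the bivariate normal CDF: one-dimensional
# adaptive quadrature of phi(x) * Phi((k - r x)/sqrt(1 - r^2)).
bvn_oracle <- function(h, k, r) {
  s <- sqrt(1 - r^2)
  integrate(function(x) dnorm(x) * pnorm((k - r * x) / s),
            -Inf, h, rel.tol = 1e-10)$value
}

# Small long-format biomarker table used by the exposure tests.
toy_biomarkers <- function() {
  data.frame(
    participant_id = c("A", "A", "A", "B", "B", "C"),
    year = c(1975, 1975, 1980, 1972, 1980, 1990),
    medium = c("hair", "hair", "blood", "hair", "hair", "hair"),
    value = c(3.0, 7.0, 20.0, 2.0, 4.0, 4.9),
    stringsAsFactors = FALSE)
}
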