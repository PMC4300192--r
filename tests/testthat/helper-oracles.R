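# Independent oracles, deliberately naive, used to verify the fast paths.

# term-by-term entropy of a single abundance row
entropy_oracle <- function(row) {
  a <- abs(row)
  s <- sum(a)
  if (s == 0) return(0)
  h <- 0
  for (v in a) {
    p <- v / s
    if (p > 0) h <- h - p * log(p)
  }
  h
}

# two-pass (mean-subtracted) Pearson correlation for one pair
cor_two_pass <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# one-pass sums-of-products form of Pearson's rho
cor_one_pass <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - sum(x) * sum(y) / n
  den <- sqrt((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
  num / den
}

# all-pairs packed vector from a per-pair oracle (per-pair double loop)
packed_oracle <- function(x, pair_fun) {
  k <- nrow(x)
  out <- numeric(k * (k - 1) / 2)
  at <- 0L
  for (i in 2:k) {
    for (j in 1:(i - 1)) {
      at <- at + 1L
      out[at] <- pair_fun(x[i, ], x[j, ])
    }
  }
  out
}

# Benjamini-Hochberg step-up via explicit sort + running minimum
bh_oracle <- function(p) {
  t_len <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(t_len)
  running <- Inf
  for (j in t_len:1) {
    running <- min(running, (t_len / j) * ps[j])
    q[j] <- min(running, 1)
  }
  out <- numeric(t_len)
  out[o] <- q
  out
}

# shared-neighbor counts by explicit per-pair summation
h_brute <- function(a) {
  k <- nrow(a)
  h <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      h[i, j] <- sum(a[i, ] * a[, j])
    }
  }
  h
}

# random expression fixture with gene/sample names
rand_expr <- function(k, n, seed = 1, mean = 0, sd = 1) {
  set.seed(seed)
  x <- matrix(rnorm(k * n, mean, sd), k, n)
  dimnames(x) <- list(sprintf("g%03d", seq_len(k)),
                      sprintf("s%03d", seq_len(n)))
  x
}

# edge_stats with prescribed q-values, for network-layer tests
stats_with_q <- function(q, gene_ids = NULL) {
  t_len <- length(q)
  k <- as.integer(round((1 + sqrt(1 + 8 * t_len)) / 2))
  stopifnot(k * (k - 1) / 2 == t_len)
  if (is.null(gene_ids)) gene_ids <- LETTERS[seq_len(k)]
  structure(list(k = k, gene_ids = gene_ids, rho = rep(0.5, t_len),
                 z = rep(1, t_len), p = q, q = q,
                 rho_bar = 0, s = 1, method = "empirical", tail = "two"),
            class = "edge_stats")
}

# network built straight from a 0/1 adjacency matrix
net_from_adjacency <- function(a, gene_ids = NULL, tau = 0.05) {
  k <- nrow(a)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%02d", seq_len(k))
  structure(list(gene_ids = gene_ids, k = k, adjacency = a,
                 connectivity = as.integer(rowSums(a)), tau = tau,
                 original_index = seq_len(k)),
            class = "coex_network")
}

# random symmetric 0/1 adjacency with zero diagonal
rand_adjacency <- function(k, p_edge, seed) {
  set.seed(seed)
  a <- matrix(0, k, k)
  a[upper.tri(a)] <- as.numeric(runif(k * (k - 1) / 2) < p_edge)
  a + t(a)
}

# reduced-scale synthetic scenario used across the pipeline tests; kept in
# the sparse-signal regime (planted pairs ~2% of all pairs) where the
# population z-statistic is calibrated, so the default tau applies
small_spec <- function(seed = 1, ...) {
  synthetic_spec(n_samples = 150,
                 modules = data.frame(size = c(15L, 15L),
                                      loading = rep(sqrt(1.5) * 0.6, 2)),
                 n_background = 60L, n_flat = 6L, seed = seed, ...)
}

# adjusted-Rand score of a pipeline result against generator truth,
# with all non-module genes collapsed to one background class on each side
pipeline_ari <- function(result, truth) {
  td <- gcoex::tidy(result)
  tr <- truth$module_label[match(td$gene_id, truth$gene_id)]
  tr[tr %in% c("background", "flat")] <- "bg"
  pred <- td$module_label
  pred[pred %in% c("unassigned", "unconnected")] <- "bg"
  adjusted_rand_index(pred, tr)
}
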