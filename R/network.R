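#' Hard-threshold edge statistics into a binary adjacency network
#'
#' A pair (i, j) is adjacent when its FDR q-value satisfies q_ij <= tau;
#' the adjacency matrix is symmetric with a zero diagonal (no self-edges:
#' applying the threshold literally to the diagonal would count every gene
#' as its own neighbor and corrupt the connectivity). Node connectivity is
#' the degree c_i = sum_j a_ij.
#'
#' @param stats An `edge_stats` object over k genes.
#' @param tau q-value threshold in `[0, 1]` (default 0.05, the conventional
#'   FDR level).
#' @return A `coex_network`: list with `gene_ids`, `k`, `adjacency` (k x k
#'   0/1 matrix), `connectivity` (integer degrees), `tau` and
#'   `original_index` (indices into the pre-pruning gene set).
#' @export
build_adjacency <- function(stats, tau = 0.05) {
  stopifnot(inherits(stats, "edge_stats"))
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau > 1) {
    stop("`tau` must be a single number in [0, 1]", call. = FALSE)
  }
  k <- stats$k
  a <- unpack_symmetric(as.numeric(stats$q <= tau), k, diagonal = 0)
  conn <- as.integer(rowSums(a))
  structure(list(gene_ids = stats$gene_ids %||% as.character(seq_len(k)),
                 k = k, adjacency = a, connectivity = conn, tau = tau,
                 original_index = seq_len(k)),
            class = "coex_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.coex_network <- function(x, ...) {
  cat(sprintf("<coex_network> %d genes, %d edges (tau = %g)\n",
              x$k, sum(x$connectivity) / 2, x$tau))
  cat(sprintf("  isolated genes: %d\n", sum(x$connectivity == 0)))
  invisible(x)
}

#' Remove zero-connectivity genes
#'
#' Returns the induced subnetwork on the genes with at least one edge, in
#' their original order. The `original_index` field maps the surviving nodes
#' back to the pre-pruning gene set so removed genes stay auditable.
#'
#' @param net A `coex_network`.
#' @return The pruned `coex_network` (attribute `removed_gene_ids` lists the
#'   dropped genes).
#' @export
prune_isolated <- function(net) {
  stopifnot(inherits(net, "coex_network"))
  keep <- which(net$connectivity > 0L)
  if (length(keep) == 0L) {
    stop(paste("every gene is isolated at tau =", net$tau,
               "- no network remains; consider a larger tau"),
         call. = FALSE)
  }
  out <- structure(list(gene_ids = net$gene_ids[keep],
                        k = length(keep),
                        adjacency = net$adjacency[keep, keep, drop = FALSE],
                        connectivity = net$connectivity[keep],
                        tau = net$tau,
                        original_index = net$original_index[keep]),
                   class = "coex_network")
  attr(out, "removed_gene_ids") <- net$gene_ids[-keep]
  out
}

#' Topological-overlap similarity matrix
#'
#' For a pruned binary network, the similarity between genes i and j is
#' s_ij = (h_ij + a_ij) / (c_i + c_j - h_ij - a_ij), where
#' h_ij = sum_u a_iu a_uj counts the neighbors shared by i and j and c_i is
#' the connectivity. Genes with identical neighbor sets score 1; genes with
#' disjoint neighborhoods and no direct edge score 0. The shared-neighbor
#' counts are obtained as the square of the adjacency matrix (one dense
#' matrix product), not a per-pair triple loop.
#'
#' @param net A pruned `coex_network` (no zero-connectivity nodes; such
#'   nodes would make the denominator vanish and must be removed with
#'   [prune_isolated()] first).
#' @return A `topo_similarity`: list with `gene_ids`, `k`, `s` (symmetric,
#'   values in `[0, 1]`, unit diagonal), `h` (shared-neighbor counts;
#'   diagonal h_ii = c_i by the definition of the product), `connectivity`
#'   and `original_index`.
#' @export
topological_similarity <- function(net) {
  stopifnot(inherits(net, "coex_network"))
  if (any(net$connectivity == 0L)) {
    stop("network contains zero-connectivity genes; prune_isolated() first",
         call. = FALSE)
  }
  a <- net$adjacency
  k <- net$k
  h <- a %*% a
  conn <- rowSums(a)
  denom <- outer(conn, conn, "+") - h - a
  off <- !diag(TRUE, k)
  # provable on pruned nets from h_ij <= min(c_i, c_j); asserted anyway
  if (any(denom[off] < 1)) {
    stop("internal error: similarity denominator < 1 on a pruned network")
  }
  s <- matrix(0, k, k)
  s[off] <- ((h + a)[off]) / denom[off]
  diag(s) <- 1
  if (any(s < 0) || any(s > 1)) {
    stop("internal error: similarity outside [0, 1]")
  }
  structure(list(gene_ids = net$gene_ids, k = k, s = s, h = h,
                 connectivity = as.integer(conn),
                 original_index = net$original_index),
            class = "topo_similarity")
}

#' @export
print.topo_similarity <- function(x, ...) {
  off <- x$s[!diag(TRUE, x$k)]
  cat(sprintf("<topo_similarity> %d genes; off-diagonal s: mean %.3f, max %.3f\n",
              x$k, if (length(off)) mean(off) else NA_real_,
              if (length(off)) max(off) else NA_real_))
  invisible(x)
}
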