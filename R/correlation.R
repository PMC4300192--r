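#' Packed strictly-lower-triangular index mapping
#'
#' All k(k-1)/2 pairwise statistics for k genes are held in a flat vector in
#' row-major strictly-lower-triangular order: pairs (2,1), (3,1), (3,2),
#' (4,1), ... in 1-based gene indices. `pair_to_index()` maps a gene pair to
#' its packed slot, `index_to_pair()` is the exact inverse.
#'
#' The closed forms are `idx = (i-1)(i-2)/2 + j` and, inverting,
#' `i = floor((1 + sqrt(1 + 8 (idx-1))) / 2) + 1`, `j = idx - (i-1)(i-2)/2`.
#' (In 0-based indexing, as used in the on-disk format documentation, these
#' read `idx0 = i0(i0-1)/2 + j0`.)
#'
#' @param i,j Gene indices with `1 <= j < i <= k`; vectorized.
#' @param idx Packed indices in `1..k(k-1)/2`; vectorized.
#' @param k Gene count (used only for range checking the inverse).
#' @return `pair_to_index()`: integer packed indices. `index_to_pair()`: an
#'   integer matrix with columns `i` and `j` (`i > j`), one row per input.
#' @examples
#' pair_to_index(2, 1)          # 1: first packed slot
#' pair_to_index(4, 3)          # 6
#' index_to_pair(6, k = 4)      # i = 4, j = 3
#' @export
pair_to_index <- function(i, j) {
  if (any(i != trunc(i)) || any(j != trunc(j))) {
    stop("gene indices must be integers", call. = FALSE)
  }
  if (any(j < 1L) || any(i <= j)) {
    stop("need 1 <= j < i: only the strictly-lower triangle is stored",
         call. = FALSE)
  }
  as.integer((i - 1) * (i - 2) / 2 + j)
}

#' @rdname pair_to_index
#' @export
index_to_pair <- function(idx, k) {
  t_len <- k * (k - 1) / 2
  if (any(idx != trunc(idx)) || any(idx < 1) || any(idx > t_len)) {
    stop(sprintf("packed index out of range 1..%d", t_len), call. = FALSE)
  }
  m <- idx - 1
  i0 <- floor((1 + sqrt(1 + 8 * m)) / 2)
  # guard against sqrt rounding at triangular-number boundaries
  i0 <- ifelse(i0 * (i0 - 1) / 2 > m, i0 - 1, i0)
  i0 <- ifelse((i0 + 1) * i0 / 2 <= m, i0 + 1, i0)
  j0 <- m - i0 * (i0 - 1) / 2
  cbind(i = as.integer(i0 + 1), j = as.integer(j0 + 1))
}

#' Construct a packed triangular correlation vector
#'
#' Container for the k(k-1)/2 strictly-lower-triangular pairwise values of a
#' symmetric k x k statistic, stored flat in the packed order defined by
#' [pair_to_index()].
#'
#' @param values Numeric vector of length `k*(k-1)/2`.
#' @param k Gene count.
#' @param gene_ids Optional character vector of length `k`.
#' @return An object of class `packed_cor`.
#' @export
packed_cor <- function(values, k, gene_ids = NULL) {
  t_len <- k * (k - 1) / 2
  if (length(values) != t_len) {
    stop(sprintf("values length %d != k(k-1)/2 = %d", length(values), t_len),
         call. = FALSE)
  }
  if (!is.null(gene_ids) && length(gene_ids) != k) {
    stop("gene_ids length must equal k", call. = FALSE)
  }
  structure(list(values = as.numeric(values), k = as.integer(k),
                 gene_ids = gene_ids),
            class = "packed_cor")
}

#' @export
print.packed_cor <- function(x, ...) {
  cat(sprintf("<packed_cor> %d genes, %d pairwise values\n",
              x$k, length(x$values)))
  if (length(x$values)) {
    cat(sprintf("  range [%.4f, %.4f], mean %.4f\n",
                min(x$values), max(x$values), mean(x$values)))
  }
  invisible(x)
}

#' All-pairs Pearson correlation in packed triangular storage
#'
#' Computes every pairwise Pearson correlation among the rows of an
#' expression matrix into a `packed_cor` vector. Rows are standardized once
#' (mean-subtracted, unit sum of squares) and the pairwise coefficients are
#' obtained by blocked matrix products over the standardized rows -- the
#' serial analogue of a massively parallel per-pair kernel -- rather than a
#' per-pair double loop, so tens of thousands of genes remain tractable.
#' The two-pass standardized form is algebraically identical to the one-pass
#' sums-of-products expression for Pearson's rho but numerically stable for
#' rows with large means.
#'
#' @param x Expression matrix (genes x samples) with `k >= 2` genes and
#'   `n >= 3` samples.
#' @param block_size Number of gene rows per block in the blocked product.
#' @return A `packed_cor` holding the k(k-1)/2 coefficients, each in
#'   `[-1, 1]`.
#' @details A gene with zero variance (constant row, including all-zero rows
#'   passed through the entropy filter) has no defined correlation; every
#'   coefficient involving it is set to 0 -- so such edges can never be
#'   called significant -- and a warning names the gene.
#' @export
pearson_all_pairs <- function(x, block_size = 2048L) {
  validate_expression(x)
  k <- nrow(x)
  n <- ncol(x)
  if (k < 2L) stop("need at least 2 genes to correlate", call. = FALSE)
  if (n < 3L) {
    stop("need at least 3 samples for a meaningful coefficient population",
         call. = FALSE)
  }
  if (block_size < 1L) stop("`block_size` must be positive", call. = FALSE)
  xc <- x - rowMeans(x)
  ss <- sqrt(rowSums(xc * xc))
  degenerate <- ss == 0
  if (any(degenerate)) {
    warning(sprintf(
      "zero-variance gene(s): %s; their correlations are set to 0",
      paste(head(rownames(x)[degenerate], 10L), collapse = ", ")),
      call. = FALSE)
    ss[degenerate] <- Inf   # standardized row becomes 0 -> rho 0
  }
  xs <- xc / ss
  t_len <- k * (k - 1) / 2
  values <- numeric(t_len)
  # row block [b0, b1] against all earlier rows 1..b1
  for (b0 in seq.int(1L, k, by = block_size)) {
    b1 <- min(b0 + block_size - 1L, k)
    blk <- xs[b0:b1, , drop = FALSE] %*% t(xs[seq_len(b1), , drop = FALSE])
    for (i in b0:b1) {
      if (i >= 2L) {
        at <- (i - 1L) * (i - 2L) / 2
        values[(at + 1L):(at + i - 1L)] <- blk[i - b0 + 1L, seq_len(i - 1L)]
      }
    }
  }
  values <- pmin(1, pmax(-1, values))
  packed_cor(values, k, gene_ids = rownames(x))
}

# Expand a packed strictly-lower-triangular vector to a full symmetric
# matrix with `diagonal` on the diagonal. Column-major upper.tri order of a
# symmetric matrix coincides with the row-major lower-triangle packed order.
unpack_symmetric <- function(values, k, diagonal = 0) {
  s <- matrix(0, k, k)
  s[upper.tri(s)] <- values
  s <- s + t(s)
  diag(s) <- diagonal
  s
}
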