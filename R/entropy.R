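#' Per-gene expression entropy
#'
#' For gene i with abundances x_ij over n samples, the normalized profile is
#' p_ij = |x_ij| / sum_k |x_ik| and the entropy is H_i = -sum_j p_ij log p_ij
#' (natural log). A gene expressed uniformly across samples attains the
#' maximum H = log n; a gene concentrated in one sample has H = 0. Because
#' uniform expression means no differential expression, high entropy marks
#' the genes the preprocessing filter removes.
#'
#' @param x Expression matrix (genes x samples), at least 2 samples.
#' @param base Logarithm base for the reported values, `exp(1)` (nats,
#'   default) or `2` (bits). The base rescales H uniformly and cannot change
#'   the gene ranking, hence never changes the filter outcome.
#' @return A tibble with columns `gene_id`, `entropy` and `retained`
#'   (logical, `NA` until a filter fraction is applied by [filter_genes()]).
#' @details Zero cells contribute nothing (0 log 0 := 0). A gene whose row is
#'   entirely zero has an undefined profile; it is assigned H = 0 so the
#'   entropy cut retains it (constant-zero rows are neutralized later, in the
#'   correlation stage, rather than silently dropped here).
#' @seealso [filter_genes()]
#' @export
gene_entropy <- function(x, base = exp(1)) {
  validate_expression(x)
  n <- ncol(x)
  if (n < 2L) {
    stop("entropy needs at least 2 samples; got 1", call. = FALSE)
  }
  if (!base %in% c(exp(1), 2)) {
    stop("`base` must be exp(1) or 2", call. = FALSE)
  }
  a <- abs(x)
  rs <- rowSums(a)
  p <- a / ifelse(rs > 0, rs, 1)
  plogp <- p * log(p)
  plogp[p == 0] <- 0
  h <- unname(-rowSums(plogp))
  h[unname(rs) == 0] <- 0
  h <- pmax(h, 0)
  if (base == 2) h <- h / log(2)
  tibble::tibble(gene_id = rownames(x), entropy = h,
                 retained = NA)
}

# Logical retention vector for an entropy cut: remove the ceiling(f*m) genes
# with the largest entropy; ties at the boundary keep the smaller row index.
entropy_retained <- function(entropy, fraction) {
  m <- length(entropy)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > 1) {
    stop("`fraction` must be a single number in [0, 1]", call. = FALSE)
  }
  if (fraction == 0) return(rep(TRUE, m))
  n_remove <- ceiling(fraction * m)
  if (n_remove >= m) {
    stop("filter fraction would remove every gene; nothing left downstream",
         call. = FALSE)
  }
  ord <- order(-entropy, -seq_len(m))
  retained <- rep(TRUE, m)
  retained[ord[seq_len(n_remove)]] <- FALSE
  retained
}

#' Remove the least-variable (highest-entropy) genes
#'
#' Drops the `ceiling(fraction * m)` genes with the largest entropy, i.e. the
#' genes closest to uniform (non-differential) expression. Surviving genes
#' keep their original order. With `fraction = 0` the input is returned
#' unchanged and no entropy is computed.
#'
#' @param x Expression matrix (genes x samples).
#' @param report Optional entropy report from [gene_entropy()] aligned to the
#'   rows of `x`; computed internally when `NULL`.
#' @param fraction Fraction of genes to remove, in `[0, 1)` (`1` is an error:
#'   it would empty the pipeline). Ties at the cut boundary retain the gene
#'   with the smaller original row index, so output is deterministic.
#' @return The filtered matrix. The completed entropy report (with the
#'   `retained` column filled) is attached as attribute `"entropy_report"`
#'   (`NULL` when `fraction = 0`).
#' @export
filter_genes <- function(x, report = NULL, fraction = 0.5) {
  validate_expression(x)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > 1) {
    stop("`fraction` must be a single number in [0, 1]", call. = FALSE)
  }
  if (fraction == 0) {
    attr(x, "entropy_report") <- NULL
    return(x)
  }
  if (is.null(report)) report <- gene_entropy(x)
  if (!identical(report$gene_id, rownames(x))) {
    stop("entropy report is not aligned to the rows of `x`", call. = FALSE)
  }
  retained <- entropy_retained(report$entropy, fraction)
  report$retained <- retained
  out <- x[retained, , drop = FALSE]
  attr(out, "entropy_report") <- report
  out
}
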