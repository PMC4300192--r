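#' Standardize a correlation-coefficient population to z-scores
#'
#' Normalizes the t = k(k-1)/2 pairwise coefficients against their own
#' population: z_i = (rho_i - rho_bar) / S, where rho_bar is the mean over
#' all t coefficients and S their sample standard deviation (denominator
#' t - 1). In a large coefficient population the z values are treated as
#' asymptotically standard normal, so each pair is tested against the bulk
#' of all pairs rather than against a per-pair null distribution.
#'
#' @param rho A `packed_cor` or a plain numeric vector of coefficients,
#'   length at least 2.
#' @return A list with `z` (standardized vector), `rho_bar` and `s`.
#' @export
normalize_coefficients <- function(rho) {
  v <- if (inherits(rho, "packed_cor")) rho$values else as.numeric(rho)
  if (length(v) < 2L) {
    stop("need at least 2 coefficients to standardize", call. = FALSE)
  }
  rho_bar <- mean(v)
  s <- sd(v)
  if (!is.finite(s) || s == 0) {
    stop(paste("degenerate coefficient population: all coefficients are",
               "identical, standard deviation is 0"), call. = FALSE)
  }
  list(z = (v - rho_bar) / s, rho_bar = rho_bar, s = s)
}

#' Convert z-scores to normal-theory p-values
#'
#' @param z Finite numeric vector of z-scores.
#' @param tail `"two"` (default): p = 2 (1 - Phi(|z|)), agnostic to the sign
#'   of co-expression. `"right"`: p = 1 - Phi(z), positive co-expression
#'   only.
#' @return p-values in `[0, 1]`.
#' @export
z_to_p <- function(z, tail = c("two", "right")) {
  tail <- match.arg(tail)
  if (any(!is.finite(z))) {
    stop("non-finite z-score(s)", call. = FALSE)
  }
  if (tail == "two") 2 * pnorm(-abs(z)) else pnorm(z, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: with p-values sorted ascending,
#' q_(i) = min over j >= i of (t p_(j) / j), capped at 1 and mapped back to
#' the original order. Monotone in p; ties share a q.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
fdr_qvalues <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be finite and in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Per-pair edge significance from a packed correlation vector
#'
#' Bundles the z-normalization, p-value transform and FDR adjustment into
#' the per-pair statistics table used to call edges.
#'
#' @param rho A `packed_cor` from [pearson_all_pairs()].
#' @param method `"empirical"` (default): z from the population
#'   standardization of [normalize_coefficients()]. `"fisher"`: the classical
#'   per-pair alternative z = atanh(rho) sqrt(n - 3); requires `n` and is a
#'   deliberate departure from the population method, offered for
#'   comparison.
#' @param tail Tail convention passed to [z_to_p()].
#' @param n Sample count; required by `method = "fisher"` (must be >= 4).
#' @return An `edge_stats` object: list with `k`, `gene_ids`, `rho`, `z`,
#'   `p`, `q`, `rho_bar`, `s` (the last two `NA` under `"fisher"`), `method`
#'   and `tail`. Use [tidy()] for a per-pair tibble.
#' @export
edge_significance <- function(rho, method = c("empirical", "fisher"),
                              tail = c("two", "right"), n = NULL) {
  method <- match.arg(method)
  tail <- match.arg(tail)
  stopifnot(inherits(rho, "packed_cor"))
  if (method == "empirical") {
    nz <- normalize_coefficients(rho)
    z <- nz$z
    rho_bar <- nz$rho_bar
    s <- nz$s
  } else {
    if (is.null(n) || n < 4) {
      stop("method 'fisher' needs the sample count n >= 4", call. = FALSE)
    }
    r <- pmin(1 - 1e-15, pmax(-1 + 1e-15, rho$values))
    z <- atanh(r) * sqrt(n - 3)
    rho_bar <- NA_real_
    s <- NA_real_
  }
  p <- z_to_p(z, tail = tail)
  q <- fdr_qvalues(p)
  structure(list(k = rho$k, gene_ids = rho$gene_ids, rho = rho$values,
                 z = z, p = p, q = q, rho_bar = rho_bar, s = s,
                 method = method, tail = tail),
            class = "edge_stats")
}

#' @export
print.edge_stats <- function(x, ...) {
  cat(sprintf("<edge_stats> %d genes, %d pairs (method %s, %s-tailed)\n",
              x$k, length(x$rho), x$method, x$tail))
  if (identical(x$method, "empirical")) {
    cat(sprintf("  rho_bar = %.4f, S = %.4f\n", x$rho_bar, x$s))
  }
  cat(sprintf("  pairs with q <= 0.05: %d\n", sum(x$q <= 0.05)))
  invisible(x)
}

#' Tidy per-pair edge statistics
#'
#' @param x An `edge_stats` object.
#' @param ... Unused.
#' @return A tibble with one row per gene pair in packed order: `gene_a`
#'   (lower index), `gene_b`, `rho`, `z`, `p`, `q`.
#' @method tidy edge_stats
#' @export
tidy.edge_stats <- function(x, ...) {
  t_len <- length(x$rho)
  ids <- if (is.null(x$gene_ids)) as.character(seq_len(x$k)) else x$gene_ids
  if (t_len == 0) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          rho = numeric(), z = numeric(), p = numeric(),
                          q = numeric()))
  }
  ij <- index_to_pair(seq_len(t_len), x$k)
  tibble::tibble(gene_a = ids[ij[, "j"]], gene_b = ids[ij[, "i"]],
                 rho = x$rho, z = x$z, p = x$p, q = x$q)
}

#' @method glance edge_stats
#' @export
glance.edge_stats <- function(x, ...) {
  tibble::tibble(k = x$k, n_pairs = length(x$rho), method = x$method,
                 tail = x$tail, rho_bar = x$rho_bar, s = x$s,
                 n_q_le_05 = sum(x$q <= 0.05))
}
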