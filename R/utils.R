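#' Validate a gene-by-sample expression matrix
#'
#' Checks the invariants every pipeline stage relies on: a numeric matrix with
#' genes as rows and samples as columns, unique row and column names, and no
#' missing or non-finite entries. Missing cells are an error, never imputed.
#'
#' @param x A numeric matrix (genes in rows, samples in columns) with unique
#'   rownames (gene identifiers) and colnames (sample identifiers).
#' @param arg Name used in error messages.
#' @return The validated matrix, invisibly unchanged.
#' @export
validate_expression <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix (genes x samples)", arg),
         call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(sprintf("`%s` must have rownames (gene IDs) and colnames (sample IDs)",
                 arg), call. = FALSE)
  }
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup)) {
    stop(sprintf("duplicated gene ID(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup)) {
    stop(sprintf("duplicated sample ID(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "missing/non-finite value at gene '%s', sample '%s'; missing data are not supported",
      rownames(x)[bad[1L]], colnames(x)[bad[2L]]), call. = FALSE)
  }
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Thin wrapper around [mclust::adjustedRandIndex()] used to score recovery of
#' planted module structure. Labels may be any atomic vectors of equal length.
#'
#' @param a,b Label vectors of equal length.
#' @return The adjusted Rand index (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  mclust::adjustedRandIndex(a, b)
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# 6-significant-digit rendering for human-readable edge tables.
fmt_sig6 <- function(x) {
  out <- formatC(x, digits = 6L, format = "g")
  gsub(" ", "", out, fixed = TRUE)
}

# Full-precision rendering for the round-trippable matrix writer.
fmt_full <- function(x) sprintf("%.17g", x)
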