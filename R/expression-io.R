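#' Read a gene-by-sample expression matrix from delimited text
#'
#' Parses a TSV/CSV abundance table: the first row is a header of sample IDs
#' (the corner cell is ignored), the first column holds gene IDs, and every
#' data cell must be a finite real. Rows are returned in file order; nothing
#' is reordered, rescaled or imputed.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter. `NULL` (default) autodetects from the
#'   extension: `","` for `.csv`, otherwise `"\t"`.
#' @param transpose If `TRUE`, the file stores samples in rows and genes in
#'   columns and is transposed after reading.
#' @return A numeric matrix with gene IDs as rownames and sample IDs as
#'   colnames.
#' @details Malformed input is a hard error, never silently repaired:
#'   duplicated gene IDs are reported by name, ragged rows by line number,
#'   and non-numeric or missing cells by their gene/sample coordinates.
#' @export
read_expression <- function(path, delimiter = NULL, transpose = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
  }
  nf <- count.fields(path, sep = delimiter, quote = "\"", comment.char = "")
  nf <- nf[!is.na(nf)]
  if (length(nf) < 2L) {
    stop("expression file needs a header row and at least one data row",
         call. = FALSE)
  }
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged row: line %d has %d fields, expected %d",
                 bad, nf[bad], nf[1L]), call. = FALSE)
  }
  dt <- data.table::fread(path, sep = delimiter, header = TRUE,
                          colClasses = "character", data.table = FALSE,
                          na.strings = NULL)
  gene_ids <- dt[[1L]]
  sample_ids <- colnames(dt)[-1L]
  if (length(sample_ids) < 1L) {
    stop("expression file has no sample columns", call. = FALSE)
  }
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) {
    stop(sprintf("duplicated gene ID(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  vals <- suppressWarnings(
    vapply(dt[-1L], as.numeric, numeric(nrow(dt)), USE.NAMES = FALSE)
  )
  vals <- matrix(vals, nrow = nrow(dt), ncol = length(sample_ids))
  if (anyNA(vals) || any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-numeric or missing cell '%s' at data row %d (gene '%s'), column %d (sample '%s')",
      dt[bad[1L], bad[2L] + 1L], bad[1L], gene_ids[bad[1L]],
      bad[2L] + 1L, sample_ids[bad[2L]]), call. = FALSE)
  }
  dimnames(vals) <- list(gene_ids, sample_ids)
  if (transpose) vals <- t(vals)
  validate_expression(vals, "expression matrix")
  vals
}

#' Write an expression matrix to delimited text at full precision
#'
#' Inverse of [read_expression()]: values are rendered with 17 significant
#' digits so a read/write round trip reproduces the matrix bit for bit.
#'
#' @param x Validated expression matrix (genes x samples).
#' @param path Output path.
#' @param delimiter Field delimiter; autodetected from the extension when
#'   `NULL`.
#' @return The path, invisibly.
#' @export
write_expression <- function(x, path, delimiter = NULL) {
  validate_expression(x)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  out <- data.frame(gene_id = rownames(x),
                    matrix(fmt_full(x), nrow = nrow(x)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("gene_id", colnames(x))
  data.table::fwrite(out, path, sep = delimiter, quote = FALSE)
  invisible(path)
}

#' Write the per-gene entropy report
#'
#' @param report Entropy report tibble from [gene_entropy()] (columns
#'   `gene_id`, `entropy`, `retained`).
#' @param path Output path (TSV).
#' @return The path, invisibly.
#' @export
write_entropy_table <- function(report, path) {
  stopifnot(is.data.frame(report),
            all(c("gene_id", "entropy", "retained") %in% names(report)))
  out <- data.frame(gene_id = report$gene_id,
                    entropy = fmt_sig6(report$entropy),
                    retained = as.integer(report$retained))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write the per-pair edge table
#'
#' One row per packed index, ascending, with columns `gene_a`, `gene_b`,
#' `rho`, `z`, `p`, `q`, `adjacent`. `gene_a` is the lower-indexed gene of the
#' pair. Floats are rendered with 6 significant digits.
#'
#' @param stats An `edge_stats` object (see [edge_significance()]).
#' @param net The unpruned [build_adjacency()] network over the same genes.
#' @param path Output path (TSV).
#' @return The path, invisibly.
#' @export
write_edge_table <- function(stats, net, path) {
  stopifnot(inherits(stats, "edge_stats"), inherits(net, "coex_network"))
  k <- stats$k
  if (net$k != k || !identical(net$gene_ids, stats$gene_ids)) {
    stop("edge statistics and network derive from different gene sets",
         call. = FALSE)
  }
  t_len <- k * (k - 1) / 2
  if (length(stats$rho) != t_len) {
    stop(sprintf("packed vector length %d does not match k(k-1)/2 = %d",
                 length(stats$rho), t_len), call. = FALSE)
  }
  if (t_len == 0) {
    writeLines("gene_a\tgene_b\trho\tz\tp\tq\tadjacent", path)
    return(invisible(path))
  }
  ij <- index_to_pair(seq_len(t_len), k)
  adjacent <- net$adjacency[cbind(ij[, "i"], ij[, "j"])]
  out <- data.frame(gene_a = stats$gene_ids[ij[, "j"]],
                    gene_b = stats$gene_ids[ij[, "i"]],
                    rho = fmt_sig6(stats$rho),
                    z = fmt_sig6(stats$z),
                    p = fmt_sig6(stats$p),
                    q = fmt_sig6(stats$q),
                    adjacent = as.integer(adjacent))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write the module assignment table
#'
#' @param assign Module assignment tibble (columns `gene_id`,
#'   `module_label`), e.g. from [identify_modules()].
#' @param path Output path (TSV).
#' @return The path, invisibly.
#' @export
write_modules_table <- function(assign, path) {
  stopifnot(is.data.frame(assign),
            all(c("gene_id", "module_label") %in% names(assign)))
  data.table::fwrite(assign[, c("gene_id", "module_label")], path,
                     sep = "\t", quote = FALSE)
  invisible(path)
}

#' Export a network to GraphML
#'
#' Nodes carry `gene_id` and `module` attributes; one edge is written per
#' unordered adjacent pair. Typically called on the pruned network so that
#' every exported node has degree at least one.
#'
#' @param net A `coex_network`.
#' @param modules Module assignment covering every gene in `net` (columns
#'   `gene_id`, `module_label`).
#' @param path Output path (`.graphml`).
#' @return The path, invisibly.
#' @export
write_graphml <- function(net, modules, path) {
  stopifnot(inherits(net, "coex_network"), is.data.frame(modules))
  missing_ids <- setdiff(net$gene_ids, modules$gene_id)
  if (length(missing_ids)) {
    stop(sprintf("gene(s) in network but absent from module labels: %s",
                 paste(head(missing_ids, 5L), collapse = ", ")),
         call. = FALSE)
  }
  if (net$k == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    g <- igraph::graph_from_adjacency_matrix(net$adjacency,
                                             mode = "undirected",
                                             diag = FALSE)
    lab <- modules$module_label[match(net$gene_ids, modules$gene_id)]
    g <- igraph::set_vertex_attr(g, "gene_id", value = net$gene_ids)
    g <- igraph::set_vertex_attr(g, "module", value = as.character(lab))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
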