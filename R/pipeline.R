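#' Run the full co-expression network pipeline
#'
#' Executes the four analysis stages in order -- entropy filtering,
#' all-pairs Pearson correlation, population z-normalization with FDR edge
#' calling, and network construction with topological-overlap module
#' identification -- and writes `entropy.tsv`, `edges.tsv`, `modules.tsv`,
#' `network.graphml` and a JSON run manifest to the output directory.
#' Everything downstream of the input is deterministic: identical input and
#' configuration give byte-identical `edges.tsv` and `modules.tsv`.
#'
#' @param input Path to a delimited expression file (see
#'   [read_expression()]) or an already-validated genes-x-samples matrix.
#' @param output_dir Output directory, created if absent.
#' @param filter_fraction Fraction of highest-entropy genes to remove
#'   (default 0.5). With 0 the entropy stage is skipped entirely -- no
#'   entropy is computed and no `entropy.tsv` is written.
#' @param tau FDR q-value threshold for edges (default 0.05).
#' @param tail,method Passed to [edge_significance()].
#' @param cut_height,min_module_size Passed to [identify_modules()].
#' @param transpose,delimiter Passed to [read_expression()] for file input.
#' @param overwrite Existing output files are an error unless `TRUE`.
#' @param quiet Suppress progress messages.
#' @return A `coex_pipeline` summary object (invisibly): stage gene counts,
#'   timings, the module assignment (including `"unconnected"` labels for
#'   pruned genes) and output paths. See [glance.coex_pipeline()] and
#'   [tidy.coex_pipeline()].
#' @details On any stage failure the partially written outputs are removed
#'   and the error is re-thrown with the stage name.
#' @export
run_pipeline <- function(input, output_dir,
                         filter_fraction = 0.5, tau = 0.05,
                         tail = "two", method = "empirical",
                         cut_height = 0.5, min_module_size = 5L,
                         transpose = FALSE, delimiter = NULL,
                         overwrite = FALSE, quiet = FALSE) {
  t_start <- proc.time()[["elapsed"]]
  say <- function(...) if (!quiet) message(sprintf(...))
  if (!dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  paths <- file.path(output_dir,
                     c(entropy = "entropy.tsv", edges = "edges.tsv",
                       modules = "modules.tsv", graphml = "network.graphml",
                       manifest = "manifest.json"))
  names(paths) <- c("entropy", "edges", "modules", "graphml", "manifest")
  existing <- paths[file.exists(paths)]
  if (length(existing) && !overwrite) {
    stop(sprintf("output file(s) already exist (use overwrite = TRUE): %s",
                 paste(basename(existing), collapse = ", ")), call. = FALSE)
  }
  written <- character(0)
  stage_seconds <- list()
  timed <- function(stage, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(code), error = function(e) {
      unlink(written)
      stop(sprintf("pipeline stage '%s' failed: %s",
                   stage, conditionMessage(e)), call. = FALSE)
    })
    stage_seconds[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  # -- input ----------------------------------------------------------------
  input_path <- NA_character_
  input_md5 <- NA_character_
  x <- timed("input", {
    if (is.character(input)) {
      input_path <- input
      input_md5 <- unname(tools::md5sum(input))
      read_expression(input, delimiter = delimiter, transpose = transpose)
    } else {
      if (transpose) input <- t(input)
      validate_expression(input, "input")
      input
    }
  })
  m_input <- nrow(x)
  n_samples <- ncol(x)
  say("input: %d genes x %d samples", m_input, n_samples)

  # -- entropy filter -------------------------------------------------------
  entropy_skipped <- filter_fraction == 0
  xf <- timed("entropy_filter", {
    if (entropy_skipped) {
      say("entropy filter: skipped (filter_fraction = 0)")
      x
    } else {
      out <- filter_genes(x, fraction = filter_fraction)
      write_entropy_table(attr(out, "entropy_report"), paths[["entropy"]])
      written <- c(written, paths[["entropy"]])
      say("entropy filter: removed %d of %d genes (fraction %.3g)",
          m_input - nrow(out), m_input, filter_fraction)
      out
    }
  })
  entropy_report <- attr(xf, "entropy_report")
  k_after_filter <- nrow(xf)

  # -- correlation ----------------------------------------------------------
  rho <- timed("correlation", pearson_all_pairs(xf))
  say("correlation: %d pairwise coefficients", length(rho$values))

  # -- significance ---------------------------------------------------------
  stats <- timed("significance",
                 edge_significance(rho, method = method, tail = tail,
                                   n = n_samples))

  # -- network + modules ----------------------------------------------------
  res <- timed("network_modules", {
    net <- build_adjacency(stats, tau = tau)
    write_edge_table(stats, net, paths[["edges"]])
    written <- c(written, paths[["edges"]])
    pruned <- prune_isolated(net)
    sim <- topological_similarity(pruned)
    assign_core <- identify_modules(sim, cut_height = cut_height,
                                    min_size = min_module_size)
    lab <- rep("unconnected", net$k)
    lab[pruned$original_index] <- assign_core$module_label
    assignment <- tibble::tibble(gene_id = net$gene_ids, module_label = lab)
    write_modules_table(assignment, paths[["modules"]])
    written <- c(written, paths[["modules"]])
    write_graphml(pruned, assignment, paths[["graphml"]])
    written <- c(written, paths[["graphml"]])
    list(net = net, pruned = pruned, assignment = assignment,
         assign_core = assign_core)
  })
  n_edges <- sum(res$net$connectivity) / 2
  n_unconnected <- res$net$k - res$pruned$k
  mods <- suppressWarnings(as.integer(res$assignment$module_label))
  n_modules <- length(unique(mods[!is.na(mods)]))
  say("network: %d edges at tau = %g; %d unconnected genes; %d modules",
      n_edges, tau, n_unconnected, n_modules)

  manifest <- list(
    package = "gcoex",
    version = as.character(packageVersion("gcoex")),
    parameters = list(filter_fraction = filter_fraction, tau = tau,
                      tail = tail, method = method, cut_height = cut_height,
                      min_module_size = min_module_size,
                      transpose = transpose),
    input = list(path = input_path, md5 = input_md5,
                 n_genes = m_input, n_samples = n_samples),
    stages = list(
      entropy_filter = list(
        status = if (entropy_skipped) "skipped" else "run",
        genes_in = m_input, genes_out = k_after_filter,
        genes_removed = m_input - k_after_filter),
      correlation = list(k = k_after_filter,
                         n_pairs = length(rho$values)),
      significance = list(method = method, tail = tail,
                          rho_bar = stats$rho_bar, s = stats$s,
                          edges_called = n_edges),
      network_modules = list(nodes_pruned = n_unconnected,
                             nodes_in_graphml = res$pruned$k,
                             n_modules = n_modules,
                             n_unassigned =
                               sum(res$assignment$module_label == "unassigned"))),
    stage_seconds = stage_seconds,
    total_seconds = round(proc.time()[["elapsed"]] - t_start, 3))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  out <- structure(list(manifest = manifest, paths = as.list(paths),
                        entropy_report = entropy_report,
                        edge_stats = stats, network = res$net,
                        pruned_network = res$pruned,
                        assignment = res$assignment),
                   class = "coex_pipeline")
  invisible(out)
}

#' @export
print.coex_pipeline <- function(x, ...) {
  st <- x$manifest$stages
  cat("<coex_pipeline>\n")
  cat(sprintf("  input: %d genes x %d samples\n",
              x$manifest$input$n_genes, x$manifest$input$n_samples))
  cat(sprintf("  entropy filter: %s (%d genes removed)\n",
              st$entropy_filter$status, st$entropy_filter$genes_removed))
  cat(sprintf("  correlation: %d genes, %d pairs\n",
              st$correlation$k, st$correlation$n_pairs))
  cat(sprintf("  edges called (q <= %g): %d\n",
              x$manifest$parameters$tau, st$significance$edges_called))
  cat(sprintf("  modules: %d (%d genes unconnected, %d unassigned)\n",
              st$network_modules$n_modules, st$network_modules$nodes_pruned,
              st$network_modules$n_unassigned))
  invisible(x)
}

#' One-row pipeline summary
#'
#' @param x A `coex_pipeline` from [run_pipeline()].
#' @param ... Unused.
#' @return A one-row tibble of headline counts.
#' @method glance coex_pipeline
#' @export
glance.coex_pipeline <- function(x, ...) {
  st <- x$manifest$stages
  tibble::tibble(
    n_genes = x$manifest$input$n_genes,
    n_samples = x$manifest$input$n_samples,
    genes_removed_by_entropy = st$entropy_filter$genes_removed,
    k_after_filter = st$entropy_filter$genes_out,
    n_pairs = st$correlation$n_pairs,
    edges_called = st$significance$edges_called,
    genes_unconnected = st$network_modules$nodes_pruned,
    n_modules = st$network_modules$n_modules)
}

#' Per-gene pipeline results
#'
#' @param x A `coex_pipeline` from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble with one row per post-filter gene: `gene_id`,
#'   `connectivity` and `module_label` (plus `entropy` when the filter ran).
#' @method tidy coex_pipeline
#' @export
tidy.coex_pipeline <- function(x, ...) {
  out <- tibble::tibble(gene_id = x$network$gene_ids,
                        connectivity = x$network$connectivity,
                        module_label = x$assignment$module_label)
  if (!is.null(x$entropy_report)) {
    out$entropy <- x$entropy_report$entropy[
      match(out$gene_id, x$entropy_report$gene_id)]
  }
  out
}
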