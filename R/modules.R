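#' Identify co-expression modules from topological-overlap similarity
#'
#' Clusters genes by average-linkage agglomerative clustering of the
#' dissimilarity d = 1 - s, cuts the tree at a fixed height, and promotes
#' every resulting group with at least `min_size` members to a module.
#' Modules are labeled "1", "2", ... by decreasing size (ties broken by the
#' smallest member index); genes in groups below `min_size` are labeled
#' `"unassigned"`. Tight modules appear as hot blocks along the diagonal of
#' the similarity matrix once rows and columns are put in dendrogram order
#' (see [order_for_heatmap()]).
#'
#' @param sim A `topo_similarity` from [topological_similarity()].
#' @param cut_height Tree cut height in `(0, 1]`, on the dissimilarity scale
#'   (default 0.5: genes merge into one module while their average
#'   topological overlap exceeds 0.5).
#' @param min_size Minimum module size (default 5).
#' @return A `module_assignment` tibble with columns `gene_id` and
#'   `module_label`; the hclust tree, cut height and minimum size are kept
#'   as attributes. Identical input gives byte-identical labels.
#' @export
identify_modules <- function(sim, cut_height = 0.5, min_size = 5L) {
  stopifnot(inherits(sim, "topo_similarity"))
  if (!is.numeric(cut_height) || length(cut_height) != 1L ||
      cut_height <= 0 || cut_height > 1) {
    stop("`cut_height` must be in (0, 1]", call. = FALSE)
  }
  if (min_size < 1L) stop("`min_size` must be >= 1", call. = FALSE)
  k <- sim$k
  if (k < 2L) {
    lab <- if (k >= 1L && min_size <= k) "1" else rep("unassigned", k)
    out <- tibble::tibble(gene_id = sim$gene_ids, module_label = lab)
    return(new_module_assignment(out, NULL, cut_height, min_size))
  }
  hc <- hclust(as.dist(1 - sim$s), method = "average")
  grp <- cutree(hc, h = cut_height)
  lab <- relabel_groups(grp, min_size)
  out <- tibble::tibble(gene_id = sim$gene_ids, module_label = lab)
  new_module_assignment(out, hc, cut_height, min_size)
}

new_module_assignment <- function(tbl, hc, cut_height, min_size) {
  structure(tbl, hclust = hc, cut_height = cut_height,
            min_size = as.integer(min_size),
            class = c("module_assignment", class(tbl)))
}

# Rename raw cutree groups: groups of size >= min_size become modules
# "1".."M" ordered by decreasing size, ties by smallest member index;
# smaller groups become "unassigned".
relabel_groups <- function(grp, min_size) {
  sizes <- table(grp)
  first_member <- vapply(names(sizes), function(g) min(which(grp == g)), 0L)
  eligible <- names(sizes)[sizes >= min_size]
  if (length(eligible) == 0L) return(rep("unassigned", length(grp)))
  ord <- eligible[order(-sizes[eligible], first_member[eligible])]
  lab <- rep("unassigned", length(grp))
  for (m in seq_along(ord)) lab[grp == ord[m]] <- as.character(m)
  lab
}

#' Dendrogram leaf order for similarity heatmaps
#'
#' Returns the permutation of gene indices given by the clustering tree's
#' leaf order. Members of each cut-height group occupy a contiguous run, so
#' applying the permutation to the rows and columns of the similarity matrix
#' places the module hot blocks on the diagonal.
#'
#' @param sim The `topo_similarity` that was clustered.
#' @param assign The matching `module_assignment`; its stored tree is reused
#'   when present (the tree is recomputed, deterministically, otherwise).
#' @return An integer permutation of `1..k`.
#' @export
order_for_heatmap <- function(sim, assign) {
  stopifnot(inherits(sim, "topo_similarity"),
            inherits(assign, "module_assignment"))
  if (!identical(assign$gene_id, sim$gene_ids)) {
    stop("module assignment does not cover the similarity matrix's genes",
         call. = FALSE)
  }
  if (sim$k < 2L) return(seq_len(sim$k))
  hc <- attr(assign, "hclust")
  if (is.null(hc)) hc <- hclust(as.dist(1 - sim$s), method = "average")
  hc$order
}

#' @method glance module_assignment
#' @export
glance.module_assignment <- function(x, ...) {
  lab <- x$module_label
  mods <- suppressWarnings(as.integer(lab))
  tibble::tibble(n_genes = nrow(x),
                 n_modules = length(unique(mods[!is.na(mods)])),
                 n_assigned = sum(!is.na(mods)),
                 n_unassigned = sum(lab == "unassigned"),
                 n_unconnected = sum(lab == "unconnected"),
                 largest_module = if (any(!is.na(mods)))
                   max(table(mods[!is.na(mods)])) else 0L)
}
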