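write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("well-formed TSV parses into a named matrix in file order", {
  path <- write_lines_tmp(c("id\ts1\ts2",
                            "GATA3\t1.5\t2",
                            "TP53\t0\t3.25",
                            "ESR1\t4\t5"))
  x <- read_expression(path)
  expect_identical(dim(x), c(3L, 2L))
  expect_identical(rownames(x), c("GATA3", "TP53", "ESR1"))
  expect_identical(colnames(x), c("s1", "s2"))
  expect_equal(x["TP53", "s2"], 3.25)
})

test_that("CSV is autodetected and transpose flips orientation", {
  path <- write_lines_tmp(c("id,g1,g2", "sampleA,1,2", "sampleB,3,4"),
                          ext = ".csv")
  x <- read_expression(path, transpose = TRUE)
  expect_identical(rownames(x), c("g1", "g2"))
  expect_identical(colnames(x), c("sampleA", "sampleB"))
  expect_equal(x["g2", "sampleA"], 2)
})

test_that("malformed input fails loudly with coordinates", {
  dup <- write_lines_tmp(c("id\ts1\ts2", "GATA3\t1\t2", "GATA3\t3\t4"))
  expect_error(read_expression(dup), "GATA3")

  na_cell <- write_lines_tmp(c("id\ts1\ts2", "g1\t1\t2", "g2\tNA\t4"))
  expect_error(read_expression(na_cell), "row 2.*g2.*column 2.*s1")

  ragged <- write_lines_tmp(c("id\ts1\ts2", "g1\t1\t2", "g2\t3"))
  expect_error(read_expression(ragged), "ragged")

  expect_error(read_expression(tempfile()), "not found")
})

test_that("write/read round trip reproduces the matrix exactly", {
  x <- rand_expr(23, 11, seed = 42, mean = 5, sd = 3)
  x[1, 1] <- pi * 1e6
  x[2, 2] <- 1 / 3
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, path)
  y <- read_expression(path)
  expect_identical(dimnames(y), dimnames(x))
  expect_identical(as.vector(y), as.vector(x))
})

test_that("edge table has one row per packed index with 6-sig-digit floats", {
  x <- rand_expr(3, 10, seed = 1)
  stats <- edge_significance(pearson_all_pairs(x))
  net <- build_adjacency(stats, tau = 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_table(stats, net, path)
  tab <- read.delim(path)
  expect_identical(nrow(tab), 3L)          # k(k-1)/2 for k = 3
  expect_identical(names(tab),
                   c("gene_a", "gene_b", "rho", "z", "p", "q", "adjacent"))
  # packed order: (2,1), (3,1), (3,2)
  expect_identical(tab$gene_a, c("g001", "g001", "g002"))
  expect_identical(tab$gene_b, c("g002", "g003", "g003"))
  expect_equal(tab$rho, signif(stats$rho, 6), tolerance = 1e-6)
  expect_true(all(tab$adjacent %in% c(0L, 1L)))
})

test_that("a perfectly correlated pair is adjacent when its q passes tau", {
  x <- rbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10),
             c = c(5, 1, 4, 2, 3))
  colnames(x) <- sprintf("s%d", 1:5)
  stats <- edge_significance(pearson_all_pairs(x))
  net <- build_adjacency(stats, tau = 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_table(stats, net, path)
  tab <- read.delim(path)
  ab <- tab[tab$gene_a == "a" & tab$gene_b == "b", ]
  expect_identical(ab$adjacent, as.integer(ab$q <= 0.5))
})

test_that("degenerate and mismatched edge tables are handled", {
  empty_stats <- stats_with_q(numeric(0), gene_ids = character(0))
  empty_net <- build_adjacency(empty_stats, tau = 0.05)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_table(empty_stats, empty_net, path)
  expect_identical(readLines(path), "gene_a\tgene_b\trho\tz\tp\tq\tadjacent")

  stats <- stats_with_q(c(0.01, 0.2, 0.04))
  net <- build_adjacency(stats)
  stats$rho <- stats$rho[-1]   # corrupt the packed length
  expect_error(write_edge_table(stats, net, path), "k\\(k-1\\)/2")
})

test_that("GraphML export carries nodes, edges and module labels", {
  a <- matrix(0, 3, 3)
  a[upper.tri(a)] <- 1
  net <- net_from_adjacency(a + t(a), gene_ids = c("x", "y", "z"))
  modules <- tibble::tibble(gene_id = c("x", "y", "z"),
                            module_label = c("1", "1", "1"))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, modules, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)
  expect_setequal(igraph::vertex_attr(g, "gene_id"), c("x", "y", "z"))
  expect_identical(unique(igraph::vertex_attr(g, "module")), "1")

  expect_error(write_graphml(net, modules[-1, ], path), "absent")
})

test_that("pruned networks export with no isolated nodes; empty is valid", {
  a <- rand_adjacency(8, 0.3, seed = 5)
  net <- prune_isolated(net_from_adjacency(a))
  modules <- tibble::tibble(gene_id = net$gene_ids,
                            module_label = rep("1", net$k))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, modules, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_true(all(igraph::degree(g) >= 1))

  empty <- net_from_adjacency(matrix(0, 0, 0), gene_ids = character(0))
  write_graphml(empty, tibble::tibble(gene_id = character(0),
                                      module_label = character(0)), path)
  g0 <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g0), 0)
})
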