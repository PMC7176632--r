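mk_topo <- function(id, nodes, edges,
                    source = "kegg_like", validate = TRUE) {
  nd <- dplyr::bind_rows(lapply(nodes, function(n) {
    tibble::tibble(node_id = n[[1]], node_type = n[[2]],
                   members = list(if (length(n) > 2) n[[3]] else character()))
  }))
  ed <- if (length(edges)) {
    dplyr::bind_rows(lapply(edges, function(e) {
      tibble::tibble(src = e[[1]], dst = e[[2]], relation = e[[3]],
                     directed = if (length(e) > 3) e[[4]] else TRUE)
    }))
  } else tibble::tibble(src = character(), dst = character(),
                        relation = character(), directed = logical())
  topo <- structure(list(pathway_id = id, name = id, source = source,
                         nodes = nd, edges = ed),
                    class = "pathway_topology")
  if (validate) validate_topology(topo)
  topo
}

gn <- function(id) list(id, "gene")
cp <- function(id) list(id, "compound")
cx <- function(id, members) list(id, "complex", members)

edge_set <- function(net) {
  e <- network_edges(net)
  sort(paste(e$gene1, e$gene2, e$edge_class))
}

test_that("regulatory, complex and compound rules convert as specified", {
  # (a) activation edge between genes -> one direct edge
  t1 <- mk_topo("t1", list(gn("A"), gn("B")), list(list("A", "B", "activation")))
  expect_equal(edge_set(topology_to_gene_graph(t1)), "A B direct")
  # (b) complex membership -> clique
  t2 <- mk_topo("t2", list(cx("CX", c("A", "B", "C"))), list())
  expect_equal(edge_set(topology_to_gene_graph(t2)),
               c("A B direct", "A C direct", "B C direct"))
  # (c) compound chain -> one indirect edge
  t3 <- mk_topo("t3", list(gn("A"), cp("c1"), cp("c2"), gn("B")),
                list(list("A", "c1", "compound_flow"),
                     list("c1", "c2", "compound_flow"),
                     list("c2", "B", "compound_flow")))
  expect_equal(edge_set(topology_to_gene_graph(t3)), "A B indirect")
  # dangling compound produces nothing
  t4 <- mk_topo("t4", list(gn("A"), cp("c1")),
                list(list("A", "c1", "compound_flow")))
  expect_equal(nrow(network_edges(topology_to_gene_graph(t4))), 0L)
  # nodes cover the gene universe even when isolated
  expect_equal(sort(network_nodes(topology_to_gene_graph(t4))$gene), "A")
})

test_that("complex cliques have k(k-1)/2 edges for k = 2..8", {
  for (k in 2:8) {
    topo <- mk_topo(paste0("k", k), list(cx("CX", sprintf("M%02d", 1:k))),
                    list())
    net <- topology_to_gene_graph(topo)
    expect_equal(nrow(network_edges(net)), k * (k - 1) / 2)
    expect_true(all(network_edges(net)$edge_class == "direct"))
  }
})

test_that("self-loops are never emitted, even for self-regulation", {
  t_self <- mk_topo("ts", list(gn("A"), gn("B")),
                    list(list("A", "A", "activation"),
                         list("A", "B", "activation")))
  net <- topology_to_gene_graph(t_self)
  e <- network_edges(net)
  expect_true(all(e$gene1 != e$gene2))
  expect_equal(edge_set(net), "A B direct")
  # complex sharing a member with the other endpoint: no self pair
  t_cx <- mk_topo("tc", list(cx("CX", c("A", "B")), gn("A"),
                             cp("c1")), list(list("CX", "A", "binding")))
  e2 <- network_edges(topology_to_gene_graph(t_cx))
  expect_true(all(e2$gene1 != e2$gene2))
})

test_that("compound-path search matches exhaustive path enumeration", {
  # a branched compound web between four genes
  topo <- mk_topo("web",
    list(gn("A"), gn("B"), gn("C"), gn("D"),
         cp("c1"), cp("c2"), cp("c3"), cp("c4")),
    list(list("A", "c1", "compound_flow"),
         list("c1", "c2", "compound_flow"),
         list("c2", "B", "compound_flow"),
         list("c1", "c3", "compound_flow", FALSE),
         list("c3", "C", "compound_flow"),
         list("D", "c4", "compound_flow"),
         list("c4", "c1", "compound_flow")))
  for (hops in 0:4) {
    net <- topology_to_gene_graph(topo, max_compound_hops = hops)
    got <- edge_set(net)
    # oracle: enumerate all simple directed paths gene -> compounds -> gene
    g <- igraph::graph_from_data_frame(dplyr::bind_rows(
      topo$edges[, c("src", "dst")],
      tibble::tibble(src = topo$edges$dst[!topo$edges$directed],
                     dst = topo$edges$src[!topo$edges$directed])))
    types <- stats::setNames(topo$nodes$node_type, topo$nodes$node_id)
    genes <- names(types)[types == "gene" & names(types) %in%
                            igraph::V(g)$name]
    pairs <- character()
    for (s in genes) for (t in setdiff(genes, s)) {
      paths <- igraph::all_simple_paths(g, s, t)
      for (p in paths) {
        nm <- igraph::V(g)$name[p]
        inner <- nm[-c(1, length(nm))]
        if (length(inner) >= 1 && length(inner) <= hops &&
            all(types[inner] == "compound")) {
          pairs <- c(pairs, paste(sort(c(s, t)), collapse = " "))
        }
      }
    }
    expected <- if (length(pairs)) sort(unique(paste(pairs, "indirect")))
                else character(0)
    expect_equal(got, expected, info = paste("hops =", hops))
  }
})

test_that("pathway selection keeps only pathways touching mutated genes", {
  t1 <- mk_topo("t1", list(gn("PIK3R1"), gn("X")),
                list(list("PIK3R1", "X", "activation")))
  t2 <- mk_topo("t2", list(gn("Y"), gn("Z")), list(list("Y", "Z", "binding")))
  t3 <- mk_topo("t3", list(cx("CX", c("TET2", "W"))), list())
  sel <- select_pathways(list(t1, t2, t3), c("PIK3R1", "TET2"))
  expect_equal(vapply(sel, function(t) t$pathway_id, ""), c("t1", "t3"))
  expect_length(select_pathways(list(t1, t2), character()), 0L)
})

test_that("merging is nonredundant, precedence-aware and order-independent", {
  f1 <- gene_network(evidence = ev_row("A", "B", "direct", "kegg_like:p1"))
  f2 <- gene_network(evidence = ev_row("B", "A", "direct", "kegg_like:p2"))
  m <- merge_networks(list(f1, f2))
  expect_equal(nrow(network_edges(m)), 1L)
  expect_length(network_edges(m)$provenance[[1]], 2L)
  # disjoint fragments add exactly
  f3 <- gene_network(evidence = ev_row("C", "D", "indirect", "kegg_like:p3"))
  m2 <- merge_networks(list(f1, f3))
  expect_equal(network_counts(m2)$n_nodes, 4L)
  expect_equal(network_counts(m2)$n_edges, 2L)
  # class precedence: direct wins over indirect for the same pair
  f4 <- gene_network(evidence = ev_row("A", "B", "indirect", "kegg_like:p4"))
  m3 <- merge_networks(list(f4, f1))
  expect_equal(network_edges(m3)$edge_class, "direct")
  # associativity / commutativity up to set equality
  perms <- list(list(f1, f3, f4), list(f4, f1, f3), list(f3, f4, f1))
  sets <- lapply(perms, function(p) edge_set(merge_networks(p)))
  expect_true(all(vapply(sets, identical, TRUE, y = sets[[1]])))
  nested <- merge_networks(list(merge_networks(list(f1, f3)), f4))
  expect_equal(edge_set(nested), sets[[1]])
})

test_that("PPI integration adds predicted edges without demoting classes", {
  net <- gene_network(evidence = ev_row("A", "B", "direct", "kegg_like:p1"))
  ppi <- tibble::tibble(gene1 = c("X", "A"), gene2 = c("Y", "B"))
  out <- integrate_ppi(net, ppi)
  e <- network_edges(out)
  expect_equal(e$edge_class[e$gene1 == "X"], "predicted")
  expect_equal(e$edge_class[e$gene1 == "A"], "direct")
  expect_true("ppi" %in% e$provenance[[which(e$gene1 == "A")]])
  expect_equal(edge_set(integrate_ppi(net, ppi[0, ])), edge_set(net))
})

test_that("expression filtering removes unexpressed and unknown genes", {
  net <- gene_network(evidence = dplyr::bind_rows(
    ev_row("A", "B", "direct", "p1"), ev_row("B", "C", "direct", "p1"),
    ev_row("C", "D", "predicted", "ppi")))
  expr <- tibble::tibble(gene = c("A", "B", "C"), nx_value = c(5, 1.0, 0.5))
  out <- expression_filter(net, expr)
  expect_equal(sort(network_nodes(out)$gene), c("A", "B"))  # C < 1, D unknown
  expect_equal(edge_set(out), "A B direct")
  expect_equal(attr(out, "dropped_unknown"), "D")
  # boundary: expression exactly 1 is kept
  expect_true("B" %in% network_nodes(out)$gene)
  keep <- expression_filter(net, expr, keep_unknown = TRUE)
  expect_true("D" %in% network_nodes(keep)$gene)
  # all expressed: unchanged
  all_expr <- tibble::tibble(gene = c("A", "B", "C", "D"), nx_value = 2)
  expect_equal(edge_set(expression_filter(net, all_expr)), edge_set(net))
})

test_that("the mutated subnetwork is the induced subgraph with isolated nodes", {
  net <- gene_network(
    genes = c("A", "B", "C", "D", "E", "F"),
    evidence = dplyr::bind_rows(
      ev_row("A", "B", "direct", "p1"), ev_row("B", "C", "direct", "p1"),
      ev_row("C", "D", "indirect", "p1"), ev_row("D", "E", "direct", "p1"),
      ev_row("E", "F", "predicted", "ppi")))
  sub <- mutated_subnetwork(net, c("A", "B", "C", "D", "E"))
  expect_equal(sub$summary$n_nodes, 5L)
  expect_equal(sub$summary$n_edges, 4L)   # planted induced 5 nodes / 4 edges
  expect_equal(sub$summary$n_isolated, 0L)
  # isolated mutated gene retained and counted separately
  sub2 <- mutated_subnetwork(net, c("A", "B", "F"))
  expect_equal(sub2$summary$n_nodes, 3L)
  expect_equal(sub2$summary$n_edges, 1L)
  expect_equal(sub2$summary$n_isolated, 1L)
  expect_equal(nrow(mutated_subnetwork(net, character())$network$nodes), 0L)
  expect_lte(mutated_subnetwork(net, LETTERS)$summary$n_nodes, 26L)
  # expression-filter and induction commute (both node restrictions)
  expr <- tibble::tibble(gene = c("A", "B", "C", "D"), nx_value = 2)
  a <- mutated_subnetwork(expression_filter(net, expr), c("A", "B", "C"))
  b <- expression_filter(mutated_subnetwork(net, c("A", "B", "C"))$network,
                         expr)
  expect_equal(edge_set(a$network), edge_set(b))
})

test_that("export formats are valid and GraphML round-trips identically", {
  net <- gene_network(
    genes = c("A", "B", "C", "Z"),
    evidence = dplyr::bind_rows(
      ev_row("A", "B", "direct", "kegg_like:p1"),
      ev_row("A", "B", "predicted", "ppi"),
      ev_row("B", "C", "indirect", "kegg_like:p2")))
  net$nodes$mutated <- c(TRUE, TRUE, FALSE, TRUE)
  net$nodes$expression <- c(5, 1, 2, 9)
  sif <- tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  lines <- readLines(sif)
  expect_equal(sort(lines),
               sort(c("A\tdirect\tB", "B\tindirect\tC", "Z")))
  gml <- tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back <- import_network_graphml(gml)
  expect_equal(edge_set(back), edge_set(net))
  expect_equal(dplyr::arrange(back$nodes, gene),
               dplyr::arrange(net$nodes, gene))
  # per-evidence provenance survives the round trip
  e0 <- network_edges(net); e1 <- network_edges(back)
  expect_equal(sort(unlist(e1$provenance)), sort(unlist(e0$provenance)))
  # empty network still exports valid GraphML
  empty <- gene_network()
  export_network(empty, gml, "graphml")
  expect_equal(nrow(import_network_graphml(gml)$nodes), 0L)
  expect_error(export_network(net, tempfile(), "xlsx"))
})

test_that("pathway JSON and GMT loaders validate their input", {
  b <- simulate_pathways(sprintf("M%d", 1:8), seed = 1)
  f <- tempfile(fileext = ".json")
  nkdriver:::.write_topology_json(b$topologies[[1]], f)
  topo <- read_pathway_json(f)
  expect_s3_class(topo, "pathway_topology")
  expect_equal(topo$pathway_id, b$topologies[[1]]$pathway_id)
  expect_equal(edge_set(topology_to_gene_graph(topo)),
               edge_set(topology_to_gene_graph(b$topologies[[1]])))
  bad <- mk_topo("bad", list(gn("A")), list(), validate = FALSE)
  bad$edges <- tibble::tibble(src = "A", dst = "ghost",
                              relation = "activation", directed = TRUE)
  expect_error(validate_topology(bad), "not declared")
  bad2 <- mk_topo("bad2", list(cx("CX", "A")), list(), validate = FALSE)
  expect_error(validate_topology(bad2), "<2 members")
  gmt <- tempfile(fileext = ".gmt")
  writeLines("setA\tdesc\tG1\tG2\tG3", gmt)
  topos <- read_gmt(gmt)
  expect_equal(pathway_genes(topos[[1]]), c("G1", "G2", "G3"))
  expect_equal(nrow(topos[[1]]$edges), 0L)
})
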