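EDGE_CLASSES <- c("direct", "indirect", "predicted")  # precedence order
RELATIONS <- c("activation", "inhibition", "binding", "catalysis",
               "compound_flow")

#' Read a typed pathway topology
#'
#' Topologies model KEGG/Reactome-like pathways as typed graphs: `gene`
#' nodes (node id = gene symbol), `compound` nodes (small molecules), and
#' `complex` nodes listing >= 2 member genes; edges carry a relation type
#' and a directed flag. The JSON schema is
#' `{pathway_id, name, source, nodes: [{node_id, node_type, members}],
#' edges: [{src, dst, relation, directed}]}`.
#'
#' `read_gmt()` loads flat gene sets as degenerate topologies (gene nodes,
#' no edges), usable for pathway selection only.
#'
#' @param path JSON (or GMT) file path.
#' @return A `pathway_topology` object (list of `pathway_id`, `name`,
#'   `source`, `nodes`, `edges`).
#' @export
read_pathway_json <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  nodes <- dplyr::bind_rows(lapply(p$nodes, function(n) {
    tibble::tibble(node_id = n$node_id, node_type = n$node_type,
                   members = list(as.character(unlist(n$members))))
  }))
  edges <- if (length(p$edges) > 0) {
    dplyr::bind_rows(lapply(p$edges, function(e) {
      tibble::tibble(src = e$src, dst = e$dst, relation = e$relation,
                     directed = isTRUE(e$directed))
    }))
  } else {
    tibble::tibble(src = character(), dst = character(),
                   relation = character(), directed = logical())
  }
  topo <- structure(list(pathway_id = p$pathway_id, name = p$name,
                         source = p$source %||% "user",
                         nodes = nodes, edges = edges),
                    class = "pathway_topology")
  validate_topology(topo)
  topo
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @rdname read_pathway_json
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lapply(lines[nzchar(lines)], function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    genes <- unique(f[-(1:2)])
    structure(list(
      pathway_id = f[1], name = f[2], source = "user",
      nodes = tibble::tibble(node_id = genes, node_type = "gene",
                             members = rep(list(character()), length(genes))),
      edges = tibble::tibble(src = character(), dst = character(),
                             relation = character(), directed = logical())
    ), class = "pathway_topology")
  })
}

#' @param topo A `pathway_topology`.
#' @rdname read_pathway_json
#' @export
validate_topology <- function(topo) {
  n <- topo$nodes
  problems <- character()
  dup <- n$node_id[duplicated(n$node_id)]
  if (length(dup)) problems <- c(problems, paste("duplicate node ids:", paste(dup, collapse = ", ")))
  n_members <- lengths(n$members)
  bad_cx <- n$node_id[n$node_type == "complex" & n_members < 2L]
  if (length(bad_cx)) problems <- c(problems, paste("complex with <2 members:", paste(bad_cx, collapse = ", ")))
  bad_plain <- n$node_id[n$node_type != "complex" & n_members > 0L]
  if (length(bad_plain)) problems <- c(problems, paste("gene/compound node with members:", paste(bad_plain, collapse = ", ")))
  if (nrow(topo$edges)) {
    dangling <- setdiff(c(topo$edges$src, topo$edges$dst), n$node_id)
    if (length(dangling)) problems <- c(problems, paste("edge endpoint not declared:", paste(dangling, collapse = ", ")))
    bad_rel <- setdiff(topo$edges$relation, RELATIONS)
    if (length(bad_rel)) problems <- c(problems, paste("unknown relation:", paste(bad_rel, collapse = ", ")))
  }
  if (length(problems)) {
    stop("invalid pathway topology '", topo$pathway_id, "': ",
         paste(problems, collapse = "; "))
  }
  invisible(topo)
}

#' Gene universe of a pathway
#'
#' All genes a pathway touches: gene-node ids plus complex members.
#'
#' @param topo A `pathway_topology`.
#' @return Character vector of gene symbols.
#' @export
pathway_genes <- function(topo) {
  n <- topo$nodes
  unique(c(n$node_id[n$node_type == "gene"],
           unlist(n$members[n$node_type == "complex"])))
}

# ---- gene_network container ---------------------------------------------

#' Construct a gene network
#'
#' An undirected, provenance-annotated gene graph. Nodes carry expression,
#' mutation status and an optional driver score; each edge keeps the set of
#' evidence entries (source pathway or PPI) that support it, each with its
#' own class, and the displayed edge class is the highest-precedence class
#' among them (`direct` > `indirect` > `predicted`). No self-loops, no
#' duplicate unordered pairs.
#'
#' @param genes Character vector of initial node names.
#' @param evidence Tibble of edge evidence rows: `gene1`, `gene2`,
#'   `edge_class`, `provenance`.
#' @return A `gene_network` object.
#' @export
gene_network <- function(genes = character(), evidence = NULL) {
  nodes <- tibble::tibble(gene = unique(genes),
                          expression = NA_real_, mutated = FALSE,
                          driver_score = NA_real_)
  net <- structure(list(nodes = nodes, edges = .empty_edges()),
                   class = "gene_network")
  if (!is.null(evidence) && nrow(evidence) > 0L) {
    net <- .add_evidence(net, evidence)
  }
  net
}

.empty_edges <- function() {
  tibble::tibble(gene1 = character(), gene2 = character(),
                 edge_class = character(),
                 provenance = list(), prov_class = list())
}

# Collapse evidence rows into canonical unique unordered-pair edges.
.add_evidence <- function(net, ev) {
  stopifnot(all(c("gene1", "gene2", "edge_class", "provenance") %in% names(ev)))
  # existing edges back to evidence rows
  old <- net$edges
  if (nrow(old)) {
    old_ev <- tidyr::unnest(
      tibble::tibble(gene1 = old$gene1, gene2 = old$gene2,
                     edge_class = old$prov_class, provenance = old$provenance),
      cols = c("edge_class", "provenance"))
    ev <- dplyr::bind_rows(old_ev, ev)
  }
  ev <- ev[ev$gene1 != ev$gene2, , drop = FALSE]  # never self-loops
  if (nrow(ev) == 0L && nrow(old) == 0L) return(net)
  swap <- ev$gene1 > ev$gene2
  tmp <- ev$gene1[swap]; ev$gene1[swap] <- ev$gene2[swap]; ev$gene2[swap] <- tmp
  ev <- dplyr::distinct(ev, .data$gene1, .data$gene2, .data$edge_class,
                        .data$provenance)
  edges <- ev |>
    dplyr::group_by(.data$gene1, .data$gene2) |>
    dplyr::summarise(
      edge_class = EDGE_CLASSES[min(match(.data$edge_class, EDGE_CLASSES))],
      provenance = list(.data$provenance),
      prov_class = list(.data$edge_class),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$gene1, .data$gene2)
  new_genes <- setdiff(unique(c(edges$gene1, edges$gene2)), net$nodes$gene)
  if (length(new_genes)) {
    net$nodes <- dplyr::bind_rows(
      net$nodes,
      tibble::tibble(gene = new_genes, expression = NA_real_,
                     mutated = FALSE, driver_score = NA_real_))
  }
  net$edges <- edges
  net
}

#' @export
print.gene_network <- function(x, ...) {
  cls <- table(factor(x$edges$edge_class, levels = EDGE_CLASSES))
  cat(sprintf("<gene_network> %d nodes, %d edges (%s)\n",
              nrow(x$nodes), nrow(x$edges),
              paste(sprintf("%s: %d", names(cls), cls), collapse = ", ")))
  invisible(x)
}

#' Network accessors
#' @param net A `gene_network`.
#' @return `network_nodes`/`network_edges` return tibbles;
#'   `network_counts` a list of node/edge/class counts.
#' @export
network_nodes <- function(net) net$nodes

#' @rdname network_nodes
#' @export
network_edges <- function(net) net$edges

#' @rdname network_nodes
#' @export
network_counts <- function(net) {
  cls <- table(factor(net$edges$edge_class, levels = EDGE_CLASSES))
  list(n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
       by_class = as.list(as.integer(cls)) |> stats::setNames(EDGE_CLASSES))
}

# ---- topology -> gene graph ---------------------------------------------

#' Convert a pathway topology into a gene-network fragment
#'
#' Biology-driven conversion of typed pathway relations into pairwise
#' gene-gene connections:
#' (a) any edge whose two endpoints resolve to genes (a gene node, or every
#' member of a complex) yields `direct` edges between all gene pairs across
#' the endpoints; (b) complex membership yields a `direct` clique among the
#' members; (c) two genes connected by a path whose internal nodes are all
#' compounds (at least 2 edges, at most `max_compound_hops` compound
#' intermediates) gain an `indirect` edge — a biosynthetic connection
#' through compound intermediates. Edge direction in the topology is
#' honored while walking compound chains but discarded in the output,
#' which is undirected. Self-loops are never emitted.
#'
#' @param topo A validated `pathway_topology`.
#' @param max_compound_hops Maximum number of compound intermediates for
#'   rule (c); `0` disables compound-path edges entirely.
#' @return A `gene_network` fragment whose nodes are the pathway's gene
#'   universe.
#' @export
topology_to_gene_graph <- function(topo, max_compound_hops = 3) {
  validate_topology(topo)
  prov <- paste0(topo$source, ":", topo$pathway_id)
  n <- topo$nodes
  types <- stats::setNames(n$node_type, n$node_id)
  members <- stats::setNames(n$members, n$node_id)
  resolve <- function(id) {
    switch(types[[id]],
           gene = id,
           complex = members[[id]],
           character())
  }
  ev <- list()
  # (a) gene/complex endpoint edges -> direct cross pairs
  for (i in seq_len(nrow(topo$edges))) {
    g1 <- resolve(topo$edges$src[i])
    g2 <- resolve(topo$edges$dst[i])
    if (length(g1) && length(g2)) {
      pairs <- expand.grid(gene1 = g1, gene2 = g2, stringsAsFactors = FALSE)
      ev[[length(ev) + 1L]] <- tibble::tibble(
        gene1 = pairs$gene1, gene2 = pairs$gene2,
        edge_class = "direct", provenance = prov)
    }
  }
  # (b) complex cliques
  for (id in n$node_id[n$node_type == "complex"]) {
    m <- members[[id]]
    if (length(m) >= 2L) {
      cmb <- utils::combn(sort(unique(m)), 2L)
      ev[[length(ev) + 1L]] <- tibble::tibble(
        gene1 = cmb[1L, ], gene2 = cmb[2L, ],
        edge_class = "direct", provenance = prov)
    }
  }
  # (c) compound-only paths between gene-resolving nodes
  if (max_compound_hops > 0L && nrow(topo$edges) > 0L) {
    ev[[length(ev) + 1L]] <- .compound_paths(topo, types, resolve,
                                             max_compound_hops, prov)
  }
  evidence <- dplyr::bind_rows(ev)
  gene_network(pathway_genes(topo), evidence)
}

# Walk compound-only chains from each gene-resolving node, honoring edge
# direction, up to `max_hops` compound intermediates.
.compound_paths <- function(topo, types, resolve, max_hops, prov) {
  e <- topo$edges
  # adjacency: directed edges go src->dst; undirected both ways
  adj <- dplyr::bind_rows(
    tibble::tibble(from = e$src, to = e$dst),
    tibble::tibble(from = e$dst[!e$directed], to = e$src[!e$directed]))
  out <- list()
  starts <- names(types)[types %in% c("gene", "complex")]
  for (s in starts) {
    # frontier: compound nodes reachable with all-compound interiors
    frontier <- unique(adj$to[adj$from == s])
    frontier <- frontier[types[frontier] == "compound"]
    seen <- character()
    hops <- 0L
    while (length(frontier) && hops < max_hops) {
      hops <- hops + 1L
      seen <- union(seen, frontier)
      nxt <- unique(adj$to[adj$from %in% frontier])
      ends <- nxt[types[nxt] %in% c("gene", "complex")]
      for (t in ends) {
        g1 <- resolve(s); g2 <- resolve(t)
        if (length(g1) && length(g2)) {
          pairs <- expand.grid(gene1 = g1, gene2 = g2,
                               stringsAsFactors = FALSE)
          out[[length(out) + 1L]] <- tibble::tibble(
            gene1 = pairs$gene1, gene2 = pairs$gene2,
            edge_class = "indirect", provenance = prov)
        }
      }
      frontier <- setdiff(nxt[types[nxt] == "compound"], seen)
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(gene1 = character(), gene2 = character(),
                   edge_class = character(), provenance = character())
}

#' Select pathways touching mutated genes
#'
#' Keeps a pathway iff its gene universe intersects the mutated gene set;
#' only selected pathways are converted and merged into the meta-network.
#'
#' @param topologies List of `pathway_topology` objects.
#' @param mutated_genes Character vector of mutated gene symbols.
#' @return The selected sublist.
#' @export
select_pathways <- function(topologies, mutated_genes) {
  Filter(function(t) length(intersect(pathway_genes(t), mutated_genes)) > 0L,
         topologies)
}

#' Merge gene-network fragments into a nonredundant meta-network
#'
#' Node union and unordered-pair edge union; evidence (provenance) sets are
#' merged and each edge's class is recomputed by precedence. Merging is
#' associative and commutative up to set equality.
#'
#' @param fragments List of `gene_network` fragments.
#' @return A single merged `gene_network`.
#' @export
merge_networks <- function(fragments) {
  if (length(fragments) == 0L) return(gene_network())
  genes <- unique(unlist(lapply(fragments, function(f) f$nodes$gene)))
  ev <- dplyr::bind_rows(lapply(fragments, function(f) {
    if (nrow(f$edges) == 0L) return(NULL)
    tidyr::unnest(
      tibble::tibble(gene1 = f$edges$gene1, gene2 = f$edges$gene2,
                     edge_class = f$edges$prov_class,
                     provenance = f$edges$provenance),
      cols = c("edge_class", "provenance"))
  }))
  gene_network(genes, ev)
}

#' Overlay protein-protein interactions
#'
#' PPI pairs absent from the meta-network are added as `predicted` edges
#' with provenance `"ppi"`; pairs already present simply gain the `"ppi"`
#' evidence entry without changing class (precedence keeps pathway-derived
#' classes on top).
#'
#' @param net A `gene_network`.
#' @param ppi Tibble or data frame whose first two columns are gene
#'   symbols (extra columns ignored).
#' @return The integrated `gene_network`.
#' @export
integrate_ppi <- function(net, ppi) {
  if (is.null(ppi) || nrow(ppi) == 0L) return(net)
  ev <- tibble::tibble(gene1 = as.character(ppi[[1]]),
                       gene2 = as.character(ppi[[2]]),
                       edge_class = "predicted", provenance = "ppi")
  .add_evidence(net, ev)
}

#' Read a PPI edge list
#'
#' Two gene-symbol columns in a TSV; an optional score column is ignored.
#'
#' @param path TSV path.
#' @return Tibble with columns `gene1`, `gene2`.
#' @export
read_ppi <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  tibble::tibble(gene1 = as.character(df[[1]]), gene2 = as.character(df[[2]]))
}

#' Read a normalized expression table
#'
#' TSV with columns `gene` and `nx_value` (normalized expression, >= 0).
#'
#' @param path TSV path.
#' @return Tibble `gene`, `nx_value`.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  tibble::as_tibble(df[, c("gene", "nx_value")])
}

#' Remove unexpressed genes from a network
#'
#' Nodes whose normalized expression is below `threshold` are removed with
#' their edges; genes absent from the expression table are treated as
#' not expressed and removed too (set `keep_unknown = TRUE` to keep them).
#' Removed-unknown genes are recorded in the `"dropped_unknown"` attribute.
#'
#' @param net A `gene_network`.
#' @param expression Tibble `gene`, `nx_value` (or named numeric vector).
#' @param threshold Minimum expression kept (default 1; the boundary value
#'   itself is kept).
#' @param keep_unknown Keep genes missing from the table?
#' @return The filtered `gene_network`.
#' @export
expression_filter <- function(net, expression, threshold = 1,
                              keep_unknown = FALSE) {
  if (is.data.frame(expression)) {
    expr <- stats::setNames(expression$nx_value, expression$gene)
  } else expr <- expression
  vals <- expr[net$nodes$gene]
  net$nodes$expression <- unname(vals)
  unknown <- net$nodes$gene[is.na(vals)]
  keep <- !is.na(vals) & vals >= threshold
  if (keep_unknown) keep <- keep | is.na(vals)
  out <- .induce(net, net$nodes$gene[keep])
  attr(out, "dropped_unknown") <- if (keep_unknown) character() else unknown
  out
}

# restrict a network to a node subset (edges pruned accordingly)
.induce <- function(net, genes) {
  net$nodes <- net$nodes[net$nodes$gene %in% genes, , drop = FALSE]
  e <- net$edges
  net$edges <- e[e$gene1 %in% genes & e$gene2 %in% genes, , drop = FALSE]
  net
}

#' Extract the mutated-gene subnetwork
#'
#' Induced subgraph over the mutated genes surviving the expression filter.
#' Mutated genes without any connection remain as isolated nodes and are
#' counted separately in the summary.
#'
#' @param net A `gene_network` (expression-filtered meta-network).
#' @param mutated_genes Character vector of mutated gene symbols.
#' @return List: `network` (the induced `gene_network` with `mutated` set)
#'   and `summary` (`n_nodes`, `n_edges`, `n_isolated`, `by_class`).
#' @export
mutated_subnetwork <- function(net, mutated_genes) {
  sub <- .induce(net, intersect(net$nodes$gene, mutated_genes))
  sub$nodes$mutated <- TRUE
  connected <- unique(c(sub$edges$gene1, sub$edges$gene2))
  cnt <- network_counts(sub)
  cnt$n_isolated <- sum(!sub$nodes$gene %in% connected)
  list(network = sub, summary = cnt)
}

#' Export / import a gene network
#'
#' `sif` writes Cytoscape simple-interaction lines
#' (`geneA <edge_class> geneB`, isolated nodes as bare names); `graphml`
#' carries node attributes (`mutated`, `expression`, `driver_score`) and
#' edge attributes (`class`, per-evidence `provenance`/`prov_class`);
#' `tsv` writes a flat edge table. `import_network_graphml()` reads a
#' GraphML export back into an identical `gene_network`.
#'
#' @param net A `gene_network`.
#' @param path Output file path.
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  e <- net$edges
  if (format == "sif") {
    connected <- unique(c(e$gene1, e$gene2))
    lines <- c(sprintf("%s\t%s\t%s", e$gene1, e$edge_class, e$gene2),
               setdiff(net$nodes$gene, connected))
    writeLines(lines, path)
  } else if (format == "tsv") {
    flat <- tibble::tibble(
      gene1 = e$gene1, gene2 = e$gene2, edge_class = e$edge_class,
      provenance = vapply(e$provenance, paste, "", collapse = ";"))
    utils::write.table(flat, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- .as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

.as_igraph <- function(net) {
  e <- net$edges
  edf <- data.frame(
    from = e$gene1, to = e$gene2, class = e$edge_class,
    provenance = vapply(e$provenance, paste, "", collapse = ";"),
    prov_class = vapply(e$prov_class, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  vdf <- data.frame(name = net$nodes$gene, mutated = net$nodes$mutated,
                    expression = net$nodes$expression,
                    driver_score = net$nodes$driver_score,
                    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}

#' @rdname export_network
#' @export
import_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  vdf <- igraph::as_data_frame(g, what = "vertices")
  edf <- igraph::as_data_frame(g, what = "edges")
  net <- gene_network(vdf$name)
  net$nodes$expression <- as.numeric(vdf$expression)
  net$nodes$mutated <- as.logical(vdf$mutated)
  net$nodes$driver_score <- as.numeric(vdf$driver_score)
  net$nodes <- net$nodes[order(match(net$nodes$gene, sort(vdf$name))), ]
  net$nodes <- dplyr::arrange(net$nodes, .data$gene)
  if (nrow(edf)) {
    ev <- dplyr::bind_rows(lapply(seq_len(nrow(edf)), function(i) {
      tibble::tibble(gene1 = edf$from[i], gene2 = edf$to[i],
                     edge_class = strsplit(edf$prov_class[i], ";")[[1]],
                     provenance = strsplit(edf$provenance[i], ";")[[1]])
    }))
    net <- .add_evidence(net, ev)
  }
  net
}
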