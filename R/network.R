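#' Read an undirected protein-interaction network
#'
#' Accepts SIF rows (`A <relation> B`, tab-separated) or 2-column edge lists;
#' gzip-compressed files are read transparently. Self-loops are dropped with
#' a message and duplicate (undirected) edges are merged. Vertices are stored
#' in lexicographic order so downstream module detection is independent of
#' input row order.
#'
#' @param path path to a SIF or 2-column edge-list file.
#' @return an [igraph::igraph] undirected simple graph; edge attribute
#'   `relation` keeps the SIF relation tag when present.
#' @export
read_network <- function(path) {
  lines <- .text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 2 & nf != 3)
  if (length(bad) > 0) {
    .stopf("malformed network row at line %d: '%s'", bad[1], lines[bad[1]])
  }
  a <- vapply(parts, `[[`, "", 1)
  b <- vapply(parts, function(p) p[[length(p)]], "")
  rel <- ifelse(nf == 3, vapply(parts, `[[`, "", 2), NA_character_)
  self <- a == b
  if (any(self)) {
    message(sum(self), " self-loop(s) dropped")
    a <- a[!self]; b <- b[!self]; rel <- rel[!self]
  }
  edges <- data.frame(from = pmin(a, b), to = pmax(a, b),
                      relation = rel, stringsAsFactors = FALSE)
  edges <- edges[!duplicated(edges[, c("from", "to")]), , drop = FALSE]
  nodes <- sort(unique(c(edges$from, edges$to)))
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Write a network as SIF or a 2-column edge list
#'
#' @param network an igraph undirected graph.
#' @param path output path.
#' @param format `"sif"` (relation defaults to `"interacts"`) or
#'   `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("sif", "edgelist")) {
  format <- match.arg(format)
  el <- igraph::as_edgelist(network)
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  rows <- if (format == "sif") {
    rel <- igraph::edge_attr(network, "relation") %||%
      rep("interacts", nrow(el))
    rel[is.na(rel)] <- "interacts"
    paste(el[, 1], rel, el[, 2], sep = "\t")
  } else {
    paste(el[, 1], el[, 2], sep = "\t")
  }
  writeLines(rows, path)
  invisible(path)
}

#' Hypergeometric linker statistic for one candidate node
#'
#' Tests whether a non-seed node touches more seed nodes than expected by
#' chance: with N network nodes, m seeds present in the network and a
#' candidate of degree k with s seed neighbors, the p-value is the
#' upper-tail hypergeometric probability of drawing >= s seeds when k
#' neighbors are drawn from the other N - 1 nodes.
#'
#' @param network an igraph undirected graph.
#' @param seeds character vector of seed gene symbols.
#' @param candidate a single non-seed gene symbol present in `network`.
#' @return one-row data.frame: `gene`, `global_degree`, `seed_neighbors`,
#'   `p_value`.
#' @export
linker_test <- function(network, seeds, candidate) {
  nodes <- igraph::V(network)$name
  if (!candidate %in% nodes) .stopf("candidate '%s' not in network", candidate)
  seeds_in <- intersect(seeds, nodes)
  if (candidate %in% seeds_in) .stopf("candidate '%s' is a seed", candidate)
  k <- igraph::degree(network, candidate)
  if (k < 1) .stopf("candidate '%s' has degree 0", candidate)
  nbrs <- igraph::neighbors(network, candidate)$name
  s <- length(intersect(nbrs, seeds_in))
  N <- length(nodes)
  m <- length(seeds_in)
  p <- phyper(s - 1, m, N - 1 - m, k, lower.tail = FALSE)
  data.frame(gene = candidate, global_degree = as.integer(k),
             seed_neighbors = as.integer(s), p_value = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the seed + linker module graph
#'
#' NetBox-style construction: the candidate pool is every non-seed node
#' adjacent to at least one seed; each candidate gets a hypergeometric
#' linker p-value ([linker_test()]); p-values are BH-adjusted across the
#' pool and candidates with q < `linker_q_max` are admitted as linkers. The
#' module graph is the background subgraph induced on the in-network seeds
#' plus the accepted linkers (isolated seeds are retained as singletons).
#'
#' @param network an igraph undirected background network.
#' @param seeds character vector of seed gene symbols.
#' @param linker_q_max BH-adjusted p-value cutoff for linker admission
#'   (default 0.005).
#' @return list of class `module_graph`: `graph` (induced igraph subgraph),
#'   `linker_stats` (data.frame with `q_value` and `accepted`),
#'   `missing_seeds` (seeds absent from the background network), `roles`
#'   (named character vector, `"seed"` or `"linker"`).
#' @export
build_module_graph <- function(network, seeds, linker_q_max = 0.005) {
  stopifnot(length(seeds) > 0, linker_q_max >= 0)
  nodes <- igraph::V(network)$name
  seeds_in <- sort(intersect(unique(seeds), nodes))
  missing_seeds <- sort(setdiff(unique(seeds), nodes))
  if (length(seeds_in) == 0) .stopf("no seed maps into the background network")
  nbr_lists <- igraph::adjacent_vertices(network, seeds_in)
  candidates <- sort(setdiff(unique(unlist(lapply(nbr_lists, function(v) v$name))),
                             seeds_in))
  if (length(candidates) > 0) {
    stats <- do.call(rbind, lapply(candidates, function(g) {
      linker_test(network, seeds_in, g)
    }))
    stats$q_value <- adjust_bh(stats$p_value)
    stats$accepted <- stats$q_value < linker_q_max
  } else {
    stats <- data.frame(gene = character(), global_degree = integer(),
                        seed_neighbors = integer(), p_value = numeric(),
                        q_value = numeric(), accepted = logical())
  }
  linkers <- stats$gene[stats$accepted]
  keep <- sort(c(seeds_in, linkers))
  graph <- igraph::induced_subgraph(network, keep)
  roles <- setNames(ifelse(keep %in% seeds_in, "seed", "linker"), keep)
  structure(list(graph = graph, linker_stats = stats,
                 missing_seeds = missing_seeds, roles = roles),
            class = "module_graph")
}

#' Divisive community detection on the module graph
#'
#' Girvan-Newman clustering: edges of maximal betweenness are removed
#' iteratively and the partition is cut from the resulting dendrogram at
#' maximal Newman-Girvan modularity Q (via
#' [igraph::cluster_edge_betweenness()]). Connected components are handled
#' independently and singletons become singleton modules. Module ids are
#' renumbered by the lexicographically smallest member so the labeling is
#' independent of input order. The modularity of an edgeless graph is 0 by
#' convention.
#'
#' @param x a `module_graph` from [build_module_graph()] or a plain igraph
#'   graph.
#' @return list of class `module_partition`: `membership` (named integer
#'   vector), `modularity` (Q of the chosen partition), `roles` (from the
#'   module graph, if available).
#' @export
detect_modules <- function(x) {
  if (inherits(x, "module_graph")) {
    graph <- x$graph
    roles <- x$roles
  } else if (igraph::is_igraph(x)) {
    graph <- x
    roles <- setNames(rep(NA_character_, igraph::vcount(x)),
                      igraph::V(x)$name)
  } else .stopf("expected a module_graph or igraph object")
  n <- igraph::vcount(graph)
  if (n == 0) .stopf("empty graph")
  nodes <- igraph::V(graph)$name
  if (igraph::ecount(graph) == 0) {
    membership <- setNames(seq_len(n), nodes)
    q <- 0
  } else {
    cl <- igraph::cluster_edge_betweenness(graph, directed = FALSE,
                                           modularity = TRUE)
    membership <- setNames(as.integer(igraph::membership(cl)), nodes)
    q <- igraph::modularity(graph, membership)
  }
  # deterministic relabeling: modules ordered by smallest member name
  first <- tapply(nodes, membership, min)
  relabel <- setNames(seq_along(first), names(first)[order(first)])
  membership <- setNames(as.integer(relabel[as.character(membership)]), nodes)
  structure(list(membership = membership, modularity = q,
                 roles = roles[nodes]),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d nodes in %d modules (Q = %.3f)\n",
              length(x$membership), length(unique(x$membership)),
              x$modularity))
  invisible(x)
}

#' Summarize modules with per-member and mean expression response
#'
#' For one condition, attaches each member's log2ratio (mean over proteins
#' mapping to the gene; linkers without measurements contribute nothing) and
#' computes the arithmetic mean log2ratio per module over measured members.
#' A module is directed `up` when its mean is > 0, `down` when < 0.
#'
#' @param partition a `module_partition`.
#' @param table a `response_table`.
#' @param condition condition label present in `table`.
#' @return list of class `module_summary`: `modules` (data.frame
#'   `module_id`, `size`, `n_measured`, `mean_log2ratio`, `direction`) and
#'   `members` (data.frame `module_id`, `gene`, `role`, `log2ratio`).
#' @export
module_summary <- function(partition, table, condition) {
  stopifnot(inherits(partition, "module_partition"))
  rows <- table[table$condition == condition, ]
  if (nrow(rows) == 0) .stopf("unknown condition '%s'", condition)
  lfc_by_gene <- tapply(rows$log2ratio, rows$gene_symbol,
                        function(v) mean(v, na.rm = TRUE))
  genes <- names(partition$membership)
  members <- data.frame(module_id = unname(partition$membership),
                        gene = genes,
                        role = unname(partition$roles[genes]),
                        log2ratio = unname(lfc_by_gene[genes]),
                        stringsAsFactors = FALSE, row.names = NULL)
  members <- members[order(members$module_id, members$gene), , drop = FALSE]
  agg <- split(members, members$module_id)
  modules <- do.call(rbind, lapply(agg, function(d) {
    measured <- d$log2ratio[!is.na(d$log2ratio)]
    m <- if (length(measured) > 0) mean(measured) else NA_real_
    data.frame(module_id = d$module_id[1], size = nrow(d),
               n_measured = length(measured), mean_log2ratio = m,
               direction = if (is.na(m)) NA_character_
                           else if (m > 0) "up" else "down",
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(modules = modules, members = members),
            class = "module_summary")
}

#' Write module memberships with expression summaries to TSV
#'
#' One row per module member: `condition`, `network_source`, `module_id`,
#' `gene`, `role`, `log2ratio`, `module_mean_log2ratio`.
#'
#' @param summary a `module_summary`.
#' @param condition condition label for the output rows.
#' @param network_source label of the background network (e.g. "fi",
#'   "indra").
#' @param path output path; when `NULL` the data.frame is returned instead.
#' @return the output data.frame, invisibly when written.
#' @export
write_modules <- function(summary, condition, network_source, path = NULL) {
  stopifnot(inherits(summary, "module_summary"))
  mm <- summary$members
  means <- summary$modules$mean_log2ratio[match(mm$module_id,
                                                summary$modules$module_id)]
  out <- data.frame(condition = condition, network_source = network_source,
                    module_id = mm$module_id, gene = mm$gene, role = mm$role,
                    log2ratio = mm$log2ratio,
                    module_mean_log2ratio = means,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (is.null(path)) return(out)
  .write_tsv(out, path)
  invisible(out)
}
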