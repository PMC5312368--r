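#' Merge pathway fragments into one bipartite biograph
#'
#' Nodes are metabolites (KEGG-style compound ids) and enzymes; edges are
#' undirected metabolite--enzyme incidences. Fragments are merged by node-id
#' union; duplicate edges collapse, accumulating pathway membership on both
#' nodes and edges. The result is bipartite by construction and every
#' operation downstream preserves that.
#'
#' @param fragments list of `pathway_fragment` objects from [parse_kgml()].
#' @return An igraph object of class `metabolic_graph` with vertex
#'   attributes `type` (`metabolite`/`enzyme`) and `pathways`
#'   (`;`-separated), edge attribute `pathways`, and graph attributes
#'   `n_pathways`, `n_metabolites`, `n_enzymes`, `n_relations`.
#' @export
build_biograph <- function(fragments) {
  if (inherits(fragments, "pathway_fragment")) fragments <- list(fragments)
  if (!length(fragments)) stop("need at least one pathway fragment")
  nodes <- do.call(rbind, lapply(fragments, function(f)
    cbind(f$nodes, pathway = f$pathway_id)))
  conflict <- stats::aggregate(type ~ id, nodes, function(t) length(unique(t)))
  if (any(conflict$type > 1))
    stop("node id used with conflicting types across files: ",
         paste(conflict$id[conflict$type > 1], collapse = ", "))
  vert <- stats::aggregate(pathway ~ id + type, nodes,
                           function(p) paste(sort(unique(p)), collapse = ";"))
  edges <- do.call(rbind, lapply(fragments, function(f)
    if (nrow(f$edges)) cbind(f$edges, pathway = f$pathway_id)))
  g <- if (is.null(edges) || !nrow(edges)) {
    igraph::make_empty_graph(directed = FALSE)
  } else {
    eagg <- stats::aggregate(pathway ~ compound + enzyme, edges,
                             function(p) paste(sort(unique(p)), collapse = ";"))
    igraph::graph_from_data_frame(eagg, directed = FALSE,
                                  vertices = data.frame(name = vert$id))
  }
  if (igraph::vcount(g) < nrow(vert)) {
    missing <- setdiff(vert$id, igraph::V(g)$name)
    g <- igraph::add_vertices(g, length(missing), name = missing)
  }
  idx <- match(igraph::V(g)$name, vert$id)
  igraph::V(g)$type <- vert$type[idx]
  igraph::V(g)$pathways <- vert$pathway[idx]
  if (igraph::ecount(g)) {
    g <- igraph::set_edge_attr(g, "pathways", value = igraph::E(g)$pathway)
    g <- igraph::delete_edge_attr(g, "pathway")
  }
  g <- igraph::set_graph_attr(g, "n_pathways",
                              length(unique(vapply(fragments, `[[`, "", "pathway_id"))))
  g <- igraph::set_graph_attr(g, "n_metabolites", sum(vert$type == "metabolite"))
  g <- igraph::set_graph_attr(g, "n_enzymes", sum(vert$type == "enzyme"))
  g <- igraph::set_graph_attr(g, "n_relations", igraph::ecount(g))
  class(g) <- c("metabolic_graph", class(g))
  g
}

#' @export
print.metabolic_graph <- function(x, ...) {
  cat("metabolic_graph: ", igraph::graph_attr(x, "n_pathways"), " pathways, ",
      igraph::graph_attr(x, "n_metabolites"), " metabolites, ",
      igraph::graph_attr(x, "n_enzymes"), " enzymes, ",
      igraph::graph_attr(x, "n_relations"), " relations\n", sep = "")
  invisible(x)
}

assert_metabolite <- function(g, id) {
  if (!id %in% igraph::V(g)$name)
    stop("node '", id, "' not in graph")
  if (igraph::V(g)$type[match(id, igraph::V(g)$name)] != "metabolite")
    stop("node '", id, "' is not a metabolite")
  invisible(id)
}

#' Shortest-path length between two metabolites
#'
#' Unweighted breadth-first distance in edge hops on the bipartite biograph;
#' metabolite--metabolite distances are even. Self-distance is 0;
#' unreachable pairs return `Inf` (distinguished from unknown ids, which
#' raise an error).
#'
#' @param g a `metabolic_graph`.
#' @param m1,m2 metabolite node ids.
#' @return Integer hop count, or `Inf` if unreachable.
#' @export
shortest_path_length <- function(g, m1, m2) {
  assert_metabolite(g, m1); assert_metabolite(g, m2)
  as.numeric(igraph::distances(g, v = m1, to = m2))
}

#' Extract the perturbed subnetwork spanned by correlated metabolite pairs
#'
#' For every pair of correlated metabolites, all nodes and edges on every
#' shortest path between them are collected; the union over pairs is the
#' perturbed network. Interior metabolite nodes that are not themselves in
#' the measured pair set are the "NMR-invisible" intermediates; enzymes on
#' the paths are the implicated enzymes. Pairs farther apart than `max_len`
#' (or unreachable) are skipped and reported. Metabolites absent from the
#' graph are reported and kept aside as external correlation-only nodes.
#'
#' @param g a `metabolic_graph`.
#' @param metabolite_pairs 2-column matrix/data frame of metabolite ids.
#' @param max_len maximum shortest-path length included (default `Inf`).
#' @param directions optional named character vector metabolite -> `up`/
#'   `down`/`unchanged`, attached to measured nodes.
#' @return A `perturbed_network` list: `graph` (igraph subgraph with vertex
#'   attribute `role` in measured/intermediate/enzyme and `direction`),
#'   `skipped_pairs`, `external_nodes`, `pairs_used`.
#' @export
extract_subnetwork <- function(g, metabolite_pairs, max_len = Inf,
                               directions = NULL) {
  metabolite_pairs <- as.matrix(metabolite_pairs)
  if (!nrow(metabolite_pairs)) stop("empty metabolite pair list")
  known <- igraph::V(g)$name[igraph::V(g)$type == "metabolite"]
  ids <- unique(as.vector(metabolite_pairs))
  external <- setdiff(ids, known)
  keep <- metabolite_pairs[, 1] %in% known & metabolite_pairs[, 2] %in% known
  pairs <- metabolite_pairs[keep, , drop = FALSE]
  vset <- character(); eset <- integer(); skipped <- list(); used <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    if (a == b) next
    d <- as.numeric(igraph::distances(g, v = a, to = b))
    if (!is.finite(d) || d > max_len) {
      skipped[[length(skipped) + 1L]] <- data.frame(m1 = a, m2 = b, distance = d)
      next
    }
    asp <- igraph::all_shortest_paths(g, from = a, to = b)$res
    for (p in asp) {
      nm <- igraph::as_ids(p)
      vset <- union(vset, nm)
      eset <- union(eset, igraph::get_edge_ids(g, rbind(nm[-length(nm)], nm[-1])))
    }
    used[[length(used) + 1L]] <- data.frame(m1 = a, m2 = b, distance = d)
  }
  measured <- unique(as.vector(pairs))
  sub <- igraph::subgraph_from_edges(g, eset, delete.vertices = TRUE)
  # a measured pair at distance 0 contributes no edges; make sure measured
  # nodes present in vset survive
  lost <- setdiff(vset, igraph::V(sub)$name)
  if (length(lost)) sub <- igraph::add_vertices(
    sub, length(lost), name = lost,
    type = igraph::V(g)$type[match(lost, igraph::V(g)$name)])
  role <- ifelse(igraph::V(sub)$type == "enzyme", "enzyme",
                 ifelse(igraph::V(sub)$name %in% measured,
                        "measured", "intermediate"))
  igraph::V(sub)$role <- role
  dir <- rep(NA_character_, igraph::vcount(sub))
  if (!is.null(directions)) {
    hit <- igraph::V(sub)$name %in% names(directions) & role == "measured"
    dir[hit] <- directions[igraph::V(sub)$name[hit]]
  }
  igraph::V(sub)$direction <- dir
  structure(list(graph = sub,
                 skipped_pairs = if (length(skipped)) do.call(rbind, skipped)
                                 else data.frame(),
                 external_nodes = external,
                 pairs_used = if (length(used)) do.call(rbind, used)
                              else data.frame()),
            class = "perturbed_network")
}

#' @export
print.perturbed_network <- function(x, ...) {
  r <- table(factor(igraph::V(x$graph)$role,
                    c("measured", "intermediate", "enzyme")))
  cat("perturbed_network: ", r[["measured"]], " measured metabolites, ",
      r[["intermediate"]], " intermediates, ", r[["enzyme"]], " enzymes, ",
      igraph::ecount(x$graph), " relations; ",
      nrow(x$skipped_pairs), " pairs skipped, ",
      length(x$external_nodes), " external nodes\n", sep = "")
  invisible(x)
}

#' Write a perturbed network as SIF plus a JSON manifest
#' @param net a `perturbed_network`.
#' @param prefix output path prefix; writes `<prefix>.sif` and
#'   `<prefix>.json`.
#' @return The two paths, invisibly.
#' @export
write_network <- function(net, prefix) {
  el <- igraph::as_edgelist(net$graph)
  sif <- file.path(paste0(prefix, ".sif"))
  utils::write.table(data.frame(el[, 1], "me", el[, 2]), sif, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  manifest <- list(
    nodes = data.frame(id = igraph::V(net$graph)$name,
                       role = igraph::V(net$graph)$role,
                       direction = igraph::V(net$graph)$direction),
    external_nodes = net$external_nodes,
    skipped_pairs = net$skipped_pairs)
  jsonlite::write_json(manifest, paste0(prefix, ".json"), dataframe = "columns",
                       digits = NA, na = "null")
  invisible(c(sif, paste0(prefix, ".json")))
}
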