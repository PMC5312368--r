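#' Metabolite-level projection of one pathway
#'
#' Pathway-impact centralities are defined over metabolites, so each
#' pathway's bipartite fragment is projected: two metabolites are adjacent
#' iff they share an enzyme (reaction) within that pathway.
#'
#' @param fragment a `pathway_fragment` from [parse_kgml()].
#' @return An undirected igraph over the pathway's metabolites.
#' @export
metabolite_projection <- function(fragment) {
  mets <- fragment$nodes$id[fragment$nodes$type == "metabolite"]
  if (!length(mets)) stop("pathway '", fragment$pathway_id, "' has no metabolites")
  el <- list()
  for (enz in unique(fragment$edges$enzyme)) {
    cpds <- sort(unique(fragment$edges$compound[fragment$edges$enzyme == enz]))
    if (length(cpds) > 1) {
      cmb <- utils::combn(cpds, 2)
      el[[length(el) + 1L]] <- t(cmb)
    }
  }
  g <- if (length(el)) {
    igraph::graph_from_edgelist(unique(do.call(rbind, el)), directed = FALSE)
  } else igraph::make_empty_graph(directed = FALSE)
  missing <- setdiff(mets, if (igraph::vcount(g)) igraph::V(g)$name else character())
  if (length(missing)) g <- igraph::add_vertices(g, length(missing), name = missing)
  g
}

#' Betweenness centrality of a pathway's metabolites
#'
#' Unordered-pair betweenness on the metabolite projection: the number of
#' shortest paths between every unordered pair of other metabolites passing
#' through the node, each pair weighted by the fraction of its shortest
#' paths using the node. Unreachable pairs contribute nothing. (The
#' unordered-pair convention halves the ordered-pair count; pathway impact
#' is invariant to this factor, which cancels in the ratio.)
#'
#' @param pathway_graph a metabolite projection ([metabolite_projection()]).
#' @return Named numeric vector of centralities.
#' @export
pathway_betweenness <- function(pathway_graph) {
  if (!igraph::vcount(pathway_graph)) stop("empty pathway graph")
  igraph::betweenness(pathway_graph, directed = FALSE)
}

#' Pathway impact of a hit set
#'
#' The summed betweenness centrality of the hit metabolites divided by the
#' summed centrality of all pathway metabolites. A pathway whose perturbed
#' metabolites are central hubs scores near 1; one hit only at leaves
#' scores 0. When every centrality is zero (e.g. a complete or edgeless
#' projection), the fraction of metabolites hit is used instead.
#'
#' @param fragment a `pathway_fragment`.
#' @param hit_metabolites character vector of perturbed metabolite ids;
#'   non-members are ignored with a warning.
#' @return Impact in `[0, 1]`.
#' @export
pathway_impact <- function(fragment, hit_metabolites) {
  g <- metabolite_projection(fragment)
  mets <- igraph::V(g)$name
  out <- setdiff(hit_metabolites, mets)
  if (length(out))
    warning("ignoring hits outside pathway '", fragment$pathway_id, "': ",
            paste(out, collapse = ", "))
  hits <- intersect(hit_metabolites, mets)
  if (!length(hits)) return(0)
  btw <- pathway_betweenness(g)
  denom <- sum(btw)
  if (denom == 0) return(length(hits) / length(mets))
  sum(btw[hits]) / denom
}

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability of observing at least `hits_in_pathway` of the
#' `total_hits` perturbed metabolites inside a pathway of `pathway_size`
#' metabolites, drawing without replacement from a universe of
#' `universe_size` metabolites.
#'
#' @param hits_in_pathway,pathway_size,total_hits,universe_size counts.
#' @return `P(X >= hits_in_pathway)`.
#' @export
enrichment_p <- function(hits_in_pathway, pathway_size, total_hits,
                         universe_size) {
  if (hits_in_pathway > min(pathway_size, total_hits) ||
      pathway_size > universe_size || total_hits > universe_size ||
      any(c(hits_in_pathway, pathway_size, total_hits, universe_size) < 0))
    stop("inconsistent enrichment counts")
  stats::phyper(hits_in_pathway - 1, pathway_size,
                universe_size - pathway_size, total_hits, lower.tail = FALSE)
}

#' Score every pathway against a hit set
#'
#' @param fragments list of `pathway_fragment`s.
#' @param hit_metabolites perturbed (measured-and-correlated) metabolites.
#' @param universe_size enrichment universe; default: all metabolites across
#'   the fragments (the merged biograph).
#' @param impact_threshold significance threshold on impact (default 0.3).
#' @param p_adjust optional `"BH"` to append Benjamini-Hochberg adjusted
#'   p-values (off by default; raw p is reported alongside impact).
#' @return A `pathway_impact_table` data frame: `pathway`, `title`,
#'   `impact`, `p`, `hits`, `size`, `significant`, sorted by impact
#'   descending then p ascending.
#' @export
pathway_impact_table <- function(fragments, hit_metabolites,
                                 universe_size = NULL,
                                 impact_threshold = 0.3, p_adjust = NULL) {
  if (inherits(fragments, "pathway_fragment")) fragments <- list(fragments)
  all_mets <- unique(unlist(lapply(fragments, function(f)
    f$nodes$id[f$nodes$type == "metabolite"])))
  if (is.null(universe_size)) universe_size <- length(all_mets)
  hit_metabolites <- unique(hit_metabolites)
  total_hits <- length(intersect(hit_metabolites, all_mets))
  rows <- lapply(fragments, function(f) {
    mets <- f$nodes$id[f$nodes$type == "metabolite"]
    hits <- intersect(hit_metabolites, mets)
    data.frame(pathway = f$pathway_id, title = f$title,
               impact = suppressWarnings(pathway_impact(f, hits)),
               p = enrichment_p(length(hits), length(mets), total_hits,
                                universe_size),
               hits = length(hits), size = length(mets),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (identical(p_adjust, "BH")) out$p_BH <- stats::p.adjust(out$p, "BH")
  out$significant <- out$impact >= impact_threshold
  out <- out[order(-out$impact, out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pathway_impact_table", "data.frame")
  out
}

#' Keep the significantly altered pathways
#'
#' @param rows a [pathway_impact_table()].
#' @param impact_threshold threshold on impact (default 0.3).
#' @return The rows with `impact >= impact_threshold`, sorted by impact
#'   descending then p ascending.
#' @export
significant_pathways <- function(rows, impact_threshold = 0.3) {
  out <- rows[rows$impact >= impact_threshold, , drop = FALSE]
  out[order(-out$impact, out$p), , drop = FALSE]
}
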