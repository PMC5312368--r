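#' Describe a toy pathway topology
#'
#' A pathway topology lists compound ids, enzyme ids, and compound--enzyme
#' incidences; [make_toy_kgml()] serialises each pathway to a KGML XML file
#' and [parse_kgml()] reads it back. Shared compound ids across pathways are
#' merged by [build_biograph()].
#'
#' @param id pathway identifier (e.g. `"toy00001"`).
#' @param title human-readable name.
#' @param compounds character vector of compound ids (KEGG-style `C.....`).
#' @param enzymes character vector of enzyme ids (EC numbers or gene ids).
#' @param incidence 2-column matrix/data frame of (compound, enzyme) pairs.
#' @return A `pathway_topology` list.
#' @export
pathway_topology <- function(id, title = id, compounds, enzymes, incidence) {
  incidence <- as.matrix(incidence)
  if (ncol(incidence) != 2) stop("incidence must have 2 columns (compound, enzyme)")
  if (!all(incidence[, 1] %in% compounds))
    stop("incidence references unknown compound: ",
         paste(setdiff(incidence[, 1], compounds), collapse = ", "))
  if (!all(incidence[, 2] %in% enzymes))
    stop("incidence references unknown enzyme: ",
         paste(setdiff(incidence[, 2], enzymes), collapse = ", "))
  if (length(intersect(compounds, enzymes)))
    stop("duplicate node id with conflicting type: ",
         paste(intersect(compounds, enzymes), collapse = ", "))
  structure(list(id = id, title = title,
                 compounds = unique(compounds), enzymes = unique(enzymes),
                 incidence = unique(incidence)),
            class = "pathway_topology")
}

#' A linear chain pathway M1-E1-M2-E2-...-Mk
#' @param id pathway id.
#' @param compounds compound ids, in chain order.
#' @param enzymes enzyme ids; `length(compounds) - 1` of them.
#' @return A [pathway_topology()].
#' @export
chain_pathway <- function(id, compounds, enzymes) {
  stopifnot(length(enzymes) == length(compounds) - 1)
  inc <- rbind(cbind(compounds[-length(compounds)], enzymes),
               cbind(compounds[-1], enzymes))
  pathway_topology(id, paste("chain", id), compounds, enzymes, inc)
}

#' Random toy pathway topologies
#'
#' Draws `n_pathways` connected toy pathways of 3--8 compounds each, joined
#' by enzymes into chains with random extra incidences; a configurable
#' fraction of compounds is shared across pathways (drawn from a common
#' pool), so the merged biograph is connected the way a genuine pathway
#' library is.
#'
#' @param n_pathways number of pathways.
#' @param seed RNG seed.
#' @param shared_pool size of the shared-compound pool (0 = fully disjoint).
#' @return A list of [pathway_topology()] objects.
#' @export
random_pathway_topology <- function(n_pathways, seed = 1, shared_pool = 5) {
  withr_seed(seed, {
    pool <- if (shared_pool > 0) sprintf("C9%04d", seq_len(shared_pool)) else character()
    lapply(seq_len(n_pathways), function(k) {
      n_c <- sample(3:8, 1)
      own <- sprintf("C%02d%03d", k, seq_len(n_c))
      if (length(pool) && stats::runif(1) < 0.6) {
        n_sh <- sample.int(min(2, length(pool)), 1)
        own[sample.int(n_c, n_sh)] <- sample(pool, n_sh)
        own <- unique(own)
      }
      enz <- sprintf("%d.%d.%d.%d", k %% 7 + 1, seq_along(own)[-1], k, seq_along(own)[-1])
      topo <- chain_pathway(sprintf("toy%05d", k), own, enz)
      # sprinkle extra incidences to create branches and cycles
      if (length(own) > 3) {
        extra <- cbind(sample(own, 2), sample(enz, 2, replace = TRUE))
        topo$incidence <- unique(rbind(topo$incidence, extra))
      }
      topo
    })
  })
}

#' Write toy pathway topologies as KGML XML files
#'
#' Emits one well-formed KGML file per pathway: `entry` elements typed
#' `compound`/`enzyme`, one `reaction` element per enzyme carrying its
#' incident compounds as substrates/products, and the enzyme entry's
#' `reaction` attribute linking the two. Shared compounds across files carry
#' identical `cpd:` identifiers.
#'
#' @param topologies list of [pathway_topology()] objects.
#' @param out_dir output directory (created if needed).
#' @return Character vector of the files written.
#' @export
make_toy_kgml <- function(topologies, out_dir) {
  if (inherits(topologies, "pathway_topology")) topologies <- list(topologies)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vapply(topologies, function(tp) {
    doc <- xml2::xml_new_root("pathway",
                              name = paste0("path:", tp$id), org = "toy",
                              number = sub("^\\D+", "", tp$id), title = tp$title)
    local_id <- stats::setNames(seq_along(c(tp$compounds, tp$enzymes)),
                                c(tp$compounds, tp$enzymes))
    for (cpd in tp$compounds)
      xml2::xml_add_child(doc, "entry", id = as.character(local_id[[cpd]]),
                          name = paste0("cpd:", cpd), type = "compound")
    for (i in seq_along(tp$enzymes)) {
      enz <- tp$enzymes[i]
      xml2::xml_add_child(doc, "entry", id = as.character(local_id[[enz]]),
                          name = paste0("ec:", enz), type = "enzyme",
                          reaction = sprintf("rn:R%s_%03d", tp$id, i))
    }
    for (i in seq_along(tp$enzymes)) {
      enz <- tp$enzymes[i]
      cpds <- tp$incidence[tp$incidence[, 2] == enz, 1]
      if (!length(cpds)) next
      rx <- xml2::xml_add_child(doc, "reaction",
                                id = as.character(1000L + i),
                                name = sprintf("rn:R%s_%03d", tp$id, i),
                                type = "reversible")
      half <- ceiling(length(cpds) / 2)
      for (cpd in cpds[seq_len(half)])
        xml2::xml_add_child(rx, "substrate", id = as.character(local_id[[cpd]]),
                            name = paste0("cpd:", cpd))
      for (cpd in cpds[-seq_len(half)])
        xml2::xml_add_child(rx, "product", id = as.character(local_id[[cpd]]),
                            name = paste0("cpd:", cpd))
    }
    path <- file.path(out_dir, paste0(tp$id, ".xml"))
    xml2::write_xml(doc, path)
    path
  }, character(1))
}

strip_kegg_prefix <- function(x) sub("^(cpd|ec|gene|rn|gl|path):", "", x)

#' Parse one KGML pathway file into a pathway fragment
#'
#' Reads `entry` elements typed `compound`, `enzyme` or `gene` (gene entries
#' are collapsed to their enzyme identity), derives compound--enzyme edges
#' from `reaction` elements (the enzyme whose `reaction` attribute names the
#' reaction is linked to every substrate and product) and from
#' compound-subtyped `relation` elements (the relation's compound is linked
#' to both enzyme endpoints).
#'
#' @param file path to a KGML XML file.
#' @return A `pathway_fragment`: `pathway_id`, `title`, `nodes` (data frame
#'   `id`, `type`, `label`), `edges` (data frame `compound`, `enzyme`).
#' @export
parse_kgml <- function(file) {
  doc <- tryCatch(xml2::read_xml(file),
                  error = function(e) stop("malformed KGML XML in '", file,
                                           "': ", conditionMessage(e)))
  pw <- strip_kegg_prefix(xml2::xml_attr(doc, "name"))
  entries <- xml2::xml_find_all(doc, ".//entry")
  if (!length(entries)) stop("no entry elements in '", file, "'")
  etype <- xml2::xml_attr(entries, "type")
  known <- etype %in% c("compound", "enzyme", "gene", "ortholog", "map", "group")
  if (any(!known))
    stop("unknown entry type '", etype[!known][1], "' in '", file, "'")
  keep <- etype %in% c("compound", "enzyme", "gene")
  entries <- entries[keep]; etype <- etype[keep]
  local <- xml2::xml_attr(entries, "id")
  gname <- strip_kegg_prefix(vapply(strsplit(xml2::xml_attr(entries, "name"),
                                             " "), `[`, "", 1))
  ntype <- ifelse(etype == "compound", "metabolite", "enzyme")
  nodes <- unique(data.frame(id = gname, type = ntype, label = gname,
                             stringsAsFactors = FALSE))
  if (anyDuplicated(nodes$id))
    stop("entry id '", nodes$id[duplicated(nodes$id)][1],
         "' used with conflicting types in '", file, "'")
  by_local <- stats::setNames(gname, local)
  type_by_local <- stats::setNames(ntype, local)
  rx_attr <- xml2::xml_attr(entries, "reaction")

  edges <- list()
  for (rx in xml2::xml_find_all(doc, ".//reaction")) {
    rname <- xml2::xml_attr(rx, "name")
    enzymes <- gname[!is.na(rx_attr) &
                       vapply(strsplit(ifelse(is.na(rx_attr), "", rx_attr), " "),
                              function(v) rname %in% v, TRUE)]
    parts <- xml2::xml_find_all(rx, "./substrate|./product")
    cpds <- strip_kegg_prefix(xml2::xml_attr(parts, "name"))
    cpds <- cpds[!is.na(cpds)]
    if (length(enzymes) && length(cpds))
      edges[[length(edges) + 1L]] <- expand.grid(compound = cpds,
                                                 enzyme = enzymes,
                                                 stringsAsFactors = FALSE)
  }
  for (rel in xml2::xml_find_all(doc, ".//relation")) {
    sub <- xml2::xml_find_first(rel, "./subtype[@name='compound']")
    if (inherits(sub, "xml_missing")) next
    cpd_local <- xml2::xml_attr(sub, "value")
    e1 <- xml2::xml_attr(rel, "entry1"); e2 <- xml2::xml_attr(rel, "entry2")
    cpd <- by_local[[cpd_local]]
    for (e in c(e1, e2)) {
      if (!is.null(type_by_local[[e]]) && type_by_local[[e]] == "enzyme" &&
          !is.null(cpd))
        edges[[length(edges) + 1L]] <- data.frame(compound = cpd,
                                                  enzyme = by_local[[e]],
                                                  stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) unique(do.call(rbind, edges))
           else data.frame(compound = character(), enzyme = character(),
                           stringsAsFactors = FALSE)
  structure(list(pathway_id = pw, title = xml2::xml_attr(doc, "title"),
                 nodes = nodes, edges = edges),
            class = "pathway_fragment")
}
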