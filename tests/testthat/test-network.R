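chain5 <- function(dir = withr::local_tempdir()) {
  topo <- chain_pathway("toy00001", c("C00001", "C00002", "C00003"),
                        c("1.1.1.1", "2.2.2.2"))
  parse_kgml(make_toy_kgml(topo, dir))
}

test_that("KGML parsing recovers toy topologies and survives round trips", {
  frag <- chain5()
  expect_equal(nrow(frag$nodes), 5L)
  expect_equal(nrow(frag$edges), 4L)
  expect_equal(sort(frag$nodes$type), c("enzyme", "enzyme", rep("metabolite", 3)))

  # isolated compound entry: node present, degree 0
  dir <- withr::local_tempdir()
  topo <- pathway_topology("toy00009", "iso", c("C00001", "C00008"),
                           "1.1.1.1", cbind("C00001", "1.1.1.1"))
  frag2 <- parse_kgml(make_toy_kgml(topo, dir))
  expect_true("C00008" %in% frag2$nodes$id)
  expect_false("C00008" %in% unlist(frag2$edges))

  # 70-pathway round trip preserves node and edge counts
  dir2 <- withr::local_tempdir()
  topos <- random_pathway_topology(70, seed = 5)
  frags <- lapply(make_toy_kgml(topos, dir2), parse_kgml)
  for (k in seq_along(topos)) {
    expect_equal(sort(frags[[k]]$nodes$id),
                 sort(c(topos[[k]]$compounds, topos[[k]]$enzymes)))
    expect_equal(nrow(frags[[k]]$edges), nrow(topos[[k]]$incidence))
  }
  expect_error(pathway_topology("p", "p", c("X1"), c("X1"),
                                cbind("X1", "X1")), "conflicting type")
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<pathway><entry id='1' name='z' type='mystery'/></pathway>", bad)
  expect_error(parse_kgml(bad), "unknown entry type")
})

test_that("biograph merging unifies shared compounds and stays bipartite", {
  dir <- withr::local_tempdir()
  t1 <- chain_pathway("toy00001", c("C00001", "C00002"), "1.1.1.1")
  t2 <- chain_pathway("toy00002", c("C00001", "C00003"), "2.2.2.2")
  g <- build_biograph(lapply(make_toy_kgml(list(t1, t2), dir), parse_kgml))
  expect_equal(sum(igraph::V(g)$name == "C00001"), 1L)
  v <- igraph::V(g)[igraph::V(g)$name == "C00001"]
  expect_equal(igraph::degree(g, v), c(C00001 = 2))
  expect_equal(igraph::graph_attr(g, "n_metabolites"), 3L)
  expect_match(igraph::V(g)$pathways[igraph::V(g)$name == "C00001"],
               "toy00001;toy00002")
  expect_true(igraph::is_bipartite(
    igraph::set_vertex_attr(g, "type", value = igraph::V(g)$type == "enzyme")))

  # disjoint fragments give one component each
  t3 <- chain_pathway("toy00003", c("C00007", "C00009"), "3.3.3.3")
  g2 <- build_biograph(lapply(make_toy_kgml(list(t1, t3),
                                            withr::local_tempdir()), parse_kgml))
  expect_equal(igraph::count_components(g2), 2L)

  # merged counts on a larger random build match the declared topology
  topos <- random_pathway_topology(12, seed = 6)
  g3 <- build_biograph(lapply(make_toy_kgml(topos, withr::local_tempdir()),
                              parse_kgml))
  all_nodes <- unique(unlist(lapply(topos, function(t) c(t$compounds, t$enzymes))))
  all_edges <- unique(do.call(rbind, lapply(topos, `[[`, "incidence")))
  expect_equal(igraph::vcount(g3), length(all_nodes))
  expect_equal(igraph::ecount(g3), nrow(all_edges))

  conflict <- pathway_topology("toy00004", "x", c("Z9"), c("1.9.9.9"),
                               cbind("Z9", "1.9.9.9"))
  conflict2 <- pathway_topology("toy00005", "x", c("C00050"), c("Z9"),
                                cbind("C00050", "Z9"))
  frags <- lapply(make_toy_kgml(list(conflict, conflict2),
                                withr::local_tempdir()), parse_kgml)
  expect_error(build_biograph(frags), "conflicting types")
})

test_that("shortest path lengths match the Floyd-Warshall oracle", {
  frag <- chain5()
  g <- build_biograph(frag)
  expect_equal(shortest_path_length(g, "C00001", "C00001"), 0)
  expect_equal(shortest_path_length(g, "C00001", "C00003"), 4)
  expect_error(shortest_path_length(g, "C00001", "C99999"), "not in graph")
  expect_error(shortest_path_length(g, "C00001", "1.1.1.1"), "not a metabolite")

  for (seed in 1:20) {
    topos <- random_pathway_topology(sample(2:5, 1), seed = seed,
                                     shared_pool = 3)
    gg <- build_biograph(lapply(make_toy_kgml(topos, withr::local_tempdir()),
                                parse_kgml))
    adj <- as.matrix(igraph::as_adjacency_matrix(gg))
    d_oracle <- oracle_floyd_warshall(adj)
    mets <- which(igraph::V(gg)$type == "metabolite")
    pick <- utils::head(mets, 4)
    for (i in pick) for (j in pick) {
      d <- shortest_path_length(gg, igraph::V(gg)$name[i], igraph::V(gg)$name[j])
      expect_equal(d, d_oracle[i, j])
    }
  }
})

test_that("subnetwork extraction collects all shortest paths and reports gaps", {
  # single pair at distance 2: one enzyme between them
  t1 <- chain_pathway("toy00001", c("C00001", "C00002"), "1.1.1.1")
  g1 <- build_biograph(parse_kgml(make_toy_kgml(t1, withr::local_tempdir())))
  net <- extract_subnetwork(g1, cbind("C00001", "C00002"),
                            directions = c(C00001 = "up"))
  expect_equal(igraph::vcount(net$graph), 3L)
  expect_equal(igraph::ecount(net$graph), 2L)
  expect_equal(sort(unique(igraph::V(net$graph)$role)), c("enzyme", "measured"))
  expect_equal(igraph::V(net$graph)$direction[
    igraph::V(net$graph)$name == "C00001"], "up")

  # two equal-length routes: both included, interior metabolites flagged
  t2 <- list(chain_pathway("toy00001", c("C00001", "C00002", "C00003"),
                           c("1.1.1.1", "2.2.2.2")),
             chain_pathway("toy00002", c("C00001", "C00004", "C00003"),
                           c("3.3.3.3", "4.4.4.4")))
  g2 <- build_biograph(lapply(make_toy_kgml(t2, withr::local_tempdir()),
                              parse_kgml))
  net2 <- extract_subnetwork(g2, cbind("C00001", "C00003"))
  expect_setequal(igraph::V(net2$graph)$name,
                  c("C00001", "C00002", "C00003", "C00004",
                    "1.1.1.1", "2.2.2.2", "3.3.3.3", "4.4.4.4"))
  interm <- igraph::V(net2$graph)$name[igraph::V(net2$graph)$role == "intermediate"]
  # oracle: interior metabolites of all shortest paths
  adj <- as.matrix(igraph::as_adjacency_matrix(g2))
  nm <- igraph::V(g2)$name
  paths <- oracle_all_shortest_paths(adj, match("C00001", nm), match("C00003", nm))
  interior <- setdiff(unique(nm[unlist(paths)]), c("C00001", "C00003"))
  interior_mets <- interior[interior %in% nm[igraph::V(g2)$type == "metabolite"]]
  expect_setequal(interm, interior_mets)

  # unreachable pair with finite max_len is excluded and reported
  t3 <- chain_pathway("toy00003", c("C00008", "C00009"), "5.5.5.5")
  g3 <- build_biograph(lapply(make_toy_kgml(list(t2[[1]], t3),
                                            withr::local_tempdir()), parse_kgml))
  net3 <- extract_subnetwork(g3, rbind(c("C00001", "C00003"),
                                       c("C00001", "C00008"),
                                       c("C00001", "C77777")))
  expect_equal(nrow(net3$skipped_pairs), 1L)
  expect_equal(net3$external_nodes, "C77777")
  expect_error(extract_subnetwork(g3, matrix(character(), 0, 2)), "empty")

  # monotone: adding a pair never removes nodes
  net_a <- extract_subnetwork(g2, cbind("C00001", "C00002"))
  net_b <- extract_subnetwork(g2, rbind(c("C00001", "C00002"),
                                        c("C00001", "C00003")))
  expect_true(all(igraph::V(net_a$graph)$name %in% igraph::V(net_b$graph)$name))
})
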