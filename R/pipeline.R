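#' Default pipeline configuration
#'
#' Returns the configuration list [run_pipeline()] consumes. Exactly one of
#' `spectra`/`assignment_map`/`kgml_dir` (real inputs) or `synthetic`
#' (a design block) must be provided; the default is a fully synthetic run
#' with a five-stage design.
#'
#' @param seed master seed; every random draw in the run derives from it.
#' @param outdir output directory (`NULL` = write nothing).
#' @return A `pipeline_config` list.
#' @export
default_config <- function(seed = 42, outdir = NULL) {
  structure(list(
    synthetic = list(
      n_metabolites = 15,
      group_sizes = c(CON = 32, GS = 11, LGD = 15, HGD = 15, GC = 11),
      n_differential = 3, effect_fold = 3,
      n_factors = 2, factor_sd = 0.55, residual_sd = 0.15,
      noise_sd = 0.005, jitter_sd = 0.002,
      resolution = 0.001,
      n_pathways = 6
    ),
    spectra = NULL, assignment_map = NULL, kgml_dir = NULL,
    exclusion = c(4.6, 5.7), norm_total = 100,
    align_max_shift = 3,
    srv = list(singlet_size = 0.01, landscape_threshold = 0.8),
    cv_folds = 7, n_ortho = 1,
    correlation_threshold = 0.9, impact_threshold = 0.3,
    alpha_strong = 0.01, alpha_weak = 0.05,
    control_group = "CON",
    seed = seed, outdir = outdir
  ), class = "pipeline_config")
}

validate_config <- function(config) {
  real <- !is.null(config$spectra)
  synth <- !is.null(config$synthetic)
  if (real == synth)
    stop("config must provide exactly one of real inputs (spectra/",
         "assignment_map/kgml_dir) or a synthetic design block")
  stopifnot(config$correlation_threshold > 0, config$correlation_threshold <= 1,
            config$impact_threshold >= 0, config$impact_threshold <= 1)
  invisible(config)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; fields override [default_config()].
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  usr <- yaml::read_yaml(path)
  cfg <- default_config()
  if (!is.null(usr$spectra)) cfg$synthetic <- NULL
  for (nm in names(usr)) {
    if (is.list(cfg[[nm]]) && is.list(usr[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], usr[[nm]])
    else cfg[[nm]] <- usr[[nm]]
  }
  if (!is.null(cfg$synthetic$group_sizes))
    cfg$synthetic$group_sizes <- unlist(cfg$synthetic$group_sizes)
  cfg
}

# Build the synthetic inputs a run needs: spectra, assignment map,
# pathway fragments, and the ground truth for reporting.
build_synthetic_inputs <- function(config) {
  sy <- config$synthetic
  seed <- config$seed
  lib <- make_metabolite_library(sy$n_metabolites, seed = seed)
  mets <- names(lib)
  eff <- NULL
  if (sy$n_differential > 0) {
    dm <- mets[seq_len(sy$n_differential)]
    grp <- names(sy$group_sizes)
    eff <- matrix(1, length(dm), length(grp), dimnames = list(dm, grp))
    # monotone progression: effect grows along the stage order
    stages <- setdiff(grp, config$control_group)
    for (s in seq_along(stages))
      eff[, stages[s]] <- sy$effect_fold^(s / length(stages))
  }
  n_fac <- sy$n_factors
  factors <- list()
  if (n_fac > 0) {
    pool <- setdiff(mets, rownames(eff))
    for (f in seq_len(n_fac)) {
      members <- pool[((f - 1) * 2 + 1):((f - 1) * 2 + 2)]
      factors[[f]] <- list(members = members, loadings = c(1, 1),
                           sd = sy$factor_sd)
    }
  }
  design <- simulation_design(group_sizes = sy$group_sizes,
                              effect_matrix = eff, latent_factors = factors,
                              base_log_sd = sy$residual_sd,
                              noise_sd = sy$noise_sd, jitter_sd = sy$jitter_sd,
                              seed = seed)
  truth <- simulate_concentrations(design, lib)
  m <- render_spectra(truth, lib, design, resolution = sy$resolution)
  # toy pathway library whose first pathway chains every assigned
  # metabolite, with the structured (differential and factor-mate)
  # metabolites in the chain interior where betweenness concentrates
  topo <- random_pathway_topology(sy$n_pathways, seed = seed + 1L)
  kegg_of <- vapply(lib, `[[`, "", "kegg_id")
  structured <- unique(c(rownames(eff), unlist(lapply(factors, `[[`, "members"))))
  plain <- setdiff(mets, structured)
  half <- ceiling(length(plain) / 2)
  ord <- c(plain[seq_len(half)], structured, plain[-seq_len(half)])
  topo[[1]] <- chain_pathway("toy00001", unname(kegg_of[ord]),
                             sprintf("9.9.9.%d", seq_len(length(ord) - 1)))
  list(spectra = m, map = truth$assignment_map, fragments_topo = topo,
       truth = truth, library = lib, kegg_of = kegg_of)
}

#' Run the full inference chain
#'
#' Preprocessing (region exclusion, segment alignment, total-sum
#' normalisation), SRV clustering, per-contrast PLS-DA/OPLS-DA with the
#' VIP/loading-correlation significance rule, OR-STOCSY correlation
#' extraction per stage-vs-control contrast, shortest-path network
#' reconstruction over the pathway library, and pathway-impact scoring.
#' Reruns with the same config and seed are bit-identical.
#'
#' @param config a `pipeline_config` ([default_config()] or
#'   [read_config()]).
#' @return A `pipeline_report` list with per-stage results and all
#'   parameters; written as JSON (plus per-stage TSVs) to `config$outdir`
#'   when set.
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  synth <- !is.null(config$synthetic)
  if (synth) {
    inputs <- build_synthetic_inputs(config)
    m <- inputs$spectra; map <- inputs$map
    fragments <- lapply(make_toy_kgml(inputs$fragments_topo,
                                      file.path(tempdir(), paste0("kgml", config$seed))),
                        parse_kgml)
    kegg_of <- inputs$kegg_of
  } else {
    m <- load_spectra(config$spectra)
    map <- read_assignment_map(config$assignment_map)
    fragments <- lapply(list.files(config$kgml_dir, "\\.xml$",
                                   full.names = TRUE), parse_kgml)
    kegg_of <- stats::setNames(names(map), names(map))
  }
  m <- exclude_region(m, config$exclusion[1], config$exclusion[2])
  # align locally within each assigned peak region (padded so the shifted
  # peak stays inside its segment), which removes per-peak jitter that a
  # whole-axis shift cannot
  pad <- (config$align_max_shift + 1) * bucket_step(m)
  segs <- lapply(map, function(w) c(min(w[, "lo"]) - pad, max(w[, "hi"]) + pad))
  segs <- Filter(function(b) b[1] >= min(m$ppm) && b[2] <= max(m$ppm), segs)
  m <- align_segments(m, segment_bounds = segs,
                      max_shift = config$align_max_shift)
  m <- normalize_total_sum(m, config$norm_total)

  params <- srv_params(singlet_size = config$srv$singlet_size,
                       resolution = bucket_step(m),
                       landscape_threshold = config$srv$landscape_threshold)
  sr <- srv(m, params)
  cm <- sr$cluster_matrix
  xs <- suppressWarnings(autoscale(cm))

  integrals <- relative_integrals(m, map)
  anova <- anova_tukey(integrals)

  biograph <- build_biograph(fragments)
  groups <- m$groups
  control <- config$control_group
  stages <- setdiff(unique(groups), control)
  contrasts <- list()
  for (st in stages) {
    sel <- groups %in% c(st, control)
    x_st <- suppressWarnings(autoscale(unclass(cm)[sel, , drop = FALSE]))
    g_st <- groups[sel]
    opls <- oplsda(x_st, g_st, n_ortho = config$n_ortho,
                   cv_folds = config$cv_folds, control = control,
                   seed = config$seed)
    rule <- significance_rule(opls$n1, opls$n2,
                              alpha_strong = config$alpha_strong,
                              alpha_weak = config$alpha_weak)
    diff_tab <- select_differential(opls, rule)
    xf <- orthogonal_filter(x_st, g_st, n_ortho = config$n_ortho,
                            control = control)
    C <- correlation_matrix(xf, variant = "OR-STOCSY",
                            filter_meta = attr(xf, "contrast"))
    edges <- threshold_edges(C, config$correlation_threshold)
    edges <- classify_edges(edges, sr$clusters, map)
    inter <- attr(edges, "inter_pairs")
    clu_met <- assign_clusters(sr$clusters, map)
    met_dir <- metabolite_directions(diff_tab, clu_met)
    contrast <- list(stage = st, opls = opls, rule = rule,
                     differential = diff_tab, edges = edges,
                     inter_pairs = inter)
    if (nrow(inter)) {
      pairs_kegg <- cbind(kegg_of[inter$metabolite_i],
                          kegg_of[inter$metabolite_j])
      dir_kegg <- stats::setNames(met_dir, kegg_of[names(met_dir)])
      net <- extract_subnetwork(biograph, pairs_kegg, directions = dir_kegg)
      hits <- igraph::V(net$graph)$name[igraph::V(net$graph)$role == "measured"]
      hits <- union(hits, intersect(as.vector(pairs_kegg),
                                    igraph::V(biograph)$name))
      contrast$network <- net
      contrast$pathway_table <- pathway_impact_table(
        fragments, hits,
        universe_size = igraph::graph_attr(biograph, "n_metabolites"),
        impact_threshold = config$impact_threshold)
    }
    contrasts[[st]] <- contrast
  }
  report <- structure(list(
    config = config,
    n_samples = nrow(m$intensities), n_buckets = ncol(m$intensities),
    n_clusters = nrow(sr$clusters),
    coverage = coverage_fraction(m, sr$clusters),
    clusters = sr$clusters, cluster_matrix = cm,
    integrals = integrals, anova = anova,
    biograph = biograph, contrasts = contrasts,
    truth = if (synth) inputs$truth else NULL
  ), class = "pipeline_report")
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

# Aggregate cluster-level labels to metabolite directions: a metabolite is
# up/down if any of its clusters is labeled so (very_significant preferred).
metabolite_directions <- function(diff_tab, cluster_metabolites) {
  out <- character()
  for (met in setdiff(unique(cluster_metabolites), "unassigned")) {
    rows <- diff_tab[cluster_metabolites == met, , drop = FALSE]
    sig <- rows[rows$label != "NS", , drop = FALSE]
    out[met] <- if (!nrow(sig)) "unchanged"
                else sig$direction[which.max(abs(sig$r))]
  }
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report: ", x$n_samples, " samples, ", x$n_buckets,
      " buckets, ", x$n_clusters, " SRV clusters (",
      sprintf("%.1f%%", 100 * x$coverage), " of signal)\n", sep = "")
  for (ct in x$contrasts) {
    nsig <- sum(ct$differential$label != "NS")
    cat("  ", ct$stage, " vs control: R2Y=", round(ct$opls$R2Y, 3),
        " Q2=", round(ct$opls$Q2, 3), "; ", nsig, " significant clusters, ",
        nrow(ct$edges), " edges (", nrow(ct$inter_pairs), " inter pairs)",
        if (!is.null(ct$pathway_table))
          paste0(", ", sum(ct$pathway_table$significant),
                 " significant pathways"),
        "\n", sep = "")
  }
  invisible(x)
}

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$clusters, file.path(outdir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$integrals, file.path(outdir, "integrals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- list(
    parameters = report$config[setdiff(names(report$config),
                                       c("outdir"))],
    n_samples = report$n_samples, n_buckets = report$n_buckets,
    n_clusters = report$n_clusters, coverage = report$coverage,
    contrasts = lapply(report$contrasts, function(ct) list(
      stage = ct$stage, R2Y = ct$opls$R2Y, Q2 = ct$opls$Q2,
      n_significant = sum(ct$differential$label != "NS"),
      n_edges = nrow(ct$edges), n_inter_pairs = nrow(ct$inter_pairs),
      significant_pathways = if (!is.null(ct$pathway_table))
        ct$pathway_table$pathway[ct$pathway_table$significant] else character()
    )))
  jsonlite::write_json(summ, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  for (ct in report$contrasts) {
    utils::write.table(ct$differential,
                       file.path(outdir, paste0("differential_", ct$stage, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ct$edges,
                       file.path(outdir, paste0("edges_", ct$stage, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(outdir)
}

#' Generate the small bundled fixture set used by the tests
#'
#' Deterministically regenerates a compact spectra TSV, assignment map and
#' toy KGML directory under `dir`.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @return Paths of the artifacts, invisibly.
#' @export
make_fixtures <- function(seed = 0, dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib <- make_metabolite_library(8, seed = seed)
  design <- simulation_design(
    group_sizes = c(CON = 8, GC = 6),
    effect_matrix = matrix(c(1, 2), 1, 2, dimnames = list("met01", c("CON", "GC"))),
    latent_factors = list(list(members = c("met03", "met04"),
                               loadings = c(1, 1), sd = 0.55),
                          list(members = c("met05", "met06"),
                               loadings = c(1, 1), sd = 0.55)),
    noise_sd = 0.002, jitter_sd = 0.001, seed = seed + 1L)
  truth <- simulate_concentrations(design, lib)
  m <- render_spectra(truth, lib, design, resolution = 0.01)
  write_spectra(m, file.path(dir, "spectra.tsv"))
  write_assignment_map(truth$assignment_map, file.path(dir, "assignment.json"))
  write_truth(truth, file.path(dir, "truth.json"))
  make_toy_kgml(random_pathway_topology(4, seed = seed + 2L),
                file.path(dir, "kgml"))
  invisible(dir)
}
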