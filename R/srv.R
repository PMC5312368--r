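#' SRV parameters
#'
#' Statistical recoupling of variables merges consecutive high-resolution
#' buckets into peak-coherent clusters. The minimum cluster length is the
#' number of buckets spanned by a resolved weak singlet:
#' `round(singlet_size / resolution)`.
#'
#' @param singlet_size peak base width of a resolved weak singlet (ppm);
#'   default 0.01.
#' @param resolution bucketing resolution (ppm); default 0.001.
#' @param landscape_threshold boundary correlation required inside a
#'   cluster, in (0, 1); default 0.8.
#' @param noise_region optional `c(lo, hi)` ppm interval of signal-free
#'   baseline; when given, the threshold is calibrated as the 95th
#'   percentile of boundary correlations inside it (and
#'   `landscape_threshold` is ignored).
#' @return An `srv_params` list.
#' @export
srv_params <- function(singlet_size = 0.01, resolution = 0.001,
                       landscape_threshold = 0.8, noise_region = NULL) {
  if (singlet_size < resolution) stop("singlet_size must be >= resolution")
  if (landscape_threshold <= 0 || landscape_threshold >= 1)
    stop("landscape_threshold must lie in (0, 1)")
  structure(list(singlet_size = singlet_size, resolution = resolution,
                 landscape_threshold = landscape_threshold,
                 noise_region = noise_region,
                 min_length = max(1L, as.integer(round(singlet_size / resolution)))),
            class = "srv_params")
}

#' Bucket-to-bucket coupling landscape
#'
#' Element `i` is the Pearson correlation, across samples, between bucket
#' `i` and bucket `i+1`. Buckets carrying the same metabolite resonance
#' co-vary almost perfectly; noise buckets do not, so runs of high boundary
#' correlation delineate peaks. Zero-variance buckets yield correlation 0 by
#' convention (they carry no statistical signal and must break runs).
#'
#' @param m a [spectrum_matrix] with >= 3 samples and >= 2 buckets.
#' @return Numeric vector of length `n_buckets - 1`.
#' @export
coupling_landscape <- function(m) {
  stopifnot(inherits(m, "spectrum_matrix"))
  x <- m$intensities
  if (nrow(x) < 3) stop("coupling landscape needs >= 3 samples")
  if (ncol(x) < 2) stop("coupling landscape needs >= 2 buckets")
  xc <- sweep(x, 2, colMeans(x))
  ss <- colSums(xc^2)
  num <- colSums(xc[, -ncol(x), drop = FALSE] * xc[, -1, drop = FALSE])
  den <- sqrt(ss[-length(ss)] * ss[-1])
  r <- ifelse(den > 0, num / den, 0)
  unname(r)
}

#' Build SRV clusters from a coupling landscape
#'
#' Clusters are maximal runs of consecutive buckets whose internal boundary
#' correlations all reach the threshold; runs shorter than the minimum
#' cluster length (`round(singlet_size / resolution)` buckets) are
#' discarded as unresolvable.
#'
#' @param landscape output of [coupling_landscape()] for the same axis.
#' @param params an [srv_params()].
#' @param ppm the bucket-centre axis the landscape was computed on.
#' @return A `cluster_set` data frame: `cluster`, `start`, `end` (bucket
#'   indices, inclusive), `ppm_hi`, `ppm_lo`, `n_buckets`, ordered by ppm
#'   (descending, i.e. by bucket index).
#' @export
build_clusters <- function(landscape, params = srv_params(), ppm = NULL) {
  stopifnot(inherits(params, "srv_params"))
  thr <- params$landscape_threshold
  if (!is.null(params$noise_region) && !is.null(ppm)) {
    sel <- which(ppm >= min(params$noise_region) & ppm <= max(params$noise_region))
    sel <- sel[sel <= length(landscape)]
    if (length(sel) >= 20)
      thr <- stats::quantile(landscape[sel], 0.95, names = FALSE)
  }
  above <- landscape >= thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (k in which(runs$values)) {
    # a run of `len` boundaries spans `len + 1` buckets
    b_start <- starts[k]; b_end <- ends[k] + 1L
    if (b_end - b_start + 1L >= params$min_length)
      out[[length(out) + 1L]] <- c(b_start, b_end)
  }
  if (!length(out)) {
    cs <- data.frame(cluster = integer(), start = integer(), end = integer(),
                     ppm_hi = numeric(), ppm_lo = numeric(),
                     n_buckets = integer())
  } else {
    mat <- do.call(rbind, out)
    cs <- data.frame(cluster = seq_len(nrow(mat)), start = mat[, 1],
                     end = mat[, 2],
                     ppm_hi = if (is.null(ppm)) NA_real_ else ppm[mat[, 1]],
                     ppm_lo = if (is.null(ppm)) NA_real_ else ppm[mat[, 2]],
                     n_buckets = mat[, 2] - mat[, 1] + 1L)
  }
  structure(cs, class = c("cluster_set", "data.frame"),
            params = params)
}

#' Run SRV on a spectrum matrix
#'
#' Convenience wrapper: coupling landscape, cluster construction on the
#' matrix's own axis, and the summarised cluster matrix.
#'
#' @param m a [spectrum_matrix].
#' @param params an [srv_params()]; its `resolution` defaults to the
#'   matrix's own bucket step when they differ.
#' @return A list `clusters` ([build_clusters()] output) and
#'   `cluster_matrix` ([summarize_clusters()] output).
#' @export
srv <- function(m, params = NULL) {
  step <- bucket_step(m)
  if (is.null(params)) params <- srv_params(resolution = step)
  clusters <- build_clusters(coupling_landscape(m), params, ppm = m$ppm)
  list(clusters = clusters, cluster_matrix = summarize_clusters(m, clusters))
}

#' Aggregate bucket intensities into SRV cluster intensities
#'
#' Cluster intensity is the sum of its member buckets' intensities per
#' sample (sum, not mean, to preserve integral semantics under total-sum
#' normalisation).
#'
#' @param m a [spectrum_matrix].
#' @param clusters a `cluster_set`.
#' @return A `cluster_matrix`: samples x clusters numeric matrix with
#'   attributes `clusters`, `groups`, `sample_ids`.
#' @export
summarize_clusters <- function(m, clusters) {
  stopifnot(inherits(m, "spectrum_matrix"), inherits(clusters, "cluster_set"))
  if (!nrow(clusters)) stop("empty cluster set: downstream analyses undefined")
  if (max(clusters$end) > ncol(m$intensities))
    stop("cluster set extends beyond the spectral axis")
  x <- vapply(seq_len(nrow(clusters)), function(k)
    rowSums(m$intensities[, clusters$start[k]:clusters$end[k], drop = FALSE]),
    numeric(nrow(m$intensities)))
  if (nrow(m$intensities) == 1L) x <- matrix(x, nrow = 1)
  dimnames(x) <- list(m$sample_ids,
                      sprintf("cl%03d_%.3f", clusters$cluster,
                              (clusters$ppm_hi + clusters$ppm_lo) / 2))
  structure(x, class = c("cluster_matrix", "matrix", "array"),
            clusters = clusters, groups = m$groups, sample_ids = m$sample_ids)
}

#' Fraction of total spectral signal captured by the clusters
#'
#' Total absolute intensity inside cluster buckets divided by total absolute
#' intensity, pooled over all samples.
#'
#' @param m a [spectrum_matrix].
#' @param clusters a `cluster_set`.
#' @return A fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(m, clusters) {
  stopifnot(inherits(m, "spectrum_matrix"))
  tot <- sum(abs(m$intensities))
  if (tot == 0) stop("all-zero matrix: coverage fraction undefined")
  if (!nrow(clusters)) return(0)
  sel <- unlist(mapply(seq.int, clusters$start, clusters$end, SIMPLIFY = FALSE))
  sum(abs(m$intensities[, unique(sel), drop = FALSE])) / tot
}

#' Map SRV clusters to assigned metabolites by ppm-window overlap
#'
#' A cluster is assigned to the metabolite whose windows overlap the
#' cluster's ppm range most (in ppm); ties break toward the metabolite with
#' the nearer window centre; clusters overlapping no window are
#' `"unassigned"`.
#'
#' @param clusters a `cluster_set` with ppm ranges.
#' @param map an `assignment_map`.
#' @return Character vector, one metabolite name (or `"unassigned"`) per
#'   cluster.
#' @export
assign_clusters <- function(clusters, map) {
  vapply(seq_len(nrow(clusters)), function(k) {
    lo <- clusters$ppm_lo[k]; hi <- clusters$ppm_hi[k]
    mid <- (lo + hi) / 2
    best <- "unassigned"; best_ov <- 0; best_d <- Inf
    for (met in names(map)) {
      w <- map[[met]]
      ov <- sum(pmax(0, pmin(hi, w[, "hi"]) - pmax(lo, w[, "lo"])))
      d <- min(abs(mid - (w[, "lo"] + w[, "hi"]) / 2))
      if (ov > best_ov || (ov > 0 && ov == best_ov && d < best_d)) {
        best <- met; best_ov <- ov; best_d <- d
      }
    }
    best
  }, character(1))
}
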