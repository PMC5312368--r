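#' Spectrum matrix container
#'
#' A `spectrum_matrix` holds bucketed 1D \eqn{^1}H NMR spectra: a samples x
#' ppm-bucket intensity matrix, sample identifiers, stage/group labels and a
#' strictly decreasing, uniformly spaced chemical-shift axis. All
#' preprocessing operations are pure (inputs never mutated) and record their
#' name and parameters in the `provenance` attribute.
#'
#' @param intensities numeric matrix, samples x buckets; all values finite.
#' @param ppm numeric vector of bucket-centre chemical shifts (ppm),
#'   strictly decreasing with uniform step.
#' @param sample_ids character vector of unique sample identifiers.
#' @param groups character or factor of per-sample group labels.
#' @param normalized logical; TRUE once total-sum normalisation was applied.
#' @param norm_total the row-sum constant when `normalized` is TRUE.
#' @param provenance list of operation records (internal bookkeeping).
#'
#' @return An object of class `spectrum_matrix`.
#' @export
spectrum_matrix <- function(intensities, ppm, sample_ids = rownames(intensities),
                            groups = NULL, normalized = FALSE,
                            norm_total = NA_real_, provenance = list()) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(intensities)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (length(sample_ids) != nrow(intensities))
    stop("sample_ids length does not match number of rows")
  if (length(ppm) != ncol(intensities))
    stop("ppm axis length (", length(ppm), ") does not match number of bucket columns (",
         ncol(intensities), ")")
  if (!all(is.finite(intensities)))
    stop("non-finite intensities in rows: ",
         paste(utils::head(sample_ids[!stats::complete.cases(intensities)], 5), collapse = ", "))
  validate_ppm_axis(ppm)
  if (is.null(groups)) groups <- rep("all", length(sample_ids))
  if (length(groups) != length(sample_ids))
    stop("groups length does not match number of samples")
  rownames(intensities) <- sample_ids
  colnames(intensities) <- format_ppm(ppm)
  structure(list(
    intensities = intensities,
    ppm = as.numeric(ppm),
    sample_ids = sample_ids,
    groups = as.character(groups),
    normalized = isTRUE(normalized),
    norm_total = norm_total,
    provenance = provenance
  ), class = "spectrum_matrix")
}

validate_ppm_axis <- function(ppm, tol = 1e-8) {
  if (length(ppm) < 2) return(invisible(ppm))
  d <- diff(ppm)
  if (any(d >= 0))
    stop("ppm axis must be strictly decreasing (violated at column ",
         which(d >= 0)[1] + 1L, ")")
  if (max(abs(d - d[1])) > tol * max(abs(d[1]), 1e-12))
    stop("ppm axis must be uniformly spaced (violated at column ",
         which.max(abs(d - d[1])) + 1L, ")")
  invisible(ppm)
}

format_ppm <- function(ppm) sprintf("%.4f", ppm)

#' @export
print.spectrum_matrix <- function(x, ...) {
  cat("spectrum_matrix: ", nrow(x$intensities), " samples x ",
      ncol(x$intensities), " buckets\n", sep = "")
  cat("  ppm range: ", max(x$ppm), " .. ", min(x$ppm),
      " (step ", signif(abs(diff(x$ppm[1:2])), 4), ")\n", sep = "")
  cat("  groups: ", paste(sprintf("%s(%d)", names(table(x$groups)),
                                  table(x$groups)), collapse = " "), "\n", sep = "")
  cat("  normalized: ", x$normalized,
      if (x$normalized) paste0(" (total ", x$norm_total, ")"), "\n", sep = "")
  if (length(x$provenance))
    cat("  provenance: ", paste(vapply(x$provenance, `[[`, "", "op"),
                                collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.spectrum_matrix <- function(x) dim(x$intensities)

add_provenance <- function(m, op, params) {
  m$provenance <- c(m$provenance, list(list(op = op, params = params)))
  m
}

bucket_step <- function(m) abs(m$ppm[1] - m$ppm[2])

#' Write bucketed spectra to TSV
#'
#' The dialect is: one header row (`sample`, `group`, then ppm-labelled bucket
#' columns in descending ppm), one row per sample.
#'
#' @param m a [spectrum_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(m, path) {
  stopifnot(inherits(m, "spectrum_matrix"))
  df <- data.frame(sample = m$sample_ids, group = m$groups,
                   m$intensities, check.names = FALSE)
  colnames(df) <- c("sample", "group", format_ppm(m$ppm))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read bucketed spectra from TSV
#'
#' Reads the dialect written by [write_spectra()]: columns `sample`, `group`,
#' then numeric ppm-labelled bucket columns on a strictly decreasing uniform
#' axis. Ragged rows, non-numeric intensities, duplicate sample ids and
#' non-uniform axes are rejected with the offending row or column named.
#'
#' @param path TSV file path.
#' @return A [spectrum_matrix].
#' @export
load_spectra <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 3 || !identical(colnames(df)[1:2], c("sample", "group")))
    stop("spectra TSV must start with columns 'sample' and 'group': ", path)
  ppm <- suppressWarnings(as.numeric(colnames(df)[-(1:2)]))
  if (anyNA(ppm))
    stop("non-numeric bucket column header: ",
         colnames(df)[-(1:2)][which(is.na(ppm))[1] + 0L])
  x <- suppressWarnings(vapply(df[-(1:2)], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) x <- matrix(x, nrow = 1, dimnames = list(NULL, colnames(df)[-(1:2)]))
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop("non-numeric intensity at sample '", df$sample[bad[1]],
         "', column '", colnames(x)[bad[2]], "'")
  }
  spectrum_matrix(x, ppm, sample_ids = df$sample, groups = df$group,
                  provenance = list(list(op = "load_spectra", params = list(path = path))))
}
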