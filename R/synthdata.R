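#' Generate a library of synthetic metabolite signatures
#'
#' Each signature is a small multiplet: 1--3 Lorentzian peaks clustered in a
#' narrow chemical-shift window, with fixed relative amplitudes and a common
#' halfwidth. Signatures stand in for assigned serum metabolites; the
#' optional `disjoint` mode forces every metabolite into its own
#' non-overlapping window, giving an unambiguous cluster-to-metabolite map.
#'
#' @param n_metabolites number of signatures (>= 2).
#' @param seed integer RNG seed; generation is fully deterministic.
#' @param ppm_range spectral window (default `c(0, 9)` ppm).
#' @param disjoint if TRUE, place each metabolite's peaks inside its own slot
#'   so no two metabolites' windows intersect.
#' @param max_peaks maximum peaks per multiplet (1--`max_peaks` drawn).
#' @param halfwidth Lorentzian half-width at half-maximum (ppm).
#' @param multiplet_span maximum spread of a multiplet's peak centres (ppm).
#' @return A list of `metabolite_signature` objects, each with fields
#'   `name`, `peaks` (matrix: `center`, `amplitude`, `halfwidth`), `kegg_id`
#'   and `window` (`c(lo, hi)` spanning its peaks plus a halfwidth margin).
#' @export
make_metabolite_library <- function(n_metabolites, seed = 1,
                                    ppm_range = c(0, 9), disjoint = TRUE,
                                    max_peaks = 3, halfwidth = 0.002,
                                    multiplet_span = 0.02) {
  if (n_metabolites < 2) stop("n_metabolites must be >= 2")
  lo <- min(ppm_range); hi <- max(ppm_range)
  margin <- multiplet_span + 10 * halfwidth
  if (disjoint) {
    slot <- (hi - lo - 2 * margin) / n_metabolites
    if (slot <= 2 * margin)
      stop("spectral window too small to place ", n_metabolites,
           " disjoint multiplets")
  }
  withr_seed(seed, {
    lib <- vector("list", n_metabolites)
    for (i in seq_len(n_metabolites)) {
      k <- sample.int(max_peaks, 1)
      if (disjoint) {
        slot_lo <- lo + margin + (i - 1) * slot
        base <- stats::runif(1, slot_lo + margin / 2, slot_lo + slot - margin / 2)
      } else {
        base <- stats::runif(1, lo + margin, hi - margin)
      }
      centers <- sort(base + stats::runif(k, 0, multiplet_span))
      amps <- stats::runif(k, 0.4, 1)
      amps <- amps / sum(amps)
      peaks <- cbind(center = centers, amplitude = amps,
                     halfwidth = rep(halfwidth, k))
      win <- c(min(centers) - 5 * halfwidth, max(centers) + 5 * halfwidth)
      lib[[i]] <- structure(list(
        name = sprintf("met%02d", i),
        peaks = peaks,
        kegg_id = sprintf("C%05d", i),
        window = win
      ), class = "metabolite_signature")
    }
  })
  names(lib) <- vapply(lib, `[[`, "", "name")
  if (any(vapply(lib, function(s) any(s$peaks[, "center"] <= lo |
                                        s$peaks[, "center"] >= hi), TRUE)))
    stop("peak placement escaped the spectral window")
  lib
}

# Evaluate an expression under a temporary RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Assignment map implied by a signature library
#' @param library output of [make_metabolite_library()].
#' @return An `assignment_map` with one window per metabolite.
#' @export
library_assignment_map <- function(library) {
  assignment_map(lapply(library, function(s) matrix(s$window, ncol = 2)))
}

#' Describe a simulation design
#'
#' @param group_sizes named integer vector, group -> n (each >= 3). Default
#'   mirrors a five-stage carcinogenesis design with unbalanced sizes
#'   32/11/15/15/11 (CON, GS, LGD, HGD, GC).
#' @param effect_matrix metabolite x group matrix of multiplicative shifts
#'   (> 0) applied to the log-mean concentration; 1 = unchanged. Metabolites
#'   absent from the matrix are unchanged everywhere.
#' @param latent_factors list of factors, each
#'   `list(members = c(...), loadings = c(...), sd = ...)`: the factor value
#'   (per sample, N(0, sd^2)) enters each member's log-concentration scaled
#'   by its loading, inducing inter-metabolite correlation.
#' @param base_log_mean,base_log_sd log-scale location/residual scale of
#'   concentrations.
#' @param noise_sd additive Gaussian noise on rendered intensities.
#' @param jitter_sd per-sample, per-metabolite peak-position jitter (ppm).
#' @param background broad unassigned baseline signals (the
#'   protein/lipoprotein envelope of real serum spectra): a list with
#'   `frac` (fraction of total spectral area carried by background; 0
#'   disables), `n` (number of broad humps), `halfwidth` (ppm) and `cv`
#'   (per-sample log-normal amplitude variation). A sizeable stable
#'   background keeps total-sum normalisation from inducing strong closure
#'   correlations, as in real spectra, and makes SRV signal coverage
#'   nontrivially below 100%.
#' @param seed integer RNG seed.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(group_sizes = c(CON = 32, GS = 11, LGD = 15,
                                              HGD = 15, GC = 11),
                              effect_matrix = NULL, latent_factors = list(),
                              base_log_mean = 0, base_log_sd = 0.2,
                              noise_sd = 0.01, jitter_sd = 0.002,
                              background = list(frac = 0.5, n = 30,
                                                halfwidth = 0.05, cv = 0.05),
                              seed = 1) {
  if (any(group_sizes < 3)) stop("every group size must be >= 3")
  if (!is.null(effect_matrix) && any(effect_matrix <= 0))
    stop("effect_matrix entries must be positive multiplicative shifts")
  for (f in latent_factors) {
    if (any(abs(f$loadings) > 1)) stop("factor loadings must lie in [-1, 1]")
    if (length(f$members) != length(f$loadings))
      stop("factor members/loadings length mismatch")
  }
  if (is.null(background) || is.null(background$frac)) background <- list(frac = 0)
  if (background$frac < 0 || background$frac >= 1)
    stop("background$frac must lie in [0, 1)")
  structure(list(group_sizes = group_sizes, effect_matrix = effect_matrix,
                 latent_factors = latent_factors,
                 base_log_mean = base_log_mean, base_log_sd = base_log_sd,
                 noise_sd = noise_sd, jitter_sd = jitter_sd,
                 background = background, seed = seed),
            class = "simulation_design")
}

#' Simulate ground-truth metabolite concentrations
#'
#' Concentrations are log-normal: each metabolite's log-concentration is
#' `base_log_mean + log(effect[met, group]) + sum_f loading * factor_f +
#' residual`, with factors shared across metabolites inducing known
#' correlations. `true_correlations` records the closed-form factor-model
#' correlation on the log scale,
#' `r = sum(l1*l2*sd_f^2) / sqrt(var1 * var2)`; at the small log-variances
#' used by default, Pearson correlation of the (exponentiated)
#' concentrations is numerically indistinguishable from it.
#'
#' @param design a [simulation_design()].
#' @param library a signature library; every metabolite named in the design
#'   must exist here.
#' @return A `synthetic_truth` list: `concentrations` (samples x
#'   metabolites), `groups`, `sample_ids`, `true_correlations` (data frame
#'   of correlated pairs with signed r), `true_differential` (metabolite x
#'   group character matrix, `up`/`down`/`unchanged`), `assignment_map`.
#' @export
simulate_concentrations <- function(design, library) {
  stopifnot(inherits(design, "simulation_design"))
  mets <- names(library)
  eff <- design$effect_matrix
  if (!is.null(eff) && !all(rownames(eff) %in% mets))
    stop("effect_matrix names metabolites absent from the library: ",
         paste(setdiff(rownames(eff), mets), collapse = ", "))
  for (f in design$latent_factors)
    if (!all(f$members %in% mets))
      stop("latent factor references unknown metabolite")
  groups <- rep(names(design$group_sizes), design$group_sizes)
  n <- length(groups)
  p <- length(mets)
  withr_seed(design$seed, {
    logc <- matrix(stats::rnorm(n * p, design$base_log_mean, design$base_log_sd),
                   n, p, dimnames = list(NULL, mets))
    for (f in design$latent_factors) {
      fval <- stats::rnorm(n, 0, f$sd)
      for (j in seq_along(f$members))
        logc[, f$members[j]] <- logc[, f$members[j]] + f$loadings[j] * fval
    }
    jitter <- matrix(stats::rnorm(n * p, 0, design$jitter_sd), n, p,
                     dimnames = list(NULL, mets))
  })
  if (!is.null(eff))
    for (met in rownames(eff))
      logc[, met] <- logc[, met] + log(eff[met, groups])
  conc <- exp(logc)
  sample_ids <- sprintf("%s_%02d", groups, unlist(lapply(design$group_sizes, seq_len)))
  rownames(conc) <- sample_ids

  # closed-form log-scale correlations between factor-mates
  covm <- diag(design$base_log_sd^2, p)
  dimnames(covm) <- list(mets, mets)
  for (f in design$latent_factors) {
    idx <- match(f$members, mets)
    covm[idx, idx] <- covm[idx, idx] + outer(f$loadings, f$loadings) * f$sd^2
  }
  sds <- sqrt(diag(covm))
  pairs <- which(upper.tri(covm) & covm != 0 &
                   !(row(covm) == col(covm)), arr.ind = TRUE)
  true_cor <- data.frame(
    met_i = mets[pairs[, 1]], met_j = mets[pairs[, 2]],
    r = covm[pairs] / (sds[pairs[, 1]] * sds[pairs[, 2]]),
    stringsAsFactors = FALSE)

  diffmat <- matrix("unchanged", p, length(design$group_sizes),
                    dimnames = list(mets, names(design$group_sizes)))
  if (!is.null(eff)) {
    diffmat[rownames(eff), colnames(eff)][eff > 1] <- "up"
    diffmat[rownames(eff), colnames(eff)][eff < 1] <- "down"
  }
  structure(list(concentrations = conc, groups = groups,
                 sample_ids = sample_ids, jitter = jitter,
                 true_correlations = true_cor, true_differential = diffmat,
                 assignment_map = library_assignment_map(library)),
            class = "synthetic_truth")
}

lorentzian <- function(x, center, halfwidth) {
  halfwidth^2 / ((x - center)^2 + halfwidth^2)
}

#' Render synthetic spectra from ground-truth concentrations
#'
#' Bucket intensity is the concentration-weighted sum of each metabolite's
#' Lorentzian multiplet (peak centres offset by the sample's jitter for that
#' metabolite) evaluated at bucket centres, plus additive Gaussian noise.
#' Linear in concentrations at zero noise.
#'
#' @param truth a `synthetic_truth` from [simulate_concentrations()].
#' @param library the signature library used to build `truth`.
#' @param design the [simulation_design()] (supplies `noise_sd` and seed).
#' @param ppm_range,resolution axis definition; default delta 9.00 -> 0.00 at
#'   0.001-ppm buckets. Tests may use coarser axes.
#' @return A [spectrum_matrix] with the truth's group labels.
#' @export
render_spectra <- function(truth, library, design,
                           ppm_range = c(0, 9), resolution = 0.001) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (resolution <= 0) stop("axis resolution must be > 0")
  ppm <- seq(max(ppm_range) - resolution / 2, min(ppm_range), by = -resolution)
  n <- nrow(truth$concentrations)
  x <- matrix(0, n, length(ppm))
  for (met in names(library)) {
    pk <- library[[met]]$peaks
    conc <- truth$concentrations[, met]
    jit <- truth$jitter[, met]
    # evaluate only near the multiplet: Lorentzian tails beyond ~200
    # halfwidths are negligible
    span <- range(pk[, "center"])
    pad <- 200 * max(pk[, "halfwidth"]) + max(abs(jit))
    sel <- which(ppm >= span[1] - pad & ppm <= span[2] + pad)
    if (!length(sel)) next
    for (i in seq_len(n)) {
      prof <- 0
      for (q in seq_len(nrow(pk)))
        prof <- prof + pk[q, "amplitude"] *
          lorentzian(ppm[sel], pk[q, "center"] + jit[i], pk[q, "halfwidth"])
      x[i, sel] <- x[i, sel] + conc[i] * prof
    }
  }
  bg <- design$background
  if (!is.null(bg) && bg$frac > 0) {
    # broad unassigned humps carrying `frac` of the total area; each hump's
    # amplitude fluctuates independently per sample (log-normal, small cv)
    assigned_area <- sum(x) / n
    lo <- min(ppm_range); hi <- max(ppm_range)
    withr_seed(design$seed + 2L, {
      centers <- stats::runif(bg$n, lo + 2 * bg$halfwidth, hi - 2 * bg$halfwidth)
      ampf <- matrix(exp(stats::rnorm(n * bg$n, 0, bg$cv)), n, bg$n)
    })
    hump_area <- pi * bg$halfwidth / resolution
    amp0 <- (bg$frac / (1 - bg$frac)) * assigned_area / (bg$n * hump_area)
    for (b in seq_len(bg$n)) {
      prof <- amp0 * lorentzian(ppm, centers[b], bg$halfwidth)
      x <- x + tcrossprod(ampf[, b], prof)
    }
  }
  if (design$noise_sd > 0) {
    withr_seed(design$seed + 1L, {
      x <- x + matrix(stats::rnorm(length(x), 0, design$noise_sd), nrow(x))
    })
  }
  spectrum_matrix(x, ppm, sample_ids = truth$sample_ids, groups = truth$groups,
                  provenance = list(list(op = "render_spectra",
                                         params = list(resolution = resolution,
                                                       noise_sd = design$noise_sd))))
}

#' Write ground truth as JSON
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- list(
    sample_ids = truth$sample_ids,
    groups = truth$groups,
    concentrations = as.data.frame(truth$concentrations),
    true_correlations = truth$true_correlations,
    true_differential = as.data.frame(truth$true_differential)
  )
  jsonlite::write_json(out, path, dataframe = "columns", digits = NA)
  invisible(path)
}
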