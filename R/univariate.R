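#' One-way ANOVA with Tukey's multiple comparisons, per metabolite
#'
#' For each metabolite column of a relative-integral table, fits a one-way
#' ANOVA of level on group and follows it with the Tukey--Kramer honest
#' significant difference test (studentized range, valid for unequal group
#' sizes).
#'
#' @param table a data frame with columns `sample`, `group` and one numeric
#'   column per metabolite, as returned by [relative_integrals()].
#' @return An `anova_result` list: `anova` (data frame `metabolite`, `F`,
#'   `p`), `tukey` (data frame `metabolite`, `comparison`, `diff`,
#'   `p_adj`), `group_means`, `group_se` (metabolite x group matrices).
#' @export
anova_tukey <- function(table) {
  mets <- setdiff(colnames(table), c("sample", "group"))
  g <- factor(table$group)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (any(table(g) < 2)) stop("every group needs >= 2 members; too small: ",
                              paste(names(which(table(g) < 2)), collapse = ", "))
  rows <- list(); tk <- list()
  gm <- matrix(NA_real_, length(mets), nlevels(g),
               dimnames = list(mets, levels(g)))
  gse <- gm
  for (met in mets) {
    v <- table[[met]]
    fit <- stats::aov(v ~ g)
    s <- summary(fit)[[1]]
    rows[[met]] <- data.frame(metabolite = met, F = s$`F value`[1],
                              p = s$`Pr(>F)`[1], stringsAsFactors = FALSE)
    th <- stats::TukeyHSD(fit)$g
    tk[[met]] <- data.frame(metabolite = met, comparison = rownames(th),
                            diff = th[, "diff"], p_adj = th[, "p adj"],
                            row.names = NULL, stringsAsFactors = FALSE)
    gm[met, ] <- tapply(v, g, mean)
    gse[met, ] <- tapply(v, g, function(z) stats::sd(z) / sqrt(length(z)))
  }
  structure(list(anova = do.call(rbind, c(rows, make.row.names = FALSE)),
                 tukey = do.call(rbind, c(tk, make.row.names = FALSE)),
                 group_means = gm, group_se = gse),
            class = "anova_result")
}

#' Row-standardised matrix for heatmap display
#'
#' Centres each metabolite row to mean zero and scales it to unit standard
#' deviation, the conventional display transform for metabolite-level
#' heatmaps.
#'
#' @param table as in [anova_tukey()], or a numeric matrix
#'   (metabolites x samples).
#' @return A metabolites x samples matrix of z-scores.
#' @export
zscore_matrix <- function(table) {
  if (is.data.frame(table)) {
    mets <- setdiff(colnames(table), c("sample", "group"))
    x <- t(as.matrix(table[mets]))
    colnames(x) <- table$sample
  } else x <- as.matrix(table)
  t(apply(x, 1, function(r) (r - mean(r)) / stats::sd(r)))
}
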