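#' Critical value of the Pearson correlation coefficient
#'
#' The two-tailed critical value at significance level `alpha` for
#' `df = n1 + n2 - 2` degrees of freedom,
#' \eqn{r^* = \sqrt{t^2 / (t^2 + df)}}, with `t` the Student-t quantile at
#' probability `1 - alpha/2`. This is the tabulated critical-r a loading
#' correlation must exceed to be declared significant; values are rounded to
#' 3 decimals for reporting (e.g. df = 41 gives 0.389 at alpha = 0.01 and
#' 0.301 at alpha = 0.05).
#'
#' @param n1,n2 the two group sizes; `df = n1 + n2 - 2` must be >= 3.
#' @param alpha two-tailed significance level in (0, 1).
#' @param digits rounding for the reported value (default 3; `NULL` for the
#'   exact value).
#' @return The critical correlation value.
#' @export
critical_r <- function(n1, n2, alpha = 0.05, digits = 3) {
  df <- n1 + n2 - 2
  if (df < 3) stop("df = n1 + n2 - 2 must be >= 3 (got ", df, ")")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  t <- stats::qt(1 - alpha / 2, df)
  r <- sqrt(t^2 / (t^2 + df))
  if (is.null(digits)) r else round(r, digits)
}

#' Significance rule for OPLS-DA loadings
#'
#' @param n1,n2 group sizes of the fitted contrast.
#' @param vip_threshold VIP gate (default 1).
#' @param alpha_strong,alpha_weak significance levels for the
#'   `very_significant` and `significant` critical-r values (defaults 0.01
#'   and 0.05).
#' @return A `significance_rule` list with the two critical values.
#' @export
significance_rule <- function(n1, n2, vip_threshold = 1,
                              alpha_strong = 0.01, alpha_weak = 0.05) {
  structure(list(n1 = n1, n2 = n2, df = n1 + n2 - 2,
                 vip_threshold = vip_threshold,
                 alpha_strong = alpha_strong, alpha_weak = alpha_weak,
                 r_strong = critical_r(n1, n2, alpha_strong, digits = NULL),
                 r_weak = critical_r(n1, n2, alpha_weak, digits = NULL)),
            class = "significance_rule")
}

#' Label variables of an OPLS-DA model by VIP and loading correlation
#'
#' A variable is `very_significant` when VIP exceeds the VIP gate and its
#' |loading correlation with tp1| exceeds the alpha = 0.01 critical value;
#' `significant` when VIP passes and |r| lies between the 0.05 and 0.01
#' critical values; otherwise `NS`. Direction is `up` when the variable
#' rises in the case class relative to the control, from the sign of the
#' loading correlation (tp1 is oriented toward the case class).
#'
#' @param model an [oplsda()] fit.
#' @param rule a [significance_rule()]; default derived from the model's own
#'   group sizes.
#' @return A data frame: `variable`, `VIP`, `r`, `label`, `direction`.
#' @export
select_differential <- function(model, rule = NULL) {
  stopifnot(inherits(model, "opls_model"))
  if (is.null(rule)) rule <- significance_rule(model$n1, model$n2)
  if (rule$n1 + rule$n2 != model$n1 + model$n2)
    stop("rule df inconsistent with the model's sample sizes")
  vip <- model$VIP; r <- model$loading_r
  lab <- ifelse(vip > rule$vip_threshold & abs(r) > rule$r_strong,
                "very_significant",
                ifelse(vip > rule$vip_threshold & abs(r) > rule$r_weak,
                       "significant", "NS"))
  data.frame(variable = if (is.null(names(r))) paste0("V", seq_along(r))
                        else names(r),
             VIP = vip, r = r, label = lab,
             direction = ifelse(lab == "NS", "unchanged",
                                ifelse(r > 0, "up", "down")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Linear discriminant boundary in a 2-D score space
#'
#' Fits an equal-covariance linear discriminant to a two-column score
#' matrix and reports the boundary line and the training misclassification
#' count. If the pooled covariance is computationally singular, a
#' pseudo-inverse is used and flagged.
#'
#' @param scores numeric matrix with 2 columns (e.g. tp1/to1 or t1/t2).
#' @param labels two-level class labels.
#' @return A list: `w` (normal vector), `b` (offset; boundary is
#'   `w . x = b`), `misclassified`, `n`, `pseudo_inverse` flag.
#' @export
linear_boundary <- function(scores, labels) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2) stop("scores must have exactly 2 columns")
  g <- factor(labels)
  if (nlevels(g) != 2) stop("exactly two classes required")
  mu <- rbind(colMeans(scores[g == levels(g)[1], , drop = FALSE]),
              colMeans(scores[g == levels(g)[2], , drop = FALSE]))
  pooled <- (stats::cov(scores[g == levels(g)[1], , drop = FALSE]) *
               (sum(g == levels(g)[1]) - 1) +
             stats::cov(scores[g == levels(g)[2], , drop = FALSE]) *
               (sum(g == levels(g)[2]) - 1)) / (nrow(scores) - 2)
  pseudo <- FALSE
  inv <- tryCatch(solve(pooled), error = function(e) {
    pseudo <<- TRUE
    MASS::ginv(pooled)
  })
  if (!pseudo && rcond(pooled) < 1e-12) { pseudo <- TRUE; inv <- MASS::ginv(pooled) }
  w <- drop(inv %*% (mu[2, ] - mu[1, ]))
  b <- sum(w * (mu[1, ] + mu[2, ]) / 2) +
    log(sum(g == levels(g)[2]) / sum(g == levels(g)[1]))
  pred <- ifelse(drop(scores %*% w) > b, levels(g)[2], levels(g)[1])
  list(w = w, b = b, misclassified = sum(pred != as.character(g)),
       n = nrow(scores), pseudo_inverse = pseudo)
}
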