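#' Autoscale a variable matrix
#'
#' Centres each column to mean 0 and scales it to unit standard deviation
#' (n-1 divisor). Zero-variance columns carry no discriminating information
#' and are dropped with a warning; their identities are recorded.
#'
#' @param x numeric matrix, samples x variables (>= 3 samples).
#' @return A `scaled_matrix`: the scaled matrix with attributes `center`,
#'   `scale`, `dropped` (names of removed columns), `NS`, `NV`.
#' @export
autoscale <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (nrow(x) < 3) stop("autoscaling needs >= 3 samples")
  ctr <- colMeans(x)
  sc <- apply(x, 2, stats::sd)
  zero <- sc <= .Machine$double.eps^0.5 * pmax(abs(ctr), 1)
  dropped <- colnames(x)[zero]
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-variance column(s): ",
            paste(utils::head(dropped, 5), collapse = ", "))
    x <- x[, !zero, drop = FALSE]; ctr <- ctr[!zero]; sc <- sc[!zero]
  }
  xs <- sweep(sweep(x, 2, ctr), 2, sc, "/")
  structure(xs, class = c("scaled_matrix", "matrix", "array"),
            center = ctr, scale = sc, dropped = dropped,
            NS = nrow(xs), NV = ncol(xs))
}

# Fix the sign of a component: largest-|loading| element made positive.
sign_fix <- function(p, t) {
  s <- sign(p[which.max(abs(p))])
  if (s < 0) list(p = -p, t = -t) else list(p = p, t = t)
}

# Deterministic 7-fold assignment: seeded shuffle then contiguous blocks.
cv_folds_assign <- function(n, k, seed) {
  ord <- withr_seed(seed, sample.int(n))
  folds <- rep(seq_len(k), length.out = n)
  folds[ord] <- sort(folds)
  folds
}

nipals_component <- function(x, tol = 1e-10, max_iter = 500) {
  t <- x[, which.max(apply(x, 2, stats::var))]
  for (i in seq_len(max_iter)) {
    p <- drop(crossprod(x, t)) / sum(t^2)
    p <- p / sqrt(sum(p^2))
    t_new <- drop(x %*% p)
    if (sqrt(sum((t_new - t)^2)) < tol * max(sqrt(sum(t_new^2)), 1e-300)) {
      t <- t_new; break
    }
    t <- t_new
  }
  sf <- sign_fix(p, t)
  list(t = sf$t, p = sf$p)
}

#' NIPALS principal component analysis
#'
#' Components are extracted sequentially by NIPALS with deterministic
#' initialisation (the column of greatest variance) and a sign convention
#' making each loading vector's largest-magnitude element positive. `R2X`
#' per component is the fraction of total sum of squares it explains;
#' `Q2cum` is estimated by row-wise k-fold cross-validation (held-out rows
#' projected onto training loadings).
#'
#' @param xs a [autoscale()]d (or at least centred) matrix.
#' @param n_comp number of components; must not exceed the matrix rank.
#' @param cv_folds folds for Q2 (default 7); `0` skips cross-validation.
#' @param seed seed for the fold shuffle.
#' @return A `pca_model`: `scores`, `loadings`, `R2X`, `R2Xcum`, `Q2cum`.
#' @export
pca_nipals <- function(xs, n_comp = 2, cv_folds = 7, seed = 1) {
  x <- unclass(as.matrix(xs))
  rk <- qr(x)$rank
  if (n_comp > rk) stop("n_comp (", n_comp, ") exceeds matrix rank (", rk, ")")
  ss_tot <- sum(x^2)
  scores <- matrix(0, nrow(x), n_comp)
  loadings <- matrix(0, ncol(x), n_comp,
                     dimnames = list(colnames(x), NULL))
  r2 <- numeric(n_comp)
  xr <- x
  for (a in seq_len(n_comp)) {
    cmp <- nipals_component(xr)
    scores[, a] <- cmp$t; loadings[, a] <- cmp$p
    xr <- xr - tcrossprod(cmp$t, cmp$p)
    r2[a] <- sum(tcrossprod(cmp$t, cmp$p)^2) / ss_tot
  }
  q2 <- NA_real_
  if (cv_folds > 1 && nrow(x) > cv_folds) {
    folds <- cv_folds_assign(nrow(x), cv_folds, seed)
    press <- 0
    for (f in seq_len(cv_folds)) {
      xtr <- x[folds != f, , drop = FALSE]
      xte <- x[folds == f, , drop = FALSE]
      ptr <- matrix(0, ncol(x), n_comp)
      xr <- xtr
      for (a in seq_len(n_comp)) {
        cmp <- nipals_component(xr)
        ptr[, a] <- cmp$p
        xr <- xr - tcrossprod(cmp$t, cmp$p)
      }
      press <- press + sum((xte - xte %*% ptr %*% t(ptr))^2)
    }
    q2 <- 1 - press / ss_tot
  }
  structure(list(scores = scores, loadings = loadings, R2X = r2,
                 R2Xcum = cumsum(r2), Q2cum = q2, n_comp = n_comp),
            class = "pca_model")
}

# Encode a two-level class vector as centred +/-1, control (reference
# level) coded -1.
encode_y <- function(groups, control = NULL) {
  g <- as.character(groups)
  lev <- unique(g)
  if (length(lev) != 2) stop("exactly two classes required, got: ",
                             paste(lev, collapse = ", "))
  if (is.null(control)) control <- lev[1]
  if (!control %in% lev) stop("control level '", control, "' not present")
  y <- ifelse(g == control, -1, 1)
  if (min(table(y)) < 3) stop("each class needs >= 3 members")
  list(y = y - mean(y), raw = y, control = control,
       case = setdiff(lev, control), n1 = sum(g != control),
       n2 = sum(g == control))
}

# One PLS1 predictive component on (x, y): w prop. x'y.
pls1_component <- function(x, y) {
  w <- drop(crossprod(x, y))
  w <- w / sqrt(sum(w^2))
  t <- drop(x %*% w)
  p <- drop(crossprod(x, t)) / sum(t^2)
  c_load <- sum(y * t) / sum(t^2)
  list(w = w, t = t, p = p, c = c_load)
}

pls1_fit <- function(x, y, n_comp) {
  n <- nrow(x); nv <- ncol(x)
  W <- matrix(0, nv, n_comp); P <- matrix(0, nv, n_comp)
  Tm <- matrix(0, n, n_comp); C <- numeric(n_comp)
  xr <- x; yr <- y
  for (a in seq_len(n_comp)) {
    cmp <- pls1_component(xr, yr)
    W[, a] <- cmp$w; Tm[, a] <- cmp$t; P[, a] <- cmp$p; C[a] <- cmp$c
    xr <- xr - tcrossprod(cmp$t, cmp$p)
    yr <- yr - cmp$c * cmp$t
  }
  # regression coefficients b: y_hat = x %*% b
  b <- W %*% solve(crossprod(P, W), C)
  list(W = W, P = P, T = Tm, C = C, b = b)
}

pls_vip <- function(W, Tm, C) {
  nv <- nrow(W)
  ssy <- C^2 * colSums(Tm^2)
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  sqrt(nv * drop(wn2 %*% ssy) / sum(ssy))
}

#' PLS discriminant analysis (two classes)
#'
#' PLS1 on the centred +/-1 class code. `R2Y` is the fitted fraction of
#' class-code variance; `Q2` comes from k-fold cross-validation
#' (contiguous-block folds after a seeded shuffle).
#'
#' @param xs autoscaled matrix.
#' @param groups two-level class labels.
#' @param n_comp number of PLS components.
#' @param cv_folds folds for Q2 (default 7).
#' @param control reference class coded -1 (default: first encountered).
#' @param seed fold-shuffle seed.
#' @return A `pls_model`: `scores`, `loadings`, `weights`, `coef`, `VIP`,
#'   `R2Y`, `Q2`, `y`, class metadata.
#' @export
plsda <- function(xs, groups, n_comp = 2, cv_folds = 7, control = NULL,
                  seed = 1) {
  x <- unclass(as.matrix(xs))
  enc <- encode_y(groups, control)
  y <- enc$y
  fit <- pls1_fit(x, y, n_comp)
  yhat <- drop(x %*% fit$b)
  r2y <- 1 - sum((y - yhat)^2) / sum(y^2)
  q2 <- pls_q2(x, y, n_comp, cv_folds, seed)
  structure(list(scores = fit$T, loadings = fit$P, weights = fit$W,
                 coef = fit$b, C = fit$C, VIP = pls_vip(fit$W, fit$T, fit$C),
                 R2Y = r2y, Q2 = q2, y = y, y_raw = enc$raw,
                 control = enc$control, case = enc$case,
                 n1 = enc$n1, n2 = enc$n2, n_comp = n_comp),
            class = "pls_model")
}

pls_q2 <- function(x, y, n_comp, cv_folds, seed) {
  if (cv_folds < 2 || nrow(x) <= cv_folds) return(NA_real_)
  folds <- cv_folds_assign(nrow(x), cv_folds, seed)
  press <- 0
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    fit <- pls1_fit(x[tr, , drop = FALSE], y[tr], n_comp)
    press <- press + sum((y[!tr] - drop(x[!tr, , drop = FALSE] %*% fit$b))^2)
  }
  1 - press / sum(y^2)
}

#' OPLS discriminant analysis (two classes)
#'
#' Splits X-variation into one predictive component (tp1, correlated with
#' the class code) and `n_ortho` orthogonal components (to, structured
#' variation uncorrelated with class). The orthogonal weight is the
#' X-loading minus its projection onto the predictive weight; after
#' deflating the orthogonal components, the predictive component is
#' refitted. VIP is computed on the predictive component only (so
#' `mean(VIP^2) = 1`); `loading_r` is the Pearson correlation of each
#' scaled variable with tp1 across samples.
#'
#' @inheritParams plsda
#' @param n_ortho number of orthogonal components (default 1; 0 reduces to
#'   plain PLS1).
#' @return An `opls_model`: `tp` (predictive scores), `p_pred`, `w_pred`,
#'   `to` (orthogonal scores, n x n_ortho), `p_ortho`, `w_ortho`, `VIP`,
#'   `loading_r`, `R2Y`, `Q2`, class metadata.
#' @export
oplsda <- function(xs, groups, n_ortho = 1, cv_folds = 7, control = NULL,
                   seed = 1) {
  x <- unclass(as.matrix(xs))
  enc <- encode_y(groups, control)
  y <- enc$y
  fit <- opls_core(x, y, n_ortho)
  yhat <- fit$c_pred * fit$tp
  r2y <- 1 - sum((y - yhat)^2) / sum(y^2)
  q2 <- opls_q2(x, y, n_ortho, cv_folds, seed)
  loading_r <- suppressWarnings(stats::cor(x, fit$tp))
  loading_r[is.na(loading_r)] <- 0
  structure(list(tp = fit$tp, p_pred = fit$p_pred, w_pred = fit$w_pred,
                 c_pred = fit$c_pred, to = fit$to, p_ortho = fit$p_ortho,
                 w_ortho = fit$w_ortho, x_filtered = fit$x_filtered,
                 VIP = drop(pls_vip(matrix(fit$w_pred), matrix(fit$tp),
                                    fit$c_pred)),
                 loading_r = drop(loading_r), R2Y = r2y, Q2 = q2,
                 y = y, y_raw = enc$raw, control = enc$control,
                 case = enc$case, n1 = enc$n1, n2 = enc$n2,
                 n_ortho = n_ortho),
            class = "opls_model")
}

# Orthogonal-projection extraction: for each orthogonal component,
# w_o = p - (w'p) w (the part of the X-loading unrelated to y), then
# deflate X by to po'.
opls_core <- function(x, y, n_ortho) {
  xr <- x
  n <- nrow(x); nv <- ncol(x)
  to <- matrix(0, n, max(n_ortho, 0))
  p_ortho <- matrix(0, nv, max(n_ortho, 0))
  w_ortho <- matrix(0, nv, max(n_ortho, 0))
  for (k in seq_len(n_ortho)) {
    w <- drop(crossprod(xr, y)); w <- w / sqrt(sum(w^2))
    t <- drop(xr %*% w)
    p <- drop(crossprod(xr, t)) / sum(t^2)
    wo <- p - drop(crossprod(w, p)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12)
      stop("deflation exhausted X before ", n_ortho,
           " orthogonal component(s) were extracted")
    wo <- wo / nwo
    t_o <- drop(xr %*% wo)
    p_o <- drop(crossprod(xr, t_o)) / sum(t_o^2)
    sf <- sign_fix(p_o, t_o)
    to[, k] <- sf$t; p_ortho[, k] <- sf$p
    w_ortho[, k] <- if (identical(sf$t, t_o)) wo else -wo
    xr <- xr - tcrossprod(sf$t, sf$p)
  }
  w <- drop(crossprod(xr, y)); w <- w / sqrt(sum(w^2))
  tp <- drop(xr %*% w)
  p_pred <- drop(crossprod(xr, tp)) / sum(tp^2)
  # predictive sign convention: tp positively correlated with y
  if (sum(tp * y) < 0) { w <- -w; tp <- -tp; p_pred <- -p_pred }
  c_pred <- sum(y * tp) / sum(tp^2)
  list(tp = tp, w_pred = w, p_pred = p_pred, c_pred = c_pred,
       to = to, p_ortho = p_ortho, w_ortho = w_ortho, x_filtered = xr)
}

opls_q2 <- function(x, y, n_ortho, cv_folds, seed) {
  if (cv_folds < 2 || nrow(x) <= cv_folds) return(NA_real_)
  folds <- cv_folds_assign(nrow(x), cv_folds, seed)
  press <- 0
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    fit <- opls_core(x[tr, , drop = FALSE], y[tr], n_ortho)
    xte <- x[!tr, , drop = FALSE]
    # remove the orthogonal components from the held-out rows, then predict
    for (k in seq_len(n_ortho)) {
      t_o <- drop(xte %*% fit$w_ortho[, k])
      xte <- xte - tcrossprod(t_o, fit$p_ortho[, k])
    }
    yhat <- fit$c_pred * drop(xte %*% fit$w_pred)
    press <- press + sum((y[!tr] - yhat)^2)
  }
  1 - press / sum(y^2)
}

#' Response-permutation validation of a PLS-DA model
#'
#' The class code is randomly permuted `n_perm` times while X is kept
#' intact; each permuted model's R2Y and Q2 are recorded against the
#' absolute correlation between the permuted and original code.
#' Regression lines of R2 and Q2 on |correlation| give the intercepts; the
#' model is judged valid when the original Q2 exceeds every permuted Q2 and
#' the Q2 regression line intersects the vertical axis below zero.
#'
#' @param xs autoscaled matrix.
#' @param groups two-level class labels.
#' @param n_comp PLS components per fit.
#' @param n_perm number of permutations (default 200).
#' @param cv_folds folds for each Q2.
#' @param control reference class.
#' @param seed RNG seed for the permutations.
#' @return A `permutation_report`: data frame `perms` (`cor_abs`, `R2`,
#'   `Q2`), `R2_intercept`, `Q2_intercept`, `R2_original`, `Q2_original`,
#'   `valid`.
#' @export
permutation_test <- function(xs, groups, n_comp = 2, n_perm = 200,
                             cv_folds = 7, control = NULL, seed = 1) {
  x <- unclass(as.matrix(xs))
  enc <- encode_y(groups, control)
  y <- enc$y
  fit0 <- pls1_fit(x, y, n_comp)
  r2_0 <- 1 - sum((y - drop(x %*% fit0$b))^2) / sum(y^2)
  q2_0 <- pls_q2(x, y, n_comp, cv_folds, seed)
  perms <- withr_seed(seed, replicate(n_perm, sample.int(length(y)),
                                      simplify = FALSE))
  rows <- lapply(seq_along(perms), function(i) {
    yp <- y[perms[[i]]]
    fit <- pls1_fit(x, yp, n_comp)
    c(cor_abs = abs(stats::cor(yp, y)),
      R2 = 1 - sum((yp - drop(x %*% fit$b))^2) / sum(yp^2),
      Q2 = pls_q2(x, yp, n_comp, cv_folds, seed + i))
  })
  df <- as.data.frame(do.call(rbind, rows))
  # intercepts of the lines through the permuted points and the original
  # model at |cor| = 1
  fit_line <- function(val, val0) {
    cf <- stats::coef(stats::lm(v ~ c, data.frame(
      v = c(df[[val]], val0), c = c(df$cor_abs, 1))))
    unname(cf[1])
  }
  r2_int <- fit_line("R2", r2_0)
  q2_int <- fit_line("Q2", q2_0)
  structure(list(perms = df, R2_intercept = r2_int, Q2_intercept = q2_int,
                 R2_original = r2_0, Q2_original = q2_0,
                 valid = q2_0 > max(df$Q2) && q2_int < 0,
                 n_perm = n_perm),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat("response permutation test: ", x$n_perm, " permutations\n",
      "  original R2Y = ", round(x$R2_original, 3),
      ", Q2 = ", round(x$Q2_original, 3), "\n",
      "  intercepts: R2 = ", round(x$R2_intercept, 3),
      ", Q2 = ", round(x$Q2_intercept, 3), "\n",
      "  verdict: ", if (x$valid) "valid" else "invalid", "\n", sep = "")
  invisible(x)
}
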