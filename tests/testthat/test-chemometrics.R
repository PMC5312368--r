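test_that("autoscaling centres, scales and drops degenerate columns", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 4, 9))
  expect_warning(xs <- autoscale(x), "zero-variance")
  expect_equal(attr(xs, "dropped"), "b")
  expect_equal(unname(xs[, "a"]), c(-1, 0, 1))
  expect_lt(max(abs(colMeans(xs))), 1e-9)
  expect_equal(unname(apply(xs, 2, sd)), c(1, 1), tolerance = 1e-9)
  # idempotent on already-scaled data
  expect_equal(unclass(autoscale(unclass(xs))), unclass(xs), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(autoscale(x[1:2, ]), "3 samples")
})

test_that("NIPALS PCA agrees with eigendecomposition and handles low rank", {
  # exact rank-1 matrix: first component explains everything
  u <- c(1, 2, -1, 0.5); v <- c(2, -1, 3)
  m1 <- pca_nipals(outer(u, v), n_comp = 1, cv_folds = 0)
  expect_equal(m1$R2X[1], 1, tolerance = 1e-9)

  set.seed(21)
  x <- scale(matrix(rnorm(6 * 4), 6, 4), scale = FALSE)
  fit <- pca_nipals(x, n_comp = 3, cv_folds = 0)
  ev <- eigen(crossprod(x))$vectors[, 1:3]
  for (a in 1:3) {
    cosang <- abs(sum(fit$loadings[, a] * ev[, a]))
    expect_lt(acos(min(cosang, 1)), 1e-6)
  }
  expect_true(all(diff(fit$R2X) < 1e-9))
  # orthonormal loadings, orthogonal scores
  expect_equal(crossprod(fit$loadings), diag(3), tolerance = 1e-8)
  off <- crossprod(fit$scores); diag(off) <- 0
  expect_lt(max(abs(off)), 1e-6)
  # sign equivariance
  fit2 <- pca_nipals(-x, n_comp = 2, cv_folds = 0)
  expect_equal(abs(fit2$scores[, 1]), abs(fit$scores[, 1]), tolerance = 1e-7)
  expect_error(pca_nipals(x, n_comp = 6), "rank")
})

test_that("PLS-DA separates a constructed separable case and RPT validates", {
  set.seed(22)
  n <- 40
  g <- rep(c("CON", "GC"), each = n / 2)
  x <- matrix(rnorm(n * 10), n)
  x[, 1] <- ifelse(g == "GC", 3, -3) + rnorm(n, 0, 0.3)
  xs <- autoscale(x)
  fit <- plsda(xs, g, n_comp = 2, cv_folds = 7, control = "CON")
  expect_gt(fit$Q2, 0.9)
  expect_equal(mean(fit$VIP^2), 1, tolerance = 1e-9)
  pt <- permutation_test(xs, g, n_comp = 2, n_perm = 50, seed = 1)
  expect_true(pt$valid)
  expect_gt(pt$Q2_original, 0.9)
  expect_lt(pt$Q2_intercept, 0)

  # y independent of X: invalid verdict
  set.seed(23)
  xnull <- autoscale(matrix(rnorm(43 * 20), 43))
  gnull <- rep(c("CON", "GS"), c(32, 11))
  ptn <- permutation_test(xnull, gnull, n_comp = 2, n_perm = 50, seed = 2)
  expect_false(ptn$valid)
  expect_error(plsda(xs, rep("A", n)), "two classes")
})

test_that("OPLS-DA splits predictive and orthogonal variation", {
  # n_ortho = 0 reduces to the first PLS component
  set.seed(24)
  g <- rep(c("CON", "GC"), each = 15)
  x <- matrix(rnorm(30 * 8), 30)
  x[, 1:2] <- x[, 1:2] + ifelse(g == "GC", 1.5, -1.5)
  xs <- autoscale(x)
  o0 <- oplsda(xs, g, n_ortho = 0, cv_folds = 0, control = "CON")
  p1 <- plsda(xs, g, n_comp = 1, cv_folds = 0, control = "CON")
  expect_equal(o0$tp, unname(p1$scores[, 1]), tolerance = 1e-9)

  # y-correlated + structured y-orthogonal component
  set.seed(25)
  n <- 60
  g2 <- rep(c("CON", "GC"), each = n / 2)
  yv <- ifelse(g2 == "GC", 1, -1)
  conf <- rnorm(n, 0, 2)             # strong structured confounder
  x2 <- cbind(sapply(1:4, function(i) yv + rnorm(n, 0, 0.5)),
              sapply(1:4, function(i) conf + rnorm(n, 0, 0.2)))
  xs2 <- autoscale(x2)
  fit <- oplsda(xs2, g2, n_ortho = 1, cv_folds = 0, control = "CON")
  expect_lt(abs(sum(fit$to[, 1] * fit$y)), 1e-8)
  expect_lt(abs(sum(fit$tp * fit$to[, 1])), 1e-8)
  pca1 <- pca_nipals(unclass(xs2), n_comp = 1, cv_folds = 0)$scores[, 1]
  expect_gt(abs(cor(fit$tp, fit$y)), abs(cor(pca1, fit$y)))

  # identical copies: VIP all exactly 1
  xc <- matrix(rnorm(30), 30, 1)[, rep(1, 5)] + ifelse(g == "GC", 1, -1)
  fit3 <- oplsda(autoscale(xc + matrix(rnorm(150, 0, 1e-8), 30)), g,
                 n_ortho = 0, cv_folds = 0, control = "CON")
  expect_equal(fit3$VIP, rep(1, 5), tolerance = 1e-3)
  expect_equal(mean(fit$VIP^2), 1, tolerance = 1e-9)
})

test_that("critical r reproduces tabulated values and is monotone", {
  expect_equal(critical_r(11, 32, 0.01), 0.389)
  expect_equal(critical_r(15, 32, 0.01), 0.372)
  expect_equal(critical_r(11, 32, 0.05), 0.301)
  expect_equal(critical_r(15, 32, 0.05), 0.288)
  # limit alpha -> 1 gives r -> 0
  expect_lt(critical_r(11, 32, 0.999, digits = NULL), 0.01)
  # strictly decreasing in df and alpha
  rs <- sapply(seq(10, 100, by = 10), function(n) critical_r(n, 32, 0.01,
                                                             digits = NULL))
  expect_true(all(diff(rs) < 0))
  ra <- sapply(c(0.001, 0.01, 0.05, 0.2), function(a) critical_r(11, 32, a,
                                                                 digits = NULL))
  expect_true(all(diff(ra) < 0))
  expect_error(critical_r(2, 2, 0.05), "df")
})

test_that("the significance rule gates on VIP and loading correlation", {
  fake <- structure(list(VIP = c(1.5, 0.9, 1.2, 1.1),
                         loading_r = c(0.40, 0.95, 0.32, -0.42),
                         n1 = 11, n2 = 32), class = "opls_model")
  tab <- select_differential(fake)
  expect_equal(tab$label,
               c("very_significant", "NS", "significant", "very_significant"))
  expect_equal(tab$direction, c("up", "unchanged", "up", "down"))
  expect_error(select_differential(fake, significance_rule(5, 5)),
               "inconsistent")
})

test_that("linear boundary classifies separated clouds and is label-symmetric", {
  set.seed(26)
  s <- rbind(matrix(rnorm(40, -4, 0.5), ncol = 2),
             matrix(rnorm(40, 4, 0.5), ncol = 2))
  lab <- rep(c("a", "b"), each = 20)
  fit <- linear_boundary(s, lab)
  expect_equal(fit$misclassified, 0L)
  # identical class distributions: near-chance error
  s2 <- matrix(rnorm(200), ncol = 2)
  fit2 <- linear_boundary(s2, rep(c("a", "b"), each = 50))
  expect_gt(fit2$misclassified, 25)
  # swapping labels keeps the same line (up to sign)
  fit3 <- linear_boundary(s, rev(lab))
  expect_equal(abs(fit3$w / sqrt(sum(fit3$w^2))),
               abs(fit$w / sqrt(sum(fit$w^2))), tolerance = 1e-9)
})

test_that("ANOVA with Tukey matches hand computation and bounds", {
  tab <- data.frame(sample = paste0("s", 1:6),
                    group = rep(c("g1", "g2"), each = 3),
                    met = c(1, 2, 3, 4, 5, 6))
  res <- anova_tukey(tab)
  expect_equal(res$anova$F, 13.5, tolerance = 1e-9)
  expect_equal(res$anova$p, pf(13.5, 1, 4, lower.tail = FALSE), tolerance = 1e-9)
  expect_equal(res$anova$p, 0.0213, tolerance = 1e-3)

  # Tukey-adjusted p never beats the unadjusted pooled-variance pairwise p
  set.seed(27)
  tab2 <- data.frame(sample = paste0("s", 1:30),
                     group = rep(c("a", "b", "c"), each = 10),
                     m1 = rnorm(30) + rep(c(0, 0.5, 1), each = 10))
  res2 <- anova_tukey(tab2)
  raw <- pairwise.t.test(tab2$m1, tab2$group, p.adjust.method = "none",
                         pool.sd = TRUE)$p.value
  raw_p <- c(raw[1, 1], raw[2, 1], raw[2, 2])
  expect_true(all(res2$tukey$p_adj >= raw_p - 1e-12))
  expect_error(anova_tukey(data.frame(sample = "s", group = "g", met = 1)),
               "2 groups")
})

test_that("z-score matrix standardises each metabolite row", {
  set.seed(28)
  tab <- data.frame(sample = paste0("s", 1:10), group = "g",
                    a = rnorm(10, 5, 2), b = runif(10, 0, 100))
  z <- zscore_matrix(tab)
  expect_equal(dim(z), c(2L, 10L))
  expect_lt(max(abs(rowMeans(z))), 1e-9)
  expect_equal(unname(apply(z, 1, sd)), c(1, 1), tolerance = 1e-9)
})
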