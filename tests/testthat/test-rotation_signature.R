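test_that("axis-aligned block loadings are a varimax fixed point", {
  set.seed(1)
  W <- rbind(cbind(matrix(rnorm(10, 2), 10, 1), 0),
             cbind(0, matrix(rnorm(10, 2), 10, 1)))
  rot <- varimax_rotate(W)
  # R is a signed permutation and the criterion is unchanged
  expect_true(all(colSums(abs(rot$R) > 1 - 1e-8) == 1))
  expect_true(all(rowSums(abs(rot$R) > 1 - 1e-8) == 1))
  expect_equal(rot$criterion, varimax_criterion(W), tolerance = 1e-10)
})

test_that("rotation is orthogonal and preserves the Gram spectrum", {
  set.seed(3)
  W <- matrix(rnorm(200), 50, 4)
  rot <- varimax_rotate(W)
  expect_lt(max(abs(crossprod(rot$R) - diag(4))), 1e-10)
  ev1 <- sort(eigen(crossprod(W), only.values = TRUE)$values)
  ev2 <- sort(eigen(crossprod(rot$W_rot), only.values = TRUE)$values)
  expect_equal(ev2, ev1, tolerance = 1e-9)
})

test_that("two-factor rotation matches a brute-force grid search", {
  set.seed(9)
  W <- matrix(rnorm(100), 50, 2)
  rot <- varimax_rotate(W)
  thetas <- seq(0, pi / 2, by = 0.001)
  crit <- vapply(thetas, function(th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    varimax_criterion(W %*% R)
  }, numeric(1))
  th_best <- thetas[which.max(crit)]
  expect_gte(rot$criterion, max(crit) - 1e-8)
  th_hat <- atan2(rot$R[2, 1], rot$R[1, 1]) %% (pi / 2)
  d <- abs(th_hat - th_best)
  expect_lt(min(d, pi / 2 - d), 0.01)
})

test_that("varimax never decreases the criterion over random starts", {
  for (s in 1:100) {
    set.seed(s)
    W <- matrix(rnorm(90), 30, 3)
    rot <- varimax_rotate(W)
    expect_gte(rot$criterion, varimax_criterion(W) - 1e-12)
  }
})

test_that("varimax agrees with an independent implementation", {
  set.seed(17)
  W <- matrix(rnorm(240), 60, 4)
  ours <- varimax_rotate(W)
  ref <- stats::varimax(W, normalize = FALSE, eps = 1e-10)
  expect_equal(varimax_criterion(ours$W_rot),
               varimax_criterion(ref$loadings[, ]), tolerance = 1e-6)
})

test_that("K = 1 returns the identity rotation", {
  W <- matrix(rnorm(10), 10, 1)
  rot <- varimax_rotate(W)
  expect_identical(rot$R, diag(1, 1))
  expect_identical(rot$W_rot, W)
  expect_error(varimax_rotate(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("reconstruction is invariant under the returned rotation", {
  g <- generate_multiomics(survival_config(n = 60, seed = 23))
  fit <- suppressWarnings(fit_factor_model(g$dataset, K = 2,
                                           max_iter = 200))
  rot <- varimax_rotate(fit$W$protein)
  Zr <- fit$Z %*% rot$R
  expect_equal(Zr %*% t(rot$W_rot), fit$Z %*% t(fit$W$protein),
               tolerance = 1e-9)
})

test_that("signature extraction recovers the planted gene set", {
  cfg <- small_config(n = 200, seed = 19)
  g <- generate_multiomics(cfg)
  fit <- suppressWarnings(fit_factor_model(g$dataset, K = 8,
                                           max_iter = 600))
  al <- align_factors(g$truth$Z_true, fit)
  khat <- al$factor_b[al$factor_a == cfg$prognostic_factor_index]
  sig <- extract_signature(fit, g$dataset, khat,
                           weight_thresh = 0.5, corr_thresh = 0.5)
  truth_genes <- g$truth$signature_genes
  precision <- mean(sig$genes %in% truth_genes)
  recall <- mean(truth_genes %in% sig$genes)
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.8)
  # stricter threshold without the correlation filter nests inside
  sig_strict <- extract_signature(fit, g$dataset, khat,
                                  weight_thresh = 0.74, corr_thresh = -1)
  sig_loose <- extract_signature(fit, g$dataset, khat,
                                 weight_thresh = 0.5, corr_thresh = -1)
  expect_true(all(sig_strict$genes %in% sig_loose$genes))
})

test_that("no-op thresholds return every nonzero-weight gene", {
  g <- generate_multiomics(survival_config(n = 80, seed = 3))
  fit <- suppressWarnings(fit_factor_model(g$dataset, K = 2,
                                           max_iter = 200))
  sig <- extract_signature(fit, g$dataset, 1, weight_thresh = 0,
                           corr_thresh = -1)
  W <- fit$W$protein
  rot <- varimax_rotate(W)
  j <- which.max(abs(rot$R[1, ]))
  nonzero <- sum(abs(rot$W_rot[, j]) > 0)
  expect_equal(length(sig$genes), nonzero)
})

test_that("signature sign convention puts the strongest feature negative", {
  g <- generate_multiomics(small_config(n = 120, seed = 7))
  fit <- suppressWarnings(fit_factor_model(g$dataset, K = 6,
                                           max_iter = 400))
  sig <- extract_signature(fit, g$dataset, 1, weight_thresh = 0.2,
                           corr_thresh = -1)
  expect_lt(sig$weights[which.max(abs(sig$weights))], 0)
  expect_lte(max(abs(sig$weights)), 1)
})

test_that("signatures are stable across regenerated cohorts", {
  sigs <- lapply(c(61, 62), function(s) {
    cfg <- small_config(n = 200, seed = s)
    g <- generate_multiomics(cfg)
    fit <- suppressWarnings(fit_factor_model(g$dataset, K = 6,
                                             max_iter = 500))
    al <- align_factors(g$truth$Z_true, fit)
    khat <- al$factor_b[al$factor_a == cfg$prognostic_factor_index]
    extract_signature(fit, g$dataset, khat, 0.5, 0.5)$genes
  })
  jaccard <- length(intersect(sigs[[1]], sigs[[2]])) /
    length(union(sigs[[1]], sigs[[2]]))
  expect_gte(jaccard, 0.8)
})

test_that("signature files round-trip", {
  sig <- structure(list(factor_index = 2L, genes = c("g1", "g2"),
                        weights = c(g1 = -1, g2 = -0.8),
                        thresholds = c(weight_thresh = 0.5,
                                       corr_thresh = 0.5),
                        provenance = list()), class = "signature_set")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, path)
  sig2 <- read_signature(path, factor_index = 2L)
  expect_equal(sig2$genes, sig$genes)
  expect_equal(sig2$weights, sig$weights)
})

test_that("top_fraction_features takes ceiling(fraction * D) by |weight|", {
  w <- c(a = 0.1, b = -0.9, c = 0.5, d = 0.2, e = 0.05,
         f = 0.3, g = 0.25, h = 0.15, i = 0.12, j = 0.11)
  expect_equal(top_fraction_features(w, 0.10), "b")
  expect_setequal(top_fraction_features(w, 1.0), names(w))
  w2 <- c(big = 0.9, neg = -0.95, small = 0.1,
          stats::setNames(rep(0, 20), paste0("z", sprintf("%02d", 1:20))))
  top <- top_fraction_features(w2, 0.10)  # ceiling(0.1 * 23) = 3
  expect_equal(length(top), 3L)
  expect_true(all(c("neg", "big", "small") %in% top))
  # lexicographic tie-break among equal |weights|
  w3 <- c(bb = 1, aa = 1, cc = 1)
  expect_equal(top_fraction_features(w3, 1 / 3), "aa")
  expect_error(top_fraction_features(numeric(0)), "non-empty")
})
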