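test_that("noiseless rank-K data is reconstructed essentially exactly", {
  cfg <- survival_config(n = 80, seed = 3, n_factors_true = 3,
                         prognostic_factor_index = 2)
  cfg$views <- lapply(cfg$views, function(v) { v$noise_sd <- 0; v })
  g <- generate_multiomics(cfg)
  fit <- fit_factor_model(g$dataset, K = 3, tol = 1e-12, max_iter = 2000)
  for (m in names(g$dataset$views)) {
    Y <- g$dataset$views[[m]]$X
    R <- Y - fit$Z %*% t(fit$W[[m]])
    expect_lt(sum(R^2) / sum(Y^2), 1e-6)
  }
  ve <- variance_explained(fit, g$dataset)
  expect_true(all(abs(ve$per_view_total - 1) < 1e-9))
})

test_that("planted factors are recovered when fitting with surplus factors", {
  cfg <- small_config(n = 150, seed = 7)
  g <- generate_multiomics(cfg)
  fit <- suppressWarnings(fit_factor_model(g$dataset, K = 8, tol = 1e-6,
                                           max_iter = 600))
  al <- align_factors(g$truth$Z_true, fit)
  expect_gte(mean(abs(al$corr)), 0.9)
})

test_that("penalized objective is non-increasing across sweeps", {
  g <- generate_multiomics(small_config(n = 80, seed = 15))
  fit <- suppressWarnings(fit_factor_model(g$dataset, K = 6, tol = 0,
                                           max_iter = 60))
  tr <- fit$fit_meta$objective_trace
  expect_true(all(diff(tr) <= 1e-8 * pmax(abs(tr[-length(tr)]), 1)))
})

test_that("reconstruction is invariant under the score/loading scale gauge", {
  g <- generate_multiomics(survival_config(n = 60, seed = 9))
  fit <- suppressWarnings(fit_factor_model(g$dataset, K = 3, max_iter = 200))
  recon <- fit$Z %*% t(fit$W$protein)
  s <- c(2, 0.5, 3)
  Z2 <- sweep(fit$Z, 2, s, "*")
  W2 <- sweep(fit$W$protein, 2, s, "/")
  expect_equal(Z2 %*% t(W2), recon, tolerance = 1e-12)
})

test_that("factor ordering is by non-increasing total variance explained", {
  g <- generate_multiomics(small_config(n = 100, seed = 4))
  fit <- suppressWarnings(fit_factor_model(g$dataset, K = 6, max_iter = 300))
  ve <- variance_explained(fit, g$dataset)
  Ds <- vapply(g$dataset$views, function(v) ncol(v$X), numeric(1))
  # weight per-view R2 by view SS share to get total explained SS share
  sstot <- vapply(names(g$dataset$views), function(m) {
    Y <- omicsfactor:::prepare_views_for_fit(g$dataset)[[m]]
    sum(Y[!is.na(Y)]^2)
  }, numeric(1))
  total <- as.vector(ve$R2 %*% sstot)
  expect_true(all(diff(total) <= 1e-6 * max(abs(total))))
})

test_that("single-view fit without ARD spans the principal-component subspace", {
  set.seed(11)
  n <- 60; D <- 40; K <- 3
  Y <- matrix(rnorm(n * D), n, D,
              dimnames = list(sprintf("S%02d", 1:n), sprintf("g%02d", 1:D)))
  ds <- multiomics_dataset(list(v = omics_view(Y, "v", "continuous")))
  fit <- suppressWarnings(fit_factor_model(ds, K = K, tol = 1e-13,
                                           max_iter = 5000, ard = FALSE))
  sv <- svd(Y, nu = K, nv = 0)
  Qa <- qr.Q(qr(fit$Z))
  Qb <- sv$u
  # principal angles between the two K-dim subspaces
  angles <- acos(pmin(1, svd(crossprod(Qa, Qb))$d))
  expect_lt(max(angles), 1e-6)
})

test_that("variance explained is zero for null scores and matches bookkeeping", {
  g <- generate_multiomics(survival_config(n = 80, seed = 5))
  fit <- suppressWarnings(fit_factor_model(g$dataset, K = 3, max_iter = 200))
  null_fit <- fit
  null_fit$Z <- fit$Z * 0
  ve0 <- variance_explained(null_fit, g$dataset)
  expect_true(all(abs(ve0$R2) < 1e-12))
  expect_true(all(abs(ve0$per_view_total) < 1e-12))

  cfg <- small_config(n = 200, seed = 19)
  g2 <- generate_multiomics(cfg)
  fit2 <- suppressWarnings(fit_factor_model(g2$dataset, K = 8,
                                            max_iter = 600))
  ve2 <- variance_explained(fit2, g2$dataset)
  expect_true(all(abs(ve2$per_view_total - g2$truth$signal_fraction) < 0.05))
  # grand total is the feature-count weighted mean
  Ds <- vapply(g2$dataset$views, function(v) ncol(v$X), numeric(1))
  expect_equal(ve2$grand_total,
               sum(ve2$per_view_total * Ds) / sum(Ds))
})

test_that("planted factor-view activity pattern is recovered", {
  cfg <- small_config(n = 200, seed = 19)
  g <- generate_multiomics(cfg)
  fit <- suppressWarnings(fit_factor_model(g$dataset, K = 8, max_iter = 600))
  ve <- variance_explained(fit, g$dataset)
  al <- align_factors(g$truth$Z_true, fit)
  act_hat <- (ve$R2[al$factor_b, , drop = FALSE] > 0.01) * 1L
  act_true <- g$truth$config$factor_view_activity
  # compare continuous views (the binary view carries little linear signal)
  expect_equal(unname(act_hat[, -1]), unname(act_true[, -1]))
})

test_that("factor matching is invariant to permutation and sign flips", {
  set.seed(2)
  Z <- matrix(rnorm(500), 100, 5,
              dimnames = list(sprintf("S%03d", 1:100), NULL))
  perm <- c(3, 1, 5, 2, 4)
  signs <- c(1, -1, 1, -1, -1)
  Z2 <- sweep(Z[, perm], 2, signs, "*")
  al <- align_factors(Z, Z2)
  expect_equal(order(perm)[al$factor_a], al$factor_b)
  expect_true(all(abs(abs(al$corr) - 1) < 1e-12))
})

test_that("matching of independent score matrices stays weak", {
  for (s in 1:10) {
    set.seed(100 + s)
    Za <- matrix(rnorm(500), 100, 5,
                 dimnames = list(sprintf("S%03d", 1:100), NULL))
    Zb <- matrix(rnorm(500), 100, 5,
                 dimnames = list(sprintf("S%03d", 1:100), NULL))
    al <- align_factors(Za, Zb)
    expect_lt(max(abs(al$corr)), 0.5)
  }
})

test_that("greedy matching with exchange refinement attains the optimum", {
  # brute-force oracle over all 5! assignments of a random |corr| matrix
  set.seed(6)
  Za <- matrix(rnorm(300), 60, 5,
               dimnames = list(sprintf("S%02d", 1:60), NULL))
  Zb <- matrix(rnorm(300), 60, 5,
               dimnames = list(sprintf("S%02d", 1:60), NULL))
  al <- align_factors(Za, Zb)
  A <- abs(cor(Za, Zb))
  perms <- permutations_5()
  best <- max(apply(perms, 1, function(p) sum(A[cbind(1:5, p)])))
  expect_equal(sum(abs(al$corr)), best, tolerance = 1e-12)
})

test_that("refits of regenerated cohorts recover the same planted factors", {
  fits <- lapply(c(51, 52), function(s) {
    g <- generate_multiomics(small_config(n = 120, seed = s))
    list(g = g,
         fit = suppressWarnings(fit_factor_model(g$dataset, K = 6,
                                                 max_iter = 400)))
  })
  for (f in fits) {
    al <- align_factors(f$g$truth$Z_true, f$fit)
    expect_gte(mean(abs(al$corr)), 0.9)
  }
})

test_that("model container round-trips bit-exactly", {
  g <- generate_multiomics(survival_config(n = 50, seed = 8))
  fit <- suppressWarnings(fit_factor_model(g$dataset, K = 2,
                                           max_iter = 100))
  path <- withr::local_tempfile(fileext = ".rds")
  write_factor_model(fit, path)
  fit2 <- read_factor_model(path)
  expect_identical(fit2, fit)
  # same config and seed -> byte-identical containers
  fitb <- suppressWarnings(fit_factor_model(g$dataset, K = 2,
                                            max_iter = 100))
  path2 <- withr::local_tempfile(fileext = ".rds")
  write_factor_model(fitb, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})

test_that("K larger than the sample count is rejected", {
  g <- generate_multiomics(survival_config(n = 30, seed = 1))
  expect_error(fit_factor_model(g$dataset, K = 31), "exceeds")
})
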