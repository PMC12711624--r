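test_that("Kaplan-Meier matches closed forms on toy data", {
  # all censored -> survival stays at 1
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))$all
  expect_true(all(km0$survival == 1))
  # all events at distinct times -> S = 2/3, 1/3, 0
  km1 <- km_estimate(c(1, 2, 3), c(1, 1, 1))$all
  expect_equal(km1$survival[km1$times %in% c(1, 2, 3)],
               c(2 / 3, 1 / 3, 0))
})

test_that("Kaplan-Meier matches a hand-computed product-limit table", {
  # classic mixed-censoring example: events at 1, 3, 5; censored at 2, 4
  time <- c(1, 2, 3, 4, 5)
  event <- c(1, 0, 1, 0, 1)
  km <- km_estimate(time, event)$all
  # hand table: S(1) = 4/5; S(3) = 4/5 * 2/3; S(5) = 4/5 * 2/3 * 0
  s_hand <- c(4 / 5, 4 / 5 * 2 / 3, 0)
  expect_equal(km$survival[km$times %in% c(1, 3, 5)], s_hand)
  # censored-only times do not change the curve value
  expect_equal(km$survival[km$times == 2], 4 / 5)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "positive")
})

test_that("log-rank is zero for identical groups and matches hand O/E/V", {
  time <- c(1, 2, 3, 4)
  event <- c(1, 0, 1, 1)
  lr0 <- logrank_test(rep(time, 2), rep(event, 2),
                      rep(c("a", "b"), each = 4))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  # 8-subject toy dataset, hand-tabulated O/E/V at each event time
  t8 <- c(1, 2, 3, 4, 5, 6, 7, 8)
  e8 <- c(1, 1, 0, 1, 1, 0, 1, 1)
  g8 <- c("A", "B", "A", "A", "B", "B", "A", "B")
  oev <- function(time, event, group) {
    O <- 0; E <- 0; V <- 0
    for (tt in sort(unique(time[event == 1]))) {
      at_risk <- time >= tt
      n <- sum(at_risk); n1 <- sum(at_risk & group == "A")
      d <- sum(time == tt & event == 1)
      d1 <- sum(time == tt & event == 1 & group == "A")
      O <- O + d1
      E <- E + d * n1 / n
      if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O - E)^2 / V
  }
  lr <- logrank_test(t8, e8, g8)
  expect_equal(lr$chi2, oev(t8, e8, g8), tolerance = 1e-9)
})

test_that("log-rank equals the Cox score test at beta = 0 on tie-free data", {
  set.seed(14)
  time <- rexp(40) + (1:40) * 1e-6  # break any accidental ties
  event <- rbinom(40, 1, 0.8)
  group <- rep(c(0, 1), 20)
  lr <- logrank_test(time, event, group)
  sc <- survival::coxph(survival::Surv(time, event) ~ group)$score
  expect_equal(lr$chi2, unname(sc), tolerance = 1e-8)
})

test_that("KM and log-rank are invariant to positive time rescaling", {
  set.seed(15)
  time <- rexp(30)
  event <- rbinom(30, 1, 0.7)
  group <- rep(c("x", "y"), 15)
  lr1 <- logrank_test(time, event, group)
  lr2 <- logrank_test(time * 7.3, event, group)
  expect_equal(lr2$chi2, lr1$chi2, tolerance = 1e-12)
  km1 <- km_estimate(time, event, group)$x
  km2 <- km_estimate(time * 7.3, event, group)$x
  expect_equal(km2$survival, km1$survival)
})

test_that("log-rank has the planted power on prognostic cohorts", {
  n_rep <- 200
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- survival_config(n = 300, seed = 3000 + r, hazard_coef = -0.7)
    g <- generate_multiomics(cfg)
    z <- g$truth$Z_true[, cfg$prognostic_factor_index]
    grp <- stratify_scores(z)
    cl <- g$dataset$clinical
    rej[r] <- logrank_test(cl$time, cl$event, grp)$p < 0.05
  }
  expect_gte(mean(rej), 0.8)
})

test_that("cox_fit matches a 1-D grid maximization of the partial likelihood", {
  # 6 subjects, 1 covariate, no ties
  time <- c(2, 4, 5, 7, 9, 12)
  event <- c(1, 1, 0, 1, 1, 0)
  x <- c(0.5, -1.2, 0.8, 1.5, -0.3, 0.1)
  fit <- cox_fit(time, event, data.frame(x = x))
  # independent oracle: grid over beta of the (tie-free) partial likelihood
  pl <- function(b) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    ll
  }
  grid <- seq(-3, 3, by = 1e-4)
  b_grid <- grid[which.max(vapply(grid, pl, numeric(1)))]
  expect_equal(unname(fit$coefficients), b_grid, tolerance = 1e-3)
  expect_equal(unname(fit$hr), exp(b_grid), tolerance = 1e-3)
  expect_true(fit$ci95[, "low"] < fit$hr & fit$hr < fit$ci95[, "high"])
})

test_that("cox_fit recovers a null effect and respects covariate scaling", {
  cfg <- survival_config(n = 2000, seed = 55, hazard_coef = 0)
  g <- generate_multiomics(cfg)
  z <- g$truth$Z_true[, cfg$prognostic_factor_index]
  cl <- g$dataset$clinical
  fit <- cox_fit(cl$time, cl$event, data.frame(z = z))
  expect_lt(abs(fit$coefficients[["z"]]), 0.08)
  # affine shift leaves beta unchanged; scaling scales beta inversely
  fit_s <- cox_fit(cl$time, cl$event, data.frame(z = 2 * z + 5))
  expect_equal(unname(fit_s$coefficients), unname(fit$coefficients) / 2,
               tolerance = 1e-6)
})

test_that("the planted hazard coefficient is recovered with correct coverage", {
  n_rep <- 200
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- survival_config(n = 500, seed = 7000 + r, hazard_coef = -0.7)
    g <- generate_multiomics(cfg)
    z <- g$truth$Z_true[, cfg$prognostic_factor_index]
    cl <- g$dataset$clinical
    fit <- cox_fit(cl$time, cl$event, data.frame(z = z))
    covered[r] <- fit$ci95[, "low"] <= exp(-0.7) &&
      exp(-0.7) <= fit$ci95[, "high"]
  }
  expect_gte(mean(covered), 0.93)
})

test_that("separation is flagged rather than fitted to infinity", {
  # perfectly separating covariate: all events in one group
  time <- c(1, 2, 3, 4, 10, 11, 12, 13)
  event <- c(1, 1, 1, 1, 0, 0, 0, 0)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  fit <- suppressWarnings(cox_fit(time, event, data.frame(x = x)))
  expect_false(fit$converged)
  # a ridge penalty rescues the fit to a finite estimate
  fit_r <- cox_fit(time, event, data.frame(x = x), ridge = 1)
  expect_true(abs(fit_r$coefficients[1]) < 15)
})

test_that("collinear covariates raise an error naming them", {
  set.seed(16)
  time <- rexp(30); event <- rbinom(30, 1, 0.8)
  x <- rnorm(30)
  expect_error(cox_fit(time, event, data.frame(a = x, b = 2 * x)),
               "collinear|singular")
  expect_error(cox_fit(time, event, data.frame(k = rep(1, 30))),
               "constant")
})

test_that("event-free strata can be dropped explicitly before fitting", {
  dat <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                    event = c(0, 0, 1, 1, 1, 0),
                    stage = c("I", "I", "II", "II", "III", "III"))
  expect_message(out <- drop_event_free_strata(dat, "stage"),
                 "strata: I")
  expect_equal(nrow(out), 4)
  expect_false("I" %in% out$stage)
})

test_that("KM curves export as step-function tables", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))$all
  path <- withr::local_tempfile(fileext = ".tsv")
  write_km_curve(km, path)
  tab <- read.delim(path)
  expect_equal(tab$survival, km$survival)
})
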