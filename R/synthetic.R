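#' Configuration for the synthetic multi-omics cohort generator
#'
#' Defines the planted structure of a simulated cohort: shared latent
#' factors, per-view loadings with a factor-by-view activity pattern, one
#' prognostic factor tied to ordinal stage and proportional-hazards
#' survival, blockwise view missingness, and a planted gene signature
#' shared by the mRNA and protein views.
#'
#' Defaults emulate the view-size asymmetry of deeply profiled tumour
#' cohorts at desk scale: a 300-gene binary mutation view and continuous
#' mRNA (1000), protein (800) and phospho (800) views over 5 true factors.
#' Signature genes load only on the prognostic factor, at magnitude
#' `signature_loading` in both mRNA and protein, so their cross-view
#' correlation exceeds 0.5 at the default noise levels.
#'
#' @param n_samples cohort size.
#' @param views list of view descriptors `list(name=, n_features=,
#'   modality=, noise_sd=)`; `noise_sd` is the residual SD added on top of
#'   the unit-scale factor signal (ignored for binary views, which are
#'   Bernoulli draws through a logistic link).
#' @param n_factors_true number of planted factors (K_true >= 1).
#' @param loading_sparsity fraction of loadings zeroed at random within
#'   each active (factor, view) pair.
#' @param factor_view_activity K_true x n_views 0/1 matrix saying which
#'   factor is active in which view; every view needs at least one active
#'   factor. `NULL` installs a structured default pattern.
#' @param prognostic_factor_index which factor drives stage and survival.
#' @param hazard_coef log-hazard per unit score on the prognostic factor
#'   (negative means high scores are protective).
#' @param censoring_rate target fraction of censored samples under
#'   independent uniform administrative censoring.
#' @param stage_link_strength coefficient of the (negated) prognostic score
#'   in the latent ordinal-stage model; higher stage at lower score.
#' @param missing_view_fraction fraction of samples with a given view
#'   fully masked (drawn independently per view).
#' @param n_signature_genes number of planted signature genes.
#' @param signature_loading planted |loading| of signature genes on the
#'   prognostic factor in the mRNA and protein views (stored with negative
#'   sign).
#' @param background_loading_max |loading| bound for non-signature genes
#'   on the prognostic factor within the signature views.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 200,
                              views = list(
                                list(name = "mutation", n_features = 300,
                                     modality = "binary", noise_sd = NA),
                                list(name = "mrna", n_features = 1000,
                                     modality = "continuous", noise_sd = 0.7),
                                list(name = "protein", n_features = 800,
                                     modality = "continuous", noise_sd = 0.5),
                                list(name = "phospho", n_features = 800,
                                     modality = "continuous", noise_sd = 1.0)),
                              n_factors_true = 5,
                              loading_sparsity = 0.3,
                              factor_view_activity = NULL,
                              prognostic_factor_index = 2,
                              hazard_coef = -0.7,
                              censoring_rate = 0.3,
                              stage_link_strength = 1,
                              missing_view_fraction = 0.1,
                              n_signature_genes = 30,
                              signature_loading = 0.8,
                              background_loading_max = 0.2,
                              seed = 1) {
  M <- length(views)
  if (n_factors_true < 1) stop("n_factors_true must be >= 1")
  fracs <- c(loading_sparsity, censoring_rate, missing_view_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (is.null(factor_view_activity))
    factor_view_activity <- default_activity(n_factors_true, M,
                                             prognostic_factor_index)
  if (!all(dim(factor_view_activity) == c(n_factors_true, M)))
    stop("factor_view_activity must be K_true x n_views")
  if (any(colSums(factor_view_activity) < 1))
    stop("every view needs at least one active factor")
  if (prognostic_factor_index > n_factors_true)
    stop("prognostic_factor_index exceeds n_factors_true")
  structure(list(n_samples = n_samples, views = views,
                 n_factors_true = n_factors_true,
                 loading_sparsity = loading_sparsity,
                 factor_view_activity = factor_view_activity,
                 prognostic_factor_index = prognostic_factor_index,
                 hazard_coef = hazard_coef, censoring_rate = censoring_rate,
                 stage_link_strength = stage_link_strength,
                 missing_view_fraction = missing_view_fraction,
                 n_signature_genes = n_signature_genes,
                 signature_loading = signature_loading,
                 background_loading_max = background_loading_max,
                 seed = seed),
            class = "simulation_config")
}

# Structured default activity pattern. Every factor gets a distinct set
# of active views (the global factor first, then the prognostic factor
# active everywhere but the first, mutation-like, view): distinct
# patterns are what make individual factors identifiable to an ARD
# model rather than only up to rotation.
default_activity <- function(K, M, pf) {
  masks <- expand.grid(rep(list(c(1L, 0L)), M))
  masks <- masks[rowSums(masks) > 0, , drop = FALSE]
  masks <- masks[order(-rowSums(masks)), , drop = FALSE]
  A <- matrix(0L, K, M)
  A[1, ] <- 1L
  pf_row <- c(0L, rep(1L, M - 1))
  used <- list(A[1, ], pf_row)
  if (K >= pf && pf != 1) A[pf, ] <- pf_row
  slot <- setdiff(seq_len(K), c(1, if (pf != 1) pf))
  mi <- 1
  for (k in slot) {
    repeat {
      cand <- as.integer(masks[((mi - 1) %% nrow(masks)) + 1, ])
      mi <- mi + 1
      if (!any(vapply(used, identical, logical(1), cand)) ||
          mi > 2 * nrow(masks)) break
    }
    A[k, ] <- cand
    used <- c(used, list(cand))
  }
  for (m in which(colSums(A) == 0)) A[1, m] <- 1L
  A
}

#' Generate a synthetic multi-omics cohort with planted structure
#'
#' Continuous views are `Y = Z W' + noise`, the binary view is Bernoulli
#' through a logistic link on `Z W'`, survival times are exponential with
#' log-hazard `hazard_coef * z` on the prognostic factor under independent
#' uniform administrative censoring, ordinal stage comes from a latent
#' threshold model on the negated prognostic score, and a configured
#' fraction of samples have each view fully masked.
#'
#' @param config a [simulation_config()].
#' @param truth optional `synthetic_truth` from a previous call with the
#'   same config; its planted loadings are reused so the new cohort is a
#'   held-out draw from the same population (fresh scores, noise,
#'   clinical and survival outcomes).
#' @return `list(dataset = multiomics_dataset, truth = synthetic_truth)`.
#'   The truth carries `Z_true`, per-view `W_true`, `signature_genes`,
#'   `hazard_coef`, `stage_labels`, realized per-view `signal_fraction`,
#'   uncensored survival times and the centred binary views.
#' @export
generate_multiomics <- function(config, truth = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_samples
  K <- config$n_factors_true
  M <- length(config$views)
  pf <- config$prognostic_factor_index
  sample_ids <- sprintf("S%04d", seq_len(n))

  feature_ids <- lapply(seq_len(M), function(m) {
    v <- config$views[[m]]
    if (v$name %in% c("mrna", "protein"))
      sprintf("g%04d", seq_len(v$n_features))
    else sprintf("%s_f%04d", v$name, seq_len(v$n_features))
  })

  if (is.null(truth)) {
    W_true <- vector("list", M)
    names(W_true) <- vapply(config$views, `[[`, character(1), "name")
    for (m in seq_len(M)) {
      v <- config$views[[m]]
      D <- v$n_features
      W <- matrix(stats::rnorm(D * K), D, K,
                  dimnames = list(feature_ids[[m]], NULL))
      keep <- matrix(stats::runif(D * K) > config$loading_sparsity, D, K)
      W <- W * keep
      W <- sweep(W, 2, config$factor_view_activity[, m], "*")
      if (v$name %in% c("mrna", "protein")) {
        sig <- seq_len(min(config$n_signature_genes, D))
        # signature genes: prognostic factor only, fixed negative loading
        W[sig, ] <- 0
        W[sig, pf] <- -config$signature_loading
        bg <- setdiff(seq_len(D), sig)
        W[bg, pf] <- stats::runif(length(bg),
                                  -config$background_loading_max,
                                  config$background_loading_max) *
          config$factor_view_activity[pf, m]
      }
      W_true[[m]] <- W
    }
    signature_genes <- sprintf("g%04d", seq_len(config$n_signature_genes))
  } else {
    W_true <- truth$W_true
    signature_genes <- truth$signature_genes
  }

  Z <- matrix(stats::rnorm(n * K), n, K, dimnames = list(sample_ids, NULL))

  views <- vector("list", M)
  signal_fraction <- stats::setNames(numeric(M), names(W_true))
  binary_centered <- list()
  masked_samples <- list()
  for (m in seq_len(M)) {
    v <- config$views[[m]]
    D <- v$n_features
    S <- Z %*% t(W_true[[m]])
    if (v$modality == "binary") {
      Y <- matrix(stats::rbinom(n * D, 1, stats::plogis(S)), n, D)
    } else {
      Y <- S + v$noise_sd * matrix(stats::rnorm(n * D), n, D)
    }
    dimnames(Y) <- list(sample_ids, feature_ids[[m]])
    n_mask <- floor(config$missing_view_fraction * n)
    drop <- if (n_mask > 0) sample(n, n_mask) else integer(0)
    if (length(drop)) Y[drop, ] <- NA
    masked_samples[[names(W_true)[m]]] <- sample_ids[drop]
    obs <- !is.na(Y)
    if (v$modality == "binary") {
      mu <- colMeans(Y, na.rm = TRUE)
      Yc <- sweep(Y, 2, mu, "-")
      keep_rows <- rowSums(obs) > 0
      B <- solve(crossprod(Z[keep_rows, , drop = FALSE]),
                 crossprod(Z[keep_rows, , drop = FALSE],
                           Yc[keep_rows, , drop = FALSE]))
      R <- Yc[keep_rows, , drop = FALSE] - Z[keep_rows, , drop = FALSE] %*% B
      signal_fraction[m] <- 1 - sum(R^2) / sum(Yc[keep_rows, ]^2)
      binary_centered[[names(W_true)[m]]] <- Yc
    } else {
      signal_fraction[m] <- sum(S[obs]^2) / sum(Y[obs]^2)
    }
    views[[m]] <- omics_view(Y, name = v$name, modality = v$modality)
  }
  names(views) <- names(W_true)

  zp <- Z[, pf]
  # survival: exponential with log-hazard hazard_coef * z, baseline median 3
  rate <- log(2) / 3 * exp(config$hazard_coef * zp)
  T_true <- stats::rexp(n, rate)
  if (config$censoring_rate > 0) {
    # administrative uniform censoring C ~ U(0, cmax); P(censored_i) =
    # min(T_i, c)/c, calibrated so the expected censored fraction matches
    target <- config$censoring_rate
    f <- function(cc) mean(pmin(T_true, cc) / cc) - target
    cmax <- tryCatch(stats::uniroot(f, c(1e-6, 1e6))$root,
                     error = function(e) stats::quantile(T_true, 1 - target))
    C <- stats::runif(n, 0, cmax)
  } else {
    C <- rep(Inf, n)
  }
  time <- pmin(T_true, C)
  event <- as.integer(T_true <= C)

  # ordinal stage: latent threshold model on the negated prognostic score
  latent_stage <- -config$stage_link_strength * zp + stats::rnorm(n)
  qs <- stats::quantile(latent_stage, c(0.25, 0.5, 0.75))
  stage <- 1L + findInterval(latent_stage, qs)

  # MSI tied (negatively) to factor 1, echoing a strong clinical correlate
  latent_msi <- -Z[, 1] + stats::rnorm(n, sd = 0.5)
  msi_cut <- stats::quantile(latent_msi, c(0.6, 0.85))
  msi <- c("MSS", "MSI-L", "MSI-H")[1L + findInterval(latent_msi, msi_cut)]

  clinical <- data.frame(
    sample_id = sample_ids,
    stage = stage,
    msi_status = msi,
    age = round(stats::rnorm(n, 65, 10)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    site = sample(c("colon", "rectum"), n, replace = TRUE, prob = c(0.7, 0.3)),
    metastasis = stats::rbinom(n, 1, 0.2),
    time = time,
    event = event,
    stringsAsFactors = FALSE)

  dataset <- multiomics_dataset(views, clinical)
  truth_out <- structure(list(
    Z_true = Z, W_true = W_true, signature_genes = signature_genes,
    hazard_coef = config$hazard_coef, stage_labels = stage,
    prognostic_factor_index = pf, signal_fraction = signal_fraction,
    uncensored_time = T_true, binary_centered = binary_centered,
    masked_samples = masked_samples, config = config),
    class = "synthetic_truth")
  list(dataset = dataset, truth = truth_out)
}

#' Generate synthetic single-cell counts with a planted signature
#'
#' Negative-binomial counts in which the planted signature genes have
#' their mean multiplied by `fold_change` in exactly one designated cell
#' type; a tissue label modulates that cell type's frequency (more common
#' in tumour than in normal tissue by `type_freq_ratio`).
#'
#' @param n_cells,n_genes dimensions of the counts matrix.
#' @param cell_types label set; `designated_type` must be among them.
#' @param designated_type the cell type over-expressing the signature.
#' @param signature_genes character vector of gene ids (must be a subset
#'   of the generated gene universe `g0001..`); must be non-empty.
#' @param fold_change multiplicative effect on signature-gene means in the
#'   designated type; 1 plants no effect.
#' @param type_freq_ratio tumour/normal frequency ratio of the designated
#'   type. Default 5.
#' @param base_type_freq frequency of the designated type in normal
#'   tissue. Default 0.05.
#' @param nb_size negative-binomial size (inverse dispersion). Default 2.
#' @param seed integer seed.
#' @return list with `counts` (cells x genes), `cell_type`, `tissue`,
#'   `base_means` (programmed per-gene means before the fold change),
#'   `designated_type` and `fold_change`.
#' @export
generate_sc_counts <- function(n_cells = 2000, n_genes = 400,
                               cell_types = c("epithelial", "tcell",
                                              "myofibroblast", "endothelial"),
                               designated_type = "myofibroblast",
                               signature_genes,
                               fold_change = 4,
                               type_freq_ratio = 5,
                               base_type_freq = 0.05,
                               nb_size = 2,
                               seed = 1) {
  if (missing(signature_genes) || !length(signature_genes))
    stop("signature_genes must be non-empty")
  if (fold_change <= 0) stop("fold_change must be > 0")
  if (!designated_type %in% cell_types)
    stop("designated_type must be one of cell_types")
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  miss <- setdiff(signature_genes, gene_ids)
  if (length(miss))
    stop("signature genes outside the gene universe: ",
         paste(utils::head(miss, 5), collapse = ", "))
  set.seed(seed)
  tissue <- sample(c("tumour", "normal"), n_cells, replace = TRUE)
  p_other <- function(p_des) {
    p <- rep((1 - p_des) / (length(cell_types) - 1), length(cell_types))
    p[cell_types == designated_type] <- p_des
    p
  }
  p_norm <- p_other(base_type_freq)
  p_tum <- p_other(min(base_type_freq * type_freq_ratio, 0.9))
  cell_type <- character(n_cells)
  is_tum <- tissue == "tumour"
  cell_type[is_tum] <- sample(cell_types, sum(is_tum), replace = TRUE,
                              prob = p_tum)
  cell_type[!is_tum] <- sample(cell_types, sum(!is_tum), replace = TRUE,
                               prob = p_norm)
  base_means <- stats::setNames(stats::rlnorm(n_genes, log(0.5), 1), gene_ids)
  mu <- matrix(rep(base_means, each = n_cells), n_cells, n_genes,
               dimnames = list(sprintf("cell%05d", seq_len(n_cells)),
                               gene_ids))
  des <- cell_type == designated_type
  mu[des, signature_genes] <- mu[des, signature_genes] * fold_change
  counts <- matrix(stats::rnbinom(n_cells * n_genes, mu = mu, size = nb_size),
                   n_cells, n_genes, dimnames = dimnames(mu))
  list(counts = counts, cell_type = cell_type, tissue = tissue,
       base_means = base_means, designated_type = designated_type,
       fold_change = fold_change)
}
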