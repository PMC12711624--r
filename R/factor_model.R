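#' Fit a multi-view Gaussian latent factor model
#'
#' Alternating least-squares estimation of `Y_m ~ Z W_m'` across views
#' sharing a sample universe, with per-view residual variance `tau_m` and
#' optional per-(factor, view) automatic relevance determination (ARD)
#' ridge precisions that shrink loadings of factor-view pairs carrying no
#' signal. Missing entries (including fully masked views) are excluded
#' from every sufficient statistic. Each view carries its own Gaussian
#' likelihood and residual variance, and the ARD prior acts at full
#' per-feature scale within each view: distinct factor-by-view activity
#' patterns are what make individual factors identifiable rather than
#' recovered only up to rotation.
#'
#' Factor scores carry a standard-normal prior, which fixes the
#' scale gauge between scores and loadings so the ARD precisions remain
#' informative. Each coordinate update (loadings, residual variances, ARD
#' precisions, scores) exactly minimises one penalised objective, so the
#' objective is non-increasing across sweeps; the trace is returned in
#' `fit_meta`.
#' Initialisation is an SVD of the row-concatenated, per-view
#' 1/sqrt(D_m)-scaled data with missing entries zero-imputed (used for
#' initialisation only), making the fit deterministic given the seed.
#'
#' Continuous views are assumed z-scored; binary views are centred
#' internally and modelled with a Gaussian likelihood (a deliberate
#' simplification appropriate when only variance-explained summaries are
#' needed from the binary layer).
#'
#' After convergence, factors are ordered by descending total variance
#' explained and the gauge is fixed by scaling each score column to unit
#' SD (absorbed into the loadings).
#'
#' @param dataset a `multiomics_dataset`.
#' @param K number of factors; must not exceed `min(n_samples, total
#'   features)`.
#' @param max_iter maximum ALS sweeps. Default 1000.
#' @param tol relative change in the penalised objective declaring
#'   convergence. Default 1e-6.
#' @param seed recorded in the fit metadata (the algorithm itself is
#'   deterministic).
#' @param ard enable ARD shrinkage. Default `TRUE`.
#' @return an object of class `factor_model`: `Z` (samples x K), `W`
#'   (per-view features x K), `tau`, `K`, `view_names`, `sample_ids`,
#'   `fit_meta` (seed, iterations, tol, objective trace, converged flag).
#' @export
fit_factor_model <- function(dataset, K = 15, max_iter = 1000, tol = 1e-6,
                             seed = 1, ard = TRUE) {
  stopifnot(inherits(dataset, "multiomics_dataset"))
  Ylist <- prepare_views_for_fit(dataset)
  n <- length(dataset$sample_ids)
  Ds <- vapply(Ylist, ncol, integer(1))
  M <- length(Ylist)
  if (K > min(n, sum(Ds)))
    stop("K exceeds min(samples, total features)")
  set.seed(seed)

  obs <- lapply(Ylist, function(Y) !is.na(Y))
  Y0 <- lapply(Ylist, function(Y) { Y[is.na(Y)] <- 0; Y })

  # SVD initialisation on per-view scaled, zero-imputed concatenation,
  # followed by a varimax rotation of the per-view-normalised initial
  # loadings: starting near sparse, axis-aligned factors keeps the ARD
  # updates from locking onto rotation-mixed axes
  Xcat <- do.call(cbind, Map(function(Y, D) Y / sqrt(D), Y0, Ds))
  sv <- svd(Xcat, nu = K, nv = 0)
  Z <- sv$u %*% diag(sv$d[seq_len(K)], K)
  zsd <- apply(Z, 2, stats::sd)
  zsd[zsd == 0] <- 1
  Z <- sweep(Z, 2, zsd, "/")
  rownames(Z) <- dataset$sample_ids
  if (K >= 2) {
    ZtZi <- solve(crossprod(Z) + 1e-8 * diag(K))
    W0 <- lapply(Y0, function(Y) t(ZtZi %*% crossprod(Z, Y)))
    Vstack <- do.call(rbind, lapply(W0, function(w)
      w / sqrt(mean(w^2) + 1e-12)))
    R0 <- varimax_rotate(Vstack, max_iter = 200)$R
    Z <- Z %*% R0
  }

  # feature groups sharing an observed-row pattern (one group per view
  # under blockwise missingness)
  fgroups <- lapply(seq_len(M), function(m) {
    key <- apply(obs[[m]], 2, function(cc) paste(which(!cc), collapse = ","))
    split(seq_len(Ds[m]), key)
  })
  # sample groups sharing an observed-entry pattern across all views
  skey <- vapply(seq_len(n), function(i) {
    paste(vapply(seq_len(M), function(m) {
      o <- obs[[m]][i, ]
      if (all(o)) "F" else if (!any(o)) "M"
      else paste0("p", paste(which(!o), collapse = ","))
    }, character(1)), collapse = "|")
  }, character(1))
  sgroups <- split(seq_len(n), skey)

  W <- lapply(seq_len(M), function(m)
    matrix(0, Ds[m], K, dimnames = list(colnames(Ylist[[m]]), NULL)))
  names(W) <- names(Ylist)
  tau <- stats::setNames(rep(1, M), names(Ylist))
  lambda <- matrix(if (ard) 1 else 1e-8, K, M,
                   dimnames = list(NULL, names(Ylist)))
  Nobs <- vapply(obs, sum, numeric(1))
  tau_floor <- 1e-10
  lambda_cap <- 1e3

  objective <- function(rss) {
    sum(vapply(seq_len(M), function(m) {
      rss[m] / (2 * tau[m]) + Nobs[m] / 2 * log(tau[m]) +
        sum(lambda[, m] * colSums(W[[m]]^2)) / 2 -
        Ds[m] / 2 * sum(log(lambda[, m]))
    }, numeric(1))) + sum(Z^2) / 2
  }
  view_rss <- function(m) {
    R <- Ylist[[m]] - Z %*% t(W[[m]])
    sum(R[obs[[m]]]^2)
  }

  trace <- numeric(0)
  J_prev <- Inf
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    rss <- numeric(M)
    for (m in seq_len(M)) {
      for (g in fgroups[[m]]) {
        miss_rows <- !obs[[m]][, g[1]]
        rows <- which(!miss_rows)
        if (!length(rows)) next
        Zo <- Z[rows, , drop = FALSE]
        A <- crossprod(Zo) + tau[m] * diag(lambda[, m], K)
        B <- crossprod(Zo, Ylist[[m]][rows, g, drop = FALSE])
        W[[m]][g, ] <- t(solve(A, B))
      }
      rss[m] <- view_rss(m)
      tau[m] <- max(rss[m] / Nobs[m], tau_floor)
      if (ard)
        lambda[, m] <- pmin(Ds[m] / (colSums(W[[m]]^2) + 1e-12), lambda_cap)
    }
    cvec <- 1 / tau
    G <- lapply(seq_len(M), function(m) cvec[m] * crossprod(W[[m]]))
    Bn <- lapply(seq_len(M), function(m) {
      Ym <- Ylist[[m]]; Ym[!obs[[m]]] <- 0
      cvec[m] * (Ym %*% W[[m]])
    })
    for (g in seq_along(sgroups)) {
      rows <- sgroups[[g]]
      key <- strsplit(names(sgroups)[g], "|", fixed = TRUE)[[1]]
      if (all(key %in% c("F", "M"))) {
        use <- which(key == "F")
        if (!length(use)) { Z[rows, ] <- 0; next }
        Mi <- Reduce(`+`, G[use]) + diag(1, K)
        Bi <- Reduce(`+`, lapply(Bn[use], function(B)
          B[rows, , drop = FALSE]))
        Z[rows, ] <- t(solve_sym(Mi, t(Bi)))
      } else {
        for (i in rows) {
          Mi <- diag(1, K); bi <- numeric(K)
          for (m in seq_len(M)) {
            o <- obs[[m]][i, ]
            if (!any(o)) next
            Wo <- W[[m]][o, , drop = FALSE]
            Mi <- Mi + cvec[m] * crossprod(Wo)
            bi <- bi + cvec[m] * drop(crossprod(Wo, Ylist[[m]][i, o]))
          }
          Z[i, ] <- solve_sym(Mi, bi)
        }
      }
    }
    rss <- vapply(seq_len(M), function(m) view_rss(m), numeric(1))
    J <- objective(rss)
    trace <- c(trace, J)
    if (is.finite(J_prev) &&
        abs(J_prev - J) <= tol * (abs(J_prev) + 1e-12)) {
      converged <- TRUE
      break
    }
    J_prev <- J
  }
  if (!converged)
    warning("factor model did not converge in ", max_iter, " sweeps")

  model <- structure(list(Z = Z, W = W, tau = tau, K = K,
                          view_names = names(Ylist),
                          sample_ids = dataset$sample_ids,
                          fit_meta = list(seed = seed, iterations = it,
                                          tol = tol,
                                          objective = utils::tail(trace, 1),
                                          objective_trace = trace,
                                          converged = converged)),
                     class = "factor_model")
  order_and_gauge(model, Ylist, obs)
}

# ridge-stabilised symmetric solve
solve_sym <- function(A, b) {
  tryCatch(solve(A, b),
           error = function(e)
             solve(A + diag(1e-10 * (1 + max(abs(diag(A)))), nrow(A)), b))
}

# order factors by total variance explained (descending), scale score
# columns to unit SD with the inverse absorbed into the loadings
order_and_gauge <- function(model, Ylist, obs) {
  K <- model$K
  M <- length(Ylist)
  expl <- numeric(K)
  for (m in seq_len(M)) {
    ss_tot <- sum(Ylist[[m]][obs[[m]]]^2)
    for (k in seq_len(K)) {
      R <- Ylist[[m]] - tcrossprod(model$Z[, k], model$W[[m]][, k])
      expl[k] <- expl[k] + (ss_tot - sum(R[obs[[m]]]^2))
    }
  }
  ord <- order(expl, decreasing = TRUE)
  model$Z <- model$Z[, ord, drop = FALSE]
  model$W <- lapply(model$W, function(w) w[, ord, drop = FALSE])
  zsd <- apply(model$Z, 2, stats::sd)
  zsd[zsd == 0 | !is.finite(zsd)] <- 1
  model$Z <- sweep(model$Z, 2, zsd, "/")
  model$W <- lapply(model$W, function(w) sweep(w, 2, zsd, "*"))
  colnames(model$Z) <- paste0("factor", seq_len(K))
  model$W <- lapply(model$W, function(w) {
    colnames(w) <- paste0("factor", seq_len(K)); w
  })
  model
}

# binary views centred, continuous passed through (assumed z-scored)
prepare_views_for_fit <- function(dataset) {
  out <- lapply(dataset$views, function(v) {
    if (v$modality == "binary") center_binary(v)$X else v$X
  })
  names(out) <- names(dataset$views)
  out
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> K = %d, %d samples, views: %s\n", x$K,
              length(x$sample_ids), paste(x$view_names, collapse = ", ")))
  cat(sprintf("  %d sweeps, converged: %s, objective %.6g\n",
              x$fit_meta$iterations, x$fit_meta$converged,
              x$fit_meta$objective))
  invisible(x)
}

#' Variance explained per factor and view
#'
#' `R2[k, m] = 1 - SS(Y_m - z_k w_mk') / SS(Y_m)` over observed entries.
#' The per-view total uses the full reconstruction `Z W_m'`; the grand
#' total is the feature-count-weighted mean of the per-view totals.
#'
#' @param model a `factor_model`.
#' @param dataset the `multiomics_dataset` the model was fitted on (same
#'   feature space).
#' @return a `variance_table`: `R2` (K x views), `per_view_total`,
#'   `grand_total`.
#' @export
variance_explained <- function(model, dataset) {
  Ylist <- prepare_views_for_fit(dataset)
  if (!identical(names(Ylist), model$view_names))
    stop("dataset views do not match the model")
  for (m in seq_along(Ylist))
    if (ncol(Ylist[[m]]) != nrow(model$W[[m]]) ||
        !identical(colnames(Ylist[[m]]), rownames(model$W[[m]])))
      stop("feature space mismatch in view '", model$view_names[m], "'")
  K <- model$K
  M <- length(Ylist)
  R2 <- matrix(NA_real_, K, M,
               dimnames = list(colnames(model$Z), model$view_names))
  per_view_total <- stats::setNames(numeric(M), model$view_names)
  for (m in seq_len(M)) {
    o <- !is.na(Ylist[[m]])
    ss_tot <- sum(Ylist[[m]][o]^2)
    for (k in seq_len(K)) {
      R <- Ylist[[m]] - tcrossprod(model$Z[, k], model$W[[m]][, k])
      R2[k, m] <- 1 - sum(R[o]^2) / ss_tot
    }
    Rfull <- Ylist[[m]] - tcrossprod(model$Z, model$W[[m]])
    per_view_total[m] <- 1 - sum(Rfull[o]^2) / ss_tot
  }
  Ds <- vapply(Ylist, ncol, numeric(1))
  structure(list(R2 = R2, per_view_total = per_view_total,
                 grand_total = sum(per_view_total * Ds) / sum(Ds)),
            class = "variance_table")
}

#' @export
print.variance_table <- function(x, ...) {
  cat("<variance_table>\n")
  print(round(x$R2, 4))
  cat("per-view totals:\n")
  print(round(x$per_view_total, 4))
  cat(sprintf("grand total (feature-weighted): %.4f\n", x$grand_total))
  invisible(x)
}

#' Match factors between two fitted models
#'
#' One-to-one matching of factor-score columns maximising the summed
#' absolute Pearson correlation over the shared samples (greedy matching
#' refined by pairwise exchanges until no swap improves the total).
#'
#' @param modelA,modelB `factor_model` objects (or bare score matrices)
#'   sharing sample ids.
#' @return a `data.frame` with columns `factor_a`, `factor_b` and the
#'   signed correlation `corr`, ordered by `factor_a`.
#' @export
align_factors <- function(modelA, modelB) {
  ZA <- if (inherits(modelA, "factor_model")) modelA$Z else as.matrix(modelA)
  ZB <- if (inherits(modelB, "factor_model")) modelB$Z else as.matrix(modelB)
  shared <- intersect(rownames(ZA), rownames(ZB))
  if (!length(shared)) stop("models share no samples")
  C <- stats::cor(ZA[shared, , drop = FALSE], ZB[shared, , drop = FALSE])
  C[!is.finite(C)] <- 0
  A <- abs(C)
  ka <- nrow(A); kb <- ncol(A)
  match_b <- rep(NA_integer_, ka)
  # greedy: repeatedly take the largest remaining |corr|
  Awork <- A
  for (step in seq_len(min(ka, kb))) {
    ij <- arrayInd(which.max(Awork), dim(Awork))
    match_b[ij[1]] <- ij[2]
    Awork[ij[1], ] <- -Inf
    Awork[, ij[2]] <- -Inf
  }
  # 2-opt refinement
  repeat {
    improved <- FALSE
    idx <- which(!is.na(match_b))
    for (i in idx) for (j in idx) {
      if (i >= j) next
      cur <- A[i, match_b[i]] + A[j, match_b[j]]
      swp <- A[i, match_b[j]] + A[j, match_b[i]]
      if (swp > cur + 1e-12) {
        tmp <- match_b[i]; match_b[i] <- match_b[j]; match_b[j] <- tmp
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  keep <- which(!is.na(match_b))
  data.frame(factor_a = keep, factor_b = match_b[keep],
             corr = C[cbind(keep, match_b[keep])])
}

#' Serialise / restore a fitted factor model
#'
#' The model container is a single hierarchical RDS file holding scores,
#' per-view loadings with feature ids, residual variances and fit
#' metadata; it reads back bit-exactly.
#'
#' @param model a `factor_model`.
#' @param path container file path.
#' @return `path` invisibly; `read_factor_model()` returns the model.
#' @export
write_factor_model <- function(model, path) {
  stopifnot(inherits(model, "factor_model"))
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname write_factor_model
#' @export
read_factor_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "factor_model"))
    stop("file does not contain a factor_model container")
  model
}
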