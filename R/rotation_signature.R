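#' Varimax rotation of a loading matrix
#'
#' Orthogonal rotation maximising the varimax criterion
#' `sum_k [ mean(w^4) - mean(w^2)^2 ]` over columns, via the classic
#' SVD-sweep algorithm; the criterion is non-decreasing per sweep. Kaiser
#' row-normalisation is off by default. `K = 1` returns the identity
#' rotation.
#'
#' @param W loadings (features x K), finite.
#' @param tol relative convergence tolerance on the sweep invariant.
#'   Default 1e-10.
#' @param max_iter maximum sweeps. Default 1000.
#' @param kaiser normalise rows to unit length before rotating (undone
#'   afterwards). Default `FALSE`.
#' @return list with `W_rot = W %*% R`, the orthogonal `R`, `criterion`
#'   (value at `W_rot`) and `iterations`.
#' @export
varimax_rotate <- function(W, tol = 1e-10, max_iter = 1000, kaiser = FALSE) {
  W <- as.matrix(W)
  if (!all(is.finite(W))) stop("loadings must be finite")
  K <- ncol(W)
  if (K < 2)
    return(list(W_rot = W, R = diag(1, K),
                criterion = varimax_criterion(W), iterations = 0L))
  Wwork <- W
  rnorm_ <- NULL
  if (kaiser) {
    rnorm_ <- sqrt(rowSums(W^2))
    rnorm_[rnorm_ == 0] <- 1
    Wwork <- W / rnorm_
  }
  D <- nrow(Wwork)
  R <- diag(1, K)
  d_prev <- 0
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    L <- Wwork %*% R
    B <- crossprod(Wwork, L^3 - L %*% diag(colMeans(L^2), K))
    sv <- svd(B)
    R <- sv$u %*% t(sv$v)
    d <- sum(sv$d)
    if (d < d_prev * (1 + tol) && it > 1) break
    d_prev <- d
  }
  W_rot <- W %*% R
  list(W_rot = W_rot, R = R, criterion = varimax_criterion(W %*% R),
       iterations = it)
}

#' Varimax criterion of a loading matrix
#' @param W loadings (features x K).
#' @return the summed per-column variance of squared loadings.
#' @export
varimax_criterion <- function(W) {
  W <- as.matrix(W)
  sum(colMeans(W^4) - colMeans(W^2)^2)
}

#' Extract a thresholded, cross-layer validated gene signature
#'
#' Pipeline: varimax-rotate the chosen view's loadings; pick the rotated
#' column best aligned with `factor_index`; standardise the factor sign so
#' its largest-|weight| feature is negative; scale weights to unit maximum
#' absolute value; keep genes with `|weight| > weight_thresh`; then keep
#' genes whose expression correlates across the two `corr_views` (Pearson,
#' common samples, observed pairs) strictly above `corr_thresh`. Setting
#' `corr_thresh <= -1` disables the correlation filter. A stricter
#' `weight_thresh` with the filter disabled reproduces the focused-
#' signature refinement path.
#'
#' @param model a fitted `factor_model`.
#' @param dataset the `multiomics_dataset` supplying the correlation
#'   views.
#' @param factor_index which (pre-rotation) factor to extract from.
#' @param weight_thresh absolute rotated-weight threshold on the
#'   max-normalised scale. Default 0.5.
#' @param corr_thresh cross-view Pearson threshold (strict). Default 0.5.
#' @param weight_view the view whose loadings are rotated. Default
#'   `"protein"`.
#' @param corr_views two views whose per-gene expression correlation
#'   validates candidates. Default `c("mrna", "protein")`.
#' @param kaiser passed to [varimax_rotate()].
#' @return a `signature_set`: `factor_index`, `genes`, `weights`
#'   (rotated, sign-standardised, max-normalised), `thresholds`,
#'   `provenance`. An empty result is returned with a warning, not an
#'   error.
#' @export
extract_signature <- function(model, dataset, factor_index,
                              weight_thresh = 0.5, corr_thresh = 0.5,
                              weight_view = "protein",
                              corr_views = c("mrna", "protein"),
                              kaiser = FALSE) {
  stopifnot(inherits(model, "factor_model"))
  if (!weight_view %in% model$view_names)
    stop("model has no view '", weight_view, "'")
  W <- model$W[[weight_view]]
  rot <- varimax_rotate(W, kaiser = kaiser)
  # rotated column carrying most of the original factor
  j <- which.max(abs(rot$R[factor_index, ]))
  w <- rot$W_rot[, j]
  # sign convention: strongest feature negative
  if (w[which.max(abs(w))] > 0) w <- -w
  mx <- max(abs(w))
  if (mx > 0) w <- w / mx
  cand <- names(w)[abs(w) > weight_thresh]
  if (corr_thresh > -1 && length(cand)) {
    if (length(corr_views) != 2 ||
        !all(corr_views %in% names(dataset$views)))
      stop("corr_views must name two views of the dataset")
    Xa <- dataset$views[[corr_views[1]]]$X
    Xb <- dataset$views[[corr_views[2]]]$X
    common <- intersect(rownames(Xa), rownames(Xb))
    keep <- vapply(cand, function(g) {
      if (!(g %in% colnames(Xa)) || !(g %in% colnames(Xb))) return(FALSE)
      a <- Xa[common, g]; b <- Xb[common, g]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 3) return(FALSE)
      r <- suppressWarnings(stats::cor(a[ok], b[ok]))
      isTRUE(r > corr_thresh)
    }, logical(1))
    cand <- cand[keep]
  }
  if (!length(cand))
    warning("signature extraction returned an empty gene set")
  structure(list(factor_index = factor_index, genes = cand,
                 weights = w[cand],
                 thresholds = c(weight_thresh = weight_thresh,
                                corr_thresh = corr_thresh),
                 provenance = list(weight_view = weight_view,
                                   corr_views = corr_views,
                                   rotated_column = j)),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> factor %d: %d genes (|weight| > %.2f%s)\n",
              x$factor_index, length(x$genes), x$thresholds["weight_thresh"],
              if (x$thresholds["corr_thresh"] > -1)
                sprintf(", cross-view corr > %.2f",
                        x$thresholds["corr_thresh"]) else ""))
  invisible(x)
}

#' Write / read a gene signature as two-column text
#' @param signature a `signature_set`.
#' @param path output path (TSV: gene, weight).
#' @return `path` invisibly; `read_signature()` returns a `signature_set`
#'   (thresholds unknown on read are `NA`).
#' @export
write_signature <- function(signature, path) {
  utils::write.table(data.frame(gene = signature$genes,
                                weight = signature$weights),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @param factor_index factor index to record on read.
#' @export
read_signature <- function(path, factor_index = NA_integer_) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  structure(list(factor_index = factor_index, genes = df$gene,
                 weights = stats::setNames(df$weight, df$gene),
                 thresholds = c(weight_thresh = NA_real_,
                                corr_thresh = NA_real_),
                 provenance = list(path = path)),
            class = "signature_set")
}

#' Top fraction of features by absolute weight
#'
#' Ranks features by `|weight|` descending (ties broken lexicographically
#' by feature id) and returns the top `ceiling(fraction * D)`.
#'
#' @param weights named per-feature weight vector (non-empty).
#' @param fraction fraction in (0, 1]. Default 0.10.
#' @return character vector of feature ids.
#' @export
top_fraction_features <- function(weights, fraction = 0.10) {
  if (!length(weights)) stop("weights must be non-empty")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (is.null(names(weights)))
    names(weights) <- sprintf("f%d", seq_along(weights))
  k <- ceiling(fraction * length(weights))
  ord <- order(-abs(weights), names(weights))
  names(weights)[ord[seq_len(k)]]
}
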