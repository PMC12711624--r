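#' Project a new cohort onto a trained factor model
#'
#' Scores a cohort on pre-trained loadings by least squares: for matched
#' features, `scores = Y pinv(W')`, the Moore-Penrose solution of
#' `Y ~ Z W'` computed via SVD with relative singular-value truncation at
#' `rcond`. For a single factor this reduces to `Y w / (w' w)`. The new
#' cohort's view should be z-scored with its own means and SDs before
#' projection. Feature ids are intersected with the model loadings;
#' unmatched features on either side are dropped and reported.
#'
#' @param model a `factor_model`.
#' @param view the new cohort's `omics_view` (z-scored).
#' @param view_name which of the model's views supplies the loadings;
#'   defaults to the view's own name.
#' @param factors indices of the factors to score (default: all).
#' @param rcond relative singular-value truncation threshold. Default
#'   1e-10.
#' @param normalize_ids case-fold ids and strip trailing `.N` version
#'   suffixes before matching. Default `FALSE`.
#' @return a `projection_result`: `scores` (samples x factors; rows of
#'   all-missing samples are `NA`), `matched_features`,
#'   `dropped_features`, `conditioning` (smallest retained singular
#'   value).
#' @export
project_cohort <- function(model, view, view_name = view$name,
                           factors = seq_len(model$K), rcond = 1e-10,
                           normalize_ids = FALSE) {
  stopifnot(inherits(model, "factor_model"), inherits(view, "omics_view"))
  if (!view_name %in% model$view_names)
    stop("model has no view named '", view_name, "'")
  Wfull <- model$W[[view_name]]
  ids_model <- rownames(Wfull)
  ids_view <- colnames(view$X)
  norm <- function(x) if (normalize_ids)
    tolower(sub("\\.\\d+$", "", x)) else x
  hit <- match(norm(ids_view), norm(ids_model))
  matched_view <- which(!is.na(hit))
  if (!length(matched_view)) stop("no features match the model loadings")
  dropped <- c(setdiff(ids_view, ids_view[matched_view]),
               setdiff(ids_model, ids_model[hit[matched_view]]))
  W <- Wfull[hit[matched_view], factors, drop = FALSE]
  Y <- view$X[, matched_view, drop = FALSE]
  if (nrow(W) < length(factors))
    stop("matched features (", nrow(W), ") fewer than requested factors (",
         length(factors), ")")
  sv <- svd(W)
  keep <- sv$d > rcond * sv$d[1]
  if (!any(keep)) stop("loading matrix is numerically rank zero")
  # pinv(W') = U diag(1/d) V'; scores = Y %*% pinv(W')
  P <- sv$u[, keep, drop = FALSE] %*%
    (t(sv$v[, keep, drop = FALSE]) / sv$d[keep])
  scores <- matrix(NA_real_, nrow(Y), length(factors),
                   dimnames = list(rownames(Y),
                                   colnames(model$Z)[factors]))
  cc <- rowSums(is.na(Y)) == 0
  if (any(cc))
    scores[cc, ] <- Y[cc, , drop = FALSE] %*% P
  partial <- which(!cc & rowSums(!is.na(Y)) > 0)
  for (i in partial) {
    o <- !is.na(Y[i, ])
    Wo <- W[o, , drop = FALSE]
    if (nrow(Wo) < length(factors)) next  # left NA: too few observed
    svo <- svd(Wo)
    ko <- svo$d > rcond * svo$d[1]
    scores[i, ] <- drop(Y[i, o] %*% (svo$u[, ko, drop = FALSE] %*%
      (t(svo$v[, ko, drop = FALSE]) / svo$d[ko])))
  }
  structure(list(scores = scores, matched_features = nrow(W),
                 dropped_features = dropped,
                 conditioning = min(sv$d[keep])),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("<projection_result> %d samples x %d factor(s); %d matched, %d dropped features; conditioning %.3g\n",
              nrow(x$scores), ncol(x$scores), x$matched_features,
              length(x$dropped_features), x$conditioning))
  invisible(x)
}

#' Stratify scores into low/high groups
#'
#' Deterministic two-group assignment by median, quantile or fixed
#' threshold; scores at or below the cut-point go to `"low"`.
#'
#' @param scores finite numeric vector.
#' @param rule `"median"`, `"quantile"` or `"threshold"`.
#' @param q quantile level for `rule = "quantile"`.
#' @param threshold cut-point for `rule = "threshold"`.
#' @return factor with levels `low`, `high`, named like `scores`.
#' @export
stratify_scores <- function(scores, rule = c("median", "quantile",
                                             "threshold"),
                            q = 0.5, threshold = NULL) {
  rule <- match.arg(rule)
  s <- scores[!is.na(scores)]
  if (!length(s) || !all(is.finite(s))) stop("scores must be finite")
  if (length(unique(s)) < 2) stop("scores are constant; cannot stratify")
  cut <- switch(rule,
                median = stats::median(s),
                quantile = stats::quantile(s, q, names = FALSE),
                threshold = {
                  if (is.null(threshold)) stop("threshold rule needs a value")
                  threshold
                })
  out <- factor(ifelse(scores <= cut, "low", "high"),
                levels = c("low", "high"))
  names(out) <- names(scores)
  out
}
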