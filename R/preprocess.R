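#' Z-score a continuous view per feature
#'
#' Each feature is centred to mean 0 and scaled to sample SD 1 (denominator
#' n - 1) over its observed entries; the missingness mask is untouched.
#' Features with fewer than two observed values or zero variance cannot be
#' standardised and are dropped with a warning.
#'
#' @param view a continuous `omics_view`.
#' @return the standardised `omics_view`.
#' @export
zscore_view <- function(view) {
  if (view$modality != "continuous")
    stop("zscore_view() expects a continuous view")
  X <- view$X
  n_obs <- colSums(!is.na(X))
  s <- apply(X, 2, stats::sd, na.rm = TRUE)
  bad <- n_obs < 2 | is.na(s) | s == 0
  if (any(bad)) {
    warning(sum(bad), " zero-variance or under-observed feature(s) dropped ",
            "from view '", view$name, "': ",
            paste(utils::head(colnames(X)[bad], 5), collapse = ", "),
            if (sum(bad) > 5) ", ..." else "")
    X <- X[, !bad, drop = FALSE]
    s <- s[!bad]
  }
  m <- colMeans(X, na.rm = TRUE)
  X <- sweep(sweep(X, 2, m, "-"), 2, s, "/")
  omics_view_unchecked(X, view$name, view$modality)
}

#' Centre a binary view per feature
#'
#' Subtracts the per-feature observed mean so a binary mutation view can
#' enter a Gaussian factor model. Values leave \{0,1\} so the returned
#' view is marked continuous.
#'
#' @param view a binary `omics_view`.
#' @return a centred `omics_view` with modality `"continuous"`.
#' @export
center_binary <- function(view) {
  if (view$modality != "binary")
    stop("center_binary() expects a binary view")
  m <- colMeans(view$X, na.rm = TRUE)
  omics_view_unchecked(sweep(view$X, 2, m, "-"), view$name, "continuous")
}

#' Filter mutation features by burden
#'
#' Keeps features mutated in strictly more than `min_mutated` samples
#' (count of 1 entries across samples).
#'
#' @param view a binary `omics_view`.
#' @param min_mutated burden cutoff; strict inequality. Default 10.
#' @return the filtered `omics_view`.
#' @export
filter_mutation_burden <- function(view, min_mutated = 10) {
  if (view$modality != "binary")
    stop("filter_mutation_burden() expects a binary view")
  burden <- colSums(view$X == 1, na.rm = TRUE)
  omics_view_unchecked(view$X[, burden > min_mutated, drop = FALSE],
                       view$name, view$modality)
}

#' Keep the k most variable features
#'
#' Features are ranked by per-feature SD (denominator n - 1, observed
#' entries only); ties at the cutoff break lexicographically by feature id.
#' The survivors keep their original relative order.
#'
#' @param view a continuous `omics_view`.
#' @param k number of features to keep; must not exceed the feature count.
#' @return the filtered `omics_view`.
#' @export
select_top_variable <- function(view, k) {
  if (view$modality != "continuous")
    stop("select_top_variable() expects a continuous view")
  D <- ncol(view$X)
  if (k > D) stop("k (", k, ") exceeds feature count (", D, ")")
  sds <- apply(view$X, 2, stats::sd, na.rm = TRUE)
  sds[is.na(sds)] <- -Inf
  ord <- order(-sds, colnames(view$X))
  keep <- colnames(view$X) %in% colnames(view$X)[ord[seq_len(k)]]
  omics_view_unchecked(view$X[, keep, drop = FALSE], view$name, view$modality)
}

#' Filter features by detection rate
#'
#' Keeps features observed in strictly more than `min_rate` of samples.
#'
#' @param view a continuous `omics_view`.
#' @param min_rate detection-rate cutoff in \[0,1\]; strict inequality.
#'   Default 0.8.
#' @return the filtered `omics_view`.
#' @export
filter_detection <- function(view, min_rate = 0.8) {
  if (view$modality != "continuous")
    stop("filter_detection() expects a continuous view")
  rate <- colMeans(!is.na(view$X))
  omics_view_unchecked(view$X[, rate > min_rate, drop = FALSE],
                       view$name, view$modality)
}

#' Restrict a dataset to its shared sample set
#'
#' With `require_all_views = TRUE`, keeps only samples that are present
#' (not fully missing) in every view — the complete-case multi-view cohort.
#' Sample order is canonicalised by id. With the flag off the dataset is
#' returned on the sorted union universe (its construction default).
#'
#' @param dataset a `multiomics_dataset`.
#' @param require_all_views require presence in every view. Default `TRUE`.
#' @return the restricted `multiomics_dataset`.
#' @export
intersect_samples <- function(dataset, require_all_views = TRUE) {
  if (!require_all_views) return(dataset)
  present <- lapply(dataset$views, function(v)
    rownames(v$X)[rowSums(!is.na(v$X)) > 0])
  common <- sort(Reduce(intersect, present))
  if (!length(common)) stop("no sample is observed in every view")
  views <- lapply(dataset$views, function(v)
    omics_view_unchecked(v$X[common, , drop = FALSE], v$name, v$modality))
  clin <- dataset$clinical
  if (!is.null(clin)) {
    clin <- clin[clin$sample_id %in% common, , drop = FALSE]
    clin <- clin[order(clin$sample_id), , drop = FALSE]
    rownames(clin) <- NULL
  }
  structure(list(views = views, clinical = clin, sample_ids = common),
            class = "multiomics_dataset")
}
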