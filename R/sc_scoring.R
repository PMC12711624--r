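#' Library-size normalise and log-transform counts
#'
#' Scales each cell to `scale_factor` total counts and applies `log1p`.
#' Provided as an explicit utility; [module_score()] does not apply it
#' silently.
#'
#' @param counts cells x genes count matrix.
#' @param scale_factor target library size. Default 1e4.
#' @return cells x genes normalised-expression matrix.
#' @export
normalize_counts <- function(counts, scale_factor = 1e4) {
  lib <- rowSums(counts)
  lib[lib == 0] <- 1
  log1p(counts / lib * scale_factor)
}

#' Expression-bin matched gene module score
#'
#' For each cell, the mean normalised expression of the signature genes
#' minus the mean expression of expression-bin-matched control genes:
#' genes are cut into `n_bins` equal-frequency bins of dataset-average
#' expression (ties broken by gene id); each signature gene draws
#' `n_ctrl` control genes uniformly from its bin (signature genes
#' excluded; with replacement when the bin is smaller), and the control
#' mean is taken over all draws. Deterministic given `seed`. Adding a
#' constant to every gene of every cell leaves the score unchanged, and
#' a constant expression matrix scores exactly 0.
#'
#' @param expr cells x genes log-normalised expression matrix.
#' @param signature a `signature_set` or character vector of gene ids.
#' @param n_bins number of expression bins. Default 24.
#' @param n_ctrl control genes per signature gene. Default 100.
#' @param seed integer seed for control sampling.
#' @param cell_types optional per-cell labels for the summary.
#' @return a `module_score_result`: `per_cell_score`, `signature_used`,
#'   `controls_per_gene`, `bins`, and `per_type_summary` (mean/median per
#'   cell type) when labels are given.
#' @export
module_score <- function(expr, signature, n_bins = 24, n_ctrl = 100,
                         seed = 1, cell_types = NULL) {
  genes <- if (inherits(signature, "signature_set")) signature$genes
           else as.character(signature)
  if (!length(genes)) stop("signature is empty")
  if (is.null(colnames(expr))) stop("expr needs gene ids as colnames")
  expr <- as.matrix(expr)
  present <- intersect(genes, colnames(expr))
  missing <- setdiff(genes, colnames(expr))
  if (!length(present))
    stop("no signature genes present in the matrix; missing: ",
         paste(utils::head(missing, 10), collapse = ", "))
  if (length(missing))
    warning(length(missing), " signature gene(s) absent: ",
            paste(utils::head(missing, 5), collapse = ", "))
  D <- ncol(expr)
  if (D < n_bins) stop("need at least n_bins genes")
  avg <- colMeans(expr)
  ord <- order(avg, colnames(expr))
  bin_of <- integer(D)
  bin_of[ord] <- ceiling(seq_len(D) * n_bins / D)
  names(bin_of) <- colnames(expr)
  set.seed(seed)
  ctrl_idx <- integer(0)
  for (g in present) {
    pool <- which(bin_of == bin_of[g])
    pool <- setdiff(pool, match(present, colnames(expr)))
    if (!length(pool)) pool <- setdiff(seq_len(D), match(present, colnames(expr)))
    draw <- if (length(pool) >= n_ctrl) sample(pool, n_ctrl)
            else sample(pool, n_ctrl, replace = TRUE)
    ctrl_idx <- c(ctrl_idx, draw)
  }
  sig_mean <- rowMeans(expr[, present, drop = FALSE])
  ctrl_mean <- rowMeans(expr[, ctrl_idx, drop = FALSE])
  score <- sig_mean - ctrl_mean
  names(score) <- rownames(expr)
  per_type <- NULL
  if (!is.null(cell_types)) {
    per_type <- do.call(rbind, lapply(split(score, cell_types), function(s)
      data.frame(n = length(s), mean = mean(s), median = stats::median(s))))
    per_type <- cbind(cell_type = rownames(per_type), per_type)
    rownames(per_type) <- NULL
  }
  structure(list(per_cell_score = score, signature_used = present,
                 controls_per_gene = n_ctrl, bins = n_bins,
                 per_type_summary = per_type),
            class = "module_score_result")
}

#' @export
print.module_score_result <- function(x, ...) {
  cat(sprintf("<module_score_result> %d cells, %d signature genes, %d bins, %d controls/gene\n",
              length(x$per_cell_score), length(x$signature_used),
              x$bins, x$controls_per_gene))
  if (!is.null(x$per_type_summary)) print(x$per_type_summary)
  invisible(x)
}

#' Fraction of score-positive cells per tissue
#'
#' Fraction of cells with score strictly above `threshold` in each
#' tissue, with the tumour/normal ratio and a bootstrap percentile CI
#' (cells resampled within tissue). Tissues with zero cells are excluded
#' with a warning; an undefined ratio (no positive cells in the
#' denominator tissue) is reported as `NA`.
#'
#' @param result a `module_score_result` (or bare score vector).
#' @param threshold positivity cut-point. Default 0.
#' @param tissue_labels per-cell tissue labels covering all cells.
#' @param subset optional logical mask restricting to a cell population
#'   (e.g. one cell type).
#' @param ratio_pair tissues forming the numerator/denominator of the
#'   ratio. Default `c("tumour", "normal")`.
#' @param n_boot bootstrap resamples for the ratio CI. Default 1000.
#' @param seed integer seed.
#' @return list with `fraction` (per tissue), `ratio`, `ratio_ci`
#'   (2.5/97.5 percentiles), `n_cells` per tissue.
#' @export
positive_fraction <- function(result, threshold = 0, tissue_labels,
                              subset = NULL,
                              ratio_pair = c("tumour", "normal"),
                              n_boot = 1000, seed = 1) {
  score <- if (inherits(result, "module_score_result"))
    result$per_cell_score else as.numeric(result)
  if (length(tissue_labels) != length(score))
    stop("tissue labels must cover all cells")
  if (!is.null(subset)) {
    score <- score[subset]
    tissue_labels <- tissue_labels[subset]
  }
  tis <- factor(tissue_labels)
  counts <- table(tis)
  if (any(counts == 0)) {
    warning("tissue(s) with zero cells excluded: ",
            paste(names(counts)[counts == 0], collapse = ", "))
    tis <- droplevels(tis)
  }
  pos <- score > threshold
  frac <- tapply(pos, tis, mean)
  n_cells <- as.vector(table(tis))
  names(n_cells) <- levels(tis)
  ratio <- NA_real_
  ratio_ci <- c(NA_real_, NA_real_)
  if (all(ratio_pair %in% levels(tis))) {
    num <- frac[ratio_pair[1]]
    den <- frac[ratio_pair[2]]
    if (!is.na(den) && den > 0) {
      ratio <- unname(num / den)
      set.seed(seed)
      i1 <- which(tis == ratio_pair[1])
      i2 <- which(tis == ratio_pair[2])
      boots <- vapply(seq_len(n_boot), function(b) {
        f1 <- mean(pos[sample(i1, replace = TRUE)])
        f2 <- mean(pos[sample(i2, replace = TRUE)])
        if (f2 > 0) f1 / f2 else NA_real_
      }, numeric(1))
      ratio_ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE,
                                  names = FALSE)
    }
  }
  list(fraction = frac, ratio = ratio, ratio_ci = ratio_ci,
       n_cells = n_cells)
}

#' Read single-cell counts
#'
#' Reads a 10x-style MTX triplet (matrix, gene and barcode files; genes in
#' MTX rows) or a dense TSV with genes in columns.
#'
#' @param matrix_path `.mtx` file, or a dense TSV when `genes_path` is
#'   `NULL`.
#' @param genes_path,barcodes_path one-column text files of gene ids and
#'   cell barcodes (MTX mode).
#' @return cells x genes dense count matrix.
#' @export
read_sc_counts <- function(matrix_path, genes_path = NULL,
                           barcodes_path = NULL) {
  if (is.null(genes_path)) {
    v <- read_matrix(matrix_path, name = "sc")
    return(v$X)
  }
  m <- Matrix::readMM(matrix_path)
  genes <- readLines(genes_path)
  barcodes <- readLines(barcodes_path)
  genes <- vapply(strsplit(genes, "\t"), `[[`, character(1), 1)
  m <- as.matrix(m)
  dimnames(m) <- list(genes, barcodes)
  t(m)
}
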