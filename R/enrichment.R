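#' Competitive permutation enrichment of factor loadings
#'
#' For each gene set, contrasts `|loading|` between in-set and out-of-set
#' genes with a pooled-variance two-sample t statistic and calibrates it
#' against a gene-label permutation null preserving the set size:
#' `p = (1 + #{|t_null| >= |t_obs|}) / (1 + n_perm)`. With
#' `exact = TRUE` the null enumerates every same-size subset of the
#' universe (feasible only for small problems) and
#' `p = #{|t| >= |t_obs|} / n_subsets` over the full enumeration
#' (the observed subset included, so p >= 1/n_subsets). Benjamini-
#' Hochberg FDR is computed across sets.
#'
#' Sets are intersected with the loading universe; sets with fewer than 3
#' genes after intersection are dropped with a warning.
#'
#' @param loadings named per-gene weight vector.
#' @param gene_sets named list of gene-id vectors.
#' @param n_perm number of permutations. Default 1000.
#' @param seed integer seed; results are deterministic given it.
#' @param exact enumerate all subsets instead of sampling permutations.
#' @return a `data.frame`: `set_name`, `n_genes_in_set`, `statistic`,
#'   `p_perm`, `fdr`.
#' @export
pcgse <- function(loadings, gene_sets, n_perm = 1000, seed = 1,
                  exact = FALSE) {
  if (!length(gene_sets)) stop("gene set collection is empty")
  if (is.null(names(loadings))) stop("loadings must be named by gene id")
  universe <- names(loadings)
  a <- abs(unname(loadings))
  D <- length(a)
  sizes0 <- lengths(gene_sets)
  gene_sets <- lapply(gene_sets, intersect, universe)
  if (any(lengths(gene_sets) > D))
    stop("a gene set is larger than the loading universe")
  small <- lengths(gene_sets) < 3
  if (any(small)) {
    warning(sum(small), " set(s) with < 3 genes after intersection dropped")
    gene_sets <- gene_sets[!small]
  }
  if (!length(gene_sets)) stop("no gene set survives the size filter")
  tstat <- function(idx) {
    x <- a[idx]; y <- a[-idx]
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
      (nx + ny - 2)
    if (sp2 <= 0) return(0)
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  }
  set.seed(seed)
  res <- lapply(names(gene_sets), function(nm) {
    idx <- match(gene_sets[[nm]], universe)
    obs <- tstat(idx)
    s <- length(idx)
    if (exact) {
      combs <- utils::combn(D, s)
      if (ncol(combs) > 2e5)
        stop("exact enumeration infeasible: ", ncol(combs), " subsets")
      null <- apply(combs, 2, tstat)
      p <- mean(abs(null) >= abs(obs) - 1e-12)
    } else {
      null <- vapply(seq_len(n_perm),
                     function(b) tstat(sample.int(D, s)), numeric(1))
      p <- (1 + sum(abs(null) >= abs(obs))) / (1 + n_perm)
    }
    data.frame(set_name = nm, n_genes_in_set = s, statistic = obs,
               p_perm = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_fdr(out$p_perm)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, capped at 1 and invariant to
#' input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @return adjusted values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then gene ids, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1)
  sets
}
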