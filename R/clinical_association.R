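#' Pearson correlation with a two-sided t test
#'
#' Product-moment correlation on complete pairs with the usual t test
#' (`t = r sqrt((n-2)/(1-r^2))`, n-2 df, two-sided). Inputs with fewer
#' than 3 complete pairs or zero variance give `r = NA` with `ok =
#' FALSE`, so callers can exclude them from FDR.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p`, `n_used`, `ok`.
#' @export
pearson_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(list(r = NA_real_, p = NA_real_, n_used = n, ok = FALSE))
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_used = n, ok = TRUE)
}

#' Factor-by-clinical-variable correlation matrix
#'
#' Tests every (factor, variable) pair with [pearson_test()] after
#' encoding ordinal and binary variables numerically, and applies one
#' Benjamini-Hochberg pass across the whole matrix. Multi-level
#' categorical variables are not Pearson-compatible and should be tested
#' with [kruskal_wallis()] instead.
#'
#' Default encodings: `stage` stays as given when numeric, otherwise
#' roman/level order; `msi_status` MSS, MSI-L, MSI-H -> 0, 1, 2; `sex`
#' F, M -> 0, 1; 0/1 variables pass through; other numeric variables pass
#' through.
#'
#' @param Z factor-score matrix (samples x K), rows named by sample id.
#' @param clinical data frame keyed by `sample_id`.
#' @param variables clinical column names to test.
#' @param encodings optional named list of named numeric vectors mapping
#'   a variable's levels to numbers, overriding the defaults.
#' @return tidy `data.frame`: `factor_index`, `variable`, `r`, `p`,
#'   `fdr`, `n_used`.
#' @export
factor_clinical_matrix <- function(Z, clinical, variables,
                                   encodings = NULL) {
  stopifnot(is.matrix(Z), "sample_id" %in% names(clinical))
  missing_vars <- setdiff(variables, names(clinical))
  if (length(missing_vars))
    stop("unknown clinical variable(s): ",
         paste(missing_vars, collapse = ", "))
  idx <- match(rownames(Z), clinical$sample_id)
  cl <- clinical[idx, , drop = FALSE]
  enc_default <- list(msi_status = c(MSS = 0, `MSI-L` = 1, `MSI-H` = 2),
                      sex = c(F = 0, M = 1))
  rows <- list()
  for (v in variables) {
    raw <- cl[[v]]
    map <- if (!is.null(encodings[[v]])) encodings[[v]]
           else enc_default[[v]]
    if (!is.null(map)) {
      num <- unname(map[as.character(raw)])
    } else if (is.numeric(raw)) {
      num <- raw
    } else {
      lev <- sort(unique(stats::na.omit(as.character(raw))))
      if (length(lev) > 2)
        stop("variable '", v, "' is multi-level categorical; ",
             "use kruskal_wallis() or supply an encoding")
      num <- as.numeric(factor(raw, levels = lev)) - 1
    }
    for (k in seq_len(ncol(Z))) {
      pt <- pearson_test(Z[, k], num)
      rows[[length(rows) + 1L]] <-
        data.frame(factor_index = k, variable = v, r = pt$r, p = pt$p,
                   n_used = pt$n_used, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  valid <- !is.na(out$p)
  out$fdr[valid] <- bh_fdr(out$p[valid])
  out[, c("factor_index", "variable", "r", "p", "fdr", "n_used")]
}

#' Kruskal-Wallis rank test of scores across groups
#'
#' Midrank handling of ties with the standard tie correction; the H
#' statistic is referred to a chi-square with (groups - 1) df.
#'
#' @param scores numeric vector.
#' @param group_labels group membership, length of `scores`; at least two
#'   non-empty groups.
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(scores, group_labels) {
  ok <- !is.na(scores) & !is.na(group_labels)
  g <- factor(group_labels[ok])
  if (nlevels(g) < 2) stop("need at least two groups")
  kt <- stats::kruskal.test(scores[ok], g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}
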