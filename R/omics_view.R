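#' Construct an omics view
#'
#' An omics view is one modality's samples x features numeric matrix with
#' row names as sample ids and column names as feature ids. Missing entries
#' are encoded as `NA`; the observation mask is implied by `!is.na()`.
#' Binary views (e.g. somatic mutation calls) may contain only 0, 1 and `NA`.
#'
#' @param X numeric matrix, samples in rows, features in columns. Row and
#'   column names are required and feature ids must be unique.
#' @param name label for the view (e.g. `"protein"`).
#' @param modality `"continuous"` or `"binary"`.
#' @return An object of class `omics_view` with elements `name`, `modality`
#'   and `X`.
#' @export
omics_view <- function(X, name, modality = c("continuous", "binary")) {
  modality <- match.arg(modality)
  if (!is.matrix(X) || !is.numeric(X))
    stop("X must be a numeric matrix")
  if (is.null(rownames(X)) || is.null(colnames(X)))
    stop("X must carry sample ids as rownames and feature ids as colnames")
  dup <- colnames(X)[duplicated(colnames(X))]
  if (length(dup))
    stop("duplicate feature ids in view '", name, "': ",
         paste(unique(dup), collapse = ", "))
  if (anyDuplicated(rownames(X)))
    stop("duplicate sample ids in view '", name, "'")
  if (modality == "binary") {
    v <- X[!is.na(X)]
    if (!all(v %in% c(0, 1)))
      stop("binary view '", name, "' contains values other than 0/1/NA")
  }
  structure(list(name = name, modality = modality, X = X),
            class = "omics_view")
}

#' @export
print.omics_view <- function(x, ...) {
  cat(sprintf("<omics_view '%s'> %s, %d samples x %d features (%.1f%% observed)\n",
              x$name, x$modality, nrow(x$X), ncol(x$X),
              100 * mean(!is.na(x$X))))
  invisible(x)
}

#' Sample and feature ids of a view
#' @param view an `omics_view`.
#' @return character vector of ids.
#' @export
view_samples <- function(view) rownames(view$X)

#' @rdname view_samples
#' @export
view_features <- function(view) colnames(view$X)

#' Observation mask of a view
#' @param view an `omics_view`.
#' @return logical matrix, `TRUE` where the entry is observed.
#' @export
view_mask <- function(view) !is.na(view$X)

#' Assemble a multi-view dataset over a shared sample universe
#'
#' Views are re-indexed onto the sorted union of their sample ids; samples
#' absent from a view appear as fully missing rows, which is how blockwise
#' view missingness is represented throughout.
#'
#' @param views named list of `omics_view` objects.
#' @param clinical optional clinical `data.frame` with a `sample_id` column;
#'   rows not matching the sample universe are dropped with a message.
#' @return An object of class `multiomics_dataset` with elements `views`,
#'   `clinical` and `sample_ids`.
#' @export
multiomics_dataset <- function(views, clinical = NULL) {
  if (!length(views)) stop("at least one view is required")
  if (is.null(names(views)) || any(!nzchar(names(views))))
    names(views) <- vapply(views, function(v) v$name, character(1))
  stopifnot(all(vapply(views, inherits, logical(1), "omics_view")))
  universe <- sort(unique(unlist(lapply(views, view_samples))))
  views <- lapply(views, function(v) {
    Xf <- matrix(NA_real_, length(universe), ncol(v$X),
                 dimnames = list(universe, colnames(v$X)))
    keep <- intersect(universe, rownames(v$X))
    Xf[keep, ] <- v$X[keep, , drop = FALSE]
    omics_view_unchecked(Xf, v$name, v$modality)
  })
  if (!is.null(clinical)) {
    if (!"sample_id" %in% names(clinical))
      stop("clinical table must have a 'sample_id' column")
    unmatched <- setdiff(clinical$sample_id, universe)
    if (length(unmatched))
      message(length(unmatched), " clinical rows without omics data dropped")
    clinical <- clinical[clinical$sample_id %in% universe, , drop = FALSE]
    clinical <- clinical[order(clinical$sample_id), , drop = FALSE]
    rownames(clinical) <- NULL
  }
  structure(list(views = views, clinical = clinical, sample_ids = universe),
            class = "multiomics_dataset")
}

# internal constructor skipping the binary-value scan (already validated)
omics_view_unchecked <- function(X, name, modality) {
  structure(list(name = name, modality = modality, X = X),
            class = "omics_view")
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat(sprintf("<multiomics_dataset> %d samples, %d views\n",
              length(x$sample_ids), length(x$views)))
  for (v in x$views)
    cat(sprintf("  %-10s %-10s %5d features, %.1f%% observed\n",
                v$name, v$modality, ncol(v$X), 100 * mean(!is.na(v$X))))
  if (!is.null(x$clinical))
    cat(sprintf("  clinical: %d rows, %d columns\n",
                nrow(x$clinical), ncol(x$clinical)))
  invisible(x)
}

#' Read a delimited omics matrix
#'
#' Reads TSV or CSV (auto-detected from the file extension) with a header
#' row and a leading id column. Empty cells and `"NA"` are treated as
#' missing. The orientation is normalised to samples x features.
#'
#' @param path file path; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @param features_in_rows set to `TRUE` when the file stores features in
#'   rows and samples in columns; the matrix is transposed on read.
#' @param name view label; defaults to the file stem.
#' @param modality `"continuous"` or `"binary"`.
#' @return an `omics_view`.
#' @export
read_matrix <- function(path, features_in_rows = FALSE,
                        name = sub("\\.[^.]*$", "", basename(path)),
                        modality = "continuous") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "")
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate ids in ", path, ": ", paste(unique(dup), collapse = ", "))
  body <- as.matrix(df[, -1, drop = FALSE])
  rownames(body) <- ids
  suppressWarnings(num <- array(as.numeric(body), dim = dim(body),
                                dimnames = dimnames(body)))
  bad <- which(!is.na(body) & body != "" & body != "NA" & is.na(num),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric cell at row '", rownames(body)[bad[1, 1]],
         "', column '", colnames(body)[bad[1, 2]], "' in ", path)
  if (features_in_rows) num <- t(num)
  omics_view(num, name = name, modality = modality)
}

#' Write an omics view as delimited text
#'
#' Round-trips with [read_matrix()]: samples in rows, feature header,
#' missing entries written as `NA`.
#'
#' @param view an `omics_view`.
#' @param path output path; `.csv` writes comma-separated, else tabs.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(view, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  # full-precision text so a write/read round-trip is bit-identical
  body <- array(sprintf("%.17g", view$X), dim = dim(view$X))
  body[is.na(view$X)] <- "NA"
  df <- data.frame(sample_id = rownames(view$X), body,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1] <- colnames(view$X)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Delimited text keyed by `sample_id`, with survival columns `time`
#' (follow-up, must be positive where present) and `event` (0/1).
#'
#' @param path file path (TSV, or CSV by extension).
#' @return a `data.frame`.
#' @export
read_clinical <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  cl <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(cl)) stop("clinical table needs 'sample_id'")
  if ("time" %in% names(cl) && any(cl$time <= 0, na.rm = TRUE))
    stop("clinical 'time' must be positive where present")
  if ("event" %in% names(cl) && !all(cl$event %in% c(0, 1, NA)))
    stop("clinical 'event' must be 0/1")
  cl
}

#' Write a clinical table
#' @param clinical data frame with `sample_id`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(clinical, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
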