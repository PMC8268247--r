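#' Construct a feature table
#'
#' A feature table holds a samples x metabolites intensity matrix together
#' with its identifiers and an explicit missing-value mask. Missing entries
#' are carried in the mask, never as sentinel numbers: after construction the
#' value matrix contains `NA` exactly where the mask is `TRUE`, and every
#' computational kernel declares how it treats the mask.
#'
#' @param values numeric matrix, samples as rows, metabolites as columns.
#'   `NA` entries are taken as missing.
#' @param sample_ids character vector of unique sample identifiers
#'   (default: rownames of `values`).
#' @param metabolite_ids character vector of unique metabolite identifiers
#'   (default: colnames of `values`).
#' @param missing_mask optional logical matrix of the same shape; if omitted
#'   it is derived from `is.na(values)`.
#' @return An object of class `feature_table` with fields `values`,
#'   `sample_ids`, `metabolite_ids`, `missing_mask`.
#' @export
feature_table <- function(values, sample_ids = rownames(values),
                          metabolite_ids = colnames(values),
                          missing_mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids))
    sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(metabolite_ids))
    metabolite_ids <- paste0("M", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  metabolite_ids <- as.character(metabolite_ids)
  if (length(sample_ids) != nrow(values))
    stop("length(sample_ids) must equal nrow(values)")
  if (length(metabolite_ids) != ncol(values))
    stop("length(metabolite_ids) must equal ncol(values)")
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  dup <- metabolite_ids[duplicated(metabolite_ids)]
  if (length(dup))
    stop("duplicate metabolite id(s): ", paste(unique(dup), collapse = ", "))
  if (is.null(missing_mask)) {
    missing_mask <- is.na(values)
  } else {
    missing_mask <- as.matrix(missing_mask)
    if (!identical(dim(missing_mask), dim(values)))
      stop("missing_mask shape must match values")
    storage.mode(missing_mask) <- "logical"
  }
  values[missing_mask] <- NA_real_
  dimnames(values) <- list(sample_ids, metabolite_ids)
  dimnames(missing_mask) <- dimnames(values)
  structure(list(values = values, sample_ids = sample_ids,
                 metabolite_ids = metabolite_ids,
                 missing_mask = missing_mask),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d metabolites (%d missing, %.1f%%)\n",
              nrow(x$values), ncol(x$values), sum(x$missing_mask),
              100 * mean(x$missing_mask)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Subset a feature table by sample and/or metabolite
#'
#' @param table a `feature_table`.
#' @param samples sample ids or row indices to keep (default all).
#' @param metabolites metabolite ids or column indices to keep (default all).
#' @return a `feature_table` restricted to the selection.
#' @export
subset_samples <- function(table, samples = NULL, metabolites = NULL) {
  stopifnot(inherits(table, "feature_table"))
  i <- if (is.null(samples)) seq_along(table$sample_ids)
       else if (is.character(samples)) match(samples, table$sample_ids)
       else samples
  j <- if (is.null(metabolites)) seq_along(table$metabolite_ids)
       else if (is.character(metabolites)) match(metabolites, table$metabolite_ids)
       else metabolites
  if (anyNA(i)) stop("unknown sample id(s)")
  if (anyNA(j)) stop("unknown metabolite id(s)")
  feature_table(table$values[i, j, drop = FALSE],
                table$sample_ids[i], table$metabolite_ids[j],
                table$missing_mask[i, j, drop = FALSE])
}

#' Read a feature table from a delimited file
#'
#' Expects sample ids in the first column and metabolite ids in the header
#' row. Blank cells and the string `"NA"` denote missing values; any other
#' non-numeric cell is an error (no silent coercion).
#'
#' @param path path to the CSV/TSV file.
#' @param sep field delimiter, `","` by default.
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           row.names = NULL, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("feature table needs an id column and >= 1 metabolite")
  sample_ids <- raw[[1]]
  met_ids <- colnames(raw)[-1]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  blank <- cells == "" | toupper(trimws(cells)) == "NA" | is.na(cells)
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(!blank & is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell at sample '%s', metabolite '%s': '%s'",
                 sample_ids[bad[1, 1]], met_ids[bad[1, 2]],
                 cells[bad[1, 1], bad[1, 2]]))
  num[blank] <- NA_real_
  feature_table(num, sample_ids, met_ids)
}

#' Write a feature table to a delimited file
#'
#' Missing entries are written as empty cells. Values are printed with full
#' double precision so a read/write round trip preserves them to printed
#' precision.
#'
#' @param table a `feature_table`.
#' @param path output path.
#' @param sep field delimiter.
#' @export
write_feature_table <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "feature_table"))
  vals <- table$values
  chr <- matrix(sprintf("%.17g", vals), nrow = nrow(vals))
  chr[table$missing_mask] <- ""
  df <- data.frame(sample_id = table$sample_ids, chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", table$metabolite_ids)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' The file must have columns `sample_id`, `role` and `outcome`. Roles are
#' one of `case`, `control`, `qc`; the outcome column must be empty for QC
#' samples and 0/1 for study samples (1 = case).
#'
#' @param path path to the metadata CSV.
#' @param sep field delimiter.
#' @return a `sample_meta` data frame with columns `sample_id`, `role`,
#'   `y` (NA for QC), and optionally `run_order`.
#' @export
read_sample_meta <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "role", "outcome")
  if (!all(need %in% colnames(raw)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  out <- trimws(raw$outcome)
  y <- suppressWarnings(as.numeric(out))
  y[out == ""] <- NA_real_
  ro <- if ("run_order" %in% colnames(raw))
    suppressWarnings(as.integer(raw$run_order)) else NA_integer_
  sample_meta(raw$sample_id, raw$role, y, ro)
}

#' Construct sample metadata
#'
#' @param sample_id character vector of unique sample ids.
#' @param role character vector, each `case`, `control` or `qc`.
#' @param y binary outcome (1 = case, 0 = control); must be `NA` for QC
#'   samples and present for study samples.
#' @param run_order optional integer acquisition order.
#' @return a data frame of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, role, y = NULL, run_order = NA_integer_) {
  sample_id <- as.character(sample_id)
  role <- as.character(role)
  bad <- setdiff(unique(role), c("case", "control", "qc"))
  if (length(bad))
    stop("unknown role(s): ", paste(bad, collapse = ", "))
  dup <- sample_id[duplicated(sample_id)]
  if (length(dup))
    stop("duplicate sample id(s) in metadata: ",
         paste(unique(dup), collapse = ", "))
  if (is.null(y))
    y <- ifelse(role == "case", 1, ifelse(role == "control", 0, NA_real_))
  y <- as.numeric(y)
  if (any(role == "qc" & !is.na(y)))
    stop("qc samples must not carry an outcome")
  miss <- role != "qc" & is.na(y)
  if (any(miss))
    stop("missing outcome for study sample(s): ",
         paste(sample_id[miss], collapse = ", "))
  cc <- role != "qc"
  if (any(!(y[cc] %in% c(0, 1))))
    stop("outcome must be 0/1 for study samples")
  if (any(role == "case" & y != 1, na.rm = TRUE) ||
      any(role == "control" & y != 0, na.rm = TRUE))
    stop("outcome inconsistent with role (case=1, control=0)")
  out <- data.frame(sample_id = sample_id, role = role, y = y,
                    run_order = as.integer(run_order),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_meta", "data.frame")
  out
}

#' Write sample metadata
#' @param meta a `sample_meta` data frame.
#' @param path output path.
#' @export
write_sample_meta <- function(meta, path) {
  df <- data.frame(sample_id = meta$sample_id, role = meta$role,
                   outcome = ifelse(is.na(meta$y), "", as.character(meta$y)),
                   run_order = ifelse(is.na(meta$run_order), "",
                                      as.character(meta$run_order)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Check that table and metadata describe the same cohort; returns meta
# reordered to match the table's rows.
align_meta <- function(table, meta) {
  stopifnot(inherits(table, "feature_table"))
  idx <- match(table$sample_ids, meta$sample_id)
  if (anyNA(idx))
    stop("sample(s) missing from metadata: ",
         paste(table$sample_ids[is.na(idx)], collapse = ", "))
  meta[idx, , drop = FALSE]
}

# Row indices of study (case/control) and qc samples, table order.
study_idx <- function(table, meta) {
  m <- align_meta(table, meta)
  which(m$role != "qc")
}
qc_idx <- function(table, meta) {
  m <- align_meta(table, meta)
  which(m$role == "qc")
}
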