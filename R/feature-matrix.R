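#' Per-platform feature matrix
#'
#' A light container for one analytical platform's sample-by-metabolite
#' intensity table. Intensities are strictly positive where observed; missing
#' cells are `NA`. Rows are samples (subject and QC), columns metabolites.
#'
#' @param platform platform name (e.g. `"polar"`, `"lipid"`, `"GC"`).
#' @param intensities numeric matrix, samples x features, with rownames
#'   (sample ids) and colnames (feature ids); `NA` marks a missing cell.
#' @param batch character/integer vector of per-sample batch labels.
#' @param is_qc logical vector flagging QC (pooled reference) samples.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(platform, intensities, batch, is_qc) {
  stopifnot(is.matrix(intensities), is.numeric(intensities))
  if (is.null(rownames(intensities)) || is.null(colnames(intensities))) {
    stop("intensities must carry sample ids (rownames) and feature ids (colnames)")
  }
  if (anyDuplicated(rownames(intensities))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(intensities)[duplicated(rownames(intensities))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(intensities))) {
    stop("duplicate feature ids: ",
         paste(unique(colnames(intensities)[duplicated(colnames(intensities))]), collapse = ", "))
  }
  obs <- intensities[!is.na(intensities)]
  if (length(obs) && any(obs <= 0)) stop("observed intensities must be strictly positive")
  if (length(batch) != nrow(intensities) || length(is_qc) != nrow(intensities)) {
    stop("batch and is_qc must have one entry per sample")
  }
  structure(
    list(platform = platform, intensities = intensities,
         batch = as.character(batch), is_qc = as.logical(is_qc)),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> platform=%s: %d samples (%d QC) x %d features, %.1f%% missing\n",
    x$platform, nrow(x$intensities), sum(x$is_qc), ncol(x$intensities),
    100 * mean(is.na(x$intensities))))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$intensities)

sample_ids <- function(fm) rownames(fm$intensities)
feature_ids <- function(fm) colnames(fm$intensities)

# Subject (non-QC) rows as a plain matrix.
subject_matrix <- function(fm) fm$intensities[!fm$is_qc, , drop = FALSE]

#' Read a feature table from TSV/CSV
#'
#' First column is the sample id; remaining columns are metabolite features.
#' Empty cells and `NA` are missing. The dialect (tab vs comma) is inferred
#' from the header line. Batch and QC annotations live in the sample metadata
#' table; supply them via `batch`/`is_qc` or join afterwards.
#'
#' @param path file path.
#' @param platform platform name to record.
#' @param batch optional per-sample batch labels (recycled lookup by sample id
#'   if named); defaults to a single batch.
#' @param is_qc optional logical per sample; defaults to detecting ids
#'   starting with `"QC"`.
#' @return a [feature_matrix()].
#' @export
read_feature_table <- function(path, platform = "platform", batch = NULL, is_qc = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", na.strings = c("", "NA"),
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2L) stop("feature table needs a sample-id column plus >= 1 feature")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    bad_lines <- which(ids %in% dup) + 1L
    stop("duplicate sample id(s) ", paste(dup, collapse = ", "),
         " at line(s) ", paste(bad_lines, collapse = ", "))
  }
  mat <- vapply(df[-1L], function(col) as.numeric(col), numeric(nrow(df)))
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = nrow(df), dimnames = list(NULL, names(df)[-1L]))
  rownames(mat) <- ids
  neg <- which(!is.na(mat) & mat <= 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop("nonpositive intensity at line ", neg[1, 1] + 1L,
         ", feature ", colnames(mat)[neg[1, 2]])
  }
  if (is.null(is_qc)) is_qc <- startsWith(ids, "QC")
  if (is.null(batch)) batch <- rep("1", nrow(mat))
  if (!is.null(names(batch))) batch <- unname(batch[ids])
  feature_matrix(platform, mat, batch, is_qc)
}

#' Write a feature table as TSV
#'
#' Missing cells are written as empty strings; round-trips through
#' [read_feature_table()] exactly for finite values (full double precision).
#'
#' @param fm a [feature_matrix()].
#' @param path output path.
#' @export
write_feature_table <- function(fm, path) {
  mat <- fm$intensities
  df <- data.frame(sample_id = rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[-1L][is.na(mat)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write the sample metadata table
#'
#' Columns: `sample_id`, `group` (LC/GC/CRC/NCD/HC), `stage`
#' (I/II/III/IV/unknown/not-applicable), `age`, `sex`, `cohort`
#' (discovery/validation), `batch`.
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "group", "stage", "age", "sex", "cohort", "batch")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  df$age <- as.numeric(df$age)
  bad <- df$group %in% c("NCD", "HC") & df$stage != "not-applicable"
  if (any(bad)) stop("stage must be not-applicable for NCD/HC samples: ",
                     paste(df$sample_id[bad][1:min(3, sum(bad))], collapse = ", "))
  df
}

#' @rdname read_sample_metadata
#' @param meta metadata data.frame.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
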