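#' Abundance tables
#'
#' Throughout the package an abundance table is an ordinary tibble with a
#' `sample_id` character column followed by one numeric column per feature
#' (MAG or KO).  Samples are rows, mirroring the samples-by-features
#' orientation of the factorised matrix.  These helpers convert between the
#' tibble form and the numeric matrix used internally.
#'
#' @param tbl A tibble with a `sample_id` column and numeric feature columns.
#' @return `as_abundance_matrix()` returns a numeric matrix with sample IDs
#'   as row names; `as_abundance_tibble()` the inverse.
#' @examples
#' tbl <- tibble::tibble(sample_id = c("s1", "s2"), f1 = c(1, 0), f2 = c(2, 3))
#' m <- as_abundance_matrix(tbl)
#' as_abundance_tibble(m)
#' @export
as_abundance_matrix <- function(tbl) {
  if (is.matrix(tbl)) {
    if (is.null(rownames(tbl))) {
      rownames(tbl) <- paste0("sample_", seq_len(nrow(tbl)))
    }
    return(tbl)
  }
  stopifnot(is.data.frame(tbl), "sample_id" %in% names(tbl))
  ids <- as.character(tbl$sample_id)
  if (anyDuplicated(ids)) stop("duplicate sample IDs: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(tbl[setdiff(names(tbl), "sample_id")])
  if (!is.numeric(m) && length(m) > 0) stop("feature columns must be numeric")
  if (!is.numeric(m)) storage.mode(m) <- "double"
  if (anyDuplicated(colnames(m))) stop("duplicate feature IDs")
  rownames(m) <- ids
  m
}

#' @rdname as_abundance_matrix
#' @param m A numeric samples-by-features matrix with row names.
#' @export
as_abundance_tibble <- function(m) {
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                   tibble::as_tibble(m))
}

check_nonnegative <- function(m, what = "abundance matrix") {
  if (any(!is.finite(m))) stop(what, " contains non-finite values")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(what, " has a negative entry at sample '", rownames(m)[bad[1]],
         "', feature '", colnames(m)[bad[2]], "'")
  }
  invisible(m)
}

#' Read or write an abundance table
#'
#' Reads a delimited samples-by-features table: first column sample IDs,
#' header row feature IDs.  The delimiter is chosen from the file
#' extension (`.csv` comma, anything else tab).  Validation rejects
#' negative entries and duplicated IDs, naming the offending cell.
#'
#' @param path File path.
#' @param kind Feature kind label, `"MAG"` or `"KO"`; stored as the
#'   `kind` attribute of the returned tibble.
#' @return A tibble with `sample_id` plus feature columns.
#' @export
read_abundance <- function(path, kind = c("MAG", "KO")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("input file not found: ", path)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  names(tbl)[1] <- "sample_id"
  tbl$sample_id <- as.character(tbl$sample_id)
  check_nonnegative(as_abundance_matrix(tbl))
  attr(tbl, "kind") <- kind
  tbl
}

#' @rdname read_abundance
#' @param tbl Abundance tibble to write.
#' @export
write_abundance <- function(tbl, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(tbl, path, delim = delim)
  invisible(path)
}
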