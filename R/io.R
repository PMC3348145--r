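# File formats: expression as TSV (genes in rows, first column
# gene_id, remaining columns = sample ids); clinical as TSV keyed by
# sample_id; per-nucleus measurements and profiles as CSV. Images as
# 8-bit grayscale PNG (TIFF readable when the tiff package is
# installed).

#' @rdname expression_io
#' @param path file path.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  m
}

#' Read and write expression matrices
#'
#' @name expression_io
#' @param matrix genes x samples numeric matrix with dimnames.
#' @export
write_expression_tsv <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix), matrix,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Expects a TSV with columns sample_id, response, os_months, os_event,
#' pfs_months, pfs_event and optionally age, stage, grade; fails fast
#' naming any missing required column.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_clinical_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "response", "os_months", "os_event",
            "pfs_months", "pfs_event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clinical table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Write an image as 8-bit grayscale PNG
#'
#' @param image matrix of intensities in \[0, 1\].
#' @param path output path (.png).
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' Read a grayscale or RGB image (PNG or TIFF)
#'
#' @param path file path; format chosen by extension.
#' @return matrix (grayscale) or 3-D array (RGB), intensities in
#'   \[0, 1\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return(png::readPNG(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the tiff package")
    return(tiff::readTIFF(path))
  }
  stop("unsupported image format: ", ext)
}
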