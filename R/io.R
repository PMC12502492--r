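#' Write a three-channel image as multi-page TIFF with a JSON sidecar
#'
#' One page per channel in the order DAPI, FITC, CY3; the channel order
#' and any ground truth travel in a JSON sidecar next to the image
#' (\code{<path>.json}).
#'
#' @param image rows x cols x 3 array in [0, 1].
#' @param path output .tif path.
#' @param truth optional \code{image_ground_truth} to serialize alongside.
#' @return \code{path}, invisibly.
#' @export
write_recap_tiff <- function(image, path, truth = NULL) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  pages <- lapply(1:3, function(ch) image[, , ch])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  side <- list(channels = c("dapi", "fitc", "cy3"))
  if (!is.null(truth)) {
    side$truth <- list(
      condition = truth$condition,
      pixel_size_um = truth$pixel_size_um,
      cyca2_positive_labels = truth$cyca2_positive_labels,
      foci_per_nucleus = as.list(truth$foci_per_nucleus)
    )
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF written by \code{\link{write_recap_tiff}}
#'
#' @param path .tif path; the JSON sidecar, when present, provides the
#'   channel order (default dapi, fitc, cy3).
#' @param n_channels expected channel count.
#' @return rows x cols x channels array with channel dimnames.
#' @export
read_recap_tiff <- function(path, n_channels = 3) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != n_channels) {
    stop("expected ", n_channels, " channel pages in ", path,
         ", found ", length(pages))
  }
  channels <- c("dapi", "fitc", "cy3")[seq_len(n_channels)]
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$channels)) channels <- side$channels
  }
  img <- array(0, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)),
               dimnames = list(NULL, NULL, channels))
  for (i in seq_along(pages)) img[, , i] <- pages[[i]]
  img
}

#' Write / read a focus table as CSV
#'
#' Strict schema: model, condition, organoid, nucleus, cyca2_positive,
#' focus_count. Reading validates the header and column types and names
#' the offending line on failure; write-then-read is the identity on the
#' table's values.
#'
#' @param foci_table the table to write.
#' @param path CSV path.
#' @return \code{path} (write) or the validated data.frame (read).
#' @export
write_foci_csv <- function(foci_table, path) {
  need <- c("model", "condition", "organoid", "nucleus", "cyca2_positive",
            "focus_count")
  stopifnot(all(need %in% names(foci_table)))
  write.csv(foci_table[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_foci_csv
#' @export
read_foci_csv <- function(path) {
  need <- c("model", "condition", "organoid", "nucleus", "cyca2_positive",
            "focus_count")
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("malformed focus CSV ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  bad <- which(!is.finite(df$focus_count) | df$focus_count < 0)
  if (length(bad)) {
    stop("malformed focus CSV ", path, ": invalid focus_count at data line ",
         bad[1])
  }
  df$cyca2_positive <- as.logical(df$cyca2_positive)
  df
}

#' Write a pipeline report bundle
#'
#' Serializes the report list to pretty JSON (tables are kept as
#' data.frames and written as arrays of records).
#'
#' @param report named list from \code{\link{run_full}}.
#' @param path output .json path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows", force = TRUE)
  invisible(path)
}
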