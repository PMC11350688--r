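# ESRI ASCII grid (.asc) reader/writer for suitability and layer rasters.
# Header: ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value; data
# rows run north to south. Stored internally as a matrix with row 1 = the
# northernmost row, plus the metadata needed to round-trip.

#' Read an ESRI ASCII grid
#'
#' @param path path to a `.asc` file.
#' @return numeric matrix (row 1 = northern row, `NA` for nodata) with
#'   attributes `xllcorner`, `yllcorner`, `cellsize`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && is.na(suppressWarnings(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  for (k in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[k]])) stop("ASCII grid header missing ", k)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[-seq_len(i)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop(sprintf("ASCII grid has %d values, expected %d x %d",
                 length(vals), hdr$nrows, hdr$ncols))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  attr(m, "xllcorner") <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  attr(m, "yllcorner") <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  attr(m, "cellsize") <- hdr$cellsize
  m
}

#' Write an ESRI ASCII grid
#'
#' @param m numeric matrix (row 1 = northern row; `NA` written as the
#'   nodata value) or a [suitability_grid()].
#' @param path output path.
#' @param cellsize cell edge length (default 1).
#' @param xllcorner,yllcorner lower-left corner coordinates.
#' @param nodata nodata sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(m, path, cellsize = 1, xllcorner = 0,
                             yllcorner = 0, nodata = -9999) {
  if (inherits(m, "suitability_grid")) {
    xllcorner <- m$xll; yllcorner <- m$yll
    m <- m$index
  }
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", xllcorner),
           sprintf("yllcorner %.10g", yllcorner),
           sprintf("cellsize %.10g", cellsize),
           sprintf("NODATA_value %.10g", nodata))
  m[is.na(m)] <- nodata
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
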