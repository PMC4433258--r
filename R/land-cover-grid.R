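#' Categorical land-cover grid
#'
#' A light container for a rectangular raster of integer land-cover codes,
#' together with the set of codes that count as forest habitat and an optional
#' nodata code. This is the input object of [compute_pfc()], [compute_rlps()]
#' and [metrics_table()].
#'
#' @param values integer matrix of category codes (rows = raster rows).
#' @param pixel_size length of a pixel edge, in the same units as the cell
#'   tessellation used later (default 1).
#' @param forest_codes non-empty vector of codes classified as forest habitat.
#' @param nodata_code optional single code marking missing pixels, or `NA` for
#'   none. Must not appear in `forest_codes`.
#'
#' @return An object of class `land_cover_grid`.
#' @examples
#' m <- matrix(c(1, 1, 0, 0, 1, 0, 0, 0, 1), 3, 3)
#' g <- land_cover_grid(m, forest_codes = 1)
#' compute_pfc(g)
#' @export
land_cover_grid <- function(values, pixel_size = 1, forest_codes = 1L,
                            nodata_code = NA) {
  if (!is.matrix(values) || nrow(values) < 1L || ncol(values) < 1L)
    stop("'values' must be a non-empty matrix of category codes")
  if (length(forest_codes) < 1L)
    stop("'forest_codes' must be non-empty")
  if (!is.na(nodata_code) && nodata_code %in% forest_codes)
    stop("'nodata_code' must be disjoint from 'forest_codes'")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number")
  structure(
    list(values = values, pixel_size = pixel_size,
         forest_codes = forest_codes, nodata_code = nodata_code),
    class = "land_cover_grid"
  )
}

#' @export
print.land_cover_grid <- function(x, ...) {
  v <- x$values
  valid <- .valid_mask(x)
  fo <- .forest_mask(x)
  cat("Land-cover grid: ", nrow(v), " x ", ncol(v), " pixels (pixel size ",
      x$pixel_size, ")\n", sep = "")
  cat("  forest codes: ", paste(x$forest_codes, collapse = ", "),
      if (!is.na(x$nodata_code)) paste0("; nodata code: ", x$nodata_code),
      "\n", sep = "")
  cat(sprintf("  forest pixels: %d / %d valid (%.1f%%)\n",
              sum(fo), sum(valid), 100 * sum(fo) / max(sum(valid), 1L)))
  invisible(x)
}

# logical masks shared by the metric functions
.valid_mask <- function(grid) {
  if (is.na(grid$nodata_code)) {
    matrix(TRUE, nrow(grid$values), ncol(grid$values))
  } else {
    grid$values != grid$nodata_code
  }
}

.forest_mask <- function(grid) {
  matrix(grid$values %in% grid$forest_codes,
         nrow(grid$values), ncol(grid$values))
}

#' Read an Esri ASCII grid into a land-cover grid
#'
#' Parses the plain-text `.asc` raster format (header lines `ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize` and optional `NODATA_value`, followed
#' by rows of codes). Only the pixel matrix, cell size and nodata code are
#' used; corner coordinates are ignored because all downstream computations
#' work in pixel/cell space.
#'
#' @param path file path of the ASCII grid.
#' @inheritParams land_cover_grid
#' @return A [land_cover_grid()].
#' @export
read_ascii_grid <- function(path, forest_codes = 1L) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) stop("not an Esri ASCII grid: too few lines")
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (key in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[key]])) stop("ASCII grid header missing '", key, "'")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (is.null(hdr$nodata_value)) NA else hdr$nodata_value
  land_cover_grid(m, pixel_size = hdr$cellsize,
                  forest_codes = forest_codes, nodata_code = nodata)
}

#' Write a land-cover grid as an Esri ASCII grid
#'
#' @param grid a [land_cover_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  v <- grid$values
  nodata <- if (is.na(grid$nodata_code)) -9999 else grid$nodata_code
  hdr <- c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    "xllcorner 0",
    "yllcorner 0",
    paste("cellsize", grid$pixel_size),
    paste("NODATA_value", nodata)
  )
  body <- apply(v, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
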