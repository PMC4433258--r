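#' Label connected forest patches
#'
#' Connected-component labelling of the forest pixels of a grid window under
#' rook (4-neighbour) or queen (8-neighbour) adjacency. Patches are confined
#' to the window: nothing outside the supplied matrix can join a patch.
#'
#' @param mask logical matrix, `TRUE` where pixels are forest.
#' @param connectivity 4 or 8 (default 8: diagonal neighbours touch).
#' @return Integer matrix of the same shape; 0 for non-forest pixels, patch
#'   labels 1..k elsewhere. Labels are assigned in column-major scan order.
#' @export
label_patches <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), is.logical(mask))
  connectivity <- match.arg(as.character(connectivity), c("8", "4"))
  nr <- nrow(mask); nc <- ncol(mask)
  if (connectivity == "4") {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  }
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    # breadth-first expansion, whole frontier at once
    while (length(frontier)) {
      r <- ((frontier - 1L) %% nr) + 1L
      co <- ((frontier - 1L) %/% nr) + 1L
      nbr <- rep(r, each = length(dr)) + dr
      nbc <- rep(co, each = length(dc)) + dc
      ok <- nbr >= 1L & nbr <= nr & nbc >= 1L & nbc <= nc
      nb <- (nbc[ok] - 1L) * nr + nbr[ok]
      nb <- unique(nb[mask[nb] & lab[nb] == 0L])
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

#' Percentage forest cover of a grid window
#'
#' The share of a window's valid (non-nodata) pixels classified as forest,
#' in percent. This is the habitat-amount variable PFC.
#'
#' @param grid a [land_cover_grid()] (typically one cell's window).
#' @return A percentage in \[0, 100\].
#' @export
compute_pfc <- function(grid) {
  stopifnot(inherits(grid, "land_cover_grid"))
  valid <- .valid_mask(grid)
  n_valid <- sum(valid)
  if (n_valid == 0L) stop("no valid pixels in window")
  100 * sum(.forest_mask(grid) & valid) / n_valid
}

#' Relative largest patch size of a grid window
#'
#' The percentage of a window's forest area contained in its single largest
#' connected forest patch (rLPS): the fragmentation variable. 100 means all
#' forest sits in one patch (no fragmentation); values near 0 mean the forest
#' is shattered into many small patches. Undefined (`NA`) when the window has
#' no forest at all, because a share of nothing is meaningless; it is never
#' coerced to 0 or 100 here.
#'
#' @inheritParams compute_pfc
#' @param connectivity 4 or 8 (default 8, queen adjacency).
#' @return A percentage in (0, 100\], or `NA_real_` when the window holds no
#'   forest pixel.
#' @export
compute_rlps <- function(grid, connectivity = 8) {
  stopifnot(inherits(grid, "land_cover_grid"))
  valid <- .valid_mask(grid)
  if (sum(valid) == 0L) stop("no valid pixels in window")
  forest <- .forest_mask(grid) & valid
  n_forest <- sum(forest)
  if (n_forest == 0L) return(NA_real_)
  lab <- label_patches(forest, connectivity)
  100 * max(tabulate(lab[lab > 0L])) / n_forest
}

#' Per-cell forest metrics over a square tessellation
#'
#' Splits a land-cover raster into equal square cells and computes PFC and
#' rLPS for every cell. Patches are clipped at cell boundaries: a patch that
#' spans two cells contributes to each cell separately.
#'
#' @inheritParams compute_rlps
#' @param cell_size edge length of a tessellation cell, in the same units as
#'   `grid$pixel_size`; must be an integer multiple of the pixel edge, and the
#'   raster dimensions must be whole numbers of cells.
#' @param min_valid_fraction optional lower bound on the fraction of a cell's
#'   pixels that are valid (non-nodata); cells below it are dropped, which
#'   reproduces coastal/edge-cell exclusion rules generically. Default 0
#'   (keep all cells with at least one valid pixel).
#' @return A data frame with one row per cell, ordered by `cell_id`:
#'   `cell_id`, `pfc`, `rlps` (`NA` for forest-free cells),
#'   `n_forest_pixels`, `n_valid_pixels`.
#' @examples
#' g <- land_cover_grid(matrix(rbinom(400, 1, 0.4), 20, 20), forest_codes = 1)
#' head(metrics_table(g, cell_size = 10))
#' @export
metrics_table <- function(grid, cell_size, connectivity = 8,
                          min_valid_fraction = 0) {
  stopifnot(inherits(grid, "land_cover_grid"))
  px <- cell_size / grid$pixel_size
  if (abs(px - round(px)) > 1e-9)
    stop("cell edge must be an integer multiple of the pixel edge")
  px <- as.integer(round(px))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  if (nr %% px != 0L || nc %% px != 0L)
    stop("tessellation misaligned: raster is ", nr, "x", nc,
         " pixels, not a whole number of ", px, "-pixel cells")
  n_cr <- nr %/% px; n_cc <- nc %/% px
  rows <- vector("list", n_cr * n_cc)
  k <- 0L
  for (i in seq_len(n_cr)) {
    for (j in seq_len(n_cc)) {
      k <- k + 1L
      win <- grid$values[((i - 1L) * px + 1L):(i * px),
                         ((j - 1L) * px + 1L):(j * px), drop = FALSE]
      wgrid <- land_cover_grid(win, pixel_size = grid$pixel_size,
                               forest_codes = grid$forest_codes,
                               nodata_code = grid$nodata_code)
      valid <- .valid_mask(wgrid)
      n_valid <- sum(valid)
      if (n_valid == 0L || n_valid / length(win) < min_valid_fraction) next
      forest <- .forest_mask(wgrid) & valid
      n_forest <- sum(forest)
      rlps <- if (n_forest == 0L) NA_real_ else {
        lab <- label_patches(forest, connectivity)
        100 * max(tabulate(lab[lab > 0L])) / n_forest
      }
      rows[[k]] <- data.frame(
        cell_id = sprintf("r%03dc%03d", i, j),
        pfc = 100 * n_forest / n_valid,
        rlps = rlps,
        n_forest_pixels = n_forest,
        n_valid_pixels = n_valid,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(cell_id = character(), pfc = numeric(),
                      rlps = numeric(), n_forest_pixels = integer(),
                      n_valid_pixels = integer())
  out <- out[order(out$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a cell-metrics table
#'
#' Plain CSV round trip for the output of [metrics_table()]; an undefined
#' rLPS is serialized as an empty field.
#'
#' @param metrics data frame from [metrics_table()] or
#'   [generate_cell_table()].
#' @param path file path.
#' @return `write_metrics_table()` returns `path` invisibly;
#'   `read_metrics_table()` returns the data frame.
#' @export
write_metrics_table <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("cell_id", "pfc", "rlps")
  if (!all(needed %in% names(out)))
    stop("metrics table must have columns: ", paste(needed, collapse = ", "))
  out$rlps <- as.numeric(out$rlps)
  out
}
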