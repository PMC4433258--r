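#' Select cells on the lower edge of the PFC-rLPS cloud
#'
#' The joint distribution of forest cover and fragmentation is funnel shaped:
#' unfragmented cells (rLPS near 100) occur at every cover, while the minimum
#' rLPS attainable drops as cover contracts. The maximum-fragmentation
#' envelope is estimated from the cells that trace the lower edge of this
#' cloud. The pfc axis is partitioned into `n_bins` equal-width bins over the
#' observed range; in each bin the `ceiling(n_edge / n_bins)` cells of
#' smallest rLPS are taken (ties broken by `cell_id`), and the selection is
#' trimmed back to exactly `n_edge` by dropping its highest-rlps members, so
#' the edge set spans the whole cover gradient.
#'
#' @param cells data frame with columns `cell_id`, `pfc`, `rlps` (forest-free
#'   cells with undefined rLPS are ignored).
#' @param n_edge number of edge cells to select (default 100).
#' @param n_bins number of pfc bins (default 25).
#' @return The selected rows of `cells`, ordered by pfc then cell_id.
#' @export
select_lower_edge_cells <- function(cells, n_edge = 100, n_bins = 25) {
  stopifnot(all(c("cell_id", "pfc", "rlps") %in% names(cells)))
  cells <- cells[!is.na(cells$rlps) & cells$pfc > 0, , drop = FALSE]
  if (nrow(cells) == 0L) stop("no forest-bearing cells to select from")
  # identical (pfc, rlps) points are one candidate: a duplicated table
  # selects the same edge as the original
  cells <- cells[order(cells$cell_id), , drop = FALSE]
  cells <- cells[!duplicated(paste(cells$pfc, cells$rlps)), , drop = FALSE]
  if (nrow(cells) <= n_edge) {
    warning("only ", nrow(cells), " forest-bearing cells available; ",
            "using all of them")
    out <- cells[order(cells$pfc, cells$cell_id), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  rng <- range(cells$pfc)
  # degenerate range: all cells in one bin
  if (diff(rng) == 0) {
    bins <- rep(1L, nrow(cells))
    n_bins <- 1L
  } else {
    bins <- findInterval(cells$pfc,
                         seq(rng[1], rng[2], length.out = n_bins + 1L),
                         rightmost.closed = TRUE, all.inside = TRUE)
  }
  per_bin <- ceiling(n_edge / n_bins)
  picked <- unlist(lapply(split(seq_len(nrow(cells)), bins), function(i) {
    o <- i[order(cells$rlps[i], cells$cell_id[i])]
    o[seq_len(min(per_bin, length(o)))]
  }), use.names = FALSE)
  if (length(picked) > n_edge) {
    # trim the highest-rlps selections so exactly n_edge remain
    o <- picked[order(cells$rlps[picked], cells$cell_id[picked])]
    picked <- o[seq_len(n_edge)]
  } else if (length(picked) < n_edge) {
    # sparse bins under-filled: top up with the lowest-rlps remaining cells
    rest <- setdiff(seq_len(nrow(cells)), picked)
    rest <- rest[order(cells$rlps[rest], cells$cell_id[rest])]
    picked <- c(picked, rest[seq_len(n_edge - length(picked))])
  }
  out <- cells[picked, , drop = FALSE]
  out <- out[order(out$pfc, out$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the maximum-fragmentation envelope
#'
#' Least-squares fourth-order polynomial regression of rLPS on PFC over the
#' lower-edge cells. The fitted curve approximates the strongest
#' fragmentation empirically observed at each forest cover.
#'
#' @param edge_cells data frame of edge cells (from
#'   [select_lower_edge_cells()]); needs >= 6 rows and >= 5 distinct pfc
#'   values.
#' @param degree polynomial degree (default 4).
#' @return An object of class `envelope_model`: `coefficients` (ascending
#'   powers, length `degree + 1`), `pfc_domain` (range of edge pfc),
#'   `edge_cell_ids`, `residual_sd`.
#' @export
fit_envelope <- function(edge_cells, degree = 4) {
  stopifnot(all(c("pfc", "rlps") %in% names(edge_cells)))
  if (nrow(edge_cells) < degree + 2L)
    stop("need at least ", degree + 2L, " edge cells")
  if (length(unique(edge_cells$pfc)) < degree + 1L)
    stop("rank deficiency: need at least ", degree + 1L,
         " distinct pfc values for a degree-", degree, " polynomial")
  fit <- stats::lm(rlps ~ poly(pfc, degree, raw = TRUE), data = edge_cells)
  structure(
    list(coefficients = unname(stats::coef(fit)),
         degree = degree,
         pfc_domain = range(edge_cells$pfc),
         edge_cell_ids = edge_cells$cell_id,
         residual_sd = stats::sigma(fit)),
    class = "envelope_model"
  )
}

#' @export
print.envelope_model <- function(x, ...) {
  cat("Maximum-fragmentation envelope: degree-", x$degree,
      " polynomial of rLPS on PFC\n", sep = "")
  cat("  coefficients (ascending powers):",
      paste(signif(x$coefficients, 4), collapse = ", "), "\n")
  cat(sprintf("  pfc domain [%.1f, %.1f], residual SD %.2f, %d edge cells\n",
              x$pfc_domain[1], x$pfc_domain[2], x$residual_sd,
              length(x$edge_cell_ids)))
  invisible(x)
}

#' Maximum-fragmentation rLPS at given forest covers
#'
#' Evaluates the envelope polynomial at the requested pfc levels and clamps
#' the result to (0, 100]: predictions are floored at `clamp_floor` (a
#' forest-bearing cell cannot have rLPS of 0) and capped at 100. Levels
#' outside the fitted pfc domain are evaluated with a warning.
#'
#' @param model an `envelope_model`.
#' @param pfc_levels forest-cover percentages to evaluate.
#' @param clamp_floor lower clamp for predictions (default 1).
#' @return rLPS percentages, full precision (round only for display).
#' @export
max_fragmentation_rlps <- function(model, pfc_levels, clamp_floor = 1) {
  stopifnot(inherits(model, "envelope_model"))
  outside <- pfc_levels < model$pfc_domain[1] | pfc_levels > model$pfc_domain[2]
  if (any(outside))
    warning("extrapolating envelope beyond its pfc domain at: ",
            paste(pfc_levels[outside], collapse = ", "))
  powers <- outer(pfc_levels, 0:model$degree, `^`)
  pred <- as.numeric(powers %*% model$coefficients)
  pmin(pmax(pred, clamp_floor), 100)
}

#' Paired evaluation grids for the two fragmentation scenarios
#'
#' Builds the matched (PFC, rLPS) evaluation points: one series at maximum
#' fragmentation (rLPS from the envelope) and one at zero fragmentation
#' (rLPS = 100 throughout).
#'
#' @param pfc_levels forest-cover levels, iterated from high toward low.
#' @param rlps_max envelope rLPS values matching `pfc_levels`.
#' @return An object of class `scenario_grid` with fields `pfc_levels`,
#'   `rlps_max`, `rlps_none`.
#' @export
scenario_grids <- function(pfc_levels, rlps_max) {
  if (length(pfc_levels) != length(rlps_max))
    stop("pfc_levels and rlps_max lengths differ")
  structure(
    list(pfc_levels = pfc_levels, rlps_max = rlps_max,
         rlps_none = rep(100, length(pfc_levels))),
    class = "scenario_grid"
  )
}

#' The published nine-level scenario grid
#'
#' The frozen evaluation grid used in the original Peninsular Spain analysis:
#' nine forest covers of 85, 75, 65, 55, 45, 35, 25, 15 and 5 percent paired
#' with maximum-fragmentation rLPS values of 90, 60, 40, 26, 20, 16, 14, 10
#' and 5 percent (the envelope read at those covers), and rLPS = 100 for the
#' zero-fragmentation scenario. Shipping this configuration lets the
#' published scenarios run without the original land-cover data.
#'
#' @return A [scenario_grids()] object.
#' @examples
#' g <- published_scenario_grid()
#' cbind(g$pfc_levels, g$rlps_max)[1:3, ]
#' @export
published_scenario_grid <- function() {
  scenario_grids(
    pfc_levels = c(85, 75, 65, 55, 45, 35, 25, 15, 5),
    rlps_max = c(90, 60, 40, 26, 20, 16, 14, 10, 5)
  )
}

#' @export
print.scenario_grid <- function(x, ...) {
  cat("Scenario grid over", length(x$pfc_levels), "forest-cover levels\n")
  print(data.frame(pfc = x$pfc_levels, rlps_max_frag = x$rlps_max,
                   rlps_zero_frag = x$rlps_none))
  invisible(x)
}
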