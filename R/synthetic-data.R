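#' Specification for a neutral forest landscape
#'
#' Parameters of the synthetic binary-raster generator: a tessellation of
#' `grid_shape` cells of `pixels_per_cell` x `pixels_per_cell` pixels each
#' (the defaults mirror 10-km cells of 100-m pixels), a target forest cover
#' and a spatial aggregation scale. Aggregation 0 gives salt-and-pepper
#' forest (maximal fragmentation at a given cover); larger values clump the
#' forest into fewer, larger patches.
#'
#' @param grid_shape integer c(rows, cols) of tessellation cells.
#' @param pixels_per_cell pixels along one cell edge.
#' @param target_cover landscape forest cover, percent in \[0, 100\].
#' @param aggregation Gaussian smoothing scale in pixels (>= 0).
#' @param seed integer seed.
#' @return An object of class `landscape_spec`.
#' @export
landscape_spec <- function(grid_shape = c(10, 10), pixels_per_cell = 100,
                           target_cover = 30, aggregation = 5, seed = 1) {
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 1L),
            pixels_per_cell >= 1L, target_cover >= 0, target_cover <= 100,
            aggregation >= 0)
  structure(list(grid_shape = as.integer(grid_shape),
                 pixels_per_cell = as.integer(pixels_per_cell),
                 target_cover = target_cover, aggregation = aggregation,
                 seed = seed),
            class = "landscape_spec")
}

# separable Gaussian blur with edge replication, used to aggregate noise
.gauss_blur <- function(m, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k <- k / sum(k)
  blur_cols <- function(mm) {
    padded <- rbind(mm[rep(1L, r), , drop = FALSE], mm,
                    mm[rep(nrow(mm), r), , drop = FALSE])
    f <- stats::filter(padded, k, sides = 2)
    matrix(as.numeric(f), nrow(padded), ncol(padded))[(r + 1L):(r + nrow(mm)),
                                                      , drop = FALSE]
  }
  t(blur_cols(t(blur_cols(m))))
}

#' Generate a neutral binary forest raster
#'
#' Thresholds spatially smoothed Gaussian noise at the rank matching the
#' target cover, so the realized forest fraction equals the target up to
#' pixel rounding. Deterministic given the spec's seed.
#'
#' @param spec a [landscape_spec()].
#' @return A [land_cover_grid()] with codes 0 (non-forest) and 1 (forest),
#'   `forest_codes = 1`.
#' @export
generate_raster <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  nr <- spec$grid_shape[1] * spec$pixels_per_cell
  nc <- spec$grid_shape[2] * spec$pixels_per_cell
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(spec$seed %% .Machine$integer.max))
  noise <- matrix(stats::rnorm(nr * nc), nr, nc)
  field <- if (spec$aggregation > 0) .gauss_blur(noise, spec$aggregation)
           else noise
  n_forest <- round(spec$target_cover / 100 * nr * nc)
  forest <- matrix(0L, nr, nc)
  if (n_forest > 0)
    forest[order(field, decreasing = TRUE)[seq_len(n_forest)]] <- 1L
  land_cover_grid(forest, pixel_size = 1, forest_codes = 1L)
}

#' Funnel parameters for the synthetic PFC-rLPS cloud
#'
#' The lower rLPS envelope of the synthetic cell table is a logistic-shaped
#' curve anchored at `floor` as cover vanishes and rising to 100 at full
#' cover; `rate` controls how late the rise happens. The observed joint
#' cloud then has the funnel structure of real landscapes: unfragmented
#' cells at every cover, with room for strong fragmentation opening up as
#' cover contracts.
#'
#' @param floor minimum attainable rLPS as pfc approaches 0 (percent).
#' @param rate approach-to-100 rate (per percent cover).
#' @return A named list with `floor` and `rate`.
#' @export
funnel_params <- function(floor = 5, rate = 0.05) {
  stopifnot(floor > 0, floor <= 100, rate >= 0)
  list(floor = floor, rate = rate)
}

#' Lower rLPS envelope of the synthetic funnel
#'
#' @param pfc cover percentage(s).
#' @param params a [funnel_params()] list.
#' @return Envelope rLPS value(s) in \[`params$floor`, 100\].
#' @export
funnel_envelope <- function(pfc, params = funnel_params()) {
  if (params$rate == 0) return(rep(params$floor, length(pfc)))
  base <- stats::plogis(-params$rate * 100)
  frac <- (stats::plogis(params$rate * (pfc - 100)) - base) / (0.5 - base)
  params$floor + (100 - params$floor) * frac
}

#' Generate a synthetic per-cell metrics table
#'
#' Draws forest cover per cell from a right-skewed distribution on (0, 100]
#' and fragmentation uniformly between the funnel's lower envelope and 100,
#' together with consistent pixel counts, emulating the joint PFC-rLPS
#' distribution of a real gridded landscape without any raster work.
#'
#' @param n_cells number of cells (default 5279, the size of a 10-km national
#'   study grid).
#' @param params funnel envelope parameters, see [funnel_params()].
#' @param seed integer seed.
#' @param pfc_shape two Beta shape parameters for cover/100 (defaults give a
#'   right-skewed cover distribution with mean about 28%).
#' @param n_valid_pixels valid pixels per cell (default 10000 = 100 x 100).
#' @return A metrics data frame (`cell_id`, `pfc`, `rlps`,
#'   `n_forest_pixels`, `n_valid_pixels`) satisfying the cell-metrics
#'   invariants.
#' @export
generate_cell_table <- function(n_cells = 5279, params = funnel_params(),
                                seed = 1, pfc_shape = c(1.1, 2.8),
                                n_valid_pixels = 10000L) {
  stopifnot(n_cells >= 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  pfc_raw <- 100 * stats::rbeta(n_cells, pfc_shape[1], pfc_shape[2])
  n_forest <- pmax(1L, as.integer(round(pfc_raw / 100 * n_valid_pixels)))
  pfc <- 100 * n_forest / n_valid_pixels
  env <- pmin(funnel_envelope(pfc, params), 100)
  rlps <- stats::runif(n_cells, env, 100)
  rlps <- pmax(rlps, 100 / n_forest)  # largest patch holds >= 1 pixel
  data.frame(
    cell_id = sprintf("s%05d", seq_len(n_cells)),
    pfc = pfc, rlps = rlps,
    n_forest_pixels = n_forest,
    n_valid_pixels = as.integer(n_valid_pixels),
    stringsAsFactors = FALSE
  )
}

#' Define a virtual species
#'
#' A species whose occurrence is governed by known logistic coefficients on
#' PFC and rLPS, used to generate datasets with known truth.
#'
#' @param name species label.
#' @param group `"herb"` or `"fern"`.
#' @param beta0,beta1,beta2 true intercept and slopes of PFC and rLPS.
#' @param range_cells cell ids of the species' native range; `NULL` means
#'   all cells offered at generation time.
#' @param seed integer seed for the occurrence draw.
#' @return An object of class `virtual_species`.
#' @export
virtual_species <- function(name, group = c("herb", "fern"),
                            beta0 = -3, beta1 = 0.05, beta2 = 0.02,
                            range_cells = NULL, seed = 1) {
  group <- match.arg(group)
  stopifnot(is.finite(beta0), is.finite(beta1), is.finite(beta2))
  structure(list(name = name, group = group, beta0 = beta0, beta1 = beta1,
                 beta2 = beta2, range_cells = range_cells, seed = seed),
            class = "virtual_species")
}

#' Draw occurrences for a virtual species
#'
#' Independent Bernoulli occurrence per cell with probability given by the
#' species' logistic coefficients; restricted to the species' range cells.
#' Deterministic given the species' seed.
#'
#' @param species a [virtual_species()].
#' @param cells metrics data frame (`cell_id`, `pfc`, `rlps`).
#' @param zero_forest_policy passed to [species_dataset()].
#' @return A [species_dataset()].
#' @export
generate_occurrences <- function(species, cells,
                                 zero_forest_policy = c("drop",
                                                        "impute-zero")) {
  stopifnot(inherits(species, "virtual_species"))
  if (!is.null(species$range_cells)) {
    cells <- cells[cells$cell_id %in% species$range_cells, , drop = FALSE]
    if (nrow(cells) == 0L) stop("range_cells match no cells")
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(species$seed %% .Machine$integer.max))
  p <- stats::plogis(species$beta0 + species$beta1 * cells$pfc +
                       species$beta2 * ifelse(is.na(cells$rlps), 0,
                                              cells$rlps))
  occ <- stats::rbinom(nrow(cells), 1L, p)
  species_dataset(
    species_name = species$name, group = species$group,
    cells = data.frame(cell_id = cells$cell_id, pfc = cells$pfc,
                       rlps = cells$rlps, occurrence = occ,
                       stringsAsFactors = FALSE),
    zero_forest_policy = match.arg(zero_forest_policy)
  )
}

# shared prevalence check
enforce_prevalence_value <- function(prevalence, low = 0.15, high = 0.70) {
  if (!(prevalence > low))
    list(pass = FALSE,
         reason = sprintf("prevalence %.3f not strictly above %.2f",
                          prevalence, low))
  else if (!(prevalence < high))
    list(pass = FALSE,
         reason = sprintf("prevalence %.3f not strictly below %.2f",
                          prevalence, high))
  else list(pass = TRUE, reason = NA_character_)
}

#' Prevalence inclusion filter
#'
#' A species enters the analysis only when it is neither under- nor
#' over-represented in its native range: prevalence strictly above `low` and
#' strictly below `high` (boundary values fail).
#'
#' @param dataset a [species_dataset()], or a bare prevalence proportion.
#' @param low,high strict bounds (defaults 0.15 and 0.70).
#' @return A list with `pass`, `prevalence` and `reason` (`NA` on pass).
#' @examples
#' enforce_prevalence(0.534)$pass   # TRUE
#' enforce_prevalence(0.15)$pass    # FALSE: boundary is excluded
#' @export
enforce_prevalence <- function(dataset, low = 0.15, high = 0.70) {
  prevalence <- if (inherits(dataset, "species_dataset")) dataset$prevalence
                else as.numeric(dataset)
  out <- enforce_prevalence_value(prevalence, low, high)
  c(list(prevalence = prevalence), out)
}

#' Simulate a full study community
#'
#' One-call generator of everything the pipeline consumes: a funnel-shaped
#' cell table and a set of virtual herb and fern species with known
#' coefficients spanning negative, null and positive fragmentation
#' responses. Sub-seeds for the species draws are derived from the top-level
#' seed as `seed + 7919 * i`.
#'
#' @param n_cells number of grid cells (default 5279).
#' @param seed top-level integer seed.
#' @param species_params data frame with columns `name`, `group`, `beta0`,
#'   `beta1`, `beta2`; defaults to a nine-species community (five herbs,
#'   four ferns) whose rLPS responses span both signs and zero.
#' @param params funnel parameters for the cell table.
#' @return A list with `cells` (metrics data frame), `species` (list of
#'   [species_dataset()]), and `truth` (the species parameter table).
#' @export
simulate_community <- function(n_cells = 5279, seed = 1,
                               species_params = NULL,
                               params = funnel_params()) {
  if (is.null(species_params)) {
    species_params <- data.frame(
      name = c("herb_negfrag", "herb_null1", "herb_null2", "herb_posfrag",
               "herb_pos2", "fern_negfrag", "fern_pos1", "fern_pos2",
               "fern_null"),
      group = c(rep("herb", 5), rep("fern", 4)),
      beta0 = c(-3.5, -2.5, -2.0, -3.0, -2.8, -3.2, -2.6, -3.0, -2.2),
      beta1 = c(0.06, 0.05, 0.04, 0.05, 0.06, 0.05, 0.05, 0.06, 0.04),
      beta2 = c(0.025, 0, 0, -0.015, -0.02, 0.02, -0.015, -0.02, 0),
      stringsAsFactors = FALSE
    )
  }
  cells <- generate_cell_table(n_cells, params = params, seed = seed)
  species <- vector("list", nrow(species_params))
  for (i in seq_len(nrow(species_params))) {
    sp <- virtual_species(
      name = species_params$name[i], group = species_params$group[i],
      beta0 = species_params$beta0[i], beta1 = species_params$beta1[i],
      beta2 = species_params$beta2[i],
      seed = seed + 7919 * i
    )
    species[[i]] <- generate_occurrences(sp, cells)
  }
  names(species) <- species_params$name
  list(cells = cells, species = species, truth = species_params)
}
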