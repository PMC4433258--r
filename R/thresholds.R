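#' Occurrence-probability curve with bootstrap confidence band
#'
#' Predicted occurrence probability along the forest-cover gradient under one
#' fragmentation scenario. Point estimates come from the original-sample fit;
#' the 95% band applies the percentile rank rule of [percentile_ci()] to the
#' predictions of the bootstrap replicate fits at each grid point. Passing
#' the same [bootstrap_fits()] object here and to [bootstrap_omega()] keeps
#' the sensitivity and threshold analyses on identical replicates.
#'
#' @inheritParams bootstrap_omega
#' @param grid a [scenario_grids()] object (e.g. [published_scenario_grid()]).
#' @param scenario `"max_frag"` (envelope rLPS) or `"zero_frag"`
#'   (rLPS = 100).
#' @return An object of class `scenario_curve`: `scenario`, `species_name`,
#'   and `points`, a data frame (pfc, rlps, p_hat, ci_low, ci_high) ordered
#'   by decreasing pfc.
#' @export
curve_with_ci <- function(data, grid, scenario = c("max_frag", "zero_frag"),
                          n_boot = 1000, seed = 1, reps = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(data, "species_dataset"), inherits(grid, "scenario_grid"))
  if (is.null(reps)) reps <- bootstrap_fits(data, n_boot, seed)
  stopifnot(inherits(reps, "bootstrap_fits"))
  rlps <- if (scenario == "max_frag") grid$rlps_max else grid$rlps_none
  pfc <- grid$pfc_levels
  ord <- order(pfc, decreasing = TRUE)
  pfc <- pfc[ord]; rlps <- rlps[ord]
  fit <- fit_logistic(data)
  p_hat <- predict_p(fit, pfc, rlps)
  # replicate predictions: B x n_levels
  eta <- reps$coef %*% rbind(1, pfc, rlps)
  p_boot <- stats::plogis(eta)
  ci <- apply(p_boot, 2L, percentile_ci)
  pts <- data.frame(pfc = pfc, rlps = rlps, p_hat = p_hat,
                    ci_low = ci["low", ], ci_high = ci["high", ])
  rownames(pts) <- NULL
  bad <- pts$ci_low > pts$p_hat | pts$ci_high < pts$p_hat
  if (any(bad))
    warning("percentile band does not bracket the point estimate at pfc = ",
            paste(pts$pfc[bad], collapse = ", "))
  structure(list(scenario = scenario, species_name = data$species_name,
                 points = pts, n_boot = reps$n_boot),
            class = "scenario_curve")
}

#' @export
print.scenario_curve <- function(x, ...) {
  cat("Occurrence curve (", x$scenario, ") for ", x$species_name,
      " [B = ", x$n_boot, "]\n", sep = "")
  print(cbind(x$points[, 1:2], round(x$points[, 3:5], 3)))
  invisible(x)
}

#' Detect the extinction threshold on a scenario curve
#'
#' A logistic model approaches occurrence probability 0 only asymptotically,
#' so the threshold is read at the 0.5 criterion: the cover at which presence
#' and absence become equally likely. Scanning from the highest forest cover
#' downward, the threshold is the first level whose 95% CI overlaps the
#' critical probability. Under the default `"reach"` rule the CI overlaps as
#' soon as its lower bound drops to the critical value (`ci_low <= critical`),
#' which also catches curves that jump past 0.5 between grid levels; the
#' `"contain"` rule requires `ci_low <= critical <= ci_high`.
#'
#' @param curve a `scenario_curve`.
#' @param critical critical occurrence probability (default 0.5).
#' @param rule `"reach"` or `"contain"`.
#' @return The threshold forest cover (pfc), or `NA_real_` when no level
#'   qualifies (the species stays safely above the criterion over the whole
#'   examined range).
#' @export
detect_threshold <- function(curve, critical = 0.5,
                             rule = c("reach", "contain")) {
  rule <- match.arg(rule)
  stopifnot(inherits(curve, "scenario_curve"))
  pts <- curve$points
  if (nrow(pts) == 0L) return(NA_real_)
  hit <- if (rule == "reach") pts$ci_low <= critical
         else pts$ci_low <= critical & critical <= pts$ci_high
  if (!any(hit)) return(NA_real_)
  pts$pfc[which(hit)[1L]]
}

#' Compare the two fragmentation scenarios for one species
#'
#' Detects the extinction threshold on each scenario curve, counts the grid
#' levels at which the scenarios' 95% CIs are disjoint, and classifies the
#' species against the fragmentation threshold hypothesis:
#' `supports_hypothesis` when the threshold under maximum fragmentation sits
#' at higher forest cover than under zero fragmentation (with at least one
#' divergent level), `opposite_response` for the reverse ordering, and
#' `null_response` otherwise. A missing threshold (curve never reaching the
#' criterion) is treated as lying below the examined cover range.
#'
#' @param curve_max,curve_zero `scenario_curve`s of the same species on
#'   identical pfc levels, scenarios `"max_frag"` and `"zero_frag"`.
#' @param critical critical occurrence probability (default 0.5).
#' @param rule threshold rule, see [detect_threshold()].
#' @return An object of class `threshold_result`: `species_name`,
#'   `threshold_max_frag`, `threshold_zero_frag`, `n_levels_divergent`,
#'   `classification`.
#' @export
compare_scenarios <- function(curve_max, curve_zero, critical = 0.5,
                              rule = c("reach", "contain")) {
  rule <- match.arg(rule)
  stopifnot(inherits(curve_max, "scenario_curve"),
            inherits(curve_zero, "scenario_curve"))
  if (!isTRUE(all.equal(curve_max$points$pfc, curve_zero$points$pfc)))
    stop("curves evaluated on different pfc levels")
  th_max <- detect_threshold(curve_max, critical, rule)
  th_zero <- detect_threshold(curve_zero, critical, rule)
  a <- curve_max$points; b <- curve_zero$points
  divergent <- a$ci_high < b$ci_low | b$ci_high < a$ci_low
  n_div <- sum(divergent)
  # NA threshold = never reached within the range = below the lowest level
  cmp_max <- if (is.na(th_max)) -Inf else th_max
  cmp_zero <- if (is.na(th_zero)) -Inf else th_zero
  classification <- if (n_div >= 1L && cmp_max > cmp_zero) {
    "supports_hypothesis"
  } else if (n_div >= 1L && cmp_zero > cmp_max) {
    "opposite_response"
  } else {
    "null_response"
  }
  structure(
    list(species_name = curve_max$species_name,
         threshold_max_frag = th_max, threshold_zero_frag = th_zero,
         n_levels_divergent = n_div, classification = classification),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("Extinction thresholds for ", x$species_name, ":\n", sep = "")
  cat(sprintf("  max fragmentation: %s%%  |  zero fragmentation: %s%%\n",
              format(x$threshold_max_frag), format(x$threshold_zero_frag)))
  cat(sprintf("  divergent levels: %d  ->  %s\n", x$n_levels_divergent,
              x$classification))
  invisible(x)
}

#' Plot the two scenario curves of a species
#'
#' Occurrence probability with 95% bands against forest cover, cover
#' decreasing rightward so that habitat loss reads left to right. Maximum
#' fragmentation is drawn with open circles, zero fragmentation with filled
#' circles; the dashed line marks the 0.5 criterion.
#'
#' @inheritParams compare_scenarios
#' @param main plot title (defaults to the species name).
#' @return Invisibly, `NULL`; called for the plot side effect.
#' @export
plot_scenarios <- function(curve_max, curve_zero, critical = 0.5,
                           main = curve_max$species_name) {
  a <- curve_max$points; b <- curve_zero$points
  xs <- -a$pfc  # decreasing cover to the right
  graphics::plot(xs, b$p_hat, type = "n", ylim = c(0, 1), xaxt = "n",
                 xlab = "Forest cover, PFC (%)",
                 ylab = "Occurrence probability", main = main)
  graphics::axis(1, at = xs, labels = a$pfc)
  graphics::abline(h = critical, lty = 2)
  graphics::arrows(xs, b$ci_low, xs, b$ci_high, angle = 90, code = 3,
                   length = 0.03)
  graphics::points(xs, b$p_hat, pch = 16)
  graphics::arrows(xs, a$ci_low, xs, a$ci_high, angle = 90, code = 3,
                   length = 0.03)
  graphics::points(xs, a$p_hat, pch = 21, bg = "white")
  invisible(NULL)
}
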