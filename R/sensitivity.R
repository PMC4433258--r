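#' Scenario endpoint constants
#'
#' The fixed evaluation points behind the two sensitivity scalars: forest
#' contraction is read between PFC = 75% and PFC = 5% with no fragmentation
#' (rLPS = 100%); fragmentation is read at a constant moderately low cover
#' (PFC = 20%) between rLPS = 100% and the empirical maximum fragmentation
#' there (rLPS = 10%).
#'
#' @param cover_high,cover_low PFC endpoints of the contraction scenario.
#' @param frag_pfc constant PFC of the fragmentation scenario.
#' @param frag_rlps_max rLPS at maximum fragmentation for `frag_pfc`.
#' @param rlps_none rLPS of the unfragmented state.
#' @return A named list of the five constants.
#' @export
scenario_constants <- function(cover_high = 75, cover_low = 5, frag_pfc = 20,
                               frag_rlps_max = 10, rlps_none = 100) {
  vals <- c(cover_high, cover_low, frag_pfc, frag_rlps_max, rlps_none)
  stopifnot(all(vals >= 0), all(vals <= 100), cover_high > cover_low)
  list(cover_high = cover_high, cover_low = cover_low, frag_pfc = frag_pfc,
       frag_rlps_max = frag_rlps_max, rlps_none = rlps_none)
}

#' Sensitivity to forest contraction (no fragmentation)
#'
#' The log ratio of predicted occurrence probabilities between low and high
#' forest cover in an unfragmented landscape:
#' \deqn{\Omega_{cover} = \ln\frac{p(PFC=5, rLPS=100)}{p(PFC=75, rLPS=100)}}
#' Negative values mean the species loses occurrence as forest contracts.
#'
#' @param fit a `logistic_fit`.
#' @param consts endpoint constants, see [scenario_constants()].
#' @return A real scalar.
#' @export
omega_cover <- function(fit, consts = scenario_constants()) {
  log(predict_p(fit, consts$cover_low, consts$rlps_none) /
        predict_p(fit, consts$cover_high, consts$rlps_none))
}

#' Sensitivity to fragmentation at constant forest cover
#'
#' The log ratio of predicted occurrence probabilities between maximum and
#' zero fragmentation at fixed cover:
#' \deqn{\Omega_{fragm} = \ln\frac{p(PFC=20, rLPS=10)}{p(PFC=20, rLPS=100)}}
#' Negative values mean fragmentation per se depresses occurrence; positive
#' values mean the species is favoured in fragmented cells.
#'
#' @inheritParams omega_cover
#' @return A real scalar.
#' @export
omega_fragm <- function(fit, consts = scenario_constants()) {
  log(predict_p(fit, consts$frag_pfc, consts$frag_rlps_max) /
        predict_p(fit, consts$frag_pfc, consts$rlps_none))
}

# omega from a bare coefficient triple, shared with the bootstrap paths
.omega_from_beta <- function(beta, metric, consts) {
  f <- list(beta0 = beta[1], beta1 = beta[2], beta2 = beta[3])
  if (metric == "cover") omega_cover(f, consts) else omega_fragm(f, consts)
}

#' Percent change implied by a sensitivity scalar
#'
#' Converts the log-ratio scalar to a signed proportional change in
#' occurrence probability, `100 * (exp(omega) - 1)`: an omega of -3 is a 95%
#' reduction, -1 a 63% reduction, -0.5 a 39% reduction and +1 a 170% increase
#' (rounded to integer percent for display).
#'
#' @param omega sensitivity scalar(s).
#' @return Signed percentage(s); negative = reduction.
#' @examples
#' round(percent_change(c(-3, -1, -0.5, 1)))
#' @export
percent_change <- function(omega) {
  100 * (expm1(omega))
}

#' Percentile-bootstrap confidence interval by the rank rule
#'
#' For B ranked bootstrap values the 95% interval is read at ranks
#' `floor(0.025 * B)` and `B - floor(0.025 * B) + 1`; at B = 1000 these are
#' positions 25 and 976.
#'
#' @param values numeric bootstrap replicates (length B >= 40).
#' @return Named vector `c(low, high)`.
#' @export
percentile_ci <- function(values) {
  b <- length(values)
  if (b < 40L) stop("need at least 40 bootstrap values for a 95% rank CI")
  s <- sort(values)
  lo <- floor(0.025 * b)
  hi <- b - lo + 1L
  c(low = s[lo], high = s[hi])
}

#' Bootstrap refits of the occurrence model
#'
#' Draws `n_boot` resamples of the species' cells — triads of (PFC, rLPS,
#' occurrence) sampled with replacement at the cell level, each resample the
#' size of the original — and refits the logistic model on each. A resample
#' whose outcome is single-class or whose fit does not converge is redrawn
#' (up to `max_redraws` extra draws per replicate) before failing hard.
#'
#' The returned replicate set is the shared currency of the downstream
#' analyses: [bootstrap_omega()] and [curve_with_ci()] both accept it, so the
#' sensitivity scalars and the scenario curves of one species can be computed
#' from the same replicates.
#'
#' @param data a [species_dataset()].
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed; the whole procedure is deterministic given it.
#' @param max_redraws extra draws allowed per replicate slot.
#' @return An object of class `bootstrap_fits`: a list with `coef`
#'   (`n_boot` x 3 matrix of replicate coefficients), `n`, `n_boot`, `seed`,
#'   `n_redraws` (total redraws used).
#' @export
bootstrap_fits <- function(data, n_boot = 1000, seed = 1, max_redraws = 50) {
  stopifnot(inherits(data, "species_dataset"), n_boot >= 1)
  d <- data$cells
  n <- nrow(d)
  x <- cbind(1, d$pfc, d$rlps)
  y <- d$occurrence
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(as.integer(seed %% .Machine$integer.max))
  coefs <- matrix(NA_real_, n_boot, 3,
                  dimnames = list(NULL, c("beta0", "beta1", "beta2")))
  n_redraws <- 0L
  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  for (b in seq_len(n_boot)) {
    ok <- FALSE
    for (try in seq_len(max_redraws + 1L)) {
      idx <- sample.int(n, n, replace = TRUE)
      yb <- y[idx]
      if (length(unique(yb)) < 2L) { n_redraws <- n_redraws + 1L; next }
      fit <- suppressWarnings(
        stats::glm.fit(x[idx, , drop = FALSE], yb,
                       family = stats::binomial(), control = ctrl))
      if (!fit$converged) { n_redraws <- n_redraws + 1L; next }
      coefs[b, ] <- fit$coefficients
      ok <- TRUE
      break
    }
    if (!ok)
      stop("bootstrap replicate ", b, " failed after ", max_redraws,
           " redraws (n = ", n, ", prevalence = ",
           signif(mean(y), 3), ")")
  }
  structure(list(coef = coefs, n = n, n_boot = n_boot, seed = seed,
                 n_redraws = n_redraws),
            class = "bootstrap_fits")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Sensitivity scalar with percentile-bootstrap confidence interval
#'
#' Point estimate of the chosen sensitivity scalar from the original-sample
#' fit, with a 95% percentile-bootstrap CI from replicate refits (rank rule
#' of [percentile_ci()]). The scalar is flagged significant when the CI
#' excludes zero.
#'
#' @inheritParams bootstrap_fits
#' @param metric `"cover"` or `"fragm"`.
#' @param consts endpoint constants, see [scenario_constants()].
#' @param reps optional precomputed [bootstrap_fits()] for this dataset; when
#'   supplied, `n_boot` and `seed` are taken from it.
#' @return An object of class `sensitivity_result`: `species_name`, `group`,
#'   `metric`, `omega`, `ci_low`, `ci_high`, `significant`, `n_boot`, and the
#'   replicate scalars in `boot_omegas`.
#' @export
bootstrap_omega <- function(data, metric = c("cover", "fragm"),
                            n_boot = 1000, seed = 1,
                            consts = scenario_constants(), reps = NULL) {
  metric <- match.arg(metric)
  stopifnot(inherits(data, "species_dataset"))
  if (is.null(reps)) reps <- bootstrap_fits(data, n_boot, seed)
  stopifnot(inherits(reps, "bootstrap_fits"))
  fit <- fit_logistic(data)
  point <- .omega_from_beta(c(fit$beta0, fit$beta1, fit$beta2), metric, consts)
  boot <- apply(reps$coef, 1L, .omega_from_beta, metric = metric,
                consts = consts)
  ci <- percentile_ci(boot)
  structure(
    list(species_name = data$species_name, group = data$group,
         metric = metric, omega = point,
         ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
         significant = !(ci["low"] <= 0 && 0 <= ci["high"]),
         n_boot = reps$n_boot, boot_omegas = boot),
    class = "sensitivity_result"
  )
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf(
    "Omega_%s[%s] = %.3f  (95%% CI %.3f .. %.3f)%s  [B = %d]\n",
    x$metric, x$species_name, x$omega, x$ci_low, x$ci_high,
    if (x$significant) " *" else "", x$n_boot))
  invisible(x)
}

#' Group-mean sensitivity with bootstrap confidence interval
#'
#' Averages the sensitivity scalar over the species of a group (e.g. all
#' herbs). The group point estimate is the mean of the species' point
#' estimates; for the CI, replicate b of the group mean is the mean of each
#' species' b-th bootstrap scalar, and the same rank rule is applied to the
#' resulting replicate means.
#'
#' @param results list of `sensitivity_result` objects for the same metric,
#'   one per species, computed with equal `n_boot`.
#' @param group_name label for the group.
#' @return A `sensitivity_result` for the group (with `boot_omegas` the
#'   replicate group means).
#' @export
group_mean_omega <- function(results, group_name = "group") {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "sensitivity_result")))
  metric <- unique(vapply(results, `[[`, character(1), "metric"))
  if (length(metric) != 1L)
    stop("all results must use the same metric")
  if (length(results) == 1L) {
    warning("group of size 1: returning the species' own result")
    out <- results[[1]]
    out$species_name <- group_name
    return(out)
  }
  bs <- vapply(results, function(r) length(r$boot_omegas), integer(1))
  if (length(unique(bs)) != 1L)
    stop("species results carry different numbers of bootstrap replicates")
  boot_mat <- vapply(results, `[[`, numeric(bs[1]), "boot_omegas")
  boot_mean <- rowMeans(boot_mat)
  point <- mean(vapply(results, `[[`, numeric(1), "omega"))
  ci <- percentile_ci(boot_mean)
  structure(
    list(species_name = group_name, group = group_name, metric = metric,
         omega = point,
         ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
         significant = !(ci["low"] <= 0 && 0 <= ci["high"]),
         n_boot = bs[1], boot_omegas = boot_mean),
    class = "sensitivity_result"
  )
}

#' Tabulate sensitivity results
#'
#' @param ... `sensitivity_result` objects (or a single list of them).
#' @return A data frame with one row per result: species, group, metric,
#'   omega, ci_low, ci_high, significant.
#' @export
sensitivity_table <- function(...) {
  results <- list(...)
  if (length(results) == 1L && !inherits(results[[1]], "sensitivity_result"))
    results <- results[[1]]
  do.call(rbind, lapply(results, function(r)
    data.frame(species = r$species_name, group = r$group, metric = r$metric,
               omega = r$omega, ci_low = r$ci_low, ci_high = r$ci_high,
               significant = r$significant, stringsAsFactors = FALSE)))
}
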