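#' Assemble a species occurrence dataset
#'
#' Joins a binary occurrence vector to per-cell forest metrics, restricted to
#' the species' native-range cells. Cells with zero forest cover carry an
#' undefined rLPS; how they enter the model is a policy choice:
#' `"drop"` (default) removes them with a recorded count, `"impute-zero"`
#' sets their rLPS to 0 (treating no forest as total fragmentation).
#'
#' @param species_name species label.
#' @param group group label, `"herb"` or `"fern"`.
#' @param cells data frame with columns `cell_id`, `pfc`, `rlps`,
#'   `occurrence` (0/1), already restricted to the native range.
#' @param zero_forest_policy `"drop"` or `"impute-zero"`.
#' @return An object of class `species_dataset`: the cleaned cell table plus
#'   `prevalence` and `n_dropped_zero_forest` attributes.
#' @export
species_dataset <- function(species_name, group = c("herb", "fern"), cells,
                            zero_forest_policy = c("drop", "impute-zero")) {
  group <- match.arg(group)
  zero_forest_policy <- match.arg(zero_forest_policy)
  needed <- c("cell_id", "pfc", "rlps", "occurrence")
  if (!all(needed %in% names(cells)))
    stop("'cells' must have columns: ", paste(needed, collapse = ", "))
  if (!all(cells$occurrence %in% c(0, 1)))
    stop("'occurrence' must be strictly binary (0/1)")
  undef <- is.na(cells$rlps)
  n_dropped <- 0L
  if (any(undef)) {
    if (zero_forest_policy == "drop") {
      n_dropped <- sum(undef)
      cells <- cells[!undef, , drop = FALSE]
    } else {
      cells$rlps[undef] <- 0
    }
  }
  if (nrow(cells) == 0L) stop("no usable cells after zero-forest policy")
  structure(
    list(species_name = species_name, group = group,
         cells = cells[, needed],
         prevalence = mean(cells$occurrence),
         n_dropped_zero_forest = n_dropped,
         zero_forest_policy = zero_forest_policy),
    class = "species_dataset"
  )
}

#' @export
print.species_dataset <- function(x, ...) {
  cat("Species dataset: ", x$species_name, " (", x$group, ")\n", sep = "")
  cat(sprintf("  %d range cells, prevalence %.3f", nrow(x$cells),
              x$prevalence))
  if (x$n_dropped_zero_forest > 0L)
    cat(sprintf("; %d forest-free cells %s", x$n_dropped_zero_forest,
                if (x$zero_forest_policy == "drop") "dropped"
                else "imputed rLPS = 0"))
  cat("\n")
  invisible(x)
}

#' Fit the two-predictor logistic occurrence model
#'
#' Maximum-likelihood fit of
#' \deqn{p = \frac{e^{\beta_0 + \beta_1 PFC + \beta_2 rLPS}}
#'             {1 + e^{\beta_0 + \beta_1 PFC + \beta_2 rLPS}}}
#' by iteratively reweighted least squares (via [stats::glm()], tolerance
#' 1e-8 on the deviance, at most 100 iterations). Predictors enter
#' untransformed and unstandardized. Quasi-separation is detected and flagged
#' rather than silently accepted.
#'
#' @param data a [species_dataset()].
#' @return An object of class `logistic_fit` with elements `beta0`, `beta1`,
#'   `beta2`, `loglik_full`, `loglik_null`, `n`, `converged`, `separation`
#'   and the underlying `glm` object.
#' @export
fit_logistic <- function(data) {
  stopifnot(inherits(data, "species_dataset"))
  d <- data$cells
  if (nrow(d) < 10L) stop("need at least 10 cells to fit")
  if (length(unique(d$occurrence)) < 2L)
    stop("degenerate outcome: only one occurrence class present")
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(occurrence ~ pfc + rlps, family = stats::binomial(),
               data = d,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (separation)
    warning("possible separation: fitted probabilities reached 0 or 1; ",
            "coefficients reported but flagged")
  null_fit <- stats::glm(occurrence ~ 1, family = stats::binomial(), data = d)
  cf <- stats::coef(fit)
  structure(
    list(beta0 = unname(cf[1]), beta1 = unname(cf[2]), beta2 = unname(cf[3]),
         loglik_full = as.numeric(stats::logLik(fit)),
         loglik_null = as.numeric(stats::logLik(null_fit)),
         n = nrow(d),
         converged = fit$converged && !separation,
         separation = separation,
         glm = fit),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic occurrence model (n =", x$n, ")\n")
  cat(sprintf("  beta0 = %.4f  beta1(PFC) = %.5f  beta2(rLPS) = %.5f\n",
              x$beta0, x$beta1, x$beta2))
  cat(sprintf("  logLik full %.2f / null %.2f; converged: %s%s\n",
              x$loglik_full, x$loglik_null, x$converged,
              if (x$separation) " (separation flagged)" else ""))
  invisible(x)
}

#' Predicted occurrence probability
#'
#' Inverse-logit of the linear predictor at given forest cover and
#' fragmentation values.
#'
#' @param fit a `logistic_fit` (or any list with `beta0`, `beta1`, `beta2`).
#' @param pfc,rlps percentages; vectorized.
#' @return Probabilities strictly in (0, 1).
#' @export
predict_p <- function(fit, pfc, rlps) {
  stats::plogis(fit$beta0 + fit$beta1 * pfc + fit$beta2 * rlps)
}

#' McFadden's pseudo R-squared
#'
#' `1 - logLik(full) / logLik(null)`; 0 when the predictors add nothing,
#' approaching 1 only for near-perfect discrimination.
#'
#' @param fit a `logistic_fit`.
#' @return Value in \[0, 1).
#' @export
mcfadden_rho2 <- function(fit) {
  if (abs(fit$loglik_null) < .Machine$double.eps)
    stop("null log-likelihood is zero; cannot form the ratio")
  1 - fit$loglik_full / fit$loglik_null
}

#' Rank-based AUC
#'
#' Area under the ROC curve as the Mann-Whitney probability that a random
#' presence scores above a random absence; ties count one half.
#'
#' @param scores numeric predicted scores or probabilities.
#' @param labels 0/1 observed outcomes.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Variance inflation factor for the two-predictor model
#'
#' With exactly two predictors the VIF of each equals `1 / (1 - r^2)` where
#' `r` is their Pearson correlation; this closed form is used directly.
#'
#' @param pfc,rlps predictor vectors over the modelled cells.
#' @return VIF (>= 1), shared by both predictors.
#' @export
vif_two_predictor <- function(pfc, rlps) {
  if (length(pfc) < 3L) stop("need at least 3 cells")
  if (stats::sd(pfc) == 0 || stats::sd(rlps) == 0)
    stop("constant predictor: VIF undefined")
  r <- stats::cor(pfc, rlps)
  1 / (1 - r^2)
}

#' Goodness-of-fit report for an occurrence model
#'
#' Bundles the likelihood-ratio chi-squared test (df = 2) against the
#' intercept-only model, McFadden's rho-squared, the rank-based AUC of the
#' fitted probabilities, and the predictor VIF. `passed` applies the
#' model-quality screen: chi-squared p < 0.05, AUC >= 0.7 and
#' rho-squared >= 0.2.
#'
#' @param fit a `logistic_fit`.
#' @param data the [species_dataset()] the fit came from.
#' @return An object of class `gof_report`.
#' @export
gof_report <- function(fit, data) {
  stopifnot(inherits(fit, "logistic_fit"), inherits(data, "species_dataset"))
  d <- data$cells
  chi2 <- 2 * (fit$loglik_full - fit$loglik_null)
  chi2 <- max(chi2, 0)
  p <- stats::pchisq(chi2, df = 2, lower.tail = FALSE)
  rho2 <- mcfadden_rho2(fit)
  a <- auc(predict_p(fit, d$pfc, d$rlps), d$occurrence)
  v <- vif_two_predictor(d$pfc, d$rlps)
  structure(
    list(chi2_stat = chi2, chi2_p = p, rho2 = rho2, auc = a, vif = v,
         passed = (p < 0.05) && (a >= 0.7) && (rho2 >= 0.2)),
    class = "gof_report"
  )
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf(
    "GOF: chi2 = %.2f (p = %.3g), rho2 = %.3f, AUC = %.3f, VIF = %.3f -> %s\n",
    x$chi2_stat, x$chi2_p, x$rho2, x$auc, x$vif,
    if (x$passed) "PASS" else "fail"))
  invisible(x)
}

#' Screen a model against the robustness criteria
#'
#' A species' model is retained for threshold analysis only if the
#' chi-squared p-value is below 0.05, AUC is at least 0.7, McFadden's
#' rho-squared is at least 0.2, and the species' prevalence lies strictly
#' between 0.15 and 0.70 (neither under- nor over-represented in its range).
#'
#' @param chi2_p likelihood-ratio test p-value, or a whole [gof_report()]
#'   object (its p, rho2 and AUC are then used and the remaining statistic
#'   arguments are ignored).
#' @param rho2 McFadden pseudo R-squared.
#' @param auc area under the ROC curve.
#' @param prevalence proportion of range cells occupied; `NA` skips the
#'   prevalence check (for pre-filtered data).
#' @return A list with `pass` (logical) and `reasons` (character vector of
#'   violated criteria, empty on pass).
#' @examples
#' screen_model(chi2_p = 1e-5, rho2 = 0.22, auc = 0.81, prevalence = 0.385)
#' screen_model(chi2_p = 1e-5, rho2 = 0.16, auc = 0.73, prevalence = 0.534)
#' @export
screen_model <- function(chi2_p, rho2, auc, prevalence = NA) {
  if (inherits(chi2_p, "gof_report")) {
    report <- chi2_p
    rho2 <- report$rho2
    auc <- report$auc
    chi2_p <- report$chi2_p
  }
  reasons <- character()
  if (!(chi2_p < 0.05))
    reasons <- c(reasons, sprintf("chi-squared p = %.3g not < 0.05", chi2_p))
  if (!(auc >= 0.7))
    reasons <- c(reasons, sprintf("AUC = %.3f below 0.7", auc))
  if (!(rho2 >= 0.2))
    reasons <- c(reasons, sprintf("rho2 = %.3f below 0.2", rho2))
  if (!is.na(prevalence)) {
    pv <- enforce_prevalence_value(prevalence)
    if (!pv$pass) reasons <- c(reasons, pv$reason)
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}
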