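# Independent oracles, deliberately written with different algorithms than
# the package paths they check.

# depth-first flood fill, one pixel at a time with an explicit stack
oracle_rlps <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  offs <- if (connectivity == 4) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
         c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  }
  sizes <- integer(0)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || seen[i, j]) next
    size <- 0L
    stack <- list(c(i, j))
    seen[i, j] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (o in offs) {
        r <- p[1] + o[1]; cc <- p[2] + o[2]
        if (r >= 1L && r <= nr && cc >= 1L && cc <= nc &&
            mask[r, cc] && !seen[r, cc]) {
          seen[r, cc] <- TRUE
          stack[[length(stack) + 1L]] <- c(r, cc)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  if (!length(sizes)) return(NA_real_)
  100 * max(sizes) / sum(sizes)
}

# brute-force AUC: enumerate every positive/negative pair
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# a species dataset simulated from known coefficients over a funnel cloud
make_dataset <- function(n = 2000, beta = c(-3, 0.05, 0.02), seed = 1,
                         name = "sim", group = "herb") {
  cells <- generate_cell_table(n_cells = n, seed = seed)
  sp <- virtual_species(name, group, beta[1], beta[2], beta[3],
                        seed = seed + 1000)
  generate_occurrences(sp, cells)
}

# a binary forest raster as plain matrix with given density
random_mask <- function(nr, nc, p, seed) {
  set.seed(seed)
  matrix(runif(nr * nc) < p, nr, nc)
}

# hand-built scenario curve, for threshold-rule tests
fake_curve <- function(pfc, p_hat, ci_low, ci_high,
                       scenario = "max_frag", species = "fake") {
  structure(list(scenario = scenario, species_name = species,
                 points = data.frame(pfc = pfc, rlps = NA_real_,
                                     p_hat = p_hat, ci_low = ci_low,
                                     ci_high = ci_high),
                 n_boot = NA_integer_),
            class = "scenario_curve")
}

# point-estimate-only curves from bare coefficients (CI collapsed to p_hat)
point_curve <- function(beta, grid, scenario) {
  fit <- list(beta0 = beta[1], beta1 = beta[2], beta2 = beta[3])
  rlps <- if (scenario == "max_frag") grid$rlps_max else grid$rlps_none
  ord <- order(grid$pfc_levels, decreasing = TRUE)
  pfc <- grid$pfc_levels[ord]; rlps <- rlps[ord]
  p <- predict_p(fit, pfc, rlps)
  fake_curve(pfc, p, p, p, scenario = scenario)
}
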