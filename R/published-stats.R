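#' Published goodness-of-fit statistics for 16 understory species
#'
#' Model-evaluation statistics (likelihood-ratio chi-squared p-value,
#' McFadden's rho-squared and AUC) reported for the forest-cover and
#' fragmentation occurrence models of ten forest understory herbs and six
#' ferns of Peninsular Spain, together with each species' prevalence within
#' its native range. Chi-squared p-values printed as "<0.0001" are stored as
#' 0.0001 (an upper bound; every screening decision is unchanged by the
#' bound because the criterion is p < 0.05). This table is the worked
#' example for [screen_model()]: applying the screen retains nine species,
#' five herbs and four ferns.
#'
#' @return A data frame with columns `species`, `group`, `chi2_p`, `rho2`,
#'   `auc`, `prevalence`.
#' @examples
#' stats <- understory_fit_stats()
#' keep <- vapply(seq_len(nrow(stats)), function(i)
#'   screen_model(stats$chi2_p[i], stats$rho2[i], stats$auc[i])$pass,
#'   logical(1))
#' table(stats$group[keep])
#' @export
understory_fit_stats <- function() {
  data.frame(
    species = c("Poa nemoralis", "Monotropa hypopitys", "Hepatica nobilis",
                "Deschampsia flexuosa", "Teucrium scorodonia",
                "Helleborus viridis", "Paeonia broteri", "Saxifraga hirsuta",
                "Paris quadrifolia", "Meconopsis cambrica",
                "Dryopteris filix-mas", "Blechnum spicant",
                "Athyrium filix-femina", "Polystichum aculeatum",
                "Asplenium onopteris", "Dryopteris dilatata"),
    group = c(rep("herb", 10), rep("fern", 6)),
    chi2_p = c(1e-4, 1e-4, 1e-4, 1e-4, 1e-4, 1e-4, 1e-4, 1e-4, 1e-4, 0.004,
               1e-4, 1e-4, 1e-4, 1e-4, 1e-4, 1e-4),
    rho2 = c(0.22, 0.21, 0.21, 0.21, 0.20, 0.16, 0.05, 0.07, 0.04, 0.03,
             0.22, 0.21, 0.20, 0.20, 0.13, 0.11),
    auc = c(0.81, 0.81, 0.78, 0.76, 0.75, 0.73, 0.70, 0.68, 0.64, 0.63,
            0.79, 0.77, 0.77, 0.76, 0.73, 0.72),
    prevalence = c(0.385, 0.204, 0.294, 0.251, 0.338, 0.534, 0.165, 0.314,
                   0.194, 0.194, 0.335, 0.392, 0.318, 0.347, 0.288, 0.183),
    stringsAsFactors = FALSE
  )
}
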