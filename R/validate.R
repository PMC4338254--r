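#' Call ZW/ZZ genotypes from banding observations
#'
#' A female-specific marker band indicates a W chromosome: individuals
#' showing the band are called ZW, individuals without it ZZ. Records with a
#' missing band observation are dropped with a warning.
#'
#' @param cohort tibble with at least `individual_id` and `band_observed`
#'   (logical); typically also `population` and `phenotypic_sex`.
#' @return the cohort tibble (minus skipped rows) with a `genotype_call`
#'   column ("ZW"/"ZZ").
#' @export
#' @examples
#' call_genotype(tibble::tibble(individual_id = c("a", "b"),
#'                              band_observed = c(TRUE, FALSE)))
call_genotype <- function(cohort) {
  stopifnot(all(c("individual_id", "band_observed") %in% names(cohort)))
  missing_band <- is.na(cohort$band_observed)
  if (any(missing_band)) {
    warn(paste0("skipping ", sum(missing_band),
                " record(s) with missing band observation: ",
                paste(utils::head(cohort$individual_id[missing_band], 5),
                      collapse = ", ")))
    cohort <- cohort[!missing_band, ]
  }
  mutate(cohort,
         genotype_call = dplyr::if_else(.data$band_observed, "ZW", "ZZ"))
}

#' Marker-phenotype concordance report
#'
#' Calls genotypes from band observations and summarises agreement with
#' phenotypic sex, per population and overall. An individual is concordant
#' when phenotypic females are ZW and phenotypic males are ZZ. Discordant
#' individuals are listed and annotated "putative sex reversal or W/Z
#' recombination" — banding alone cannot distinguish a naturally sex-
#' reversed ZZ neo-female from a W/Z recombinant, so the report carries both
#' hypotheses rather than "correcting" the call.
#'
#' @param cohort tibble with `individual_id`, `population`,
#'   `phenotypic_sex` ("F"/"M"), `band_observed` (logical).
#' @return list of class `zw_concordance`: `by_population` (tibble with
#'   `population`, `n_typed`, `n_concordant`, `n_discordant`,
#'   `concordance_fraction`; last row is the overall total), `discordant`
#'   (tibble of flagged individuals with their annotation), and `n_typed`,
#'   `n_concordant`, `concordance_fraction` scalars for the whole cohort.
#' @export
#' @examples
#' design <- tibble::tibble(population = "demo",
#'                          phenotypic_sex = c("F", "M"), n = c(5, 5))
#' concordance_report(simulate_validation_cohort(design, seed = 1))
concordance_report <- function(cohort) {
  stopifnot(all(c("individual_id", "population", "phenotypic_sex",
                  "band_observed") %in% names(cohort)))
  if (nrow(cohort) == 0) abort("cohort is empty")
  called <- call_genotype(cohort)
  if (nrow(called) == 0) abort("no records with band observations")
  called <- mutate(called,
                   concordant = (.data$phenotypic_sex == "F" &
                                   .data$genotype_call == "ZW") |
                     (.data$phenotypic_sex == "M" &
                        .data$genotype_call == "ZZ"))
  per_pop <- called |>
    group_by(.data$population) |>
    summarise(n_typed = n(),
              n_concordant = sum(.data$concordant),
              n_discordant = sum(!.data$concordant),
              concordance_fraction = mean(.data$concordant),
              .groups = "drop")
  overall <- tibble(population = "(overall)",
                    n_typed = nrow(called),
                    n_concordant = sum(called$concordant),
                    n_discordant = sum(!called$concordant),
                    concordance_fraction = mean(called$concordant))
  discordant <- called |>
    filter(!.data$concordant) |>
    select("individual_id", "population", "phenotypic_sex",
           "genotype_call") |>
    mutate(annotation = "putative sex reversal or W/Z recombination")
  structure(list(
    by_population = bind_rows(per_pop, overall),
    discordant = discordant,
    n_typed = overall$n_typed,
    n_concordant = overall$n_concordant,
    concordance_fraction = overall$concordance_fraction
  ), class = "zw_concordance")
}

#' @export
print.zw_concordance <- function(x, ...) {
  cat("Marker-phenotype concordance: ", x$n_concordant, "/", x$n_typed,
      " (", sprintf("%.2f%%", 100 * x$concordance_fraction), ")\n",
      sep = "")
  print(x$by_population)
  if (nrow(x$discordant)) {
    cat("Discordant individuals:\n")
    print(x$discordant)
  }
  invisible(x)
}
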