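# readers/writers for the plain-text interchange formats the pipeline uses

#' Write transcript sequences to FASTA
#'
#' @param transcripts tibble with `transcript_id` and `sequence` columns
#'   (e.g. from [simulate_transcriptome()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_transcripts_fasta <- function(transcripts, path) {
  seqs <- Biostrings::DNAStringSet(transcripts$sequence)
  names(seqs) <- transcripts$transcript_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read sequences from FASTA into a tibble
#'
#' @param path FASTA file path.
#' @return tibble: `transcript_id`, `length_bp`, `n_count`, `sequence`.
#' @export
read_transcripts_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  tibble(transcript_id = names(seqs),
         length_bp = Biostrings::width(seqs),
         n_count = Biostrings::vcountPattern("N", seqs),
         sequence = unname(as.character(seqs)))
}

#' Write a count matrix and pool metadata to TSV
#'
#' Writes the counts tibble (header row of pool ids) and a sidecar pool
#' metadata table (`pool_id`, `sex`, `library_size`).
#'
#' @param cm `zw_counts` list from [simulate_count_matrix()].
#' @param counts_path,pools_path output TSV paths.
#' @return `counts_path`, invisibly.
#' @export
write_count_matrix <- function(cm, counts_path, pools_path) {
  readr::write_tsv(cm$counts, counts_path)
  readr::write_tsv(cm$pools, pools_path)
  invisible(counts_path)
}

#' Read a count matrix and pool metadata from TSV
#'
#' @param counts_path,pools_path TSV paths written by
#'   [write_count_matrix()].
#' @return `zw_counts` list (`counts`, `pools`).
#' @export
read_count_matrix <- function(counts_path, pools_path) {
  counts <- readr::read_tsv(counts_path, show_col_types = FALSE)
  pools <- readr::read_tsv(pools_path, show_col_types = FALSE)
  check_counts_input(counts, pools)
  structure(list(counts = counts, pools = pools), class = "zw_counts")
}

#' Read a validation cohort from TSV
#'
#' Expects columns `individual_id`, `population`, `phenotypic_sex`,
#' `band_observed` (0/1 or TRUE/FALSE).
#'
#' @param path TSV path.
#' @return cohort tibble ready for [concordance_report()].
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("individual_id", "population", "phenotypic_sex",
                  "band_observed") %in% names(cohort)))
  mutate(cohort, band_observed = as.logical(.data$band_observed))
}

# screen report with boolean flags as 0/1 and the posterior to 6 decimals
write_screen_report <- function(screen, path) {
  out <- screen |>
    mutate(posterior_de = sprintf("%.6f", .data$posterior_de),
           across(c("exclusive", "length_ok", "posterior_ok",
                    "excluded_as_contaminant", "final_candidate"),
                  as.integer))
  readr::write_tsv(out, path)
  invisible(path)
}
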