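#' Pooled RNA-seq study design
#'
#' Describes the pooled sequencing layout the screen assumes: several pools
#' per sex, each pool combining RNA from a fixed number of individuals, with
#' per-pool library sizes varying around a target depth. Defaults reproduce
#' the design the screen was developed for: six female and six male pools of
#' two fish each.
#'
#' @param n_female_pools,n_male_pools number of pools per sex (default 6 + 6).
#' @param fish_per_pool individuals pooled per library (default 2).
#' @param target_library_size expected reads per pool (default 1e6; the
#'   simulator works in expected-reads space so absolute depth only sets the
#'   count scale).
#' @param library_size_cv coefficient of variation of per-pool library sizes
#'   (log-normal; default 0.2).
#' @param dispersion_log_mean,dispersion_log_sd log-normal distribution of
#'   gene-wise negative-binomial dispersions phi (variance = mu + phi mu^2);
#'   defaults `log(0.1)` and 0.5, typical of bulk RNA-seq replicates.
#' @param seed integer seed controlling all draws under this design.
#' @return a list of class `pool_design`.
#' @export
#' @examples
#' pool_design(seed = 1)
pool_design <- function(n_female_pools = 6, n_male_pools = 6,
                        fish_per_pool = 2, target_library_size = 1e6,
                        library_size_cv = 0.2,
                        dispersion_log_mean = log(0.1),
                        dispersion_log_sd = 0.5,
                        seed = 1L) {
  stopifnot(n_female_pools >= 1, n_male_pools >= 1, fish_per_pool >= 1)
  if (target_library_size <= 0) {
    abort("target_library_size must be strictly positive")
  }
  if (library_size_cv < 0) abort("library_size_cv must be non-negative")
  structure(list(
    n_female_pools = as.integer(n_female_pools),
    n_male_pools = as.integer(n_male_pools),
    fish_per_pool = as.integer(fish_per_pool),
    target_library_size = target_library_size,
    library_size_cv = library_size_cv,
    dispersion_log_mean = dispersion_log_mean,
    dispersion_log_sd = dispersion_log_sd,
    seed = as.integer(seed)
  ), class = "pool_design")
}

# reference library size at which expected reads/pool are specified
REF_LIBRARY_SIZE <- 1e6

transcript_classes <- c("autosomal", "z_linked", "w_linked",
                        "female_biased", "male_biased", "contaminant")

# largest-remainder apportionment of n among fractions p (ties by order)
largest_remainder <- function(n, p) {
  exact <- n * p
  base <- floor(exact)
  rem <- exact - base
  short <- n - sum(base)
  if (short > 0) {
    idx <- order(-rem, seq_along(p))[seq_len(short)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Simulate a truth-tabled ZW transcriptome
#'
#' Generates a synthetic transcript universe with known class labels:
#' ordinary autosomal transcripts, Z-linked transcripts, W-linked transcripts
#' (present only in female genomes, the target class of the screen),
#' sex-biased autosomal transcripts, and bacterial contaminants that are
#' expressed in random pools irrespective of sex. Sequences are i.i.d.
#' uniform over ACGT; expression is parameterised as expected reads per pool
#' at a reference library size of 1e6, drawn log-normal per transcript.
#'
#' W-linked transcripts get a floor of `w_expected_reads_min` expected reads
#' per female pool so that a screen run at default settings faces targets it
#' is meant to recover; lowering the floor makes recovery a power question.
#'
#' @param n_transcripts number of transcripts to generate (must be >= 1).
#' @param class_proportions named numeric vector of class fractions over
#'   `r paste(transcript_classes, collapse = ", ")`; must sum to 1. Classes
#'   omitted get 0. Counts follow largest-remainder rounding.
#' @param length_range integer 2-vector, min/max transcript length in bp
#'   (uniform; min >= 100).
#' @param seed integer seed; per-transcript child streams make the output
#'   invariant to evaluation order.
#' @param expected_reads_meanlog,expected_reads_sdlog log-normal parameters
#'   of expected reads per pool at the reference depth (defaults log(100), 1).
#' @param w_expected_reads_min floor on expected reads per female pool for
#'   w_linked transcripts (default 20).
#' @param fold_change_biased expression fold change applied to the favoured
#'   sex of female_biased/male_biased transcripts (default 4).
#' @param n_rate per-base probability of an ambiguous N (default 0, so the
#'   N-exclusion branch of [assembly_coverage()] is opt-in).
#' @return a tibble (one row per transcript) with columns `transcript_id`,
#'   `class_label`, `length_bp`, `n_count`, `base_rate` (expected reads per
#'   bp per unit library size), `fold_change`, `sequence`.
#' @export
#' @examples
#' tx <- simulate_transcriptome(20, c(w_linked = 0.2, autosomal = 0.8),
#'                              seed = 1)
#' table(tx$class_label)
simulate_transcriptome <- function(n_transcripts,
                                   class_proportions = c(autosomal = 0.86,
                                                         z_linked = 0.02,
                                                         w_linked = 0.02,
                                                         female_biased = 0.04,
                                                         male_biased = 0.04,
                                                         contaminant = 0.02),
                                   length_range = c(501L, 3000L),
                                   seed = 1L,
                                   expected_reads_meanlog = log(100),
                                   expected_reads_sdlog = 1,
                                   w_expected_reads_min = 20,
                                   fold_change_biased = 4,
                                   n_rate = 0) {
  if (n_transcripts < 1) abort("n_transcripts must be at least 1")
  unknown <- setdiff(names(class_proportions), transcript_classes)
  if (length(unknown)) {
    abort(paste0("unknown transcript class(es): ",
                 paste(unknown, collapse = ", ")))
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    abort("class_proportions must sum to 1")
  }
  if (any(class_proportions < 0)) abort("class_proportions must be >= 0")
  if (length_range[1] < 100) abort("minimum transcript length is 100 bp")
  if (length_range[2] < length_range[1]) abort("invalid length_range")

  n_per_class <- largest_remainder(n_transcripts, unname(class_proportions))
  classes <- rep(names(class_proportions), n_per_class)

  rows <- purrr::map(seq_len(n_transcripts), function(i) {
    cls <- classes[i]
    with_seed(child_seed(seed, i), {
      len <- sample(length_range[1]:length_range[2], 1)
      expected <- rlnorm(1, expected_reads_meanlog, expected_reads_sdlog)
      if (cls == "w_linked") expected <- max(expected, w_expected_reads_min)
      fold <- switch(cls,
                     female_biased = fold_change_biased,
                     male_biased = fold_change_biased,
                     z_linked = 2,
                     1)
      seq <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
      n_count <- 0L
      if (n_rate > 0) {
        pos <- which(runif(len) < n_rate)
        if (length(pos)) {
          ch <- strsplit(seq, "", fixed = TRUE)[[1]]
          ch[pos] <- "N"
          seq <- paste(ch, collapse = "")
          n_count <- length(pos)
        }
      }
      tibble(
        transcript_id = sprintf("contig%05d", i),
        class_label = cls,
        length_bp = as.integer(len),
        n_count = n_count,
        base_rate = expected / (len * REF_LIBRARY_SIZE),
        fold_change = fold,
        sequence = seq
      )
    })
  })
  bind_rows(rows)
}

# per-sex expression multiplier for a transcript class
sex_multiplier <- function(class_label, fold_change, sex) {
  female <- sex == "F"
  dplyr::case_when(
    class_label == "w_linked" & !female ~ 0,
    class_label == "w_linked" ~ 1,
    class_label == "female_biased" & female ~ fold_change,
    class_label == "male_biased" & !female ~ fold_change,
    class_label == "z_linked" & !female ~ fold_change,
    .default = 1
  )
}

#' Simulate a pooled count matrix under negative-binomial noise
#'
#' Draws per-pool read counts for each transcript with mean
#' `base_rate * sex_multiplier * length_bp * library_size` and gene-wise
#' negative-binomial dispersion (variance = mu + phi mu^2, phi log-normal
#' from the design). W-linked transcripts have structural zeros in every
#' male pool: the draw is skipped, not merely given mean zero. Contaminants
#' are switched on in a random half of pools irrespective of sex, so they
#' can mimic female-exclusive expression by sampling chance alone.
#'
#' @param transcripts tibble from [simulate_transcriptome()].
#' @param design a [pool_design()].
#' @return list with class `zw_counts`: `counts` (tibble: `contig_id`,
#'   `length_bp`, one integer column per pool) and `pools` (tibble:
#'   `pool_id`, `sex`, `library_size`).
#' @export
#' @examples
#' tx <- simulate_transcriptome(10, c(w_linked = 0.2, autosomal = 0.8),
#'                              seed = 1)
#' cm <- simulate_count_matrix(tx, pool_design(seed = 2))
#' cm$counts
simulate_count_matrix <- function(transcripts, design) {
  stopifnot(inherits(design, "pool_design"), nrow(transcripts) >= 1)
  n_pools <- design$n_female_pools + design$n_male_pools
  pool_id <- c(sprintf("F%d", seq_len(design$n_female_pools)),
               sprintf("M%d", seq_len(design$n_male_pools)))
  sex <- c(rep("F", design$n_female_pools), rep("M", design$n_male_pools))

  lib <- with_seed(child_seed(design$seed, 0), {
    if (design$library_size_cv == 0) {
      rep(design$target_library_size, n_pools)
    } else {
      sdlog <- sqrt(log(1 + design$library_size_cv^2))
      rlnorm(n_pools, log(design$target_library_size) - sdlog^2 / 2, sdlog)
    }
  })
  if (any(lib <= 0)) abort("library sizes must be strictly positive")

  count_rows <- purrr::map(seq_len(nrow(transcripts)), function(i) {
    tr <- transcripts[i, ]
    with_seed(child_seed(design$seed, i), {
      phi <- rlnorm(1, design$dispersion_log_mean, design$dispersion_log_sd)
      mult <- sex_multiplier(tr$class_label, tr$fold_change, sex)
      if (tr$class_label == "contaminant") {
        mult <- mult * rbinom(n_pools, 1, 0.5)
      }
      mu <- tr$base_rate * mult * tr$length_bp * lib
      y <- integer(n_pools)
      pos <- mu > 0
      if (any(pos)) {
        y[pos] <- if (phi < 1e-12) {
          rpois(sum(pos), mu[pos])
        } else {
          rnbinom(sum(pos), mu = mu[pos], size = 1 / phi)
        }
      }
      y
    })
  })
  counts <- matrix(unlist(count_rows), nrow = nrow(transcripts), byrow = TRUE,
                   dimnames = list(NULL, pool_id))
  structure(list(
    counts = bind_cols(
      tibble(contig_id = transcripts$transcript_id,
             length_bp = transcripts$length_bp),
      as_tibble(counts)
    ),
    pools = tibble(pool_id = pool_id, sex = sex, library_size = lib)
  ), class = "zw_counts")
}

#' Simulate an orthologous sequence pair with known differences
#'
#' Copies a template and substitutes bases at `round(rate * length)`
#' positions drawn uniformly without replacement, recording the truth set of
#' differing positions. Used to exercise species-diagnostic primer design
#' against a known answer.
#'
#' @param template DNA string over ACGT.
#' @param substitution_rate fraction of sites to mutate, in \[0, 0.25\].
#' @param seed integer seed.
#' @return list: `seq_a` (the template), `seq_b` (mutated copy),
#'   `positions` (sorted 1-based positions of every substitution).
#' @export
#' @examples
#' pair <- simulate_ortholog_pair(strrep("ACGT", 50), 0.05, seed = 7)
#' length(pair$positions)
simulate_ortholog_pair <- function(template, substitution_rate, seed = 1L) {
  assert_dna(template, "template")
  if (substitution_rate < 0 || substitution_rate > 0.25) {
    abort("substitution_rate must be in [0, 0.25]")
  }
  len <- nchar(template)
  n_sub <- round(substitution_rate * len)
  ch <- strsplit(template, "", fixed = TRUE)[[1]]
  positions <- integer(0)
  if (n_sub > 0) {
    with_seed(child_seed(seed, 1), {
      positions <- sort(sample.int(len, n_sub))
      for (p in positions) {
        ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
      }
    })
  }
  list(seq_a = template, seq_b = paste(ch, collapse = ""),
       positions = positions)
}

#' Simulate a genotype-truthed validation cohort
#'
#' Builds per-individual records for a marker validation study: phenotypic
#' sex by population, true genotype set from phenotypic sex (ZW for females,
#' ZZ for males) and flipped with probability `sex_reversal_rate` to create
#' sex-reversed or recombinant individuals, and the female-specific band
#' observed iff the genotype carries a W.
#'
#' @param n_per_group tibble/data frame with columns `population`,
#'   `phenotypic_sex` ("F"/"M"), `n`.
#' @param sex_reversal_rate probability a record's genotype is discordant
#'   with its phenotypic sex (default 0).
#' @param seed integer seed.
#' @return tibble of cohort records: `individual_id`, `population`,
#'   `phenotypic_sex`, `genotype`, `band_observed`.
#' @export
#' @examples
#' design <- tibble::tibble(population = "demo",
#'                          phenotypic_sex = c("F", "M"), n = c(3, 3))
#' simulate_validation_cohort(design, seed = 1)
simulate_validation_cohort <- function(n_per_group, sex_reversal_rate = 0,
                                       seed = 1L) {
  stopifnot(all(c("population", "phenotypic_sex", "n") %in%
                  names(n_per_group)))
  if (any(n_per_group$n < 0)) abort("group counts must be >= 0")
  if (sex_reversal_rate < 0 || sex_reversal_rate > 1) {
    abort("sex_reversal_rate must be in [0, 1]")
  }
  records <- tidyr::uncount(as_tibble(n_per_group), .data$n)
  n <- nrow(records)
  if (n == 0) return(mutate(records, individual_id = character(0),
                            genotype = character(0),
                            band_observed = logical(0)))
  with_seed(child_seed(seed, 2), {
    flipped <- runif(n) < sex_reversal_rate
    records |>
      mutate(
        individual_id = sprintf("ind%04d", row_number()),
        genotype = dplyr::if_else(
          xor(.data$phenotypic_sex == "F", flipped), "ZW", "ZZ"),
        band_observed = .data$genotype == "ZW"
      ) |>
      select("individual_id", "population", "phenotypic_sex",
             "genotype", "band_observed")
  })
}
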