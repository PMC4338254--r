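#' Default demo pipeline configuration
#'
#' A nested configuration covering every pipeline stage, with all screening
#' and primer-design thresholds at their published defaults and a simulation
#' sized so the whole run takes seconds: 1,000 transcripts of which 20 are
#' W-linked at a floor of 20 expected reads per female pool, 6 + 6 pools of
#' 2 fish. Configurations round-trip through YAML via
#' [read_pipeline_config()] / [write_pipeline_config()].
#'
#' @param seed global integer seed; each stage derives its own child seed.
#' @return nested list of class `pipeline_config`.
#' @export
demo_config <- function(seed = 20150223L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(
      n_transcripts = 1000L,
      class_proportions = list(autosomal = 0.86, z_linked = 0.02,
                               w_linked = 0.02, female_biased = 0.04,
                               male_biased = 0.04, contaminant = 0.02),
      length_range = c(501L, 3000L),
      w_expected_reads_min = 20,
      design = list(n_female_pools = 6L, n_male_pools = 6L,
                    fish_per_pool = 2L, target_library_size = 1e6,
                    library_size_cv = 0.2,
                    dispersion_log_mean = -2.3026,
                    dispersion_log_sd = 0.5)
    ),
    screen = list(min_length_bp = 501L, posterior_threshold = 1 - 1e-6,
                  min_female_pools_present = 1L, max_male_reads_total = 0L,
                  prior_de = 0.05, exclusion_list = character(0)),
    primers = list(tm_min = 59, tm_opt = 60, tm_max = 61,
                   tm_pair_max_diff = 1, max_poly_x = 3L, gc_clamp = 1L,
                   product_min = 480L, product_opt = 500L,
                   product_max = 520L, n_templates = 3L,
                   control_product_bp = 259L, min_separation_bp = 40L),
    diagnostic = list(template_length = 1000L, substitution_rate = 0.05,
                      min_differences = 2L),
    clock = list(
      loci = list(
        list(locus = "cytb", n_differences = 41L, n_sites = 876L,
             rate_fast = 0.0076, rate_slow = 0.0036),
        list(locus = "control_region", n_differences = 6L, n_sites = 396L,
             rate_fast = 0.044, rate_slow = 0.004)
      )
    ),
    cohort = list(
      groups = list(
        list(population = "Mexico", phenotypic_sex = "F", n = 25L),
        list(population = "Mexico", phenotypic_sex = "M", n = 19L),
        list(population = "NewZealand", phenotypic_sex = "F", n = 29L),
        list(population = "NewZealand", phenotypic_sex = "M", n = 42L)
      ),
      sex_reversal_rate = 0.01
    )
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a `pipeline_config` list;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$screen)) {
    cfg$screen$exclusion_list <- as.character(cfg$screen$exclusion_list)
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config` list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_error <- function(stage, parent) {
  abort(paste0("pipeline stage '", stage, "' failed: ",
               conditionMessage(parent)))
}

#' Run the full marker-discovery pipeline
#'
#' Executes simulate, screen, design-primers, design-diagnostic, clock and
#' validate in order, writing per-stage TSV/FASTA outputs under `outdir`
#' plus a JSON manifest recording the seed, a config hash, the package
#' version and the MD5 of every output. Re-running with the same config
#' yields byte-identical TSV outputs. A stage failure aborts with an error
#' naming the stage and leaves a `FAILED` marker file next to the partial
#' outputs.
#'
#' @param config a `pipeline_config`, e.g. [demo_config()].
#' @param outdir output directory (created if needed).
#' @return the manifest, invisibly: list with `seed`, `config_hash`,
#'   `version`, and a tibble `outputs` (`stage`, `file`, `md5`).
#' @export
run_pipeline <- function(config = demo_config(), outdir = tempfile("zwrun")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  failed_marker <- file.path(outdir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  outputs <- list()
  note <- function(stage, file) {
    outputs[[length(outputs) + 1]] <<- tibble(stage = stage, file = file)
  }
  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e) {
      writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
                 failed_marker)
      stage_error(stage, e)
    })
  }
  seed <- config$seed

  # -- simulate ------------------------------------------------------------
  sim <- run_stage("simulate", {
    sc <- config$simulate
    tx <- simulate_transcriptome(
      n_transcripts = sc$n_transcripts,
      class_proportions = unlist(sc$class_proportions),
      length_range = sc$length_range,
      seed = child_seed(seed, 101),
      w_expected_reads_min = sc$w_expected_reads_min %||% 20
    )
    design <- do.call(pool_design,
                      c(sc$design, list(seed = child_seed(seed, 102))))
    cm <- simulate_count_matrix(tx, design)
    readr::write_tsv(select(tx, -"sequence"),
                     file.path(outdir, "truth_table.tsv"))
    write_transcripts_fasta(tx, file.path(outdir, "transcripts.fasta"))
    write_count_matrix(cm, file.path(outdir, "counts.tsv"),
                       file.path(outdir, "pools.tsv"))
    note("simulate", "truth_table.tsv")
    note("simulate", "transcripts.fasta")
    note("simulate", "counts.tsv")
    note("simulate", "pools.tsv")
    list(tx = tx, cm = cm)
  })

  # -- screen --------------------------------------------------------------
  screen <- run_stage("screen", {
    cfg <- do.call(screen_config, config$screen)
    rep <- select_candidates(sim$cm$counts, sim$cm$pools, cfg)
    write_screen_report(rep, file.path(outdir, "candidates.tsv"))
    note("screen", "candidates.tsv")
    rep
  })

  # -- design-primers ------------------------------------------------------
  primer_pairs <- run_stage("design-primers", {
    pc <- config$primers
    constraints <- design_constraints(
      tm_min = pc$tm_min, tm_opt = pc$tm_opt, tm_max = pc$tm_max,
      tm_pair_max_diff = pc$tm_pair_max_diff, max_poly_x = pc$max_poly_x,
      gc_clamp = pc$gc_clamp, product_min = pc$product_min,
      product_opt = pc$product_opt, product_max = pc$product_max)
    cand_ids <- utils::head(screen$contig_id[screen$final_candidate],
                            pc$n_templates %||% 3L)
    designs <- purrr::map(cand_ids, function(id) {
      tpl <- sim$tx$sequence[sim$tx$transcript_id == id]
      pairs <- enumerate_candidate_pairs(tpl, constraints)
      if (nrow(pairs)) mutate(pairs, contig_id = id, .before = 1)
      else NULL
    })
    designs <- bind_rows(designs)
    if (nrow(designs) == 0) {
      designs <- tibble(contig_id = character(0), forward_seq = character(0),
                        reverse_seq = character(0), product_bp = integer(0),
                        tm_diff = numeric(0), score = numeric(0))
    }
    readr::write_tsv(designs, file.path(outdir, "primer_pairs.tsv"))
    note("design-primers", "primer_pairs.tsv")
    designs
  })

  # -- design-diagnostic ---------------------------------------------------
  diagnostic <- run_stage("design-diagnostic", {
    dc <- config$diagnostic
    template <- with_seed(child_seed(seed, 103), {
      paste(sample(DNA_BASES, dc$template_length, replace = TRUE),
            collapse = "")
    })
    pair <- simulate_ortholog_pair(template, dc$substitution_rate,
                                   seed = child_seed(seed, 104))
    aln <- global_align(pair$seq_a, pair$seq_b)
    designs <- design_diagnostic_primers(aln, target = "a",
                                         min_differences =
                                           dc$min_differences %||% 2L)
    readr::write_tsv(designs, file.path(outdir, "diagnostic_primers.tsv"))
    note("design-diagnostic", "diagnostic_primers.tsv")
    if (nrow(designs)) {
      top <- designs[1, ]
      amp <- in_silico_pcr(pair$seq_a, top$forward_seq, top$reverse_seq)
      readr::write_tsv(amp, file.path(outdir, "diagnostic_amplicons.tsv"))
      note("design-diagnostic", "diagnostic_amplicons.tsv")
    }
    designs
  })

  # -- clock ---------------------------------------------------------------
  clock <- run_stage("clock", {
    est <- bind_rows(purrr::map(config$clock$loci, function(l) {
      divergence_estimate(l$n_differences, l$n_sites,
                          clock_rates(l$locus, l$rate_fast, l$rate_slow))
    }))
    readr::write_tsv(est, file.path(outdir, "divergence.tsv"))
    note("clock", "divergence.tsv")
    est
  })

  # -- validate ------------------------------------------------------------
  concordance <- run_stage("validate", {
    cc <- config$cohort
    groups <- bind_rows(purrr::map(cc$groups, as_tibble))
    cohort <- simulate_validation_cohort(groups, cc$sex_reversal_rate,
                                         seed = child_seed(seed, 105))
    readr::write_tsv(cohort, file.path(outdir, "cohort.tsv"))
    rep <- concordance_report(cohort)
    readr::write_tsv(rep$by_population,
                     file.path(outdir, "concordance.tsv"))
    jsonlite::write_json(glance(rep), file.path(outdir, "concordance.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    note("validate", "concordance.tsv")
    note("validate", "cohort.tsv")
    note("validate", "concordance.json")
    rep
  })

  outputs <- bind_rows(outputs) |>
    mutate(md5 = unname(tools::md5sum(file.path(outdir, .data$file))))
  manifest <- list(
    seed = seed,
    config_hash = rlang::hash(unclass(config)),
    version = as.character(utils::packageVersion("zwscreen")),
    outputs = outputs
  )
  jsonlite::write_json(
    list(seed = seed, config_hash = manifest$config_hash,
         version = manifest$version, outputs = outputs),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(c(manifest, list(
    screen = screen, primer_pairs = primer_pairs, diagnostic = diagnostic,
    clock = clock, concordance = concordance, truth = sim$tx,
    outdir = outdir)))
}
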