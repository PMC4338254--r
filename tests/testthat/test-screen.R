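test_that("normalization divides by library size and length with the median scale", {
  counts <- one_contig_counts(rep(10, 6), rep(10, 6), length_bp = 1000)
  pools <- equal_pools(lib = 1e6)
  norm <- normalize_counts(counts, pools)
  # scale = median lib * median length = 1e9; 10 / (1e6 * 1e3) * 1e9 = 10
  expect_equal(as.numeric(norm[1, pools$pool_id]), rep(10, 12))
  expect_equal(attr(norm, "scale"), 1e9)

  # zero row stays zero; doubling one pool's library halves its rates
  z <- one_contig_counts(rep(0, 6), rep(0, 6))
  expect_true(all(normalize_counts(z, pools)[1, pools$pool_id] == 0))
  pools2 <- pools
  pools2$library_size[1] <- 2e6
  norm2 <- normalize_counts(counts, pools2)
  expect_equal(norm2$F1, norm2$F2 / 2)

  badpools <- pools
  badpools$library_size[3] <- 0
  expect_error(normalize_counts(counts, badpools), "F3")
})

test_that("female exclusivity requires zero male reads and female presence", {
  pools <- equal_pools()
  cfg <- screen_config()
  expect_true(female_exclusive_filter(
    one_contig_counts(c(3, 0, 0, 0, 0, 0), rep(0, 6)), pools, cfg))
  expect_false(female_exclusive_filter(
    one_contig_counts(c(3, 0, 0, 0, 0, 0), c(0, 0, 1, 0, 0, 0)), pools, cfg))
  expect_false(female_exclusive_filter(
    one_contig_counts(rep(0, 6), rep(0, 6)), pools, cfg))

  # oracle: brute-force re-scan of a simulated matrix
  tx <- simulate_transcriptome(120, c(w_linked = 0.2, autosomal = 0.7,
                                      contaminant = 0.1), seed = 21)
  cm <- simulate_count_matrix(tx, pool_design(seed = 22))
  got <- female_exclusive_filter(cm$counts, cm$pools, cfg)
  m_cols <- cm$pools$pool_id[cm$pools$sex == "M"]
  f_cols <- cm$pools$pool_id[cm$pools$sex == "F"]
  want <- vapply(seq_len(nrow(cm$counts)), function(i) {
    male <- sum(as.numeric(cm$counts[i, m_cols]))
    fem <- sum(as.numeric(cm$counts[i, f_cols]) >= 1)
    male <= 0 && fem >= 1
  }, logical(1))
  expect_identical(got, want)
})

test_that("dispersion estimate matches hand-computed moments and floors at zero", {
  pools <- equal_pools()
  # equal counts, equal offsets -> zero variance -> 0
  expect_equal(as.numeric(estimate_dispersion(rep(7, 12),
                                              pools$library_size, 1000)), 0)
  # two pools {0, 20}: scaled counts are the counts themselves;
  # s2 = 200, m = 10 -> phi = (200 - 10) / 100 = 1.9
  expect_equal(as.numeric(estimate_dispersion(c(0, 20), c(1e6, 1e6), 1000)),
               (var(c(0, 20)) - 10) / 100)
  # all-zero row flags itself
  z <- estimate_dispersion(rep(0, 12), pools$library_size, 1000)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "all_zero"))
  # Poisson rows are on average not over-dispersed
  phis <- vapply(1:400, function(s) {
    y <- withr::with_seed(s, rpois(12, 30))
    as.numeric(estimate_dispersion(y, pools$library_size, 1000, pools$sex))
  }, numeric(1))
  # flooring at 0 biases the mean up a little; it must still be near 0
  expect_lt(mean(phis), 3 * sd(phis) / sqrt(length(phis)) + 0.01)
})

test_that("DE posterior behaves like a penalised two-model comparison", {
  pools <- equal_pools()
  cfg <- screen_config()

  # identical counts: the sex model gains nothing and pays the BIC penalty
  flat <- de_posterior(rep(20, 12), pools, 1000, cfg)
  expect_lt(flat$posterior_de, cfg$prior_de)
  # the two model scores then differ exactly by half a log(n)
  expect_equal(flat$log_score_de,
               flat$log_score_null - 0.5 * log(12), tolerance = 1e-8)

  # female-only expression: posterior indistinguishable from 1
  fem <- de_posterior(c(50, 60, 55, 45, 50, 52, rep(0, 6)), pools, 1000, cfg)
  expect_gt(fem$posterior_de, 0.999)
  expect_equal(fem$theta_m, 0)
  # independent evaluation of both penalised likelihoods (phi = 0 here:
  # within-sex variance of the female counts is below their mean)
  off <- pools$library_size * 1000
  y <- c(50, 60, 55, 45, 50, 52, rep(0, 6))
  ll0 <- sum(dpois(y, sum(y) / sum(off) * off, log = TRUE))
  llf <- sum(dpois(y[1:6], sum(y[1:6]) / sum(off[1:6]) * off[1:6],
                   log = TRUE))
  s0 <- ll0 - 0.5 * log(12)
  s1 <- llf + 0 - log(12)
  want <- 1 / (1 + (0.95 / 0.05) * exp(s0 - s1))
  expect_equal(fem$posterior_de, want, tolerance = 1e-8)

  # symmetry: swapping sex labels swaps the rates, not the posterior
  swapped_pools <- pools
  swapped_pools$sex <- rep(c("M", "F"), each = 6)
  swapped <- de_posterior(c(50, 60, 55, 45, 50, 52, rep(0, 6)),
                          swapped_pools, 1000, cfg)
  expect_equal(swapped$posterior_de, fem$posterior_de, tolerance = 1e-10)
  expect_equal(swapped$theta_f, fem$theta_m)
  expect_equal(swapped$theta_m, fem$theta_f)
})

test_that("DE posterior is invariant to a global library-size rescaling", {
  pools <- equal_pools()
  y <- c(35, 10, 22, 41, 17, 28, 3, 9, 1, 4, 12, 6)
  base <- de_posterior(y, pools, 1500)
  pools10 <- pools
  pools10$library_size <- pools10$library_size * 10
  scaled <- de_posterior(y, pools10, 1500)
  expect_equal(scaled$posterior_de, base$posterior_de, tolerance = 1e-6)
  expect_equal(scaled$theta_f * 10, base$theta_f, tolerance = 1e-6)
})

test_that("candidate selection applies all published criteria", {
  pools <- equal_pools()
  counts <- dplyr::bind_rows(
    one_contig_counts(c(80, 90, 85, 70, 75, 88), rep(0, 6),
                      length_bp = 500, id = "len500"),
    one_contig_counts(c(80, 90, 85, 70, 75, 88), rep(0, 6),
                      length_bp = 501, id = "len501"),
    one_contig_counts(c(80, 90, 85, 70, 75, 88), c(1, 0, 0, 0, 0, 0),
                      length_bp = 900, id = "one_male_read"),
    one_contig_counts(c(80, 90, 85, 70, 75, 88), rep(0, 6),
                      length_bp = 900, id = "listed_contaminant")
  )
  cfg <- screen_config(exclusion_list = "listed_contaminant")
  rep <- select_candidates(counts, pools, cfg)
  row <- function(id) rep[rep$contig_id == id, ]

  # exactly 500 bp fails the strictly-greater length criterion
  expect_false(row("len500")$length_ok)
  expect_false(row("len500")$final_candidate)
  expect_true(row("len501")$final_candidate)
  # a single male read anywhere breaks exclusivity
  expect_false(row("one_male_read")$exclusive)
  expect_false(row("one_male_read")$final_candidate)
  # exclusion-listed contigs never reach final candidacy
  expect_true(row("listed_contaminant")$excluded_as_contaminant)
  expect_true(row("listed_contaminant")$posterior_ok)
  expect_false(row("listed_contaminant")$final_candidate)
  # flag algebra
  expect_identical(rep$final_candidate,
                   rep$exclusive & rep$length_ok & rep$posterior_ok &
                     !rep$excluded_as_contaminant)

  expect_warning(select_candidates(counts, pools,
                                   screen_config(exclusion_list = "nope")),
                 "nope")
})

test_that("screen output is invariant to row permutation of the matrix", {
  tx <- simulate_transcriptome(60, seed = 31)
  cm <- simulate_count_matrix(tx, pool_design(seed = 32))
  rep1 <- select_candidates(cm$counts, cm$pools)
  perm <- withr::with_seed(1, sample(nrow(cm$counts)))
  rep2 <- select_candidates(cm$counts[perm, ], cm$pools)
  expect_equal(tidy(rep1), tidy(rep2))
})

test_that("screen recovers simulated W-linked transcripts", {
  tx <- simulate_transcriptome(
    200, c(w_linked = 0.1, autosomal = 0.8, female_biased = 0.05,
           contaminant = 0.05), seed = 41, length_range = c(501L, 3000L))
  cm <- simulate_count_matrix(tx, pool_design(seed = 42))
  rep <- select_candidates(cm$counts, cm$pools)
  w_ids <- tx$transcript_id[tx$class_label == "w_linked"]
  cand <- rep$contig_id[rep$final_candidate]
  expect_true(all(w_ids %in% cand))
  # any non-W candidate must owe its candidacy to a sampling-zero male
  # profile, never to an actual male read
  expect_true(all(rep$male_total[rep$final_candidate] == 0))
})

test_that("assembly coverage and N50 match direct formula evaluation", {
  expect_equal(assembly_coverage(1000, 200, 1200, 0), 1)
  expect_equal(assembly_coverage(1000, 200, 1300, 100), 1)
  expect_error(assembly_coverage(1000, 200, 100, 100), "positive")

  withr::with_seed(51, {
    for (i in 1:50) {
      g <- sample(200:3000, 1); u <- sample(0:500, 1)
      cl <- sample(200:3000, 1); nn <- sample(0:(cl - 1), 1)
      expect_equal(assembly_coverage(g, u, cl, nn), (g + u) / (cl - nn))
    }
  })

  expect_equal(compute_n50(c(5, 4, 3, 2, 1)), 4)
  expect_equal(compute_n50(7), 7)
  expect_equal(compute_n50(rep(42, 9)), 42)
  expect_error(compute_n50(integer(0)), "non-empty")
  withr::with_seed(52, {
    for (i in 1:50) {
      lens <- sample(100:5000, sample(1:40, 1), replace = TRUE)
      expect_equal(compute_n50(lens), brute_force_n50(lens))
    }
  })

  m <- assembly_metrics(c(5, 4, 3, 2, 1), kmer_size = 33)
  expect_equal(m$total_length, 15)
  expect_equal(m$n50, 4)
})
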