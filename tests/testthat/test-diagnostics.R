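test_that("global alignment matches exhaustive enumeration on short pairs", {
  # identical sequences: no gaps, score = match * length
  id <- global_align("ACGTAC", "ACGTAC")
  expect_equal(id$score, 12)
  expect_equal(id$aligned_a, "ACGTAC")
  expect_length(id$difference_positions, 0)
  # single forced mismatch
  one <- global_align("ACGT", "AGGT")
  expect_equal(one$difference_positions, 2)

  withr::with_seed(71, {
    for (i in 1:100) {
      a <- random_dna(sample(2:6, 1))
      b <- random_dna(sample(2:6, 1))
      got <- global_align(a, b)
      expect_equal(got$score, brute_force_align_score(a, b),
                   info = paste(a, b))
      # the returned alignment itself scores what it claims
      ca <- strsplit(got$aligned_a, "", fixed = TRUE)[[1]]
      cb <- strsplit(got$aligned_b, "", fixed = TRUE)[[1]]
      runs <- rle(ifelse(ca == "-", "ga", ifelse(cb == "-", "gb", "m")))
      rescore <- sum(ifelse(ca != "-" & cb != "-",
                            ifelse(ca == cb, 2, -1), 0)) -
        sum(12 + 2 * runs$lengths[runs$values != "m"])
      expect_equal(rescore, got$score, info = paste(a, b))
    }
  })
})

test_that("global alignment agrees with an independent aligner on longer pairs", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                  baseOnly = TRUE)
  withr::with_seed(72, {
    for (i in 1:25) {
      a <- random_dna(sample(20:60, 1))
      b <- random_dna(sample(20:60, 1))
      got <- global_align(a, b)
      ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                           substitutionMatrix = mat,
                                           gapOpening = 12,
                                           gapExtension = 2)
      expect_equal(got$score, Biostrings::score(ref), info = paste(a, b))
    }
  })
})

test_that("alignment score is symmetric and errors on empty input", {
  withr::with_seed(73, {
    a <- random_dna(30); b <- random_dna(25)
    expect_equal(global_align(a, b)$score, global_align(b, a)$score)
  })
  expect_error(global_align("", "ACGT"), "non-empty")
})

test_that("discriminating sites recover the simulator truth set exactly", {
  expect_equal(nrow(discriminating_sites(global_align("ACGTAC", "ACGTAC"))),
               0)
  withr::with_seed(74, {
    for (s in 1:5) {
      tpl <- random_dna(800)
      pair <- simulate_ortholog_pair(tpl, 0.04, seed = s)
      aln <- global_align(pair$seq_a, pair$seq_b)
      sites <- discriminating_sites(aln)
      expect_equal(sites$column, pair$positions)
      av <- strsplit(pair$seq_a, "", fixed = TRUE)[[1]]
      bv <- strsplit(pair$seq_b, "", fixed = TRUE)[[1]]
      expect_equal(sites$base_a, av[pair$positions])
      expect_equal(sites$base_b, bv[pair$positions])
    }
  })
  # gap columns are never reported
  gap <- global_align("AAACCCGGGTTTACGTACGT", "AAACCCTTTACGTACGT")
  sites <- discriminating_sites(gap)
  ca <- strsplit(gap$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(gap$aligned_b, "", fixed = TRUE)[[1]]
  expect_true(all(ca[sites$column] != "-" & cb[sites$column] != "-"))
})

test_that("diagnostic primers anchor 3' on true differences with positive delta-Tm", {
  expect_identical(
    attr(design_diagnostic_primers(global_align("ACGTACGTACGTACGTACGT",
                                                "ACGTACGTACGTACGTACGT")),
         "reason"),
    "insufficient_divergence")

  withr::with_seed(75, {
    for (s in 1:4) {
      tpl <- random_dna(1000)
      pair <- simulate_ortholog_pair(tpl, 0.05, seed = 100 + s)
      aln <- global_align(pair$seq_a, pair$seq_b)
      designs <- design_diagnostic_primers(aln, min_differences = 2)
      expect_gt(nrow(designs), 0)
      # forward 3' end and reverse 3' end sit on truth-set positions
      expect_true(all(designs$forward_end %in% pair$positions))
      expect_true(all(designs$reverse_start %in% pair$positions))
      expect_true(all(designs$forward_delta_tm > 0))
      expect_true(all(designs$reverse_delta_tm > 0))
      expect_true(all(designs$forward_diffs >= 2))
      expect_true(all(designs$reverse_diffs >= 2))
      # ranking: pair minimum delta-Tm is non-increasing
      expect_true(all(diff(designs$min_delta_tm) <= 1e-9))
    }
    # a stricter site requirement propagates to every emitted primer
    tpl <- random_dna(1000)
    pair <- simulate_ortholog_pair(tpl, 0.05, seed = 200)
    aln <- global_align(pair$seq_a, pair$seq_b)
    strict <- design_diagnostic_primers(aln, min_differences = 3)
    expect_true(all(strict$forward_diffs >= 3))
    expect_true(all(strict$reverse_diffs >= 3))
  })
})

test_that("an extra covered difference strictly increases delta-Tm", {
  # same window, same length: version with two mismatches vs one
  primer <- "AGCGTAAGCTTGCATGCCTG"
  ctx1 <- primer; substr(ctx1, 10, 10) <- "C"
  ctx2 <- ctx1; substr(ctx2, 4, 4) <- "A"
  d1 <- melting_temperature(primer) -
    melting_temperature(primer, complement_context = ctx1)
  d2 <- melting_temperature(primer) -
    melting_temperature(primer, complement_context = ctx2)
  expect_gt(d1, 0)
  expect_gt(d2, d1)
})

test_that("in-silico PCR finds constructed products and honours the 3' rule", {
  withr::with_seed(76, tpl <- random_dna(200))
  fwd <- substr(tpl, 1, 20)
  rev <- zwscreen:::revcomp(substr(tpl, 181, 200))
  hit <- in_silico_pcr(tpl, fwd, rev)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 1)
  expect_equal(hit$end, 200)
  expect_equal(hit$product_bp, 200)

  # a 3'-terminal mismatch on the forward primer kills the site
  fwd_bad <- fwd
  substr(fwd_bad, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                     substr(fwd, 20, 20))[1]
  expect_equal(nrow(in_silico_pcr(tpl, fwd_bad, rev)), 0)
  # ... unless the 3' match requirement is lifted
  expect_equal(nrow(in_silico_pcr(tpl, fwd_bad, rev,
                                  require_3prime_match = FALSE)), 1)
  # internal mismatches are tolerated up to the cap
  fwd_mm2 <- fwd
  substr(fwd_mm2, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                   substr(fwd, 5, 5))[1]
  substr(fwd_mm2, 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                     substr(fwd, 11, 11))[1]
  expect_equal(nrow(in_silico_pcr(tpl, fwd_mm2, rev)), 1)
  expect_equal(nrow(in_silico_pcr(tpl, fwd_mm2, rev,
                                  max_internal_mismatches = 1)), 0)
})

test_that("in-silico PCR equals a brute-force all-positions scan", {
  withr::with_seed(77, {
    for (i in 1:100) {
      tpl <- random_dna(sample(80:150, 1))
      # primers lifted from the template (sometimes mutated) or random
      pick <- function() {
        plen <- sample(12:18, 1)
        if (runif(1) < 0.7) {
          s <- sample(seq_len(nchar(tpl) - plen + 1), 1)
          p <- substr(tpl, s, s + plen - 1)
          if (runif(1) < 0.5) {
            pos <- sample(plen, 1)
            substr(p, pos, pos) <- sample(c("A", "C", "G", "T"), 1)
          }
          if (runif(1) < 0.5) p else zwscreen:::revcomp(p)
        } else {
          random_dna(plen)
        }
      }
      fwd <- pick(); rev <- pick()
      got <- in_silico_pcr(tpl, fwd, rev)
      want <- brute_force_pcr(tpl, fwd, rev)
      key <- function(d) sort(paste(d$start, d$end, d$product_bp, d$strand))
      expect_identical(key(got), key(want), info = paste("case", i))
    }
  })
})

test_that("in-silico PCR is strand-symmetric", {
  withr::with_seed(78, {
    for (i in 1:10) {
      tpl <- random_dna(150)
      fwd <- substr(tpl, 11, 26)
      rev <- zwscreen:::revcomp(substr(tpl, 120, 135))
      fwdhits <- in_silico_pcr(tpl, fwd, rev)
      mirror <- in_silico_pcr(zwscreen:::revcomp(tpl), rev, fwd)
      expect_equal(nrow(fwdhits), nrow(mirror))
      if (nrow(fwdhits)) {
        n <- nchar(tpl)
        expect_setequal(n - fwdhits$end + 1, mirror$start)
        expect_setequal(n - fwdhits$start + 1, mirror$end)
      }
    }
  })
})
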