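#' Interspecies discriminating sites from an alignment
#'
#' Lists exactly the alignment columns where both sequences are ungapped and
#' the bases differ — the sites a species-diagnostic primer can anchor on.
#'
#' @param alignment an `ortholog_alignment` from [global_align()].
#' @return tibble: `column` (1-based alignment column), `base_a`, `base_b`.
#' @export
#' @examples
#' discriminating_sites(global_align("ACGT", "AGGT"))
discriminating_sites <- function(alignment) {
  stopifnot(inherits(alignment, "ortholog_alignment"))
  ca <- strsplit(alignment$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(alignment$aligned_b, "", fixed = TRUE)[[1]]
  cols <- which(ca != "-" & cb != "-" & ca != cb)
  tibble(column = cols, base_a = ca[cols], base_b = cb[cols])
}

# longest runs of alignment columns ungapped in both sequences
ungapped_blocks <- function(ca, cb) {
  ok <- ca != "-" & cb != "-"
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble(start = starts[r$values], end = ends[r$values])
}

# enumerate primer windows whose 3' end sits on a difference column and
# which cover >= min_differences differences; orientation "+" anchors the
# right edge, "-" the left edge (reverse primer 3' end on template).
diagnostic_windows <- function(target_seq, other_seq, diff_cols, blocks,
                               orientation, min_differences, constraints) {
  lens <- constraints$primer_len_min:constraints$primer_len_max
  rows <- list()
  for (d in diff_cols) {
    blk <- blocks[blocks$start <= d & blocks$end >= d, ]
    if (nrow(blk) == 0) next
    for (len in lens) {
      if (orientation == "+") {
        start <- d - len + 1; end <- d
      } else {
        start <- d; end <- d + len - 1
      }
      if (start < blk$start[1] || end > blk$end[1]) next
      covered <- sum(diff_cols >= start & diff_cols <= end)
      if (covered < min_differences) next
      window_target <- substr(target_seq, start, end)
      window_other <- substr(other_seq, start, end)
      if (orientation == "+") {
        primer <- window_target
        context <- window_other
      } else {
        primer <- revcomp(window_target)
        context <- revcomp(window_other)
      }
      tm_on <- melting_temperature(primer, na_mM = constraints$na_mM,
                                   oligo_nM = constraints$oligo_nM)
      tm_off <- melting_temperature(primer, complement_context = context,
                                    na_mM = constraints$na_mM,
                                    oligo_nM = constraints$oligo_nM)
      rows[[length(rows) + 1]] <- tibble(
        orientation = orientation, start = start, end = end,
        anchor_column = d, sequence = primer,
        n_differences_covered = covered,
        three_prime_on_difference = TRUE,
        tm_on_target = tm_on, tm_off_target = tm_off,
        delta_tm = tm_on - tm_off
      )
    }
  }
  if (length(rows)) bind_rows(rows) else tibble(
    orientation = character(0), start = integer(0), end = integer(0),
    anchor_column = integer(0), sequence = character(0),
    n_differences_covered = integer(0),
    three_prime_on_difference = logical(0), tm_on_target = numeric(0),
    tm_off_target = numeric(0), delta_tm = numeric(0))
}

#' Design species-diagnostic primer pairs anchored on differences
#'
#' Designs allele-/species-specific primers for one member of an aligned
#' ortholog pair: every emitted primer has its 3'-terminal base on an
#' interspecies difference (so extension fails on the off-target species)
#' and covers at least `min_differences` such differences. For each window
#' the on-target Tm (perfect duplex) and off-target Tm (same oligo against
#' the other species, mismatch stacks zeroed) are computed; forward/reverse
#' pairs are ranked by the pair's minimum delta-Tm, descending, then by
#' total differences covered, then leftmost position — i.e. maximum melting
#' temperature difference between the species.
#'
#' @param alignment an `ortholog_alignment` from [global_align()].
#' @param target which sequence the primers should amplify ("a" or "b").
#' @param min_differences minimum differences a primer must cover
#'   (default 2).
#' @param constraints a [design_constraints()]; supplies primer length
#'   bounds and Tm chemistry (the sexing-assay Tm window is not applied —
#'   diagnostic primers are ranked by interspecies delta-Tm instead).
#' @param max_pairs cap on returned pairs (default 50).
#' @return tibble of class `zw_diagnostic_pairs`, one row per pair, with
#'   forward/reverse sequence, alignment coordinates, per-primer covered
#'   differences, both Tms, per-primer and pair delta-Tm, and the predicted
#'   product span on the alignment. If fewer than `min_differences` sites
#'   exist, a zero-row tibble with attribute `reason =
#'   "insufficient_divergence"`.
#' @export
design_diagnostic_primers <- function(alignment, target = "a",
                                      min_differences = 2L,
                                      constraints = design_constraints(),
                                      max_pairs = 50L) {
  stopifnot(inherits(alignment, "ortholog_alignment"),
            target %in% c("a", "b"))
  sites <- discriminating_sites(alignment)
  empty <- function(reason) {
    out <- tibble(
      forward_seq = character(0), forward_start = integer(0),
      forward_end = integer(0), forward_diffs = integer(0),
      forward_delta_tm = numeric(0),
      reverse_seq = character(0), reverse_start = integer(0),
      reverse_end = integer(0), reverse_diffs = integer(0),
      reverse_delta_tm = numeric(0),
      product_span = integer(0), min_delta_tm = numeric(0))
    class(out) <- c("zw_diagnostic_pairs", class(out))
    attr(out, "reason") <- reason
    out
  }
  if (nrow(sites) < min_differences) {
    return(empty("insufficient_divergence"))
  }
  target_seq <- if (target == "a") alignment$aligned_a else
    alignment$aligned_b
  other_seq <- if (target == "a") alignment$aligned_b else
    alignment$aligned_a
  ca <- strsplit(target_seq, "", fixed = TRUE)[[1]]
  cb <- strsplit(other_seq, "", fixed = TRUE)[[1]]
  blocks <- ungapped_blocks(ca, cb)

  fwd <- diagnostic_windows(target_seq, other_seq, sites$column, blocks,
                            "+", min_differences, constraints)
  rev <- diagnostic_windows(target_seq, other_seq, sites$column, blocks,
                            "-", min_differences, constraints)
  if (nrow(fwd) == 0 || nrow(rev) == 0) {
    return(empty("no_anchored_window"))
  }
  # keep the strongest windows per orientation before pairing
  top_n <- 100L
  fwd <- fwd |> arrange(desc(.data$delta_tm), .data$start) |>
    utils::head(top_n)
  rev <- rev |> arrange(desc(.data$delta_tm), .data$start) |>
    utils::head(top_n)
  pairs <- tidyr::expand_grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
  keep <- rev$start[pairs$r] > fwd$end[pairs$f]
  if (!any(keep)) return(empty("no_productive_pair"))
  fi <- pairs$f[keep]; ri <- pairs$r[keep]
  out <- tibble(
    forward_seq = fwd$sequence[fi],
    forward_start = fwd$start[fi], forward_end = fwd$end[fi],
    forward_diffs = fwd$n_differences_covered[fi],
    forward_delta_tm = fwd$delta_tm[fi],
    reverse_seq = rev$sequence[ri],
    reverse_start = rev$start[ri], reverse_end = rev$end[ri],
    reverse_diffs = rev$n_differences_covered[ri],
    reverse_delta_tm = rev$delta_tm[ri],
    product_span = rev$end[ri] - fwd$start[fi] + 1L
  ) |>
    mutate(min_delta_tm = pmin(.data$forward_delta_tm,
                               .data$reverse_delta_tm)) |>
    arrange(desc(.data$min_delta_tm),
            desc(.data$forward_diffs + .data$reverse_diffs),
            .data$forward_start, .data$reverse_end) |>
    utils::head(max_pairs)
  class(out) <- c("zw_diagnostic_pairs", class(out))
  out
}

# mismatch count between primer (5'->3') and a template window given as the
# sense-strand sequence the primer should equal
binding_sites <- function(primer, template, max_internal_mismatches,
                          require_3prime_match, primer_revcomp = FALSE) {
  plen <- nchar(primer)
  tlen <- nchar(template)
  if (tlen < plen) return(integer(0))
  starts <- seq_len(tlen - plen + 1)
  windows <- substring(template, starts, starts + plen - 1)
  probe <- if (primer_revcomp) revcomp(primer) else primer
  pch <- strsplit(probe, "", fixed = TRUE)[[1]]
  wch <- strsplit(windows, "", fixed = TRUE)
  ok <- vapply(wch, function(w) {
    mm <- w != pch
    # for a revcomp probe the primer 3' end sits at the window start
    three_prime_mm <- if (primer_revcomp) mm[1] else mm[plen]
    if (require_3prime_match && three_prime_mm) return(FALSE)
    sum(mm) <= max_internal_mismatches
  }, logical(1))
  starts[ok]
}

#' In-silico PCR product prediction
#'
#' Scans a template for binding sites of a forward and a reverse primer in
#' productive orientation and reports every predicted amplicon. A site binds
#' when it has at most `max_internal_mismatches` mismatches and (by default)
#' a perfectly matched 3'-terminal base — the allele-specific PCR rule. Both
#' template strands are scanned, so amplicons where the roles of the two
#' primers are exchanged (product on the opposite strand) are reported too.
#' Product size is the inclusive span between the two primers' 5' ends.
#'
#' @param template template sequence 5'->3' (ACGT).
#' @param forward,reverse primer sequences 5'->3', >= 12 bases.
#' @param max_internal_mismatches mismatches tolerated per site (default 2).
#' @param require_3prime_match reject sites whose 3'-terminal base
#'   mismatches (default TRUE).
#' @return tibble: `start`, `end` (1-based inclusive on the given
#'   template), `product_bp`, `strand` ("+" when the forward primer matches
#'   the plus strand). Zero rows when nothing amplifies.
#' @export
#' @examples
#' tpl <- strrep("ACGT", 50)
#' in_silico_pcr(tpl, substr(tpl, 1, 20),
#'               zwscreen:::revcomp(substr(tpl, 181, 200)))
in_silico_pcr <- function(template, forward, reverse,
                          max_internal_mismatches = 2L,
                          require_3prime_match = TRUE) {
  assert_dna(template, "template")
  assert_dna(forward, "forward primer"); assert_dna(reverse, "reverse primer")
  if (nchar(forward) < 12 || nchar(reverse) < 12) {
    abort("primers must be at least 12 bases")
  }
  scan_orientation <- function(p_fwd, p_rev, strand) {
    f_sites <- binding_sites(p_fwd, template, max_internal_mismatches,
                             require_3prime_match)
    r_sites <- binding_sites(p_rev, template, max_internal_mismatches,
                             require_3prime_match, primer_revcomp = TRUE)
    if (!length(f_sites) || !length(r_sites)) return(NULL)
    grid <- tidyr::expand_grid(fs = f_sites, rs = r_sites)
    f_end <- grid$fs + nchar(p_fwd) - 1
    r_end <- grid$rs + nchar(p_rev) - 1
    keep <- grid$rs > f_end  # non-overlapping, productive orientation
    if (!any(keep)) return(NULL)
    tibble(start = grid$fs[keep], end = r_end[keep],
           product_bp = r_end[keep] - grid$fs[keep] + 1L,
           strand = strand)
  }
  out <- bind_rows(
    scan_orientation(forward, reverse, "+"),
    scan_orientation(reverse, forward, "-")
  )
  if (nrow(out) == 0) {
    return(tibble(start = integer(0), end = integer(0),
                  product_bp = integer(0), strand = character(0)))
  }
  out |> dplyr::distinct() |> arrange(.data$start, .data$end, .data$strand)
}
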