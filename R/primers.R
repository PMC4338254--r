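#' Primer design constraints
#'
#' Constraint set for sexing-marker primer design. Defaults reproduce the
#' settings the assay was developed with: Tm min/opt/max 59/60/61 with at
#' most 1 degree difference within a pair, homopolymer runs capped at 3, a
#' one-base G/C clamp at the 3' end, and products of 480-520 bp (optimum
#' 500) so that genomic introns enlarging a product remain detectable.
#'
#' @param tm_min,tm_opt,tm_max primer Tm bounds and optimum, degrees C.
#' @param tm_pair_max_diff maximum |Tm_F - Tm_R| within a pair, degrees C.
#' @param max_poly_x longest allowed homopolymer run.
#' @param gc_clamp number of 3'-terminal bases required to be G or C.
#' @param product_min,product_opt,product_max product size bounds, bp.
#' @param primer_len_min,primer_len_max primer length bounds, bp.
#' @param na_mM,oligo_nM salt and oligo concentrations for Tm calculation.
#' @return list of class `design_constraints`.
#' @export
design_constraints <- function(tm_min = 59, tm_opt = 60, tm_max = 61,
                               tm_pair_max_diff = 1,
                               max_poly_x = 3, gc_clamp = 1,
                               product_min = 480, product_opt = 500,
                               product_max = 520,
                               primer_len_min = 18, primer_len_max = 27,
                               na_mM = 50, oligo_nM = 500) {
  if (!(tm_min <= tm_opt && tm_opt <= tm_max)) {
    abort("need tm_min <= tm_opt <= tm_max")
  }
  if (!(product_min <= product_opt && product_opt <= product_max)) {
    abort("need product_min <= product_opt <= product_max")
  }
  structure(as.list(environment()), class = "design_constraints")
}

#' Quality flags for a single primer
#'
#' @param sequence primer 5'->3'.
#' @param constraints a [design_constraints()].
#' @return one-row tibble: `sequence`, `tm_c`, `gc_fraction`, `max_run`,
#'   `tm_ok`, `clamp_ok`, `run_ok`.
#' @export
#' @examples
#' primer_quality("AGCGTAAGCTTGCATGCCTG")
primer_quality <- function(sequence, constraints = design_constraints()) {
  assert_dna(sequence, "primer")
  tm <- melting_temperature(sequence, na_mM = constraints$na_mM,
                            oligo_nM = constraints$oligo_nM)
  tail_bases <- substring(sequence,
                          nchar(sequence) - constraints$gc_clamp + 1,
                          nchar(sequence))
  clamp_ok <- constraints$gc_clamp == 0 ||
    !grepl("[AT]", tail_bases)
  run <- max_homopolymer_run(sequence)
  tibble(
    sequence = sequence,
    tm_c = tm,
    gc_fraction = gc_fraction(sequence),
    max_run = run,
    tm_ok = tm >= constraints$tm_min & tm <= constraints$tm_max,
    clamp_ok = clamp_ok,
    run_ok = run <= constraints$max_poly_x
  )
}

# Tm for every window of the template in one pass: per-position stack
# dH/dS cumulative sums give O(1) window sums. Returns a function
# tm(start, end) vectorised over equal-length windows.
template_tm_fun <- function(template, na_mM, oligo_nM) {
  ch <- strsplit(template, "", fixed = TRUE)[[1]]
  n <- length(ch)
  stacks <- paste0(ch[-n], ch[-1])
  cum_dh <- c(0, cumsum(NN_DH[stacks]))
  cum_ds <- c(0, cumsum(NN_DS[stacks]))
  rln <- GAS_CONSTANT * log(oligo_nM * 1e-9 / 4)
  salt <- 16.6 * log10(na_mM / 1000)
  function(start, end) {
    dh <- cum_dh[end] - cum_dh[start] + INIT_DH[ch[start]] + INIT_DH[ch[end]]
    ds <- cum_ds[end] - cum_ds[start] + INIT_DS[ch[start]] + INIT_DS[ch[end]]
    1000 * dh / (ds + rln) - 273.15 + salt
  }
}

# all windows of the template passing single-primer constraints, for one
# orientation; returns tibble with start/end (1-based template coords),
# primer sequence, tm
candidate_windows <- function(template, constraints, strand) {
  n <- nchar(template)
  lens <- constraints$primer_len_min:constraints$primer_len_max
  tmf <- template_tm_fun(template, constraints$na_mM, constraints$oligo_nM)
  grid <- tidyr::expand_grid(start = seq_len(n), len = lens) |>
    mutate(end = .data$start + .data$len - 1) |>
    filter(.data$end <= n)
  window_seq <- substring(template, grid$start, grid$end)
  primer_seq <- if (strand == "+") window_seq else revcomp(window_seq)
  # duplex Tm is strand-independent; clamp/runs are checked on the primer
  tm <- tmf(grid$start, grid$end)
  clamp_end <- if (constraints$gc_clamp == 0) {
    rep(TRUE, nrow(grid))
  } else {
    tail3 <- if (strand == "+") {
      substring(template, grid$end - constraints$gc_clamp + 1, grid$end)
    } else {
      # reverse primer 3' end corresponds to the window start on template
      substring(template, grid$start, grid$start + constraints$gc_clamp - 1)
    }
    !grepl("[AT]", tail3)
  }
  grid |>
    mutate(sequence = primer_seq, tm_c = tm, clamp_ok = clamp_end,
           max_run = max_homopolymer_run(window_seq), strand = strand) |>
    filter(.data$tm_c >= constraints$tm_min,
           .data$tm_c <= constraints$tm_max,
           .data$clamp_ok,
           .data$max_run <= constraints$max_poly_x)
}

#' Enumerate and rank primer pairs on a template
#'
#' Exhaustively enumerates forward and reverse primer windows within the
#' length bounds, keeps windows passing the single-primer constraints (Tm
#' window, G/C clamp, homopolymer cap), and pairs them when the product size
#' falls in the configured range and the pair's Tm difference is within
#' bounds. Product size is the inclusive span from the forward primer's 5'
#' base to the reverse primer's 5' base on the template. Pairs are ranked by
#' `|Tm_F - tm_opt| + |Tm_R - tm_opt| + |product - product_opt|/100`, ties
#' broken by leftmost forward start then reverse end.
#'
#' @param template template sequence 5'->3' (ACGT).
#' @param constraints a [design_constraints()].
#' @return tibble of class `zw_primer_pairs`, one row per feasible pair:
#'   forward/reverse sequences and 1-based positions, Tms, `product_bp`,
#'   `tm_diff`, `score`. Zero rows if nothing is feasible; the attribute
#'   `failure_summary` then reports counts per failed criterion.
#' @export
enumerate_candidate_pairs <- function(template,
                                      constraints = design_constraints()) {
  assert_dna(template, "template")
  n <- nchar(template)
  empty <- function(reason) {
    out <- tibble(
      forward_seq = character(0), forward_start = integer(0),
      forward_end = integer(0), forward_tm = numeric(0),
      reverse_seq = character(0), reverse_start = integer(0),
      reverse_end = integer(0), reverse_tm = numeric(0),
      product_bp = integer(0), tm_diff = numeric(0), score = numeric(0)
    )
    class(out) <- c("zw_primer_pairs", class(out))
    attr(out, "failure_summary") <- reason
    out
  }
  if (n < constraints$product_min) {
    return(empty(c(template_too_short = 1)))
  }
  fwd <- candidate_windows(template, constraints, "+")
  rev <- candidate_windows(template, constraints, "-")
  if (nrow(fwd) == 0 || nrow(rev) == 0) {
    return(empty(c(no_forward_window = as.integer(nrow(fwd) == 0),
                   no_reverse_window = as.integer(nrow(rev) == 0))))
  }
  pairs <- tidyr::expand_grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
  product <- rev$end[pairs$r] - fwd$start[pairs$f] + 1
  keep_prod <- product >= constraints$product_min &
    product <= constraints$product_max
  # primers must not overlap each other
  keep_prod <- keep_prod & rev$start[pairs$r] > fwd$end[pairs$f]
  tm_diff <- abs(fwd$tm_c[pairs$f] - rev$tm_c[pairs$r])
  keep_tm <- tm_diff <= constraints$tm_pair_max_diff
  keep <- keep_prod & keep_tm
  if (!any(keep)) {
    return(empty(c(product_size = sum(!keep_prod),
                   tm_pair_diff = sum(keep_prod & !keep_tm))))
  }
  fi <- pairs$f[keep]; ri <- pairs$r[keep]
  out <- tibble(
    forward_seq = fwd$sequence[fi],
    forward_start = fwd$start[fi], forward_end = fwd$end[fi],
    forward_tm = fwd$tm_c[fi],
    reverse_seq = rev$sequence[ri],
    reverse_start = rev$start[ri], reverse_end = rev$end[ri],
    reverse_tm = rev$tm_c[ri],
    product_bp = as.integer(product[keep]),
    tm_diff = tm_diff[keep]
  ) |>
    mutate(score = abs(.data$forward_tm - constraints$tm_opt) +
             abs(.data$reverse_tm - constraints$tm_opt) +
             abs(.data$product_bp - constraints$product_opt) / 100) |>
    arrange(.data$score, .data$forward_start, .data$reverse_end)
  class(out) <- c("zw_primer_pairs", class(out))
  attr(out, "constraints") <- constraints
  out
}

#' Multiplex product-size compatibility
#'
#' A multiplex PCR with a positive control is readable on a gel only if all
#' product sizes are separated and the control band sits below every
#' candidate band. Checks all pairwise separations and the control position.
#'
#' @param product_sizes candidate product sizes in bp.
#' @param control_product_bp positive-control product size (default 259).
#' @param min_separation_bp minimum band separation in bp (default 40).
#' @return list: `compatible` (logical) and `conflicts` (tibble of
#'   offending pairs; the control appears as id "control").
#' @export
#' @examples
#' multiplex_compatible(c(500), control_product_bp = 259)
multiplex_compatible <- function(product_sizes, control_product_bp = 259,
                                 min_separation_bp = 40) {
  if (any(c(product_sizes, control_product_bp) <= 0)) {
    abort("product sizes must be positive")
  }
  ids <- paste0("candidate", seq_along(product_sizes))
  all_ids <- c(ids, "control")
  all_sizes <- c(product_sizes, control_product_bp)
  conflicts <- list()
  m <- length(all_sizes)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (abs(all_sizes[i] - all_sizes[j]) < min_separation_bp) {
        conflicts[[length(conflicts) + 1]] <-
          tibble(id_a = all_ids[i], id_b = all_ids[j],
                 size_a = all_sizes[i], size_b = all_sizes[j])
      }
    }
  }
  control_below <- length(product_sizes) == 0 ||
    control_product_bp < min(product_sizes)
  conflicts <- if (length(conflicts)) bind_rows(conflicts) else
    tibble(id_a = character(0), id_b = character(0),
           size_a = numeric(0), size_b = numeric(0))
  list(compatible = nrow(conflicts) == 0 && control_below,
       control_below_candidates = control_below,
       conflicts = conflicts)
}
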