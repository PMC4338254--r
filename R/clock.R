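#' Calibrated molecular-clock rate range
#'
#' A locus-specific range of substitution rates (changes/site/Myr) from
#' calibrated teleost mitochondrial clocks. Bundled presets:
#' `clock_rates("cytb")` gives 0.0076-0.0036 and
#' `clock_rates("control_region")` gives 0.044-0.004.
#'
#' @param locus_name preset name ("cytb", "control_region") or any label
#'   when rates are supplied.
#' @param rate_fast,rate_slow fastest and slowest calibrated rates,
#'   changes/site/Myr.
#' @return list of class `clock_rate_range`.
#' @export
clock_rates <- function(locus_name, rate_fast = NULL, rate_slow = NULL) {
  presets <- list(cytb = c(fast = 0.0076, slow = 0.0036),
                  control_region = c(fast = 0.044, slow = 0.004))
  if (is.null(rate_fast) || is.null(rate_slow)) {
    if (!locus_name %in% names(presets)) {
      abort(paste0("no preset rates for '", locus_name,
                   "'; supply rate_fast and rate_slow"))
    }
    rate_fast <- presets[[locus_name]][["fast"]]
    rate_slow <- presets[[locus_name]][["slow"]]
  }
  if (!(rate_fast >= rate_slow && rate_slow > 0)) {
    abort("need rate_fast >= rate_slow > 0")
  }
  structure(list(locus_name = locus_name, rate_fast = rate_fast,
                 rate_slow = rate_slow), class = "clock_rate_range")
}

#' Uncorrected pairwise distance (p-distance)
#'
#' The fraction of differing sites between two aligned sequences, with no
#' multiple-hit correction, rounded half-up to 4 decimals (2 decimals as a
#' percentage) — the reporting precision the downstream age calculation
#' uses. Either give counts directly or an `ortholog_alignment`, in which
#' case ungapped mismatch columns over ungapped columns are counted.
#'
#' @param n_differences number of differing sites, or an
#'   `ortholog_alignment`.
#' @param n_sites number of compared sites (ignored when an alignment is
#'   given).
#' @return p-distance as a fraction rounded to 4 decimals.
#' @export
#' @examples
#' p_distance(6, 396)   # 0.0152
#' p_distance(41, 876)  # 0.0468
p_distance <- function(n_differences, n_sites = NULL) {
  if (inherits(n_differences, "ortholog_alignment")) {
    aln <- n_differences
    ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
    cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
    ungapped <- ca != "-" & cb != "-"
    n_sites <- sum(ungapped)
    n_differences <- sum(ungapped & ca != cb)
  }
  if (is.null(n_sites) || n_sites <= 0) {
    abort("n_sites must be a positive integer")
  }
  if (n_differences < 0 || n_differences > n_sites) {
    abort("need 0 <= n_differences <= n_sites")
  }
  round_half_up(n_differences / n_sites, 4)
}

#' Divergence-time range from a p-distance and a clock-rate range
#'
#' Divides the (pre-rounded) p-distance by the fastest and slowest
#' calibrated rates to bracket the divergence time:
#' `t_min = p / rate_fast`, `t_max = p / rate_slow`, each rounded half-up to
#' 2 decimals (Myr). No multiple-hit correction is applied.
#'
#' @param p p-distance as a fraction (as returned by [p_distance()], i.e.
#'   already rounded to 4 decimals).
#' @param rates a [clock_rates()] range.
#' @return one-row tibble of class `zw_divergence`: `locus`, `p_distance`,
#'   `rate_fast`, `rate_slow`, `t_min_myr`, `t_max_myr`.
#' @export
#' @examples
#' divergence_time_range(p_distance(41, 876), clock_rates("cytb"))
divergence_time_range <- function(p, rates) {
  stopifnot(inherits(rates, "clock_rate_range"))
  if (p < 0) abort("p must be >= 0")
  out <- tibble(
    locus = rates$locus_name,
    p_distance = p,
    rate_fast = rates$rate_fast,
    rate_slow = rates$rate_slow,
    t_min_myr = round_half_up(p / rates$rate_fast, 2),
    t_max_myr = round_half_up(p / rates$rate_slow, 2)
  )
  class(out) <- c("zw_divergence", class(out))
  out
}

#' Full divergence estimate from difference counts
#'
#' Convenience wrapper: p-distance from counts, then the age range.
#'
#' @param n_differences,n_sites aligned difference and site counts.
#' @param rates a [clock_rates()] range.
#' @return one-row `zw_divergence` tibble with `n_differences`, `n_sites`
#'   prepended.
#' @export
#' @examples
#' divergence_estimate(6, 396, clock_rates("control_region"))
divergence_estimate <- function(n_differences, n_sites, rates) {
  p <- p_distance(n_differences, n_sites)
  out <- bind_cols(tibble(n_differences = n_differences, n_sites = n_sites),
                   divergence_time_range(p, rates))
  class(out) <- c("zw_divergence", class(out))
  out
}
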