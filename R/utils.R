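# internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed percentages and ages in the
#' reporting conventions used here round half up (0.015151 -> 0.0152,
#' 0.345 -> 0.35), so a half-up rule is applied wherever a value is rounded
#' for reporting.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Reverse complement of a DNA string
#' @param x character vector of sequences over ACGTN.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# derive a reproducible child seed (< 2^31) from a base seed and an index;
# used so per-row draws are invariant to evaluation order
child_seed <- function(seed, index) {
  m <- 2147483647
  mixed <- ((as.numeric(seed) %% m) * 48271) %% m +
    (as.numeric(index) * 69621) %% m
  as.integer(mixed %% m)
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

assert_dna <- function(x, what = "sequence", allow_n = FALSE) {
  pattern <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- !grepl(pattern, x)
  if (any(bad)) {
    abort(sprintf("%s must contain only %s (offending value: '%s')",
                  what, if (allow_n) "A/C/G/T/N" else "A/C/G/T",
                  substr(x[bad][1], 1, 30)))
  }
  invisible(x)
}

# longest homopolymer run length
max_homopolymer_run <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE), function(ch) {
    max(rle(ch)$lengths)
  }, numeric(1))
}

gc_fraction <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE), function(ch) {
    mean(ch %in% c("G", "C"))
  }, numeric(1))
}
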