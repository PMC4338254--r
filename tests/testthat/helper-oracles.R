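# independent oracles and small fixture builders used across test files

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# six F + six M pools at equal depth
equal_pools <- function(lib = 1e6) {
  tibble::tibble(pool_id = c(paste0("F", 1:6), paste0("M", 1:6)),
                 sex = rep(c("F", "M"), each = 6),
                 library_size = lib)
}

# one-row counts tibble in the screen's input shape
one_contig_counts <- function(f_counts, m_counts, length_bp = 1000,
                              id = "contigX") {
  row <- c(list(contig_id = id, length_bp = length_bp),
           as.list(stats::setNames(c(f_counts, m_counts),
                                   c(paste0("F", seq_along(f_counts)),
                                     paste0("M", seq_along(m_counts))))))
  tibble::as_tibble(row)
}

# Exhaustive global-alignment score: plain recursion over all monotone
# alignment paths with an affine gap state; no dynamic-programming reuse,
# so it is independent of the package's matrices. Gap of length k costs
# open + k * extend.
brute_force_align_score <- function(a, b, match = 2, mismatch = -1,
                                    gap_open = 12, gap_extend = 2) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      s <- (if (av[i] == bv[j]) match else mismatch) + rec(i + 1, j + 1, "M")
      if (s > best) best <- s
    }
    if (i <= n) {
      cost <- if (prev == "E") -gap_extend else -(gap_open + gap_extend)
      s <- cost + rec(i + 1, j, "E")
      if (s > best) best <- s
    }
    if (j <= m) {
      cost <- if (prev == "F") -gap_extend else -(gap_open + gap_extend)
      s <- cost + rec(i, j + 1, "F")
      if (s > best) best <- s
    }
    best
  }
  rec(1, 1, "M")
}

# brute-force in-silico PCR: scan every start position for both primers on
# both strands with straightforward character comparisons
brute_force_pcr <- function(template, forward, reverse,
                            max_internal_mismatches = 2,
                            require_3prime_match = TRUE) {
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1]]),
          collapse = "")
  }
  sites <- function(primer, as_right_primer) {
    plen <- nchar(primer)
    probe <- if (as_right_primer) rc(primer) else primer
    hits <- integer(0)
    for (s in seq_len(nchar(template) - plen + 1)) {
      w <- substr(template, s, s + plen - 1)
      mm <- strsplit(w, "", fixed = TRUE)[[1]] !=
        strsplit(probe, "", fixed = TRUE)[[1]]
      tp <- if (as_right_primer) mm[1] else mm[plen]
      if (require_3prime_match && tp) next
      if (sum(mm) <= max_internal_mismatches) hits <- c(hits, s)
    }
    hits
  }
  out <- list()
  for (orient in c("+", "-")) {
    left <- if (orient == "+") forward else reverse
    right <- if (orient == "+") reverse else forward
    for (fs in sites(left, FALSE)) {
      for (rs in sites(right, TRUE)) {
        if (rs > fs + nchar(left) - 1) {
          re <- rs + nchar(right) - 1
          out[[length(out) + 1]] <- data.frame(
            start = fs, end = re, product_bp = re - fs + 1, strand = orient)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      product_bp = integer(0), strand = character(0)))
  }
  res <- unique(do.call(rbind, out))
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}

# direct N50 from the definition: largest L with sum(lengths >= L) >= total/2
brute_force_n50 <- function(lengths) {
  total <- sum(lengths)
  max(Filter(function(L) sum(lengths[lengths >= L]) >= total / 2,
             sort(unique(lengths))))
}
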