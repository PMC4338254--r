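#' Global alignment with affine gap penalties
#'
#' Needleman–Wunsch global alignment of two DNA sequences with an affine gap
#' cost (a gap of length k costs `gap_open + k * gap_extend`). The dynamic
#' program is exact; the traceback is deterministic, preferring a diagonal
#' move, then a gap in `seq_b` (up), then a gap in `seq_a` (left) at score
#' ties. Default scores echo the gap weights used for the published
#' alignments (open 12, extend 2) with simple DNA match/mismatch scoring.
#'
#' @param seq_a,seq_b DNA strings over ACGT.
#' @param match match score (default 2).
#' @param mismatch mismatch score (default -1).
#' @param gap_open gap opening penalty, positive (default 12).
#' @param gap_extend per-base gap extension penalty, positive (default 2).
#' @return list of class `ortholog_alignment`: `aligned_a`, `aligned_b`
#'   (equal-length strings with `-` gaps), `score`, and
#'   `difference_positions` (alignment columns where both are ungapped and
#'   unequal, ascending).
#' @export
#' @examples
#' global_align("ACGT", "AGGT")$difference_positions
global_align <- function(seq_a, seq_b, match = 2, mismatch = -1,
                         gap_open = 12, gap_extend = 2) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    abort("sequences must be non-empty")
  }
  assert_dna(seq_a, "seq_a"); assert_dna(seq_b, "seq_b")
  a <- strsplit(seq_a, "", fixed = TRUE)[[1]]
  b <- strsplit(seq_b, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  go <- -abs(gap_open); ge <- -abs(gap_extend)
  NEG <- -1e18

  # M[i+1, j+1]: best score of alignment of a[1..i], b[1..j] ending in a
  # diagonal; E ends with gap in seq_b (consumes a, "up"); F ends with gap
  # in seq_a (consumes b, "left"). Row-wise DP, vectorised along j.
  M <- matrix(NEG, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F_ <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  F_[1, 2:(m + 1)] <- go + ge * seq_len(m)
  E[2:(n + 1), 1] <- go + ge * seq_len(n)

  for (i in 2:(n + 1)) {
    prev_best <- pmax(M[i - 1, ], E[i - 1, ], F_[i - 1, ])
    # E: gap in b, moving down
    E[i, ] <- pmax(pmax(M[i - 1, ], F_[i - 1, ]) + go + ge,
                   E[i - 1, ] + ge)
    # M: diagonal
    sub <- ifelse(a[i - 1] == b, match, mismatch)
    M[i, 2:(m + 1)] <- prev_best[1:m] + sub
    # F: gap in a, moving right; sequential along j -> cummax trick:
    # F[j] = max(max(M[j-1],E[j-1]) + go + ge, F[j-1] + ge)
    #      = ge*j + max over k<=j-1 of base[k] where
    #        base[k] = max(M[k],E[k],F0...) handled via cummax
    open_base <- pmax(M[i, ], E[i, ]) + go  # at column k, opening after k
    run <- rep(NEG, m + 1)
    # F[i, j] = max_{k < j} ( max(M[i,k], E[i,k]) + go + ge*(j-k) )
    # => F[i, j] - ge*j = cummax_{k<j} (open_base[k] - ge*k)
    shifted <- open_base - ge * (0:m)
    run[2:(m + 1)] <- cummax(shifted[1:m])
    F_[i, 2:(m + 1)] <- run[2:(m + 1)] + ge * (1:m)
  }

  score <- max(M[n + 1, m + 1], E[n + 1, m + 1], F_[n + 1, m + 1])

  # traceback with deterministic preference: diagonal (M) > up (E) > left (F)
  tol <- 1e-9
  pick_state <- function(vals, target) {
    # vals named M/E/F; first match in preference order wins
    for (s in c("M", "E", "F")) {
      if (!is.na(vals[[s]]) && abs(vals[[s]] - target) < tol) return(s)
    }
    abort("alignment traceback failed (internal error)")
  }
  out_a <- character(0); out_b <- character(0)
  i <- n; j <- m
  state <- pick_state(list(M = M[n + 1, m + 1], E = E[n + 1, m + 1],
                           F = F_[n + 1, m + 1]), score)
  while (i > 0 || j > 0) {
    if (state == "M") {
      out_a <- c(a[i], out_a); out_b <- c(b[j], out_b)
      target <- M[i + 1, j + 1] - (if (a[i] == b[j]) match else mismatch)
      i <- i - 1; j <- j - 1
      if (i == 0 && j == 0) break
      state <- pick_state(list(M = M[i + 1, j + 1], E = E[i + 1, j + 1],
                               F = F_[i + 1, j + 1]), target)
    } else if (state == "E") {
      out_a <- c(a[i], out_a); out_b <- c("-", out_b)
      target <- E[i + 1, j + 1]
      i <- i - 1
      if (i == 0 && j == 0) break
      state <- pick_state(list(M = M[i + 1, j + 1] + go + ge,
                               E = E[i + 1, j + 1] + ge,
                               F = F_[i + 1, j + 1] + go + ge), target)
    } else {
      out_a <- c("-", out_a); out_b <- c(b[j], out_b)
      target <- F_[i + 1, j + 1]
      j <- j - 1
      if (i == 0 && j == 0) break
      state <- pick_state(list(M = M[i + 1, j + 1] + go + ge,
                               E = E[i + 1, j + 1] + go + ge,
                               F = F_[i + 1, j + 1] + ge), target)
    }
  }

  aligned_a <- paste(out_a, collapse = "")
  aligned_b <- paste(out_b, collapse = "")
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  structure(list(
    aligned_a = aligned_a,
    aligned_b = aligned_b,
    score = score,
    difference_positions = which(ca != "-" & cb != "-" & ca != cb)
  ), class = "ortholog_alignment")
}

#' @export
print.ortholog_alignment <- function(x, ...) {
  cat("Global alignment (score ", x$score, ", ",
      length(x$difference_positions), " substitution column(s))\n",
      sep = "")
  cat("A: ", substr(x$aligned_a, 1, 60),
      if (nchar(x$aligned_a) > 60) "..." else "", "\n", sep = "")
  cat("B: ", substr(x$aligned_b, 1, 60),
      if (nchar(x$aligned_b) > 60) "..." else "", "\n", sep = "")
  invisible(x)
}
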