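#' Screen configuration
#'
#' Settings of the female-specific candidate screen. Defaults encode the
#' published criteria: candidates must be strictly longer than 500 bp,
#' assembled exclusively from female reads (zero reads in every male pool),
#' and carry a differential-expression posterior indistinguishable from 1.
#'
#' @param min_length_bp minimum contig length in bp; candidates must satisfy
#'   `length_bp >= min_length_bp`. Default 501, i.e. strictly > 500 bp.
#' @param posterior_threshold posterior_de required for the DE criterion
#'   (default `1 - 1e-6`, operationalising "likelihood of DE = 1").
#' @param min_female_pools_present minimum number of female pools with at
#'   least one read (default 1; per-pool assembly needs only one pool).
#' @param max_male_reads_total maximum total reads across male pools
#'   (default 0 — true exclusivity).
#' @param prior_de prior probability of differential expression used in the
#'   two-model posterior (default 0.05).
#' @param exclusion_list character vector of contig ids to drop as known
#'   contaminants (e.g. from a database search done outside this package).
#' @return list of class `screen_config`.
#' @export
screen_config <- function(min_length_bp = 501L,
                          posterior_threshold = 1 - 1e-6,
                          min_female_pools_present = 1L,
                          max_male_reads_total = 0L,
                          prior_de = 0.05,
                          exclusion_list = character(0)) {
  if (posterior_threshold <= 0 || posterior_threshold > 1) {
    abort("posterior_threshold must be in (0, 1]")
  }
  if (prior_de <= 0 || prior_de >= 1) abort("prior_de must be in (0, 1)")
  if (min_length_bp < 0 || max_male_reads_total < 0 ||
      min_female_pools_present < 0) {
    abort("thresholds must be non-negative")
  }
  structure(list(
    min_length_bp = as.integer(min_length_bp),
    posterior_threshold = posterior_threshold,
    min_female_pools_present = as.integer(min_female_pools_present),
    max_male_reads_total = as.integer(max_male_reads_total),
    prior_de = prior_de,
    exclusion_list = as.character(exclusion_list)
  ), class = "screen_config")
}

check_counts_input <- function(counts, pools) {
  stopifnot(is.data.frame(counts), is.data.frame(pools),
            all(c("contig_id", "length_bp") %in% names(counts)),
            all(c("pool_id", "sex", "library_size") %in% names(pools)))
  missing_pools <- setdiff(pools$pool_id, names(counts))
  if (length(missing_pools)) {
    abort(paste0("counts is missing pool column(s): ",
                 paste(missing_pools, collapse = ", ")))
  }
  bad_lib <- pools$pool_id[pools$library_size <= 0]
  if (length(bad_lib)) {
    abort(paste0("non-positive library size for pool(s): ",
                 paste(bad_lib, collapse = ", ")))
  }
  bad_len <- counts$contig_id[counts$length_bp <= 0]
  if (length(bad_len)) {
    abort(paste0("non-positive length for contig(s): ",
                 paste(utils::head(bad_len, 5), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Normalize counts over library size and gene length
#'
#' Converts raw per-pool counts to rates
#' `counts / (library_size * length_bp) * scale`, with
#' `scale = median(library_size) * median(length_bp)` so values stay on a
#' readable count-like scale. The scale is attached as attribute `scale`.
#'
#' @param counts counts tibble (`contig_id`, `length_bp`, one column per
#'   pool), e.g. `simulate_count_matrix(...)$counts`.
#' @param pools pool metadata tibble (`pool_id`, `sex`, `library_size`).
#' @return tibble of the same shape with normalized rates in pool columns.
#' @export
normalize_counts <- function(counts, pools) {
  check_counts_input(counts, pools)
  scale <- median(pools$library_size) * median(counts$length_bp)
  out <- counts
  for (k in seq_len(nrow(pools))) {
    p <- pools$pool_id[k]
    out[[p]] <- counts[[p]] / (pools$library_size[k] * counts$length_bp) *
      scale
  }
  attr(out, "scale") <- scale
  out
}

#' Does a contig pass the female-exclusivity criterion?
#'
#' A contig is "constructed exclusively from female reads" when its total
#' count over male pools is at most `max_male_reads_total` (default 0) and
#' it is present (>= 1 read) in at least `min_female_pools_present` female
#' pools.
#'
#' @inheritParams normalize_counts
#' @param config a [screen_config()].
#' @return logical vector, one element per contig row.
#' @export
female_exclusive_filter <- function(counts, pools, config = screen_config()) {
  check_counts_input(counts, pools)
  f_pools <- pools$pool_id[pools$sex == "F"]
  m_pools <- pools$pool_id[pools$sex == "M"]
  male_total <- rowSums(as.matrix(counts[m_pools]))
  female_present <- rowSums(as.matrix(counts[f_pools]) >= 1)
  male_total <= config$max_male_reads_total &
    female_present >= config$min_female_pools_present
}

#' Method-of-moments NB dispersion for one contig
#'
#' Counts are offset-scaled to a common depth (`x = y / offset * mean(offset)`
#' with `offset = library_size * length_bp`), the sample variance is pooled
#' within sexes (so a real sex effect does not inflate it), and
#' `phi_hat = max(0, (s2 - m) / m^2)` with `m` the overall mean of the scaled
#' counts. Under-dispersed rows floor at 0; an all-zero row returns 0 with
#' attribute `all_zero = TRUE`.
#'
#' @param row_counts integer vector of per-pool counts (>= 2 pools).
#' @param library_sizes per-pool library sizes.
#' @param contig_length contig length in bp.
#' @param pool_sex per-pool "F"/"M" labels; if omitted all pools are pooled
#'   as one group.
#' @return non-negative dispersion estimate.
#' @export
estimate_dispersion <- function(row_counts, library_sizes, contig_length,
                                pool_sex = NULL) {
  if (length(row_counts) < 2) abort("need at least 2 pools")
  offsets <- library_sizes * contig_length
  if (any(offsets <= 0)) abort("offsets must be positive")
  if (all(row_counts == 0)) {
    return(structure(0, all_zero = TRUE))
  }
  x <- row_counts / offsets * mean(offsets)
  groups <- if (is.null(pool_sex)) rep("all", length(x)) else pool_sex
  ss <- tapply(x, groups, function(v) {
    if (length(v) < 2) c(0, 0) else c((length(v) - 1) * stats::var(v),
                                      length(v) - 1)
  })
  ss <- do.call(rbind, ss)
  df <- sum(ss[, 2])
  s2 <- if (df > 0) sum(ss[, 1]) / df else 0
  m <- mean(x)
  max(0, (s2 - m) / m^2)
}

# NB log-likelihood for counts y with mean theta * offsets, dispersion phi
nb_loglik <- function(theta, y, offsets, phi) {
  if (theta < 0) return(-Inf)
  if (theta == 0) return(if (all(y == 0)) 0 else -Inf)
  mu <- theta * offsets
  if (phi < 1e-12) {
    sum(dpois(y, mu, log = TRUE))
  } else {
    sum(dnbinom(y, mu = mu, size = 1 / phi, log = TRUE))
  }
}

# maximize nb_loglik over theta >= 0
nb_fit_theta <- function(y, offsets, phi) {
  if (all(y == 0)) return(list(theta = 0, loglik = 0, converged = TRUE))
  theta0 <- sum(y) / sum(offsets)  # exact MLE for Poisson / equal offsets
  if (phi < 1e-12) {
    return(list(theta = theta0, loglik = nb_loglik(theta0, y, offsets, phi),
                converged = TRUE))
  }
  opt <- tryCatch(
    optimize(function(lt) nb_loglik(exp(lt), y, offsets, phi),
             lower = log(theta0) - 8, upper = log(theta0) + 8,
             maximum = TRUE, tol = 1e-10),
    error = function(e) NULL
  )
  if (is.null(opt)) {
    return(list(theta = theta0, loglik = nb_loglik(theta0, y, offsets, phi),
                converged = FALSE))
  }
  list(theta = exp(opt$maximum), loglik = opt$objective, converged = TRUE)
}

#' Two-model differential-expression posterior for one contig
#'
#' Replaces an opaque "likelihood of differential expression" with a defined
#' statistic: counts are modelled negative-binomially with offsets
#' `library_size * length_bp` and the contig's method-of-moments dispersion,
#' under a null model M0 (one shared rate theta) and an alternative M1
#' (sex-specific rates theta_F, theta_M). Each model gets a BIC-penalised
#' score `S = loglik - (k/2) log(n_pools)` and the posterior is
#' `p1 exp(S1) / (p0 exp(S0) + p1 exp(S1))`, computed in log space, with
#' `p1 = prior_de`.
#'
#' @param row_counts per-pool counts for one contig.
#' @param pools pool metadata tibble (`pool_id`, `sex`, `library_size`).
#' @param contig_length contig length in bp.
#' @param config a [screen_config()] (supplies `prior_de`).
#' @return one-row tibble: `theta_null`, `theta_f`, `theta_m`, `dispersion`,
#'   `log_score_null`, `log_score_de`, `posterior_de`, `converged`.
#' @export
#' @examples
#' pools <- tibble::tibble(pool_id = c(paste0("F", 1:3), paste0("M", 1:3)),
#'                         sex = rep(c("F", "M"), each = 3),
#'                         library_size = 1e6)
#' de_posterior(c(40, 50, 45, 0, 0, 0), pools, contig_length = 1000)
de_posterior <- function(row_counts, pools, contig_length,
                         config = screen_config()) {
  sex <- pools$sex
  if (!all(c("F", "M") %in% sex)) abort("both sexes must be represented")
  offsets <- pools$library_size * contig_length
  phi <- as.numeric(estimate_dispersion(row_counts, pools$library_size,
                                        contig_length, sex))
  n <- length(row_counts)
  f <- sex == "F"

  fit0 <- nb_fit_theta(row_counts, offsets, phi)
  fit_f <- nb_fit_theta(row_counts[f], offsets[f], phi)
  fit_m <- nb_fit_theta(row_counts[!f], offsets[!f], phi)

  s0 <- fit0$loglik - 0.5 * 1 * log(n)
  s1 <- fit_f$loglik + fit_m$loglik - 0.5 * 2 * log(n)
  # posterior in log space: 1 / (1 + (p0/p1) exp(s0 - s1))
  log_odds_against <- log((1 - config$prior_de) / config$prior_de) + s0 - s1
  posterior <- 1 / (1 + exp(log_odds_against))

  tibble(
    theta_null = fit0$theta, theta_f = fit_f$theta, theta_m = fit_m$theta,
    dispersion = phi, log_score_null = s0, log_score_de = s1,
    posterior_de = posterior,
    converged = fit0$converged && fit_f$converged && fit_m$converged
  )
}

#' Select female-specific candidate contigs
#'
#' Applies the three published criteria to every contig of a pooled count
#' matrix — female exclusivity, length strictly over the threshold, and a
#' differential-expression posterior at or above `posterior_threshold` —
#' and removes contigs on the contaminant exclusion list. The result is a
#' per-contig report with one flag per criterion; `final_candidate` is their
#' conjunction.
#'
#' @inheritParams normalize_counts
#' @param config a [screen_config()].
#' @return tibble of class `zw_screen`, ordered by descending posterior then
#'   contig id: `contig_id`, `length_bp`, `female_total`, `male_total`,
#'   `posterior_de`, `exclusive`, `length_ok`, `posterior_ok`,
#'   `excluded_as_contaminant`, `final_candidate`.
#' @export
select_candidates <- function(counts, pools, config = screen_config()) {
  check_counts_input(counts, pools)
  unknown <- setdiff(config$exclusion_list, counts$contig_id)
  if (length(unknown)) {
    warn(paste0("exclusion list ids not present in matrix: ",
                paste(unknown, collapse = ", ")))
  }
  f_pools <- pools$pool_id[pools$sex == "F"]
  m_pools <- pools$pool_id[pools$sex == "M"]
  exclusive <- female_exclusive_filter(counts, pools, config)
  post <- purrr::map_dbl(seq_len(nrow(counts)), function(i) {
    de_posterior(as.numeric(counts[i, pools$pool_id]), pools,
                 counts$length_bp[i], config)$posterior_de
  })
  out <- counts |>
    mutate(
      female_total = rowSums(as.matrix(counts[f_pools])),
      male_total = rowSums(as.matrix(counts[m_pools])),
      posterior_de = post,
      exclusive = exclusive,
      length_ok = .data$length_bp >= config$min_length_bp,
      posterior_ok = post >= config$posterior_threshold,
      excluded_as_contaminant = .data$contig_id %in% config$exclusion_list,
      final_candidate = .data$exclusive & .data$length_ok &
        .data$posterior_ok & !.data$excluded_as_contaminant
    ) |>
    select("contig_id", "length_bp", "female_total", "male_total",
           "posterior_de", "exclusive", "length_ok", "posterior_ok",
           "excluded_as_contaminant", "final_candidate") |>
    arrange(desc(.data$posterior_de), .data$contig_id)
  class(out) <- c("zw_screen", class(out))
  attr(out, "config") <- config
  out
}

#' Assembly coverage of a reference gene by a contig
#'
#' `(gene_length + avg_utr_length) / (contig_length - n_count)`: the
#' reference span (gene plus average UTR) divided by the contig length with
#' ambiguous N bases excluded. Used to evaluate assemblies against a close
#' reference genome when choosing a k-mer size.
#'
#' @param gene_length_bp reference gene length (bp).
#' @param avg_utr_length_bp average UTR length to add to the gene (bp).
#' @param contig_length_bp contig length (bp).
#' @param n_count ambiguous N bases within the contig.
#' @return coverage ratio (vectorised).
#' @export
#' @examples
#' assembly_coverage(1000, 200, 1300, 100)
assembly_coverage <- function(gene_length_bp, avg_utr_length_bp,
                              contig_length_bp, n_count = 0) {
  if (any(n_count < 0)) abort("n_count must be >= 0")
  denom <- contig_length_bp - n_count
  if (any(denom <= 0)) {
    abort("contig length excluding N bases must be positive")
  }
  (gene_length_bp + avg_utr_length_bp) / denom
}

#' N50 of a set of contig lengths
#'
#' The largest length L such that contigs of length >= L together contain at
#' least half the total assembly length.
#'
#' @param lengths positive integer vector of contig lengths.
#' @return the N50 length.
#' @export
#' @examples
#' compute_n50(c(5, 4, 3, 2, 1))  # 4
compute_n50 <- function(lengths) {
  if (length(lengths) == 0) abort("lengths must be non-empty")
  if (any(lengths <= 0)) abort("lengths must be positive")
  sorted <- sort(lengths, decreasing = TRUE)
  sorted[which(cumsum(sorted) >= sum(sorted) / 2)[1]]
}

#' Assembly summary metrics
#'
#' @param lengths contig lengths in bp.
#' @param kmer_size assembly k-mer size recorded as metadata (optional).
#' @return one-row tibble: `kmer_size`, `n_contigs`, `total_length`, `n50`.
#' @export
assembly_metrics <- function(lengths, kmer_size = NA_integer_) {
  tibble(kmer_size = as.integer(kmer_size),
         n_contigs = length(lengths),
         total_length = sum(lengths),
         n50 = compute_n50(lengths))
}
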