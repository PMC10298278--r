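#' Observed homozygosity F = sum of squared allele frequencies
#'
#' @param freqs Numeric vector of allele frequencies, or a frequency
#'   table data frame with a \code{frequency} column.
#' @return Scalar F in [1/k, 1].
#' @export
observed_homozygosity <- function(freqs) {
  if (is.data.frame(freqs)) freqs <- freqs$frequency
  if (length(freqs) == 0) stop("empty frequency table")
  sum(freqs^2)
}

# all partitions of n into exactly k parts (each row non-increasing)
partitions_nk <- function(n, k, max_part = n - k + 1L) {
  if (k == 1L) {
    if (n <= max_part) return(list(n)) else return(list())
  }
  out <- list()
  hi <- min(max_part, n - k + 1L)
  lo <- as.integer(ceiling(n / k))
  if (hi < lo) return(out)
  for (first in seq(hi, lo)) {
    for (rest in partitions_nk(n - first, k - 1L, first))
      out[[length(out) + 1L]] <- c(first, rest)
  }
  out
}

# log Ewens conditional weight of a partition given k: proportional to
# n! / (prod_j j^{a_j} a_j!) where a_j = multiplicity of part size j
ewens_log_weight <- function(parts) {
  a <- table(parts)
  sizes <- as.numeric(names(a))
  -sum(a * log(sizes)) - sum(lgamma(as.numeric(a) + 1))
}

#' Exact conditional Ewens distribution of allele configurations
#'
#' Enumerates all partitions of n chromosomes into k allele classes
#' with their theta-free Ewens conditional probabilities
#' (proportional to n! / prod_j j^{a_j} a_j!).
#'
#' @param n Sample size in chromosomes.
#' @param k Number of alleles.
#' @return Data frame with columns \code{partition} (list column of
#'   integer vectors), \code{prob}, \code{F} (homozygosity).
#' @export
ewens_conditional_exact <- function(n, k) {
  stopifnot(k >= 1, k <= n)
  parts <- partitions_nk(n, k)
  lw <- vapply(parts, ewens_log_weight, 0)
  w <- exp(lw - max(lw))
  data.frame(
    partition = I(parts),
    prob = w / sum(w),
    F = vapply(parts, function(p) sum((p / n)^2), 0))
}

watterson_theta <- function(n, k) {
  if (k <= 1) return(1e-8)
  if (k >= n) return(1e8)
  f <- function(theta) sum(theta / (theta + 0:(n - 1))) - k
  stats::uniroot(f, c(1e-8, 1e8), tol = 1e-10)$root
}

crp_seat <- function(new_table) {
  # Chinese restaurant process, given the new-table indicators:
  # conditional on not opening a table, customer i joins the table of
  # a uniformly chosen previous customer (probability of joining a
  # table of size s is then s / (i - 1), the CRP law).
  n <- length(new_table)
  i <- seq_len(n)
  target <- 1L + floor(stats::runif(n) * (i - 1))  # uniform in 1..(i-1)
  tbl <- integer(n)
  nt <- 0L
  for (j in i) {
    if (new_table[j]) { nt <- nt + 1L; tbl[j] <- nt }
    else tbl[j] <- tbl[target[j]]
  }
  tabulate(tbl, nbins = nt)
}

#' Sample homozygosity under the Ewens neutral null, conditional on k
#'
#' Draws allele-count configurations from the Ewens sampling formula
#' conditioned on observing k alleles in n chromosomes (the
#' conditional law is free of theta) and returns the homozygosity
#' sum (n_i / n)^2 of each draw. For n <= 20 the exact conditional
#' distribution is enumerated and sampled directly; for larger n a
#' Chinese-restaurant-process sampler with rejection on the realized
#' allele count is used, with its theta set so that E[K] = k
#' (Watterson's moment choice — this affects only rejection
#' efficiency, not the sampled law).
#'
#' @param n Sample size in chromosomes.
#' @param k Number of alleles (2 <= k <= n; k = n is degenerate but
#'   allowed).
#' @param replicates Number of draws.
#' @param seed Integer seed.
#' @return Numeric vector of length \code{replicates}.
#' @export
ewens_null_sample <- function(n, k, replicates = 10000, seed) {
  vapply(ewens_null_partitions(n, k, replicates, seed),
         function(cfg) sum((cfg / n)^2), 0)
}

#' Sample allele-count configurations from the conditional Ewens null
#'
#' Same sampler as \code{\link{ewens_null_sample}}, returning the
#' drawn allele-count configurations themselves.
#'
#' @inheritParams ewens_null_sample
#' @return List of \code{replicates} integer vectors of length k
#'   summing to n.
#' @export
ewens_null_partitions <- function(n, k, replicates = 10000, seed) {
  stopifnot(k >= 1, k <= n, replicates >= 1)
  if (missing(seed)) stop("seed is required")
  if (k == n)
    return(rep(list(rep(1L, n)), replicates))
  withr::with_seed(seed, {
    if (n <= 20) {
      ex <- ewens_conditional_exact(n, k)
      idx <- sample.int(nrow(ex), replicates, replace = TRUE,
                        prob = ex$prob)
      return(lapply(idx, function(i) as.integer(ex$partition[[i]])))
    }
    theta <- watterson_theta(n, k)
    pr_new <- theta / (theta + seq_len(n) - 1)
    out <- vector("list", replicates)
    got <- 0L
    while (got < replicates) {
      # cheap rejection: the number of tables depends only on the
      # new-table indicators, so seat customers only for accepted draws
      ind <- stats::runif(n) < pr_new
      if (sum(ind) != k) next
      got <- got + 1L
      out[[got]] <- crp_seat(ind)
    }
    out
  })
}

#' Ewens-Watterson homozygosity test of neutrality
#'
#' Compares the observed homozygosity F_obs = sum p_i^2 of a locus
#' with its neutral expectation conditional on the sample size n and
#' the observed allele count k. F_exp and its SD are the mean and
#' standard deviation of the conditional null sample; the normalized
#' deviate is F_nd = (F_obs - F_exp) / sd_F. The p-value is the
#' lower-tail proportion of null draws with F <= F_obs (balancing
#' selection depresses homozygosity), with the (r + 1) / (R + 1)
#' convention so p is never exactly 0.
#'
#' @param freq_table Frequency table data frame (or numeric frequency
#'   vector) for one locus.
#' @param n Sample size in chromosomes (default: taken from the
#'   table's \code{two_n} column).
#' @param replicates Null sample size.
#' @param seed Integer seed.
#' @param locus Optional locus label.
#' @return List of class \code{ewh_result}: \code{locus}, \code{n},
#'   \code{k}, \code{F_obs}, \code{F_exp}, \code{sd_F}, \code{F_nd},
#'   \code{p_value}, \code{replicates}, \code{seed}.
#' @export
ewh_test <- function(freq_table, n = NULL, replicates = 10000, seed,
                     locus = NA_character_) {
  if (missing(seed)) stop("seed is required")
  if (is.data.frame(freq_table)) {
    if (is.null(n) && "two_n" %in% names(freq_table))
      n <- freq_table$two_n[1]
    if (is.na(locus) && "locus" %in% names(freq_table))
      locus <- freq_table$locus[1]
    freqs <- freq_table$frequency
  } else freqs <- freq_table
  if (is.null(n)) stop("sample size n is required")
  freqs <- freqs[freqs > 0]
  k <- length(freqs)
  F_obs <- sum(freqs^2)
  null_F <- ewens_null_sample(n, k, replicates, seed)
  F_exp <- mean(null_F)
  sd_F <- stats::sd(null_F)
  res <- list(locus = locus, n = n, k = k,
              F_obs = F_obs, F_exp = F_exp, sd_F = sd_F,
              F_nd = (F_obs - F_exp) / sd_F,
              p_value = (sum(null_F <= F_obs + 1e-12) + 1) /
                        (replicates + 1),
              replicates = replicates, seed = seed)
  class(res) <- "ewh_result"
  res
}

#' @export
print.ewh_result <- function(x, ...) {
  cat("Ewens-Watterson homozygosity test",
      if (!is.na(x$locus)) paste0("(", x$locus, ")"), "\n",
      sprintf(" n = %d  k = %d\n F_obs = %.4f  F_exp = %.4f  F_nd = %.3f\n p = %.4f (%d replicates)\n",
              x$n, x$k, x$F_obs, x$F_exp, x$F_nd, x$p_value,
              x$replicates))
  invisible(x)
}
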