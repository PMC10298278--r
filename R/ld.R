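#' Haplotype-level linkage disequilibrium for one allele pair
#'
#' Computes, for a haplotype carrying allele i at one locus and allele
#' j at another, the gametic disequilibrium D = h - p q, its
#' normalization D' = D / Dmax (Lewontin), the 1-df chi-square
#' statistic 2n D^2 / (p(1-p) q(1-q)) from the 2x2 collapse of the
#' joint table, and the corresponding p-value.
#'
#' Dmax is min(p(1-q), q(1-p)) when D >= 0 and min(pq, (1-p)(1-q))
#' otherwise; D' is 0 when Dmax is 0.
#'
#' @param h Haplotype frequency (vectorized).
#' @param p,q Allele frequencies at the two loci (0 < p, q < 1).
#' @param two_n Number of chromosomes.
#' @return Data frame with columns \code{h}, \code{p}, \code{q},
#'   \code{D}, \code{Dprime}, \code{chi2}, \code{p_value}.
#' @export
pairwise_ld <- function(h, p, q, two_n) {
  if (any(p <= 0 | p >= 1 | q <= 0 | q >= 1))
    stop("allele frequencies must lie strictly between 0 and 1")
  if (any(h < 0) || any(h > pmin(p, q) + 1e-9))
    stop("inconsistent haplotype frequency: h exceeds min(p, q)")
  D <- h - p * q
  dmax <- ifelse(D >= 0, pmin(p * (1 - q), q * (1 - p)),
                 pmin(p * q, (1 - p) * (1 - q)))
  dprime <- ifelse(dmax == 0, 0, D / dmax)
  chi2 <- two_n * D^2 / (p * (1 - p) * q * (1 - q))
  data.frame(h = h, p = p, q = q, D = D, Dprime = dprime, chi2 = chi2,
             p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

check_joint <- function(joint) {
  joint <- as.matrix(joint)
  if (abs(sum(joint) - 1) > 1e-9)
    stop("joint haplotype frequencies must sum to 1")
  if (any(joint < 0)) stop("negative joint frequency")
  joint
}

drop_zero_margins <- function(joint) {
  joint[rowSums(joint) > 0, colSums(joint) > 0, drop = FALSE]
}

#' Overall multiallelic D'
#'
#' Frequency-weighted mean absolute normalized disequilibrium over all
#' cells of a two-locus joint haplotype frequency table:
#' sum_ij p_i q_j |D'_ij|.
#'
#' @param joint Matrix of joint haplotype frequencies (rows = alleles
#'   at locus a, columns = alleles at locus b), summing to 1.
#' @return Scalar in [0, 1].
#' @export
overall_dprime <- function(joint) {
  joint <- drop_zero_margins(check_joint(joint))
  p <- rowSums(joint); q <- colSums(joint)
  pq <- outer(p, q)
  D <- joint - pq
  dmax <- ifelse(D >= 0,
                 pmin(outer(p, 1 - q), outer(1 - p, q)),
                 pmin(pq, outer(1 - p, 1 - q)))
  dprime <- ifelse(dmax == 0, 0, D / dmax)
  sum(pq * abs(dprime))
}

#' Multiallelic global LD statistic Wn
#'
#' Cramer's-V analogue for a two-locus joint haplotype table:
#' Wn = sqrt( sum_ij D_ij^2 / (p_i q_j) / (min(ka, kb) - 1) ).
#'
#' @inheritParams overall_dprime
#' @return Scalar in [0, 1].
#' @export
wn <- function(joint) {
  joint <- drop_zero_margins(check_joint(joint))
  ka <- nrow(joint); kb <- ncol(joint)
  if (ka < 2 || kb < 2)
    stop("Wn is undefined for a monomorphic locus")
  p <- rowSums(joint); q <- colSums(joint)
  D <- joint - outer(p, q)
  sqrt(sum(D^2 / outer(p, q)) / (min(ka, kb) - 1))
}

#' Conditional asymmetric linkage disequilibrium (ALD)
#'
#' For loci a (rows) and b (columns), the ALD of a conditioned on b is
#' W_a/b = sqrt( (F_a/b - F_a) / (1 - F_a) ), where F_a = sum_i p_i^2
#' is the homozygosity of locus a and F_a/b = sum_ij h_ij^2 / q_j its
#' conditional analogue given locus-b alleles. W_a/b measures how much
#' of the variation at locus a is determined by the allele carried at
#' locus b; the two directions differ when one locus is more
#' polymorphic than the other.
#'
#' @inheritParams overall_dprime
#' @return Named list with \code{W_a_given_b} and \code{W_b_given_a}.
#' @export
ald <- function(joint) {
  joint <- drop_zero_margins(check_joint(joint))
  p <- rowSums(joint); q <- colSums(joint)
  F_a <- sum(p^2); F_b <- sum(q^2)
  if (F_a >= 1 - 1e-12 || F_b >= 1 - 1e-12)
    stop("ALD is undefined for a monomorphic locus")
  F_ab <- sum(sweep(joint^2, 2, q, "/"))   # sum_ij h_ij^2 / q_j
  F_ba <- sum(sweep(joint^2, 1, p, "/"))   # sum_ij h_ij^2 / p_i
  list(W_a_given_b = sqrt(max(0, (F_ab - F_a) / (1 - F_a))),
       W_b_given_a = sqrt(max(0, (F_ba - F_b) / (1 - F_b))))
}

#' Joint two-locus haplotype frequency table from founder chromosomes
#'
#' @param founders Founder data frame (see
#'   \code{\link{count_allele_frequencies}}).
#' @param loci Character vector of two locus names; the first indexes
#'   rows.
#' @param n_fields Resolution.
#' @return Matrix of joint frequencies with allele dimnames.
#' @export
joint_haplotype_table <- function(founders, loci, n_fields = 1) {
  stopifnot(length(loci) == 2)
  a <- reduce_resolution(founders[[loci[1]]], n_fields)
  b <- reduce_resolution(founders[[loci[2]]], n_fields)
  table(a, b) / length(a)
}

#' Full LD summary for a locus pair
#'
#' Builds the joint haplotype table by direct counting over founder
#' chromosomes, then reports the global statistics (overall D', Wn,
#' both ALD directions, number of distinct observed haplotypes) and the
#' per-haplotype statistics (frequency, SD, D, D', chi-square, p) for
#' every observed haplotype.
#'
#' @inheritParams joint_haplotype_table
#' @param min_frequency Display filter on the per-haplotype table.
#' @param bonferroni If TRUE, add a Bonferroni-adjusted p-value column
#'   (adjusted over the observed haplotypes of this pair).
#' @return List of class \code{ld_summary}: \code{loci},
#'   \code{overall_dprime}, \code{wn}, \code{W_a_given_b},
#'   \code{W_b_given_a}, \code{n_haplotypes}, \code{two_n} and
#'   \code{haplotypes} (data frame).
#' @export
ld_summary_for_pair <- function(founders, loci, n_fields = 1,
                                min_frequency = 0, bonferroni = FALSE) {
  joint <- as.matrix(joint_haplotype_table(founders, loci, n_fields))
  two_n <- nrow(founders)
  nhap <- sum(joint > 0)
  a <- ald(joint)
  cells <- which(joint > 0, arr.ind = TRUE)
  p <- rowSums(joint); q <- colSums(joint)
  hap <- data.frame(
    allele_a = rownames(joint)[cells[, 1]],
    allele_b = colnames(joint)[cells[, 2]],
    stringsAsFactors = FALSE)
  hap$haplotype <- paste(hap$allele_a, hap$allele_b, sep = "~")
  ok <- p[cells[, 1]] < 1 & q[cells[, 2]] < 1
  stats <- pairwise_ld(joint[cells][ok], p[cells[, 1]][ok],
                       q[cells[, 2]][ok], two_n)
  hap <- hap[ok, , drop = FALSE]
  hap$frequency <- stats$h
  hap$sd <- sqrt(stats$h * (1 - stats$h) / (two_n - 1))
  hap$D <- stats$D
  hap$Dprime <- stats$Dprime
  hap$chi2 <- stats$chi2
  hap$p_value <- stats$p_value
  if (bonferroni)
    hap$p_bonferroni <- pmin(1, hap$p_value * nrow(hap))
  hap <- hap[order(-hap$frequency, hap$haplotype), ]
  hap <- hap[hap$frequency >= min_frequency, ]
  rownames(hap) <- NULL
  structure(list(loci = loci,
                 overall_dprime = overall_dprime(joint),
                 wn = wn(joint),
                 W_a_given_b = a$W_a_given_b,
                 W_b_given_a = a$W_b_given_a,
                 n_haplotypes = nhap,
                 two_n = two_n,
                 haplotypes = hap),
            class = "ld_summary")
}

#' @export
print.ld_summary <- function(x, ...) {
  cat(sprintf("%s~%s: D' = %.3f  Wn = %.3f  W_%s/%s = %.3f  W_%s/%s = %.3f  (%d haplotypes)\n",
              x$loci[1], x$loci[2], x$overall_dprime, x$wn,
              x$loci[1], x$loci[2], x$W_a_given_b,
              x$loci[2], x$loci[1], x$W_b_given_a, x$n_haplotypes))
  invisible(x)
}

#' LD summaries for every locus pair
#'
#' @inheritParams ld_summary_for_pair
#' @param loci Loci to pair (default: all covered loci in canonical
#'   order).
#' @return Data frame, one row per pair, with the global statistics.
#'   The full per-pair summaries are attached as attribute
#'   \code{"summaries"}.
#' @export
ld_summary_all <- function(founders,
                           loci = intersect(hla_loci(), names(founders)),
                           n_fields = 1) {
  pairs <- utils::combn(loci, 2)
  out <- lapply(seq_len(ncol(pairs)), function(i)
    ld_summary_for_pair(founders, pairs[, i], n_fields))
  df <- data.frame(
    pair = vapply(out, function(s) paste(s$loci, collapse = "~"), ""),
    overall_dprime = vapply(out, `[[`, 0, "overall_dprime"),
    wn = vapply(out, `[[`, 0, "wn"),
    W_a_given_b = vapply(out, `[[`, 0, "W_a_given_b"),
    W_b_given_a = vapply(out, `[[`, 0, "W_b_given_a"),
    n_haplotypes = vapply(out, `[[`, 0L, "n_haplotypes"))
  attr(df, "summaries") <- out
  df
}
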