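#' Allele frequencies by direct counting over founder chromosomes
#'
#' Counts alleles at one locus over the pooled founder haplotypes
#' (2 chromosomes per parent) and reports direct-count frequencies
#' p = count / 2n with binomial standard deviations
#' sqrt(p (1 - p) / (2n - 1)) (sample-corrected denominator, the form
#' the published frequency tables use).
#'
#' @param founders Founder data frame from \code{\link{phase_cohort}}
#'   (or any data frame with one column per locus, one row per
#'   chromosome).
#' @param locus Locus name.
#' @param n_fields Resolution: number of allele-name fields to keep
#'   (1 = allele lineage level).
#' @return Data frame with columns \code{locus}, \code{allele},
#'   \code{count}, \code{frequency}, \code{sd}, \code{two_n}, sorted by
#'   decreasing frequency then allele name.
#' @export
count_allele_frequencies <- function(founders, locus, n_fields = 1) {
  if (!locus %in% names(founders))
    stop("locus ", locus, " not covered by the founder haplotypes")
  alleles <- reduce_resolution(founders[[locus]], n_fields)
  if (length(alleles) == 0) stop("no founder chromosomes")
  two_n <- length(alleles)
  tab <- table(alleles)
  out <- data.frame(locus = locus,
                    allele = names(tab),
                    count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$frequency <- out$count / two_n
  out$sd <- sqrt(out$frequency * (1 - out$frequency) / (two_n - 1))
  out$two_n <- two_n
  out <- out[order(-out$frequency, out$allele), ]
  rownames(out) <- NULL
  out
}

#' Haplotype frequencies by direct counting
#'
#' Direct counts of multi-locus haplotypes over founder chromosomes,
#' for any subset of the typed loci and at any resolution.
#'
#' @inheritParams count_allele_frequencies
#' @param loci Locus subset, in the desired output order (default:
#'   display order A~B~C~DRB1~DQB1 restricted to covered loci).
#' @param min_frequency Display filter: drop rows below this frequency
#'   (applied after counting; counts and SDs are unaffected).
#' @return Data frame with columns \code{haplotype}, \code{count},
#'   \code{frequency}, \code{sd}, \code{two_n}.
#' @export
count_haplotype_frequencies <- function(founders,
                                        loci = intersect(haplotype_display_order(),
                                                         names(founders)),
                                        n_fields = 1,
                                        min_frequency = 0) {
  absent <- setdiff(loci, names(founders))
  if (length(absent) > 0)
    stop("loci not covered by the founder haplotypes: ",
         paste(absent, collapse = ", "))
  if (nrow(founders) == 0) stop("no founder chromosomes")
  two_n <- nrow(founders)
  mat <- vapply(loci, function(l) reduce_resolution(founders[[l]], n_fields),
                character(two_n))
  haps <- apply(matrix(mat, nrow = two_n), 1L, paste, collapse = "~")
  tab <- table(haps)
  out <- data.frame(haplotype = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$frequency <- out$count / two_n
  out$sd <- sqrt(out$frequency * (1 - out$frequency) / (two_n - 1))
  out$two_n <- two_n
  out <- out[order(-out$frequency, out$haplotype), ]
  out <- out[out$frequency >= min_frequency, ]
  rownames(out) <- NULL
  attr(out, "loci") <- loci
  out
}

hwe_log_stat <- function(pair_ids, k, het) {
  # log conditional probability of the genotype array given allele
  # counts, up to a constant over permutations:
  #   log P = const + n_het log 2 - sum(log n_gt!)
  counts <- tabulate(pair_ids, nbins = k * (k + 1L) / 2L)
  het * log(2) - sum(lgamma(counts[counts > 0L] + 1))
}

#' Hardy-Weinberg exact test by Monte Carlo permutation
#'
#' Guo-Thompson style exact test for a multiallelic locus: the 2n
#' observed alleles are repeatedly shuffled into n random genotype
#' pairs, and the p-value is the proportion of shuffles whose
#' conditional probability given the allele counts is less than or
#' equal to that of the observed genotype array (the observed array
#' counts in both numerator and denominator).
#'
#' @param genotypes Two-column character matrix or data frame: the two
#'   alleles of each individual at one locus.
#' @param replicates Number of Monte Carlo shuffles (>= 1000).
#' @param seed Integer seed (mandatory, for reproducibility).
#' @param locus Optional locus label carried through to the result.
#' @return List of class \code{hwe_result}: \code{locus}, \code{n},
#'   \code{k}, \code{p_value}, \code{monomorphic}, \code{replicates},
#'   \code{seed}, \code{statistic}.
#' @export
hwe_exact_test <- function(genotypes, replicates = 10000, seed,
                           locus = NA_character_) {
  genotypes <- as.matrix(genotypes)
  stopifnot(ncol(genotypes) == 2, nrow(genotypes) >= 2,
            replicates >= 1000)
  if (missing(seed)) stop("seed is required")
  alleles <- factor(c(genotypes[, 1], genotypes[, 2]))
  k <- nlevels(alleles)
  n <- nrow(genotypes)
  base <- list(locus = locus, n = n, k = k, replicates = replicates,
               seed = seed,
               statistic = "conditional probability of genotype array given allele counts")
  if (k == 1L) {
    res <- c(base, list(p_value = 1, monomorphic = TRUE))
    class(res) <- "hwe_result"
    return(res)
  }
  code <- as.integer(alleles)
  a <- code[seq_len(n)]
  b <- code[n + seq_len(n)]
  pair_id <- function(a, b) {
    i <- pmin(a, b); j <- pmax(a, b)
    i + j * (j - 1L) %/% 2L
  }
  obs <- hwe_log_stat(pair_id(a, b), k, sum(a != b))
  pool <- code
  count <- 0L
  withr::with_seed(seed, {
    for (r in seq_len(replicates)) {
      perm <- sample(pool)
      pa <- perm[seq_len(n)]
      pb <- perm[n + seq_len(n)]
      s <- hwe_log_stat(pair_id(pa, pb), k, sum(pa != pb))
      if (s <= obs + 1e-9) count <- count + 1L
    }
  })
  res <- c(base, list(p_value = (count + 1) / (replicates + 1),
                      monomorphic = FALSE))
  class(res) <- "hwe_result"
  res
}

#' @export
print.hwe_result <- function(x, ...) {
  cat("Hardy-Weinberg exact test",
      if (!is.na(x$locus)) paste0("(", x$locus, ")"), "\n",
      " n =", x$n, " k =", x$k, "\n",
      " Monte Carlo p =", format(x$p_value, digits = 4),
      paste0("(", x$replicates, " replicates)"), "\n")
  if (x$monomorphic) cat("  [monomorphic locus]\n")
  invisible(x)
}
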