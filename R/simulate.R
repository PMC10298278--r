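#' Specification of a synthetic family cohort
#'
#' Describes the study conditions emulated by the simulator: parental
#' haplotypes drawn from a five-locus haplotype pool, nuclear families
#' with a uniform number of children (default 2 to 7 per family, the
#' reported sibling range), optional recombination between adjacent
#' loci, and optional missing genotypes.
#'
#' @param pool Data frame with one column per locus (canonical order)
#'   and a \code{frequency} column summing to 1; see
#'   \code{\link{pool_from_frequency_tables}}.
#' @param n_families Number of nuclear families (default 100,
#'   yielding 2n = 400 founder chromosomes).
#' @param children_range Inclusive integer range of children per
#'   family (default c(2, 7)), drawn uniformly.
#' @param recombination_rate Per-adjacent-locus-interval crossover
#'   probability in gametes (default 0).
#' @param missing_rate Per-allele missingness probability in the
#'   emitted genotype table (default 0).
#' @param seed Integer seed (mandatory).
#' @return List of class \code{sim_spec}.
#' @export
simulation_spec <- function(pool, n_families = 100,
                            children_range = c(2, 7),
                            recombination_rate = 0,
                            missing_rate = 0, seed) {
  if (missing(seed)) stop("seed is required")
  loci <- setdiff(names(pool), "frequency")
  stopifnot(all(loci %in% hla_loci()), nrow(pool) > 0)
  if (abs(sum(pool$frequency) - 1) > 1e-9)
    stop("pool frequencies must sum to 1")
  stopifnot(recombination_rate >= 0, recombination_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            children_range[1] >= 0,
            children_range[2] >= children_range[1])
  structure(list(pool = pool, loci = loci, n_families = n_families,
                 children_range = children_range,
                 recombination_rate = recombination_rate,
                 missing_rate = missing_rate, seed = seed),
            class = "sim_spec")
}

#' Build a haplotype pool from allele frequency tables
#'
#' \code{ld_mode = "independent"} builds the full product pool of the
#' per-locus marginals (all allele combinations, frequency = product
#' of marginals), so every pairwise D is 0 by construction.
#' \code{ld_mode = "table"} takes an explicit joint haplotype list
#' (e.g. the published five-locus haplotype table) and spreads the
#' remaining probability mass over filler haplotypes built by a
#' deterministic comonotone (quantile) coupling of the residual
#' per-locus marginals, so the returned pool marginalizes back to the
#' input allele frequencies exactly at every locus.
#'
#' @param freq_tables Data frame of per-locus allele frequencies
#'   (columns \code{locus}, \code{allele}, \code{frequency}), e.g.
#'   \code{\link{uae_frequencies}()}.
#' @param ld_mode \code{"independent"} or \code{"table"}.
#' @param haplotypes For \code{"table"} mode: data frame with columns
#'   \code{haplotype} (allele names joined by \code{"~"}) and
#'   \code{frequency}.
#' @return Pool data frame (one column per locus plus
#'   \code{frequency}), frequencies summing to 1.
#' @export
pool_from_frequency_tables <- function(freq_tables,
                                       ld_mode = c("independent", "table"),
                                       haplotypes = NULL) {
  ld_mode <- match.arg(ld_mode)
  loci <- intersect(hla_loci(), unique(freq_tables$locus))
  marg <- lapply(loci, function(l) {
    t <- freq_tables[freq_tables$locus == l, ]
    s <- sum(t$frequency)
    if (abs(s - 1) > 1e-6) stop("marginals for ", l, " do not sum to 1")
    t
  })
  names(marg) <- loci
  if (ld_mode == "independent") {
    grids <- expand.grid(lapply(marg, function(t) t$allele),
                         stringsAsFactors = FALSE)
    names(grids) <- loci
    f <- Reduce(`*`, lapply(loci, function(l) {
      marg[[l]]$frequency[match(grids[[l]], marg[[l]]$allele)]
    }))
    pool <- cbind(grids, frequency = f)
    pool <- pool[pool$frequency > 0, ]
    rownames(pool) <- NULL
    return(pool)
  }
  stopifnot(!is.null(haplotypes))
  hap_alleles <- t(vapply(haplotypes$haplotype, split_haplotype,
                          character(length(loci))))
  hap_loci <- allele_locus(hap_alleles[1, ])
  pool <- as.data.frame(hap_alleles[, match(loci, hap_loci),
                                    drop = FALSE],
                        stringsAsFactors = FALSE)
  names(pool) <- loci
  rownames(pool) <- NULL
  pool$frequency <- haplotypes$frequency
  # explicit list must not exceed any marginal; residual mass per allele
  residual <- list()
  for (l in loci) {
    agg <- tapply(pool$frequency, pool[[l]], sum)
    r <- stats::setNames(marg[[l]]$frequency, marg[[l]]$allele)
    if (any(!names(agg) %in% names(r)))
      stop("explicit haplotype carries an allele absent from the ",
           l, " marginal")
    if (any(agg > r[names(agg)] + 1e-9))
      stop("explicit haplotype frequencies exceed the ", l, " marginal")
    r[names(agg)] <- r[names(agg)] - agg
    residual[[l]] <- r[r > 1e-12]
  }
  remaining <- 1 - sum(pool$frequency)
  if (remaining < -1e-9) stop("explicit haplotype frequencies exceed 1")
  if (remaining > 1e-9) {
    # comonotone coupling of the residual marginals: lay each locus's
    # residual allele mass over [0, remaining] in decreasing-frequency
    # order and cut at the union of the boundaries; each segment is one
    # filler haplotype, so filler marginals equal the residuals exactly
    cum <- lapply(residual, function(r) {
      r <- sort(r, decreasing = TRUE)
      cumsum(r) * remaining / sum(r)
    })
    breaks <- sort(unique(c(0, unlist(cum))))
    breaks <- breaks[breaks <= remaining + 1e-12]
    mids <- (utils::head(breaks, -1) + breaks[-1]) / 2
    filler <- as.data.frame(lapply(loci, function(l) {
      names(cum[[l]])[findInterval(mids, c(0, cum[[l]]),
                                   rightmost.closed = TRUE)]
    }), stringsAsFactors = FALSE)
    names(filler) <- loci
    filler$frequency <- diff(breaks)
    pool <- rbind(pool, filler[filler$frequency > 1e-12, ])
    rownames(pool) <- NULL
  }
  pool
}

#' Default simulation specification
#'
#' The study conditions of the source cohort: 100 nuclear families
#' with 2--7 children each, no recombination or missingness, and a
#' parental haplotype pool built in \code{"table"} mode from the
#' packaged published five-locus haplotype list (including
#' A*26~B*08~C*07~DRB1*03~DQB1*02 at 0.0425) with filler mass derived
#' from the packaged lineage marginals.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to \code{\link{simulation_spec}}.
#' @return A \code{sim_spec}.
#' @export
default_simulation_spec <- function(seed, ...) {
  pool <- pool_from_frequency_tables(uae_frequencies(), "table",
                                     haplotypes = uae_haplotypes_5locus())
  simulation_spec(pool = pool, seed = seed, ...)
}

make_gamete <- function(hap1, hap2, rate) {
  L <- length(hap1)
  src <- integer(L)
  src[1] <- sample.int(2L, 1L)
  if (L > 1) {
    cross <- stats::runif(L - 1) < rate
    for (l in 2:L) src[l] <- if (cross[l - 1]) 3L - src[l - 1] else src[l - 1]
  }
  ifelse(src == 1L, hap1, hap2)
}

#' Simulate a nuclear-family cohort with known truth
#'
#' Each parent receives two haplotypes drawn independently from the
#' pool (random mating); each child receives one gamete per parent,
#' a parental haplotype subject to independent crossovers between
#' adjacent loci at the specified rate. Genotypes are then unphased
#' (allele pairs sorted per locus) and masked at the missing rate.
#' Fully reproducible given the spec's seed.
#'
#' @param spec A \code{\link{simulation_spec}}.
#' @return List with \code{cohort} (data frame in the genotype-file
#'   layout) and \code{truth} (list: \code{founders} data frame like
#'   the phaser's output; \code{children} data frame with the
#'   transmitted paternal/maternal haplotypes per child).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  pool <- spec$pool
  if (nrow(pool) == 0) stop("empty haplotype pool")
  loci <- spec$loci
  hapmat <- as.matrix(pool[, loci, drop = FALSE])
  withr::with_seed(spec$seed, {
    rows <- list(); tru_f <- list(); tru_c <- list()
    for (fam in seq_len(spec$n_families)) {
      fid <- sprintf("F%03d", fam)
      idx <- sample.int(nrow(pool), 4, replace = TRUE,
                        prob = pool$frequency)
      fhap <- hapmat[idx[1:2], , drop = FALSE]
      mhap <- hapmat[idx[3:4], , drop = FALSE]
      tru_f[[fam]] <- data.frame(
        family_id = fid,
        parent = rep(c("father", "mother"), each = 2),
        hap_index = rep(1:2, 2),
        rbind(fhap, mhap), stringsAsFactors = FALSE)
      nkids <- sample(spec$children_range[1]:spec$children_range[2], 1)
      mem <- list(
        father = list(id = paste0(fid, "_P1"), g = fhap),
        mother = list(id = paste0(fid, "_P2"), g = mhap))
      kids <- list()
      for (ci in seq_len(nkids)) {
        pg <- make_gamete(fhap[1, ], fhap[2, ], spec$recombination_rate)
        mg <- make_gamete(mhap[1, ], mhap[2, ], spec$recombination_rate)
        kid_id <- paste0(fid, "_C", ci)
        kids[[ci]] <- list(id = kid_id, g = rbind(pg, mg))
        tc <- data.frame(family_id = fid, individual_id = kid_id,
                         stringsAsFactors = FALSE)
        for (l in seq_along(loci)) {
          tc[[paste0("pat_", loci[l])]] <- pg[l]
          tc[[paste0("mat_", loci[l])]] <- mg[l]
        }
        tru_c[[length(tru_c) + 1L]] <- tc
      }
      emit <- function(id, role, father_id, mother_id, g) {
        # unphase: sort the allele pair per locus
        row <- list(family_id = fid, individual_id = id,
                    father_id = father_id, mother_id = mother_id,
                    role = role)
        for (l in seq_along(loci)) {
          pair <- sort(g[, l])
          if (spec$missing_rate > 0) {
            mask <- stats::runif(2) < spec$missing_rate
            pair[mask] <- "."
          }
          row[[paste0(loci[l], "_1")]] <- pair[1]
          row[[paste0(loci[l], "_2")]] <- pair[2]
        }
        as.data.frame(row, stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <-
        emit(mem$father$id, "father", ".", ".", mem$father$g)
      rows[[length(rows) + 1L]] <-
        emit(mem$mother$id, "mother", ".", ".", mem$mother$g)
      for (kid in kids)
        rows[[length(rows) + 1L]] <-
          emit(kid$id, "child", mem$father$id, mem$mother$id, kid$g)
    }
    cohort <- do.call(rbind, rows)
    founders <- do.call(rbind, tru_f)
    names(founders) <- c("family_id", "parent", "hap_index", loci)
    rownames(cohort) <- rownames(founders) <- NULL
    class(cohort) <- c("hla_cohort", "data.frame")
    attr(founders, "loci") <- loci
    list(cohort = cohort,
         truth = list(founders = founders,
                      children = do.call(rbind, tru_c)))
  })
}
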