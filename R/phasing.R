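#' Extract one individual's genotype as a 2 x L allele matrix
#'
#' @param row One-row cohort data frame.
#' @param loci Loci to extract (canonical order).
#' @return A 2 x length(loci) character matrix; columns named by locus.
#' @export
genotype_matrix <- function(row, loci = hla_loci()) {
  g <- rbind(unlist(row[paste0(loci, "_1")], use.names = FALSE),
             unlist(row[paste0(loci, "_2")], use.names = FALSE))
  colnames(g) <- loci
  g
}

#' Enumerate all phase configurations of one unphased genotype
#'
#' A genotype heterozygous at h loci admits 2^max(h-1, 0) distinct
#' unordered splits into two haplotypes; a fully homozygous genotype
#' admits exactly one.
#'
#' @param g A 2 x L genotype matrix (see \code{\link{genotype_matrix}});
#'   all loci typed.
#' @return A list of 2 x L haplotype matrices (row 1 / row 2 = the two
#'   haplotypes).
#' @export
enumerate_parent_phases <- function(g) {
  if (any(g == "." | is.na(g)))
    stop("missing locus in genotype")
  loci <- colnames(g)
  het <- which(g[1, ] != g[2, ])
  h <- length(het)
  if (h <= 1) return(list(g))
  # fix the assignment at the first heterozygous locus, flip the rest
  flips <- het[-1]
  out <- vector("list", 2^length(flips))
  for (m in seq_len(2^length(flips)) - 1L) {
    hap <- g
    for (b in seq_along(flips)) {
      if (bitwAnd(m, bitwShiftL(1L, b - 1L)) != 0L)
        hap[, flips[b]] <- hap[2:1, flips[b]]
    }
    out[[m + 1L]] <- hap
  }
  out
}

child_explained <- function(fhap, mhap, child_g) {
  # returns the list of (paternal index, maternal index) pairs explaining
  # the child, or an empty list
  res <- list()
  for (f in 1:2) for (m in 1:2) {
    ok <- TRUE
    for (l in seq_len(ncol(child_g))) {
      a <- sort(unname(c(fhap[f, l], mhap[m, l])))
      b <- sort(unname(child_g[, l]))
      if (!identical(a, b)) { ok <- FALSE; break }
    }
    if (ok) res[[length(res) + 1L]] <- c(f, m)
  }
  res
}

#' Phase one nuclear family by segregation analysis
#'
#' Enumerates all joint parental phase configurations and retains those
#' under which every child genotype is the locus-wise union of one
#' paternal and one maternal haplotype (no recombination). The family is
#' \code{unique} if all admissible configurations yield the same founder
#' haplotype multiset, \code{inconsistent} if none is admissible (or a
#' child carries an allele absent from both parents), and
#' \code{ambiguous} otherwise.
#'
#' @param fam Cohort data frame rows for one family (two parents,
#'   >= 1 child).
#' @param loci Loci to phase over; all members must be typed at these.
#' @return A list of class \code{phased_family} with elements
#'   \code{family_id}, \code{status}, \code{father_haplotypes},
#'   \code{mother_haplotypes} (2 x L matrices), \code{transmissions}
#'   (n_children x 2 matrix of haplotype indices), \code{loci} and,
#'   for inconsistent families, \code{offending_locus}.
#' @export
phase_family <- function(fam, loci = hla_loci()) {
  fam <- as.data.frame(fam)
  fid <- fam$family_id[1]
  father <- fam[fam$role == "father", , drop = FALSE]
  mother <- fam[fam$role == "mother", , drop = FALSE]
  kids   <- fam[fam$role == "child", , drop = FALSE]
  if (nrow(father) != 1 || nrow(mother) != 1)
    stop("family ", fid, " must have exactly one father and one mother")
  if (nrow(kids) < 1)
    stop("family ", fid, " has no children")
  fg <- genotype_matrix(father, loci)
  mg <- genotype_matrix(mother, loci)
  kg <- lapply(seq_len(nrow(kids)), function(i)
    genotype_matrix(kids[i, ], loci))
  if (any(c(fg, mg, unlist(kg)) == "."))
    stop("missing locus in family ", fid)

  res <- list(family_id = fid, loci = loci, n_children = nrow(kids),
              child_ids = kids$individual_id)
  # Mendelian pre-check: every child allele pair must be splittable
  # between the parents at each locus
  for (ci in seq_along(kg)) {
    for (l in seq_along(loci)) {
      c1 <- kg[[ci]][1, l]; c2 <- kg[[ci]][2, l]
      ok <- (c1 %in% fg[, l] && c2 %in% mg[, l]) ||
            (c2 %in% fg[, l] && c1 %in% mg[, l])
      if (!ok) {
        res$status <- "inconsistent"
        res$offending_locus <- loci[l]
        class(res) <- "phased_family"
        return(res)
      }
    }
  }

  fphases <- enumerate_parent_phases(fg)
  mphases <- enumerate_parent_phases(mg)
  admissible <- list()
  for (fp in fphases) for (mp in mphases) {
    trans <- matrix(NA_integer_, nrow = length(kg), ncol = 2)
    ok <- TRUE
    for (ci in seq_along(kg)) {
      expl <- child_explained(fp, mp, kg[[ci]])
      if (length(expl) == 0) { ok <- FALSE; break }
      trans[ci, ] <- expl[[1]]
    }
    if (ok)
      admissible[[length(admissible) + 1L]] <-
        list(father = fp, mother = mp, trans = trans)
  }

  if (length(admissible) == 0) {
    res$status <- "inconsistent"
  } else {
    founder_key <- vapply(admissible, function(cfg) {
      haps <- c(apply(cfg$father, 1, paste, collapse = "~"),
                apply(cfg$mother, 1, paste, collapse = "~"))
      paste(sort(haps), collapse = "|")
    }, character(1))
    res$status <- if (length(unique(founder_key)) == 1L)
      "unique" else "ambiguous"
    cfg <- admissible[[1]]
    res$father_haplotypes <- cfg$father
    res$mother_haplotypes <- cfg$mother
    res$transmissions <- cfg$trans
    res$n_admissible <- length(admissible)
  }
  class(res) <- "phased_family"
  res
}

#' @export
print.phased_family <- function(x, ...) {
  cat("Family", x$family_id, "-", x$status, "\n")
  if (!is.null(x$father_haplotypes)) {
    cat("  father:", apply(x$father_haplotypes, 1, paste, collapse = "~"),
        "\n  mother:", apply(x$mother_haplotypes, 1, paste, collapse = "~"),
        "\n")
  }
  invisible(x)
}

#' Phase a whole cohort and pool founder haplotypes
#'
#' Applies \code{\link{phase_family}} to every family and pools the
#' four founder haplotypes of each family whose phase is resolved with
#' certainty (\code{status = "unique"}). Families with missing data at
#' any requested locus are excluded up front; ambiguous and
#' inconsistent families are reported, not raised.
#'
#' @param cohort Cohort data frame.
#' @param loci Loci to phase over.
#' @return A list with elements \code{founders} (data frame: one row
#'   per founder chromosome with columns \code{family_id},
#'   \code{parent}, \code{hap_index} and one column per locus) and
#'   \code{report} (list of class \code{phasing_report}: counts per
#'   status and itemized exclusions).
#' @export
phase_cohort <- function(cohort, loci = hla_loci()) {
  cohort <- as.data.frame(cohort)
  fids <- unique(cohort$family_id)
  gcols <- genotype_columns(loci)
  founders <- list()
  status <- character(0)
  excluded <- data.frame(family_id = character(0), reason = character(0))
  phased <- list()
  for (fid in fids) {
    fam <- cohort[cohort$family_id == fid, , drop = FALSE]
    if (any(fam[, gcols] == "." | is.na(fam[, gcols]))) {
      status[fid] <- "excluded"
      excluded <- rbind(excluded,
                        data.frame(family_id = fid,
                                   reason = "missing genotype data"))
      next
    }
    pf <- phase_family(fam, loci)
    status[fid] <- pf$status
    phased[[fid]] <- pf
    if (pf$status == "unique") {
      haps <- rbind(pf$father_haplotypes, pf$mother_haplotypes)
      df <- as.data.frame(haps, stringsAsFactors = FALSE)
      names(df) <- loci
      df <- cbind(family_id = fid,
                  parent = rep(c("father", "mother"), each = 2),
                  hap_index = rep(1:2, 2), df)
      founders[[length(founders) + 1L]] <- df
    } else {
      excluded <- rbind(excluded,
                        data.frame(family_id = fid, reason = pf$status))
    }
  }
  founders <- if (length(founders) > 0) do.call(rbind, founders) else {
    empty <- data.frame(family_id = character(0), parent = character(0),
                        hap_index = integer(0))
    for (l in loci) empty[[l]] <- character(0)
    empty
  }
  rownames(founders) <- NULL
  attr(founders, "loci") <- loci
  report <- structure(list(
    n_families = length(fids),
    n_unique = sum(status == "unique"),
    n_ambiguous = sum(status == "ambiguous"),
    n_inconsistent = sum(status == "inconsistent"),
    n_excluded_missing = sum(status == "excluded"),
    excluded = excluded), class = "phasing_report")
  list(founders = founders, report = report, families = phased)
}

#' @export
print.phasing_report <- function(x, ...) {
  cat("Segregation phasing of", x$n_families, "families:\n",
      " unique:", x$n_unique, "\n",
      " ambiguous:", x$n_ambiguous, "\n",
      " inconsistent:", x$n_inconsistent, "\n",
      " excluded (missing data):", x$n_excluded_missing, "\n")
  invisible(x)
}
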