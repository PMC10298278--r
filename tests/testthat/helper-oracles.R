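# Literal, loop-based reference implementations used as independent
# oracles. Deliberately naive: scalar arithmetic, explicit loops, no
# shared code with the package internals.

oracle_pairwise_ld <- function(h, p, q, two_n) {
  D <- h - p * q
  if (D >= 0) dmax <- min(p * (1 - q), q * (1 - p))
  else dmax <- min(p * q, (1 - p) * (1 - q))
  dprime <- if (dmax == 0) 0 else D / dmax
  chi2 <- two_n * D^2 / (p * (1 - p) * q * (1 - q))
  list(D = D, Dprime = dprime, chi2 = chi2)
}

oracle_overall_dprime <- function(joint) {
  p <- rowSums(joint); q <- colSums(joint)
  acc <- 0
  for (i in seq_along(p)) for (j in seq_along(q)) {
    D <- joint[i, j] - p[i] * q[j]
    dmax <- if (D >= 0) min(p[i] * (1 - q[j]), q[j] * (1 - p[i]))
            else min(p[i] * q[j], (1 - p[i]) * (1 - q[j]))
    dp <- if (dmax == 0) 0 else D / dmax
    acc <- acc + p[i] * q[j] * abs(dp)
  }
  unname(acc)
}

oracle_wn <- function(joint) {
  p <- rowSums(joint); q <- colSums(joint)
  acc <- 0
  for (i in seq_along(p)) for (j in seq_along(q))
    acc <- acc + (joint[i, j] - p[i] * q[j])^2 / (p[i] * q[j])
  unname(sqrt(acc / (min(length(p), length(q)) - 1)))
}

oracle_ald <- function(joint) {
  p <- rowSums(joint); q <- colSums(joint)
  F_a <- sum(p^2); F_b <- sum(q^2)
  F_ab <- 0; F_ba <- 0
  for (i in seq_along(p)) for (j in seq_along(q)) {
    F_ab <- F_ab + joint[i, j]^2 / q[j]
    F_ba <- F_ba + joint[i, j]^2 / p[i]
  }
  list(W_a_given_b = unname(sqrt((F_ab - F_a) / (1 - F_a))),
       W_b_given_a = unname(sqrt((F_ba - F_b) / (1 - F_b))))
}

# random joint haplotype frequency table with no zero margins
random_joint_table <- function(ka, kb) {
  m <- matrix(stats::rexp(ka * kb), ka, kb)
  m <- m / sum(m)
  rownames(m) <- paste0("a", seq_len(ka))
  colnames(m) <- paste0("b", seq_len(kb))
  m
}

# --- brute-force segregation phasing oracle ------------------------------

# all ordered splits of a 2 x L genotype into two haplotypes (2^L of them)
oracle_all_splits <- function(g) {
  L <- ncol(g)
  out <- list()
  for (m in 0:(2^L - 1)) {
    h1 <- character(L); h2 <- character(L)
    for (l in seq_len(L)) {
      if (bitwAnd(m, bitwShiftL(1L, l - 1L)) != 0L) {
        h1[l] <- g[2, l]; h2[l] <- g[1, l]
      } else {
        h1[l] <- g[1, l]; h2[l] <- g[2, l]
      }
    }
    out[[length(out) + 1L]] <- rbind(h1, h2)
  }
  out
}

# set of admissible founder-haplotype multisets for a family, by trying
# every ordered split of both parents against every child
oracle_founder_multisets <- function(fg, mg, kids) {
  keys <- character(0)
  for (fp in oracle_all_splits(fg)) for (mp in oracle_all_splits(mg)) {
    all_ok <- TRUE
    for (kg in kids) {
      child_ok <- FALSE
      for (f in 1:2) for (m in 1:2) {
        ok <- TRUE
        for (l in seq_len(ncol(kg))) {
          want <- sort(unname(kg[, l]))
          got <- sort(c(fp[f, l], mp[m, l]))
          if (!all(want == got)) { ok <- FALSE; break }
        }
        if (ok) child_ok <- TRUE
      }
      if (!child_ok) { all_ok <- FALSE; break }
    }
    if (all_ok) {
      haps <- c(paste(fp[1, ], collapse = "~"), paste(fp[2, ], collapse = "~"),
                paste(mp[1, ], collapse = "~"), paste(mp[2, ], collapse = "~"))
      keys <- c(keys, paste(sort(haps), collapse = "|"))
    }
  }
  unique(keys)
}

oracle_phase_status <- function(fam, loci) {
  fg <- genotype_matrix(fam[fam$role == "father", ], loci)
  mg <- genotype_matrix(fam[fam$role == "mother", ], loci)
  kids <- lapply(which(fam$role == "child"), function(i)
    genotype_matrix(fam[i, ], loci))
  ms <- oracle_founder_multisets(fg, mg, kids)
  if (length(ms) == 0) "inconsistent"
  else if (length(ms) == 1) "unique"
  else "ambiguous"
}

# --- small synthetic families for property tests -------------------------

# random 3-locus family: parents drawn from small allele sets, children
# by Mendelian transmission (guaranteed consistent)
random_family <- function(fid, n_children = 2, n_alleles = 3,
                          loci = c("A", "C", "B")) {
  alleles <- lapply(loci, function(l)
    paste0(l, "*", sprintf("%02d", seq_len(n_alleles))))
  fhap <- sapply(alleles, sample, size = 2, replace = TRUE)
  mhap <- sapply(alleles, sample, size = 2, replace = TRUE)
  row_of <- function(id, role, fa, mo, g) {
    r <- list(family_id = fid, individual_id = id, father_id = fa,
              mother_id = mo, role = role)
    for (l in seq_along(loci)) {
      pair <- sort(g[, l])
      r[[paste0(loci[l], "_1")]] <- pair[1]
      r[[paste0(loci[l], "_2")]] <- pair[2]
    }
    as.data.frame(r, stringsAsFactors = FALSE)
  }
  rows <- list(row_of("P1", "father", ".", ".", fhap),
               row_of("P2", "mother", ".", ".", mhap))
  for (ci in seq_len(n_children)) {
    pg <- fhap[sample(1:2, 1), ]
    mg <- mhap[sample(1:2, 1), ]
    rows[[length(rows) + 1L]] <-
      row_of(paste0("C", ci), "child", "P1", "P2", rbind(pg, mg))
  }
  do.call(rbind, rows)
}

# build a founder chromosome data frame directly from haplotype strings
founders_from_strings <- function(haps, loci) {
  mat <- do.call(rbind, strsplit(haps, "~", fixed = TRUE))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- loci
  rownames(df) <- NULL
  attr(df, "loci") <- loci
  df
}

# simple two-population frequency tables for distance/CA tests
toy_population <- function(freqs_by_locus, two_n = 100) {
  do.call(rbind, lapply(names(freqs_by_locus), function(l) {
    f <- freqs_by_locus[[l]]
    data.frame(locus = l, allele = names(f), frequency = unname(f),
               two_n = two_n, stringsAsFactors = FALSE)
  }))
}
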