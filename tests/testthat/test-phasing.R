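make_genotype <- function(...) {
  g <- cbind(...)
  colnames(g) <- allele_locus(g[1, ])
  g
}

test_that("phase enumeration counts 2^(h-1) distinct splits", {
  hom <- make_genotype(c("A*01", "A*01"), c("B*08", "B*08"))
  expect_length(enumerate_parent_phases(hom), 1)

  het2 <- make_genotype(c("A*01", "A*02"), c("B*08", "B*51"))
  expect_length(enumerate_parent_phases(het2), 2)

  het5 <- make_genotype(c("A*01", "A*02"), c("C*07", "C*04"),
                        c("B*08", "B*51"), c("DRB1*03", "DRB1*07"),
                        c("DQB1*02", "DQB1*03"))
  phases <- enumerate_parent_phases(het5)
  expect_length(phases, 16)
  # matches exhaustive enumeration of all 32 ordered splits collapsed
  # by pair symmetry
  keys <- vapply(oracle_all_splits(het5), function(s)
    paste(sort(c(paste(s[1, ], collapse = "~"),
                 paste(s[2, ], collapse = "~"))), collapse = "|"),
    character(1))
  expect_length(unique(keys), 16)
  got <- vapply(phases, function(s)
    paste(sort(c(paste(s[1, ], collapse = "~"),
                 paste(s[2, ], collapse = "~"))), collapse = "|"),
    character(1))
  expect_setequal(got, unique(keys))

  expect_error(enumerate_parent_phases(
    make_genotype(c("A*01", "."), c("B*08", "B*08"))), "missing")
})

fam_row <- function(fid, id, role, fa, mo, g, loci) {
  r <- list(family_id = fid, individual_id = id, father_id = fa,
            mother_id = mo, role = role)
  for (l in seq_along(loci)) {
    pair <- sort(g[, l])
    r[[paste0(loci[l], "_1")]] <- pair[1]
    r[[paste0(loci[l], "_2")]] <- pair[2]
  }
  as.data.frame(r, stringsAsFactors = FALSE)
}

test_that("segregation resolves, flags ambiguity, and detects Mendelian errors", {
  loci <- c("A", "B")
  # father heterozygous at both loci, mother homozygous; two children
  # that jointly pin A*26 to B*08
  fg <- make_genotype(c("A*26", "A*02"), c("B*08", "B*51"))
  mg <- make_genotype(c("A*01", "A*01"), c("B*07", "B*07"))
  k1 <- rbind(c("A*26", "B*08"), c("A*01", "B*07"))
  colnames(k1) <- loci
  k2 <- rbind(c("A*02", "B*51"), c("A*01", "B*07"))
  colnames(k2) <- loci
  fam <- rbind(fam_row("F1", "P1", "father", ".", ".", fg, loci),
               fam_row("F1", "P2", "mother", ".", ".", mg, loci),
               fam_row("F1", "C1", "child", "P1", "P2", k1, loci),
               fam_row("F1", "C2", "child", "P1", "P2", k2, loci))
  pf <- phase_family(fam, loci)
  expect_equal(pf$status, "unique")
  fh <- apply(pf$father_haplotypes, 1, paste, collapse = "~")
  expect_true("A*26~B*08" %in% fh)

  # fully homozygous parents: unique regardless of children
  fg <- make_genotype(c("A*26", "A*26"), c("B*08", "B*08"))
  mg <- make_genotype(c("A*01", "A*01"), c("B*07", "B*07"))
  kid <- rbind(c("A*26", "B*08"), c("A*01", "B*07"))
  colnames(kid) <- loci
  fam <- rbind(fam_row("F2", "P1", "father", ".", ".", fg, loci),
               fam_row("F2", "P2", "mother", ".", ".", mg, loci),
               fam_row("F2", "C1", "child", "P1", "P2", kid, loci))
  expect_equal(phase_family(fam, loci)$status, "unique")

  # identically heterozygous parents at both loci, one doubly
  # heterozygous child: multiple admissible founder multisets
  fg <- make_genotype(c("A*01", "A*02"), c("B*08", "B*51"))
  mg <- make_genotype(c("A*01", "A*02"), c("B*08", "B*51"))
  kid <- rbind(c("A*01", "B*08"), c("A*02", "B*51"))
  colnames(kid) <- loci
  fam <- rbind(fam_row("F3", "P1", "father", ".", ".", fg, loci),
               fam_row("F3", "P2", "mother", ".", ".", mg, loci),
               fam_row("F3", "C1", "child", "P1", "P2", kid, loci))
  expect_equal(phase_family(fam, loci)$status, "ambiguous")

  # child allele absent from both parents: inconsistent, locus named
  fg <- make_genotype(c("A*01", "A*01"), c("B*08", "B*08"))
  mg <- make_genotype(c("A*01", "A*01"), c("B*08", "B*08"))
  kid <- rbind(c("A*03", "B*08"), c("A*01", "B*08"))
  colnames(kid) <- loci
  fam <- rbind(fam_row("F4", "P1", "father", ".", ".", fg, loci),
               fam_row("F4", "P2", "mother", ".", ".", mg, loci),
               fam_row("F4", "C1", "child", "P1", "P2", kid, loci))
  pf <- phase_family(fam, loci)
  expect_equal(pf$status, "inconsistent")
  expect_equal(pf$offending_locus, "A")
})

test_that("phase_family agrees with the brute-force oracle on random families", {
  set.seed(101)
  loci <- c("A", "C", "B")
  mismatches <- 0
  for (i in 1:400) {
    fam <- random_family(paste0("F", i),
                         n_children = sample(1:4, 1),
                         n_alleles = sample(2:3, 1), loci = loci)
    got <- phase_family(fam, loci)$status
    want <- oracle_phase_status(fam, loci)
    if (got != want) mismatches <- mismatches + 1
  }
  expect_equal(mismatches, 0)
})

test_that("unique phases reproduce every child genotype (soundness)", {
  set.seed(202)
  loci <- c("A", "C", "B")
  checked <- 0
  for (i in 1:100) {
    fam <- random_family(paste0("F", i), n_children = 3, loci = loci)
    pf <- phase_family(fam, loci)
    if (pf$status != "unique") next
    kids <- fam[fam$role == "child", , drop = FALSE]
    for (ci in seq_len(nrow(kids))) {
      tr <- pf$transmissions[ci, ]
      derived <- rbind(pf$father_haplotypes[tr[1], ],
                       pf$mother_haplotypes[tr[2], ])
      observed <- genotype_matrix(kids[ci, ], loci)
      for (l in seq_along(loci))
        expect_equal(sort(unname(derived[, l])),
                     sort(unname(observed[, l])))
      checked <- checked + 1
    }
  }
  expect_gt(checked, 50)
})

test_that("adding a child never turns a unique family ambiguous", {
  set.seed(303)
  loci <- c("A", "C", "B")
  for (i in 1:60) {
    fam <- random_family(paste0("F", i), n_children = 4, loci = loci)
    kids <- which(fam$role == "child")
    s3 <- phase_family(fam[-kids[4], ], loci)$status
    s4 <- phase_family(fam, loci)$status
    if (s3 == "unique") expect_true(s4 %in% c("unique", "inconsistent"))
    # (inconsistent impossible here by construction, but allowed by the
    # monotonicity contract)
    if (s3 == "unique") expect_equal(s4, "unique")
  }
})

test_that("phase_cohort pools 4 founders per unique family and itemizes the rest", {
  spec <- default_simulation_spec(seed = 5, n_families = 30)
  sim <- simulate_cohort(spec)
  ph <- phase_cohort(sim$cohort)
  rep <- ph$report
  expect_equal(rep$n_unique + rep$n_ambiguous + rep$n_inconsistent +
                 rep$n_excluded_missing, 30)
  expect_equal(nrow(ph$founders), 4 * rep$n_unique)
  # recombination-free cohort: no inconsistent families
  expect_equal(rep$n_inconsistent, 0)

  # uniquely phased families recover the simulator's founder truth
  truth <- sim$truth$founders
  loci <- hla_loci()
  for (fid in unique(ph$founders$family_id)) {
    got <- sort(unname(apply(ph$founders[ph$founders$family_id == fid,
                                         loci], 1, paste, collapse = "~")))
    want <- sort(unname(apply(truth[truth$family_id == fid, loci],
                              1, paste, collapse = "~")))
    expect_equal(got, want)
  }

  # a lone inconsistent family yields no founders
  bad <- as.data.frame(sim$cohort[sim$cohort$family_id == "F001", ])
  bad$A_1[bad$role == "child"][1] <- "A*74"
  bad$A_2[bad$role == "child"][1] <- "A*74"
  ph1 <- phase_cohort(validate_cohort(bad))
  expect_equal(nrow(ph1$founders), 0)
  expect_equal(ph1$report$n_inconsistent, 1)
})
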