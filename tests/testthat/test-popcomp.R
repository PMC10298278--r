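test_that("Nei distance has its closed-form values on toy populations", {
  p1 <- toy_population(list(A = c("A*01" = 0.6, "A*02" = 0.4),
                            B = c("B*08" = 1.0)))
  expect_equal(nei_sgd(p1, p1), 0)

  # fixed for different alleles at the shared locus: infinite distance
  pa <- toy_population(list(A = c("A*01" = 1)))
  pb <- toy_population(list(A = c("A*02" = 1)))
  expect_error(nei_sgd(pa, pb), "infinite")

  # no shared locus
  pc <- toy_population(list(B = c("B*08" = 1)))
  expect_error(nei_sgd(pa, pc), "no shared locus")

  # hand-computed J-sums for two random 3-allele populations at 2 loci
  x <- toy_population(list(A = c("A*01" = 0.5, "A*02" = 0.3, "A*03" = 0.2),
                           B = c("B*08" = 0.7, "B*51" = 0.2, "B*35" = 0.1)))
  y <- toy_population(list(A = c("A*01" = 0.2, "A*02" = 0.5, "A*03" = 0.3),
                           B = c("B*08" = 0.4, "B*51" = 0.4, "B*35" = 0.2)))
  jx <- ((0.25 + 0.09 + 0.04) + (0.49 + 0.04 + 0.01)) / 2
  jy <- ((0.04 + 0.25 + 0.09) + (0.16 + 0.16 + 0.04)) / 2
  jxy <- ((0.1 + 0.15 + 0.06) + (0.28 + 0.08 + 0.02)) / 2
  expect_equal(nei_sgd(x, y), -log(jxy / sqrt(jx * jy)),
               tolerance = 1e-12)
})

test_that("distance matrices are symmetric and respect mixtures", {
  a <- toy_population(list(A = c("A*01" = 0.8, "A*02" = 0.2)))
  c_ <- toy_population(list(A = c("A*01" = 0.2, "A*02" = 0.8)))
  b <- toy_population(list(A = c("A*01" = 0.5, "A*02" = 0.5)))
  d <- sgd_matrix(list(A = a, B = b, C = c_))
  expect_equal(d, t(d))
  expect_equal(diag(d), c(A = 0, B = 0, C = 0))
  expect_equal(d["A", "B"], nei_sgd(a, b))
  # B is the even mixture of A and C: closer to A than C is
  expect_lt(d["A", "B"], d["A", "C"])
})

test_that("NJ recovers additive trees exactly", {
  # ((A,B),(C,D)) with all five branches length 1
  d <- matrix(c(0, 2, 3, 3,
                2, 0, 3, 3,
                3, 3, 0, 2,
                3, 3, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), LETTERS[1:4])
  # path lengths reproduce the additive input
  expect_equal(stats::cophenetic(tr)[LETTERS[1:4], LETTERS[1:4]], d,
               tolerance = 1e-8)

  # three taxa: closed-form three-point branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(d3)
  expect_equal(stats::cophenetic(t3)[c("x", "y", "z"), c("x", "y", "z")],
               d3, tolerance = 1e-8)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|taxa")
})

test_that("NJ matches random additive trees and the reference implementation", {
  skip_if_not_installed("phangorn")
  set.seed(404)
  for (i in 1:12) {
    n <- sample(5:8, 1)
    ref <- ape::rtree(n, rooted = FALSE,
                      br = function(k) stats::runif(k, 0.3, 1.5))
    d <- stats::cophenetic(ref)
    tr <- nj_tree(d)
    # additive input: topology and path lengths recovered exactly
    expect_equal(stats::cophenetic(tr)[rownames(d), colnames(d)], d,
                 tolerance = 1e-7)
    expect_equal(phangorn::RF.dist(tr, ref), 0)
    # agreement with the ape reference implementation
    expect_equal(phangorn::RF.dist(tr, ape::nj(d)), 0)
  }
})

test_that("NJ tie-breaks deterministically on the smallest label pair", {
  # four equidistant taxa: every Q entry ties; the lexicographically
  # smallest pair (a, b) must be joined first
  labs <- c("d", "b", "c", "a")
  d <- matrix(1, 4, 4, dimnames = list(labs, labs)); diag(d) <- 0
  tr <- nj_tree(d)
  expect_identical(nj_tree(d)$edge, tr$edge)  # deterministic
  # a and b form the first-joined cherry under the tie-break
  root <- length(tr$tip.label) + 1L
  inner <- setdiff(unique(tr$edge[, 1]), root)
  expect_length(inner, 1)
  kids <- tr$edge[tr$edge[, 1] == inner, 2]
  expect_setequal(tr$tip.label[kids[kids <= 4]], c("a", "b"))
})

test_that("bootstrap supports behave at the extremes and are reproducible", {
  mk <- function(p) toy_population(list(
    A = c("A*01" = p, "A*02" = 1 - p),
    B = c("B*08" = p, "B*51" = 1 - p)), two_n = 5000)
  pops <- list(P1 = mk(0.90), P2 = mk(0.88), P3 = mk(0.10), P4 = mk(0.12))
  tr <- bootstrap_supports(pops, replicates = 60, seed = 11)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  # the single internal edge separates the two pairs with full support
  expect_true(any(sup[!is.na(sup)] >= 95))

  # replicates = 1: supports only 0 or 100
  tr1 <- bootstrap_supports(pops, replicates = 1, seed = 3)
  s1 <- suppressWarnings(as.numeric(tr1$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))

  # fixed seed: identical supports, regardless of input order
  tr2 <- bootstrap_supports(pops, replicates = 60, seed = 11)
  expect_identical(tr$node.label, tr2$node.label)
  tr3 <- bootstrap_supports(rev(pops), replicates = 60, seed = 11)
  expect_identical(sort(tr$node.label), sort(tr3$node.label))

  nores <- lapply(pops, function(p) { p$two_n <- NULL; p })
  expect_error(bootstrap_supports(nores, replicates = 5, seed = 1),
               "two_n")
})

test_that("correspondence analysis reproduces chi-square geometry", {
  # rank-1 table: no inertia, all coordinates zero
  r1 <- outer(c(2, 3, 5), c(1, 4, 2))
  expect_equal(correspondence_analysis(r1, dims = 2)$total_inertia, 0,
               tolerance = 1e-12)
  expect_equal(max(abs(correspondence_analysis(r1, 2)$row_coords)), 0,
               tolerance = 1e-6)

  x <- matrix(c(20, 5, 3,
                4, 18, 6,
                2, 6, 25), 3, 3, byrow = TRUE,
              dimnames = list(paste0("P", 1:3), paste0("al", 1:3)))
  ca <- correspondence_analysis(x, dims = 2)

  # axis inertias sum to the total chi-square inertia
  P <- x / sum(x); r <- rowSums(P); cc <- colSums(P)
  total <- sum((P - outer(r, cc))^2 / outer(r, cc))
  expect_lt(abs(sum(ca$inertia) - total), 1e-10)

  # squared distance between row points equals the chi-square
  # distance between row profiles
  prof <- sweep(P, 1, r, "/")
  chi2_dist <- sum((prof[1, ] - prof[2, ])^2 / cc)
  expect_equal(sum((ca$row_coords[1, ] - ca$row_coords[2, ])^2),
               chi2_dist, tolerance = 1e-10)

  # permutation invariance up to row order
  perm <- c(3, 1, 2)
  ca2 <- correspondence_analysis(x[perm, ], dims = 2)
  expect_equal(abs(ca2$row_coords), abs(ca$row_coords[perm, ]),
               tolerance = 1e-8)

  expect_error(correspondence_analysis(rbind(c(1, 2), c(0, 0))),
               "all-zero")
  expect_error(correspondence_analysis(x, dims = 3), "dims")
})

test_that("correspondence analysis agrees with the MASS reference", {
  skip_if_not_installed("MASS")
  x <- matrix(c(30, 10, 5, 8, 2,
                6, 25, 10, 2, 7,
                4, 8, 22, 9, 3,
                9, 3, 6, 28, 4), 4, 5, byrow = TRUE)
  dimnames(x) <- list(paste0("P", 1:4), paste0("a", 1:5))
  ca <- correspondence_analysis(x, dims = 2)
  ref <- MASS::corresp(x, nf = 2)
  # canonical correlations = singular values
  expect_equal(ca$singular_values[1:2], ref$cor[1:2], tolerance = 1e-8)
  # principal coordinates match up to axis sign
  refrow <- sweep(ref$rscore, 2, ref$cor[1:2], "*")
  for (ax in 1:2)
    expect_equal(abs(ca$row_coords[, ax]), abs(refrow[, ax]),
                 tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("classical scaling of a distance matrix preserves distances", {
  d <- matrix(c(0, 2, 3, 3, 2, 0, 3, 3, 3, 3, 0, 2, 3, 3, 2, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  xy <- sgd_mds(d, dims = 3)
  expect_equal(dim(xy)[1], 4)
  expect_equal(as.matrix(dist(xy)), d, ignore_attr = TRUE,
               tolerance = 1e-6)
})
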