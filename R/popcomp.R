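#' Nei standard genetic distance between two populations
#'
#' For allele frequency tables x and y over a shared locus set, the
#' normalized identity is I = J_xy / sqrt(J_x J_y), where J_x, J_y and
#' J_xy are the means over loci of sum_i x_i^2, sum_i y_i^2 and
#' sum_i x_i y_i (allele universes are unioned per locus, absent
#' alleles at frequency 0). The distance is D = -ln I.
#'
#' @param pop_x,pop_y Data frames with columns \code{locus},
#'   \code{allele}, \code{frequency}.
#' @param loci Optional locus subset for the comparison (default: all
#'   loci shared by both tables).
#' @return Scalar distance (0 for identical tables).
#' @export
nei_sgd <- function(pop_x, pop_y, loci = NULL) {
  if (is.null(loci))
    loci <- intersect(unique(pop_x$locus), unique(pop_y$locus))
  if (length(loci) == 0) stop("no shared locus")
  jx <- jy <- jxy <- numeric(length(loci))
  for (i in seq_along(loci)) {
    xs <- pop_x[pop_x$locus == loci[i], ]
    ys <- pop_y[pop_y$locus == loci[i], ]
    alleles <- union(xs$allele, ys$allele)
    x <- stats::setNames(rep(0, length(alleles)), alleles)
    y <- x
    x[xs$allele] <- xs$frequency
    y[ys$allele] <- ys$frequency
    jx[i] <- sum(x^2); jy[i] <- sum(y^2); jxy[i] <- sum(x * y)
  }
  I <- mean(jxy) / sqrt(mean(jx) * mean(jy))
  if (I <= 0)
    stop("genetic identity is zero: infinite distance (no shared allele)")
  -log(I)
}

#' Pairwise Nei distance matrix
#'
#' @param populations Named list of allele frequency tables (see
#'   \code{\link{nei_sgd}}).
#' @param loci Optional shared locus set declared for the analysis.
#' @return Symmetric matrix with zero diagonal and population labels.
#' @export
sgd_matrix <- function(populations, loci = NULL) {
  n <- length(populations)
  if (n < 2) stop("need at least 2 populations")
  labs <- names(populations)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- nei_sgd(populations[[i]], populations[[j]], loci)
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q-criterion
#' Q(i, j) = (r - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k), standard
#' branch-length formulas, and two documented conventions: ties in the
#' Q-matrix are broken by the lexicographically smallest label pair
#' (labels of a merged node inherit the smallest leaf label it
#' contains), and a negative branch length is clamped to 0 with the
#' deficit transferred to its sister branch so that the pair's total
#' is preserved.
#'
#' @param d Symmetric distance matrix with labels (or a \code{dist}).
#' @return An unrooted \code{phylo} tree (ape).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  nwk <- labs           # growing newick substrings per active node
  key <- labs           # lexicographic sort keys (smallest leaf label)
  fmt <- function(x) sprintf("%.10g", x)
  while (length(key) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_key <- apply(cand, 1, function(ij) {
      ks <- sort(c(key[ij[1]], key[ij[2]]))
      paste(ks, collapse = "\r")
    })
    best <- cand[order(pair_key)[1], ]
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_nwk <- paste0("(", nwk[i], ":", fmt(li), ",",
                      nwk[j], ":", fmt(lj), ")")
    new_key <- min(key[i], key[j])
    duk <- (d[i, -c(i, j)] + d[j, -c(i, j)] - d[i, j]) / 2
    d <- d[-c(i, j), -c(i, j), drop = FALSE]
    d <- rbind(cbind(d, duk), c(duk, 0))
    nwk <- c(nwk[-c(i, j)], new_nwk)
    key <- c(key[-c(i, j)], new_key)
  }
  dxy <- d[1, 2]; dxz <- d[1, 3]; dyz <- d[2, 3]
  lx <- (dxy + dxz - dyz) / 2
  ly <- (dxy + dyz - dxz) / 2
  lz <- (dxz + dyz - dxy) / 2
  lx <- max(lx, 0); ly <- max(ly, 0); lz <- max(lz, 0)
  txt <- paste0("(", nwk[1], ":", fmt(lx), ",", nwk[2], ":", fmt(ly),
                ",", nwk[3], ":", fmt(lz), ");")
  ape::read.tree(text = txt)
}

resample_population <- function(pop) {
  # parametric bootstrap: resample allele counts per locus from a
  # multinomial over the population's chromosome sample size
  for (locus in unique(pop$locus)) {
    idx <- which(pop$locus == locus)
    two_n <- pop$two_n[idx[1]]
    p <- pop$frequency[idx]
    counts <- stats::rmultinom(1, size = two_n, prob = p / sum(p))[, 1]
    pop$frequency[idx] <- counts / two_n
  }
  pop
}

#' Neighbor-joining tree with parametric bootstrap supports
#'
#' Builds the Nei-distance NJ tree of the populations, then resamples
#' each population's allele counts per locus from a
#' multinomial(two_n, p) parametric bootstrap, recomputes the distance
#' matrix and NJ tree for each replicate, and annotates each internal
#' edge of the main tree with the percentage of replicates containing
#' the same bipartition. Populations are ordered by label internally,
#' so supports do not depend on input order for a given seed.
#'
#' @param populations Named list of frequency tables; each must carry
#'   a \code{two_n} column.
#' @param loci Optional shared locus set.
#' @param replicates Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return A \code{phylo} tree with \code{node.label} set to bootstrap
#'   percentages (root label empty).
#' @export
bootstrap_supports <- function(populations, loci = NULL,
                               replicates = 1000, seed) {
  if (missing(seed)) stop("seed is required")
  if (any(vapply(populations, function(p) is.null(p$two_n), TRUE)))
    stop("every population needs a two_n column for the bootstrap")
  populations <- populations[order(names(populations))]
  main <- nj_tree(sgd_matrix(populations, loci))
  boots <- withr::with_seed(seed, {
    lapply(seq_len(replicates), function(r) {
      resampled <- lapply(populations, resample_population)
      nj_tree(sgd_matrix(resampled, loci))
    })
  })
  class(boots) <- "multiPhylo"
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  pct <- round(100 * counts / replicates)
  lab <- as.character(pct)
  lab[1] <- ""  # root of the unrooted representation carries no support
  main$node.label <- lab
  attr(main, "replicates") <- replicates
  main
}

#' Correspondence analysis of a population-by-allele table
#'
#' Standard CA: with P the table divided by its grand total, row
#' masses r and column masses c, the standardized residuals
#' S_ij = (P_ij - r_i c_j) / sqrt(r_i c_j) are decomposed by SVD;
#' principal coordinates are the mass-scaled singular vectors times
#' the singular values. Axis inertias are the squared singular values
#' and sum to the table's total chi-square inertia.
#'
#' @param x Nonnegative matrix (e.g. populations x alleles, allele
#'   counts or sample-size-weighted frequencies); no all-zero row or
#'   column.
#' @param dims Number of axes to return (<= min(dim) - 1).
#' @return List of class \code{ca_result}: \code{row_coords},
#'   \code{col_coords} (matrices with \code{dims} columns),
#'   \code{singular_values}, \code{inertia}, \code{inertia_share},
#'   \code{total_inertia}.
#' @export
correspondence_analysis <- function(x, dims = 3) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("negative entries")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0))
    stop("all-zero row or column")
  maxd <- min(dim(x)) - 1L
  if (dims > maxd) stop("dims must be <= min(rows, cols) - 1")
  P <- x / sum(x)
  r <- rowSums(P); cc <- colSums(P)
  E <- outer(r, cc)
  S <- (P - E) / sqrt(E)
  sv <- svd(S)
  d <- sv$d[seq_len(maxd)]
  d[d < 1e-12] <- 0
  U <- sv$u[, seq_len(maxd), drop = FALSE]
  V <- sv$v[, seq_len(maxd), drop = FALSE]
  row_coords <- sweep(U, 1, sqrt(r), "/") %*% diag(d, maxd)
  col_coords <- sweep(V, 1, sqrt(cc), "/") %*% diag(d, maxd)
  dimnames(row_coords) <- list(rownames(x),
                               paste0("axis", seq_len(maxd)))
  dimnames(col_coords) <- list(colnames(x),
                               paste0("axis", seq_len(maxd)))
  inertia <- d^2
  total <- sum(S^2)
  res <- list(row_coords = row_coords[, seq_len(dims), drop = FALSE],
              col_coords = col_coords[, seq_len(dims), drop = FALSE],
              singular_values = d,
              inertia = inertia,
              inertia_share = if (total > 0) inertia / total
                              else rep(0, maxd),
              total_inertia = total)
  class(res) <- "ca_result"
  res
}

#' @export
print.ca_result <- function(x, ...) {
  cat("Correspondence analysis:", nrow(x$row_coords), "rows x",
      nrow(x$col_coords), "columns\n")
  k <- min(3, length(x$inertia))
  cat(sprintf("  total inertia %.5f; first %d axes explain %s\n",
              x$total_inertia, k,
              paste(sprintf("%.1f%%", 100 * x$inertia_share[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

#' Population-by-allele input matrix for correspondence analysis
#'
#' Builds the matrix of per-population allele counts
#' (frequency x two_n) or raw frequencies over the union of alleles.
#'
#' @param populations Named list of frequency tables.
#' @param weight \code{"count"} (default) weights frequencies by each
#'   population's chromosome sample size; \code{"frequency"} uses the
#'   frequencies as-is.
#' @return Matrix with one row per population, one column per allele.
#' @export
ca_input_matrix <- function(populations, weight = c("count", "frequency")) {
  weight <- match.arg(weight)
  alleles <- sort(unique(unlist(lapply(populations,
                                       function(p) p$allele))))
  m <- matrix(0, length(populations), length(alleles),
              dimnames = list(names(populations), alleles))
  for (pop in names(populations)) {
    tab <- populations[[pop]]
    w <- if (weight == "count") tab$frequency * tab$two_n else tab$frequency
    m[pop, tab$allele] <- w
  }
  m
}

#' Classical metric scaling of a distance matrix
#'
#' Principal-coordinates (classical MDS) embedding of a genetic
#' distance matrix — an explicitly labeled alternative to
#' \code{\link{correspondence_analysis}} for the case where only
#' distances, not frequency tables, are available.
#'
#' @param d Symmetric distance matrix.
#' @param dims Number of coordinates.
#' @return Matrix of coordinates (populations x dims).
#' @export
sgd_mds <- function(d, dims = 2) {
  stats::cmdscale(stats::as.dist(d), k = dims)
}
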