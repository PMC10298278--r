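genotype_columns <- function(loci = hla_loci()) {
  as.vector(t(outer(loci, c("_1", "_2"), paste0)))
}

#' Read a family genotype table
#'
#' Reads a tab-separated PED-like file with a header row and columns
#' \code{family_id}, \code{individual_id}, \code{father_id},
#' \code{mother_id}, \code{role} (one of \code{father}, \code{mother},
#' \code{child}) followed by two allele columns per locus
#' (\code{A_1, A_2, C_1, C_2, B_1, B_2, DRB1_1, DRB1_2, DQB1_1,
#' DQB1_2}). Missing alleles are encoded \code{"."}.
#'
#' Parentage references of every child are checked against the family's
#' members, and each allele is validated against its column's locus.
#'
#' @param path File path.
#' @return A data frame of class \code{hla_cohort}, one row per
#'   individual.
#' @export
read_family_genotypes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          check.names = FALSE)
  required <- c("family_id", "individual_id", "father_id", "mother_id",
                "role", genotype_columns())
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  validate_cohort(df[, required])
}

#' Validate and class a cohort data frame
#'
#' @param df Data frame in the layout of
#'   \code{\link{read_family_genotypes}}.
#' @return The validated data frame with class \code{hla_cohort}.
#' @export
validate_cohort <- function(df) {
  line_of <- function(i) i + 1L  # header occupies line 1
  bad_role <- which(!df$role %in% c("father", "mother", "child"))
  if (length(bad_role) > 0)
    stop("malformed row at line ", line_of(bad_role[1]),
         ": unknown role ", sQuote(df$role[bad_role[1]]))
  for (locus in hla_loci()) {
    for (col in paste0(locus, c("_1", "_2"))) {
      vals <- df[[col]]
      typed <- which(vals != "." & !is.na(vals))
      if (length(typed) == 0) next
      loci_seen <- allele_locus(vals[typed])
      bad <- typed[loci_seen != locus]
      if (length(bad) > 0)
        stop("allele/locus mismatch at line ", line_of(bad[1]),
             ": ", sQuote(df[[col]][bad[1]]), " in column ", col)
      for (i in typed) parse_allele_name(vals[i])
    }
  }
  for (fid in unique(df$family_id)) {
    fam <- df[df$family_id == fid, ]
    if (anyDuplicated(fam$individual_id))
      stop("duplicate individual_id in family ", fid)
    parents <- fam$individual_id[fam$role %in% c("father", "mother")]
    kids <- which(df$family_id == fid & df$role == "child")
    for (i in kids) {
      if (!(df$father_id[i] %in% parents) || !(df$mother_id[i] %in% parents))
        stop("orphan child at line ", line_of(i), ": parents ",
             df$father_id[i], "/", df$mother_id[i],
             " not found in family ", fid)
    }
  }
  class(df) <- c("hla_cohort", "data.frame")
  df
}

#' Write a family genotype table
#'
#' @param cohort A cohort data frame (see
#'   \code{\link{read_family_genotypes}}).
#' @param path Output path; tab-separated, UTF-8, LF line endings.
#' @export
write_family_genotypes <- function(cohort, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  cols <- c("family_id", "individual_id", "father_id", "mother_id",
            "role", genotype_columns())
  writeLines(paste(cols, collapse = "\t"), con, sep = "\n")
  apply(as.data.frame(cohort)[, cols], 1L, function(r)
    writeLines(paste(r, collapse = "\t"), con, sep = "\n"))
  invisible(path)
}

#' Read per-population allele frequency tables
#'
#' Long-format CSV with columns \code{population}, \code{locus},
#' \code{allele}, \code{frequency}, \code{two_n} (chromosome sample
#' size). Frequencies are grouped by population and locus; each locus
#' group must sum to 1 within 1e-3, otherwise it is renormalized with a
#' warning.
#'
#' @param path File path.
#' @return A named list (one element per population) of data frames
#'   with columns \code{locus}, \code{allele}, \code{frequency},
#'   \code{two_n}.
#' @export
read_population_frequencies <- function(path) {
  df <- utils::read.csv(path, colClasses = c(population = "character",
                                             locus = "character",
                                             allele = "character",
                                             frequency = "numeric",
                                             two_n = "numeric"))
  if (nrow(df) == 0) return(structure(list(), names = character(0)))
  if (any(df$frequency < 0))
    stop("negative frequency for ",
         df$allele[which(df$frequency < 0)[1]])
  key <- paste(df$population, df$locus, df$allele)
  if (anyDuplicated(key))
    stop("duplicate (population, locus, allele) key: ",
         key[which(duplicated(key))[1]])
  out <- list()
  for (pop in unique(df$population)) {
    sub <- df[df$population == pop, c("locus", "allele", "frequency", "two_n")]
    for (locus in unique(sub$locus)) {
      idx <- sub$locus == locus
      s <- sum(sub$frequency[idx])
      if (abs(s - 1) > 1e-3) {
        warning("frequencies for ", pop, "/", locus, " sum to ",
                format(s), "; renormalizing")
        sub$frequency[idx] <- sub$frequency[idx] / s
      }
    }
    rownames(sub) <- NULL
    out[[pop]] <- sub
  }
  out
}

#' Write a frequency table as CSV
#'
#' Writes allele or haplotype frequency tables with 4-decimal
#' frequencies, UTF-8, LF line endings.
#'
#' @param tab Data frame from \code{\link{count_allele_frequencies}} or
#'   \code{\link{count_haplotype_frequencies}}.
#' @param path Output path.
#' @export
write_frequency_table <- function(tab, path) {
  out <- as.data.frame(tab)
  for (col in intersect(c("frequency", "sd"), names(out)))
    out[[col]] <- sprintf("%.4f", out[[col]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con, sep = "\n")
  apply(out, 1L, function(r) writeLines(paste(r, collapse = ","),
                                        con, sep = "\n"))
  invisible(path)
}

#' Packaged Emirati allele lineage frequencies
#'
#' One-field (allele lineage) frequencies at the five loci for the
#' Emirati family cohort (2n = 400 founder chromosomes), transcribed
#' from the published frequency table.
#'
#' @return A data frame with columns \code{locus}, \code{allele},
#'   \code{frequency}, \code{two_n}.
#' @export
uae_frequencies <- function() {
  path <- system.file("extdata", "emirati_allele_lineages.csv",
                      package = "hlafam", mustWork = TRUE)
  read_population_frequencies(path)[["Emirati"]]
}

#' Packaged Emirati two-locus haplotype frequencies
#'
#' Frequent (>= 1\%) two-locus lineage haplotypes with direct-count
#' frequencies and binomial SDs (2n = 400), transcribed from the
#' published haplotype table.
#'
#' @return Data frame with columns \code{haplotype}, \code{frequency},
#'   \code{sd}.
#' @export
uae_haplotypes_2locus <- function() {
  path <- system.file("extdata", "emirati_2locus_haplotypes.csv",
                      package = "hlafam", mustWork = TRUE)
  utils::read.csv(path, colClasses = c(haplotype = "character",
                                       frequency = "numeric",
                                       sd = "numeric"))
}

#' Packaged Emirati five-locus haplotype frequencies
#'
#' Most frequent (>= 0.75\%) A~B~C~DRB1~DQB1 lineage haplotypes with
#' direct-count frequencies and binomial SDs (2n = 400), transcribed
#' from the published haplotype table.
#'
#' @return Data frame with columns \code{haplotype}, \code{frequency},
#'   \code{sd}.
#' @export
uae_haplotypes_5locus <- function() {
  path <- system.file("extdata", "emirati_5locus_haplotypes.csv",
                      package = "hlafam", mustWork = TRUE)
  utils::read.csv(path, colClasses = c(haplotype = "character",
                                       frequency = "numeric",
                                       sd = "numeric"))
}

#' Read a PHYLIP square distance matrix
#'
#' @param path File path.
#' @return Symmetric numeric matrix with population labels.
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  labs <- character(n)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    toks <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    labs[i] <- toks[1]
    m[i, ] <- as.numeric(toks[-1])
  }
  dimnames(m) <- list(labs, labs)
  m
}

#' Write a PHYLIP square distance matrix
#'
#' @param d Symmetric matrix with dimnames.
#' @param path Output path.
#' @export
write_phylip_dist <- function(d, path) {
  d <- as.matrix(d)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con, sep = "\n")
  labs <- sprintf("%-10s", rownames(d))
  for (i in seq_len(nrow(d)))
    writeLines(paste0(labs[i], paste(sprintf("%.6f", d[i, ]),
                                     collapse = "  ")), con, sep = "\n")
  invisible(path)
}
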