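#' Assemble a pipeline configuration
#'
#' @param genotypes Path to a family genotype TSV (or an
#'   \code{hla_cohort} data frame).
#' @param reference_frequencies Optional path to a long-format
#'   population frequency CSV for the comparison stages.
#' @param loci Locus subset to analyze.
#' @param n_fields Resolution level (1 = allele lineage).
#' @param stages Character vector of enabled statistics among
#'   \code{"hwe"}, \code{"ld"}, \code{"ewh"}, \code{"distances"},
#'   \code{"tree"}, \code{"ca"}.
#' @param replicates Named list of Monte Carlo replicate counts
#'   (\code{hwe}, \code{ewh}, \code{bootstrap}).
#' @param seed Integer seed; required whenever a Monte Carlo stage is
#'   enabled.
#' @param out_dir Output directory.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(genotypes,
                            reference_frequencies = NULL,
                            loci = hla_loci(),
                            n_fields = 1,
                            stages = c("hwe", "ld", "ewh"),
                            replicates = list(hwe = 10000, ewh = 10000,
                                              bootstrap = 1000),
                            seed = NULL,
                            out_dir = "hlafam_out") {
  mc <- intersect(stages, c("hwe", "ewh", "tree"))
  if (length(mc) > 0 && is.null(seed))
    stop("seed is required when Monte Carlo stages are enabled: ",
         paste(mc, collapse = ", "))
  structure(list(genotypes = genotypes,
                 reference_frequencies = reference_frequencies,
                 loci = loci, n_fields = n_fields, stages = stages,
                 replicates = replicates, seed = seed,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with the fields of
#'   \code{\link{pipeline_config}}.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

stage_seed <- function(seed, offset) (seed + offset) %% .Machine$integer.max

#' Run the full family-based HLA analysis pipeline
#'
#' Executes, in order: segregation phasing with report; per-locus
#' allele frequency tables; Hardy-Weinberg exact tests; two-locus LD
#' summaries and per-haplotype tables; the five-locus haplotype table;
#' Ewens-Watterson tests; and, when reference populations are
#' supplied, the Nei distance matrix, the NJ tree with bootstrap
#' supports, and correspondence analysis coordinates. A run manifest
#' (package version, seed, configuration hash) is written alongside
#' the outputs. A stage failure aborts with the stage name; outputs
#' written so far are retained.
#'
#' @param config A \code{\link{pipeline_config}} (or path to a YAML
#'   config).
#' @return Invisibly, a list with the in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- run_stage("input", {
    if (is.character(config$genotypes))
      read_family_genotypes(config$genotypes)
    else validate_cohort(as.data.frame(config$genotypes))
  })

  phased <- run_stage("phasing", phase_cohort(cohort, config$loci))
  results$phasing <- phased$report
  rep_df <- with(phased$report, data.frame(
    status = c("unique", "ambiguous", "inconsistent", "excluded_missing"),
    n = c(n_unique, n_ambiguous, n_inconsistent, n_excluded_missing)))
  utils::write.csv(rep_df, file.path(out, "phasing_report.csv"),
                   row.names = FALSE)
  if (nrow(phased$report$excluded) > 0)
    utils::write.csv(phased$report$excluded,
                     file.path(out, "excluded_families.csv"),
                     row.names = FALSE)
  founders <- phased$founders

  results$frequencies <- run_stage("frequencies", {
    lapply(stats::setNames(config$loci, config$loci), function(l) {
      tab <- count_allele_frequencies(founders, l, config$n_fields)
      write_frequency_table(tab, file.path(out, paste0("freq_", l, ".csv")))
      tab
    })
  })

  if ("hwe" %in% config$stages) {
    results$hwe <- run_stage("hwe", {
      parents <- cohort[cohort$role %in% c("father", "mother"), ]
      res <- lapply(seq_along(config$loci), function(i) {
        l <- config$loci[i]
        g <- reduce_resolution(
          as.matrix(parents[, paste0(l, c("_1", "_2"))]),
          config$n_fields)
        g <- matrix(g, ncol = 2)
        g <- g[g[, 1] != "." & g[, 2] != ".", , drop = FALSE]
        hwe_exact_test(g, replicates = config$replicates$hwe,
                       seed = stage_seed(config$seed, i), locus = l)
      })
      df <- data.frame(locus = config$loci,
                       n = vapply(res, `[[`, 0, "n"),
                       k = vapply(res, `[[`, 0, "k"),
                       p_value = vapply(res, `[[`, 0, "p_value"))
      utils::write.csv(df, file.path(out, "hwe.csv"), row.names = FALSE)
      res
    })
  }

  if ("ld" %in% config$stages && length(config$loci) >= 2) {
    results$ld <- run_stage("ld", {
      summ <- ld_summary_all(founders, config$loci, config$n_fields)
      utils::write.csv(summ, file.path(out, "ld_summary.csv"),
                       row.names = FALSE)
      for (s in attr(summ, "summaries")) {
        utils::write.csv(s$haplotypes,
                         file.path(out, sprintf("ld_pairs_%s_%s.csv",
                                                s$loci[1], s$loci[2])),
                         row.names = FALSE)
      }
      summ
    })
    results$haplotypes <- run_stage("haplotypes", {
      tab <- count_haplotype_frequencies(
        founders, intersect(haplotype_display_order(), config$loci),
        config$n_fields)
      write_frequency_table(tab, file.path(out, "haplotypes.csv"))
      tab
    })
  }

  if ("ewh" %in% config$stages) {
    results$ewh <- run_stage("ewh", {
      res <- lapply(seq_along(config$loci), function(i) {
        l <- config$loci[i]
        ewh_test(results$frequencies[[l]],
                 replicates = config$replicates$ewh,
                 seed = stage_seed(config$seed, 100 + i), locus = l)
      })
      df <- data.frame(locus = config$loci,
                       n = vapply(res, `[[`, 0, "n"),
                       k = vapply(res, `[[`, 0, "k"),
                       F_obs = vapply(res, `[[`, 0, "F_obs"),
                       F_exp = vapply(res, `[[`, 0, "F_exp"),
                       F_nd = vapply(res, `[[`, 0, "F_nd"),
                       p_value = vapply(res, `[[`, 0, "p_value"))
      utils::write.csv(df, file.path(out, "ewh.csv"), row.names = FALSE)
      res
    })
  }

  comparison <- intersect(config$stages, c("distances", "tree", "ca"))
  if (length(comparison) > 0) {
    if (is.null(config$reference_frequencies)) {
      message("comparison stages skipped: no reference populations supplied")
    } else {
      pops <- run_stage("reference input",
                        read_population_frequencies(config$reference_frequencies))
      self <- lapply(results$frequencies, function(t)
        t[, c("locus", "allele", "frequency", "two_n")])
      pops$Study <- do.call(rbind, self)
      if ("distances" %in% comparison) {
        results$sgd <- run_stage("distances", {
          d <- sgd_matrix(pops, config$loci)
          write_phylip_dist(d, file.path(out, "sgd_matrix.phy"))
          d
        })
      }
      if ("tree" %in% comparison) {
        results$tree <- run_stage("tree", {
          tr <- bootstrap_supports(pops, config$loci,
                                   replicates = config$replicates$bootstrap,
                                   seed = stage_seed(config$seed, 200))
          ape::write.tree(tr, file.path(out, "nj_tree.nwk"))
          tr
        })
      }
      if ("ca" %in% comparison) {
        results$ca <- run_stage("ca", {
          m <- ca_input_matrix(pops)
          ca <- correspondence_analysis(m, dims = min(3, min(dim(m)) - 1))
          write_ca_coords(ca, out)
          ca
        })
      }
    }
  }

  manifest <- list(
    package = "hlafam",
    version = as.character(utils::packageVersion("hlafam")),
    seed = config$seed,
    loci = config$loci,
    n_fields = config$n_fields,
    stages = config$stages,
    two_n = 4 * phased$report$n_unique,
    config_hash = config_hash(config))
  yaml::write_yaml(manifest, file.path(out, "manifest.yml"))
  results$manifest <- manifest
  invisible(results)
}

config_hash <- function(config) {
  # hash of the analysis-relevant settings; the output directory does
  # not influence results and is excluded
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg[sort(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}

write_ca_coords <- function(ca, out) {
  hdr <- paste0("# inertia shares: ",
                paste(sprintf("%.4f", ca$inertia_share), collapse = ", "))
  for (what in c("row", "col")) {
    coords <- ca[[paste0(what, "_coords")]]
    path <- file.path(out, paste0("ca_", what, "_coords.csv"))
    con <- file(path, "wb")
    writeLines(hdr, con, sep = "\n")
    writeLines(paste(c("label", colnames(coords)), collapse = ","),
               con, sep = "\n")
    for (i in seq_len(nrow(coords)))
      writeLines(paste(c(rownames(coords)[i],
                         sprintf("%.6f", coords[i, ])), collapse = ","),
                 con, sep = "\n")
    close(con)
  }
  invisible(NULL)
}
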