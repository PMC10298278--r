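#' Canonical HLA loci
#'
#' The five classical loci handled by the package, in canonical
#' chromosome-order-like ordering (class I A, C, B followed by class II
#' DRB1, DQB1). This is the order used for genotype file columns and
#' for phasing.
#'
#' @return Character vector of locus names.
#' @export
hla_loci <- function() c("A", "C", "B", "DRB1", "DQB1")

#' Display order for multi-locus haplotype strings
#'
#' Five-locus haplotypes are conventionally printed A~B~C~DRB1~DQB1;
#' any explicit locus subset passed to haplotype functions overrides this.
#'
#' @return Character vector of locus names.
#' @export
haplotype_display_order <- function() c("A", "B", "C", "DRB1", "DQB1")

#' Parse an HLA allele name
#'
#' Accepts names of the form \code{"A*26:01:01"} or \code{"DQB1*02"}:
#' a locus token, an asterisk, then 1--4 colon-separated numeric fields.
#' Field strings keep their leading zeros; a one-field name denotes an
#' allele lineage.
#'
#' @param text Allele name string.
#' @return An object of class \code{hla_allele} with elements
#'   \code{locus}, \code{fields} (character vector) and \code{raw}.
#' @examples
#' parse_allele_name("A*26:01:01")
#' parse_allele_name("DQB1*02")
#' @export
parse_allele_name <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("\\*", text))
    stop("malformed allele name (no '*'): ", sQuote(text))
  parts <- strsplit(text, "*", fixed = TRUE)[[1]]
  locus <- parts[1]
  if (!locus %in% hla_loci())
    stop("unknown locus token ", sQuote(locus), " in ", sQuote(text))
  rest <- if (length(parts) >= 2) parts[2] else ""
  if (identical(rest, "") || is.na(rest))
    stop("empty field list in ", sQuote(text))
  fields <- strsplit(rest, ":", fixed = TRUE)[[1]]
  bad <- fields[!grepl("^[0-9]+$", fields)]
  if (length(fields) == 0L || any(fields == "") || length(bad) > 0L)
    stop("non-numeric or empty field ", sQuote(bad[1]), " in ", sQuote(text))
  structure(list(locus = locus, fields = fields, raw = text),
            class = "hla_allele")
}

#' @export
format.hla_allele <- function(x, ...) {
  paste0(x$locus, "*", paste(x$fields, collapse = ":"))
}

#' @export
print.hla_allele <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.hla_allele <- function(x, ...) format(x)

#' Locus of one or more allele names
#'
#' @param x Character vector of allele names (or a single
#'   \code{hla_allele}).
#' @return Character vector of locus tokens.
#' @export
allele_locus <- function(x) {
  if (inherits(x, "hla_allele")) return(x$locus)
  sub("\\*.*$", "", x)
}

#' Truncate allele names to a given number of fields
#'
#' Reduces typing resolution by keeping only the first
#' \code{min(n_fields, available)} colon-separated fields, e.g.
#' \code{reduce_resolution("A*26:01:01", 1)} gives the lineage
#' \code{"A*26"}. Idempotent; names already at or below the requested
#' resolution are returned unchanged.
#'
#' @param a Character vector of allele names, or an \code{hla_allele}.
#' @param n_fields Number of fields to keep (>= 1).
#' @return Same type as \code{a}.
#' @export
reduce_resolution <- function(a, n_fields) {
  stopifnot(is.numeric(n_fields), length(n_fields) == 1L, n_fields >= 1)
  n_fields <- as.integer(n_fields)
  if (inherits(a, "hla_allele")) {
    keep <- seq_len(min(n_fields, length(a$fields)))
    return(structure(list(locus = a$locus, fields = a$fields[keep],
                          raw = a$raw), class = "hla_allele"))
  }
  vapply(a, function(s) {
    if (is.na(s) || s == ".") return(s)
    star <- regexpr("*", s, fixed = TRUE)
    fields <- strsplit(substring(s, star + 1L), ":", fixed = TRUE)[[1]]
    keep <- seq_len(min(n_fields, length(fields)))
    paste0(substring(s, 1L, star), paste(fields[keep], collapse = ":"))
  }, character(1), USE.NAMES = FALSE)
}

#' Join alleles into a haplotype string
#'
#' @param alleles Character vector of allele names, one per locus, in
#'   the desired locus order.
#' @return Single string with alleles joined by \code{"~"}.
#' @export
haplotype_string <- function(alleles) {
  loci <- allele_locus(alleles)
  if (anyDuplicated(loci))
    stop("repeated locus in haplotype: ", paste(loci, collapse = ", "))
  paste(alleles, collapse = "~")
}

#' Split a haplotype string into its allele names
#'
#' @param x Haplotype string, alleles joined by \code{"~"}.
#' @return Character vector of allele names.
#' @export
split_haplotype <- function(x) strsplit(x, "~", fixed = TRUE)[[1]]
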