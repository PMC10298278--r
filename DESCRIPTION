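Package: hlafam
Title: Family-Based HLA Population Genetics
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for population-genetic analysis of HLA genotype data from
    nuclear families. Parental haplotypes at HLA-A, -C, -B, -DRB1 and -DQB1
    are phased by segregation (pedigree) analysis, and allele and haplotype
    frequencies are estimated by direct counting over founder chromosomes.
    Implements Hardy-Weinberg exact testing by Monte Carlo permutation, the
    Ewens-Watterson homozygosity test of neutrality with an exact
    conditional-on-k null sampler, pairwise and multiallelic linkage
    disequilibrium (D', Wn) and conditional asymmetric LD, Nei standard
    genetic distances between populations, neighbor-joining dendrograms with
    parametric bootstrap supports, and correspondence analysis of
    population-by-allele frequency tables. Includes a family-cohort
    simulator with Mendelian transmission, recombination and missingness for
    end-to-end validation against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    tools,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS,
    phangorn,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
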