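Package: karyomapr
Title: Genome-Wide Karyomapping for Preimplantation Genetic Diagnosis
Version: 0.1.0
Authors@R:
    person("karyomapr", "developers", email = "karyomapr@example.org",
           role = c("aut", "cre"))
Description: Linkage-based haplotyping of single-cell embryo SNP genotypes
    against parental genotypes and a reference relative ("karyomapping").
    Classifies informative SNP loci, phases embryo calls into key and
    non-key evidence robust to allele dropout, segments chromosomes into
    parental haploblocks with a two-state hidden Markov model, calls
    crossovers and reference-origin ("common") crossovers, diagnoses
    single-gene-defect inheritance at configured disease loci, flags
    monosomy, meiotic trisomy and consanguineous (identical-by-descent)
    regions, and ships a family/meiosis/whole-genome-amplification
    simulator so the full pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
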