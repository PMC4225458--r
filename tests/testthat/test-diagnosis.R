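# Disease-locus phasing and inheritance-mode calling.

hbb <- disease_locus("HBB", "11", 5.2e6, 5.25e6, "autosomal_recessive")

mk_ev <- function(pos, supported, strength) {
  data.frame(position_bp = pos, supported = supported, strength = strength,
             stringsAsFactors = FALSE)
}
one_block <- function(hap = "H1", start = 3e6, end = 7.5e6) {
  data.frame(start_bp = start, end_bp = end, haplotype = hap,
             stringsAsFactors = FALSE)
}

test_that("majority haplotype is assigned despite two isolated opposing
           key calls near the gene", {
  ev <- mk_ev(c(4.0e6, 4.3e6, 4.6e6, 5.18e6, 5.19e6, 5.5e6, 6.0e6),
              c("H1", "H1", "H1", "H2", "H2", "H1", "H1"),
              rep("key", 7))
  ph <- phase_disease_locus(one_block("H1"), ev, hbb)
  expect_identical(ph$haplotype, "H1")
  expect_identical(ph$n_conflict_key, 2L)
})

test_that("a crossover in the flank truncates evidence; 1 key + 3 nonkey
           between crossover and gene suffice", {
  # crossover 5' of the gene; beyond it the evidence supports H2
  ev <- mk_ev(c(3.2e6, 3.3e6, 3.4e6, 4.2e6, 4.5e6, 4.8e6, 5.0e6),
              c("H2", "H2", "H2", "H1", "H1", "H1", "H1"),
              c("key", "key", "key", "key", "nonkey", "nonkey", "nonkey"))
  blocks <- data.frame(start_bp = c(3.2e6, 4.2e6),
                       end_bp = c(3.4e6, 5.0e6),
                       haplotype = c("H2", "H1"), stringsAsFactors = FALSE)
  xo <- data.frame(left_bp = 3.4e6, right_bp = 4.2e6)
  ph <- phase_disease_locus(blocks, ev, hbb, xo)
  expect_identical(ph$haplotype, "H1")
  expect_true(ph$crossover_in_flank)
  expect_identical(ph$n_key_5p + ph$n_nonkey_5p, 4L)

  # same layout but with zero key calls between crossover and gene:
  # 2 nonkey alone do not reach the threshold
  ev2 <- mk_ev(c(3.2e6, 3.3e6, 3.4e6, 4.5e6, 4.8e6),
               c("H2", "H2", "H2", "H1", "H1"),
               c("key", "key", "key", "nonkey", "nonkey"))
  ph2 <- phase_disease_locus(blocks, ev2, hbb, xo)
  expect_identical(ph2$haplotype, "undetermined")
  expect_identical(ph2$reason, "insufficient_evidence")
})

test_that("no evidence, crossover in gene, and no blocks all yield
           undetermined", {
  expect_identical(
    phase_disease_locus(one_block(), mk_ev(numeric(0), character(0),
                                           character(0)), hbb)$haplotype,
    "undetermined")
  xo_in_gene <- data.frame(left_bp = 5.21e6, right_bp = 5.23e6)
  ph <- phase_disease_locus(one_block(), mk_ev(4e6, "H1", "key"), hbb,
                            xo_in_gene)
  expect_identical(ph$reason, "crossover_in_gene")
  expect_identical(
    phase_disease_locus(one_block()[0, ], mk_ev(4e6, "H1", "key"),
                        hbb)$reason,
    "no_coverage")
})

test_that("autosomal recessive mapping follows the reference status", {
  phase_of <- function(pat, mat) {
    list(paternal = list(haplotype = pat, reason = NA),
         maternal = list(haplotype = mat, reason = NA))
  }
  # carrier sibling, paternal side: paternal mutant H1, maternal mutant H2
  cc_carrier <- case_config("f", "m", "r", "e1",
                            reference_disease_status = "carrier",
                            reference_carrier_side = "paternal",
                            disease_loci = list(hbb))
  expect_identical(
    call_disease_status(phase_of("H1", "H2"), hbb, cc_carrier)$status,
    "affected")           # blue/green
  expect_identical(
    call_disease_status(phase_of("H2", "H1"), hbb, cc_carrier)$status,
    "unaffected")         # red/orange
  expect_identical(
    call_disease_status(phase_of("H1", "H1"), hbb, cc_carrier)$status,
    "carrier_paternal")   # blue/orange

  # affected child reference: both H1 mutant
  cc_aff <- case_config("f", "m", "r", "e1",
                        reference_disease_status = "affected",
                        disease_loci = list(hbb))
  expect_identical(
    call_disease_status(phase_of("H1", "H2"), hbb, cc_aff)$status,
    "carrier_paternal")
  expect_identical(
    call_disease_status(phase_of("H1", "H1"), hbb, cc_aff)$status,
    "affected")
  expect_identical(
    call_disease_status(phase_of("undetermined", "H1"), hbb,
                        cc_aff)$status,
    "no_result")
})

test_that("X-linked recessive distinguishes embryo sex; dominant modes
           use exclusion labels with grandparent references", {
  xl <- disease_locus("DMD", "X", 31e6, 33e6, "x_linked_recessive")
  cc <- case_config("f", "m", "r", "e1",
                    reference_disease_status = "affected",
                    disease_loci = list(xl))
  ph <- list(paternal = list(haplotype = "undetermined", reason = NA),
             maternal = list(haplotype = "H1", reason = NA))
  expect_identical(call_disease_status(ph, xl, cc, "male")$status,
                   "affected")
  expect_identical(call_disease_status(ph, xl, cc, "female")$status,
                   "carrier_maternal")
  expect_identical(call_disease_status(ph, xl, cc, "unknown")$status,
                   "no_result")

  htt <- disease_locus("HTT", "4", 3.0e6, 3.2e6, "autosomal_dominant",
                       at_risk_parent = "paternal")
  cc_gp <- case_config("f", "m", "gp", "e1",
                       reference_relation = "paternal_grandparent",
                       reference_disease_status = "affected",
                       disease_loci = list(htt))
  ph_h1 <- list(paternal = list(haplotype = "H1", reason = NA),
                maternal = list(haplotype = "undetermined", reason = NA))
  ph_h2 <- list(paternal = list(haplotype = "H2", reason = NA),
                maternal = list(haplotype = "undetermined", reason = NA))
  expect_identical(call_disease_status(ph_h1, htt, cc_gp)$status,
                   "high_risk")
  expect_identical(call_disease_status(ph_h2, htt, cc_gp)$status,
                   "low_risk")
})

test_that("swapping parental labels together with the carrier side mirrors
           the diagnosis", {
  phase_of <- function(pat, mat) {
    list(paternal = list(haplotype = pat, reason = NA),
         maternal = list(haplotype = mat, reason = NA))
  }
  for (pat in c("H1", "H2")) for (mat in c("H1", "H2")) {
    cc_p <- case_config("f", "m", "r", "e1",
                        reference_disease_status = "carrier",
                        reference_carrier_side = "paternal",
                        disease_loci = list(hbb))
    cc_m <- case_config("f", "m", "r", "e1",
                        reference_disease_status = "carrier",
                        reference_carrier_side = "maternal",
                        disease_loci = list(hbb))
    a <- call_disease_status(phase_of(pat, mat), hbb, cc_p)$status
    b <- call_disease_status(phase_of(mat, pat), hbb, cc_m)$status
    mirror <- c(affected = "affected", unaffected = "unaffected",
                carrier_paternal = "carrier_maternal",
                carrier_maternal = "carrier_paternal")
    expect_identical(unname(mirror[a]), b)
  }
})

test_that("zero-noise simulations reproduce truth across modes", {
  specs <- list(
    list(mode = "autosomal_recessive", rel = "sibling", chrom = "7"),
    list(mode = "autosomal_dominant", rel = "paternal_grandparent",
         chrom = "4"),
    list(mode = "x_linked_recessive", rel = "sibling", chrom = "X"),
    list(mode = "x_linked_dominant", rel = "sibling", chrom = "X"),
    list(mode = "deletion_linked", rel = "sibling", chrom = "15"))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    dl <- disease_locus("GENE", sp$chrom, 1.5e7, 1.51e7, sp$mode,
                        at_risk_parent =
                          if (sp$mode %in% c("autosomal_dominant",
                                             "deletion_linked"))
                            "paternal" else NULL)
    cfg <- sim_config(
      chromosomes = data.frame(chromosome = sp$chrom, length_bp = 3e7),
      n_embryos = 4L, seed = 500 + i, p_ado = 0, p_error = 0,
      p_nocall = 0, p_nocall_gdna = 0,
      reference_relation = sp$rel, disease_loci = list(dl))
    v <- validate_case(cfg)
    expect_identical(v$per_embryo$truth, v$per_embryo$called,
                     info = sp$mode)
  }
})

test_that("nonkey-only evidence below threshold never yields a call", {
  for (n_nonkey in 0:2) {
    pos <- 4e6 + seq_len(max(n_nonkey, 1)) * 1e5
    ev <- mk_ev(pos[seq_len(n_nonkey)], rep("H1", n_nonkey),
                rep("nonkey", n_nonkey))
    ph <- phase_disease_locus(one_block("H1"), ev, hbb)
    expect_identical(ph$haplotype, "undetermined")
  }
})
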