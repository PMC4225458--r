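# Locus classification, unique-allele finding, reference linkage, and
# key/non-key phasing of embryo calls.

calls4 <- c("AA", "AB", "BB", "NC")

test_that("classification is exhaustive, mutually exclusive, and matches
           the defining cases", {
  grid <- expand.grid(father = calls4, mother = calls4,
                      stringsAsFactors = FALSE)
  cls <- classify_locus(grid$father, grid$mother, "1")
  expect_true(all(cls %in% c("paternal_informative", "maternal_informative",
                             "uninformative", "obligate_heterozygous",
                             "excluded")))
  expect_identical(classify_locus("AB", "AA", "1"), "paternal_informative")
  expect_identical(classify_locus("AB", "AB", "1"), "uninformative")
  expect_identical(classify_locus("AA", "BB", "1"), "obligate_heterozygous")
  expect_identical(classify_locus("NC", "AA", "1"), "excluded")
  # X: a heterozygous father call contradicts hemizygosity
  expect_identical(classify_locus("AB", "AA", "X"), "excluded")
  expect_identical(classify_locus("AA", "AB", "X"), "maternal_informative")
  expect_identical(classify_locus("AA", "AB", "Y"), "excluded")
})

test_that("unique allele is the heterozygous parent's allele missing from
           the homozygote", {
  expect_identical(find_unique_allele("AB", "AA"),
                   list(parent = "paternal", allele = "B"))
  expect_identical(find_unique_allele("AB", "BB"),
                   list(parent = "paternal", allele = "A"))
  expect_identical(find_unique_allele("BB", "AB"),
                   list(parent = "maternal", allele = "A"))
  expect_error(find_unique_allele("AB", "AB"), "non-informative")
})

test_that("sibling reference links presence to H1, absence to H2, flags
           impossible calls; grandparent reference needs homozygosity", {
  # father AB x mother AA, unique allele B (paternal)
  sib <- function(ref) assign_reference_linkage("AB", "AA", ref, "sibling")
  expect_identical(sib("AB")[c("usable", "linked_hap")],
                   list(usable = TRUE, linked_hap = "H1"))
  expect_identical(sib("AA")[c("usable", "linked_hap")],
                   list(usable = TRUE, linked_hap = "H2"))
  expect_false(sib("NC")$usable)
  bb <- sib("BB")   # impossible: mother has no B to give
  expect_false(bb$usable)
  expect_true(bb$ref_inconsistent)

  gp <- function(ref) assign_reference_linkage("AB", "AA", ref,
                                               "paternal_grandparent")
  expect_false(gp("AB")$usable)            # het grandparent: ambiguous
  expect_identical(gp("BB")$linked_hap, "H1")
  expect_identical(gp("AA")$linked_hap, "H2")
  # locus informative for the unrelated parent: unusable
  mg <- assign_reference_linkage("AA", "AB", "BB", "paternal_grandparent")
  expect_false(mg$usable)
})

test_that("embryo calls phase to key on presence, nonkey on absence,
           anomalous unique-homozygote stays key", {
  # unique allele B on H1
  expect_identical(phase_embryo_call("AB", "B", "H1"),
                   list(supported = "H1", strength = "key",
                        anomaly = FALSE))
  expect_identical(phase_embryo_call("AA", "B", "H1"),
                   list(supported = "H2", strength = "nonkey",
                        anomaly = FALSE))
  expect_identical(phase_embryo_call("BB", "B", "H1"),
                   list(supported = "H1", strength = "key",
                        anomaly = TRUE))
  expect_null(phase_embryo_call("NC", "B", "H1"))
})

test_that("ADO immunity: exhaustive enumeration over parents, truth and
           dropout never yields a wrong key call", {
  # informative parent het with unique allele u on haplotype L; other
  # parent homozygous for the other allele o. True embryo genotype is
  # (transmitted in {u, o}) + o. Dropout patterns on true heterozygotes:
  # keep both / drop first / drop second / drop both (NC).
  for (u in c("A", "B")) {
    o <- setdiff(c("A", "B"), u)
    for (L in c("H1", "H2")) {
      for (transmitted in c(u, o)) {
        true_hap <- if (transmitted == u) L else
          setdiff(c("H1", "H2"), L)
        true_geno <- paste(sort(c(transmitted, o)), collapse = "")
        observable <- if (true_geno == "AB") {
          c("AB", paste0(o, o), paste0(u, u)[0], "NC")  # drop u / drop o
        } else {
          true_geno  # dropout at homozygotes is invisible
        }
        if (true_geno == "AB") {
          observable <- c("AB", paste0(o, o), "NC")
        }
        for (obs in observable) {
          pc <- phase_embryo_call(obs, u, L)
          if (!is.null(pc) && pc$strength == "key") {
            expect_identical(pc$supported, true_hap)
          }
          # dropout can only push evidence toward the complement as nonkey
          if (!is.null(pc) && !identical(pc$supported, true_hap)) {
            expect_identical(pc$strength, "nonkey")
          }
        }
      }
    }
  }
})

test_that("phasing the sibling reference as if it were an embryo yields H1
           everywhere usable", {
  cfg <- small_ar_case(seed = 31, n_embryos = 1L, length_bp = 1e7,
                       p_ado = 0, p_error = 0, p_nocall = 0)
  sim <- simulate_family(cfg)
  g <- sim$genotypes
  # rebuild with the reference duplicated as an embryo
  calls <- cbind(g$calls, ref_as_embryo = g$calls[, "reference"])
  g2 <- karyomapr:::new_karyo_genotypes(sim$manifest, calls)
  cc <- sim$case_config
  cc$embryos <- "ref_as_embryo"
  cc$embryo_sex <- c(ref_as_embryo = "female")
  cc$disease_loci <- list()
  pt <- build_phase_table(g2, cc)
  expect_gt(nrow(pt$evidence), 100)
  expect_true(all(pt$evidence$supported == "H1"))
})

test_that("informative fraction matches Hardy-Weinberg at allele frequency
           0.5 and grandparent references halve usable loci", {
  cfg <- sim_config(chromosomes = data.frame(chromosome = "1",
                                             length_bp = 2e7),
                    freq_range = c(0.5, 0.5), n_embryos = 1L, seed = 41,
                    p_nocall_gdna = 0)
  sim <- simulate_family(cfg)
  pm <- build_phase_map(sim$genotypes, sim$case_config)
  n <- nrow(pm)
  # P(father AB) * P(mother hom) = 0.5 * 0.5
  frac_pat <- mean(pm$class == "paternal_informative")
  expect_lt(abs(frac_pat - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  # sibling: essentially all informative loci usable
  expect_gt(sum(pm$usable) / sum(pm$class %in%
    c("paternal_informative", "maternal_informative")), 0.98)

  cfg_gp <- sim_config(chromosomes = data.frame(chromosome = "1",
                                                length_bp = 2e7),
                       freq_range = c(0.5, 0.5), n_embryos = 1L, seed = 41,
                       p_nocall_gdna = 0,
                       reference_relation = "paternal_grandparent")
  sim_gp <- simulate_family(cfg_gp)
  pm_gp <- build_phase_map(sim_gp$genotypes, sim_gp$case_config)
  # only the paternal side is phasable
  expect_true(all(pm_gp$inf_parent[pm_gp$usable] == "paternal"))
  # grandparent homozygous at half its loci at p = 0.5
  n_pat <- sum(pm_gp$class == "paternal_informative")
  frac_usable <- sum(pm_gp$usable) / n_pat
  expect_lt(abs(frac_usable - 0.5), 3 * sqrt(0.25 / n_pat))
})

test_that("all-NC embryo produces empty evidence", {
  m <- tiny_manifest(20L)
  g <- make_genotypes(m, f = "AB", mo = "AA", r = "AB", e1 = "NC")
  cc <- case_config("f", "mo", "r", "e1")
  pt <- build_phase_table(g, cc)
  expect_identical(nrow(pt$evidence), 0L)
})
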