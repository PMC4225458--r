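# Synthetic-family generator: parental haplotypes, a sibling or grandparent
# reference, and single-cell embryo observations with recombination, allele
# dropout, miscalls, no-calls, aneuploidy and parental IBD -- with full
# ground-truth records so every pipeline stage can be validated.
#
# The stated world: a ~300K-SNP array with median inter-SNP spacing ~6 kb;
# MDA single-cell noise with call rates in the 75-95% range and elevated
# ADO. Defaults: per-allele ADO 0.15, no-call 0.10, miscall 0.005, uniform
# 1 cM/Mb map, per-locus B-allele frequency uniform on [0.1, 0.5].

#' Simulation configuration
#'
#' @param chromosomes data.frame with `chromosome` and `length_bp`.
#' @param median_spacing_bp median inter-SNP spacing (exponential
#'   spacing model), default 6000.
#' @param freq_range range the per-locus B-allele frequency is drawn
#'   uniformly from, default c(0.1, 0.5).
#' @param cM_per_Mb uniform genetic-map rate, default 1.
#' @param p_ado per-allele dropout probability for single-cell samples,
#'   default 0.15.
#' @param p_error miscall probability, default 0.005.
#' @param p_nocall no-call probability, default 0.10.
#' @param p_nocall_gdna no-call probability for genomic-DNA samples
#'   (parents, reference), default 0.01 (call rate > 98%).
#' @param n_embryos number of embryos, default 4.
#' @param reference_relation see [case_config()].
#' @param disease_loci list of [disease_locus()] entries; mutant
#'   haplotype indices are drawn per parent and recorded in the truth.
#' @param embryo_sexes optional character vector recycled over embryos
#'   (`male`/`female`); default alternating.
#' @param aneuploidy list of injections, each
#'   `list(embryo = i, chromosome = "1", type = ...)` with type one of
#'   `monosomy_paternal`, `monosomy_maternal`, `trisomy_paternal`,
#'   `trisomy_maternal`.
#' @param ibd optional `list(chromosome =, start_bp =, end_bp =)`
#'   segment copied from one paternal haplotype onto one maternal
#'   haplotype (parental identity by descent).
#' @param seed mandatory integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(chromosomes = data.frame(chromosome = "1",
                                                length_bp = 1e8),
                       median_spacing_bp = 6000,
                       freq_range = c(0.1, 0.5),
                       cM_per_Mb = 1.0,
                       p_ado = 0.15, p_error = 0.005, p_nocall = 0.10,
                       p_nocall_gdna = 0.01,
                       n_embryos = 4L,
                       reference_relation = "sibling",
                       disease_loci = list(),
                       embryo_sexes = NULL,
                       aneuploidy = list(),
                       ibd = NULL,
                       seed = 1L) {
  stopifnot(is.data.frame(chromosomes),
            all(c("chromosome", "length_bp") %in% names(chromosomes)),
            p_ado >= 0, p_ado < 1, p_error >= 0, p_error < 1,
            p_nocall >= 0, p_nocall < 1, !is.null(seed))
  chromosomes$chromosome <- sub("^chr", "",
                                as.character(chromosomes$chromosome))
  reference_relation <- match.arg(reference_relation, .RELATIONS)
  disease_loci <- lapply(disease_loci, function(dl) {
    if (inherits(dl, "disease_locus")) dl else do.call(disease_locus, dl)
  })
  if (is.null(embryo_sexes)) {
    embryo_sexes <- rep_len(c("female", "male"), n_embryos)
  } else {
    embryo_sexes <- rep_len(embryo_sexes, n_embryos)
  }
  structure(list(chromosomes = chromosomes,
                 median_spacing_bp = median_spacing_bp,
                 freq_range = freq_range, cM_per_Mb = cM_per_Mb,
                 p_ado = p_ado, p_error = p_error, p_nocall = p_nocall,
                 p_nocall_gdna = p_nocall_gdna,
                 n_embryos = as.integer(n_embryos),
                 reference_relation = reference_relation,
                 disease_loci = disease_loci,
                 embryo_sexes = embryo_sexes,
                 aneuploidy = aneuploidy, ibd = ibd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Exponentially spaced SNP positions with the configured median spacing.
sim_positions <- function(length_bp, median_spacing_bp) {
  rate <- log(2) / median_spacing_bp
  n_guess <- ceiling(length_bp * rate * 1.3) + 50L
  gaps <- stats::rexp(n_guess, rate)
  pos <- cumsum(gaps)
  while (sum(gaps) < length_bp) {
    more <- stats::rexp(n_guess, rate)
    gaps <- c(gaps, more)
    pos <- cumsum(gaps)
  }
  unique(pmax(1, round(pos[pos <= length_bp])))
}

#' Simulate the four parental haplotypes (and grandparents if needed)
#'
#' Haplotypes are independent Bernoulli draws of the B allele at each
#' locus from the per-locus frequency. For grandparent references the
#' related parent's first haplotype is itself produced by a simulated
#' grandparental meiosis, so the grandparent's genotype and the
#' grandparent-derived chromosome are both known. An optional IBD segment
#' copies part of one paternal haplotype onto one maternal haplotype.
#'
#' @param config a [sim_config()].
#' @return a `sim_family` skeleton: `manifest`, per-chromosome `chrom`
#'   entries (`positions`, `freq`, `father`/`mother` 2 x n haplotype
#'   matrices, optional `grandparent`), and metadata.
#' @export
simulate_parents <- function(config) {
  chroms <- list()
  ids <- list()
  rel_side <- reference_side(config$reference_relation)
  for (r in seq_len(nrow(config$chromosomes))) {
    ch <- config$chromosomes$chromosome[r]
    pos <- sim_positions(config$chromosomes$length_bp[r],
                         config$median_spacing_bp)
    n <- length(pos)
    freq <- stats::runif(n, config$freq_range[1], config$freq_range[2])
    draw <- function() stats::runif(n) < freq
    fa <- rbind(draw(), draw())
    mo <- rbind(draw(), draw())
    gp <- NULL
    if (!is.na(rel_side)) {
      # grandparental pair; the related parent's haplotype 1 is the
      # gamete of the reference grandparent
      gp <- rbind(draw(), draw())
      gam <- simulate_meiosis(gp, pos, config$chromosomes$length_bp[r],
                              config$cM_per_Mb)
      if (rel_side == "paternal") fa[1L, ] <- gam$alleles
      else mo[1L, ] <- gam$alleles
    }
    chroms[[ch]] <- list(chromosome = ch, length_bp =
                           config$chromosomes$length_bp[r],
                         positions = pos, freq = freq,
                         father = fa, mother = mo, grandparent = gp)
    ids[[ch]] <- sprintf("snp_%s_%06d", ch, seq_len(n))
  }
  # parental IBD: copy a paternal haplotype segment onto a maternal one
  if (!is.null(config$ibd)) {
    seg <- config$ibd
    cc <- chroms[[sub("^chr", "", as.character(seg$chromosome))]]
    sel <- cc$positions >= seg$start_bp & cc$positions <= seg$end_bp
    cc$mother[1L, sel] <- cc$father[1L, sel]
    cc$ibd_truth <- c(start_bp = min(cc$positions[sel]),
                      end_bp = max(cc$positions[sel]))
    chroms[[cc$chromosome]] <- cc
  }
  manifest <- snp_manifest(
    locus_id = unlist(ids, use.names = FALSE),
    chromosome = rep(names(chroms),
                     vapply(chroms, function(c) length(c$positions), 0L)),
    position_bp = unlist(lapply(chroms, `[[`, "positions"),
                         use.names = FALSE)
  )
  structure(list(manifest = manifest, chrom = chroms, config = config),
            class = "sim_family")
}

#' Simulate one meiosis of a chromosome
#'
#' Crossover count is Poisson with mean equal to the map length in
#' Morgans (no interference); positions are uniform on the (uniform-rate)
#' genetic map; the gamete alternates between the two parental haplotypes
#' at the crossovers, starting from a fair-coin haplotype.
#'
#' @param haps 2 x n logical haplotype matrix (TRUE = B allele).
#' @param positions_bp locus positions.
#' @param length_bp chromosome length.
#' @param cM_per_Mb uniform map rate.
#' @return list: `alleles` (logical gamete), `hap_at` (1/2 per locus),
#'   `crossovers_bp` (sorted), `start_hap`.
#' @export
simulate_meiosis <- function(haps, positions_bp, length_bp,
                             cM_per_Mb = 1.0) {
  morgans <- length_bp * cM_per_Mb * 1e-8
  n_xo <- stats::rpois(1L, morgans)
  xo <- sort(stats::runif(n_xo, 0, length_bp))
  start <- sample(1:2, 1L)
  hap_at <- if (n_xo == 0L) rep(start, length(positions_bp)) else {
    seg <- findInterval(positions_bp, xo)
    ifelse(seg %% 2L == 0L, start, 3L - start)
  }
  alleles <- haps[cbind(hap_at, seq_along(positions_bp))]
  list(alleles = alleles, hap_at = hap_at, crossovers_bp = xo,
       start_hap = start)
}

# Genotype strings from two allele vectors (TRUE = B).
geno_from_alleles <- function(a1, a2) {
  c("AA", "AB", "BB")[a1 + a2 + 1L]
}

#' Apply single-cell whole-genome-amplification noise to true genotypes
#'
#' Per locus: with `p_nocall` the call is NC; otherwise each allele of a
#' heterozygote drops independently with `p_ado` (both dropping gives NC,
#' one gives an apparent homozygote; dropout at homozygotes is
#' invisible); finally with `p_error` the call is replaced by a uniformly
#' chosen different call.
#'
#' @param true_calls canonical true genotype vector.
#' @param p_ado,p_error,p_nocall noise probabilities.
#' @return observed canonical call vector.
#' @export
simulate_embryo_observation <- function(true_calls, p_ado = 0.15,
                                        p_error = 0.005, p_nocall = 0.10) {
  n <- length(true_calls)
  obs <- true_calls
  het <- which(obs == "AB")
  if (length(het) && p_ado > 0) {
    dropA <- stats::runif(length(het)) < p_ado
    dropB <- stats::runif(length(het)) < p_ado
    obs[het[dropA & dropB]] <- "NC"
    obs[het[dropA & !dropB]] <- "BB"
    obs[het[!dropA & dropB]] <- "AA"
  }
  if (p_error > 0) {
    err <- which(stats::runif(n) < p_error & obs != "NC")
    if (length(err)) {
      obs[err] <- vapply(obs[err], function(g) {
        sample(setdiff(c("AA", "AB", "BB"), g), 1L)
      }, character(1))
    }
  }
  nc <- stats::runif(n) < p_nocall
  obs[nc] <- "NC"
  obs
}

#' Simulate a complete family: reference, embryos, noise and truth
#'
#' Builds on [simulate_parents()]: adds the reference (an extra sibling
#' meiosis pair, or the grandparent simulated there), per-embryo meioses
#' with Poisson crossovers, aneuploidy injections, observation noise, and
#' a full truth record including each embryo's true disease status per
#' configured locus. Mutant haplotype indices are drawn per parent; the
#' emitted case configuration's reference disease status is derived from
#' the haplotypes the reference actually inherited at the gene.
#'
#' @param config a [sim_config()].
#' @return a `sim_case` list: `manifest`, `genotypes`
#'   (`karyo_genotypes`), `case_config` (`karyo_case_config`), `truth`.
#' @export
simulate_family <- function(config) {
  set.seed(config$seed)
  fam <- simulate_parents(config)
  m <- fam$manifest
  rel_side <- reference_side(config$reference_relation)
  n_total <- nrow(m)
  chrom_of <- m$chromosome

  # mutant haplotype indices per disease locus (parental truth)
  dl_truth <- lapply(config$disease_loci, function(dl) {
    list(gene = dl$gene_name, mode = dl$mode,
         father_mut = sample(1:2, 1L), mother_mut = sample(1:2, 1L))
  })

  hap_at_gene <- function(hap_at, cc, dl) {
    # transmitted haplotype across the gene; NA if recombinant inside
    sel <- cc$positions >= dl$start_bp & cc$positions <= dl$end_bp
    if (!any(sel)) {
      sel <- which.min(abs(cc$positions - (dl$start_bp + dl$end_bp) / 2))
    }
    h <- unique(hap_at[sel])
    if (length(h) == 1L) h else NA_integer_
  }

  # --- reference ---------------------------------------------------------
  ref_truth <- list()
  ref_calls <- character(n_total)
  ref_sex <- "female"
  if (any(vapply(config$disease_loci, function(d)
    d$mode == "x_linked_recessive", TRUE))) ref_sex <- "male"
  for (ch in names(fam$chrom)) {
    cc <- fam$chrom[[ch]]
    i <- which(chrom_of == ch)
    if (is.na(rel_side)) {
      is_x <- ch == "X"
      pat <- if (is_x && ref_sex == "male") NULL
             else if (is_x) list(alleles = cc$father[1L, ],
                                 hap_at = rep(1L, length(i)),
                                 crossovers_bp = numeric(0))
             else simulate_meiosis(cc$father, cc$positions, cc$length_bp,
                                   config$cM_per_Mb)
      mat <- simulate_meiosis(cc$mother, cc$positions, cc$length_bp,
                              config$cM_per_Mb)
      g <- if (is.null(pat)) geno_from_alleles(mat$alleles, mat$alleles)
           else geno_from_alleles(pat$alleles, mat$alleles)
      ref_truth[[ch]] <- list(paternal = pat, maternal = mat)
      ref_calls[i] <- g
    } else {
      # the reference IS the grandparent simulated in simulate_parents
      gp <- fam$chrom[[ch]]$grandparent
      ref_calls[i] <- geno_from_alleles(gp[1L, ], gp[2L, ])
      ref_truth[[ch]] <- list(grandparent = TRUE)
    }
  }
  ref_calls <- simulate_embryo_observation(ref_calls, p_ado = 0,
                                           p_error = 0,
                                           p_nocall = config$p_nocall_gdna)

  # reference disease status derived from what it actually inherited
  ref_status <- "affected"; carrier_side <- NULL
  if (length(config$disease_loci)) {
    dl <- config$disease_loci[[1L]]
    tr <- dl_truth[[1L]]
    cc <- fam$chrom[[dl$chromosome]]
    if (is.na(rel_side)) {
      rt <- ref_truth[[dl$chromosome]]
      pat_h <- if (is.null(rt$paternal)) NA_integer_
               else hap_at_gene(rt$paternal$hap_at, cc, dl)
      mat_h <- hap_at_gene(rt$maternal$hap_at, cc, dl)
      if (dl$mode == "autosomal_recessive") {
        pat_c <- isTRUE(pat_h == tr$father_mut)
        mat_c <- isTRUE(mat_h == tr$mother_mut)
        if (pat_c && mat_c) ref_status <- "affected"
        else if (!pat_c && !mat_c) ref_status <- "unaffected"
        else {
          ref_status <- "carrier"
          carrier_side <- if (pat_c) "paternal" else "maternal"
        }
      } else if (dl$mode %in% c("x_linked_recessive", "x_linked_dominant")) {
        has <- isTRUE(mat_h == tr$mother_mut)
        ref_status <- if (dl$mode == "x_linked_recessive") {
          # male reference (affected son or unaffected son)
          if (has) "affected" else "unaffected"
        } else {
          if (has) "affected" else "unaffected"
        }
      } else {
        side_mut <- if (dl$at_risk_parent == "paternal") tr$father_mut
                    else tr$mother_mut
        h <- if (dl$at_risk_parent == "paternal") pat_h else mat_h
        ref_status <- if (isTRUE(h == side_mut)) "affected" else "unaffected"
      }
    } else {
      # exclusion testing: the grandparent's own status is configured
      # affected; risk travels on the grandparent-derived chromosome
      # (the related parent's haplotype 1 by construction)
      ref_status <- "affected"
      if (dl$at_risk_parent == "paternal") tr$father_mut <- 1L
      else tr$mother_mut <- 1L
      dl_truth[[1L]] <- tr
    }
  }

  # --- embryos ------------------------------------------------------------
  embryo_ids <- sprintf("embryo_%02d", seq_len(config$n_embryos))
  sexes <- stats::setNames(config$embryo_sexes, embryo_ids)
  calls <- matrix("NC", n_total, config$n_embryos + 3L)
  colnames(calls) <- c("father", "mother", "reference", embryo_ids)
  emb_truth <- list()
  for (k in seq_len(config$n_embryos)) {
    emb <- embryo_ids[k]
    sex <- sexes[[emb]]
    true_g <- character(n_total)
    tr_ch <- list()
    for (ch in names(fam$chrom)) {
      cc <- fam$chrom[[ch]]
      i <- which(chrom_of == ch)
      is_x <- ch == "X"
      pat <- if (is_x && sex == "male") NULL
             else if (is_x) list(alleles = cc$father[1L, ],
                                 hap_at = rep(1L, length(i)),
                                 crossovers_bp = numeric(0))
             else simulate_meiosis(cc$father, cc$positions, cc$length_bp,
                                   config$cM_per_Mb)
      mat <- simulate_meiosis(cc$mother, cc$positions, cc$length_bp,
                              config$cM_per_Mb)
      an <- Filter(function(a) a$embryo == k &&
                     sub("^chr", "", a$chromosome) == ch,
                   config$aneuploidy)
      atype <- if (length(an)) an[[1L]]$type else "none"
      extra <- NULL
      if (atype == "monosomy_paternal") pat <- NULL
      if (atype == "monosomy_maternal") mat <- NULL
      if (atype %in% c("trisomy_paternal", "trisomy_maternal")) {
        src <- if (atype == "trisomy_paternal") cc$father else cc$mother
        extra <- simulate_meiosis(src, cc$positions, cc$length_bp,
                                  config$cM_per_Mb)
        prime <- if (atype == "trisomy_paternal") pat else mat
        mid <- which.min(abs(cc$positions - cc$length_bp / 2))
        if (extra$hap_at[mid] == prime$hap_at[mid]) {
          # meiosis-I style: the two chromatids come from different
          # homologs around the centromere
          extra$hap_at <- 3L - extra$hap_at
          extra$alleles <- src[cbind(extra$hap_at,
                                     seq_along(cc$positions))]
        }
      }
      present <- list(pat, mat, extra)
      present <- present[!vapply(present, is.null, TRUE)]
      hasA <- Reduce(`|`, lapply(present, function(g) !g$alleles))
      hasB <- Reduce(`|`, lapply(present, function(g) g$alleles))
      true_g[i] <- ifelse(hasA & hasB, "AB", ifelse(hasB, "BB", "AA"))
      tr_ch[[ch]] <- list(
        paternal_hap = if (is.null(pat)) NULL else pat$hap_at,
        maternal_hap = if (is.null(mat)) NULL else mat$hap_at,
        paternal_xo = if (is.null(pat)) NULL else pat$crossovers_bp,
        maternal_xo = if (is.null(mat)) NULL else mat$crossovers_bp,
        aneuploidy = atype
      )
    }
    calls[, emb] <- simulate_embryo_observation(
      true_g, config$p_ado, config$p_error, config$p_nocall)
    # true disease status per configured locus
    statuses <- lapply(seq_along(config$disease_loci), function(j) {
      dl <- config$disease_loci[[j]]
      tr <- dl_truth[[j]]
      cc <- fam$chrom[[dl$chromosome]]
      tc <- tr_ch[[dl$chromosome]]
      ph <- if (is.null(tc$paternal_hap)) NA_integer_
            else hap_at_gene(tc$paternal_hap, cc, dl)
      mh <- if (is.null(tc$maternal_hap)) NA_integer_
            else hap_at_gene(tc$maternal_hap, cc, dl)
      true_status(dl, tr, ph, mh, sex,
                  exclusion = !is.na(rel_side))
    })
    names(statuses) <- vapply(config$disease_loci, `[[`, "", "gene_name")
    emb_truth[[emb]] <- list(chrom = tr_ch, sex = sex,
                             disease_status = statuses,
                             true_calls = true_g)
  }

  # --- parents observed at genomic-DNA quality ---------------------------
  for (ch in names(fam$chrom)) {
    cc <- fam$chrom[[ch]]
    i <- which(chrom_of == ch)
    fa_g <- if (ch == "X") geno_from_alleles(cc$father[1L, ],
                                             cc$father[1L, ])
            else geno_from_alleles(cc$father[1L, ], cc$father[2L, ])
    mo_g <- geno_from_alleles(cc$mother[1L, ], cc$mother[2L, ])
    calls[i, "father"] <- fa_g
    calls[i, "mother"] <- mo_g
  }
  calls[, "father"] <- simulate_embryo_observation(
    calls[, "father"], 0, 0, config$p_nocall_gdna)
  calls[, "mother"] <- simulate_embryo_observation(
    calls[, "mother"], 0, 0, config$p_nocall_gdna)
  calls[, "reference"] <- ref_calls

  genotypes <- new_karyo_genotypes(m, calls)
  cfg <- case_config(
    father = "father", mother = "mother", reference = "reference",
    embryos = embryo_ids,
    reference_relation = config$reference_relation,
    reference_disease_status = ref_status,
    reference_carrier_side = carrier_side,
    disease_loci = config$disease_loci,
    embryo_sex = sexes
  )
  truth <- list(
    seed = config$seed,
    disease = dl_truth,
    reference = list(sex = ref_sex, status = ref_status,
                     carrier_side = carrier_side,
                     meioses = if (is.na(rel_side)) lapply(
                       ref_truth, function(r) list(
                         paternal_xo = if (is.null(r$paternal)) NULL
                                       else r$paternal$crossovers_bp,
                         maternal_xo = if (is.null(r$maternal)) NULL
                                       else r$maternal$crossovers_bp,
                         paternal_hap = if (is.null(r$paternal)) NULL
                                        else r$paternal$hap_at,
                         maternal_hap = if (is.null(r$maternal)) NULL
                                        else r$maternal$hap_at))
                     else NULL),
    embryos = emb_truth,
    ibd = lapply(fam$chrom, function(cc) cc$ibd_truth)
  )
  structure(list(manifest = m, genotypes = genotypes, case_config = cfg,
                 truth = truth, family = fam),
            class = "sim_case")
}

# Truth disease status under the same vocabulary the pipeline emits.
true_status <- function(dl, tr, pat_hap, mat_hap, sex, exclusion) {
  if (dl$mode == "autosomal_recessive") {
    if (is.na(pat_hap) || is.na(mat_hap)) return("no_result")
    pat <- pat_hap == tr$father_mut
    mat <- mat_hap == tr$mother_mut
    if (pat && mat) "affected"
    else if (pat) "carrier_paternal"
    else if (mat) "carrier_maternal"
    else "unaffected"
  } else if (dl$mode == "x_linked_recessive") {
    if (is.na(mat_hap)) return("no_result")
    has <- mat_hap == tr$mother_mut
    if (!has) {
      if (exclusion) "low_risk" else "unaffected"
    } else if (sex == "male") {
      if (exclusion) "high_risk" else "affected"
    } else "carrier_maternal"
  } else {
    h <- if (dl$at_risk_parent == "paternal") pat_hap else mat_hap
    mut <- if (dl$at_risk_parent == "paternal") tr$father_mut
           else tr$mother_mut
    if (is.na(h)) return("no_result")
    has <- h == mut
    if (exclusion) {
      if (has) "high_risk" else "low_risk"
    } else {
      if (has) "affected" else "unaffected"
    }
  }
}

#' Write a simulated case to disk
#'
#' Emits everything [run_case()] needs -- `manifest.tsv`,
#' `genotypes.tsv`, `case.json` -- plus `truth.json`. Deterministic
#' given the configuration seed.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return the `sim_case`, invisibly.
#' @export
simulate_case <- function(config, out_dir) {
  sim <- simulate_family(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_snp_manifest(sim$manifest, file.path(out_dir, "manifest.tsv"))
  write_genotype_table(sim$genotypes, file.path(out_dir, "genotypes.tsv"))
  write_case_config(sim$case_config, file.path(out_dir, "case.json"))
  truth <- sim$truth
  if (!is.null(truth$reference$meioses)) {
    truth$reference$meioses <- lapply(truth$reference$meioses, function(r) {
      r$paternal_hap <- NULL; r$maternal_hap <- NULL; r
    })
  }
  truth$embryos <- lapply(truth$embryos, function(e) {
    e$true_calls <- NULL  # bulky; regenerable from the seed
    e$chrom <- lapply(e$chrom, function(tc) {
      tc$paternal_hap <- NULL; tc$maternal_hap <- NULL; tc
    })
    e
  })
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(sim)
}
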