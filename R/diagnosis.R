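# Disease-locus phasing and inheritance calling.
#
# The disease locus is phased by linkage: the parental haplotype assigned
# to the haploblock overlapping the gene (or, failing direct overlap, the
# nearest flanking block) is combined with the mutant-haplotype mapping
# implied by the reference's disease status and the inheritance mode.
# Karyomapping is an indirect linkage method: no mutation is detected.

#' Phase a disease locus for one embryo and one parent
#'
#' Evidence is counted inside the gene and its two flanks (default 2 Mb
#' each). When a crossover falls inside a flank only evidence between the
#' crossover and the gene contributes; a crossover overlapping the gene
#' interval itself makes the locus undetermined (linkage cannot resolve a
#' recombination between mutation and markers). Assignment requires at
#' least 2 supporting key calls, or 1 key plus 3 non-key, inside the
#' (truncated) window. Conflicting key calls are tolerated while they
#' look like isolated miscalls: no run of more than `max_conflict_keys`
#' consecutive conflicting keys (a contiguous conflicting stretch would
#' mean a double recombination between its flanking keys, probability
#' ~1e-5 at observed key spacing), and fewer conflicting than supporting
#' keys overall.
#'
#' @param blocks haploblocks for this embryo/parent on the disease
#'   chromosome ([segment_haploblocks()] output).
#' @param evidence phased calls for this embryo/parent/chromosome
#'   (`position_bp`, `supported`, `strength`).
#' @param locus a [disease_locus()].
#' @param crossovers crossover events for the same track (`left_bp`,
#'   `right_bp`), possibly with `is_common`.
#' @param min_key,min_key_alt,min_nonkey_alt,max_conflict_keys evidence
#'   thresholds (defaults: 2 key, or 1 key + 3 non-key; conflicting-key
#'   runs longer than 2 disqualify).
#' @return list: `haplotype` (`H1`/`H2`/`undetermined`), `reason`, and
#'   counts `n_key_gene`/`n_key_5p`/`n_key_3p` (same for nonkey),
#'   `n_conflict_key`, `crossover_in_flank`.
#' @export
phase_disease_locus <- function(blocks, evidence, locus, crossovers = NULL,
                                min_key = 2L, min_key_alt = 1L,
                                min_nonkey_alt = 3L,
                                max_conflict_keys = 2L) {
  g1 <- locus$start_bp; g2 <- locus$end_bp; fl <- locus$flank_bp
  w1 <- g1 - fl; w2 <- g2 + fl
  out <- list(haplotype = "undetermined", reason = NA_character_,
              n_key_gene = 0L, n_nonkey_gene = 0L,
              n_key_5p = 0L, n_nonkey_5p = 0L,
              n_key_3p = 0L, n_nonkey_3p = 0L,
              n_conflict_key = 0L, crossover_in_flank = FALSE)
  if (is.null(blocks) || nrow(blocks) == 0L) {
    out$reason <- "no_coverage"
    return(out)
  }
  if (!is.null(crossovers) && nrow(crossovers) > 0L) {
    xo <- crossovers
    # crossover interval touching the gene: unresolvable by linkage
    if (any(xo$left_bp < g2 & xo$right_bp > g1)) {
      out$reason <- "crossover_in_gene"
      return(out)
    }
    left_xo <- xo$right_bp[xo$right_bp <= g1]
    right_xo <- xo$left_bp[xo$left_bp >= g2]
    if (length(left_xo) && max(left_xo) > w1) {
      w1 <- max(left_xo); out$crossover_in_flank <- TRUE
    }
    if (length(right_xo) && min(right_xo) < w2) {
      w2 <- min(right_xo); out$crossover_in_flank <- TRUE
    }
  }
  # haplotype of the block overlapping the gene; else nearest block(s)
  # inside the truncated window
  ov <- blocks$start_bp <= g2 & blocks$end_bp >= g1
  if (any(ov)) {
    haps <- unique(blocks$haplotype[ov])
    if (length(haps) > 1L) {
      out$reason <- "crossover_in_gene"
      return(out)
    }
    hap <- haps
  } else {
    left <- blocks[blocks$end_bp < g1 & blocks$end_bp >= w1, , drop = FALSE]
    right <- blocks[blocks$start_bp > g2 & blocks$start_bp <= w2, ,
                    drop = FALSE]
    hl <- if (nrow(left)) left$haplotype[which.max(left$end_bp)] else NULL
    hr <- if (nrow(right)) right$haplotype[which.min(right$start_bp)] else NULL
    cand <- unique(c(hl, hr))
    if (length(cand) == 0L) {
      out$reason <- "no_informative_coverage"
      return(out)
    }
    if (length(cand) > 1L) {
      out$reason <- "crossover_in_gene"
      return(out)
    }
    hap <- cand
  }
  ev <- evidence[evidence$position_bp >= w1 & evidence$position_bp <= w2, ,
                 drop = FALSE]
  region <- ifelse(ev$position_bp < g1, "5p",
            ifelse(ev$position_bp > g2, "3p", "gene"))
  supp <- ev$supported == hap
  cnt <- function(reg, str, s) {
    sum(region == reg & ev$strength == str & supp == s)
  }
  out$n_key_gene <- cnt("gene", "key", TRUE)
  out$n_nonkey_gene <- cnt("gene", "nonkey", TRUE)
  out$n_key_5p <- cnt("5p", "key", TRUE)
  out$n_nonkey_5p <- cnt("5p", "nonkey", TRUE)
  out$n_key_3p <- cnt("3p", "key", TRUE)
  out$n_nonkey_3p <- cnt("3p", "nonkey", TRUE)
  out$n_conflict_key <- sum(ev$strength == "key" & !supp)
  n_key <- out$n_key_gene + out$n_key_5p + out$n_key_3p
  n_nonkey <- out$n_nonkey_gene + out$n_nonkey_5p + out$n_nonkey_3p
  enough <- n_key >= min_key ||
    (n_key >= min_key_alt && n_nonkey >= min_nonkey_alt)
  # conflicts must look like isolated miscalls, never a contiguous
  # stretch (that would be a double recombination, not noise)
  key_seq <- supp[ev$strength == "key"]
  max_run <- if (any(!key_seq)) {
    r <- rle(key_seq); max(r$lengths[!r$values])
  } else 0L
  clean <- max_run <= max_conflict_keys && out$n_conflict_key < n_key
  if (enough && clean) {
    out$haplotype <- hap
  } else {
    out$reason <- if (!enough) "insufficient_evidence" else "key_conflict"
  }
  out
}

# Mutant-haplotype mapping implied by the reference's status.
# Returns list(paternal=, maternal=) over {"H1","H2",NA}.
mutant_haplotypes <- function(locus, config) {
  mode <- locus$mode
  status <- config$reference_disease_status
  side <- reference_side(config$reference_relation)
  if (mode == "autosomal_recessive") {
    # sibling reference enforced at config validation
    switch(status,
      affected = list(paternal = "H1", maternal = "H1"),
      carrier = if (config$reference_carrier_side == "paternal") {
        list(paternal = "H1", maternal = "H2")
      } else {
        list(paternal = "H2", maternal = "H1")
      },
      unaffected = list(paternal = "H2", maternal = "H2"))
  } else if (mode == "x_linked_recessive" || mode == "x_linked_dominant") {
    mut <- if (status == "affected" || status == "carrier") "H1" else "H2"
    list(paternal = NA_character_, maternal = mut)
  } else {
    # autosomal_dominant / deletion_linked: risk travels on one configured
    # parental side; affected reference tags H1, unaffected tags H2
    mut <- if (status == "affected") "H1" else "H2"
    if (locus$at_risk_parent == "paternal") {
      list(paternal = mut, maternal = NA_character_)
    } else {
      list(paternal = NA_character_, maternal = mut)
    }
  }
}

#' Call disease status from phased-locus evidence
#'
#' Combines the per-parent haplotype assignments with the mutant-haplotype
#' mapping implied by the reference's disease status:
#' \itemize{
#' \item autosomal recessive: both sides mutant gives `affected`, one
#'   side `carrier_paternal`/`carrier_maternal`, none `unaffected`.
#' \item autosomal dominant / deletion-linked: carrying the at-risk
#'   parent's mutant haplotype gives `affected` with a sibling reference;
#'   with a grandparent/relative reference the call is exclusion-style
#'   `high_risk`/`low_risk` (the at-risk parent's own status is never
#'   asserted).
#' \item X-linked recessive: male embryos carrying the mutant maternal X
#'   are `affected` (`high_risk` for grandparent references), females
#'   `carrier_maternal`; X-linked dominant affects both sexes.
#' }
#' Any required-but-undetermined parental haplotype, or unknown embryo sex
#' in an X-linked mode, yields `no_result`.
#'
#' @param phase list with per-parent [phase_disease_locus()] results
#'   (`paternal`, `maternal`).
#' @param locus a [disease_locus()].
#' @param config a `karyo_case_config`.
#' @param embryo_sex `male`/`female`/`unknown` (X-linked modes only).
#' @return list with `status` and `reason`.
#' @export
call_disease_status <- function(phase, locus, config,
                                embryo_sex = "unknown") {
  mut <- mutant_haplotypes(locus, config)
  exclusion <- config$reference_relation != "sibling"
  need <- switch(locus$mode,
                 autosomal_recessive = c("paternal", "maternal"),
                 x_linked_recessive = "maternal",
                 x_linked_dominant = "maternal",
                 locus$at_risk_parent)
  hap <- lapply(phase, `[[`, "haplotype")
  for (p in need) {
    if (is.null(hap[[p]]) || hap[[p]] == "undetermined") {
      return(list(status = "no_result",
                  reason = phase[[p]]$reason %||% "undetermined"))
    }
  }
  carries <- function(p) identical(hap[[p]], mut[[p]])
  if (locus$mode == "autosomal_recessive") {
    pat <- carries("paternal"); mat <- carries("maternal")
    status <- if (pat && mat) "affected"
              else if (pat) "carrier_paternal"
              else if (mat) "carrier_maternal"
              else "unaffected"
    return(list(status = status, reason = NA_character_))
  }
  if (locus$mode == "x_linked_recessive") {
    if (!embryo_sex %in% c("male", "female")) {
      return(list(status = "no_result", reason = "unknown_embryo_sex"))
    }
    has_mut <- carries("maternal")
    status <- if (!has_mut) {
      if (exclusion) "low_risk" else "unaffected"
    } else if (embryo_sex == "male") {
      if (exclusion) "high_risk" else "affected"
    } else {
      "carrier_maternal"
    }
    return(list(status = status, reason = NA_character_))
  }
  # dominant-type: autosomal_dominant, x_linked_dominant, deletion_linked
  has_mut <- carries(need)
  status <- if (exclusion) {
    if (has_mut) "high_risk" else "low_risk"
  } else {
    if (has_mut) "affected" else "unaffected"
  }
  list(status = status, reason = NA_character_)
}

#' Diagnose every embryo of a case at every configured disease locus
#'
#' @param result intermediate case results as assembled by [run_case()]:
#'   needs `blocks`, `crossovers`, `evidence`, `qc`, `chrom_status`,
#'   `embryo_sex`.
#' @param config a `karyo_case_config`.
#' @return list of per-embryo diagnosis records (`embryo`, `status`,
#'   per-locus evidence, `notes`); QC-excluded embryos are `no_result`
#'   with reason `low_call_rate`, and monosomy/trisomy of a disease
#'   chromosome voids that locus with an aneuploidy note.
#' @export
diagnose_case <- function(result, config) {
  lapply(config$embryos, function(emb) {
    qc <- result$qc[result$qc$sample_id == emb, ]
    if (nrow(qc) && qc$excluded) {
      return(list(embryo = emb, status = "no_result",
                  reason = "low_call_rate", loci = list(), notes = character()))
    }
    loci <- list()
    notes <- character()
    overall <- NA_character_
    for (dl in config$disease_loci) {
      cs <- result$chrom_status
      an <- cs[cs$embryo == emb & cs$chromosome == dl$chromosome, ,
               drop = FALSE]
      aneuploid <- nrow(an) > 0L && !an$status %in% c("disomy", "unknown")
      phase <- list()
      for (p in c("paternal", "maternal")) {
        bl <- result$blocks[result$blocks$embryo == emb &
                              result$blocks$parent == p &
                              result$blocks$chromosome == dl$chromosome, ,
                            drop = FALSE]
        ev <- result$evidence[result$evidence$embryo == emb &
                                result$evidence$parent == p &
                                result$evidence$chromosome == dl$chromosome, ,
                              drop = FALSE]
        # common (reference-origin) crossovers flip the H1/H2 label
        # convention just like real ones, so they truncate flanks too
        xo <- result$crossovers[result$crossovers$embryo == emb &
                                  result$crossovers$parent == p &
                                  result$crossovers$chromosome ==
                                    dl$chromosome, , drop = FALSE]
        phase[[p]] <- phase_disease_locus(bl, ev, dl, xo)
      }
      call <- if (aneuploid) {
        notes <- c(notes, sprintf("aneuploidy at %s: %s", dl$gene_name,
                                  an$status))
        list(status = "no_result", reason = paste0("aneuploidy_",
                                                   an$status))
      } else {
        call_disease_status(phase, dl, config,
                            result$embryo_sex[[emb]] %||% "unknown")
      }
      ibd_ov <- FALSE
      if (!is.null(result$ibd_regions) && nrow(result$ibd_regions)) {
        ir <- result$ibd_regions
        ibd_ov <- any(ir$chromosome == dl$chromosome &
                        ir$start_bp <= dl$end_bp + dl$flank_bp &
                        ir$end_bp >= dl$start_bp - dl$flank_bp)
        if (ibd_ov) {
          notes <- c(notes, sprintf(
            "consanguinity: IBD region overlaps %s +/- flank", dl$gene_name))
        }
      }
      loci[[dl$gene_name]] <- list(
        gene = dl$gene_name, mode = dl$mode, status = call$status,
        reason = call$reason, phase = phase, consanguinity_warning = ibd_ov
      )
      if (is.na(overall)) overall <- call$status
    }
    list(embryo = emb,
         status = if (length(loci)) overall else "karyomap_only",
         reason = NA_character_, loci = loci, notes = notes)
  })
}
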