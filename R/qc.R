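# Sample-level QC and chromosome-level abnormality detection.
#
# Monosomy: only one parental haplotype is detectable -- the missing
# parent's unique alleles essentially never appear (no key calls for
# either haplotype) and that parent's allele looks "dropped" at nearly all
# obligate-heterozygous loci. Meiotic trisomy: both haplotypes of one
# parent are detected, interleaved, in a restricted region. Consanguinity:
# parental genotypes share long runs with no opposite homozygotes.

#' Call-rate QC for one sample
#'
#' Call rate is computed genome-wide over all non-Y manifest loci and is
#' deliberately not re-normalized for suspected aneuploidy (the <60% rule
#' applies to euploid samples; the caveat is carried in the report).
#'
#' @param calls canonical call vector in manifest order.
#' @param manifest the `karyo_manifest`.
#' @param sample_id sample label for the report.
#' @param threshold exclusion threshold on call rate (default 0.60).
#' @return data.frame row: `sample_id`, `call_rate`, `excluded`, `reason`.
#' @export
qc_sample <- function(calls, manifest, sample_id = "sample",
                      threshold = 0.60) {
  cr <- call_rate(calls, keep = !manifest$excluded)
  excl <- !is.na(cr) && cr < threshold
  data.frame(
    sample_id = sample_id, call_rate = cr, excluded = excl,
    reason = if (excl) "low_call_rate" else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Detect whole-chromosome monosomy for one embryo
#'
#' A parent's chromosome is called missing when (a) the fraction of that
#' parent's usable informative loci yielding key calls is below `k_mono`
#' for BOTH haplotypes and (b) the apparent dropout fraction of that
#' parent's allele at called obligate-heterozygous loci exceeds `d_mono`;
#' each metric must rest on at least `min_loci` loci, otherwise the status
#' is `unknown`.
#'
#' @param embryo_calls canonical embryo calls (manifest order).
#' @param phase_map [build_phase_map()] output.
#' @param father_calls,mother_calls parental call vectors.
#' @param chromosome chromosome to test.
#' @param k_mono key-fraction ceiling (default 0.02).
#' @param d_mono apparent-dropout floor (default 0.9).
#' @param min_loci minimum loci per metric (default 30).
#' @return list with `status` (`disomy`, `monosomy_paternal_missing`,
#'   `monosomy_maternal_missing`, `unknown`) and the supporting metrics.
#' @export
detect_monosomy <- function(embryo_calls, phase_map, father_calls,
                            mother_calls, chromosome, k_mono = 0.02,
                            d_mono = 0.9, min_loci = 30L) {
  on_chr <- phase_map$chromosome == chromosome
  oblig <- which(on_chr & phase_map$class == "obligate_heterozygous")
  metrics <- list()
  verdict <- c(paternal = NA, maternal = NA)
  for (p in c("paternal", "maternal")) {
    idx <- which(on_chr & phase_map$usable & phase_map$inf_parent == p)
    callable <- idx[embryo_calls[idx] != "NC"]
    n_inf <- length(callable)
    key_frac <- c(H1 = NA_real_, H2 = NA_real_)
    if (n_inf > 0L) {
      u <- phase_map$unique_allele[callable]
      L <- phase_map$linked_hap[callable]
      has_u <- (u == "A" & embryo_calls[callable] %in% c("AA", "AB")) |
               (u == "B" & embryo_calls[callable] %in% c("AB", "BB"))
      key_frac["H1"] <- sum(has_u & L == "H1") / n_inf
      key_frac["H2"] <- sum(has_u & L == "H2") / n_inf
    }
    # allele the tested parent contributes at obligate-het loci
    par_call <- if (p == "paternal") father_calls else mother_calls
    other_call <- if (p == "paternal") mother_calls else father_calls
    called <- oblig[embryo_calls[oblig] != "NC"]
    n_ob <- length(called)
    drop_frac <- NA_real_
    if (n_ob > 0L) {
      other_al <- substr(other_call[called], 1L, 1L)
      # embryo homozygous for the OTHER parent's allele: tested parent's
      # allele absent
      drop_frac <- mean(embryo_calls[called] == paste0(other_al, other_al))
    }
    metrics[[p]] <- list(n_informative = n_inf, key_frac = key_frac,
                         n_obligate = n_ob, dropout_frac = drop_frac)
    verdict[p] <- if (n_inf < min_loci || n_ob < min_loci) NA else {
      all(key_frac < k_mono) && drop_frac > d_mono
    }
  }
  status <- if (anyNA(verdict)) "unknown"
            else if (verdict["paternal"]) "monosomy_paternal_missing"
            else if (verdict["maternal"]) "monosomy_maternal_missing"
            else "disomy"
  list(status = status, metrics = metrics)
}

#' Detect meiotic trisomy for one embryo, parent and chromosome
#'
#' Scans windows of `w` consecutive key calls of one parent. A window
#' fires when it is not explainable by at most two crossovers plus
#' isolated miscalls: the best fit with up to two changepoints (three
#' alternating segments) must leave at least `ceiling(t_tri * w)`
#' mismatching key calls. In a disomic window the residual is just the
#' miscall count, whatever real crossovers fall inside it (a close
#' embryo-plus-reference crossover pair is two changepoints), and 8
#' miscall keys of 30 is unreachable by noise (Binom(30, ~0.015) >= 8 is
#' ~1e-8 per window; three real crossovers within ~800 kb similarly
#' rare). In a true meiosis-I trisomy both haplotypes interleave at
#' about half the key calls each, leaving a large residual in ~75% of
#' windows, and a trisomic region spans many windows.
#'
#' @param evidence phased calls for one (embryo, parent, chromosome)
#'   track (`position_bp`, `supported`, `strength`).
#' @param w window size in key calls (default 30).
#' @param t_tri minimum fraction of a window's key calls left
#'   unexplained by the best two-changepoint fit (default 0.25).
#' @return list with `trisomy` (logical), `region` (bp span of firing
#'   windows or `NULL`).
#' @export
detect_meiotic_trisomy <- function(evidence, w = 30L, t_tri = 0.25) {
  keys <- evidence[evidence$strength == "key", , drop = FALSE]
  n <- nrow(keys)
  if (n < w) return(list(trisomy = FALSE, region = NULL))
  s1 <- as.integer(keys$supported == "H1")
  nw <- n - w + 1L
  cs <- c(0L, cumsum(s1))
  i <- seq_len(nw)
  h1_win <- cs[i + w] - cs[i]
  resid <- rep.int(w, nw)
  for (k1 in 0:w) {
    h1_a <- cs[i + k1] - cs[i]                 # H1 count in segment 1
    for (k2 in k1:w) {
      h1_b <- cs[i + k2] - cs[i + k1]          # H1 count in segment 2
      h1_c <- h1_win - h1_a - h1_b             # H1 count in segment 3
      # orientation H1|H2|H1 and its mirror
      mis_a <- (k1 - h1_a) + h1_b + (w - k2 - h1_c)
      mis_b <- h1_a + (k2 - k1 - h1_b) + h1_c
      resid <- pmin(resid, mis_a, mis_b)
    }
  }
  fire <- resid >= ceiling(t_tri * w)
  if (!any(fire)) return(list(trisomy = FALSE, region = NULL))
  i1 <- min(which(fire)); i2 <- max(which(fire)) + w - 1L
  list(trisomy = TRUE,
       region = c(start_bp = keys$position_bp[i1],
                  end_bp = keys$position_bp[i2]))
}

#' Chromosome status for every embryo and chromosome of a case
#'
#' Combines [detect_monosomy()] and [detect_meiotic_trisomy()]; monosomy
#' takes precedence (a missing chromosome produces no interleaved
#' evidence anyway).
#'
#' @param genotypes a `karyo_genotypes`.
#' @param config a `karyo_case_config`.
#' @param phase_map [build_phase_map()] output.
#' @param evidence full evidence table from [build_phase_table()].
#' @return data.frame: `embryo`, `chromosome`, `status`, `region_start`,
#'   `region_end`.
#' @export
chromosome_status <- function(genotypes, config, phase_map, evidence) {
  fa <- sample_calls(genotypes, config$father)
  mo <- sample_calls(genotypes, config$mother)
  chroms <- setdiff(unique(genotypes$manifest$chromosome), "Y")
  rows <- list()
  for (emb in config$embryos) {
    ec <- sample_calls(genotypes, emb)
    for (ch in chroms) {
      mono <- detect_monosomy(ec, phase_map, fa, mo, ch)
      status <- mono$status
      r1 <- NA_real_; r2 <- NA_real_
      if (status == "disomy") {
        for (p in c("paternal", "maternal")) {
          ev <- evidence[evidence$embryo == emb & evidence$parent == p &
                           evidence$chromosome == ch, , drop = FALSE]
          tri <- detect_meiotic_trisomy(ev)
          if (tri$trisomy) {
            status <- paste0("trisomy_",
                             if (p == "paternal") "paternal" else "maternal")
            r1 <- tri$region[["start_bp"]]; r2 <- tri$region[["end_bp"]]
            break
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        embryo = emb, chromosome = ch, status = status,
        region_start = r1, region_end = r2, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Detect consanguineous (identical-by-descent) regions in the parents
#'
#' Scans each chromosome for maximal runs of loci at which both parents
#' are called and no opposite-homozygote pair (AAxBB or BBxAA) occurs.
#' Runs of at least `n_ibd` SNPs spanning at least `L_ibd` bp are
#' reported; in such regions the parents share a chromosome with an
#' identical SNP genotype and marker informativeness collapses.
#'
#' @param father_calls,mother_calls canonical parental call vectors.
#' @param manifest the `karyo_manifest`.
#' @param n_ibd minimum SNPs per region (default 100).
#' @param L_ibd minimum region span in bp (default 5e6).
#' @return data.frame: `chromosome`, `start_bp`, `end_bp`, `n_snps`,
#'   `n_opposite_hom` (always 0 by construction).
#' @export
detect_consanguineous_regions <- function(father_calls, mother_calls,
                                          manifest, n_ibd = 100L,
                                          L_ibd = 5e6) {
  out <- list()
  for (ch in setdiff(unique(manifest$chromosome), "Y")) {
    idx <- which(manifest$chromosome == ch &
                   father_calls != "NC" & mother_calls != "NC")
    if (!length(idx)) next
    fa <- father_calls[idx]; mo <- mother_calls[idx]
    opp <- (fa == "AA" & mo == "BB") | (fa == "BB" & mo == "AA")
    r <- rle(!opp)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (b in which(r$values)) {
      i <- idx[starts[b]:ends[b]]
      span <- manifest$position_bp[i[length(i)]] - manifest$position_bp[i[1L]]
      if (length(i) >= n_ibd && span >= L_ibd) {
        out[[length(out) + 1L]] <- data.frame(
          chromosome = ch,
          start_bp = manifest$position_bp[i[1L]],
          end_bp = manifest$position_bp[i[length(i)]],
          n_snps = length(i), n_opposite_hom = 0L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chromosome = character(), start_bp = numeric(),
                      end_bp = numeric(), n_snps = integer(),
                      n_opposite_hom = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
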