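# Informative-locus classification and reference-based phasing.
#
# At an informative locus one parent is heterozygous (AB) and the other
# homozygous, so one allele (the "unique" allele) tags exactly one of the
# four parental chromosomes. The reference individual links that allele to a
# specific parental haplotype: H1 is the chromosome of the informative
# parent inherited by (or, for grandparent references, derived from) the
# reference, H2 the other. Embryo observations then become "key" evidence
# (unique allele present -- a state allele dropout cannot fabricate) or
# "non-key" evidence (unique allele absent, which dropout can mimic).

.LOCUS_CLASSES <- c("paternal_informative", "maternal_informative",
                    "uninformative", "obligate_heterozygous", "excluded")

#' Classify loci by parental informativeness
#'
#' A total, deterministic function of the parental calls and chromosome:
#' one parent heterozygous and the other homozygous is informative for the
#' heterozygous parent; opposite homozygotes (AAxBB) are
#' `obligate_heterozygous` (reserved for allele-dropout estimation); any
#' parental no-call, Y-chromosome loci, and X loci with a heterozygous
#' father call (impossible under hemizygosity) are `excluded`; everything
#' else is `uninformative`.
#'
#' @param father,mother canonical parental calls (vectorized).
#' @param chromosome chromosome label(s), recycled to call length.
#' @return character vector of locus classes.
#' @export
classify_locus <- function(father, mother, chromosome) {
  n <- length(father)
  stopifnot(length(mother) == n)
  chromosome <- rep_len(sub("^chr", "", as.character(chromosome)), n)
  cls <- rep("uninformative", n)
  hom <- c("AA", "BB")
  cls[father == "AB" & mother %in% hom] <- "paternal_informative"
  cls[mother == "AB" & father %in% hom] <- "maternal_informative"
  cls[(father == "AA" & mother == "BB") |
      (father == "BB" & mother == "AA")] <- "obligate_heterozygous"
  cls[father == "NC" | mother == "NC"] <- "excluded"
  cls[chromosome == "X" & father == "AB"] <- "excluded"
  cls[chromosome == "Y"] <- "excluded"
  cls
}

#' Find the allele unique to one parental chromosome
#'
#' At an informative locus the heterozygous parent carries one allele that
#' the homozygous parent lacks; that allele sits on exactly one of the four
#' parental chromosomes.
#'
#' @param father,mother canonical parental calls (vectorized).
#' @return list with `parent` (`paternal`/`maternal`) and `allele`
#'   (`A`/`B`); `NA` entries where the locus is not informative.
#' @export
find_unique_allele <- function(father, mother) {
  cls <- classify_locus(father, mother, chromosome = "1")
  parent <- ifelse(cls == "paternal_informative", "paternal",
            ifelse(cls == "maternal_informative", "maternal", NA))
  hom_call <- ifelse(cls == "paternal_informative", mother,
              ifelse(cls == "maternal_informative", father, NA))
  allele <- ifelse(hom_call == "AA", "B",
            ifelse(hom_call == "BB", "A", NA))
  if (length(father) == 1L && is.na(parent)) {
    stop("find_unique_allele called on a non-informative locus",
         call. = FALSE)
  }
  list(parent = parent, allele = allele)
}

#' Build the per-locus phase map for a case
#'
#' Classifies every manifest locus, finds the unique allele at informative
#' loci, and links it to a parental haplotype through the reference:
#' \itemize{
#' \item Sibling reference: unique allele present in the reference call
#'   implies it sits on H1 (the chromosome the reference inherited),
#'   absent implies H2; reference no-calls and Mendelian-impossible
#'   reference calls void the locus (the latter counted as reference
#'   inconsistencies).
#' \item Grandparent/relative reference: only loci informative for the
#'   related parent are usable, and only where the reference call is
#'   homozygous -- homozygous for the unique allele implies the
#'   grandparent-derived chromosome (H1) carries it, homozygous for the
#'   other allele implies H2; heterozygous reference calls are unusable.
#' }
#'
#' @param genotypes a `karyo_genotypes` holding all case samples.
#' @param config a `karyo_case_config`.
#' @return data.frame with one row per manifest locus: `class`,
#'   `inf_parent`, `unique_allele`, `linked_hap`, `usable`,
#'   `ref_inconsistent`.
#' @export
build_phase_map <- function(genotypes, config) {
  m <- genotypes$manifest
  fa <- sample_calls(genotypes, config$father)
  mo <- sample_calls(genotypes, config$mother)
  re <- sample_calls(genotypes, config$reference)
  cls <- classify_locus(fa, mo, m$chromosome)
  inf <- cls %in% c("paternal_informative", "maternal_informative")
  parent <- rep(NA_character_, nrow(m))
  allele <- rep(NA_character_, nrow(m))
  if (any(inf)) {
    ua <- find_unique_allele(fa[inf], mo[inf])
    parent[inf] <- ua$parent
    allele[inf] <- ua$allele
  }
  linked <- rep(NA_character_, nrow(m))
  usable <- rep(FALSE, nrow(m))
  incons <- rep(FALSE, nrow(m))
  side <- reference_side(config$reference_relation)
  if (is.na(side)) {
    # sibling: phase both parents by presence/absence of the unique allele
    i <- which(inf)
    if (length(i)) {
      has_u <- mapply(function(c, a) call_contains(c, a), re[i], allele[i])
      hom_other <- mapply(function(c, a) call_hom(c, other_allele(a)),
                          re[i], allele[i])
      # Mendelian check (autosomes): the sibling cannot be homozygous for
      # the unique allele, since the homozygous parent lacks it entirely.
      bad <- mapply(function(c, a) call_hom(c, a), re[i], allele[i]) &
             m$chromosome[i] != "X"
      nc <- re[i] == "NC"
      linked[i][has_u & !bad & !nc] <- "H1"
      linked[i][hom_other & !bad & !nc] <- "H2"
      usable[i] <- !nc & !bad & (has_u | hom_other)
      incons[i] <- bad
    }
  } else {
    i <- which(inf & parent == side)
    if (length(i)) {
      hom_u <- mapply(function(c, a) call_hom(c, a), re[i], allele[i])
      hom_other <- mapply(function(c, a) call_hom(c, other_allele(a)),
                          re[i], allele[i])
      linked[i][hom_u] <- "H1"
      linked[i][hom_other] <- "H2"
      usable[i] <- hom_u | hom_other
    }
  }
  data.frame(locus_id = m$locus_id, chromosome = m$chromosome,
             position_bp = m$position_bp, class = cls, inf_parent = parent,
             unique_allele = allele, linked_hap = linked, usable = usable,
             ref_inconsistent = incons, stringsAsFactors = FALSE)
}

#' Link one informative locus through the reference
#'
#' Scalar convenience wrapper around the linkage rules of
#' [build_phase_map()], useful for inspecting a single locus.
#'
#' @param father,mother,reference canonical calls at the locus.
#' @param relation reference relation (see [case_config()]).
#' @param chromosome chromosome label (default autosomal).
#' @return list with `usable`, `linked_hap` and `ref_inconsistent`.
#' @export
assign_reference_linkage <- function(father, mother, reference,
                                     relation = "sibling",
                                     chromosome = "1") {
  relation <- match.arg(relation, .RELATIONS)
  cls <- classify_locus(father, mother, chromosome)
  if (!cls %in% c("paternal_informative", "maternal_informative")) {
    stop("locus is not informative", call. = FALSE)
  }
  ua <- find_unique_allele(father, mother)
  side <- reference_side(relation)
  out <- list(usable = FALSE, linked_hap = NA_character_,
              ref_inconsistent = FALSE)
  if (reference == "NC") return(out)
  if (is.na(side)) {
    if (call_hom(reference, ua$allele) && chromosome != "X") {
      out$ref_inconsistent <- TRUE
      return(out)
    }
    if (call_contains(reference, ua$allele)) {
      out$usable <- TRUE; out$linked_hap <- "H1"
    } else if (call_hom(reference, other_allele(ua$allele))) {
      out$usable <- TRUE; out$linked_hap <- "H2"
    }
  } else {
    if (ua$parent != side) return(out)
    if (call_hom(reference, ua$allele)) {
      out$usable <- TRUE; out$linked_hap <- "H1"
    } else if (call_hom(reference, other_allele(ua$allele))) {
      out$usable <- TRUE; out$linked_hap <- "H2"
    }
  }
  out
}

#' Convert one embryo call into phased evidence
#'
#' Implements the key/non-key dichotomy: the unique allele's PRESENCE in
#' the embryo call supports the haplotype carrying it and cannot have been
#' produced by allele dropout (key); its ABSENCE in a called homozygote of
#' the other allele supports the complementary haplotype but could be a
#' dropout artifact (non-key). An embryo homozygous for the unique allele
#' is still key for its haplotype (the allele's presence is dropout-proof)
#' but is flagged anomalous, since the other parent's obligate allele is
#' missing.
#'
#' @param embryo canonical embryo call.
#' @param unique_allele `A` or `B`.
#' @param linked_hap haplotype carrying the unique allele (`H1`/`H2`).
#' @return list with `supported`, `strength` (`key`/`nonkey`), `anomaly`;
#'   `NULL` for a no-call.
#' @export
phase_embryo_call <- function(embryo, unique_allele, linked_hap) {
  if (embryo == "NC") return(NULL)
  if (call_contains(embryo, unique_allele)) {
    list(supported = linked_hap, strength = "key",
         anomaly = call_hom(embryo, unique_allele))
  } else if (call_hom(embryo, other_allele(unique_allele))) {
    list(supported = other_hap(linked_hap), strength = "nonkey",
         anomaly = FALSE)
  } else {
    NULL
  }
}

#' Build the full phased-evidence table for a case
#'
#' One pass over all loci producing, for each embryo and each phasable
#' parent, a position-ordered sequence of key/non-key phased calls.
#' Embryo sex (needed on the X chromosome) is taken from the
#' configuration; `unknown` is inferred as male when fewer than 2% of the
#' embryo's called informative X loci are heterozygous.
#'
#' @param genotypes a `karyo_genotypes`.
#' @param config a `karyo_case_config`.
#' @param phase_map optional precomputed [build_phase_map()] result.
#' @return list with `phase_map`, `evidence` (data.frame: `embryo`,
#'   `parent`, `chromosome`, `position_bp`, `locus_idx`, `supported`,
#'   `strength`, `anomaly`), `embryo_sex` (possibly inferred), and
#'   `counts` (per-embryo evidence totals).
#' @export
build_phase_table <- function(genotypes, config, phase_map = NULL) {
  if (is.null(phase_map)) phase_map <- build_phase_map(genotypes, config)
  m <- genotypes$manifest
  use <- which(phase_map$usable)
  sexes <- config$embryo_sex
  ev_list <- list()
  for (emb in config$embryos) {
    ec <- sample_calls(genotypes, emb)
    sex <- sexes[[emb]]
    if (identical(sex, "unknown") && any(m$chromosome == "X")) {
      xin <- which(phase_map$class %in%
                     c("paternal_informative", "maternal_informative") &
                   m$chromosome == "X")
      called <- xin[ec[xin] != "NC"]
      if (length(called) >= 20L) {
        sex <- if (mean(ec[called] == "AB") < 0.02) "male" else "female"
        sexes[[emb]] <- sex
      }
    }
    i <- use
    u <- phase_map$unique_allele[i]
    L <- phase_map$linked_hap[i]
    call <- ec[i]
    has_u <- (u == "A" & call %in% c("AA", "AB")) |
             (u == "B" & call %in% c("AB", "BB"))
    hom_other <- (u == "A" & call == "BB") | (u == "B" & call == "AA")
    hom_u <- (u == "A" & call == "AA") | (u == "B" & call == "BB")
    keep <- call != "NC" & (has_u | hom_other)
    supported <- ifelse(has_u, L, other_hap(L))
    strength <- ifelse(has_u, "key", "nonkey")
    anomaly <- hom_u & m$chromosome[i] != "X"
    ev <- data.frame(
      embryo = rep(emb, sum(keep)),
      parent = phase_map$inf_parent[i][keep],
      chromosome = m$chromosome[i][keep],
      position_bp = m$position_bp[i][keep],
      locus_idx = i[keep],
      supported = supported[keep],
      strength = strength[keep],
      anomaly = anomaly[keep],
      stringsAsFactors = FALSE
    )
    ev_list[[emb]] <- ev
  }
  evidence <- do.call(rbind, c(ev_list, list(make.row.names = FALSE)))
  if (is.null(evidence)) {
    evidence <- data.frame(embryo = character(), parent = character(),
                           chromosome = character(), position_bp = integer(),
                           locus_idx = integer(), supported = character(),
                           strength = character(), anomaly = logical())
  }
  evidence <- evidence[order(match(evidence$embryo, config$embryos),
                             evidence$parent,
                             chrom_rank(evidence$chromosome),
                             evidence$position_bp), , drop = FALSE]
  rownames(evidence) <- NULL
  counts <- as.data.frame(table(embryo = evidence$embryo,
                                parent = evidence$parent,
                                strength = evidence$strength),
                          stringsAsFactors = FALSE)
  list(phase_map = phase_map, evidence = evidence, embryo_sex = sexes,
       counts = counts)
}
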