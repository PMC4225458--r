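# Case configuration: pedigree roles, reference relation and disease status,
# disease loci and inheritance modes. Stored as a single JSON document and
# validated on load.

.RELATIONS <- c("sibling", "paternal_grandparent", "maternal_grandparent",
                "paternal_relative", "maternal_relative")
.MODES <- c("autosomal_dominant", "autosomal_recessive",
            "x_linked_recessive", "x_linked_dominant", "deletion_linked")
.REF_STATUS <- c("affected", "unaffected", "carrier")

#' Construct a disease-locus specification
#'
#' @param gene_name label for the locus.
#' @param chromosome chromosome carrying the gene.
#' @param start_bp,end_bp 1-based inclusive gene interval.
#' @param mode inheritance mode, one of
#'   `autosomal_dominant`, `autosomal_recessive`, `x_linked_recessive`,
#'   `x_linked_dominant`, `deletion_linked`.
#' @param flank_bp width of each flanking region used for phasing
#'   (default 2 Mb on each side of the gene).
#' @param at_risk_parent for dominant-type modes, which parent transmits
#'   the risk haplotype (`paternal` or `maternal`); X-linked modes are
#'   maternal by construction (the father's X cannot be phased).
#' @return a `disease_locus` list.
#' @export
disease_locus <- function(gene_name, chromosome, start_bp, end_bp, mode,
                          flank_bp = 2e6, at_risk_parent = NULL) {
  mode <- match.arg(mode, .MODES)
  chromosome <- sub("^chr", "", as.character(chromosome))
  start_bp <- as.numeric(start_bp); end_bp <- as.numeric(end_bp)
  if (start_bp > end_bp) stop("start_bp > end_bp", call. = FALSE)
  if (flank_bp <= 0) stop("flank_bp must be > 0", call. = FALSE)
  if (mode %in% c("x_linked_recessive", "x_linked_dominant")) {
    if (chromosome != "X") {
      stop("X-linked mode requires chromosome X", call. = FALSE)
    }
    at_risk_parent <- "maternal"
  }
  if (mode %in% c("autosomal_dominant", "deletion_linked") &&
      is.null(at_risk_parent)) {
    stop("dominant-type modes require at_risk_parent", call. = FALSE)
  }
  if (!is.null(at_risk_parent)) {
    at_risk_parent <- match.arg(at_risk_parent, c("paternal", "maternal"))
  }
  structure(list(gene_name = gene_name, chromosome = chromosome,
                 start_bp = start_bp, end_bp = end_bp, mode = mode,
                 flank_bp = as.numeric(flank_bp),
                 at_risk_parent = at_risk_parent),
            class = "disease_locus")
}

#' Construct a case configuration
#'
#' @param father,mother,reference sample ids (exactly one of each).
#' @param embryos character vector of embryo sample ids (at least one).
#' @param reference_relation how the reference relates to the family:
#'   `sibling` (a child of the couple) or a grandparent/relative on one
#'   parental side. Non-sibling references phase only the related parent
#'   and only at loci where the reference is homozygous.
#' @param reference_disease_status `affected`, `unaffected` or `carrier`.
#'   For autosomal-recessive cases, `unaffected` asserts a known
#'   non-carrier; `carrier` additionally needs `reference_carrier_side`.
#' @param reference_carrier_side for a carrier sibling reference in a
#'   recessive case, the parental side whose mutant haplotype the
#'   reference inherited (`paternal` or `maternal`). The tool refuses to
#'   guess this.
#' @param disease_loci list of [disease_locus()] entries (may be empty for
#'   karyomapping-only runs).
#' @param embryo_sex named character vector/list (`male`, `female`,
#'   `unknown`) per embryo; required by X-linked modes, inferred from X
#'   heterozygosity when `unknown`.
#' @return a validated `karyo_case_config`.
#' @export
case_config <- function(father, mother, reference, embryos,
                        reference_relation = "sibling",
                        reference_disease_status = "affected",
                        reference_carrier_side = NULL,
                        disease_loci = list(),
                        embryo_sex = NULL) {
  reference_relation <- match.arg(reference_relation, .RELATIONS)
  reference_disease_status <- match.arg(reference_disease_status, .REF_STATUS)
  ids <- c(father, mother, reference)
  if (length(ids) != 3L || anyDuplicated(c(ids, embryos))) {
    stop("need exactly one father, mother and reference, distinct from embryos",
         call. = FALSE)
  }
  if (length(embryos) < 1L) stop("need at least one embryo", call. = FALSE)
  if (!is.null(reference_carrier_side)) {
    reference_carrier_side <- match.arg(reference_carrier_side,
                                        c("paternal", "maternal"))
  }
  disease_loci <- lapply(disease_loci, function(dl) {
    if (inherits(dl, "disease_locus")) dl else do.call(disease_locus, dl)
  })
  if (is.null(embryo_sex)) {
    embryo_sex <- stats::setNames(rep("unknown", length(embryos)), embryos)
  } else {
    embryo_sex <- unlist(embryo_sex)
    embryo_sex <- stats::setNames(
      as.character(embryo_sex)[match(embryos, names(embryo_sex))], embryos)
    embryo_sex[is.na(embryo_sex)] <- "unknown"
  }
  stopifnot(all(embryo_sex %in% c("male", "female", "unknown")))
  cfg <- structure(list(
    father = father, mother = mother, reference = reference,
    embryos = as.character(embryos),
    reference_relation = reference_relation,
    reference_disease_status = reference_disease_status,
    reference_carrier_side = reference_carrier_side,
    disease_loci = disease_loci,
    embryo_sex = embryo_sex
  ), class = "karyo_case_config")
  validate_case_config(cfg)
  cfg
}

# Mode/reference expressibility checks that need no manifest.
validate_case_config <- function(cfg) {
  rel_side <- reference_side(cfg$reference_relation)
  for (dl in cfg$disease_loci) {
    if (dl$mode == "autosomal_recessive") {
      if (cfg$reference_relation != "sibling") {
        stop("autosomal_recessive diagnosis requires a sibling reference ",
             "(both parental sides must be phased)", call. = FALSE)
      }
      if (cfg$reference_disease_status == "carrier" &&
          is.null(cfg$reference_carrier_side)) {
        stop("carrier reference in a recessive case requires ",
             "reference_carrier_side", call. = FALSE)
      }
    }
    if (!is.null(dl$at_risk_parent) && !is.na(rel_side) &&
        rel_side != dl$at_risk_parent) {
      stop(sprintf(
        "disease locus %s is transmitted on the %s side but the reference only phases the %s side",
        dl$gene_name, dl$at_risk_parent, rel_side), call. = FALSE)
    }
  }
  invisible(cfg)
}

# Which parental side a non-sibling reference phases; NA = both (sibling).
reference_side <- function(relation) {
  switch(relation,
         sibling = NA_character_,
         paternal_grandparent = , paternal_relative = "paternal",
         maternal_grandparent = , maternal_relative = "maternal")
}

#' Read a case configuration from JSON
#' @param path path to the JSON case file.
#' @return a validated `karyo_case_config`.
#' @export
read_case_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  dl <- raw$disease_loci
  if (is.data.frame(dl)) {
    dl <- lapply(seq_len(nrow(dl)), function(i) {
      as.list(dl[i, !vapply(dl[i, ], function(v) is.na(v)[1], TRUE),
                 drop = FALSE])
    })
  }
  case_config(
    father = raw$father, mother = raw$mother, reference = raw$reference,
    embryos = raw$embryos,
    reference_relation = raw$reference_relation %||% "sibling",
    reference_disease_status = raw$reference_disease_status %||% "affected",
    reference_carrier_side = raw$reference_carrier_side,
    disease_loci = dl %||% list(),
    embryo_sex = raw$embryo_sex
  )
}

#' Write a case configuration to JSON
#' @param cfg a `karyo_case_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_case_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$disease_loci <- lapply(out$disease_loci, function(dl) {
    dl <- unclass(dl)
    dl[!vapply(dl, is.null, TRUE)]
  })
  out$embryo_sex <- as.list(out$embryo_sex)
  out <- out[!vapply(out, is.null, TRUE)]
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
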