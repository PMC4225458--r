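# SNP manifest: the ordered locus table every sample vector is aligned to.
# Internal coordinates are 1-based inclusive throughout; BED export converts.

#' Construct a SNP manifest
#'
#' @param locus_id unique locus identifiers.
#' @param chromosome chromosome labels (`1`..`22`, `X`; `Y` rows are kept but
#'   flagged `excluded` and never enter analysis).
#' @param position_bp 1-based physical positions.
#' @return a `karyo_manifest` data.frame sorted by (chromosome, position),
#'   with an `excluded` column marking Y-chromosome rows.
#' @details Chromosomes sort numerically with X after 22 and Y last.
#'   Duplicate positions are retained with stable order by `locus_id`.
#' @export
snp_manifest <- function(locus_id, chromosome, position_bp) {
  locus_id <- as.character(locus_id)
  chromosome <- sub("^chr", "", as.character(chromosome))
  position_bp <- as.integer(position_bp)
  if (anyDuplicated(locus_id)) {
    stop("duplicate locus_id: ",
         paste(unique(locus_id[duplicated(locus_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(position_bp < 1L, na.rm = TRUE) || anyNA(position_bp)) {
    stop("position_bp must be integer >= 1", call. = FALSE)
  }
  m <- data.frame(
    locus_id = locus_id,
    chromosome = chromosome,
    position_bp = position_bp,
    excluded = chromosome == "Y",
    stringsAsFactors = FALSE
  )
  ord <- order(chrom_rank(m$chromosome), m$position_bp, m$locus_id)
  m <- m[ord, , drop = FALSE]
  rownames(m) <- NULL
  class(m) <- c("karyo_manifest", "data.frame")
  m
}

# Sort key: autosomes numeric, then X, then Y, then anything else.
chrom_rank <- function(chrom) {
  r <- suppressWarnings(as.numeric(chrom))
  r[chrom == "X"] <- 23
  r[chrom == "Y"] <- 24
  r[is.na(r)] <- 25
  r
}

#' Read a SNP manifest from a tab-separated file
#'
#' Expects header columns `locus_id`, `chromosome`, `position_bp`. Rows out
#' of (chromosome, position) order are sorted with a warning; duplicate
#' `locus_id` values are an error. Y-chromosome rows are loaded but marked
#' excluded from analysis.
#'
#' @param path path to the TSV file.
#' @return a `karyo_manifest`.
#' @export
read_snp_manifest <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character", check.names = FALSE)
  need <- c("locus_id", "chromosome", "position_bp")
  if (!all(need %in% names(d))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  m <- snp_manifest(d$locus_id, d$chromosome, d$position_bp)
  if (!identical(m$locus_id, d$locus_id)) {
    warning("manifest rows were not sorted by (chromosome, position); sorted",
            call. = FALSE)
  }
  m
}

#' Write a SNP manifest to TSV
#' @param manifest a `karyo_manifest`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_manifest <- function(manifest, path) {
  utils::write.table(
    manifest[, c("locus_id", "chromosome", "position_bp")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
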