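# Result writers. Internal coordinates are 1-based inclusive; BED export
# converts to 0-based half-open.

#' Write case outputs: haploblock/crossover BED, diagnosis JSON, karyomap TSV
#'
#' \itemize{
#' \item `haploblocks.bed`: one line per block, name `parent:haplotype`,
#'   score = supporting key-SNP count (capped at 1000 per BED).
#' \item `crossovers.bed`: one line per event, name
#'   `parent:from-to[:common]`.
#' \item `diagnosis.json`: per-embryo status, per-locus evidence counts,
#'   QC fields, chromosome statuses, IBD regions, run parameters.
#' \item `karyomap.tsv`: one row per phased informative call per embryo
#'   (position, parent, supported haplotype, key/nonkey) -- the dot-track
#'   table.
#' }
#'
#' @param result a `karyo_case_result` from [run_case()].
#' @param out_dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_case_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  paths <- character()

  bl <- result$blocks
  bed <- if (nrow(bl)) {
    data.frame(chrom = paste0("chr", bl$chromosome),
               start = format_bp(bl$start_bp - 1),
               end = format_bp(bl$end_bp),
               name = paste0(bl$embryo, ":", bl$parent, ":", bl$haplotype),
               score = pmin(bl$n_key, 1000L),
               strand = ".")
  } else bed_empty()
  p <- file.path(out_dir, "haploblocks.bed")
  write_bed(bed, p, "haploblocks")
  paths <- c(paths, p)

  xo <- result$crossovers
  bed <- if (nrow(xo)) {
    nm <- paste0(xo$embryo, ":", xo$parent, ":", xo$from_hap, "-",
                 xo$to_hap, ifelse(xo$is_common, ":common", ""))
    data.frame(chrom = paste0("chr", xo$chromosome),
               start = format_bp(xo$left_bp - 1),
               end = format_bp(xo$right_bp),
               name = nm, score = 0L, strand = ".")
  } else bed_empty()
  p <- file.path(out_dir, "crossovers.bed")
  write_bed(bed, p, "crossovers")
  paths <- c(paths, p)

  km <- result$evidence[, c("embryo", "parent", "chromosome",
                            "position_bp", "supported", "strength",
                            "anomaly")]
  p <- file.path(out_dir, "karyomap.tsv")
  utils::write.table(km, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  p <- file.path(out_dir, "diagnosis.json")
  jsonlite::write_json(
    list(diagnoses = result$diagnoses,
         qc = result$qc,
         chromosome_status = result$chrom_status,
         ibd_regions = result$ibd_regions,
         embryo_sex = as.list(result$embryo_sex),
         ado = result$ado,
         parameters = result$parameters),
    p, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null",
    na = "null")
  paths <- c(paths, p)
  invisible(paths)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

bed_empty <- function() {
  data.frame(chrom = character(), start = character(), end = character(),
             name = character(), score = integer(), strand = character())
}

write_bed <- function(bed, path, track) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track name="%s"', track), con)
  if (nrow(bed)) {
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
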