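# Genotype container: a loci x samples character matrix of canonical calls,
# aligned 1:1 to a karyo_manifest. Built from a wide TSV (row = locus,
# column = sample) or from a GT-only VCF.

new_karyo_genotypes <- function(manifest, calls, n_missing = NULL) {
  stopifnot(inherits(manifest, "karyo_manifest"),
            is.matrix(calls), nrow(calls) == nrow(manifest))
  rownames(calls) <- manifest$locus_id
  if (is.null(n_missing)) n_missing <- integer(ncol(calls))
  samples <- data.frame(
    sample_id = colnames(calls),
    n_missing = as.integer(n_missing),
    call_rate = apply(calls, 2L, function(x) call_rate(x)),
    stringsAsFactors = FALSE
  )
  structure(list(manifest = manifest, calls = calls, samples = samples),
            class = "karyo_genotypes")
}

#' @export
print.karyo_genotypes <- function(x, ...) {
  cat(sprintf("karyo_genotypes: %d loci x %d samples\n",
              nrow(x$calls), ncol(x$calls)))
  print(x$samples)
  invisible(x)
}

#' Read a wide genotype table aligned to a manifest
#'
#' Reads a tab-separated table with a `locus_id` column and one column per
#' sample, cells in `AA`/`AB`/`BA`/`BB`/`NC`/`./.`. `BA` is normalized to
#' `AB`. Loci present in the manifest but absent from the table are filled
#' with `NC` and counted per sample; loci absent from the manifest are an
#' error. Duplicate sample columns or unknown tokens are errors.
#'
#' @param path path to the TSV file.
#' @param manifest a `karyo_manifest` the calls are aligned to.
#' @return a `karyo_genotypes` object (calls matrix in manifest order,
#'   per-sample missing counts and call rates).
#' @export
read_genotype_table <- function(path, manifest) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character", check.names = FALSE)
  if (!"locus_id" %in% names(d)) {
    stop("genotype table must have a locus_id column", call. = FALSE)
  }
  sample_ids <- names(d)[names(d) != "locus_id"]
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample column(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(d$locus_id)) {
    stop("duplicated locus_id rows in genotype table", call. = FALSE)
  }
  unknown <- setdiff(d$locus_id, manifest$locus_id)
  if (length(unknown)) {
    stop("genotype table contains loci not in manifest: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  idx <- match(manifest$locus_id, d$locus_id)
  missing_locus <- is.na(idx)
  calls <- matrix("NC", nrow(manifest), length(sample_ids),
                  dimnames = list(manifest$locus_id, sample_ids))
  for (s in sample_ids) {
    col <- rep("NC", nrow(manifest))
    raw <- d[[s]][idx[!missing_locus]]
    bad <- !(raw %in% c(.GENO_LEVELS, "BA", "./.", ""))
    if (any(bad)) {
      stop(sprintf("unknown genotype token '%s' at locus %s, sample %s",
                   raw[bad][1], d$locus_id[idx[!missing_locus]][bad][1], s),
           call. = FALSE)
    }
    col[!missing_locus] <- normalize_calls(raw)
    calls[, s] <- col
  }
  new_karyo_genotypes(manifest, calls,
                      n_missing = rep(sum(missing_locus), length(sample_ids)))
}

#' Write a genotype table (wide TSV)
#'
#' Inverse of [read_genotype_table()]: one row per manifest locus, one
#' column per sample. A write/reload round trip reproduces calls exactly.
#'
#' @param genotypes a `karyo_genotypes`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(genotypes, path) {
  d <- data.frame(locus_id = genotypes$manifest$locus_id,
                  genotypes$calls, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a GT-only VCF
#'
#' Alternate reader for interoperability with sequencing pipelines: diploid
#' GT fields map `0/0` to `AA`, `0/1` (or `1/0`) to `AB`, `1/1` to `BB` and
#' `./.` to `NC`; phased separators (`|`) are accepted and ignored.
#' Multi-allelic records are skipped with a warning. Records are matched to
#' the manifest by (chromosome, position); unmatched records are skipped.
#'
#' @param path path to an uncompressed VCF file.
#' @param manifest a `karyo_manifest`.
#' @return a `karyo_genotypes`.
#' @export
read_genotypes_vcf <- function(path, manifest) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("no #CHROM header line in VCF", call. = FALSE)
  cols <- strsplit(sub("^#", "", lines[hdr[1]]), "\t")[[1]]
  sample_ids <- cols[-(1:9)]
  body <- lines[-seq_len(hdr[1])]
  body <- body[!startsWith(body, "#")]
  calls <- matrix("NC", nrow(manifest), length(sample_ids),
                  dimnames = list(manifest$locus_id, sample_ids))
  n_multi <- 0L
  key <- paste(manifest$chromosome, manifest$position_bp)
  for (ln in body) {
    f <- strsplit(ln, "\t")[[1]]
    if (grepl(",", f[5], fixed = TRUE)) { n_multi <- n_multi + 1L; next }
    i <- match(paste(sub("^chr", "", f[1]), f[2]), key)
    if (is.na(i)) next
    gt <- sub(":.*$", "", f[-(1:9)])
    gt <- gsub("|", "/", gt, fixed = TRUE)
    g <- rep("NC", length(gt))
    g[gt == "0/0"] <- "AA"
    g[gt %in% c("0/1", "1/0")] <- "AB"
    g[gt == "1/1"] <- "BB"
    calls[i, ] <- g
  }
  if (n_multi > 0L) {
    warning(sprintf("skipped %d multi-allelic VCF record(s)", n_multi),
            call. = FALSE)
  }
  new_karyo_genotypes(manifest, calls)
}

# Subset one sample's call vector.
sample_calls <- function(genotypes, sample_id) {
  if (!sample_id %in% colnames(genotypes$calls)) {
    stop("unknown sample: ", sample_id, call. = FALSE)
  }
  genotypes$calls[, sample_id]
}
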