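#' @keywords internal
"_PACKAGE"

# Canonical genotype vocabulary. Calls are unphased, unordered allele pairs
# over the two array design alleles A and B, plus NC (no call). "BA" and the
# VCF missing token "./." are accepted on input and normalized here.

.GENO_LEVELS <- c("AA", "AB", "BB", "NC")

#' Normalize raw genotype tokens to canonical calls
#'
#' Accepts `AA`, `AB`, `BA`, `BB`, `NC` and the VCF-style missing token
#' `./.`; `BA` is canonicalized to `AB` (calls are unordered pairs) and
#' `./.` to `NC`.
#'
#' @param x character vector of raw tokens.
#' @return character vector over `AA`, `AB`, `BB`, `NC`.
#' @examples
#' normalize_calls(c("BA", "./.", "AA"))
#' @export
normalize_calls <- function(x) {
  x <- as.character(x)
  x[x == "BA"] <- "AB"
  x[x == "./." | is.na(x) | x == ""] <- "NC"
  bad <- !(x %in% .GENO_LEVELS)
  if (any(bad)) {
    stop("unknown genotype token(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  x
}

# TRUE where the call carries the given allele ("A" or "B"); NC carries none.
call_contains <- function(calls, allele) {
  if (allele == "A") calls %in% c("AA", "AB") else calls %in% c("AB", "BB")
}

# Homozygote for a given allele.
call_hom <- function(calls, allele) {
  calls == paste0(allele, allele)
}

other_allele <- function(allele) ifelse(allele == "A", "B", "A")

other_hap <- function(hap) ifelse(hap == "H1", "H2", "H1")

#' Call rate of a genotype vector
#'
#' Fraction of non-NC calls, optionally restricted to a subset of loci.
#'
#' @param calls character vector of canonical calls.
#' @param keep optional logical vector selecting the loci to count.
#' @return numeric scalar in \[0, 1\]; `NA` if no loci are counted.
#' @export
call_rate <- function(calls, keep = NULL) {
  if (!is.null(keep)) calls <- calls[keep]
  if (length(calls) == 0L) return(NA_real_)
  mean(calls != "NC")
}
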