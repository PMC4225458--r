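# End-to-end orchestration: QC -> phase -> HMM segmentation -> aneuploidy
# and IBD screening -> diagnosis. Deterministic given inputs and
# parameters.

#' Run a complete karyomapping case
#'
#' @param genotypes a `karyo_genotypes` (or path handling via
#'   [read_case_dir()]).
#' @param config a `karyo_case_config`.
#' @param params an [hmm_params()] list; the per-sample allele-dropout
#'   rate estimated from obligate-heterozygous loci overrides `p_ado`
#'   per embryo.
#' @param call_rate_min QC exclusion threshold (default 0.60).
#' @return a `karyo_case_result` list: `qc`, `ado`, `phase_map`,
#'   `evidence`, `blocks`, `crossovers`, `chrom_status`, `ibd_regions`,
#'   `diagnoses`, `embryo_sex`, `parameters`, `log`.
#' @export
run_case <- function(genotypes, config, params = hmm_params(),
                     call_rate_min = 0.60) {
  m <- genotypes$manifest
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))

  for (dl in config$disease_loci) {
    if (!dl$chromosome %in% m$chromosome) {
      stop(sprintf("disease locus %s: chromosome %s not in manifest",
                   dl$gene_name, dl$chromosome), call. = FALSE)
    }
  }
  missing_samples <- setdiff(
    c(config$father, config$mother, config$reference, config$embryos),
    colnames(genotypes$calls))
  if (length(missing_samples)) {
    stop("samples missing from genotype data: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }

  qc <- do.call(rbind, lapply(
    c(config$father, config$mother, config$reference, config$embryos),
    function(s) qc_sample(sample_calls(genotypes, s), m, s,
                          threshold = call_rate_min)))
  for (s in qc$sample_id[qc$excluded]) {
    say("sample %s excluded: call rate %.3f < %.2f", s,
        qc$call_rate[qc$sample_id == s], call_rate_min)
  }

  phase_map <- build_phase_map(genotypes, config)
  say("informative loci: %d paternal, %d maternal; %d usable; %d reference-inconsistent",
      sum(phase_map$class == "paternal_informative"),
      sum(phase_map$class == "maternal_informative"),
      sum(phase_map$usable), sum(phase_map$ref_inconsistent))

  active <- config$embryos[!config$embryos %in%
                             qc$sample_id[qc$excluded]]
  cfg_active <- config
  cfg_active$embryos <- active
  # ADO is measurable only where the embryo is an obligate diploid
  # heterozygote: autosomal loci (a male embryo's X is hemizygous)
  oblig <- which(phase_map$class == "obligate_heterozygous" &
                   !phase_map$chromosome %in% c("X", "Y"))

  pt <- if (length(active)) build_phase_table(genotypes, cfg_active,
                                              phase_map)
        else list(evidence = empty_evidence(), embryo_sex = config$embryo_sex)
  evidence <- pt$evidence

  ado <- lapply(stats::setNames(active, active), function(emb) {
    estimate_ado_rate(sample_calls(genotypes, emb), oblig,
                      fallback = params$p_ado)
  })
  for (emb in names(ado)) {
    if (ado[[emb]]$warning) {
      say("embryo %s: too few obligate-het loci (%d); ADO fallback %.2f",
          emb, ado[[emb]]$n_called, params$p_ado)
    }
  }

  blocks_list <- list(); xo_list <- list()
  for (emb in active) {
    p_emb <- params
    # clamp: emissions must stay finite even for degenerate estimates
    p_emb$p_ado <- min(ado[[emb]]$rate, 0.9)
    for (par in c("paternal", "maternal")) {
      for (ch in setdiff(unique(m$chromosome), "Y")) {
        ev <- evidence[evidence$embryo == emb & evidence$parent == par &
                         evidence$chromosome == ch, , drop = FALSE]
        if (nrow(ev) == 0L) next
        hmm <- run_hmm(ev$supported, ev$strength, ev$position_bp, p_emb)
        bl <- segment_haploblocks(hmm$path, ev$supported, ev$strength,
                                  ev$position_bp, p_emb)
        if (nrow(bl) == 0L) next
        bl <- cbind(embryo = emb, parent = par, chromosome = ch, bl,
                    stringsAsFactors = FALSE)
        blocks_list[[length(blocks_list) + 1L]] <- bl
        xo <- call_crossovers(bl, ev)
        if (nrow(xo)) {
          xo_list[[length(xo_list) + 1L]] <-
            cbind(embryo = emb, parent = par, chromosome = ch, xo,
                  stringsAsFactors = FALSE)
        }
      }
    }
  }
  blocks <- rbind_or_empty(blocks_list, empty_case_blocks())
  crossovers <- rbind_or_empty(xo_list, empty_case_crossovers())
  crossovers <- detect_common_crossovers(crossovers, blocks,
                                         config$reference_relation)

  chrom_status <- if (length(active)) {
    chromosome_status(genotypes, cfg_active, phase_map, evidence)
  } else {
    data.frame(embryo = character(), chromosome = character(),
               status = character(), region_start = numeric(),
               region_end = numeric(), stringsAsFactors = FALSE)
  }
  ibd <- detect_consanguineous_regions(
    sample_calls(genotypes, config$father),
    sample_calls(genotypes, config$mother), m)
  if (nrow(ibd)) {
    say("consanguinity: %d IBD region(s) detected", nrow(ibd))
  }

  result <- list(qc = qc, ado = ado, phase_map = phase_map,
                 evidence = evidence, blocks = blocks,
                 crossovers = crossovers, chrom_status = chrom_status,
                 ibd_regions = ibd,
                 embryo_sex = pt$embryo_sex %||% config$embryo_sex,
                 parameters = list(e_key = params$e_key,
                                   p_ado_default = params$p_ado,
                                   cM_per_Mb = params$cM_per_Mb,
                                   min_block_keys = params$min_block_keys,
                                   call_rate_min = call_rate_min))
  result$diagnoses <- diagnose_case(result, config)
  result$log <- log
  class(result) <- "karyo_case_result"
  result
}

empty_evidence <- function() {
  data.frame(embryo = character(), parent = character(),
             chromosome = character(), position_bp = integer(),
             locus_idx = integer(), supported = character(),
             strength = character(), anomaly = logical(),
             stringsAsFactors = FALSE)
}

empty_case_blocks <- function() {
  cbind(data.frame(embryo = character(), parent = character(),
                   chromosome = character(), stringsAsFactors = FALSE),
        empty_blocks())
}

empty_case_crossovers <- function() {
  data.frame(embryo = character(), parent = character(),
             chromosome = character(), left_bp = numeric(),
             right_bp = numeric(), from_hap = character(),
             to_hap = character(), stringsAsFactors = FALSE)
}

rbind_or_empty <- function(lst, empty) {
  if (!length(lst)) return(empty)
  out <- do.call(rbind, c(lst, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Load a case directory and run it
#'
#' Expects `manifest.tsv`, `genotypes.tsv` (or `genotypes.vcf`) and
#' `case.json` as written by [simulate_case()] or assembled by hand.
#'
#' @param case_dir directory with the case inputs.
#' @param out_dir optional output directory; when given, results are
#'   written via [write_case_outputs()].
#' @param ... passed to [run_case()].
#' @return a `karyo_case_result`, invisibly when writing.
#' @export
run_case_dir <- function(case_dir, out_dir = NULL, ...) {
  manifest <- read_snp_manifest(file.path(case_dir, "manifest.tsv"))
  gt_path <- file.path(case_dir, "genotypes.tsv")
  genotypes <- if (file.exists(gt_path)) {
    read_genotype_table(gt_path, manifest)
  } else {
    read_genotypes_vcf(file.path(case_dir, "genotypes.vcf"), manifest)
  }
  config <- read_case_config(file.path(case_dir, "case.json"))
  result <- run_case(genotypes, config, ...)
  if (!is.null(out_dir)) {
    write_case_outputs(result, out_dir)
    return(invisible(result))
  }
  result
}

#' Simulate a case, analyze it, and compare calls to the simulated truth
#'
#' @param config a [sim_config()].
#' @param params an [hmm_params()] list.
#' @return list with `concordance` (fraction of embryo disease-status
#'   calls matching truth, no_result counted discordant), `per_embryo`
#'   comparison table, the `result` and the `sim`.
#' @export
validate_case <- function(config, params = hmm_params()) {
  sim <- simulate_family(config)
  result <- run_case(sim$genotypes, sim$case_config, params)
  rows <- list()
  for (d in result$diagnoses) {
    emb <- d$embryo
    for (g in names(d$loci)) {
      truth <- sim$truth$embryos[[emb]]$disease_status[[g]]
      called <- d$loci[[g]]$status
      rows[[length(rows) + 1L]] <- data.frame(
        embryo = emb, gene = g, truth = truth, called = called,
        concordant = identical(truth, called) && called != "no_result",
        stringsAsFactors = FALSE)
    }
    if (!length(d$loci)) {
      rows[[length(rows) + 1L]] <- data.frame(
        embryo = emb, gene = NA_character_, truth = NA_character_,
        called = d$status, concordant = NA, stringsAsFactors = FALSE)
    }
  }
  per_embryo <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  conc <- if (all(is.na(per_embryo$concordant))) NA_real_
          else mean(per_embryo$concordant, na.rm = TRUE)
  list(concordance = conc, per_embryo = per_embryo, result = result,
       sim = sim)
}
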