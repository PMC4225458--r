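# Shared fixtures: tiny manifests and genotype objects built in code, and
# an independent brute-force HMM oracle used to check the dynamic program.

tiny_manifest <- function(n = 10L, chrom = "11", spacing = 1e5,
                          start = 1e5) {
  snp_manifest(sprintf("rs%03d", seq_len(n)),
               rep(chrom, n),
               start + spacing * (seq_len(n) - 1L))
}

make_genotypes <- function(manifest, ...) {
  cols <- list(...)
  calls <- do.call(cbind, lapply(cols, function(x) {
    normalize_calls(rep_len(x, nrow(manifest)))
  }))
  colnames(calls) <- names(cols)
  karyomapr:::new_karyo_genotypes(manifest, calls)
}

# Brute-force most-probable-path oracle: enumerates every state path and
# scores it with the generative model written out from first principles
# (independently of the package's Viterbi implementation).
brute_force_path <- function(supported, strength, positions_bp,
                             e_key = 0.005, p_ado = 0.15,
                             cM_per_Mb = 1.0) {
  n <- length(supported)
  emis <- function(state, i) {
    # unique allele sits on the supported hap for key calls, on the
    # complement for non-key calls
    u_on <- if (strength[i] == "key") supported[i] else {
      setdiff(c("H1", "H2"), supported[i])
    }
    key_obs <- strength[i] == "key"
    if (state == u_on) {
      if (key_obs) (1 - p_ado) * (1 - e_key) else p_ado * (1 - e_key) + e_key
    } else {
      if (key_obs) e_key else 1 - e_key
    }
  }
  d <- diff(positions_bp) * cM_per_Mb * 1e-8
  theta <- 0.5 * (1 - exp(-2 * d))
  best <- -Inf; best_path <- NULL; all_ll <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    path <- ifelse(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0, "H2", "H1")
    ll <- log(0.5) + log(emis(path[1], 1L))
    if (n > 1) for (t in 2:n) {
      tr <- if (path[t] == path[t - 1]) 1 - theta[t - 1] else theta[t - 1]
      ll <- ll + log(tr) + log(emis(path[t], t))
    }
    all_ll[mask + 1L] <- ll
    if (ll > best + 1e-12) { best <- ll; best_path <- path }
  }
  m <- max(all_ll)
  list(path = best_path, path_loglik = best,
       total_loglik = m + log(sum(exp(all_ll - m))))
}

# Score one path under the oracle's generative model.
score_path <- function(path, supported, strength, positions_bp,
                       e_key = 0.005, p_ado = 0.15, cM_per_Mb = 1.0) {
  n <- length(path)
  emis <- function(state, i) {
    u_on <- if (strength[i] == "key") supported[i] else {
      setdiff(c("H1", "H2"), supported[i])
    }
    key_obs <- strength[i] == "key"
    if (state == u_on) {
      if (key_obs) (1 - p_ado) * (1 - e_key) else p_ado * (1 - e_key) + e_key
    } else {
      if (key_obs) e_key else 1 - e_key
    }
  }
  d <- diff(positions_bp) * cM_per_Mb * 1e-8
  theta <- 0.5 * (1 - exp(-2 * d))
  ll <- log(0.5) + log(emis(path[1], 1L))
  if (n > 1) for (t in 2:n) {
    tr <- if (path[t] == path[t - 1]) 1 - theta[t - 1] else theta[t - 1]
    ll <- ll + log(tr) + log(emis(path[t], t))
  }
  ll
}

# Small simulated AR sibling case used by several test files.
small_ar_case <- function(seed = 11, n_embryos = 3L, length_bp = 4e7,
                          p_ado = 0.15, p_error = 0.005, p_nocall = 0.10) {
  sim_config(
    chromosomes = data.frame(chromosome = "11", length_bp = length_bp),
    n_embryos = n_embryos, seed = seed,
    p_ado = p_ado, p_error = p_error, p_nocall = p_nocall,
    disease_loci = list(disease_locus("HBB", "11", length_bp / 2,
                                      length_bp / 2 + 5e4,
                                      "autosomal_recessive")))
}
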