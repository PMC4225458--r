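# Two-state hidden Markov segmentation of phased evidence into haploblocks.
#
# Hidden states are the two haplotypes {H1, H2} of one parent along one
# chromosome of one embryo. Observations are the key/non-key phased calls.
# Transitions follow the Haldane map function under a uniform cM/Mb rate;
# emissions encode that key evidence is wrong only through genotyping error
# while non-key evidence can also arise from allele dropout.

#' HMM parameters
#'
#' @param e_key probability a key call supports the wrong haplotype
#'   (residual genotyping error), default 0.005.
#' @param p_ado per-allele dropout probability; estimated per sample from
#'   obligate-heterozygous loci, fallback default 0.15.
#' @param cM_per_Mb uniform genetic-map rate (centimorgan per megabase),
#'   default 1.
#' @param min_block_keys minimum key-call support to report a haploblock,
#'   default 2.
#' @return a `hmm_params` list.
#' @export
hmm_params <- function(e_key = 0.005, p_ado = 0.15, cM_per_Mb = 1.0,
                       min_block_keys = 2L) {
  stopifnot(e_key >= 0, e_key < 0.5, p_ado >= 0, p_ado < 1, cM_per_Mb > 0,
            min_block_keys >= 0)
  structure(list(e_key = e_key, p_ado = p_ado, cM_per_Mb = cM_per_Mb,
                 min_block_keys = as.integer(min_block_keys)),
            class = "hmm_params")
}

#' Estimate the allele-dropout rate of a single-cell sample
#'
#' At obligate-heterozygous loci (parents are opposite homozygotes) any
#' euploid embryo must be AB, so a homozygous embryo call there means one
#' allele dropped out. The rate is the homozygous fraction of the called
#' obligate-heterozygous loci.
#'
#' @param embryo_calls canonical embryo call vector (manifest order).
#' @param obligate_idx indices of obligate-heterozygous loci.
#' @param min_called minimum called loci required (default 50); below
#'   this the fallback is returned with `warning = TRUE`.
#' @param fallback rate used when too few loci are called (default 0.15).
#' @return list with `rate`, `n_called`, `warning`.
#' @export
estimate_ado_rate <- function(embryo_calls, obligate_idx, min_called = 50L,
                              fallback = 0.15) {
  calls <- embryo_calls[obligate_idx]
  called <- calls[calls != "NC"]
  if (length(called) < min_called) {
    return(list(rate = fallback, n_called = length(called), warning = TRUE))
  }
  list(rate = mean(called %in% c("AA", "BB")), n_called = length(called),
       warning = FALSE)
}

#' Haldane transition probability between adjacent loci
#'
#' Probability that the transmitted parental haplotype switches between two
#' loci `distance_bp` apart, under a uniform map:
#' theta = (1 - exp(-2 d)) / 2 with d = distance_bp * cM_per_Mb * 1e-8
#' Morgans. Monotone in distance, capped at 1/2.
#'
#' @param distance_bp non-negative physical distance in bp (vectorized).
#' @param params an [hmm_params()] list.
#' @return recombination fraction(s) in \[0, 0.5\].
#' @export
transition_probability <- function(distance_bp, params = hmm_params()) {
  if (any(distance_bp < 0)) stop("distance_bp must be >= 0", call. = FALSE)
  d <- distance_bp * params$cM_per_Mb * 1e-8
  0.5 * (1 - exp(-2 * d))
}

#' Crude double-recombination probability over an interval
#'
#' Square of the interval's recombination fraction under the small-distance
#' linear conversion r = distance_bp * cM_per_Mb * 1e-8, i.e. two
#' independent recombinations between the same flanking markers. For a
#' ~415-kb interval at 1 cM/Mb this is 1.72e-5.
#'
#' @inheritParams transition_probability
#' @return probability (vectorized).
#' @export
double_recombination_probability <- function(distance_bp,
                                             params = hmm_params()) {
  if (any(distance_bp < 0)) stop("distance_bp must be >= 0", call. = FALSE)
  (distance_bp * params$cM_per_Mb * 1e-8)^2
}

# Per-locus emission log-likelihoods for states (H1, H2).
# A key call supporting hap L: the unique allele (on L) was observed;
# from state L that happens with (1-p_ado)(1-e_key), from the other state
# only through error, e_key. A non-key call supporting the complement of
# L: from the complement state with 1-e_key, from state L through dropout
# or error, p_ado(1-e_key)+e_key. Each state's two outcome probabilities
# sum to one, so this is a proper emission distribution over the two
# observable evidence outcomes.
emission_loglik <- function(supported, strength, params) {
  e <- params$e_key; a <- params$p_ado
  is_key <- strength == "key"
  # state carrying the unique allele = supported hap for key calls,
  # the complement for non-key calls
  lu_key <- log((1 - a) * (1 - e))     # key obs from unique-carrier state
  lu_non <- log(a * (1 - e) + e)       # non-key obs from unique-carrier state
  lo_key <- log(e)                     # key obs from other state
  lo_non <- log(1 - e)                 # non-key obs from other state
  n <- length(supported)
  ll <- matrix(0, n, 2L)
  s1 <- supported == "H1"
  # key & supports H1  -> unique on H1: ll = (lu_key, lo_key)
  # key & supports H2  -> unique on H2: ll = (lo_key, lu_key)
  # nonkey & supports H1 -> unique on H2: ll = (lo_non, lu_non)
  # nonkey & supports H2 -> unique on H1: ll = (lu_non, lo_non)
  ll[is_key & s1, ] <- rep(c(lu_key, lo_key), each = sum(is_key & s1))
  ll[is_key & !s1, ] <- rep(c(lo_key, lu_key), each = sum(is_key & !s1))
  ll[!is_key & s1, ] <- rep(c(lo_non, lu_non), each = sum(!is_key & s1))
  ll[!is_key & !s1, ] <- rep(c(lu_non, lo_non), each = sum(!is_key & !s1))
  ll
}

#' Decode one evidence track with the two-state HMM
#'
#' Most-probable state path (dynamic programming over all paths, ties
#' broken toward the previous state so no spurious transition is
#' introduced) plus per-locus posteriors by forward-backward. Initial
#' distribution is uniform (1/2, 1/2).
#'
#' @param supported character vector (`H1`/`H2`) of supported haplotypes.
#' @param strength character vector (`key`/`nonkey`).
#' @param positions_bp strictly increasing physical positions.
#' @param params an [hmm_params()] list (use the sample's estimated
#'   `p_ado`).
#' @return list with `path` (`H1`/`H2` per locus), `posterior` (n x 2
#'   matrix, rows sum to 1) and `loglik`.
#' @export
run_hmm <- function(supported, strength, positions_bp,
                    params = hmm_params()) {
  n <- length(supported)
  stopifnot(n >= 1L, length(strength) == n, length(positions_bp) == n)
  if (n > 1L && any(diff(positions_bp) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  em <- emission_loglik(supported, strength, params)
  theta <- if (n > 1L) {
    transition_probability(diff(positions_bp), params)
  } else numeric(0)
  lstay <- log(1 - theta); lswitch <- log(theta)

  # Viterbi in log space; back-pointers prefer staying on ties.
  delta <- matrix(-Inf, n, 2L)
  psi <- matrix(1L, n, 2L)
  delta[1L, ] <- log(0.5) + em[1L, ]
  if (n > 1L) {
    for (t in 2:n) {
      for (s in 1:2) {
        from_same <- delta[t - 1L, s] + lstay[t - 1L]
        from_other <- delta[t - 1L, 3L - s] + lswitch[t - 1L]
        if (from_other > from_same) {
          delta[t, s] <- from_other + em[t, s]; psi[t, s] <- 3L - s
        } else {
          delta[t, s] <- from_same + em[t, s]; psi[t, s] <- s
        }
      }
    }
  }
  path <- integer(n)
  path[n] <- if (delta[n, 2L] > delta[n, 1L]) 2L else 1L
  if (n > 1L) for (t in (n - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]

  # forward-backward with per-step scaling
  fwd <- matrix(0, n, 2L); bwd <- matrix(0, n, 2L)
  scale <- numeric(n)
  f <- 0.5 * exp(em[1L, ] - max(em[1L, ]))
  scale[1L] <- sum(f); fwd[1L, ] <- f / scale[1L]
  loglik <- log(scale[1L]) + max(em[1L, ])
  if (n > 1L) {
    for (t in 2:n) {
      e_t <- exp(em[t, ] - max(em[t, ]))
      f <- c(fwd[t - 1L, 1L] * (1 - theta[t - 1L]) +
               fwd[t - 1L, 2L] * theta[t - 1L],
             fwd[t - 1L, 1L] * theta[t - 1L] +
               fwd[t - 1L, 2L] * (1 - theta[t - 1L])) * e_t
      scale[t] <- sum(f); fwd[t, ] <- f / scale[t]
      loglik <- loglik + log(scale[t]) + max(em[t, ])
    }
  }
  bwd[n, ] <- 1
  if (n > 1L) {
    for (t in (n - 1L):1L) {
      e_n <- exp(em[t + 1L, ] - max(em[t + 1L, ]))
      b <- bwd[t + 1L, ] * e_n
      bwd[t, ] <- c(b[1L] * (1 - theta[t]) + b[2L] * theta[t],
                    b[1L] * theta[t] + b[2L] * (1 - theta[t]))
      bwd[t, ] <- bwd[t, ] / sum(bwd[t, ])
    }
  }
  post <- fwd * bwd
  post <- post / rowSums(post)
  colnames(post) <- c("H1", "H2")
  list(path = c("H1", "H2")[path], posterior = post, loglik = loglik)
}

#' Segment a decoded state path into haploblocks
#'
#' Maximal runs of constant state become candidate blocks; blocks with
#' fewer than `min_block_keys` supporting key calls are merged into the
#' neighbor with stronger key support (maximality re-run after each
#' merge), which absorbs single-SNP artifacts. Block spans never extend
#' beyond their member loci, so informative-SNP deserts (for example
#' pericentromeric regions) stay uncovered rather than interpolated.
#'
#' @param path state path from [run_hmm()].
#' @param supported,strength the evidence vectors the path was decoded
#'   from.
#' @param positions_bp member-locus positions.
#' @param params an [hmm_params()] list (for `min_block_keys`).
#' @return data.frame of blocks: `start_bp`, `end_bp`, `haplotype`,
#'   `n_key`, `n_nonkey`, `n_conflicting`, `first_idx`, `last_idx`.
#' @export
segment_haploblocks <- function(path, supported, strength, positions_bp,
                                params = hmm_params()) {
  n <- length(path)
  if (n == 0L) return(empty_blocks())
  state <- path
  repeat {
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- length(r$values)
    n_key <- vapply(seq_len(k), function(b) {
      i <- starts[b]:ends[b]
      sum(strength[i] == "key" & supported[i] == r$values[b])
    }, integer(1))
    weak <- which(n_key < params$min_block_keys)
    if (!length(weak) || k == 1L) break
    b <- weak[which.min(n_key[weak])]
    nb <- if (b == 1L) 2L
          else if (b == k) k - 1L
          else if (n_key[b + 1L] >= n_key[b - 1L]) b + 1L else b - 1L
    state[starts[b]:ends[b]] <- r$values[nb]
  }
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  blocks <- do.call(rbind, lapply(seq_len(k), function(b) {
    i <- starts[b]:ends[b]
    hap <- r$values[b]
    data.frame(
      start_bp = positions_bp[starts[b]], end_bp = positions_bp[ends[b]],
      haplotype = hap,
      n_key = sum(strength[i] == "key" & supported[i] == hap),
      n_nonkey = sum(strength[i] == "nonkey" & supported[i] == hap),
      n_conflicting = sum(supported[i] != hap),
      first_idx = starts[b], last_idx = ends[b],
      stringsAsFactors = FALSE
    )
  }))
  # a lone block below the reporting threshold is dropped, not invented
  blocks <- blocks[blocks$n_key >= params$min_block_keys |
                     nrow(blocks) > 1L, , drop = FALSE]
  rownames(blocks) <- NULL
  blocks
}

empty_blocks <- function() {
  data.frame(start_bp = numeric(), end_bp = numeric(),
             haplotype = character(), n_key = integer(),
             n_nonkey = integer(), n_conflicting = integer(),
             first_idx = integer(), last_idx = integer(),
             stringsAsFactors = FALSE)
}

#' Call crossovers between adjacent haploblocks
#'
#' One event per adjacent block pair on a track; the event interval runs
#' from the last member locus of the left block to the first member
#' locus of the right block. When the track's evidence is supplied, a
#' miscall-robust uncertainty interval (`key_left_bp`, `key_right_bp`)
#' is added: non-key calls are ADO-corruptible and cannot pin a
#' crossover, and a single key call can itself be an isolated miscall,
#' so the robust bounds run to the second supporting key call inward of
#' each flanking block (two consecutive keys confirm a haplotype, the
#' same logic as the two-key minimum for reporting a block).
#'
#' @param blocks ordered blocks for one (embryo, parent, chromosome)
#'   track, as returned by [segment_haploblocks()].
#' @param evidence optional evidence data.frame (`position_bp`,
#'   `supported`, `strength`) the blocks were segmented from.
#' @return data.frame of events: `left_bp`, `right_bp`, `from_hap`,
#'   `to_hap`, and with evidence `key_left_bp`, `key_right_bp`.
#' @export
call_crossovers <- function(blocks, evidence = NULL) {
  k <- nrow(blocks)
  if (k < 2L) {
    return(data.frame(left_bp = numeric(), right_bp = numeric(),
                      from_hap = character(), to_hap = character(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    left_bp = blocks$end_bp[-k], right_bp = blocks$start_bp[-1L],
    from_hap = blocks$haplotype[-k], to_hap = blocks$haplotype[-1L],
    stringsAsFactors = FALSE
  )
  if (!is.null(evidence)) {
    out$key_left_bp <- out$left_bp
    out$key_right_bp <- out$right_bp
    for (j in seq_len(k - 1L)) {
      kl <- evidence$position_bp[evidence$strength == "key" &
                                   evidence$supported == out$from_hap[j] &
                                   evidence$position_bp <= out$left_bp[j]]
      kr <- evidence$position_bp[evidence$strength == "key" &
                                   evidence$supported == out$to_hap[j] &
                                   evidence$position_bp >= out$right_bp[j]]
      kl <- sort(kl, decreasing = TRUE)
      kr <- sort(kr)
      if (length(kl) >= 2L) out$key_left_bp[j] <- kl[2L]
      else if (length(kl)) out$key_left_bp[j] <- kl[1L]
      if (length(kr) >= 2L) out$key_right_bp[j] <- kr[2L]
      else if (length(kr)) out$key_right_bp[j] <- kr[1L]
    }
  }
  out
}

#' Flag common (reference-origin) crossovers across embryos
#'
#' With a sibling reference the phase convention flips wherever the
#' reference itself recombined, so every embryo's karyomap shows an
#' apparent crossover at the same interval. Crossovers on the same parent
#' and chromosome whose intervals overlap in at least
#' `max(2, ceiling(0.75 * embryos with block coverage across the
#' interval))` embryos are flagged `is_common`. Grandparent-reference
#' cases are left untouched: there only genuine embryo crossovers are
#' identified.
#'
#' @param crossovers data.frame with columns `embryo`, `parent`,
#'   `chromosome`, `left_bp`, `right_bp`.
#' @param blocks data.frame of all haploblocks (for coverage), with
#'   columns `embryo`, `parent`, `chromosome`, `start_bp`, `end_bp`.
#' @param relation the case's reference relation.
#' @return `crossovers` with an `is_common` logical column.
#' @export
detect_common_crossovers <- function(crossovers, blocks,
                                     relation = "sibling") {
  crossovers$is_common <- rep(FALSE, nrow(crossovers))
  if (relation != "sibling" || nrow(crossovers) == 0L) return(crossovers)
  embryos <- unique(crossovers$embryo)
  if (length(embryos) < 2L) return(crossovers)
  for (i in seq_len(nrow(crossovers))) {
    x <- crossovers[i, ]
    same <- crossovers$parent == x$parent &
            crossovers$chromosome == x$chromosome &
            crossovers$left_bp <= x$right_bp &
            crossovers$right_bp >= x$left_bp
    n_hit <- length(unique(crossovers$embryo[same]))
    bl <- blocks[blocks$parent == x$parent &
                   blocks$chromosome == x$chromosome, , drop = FALSE]
    cov <- vapply(unique(bl$embryo), function(e) {
      be <- bl[bl$embryo == e, ]
      min(be$start_bp) <= x$left_bp && max(be$end_bp) >= x$right_bp
    }, logical(1))
    n_cov <- sum(cov)
    crossovers$is_common[i] <- n_hit >= max(2L, ceiling(0.75 * n_cov))
  }
  crossovers
}
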