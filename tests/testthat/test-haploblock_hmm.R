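# Map functions, ADO estimation, Viterbi/forward-backward, block
# segmentation, crossover calling and common-crossover flagging.

test_that("Haldane transition probability: closed form, monotone, capped", {
  p <- hmm_params()
  expect_identical(transition_probability(0, p), 0)
  expect_equal(transition_probability(1e6, p), 0.5 * (1 - exp(-0.02)))
  expect_equal(transition_probability(1e6, p), 0.009901, tolerance = 1e-4)
  d <- seq(0, 5e8, length.out = 50)
  th <- transition_probability(d, p)
  expect_true(all(diff(th) >= 0))
  expect_true(all(th <= 0.5))
  expect_equal(transition_probability(1e12, p), 0.5)
  expect_error(transition_probability(-1, p), ">= 0")
})

test_that("double-recombination probability reproduces the 415-kb figure", {
  expect_equal(double_recombination_probability(415000), 1.72e-5,
               tolerance = 5e-3)
  expect_identical(double_recombination_probability(0), 0)
  expect_equal(double_recombination_probability(1e6), 1e-4)
})

test_that("ADO rate estimation: direct count, zero, and fallback", {
  oblig <- 1:100
  calls <- rep("AB", 100)
  calls[1:10] <- "AA"
  expect_equal(estimate_ado_rate(calls, oblig)$rate, 0.10)
  expect_equal(estimate_ado_rate(rep("AB", 100), oblig)$rate, 0)
  r <- estimate_ado_rate(rep("NC", 100), oblig)
  expect_equal(r$rate, 0.15)
  expect_true(r$warning)
})

test_that("clean switch decodes one transition; isolated conflict is
           absorbed; single call is trivial", {
  pos <- 1e5 * (1:10)
  p <- hmm_params(p_ado = 0.15)
  h <- run_hmm(rep(c("H1", "H2"), each = 5), rep("key", 10), pos, p)
  expect_identical(h$path, rep(c("H1", "H2"), each = 5))

  supp <- rep("H1", 9); supp[5] <- "H2"
  h2 <- run_hmm(supp, rep("key", 9), 1e5 * (1:9), p)
  expect_identical(h2$path, rep("H1", 9))

  h3 <- run_hmm("H2", "key", 5e5, p)
  expect_identical(h3$path, "H2")
})

test_that("dynamic-programming path equals brute-force argmax on random
           instances (<= 12 loci)", {
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(2:12, 1)
    supported <- sample(c("H1", "H2"), n, TRUE)
    strength <- sample(c("key", "nonkey"), n, TRUE,
                       prob = c(0.6, 0.4))
    pos <- sort(sample.int(5e7, n))
    ado <- runif(1, 0.05, 0.3)
    p <- hmm_params(p_ado = ado)
    got <- run_hmm(supported, strength, pos, p)
    want <- brute_force_path(supported, strength, pos,
                             e_key = p$e_key, p_ado = ado)
    # the forward likelihood sums over all paths; the decoded path must
    # match the exhaustive argmax
    expect_equal(got$loglik, want$total_loglik, tolerance = 1e-8)
    expect_identical(got$path, want$path)
  }
})

test_that("posteriors are normalized and concentrate on the decoded path
           for clean evidence", {
  set.seed(7)
  n <- 200
  supp <- rep(c("H1", "H2"), each = n / 2)
  h <- run_hmm(supp, rep("key", n), sort(sample.int(1e8, n)), hmm_params())
  expect_true(all(abs(rowSums(h$posterior) - 1) < 1e-9))
  expect_gt(mean(h$posterior[cbind(seq_len(n),
                                   match(h$path, c("H1", "H2")))]), 0.95)
})

test_that("increasing e_key never increases the block count on fixed
           evidence", {
  set.seed(12)
  n <- 120
  supp <- rep("H1", n)
  supp[sample(n, 12)] <- "H2"
  pos <- sort(sample.int(6e7, n))
  counts <- vapply(c(0.001, 0.005, 0.02, 0.1), function(e) {
    p <- hmm_params(e_key = e)
    h <- run_hmm(supp, rep("key", n), pos, p)
    nrow(segment_haploblocks(h$path, supp, rep("key", n), pos, p))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("segmentation merges weak blocks and leaves deserts uncovered", {
  p <- hmm_params(min_block_keys = 2L)
  pos <- 1e5 * (1:10)
  path <- rep(c("H1", "H2"), each = 5)
  supp <- path; str <- rep("key", 10)
  b <- segment_haploblocks(path, supp, str, pos, p)
  expect_identical(nrow(b), 2L)
  expect_identical(b$start_bp, c(1e5, 6e5))
  expect_identical(b$end_bp, c(5e5, 10e5))

  # middle block with a single key supporter is merged away
  path2 <- c(rep("H1", 4), "H2", rep("H1", 5))
  b2 <- segment_haploblocks(path2, path2, str, pos, p)
  expect_identical(nrow(b2), 1L)
  expect_identical(b2$haplotype, "H1")

  expect_identical(nrow(segment_haploblocks(character(0), character(0),
                                            character(0), numeric(0), p)),
                   0L)
})

test_that("k blocks yield k-1 crossover events with adjacent-locus
           intervals", {
  b <- data.frame(start_bp = c(1, 11, 21) * 1e6,
                  end_bp = c(10, 20, 30) * 1e6,
                  haplotype = c("H1", "H2", "H1"),
                  stringsAsFactors = FALSE)
  xo <- call_crossovers(b)
  expect_identical(nrow(xo), 2L)
  expect_identical(xo$left_bp, c(10e6, 20e6))
  expect_identical(xo$right_bp, c(11e6, 21e6))
  expect_identical(nrow(call_crossovers(b[1, ])), 0L)
})

test_that("common crossovers are flagged only for sibling references and
           shared intervals", {
  mk_xo <- function(embryo, left, right) {
    data.frame(embryo = embryo, parent = "paternal", chromosome = "1",
               left_bp = left, right_bp = right, from_hap = "H1",
               to_hap = "H2", stringsAsFactors = FALSE)
  }
  blocks <- do.call(rbind, lapply(sprintf("e%d", 1:4), function(e) {
    data.frame(embryo = e, parent = "paternal", chromosome = "1",
               start_bp = 1, end_bp = 6e7, stringsAsFactors = FALSE)
  }))
  shared <- do.call(rbind, lapply(sprintf("e%d", 1:4), function(e) {
    mk_xo(e, 2.0e7, 2.1e7)
  }))
  private <- mk_xo("e1", 4.0e7, 4.1e7)
  xo <- rbind(shared, private)
  out <- detect_common_crossovers(xo, blocks, "sibling")
  expect_identical(out$is_common, c(rep(TRUE, 4), FALSE))
  out_gp <- detect_common_crossovers(xo, blocks, "paternal_grandparent")
  expect_false(any(out_gp$is_common))
})

test_that("simulated single-crossover meiosis is recovered inside the
           reported interval", {
  cfg <- small_ar_case(seed = 77, n_embryos = 2L, length_bp = 5e7)
  sim <- simulate_family(cfg)
  res <- run_case(sim$genotypes, sim$case_config)
  # check every true observable switch lands inside a reported interval
  found <- 0L; total <- 0L
  for (emb in sim$case_config$embryos) {
    for (par in c("paternal", "maternal")) {
      tr <- sim$truth$embryos[[emb]]$chrom[["11"]]
      ref <- sim$truth$reference$meioses[["11"]]
      true_xo <- sort(c(tr[[paste0(substr(par, 1, 8), "_xo")]],
                        ref[[paste0(substr(par, 1, 8), "_xo")]]))
      hap_e <- tr[[paste0(substr(par, 1, 8), "_hap")]]
      hap_r <- ref[[paste0(substr(par, 1, 8), "_hap")]]
      state <- ifelse(hap_e == hap_r, "H1", "H2")
      pos <- sim$manifest$position_bp
      xo <- res$crossovers[res$crossovers$embryo == emb &
                             res$crossovers$parent == par, ]
      for (x in true_xo) {
        lo_i <- which(pos < x); hi_i <- which(pos > x)
        if (!length(lo_i) || !length(hi_i)) next
        lo <- max(lo_i); hi <- min(hi_i)
        if (state[lo] == state[hi]) next  # cancelled by a paired switch
        total <- total + 1L
        found <- found + any(xo$left_bp <= x & xo$right_bp >= x)
      }
    }
  }
  expect_gt(total, 0L)
  expect_identical(found, total)
})
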