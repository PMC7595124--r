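# Two-state ancestry HMM: emission estimation, decoding, segmentation,
# exchange calling.

make_track <- function(n_a, n_b, chrom = "chr01", wsize = 1e4) {
  tibble::tibble(chrom = chrom,
                 start = (seq_along(n_a) - 1) * wsize,
                 end = seq_along(n_a) * wsize,
                 window = seq_along(n_a) - 1L,
                 n_A = n_a, n_B = n_b)
}

sample_track <- function(states, p_a, p_b, depth = 20, chrom = "chr01") {
  tot <- rpois(length(states), depth)
  p <- ifelse(states == 1, p_a, p_b)
  n_a <- rbinom(length(states), tot, p)
  make_track(n_a, tot - n_a, chrom = chrom)
}

test_that("emission estimates recover generative parameters", {
  set.seed(71)
  # pure chromosomes at p = 0.9 / 0.1
  tr_a <- sample_track(rep(1, 400), 0.9, 0.1, chrom = "chrA")
  tr_b <- sample_track(rep(2, 400), 0.9, 0.1, chrom = "chrB")
  track <- dplyr::bind_rows(tr_a, tr_b)
  part <- structure(list(assignment = c(chrA = "A", chrB = "B")),
                    class = "subgenome_partition")
  params <- estimate_emissions(track, part)
  n_occ <- sum((tr_a$n_A + tr_a$n_B)[1:300])
  expect_lt(abs(params$p_A - 0.9), 3 * sqrt(0.9 * 0.1 / n_occ))
  expect_lt(abs(params$p_B - 0.1), 3 * sqrt(0.9 * 0.1 / n_occ))
  # symmetric data: p_A + p_B ~ 1
  expect_lt(abs(params$p_A + params$p_B - 1), 0.05)

  expect_error(estimate_emissions(make_track(rep(0L, 10), rep(0L, 10)), part),
               class = "subgenomics_degenerate_error")
})

test_that("EM refinement recovers known parameters", {
  set.seed(72)
  errs <- vapply(1:10, function(s) {
    set.seed(s)
    states <- rep(c(1, 2), each = 150)
    tr <- dplyr::bind_rows(
      sample_track(states, 0.85, 0.12, chrom = "chrA"),
      sample_track(rev(states), 0.85, 0.12, chrom = "chrB"))
    part <- structure(list(assignment = c(chrA = "A", chrB = "B")),
                      class = "subgenome_partition")
    params <- estimate_emissions(tr, part, em = TRUE)
    abs(params$p_A - 0.85)
  }, numeric(1))
  expect_lt(mean(errs), 0.02)
})

test_that("decoding is exact: strong signal, uninformative limits, posteriors", {
  params <- new_hmm_params(0.9, 0.1)
  tr <- make_track(rep(20L, 15), rep(0L, 15))
  dec <- decode_ancestry(tr, params)
  expect_true(all(dec$state == "A"))
  expect_equal(dec$posterior_A + dec$posterior_B, rep(1, 15), tolerance = 1e-9)

  # p_A == p_B is rejected by the constructor; verify near-equal emissions
  # leave posteriors at the start distribution
  near <- structure(list(p_A = 0.5 + 1e-12, p_B = 0.5 - 1e-12,
                         switch_prob = 1e-3, start_probs = c(0.5, 0.5)),
                    class = "hmm_params")
  dec2 <- decode_ancestry(make_track(c(5L, 3L, 7L), c(4L, 6L, 2L)), near)
  expect_equal(dec2$posterior_A, rep(0.5, 3), tolerance = 1e-6)
})

test_that("Viterbi equals exhaustive enumeration on short instances", {
  set.seed(73)
  for (inst in 1:40) {
    n <- sample(2:9, 1)
    p_a <- runif(1, 0.6, 0.95)
    p_b <- runif(1, 0.05, 0.4)
    tau <- runif(1, 1e-4, 0.3)
    tot <- rpois(n, 8)
    n_a <- rbinom(n, tot, sample(c(p_a, p_b), n, replace = TRUE))
    params <- new_hmm_params(p_a, p_b, tau)
    le <- subgenomics:::emission_loglik(n_a, tot - n_a, params)
    got <- subgenomics:::hmm_viterbi(le, log(1 - tau), log(tau), log(c(0.5, 0.5)))
    want <- oracle_viterbi(le, log(1 - tau), log(tau), log(c(0.5, 0.5)))
    got_score <- sum(le[cbind(seq_len(n), got)]) + log(0.5) +
      sum(ifelse(diff(got) == 0, log(1 - tau), log(tau)))
    expect_equal(got_score, want$score, tolerance = 1e-9)
  }
})

test_that("forward-backward likelihood matches direct summation", {
  set.seed(74)
  params <- new_hmm_params(0.8, 0.2, 0.01)
  n <- 6
  tot <- rpois(n, 10)
  n_a <- rbinom(n, tot, 0.6)
  le <- subgenomics:::emission_loglik(n_a, tot - n_a, params)
  fb <- subgenomics:::hmm_forward_backward(le, log(0.99), log(0.01),
                                           log(c(0.5, 0.5)))
  # direct likelihood: sum over all 2^n paths
  grid <- as.matrix(expand.grid(rep(list(1:2), n)))
  liks <- apply(grid, 1, function(path) {
    s <- log(0.5) + le[1, path[1]]
    for (t in 2:n) {
      s <- s + (if (path[t] == path[t - 1]) log(0.99) else log(0.01)) +
        le[t, path[t]]
    }
    exp(s)
  })
  expect_equal(fb$loglik, log(sum(liks)), tolerance = 1e-9)
  expect_equal(rowSums(fb$posterior), rep(1, n), tolerance = 1e-9)
})

test_that("segmentation smooths short runs and tiles the chromosome", {
  params <- new_hmm_params(0.9, 0.1)
  # constant path -> single segment
  dec <- decode_ancestry(make_track(rep(10L, 12), rep(0L, 12)), params)
  seg <- segment_ancestry(dec)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start, 0)
  expect_equal(seg$end, 12e4)

  # alternating single-window path collapses to one segment at min_windows = 3
  dec_alt <- decode_ancestry(
    make_track(rep(c(20L, 0L), 6), rep(c(0L, 20L), 6)),
    new_hmm_params(0.9, 0.1, switch_prob = 0.49))
  expect_gt(length(rle(dec_alt$state)$lengths), 1)
  seg_alt <- segment_ancestry(dec_alt, min_windows = 3)
  expect_equal(nrow(seg_alt), 1)

  # adjacent segments always differ in state
  set.seed(75)
  dec_r <- decode_ancestry(
    make_track(rbinom(60, 20, rep(c(0.9, 0.1, 0.9), each = 20)),
               rbinom(60, 20, rep(c(0.1, 0.9, 0.1), each = 20))),
    params)
  seg_r <- segment_ancestry(dec_r)
  expect_true(all(diff(match(seg_r$state, c("A", "B"))) != 0))
})

test_that("lowering switch_prob never increases the segment count", {
  set.seed(76)
  tot <- rpois(80, 15)
  n_a <- rbinom(80, tot, rep(c(0.88, 0.12, 0.88, 0.12), each = 20))
  tr <- make_track(n_a, tot - n_a)
  n_seg <- vapply(c(0.2, 0.05, 1e-2, 1e-3, 1e-4, 1e-6), function(tau) {
    nrow(segment_ancestry(decode_ancestry(tr, new_hmm_params(0.9, 0.1, tau)),
                          min_windows = 1))
  }, numeric(1))
  expect_true(all(diff(n_seg) <= 0))
})

test_that("exchange calls match planted truth", {
  ex <- tibble::tibble(pair = 1, breakpoint_fraction = 0.2, reciprocal = TRUE)
  sim <- simulate_allotetraploid(seed = 77, n_pairs = 2,
                                 chromosome_length = 2e5, n_copies = 100,
                                 exchanges = ex)
  res <- assign_subgenomes(sim$genome, sim$homeolog_map, window_size = 1e4)
  params <- estimate_emissions(res$track, res$partition)
  segs <- segment_ancestry(decode_ancestry(res$track, params))
  calls <- call_exchanges(segs, res$partition, sim$homeolog_map)
  expect_equal(nrow(calls), 2)
  expect_true(all(calls$reciprocal))
  expect_true(all(calls$distal))
  # boundary within 2 windows of truth
  truth_iv <- sim$truth$exchange_intervals
  for (i in seq_len(nrow(calls))) {
    tr_start <- truth_iv$start[truth_iv$chromosome == calls$chrom[i]]
    expect_lt(abs(calls$start[i] - tr_start), 2 * 1e4 + 1)
  }

  # pure chromosomes: zero calls
  pure <- simulate_allotetraploid(seed = 78, n_pairs = 2,
                                  chromosome_length = 2e5, n_copies = 100)
  res_p <- assign_subgenomes(pure$genome, pure$homeolog_map, window_size = 1e4)
  params_p <- estimate_emissions(res_p$track, res_p$partition)
  calls_p <- call_exchanges(segment_ancestry(decode_ancestry(res_p$track, params_p)),
                            res_p$partition, pure$homeolog_map)
  expect_equal(nrow(calls_p), 0)
})

test_that("non-reciprocal exchanges are called one-sided", {
  ex <- tibble::tibble(pair = 1, breakpoint_fraction = 0.25, reciprocal = FALSE)
  sim <- simulate_allotetraploid(seed = 79, n_pairs = 2,
                                 chromosome_length = 2e5, n_copies = 100,
                                 exchanges = ex)
  res <- assign_subgenomes(sim$genome, sim$homeolog_map, window_size = 1e4)
  params <- estimate_emissions(res$track, res$partition)
  calls <- call_exchanges(segment_ancestry(decode_ancestry(res$track, params)),
                          res$partition, sim$homeolog_map)
  expect_equal(nrow(calls), 1)
  expect_false(calls$reciprocal[1])
  expect_equal(unname(res$partition$assignment[calls$chrom[1]]), "B")
})
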