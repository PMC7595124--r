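# Synthetic-data generator: construction, determinism, and statistical
# calibration against closed-form expectations.

test_that("simulate_ancestor builds sequences of the requested composition", {
  g <- simulate_ancestor(2, 1e5, gc_content = 0.5, seed = 7)
  expect_length(g, 2)
  expect_true(all(Biostrings::width(g) == 1e5))
  # A+T fraction within 3 binomial s.d. of 0.5
  at <- Biostrings::letterFrequency(g, c("A", "T"))
  at_frac <- rowSums(at) / 1e5
  expect_true(all(abs(at_frac - 0.5) < 3 * sqrt(0.25 / 1e5)))

  g_gc1 <- simulate_ancestor(1, 500, gc_content = 1, seed = 1)
  expect_match(as.character(g_gc1[[1]]), "^[GC]+$")

  expect_error(simulate_ancestor(1, -5, seed = 1), class = "subgenomics_input_error")
})

test_that("simulation is byte-identical for a fixed seed", {
  expect_identical(as.character(simulate_ancestor(2, 2e4, seed = 3)),
                   as.character(simulate_ancestor(2, 2e4, seed = 3)))
  g <- simulate_ancestor(1, 2e4, seed = 3)
  expect_identical(as.character(diverge(g, 1e-8, 5e6, seed = 9)),
                   as.character(diverge(g, 1e-8, 5e6, seed = 9)))
  s1 <- simulate_allotetraploid(seed = 11, n_pairs = 2,
                                chromosome_length = 3e4, n_copies = 10)
  s2 <- simulate_allotetraploid(seed = 11, n_pairs = 2,
                                chromosome_length = 3e4, n_copies = 10)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth$te_registry, s2$truth$te_registry)
})

test_that("diverge matches the Jukes-Cantor closed form", {
  g <- simulate_ancestor(1, 1e6, seed = 5)
  expect_identical(as.character(diverge(g, 1e-8, 0, seed = 1)),
                   as.character(g))
  # expected p = (3/4)(1 - exp(-4/3 * 1e-8 * 5e6)) = 0.0484
  mut <- diverge(g, 1e-8, 5e6, seed = 6)
  p_obs <- mean(strsplit(as.character(g[[1]]), "")[[1]] !=
                  strsplit(as.character(mut[[1]]), "")[[1]])
  p_exp <- 0.75 * (1 - exp(-4 / 3 * 1e-8 * 5e6))
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 1e6))
  # two seeds: different mutation sets, same expectation
  mut2 <- diverge(g, 1e-8, 5e6, seed = 7)
  expect_false(identical(as.character(mut), as.character(mut2)))
  p_obs2 <- mean(strsplit(as.character(g[[1]]), "")[[1]] !=
                   strsplit(as.character(mut2[[1]]), "")[[1]])
  expect_lt(abs(p_obs2 - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 1e6))
  expect_error(diverge(g, 1e-6, 1e6, seed = 1),
               class = "subgenomics_saturation_error")
})

test_that("plant_te_burst registers every copy at its true coordinates", {
  g <- simulate_ancestor(2, 2e4, seed = 8)
  fam <- make_ltr_consensus(100, 50, seed = 8)

  none <- plant_te_burst(g, "f", fam$consensus, 0, 1, 2.1e-8)
  expect_identical(as.character(none$genome), as.character(g))
  expect_equal(nrow(none$registry), 0)

  res <- plant_te_burst(g, "f", fam$consensus, 30, burst_age = 0, rate = 2.1e-8,
                        target_chromosomes = "chr01", ltr_length = 50, seed = 9)
  expect_equal(nrow(res$registry), 30)
  expect_true(all(res$registry$chromosome == "chr01"))
  # age 0: every registered interval holds the untouched consensus
  seqs <- as.character(res$genome)
  for (i in seq_len(nrow(res$registry))) {
    expect_identical(substring(seqs[["chr01"]], res$registry$start[i] + 1,
                               res$registry$end[i]),
                     fam$consensus)
  }
  # length accounting
  expect_equal(nchar(seqs[["chr01"]]), 2e4 + 30 * nchar(fam$consensus))
  expect_equal(nchar(seqs[["chr02"]]), 2e4)
})

test_that("planted LTR-LTR divergence matches the 2*rate*age expectation", {
  rate <- 2.1e-8
  age <- 4
  pairs <- simulate_ltr_pairs(150, ltr_length = 400, age_my = age,
                              rate = rate, seed = 10)
  p_obs <- mean(purrr::map2_dbl(pairs$ltr_1, pairs$ltr_2, p_distance))
  p_exp <- 0.75 * (1 - exp(-4 / 3 * 2 * rate * age * 1e6))
  n_sites <- 150 * 400
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n_sites))
})

test_that("hybridize conserves sequence and swaps reciprocal tails", {
  ga <- simulate_ancestor(2, 1e4, seed = 12, prefix = "a")
  gb <- simulate_ancestor(2, 1e4, seed = 13, prefix = "b")

  plain <- hybridize(ga, gb)
  expect_equal(nrow(plain$truth$exchange_intervals), 0)
  expect_setequal(names(plain$genome),
                  sprintf("chr%02d", 1:4))
  expect_equal(unname(plain$truth$subgenome_of_chromosome[c("chr01", "chr02")]),
               c("A", "B"))

  ex <- tibble::tibble(pair = 1, breakpoint_fraction = 0.2, reciprocal = TRUE)
  hy <- hybridize(ga, gb, exchanges = ex)
  iv <- hy$truth$exchange_intervals
  expect_equal(nrow(iv), 2)
  expect_setequal(iv$donor, c("A", "B"))
  expect_equal(iv$end - iv$start, rep(2000, 2))  # equal-length partners
  # dosage conservation
  expect_equal(sum(Biostrings::width(hy$genome)),
               sum(Biostrings::width(ga)) + sum(Biostrings::width(gb)))
  # the A chromosome's tail now carries the B progenitor sequence
  a_tail <- substring(as.character(hy$genome[["chr01"]]), 8001, 10000)
  b_orig <- substring(as.character(gb[[1]]), 8001, 10000)
  expect_identical(a_tail, b_orig)

  expect_error(
    hybridize(ga, gb, exchanges = tibble::tibble(pair = 1,
                                                 breakpoint_fraction = 0.7)),
    class = "subgenomics_input_error")
  expect_error(hybridize(ga, simulate_ancestor(3, 1e3, seed = 1)),
               class = "subgenomics_input_error")
})

test_that("hybridize remaps TE registry coordinates through exchanges", {
  ga <- simulate_ancestor(1, 2e4, seed = 20, prefix = "a")
  gb <- simulate_ancestor(1, 2e4, seed = 21, prefix = "b")
  fam <- make_ltr_consensus(80, 40, seed = 20)
  pa <- plant_te_burst(ga, "fA", fam$consensus, 15, 0, 2.1e-8,
                       ltr_length = 40, seed = 22)
  ex <- tibble::tibble(pair = 1, breakpoint_fraction = 0.3, reciprocal = TRUE)
  hy <- hybridize(pa$genome, gb, exchanges = ex, registry_a = pa$registry)
  seqs <- as.character(hy$genome)
  reg <- hy$truth$te_registry
  # every fully contained copy is recoverable at its registered coordinates
  # (copies straddling a breakpoint keep their start-side chromosome and are
  # truncated by the swap, so they are excluded here)
  iv <- hy$truth$exchange_intervals
  bp_of <- setNames(iv$start, iv$chromosome)
  contained <- reg$end <= bp_of[reg$chromosome] |
    reg$start >= bp_of[reg$chromosome]
  hits <- vapply(which(contained), function(i) {
    substring(seqs[[reg$chromosome[i]]], reg$start[i] + 1, reg$end[i]) ==
      fam$consensus
  }, logical(1))
  expect_true(all(hits))
  expect_true(any(reg$chromosome == "chr02"))  # some copies moved with the tail
})

test_that("homeolog count simulation obeys its construction contracts", {
  hs <- simulate_homeolog_counts(n_pairs = 400, median_bias = 1.0,
                                 dispersion = 0, silent_fraction = 0,
                                 ratio_sdlog = 0, library_size = 1e6,
                                 seed = 30)
  # column sums approximate the library size (Poisson fluctuation)
  expect_true(all(abs(colSums(hs$counts) - 1e6) < 4 * sqrt(1e6)))
  cm <- cpm(hs$counts, hs$groups)
  rec <- pair_cpm_records(cm, hs$pairs)
  est <- pair_bias_stats(rec)$pooled$median_BA[1]
  expect_lt(abs(est - 1.0), 0.02)
})

test_that("admixed accession depths track the planted dosage", {
  markers <- tibble::tibble(chrom = "chr01", pos = seq(1000, 1e6, by = 1000))
  blocks <- tibble::tibble(chrom = "chr01", start = 0, end = 1e6, dosage_1 = 1)
  # diploid F1, no error, high depth: species-1 fraction -> 0.5
  f1 <- simulate_admixed_accession(2, markers, blocks, depth_mean = 400,
                                   error_rate = 0, seed = 40)
  frac <- sum(f1$depths$depth_1) / sum(f1$depths$depth_1 + f1$depths$depth_2)
  expect_lt(abs(frac - 0.5), 0.005)
  # triploid 2:1 genome-wide
  blocks3 <- dplyr::mutate(blocks, dosage_1 = 2)
  tri <- simulate_admixed_accession(3, markers, blocks3, depth_mean = 10,
                                    error_rate = 0, seed = 41)
  frac3 <- sum(tri$depths$depth_1) / sum(tri$depths$depth_1 + tri$depths$depth_2)
  expect_lt(abs(frac3 - 2 / 3), 0.01)
  # determinism
  tri2 <- simulate_admixed_accession(3, markers, blocks3, depth_mean = 10,
                                     error_rate = 0, seed = 41)
  expect_identical(tri$depths, tri2$depths)
  expect_error(
    simulate_admixed_accession(2, markers, dplyr::mutate(blocks, dosage_1 = 3)),
    class = "subgenomics_input_error")
})

test_that("statistical calibration holds across seeds", {
  # empirical p-distances within 3 binomial s.d. over 20 seeds
  rate <- 1e-8
  time <- 3e6
  p_exp <- 0.75 * (1 - exp(-4 / 3 * rate * time))
  g <- simulate_ancestor(1, 5e4, seed = 50)
  devs <- vapply(1:20, function(s) {
    mut <- diverge(g, rate, time, seed = s)
    p_distance(as.character(g[[1]]), as.character(mut[[1]]))
  }, numeric(1))
  tol <- 3 * sqrt(p_exp * (1 - p_exp) / 5e4)
  expect_true(all(abs(devs - p_exp) < tol))
})
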