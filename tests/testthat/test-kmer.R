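# k-mer counting, diagnostic selection, clustering, and density tracks.

test_that("count_kmers counts canonical k-mers exactly", {
  tab <- kmer_count_table(count_kmers(c(chr1 = "AAAA"), k = 3))
  expect_equal(tab, tibble::tibble(kmer = "AAA", chrom = "chr1", n = 2L))

  # palindromic k-mer counted once per position
  tab2 <- kmer_count_table(count_kmers(c(chr1 = "ACGT"), k = 4))
  expect_equal(tab2$n, 1L)
  expect_equal(tab2$kmer, "ACGT")

  # canonical form: a k-mer and its reverse complement pool together
  tab3 <- kmer_count_table(count_kmers(c(chr1 = "TTT", chr2 = "AAA"), k = 3))
  expect_equal(sort(tab3$chrom), c("chr1", "chr2"))
  expect_true(all(tab3$kmer == "AAA"))

  # windows containing N are skipped
  tab4 <- kmer_count_table(count_kmers(c(chr1 = "AANAA"), k = 2))
  expect_equal(sum(tab4$n), 2L)

  expect_error(count_kmers(character(0)), class = "subgenomics_input_error")
  expect_error(count_kmers(c(chr1 = "")), class = "subgenomics_input_error")
})

test_that("total counts equal the number of countable windows", {
  g <- simulate_ancestor(1, 1e4, seed = 60)
  for (k in c(5, 13)) {
    counts <- count_kmers(g, k = k)
    expect_equal(sum(counts$dt$n), 1e4 - k + 1)
  }
})

test_that("counting agrees with the brute-force substring oracle", {
  g <- as.character(simulate_ancestor(2, 3000, seed = 61))
  got <- dplyr::arrange(kmer_count_table(count_kmers(g, k = 7)),
                        kmer, chrom)
  want <- dplyr::arrange(oracle_count_kmers(g, 7), kmer, chrom)
  expect_equal(got, want)
})

test_that("diagnostic selection equals brute-force rule application", {
  sim <- small_tetraploid(seed = 62, n_copies = 40)
  counts <- count_kmers(sim$genome, k = 13)
  sel <- select_diagnostic_kmers(counts, sim$homeolog_map, min_total = 10,
                                 min_fold = 2)
  want <- oracle_select_kmers(kmer_count_table(counts),
                              counts$chromosome_lengths,
                              sim$homeolog_map, min_total = 10, min_fold = 2)
  expect_setequal(sel$kmer, want)
  expect_gt(nrow(sel), 0)
})

test_that("selection rejects balanced k-mers and respects thresholds", {
  # two pairs; k-mer X enriched in member_1 of both pairs, k-mer Y balanced
  seqs <- c(chr1 = strrep("ACGTTGCACCGGA", 12),  # 12 occurrences of X
            chr2 = paste0(strrep("ACGTTGCACCGGA", 2),
                          strrep("GATTACAGATTAC", 10)),
            chr3 = strrep("ACGTTGCACCGGA", 12),
            chr4 = strrep("GATTACAGATTAC", 12))
  map <- tibble::tibble(member_1 = c("chr1", "chr3"),
                        member_2 = c("chr2", "chr4"))
  counts <- count_kmers(seqs, k = 13)
  sel <- select_diagnostic_kmers(counts, map, min_total = 5, min_fold = 2,
                                 length_normalize = FALSE)
  expect_true("ACGTTGCACCGGA" %in% sel$kmer)

  # a k-mer with equal counts in both members of any pair is rejected
  seqs_eq <- c(chr1 = strrep("ACGTTGCACCGGA", 6),
               chr2 = strrep("ACGTTGCACCGGA", 6))
  sel_eq <- select_diagnostic_kmers(count_kmers(seqs_eq, k = 13),
                                    tibble::tibble(member_1 = "chr1",
                                                   member_2 = "chr2"),
                                    min_total = 5, min_fold = 2,
                                    length_normalize = FALSE)
  expect_false("ACGTTGCACCGGA" %in% sel_eq$kmer)

  expect_error(select_diagnostic_kmers(counts, tibble::tibble(member_1 = character(),
                                                              member_2 = character())),
               class = "subgenomics_input_error")
})

test_that("raising thresholds never enlarges the diagnostic set", {
  sim <- small_tetraploid(seed = 63, n_copies = 40)
  counts <- count_kmers(sim$genome, k = 13)
  base <- select_diagnostic_kmers(counts, sim$homeolog_map,
                                  min_total = 10, min_fold = 2)
  for (mt in c(20, 40)) {
    sel <- select_diagnostic_kmers(counts, sim$homeolog_map,
                                   min_total = mt, min_fold = 2)
    expect_true(all(sel$kmer %in% base$kmer))
  }
  for (mf in c(3, 5)) {
    sel <- select_diagnostic_kmers(counts, sim$homeolog_map,
                                   min_total = 10, min_fold = mf)
    expect_true(all(sel$kmer %in% base$kmer))
  }
})

test_that("clustering recovers the planted bipartition", {
  sim <- small_tetraploid(seed = 64)
  res <- assign_subgenomes(sim$genome, sim$homeolog_map)
  truth <- sim$truth$subgenome_of_chromosome
  expect_equal(res$partition$assignment[names(truth)], truth)
  expect_true(res$partition$consistent)
  expect_gt(res$partition$score, 0.5)

  # single pair: bipartition is the pair itself
  one <- simulate_allotetraploid(seed = 65, n_pairs = 1,
                                 chromosome_length = 6e4, n_copies = 40)
  res1 <- assign_subgenomes(one$genome, one$homeolog_map)
  expect_setequal(unname(res1$partition$assignment), c("A", "B"))
})

test_that("consistency filter removes shared-family and conflicted k-mers", {
  sim <- small_tetraploid(seed = 66)
  res <- assign_subgenomes(sim$genome, sim$homeolog_map)
  # no k-mer of the shared family survives
  shared_copies <- sim$truth$te_registry[sim$truth$te_registry$family == "famShared", ]
  seqs <- as.character(sim$genome)
  shared_kmers <- unique(unlist(lapply(seq_len(nrow(shared_copies)), function(i) {
    s <- substring(seqs[[shared_copies$chromosome[i]]],
                   shared_copies$start[i] + 1, shared_copies$end[i])
    km <- substring(s, 1:(nchar(s) - 12), 13:nchar(s))
    pmin(km, as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(km))))
  })))
  expect_length(intersect(res$kmers$kmer, shared_kmers), 0)
  expect_false(anyNA(res$kmers$label))

  # a k-mer favoring A on one pair and B on the other is removed at 0 conflicts
  fake <- res$kmers[1, ]
  fav <- attr(res$kmers, "favored")
  fav[1, 2] <- setdiff(c(sim$homeolog_map$member_1[2],
                         sim$homeolog_map$member_2[2]), fav[1, 2])[1]
  attr(res$kmers, "favored") <- fav
  filtered <- consistency_filter(res$kmers, res$partition, max_conflicts = 0)
  expect_false(fake$kmer %in% filtered$kmer)
  # identity on an already-consistent set
  again <- consistency_filter(filtered, res$partition, max_conflicts = 0)
  expect_equal(nrow(again), nrow(filtered))
})

test_that("density track conserves counts and separates subgenomes", {
  sim <- small_tetraploid(seed = 67)
  res <- assign_subgenomes(sim$genome, sim$homeolog_map, window_size = 5e3)
  track <- res$track
  # windows tile each chromosome
  by_chrom <- split(track, track$chrom)
  for (tr in by_chrom) {
    expect_equal(tr$start[-1], tr$end[-nrow(tr)])
  }
  # sum over windows equals chromosome totals restricted to the set
  ka <- res$kmers$code[res$kmers$label == "A"]
  dt <- res$counts$dt
  for (ch in unique(track$chrom)) {
    expect_equal(sum(track$n_A[track$chrom == ch]),
                 sum(dt$n[dt$chrom == ch & dt$code %in% ka]))
  }
  # planted A chromosomes have n_A-dominated windows (sign test)
  truth <- sim$truth$subgenome_of_chromosome
  a_chr <- names(truth)[truth == "A"]
  tr_a <- track[track$chrom %in% a_chr & (track$n_A + track$n_B) > 0, ]
  n_pos <- sum(tr_a$n_A > tr_a$n_B)
  n_tot <- sum(tr_a$n_A != tr_a$n_B)
  expect_lt(binom.test(n_pos, n_tot, alternative = "greater")$p.value, 0.01)

  # chromosome without any diagnostic occurrence: all-zero track
  blank <- density_track(c(chrX = strrep("A", 2e4)), res$kmers,
                         window_size = 5e3)
  expect_true(all(blank$n_A + blank$n_B == 0))
})

test_that("homeolog map io round-trips with exclusions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#excluded chr09", "chr01\tchr02", "chr03\tchr04"), path)
  map <- read_homeolog_map(path)
  expect_equal(map$member_1, c("chr01", "chr03"))
  expect_equal(attr(map, "excluded"), "chr09")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr01\tchr02", "chr01\tchr04"), path2)
  expect_error(read_homeolog_map(path2), class = "subgenomics_input_error")
})
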