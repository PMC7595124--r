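# Independent brute-force oracles used to freeze expected values. These
# deliberately avoid the package's internal code paths: counting by direct
# substring extraction, Viterbi by exhaustive path enumeration, codon
# accounting by explicit recursion.

# canonical k-mer counting by direct substring extraction
oracle_count_kmers <- function(seqs, k) {
  rows <- list()
  for (ch in names(seqs)) {
    s <- seqs[[ch]]
    n <- nchar(s)
    if (n < k) next
    kmers <- substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
    ok <- !grepl("[^ACGT]", kmers)
    kmers <- kmers[ok]
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
    canon <- pmin(kmers, rc)
    tab <- table(canon)
    rows[[ch]] <- tibble::tibble(kmer = names(tab), chrom = ch,
                                 n = as.integer(tab))
  }
  dplyr::bind_rows(rows)
}

# diagnostic-k-mer selection by direct application of the written rules
oracle_select_kmers <- function(counts_tbl, lengths, map, min_total, min_fold,
                                length_normalize = TRUE) {
  wide <- tidyr::pivot_wider(counts_tbl, names_from = "chrom",
                             values_from = "n", values_fill = 0L)
  for (ch in setdiff(names(lengths), names(wide))) wide[[ch]] <- 0L
  keep <- character(0)
  for (i in seq_len(nrow(wide))) {
    total <- sum(as.numeric(wide[i, names(lengths)]))
    if (total < min_total) next
    all_pass <- TRUE
    for (p in seq_len(nrow(map))) {
      m1 <- map$member_1[[p]]; m2 <- map$member_2[[p]]
      d1 <- (as.numeric(wide[i, m1]) + 1)
      d2 <- (as.numeric(wide[i, m2]) + 1)
      if (length_normalize) {
        d1 <- d1 / (lengths[[m1]] / 1e6)
        d2 <- d2 / (lengths[[m2]] / 1e6)
      }
      if (d1 == d2 || max(d1, d2) / min(d1, d2) < min_fold) {
        all_pass <- FALSE
        break
      }
    }
    if (all_pass) keep <- c(keep, wide$kmer[[i]])
  }
  sort(keep)
}

# exhaustive Viterbi: enumerate all S^n state paths
oracle_viterbi <- function(logemis, log_stay, log_switch, log_start) {
  n <- nrow(logemis)
  S <- ncol(logemis)
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))
  score <- apply(grid, 1, function(path) {
    s <- log_start[path[1]] + logemis[1, path[1]]
    if (n > 1) {
      for (t in 2:n) {
        s <- s + (if (path[t] == path[t - 1]) log_stay else log_switch) +
          logemis[t, path[t]]
      }
    }
    s
  })
  list(path = grid[which.max(score), ], score = max(score))
}

# per-codon NG86 accounting by explicit recursion over change orderings
oracle_codon_counts <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  syn_sites <- function(codon) {
    b <- strsplit(codon, "")[[1]]
    s <- 0
    for (pos in 1:3) {
      for (alt in setdiff(c("A", "C", "G", "T"), b[pos])) {
        nb <- b; nb[pos] <- alt
        aa2 <- gc[[paste(nb, collapse = "")]]
        if (aa2 != "*" && aa2 == gc[[codon]]) s <- s + 1 / 3
      }
    }
    s
  }
  walk <- function(cur, target, remaining) {
    # returns matrix of (sd, nd) for each complete stop-free ordering
    if (length(remaining) == 0) return(matrix(c(0, 0), 1))
    out <- NULL
    for (pos in remaining) {
      nxt <- cur; nxt[pos] <- target[pos]
      if (gc[[paste(nxt, collapse = "")]] == "*") next
      step <- if (gc[[paste(nxt, collapse = "")]] == gc[[paste(cur, collapse = "")]]) {
        c(1, 0)
      } else {
        c(0, 1)
      }
      sub <- walk(nxt, target, setdiff(remaining, pos))
      if (!is.null(sub)) out <- rbind(out, sweep(sub, 2, step, "+"))
    }
    out
  }
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(b1 != b2)
  paths <- walk(b1, b2, diff_pos)
  diffs <- if (is.null(paths)) c(NA, NA) else colMeans(paths)
  list(s_sites = (syn_sites(c1) + syn_sites(c2)) / 2,
       sd = diffs[1], nd = diffs[2])
}

# small deterministic synthetic tetraploid used by several test files
small_tetraploid <- function(seed = 42, exchanges = NULL, n_copies = 60) {
  simulate_allotetraploid(seed = seed, n_pairs = 2, chromosome_length = 8e4,
                          n_copies = n_copies, exchanges = exchanges)
}
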