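# Canonical k-mer counting and subgenome-diagnostic k-mer selection.
#
# k-mers are held as base-4 integer codes (A=0, C=1, G=2, T=3, most
# significant digit first); the canonical form of a k-mer is the
# lexicographic minimum of itself and its reverse complement. Codes up to
# k = 25 fit exactly in a double.

.datatable.aware <- TRUE

#' @importFrom data.table data.table as.data.table dcast := .N
NULL

rolling_canonical_codes <- function(codes, k) {
  n <- length(codes)
  m <- n - k + 1L
  if (m < 1L) return(numeric(0))
  fw <- numeric(m)
  rc <- numeric(m)
  for (j in seq_len(k)) {
    cj <- as.numeric(codes[j:(m + j - 1L)])
    fw <- fw + cj * 4^(k - j)
    rc <- rc + (3 - cj) * 4^(j - 1)
  }
  pmin(fw, rc)
}

#' Decode a base-4 k-mer code to its sequence
#'
#' @param code Numeric vector of k-mer codes.
#' @param k k-mer length.
#' @return Character vector of k-mer sequences.
#' @export
decode_kmer <- function(code, k) {
  vapply(code, function(x) {
    digits <- integer(k)
    for (j in k:1) {
      digits[j] <- x %% 4
      x <- x %/% 4
    }
    paste(.BASES[digits + 1L], collapse = "")
  }, character(1))
}

encode_kmer <- function(kmer) {
  vapply(kmer, function(s) {
    sum(as.numeric(seq_to_codes(s)) * 4^((nchar(s) - 1):0))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Count canonical k-mers per chromosome
#'
#' Counts every k-length window of each chromosome in canonical form (the
#' lexicographic minimum of the k-mer and its reverse complement). Windows
#' containing any non-ACGT character are skipped.
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param k k-mer length (default 13).
#' @return A `kmer_counts` object: list with `dt` (data.table of `code`,
#'   `chrom`, `n`), `k`, and `chromosome_lengths`.
#' @export
#' @examples
#' counts <- count_kmers(c(chr1 = "AAAA"), k = 3)
#' kmer_count_table(counts)  # AAA seen twice
count_kmers <- function(genome, k = 13) {
  seqs <- as_character_genome(genome)
  if (length(seqs) == 0 || all(!nzchar(seqs))) {
    stop_input("Empty genome: no sequences to count.")
  }
  if (k < 1) stop_input("`k` must be >= 1.")
  if (k > 25) stop_input("`k` must be <= 25 for exact integer coding.")
  parts <- lapply(names(seqs), function(ch) {
    vals <- rolling_canonical_codes(seq_to_codes(seqs[[ch]]), k)
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) return(NULL)
    data.table(code = vals, chrom = ch)
  })
  dt <- data.table::rbindlist(purrr::compact(parts))
  if (nrow(dt) == 0) stop_input("No countable k-length windows in the genome.")
  dt <- dt[, list(n = .N), by = c("code", "chrom")]
  structure(list(dt = dt, k = k,
                 chromosome_lengths = nchar(seqs)),
            class = "kmer_counts")
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat(sprintf("<kmer_counts> k = %d, %d chromosomes, %s distinct canonical k-mers\n",
              x$k, length(x$chromosome_lengths),
              format(length(unique(x$dt$code)), big.mark = ",")))
  invisible(x)
}

#' Tidy view of a k-mer count object
#'
#' @param x A `kmer_counts` object.
#' @param decode Decode codes to sequences (slow for large sets).
#' @return A tibble with `kmer` (or `code`), `chrom`, `n`.
#' @export
kmer_count_table <- function(x, decode = TRUE) {
  out <- as_tibble(x$dt)
  if (decode) {
    out$kmer <- decode_kmer(out$code, x$k)
    out <- out[, c("kmer", "chrom", "n")]
  }
  out
}

#' Read a homeolog map
#'
#' Two-column TSV of paired chromosome names; lines starting `#excluded`
#' list chromosomes (such as fusion products) left out of all pairs.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `member_1`, `member_2` and attribute
#'   `excluded`.
#' @export
read_homeolog_map <- function(path) {
  lines <- readLines(path)
  excl <- character()
  is_excl <- grepl("^#excluded", lines)
  if (any(is_excl)) {
    excl <- unlist(strsplit(sub("^#excluded\\s+", "", lines[is_excl]), "\\s+"))
  }
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t|\\s+")
  map <- tibble(member_1 = vapply(parts, `[[`, "", 1),
                member_2 = vapply(parts, `[[`, "", 2))
  validate_homeolog_map(map, excl)
  attr(map, "excluded") <- excl
  map
}

validate_homeolog_map <- function(map, excluded = character()) {
  all_members <- c(map$member_1, map$member_2)
  if (anyDuplicated(all_members)) {
    stop_input("Each chromosome may appear in at most one homeolog pair.")
  }
  if (length(intersect(all_members, excluded)) > 0) {
    stop_input("Excluded chromosomes must not appear in any pair.")
  }
  invisible(map)
}

#' Select subgenome-diagnostic k-mers
#'
#' Retains k-mers that (1) occur at least `min_total` times across the
#' genome and (2) are at least `min_fold`-enriched (on length-normalized
#' densities by default) in one member of every homeologous chromosome pair.
#' A pseudocount of 1 keeps zero counts finite while preserving the
#' at-least-`min_fold` semantics; ties at exactly `min_fold` are retained.
#' Subgenome labels are assigned downstream by [consistency_filter()] once a
#' partition exists.
#'
#' @param counts A `kmer_counts` object.
#' @param homeolog_map Tibble with `member_1`, `member_2` columns (see
#'   [read_homeolog_map()]); chromosomes listed in its `excluded` attribute
#'   contribute to genome-wide totals but not to pair folds.
#' @param min_total Minimum genome-wide occurrence count. Default scales the
#'   reference threshold of 100 per 2 Gb to the genome at hand, with a floor
#'   of 10.
#' @param min_fold Minimum per-pair enrichment fold (default 2).
#' @param length_normalize Compare densities per Mb rather than raw counts.
#' @return A `diagnostic_kmers` tibble: `kmer`, `code`, `total`, `min_pair_fold`,
#'   `label` (NA until [consistency_filter()]), with attributes `favored`
#'   (k-mer x pair matrix of favored chromosome names), `profile` (k-mer x
#'   chromosome density matrix), `k`, `homeolog_map`, `min_total`, `min_fold`.
#' @export
select_diagnostic_kmers <- function(counts, homeolog_map, min_total = NULL,
                                    min_fold = 2, length_normalize = TRUE) {
  if (!inherits(counts, "kmer_counts")) stop_input("`counts` must be a kmer_counts object.")
  if (nrow(homeolog_map) == 0) stop_input("Homeolog map has zero pairs.")
  validate_homeolog_map(homeolog_map, attr(homeolog_map, "excluded") %||% character())
  members <- c(homeolog_map$member_1, homeolog_map$member_2)
  missing_m <- setdiff(members, names(counts$chromosome_lengths))
  if (length(missing_m) > 0) {
    stop_input(paste0("Count matrix lacks chromosomes: ",
                      paste(missing_m, collapse = ", ")))
  }
  genome_size <- sum(counts$chromosome_lengths)
  if (is.null(min_total)) {
    min_total <- max(10, round(100 * genome_size / 2e9))
  }

  dt <- counts$dt
  totals <- dt[, list(total = sum(n)), by = "code"]
  cand <- totals[totals$total >= min_total, ]
  if (nrow(cand) == 0) {
    return(new_diagnostic_kmers(
      tibble(kmer = character(), code = numeric(), total = integer(),
             min_pair_fold = numeric(), label = character()),
      favored = matrix(character(), 0, nrow(homeolog_map)),
      profile = matrix(numeric(), 0, length(members),
                       dimnames = list(NULL, members)),
      counts = counts, homeolog_map = homeolog_map,
      min_total = min_total, min_fold = min_fold))
  }

  sub <- dt[dt$code %in% cand$code, ]
  wide <- dcast(sub, code ~ chrom, value.var = "n", fill = 0L)
  for (ch in setdiff(members, names(wide))) wide[[ch]] <- 0L
  codes <- wide$code
  W <- as.matrix(wide[, members, with = FALSE])
  len_mb <- counts$chromosome_lengths[members] / 1e6
  dens <- if (length_normalize) {
    sweep(W + 1, 2, len_mb, "/")
  } else {
    W + 1
  }

  n_pairs <- nrow(homeolog_map)
  fold <- matrix(NA_real_, length(codes), n_pairs)
  favored <- matrix(NA_character_, length(codes), n_pairs)
  for (p in seq_len(n_pairs)) {
    d1 <- dens[, homeolog_map$member_1[[p]]]
    d2 <- dens[, homeolog_map$member_2[[p]]]
    fold[, p] <- pmax(d1, d2) / pmin(d1, d2)
    favored[, p] <- ifelse(d1 > d2, homeolog_map$member_1[[p]],
                           ifelse(d2 > d1, homeolog_map$member_2[[p]],
                                  NA_character_))
  }
  keep <- rowSums(fold >= min_fold & !is.na(favored)) == n_pairs
  totals_kept <- cand$total[match(codes[keep], cand$code)]

  new_diagnostic_kmers(
    tibble(kmer = decode_kmer(codes[keep], counts$k),
           code = codes[keep],
           total = as.integer(totals_kept),
           min_pair_fold = apply(fold[keep, , drop = FALSE], 1, min),
           label = NA_character_),
    favored = favored[keep, , drop = FALSE],
    profile = sweep(W[keep, , drop = FALSE], 2, len_mb, "/"),
    counts = counts, homeolog_map = homeolog_map,
    min_total = min_total, min_fold = min_fold)
}

new_diagnostic_kmers <- function(tbl, favored, profile, counts, homeolog_map,
                                 min_total, min_fold) {
  structure(tbl,
            class = c("diagnostic_kmers", class(tibble())),
            favored = favored, profile = profile, k = counts$k,
            chromosome_lengths = counts$chromosome_lengths,
            homeolog_map = homeolog_map,
            min_total = min_total, min_fold = min_fold)
}

#' Cluster chromosomes into two subgenomes
#'
#' Hierarchically clusters chromosomes on their length-normalized diagnostic
#' k-mer density profiles (correlation distance, average linkage) and returns
#' the top-level bipartition. The cluster containing the anchor chromosome
#' (default: the lexicographically smallest name) is labeled "A" for
#' reproducibility. A bipartition that splits a homeolog pair onto one side
#' is flagged inconsistent rather than rejected.
#'
#' @param kmers A `diagnostic_kmers` object with >= 2 k-mers.
#' @param anchor Chromosome name forced into subgenome "A".
#' @return A `subgenome_partition`: list with `assignment` (named chr ->
#'   "A"/"B"), `tbl` (tibble), `hclust`, `score` (mean silhouette width on
#'   correlation distance), `consistent` (pair-integrity flag).
#' @export
cluster_chromosomes <- function(kmers, anchor = NULL) {
  if (nrow(kmers) < 2) stop_input("Need >= 2 diagnostic k-mers to cluster.")
  map <- attr(kmers, "homeolog_map")
  members <- c(map$member_1, map$member_2)
  P <- attr(kmers, "profile")[, members, drop = FALSE]
  cm <- suppressWarnings(stats::cor(P))
  cm[is.na(cm)] <- 0
  d <- stats::as.dist(1 - cm)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, k = 2)

  anchor <- anchor %||% sort(members)[1]
  if (!anchor %in% names(cl)) stop_input("`anchor` is not a clustered chromosome.")
  lab <- ifelse(cl == cl[[anchor]], "A", "B")
  assignment <- setNames(lab, names(cl))

  consistent <- all(assignment[map$member_1] != assignment[map$member_2])
  if (!consistent) {
    warn("Bipartition splits at least one homeolog pair onto one side; partition flagged inconsistent.")
  }
  structure(list(
    assignment = assignment,
    tbl = tibble(chromosome = names(assignment), subgenome = unname(assignment)),
    hclust = hc,
    score = silhouette_score(as.matrix(d), cl),
    consistent = consistent
  ), class = "subgenome_partition")
}

silhouette_score <- function(dm, cl) {
  n <- length(cl)
  if (length(unique(cl)) < 2) return(NA_real_)
  s <- vapply(seq_len(n), function(i) {
    own <- cl == cl[[i]]
    own[i] <- FALSE
    a <- if (any(own)) mean(dm[i, own]) else 0
    b <- mean(dm[i, cl != cl[[i]]])
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' @export
print.subgenome_partition <- function(x, ...) {
  cat("<subgenome_partition>\n")
  print(x$tbl, n = Inf)
  cat(sprintf("silhouette score %.3f; pair-consistent: %s\n",
              x$score, x$consistent))
  invisible(x)
}

#' Remove k-mers inconsistent with the subgenome partition
#'
#' For each retained k-mer, maps its per-pair favored chromosome to a
#' subgenome via the partition; k-mers whose favored side conflicts with
#' their majority subgenome on more than `max_conflicts` pairs are removed,
#' and subgenome labels are (re)computed for the survivors.
#'
#' @param kmers A `diagnostic_kmers` object.
#' @param partition A `subgenome_partition`.
#' @param max_conflicts Maximum tolerated conflicting pairs (default 0).
#' @return The filtered `diagnostic_kmers` with `label` filled in.
#' @export
consistency_filter <- function(kmers, partition, max_conflicts = 0) {
  if (nrow(kmers) == 0) stop_input("No k-mers to filter.")
  favored <- attr(kmers, "favored")
  side <- matrix(partition$assignment[favored], nrow(favored))
  n_a <- rowSums(side == "A")
  n_b <- rowSums(side == "B")
  label <- ifelse(n_a >= n_b, "A", "B")
  conflicts <- pmin(n_a, n_b)
  keep <- conflicts <= max_conflicts
  if (!any(keep)) {
    stop_degenerate(paste(
      "All k-mers conflict with the partition;",
      "consider relaxing `max_conflicts` or the selection thresholds."))
  }
  out <- kmers[keep, , drop = FALSE]
  out$label <- label[keep]
  attr(out, "favored") <- favored[keep, , drop = FALSE]
  attr(out, "profile") <- attr(kmers, "profile")[keep, , drop = FALSE]
  for (a in c("k", "chromosome_lengths", "homeolog_map", "min_total", "min_fold")) {
    attr(out, a) <- attr(kmers, a)
  }
  class(out) <- class(kmers)
  out
}

#' Per-window diagnostic k-mer density track
#'
#' Counts occurrences of A- and B-labeled diagnostic k-mers in
#' non-overlapping windows along each chromosome (last window truncated).
#' This is the observation sequence for the ancestry HMM.
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param kmers A labeled `diagnostic_kmers` object (after
#'   [consistency_filter()]).
#' @param window_size Window size in bp (>= k).
#' @param chromosomes Chromosomes to scan (default: all in `genome`).
#' @return A tibble `chrom`, `start`, `end` (0-based half-open), `window`,
#'   `n_A`, `n_B`.
#' @export
density_track <- function(genome, kmers, window_size = 1e4,
                          chromosomes = NULL) {
  k <- attr(kmers, "k")
  if (window_size < k) stop_input("`window_size` must be >= k.")
  if (anyNA(kmers$label)) {
    stop_input("k-mers must be labeled; run consistency_filter() first.")
  }
  seqs <- as_character_genome(genome)
  chromosomes <- chromosomes %||% names(seqs)
  codes_a <- sort(kmers$code[kmers$label == "A"])
  codes_b <- sort(kmers$code[kmers$label == "B"])
  parts <- lapply(chromosomes, function(ch) {
    L <- nchar(seqs[[ch]])
    n_win <- max(1L, as.integer(ceiling(L / window_size)))
    vals <- rolling_canonical_codes(seq_to_codes(seqs[[ch]]), k)
    win_of <- function(codes_set) {
      hit <- which(!is.na(vals) & vals %in% codes_set)
      tabulate((hit - 1L) %/% window_size + 1L, nbins = n_win)
    }
    start <- (seq_len(n_win) - 1L) * window_size
    tibble(chrom = ch, start = start,
           end = pmin(L, start + window_size),
           window = seq_len(n_win) - 1L,
           n_A = win_of(codes_a), n_B = win_of(codes_b))
  })
  dplyr::bind_rows(parts)
}

#' Run the full subgenome-phasing pipeline
#'
#' Convenience wrapper: count k-mers, select diagnostic k-mers, cluster
#' chromosomes, apply the consistency filter, and compute density tracks.
#'
#' @inheritParams count_kmers
#' @inheritParams select_diagnostic_kmers
#' @inheritParams consistency_filter
#' @inheritParams density_track
#' @return A list: `counts`, `kmers` (labeled), `partition`, `track`.
#' @export
assign_subgenomes <- function(genome, homeolog_map, k = 13, min_total = NULL,
                              min_fold = 2, length_normalize = TRUE,
                              max_conflicts = 0, window_size = 1e4,
                              anchor = NULL) {
  counts <- count_kmers(genome, k = k)
  kmers <- select_diagnostic_kmers(counts, homeolog_map,
                                   min_total = min_total, min_fold = min_fold,
                                   length_normalize = length_normalize)
  partition <- cluster_chromosomes(kmers, anchor = anchor)
  kmers <- consistency_filter(kmers, partition, max_conflicts = max_conflicts)
  track <- density_track(genome, kmers, window_size = window_size)
  list(counts = counts, kmers = kmers, partition = partition, track = track)
}
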