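# Molecular dating: p-distances, Jukes-Cantor correction, LTR insertion
# ages, substitution-rate calibration, Nei-Gojobori Ks/Ka, and event dating
# from Ks distributions.

#' Observed proportion of differing sites between two aligned sequences
#'
#' Counts differences over the comparable columns only: positions where
#' either sequence carries a gap or an ambiguous base are dropped (pairwise
#' deletion).
#'
#' @param seq_1,seq_2 Aligned DNA sequences of equal length.
#' @return Fraction of differing comparable sites.
#' @export
#' @examples
#' p_distance("AAAA", "AAAT")  # 0.25
p_distance <- function(seq_1, seq_2) {
  if (nchar(seq_1) != nchar(seq_2)) {
    stop_input("Aligned sequences must have equal length.")
  }
  if (nchar(seq_1) == 0) stop_input("Zero-length alignment.")
  c1 <- seq_to_codes(seq_1)
  c2 <- seq_to_codes(seq_2)
  ok <- !is.na(c1) & !is.na(c2)
  if (!any(ok)) stop_input("No comparable (ungapped, unambiguous) sites.")
  mean(c1[ok] != c2[ok])
}

#' Jukes-Cantor distance from an observed p-distance
#'
#' \eqn{d = -(3/4) \log(1 - 4p/3)} substitutions per site. The exact inverse
#' of the simulator's mutation process: the expected p after evolving for
#' rate x time d is \eqn{(3/4)(1 - e^{-4d/3})}.
#'
#' @param p Observed proportion of differing sites, in [0, 0.75).
#' @return Distance in substitutions per site.
#' @export
#' @examples
#' jukes_cantor(0.1)  # ~0.1073
jukes_cantor <- function(p) {
  if (any(p < 0)) stop_input("`p` must be non-negative.")
  if (any(p >= 0.75)) {
    stop_saturation("p >= 0.75 saturates the Jukes-Cantor correction.")
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' LTR insertion age from terminal-repeat divergence
#'
#' The two terminal repeats of an LTR retrotransposon are identical at
#' insertion and diverge along two independent branches, so the insertion
#' age is `distance / (2 * rate)`.
#'
#' @param distance Jukes-Cantor distance between the two LTRs of a copy
#'   (substitutions/site).
#' @param rate Substitution rate per site per year.
#' @return Age in My.
#' @export
#' @examples
#' ltr_insertion_age(0.105, 2.1e-8)  # 2.5 My
ltr_insertion_age <- function(distance, rate) {
  if (any(rate <= 0)) stop_input("`rate` must be positive.")
  if (any(distance < 0)) stop_input("`distance` must be non-negative.")
  distance / (2 * rate) / 1e6
}

#' Calibrate the substitution rate from shared TE families
#'
#' Families active in both the focal lineage and an outgroup clock the rate:
#' each family's rate is its median element-to-outgroup distance divided by
#' twice the split time; the overall rate is the median across families.
#' The default split time of 10 My is the miscanthus-sorghum divergence.
#'
#' @param family_distances A named list of numeric vectors (per-family
#'   element-to-outgroup JC distances) or a tibble with columns `family`,
#'   `distance`.
#' @param split_time_my Divergence time of the two lineages in My.
#' @return A `rate_calibration` list: `rate` (substitutions/site/year),
#'   `per_family` tibble, `split_time_my`.
#' @export
#' @examples
#' calibrate_rate(list(f1 = 0.42), split_time_my = 10)$rate  # 2.1e-08
calibrate_rate <- function(family_distances, split_time_my = 10) {
  if (is.data.frame(family_distances)) {
    family_distances <- split(family_distances$distance, family_distances$family)
  }
  if (length(family_distances) == 0) {
    stop_input("Need at least one family to calibrate a rate.")
  }
  per_family <- tibble(
    family = names(family_distances) %||% as.character(seq_along(family_distances)),
    median_distance = vapply(family_distances, median, numeric(1)),
    rate = vapply(family_distances, median, numeric(1)) / (2 * split_time_my * 1e6)
  )
  structure(list(rate = median(per_family$rate), per_family = per_family,
                 split_time_my = split_time_my),
            class = "rate_calibration")
}

#' @export
print.rate_calibration <- function(x, ...) {
  cat(sprintf("<rate_calibration> rate = %.3g subs/site/year (%d families, split %g My)\n",
              x$rate, nrow(x$per_family), x$split_time_my))
  invisible(x)
}

#' Extract LTR-LTR pairs from a TE registry
#'
#' Pulls the two terminal repeats of every registered LTR element copy out of
#' the genome sequence, ready for [date_ltr_copies()].
#'
#' @param genome The genome the registry indexes.
#' @param registry TE registry tibble (see [plant_te_burst()]).
#' @param family Optional family name filter.
#' @return A tibble: `family`, `chromosome`, `start`, `age_my`, `ltr_1`,
#'   `ltr_2`.
#' @export
extract_ltr_pairs <- function(genome, registry, family = NULL) {
  seqs <- as_character_genome(genome)
  reg <- registry[registry$ltr_length > 0, , drop = FALSE]
  if (!is.null(family)) reg <- reg[reg$family %in% family, , drop = FALSE]
  if (nrow(reg) == 0) return(tibble(family = character(), chromosome = character(),
                                    start = integer(), age_my = numeric(),
                                    ltr_1 = character(), ltr_2 = character()))
  tibble(
    family = reg$family, chromosome = reg$chromosome, start = reg$start,
    age_my = reg$age_my,
    ltr_1 = substring(seqs[reg$chromosome], reg$start + 1L,
                      reg$start + reg$ltr_length),
    ltr_2 = substring(seqs[reg$chromosome], reg$end - reg$ltr_length + 1L,
                      reg$end)
  )
}

#' Date LTR element copies from terminal-repeat divergence
#'
#' @param pairs Tibble with `ltr_1`, `ltr_2` columns (see
#'   [extract_ltr_pairs()] or [simulate_ltr_pairs()]).
#' @param rate Substitution rate per site per year.
#' @return The input with `p`, `d` (JC distance), and `age_my` columns;
#'   saturated pairs (p >= 0.75) get `NA` and `saturated = TRUE`.
#' @export
date_ltr_copies <- function(pairs, rate) {
  if (rate <= 0) stop_input("`rate` must be positive.")
  p <- purrr::map2_dbl(pairs$ltr_1, pairs$ltr_2, p_distance)
  saturated <- p >= 0.75
  d <- ifelse(saturated, NA_real_, -0.75 * log(1 - 4 * pmin(p, 0.7499) / 3))
  d[saturated] <- NA_real_
  dplyr::mutate(pairs, p = p, d = d,
                age_my = ifelse(saturated, NA_real_, d / (2 * rate) / 1e6),
                saturated = saturated)
}

#' Simulate dated LTR pairs
#'
#' Generates `n` element copies whose two terminal repeats were identical at
#' insertion `age_my` ago and have each evolved independently since, i.e.
#' LTR-LTR divergence with expectation `2 * rate * age`.
#'
#' @param n Number of copies.
#' @param ltr_length Terminal repeat length in bp.
#' @param age_my Insertion age in My.
#' @param rate Substitution rate per site per year.
#' @param seed Integer seed, or `NULL`.
#' @return A tibble: `id`, `age_my`, `ltr_1`, `ltr_2`.
#' @export
simulate_ltr_pairs <- function(n, ltr_length = 300, age_my, rate, seed = NULL) {
  with_seed(seed, {
    p_change <- 0.75 * (1 - exp(-(4 / 3) * rate * age_my * 1e6))
    anc <- vapply(seq_len(n), function(i) {
      paste(sample(.BASES, ltr_length, TRUE), collapse = "")
    }, character(1))
    tibble(id = sprintf("ltr%04d", seq_len(n)), age_my = age_my,
           ltr_1 = vapply(anc, mutate_sequence, character(1), p_change,
                          USE.NAMES = FALSE),
           ltr_2 = vapply(anc, mutate_sequence, character(1), p_change,
                          USE.NAMES = FALSE))
  })
}

# -- Nei-Gojobori Ks/Ka -------------------------------------------------------

.PERMS <- list(list(1L), list(c(1L, 2L), c(2L, 1L)),
               list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                    c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

codon_aa <- function(codon) Biostrings::GENETIC_CODE[[codon]]

# synonymous site count of one codon (changes to stop count as nonsynonymous)
codon_syn_sites <- function(codon) {
  aa <- codon_aa(codon)
  bases <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    for (alt in setdiff(.BASES, bases[pos])) {
      nb <- bases
      nb[pos] <- alt
      alt_aa <- codon_aa(paste(nb, collapse = ""))
      if (alt_aa != "*" && alt_aa == aa) s <- s + 1 / 3
    }
  }
  s
}

# expected syn/nonsyn differences for one codon pair, averaged over equally
# weighted mutational pathways; pathways through stop codons are excluded
codon_pair_diffs <- function(c1, c2) {
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(b1 != b2)
  nd <- length(diff_pos)
  if (nd == 0) return(c(sd = 0, nd = 0))
  paths <- .PERMS[[nd]]
  count_path <- function(ord) {
    cur <- b1
    sd <- ndd <- 0
    for (pos in diff_pos[ord]) {
      aa_from <- codon_aa(paste(cur, collapse = ""))
      cur[pos] <- b2[pos]
      codon_to <- paste(cur, collapse = "")
      aa_to <- codon_aa(codon_to)
      if (aa_to == "*" || aa_from == "*") return(NULL)
      if (aa_to == aa_from) sd <- sd + 1 else ndd <- ndd + 1
    }
    c(sd = sd, nd = ndd)
  }
  res <- purrr::compact(lapply(paths, count_path))
  if (length(res) == 0) {
    # all pathways pass through a stop: fall back to counting every step,
    # stop-involving steps as nonsynonymous
    res <- lapply(paths, function(ord) {
      cur <- b1
      sd <- ndd <- 0
      for (pos in diff_pos[ord]) {
        aa_from <- codon_aa(paste(cur, collapse = ""))
        cur[pos] <- b2[pos]
        aa_to <- codon_aa(paste(cur, collapse = ""))
        if (aa_to != "*" && aa_from != "*" && aa_to == aa_from) {
          sd <- sd + 1
        } else {
          ndd <- ndd + 1
        }
      }
      c(sd = sd, nd = ndd)
    })
  }
  colMeans(do.call(rbind, res))
}

# lazily built lookup tables: synonymous sites per codon and pathway-averaged
# (sd, nd) for every codon pair
.ng_env <- new.env(parent = emptyenv())

ng_tables <- function() {
  if (!is.null(.ng_env$syn)) return(.ng_env)
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  syn <- vapply(sense, codon_syn_sites, numeric(1))
  sd_mat <- nd_mat <- matrix(NA_real_, length(sense), length(sense),
                             dimnames = list(sense, sense))
  for (c1 in sense) {
    for (c2 in sense) {
      dd <- codon_pair_diffs(c1, c2)
      sd_mat[c1, c2] <- dd[["sd"]]
      nd_mat[c1, c2] <- dd[["nd"]]
    }
  }
  .ng_env$syn <- syn
  .ng_env$sd_mat <- sd_mat
  .ng_env$nd_mat <- nd_mat
  .ng_env
}

#' Synonymous and nonsynonymous divergence (Nei-Gojobori 1986)
#'
#' Pathway-counting estimator: synonymous site counts per codon (changes to
#' stop codons count as nonsynonymous), differences averaged over equally
#' weighted mutational pathways (pathways through stop codons excluded), and
#' Jukes-Cantor correction of the resulting proportions.
#'
#' @param cds_1,cds_2 Aligned coding sequences, equal length divisible by 3,
#'   no internal stop codons. Codons containing gaps or ambiguous bases are
#'   skipped (pairwise deletion).
#' @return A list: `Ks`, `Ka` (substitutions/site; `NA` when saturated),
#'   `S`, `N` (site counts), `Sd`, `Nd` (difference counts), `ps`, `pn`,
#'   `saturated`.
#' @export
#' @examples
#' ks_nei_gojobori("GGATTT", "GGCTTT")$Sd  # one synonymous difference
ks_nei_gojobori <- function(cds_1, cds_2) {
  if (nchar(cds_1) != nchar(cds_2)) stop_input("CDS alignment lengths differ.")
  if (nchar(cds_1) %% 3 != 0) stop_input("CDS length must be divisible by 3.")
  n_codons <- nchar(cds_1) / 3
  if (n_codons == 0) stop_input("Empty CDS alignment.")
  idx <- 3 * seq_len(n_codons) - 2
  co1 <- toupper(substring(cds_1, idx, idx + 2))
  co2 <- toupper(substring(cds_2, idx, idx + 2))
  ok <- !grepl("[^ACGT]", co1) & !grepl("[^ACGT]", co2)
  if (any(Biostrings::GENETIC_CODE[co1[ok]] == "*" |
            Biostrings::GENETIC_CODE[co2[ok]] == "*")) {
    stop_input("Internal stop codon in CDS alignment.")
  }
  if (!any(ok)) stop_input("No comparable codons in alignment.")
  tabs <- ng_tables()
  co1 <- co1[ok]
  co2 <- co2[ok]
  S <- sum((tabs$syn[co1] + tabs$syn[co2]) / 2)
  N <- 3 * sum(ok) - S
  Sd <- sum(tabs$sd_mat[cbind(co1, co2)])
  Nd <- sum(tabs$nd_mat[cbind(co1, co2)])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  saturated <- ps >= 0.75 || pn >= 0.75
  list(Ks = if (ps >= 0.75) NA_real_ else jukes_cantor(ps),
       Ka = if (pn >= 0.75) NA_real_ else jukes_cantor(pn),
       S = S, N = N, Sd = unname(Sd), Nd = unname(Nd),
       ps = ps, pn = pn, saturated = saturated)
}

#' Date an event from a Ks distribution
#'
#' Estimates the event time as the mode of the Ks distribution (Gaussian
#' kernel density, Silverman's rule-of-thumb bandwidth) divided by twice the
#' synonymous substitution rate. The mode is preferred over the mean because
#' Ks distributions are right-skewed by saturation. All local maxima are
#' reported (ordered by density) so bimodal inputs expose both components;
#' a seeded bootstrap gives a confidence interval.
#'
#' @param ks_values Numeric vector of Ks values (>= 20 for a stable mode).
#' @param rate Synonymous substitution rate per site per year.
#' @param n_boot Bootstrap resamples for the CI (default 200).
#' @param conf Confidence level.
#' @param seed Integer seed for the bootstrap, or `NULL`.
#' @return A `ks_event_time` list: `time_my`, `mode_ks`, `modes` (tibble of
#'   all local maxima with their times), `ci_my`, `n`.
#' @export
event_time_from_ks <- function(ks_values, rate, n_boot = 200, conf = 0.95,
                               seed = NULL) {
  ks_values <- ks_values[!is.na(ks_values)]
  if (length(ks_values) < 20) {
    stop_input("Need >= 20 Ks values for a stable mode estimate.")
  }
  if (rate <= 0) stop_input("`rate` must be positive.")
  to_my <- function(ks) ks / (2 * rate) / 1e6
  if (sd(ks_values) == 0) {
    t0 <- to_my(ks_values[1])
    return(structure(list(time_my = t0, mode_ks = ks_values[1],
                          modes = tibble(ks = ks_values[1], density = Inf,
                                         time_my = t0),
                          ci_my = c(t0, t0), n = length(ks_values)),
                     class = "ks_event_time"))
  }
  mode_of <- function(x) {
    d <- density(x, bw = "nrd0")
    d$x[which.max(d$y)]
  }
  d <- density(ks_values, bw = "nrd0")
  is_max <- which(diff(sign(diff(d$y))) == -2) + 1
  if (length(is_max) == 0) is_max <- which.max(d$y)
  modes <- tibble(ks = d$x[is_max], density = d$y[is_max])
  modes <- modes[order(-modes$density), ]
  modes$time_my <- to_my(modes$ks)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      to_my(mode_of(sample(ks_values, replace = TRUE)))
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  structure(list(time_my = modes$time_my[1], mode_ks = modes$ks[1],
                 modes = modes,
                 ci_my = unname(quantile(boot, c(alpha, 1 - alpha))),
                 n = length(ks_values)),
            class = "ks_event_time")
}

#' @export
print.ks_event_time <- function(x, ...) {
  cat(sprintf("<ks_event_time> %.2f My (mode Ks = %.4f, n = %d, CI %.2f-%.2f My)\n",
              x$time_my, x$mode_ks, x$n, x$ci_my[1], x$ci_my[2]))
  if (nrow(x$modes) > 1) {
    cat(sprintf("  %d additional mode(s) at Ks = %s\n", nrow(x$modes) - 1,
                paste(sprintf("%.3f", x$modes$ks[-1]), collapse = ", ")))
  }
  invisible(x)
}
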