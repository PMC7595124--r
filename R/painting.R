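# Chromosome painting of admixed accessions: species-diagnostic marker
# discovery from exemplar genotypes, read-depth dosage likelihoods per
# window, HMM smoothing over dosage states, and genome-wide summaries.

#' Discover species-diagnostic fixed-difference markers
#'
#' Retains biallelic sites where every non-missing exemplar genotype of
#' species 1 is homozygous for one allele and every non-missing exemplar of
#' species 2 is homozygous for the other, with at least one non-missing
#' exemplar per species. Sites inside the repeat mask are removed.
#'
#' @param genotypes Tibble with `chrom`, `pos` and one column per exemplar
#'   holding diploid calls as `"X/Y"` strings (`NA` = missing).
#' @param species Named character vector mapping exemplar column names to
#'   two species identifiers.
#' @param mask Optional repeat mask tibble (`chrom`, `start`, `end`; 0-based
#'   half-open).
#' @return An `ancestry_markers` tibble: `chrom`, `pos`, `allele_1`,
#'   `allele_2` (alleles of the first and second species level), positions
#'   strictly increasing per chromosome.
#' @export
discover_markers <- function(genotypes, species, mask = NULL) {
  ex <- names(species)
  if (length(ex) == 0 || !all(ex %in% names(genotypes))) {
    stop_input("`species` must name exemplar columns present in `genotypes`.")
  }
  sp_levels <- unique(unname(species))
  if (length(sp_levels) != 2) stop_input("Exactly two species are required.")
  if (min(table(factor(species, sp_levels))) < 2) {
    stop_input("Need >= 2 exemplars per species.")
  }
  g <- as.matrix(genotypes[, ex, drop = FALSE])
  hom_allele <- function(call) {
    # homozygous call -> its allele; het or missing -> NA
    a <- strsplit(call, "/", fixed = TRUE)
    vapply(a, function(x) {
      if (length(x) == 2 && !anyNA(x) && x[1] == x[2]) x[1] else NA_character_
    }, character(1))
  }
  alle <- matrix(hom_allele(as.vector(g)), nrow = nrow(g),
                 dimnames = dimnames(g))
  species_allele <- function(sp) {
    cols <- ex[species[ex] == sp]
    sub <- alle[, cols, drop = FALSE]
    has_het_or_missing_call <- !is.na(g[, cols, drop = FALSE]) & is.na(sub)
    apply_ok <- rowSums(!is.na(sub)) >= 1 &          # >= 1 non-missing exemplar
      rowSums(has_het_or_missing_call) == 0          # no het among called
    a <- vapply(seq_len(nrow(sub)), function(i) {
      u <- unique(sub[i, !is.na(sub[i, ])])
      if (length(u) == 1) u else NA_character_
    }, character(1))
    ifelse(apply_ok, a, NA_character_)
  }
  a1 <- species_allele(sp_levels[1])
  a2 <- species_allele(sp_levels[2])
  keep <- !is.na(a1) & !is.na(a2) & a1 != a2
  out <- tibble(chrom = genotypes$chrom[keep], pos = genotypes$pos[keep],
                allele_1 = a1[keep], allele_2 = a2[keep])
  if (!is.null(mask) && nrow(mask) > 0) {
    masked <- unlist(lapply(split(seq_len(nrow(out)), out$chrom), function(idx) {
      ch <- out$chrom[idx[1]]
      m <- mask[mask$chrom == ch, , drop = FALSE]
      idx[positions_in_mask(out$pos[idx], m)]
    }))
    if (length(masked) > 0) out <- out[-masked, , drop = FALSE]
  }
  out <- dplyr::arrange(out, .data$chrom, .data$pos)
  class(out) <- c("ancestry_markers", class(out))
  out
}

#' Per-window ancestry dosage likelihoods from read depths
#'
#' For every window and dosage g in 0..ploidy, sums binomial log-likelihoods
#' of the species-1 read counts with success probability `g/ploidy` shifted
#' by the sequencing error rate. Windows without any sequenced marker are
#' reported as missing.
#'
#' @param observations Tibble `chrom`, `pos`, `depth_1`, `depth_2` (reads
#'   supporting each species' allele; see [simulate_admixed_accession()]).
#' @param ploidy Accession ploidy (2, 3, or 4).
#' @param window_size Window size in bp.
#' @param error_rate Per-read error probability (default 0.01).
#' @param chromosome_lengths Optional named vector to fix the window grid;
#'   defaults to the span of the observed markers.
#' @return A `dosage_windows` tibble: `chrom`, `window`, `start`, `end`,
#'   `n_markers`, `depth`, `missing`, `loglik` (list column, length
#'   ploidy + 1), `dosage_ml`, `posterior_ml`.
#' @export
window_dosage <- function(observations, ploidy, window_size,
                          error_rate = 0.01, chromosome_lengths = NULL) {
  if (!ploidy %in% 2:4) stop_input("`ploidy` must be 2, 3, or 4.")
  if (any(observations$depth_1 < 0 | observations$depth_2 < 0)) {
    stop_input("Read depths must be non-negative.")
  }
  g <- 0:ploidy
  p <- g / ploidy
  p_adj <- p * (1 - error_rate) + (1 - p) * error_rate
  parts <- lapply(split(observations, observations$chrom), function(obs) {
    ch <- obs$chrom[1]
    L <- if (!is.null(chromosome_lengths)) chromosome_lengths[[ch]] else max(obs$pos)
    n_win <- max(1L, as.integer(ceiling(L / window_size)))
    w <- (obs$pos - 1) %/% window_size
    rows <- lapply(seq_len(n_win) - 1L, function(wi) {
      sel <- which(w == wi)
      tot <- obs$depth_1[sel] + obs$depth_2[sel]
      sel <- sel[tot > 0]
      if (length(sel) == 0) {
        return(tibble(chrom = ch, window = wi, start = wi * window_size,
                      end = min(L, (wi + 1) * window_size), n_markers = 0L,
                      depth = 0L, missing = TRUE,
                      loglik = list(rep(0, ploidy + 1)),
                      dosage_ml = NA_integer_, posterior_ml = NA_real_))
      }
      d1 <- obs$depth_1[sel]
      tot <- d1 + obs$depth_2[sel]
      ll <- vapply(p_adj, function(pp) sum(dbinom(d1, tot, pp, log = TRUE)),
                   numeric(1))
      post <- exp(ll - max(ll))
      post <- post / sum(post)
      tibble(chrom = ch, window = wi, start = wi * window_size,
             end = min(L, (wi + 1) * window_size),
             n_markers = length(sel), depth = as.integer(sum(tot)),
             missing = FALSE, loglik = list(ll),
             dosage_ml = g[which.max(ll)], posterior_ml = max(post))
    })
    dplyr::bind_rows(rows)
  })
  out <- dplyr::bind_rows(parts)
  attr(out, "ploidy") <- ploidy
  attr(out, "error_rate") <- error_rate
  class(out) <- c("dosage_windows", class(out))
  out
}

#' Smooth window dosage likelihoods into segments
#'
#' HMM over dosage states 0..ploidy with per-boundary switch probability
#' `tau`, uniform among alternative states; the Viterbi path (ties toward
#' the previous state) is collapsed into maximal constant-dosage runs.
#' Missing windows carry no likelihood and are bridged by the flanking
#' state.
#'
#' @param windows A `dosage_windows` tibble from [window_dosage()].
#' @param ploidy Accession ploidy; defaults to the attribute on `windows`.
#' @param tau Per-boundary switch probability (default 1e-3). As `tau` tends
#'   to 0.5 the path approaches the per-window ML calls; as it tends to 0 a
#'   single genome-wide state wins.
#' @return A `dosage_segments` tibble: `chrom`, `start`, `end`, `dosage_1`,
#'   `dosage_2`, `mean_posterior`, `n_windows`.
#' @export
smooth_dosage <- function(windows, ploidy = NULL, tau = 1e-3) {
  ploidy <- ploidy %||% attr(windows, "ploidy")
  if (is.null(ploidy)) stop_input("`ploidy` not given and not on `windows`.")
  if (all(windows$missing)) stop_degenerate("All windows are missing (zero depth).")
  S <- ploidy + 1
  ls <- log(1 - tau)
  lw <- log(tau / ploidy)
  l0 <- rep(log(1 / S), S)
  parts <- lapply(split(windows, windows$chrom), function(wd) {
    wd <- wd[order(wd$window), , drop = FALSE]
    le <- do.call(rbind, wd$loglik)
    path <- hmm_viterbi(le, ls, lw, l0)
    fb <- hmm_forward_backward(le, ls, lw, l0)
    r <- rle(path)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    tibble(chrom = wd$chrom[1],
           start = wd$start[starts], end = wd$end[ends],
           dosage_1 = r$values - 1L, dosage_2 = ploidy - (r$values - 1L),
           mean_posterior = vapply(seq_along(starts), function(j) {
             mean(fb$posterior[starts[j]:ends[j], r$values[j]])
           }, numeric(1)),
           n_windows = r$lengths)
  })
  out <- dplyr::bind_rows(parts)
  attr(out, "ploidy") <- ploidy
  class(out) <- c("dosage_segments", class(out))
  out
}

#' Genome-wide ancestry summary
#'
#' Length-weighted ancestry fractions per species, the modal dosage vector,
#' and the segments deviating from the mode (candidate introgressions or
#' conversions).
#'
#' @param segments A `dosage_segments` tibble from [smooth_dosage()].
#' @param ploidy Accession ploidy; defaults to the attribute on `segments`.
#' @return An `ancestry_summary` list: `fraction_1`, `fraction_2`,
#'   `modal_dosage` (length-2 vector), `deviant_segments` (tibble),
#'   `deviant_window_fraction`.
#' @export
genome_summary <- function(segments, ploidy = NULL) {
  ploidy <- ploidy %||% attr(segments, "ploidy")
  if (nrow(segments) == 0) stop_input("No segments to summarize.")
  len <- segments$end - segments$start
  frac_1 <- sum(segments$dosage_1 * len) / (ploidy * sum(len))
  by_dosage <- tapply(len, segments$dosage_1, sum)
  modal_1 <- as.integer(names(by_dosage)[which.max(by_dosage)])
  deviant <- segments[segments$dosage_1 != modal_1, , drop = FALSE]
  structure(list(
    fraction_1 = frac_1, fraction_2 = 1 - frac_1,
    modal_dosage = c(modal_1, ploidy - modal_1),
    deviant_segments = as_tibble(deviant),
    deviant_window_fraction = sum(deviant$n_windows) / sum(segments$n_windows)
  ), class = "ancestry_summary")
}

#' @export
print.ancestry_summary <- function(x, ...) {
  cat(sprintf("<ancestry_summary> fractions %.3f : %.3f, modal dosage %d:%d, %.1f%% deviant windows\n",
              x$fraction_1, x$fraction_2, x$modal_dosage[1], x$modal_dosage[2],
              100 * x$deviant_window_fraction))
  invisible(x)
}

#' Paint an accession end to end
#'
#' Convenience wrapper: window likelihoods, HMM smoothing, and summary.
#'
#' @inheritParams window_dosage
#' @inheritParams smooth_dosage
#' @return A list: `windows`, `segments`, `summary`.
#' @export
paint_ancestry <- function(observations, ploidy, window_size,
                           error_rate = 0.01, tau = 1e-3,
                           chromosome_lengths = NULL) {
  windows <- window_dosage(observations, ploidy, window_size,
                           error_rate = error_rate,
                           chromosome_lengths = chromosome_lengths)
  segments <- smooth_dosage(windows, ploidy = ploidy, tau = tau)
  list(windows = windows, segments = segments,
       summary = genome_summary(segments, ploidy = ploidy))
}
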