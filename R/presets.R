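# Preset synthetic datasets: one call gives a dataset plus its ground truth.

#' Simulate a complete synthetic allotetraploid
#'
#' End-to-end preset: an ancestral genome diverges into A and B progenitor
#' lineages; each receives a lineage-specific LTR retrotransposon burst; a
#' shared burst (postdating hybridization) hits both; the two genomes are
#' merged into a tetraploid, optionally with reciprocal distal exchanges.
#' Defaults give 4 homeolog pairs of 500 kb with 200-copy bursts -- a
#' desk-scale genome on which the subgenome-phasing pipeline recovers the
#' planted truth.
#'
#' @param seed Integer seed (required: the dataset is defined by it).
#' @param n_pairs Number of homeolog pairs.
#' @param chromosome_length Progenitor chromosome length in bp.
#' @param gc_content GC fraction of the ancestor.
#' @param divergence_time_my Progenitor divergence time in My (each lineage
#'   evolves this long from the common ancestor).
#' @param rate Substitution rate per site per year.
#' @param n_copies Copies per TE family.
#' @param burst_age_specific Age (My) of the A- and B-specific bursts; must
#'   predate hybridization to be subgenome-specific.
#' @param burst_age_shared Age (My) of the shared post-hybridization burst.
#' @param element_internal,element_ltr Element internal / terminal-repeat
#'   lengths in bp.
#' @param exchanges Optional exchange tibble passed to [hybridize()].
#' @return A list: `genome` (DNAStringSet), `truth` (`synthetic_truth` with
#'   TE registry, subgenome labels, exchange intervals), `homeolog_map`,
#'   `families` (per-family consensus and ages), `rate`.
#' @export
#' @examples
#' sim <- simulate_allotetraploid(seed = 1, n_pairs = 2,
#'                                chromosome_length = 5e4, n_copies = 40)
simulate_allotetraploid <- function(seed, n_pairs = 4, chromosome_length = 5e5,
                                    gc_content = 0.44, divergence_time_my = 7.2,
                                    rate = 2.1e-8, n_copies = 200,
                                    burst_age_specific = 4,
                                    burst_age_shared = 1.5,
                                    element_internal = 400, element_ltr = 300,
                                    exchanges = NULL) {
  if (burst_age_specific >= divergence_time_my) {
    stop_input("Subgenome-specific bursts must be younger than the progenitor divergence.")
  }
  with_seed(seed, {
    anc <- simulate_ancestor(n_pairs, chromosome_length, gc_content)
    t_years <- divergence_time_my * 1e6
    gen_a <- diverge(anc, rate, t_years)
    gen_b <- diverge(anc, rate, t_years)

    fam_a <- make_ltr_consensus(element_internal, element_ltr, gc_content)
    fam_b <- make_ltr_consensus(element_internal, element_ltr, gc_content)
    fam_s <- make_ltr_consensus(element_internal, element_ltr, gc_content)

    pa <- plant_te_burst(gen_a, "famA", fam_a$consensus, n_copies,
                         burst_age_specific, rate, ltr_length = element_ltr)
    pb <- plant_te_burst(gen_b, "famB", fam_b$consensus, n_copies,
                         burst_age_specific, rate, ltr_length = element_ltr)
    # shared burst: half the copies on each progenitor's chromosome set
    pa <- plant_te_burst(pa$genome, "famShared", fam_s$consensus,
                         ceiling(n_copies / 2), burst_age_shared, rate,
                         ltr_length = element_ltr, registry = pa$registry)
    pb <- plant_te_burst(pb$genome, "famShared", fam_s$consensus,
                         ceiling(n_copies / 2), burst_age_shared, rate,
                         ltr_length = element_ltr, registry = pb$registry)

    hy <- hybridize(pa$genome, pb$genome, exchanges = exchanges,
                    registry_a = pa$registry, registry_b = pb$registry)
    hy$families <- list(
      famA = c(fam_a, list(target = "A", age_my = burst_age_specific)),
      famB = c(fam_b, list(target = "B", age_my = burst_age_specific)),
      famShared = c(fam_s, list(target = "both", age_my = burst_age_shared))
    )
    hy$rate <- rate
    hy
  })
}

#' Simulate homeolog expression count matrices with planted bias
#'
#' Per-pair baseline expression is lognormal; the B member is scaled by a
#' per-pair ratio whose median is `median_bias`. Counts are drawn
#' negative-binomially with the given dispersion, and a `silent_fraction` of
#' gene-sample-group cells is zeroed to mimic tissue-restricted expression.
#' A fraction of pairs can be marked "exchanged", with the planted bias
#' following either the source subgenome or the current location.
#'
#' @param n_pairs Number of homeolog pairs.
#' @param median_bias Planted median B/A expression ratio (> 0).
#' @param dispersion Negative-binomial dispersion (variance = mu + dispersion
#'   * mu^2); 0 gives Poisson.
#' @param n_groups Number of sample groups (tissues/timepoints).
#' @param n_replicates Replicates per group.
#' @param library_size Target library size per replicate column.
#' @param silent_fraction Fraction of pair-group cells silenced, in [0, 1).
#' @param ratio_sdlog Spread (sdlog) of per-pair log-ratios around the median.
#' @param exchanged_fraction Fraction of pairs in exchanged regions.
#' @param bias_follows For exchanged pairs, whether expression bias follows
#'   the `"source"` subgenome or the `"location"` the gene now occupies.
#' @param seed Integer seed, or `NULL`.
#' @return A list: `counts` (integer matrix, 2 * n_pairs genes x columns),
#'   `groups` (column group labels), `pairs` (tibble `pair_id`, `gene_A`,
#'   `gene_B`, `status`), `truth` (planted parameters and per-pair ratios).
#' @export
simulate_homeolog_counts <- function(n_pairs = 5000, median_bias = 1.04,
                                     dispersion = 0.05, n_groups = 2,
                                     n_replicates = 2, library_size = 2e7,
                                     silent_fraction = 0.1, ratio_sdlog = 0.25,
                                     exchanged_fraction = 0,
                                     bias_follows = c("source", "location"),
                                     seed = NULL) {
  if (median_bias <= 0) stop_input("`median_bias` must be positive.")
  if (silent_fraction < 0 || silent_fraction >= 1) {
    stop_input("`silent_fraction` must lie in [0, 1).")
  }
  bias_follows <- match.arg(bias_follows)
  with_seed(seed, {
    gene_a <- sprintf("pair%05d.A", seq_len(n_pairs))
    gene_b <- sprintf("pair%05d.B", seq_len(n_pairs))
    status <- rep("ancestral", n_pairs)
    n_ex <- round(exchanged_fraction * n_pairs)
    if (n_ex > 0) status[sample.int(n_pairs, n_ex)] <- "exchanged"

    baseline <- rlnorm(n_pairs, meanlog = log(50), sdlog = 1.2)
    ratio <- median_bias * exp(rnorm(n_pairs, 0, ratio_sdlog))
    # source-oriented ratio: expression(source-B copy) / expression(source-A copy)
    # current-location A column of an exchanged pair holds the source-B copy.
    mu_a <- ifelse(status == "exchanged" & bias_follows == "source",
                   baseline * ratio, baseline)
    mu_b <- ifelse(status == "exchanged" & bias_follows == "source",
                   baseline, baseline * ratio)

    cols <- as.vector(outer(seq_len(n_replicates), seq_len(n_groups),
                            function(r, g) sprintf("g%d_r%d", g, r)))
    groups <- rep(sprintf("g%d", seq_len(n_groups)), each = n_replicates)
    mu <- rbind(matrix(mu_a, n_pairs, 1), matrix(mu_b, n_pairs, 1))[, 1]
    genes <- c(gene_a, gene_b)

    silent <- matrix(FALSE, 2 * n_pairs, n_groups)
    if (silent_fraction > 0) {
      silent[] <- runif(length(silent)) < silent_fraction
    }
    counts <- matrix(0L, 2 * n_pairs, length(cols),
                     dimnames = list(genes, cols))
    for (j in seq_along(cols)) {
      g <- match(groups[[j]], sprintf("g%d", seq_len(n_groups)))
      m <- mu * !silent[, g]
      lambda <- m / sum(m) * library_size
      counts[, j] <- if (dispersion > 0) {
        rnbinom(length(lambda), mu = lambda, size = 1 / dispersion)
      } else {
        rpois(length(lambda), lambda)
      }
    }
    pairs <- tibble(pair_id = sprintf("pair%05d", seq_len(n_pairs)),
                    gene_A = gene_a, gene_B = gene_b, status = status)
    list(counts = counts, groups = groups, pairs = pairs,
         truth = list(median_bias = median_bias, ratio = ratio,
                      bias_follows = bias_follows, status = status))
  })
}

#' Simulate an ortholog table with planted retention fractions
#'
#' Each row is an ancestral (outgroup) gene; its A and B co-ortholog lists
#' are retained independently with the planted probabilities.
#'
#' @param n Number of ancestral genes.
#' @param retention_a,retention_b Retention probabilities per subgenome.
#' @param seed Integer seed, or `NULL`.
#' @return A tibble with columns `ancestral_id`, `orthologs_A`,
#'   `orthologs_B` (list columns of gene ids).
#' @export
simulate_ortholog_table <- function(n = 15000, retention_a = 0.839,
                                    retention_b = 0.871, seed = NULL) {
  with_seed(seed, {
    keep_a <- runif(n) < retention_a
    keep_b <- runif(n) < retention_b
    tibble(
      ancestral_id = sprintf("anc%05d", seq_len(n)),
      orthologs_A = purrr::map2(keep_a, seq_len(n),
                                ~ if (.x) sprintf("A%05d", .y) else character()),
      orthologs_B = purrr::map2(keep_b, seq_len(n),
                                ~ if (.x) sprintf("B%05d", .y) else character())
    )
  })
}

#' Simulate diverged homeolog coding-sequence pairs
#'
#' Each pair descends from a random stop-free ancestral CDS; both copies
#' evolve independently for `time_my` under Jukes-Cantor at the given rate
#' (no selection, so synonymous sites clock at the nucleotide rate). Codons
#' that acquire an internal stop in either copy are masked to `NNN` in both,
#' which downstream Ks estimation skips by pairwise deletion.
#'
#' @param n_pairs Number of CDS pairs.
#' @param n_codons Codons per CDS.
#' @param time_my Divergence time in My (each branch evolves this long).
#' @param rate Substitution rate per site per year.
#' @param seed Integer seed, or `NULL`.
#' @return A tibble: `id`, `cds_1`, `cds_2`.
#' @export
simulate_coding_pairs <- function(n_pairs, n_codons = 300, time_my, rate,
                                  seed = NULL) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  stops <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"]
  p_change <- 0.75 * (1 - exp(-(4 / 3) * rate * time_my * 1e6))
  with_seed(seed, {
    rows <- lapply(seq_len(n_pairs), function(i) {
      anc <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
      s1 <- mutate_sequence(anc, p_change)
      s2 <- mutate_sequence(anc, p_change)
      idx <- 3 * seq_len(n_codons) - 2
      co1 <- substring(s1, idx, idx + 2)
      co2 <- substring(s2, idx, idx + 2)
      bad <- co1 %in% stops | co2 %in% stops
      if (any(bad)) {
        co1[bad] <- "NNN"
        co2[bad] <- "NNN"
        s1 <- paste(co1, collapse = "")
        s2 <- paste(co2, collapse = "")
      }
      tibble(id = sprintf("pair%04d", i), cds_1 = s1, cds_2 = s2)
    })
    dplyr::bind_rows(rows)
  })
}

#' Simulate allele read depths for an admixed accession
#'
#' At each ancestry-informative marker, total read depth is Poisson and the
#' species-1 read count is binomial with success probability
#' `dosage_1 / ploidy`, shifted by the sequencing error rate.
#'
#' @param ploidy Accession ploidy (2, 3, or 4).
#' @param markers Tibble with `chrom` and `pos` (1-based positions).
#' @param blocks Ancestry truth: tibble `chrom`, `start`, `end` (0-based
#'   half-open), `dosage_1` (copies of species-1 ancestry, 0..ploidy).
#'   Blocks must tile each chromosome's marker range.
#' @param depth_mean Mean total depth per marker.
#' @param error_rate Per-read probability of reporting the wrong species
#'   allele.
#' @param seed Integer seed, or `NULL`.
#' @return A list: `depths` tibble (`chrom`, `pos`, `depth_1`, `depth_2`)
#'   and `truth` (the blocks, with `dosage_2 = ploidy - dosage_1`).
#' @export
simulate_admixed_accession <- function(ploidy, markers, blocks,
                                       depth_mean = 10, error_rate = 0.01,
                                       seed = NULL) {
  if (!ploidy %in% 2:4) stop_input("`ploidy` must be 2, 3, or 4.")
  if (any(blocks$dosage_1 < 0 | blocks$dosage_1 > ploidy)) {
    stop_input("Block dosage must lie in 0..ploidy.")
  }
  with_seed(seed, {
    m <- dplyr::arrange(markers, .data$chrom, .data$pos)
    dos <- rep(NA_real_, nrow(m))
    for (ch in unique(blocks$chrom)) {
      bl <- blocks[blocks$chrom == ch, , drop = FALSE]
      sel <- which(m$chrom == ch)
      idx <- findInterval(m$pos[sel] - 1L, bl$start)
      ok <- idx >= 1 & (m$pos[sel] - 1L) < bl$end[pmax(idx, 1L)]
      dos[sel[ok]] <- bl$dosage_1[idx[ok]]
    }
    if (anyNA(dos)) stop_input("Every marker must be covered by an ancestry block.")
    p <- dos / ploidy
    p_adj <- p * (1 - error_rate) + (1 - p) * error_rate
    total <- rpois(nrow(m), depth_mean)
    d1 <- rbinom(nrow(m), total, p_adj)
    depths <- tibble(chrom = m$chrom, pos = m$pos,
                     depth_1 = d1, depth_2 = total - d1)
    truth <- dplyr::mutate(blocks, dosage_2 = ploidy - .data$dosage_1)
    list(depths = depths, truth = truth, ploidy = ploidy)
  })
}

#' Simulate a triploid interspecific hybrid with deviant ancestry blocks
#'
#' "Illinois-like" preset: a triploid whose genome-wide ancestry dosage is
#' 2:1 (species 1 : species 2), with a chosen fraction of each chromosome
#' carrying a deviant 1:2 block. Blocks are aligned to an implicit grid of
#' `n_windows_per_chrom` windows so the deviant fraction is exact.
#'
#' @param seed Integer seed.
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Chromosome length in bp.
#' @param n_markers_per_chrom Ancestry-informative markers per chromosome.
#' @param n_windows_per_chrom Windows per chromosome for block alignment.
#' @param deviant_fraction Fraction of windows carrying the deviant dosage.
#' @param ploidy Ploidy (default 3).
#' @param dosage_major,dosage_deviant Species-1 copy number in the bulk and
#'   in deviant blocks.
#' @param depth_mean,error_rate Sequencing model parameters.
#' @return As [simulate_admixed_accession()], plus `window_size` and
#'   `markers`.
#' @export
simulate_triploid_preset <- function(seed, n_chromosomes = 4,
                                     chromosome_length = 2e7,
                                     n_markers_per_chrom = 1000,
                                     n_windows_per_chrom = 20,
                                     deviant_fraction = 0.05, ploidy = 3,
                                     dosage_major = 2, dosage_deviant = 1,
                                     depth_mean = 10, error_rate = 0.01) {
  with_seed(seed, {
    wsize <- chromosome_length / n_windows_per_chrom
    chroms <- sprintf("chr%02d", seq_len(n_chromosomes))
    markers <- dplyr::bind_rows(lapply(chroms, function(ch) {
      tibble(chrom = ch,
             pos = sort(sample.int(chromosome_length, n_markers_per_chrom)))
    }))
    n_dev <- round(deviant_fraction * n_windows_per_chrom)
    blocks <- dplyr::bind_rows(lapply(chroms, function(ch) {
      if (n_dev == 0) {
        return(tibble(chrom = ch, start = 0, end = chromosome_length,
                      dosage_1 = dosage_major))
      }
      w0 <- sample.int(n_windows_per_chrom - n_dev, 1)  # deviant run start
      cuts <- c(0, w0 * wsize, (w0 + n_dev) * wsize, chromosome_length)
      tibble(chrom = ch, start = cuts[c(1, 2, 3)], end = cuts[c(2, 3, 4)],
             dosage_1 = c(dosage_major, dosage_deviant, dosage_major))
    }))
    blocks <- blocks[blocks$end > blocks$start, , drop = FALSE]
    out <- simulate_admixed_accession(ploidy, markers, blocks,
                                      depth_mean = depth_mean,
                                      error_rate = error_rate)
    out$window_size <- wsize
    out$markers <- markers
    out
  })
}

#' Simulate an exemplar genotype panel for marker discovery
#'
#' Generates candidate SNP sites of several classes -- true fixed differences
#' between two species, shared polymorphisms, and species-private
#' polymorphisms -- genotypes them in diploid exemplars (with optional
#' missingness and heterozygous contamination), and emits a repeat mask.
#' The truth lists the fixed-difference sites outside the mask, i.e. the set
#' an exhaustive scan should recover.
#'
#' @param seed Integer seed.
#' @param n_sites Number of candidate sites.
#' @param n_exemplars Diploid exemplars per species.
#' @param chrom_length Chromosome length (single chromosome panel).
#' @param fixed_fraction Fraction of sites that are true fixed differences.
#' @param missing_rate Per-genotype missing probability.
#' @param het_sites Number of fixed-difference sites corrupted to
#'   heterozygous in one exemplar (these must be rejected).
#' @param mask_fraction Fraction of the chromosome covered by the repeat
#'   mask.
#' @return A list: `genotypes` (tibble `chrom`, `pos`, one column per
#'   exemplar with `"X/Y"` calls or `NA`), `species` (named vector mapping
#'   exemplar to species), `mask` (tibble `chrom`, `start`, `end`), `truth`
#'   (tibble of recoverable fixed-difference markers).
#' @export
simulate_exemplar_panel <- function(seed, n_sites = 2000, n_exemplars = 2,
                                    chrom_length = 1e6, fixed_fraction = 0.5,
                                    missing_rate = 0.05, het_sites = 20,
                                    mask_fraction = 0.1) {
  with_seed(seed, {
    pos <- sort(sample.int(chrom_length, n_sites))
    class <- sample(c("fixed", "shared", "private"), n_sites, replace = TRUE,
                    prob = c(fixed_fraction, (1 - fixed_fraction) / 2,
                             (1 - fixed_fraction) / 2))
    al <- t(vapply(seq_len(n_sites), function(i) sample(.BASES, 2), character(2)))
    ex_names <- c(sprintf("sp1_ex%d", seq_len(n_exemplars)),
                  sprintf("sp2_ex%d", seq_len(n_exemplars)))
    species <- setNames(rep(c("sp1", "sp2"), each = n_exemplars), ex_names)

    geno <- matrix(NA_character_, n_sites, length(ex_names),
                   dimnames = list(NULL, ex_names))
    for (i in seq_len(n_sites)) {
      a1 <- al[i, 1]; a2 <- al[i, 2]
      g <- switch(class[[i]],
        fixed = c(rep(paste0(a1, "/", a1), n_exemplars),
                  rep(paste0(a2, "/", a2), n_exemplars)),
        shared = rep(paste0(a1, "/", a1), 2 * n_exemplars),
        private = {
          g0 <- rep(paste0(a1, "/", a1), 2 * n_exemplars)
          g0[sample.int(2 * n_exemplars, 1)] <- paste0(a1, "/", a2)
          g0
        })
      geno[i, ] <- g
    }
    # corrupt some fixed sites with a heterozygous call (not fixed -> reject)
    fixed_idx <- which(class == "fixed")
    het_idx <- head(fixed_idx, het_sites)
    for (i in het_idx) {
      geno[i, sample.int(length(ex_names), 1)] <- paste0(al[i, 1], "/", al[i, 2])
    }
    # missingness (never blanking a whole species at a site)
    miss <- matrix(runif(length(geno)) < missing_rate, nrow(geno))
    for (sp in unique(species)) {
      cols <- which(species[colnames(geno)] == sp)
      all_miss <- rowSums(miss[, cols, drop = FALSE]) == length(cols)
      miss[all_miss, cols[1]] <- FALSE
    }
    geno[miss] <- NA_character_

    n_mask <- max(1L, round(mask_fraction * chrom_length / 5e4))
    mask_start <- sort(sample.int(chrom_length - 5e4, n_mask))
    mask <- tibble(chrom = "chr01", start = mask_start, end = mask_start + 5e4)

    genotypes <- dplyr::bind_cols(tibble(chrom = "chr01", pos = pos),
                                  as_tibble(geno))
    truth_ok <- class == "fixed" & !(seq_len(n_sites) %in% het_idx) &
      !positions_in_mask(pos, mask)
    truth <- tibble(chrom = "chr01", pos = pos[truth_ok],
                    allele_sp1 = al[truth_ok, 1], allele_sp2 = al[truth_ok, 2])
    list(genotypes = genotypes, species = species, mask = mask, truth = truth)
  })
}

positions_in_mask <- function(pos, mask) {
  if (is.null(mask) || nrow(mask) == 0) return(rep(FALSE, length(pos)))
  mask <- merge_intervals(mask[order(mask$start), , drop = FALSE])
  idx <- findInterval(pos - 1L, mask$start)
  idx >= 1 & (pos - 1L) < mask$end[pmax(idx, 1L)]
}

merge_intervals <- function(iv) {
  if (nrow(iv) <= 1) return(iv)
  start <- iv$start; end <- iv$end
  keep_start <- numeric(0); keep_end <- numeric(0)
  cs <- start[1]; ce <- end[1]
  for (i in seq_len(nrow(iv))[-1]) {
    if (start[i] <= ce) {
      ce <- max(ce, end[i])
    } else {
      keep_start <- c(keep_start, cs); keep_end <- c(keep_end, ce)
      cs <- start[i]; ce <- end[i]
    }
  }
  tibble(chrom = iv$chrom[1], start = c(keep_start, cs), end = c(keep_end, ce))
}
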