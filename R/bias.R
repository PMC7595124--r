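# Subgenome bias in gene retention (exact 2x2 test) and homeolog expression
# (median B/A ratio, X-fold bias counts), with exchanged-region
# stratification in source-subgenome orientation.

#' Counts per million after combining replicates
#'
#' Sums replicate columns within each group, then scales every group column
#' to counts per million.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @param groups Character vector assigning each column to a replicate group.
#' @return A cpm matrix, genes x groups; every column sums to 1e6.
#' @export
#' @examples
#' cpm(matrix(c(3, 7), 1, 2, dimnames = list("g", c("r1", "r2"))),
#'     groups = c("a", "a"))
cpm <- function(counts, groups) {
  if (length(groups) != ncol(counts)) {
    stop_input("`groups` must assign every column to exactly one group.")
  }
  if (any(counts < 0)) stop_input("Counts must be non-negative.")
  glev <- unique(groups)
  combined <- vapply(glev, function(g) {
    rowSums(counts[, groups == g, drop = FALSE])
  }, numeric(nrow(counts)))
  combined <- matrix(combined, nrow = nrow(counts),
                     dimnames = list(rownames(counts), glev))
  tot <- colSums(combined)
  if (any(tot == 0)) {
    stop_degenerate(paste0("Zero-total replicate group(s): ",
                           paste(glev[tot == 0], collapse = ", ")))
  }
  sweep(combined, 2, tot, "/") * 1e6
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by full hypergeometric enumeration: the sum of the
#' probabilities of all tables with the observed margins whose point
#' probability does not exceed that of the observed table (within 1e-7
#' relative tolerance).
#'
#' @param a,b,c,d Cell counts, row-wise: `matrix(c(a, b, c, d), 2, byrow = TRUE)`.
#' @return The two-sided p-value; an all-zero table gives 1 by convention.
#' @export
#' @examples
#' fisher_exact_2x2(1, 9, 11, 3)
fisher_exact_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != round(c(a, b, c, d)))) {
    stop_input("Cell counts must be non-negative integers.")
  }
  if (a + b + c + d == 0) return(1)
  x <- max(0, (a + b) - (b + d)):min(a + b, a + c)
  probs <- dhyper(x, a + c, b + d, a + b)
  obs <- dhyper(a, a + c, b + d, a + b)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

#' Subgenome gene-retention fractions and exact test
#'
#' Treats each ortholog-table row as one ancestral (preduplication) gene; it
#' counts as retained on a subgenome when its co-ortholog list there is
#' non-empty. Retention fractions per subgenome are compared with a
#' two-sided exact test on the 2x2 retained/lost table.
#'
#' @param ortholog_table Tibble with list columns `orthologs_A`,
#'   `orthologs_B` (see [simulate_ortholog_table()]).
#' @return A `retention_summary` list: `retained_A`, `lost_A`, `retained_B`,
#'   `lost_B`, `fraction_A`, `fraction_B`, `p_two_sided`.
#' @export
retention_fractions <- function(ortholog_table) {
  if (nrow(ortholog_table) == 0) stop_input("Empty ortholog table.")
  ret_a <- lengths(ortholog_table$orthologs_A) > 0
  ret_b <- lengths(ortholog_table$orthologs_B) > 0
  n <- nrow(ortholog_table)
  out <- list(
    retained_A = sum(ret_a), lost_A = n - sum(ret_a),
    retained_B = sum(ret_b), lost_B = n - sum(ret_b),
    fraction_A = mean(ret_a), fraction_B = mean(ret_b),
    p_two_sided = fisher_exact_2x2(sum(ret_a), n - sum(ret_a),
                                   sum(ret_b), n - sum(ret_b))
  )
  structure(out, class = "retention_summary")
}

#' @export
print.retention_summary <- function(x, ...) {
  cat(sprintf("<retention_summary> A: %.1f%% (%d/%d), B: %.1f%% (%d/%d), two-sided exact p = %.3g\n",
              100 * x$fraction_A, x$retained_A, x$retained_A + x$lost_A,
              100 * x$fraction_B, x$retained_B, x$retained_B + x$lost_B,
              x$p_two_sided))
  invisible(x)
}

#' Build per-pair homeolog expression records
#'
#' Joins a cpm matrix to a homeolog pair table, one record per pair and
#' sample group.
#'
#' @param cpm_matrix cpm matrix from [cpm()] (genes x groups).
#' @param pairs Tibble with `pair_id`, `gene_A`, `gene_B` and optional
#'   `status` ("ancestral"/"exchanged").
#' @return A tibble: `pair_id`, `group`, `cpm_A`, `cpm_B`, `status`.
#' @export
pair_cpm_records <- function(cpm_matrix, pairs) {
  missing_g <- setdiff(c(pairs$gene_A, pairs$gene_B), rownames(cpm_matrix))
  if (length(missing_g) > 0) {
    stop_input(paste0(length(missing_g), " pair genes missing from cpm matrix."))
  }
  status <- pairs$status %||% rep("ancestral", nrow(pairs))
  dplyr::bind_rows(lapply(colnames(cpm_matrix), function(g) {
    tibble(pair_id = pairs$pair_id, group = g,
           cpm_A = cpm_matrix[pairs$gene_A, g],
           cpm_B = cpm_matrix[pairs$gene_B, g],
           status = status)
  }))
}

#' Homeolog expression-bias statistics
#'
#' For each sample group and pooled across groups: the median B/A cpm ratio
#' over pairs where both members exceed `min_cpm` (a one-sided silent member
#' would make the ratio infinite), and counts of pairs expressed at least
#' X-fold higher from one subgenome, over pairs where at least one member
#' exceeds `min_cpm`, with the silent member floored at a 0.5-cpm
#' pseudocount. The percent excess of B-favored pairs is
#' `100 * (n_B - n_A) / (n_B + n_A)` at each fold.
#'
#' @param records Record tibble from [pair_cpm_records()].
#' @param min_cpm Expression floor (strictly greater-than; default 0.5).
#' @param folds Fold thresholds (default 2, 5, 10).
#' @return A `bias_report`: list with `by_group` and `pooled` tibbles
#'   (median ratio and per-fold counts) and the parameters used.
#' @export
pair_bias_stats <- function(records, min_cpm = 0.5, folds = c(2, 5, 10)) {
  if (nrow(records) == 0) stop_input("No expression records.")
  qualifying <- records$cpm_A > min_cpm | records$cpm_B > min_cpm
  if (!any(qualifying)) stop_input("No pair passes the cpm filter.")
  stats_for <- function(rec) {
    both <- rec$cpm_A > min_cpm & rec$cpm_B > min_cpm
    either <- rec$cpm_A > min_cpm | rec$cpm_B > min_cpm
    ratio <- rec$cpm_B[both] / rec$cpm_A[both]
    effA <- pmax(rec$cpm_A[either], 0.5)
    effB <- pmax(rec$cpm_B[either], 0.5)
    fold_counts <- dplyr::bind_rows(lapply(folds, function(X) {
      n_b <- sum(effB >= X * effA)
      n_a <- sum(effA >= X * effB)
      tibble(fold = X, n_B_favored = n_b, n_A_favored = n_a,
             excess_pct = if (n_a + n_b > 0) 100 * (n_b - n_a) / (n_b + n_a) else 0)
    }))
    list(n_ratio = sum(both), n_fold = sum(either),
         median_BA = if (any(both)) median(ratio) else NA_real_,
         folds = fold_counts)
  }
  per_group <- lapply(split(records, records$group), stats_for)
  by_group <- dplyr::bind_rows(lapply(names(per_group), function(g) {
    s <- per_group[[g]]
    dplyr::mutate(s$folds, group = g, n_pairs_ratio = s$n_ratio,
                  median_BA = s$median_BA, .before = 1)
  }))
  pooled_s <- stats_for(records)
  pooled <- dplyr::mutate(pooled_s$folds, group = "pooled",
                          n_pairs_ratio = pooled_s$n_ratio,
                          median_BA = pooled_s$median_BA, .before = 1)
  structure(list(by_group = by_group, pooled = pooled,
                 min_cpm = min_cpm, folds = folds),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("<bias_report> pooled median B/A = %.4f over %d pairs (cpm > %g)\n",
              x$pooled$median_BA[1], x$pooled$n_pairs_ratio[1], x$min_cpm))
  print(x$pooled[, c("fold", "n_B_favored", "n_A_favored", "excess_pct")])
  invisible(x)
}

#' Expression bias stratified by homeologous-exchange status
#'
#' Computes bias statistics separately for pairs in ancestral regions and for
#' pairs in exchanged regions, orienting exchanged pairs by their source
#' subgenome (an exchanged pair's current A-location gene descends from the B
#' progenitor, so its ratio is flipped). Reports the difference of stratum
#' medians with a seeded bootstrap confidence interval; if bias tracks the
#' current location instead of the source, the exchanged-stratum median flips
#' to the reciprocal side of 1.
#'
#' @param records Record tibble from [pair_cpm_records()] with a `status`
#'   column ("ancestral"/"exchanged").
#' @param min_cpm Expression floor.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap, or `NULL`.
#' @return A `stratified_bias` list: `ancestral`, `exchanged` (bias reports,
#'   `NULL` with a flag when a stratum is empty), `median_diff`, `ci`,
#'   `orientation` ("source").
#' @export
exchanged_region_bias <- function(records, min_cpm = 0.5, n_boot = 1000,
                                  seed = NULL) {
  if (!"status" %in% names(records)) {
    stop_input("`records` needs a `status` column (ancestral/exchanged).")
  }
  oriented <- records
  flip <- oriented$status == "exchanged"
  tmp <- oriented$cpm_A[flip]
  oriented$cpm_A[flip] <- oriented$cpm_B[flip]
  oriented$cpm_B[flip] <- tmp

  strata <- split(oriented, oriented$status)
  get_report <- function(s) {
    if (is.null(strata[[s]]) || nrow(strata[[s]]) == 0) return(NULL)
    pair_bias_stats(strata[[s]], min_cpm = min_cpm)
  }
  anc <- get_report("ancestral")
  exc <- get_report("exchanged")
  missing_stratum <- c("ancestral", "exchanged")[c(is.null(anc), is.null(exc))]
  med_diff <- ci <- NULL
  if (is.null(anc) || is.null(exc)) {
    warn(sprintf("Empty stratum: %s; difference of medians not computed.",
                 paste(missing_stratum, collapse = ", ")))
  } else {
    ratios <- function(rec) {
      both <- rec$cpm_A > min_cpm & rec$cpm_B > min_cpm
      rec$cpm_B[both] / rec$cpm_A[both]
    }
    r_anc <- ratios(strata$ancestral)
    r_exc <- ratios(strata$exchanged)
    med_diff <- median(r_exc) - median(r_anc)
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        median(sample(r_exc, replace = TRUE)) -
          median(sample(r_anc, replace = TRUE))
      }, numeric(1))
    })
    ci <- unname(quantile(boot, c(0.025, 0.975)))
  }
  structure(list(ancestral = anc, exchanged = exc, median_diff = med_diff,
                 ci = ci, missing = missing_stratum, orientation = "source"),
            class = "stratified_bias")
}

#' @export
print.stratified_bias <- function(x, ...) {
  cat("<stratified_bias> (source-subgenome orientation)\n")
  for (s in c("ancestral", "exchanged")) {
    r <- x[[s]]
    if (is.null(r)) {
      cat(sprintf("  %s: missing\n", s))
    } else {
      cat(sprintf("  %s: median B/A = %.4f (%d pairs)\n", s,
                  r$pooled$median_BA[1], r$pooled$n_pairs_ratio[1]))
    }
  }
  if (!is.null(x$median_diff)) {
    cat(sprintf("  difference of medians %.4f (95%% CI %.4f to %.4f)\n",
                x$median_diff, x$ci[1], x$ci[2]))
  }
  invisible(x)
}
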