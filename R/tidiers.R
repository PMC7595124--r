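# broom-style tidiers for the package's fitted/result objects.

#' Tidy a subgenome partition
#'
#' @param x A `subgenome_partition`.
#' @param ... Unused.
#' @return A tibble with `chromosome` and `subgenome`.
#' @export
tidy.subgenome_partition <- function(x, ...) {
  x$tbl
}

#' One-row summary of a subgenome partition
#'
#' @param x A `subgenome_partition`.
#' @param ... Unused.
#' @return A tibble with `n_chromosomes`, `score`, `consistent`.
#' @export
glance.subgenome_partition <- function(x, ...) {
  tibble(n_chromosomes = length(x$assignment), score = x$score,
         consistent = x$consistent)
}

#' Tidy a retention summary
#'
#' @param x A `retention_summary`.
#' @param ... Unused.
#' @return A tibble with one row per subgenome.
#' @export
tidy.retention_summary <- function(x, ...) {
  tibble(subgenome = c("A", "B"),
         retained = c(x$retained_A, x$retained_B),
         lost = c(x$lost_A, x$lost_B),
         fraction = c(x$fraction_A, x$fraction_B))
}

#' One-row summary of a retention test
#'
#' @param x A `retention_summary`.
#' @param ... Unused.
#' @return A tibble with the fractions and the two-sided exact p-value.
#' @export
glance.retention_summary <- function(x, ...) {
  tibble(fraction_A = x$fraction_A, fraction_B = x$fraction_B,
         p_two_sided = x$p_two_sided)
}

#' Tidy an expression-bias report
#'
#' @param x A `bias_report`.
#' @param ... Unused.
#' @return The per-group fold-count tibble, pooled rows included.
#' @export
tidy.bias_report <- function(x, ...) {
  dplyr::bind_rows(x$by_group, x$pooled)
}

#' One-row summary of an expression-bias report
#'
#' @param x A `bias_report`.
#' @param ... Unused.
#' @return A tibble with the pooled median ratio and pair count.
#' @export
glance.bias_report <- function(x, ...) {
  tibble(median_BA = x$pooled$median_BA[1],
         n_pairs = x$pooled$n_pairs_ratio[1], min_cpm = x$min_cpm)
}

#' Tidy a Ks event-time estimate
#'
#' @param x A `ks_event_time`.
#' @param ... Unused.
#' @return The tibble of density modes with their implied times.
#' @export
tidy.ks_event_time <- function(x, ...) {
  x$modes
}

#' One-row summary of a Ks event-time estimate
#'
#' @param x A `ks_event_time`.
#' @param ... Unused.
#' @return A tibble with the time, mode, CI, and sample size.
#' @export
glance.ks_event_time <- function(x, ...) {
  tibble(time_my = x$time_my, mode_ks = x$mode_ks,
         ci_low_my = x$ci_my[1], ci_high_my = x$ci_my[2], n = x$n)
}

#' Tidy an ancestry summary
#'
#' @param x An `ancestry_summary`.
#' @param ... Unused.
#' @return A tibble with one row per species.
#' @export
tidy.ancestry_summary <- function(x, ...) {
  tibble(species = c(1L, 2L),
         fraction = c(x$fraction_1, x$fraction_2),
         modal_dosage = x$modal_dosage)
}
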