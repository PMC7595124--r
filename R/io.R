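# Plain-text serialization: FASTA for genomes, BED for intervals and tracks,
# TSV + JSON for ground truth. All coordinates written 0-based half-open.

#' Write a genome as FASTA
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @param width Line width (default 80).
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 80) {
  Biostrings::writeXStringSet(as_dnastringset(as_character_genome(genome)),
                              path, width = width)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write a density track as BED4
#'
#' One line per window: chrom, start, end, and `"nA|nB"` in the name column.
#'
#' @param track Tibble from [density_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_bed <- function(track, path) {
  lines <- sprintf("%s\t%d\t%d\t%d|%d", track$chrom, as.integer(track$start),
                   as.integer(track$end), track$n_A, track$n_B)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED4 density track
#'
#' @param path BED4 path written by [write_track_bed()].
#' @return A density-track tibble (`chrom`, `start`, `end`, `window`,
#'   `n_A`, `n_B`).
#' @export
read_track_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", col.names = c("chrom", "start",
                                                           "end", "name"))
  ab <- do.call(rbind, strsplit(raw$name, "|", fixed = TRUE))
  out <- tibble(chrom = raw$chrom, start = raw$start, end = raw$end,
                n_A = as.integer(ab[, 1]), n_B = as.integer(ab[, 2]))
  dplyr::mutate(dplyr::group_by(out, .data$chrom),
                window = dplyr::row_number() - 1L,
                .after = "end") |> dplyr::ungroup()
}

#' Write ancestry or dosage segments as BED6
#'
#' The name column carries the state (or dosage vector `d1:d2`), the score
#' column the mean posterior scaled to 0-1000.
#'
#' @param segments Tibble from [segment_ancestry()] or [smooth_dosage()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  name <- if ("state" %in% names(segments)) {
    segments$state
  } else {
    sprintf("%d:%d", segments$dosage_1, segments$dosage_2)
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.", segments$chrom,
                   as.integer(segments$start), as.integer(segments$end),
                   name, as.integer(round(1000 * segments$mean_posterior)))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize synthetic ground truth
#'
#' Writes the truth of a synthetic dataset as BED-compatible TSVs (exchange
#' intervals, TE registry) plus a JSON sidecar holding the scalar fields.
#'
#' @param truth A `synthetic_truth` object (see [hybridize()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(truth$exchange_intervals,
                     file.path(dir, "exchange_intervals.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$te_registry, file.path(dir, "te_registry.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(subgenome_of_chromosome = as.list(truth$subgenome_of_chromosome),
         chromosome_lengths = as.list(truth$chromosome_lengths)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
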