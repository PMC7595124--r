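# Synthetic allotetraploid data generator with planted ground truth.
#
# The generator emulates the evolutionary history the analysis modules are
# built to reconstruct: two progenitor lineages diverge from a common
# ancestor, each accumulates lineage-specific transposon bursts, the two are
# merged into a tetraploid with optional reciprocal distal exchanges, and a
# shared burst postdates hybridization. Companion generators produce homeolog
# count matrices with a planted median B/A bias, dated LTR pairs, and admixed
# accessions with planted ancestry blocks. Every dataset ships with its truth.

#' Simulate an ancestral genome
#'
#' Draws `n_chromosomes` i.i.d. random DNA sequences at the requested GC
#' content. This is the common ancestor from which the two progenitor
#' lineages are derived with [diverge()].
#'
#' @param n_chromosomes Number of chromosomes (>= 1).
#' @param chromosome_length Length of each chromosome in bp.
#' @param gc_content Fraction of G+C in (0, 1]; 0.5 gives uniform bases.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param prefix Chromosome name prefix.
#' @return A [Biostrings::DNAStringSet] named `<prefix>01`, `<prefix>02`, ...
#' @export
#' @examples
#' anc <- simulate_ancestor(2, 1000, seed = 1)
simulate_ancestor <- function(n_chromosomes, chromosome_length, gc_content = 0.5,
                              seed = NULL, prefix = "chr") {
  if (n_chromosomes < 1) stop_input("`n_chromosomes` must be >= 1.")
  if (chromosome_length <= 0) stop_input("`chromosome_length` must be positive.")
  if (gc_content < 0 || gc_content > 1) stop_input("`gc_content` must be in [0, 1].")
  probs <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2, (1 - gc_content) / 2)
  with_seed(seed, {
    seqs <- vapply(seq_len(n_chromosomes), function(i) {
      paste(sample(.BASES, chromosome_length, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
    names(seqs) <- sprintf("%s%02d", prefix, seq_len(n_chromosomes))
    Biostrings::DNAStringSet(seqs)
  })
}

#' Mutate a genome under the Jukes-Cantor model
#'
#' Applies `rate * time` expected substitutions per site under the
#' Jukes-Cantor model: each site changes to one of the three other bases with
#' probability \eqn{(3/4)(1 - e^{-(4/3) r t})}, the exact JC transition
#' probability, so the expected observed p-distance to the input equals that
#' closed form and inverts exactly through [jukes_cantor()].
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param rate Substitution rate per site per year.
#' @param time Elapsed time in years.
#' @param seed Integer seed, or `NULL`.
#' @return A mutated genome of the same class and names as the input.
#' @export
diverge <- function(genome, rate, time, seed = NULL) {
  d <- rate * time
  if (d < 0) stop_input("`rate * time` must be non-negative.")
  if (d >= 0.7) {
    stop_saturation(sprintf(
      "rate * time = %.3g saturates the Jukes-Cantor model (limit 0.7).", d))
  }
  seqs <- as_character_genome(genome)
  p_change <- 0.75 * (1 - exp(-(4 / 3) * d))
  out <- with_seed(seed, {
    vapply(seqs, function(s) mutate_sequence(s, p_change), character(1))
  })
  names(out) <- names(seqs)
  if (inherits(genome, "DNAStringSet")) Biostrings::DNAStringSet(out) else out
}

mutate_sequence <- function(s, p_change) {
  if (p_change == 0) return(s)
  codes <- seq_to_codes(s)
  n <- length(codes)
  n_mut <- rbinom(1L, n, p_change)
  if (n_mut == 0L) return(s)
  idx <- sample.int(n, n_mut)
  idx <- idx[!is.na(codes[idx])]
  if (length(idx) == 0L) return(s)
  codes[idx] <- (codes[idx] + sample.int(3L, length(idx), replace = TRUE)) %% 4L
  codes_to_seq(codes)
}

#' Build an LTR retrotransposon consensus
#'
#' Constructs a consensus element `LTR + internal + LTR` whose two terminal
#' repeats are identical, as they are at the moment of insertion. Copies
#' planted with [plant_te_burst()] then accumulate substitutions, so the two
#' LTRs of a copy diverge with expectation `2 * rate * age` -- the molecular
#' clock [ltr_insertion_age()] reads.
#'
#' @param internal_length,ltr_length Lengths in bp of the internal region and
#'   of each terminal repeat.
#' @param gc_content GC fraction of the consensus.
#' @param seed Integer seed, or `NULL`.
#' @return A list with `consensus` (character) and `ltr_length`.
#' @export
make_ltr_consensus <- function(internal_length = 400, ltr_length = 300,
                               gc_content = 0.5, seed = NULL) {
  with_seed(seed, {
    probs <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
               (1 - gc_content) / 2)
    ltr <- paste(sample(.BASES, ltr_length, TRUE, prob = probs), collapse = "")
    internal <- paste(sample(.BASES, internal_length, TRUE, prob = probs),
                      collapse = "")
    list(consensus = paste0(ltr, internal, ltr), ltr_length = ltr_length)
  })
}

#' Plant a transposable element burst
#'
#' Inserts `n_copies` of a family consensus at uniform random positions on the
#' target chromosomes. Each copy is independently mutated for its age at the
#' given rate before insertion, so for LTR families (identical terminal
#' repeats in the consensus) the two LTRs of a copy diverge with expectation
#' `2 * rate * age`. Insertions do not nest by default: a position landing
#' inside a previously registered copy is re-drawn.
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param family_id Family name recorded in the registry.
#' @param consensus Element consensus sequence (character scalar).
#' @param n_copies Number of copies to insert.
#' @param burst_age Age of the burst in My (every copy gets this age).
#' @param rate Substitution rate per site per year.
#' @param target_chromosomes Chromosome names to insert into; default all.
#' @param ltr_length Length of each terminal repeat within the consensus
#'   (0 for non-LTR families); recorded in the registry.
#' @param allow_nesting If `TRUE`, insertions may land inside earlier copies.
#' @param registry Prior registry tibble to extend (coordinates are shifted
#'   for the new insertions).
#' @param seed Integer seed, or `NULL`.
#' @return A list with the updated `genome` and the `registry` tibble
#'   (`family`, `chromosome`, `start`, `end`, `age_my`, `ltr_length`;
#'   0-based half-open coordinates). Attribute `n_redraws` counts rejected
#'   draws.
#' @export
plant_te_burst <- function(genome, family_id, consensus, n_copies, burst_age,
                           rate, target_chromosomes = NULL, ltr_length = 0,
                           allow_nesting = FALSE, registry = NULL, seed = NULL) {
  if (!nzchar(consensus)) stop_input("`consensus` must be a non-empty sequence.")
  seqs <- as_character_genome(genome)
  target_chromosomes <- target_chromosomes %||% names(seqs)
  missing_t <- setdiff(target_chromosomes, names(seqs))
  if (length(missing_t) > 0) {
    stop_input(paste0("Target chromosomes not in genome: ",
                      paste(missing_t, collapse = ", ")))
  }
  if (is.null(registry)) registry <- empty_te_registry()
  elem_len <- nchar(consensus)
  if (n_copies == 0) {
    out <- if (inherits(genome, "DNAStringSet")) genome else seqs
    return(list(genome = out, registry = registry))
  }

  with_seed(seed, {
    lens <- nchar(seqs[target_chromosomes])
    chrom_of <- sample(target_chromosomes, n_copies, replace = TRUE,
                       prob = lens / sum(lens))
    n_redraws <- 0L
    pos_of <- integer(n_copies)
    for (i in seq_len(n_copies)) {
      ch <- chrom_of[[i]]
      prior <- registry[registry$chromosome == ch, , drop = FALSE]
      repeat {
        p <- sample.int(lens[[ch]] + 1L, 1L) - 1L  # insert before base p (0-based)
        if (allow_nesting || nrow(prior) == 0L ||
            !any(p > prior$start & p < prior$end)) break
        n_redraws <- n_redraws + 1L
      }
      pos_of[[i]] <- p
    }
    copies <- vapply(seq_len(n_copies), function(i) {
      p_change <- 0.75 * (1 - exp(-(4 / 3) * rate * burst_age * 1e6))
      mutate_sequence(consensus, p_change)
    }, character(1))

    new_rows <- vector("list", length(target_chromosomes))
    names(new_rows) <- target_chromosomes
    for (ch in target_chromosomes) {
      sel <- which(chrom_of == ch)
      if (length(sel) == 0L) {
        new_rows[[ch]] <- NULL
        next
      }
      ord <- order(pos_of[sel])
      sel <- sel[ord]
      p <- pos_of[sel]
      # final coordinates: each earlier insertion shifts later ones by elem_len
      starts <- p + (seq_along(p) - 1L) * elem_len
      s <- seqs[[ch]]
      L <- nchar(s)
      bounds <- c(0L, p, L)
      pieces <- substring(s, bounds[-length(bounds)] + 1L, bounds[-1L])
      interleaved <- character(2L * length(p) + 1L)
      interleaved[seq(1L, by = 2L, length.out = length(pieces))] <- pieces
      interleaved[seq(2L, by = 2L, length.out = length(p))] <- copies[sel]
      seqs[[ch]] <- paste(interleaved, collapse = "")
      # shift prior registry entries downstream of the new insertion points
      hit <- registry$chromosome == ch
      if (any(hit)) {
        shift <- findInterval(registry$start[hit], p) * elem_len
        registry$start[hit] <- registry$start[hit] + shift
        registry$end[hit] <- registry$end[hit] + shift
      }
      new_rows[[ch]] <- tibble(
        family = family_id, chromosome = ch,
        start = starts, end = starts + elem_len,
        age_my = burst_age, ltr_length = as.integer(ltr_length)
      )
    }
    registry <- dplyr::bind_rows(c(list(registry),
                                   unname(purrr::compact(new_rows))))
    out <- if (inherits(genome, "DNAStringSet")) Biostrings::DNAStringSet(seqs) else seqs
    structure(list(genome = out, registry = registry), n_redraws = n_redraws)
  })
}

empty_te_registry <- function() {
  tibble(family = character(), chromosome = character(),
         start = integer(), end = integer(),
         age_my = numeric(), ltr_length = integer())
}

#' Merge two progenitor genomes into an allotetraploid
#'
#' Combines the chromosomes of two progenitor genomes (paired by index) into
#' one tetraploid genome and applies the requested homeologous exchanges. A
#' reciprocal exchange at `breakpoint_fraction` f swaps the distal fraction f
#' of each partner, conserving total sequence length; a non-reciprocal
#' exchange overwrites the B member's distal tail with a copy of the A
#' member's tail. TE registry coordinates of copies lying in swapped tails
#' are remapped to the receiving chromosome.
#'
#' @param genome_a,genome_b Progenitor genomes with equal chromosome counts.
#' @param exchanges Optional tibble with columns `pair` (1-based pair index),
#'   `breakpoint_fraction` in (0, 0.5), and `reciprocal` (logical, default
#'   `TRUE`).
#' @param registry_a,registry_b Optional TE registries for the progenitors.
#' @return A list with `genome` (DNAStringSet, chromosomes renamed
#'   `chr01`...`chr2n`, A member of pair i first), `truth` (a
#'   `synthetic_truth` list), and `homeolog_map` (tibble of paired names).
#' @export
hybridize <- function(genome_a, genome_b, exchanges = NULL,
                      registry_a = NULL, registry_b = NULL) {
  a <- as_character_genome(genome_a)
  b <- as_character_genome(genome_b)
  if (length(a) != length(b)) {
    stop_input("Progenitor genomes must have equal chromosome counts.")
  }
  n <- length(a)
  name_a <- sprintf("chr%02d", 2L * seq_len(n) - 1L)
  name_b <- sprintf("chr%02d", 2L * seq_len(n))

  reg <- dplyr::bind_rows(
    remap_names(registry_a %||% empty_te_registry(), names(a), name_a),
    remap_names(registry_b %||% empty_te_registry(), names(b), name_b)
  )
  seqs <- c(setNames(a, name_a), setNames(b, name_b))[order(c(name_a, name_b))]
  subg <- setNames(rep(c("A", "B"), n), c(rbind(name_a, name_b)))

  intervals <- tibble(chromosome = character(), start = integer(),
                      end = integer(), donor = character())
  if (!is.null(exchanges) && nrow(exchanges) > 0) {
    if (!all(c("pair", "breakpoint_fraction") %in% names(exchanges))) {
      stop_input("`exchanges` needs columns `pair` and `breakpoint_fraction`.")
    }
    if (!"reciprocal" %in% names(exchanges)) exchanges$reciprocal <- TRUE
    for (j in seq_len(nrow(exchanges))) {
      i <- exchanges$pair[[j]]
      f <- exchanges$breakpoint_fraction[[j]]
      if (f <= 0 || f >= 0.5) {
        stop_input("`breakpoint_fraction` must lie in (0, 0.5).")
      }
      ca <- name_a[[i]]; cb <- name_b[[i]]
      la <- nchar(seqs[[ca]]); lb <- nchar(seqs[[cb]])
      bpa <- la - as.integer(floor(f * la))
      bpb <- lb - as.integer(floor(f * lb))
      tail_a <- substring(seqs[[ca]], bpa + 1L, la)
      tail_b <- substring(seqs[[cb]], bpb + 1L, lb)
      if (isTRUE(exchanges$reciprocal[[j]])) {
        seqs[[ca]] <- paste0(substring(seqs[[ca]], 1L, bpa), tail_b)
        seqs[[cb]] <- paste0(substring(seqs[[cb]], 1L, bpb), tail_a)
        intervals <- dplyr::bind_rows(
          intervals,
          tibble(chromosome = ca, start = bpa, end = nchar(seqs[[ca]]), donor = "B"),
          tibble(chromosome = cb, start = bpb, end = nchar(seqs[[cb]]), donor = "A")
        )
        reg <- remap_tail(reg, ca, cb, bpa, bpb, swap = TRUE)
      } else {
        seqs[[cb]] <- paste0(substring(seqs[[cb]], 1L, bpb), tail_a)
        intervals <- dplyr::bind_rows(
          intervals,
          tibble(chromosome = cb, start = bpb, end = nchar(seqs[[cb]]), donor = "A")
        )
        reg <- remap_tail(reg, ca, cb, bpa, bpb, swap = FALSE)
      }
    }
  }

  homeolog_map <- tibble(member_1 = name_a, member_2 = name_b)
  truth <- structure(list(
    subgenome_of_chromosome = subg,
    exchange_intervals = intervals,
    te_registry = reg,
    chromosome_lengths = setNames(nchar(seqs), names(seqs))
  ), class = "synthetic_truth")
  list(genome = Biostrings::DNAStringSet(seqs), truth = truth,
       homeolog_map = homeolog_map)
}

remap_names <- function(registry, old, new) {
  if (nrow(registry) == 0) return(registry)
  registry$chromosome <- new[match(registry$chromosome, old)]
  registry
}

# Move registry entries in the exchanged tails to the receiving chromosome.
# Copies straddling a breakpoint stay with the chromosome holding their start.
remap_tail <- function(reg, ca, cb, bpa, bpb, swap) {
  in_a <- reg$chromosome == ca & reg$start >= bpa
  in_b <- reg$chromosome == cb & reg$start >= bpb
  if (swap) {
    len_a <- reg$end[in_a] - reg$start[in_a]
    len_b <- reg$end[in_b] - reg$start[in_b]
    new_start_a <- bpb + (reg$start[in_a] - bpa)
    new_start_b <- bpa + (reg$start[in_b] - bpb)
    reg$chromosome[in_a] <- cb
    reg$start[in_a] <- new_start_a
    reg$end[in_a] <- new_start_a + len_a
    reg$chromosome[in_b] <- ca
    reg$start[in_b] <- new_start_b
    reg$end[in_b] <- new_start_b + len_b
  } else {
    # one-sided: tail copies of B are overwritten (drop), A tail copies are
    # duplicated onto B
    dup <- reg[in_a, , drop = FALSE]
    if (nrow(dup) > 0) {
      off <- dup$start - bpa
      len <- dup$end - dup$start
      dup$chromosome <- cb
      dup$start <- bpb + off
      dup$end <- dup$start + len
    }
    reg <- dplyr::bind_rows(reg[!in_b, , drop = FALSE], dup)
  }
  reg
}
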