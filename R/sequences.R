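# Low-level DNA sequence helpers shared by the simulator and the k-mer counter.
# Sequences travel as Biostrings::DNAStringSet at the interface and as integer
# code vectors (A=0, C=1, G=2, T=3, anything else NA) internally.

.CODE_LUT <- {
  lut <- rep(NA_integer_, 127L)
  lut[utf8ToInt(c("A"))] <- 0L
  lut[utf8ToInt(c("C"))] <- 1L
  lut[utf8ToInt(c("G"))] <- 2L
  lut[utf8ToInt(c("T"))] <- 3L
  lut[utf8ToInt(c("a"))] <- 0L
  lut[utf8ToInt(c("c"))] <- 1L
  lut[utf8ToInt(c("g"))] <- 2L
  lut[utf8ToInt(c("t"))] <- 3L
  lut
}

.BASES <- c("A", "C", "G", "T")

seq_to_codes <- function(s) {
  .CODE_LUT[utf8ToInt(s)]
}

codes_to_seq <- function(codes) {
  out <- rep("N", length(codes))
  ok <- !is.na(codes)
  out[ok] <- .BASES[codes[ok] + 1L]
  paste(out, collapse = "")
}

as_character_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else if (is.character(genome)) {
    if (is.null(names(genome))) {
      names(genome) <- sprintf("chr%02d", seq_along(genome))
    }
    genome
  } else {
    stop_input("`genome` must be a DNAStringSet or a named character vector.")
  }
}

as_dnastringset <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  Biostrings::DNAStringSet(x)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' state afterwards. With `seed = NULL` the expression simply uses the
#' current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Reverse complement of DNA strings
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that accepts and
#' returns plain character vectors.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
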