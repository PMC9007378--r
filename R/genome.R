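#' Deterministic synthetic stand-in for the rCRS sequence
#'
#' Builds a reproducible 16,569-nucleotide circular sequence with the gross
#' features of the revised Cambridge Reference Sequence that the analysis
#' machinery relies on: the exact length, the L-strand base composition
#' (A 30.9%, C 31.3%, G 13.1%, T 24.7%), the `N` placeholder at position
#' 3107, and the two prominent D-loop poly-C tracts (around 303--315 and
#' 16184--16193). It is *not* the real rCRS: base identities elsewhere are
#' random (fixed internal seed), so sequence-derived results (codons,
#' trinucleotide contexts) are internally consistent but do not reproduce the
#' true human sequence. Supply the genuine NC_012920.1 FASTA to [mt_genome()]
#' for real-data work.
#'
#' @return Character vector of 16,569 single bases.
#' @seealso [mt_genome()]
#' @export
synthetic_mt_sequence <- function() {
  withr::with_seed(20120920L, {
    comp <- c(A = 0.309, C = 0.313, G = 0.131, T = 0.247)
    bases <- sample(names(comp), MT_LENGTH, replace = TRUE, prob = comp)
    # D-loop poly-C tract interrupted by T at 310, as in the rCRS
    bases[303:315] <- c(rep("C", 7), "T", rep("C", 5))
    # hypervariable-region poly-C tract
    bases[16184:16193] <- "C"
    bases[MT_PLACEHOLDER] <- "N"
    bases
  })
}

#' Load the circular mitochondrial reference genome
#'
#' Reads a single-sequence FASTA (via Biostrings) and returns the circular
#' genome model used throughout the package. With `fasta = NULL` the packaged
#' synthetic rCRS stand-in is used (see [synthetic_mt_sequence()]); pass the
#' path to the real NC_012920.1 FASTA for real analyses. The sequence must be
#' exactly 16,569 nucleotides (rCRS numbering, L-strand convention); position
#' 3107 is flagged non-callable.
#'
#' @param fasta Path to a FASTA file, or `NULL` for the packaged synthetic
#'   reference.
#' @return An object of class `mt_genome`: a list with `bases` (character
#'   vector of length 16,569), `length`, and `name`.
#' @export
#' @examples
#' g <- mt_genome()
#' g$length
mt_genome <- function(fasta = NULL) {
  if (is.null(fasta)) {
    fasta <- system.file("extdata", "synthetic_rcrs.fasta",
      package = "mtburden", mustWork = TRUE
    )
  }
  ss <- Biostrings::readDNAStringSet(fasta)
  if (length(ss) < 1) abort("FASTA file contains no sequence")
  bases <- strsplit(toupper(as.character(ss[[1]])), "")[[1]]
  if (length(bases) != MT_LENGTH) {
    abort(sprintf(
      "mitochondrial reference must be %d nt (rCRS numbering); got %d",
      MT_LENGTH, length(bases)
    ))
  }
  structure(
    list(bases = bases, length = MT_LENGTH, name = names(ss)[1]),
    class = "mt_genome"
  )
}

#' @export
print.mt_genome <- function(x, ...) {
  cat(sprintf(
    "<mt_genome> %s (%d bp, circular; position %d non-callable)\n",
    x$name %||% "unnamed", x$length, MT_PLACEHOLDER
  ))
  invisible(x)
}

#' Callable positions of the genome
#'
#' All positions except the rCRS placeholder at 3107.
#'
#' @param genome An `mt_genome`.
#' @return Integer vector of callable 1-based positions.
#' @export
callable_positions <- function(genome) {
  setdiff(seq_len(genome$length), MT_PLACEHOLDER)
}

#' Trinucleotide context on the L strand
#'
#' Returns the 5'-to-3' L-strand triplet centred on each position, wrapping
#' circularly across the origin (the 5' neighbour of position 1 is position
#' 16,569).
#'
#' @param pos Integer vector of 1-based positions.
#' @param genome An `mt_genome`.
#' @return Character vector of 3-mers; the middle base is the reference base
#'   at `pos`.
#' @export
#' @examples
#' g <- mt_genome()
#' trinucleotide_context(c(1, 16569), g)
trinucleotide_context <- function(pos, genome) {
  check_positions(pos)
  b <- genome$bases
  paste0(b[mt_wrap(pos - 1L)], b[pos], b[mt_wrap(pos + 1L)])
}

#' Homopolymer mask
#'
#' Flags every position inside a run of `min_run` or more identical
#' nucleotides, plus any explicitly supplied extra regions. Variant calls in
#' such tracts are unreliable with short-read data and are removed by the QC
#' cascade ([homopolymer_site_filter()]).
#'
#' @param genome An `mt_genome`, or a plain character string / vector of
#'   bases (useful for testing).
#' @param min_run Minimum run length to mask (default 5; must be >= 2).
#' @param extra_regions Optional data frame with `start`/`end` columns
#'   (1-based inclusive) of additional regions to mask.
#' @return An object of class `mt_mask`: list with sorted integer `positions`,
#'   `min_run` and the extra regions used.
#' @export
#' @examples
#' build_homopolymer_mask("AACCCCCCA", min_run = 5)$positions
build_homopolymer_mask <- function(genome, min_run = 5L, extra_regions = NULL) {
  if (min_run < 2) abort("`min_run` must be >= 2")
  bases <- if (inherits(genome, "mt_genome")) {
    genome$bases
  } else if (is.character(genome) && length(genome) == 1) {
    strsplit(toupper(genome), "")[[1]]
  } else if (is.character(genome)) {
    toupper(genome)
  } else {
    abort("`genome` must be an mt_genome or a character sequence")
  }
  r <- rle(bases)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_run & r$values %in% MT_BASES
  pos <- if (any(keep)) {
    unlist(Map(seq.int, starts[keep], ends[keep]), use.names = FALSE)
  } else {
    integer(0)
  }
  if (!is.null(extra_regions) && nrow(extra_regions) > 0) {
    extra <- unlist(
      Map(seq.int, extra_regions$start, extra_regions$end),
      use.names = FALSE
    )
    pos <- union(pos, extra)
  }
  structure(
    list(
      positions = sort(unique(as.integer(pos))),
      min_run = as.integer(min_run),
      extra_regions = extra_regions
    ),
    class = "mt_mask"
  )
}

#' @export
print.mt_mask <- function(x, ...) {
  cat(sprintf(
    "<mt_mask> %d masked positions (runs >= %d%s)\n",
    length(x$positions), x$min_run,
    if (!is.null(x$extra_regions)) " + extra regions" else ""
  ))
  invisible(x)
}
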