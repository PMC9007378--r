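#' @importFrom rlang .data abort %||%
#' @importFrom stats aov coef dbeta glm model.matrix optim pchisq pnorm
#'   qchisq quantile rbeta rbinom rnbinom rnorm rpois runif sd setNames
#'   binomial poisson complete.cases cor.test dchisq fitted integrate
#'   ks.test p.adjust rexp wilcox.test var
#' @importFrom utils head packageVersion
NULL

# Length of the rCRS mitochondrial reference (positions 1..16569, 1-based).
MT_LENGTH <- 16569L

# rCRS position 3107 is a historical placeholder ('N'); never callable.
MT_PLACEHOLDER <- 3107L

MT_BASES <- c("A", "C", "G", "T")

#' Wrap positions around the circular mitochondrial genome
#'
#' Maps any integer onto 1..16569 modulo the genome length, so neighbour
#' arithmetic (e.g. the 5' neighbour of position 1) lands on the far end of
#' the molecule.
#'
#' @param pos Integer vector of (possibly out-of-range) positions.
#' @param length Genome length, default 16569.
#' @return Integer vector in `1..length`.
#' @export
#' @examples
#' mt_wrap(c(0, 1, 16569, 16570))
mt_wrap <- function(pos, length = MT_LENGTH) {
  as.integer(((pos - 1L) %% length) + 1L)
}

check_positions <- function(pos, what = "pos") {
  if (length(pos) == 0) return(invisible(pos))
  if (anyNA(pos) || any(pos < 1L) || any(pos > MT_LENGTH)) {
    bad <- unique(pos[is.na(pos) | pos < 1L | pos > MT_LENGTH])
    abort(sprintf(
      "`%s` must lie in 1..%d; offending values: %s",
      what, MT_LENGTH, paste(head(bad, 5), collapse = ", ")
    ))
  }
  invisible(pos)
}

mt_complement <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan", x)
}

mt_revcomp <- function(x) {
  vapply(
    strsplit(mt_complement(x), ""),
    function(b) paste(rev(b), collapse = ""),
    character(1)
  )
}

check_bases <- function(x, what = "base") {
  bad <- !x %in% MT_BASES
  if (any(bad)) {
    abort(sprintf(
      "`%s` must be one of A, C, G, T; offending values: %s",
      what, paste(unique(x[bad])[1:min(5, sum(bad))], collapse = ", ")
    ))
  }
  invisible(x)
}

# Transition partner of each base.
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

is_transition <- function(ref, alt) {
  unname(TRANSITION[ref] == alt)
}
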