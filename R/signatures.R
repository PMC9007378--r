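# Trinucleotide mutational signatures stratified by strand and replication
# arc, and the one-tail two-proportions asymmetry test between arcs.

PYR_SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Classify a substitution under the pyrimidine convention
#'
#' Substitutions are reported with a pyrimidine (C or T) reference and
#' attributed to the mtDNA strand carrying that pyrimidine: changes with a
#' pyrimidine reference on the deposited L strand stay as written (L
#' strand); purine-reference changes are complemented and attributed to the
#' heavy strand.
#'
#' @param ref,alt Reference and alternative bases on the L strand.
#' @return Tibble with `substitution` (one of the six pyrimidine changes)
#'   and `strand` (`"L"` or `"H"`).
#' @export
#' @examples
#' classify_substitution(c("C", "G", "A"), c("T", "A", "G"))
classify_substitution <- function(ref, alt) {
  check_bases(ref, "ref")
  check_bases(alt, "alt")
  if (any(ref == alt)) abort("`alt` must differ from `ref`")
  pyr <- ref %in% c("C", "T")
  tibble::tibble(
    substitution = ifelse(pyr,
      paste0(ref, ">", alt),
      paste0(mt_complement(ref), ">", mt_complement(alt))
    ),
    strand = ifelse(pyr, "L", "H")
  )
}

#' Strand- and arc-resolved trinucleotide signature matrix
#'
#' Aggregates heteroplasmic calls in the requested HF range into the 96
#' trinucleotide substitution contexts (6 pyrimidine changes x 16 flanking
#' contexts), stratified by the strand carrying the pyrimidine and by
#' replication arc. Contexts are read 5'-to-3' on the attributing strand
#' (the L-strand triplet is reverse-complemented for heavy-strand
#' attributions), wrapping circularly at the origin. Frequencies are
#' normalised within each strand x arc stratum.
#'
#' @param calls Call tibble (QC-passed).
#' @param annotation An [mt_annotation()].
#' @param hf_range Inclusive HF range of calls to aggregate (default the
#'   heteroplasmic range 0.05--0.95; use `c(0.05, 0.10)` for the low-level
#'   stratum).
#' @return Tibble of class `mt_signature`: the complete
#'   substitution x context x strand x arc grid (384 rows) with `count`
#'   and within-stratum `frequency`.
#' @export
build_signature_matrix <- function(calls, annotation = default_annotation(),
                                   hf_range = c(0.05, 0.95)) {
  check_calls(calls)
  sel <- calls[calls$hf >= hf_range[1] & calls$hf <= hf_range[2], ]
  grid <- tidyr::expand_grid(
    substitution = PYR_SUBSTITUTIONS,
    five = MT_BASES, three = MT_BASES,
    strand = c("L", "H"), arc = c("minor", "major")
  )
  # calls whose flanking context touches the position-3107 placeholder have
  # no resolvable triplet and are excluded (counted in the attribute)
  ctx0 <- trinucleotide_context(pmax(pmin(sel$pos, MT_LENGTH), 1L), annotation$genome)
  has_n <- grepl("N", ctx0)
  n_ctx_na <- sum(has_n)
  sel <- sel[!has_n, ]
  if (nrow(sel)) {
    cls <- classify_substitution(sel$ref, sel$alt)
    ctx <- trinucleotide_context(sel$pos, annotation$genome)
    ctx <- ifelse(cls$strand == "H", mt_revcomp(ctx), ctx)
    obs <- tibble::tibble(
      substitution = cls$substitution,
      five = substr(ctx, 1, 1),
      three = substr(ctx, 3, 3),
      strand = cls$strand,
      arc = arc_of(sel$pos, annotation$arcs)
    ) |>
      dplyr::count(.data$substitution, .data$five, .data$three,
        .data$strand, .data$arc,
        name = "count"
      )
  } else {
    obs <- dplyr::mutate(grid[0, ], count = integer(0))
  }
  out <- grid |>
    dplyr::left_join(obs, by = c("substitution", "five", "three", "strand", "arc")) |>
    dplyr::mutate(count = tidyr::replace_na(.data$count, 0L)) |>
    dplyr::group_by(.data$strand, .data$arc) |>
    dplyr::mutate(
      frequency = .data$count / max(sum(.data$count), 1L)
    ) |>
    dplyr::ungroup()
  attr(out, "hf_range") <- hf_range
  attr(out, "n_calls") <- nrow(sel)
  attr(out, "n_context_dropped") <- n_ctx_na
  class(out) <- c("mt_signature", class(out))
  out
}

#' Aggregate a signature matrix over contexts
#'
#' Collapses the 16 flanking contexts of each substitution, per strand and
#' arc.
#'
#' @param signature An `mt_signature`.
#' @return Tibble with `substitution`, `strand`, `arc`, `count`,
#'   `frequency` (within strand x arc).
#' @export
signature_aggregate <- function(signature) {
  signature |>
    dplyr::group_by(.data$substitution, .data$strand, .data$arc) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::group_by(.data$strand, .data$arc) |>
    dplyr::mutate(
      frequency = .data$count / max(sum(.data$count), 1L)
    ) |>
    dplyr::ungroup()
}

#' Replication-arc asymmetry test
#'
#' One-tail two-proportions Z test comparing, for a given substitution and
#' strand, its share of that strand's substitutions in the major arc
#' against the minor arc, with the pooled-proportion standard error. The
#' alternative is "greater in the major arc" (the replication-mechanism
#' hypothesis); a two-sided p is available via `alternative`.
#'
#' @param signature An `mt_signature` from [build_signature_matrix()].
#' @param substitutions Substitutions to test (default: all six).
#' @param strands Strands to test (default both).
#' @param alternative `"greater"` (major > minor, one-tailed) or
#'   `"two.sided"`.
#' @return Tibble of class `mt_asymmetry` with counts, proportions, `z` and
#'   `p.value`, one row per substitution x strand; attribute
#'   `family_threshold` is `0.05 / number of tests run`.
#' @export
arc_asymmetry_test <- function(signature,
                               substitutions = PYR_SUBSTITUTIONS,
                               strands = c("H", "L"),
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  agg <- signature_aggregate(signature)
  totals <- agg |>
    dplyr::group_by(.data$strand, .data$arc) |>
    dplyr::summarise(n = sum(.data$count), .groups = "drop")
  rows <- tidyr::expand_grid(substitution = substitutions, strand = strands)
  out <- purrr::pmap_dfr(rows, function(substitution, strand) {
    n_major <- totals$n[totals$strand == strand & totals$arc == "major"]
    n_minor <- totals$n[totals$strand == strand & totals$arc == "minor"]
    if (n_major == 0 || n_minor == 0) {
      abort(sprintf(
        "no substitutions on strand %s in one of the arcs; proportions undefined", strand
      ))
    }
    x_major <- agg$count[agg$substitution == substitution &
      agg$strand == strand & agg$arc == "major"]
    x_minor <- agg$count[agg$substitution == substitution &
      agg$strand == strand & agg$arc == "minor"]
    p1 <- x_major / n_major
    p2 <- x_minor / n_minor
    pool <- (x_major + x_minor) / (n_major + n_minor)
    se <- sqrt(pool * (1 - pool) * (1 / n_major + 1 / n_minor))
    z <- if (se == 0) 0 else (p1 - p2) / se
    p <- if (alternative == "greater") {
      pnorm(z, lower.tail = FALSE)
    } else {
      2 * pnorm(abs(z), lower.tail = FALSE)
    }
    tibble::tibble(
      substitution = substitution, strand = strand,
      x_major = x_major, n_major = n_major,
      x_minor = x_minor, n_minor = n_minor,
      prop_major = p1, prop_minor = p2, z = z, p.value = p
    )
  })
  attr(out, "alternative") <- alternative
  attr(out, "family_threshold") <- 0.05 / nrow(out)
  class(out) <- c("mt_asymmetry", class(out))
  out
}
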