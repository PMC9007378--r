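# Heteroplasmy classification and per-individual burden aggregation.

HET_CLASSES <- c("low", "intermediate", "homoplasmy")
BURDEN_CATEGORIES <- c(
  "non-synonymous", "synonymous", "tRNA", "rRNA", "D-loop", "intergenic"
)

#' Classify heteroplasmic fraction
#'
#' Three classes by heteroplasmic fraction: low-level (5--10%), intermediate
#' (10--95%) and homoplasmy (>95%). Boundaries are resolved half-open
#' upward: HF exactly 0.10 is intermediate and exactly 0.95 is homoplasmy.
#' Calls below 5% are a QC violation (they are removed upstream) and are
#' rejected.
#'
#' @param hf Numeric vector of heteroplasmic fractions in \[0.05, 1\].
#' @return Factor with levels `low`, `intermediate`, `homoplasmy`.
#' @export
#' @examples
#' classify_hf(c(0.07, 0.50, 0.96))
classify_hf <- function(hf) {
  if (anyNA(hf) || any(hf < 0.05) || any(hf > 1)) {
    abort("`hf` must lie in [0.05, 1]; sub-5% calls are removed by QC")
  }
  cut(hf,
    breaks = c(0.05, 0.10, 0.95, Inf), right = FALSE,
    labels = HET_CLASSES
  )
}

# functional category lookup against the precomputed consequence table
call_category <- function(calls, annotation) {
  check_positions(calls$pos)
  cat <- annotation$consequences[cbind(calls$pos, match(calls$alt, MT_BASES))]
  if (anyNA(cat)) {
    bad <- calls$pos[is.na(cat)]
    abort(sprintf(
      "cannot annotate variant(s) at position(s) %s (alt equals reference, or placeholder site)",
      paste(head(unique(bad), 5), collapse = ", ")
    ))
  }
  cat
}

#' Per-individual burden table
#'
#' Counts each sample's QC-passed variants by heteroplasmy class and
#' functional category. Samples without calls appear with zero counts, so
#' the table is a complete sample x class x category grid — the response
#' used by the burden regressions.
#'
#' @param calls QC-passed call tibble.
#' @param samples Sample tibble; every call's `sample_id` must appear here.
#' @param annotation An [mt_annotation()].
#' @return Tibble of class `mt_burden` with columns `sample_id`,
#'   `het_class`, `category`, `n`.
#' @export
#' @examples
#' cohort <- generate_cohort(simulation_config(n_cases = 20, n_controls = 20), seed = 3)
#' b <- individual_burden(cohort$calls, cohort$samples)
#' burden_totals(b)
individual_burden <- function(calls, samples, annotation = default_annotation()) {
  check_calls(calls)
  unknown <- setdiff(calls$sample_id, samples$sample_id)
  if (length(unknown)) {
    abort(sprintf(
      "calls reference sample(s) absent from `samples`: %s",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  counted <- calls |>
    dplyr::mutate(
      het_class = classify_hf(.data$hf),
      category = call_category(calls, annotation)
    ) |>
    dplyr::count(.data$sample_id, .data$het_class, .data$category)
  grid <- tidyr::expand_grid(
    sample_id = samples$sample_id,
    het_class = factor(HET_CLASSES, levels = HET_CLASSES),
    category = BURDEN_CATEGORIES
  )
  out <- grid |>
    dplyr::left_join(counted, by = c("sample_id", "het_class", "category")) |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
  class(out) <- c("mt_burden", class(out))
  out
}

#' Per-sample class totals of a burden table
#'
#' @param burden An `mt_burden` tibble from [individual_burden()].
#' @return Wide tibble: `sample_id`, `low`, `intermediate`, `homoplasmy`.
#' @export
burden_totals <- function(burden) {
  burden |>
    dplyr::group_by(.data$sample_id, .data$het_class) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "het_class", values_from = "n")
}

#' Variant sharing spectrum
#'
#' Assigns every variant allele its carrier count and sharing class —
#' singleton, shared by 2--10 individuals, or by more than 10 — together
#' with the mean HF among carriers.
#'
#' @param calls QC-passed call tibble.
#' @return Tibble with `pos`, `alt`, `n_carriers`, `sharing_class`
#'   (factor `singleton` / `2-10` / `>10`), `mean_hf`.
#' @export
sharing_spectrum <- function(calls) {
  check_calls(calls)
  calls |>
    dplyr::group_by(.data$pos, .data$alt) |>
    dplyr::summarise(
      n_carriers = dplyr::n_distinct(.data$sample_id),
      mean_hf = mean(.data$hf),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      sharing_class = cut(.data$n_carriers,
        breaks = c(0, 1, 10, Inf),
        labels = c("singleton", "2-10", ">10")
      )
    )
}

#' Length-normalised per-locus variant frequency
#'
#' For each of the 39 region sets (37 genes, D-loop, intergenic aggregate)
#' and each heteroplasmy class: the number of distinct variant alleles of
#' that class falling in the region, divided by the region length in bp.
#' The D-loop wrap is handled (positions 16024--16569 and 1--576 both count
#' toward the single D-loop locus); a variant inside two overlapping genes
#' counts toward both.
#'
#' @param calls QC-passed call tibble.
#' @param annotation An [mt_annotation()].
#' @return Tibble with `locus`, `het_class`, `n_sites`, `length_bp`,
#'   `frequency`.
#' @export
locus_frequency <- function(calls, annotation = default_annotation()) {
  check_calls(calls)
  sets <- annotation$region_sets
  sites <- calls |>
    dplyr::mutate(het_class = classify_hf(.data$hf)) |>
    dplyr::distinct(.data$pos, .data$alt, .data$het_class)
  purrr::map_dfr(names(sets), function(nm) {
    span <- sets[[nm]]
    in_region <- sites[sites$pos %in% span, ]
    counts <- table(factor(in_region$het_class, levels = HET_CLASSES))
    tibble::tibble(
      locus = nm,
      het_class = factor(HET_CLASSES, levels = HET_CLASSES),
      n_sites = as.integer(counts),
      length_bp = length(span),
      frequency = as.integer(counts) / length(span)
    )
  })
}
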