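# The variant/sample quality-control cascade: sample breadth-of-coverage,
# per-call read support, homopolymer masking, within-group heteroplasmy
# prevalence, reference-panel concordance, and the optional
# coefficient-of-variation screen for NUMT pseudo-heteroplasmies.

CALL_COLUMNS <- c("sample_id", "pos", "ref", "alt", "hf", "depth", "alt_fwd", "alt_rev")

check_calls <- function(calls) {
  missing <- setdiff(CALL_COLUMNS, names(calls))
  if (length(missing)) {
    abort(sprintf("call table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  invisible(calls)
}

#' Sample breadth-of-coverage filter
#'
#' Retains samples whose fraction of the mitochondrial genome covered by at
#' least one read exceeds the threshold (strictly).
#'
#' @param samples Sample tibble with a `covered_fraction` column.
#' @param min_covered_fraction Threshold, default 0.95.
#' @return Filtered sample tibble.
#' @export
filter_samples <- function(samples, min_covered_fraction = 0.95) {
  if (!"covered_fraction" %in% names(samples)) {
    abort("`samples` lacks a `covered_fraction` column")
  }
  dplyr::filter(samples, .data$covered_fraction > min_covered_fraction)
}

#' Per-call read-support filter
#'
#' Retains calls with read depth at least `min_depth`, at least
#' `min_alt_reads` alternative-allele reads in total, at least one
#' alternative read on each strand, and heteroplasmic fraction of at least
#' `min_hf`.
#'
#' @param calls Call tibble (see [generate_cohort()] for the schema).
#' @param min_depth,min_alt_reads,min_hf Thresholds (defaults 500, 25, 0.05).
#' @return Filtered call tibble.
#' @export
basic_call_filter <- function(calls, min_depth = 500, min_alt_reads = 25, min_hf = 0.05) {
  check_calls(calls)
  dplyr::filter(
    calls,
    .data$depth >= min_depth,
    .data$alt_fwd + .data$alt_rev >= min_alt_reads,
    .data$alt_fwd >= 1, .data$alt_rev >= 1,
    .data$hf >= min_hf
  )
}

#' Homopolymer-tract filter
#'
#' Removes calls at positions inside the homopolymer mask.
#'
#' @param calls Call tibble.
#' @param mask An `mt_mask` (see [build_homopolymer_mask()]).
#' @return Filtered call tibble.
#' @export
homopolymer_site_filter <- function(calls, mask) {
  check_calls(calls)
  dplyr::filter(calls, !.data$pos %in% mask$positions)
}

#' Within-group heteroplasmy prevalence filter
#'
#' For each variant allele and study group, if the fraction of the group's
#' individuals carrying it heteroplasmically (0.05 <= HF <= 0.95) exceeds
#' `max_het_prevalence`, the heteroplasmic calls at that site are removed —
#' within the offending group only by default, or cohort-wide with
#' `scope = "cohort"`. Homoplasmic calls are always retained.
#'
#' @param calls Call tibble.
#' @param samples Sample tibble (defines group membership and sizes).
#' @param max_het_prevalence Threshold, default 0.02 (strict "more than").
#' @param scope `"group"` (default) or `"cohort"`.
#' @return Filtered call tibble.
#' @export
cohort_prevalence_filter <- function(calls, samples, max_het_prevalence = 0.02,
                                     scope = c("group", "cohort")) {
  check_calls(calls)
  scope <- match.arg(scope)
  if (nrow(calls) == 0) return(calls)
  grp <- samples |>
    dplyr::count(.data$group, name = "group_n")
  ann <- calls |>
    dplyr::left_join(
      dplyr::select(samples, "sample_id", "group"),
      by = "sample_id"
    ) |>
    dplyr::mutate(is_het = .data$hf >= 0.05 & .data$hf <= 0.95)
  if (scope == "cohort") {
    flagged <- ann |>
      dplyr::filter(.data$is_het) |>
      dplyr::distinct(.data$pos, .data$alt, .data$sample_id, .data$group) |>
      dplyr::count(.data$pos, .data$alt, .data$group, name = "n_car") |>
      dplyr::left_join(grp, by = "group") |>
      dplyr::group_by(.data$pos, .data$alt) |>
      dplyr::summarise(
        over = any(.data$n_car / .data$group_n > max_het_prevalence),
        .groups = "drop"
      ) |>
      dplyr::filter(.data$over)
    keep <- !(ann$is_het & paste(ann$pos, ann$alt) %in% paste(flagged$pos, flagged$alt))
  } else {
    flagged <- ann |>
      dplyr::filter(.data$is_het) |>
      dplyr::distinct(.data$pos, .data$alt, .data$sample_id, .data$group) |>
      dplyr::count(.data$pos, .data$alt, .data$group, name = "n_car") |>
      dplyr::left_join(grp, by = "group") |>
      dplyr::filter(.data$n_car / .data$group_n > max_het_prevalence)
    key <- paste(ann$pos, ann$alt, ann$group)
    keep <- !(ann$is_het & key %in% paste(flagged$pos, flagged$alt, flagged$group))
  }
  calls[keep, ]
}

#' Reference-panel concordance filter
#'
#' Removes homoplasmic variants (HF > 0.95) whose cohort allele frequency
#' differs from a reference panel's frequency by more than `max_af_diff` in
#' *either* panel; alleles absent from a panel are treated as panel
#' frequency 0.
#'
#' @param calls Call tibble.
#' @param panel_afs List of panel tibbles (`pos`, `alt`, `af`), e.g. from
#'   [make_panel_afs()].
#' @param samples Sample tibble (cohort allele frequencies use its size as
#'   denominator).
#' @param max_af_diff Threshold, default 0.9.
#' @return Filtered call tibble.
#' @export
panel_concordance_filter <- function(calls, panel_afs, samples, max_af_diff = 0.9) {
  check_calls(calls)
  if (nrow(calls) == 0) return(calls)
  n <- nrow(samples)
  afs <- calls |>
    dplyr::group_by(.data$pos, .data$alt) |>
    dplyr::summarise(af = sum(.data$hf > 0.95) / n, .groups = "drop")
  discordant <- rep(FALSE, nrow(afs))
  for (panel in panel_afs) {
    m <- match(paste(afs$pos, afs$alt), paste(panel$pos, panel$alt))
    panel_af <- ifelse(is.na(m), 0, panel$af[m])
    discordant <- discordant | abs(afs$af - panel_af) > max_af_diff
  }
  bad <- afs[discordant, c("pos", "alt")]
  keep <- !(calls$hf > 0.95 & paste(calls$pos, calls$alt) %in% paste(bad$pos, bad$alt))
  calls[keep, ]
}

#' Per-site heteroplasmic-fraction statistics
#'
#' Computes carrier counts, mean and SD of HF, and the coefficient of
#' variation (CV = sd/mean) per variant allele over its heteroplasmic
#' carriers (0.05 <= HF <= 0.95). The CV is reported only for sites with at
#' least `min_carriers` heteroplasmic carriers.
#'
#' @param calls Call tibble.
#' @param min_carriers Minimum heteroplasmic carriers for a defined CV.
#' @return Tibble with `pos`, `alt`, `n_het_carriers`, `mean_hf`, `sd_hf`,
#'   `cv`.
#' @export
site_hf_stats <- function(calls, min_carriers = 3) {
  check_calls(calls)
  calls |>
    dplyr::filter(.data$hf >= 0.05, .data$hf <= 0.95) |>
    dplyr::group_by(.data$pos, .data$alt) |>
    dplyr::summarise(
      n_het_carriers = dplyr::n_distinct(.data$sample_id),
      mean_hf = mean(.data$hf),
      sd_hf = sd(.data$hf),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      cv = ifelse(
        .data$n_het_carriers >= min_carriers & .data$mean_hf > 0,
        .data$sd_hf / .data$mean_hf, NA_real_
      )
    )
}

#' Coefficient-of-variation site filter for NUMT pseudo-heteroplasmies
#'
#' NUMT co-amplification produces "pseudo-heteroplasmies" with nearly the
#' same HF in every carrier, hence an unusually low coefficient of variation
#' of HF across carriers. This filter computes the CV per variant allele
#' over heteroplasmic carriers (requiring at least `min_carriers`), and
#' removes — entirely — all sites whose CV falls at or below the requested
#' percentile of the CV distribution. Sites with fewer carriers never enter
#' the CV distribution and are never removed.
#'
#' @param calls Call tibble.
#' @param percentile Bottom percentile of the CV distribution to remove
#'   (default 25).
#' @param min_carriers Carrier floor for a defined CV (default 3).
#' @return List with `calls` (filtered), `site_stats` (with a `removed`
#'   flag) and `cv_threshold`.
#' @export
cv_site_filter <- function(calls, percentile = 25, min_carriers = 3) {
  check_calls(calls)
  stats <- site_hf_stats(calls, min_carriers)
  defined <- !is.na(stats$cv)
  if (!any(defined)) {
    warning("no site reaches the carrier floor; CV filter is a no-op")
    stats$removed <- FALSE
    return(list(calls = calls, site_stats = stats, cv_threshold = NA_real_))
  }
  thr <- unname(quantile(stats$cv[defined], percentile / 100))
  stats$removed <- defined & stats$cv <= thr
  bad <- stats[stats$removed, c("pos", "alt")]
  keep <- !paste(calls$pos, calls$alt) %in% paste(bad$pos, bad$alt)
  list(calls = calls[keep, ], site_stats = stats, cv_threshold = thr)
}

#' Apply the full quality-control cascade
#'
#' Runs the filters in pipeline order — sample coverage, per-call read
#' support, homopolymer mask, within-group prevalence, panel concordance
#' (when panels are supplied), and optionally the CV-based NUMT screen —
#' logging per-stage removal counts. The CV filter is a robustness
#' re-analysis and is off by default.
#'
#' @param calls Call tibble.
#' @param samples Sample tibble.
#' @param annotation An [mt_annotation()] (supplies the homopolymer mask).
#' @param panel_afs Optional list of panel AF tibbles.
#' @param min_covered_fraction,min_depth,min_alt_reads,min_hf,max_het_prevalence,max_af_diff
#'   Stage thresholds (defaults: 0.95, 500, 25, 0.05, 0.02, 0.9).
#' @param prevalence_scope `"group"` or `"cohort"`.
#' @param cv_filter Enable the CV-based NUMT screen (default `FALSE`).
#' @param cv_percentile,cv_min_carriers CV screen settings.
#' @return Object of class `mt_qc`: list with filtered `calls` and
#'   `samples`, a `stages` tibble of per-stage counts, `site_stats` (when
#'   the CV filter ran), and the echoed `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(simulation_config(n_cases = 40, n_controls = 40), seed = 2)
#' qc <- apply_qc_cascade(cohort$calls, cohort$samples, panel_afs = cohort$panel_afs)
#' qc$stages
apply_qc_cascade <- function(calls, samples,
                             annotation = default_annotation(),
                             panel_afs = NULL,
                             min_covered_fraction = 0.95,
                             min_depth = 500, min_alt_reads = 25, min_hf = 0.05,
                             max_het_prevalence = 0.02,
                             prevalence_scope = "group",
                             max_af_diff = 0.9,
                             cv_filter = FALSE,
                             cv_percentile = 25, cv_min_carriers = 3) {
  check_calls(calls)
  stages <- list()
  note <- function(stage, n_in, out, unit) {
    stages[[length(stages) + 1]] <<- tibble::tibble(
      stage = stage, unit = unit, n_in = n_in, n_removed = n_in - out, n_out = out
    )
  }

  s0 <- nrow(samples)
  samples <- filter_samples(samples, min_covered_fraction)
  note("sample_coverage", s0, nrow(samples), "samples")

  c0 <- nrow(calls)
  calls <- dplyr::filter(calls, .data$sample_id %in% samples$sample_id)
  note("calls_of_removed_samples", c0, nrow(calls), "calls")

  c0 <- nrow(calls)
  calls <- basic_call_filter(calls, min_depth, min_alt_reads, min_hf)
  note("basic_call", c0, nrow(calls), "calls")

  c0 <- nrow(calls)
  calls <- homopolymer_site_filter(calls, annotation$mask)
  note("homopolymer", c0, nrow(calls), "calls")

  c0 <- nrow(calls)
  calls <- cohort_prevalence_filter(calls, samples, max_het_prevalence, prevalence_scope)
  note("cohort_prevalence", c0, nrow(calls), "calls")

  site_stats <- NULL
  if (!is.null(panel_afs)) {
    c0 <- nrow(calls)
    calls <- panel_concordance_filter(calls, panel_afs, samples, max_af_diff)
    note("panel_concordance", c0, nrow(calls), "calls")
  }
  cv_threshold <- NA_real_
  if (isTRUE(cv_filter)) {
    c0 <- nrow(calls)
    res <- cv_site_filter(calls, cv_percentile, cv_min_carriers)
    calls <- res$calls
    site_stats <- res$site_stats
    cv_threshold <- res$cv_threshold
    note("cv_numt", c0, nrow(calls), "calls")
  }

  structure(
    list(
      calls = calls,
      samples = samples,
      stages = dplyr::bind_rows(stages),
      site_stats = site_stats,
      cv_threshold = cv_threshold,
      config = list(
        min_covered_fraction = min_covered_fraction, min_depth = min_depth,
        min_alt_reads = min_alt_reads, min_hf = min_hf,
        max_het_prevalence = max_het_prevalence,
        prevalence_scope = prevalence_scope, max_af_diff = max_af_diff,
        cv_filter = cv_filter, cv_percentile = cv_percentile,
        cv_min_carriers = cv_min_carriers
      )
    ),
    class = "mt_qc"
  )
}

#' @export
print.mt_qc <- function(x, ...) {
  cat("<mt_qc> filter cascade\n")
  print(x$stages, n = Inf)
  invisible(x)
}
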