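# End-to-end analysis: QC -> burden -> association -> signatures (and
# optionally the region scan), with a machine-readable run report.

#' Run the full heteroplasmy burden analysis
#'
#' Chains the pipeline stages on a cohort (synthetic or loaded from files):
#' the QC cascade, heteroplasmy classification and burden aggregation, the
#' disease-association regression suite, the strand/arc mutational
#' signature with asymmetry tests, and optionally the per-locus region
#' burden scan. All randomness downstream of the cohort itself is
#' deterministic, and every threshold used is echoed in the report.
#'
#' @param cohort An `mt_cohort` (or a list with `calls`, `samples`,
#'   `panel_afs`).
#' @param annotation An [mt_annotation()].
#' @param run_regions Also run the per-locus SKAT-O scan (slower).
#' @param cv_filter Enable the CV-based NUMT screen in QC.
#' @param out_dir Optional directory: results are written as TSV plus a
#'   JSON run report.
#' @param ... Further arguments passed to [apply_qc_cascade()].
#' @return Object of class `mt_report`: list with `qc`, `burden`,
#'   `associations`, `signature`, `asymmetry`, optionally `region_scan`,
#'   and `meta`.
#' @export
#' @examples
#' cohort <- generate_cohort(simulation_config(n_cases = 60, n_controls = 60), seed = 7)
#' rep <- run_pipeline(cohort)
#' rep$associations
run_pipeline <- function(cohort, annotation = default_annotation(),
                         run_regions = FALSE, cv_filter = FALSE,
                         out_dir = NULL, ...) {
  qc <- apply_qc_cascade(
    cohort$calls, cohort$samples,
    annotation = annotation, panel_afs = cohort$panel_afs,
    cv_filter = cv_filter, ...
  )
  burden <- individual_burden(qc$calls, qc$samples, annotation)
  assoc <- burden_association_suite(burden, qc$samples)
  signature <- build_signature_matrix(qc$calls, annotation)
  asym <- tryCatch(arc_asymmetry_test(signature), error = function(e) {
    message("arc asymmetry tests skipped: ", conditionMessage(e))
    NULL
  })
  region_scan <- NULL
  if (isTRUE(run_regions)) {
    region_scan <- genomewide_region_scan(
      qc$calls, qc$samples,
      regions = "loci", annotation = annotation
    )
  }
  report <- structure(
    list(
      qc = qc,
      burden = burden,
      associations = assoc,
      signature = signature,
      asymmetry = asym,
      region_scan = region_scan,
      meta = list(
        package_version = as.character(packageVersion("mtburden")),
        seed = cohort$seed %||% NA_integer_,
        n_samples = nrow(cohort$samples),
        n_calls_in = nrow(cohort$calls),
        n_calls_out = nrow(qc$calls),
        qc_config = qc$config,
        association_threshold = attr(assoc, "threshold"),
        asymmetry_threshold = attr(asym, "family_threshold")
      )
    ),
    class = "mt_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a run report to disk
#'
#' Emits the per-stage filter counts, association results, signature matrix
#' and asymmetry tests as TSV, plus a JSON report carrying the same numbers
#' at full precision (rounding is applied only in the printed,
#' human-readable form).
#'
#' @param report An `mt_report`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$qc$stages, file.path(dir, "qc_stages.tsv"))
  readr::write_tsv(report$associations, file.path(dir, "associations.tsv"))
  readr::write_tsv(report$signature, file.path(dir, "signature_matrix.tsv"))
  if (!is.null(report$asymmetry)) {
    readr::write_tsv(report$asymmetry, file.path(dir, "arc_asymmetry.tsv"))
  }
  if (!is.null(report$region_scan)) {
    readr::write_tsv(report$region_scan, file.path(dir, "region_scan.tsv"))
  }
  json <- list(
    meta = report$meta,
    qc_stages = report$qc$stages,
    associations = report$associations,
    asymmetry = report$asymmetry
  )
  jsonlite::write_json(
    json, file.path(dir, "run_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @export
print.mt_report <- function(x, ...) {
  cat("<mt_report> mtDNA heteroplasmy burden analysis\n")
  cat(sprintf(
    "  samples: %d in, %d after QC; calls: %d in, %d after QC\n",
    x$meta$n_samples, nrow(x$qc$samples), x$meta$n_calls_in, x$meta$n_calls_out
  ))
  cat(sprintf(
    "  association family threshold (Bonferroni): %s\n",
    format(signif(x$meta$association_threshold, 1))
  ))
  a <- x$associations
  for (i in seq_len(nrow(a))) {
    cat(sprintf(
      "  %s vs control, %s%s: beta %.2f (se %.2f), p %.2g\n",
      a$disease[i], a$het_class[i],
      ifelse(is.na(a$category[i]), "", paste0(" [", a$category[i], "]")),
      a$estimate[i], a$std.error[i], a$p.value[i]
    ))
  }
  invisible(x)
}
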