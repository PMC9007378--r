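# File interchange: calls and samples as TSV, calls as minimal multi-sample
# VCF, region/mask interchange as BED (0-based half-open), reports as JSON.

call_col_types <- readr::cols(
  sample_id = readr::col_character(),
  pos = readr::col_integer(),
  ref = readr::col_character(),
  alt = readr::col_character(),
  hf = readr::col_double(),
  depth = readr::col_integer(),
  alt_fwd = readr::col_integer(),
  alt_rev = readr::col_integer(),
  .default = readr::col_character()
)

validate_call_records <- function(calls, path) {
  bad_pos <- sum(calls$pos < 1 | calls$pos > MT_LENGTH, na.rm = TRUE)
  bad_hf <- sum(calls$hf < 0 | calls$hf > 1, na.rm = TRUE)
  if (bad_pos + bad_hf > 0) {
    abort(sprintf(
      "%s: %d record(s) with position outside 1..%d, %d with HF outside [0,1]",
      path, bad_pos, MT_LENGTH, bad_hf
    ))
  }
  invisible(calls)
}

#' Read and write variant-call tables
#'
#' TSV is the primary interchange format (one row per sample x site x
#' allele with HF, depth and per-strand alternative read counts); a minimal
#' multi-sample VCF with `HF`, `DP`, `ALF` and `ALR` FORMAT fields is
#' supported for interoperability (`.vcf` extension). Round trips are
#' lossless for all call fields.
#'
#' @param path File path; format chosen by extension (`.vcf` vs TSV).
#' @param calls Call tibble.
#' @return `read_calls()` returns the call tibble; writers return the path
#'   invisibly.
#' @export
read_calls <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    return(read_calls_vcf(path))
  }
  calls <- readr::read_tsv(path, col_types = call_col_types, progress = FALSE)
  missing <- setdiff(CALL_COLUMNS, names(calls))
  if (length(missing)) {
    abort(sprintf(
      "%s: missing required column(s): %s", path, paste(missing, collapse = ", ")
    ))
  }
  validate_call_records(calls, path)
  calls
}

#' @rdname read_calls
#' @export
write_calls <- function(calls, path) {
  check_calls(calls)
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    return(write_calls_vcf(calls, path))
  }
  readr::write_tsv(calls, path)
  invisible(path)
}

# minimal VCF writer: one record per (pos, ref, alt); per-sample FORMAT
# HF:DP:ALF:ALR, "." for non-carriers
write_calls_vcf <- function(calls, path) {
  check_calls(calls)
  sample_ids <- sort(unique(calls$sample_id))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chrM,length=%d>", MT_LENGTH),
    "##FORMAT=<ID=HF,Number=1,Type=Float,Description=\"Heteroplasmic fraction\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=ALF,Number=1,Type=Integer,Description=\"Alt reads, forward strand\">",
    "##FORMAT=<ID=ALR,Number=1,Type=Integer,Description=\"Alt reads, reverse strand\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
      sample_ids
    ), collapse = "\t")
  )
  variants <- calls |>
    dplyr::distinct(.data$pos, .data$ref, .data$alt) |>
    dplyr::arrange(.data$pos, .data$alt)
  key_calls <- paste(calls$pos, calls$alt, calls$sample_id)
  records <- vapply(seq_len(nrow(variants)), function(i) {
    cells <- rep(".", length(sample_ids))
    m <- match(paste(variants$pos[i], variants$alt[i], sample_ids), key_calls)
    hit <- which(!is.na(m))
    cells[hit] <- sprintf(
      "%s:%d:%d:%d",
      format(calls$hf[m[hit]], trim = TRUE, digits = 15),
      calls$depth[m[hit]], calls$alt_fwd[m[hit]], calls$alt_rev[m[hit]]
    )
    paste(c(
      "chrM", variants$pos[i], ".", variants$ref[i], variants$alt[i],
      ".", "PASS", ".", "HF:DP:ALF:ALR", cells
    ), collapse = "\t")
  }, character(1))
  writeLines(c(header, records), path)
  invisible(path)
}

# VCF reader built on vcfR
read_calls_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  get_field <- function(el, numeric = TRUE) {
    m <- vcfR::extract.gt(v, element = el, as.numeric = numeric)
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(fix))
    m
  }
  hf <- get_field("HF")
  dp <- get_field("DP")
  alf <- get_field("ALF")
  alr <- get_field("ALR")
  idx <- which(!is.na(hf), arr.ind = TRUE)
  if (!nrow(idx)) {
    return(tibble::tibble(
      sample_id = character(0), pos = integer(0), ref = character(0),
      alt = character(0), hf = numeric(0), depth = integer(0),
      alt_fwd = integer(0), alt_rev = integer(0)
    ))
  }
  calls <- tibble::tibble(
    sample_id = colnames(hf)[idx[, 2]],
    pos = as.integer(fix[idx[, 1], "POS"]),
    ref = fix[idx[, 1], "REF"],
    alt = fix[idx[, 1], "ALT"],
    hf = hf[idx],
    depth = as.integer(dp[idx]),
    alt_fwd = as.integer(alf[idx]),
    alt_rev = as.integer(alr[idx])
  ) |>
    dplyr::arrange(.data$sample_id, .data$pos, .data$alt)
  validate_call_records(calls, path)
  calls
}

#' Read and write sample metadata tables
#'
#' @param samples Sample tibble.
#' @param path TSV path.
#' @return `read_samples()` returns the tibble; the writer returns the path
#'   invisibly.
#' @export
read_samples <- function(path) {
  s <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    group = readr::col_character(),
    age = readr::col_double(),
    sex = readr::col_character(),
    mean_depth = readr::col_double(),
    mt_ancestry = readr::col_character(),
    covered_fraction = readr::col_double(),
    .default = readr::col_guess()
  ), progress = FALSE)
  needed <- c("sample_id", "group", "age", "sex", "mean_depth", "mt_ancestry", "covered_fraction")
  missing <- setdiff(needed, names(s))
  if (length(missing)) {
    abort(sprintf("%s: missing required column(s): %s", path, paste(missing, collapse = ", ")))
  }
  s
}

#' @rdname read_samples
#' @export
write_samples <- function(samples, path) {
  readr::write_tsv(samples, path)
  invisible(path)
}

#' Read and write panel allele-frequency tables
#'
#' @param panel Tibble with `pos`, `ref`, `alt`, `af`.
#' @param path TSV path.
#' @return `read_panel()` returns the tibble; the writer returns the path.
#' @export
read_panel <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    pos = readr::col_integer(), ref = readr::col_character(),
    alt = readr::col_character(), af = readr::col_double()
  ), progress = FALSE)
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  readr::write_tsv(panel, path)
  invisible(path)
}

#' BED interchange for region sets and masks
#'
#' Internal coordinates are 1-based inclusive (rCRS "m." convention); BED
#' files are 0-based half-open. `positions_to_bed()` collapses a position
#' set into maximal intervals; `bed_to_positions()` expands a BED tibble
#' back.
#'
#' @param positions Integer vector of 1-based positions.
#' @param name Interval name stem.
#' @param bed Tibble with `start`, `end` (0-based half-open).
#' @param path BED file path.
#' @return Tibbles / integer vectors; writers return the path invisibly.
#' @export
positions_to_bed <- function(positions, name = "region") {
  if (!length(positions)) {
    return(tibble::tibble(chrom = character(0), start = integer(0), end = integer(0), name = character(0)))
  }
  p <- sort(unique(as.integer(positions)))
  brk <- c(0L, which(diff(p) > 1L), length(p))
  tibble::tibble(
    chrom = "chrM",
    start = p[head(brk, -1) + 1L] - 1L,
    end = p[brk[-1]],
    name = name
  )
}

#' @rdname positions_to_bed
#' @export
bed_to_positions <- function(bed) {
  unlist(Map(function(s, e) seq.int(s + 1L, e), bed$start, bed$end), use.names = FALSE)
}

#' @rdname positions_to_bed
#' @export
write_bed <- function(bed, path) {
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname positions_to_bed
#' @export
read_bed <- function(path) {
  b <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "name"),
    col_types = "ciic", progress = FALSE
  )
  b
}

#' Write a cohort to a directory
#'
#' Writes calls (TSV and VCF), samples, panel AFs and score tables of a
#' synthetic cohort as plain-text files.
#'
#' @param cohort An `mt_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_calls(cohort$calls, file.path(dir, "calls.tsv"))
  write_calls_vcf(
    dplyr::select(cohort$calls, dplyr::all_of(CALL_COLUMNS)),
    file.path(dir, "calls.vcf")
  )
  write_samples(cohort$samples, file.path(dir, "samples.tsv"))
  write_panel(cohort$panel_afs$genbank, file.path(dir, "panel_genbank.tsv"))
  write_panel(cohort$panel_afs$kgenomes, file.path(dir, "panel_1kg.tsv"))
  readr::write_tsv(cohort$scores$phastcons, file.path(dir, "phastcons.tsv"))
  readr::write_tsv(cohort$scores$mutpred, file.path(dir, "mutpred.tsv"))
  readr::write_tsv(cohort$calls[, c("sample_id", "pos", "alt", "origin")],
    file.path(dir, "truth.tsv")
  )
  invisible(dir)
}
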