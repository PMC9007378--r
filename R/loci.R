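#' The rCRS locus map
#'
#' The standard annotation of the 16,569 bp mitochondrial genome: 13
#' protein-coding genes, 22 tRNAs, 2 rRNAs (37 genes), plus the non-coding
#' D-loop. Coordinates are 1-based inclusive in rCRS numbering. The D-loop
#' wraps the origin and is stored as a single row with `start > end`
#' (16024..16569 joined to 1..576). `strand` is `"L"` when the gene's sense
#' sequence is the deposited L strand and `"H"` for the nine genes (MT-ND6
#' and eight tRNAs) read from the heavy strand, i.e. the reverse complement.
#' The 89 positions falling between annotations form the intergenic
#' aggregate, available through [mt_region_sets()].
#'
#' @return Tibble with columns `locus`, `start`, `end`, `strand`, `class`.
#' @export
#' @examples
#' mt_locus_map()
mt_locus_map <- function() {
  tibble::tribble(
    ~locus,      ~start, ~end,   ~strand, ~class,
    "MT-TF",     577L,   647L,   "L", "tRNA",
    "MT-RNR1",   648L,   1601L,  "L", "rRNA",
    "MT-TV",     1602L,  1670L,  "L", "tRNA",
    "MT-RNR2",   1671L,  3229L,  "L", "rRNA",
    "MT-TL1",    3230L,  3304L,  "L", "tRNA",
    "MT-ND1",    3307L,  4262L,  "L", "protein",
    "MT-TI",     4263L,  4331L,  "L", "tRNA",
    "MT-TQ",     4329L,  4400L,  "H", "tRNA",
    "MT-TM",     4402L,  4469L,  "L", "tRNA",
    "MT-ND2",    4470L,  5511L,  "L", "protein",
    "MT-TW",     5512L,  5579L,  "L", "tRNA",
    "MT-TA",     5587L,  5655L,  "H", "tRNA",
    "MT-TN",     5657L,  5729L,  "H", "tRNA",
    "MT-TC",     5761L,  5826L,  "H", "tRNA",
    "MT-TY",     5826L,  5891L,  "H", "tRNA",
    "MT-CO1",    5904L,  7445L,  "L", "protein",
    "MT-TS1",    7446L,  7514L,  "H", "tRNA",
    "MT-TD",     7518L,  7585L,  "L", "tRNA",
    "MT-CO2",    7586L,  8269L,  "L", "protein",
    "MT-TK",     8295L,  8364L,  "L", "tRNA",
    "MT-ATP8",   8366L,  8572L,  "L", "protein",
    "MT-ATP6",   8527L,  9207L,  "L", "protein",
    "MT-CO3",    9207L,  9990L,  "L", "protein",
    "MT-TG",     9991L,  10058L, "L", "tRNA",
    "MT-ND3",    10059L, 10404L, "L", "protein",
    "MT-TR",     10405L, 10469L, "L", "tRNA",
    "MT-ND4L",   10470L, 10766L, "L", "protein",
    "MT-ND4",    10760L, 12137L, "L", "protein",
    "MT-TH",     12138L, 12206L, "L", "tRNA",
    "MT-TS2",    12207L, 12265L, "L", "tRNA",
    "MT-TL2",    12266L, 12336L, "L", "tRNA",
    "MT-ND5",    12337L, 14148L, "L", "protein",
    "MT-ND6",    14149L, 14673L, "H", "protein",
    "MT-TE",     14674L, 14742L, "H", "tRNA",
    "MT-CYB",    14747L, 15887L, "L", "protein",
    "MT-TT",     15888L, 15953L, "L", "tRNA",
    "MT-TP",     15956L, 16023L, "H", "tRNA",
    "MT-DLOOP",  16024L, 576L,   "L", "D-loop"
  )
}

# 1-based positions covered by one locus row (handles the D-loop wrap).
locus_span <- function(start, end) {
  if (start <= end) seq.int(start, end) else c(seq.int(start, MT_LENGTH), seq.int(1L, end))
}

#' Region sets over the mitochondrial genome
#'
#' Expands the locus map into named position sets: the 37 genes, the D-loop,
#' and the intergenic aggregate (the 89 positions between annotations),
#' giving 39 region sets whose union covers all 16,569 positions.
#'
#' @param map Locus map tibble, default [mt_locus_map()].
#' @return Named list of integer position vectors (39 elements).
#' @export
mt_region_sets <- function(map = mt_locus_map()) {
  sets <- lapply(seq_len(nrow(map)), function(i) {
    locus_span(map$start[i], map$end[i])
  })
  names(sets) <- map$locus
  covered <- sort(unique(unlist(sets)))
  sets[["intergenic"]] <- setdiff(seq_len(MT_LENGTH), covered)
  sets
}

#' Replication-arc partition of the genome
#'
#' The two mtDNA replication origins split the molecule into a minor arc and
#' a major arc. Positions `[191, 5799)` (from the heavy-strand origin OriH at
#' m.191 up to, but excluding, the light-strand origin OriL at m.5799) form
#' the minor arc; the remainder, `[5799, 16569]` plus `[1, 191)`, forms the
#' major arc, which is exposed single-stranded for longest during
#' strand-asymmetric replication.
#'
#' @return List with `ori_h`, `ori_l`, and integer position sets `minor` and
#'   `major`.
#' @export
mt_arc_map <- function() {
  minor <- seq.int(191L, 5798L)
  list(
    ori_h = 191L,
    ori_l = 5799L,
    minor = minor,
    major = c(seq.int(5799L, MT_LENGTH), seq.int(1L, 190L))
  )
}

#' Replication arc of a position
#'
#' @param pos Integer vector of 1-based positions.
#' @param arcs Arc map, default [mt_arc_map()].
#' @return Character vector, `"minor"` or `"major"`.
#' @export
#' @examples
#' arc_of(c(100, 3000, 7028))
arc_of <- function(pos, arcs = mt_arc_map()) {
  check_positions(pos)
  ifelse(pos >= arcs$ori_h & pos < arcs$ori_l, "minor", "major")
}

#' Assign genomic positions to mitochondrial loci
#'
#' Returns every locus covering each query position; positions between
#' annotations are reported as the intergenic aggregate. Overlapping genes
#' (e.g. MT-ATP8/MT-ATP6, MT-ND4L/MT-ND4) yield one row per gene.
#'
#' @param pos Integer vector of 1-based positions.
#' @param map Locus map tibble, default [mt_locus_map()].
#' @return Tibble with columns `pos`, `locus`, `class`, one row per
#'   (position, covering locus).
#' @export
#' @examples
#' assign_locus(c(263, 7028, 11719))
assign_locus <- function(pos, map = mt_locus_map()) {
  check_positions(pos)
  hits <- purrr::map_dfr(seq_along(pos), function(i) {
    p <- pos[i]
    in_row <- ifelse(
      map$start <= map$end,
      p >= map$start & p <= map$end,
      p >= map$start | p <= map$end
    )
    if (any(in_row)) {
      tibble::tibble(pos = p, locus = map$locus[in_row], class = map$class[in_row])
    } else {
      tibble::tibble(pos = p, locus = "intergenic", class = "intergenic")
    }
  })
  hits
}

.mt_cache <- new.env(parent = emptyenv())

# Vertebrate mitochondrial genetic code (NCBI table 2), cached.
mt_code <- function() {
  if (is.null(.mt_cache$code)) {
    .mt_cache$code <- Biostrings::getGeneticCode("2")
  }
  .mt_cache$code
}

# Translate codons with the vertebrate mitochondrial genetic code.
mt_translate <- function(codons) {
  unname(mt_code()[codons])
}

# Per-gene coding consequence of a substitution. `row` is one protein row of
# the locus map. Incomplete terminal codons are completed with A
# (polyadenylation completes the stop codon in mitochondrial mRNAs).
gene_consequence <- function(pos, alt, row, genome) {
  b <- genome$bases
  if (row$strand == "L") {
    off <- pos - row$start
    cstart <- row$start + (off %/% 3L) * 3L
    cpos <- cstart + 0:2
    within <- off %% 3L
    codon <- ifelse(cpos > row$end, "A", b[pmin(cpos, MT_LENGTH)])
    alt_base <- alt
  } else {
    off <- row$end - pos
    cstart <- row$end - (off %/% 3L) * 3L
    cpos <- cstart - 0:2
    within <- off %% 3L
    codon <- ifelse(cpos < row$start, "A", mt_complement(b[pmax(cpos, 1L)]))
    alt_base <- mt_complement(alt)
  }
  ref_codon <- paste(codon, collapse = "")
  codon[within + 1L] <- alt_base
  alt_codon <- paste(codon, collapse = "")
  if (grepl("N", ref_codon) || grepl("N", alt_codon)) return(NA_character_)
  if (identical(mt_translate(ref_codon), mt_translate(alt_codon))) {
    "synonymous"
  } else {
    "non-synonymous"
  }
}

#' Functional consequence of a single-nucleotide substitution
#'
#' Protein-coding variants are translated with the vertebrate mitochondrial
#' genetic code, honouring gene strand (H-strand genes are read
#' reverse-complemented) and reading frame; variants in non-coding loci are
#' labelled by locus class. A variant overlapping two genes is called
#' non-synonymous if it is non-synonymous in *any* of them (the conservative
#' choice for burden aggregation).
#'
#' @param pos,ref,alt Vectors of 1-based positions and reference/alternative
#'   bases (on the deposited L strand). `ref` must match the genome.
#' @param genome An `mt_genome`.
#' @param map Locus map, default [mt_locus_map()].
#' @return Character vector with values in `synonymous`, `non-synonymous`,
#'   `tRNA`, `rRNA`, `D-loop`, `intergenic`.
#' @export
consequence <- function(pos, ref, alt, genome = mt_genome(), map = mt_locus_map()) {
  check_positions(pos)
  check_bases(ref, "ref")
  check_bases(alt, "alt")
  if (any(ref == alt)) abort("`alt` must differ from `ref`")
  mism <- genome$bases[pos] != ref
  if (any(mism)) {
    abort(sprintf(
      "`ref` does not match the reference at position(s) %s",
      paste(head(pos[mism], 5), collapse = ", ")
    ))
  }
  protein_rows <- map[map$class == "protein", ]
  vapply(seq_along(pos), function(i) {
    p <- pos[i]
    hit <- assign_locus(p, map)
    cls <- hit$class
    if (any(cls == "protein")) {
      rows <- protein_rows[protein_rows$locus %in% hit$locus, ]
      cons <- vapply(seq_len(nrow(rows)), function(j) {
        gene_consequence(p, alt[i], rows[j, ], genome)
      }, character(1))
      if (any(cons == "non-synonymous", na.rm = TRUE)) "non-synonymous" else "synonymous"
    } else if (any(cls == "tRNA")) {
      "tRNA"
    } else if (any(cls == "rRNA")) {
      "rRNA"
    } else if (any(cls == "D-loop")) {
      "D-loop"
    } else {
      "intergenic"
    }
  }, character(1))
}

# Vectorised per-gene consequence block: for every position of one protein
# gene and every L-strand alt base, synonymous / non-synonymous.
gene_cons_block <- function(row, genome) {
  code <- mt_code()
  pos <- seq.int(row$start, row$end)
  if (row$strand == "L") {
    off <- pos - row$start
    cstart <- row$start + (off %/% 3L) * 3L
    cp <- cbind(cstart, cstart + 1L, cstart + 2L)
    within <- off %% 3L
    bat <- function(p) ifelse(p > row$end, "A", genome$bases[pmin(p, MT_LENGTH)])
    sense <- identity
  } else {
    off <- row$end - pos
    cstart <- row$end - (off %/% 3L) * 3L
    cp <- cbind(cstart, cstart - 1L, cstart - 2L)
    within <- off %% 3L
    bat <- function(p) ifelse(p < row$start, "A", mt_complement(genome$bases[pmax(p, 1L)]))
    sense <- mt_complement
  }
  b1 <- bat(cp[, 1]); b2 <- bat(cp[, 2]); b3 <- bat(cp[, 3])
  ref_aa <- code[paste0(b1, b2, b3)]
  res <- matrix(NA_character_, length(pos), 4, dimnames = list(NULL, MT_BASES))
  for (a in MT_BASES) {
    sa <- sense(a)
    alt_aa <- code[paste0(
      ifelse(within == 0L, sa, b1),
      ifelse(within == 1L, sa, b2),
      ifelse(within == 2L, sa, b3)
    )]
    res[, a] <- ifelse(
      is.na(ref_aa) | is.na(alt_aa), NA_character_,
      ifelse(ref_aa == alt_aa, "synonymous", "non-synonymous")
    )
  }
  list(pos = pos, res = res)
}

#' Whole-genome substitution consequence table
#'
#' Precomputes [consequence()] for every position and alternative base in one
#' vectorised pass; used by [mt_annotation()] so cohort-scale annotation is a
#' table lookup. Cells where `alt` equals the reference base, or where the
#' reference base is the position-3107 placeholder, are `NA`.
#'
#' @inheritParams consequence
#' @return A 16,569 x 4 character matrix (columns A, C, G, T).
#' @export
consequence_table <- function(genome = mt_genome(), map = mt_locus_map()) {
  tab <- matrix(NA_character_, MT_LENGTH, 4, dimnames = list(NULL, MT_BASES))
  for (i in seq_len(nrow(map))) {
    row <- map[i, ]
    if (row$class == "protein") next
    span <- locus_span(row$start, row$end)
    for (a in MT_BASES) tab[span, a] <- row$class
  }
  uncov <- apply(tab, 1, function(r) all(is.na(r)))
  tab[uncov, ] <- "intergenic"
  for (i in which(map$class == "protein")) {
    blk <- gene_cons_block(map[i, ], genome)
    for (a in MT_BASES) {
      old <- tab[blk$pos, a]
      new <- blk$res[, a]
      # a variant overlapping two genes is non-synonymous if non-synonymous
      # in any of them; protein consequence outranks non-coding classes
      upd <- ifelse(
        old %in% c("synonymous", "non-synonymous"),
        ifelse(old == "non-synonymous" | new == "non-synonymous",
          "non-synonymous", "synonymous"
        ),
        new
      )
      tab[blk$pos, a] <- ifelse(is.na(new), old, upd)
    }
  }
  # alt equal to the reference, and the placeholder, are not substitutions
  ref_idx <- match(genome$bases, MT_BASES)
  ok <- !is.na(ref_idx)
  tab[cbind(which(ok), ref_idx[ok])] <- NA_character_
  tab[MT_PLACEHOLDER, ] <- NA_character_
  tab
}

#' Bundle the reference annotation used across the pipeline
#'
#' Convenience constructor collecting the genome, locus map, region sets,
#' replication arcs and homopolymer mask into one object that downstream
#' functions accept as `annotation`.
#'
#' @param genome An `mt_genome` (default: packaged synthetic reference).
#' @param min_run Homopolymer run-length threshold for the mask.
#' @param extra_mask_regions Optional extra masked regions
#'   (data frame with `start`, `end`).
#' @return Object of class `mt_annotation`.
#' @export
#' @examples
#' ann <- mt_annotation()
#' length(ann$region_sets)
mt_annotation <- function(genome = mt_genome(), min_run = 5L,
                          extra_mask_regions = NULL) {
  map <- mt_locus_map()
  structure(
    list(
      genome = genome,
      locus_map = map,
      region_sets = mt_region_sets(map),
      arcs = mt_arc_map(),
      mask = build_homopolymer_mask(genome, min_run, extra_mask_regions),
      consequences = consequence_table(genome, map)
    ),
    class = "mt_annotation"
  )
}

#' @export
print.mt_annotation <- function(x, ...) {
  cat(sprintf(
    "<mt_annotation> %d region sets, %d masked positions, OriH %d / OriL %d\n",
    length(x$region_sets), length(x$mask$positions), x$arcs$ori_h, x$arcs$ori_l
  ))
  invisible(x)
}
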