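# Circular genome model, locus map, consequences, contexts, arcs, mask.

test_that("genome model has the rCRS dimensions and placeholder", {
  g <- mt_genome()
  expect_equal(g$length, 16569L)
  expect_equal(g$bases[3107], "N")
  expect_false(3107 %in% callable_positions(g))
  expect_equal(length(callable_positions(g)), 16568L)
  # packaged FASTA is exactly the deterministic synthetic sequence
  expect_identical(g$bases, synthetic_mt_sequence())
})

test_that("position wrapping is circular", {
  expect_equal(mt_wrap(c(0L, 16570L, 1L, 16569L)), c(16569L, 1L, 1L, 16569L))
})

test_that("locus assignment matches the rCRS map at hallmark positions", {
  expect_equal(assign_locus(263)$locus, "MT-DLOOP")
  expect_equal(assign_locus(263)$class, "D-loop")
  expect_equal(assign_locus(7028)$locus, "MT-CO1")
  expect_equal(assign_locus(7028)$class, "protein")
  expect_equal(assign_locus(11719)$locus, "MT-ND4")
  # wrap: both halves of the D-loop
  expect_equal(assign_locus(16200)$locus, "MT-DLOOP")
  expect_equal(assign_locus(100)$locus, "MT-DLOOP")
  # overlapping genes yield two rows
  ov <- assign_locus(8540)
  expect_setequal(ov$locus, c("MT-ATP8", "MT-ATP6"))
  # unannotated positions fall into the intergenic aggregate
  expect_equal(assign_locus(3305)$locus, "intergenic")
  expect_error(assign_locus(0), "1\\.\\.16569")
  expect_error(assign_locus(16570), "1\\.\\.16569")
})

test_that("the 39 region sets partition-cover the genome with an 89-position intergenic aggregate", {
  sets <- mt_region_sets()
  expect_length(sets, 39L)
  expect_equal(length(sets$intergenic), 89L)
  expect_setequal(unique(unlist(sets)), 1:16569)
  map <- mt_locus_map()
  expect_equal(sum(map$class == "protein"), 13L)
  expect_equal(sum(map$class == "tRNA"), 22L)
  expect_equal(sum(map$class == "rRNA"), 2L)
  # D-loop wraps the origin: 16024..16569 plus 1..576
  expect_equal(length(sets[["MT-DLOOP"]]), 546L + 576L)
})

test_that("replication arcs partition the genome at OriH 191 / OriL 5799", {
  arcs <- mt_arc_map()
  expect_equal(arcs$ori_h, 191L)
  expect_equal(arcs$ori_l, 5799L)
  expect_length(intersect(arcs$minor, arcs$major), 0)
  expect_equal(length(arcs$minor) + length(arcs$major), 16569L)
  expect_equal(arc_of(3000), "minor")
  expect_equal(arc_of(7028), "major")
  expect_equal(arc_of(100), "major")
  expect_equal(arc_of(191), "minor")
  expect_equal(arc_of(5799), "major")
  tab <- table(arc_of(1:16569))
  expect_equal(sum(tab), 16569L)
})

test_that("trinucleotide context wraps the origin and reconstructs the genome", {
  g <- mt_genome()
  expect_equal(
    trinucleotide_context(1, g),
    paste0(g$bases[16569], g$bases[1], g$bases[2])
  )
  expect_equal(
    trinucleotide_context(16569, g),
    paste0(g$bases[16568], g$bases[16569], g$bases[1])
  )
  ctx <- trinucleotide_context(1:16569, g)
  expect_length(ctx, 16569L)
  expect_identical(substr(ctx, 2, 2), g$bases)
})

test_that("homopolymer mask finds runs and honours extra regions", {
  expect_length(build_homopolymer_mask("ACGTACGT", min_run = 5)$positions, 0)
  expect_equal(build_homopolymer_mask("AACCCCCCA", min_run = 5)$positions, 3:8)
  m <- mt_genome() |> build_homopolymer_mask(min_run = 5)
  expect_true(all(303:309 %in% m$positions))
  expect_true(all(311:315 %in% m$positions))
  expect_false(310 %in% m$positions)
  extra <- build_homopolymer_mask("ACGTACGT", 5, data.frame(start = 2, end = 3))
  expect_equal(extra$positions, 2:3)
  expect_error(build_homopolymer_mask("ACGT", min_run = 1), ">= 2")
})

test_that("consequence translates protein codons with the mitochondrial code", {
  g <- mt_genome()
  ann <- fixture_annotation()
  # third-codon-position transitions in MT-CO1 / MT-ND4 are synonymous
  # under the vertebrate mitochondrial code (two-fold degenerate families)
  for (p in c(7028L, 11719L)) {
    r <- g$bases[p]
    a <- c(A = "G", G = "A", C = "T", T = "C")[[r]]
    expect_equal(consequence(p, r, a, g), "synonymous")
  }
  r263 <- g$bases[263]
  expect_equal(consequence(263, r263, setdiff(c("A", "G"), r263)[1] %||% "G", g), "D-loop")
  expect_equal(
    consequence(1000, g$bases[1000], setdiff(c("A", "C", "G", "T"), g$bases[1000])[1], g),
    "rRNA"
  )
  expect_error(consequence(7028, setdiff(c("A", "C", "G", "T"), g$bases[7028])[1], g$bases[7028], g),
    "does not match"
  )
})

test_that("consequence agrees with an independent translation oracle", {
  skip_if_not_installed("seqinr")
  g <- mt_genome()
  ann <- fixture_annotation()
  map <- mt_locus_map()
  genes <- map[map$class == "protein", ]
  set.seed(7)
  for (i in 1:40) {
    row <- genes[sample.int(nrow(genes), 1), ]
    pos <- sample(row$start:row$end, 1)
    # keep clear of incomplete terminal codons for the oracle comparison
    if (row$strand == "L" && pos > row$end - 3) next
    if (row$strand == "H" && pos < row$start + 3) next
    ref <- g$bases[pos]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    # oracle: translate the whole gene with seqinr under the vertebrate
    # mitochondrial code before and after the substitution
    seq_ref <- g$bases[row$start:row$end]
    seq_alt <- seq_ref
    seq_alt[pos - row$start + 1] <- alt
    orient <- function(s) if (row$strand == "L") s else rev(seqinr::comp(s, forceToLower = FALSE))
    usable <- (length(seq_ref) %/% 3) * 3
    aa_ref <- seqinr::translate(orient(seq_ref)[1:usable], numcode = 2)
    aa_alt <- seqinr::translate(orient(seq_alt)[1:usable], numcode = 2)
    expected <- if (identical(aa_ref, aa_alt)) "synonymous" else "non-synonymous"
    got <- consequence(pos, ref, alt, g)
    # overlapping-gene positions may legitimately escalate to non-synonymous
    other <- genes$locus[genes$start <= pos & genes$end >= pos]
    if (length(other) > 1 && expected == "synonymous") next
    expect_equal(got, expected, label = sprintf("pos %d %s>%s in %s", pos, ref, alt, row$locus))
  }
})

test_that("the precomputed consequence table matches elementwise computation", {
  ann <- fixture_annotation()
  g <- ann$genome
  set.seed(11)
  pos <- sample(setdiff(1:16569, 3107), 60)
  for (p in pos) {
    r <- g$bases[p]
    for (a in setdiff(c("A", "C", "G", "T"), r)) {
      expect_equal(unname(ann$consequences[p, a]), consequence(p, r, a, g))
    }
    expect_true(is.na(ann$consequences[p, r]))
  }
  expect_true(all(is.na(ann$consequences[3107, ])))
})

test_that("H-strand genes are read reverse-complemented", {
  g <- mt_genome()
  map <- mt_locus_map()
  nd6 <- map[map$locus == "MT-ND6", ]
  expect_equal(nd6$strand, "H")
  # a substitution silent on the H-strand codon third position:
  # pick the position whose offset from the gene 3' end (= start of the
  # reverse-complemented frame) is 2 mod 3
  pos <- nd6$end - 2L # codon 1, position 3 in the H-strand frame
  r <- g$bases[pos]
  a <- c(A = "G", G = "A", C = "T", T = "C")[[r]]
  expect_equal(consequence(pos, r, a, g), "synonymous")
})
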