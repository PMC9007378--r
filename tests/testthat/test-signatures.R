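# Trinucleotide signature machinery and the arc asymmetry test.

test_that("substitutions are classified under the pyrimidine convention", {
  cl <- classify_substitution(c("C", "G", "A", "T"), c("T", "A", "G", "C"))
  expect_equal(cl$substitution, c("C>T", "C>T", "T>C", "T>C"))
  expect_equal(cl$strand, c("L", "H", "H", "L"))
  expect_error(classify_substitution("N", "A"), "A, C, G, T")
  expect_error(classify_substitution("C", "C"), "differ")
})

test_that("signature matrix increments the right cell and conserves counts", {
  ann <- fixture_annotation()
  g <- ann$genome
  # find a position with an L-strand C and known flanks
  pos <- which(g$bases == "C")[200]
  call <- make_call(pos = pos, ref = "C", alt = "T", hf = 0.3)
  sig <- build_signature_matrix(call, ann)
  ctx <- trinucleotide_context(pos, g)
  hit <- sig[sig$count > 0, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$substitution, "C>T")
  expect_equal(hit$five, substr(ctx, 1, 1))
  expect_equal(hit$three, substr(ctx, 3, 3))
  expect_equal(hit$strand, "L")
  expect_equal(hit$arc, unname(arc_of(pos)))
  # conservation over a cohort: total count equals input heteroplasmic calls
  co <- fixture_cohort()
  qc <- apply_qc_cascade(co$calls, co$samples, panel_afs = co$panel_afs)
  sig2 <- build_signature_matrix(qc$calls, ann)
  n_in_range <- sum(qc$calls$hf >= 0.05 & qc$calls$hf <= 0.95)
  expect_equal(sum(sig2$count) + attr(sig2, "n_context_dropped"), n_in_range)
  expect_equal(nrow(sig2), 6L * 16L * 2L * 2L)
  # stratum frequencies sum to one where populated
  fr <- sig2 |>
    dplyr::group_by(strand, arc) |>
    dplyr::summarise(f = sum(frequency), n = sum(count), .groups = "drop")
  expect_true(all(abs(fr$f[fr$n > 0] - 1) < 1e-12))
})

test_that("context aggregation reproduces substitution totals", {
  co <- fixture_cohort()
  sig <- build_signature_matrix(co$calls, fixture_annotation())
  agg <- signature_aggregate(sig)
  merged <- sig |>
    dplyr::group_by(substitution, strand, arc) |>
    dplyr::summarise(count = sum(count), .groups = "drop")
  expect_equal(
    dplyr::arrange(agg[, c("substitution", "strand", "arc", "count")], substitution, strand, arc),
    dplyr::arrange(merged, substitution, strand, arc)
  )
})

test_that("relabelling calls to the opposite strand swaps H and L counts exactly", {
  co <- fixture_cohort()
  ann <- fixture_annotation()
  sig <- build_signature_matrix(co$calls, ann)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  flipped <- dplyr::mutate(co$calls,
    ref = unname(comp[ref]), alt = unname(comp[alt])
  )
  # complementing ref/alt flips the strand attribution: per substitution
  # and arc, (sub, H) counts map onto (sub, L) exactly; at context level
  # the flanks transform by reverse complement
  sigf <- build_signature_matrix(flipped, ann)
  swap <- c(L = "H", H = "L")
  a <- signature_aggregate(sig) |>
    dplyr::arrange(substitution, strand, arc)
  b <- signature_aggregate(sigf) |>
    dplyr::mutate(strand = unname(swap[strand])) |>
    dplyr::arrange(substitution, strand, arc)
  expect_equal(a$count, b$count)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  b_ctx <- sigf |>
    dplyr::mutate(
      strand = unname(swap[strand]),
      new_five = unname(comp[three]), new_three = unname(comp[five])
    ) |>
    dplyr::arrange(substitution, new_five, new_three, strand, arc)
  a_ctx <- dplyr::arrange(sig, substitution, five, three, strand, arc)
  expect_equal(a_ctx$count, b_ctx$count)
})

test_that("asymmetry z statistic matches the pooled-proportion formula", {
  # hand construction: x/n = 30/100 major vs 15/100 minor
  sig <- tidyr::expand_grid(
    substitution = c("C>T", "T>C"), five = "A", three = "A",
    strand = "H", arc = c("minor", "major")
  )
  sig$count <- c(15L, 30L, 85L, 70L) # C>T minor/major, T>C minor/major
  class(sig) <- c("mt_signature", class(sig))
  at <- arc_asymmetry_test(sig, substitutions = "C>T", strands = "H")
  expect_equal(at$x_major, 30L)
  expect_equal(at$n_major, 100L)
  expect_equal(at$z, 2.5401, tolerance = 1e-4)
  expect_equal(at$p.value, 0.0055, tolerance = 2e-2)
  # oracle: exhaustive binomial simulation under the pooled null
  set.seed(9)
  sims <- rbinom(4e5, 100, 0.225) / 100 - rbinom(4e5, 100, 0.225) / 100
  p_mc <- mean(sims >= 30 / 100 - 15 / 100)
  expect_lt(abs(at$p.value - p_mc), 0.005)
  # equal proportions give z = 0 and one-tail p = 0.5
  sig0 <- sig
  sig0$count <- c(20L, 20L, 80L, 80L)
  at0 <- arc_asymmetry_test(sig0, substitutions = "C>T", strands = "H")
  expect_equal(at0$z, 0)
  expect_equal(at0$p.value, 0.5)
  # swapping arcs negates z
  sig_sw <- sig
  sig_sw$arc <- rep(c("major", "minor"), 2)
  at_sw <- arc_asymmetry_test(sig_sw, substitutions = "C>T", strands = "H")
  expect_equal(at_sw$z, -at$z)
  # zero denominator errors
  sig_z <- sig
  sig_z$count <- c(0L, 30L, 0L, 70L)
  expect_error(arc_asymmetry_test(sig_z, substitutions = "C>T", strands = "H"), "undefined")
})

test_that("two-sided alternative doubles the tail", {
  sig <- tidyr::expand_grid(
    substitution = c("C>T", "T>C"), five = "A", three = "A",
    strand = "H", arc = c("minor", "major")
  )
  sig$count <- c(15L, 30L, 85L, 70L)
  class(sig) <- c("mt_signature", class(sig))
  g <- arc_asymmetry_test(sig, "C>T", "H")
  t2 <- arc_asymmetry_test(sig, "C>T", "H", alternative = "two.sided")
  expect_equal(t2$p.value, 2 * g$p.value)
})

test_that("the family threshold defaults to the number of tests run", {
  co <- fixture_cohort()
  sig <- build_signature_matrix(co$calls, fixture_annotation())
  at <- arc_asymmetry_test(sig)
  expect_equal(nrow(at), 12L)
  expect_equal(attr(at, "family_threshold"), 0.05 / 12)
})

test_that("the generator's replication asymmetry is detected in somatic heteroplasmies", {
  co <- generate_cohort(simulation_config(), seed = 808)
  qc <- apply_qc_cascade(co$calls, co$samples, panel_afs = co$panel_afs)
  sig <- build_signature_matrix(qc$calls, fixture_annotation())
  at <- arc_asymmetry_test(sig)
  p_ct <- at$p.value[at$substitution == "C>T" & at$strand == "H"]
  p_tc <- at$p.value[at$substitution == "T>C" & at$strand == "L"]
  expect_lt(p_ct, 0.003)
  expect_lt(p_tc, 0.003)
})
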