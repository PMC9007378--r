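# The quality-control cascade: stage boundaries, subset/idempotence
# properties, and truth-conditioned recovery on synthetic data.

test_that("sample coverage filter uses a strict threshold", {
  s <- make_samples(3)
  s$covered_fraction <- c(0.96, 0.95, 0.90)
  kept <- filter_samples(s)
  expect_equal(kept$sample_id, "S1")
  empty <- filter_samples(s[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("basic call filter enforces depth, alt support, strand and HF", {
  ok <- make_call(depth = 1000, hf = 0.20, alt_fwd = 15, alt_rev = 15)
  one_strand <- make_call(depth = 1000, hf = 0.20, alt_fwd = 30, alt_rev = 0)
  shallow <- make_call(depth = 499, hf = 0.20, alt_fwd = 15, alt_rev = 15)
  few_alt <- make_call(depth = 1000, hf = 0.20, alt_fwd = 12, alt_rev = 12)
  low_hf <- make_call(depth = 1000, hf = 0.04, alt_fwd = 20, alt_rev = 20)
  calls <- dplyr::bind_rows(ok, one_strand, shallow, few_alt, low_hf)
  kept <- basic_call_filter(calls)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$depth, 1000L)
  expect_equal(kept$alt_fwd, 15L)
  # boundary: depth exactly 500 and 25 alt reads are retained
  edge <- make_call(depth = 500, hf = 0.05, alt_fwd = 13, alt_rev = 12)
  expect_equal(nrow(basic_call_filter(edge)), 1L)
})

test_that("homopolymer filter removes masked positions only", {
  ann <- fixture_annotation()
  masked_pos <- ann$mask$positions[1]
  outside <- setdiff(seq(masked_pos + 1, masked_pos + 50), ann$mask$positions)[1]
  calls <- dplyr::bind_rows(
    make_call(pos = masked_pos),
    make_call(pos = outside)
  )
  kept <- homopolymer_site_filter(calls, ann$mask)
  expect_equal(kept$pos, outside)
  empty_mask <- build_homopolymer_mask("ACGTACGT", 5)
  expect_identical(homopolymer_site_filter(calls, empty_mask), calls)
})

test_that("prevalence filter removes heteroplasmic calls in the offending group only", {
  s <- dplyr::bind_rows(make_samples(100, "HTN"), {
    x <- make_samples(100, "control")
    x$sample_id <- sprintf("C%d", 1:100)
    x
  })
  # one site heteroplasmic in 5 HTN carriers (5%) and 1 control (1%),
  # plus a homoplasmic call at the same site
  het_htn <- purrr::map_dfr(1:5, function(i) make_call(sprintf("S%d", i), pos = 4000, hf = 0.3))
  het_ctl <- make_call("C1", pos = 4000, hf = 0.3)
  hom <- make_call("S6", pos = 4000, hf = 0.99)
  calls <- dplyr::bind_rows(het_htn, het_ctl, hom)
  kept <- cohort_prevalence_filter(calls, s)
  expect_equal(sort(kept$sample_id), c("C1", "S6"))
  # exactly at 2% (2 of 100) is retained under the strict "more than" rule
  two <- purrr::map_dfr(1:2, function(i) make_call(sprintf("S%d", i), pos = 4100, hf = 0.3))
  expect_equal(nrow(cohort_prevalence_filter(two, s)), 2L)
  # cohort-wide scope removes the control call too
  kept_all <- cohort_prevalence_filter(calls, s, scope = "cohort")
  expect_equal(kept_all$sample_id, "S6")
})

test_that("panel concordance filter removes discordant homoplasmies", {
  s <- make_samples(20)
  hom <- purrr::map_dfr(1:19, function(i) make_call(sprintf("S%d", i), pos = 6000, hf = 0.99))
  het <- make_call("S20", pos = 6000, hf = 0.3)
  other <- make_call("S1", pos = 6200, hf = 0.99)
  calls <- dplyr::bind_rows(hom, het, other)
  panel <- list(tibble::tibble(pos = 6000L, alt = hom$alt[1], af = 0.01))
  kept <- panel_concordance_filter(calls, panel, s)
  # cohort AF 0.95 vs panel 0.01: homoplasmic calls removed, the
  # heteroplasmic call stays; the allele absent from the panel (af -> 0,
  # cohort AF 0.05) is concordant enough to stay
  expect_equal(sort(unique(kept$pos)), c(6000L, 6200L))
  expect_true(all(kept$hf[kept$pos == 6000] <= 0.95))
  # concordant frequencies survive
  panel2 <- list(tibble::tibble(pos = 6000L, alt = hom$alt[1], af = 0.90))
  expect_equal(nrow(panel_concordance_filter(calls, panel2, s)), nrow(calls))
})

test_that("CV filter removes low-variability sites at the requested percentile", {
  # 100 sites, each with 3 carriers, constructed with strictly increasing CV
  calls <- purrr::map_dfr(1:100, function(j) {
    hfs <- 0.4 + c(-1, 0, 1) * (j / 1200)
    purrr::map_dfr(1:3, function(i) {
      make_call(sprintf("S%d_%d", j, i), pos = 1000 + j, hf = hfs[i])
    })
  })
  res <- cv_site_filter(calls, percentile = 25, min_carriers = 3)
  removed <- res$site_stats[res$site_stats$removed, ]
  expect_equal(nrow(removed), 25L)
  expect_equal(sort(removed$pos), 1000 + 1:25)
  # identical HF in all carriers -> CV 0 -> removed at any positive percentile
  flat <- purrr::map_dfr(1:10, function(i) make_call(sprintf("F%d", i), pos = 2000, hf = 0.30))
  res2 <- cv_site_filter(dplyr::bind_rows(calls, flat), percentile = 25)
  expect_true(2000 %in% res2$site_stats$pos[res2$site_stats$removed])
  # single-carrier sites never enter the CV distribution nor get removed
  single <- make_call("Z1", pos = 3000, hf = 0.2)
  res3 <- cv_site_filter(dplyr::bind_rows(calls, single), percentile = 25)
  st <- res3$site_stats[res3$site_stats$pos == 3000, ]
  expect_true(is.na(st$cv))
  expect_false(st$removed)
  expect_true(3000 %in% res3$calls$pos)
  # all sites below the carrier floor -> warning, no-op
  expect_warning(res4 <- cv_site_filter(single, percentile = 25), "no-op")
  expect_identical(res4$calls, single)
})

test_that("each stage returns a subset of its input and the cascade is idempotent", {
  co <- fixture_cohort()
  qc1 <- apply_qc_cascade(co$calls, co$samples, panel_afs = co$panel_afs)
  key <- function(d) paste(d$sample_id, d$pos, d$alt)
  expect_true(all(key(qc1$calls) %in% key(co$calls)))
  expect_true(all(qc1$stages$n_removed >= 0))
  expect_equal(qc1$stages$n_out, qc1$stages$n_in - qc1$stages$n_removed)
  qc2 <- apply_qc_cascade(qc1$calls, qc1$samples, panel_afs = co$panel_afs)
  expect_identical(qc2$calls, qc1$calls)
  expect_identical(qc2$samples, qc1$samples)
})

test_that("pure per-call predicates commute", {
  co <- fixture_cohort()
  ann <- fixture_annotation()
  a <- co$calls |> basic_call_filter() |> homopolymer_site_filter(ann$mask)
  b <- co$calls |> homopolymer_site_filter(ann$mask) |> basic_call_filter()
  expect_identical(a, b)
})

test_that("the cascade removes at least 95% of truth-labelled artifacts", {
  co <- fixture_cohort()
  qc <- apply_qc_cascade(co$calls, co$samples, panel_afs = co$panel_afs)
  surviving_samples <- qc$samples$sample_id
  art_in <- sum(co$calls$origin == "artifact" & co$calls$sample_id %in% surviving_samples)
  art_out <- sum(qc$calls$origin == "artifact")
  expect_gte(1 - art_out / art_in, 0.95)
  # and keeps the bulk of genuine somatic variation
  som_in <- sum(co$calls$origin == "somatic" & co$calls$sample_id %in% surviving_samples)
  som_out <- sum(qc$calls$origin == "somatic")
  expect_gt(som_out / som_in, 0.9)
})

test_that("the CV filter removes NUMT sites preferentially", {
  co <- generate_cohort(simulation_config(), seed = 555)
  qc <- apply_qc_cascade(co$calls, co$samples,
    panel_afs = co$panel_afs,
    cv_filter = TRUE
  )
  st <- qc$site_stats
  numt_key <- paste(co$truth$numt_sites$pos, co$truth$numt_sites$alt)
  is_numt <- paste(st$pos, st$alt) %in% numt_key
  expect_gte(sum(st$removed & is_numt) / nrow(co$truth$numt_sites), 0.8)
  # enrichment: odds of removal for NUMT sites exceed those of other sites
  tab <- table(removed = st$removed, numt = is_numt)
  or <- (tab["TRUE", "TRUE"] * tab["FALSE", "FALSE"]) /
    (max(tab["TRUE", "FALSE"], 0.5) * max(tab["FALSE", "TRUE"], 0.5))
  expect_gt(or, 1)
})
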