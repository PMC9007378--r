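# Tiles, region matrices, the SKAT/burden combination test and its
# permutation oracle.

test_that("tile construction matches the makewindows convention", {
  expect_equal(nrow(make_tiles(16569, 100, 10)), 1657L)
  t10 <- make_tiles(100, 100, 10)
  expect_equal(nrow(t10), 10L)
  expect_equal(t10$start, seq(0L, 90L, 10L))
  expect_equal(t10$end, pmin(t10$start + 100L, 100L))
  expect_equal(sum(t10$end == 100L), 10L) # last nine truncated + the full first
  t5 <- make_tiles(50, 100, 10)
  expect_equal(nrow(t5), 5L)
  expect_true(all(t5$end == 50L))
  expect_error(make_tiles(100, 0, 10), "positive")
  expect_error(make_tiles(100, 5, 10), ">=")
})

test_that("tile count formula matches brute-force enumeration for all L <= 500", {
  for (L in 1:500) {
    starts <- seq(0L, L - 1L, by = 10L)
    expect_equal(nrow(make_tiles(L, 100, 10)), length(starts))
  }
})

test_that("region matrices code carriers with wrap handling and beta weights", {
  s <- make_samples(100)
  calls <- dplyr::bind_rows(
    purrr::map_dfr(1:3, function(i) make_call(sprintf("S%d", i), pos = 300, hf = 0.5)),
    make_call("S4", pos = 16100, hf = 0.5),
    make_call("S5", pos = 250, hf = 0.07) # low class: excluded by default
  )
  rm1 <- region_matrix(calls, 251:350, s)
  expect_equal(ncol(rm1$G), 1L)
  expect_equal(sum(rm1$G), 3L)
  expect_equal(rm1$weights, dbeta(0.03, 1, 25))
  # D-loop wrap: both 16100 and 300 belong to the wrapped region set
  dloop <- fixture_annotation()$region_sets[["MT-DLOOP"]]
  rm2 <- region_matrix(calls, dloop, s)
  expect_equal(sort(rm2$variants$pos), c(300L, 16100L))
  # a region with no qualifying variant signals empty
  expect_null(region_matrix(calls, 9000:9100, s))
  # low-class request picks up the low call instead
  rm3 <- region_matrix(calls, 200:400, s, het_class = "low")
  expect_equal(rm3$variants$pos, 250L)
})

test_that("single-variant regions give identical SKAT, burden and combined p", {
  set.seed(21)
  n <- 200
  y <- rep(c(1, 0), each = n / 2)
  G <- matrix(rbinom(n, 1, 0.15), ncol = 1)
  res <- skat_o_test(G, y)
  expect_equal(res$p_skat, res$p_burden)
  expect_equal(res$p_skat, res$p_skato)
})

test_that("rho = 1 reduces to the collapsing burden score test", {
  set.seed(22)
  n <- 300
  y <- rbinom(n, 1, 0.4)
  G <- sapply(c(0.1, 0.2, 0.15), function(f) rbinom(n, 1, f))
  res <- skat_o_test(G, y, rho = 1, small_sample = FALSE)
  # burden score test: z^2 on the weighted carrier sum
  w <- dbeta(colMeans(G), 1, 25)
  b <- drop(G %*% w)
  mu <- mean(y)
  s <- sum(b * (y - mu))
  v <- sum((b - mean(b))^2) * mu * (1 - mu)
  p_ref <- pchisq(s^2 / v, df = 1, lower.tail = FALSE)
  expect_equal(res$p_burden, p_ref, tolerance = 1e-6)
})

test_that("degenerate columns are dropped and fully empty regions signal NULL", {
  set.seed(23)
  n <- 100
  y <- rbinom(n, 1, 0.5)
  G <- cbind(rbinom(n, 1, 0.2), 0L, 1L)
  expect_message(res <- skat_o_test(G, y), "degenerate")
  expect_equal(res$n_variants, 1L)
  expect_null(suppressMessages(skat_o_test(matrix(0L, n, 2), y)))
})

test_that("the test is invariant to variant column order", {
  set.seed(24)
  n <- 250
  y <- rbinom(n, 1, 0.5)
  G <- sapply(c(0.05, 0.1, 0.2, 0.3), function(f) rbinom(n, 1, f))
  a <- skat_o_test(G, y)
  b <- skat_o_test(G[, 4:1], y)
  expect_equal(a$p_skato, b$p_skato, tolerance = 1e-10)
  expect_equal(a$p_skat, b$p_skat, tolerance = 1e-10)
  expect_equal(a$p_burden, b$p_burden, tolerance = 1e-10)
})

test_that("permutation p-values are reproducible and exact at full separation", {
  y <- rep(c(1, 0), each = 20)
  G <- matrix(as.integer(y == 1), ncol = 1)
  p <- permutation_region_test(G, y, n_perm = 2000, seed = 1)
  expect_equal(p, 1 / 2001)
  p2 <- permutation_region_test(G, y, n_perm = 2000, seed = 1)
  expect_identical(p, p2)
  expect_error(permutation_region_test(G, y, n_perm = 100, seed = 1), "1000")
})

test_that("moment-matching p agrees with the permutation oracle on small instances", {
  # instances with adequate carrier counts in the decision-relevant range
  mk <- function(n, seed, effect) {
    set.seed(seed)
    X <- cbind(age = rnorm(n, 60, 8))
    G <- sapply(c(0.05, 0.12, 0.08, 0.15, 0.1), function(f) rbinom(n, 1, f))
    y <- rbinom(n, 1, plogis(-0.2 + effect * (G %*% rep(1, 5))))
    list(G = G, y = y, X = X)
  }
  for (inst in list(
    mk(150, 1, 0.6), mk(150, 2, 0.6),
    mk(300, 1, 0.5), mk(300, 2, 0.5)
  )) {
    res <- suppressMessages(skat_o_test(inst$G, inst$y, inst$X))
    pp <- permutation_region_test(inst$G, inst$y, inst$X,
      n_perm = 20000, seed = 9, statistic = "skato"
    )
    expect_lt(abs(res$p_skato - pp), 0.02)
  }
})

test_that("null p-values are approximately uniform (KS over replicates)", {
  set.seed(77)
  pv <- replicate(200, {
    n <- 150
    G <- sapply(runif(4, 0.05, 0.2), function(f) rbinom(n, 1, f))
    y <- rbinom(n, 1, 0.5)
    suppressMessages(skat_o_test(G, y))$p_skat
  })
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("the genome-wide scan attaches the family threshold and skips empty regions", {
  co <- fixture_cohort()
  qc <- apply_qc_cascade(co$calls, co$samples, panel_afs = co$panel_afs)
  scan <- genomewide_region_scan(qc$calls, qc$samples, "loci")
  expect_equal(nrow(scan), 39L)
  expect_equal(attr(scan, "threshold_echo"), 0.001)
  expect_true(all(scan$p_skato[scan$tested] > 0 & scan$p_skato[scan$tested] <= 1))
  expect_true(all(is.na(scan$p_skato[!scan$tested])))
  # tiles: a handful of windows, threshold 0.05 / count
  tiles <- make_tiles()[100:110, ]
  scan2 <- genomewide_region_scan(qc$calls, qc$samples, tiles)
  expect_equal(attr(scan2, "threshold"), 0.05 / 11)
  full_thr <- bonferroni_threshold(0.05, nrow(make_tiles()))
  expect_equal(signif(full_thr, 1), 3e-5)
})
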