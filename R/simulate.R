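# Synthetic cohort generator: per-sample mtDNA variant calls with the
# statistical structure the downstream analysis assumes, plus truth labels
# for every injected call so filters and models can be validated.

# fraction of a Uniform(lo, hi) draw falling in [a, b)
unif_frac <- function(lo, hi, a, b) {
  if (hi <= lo) return(0)
  max(0, min(hi, b) - max(lo, a)) / (hi - lo)
}

# E[exp(s * Age)] for Age ~ Uniform(a, b); the calibration term that converts
# a target marginal mean into a log-linear intercept.
unif_mgf <- function(s, a, b) {
  if (s == 0) return(1)
  (exp(s * b) - exp(s * a)) / (s * (b - a))
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults encode the cohort structure the package is designed around:
#' per-individual means of about 9 homoplasmies, 1.3 intermediate
#' (HF 10--95%) and 0.3 low-level (HF 5--10%) heteroplasmies; an age slope of
#' 0.02 per year (log scale) on the somatic low-level rate; a case-control
#' log-effect of 0.27 on intermediate burden (0.28 for its non-synonymous
#' component); 99.8% transitions among heteroplasmies with the
#' replication-strand signature (C>T on the heavy strand / T>C on the light
#' strand, enriched in the major arc); NUMT pseudo-heteroplasmies with
#' near-constant HF across carriers; and homopolymer-tract artifacts.
#' Somatic rate intercepts are calibrated analytically from the target means
#' given the age range and case mix unless supplied explicitly.
#'
#' @param n_cases,n_controls Cohort composition.
#' @param case_group Disease label for cases (`"HTN"`, `"IHD"`, `"IS"`).
#' @param age_range Ages are drawn uniformly from this interval (years).
#' @param mean_low,mean_intermediate,mean_homoplasmies Target marginal means
#'   of per-individual variant counts by heteroplasmy class.
#' @param homoplasmy_size_dispersion Negative binomial size parameter of the
#'   haplotype-size distribution (controls the spread around
#'   `mean_homoplasmies`).
#' @param somatic_rate_age_slope Log-scale age slope of the somatic low-level
#'   heteroplasmy rate (per year).
#' @param somatic_rate_intercept,intermediate_rate_intercept Optional explicit
#'   log-scale intercepts; `NULL` means "calibrate from the target mean".
#' @param intermediate_age_slope Log-scale age slope of the intermediate rate.
#' @param case_effect_intermediate,case_effect_low Log-scale case-control
#'   effects on the intermediate and low-level rates.
#' @param case_effect_nonsyn Log-scale case-control effect on the
#'   non-synonymous component of intermediate burden (realised by slightly
#'   biasing case variant placement toward non-synonymous sites).
#' @param transition_fraction Fraction of heteroplasmic variants that are
#'   transitions.
#' @param signature_bias Probability mass of the replication-asymmetric pair
#'   (C>T-on-H / T>C-on-L) among somatic transitions.
#' @param major_arc_odds Odds multiplier applied to major-arc placement of
#'   the strand-asymmetric transitions.
#' @param hf_low_beta,hf_intermediate_beta,hf_homoplasmy_beta Beta shape
#'   pairs for HF draws, rescaled to (0.05, 0.10), (0.10, 0.95) and
#'   (0.95, 1.00) respectively.
#' @param numt_sites,numt_carrier_fraction,numt_hf_range,numt_hf_jitter NUMT
#'   pseudo-heteroplasmy model: number of affected sites, per-sample carrier
#'   probability, range of the site-level shared HF, and the (small) SD of
#'   the per-carrier jitter around it.
#' @param artifact_rate Expected number of artifact calls per sample.
#' @param artifact_strand_bias_fraction Fraction of artifacts that are
#'   strand-biased (all alternative reads on one strand) rather than placed
#'   in homopolymer tracts.
#' @param artifact_hf_range HF range of artifact calls.
#' @param depth_mean,depth_between_sd Mean and between-sample SD of
#'   per-sample mean read depth.
#' @param depth_size Negative binomial size of per-site depth around the
#'   sample mean.
#' @param coverage_dropout_fraction Fraction of samples with mtDNA breadth of
#'   coverage below the 95% QC threshold.
#' @param n_haplotypes,n_panel_sites,n_backbone_sites Haplogroup model: a
#'   pool of haplotypes built over `n_panel_sites` polymorphic sites, of
#'   which `n_backbone_sites` are near-universal (rCRS-vs-population
#'   backbone differences).
#' @param discordant_fraction Fraction of polymorphic sites given a
#'   reference-panel allele frequency discordant by more than 0.9 (exercises
#'   the panel-concordance filter).
#' @param panel_noise_sd SD of the noise between cohort and panel allele
#'   frequencies at concordant sites.
#' @param high_path_fraction Fraction of non-synonymous variants given a
#'   pathogenicity score of at least 0.7.
#' @param pathogenic_hf_skew Strength of the preference for assigning high
#'   pathogenicity scores to lower-HF variants (0 = none).
#' @return Object of class `mt_sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(n_cases = 50, n_controls = 50)
#' cfg$mean_intermediate
simulation_config <- function(n_cases = 1000L, n_controls = 1000L,
                              case_group = c("HTN", "IHD", "IS"),
                              age_range = c(30, 90),
                              mean_low = 0.3, mean_intermediate = 1.3,
                              mean_homoplasmies = 9,
                              homoplasmy_size_dispersion = 0.5,
                              somatic_rate_age_slope = 0.02,
                              somatic_rate_intercept = NULL,
                              intermediate_age_slope = 0,
                              intermediate_rate_intercept = NULL,
                              case_effect_intermediate = 0.27,
                              case_effect_nonsyn = 0.28,
                              case_effect_low = 0,
                              transition_fraction = 0.998,
                              signature_bias = 0.8,
                              major_arc_odds = 4,
                              hf_low_beta = c(2, 2),
                              hf_intermediate_beta = c(1.6, 1.1),
                              hf_homoplasmy_beta = c(8, 1),
                              numt_sites = 8L,
                              numt_carrier_fraction = 0.005,
                              numt_hf_range = c(0.10, 0.30),
                              numt_hf_jitter = 0.005,
                              artifact_rate = 0.05,
                              artifact_strand_bias_fraction = 0.4,
                              artifact_hf_range = c(0.05, 0.15),
                              depth_mean = 1088, depth_between_sd = 90,
                              depth_size = 30,
                              coverage_dropout_fraction = 0.02,
                              n_haplotypes = 60L, n_panel_sites = 150L,
                              n_backbone_sites = 5L,
                              discordant_fraction = 0.01,
                              panel_noise_sd = 0.03,
                              high_path_fraction = 0.25,
                              pathogenic_hf_skew = 2) {
  case_group <- match.arg(case_group)
  cfg <- as.list(environment())
  probs <- c(
    transition_fraction, signature_bias, numt_carrier_fraction,
    artifact_strand_bias_fraction, coverage_dropout_fraction,
    discordant_fraction, high_path_fraction
  )
  if (any(probs < 0 | probs > 1)) abort("probability parameters must lie in [0, 1]")
  if (any(c(
    mean_low, mean_intermediate, mean_homoplasmies, artifact_rate,
    numt_sites, major_arc_odds, panel_noise_sd, pathogenic_hf_skew
  ) < 0)) {
    abort("rate parameters must be non-negative")
  }
  if (n_cases < 0 || n_controls < 0) abort("cohort sizes must be non-negative")
  if (age_range[2] <= age_range[1]) abort("`age_range` must be increasing")
  if (numt_hf_range[1] < 0.05 || numt_hf_range[2] > 0.95) {
    abort("`numt_hf_range` must lie within the heteroplasmic range [0.05, 0.95]")
  }
  structure(cfg, class = "mt_sim_config")
}

#' @export
print.mt_sim_config <- function(x, ...) {
  cat(sprintf(
    "<mt_sim_config> %d cases (%s) / %d controls; target means %.2f int / %.2f low / %.1f homoplasmic\n",
    x$n_cases, x$case_group, x$n_controls,
    x$mean_intermediate, x$mean_low, x$mean_homoplasmies
  ))
  invisible(x)
}

# expected per-sample contamination counts by heteroplasmy class
contamination_means <- function(cfg) {
  numt_total <- cfg$numt_sites * cfg$numt_carrier_fraction
  art_total <- cfg$artifact_rate
  list(
    numt_low = numt_total * unif_frac(cfg$numt_hf_range[1], cfg$numt_hf_range[2], 0.05, 0.10),
    numt_int = numt_total * unif_frac(cfg$numt_hf_range[1], cfg$numt_hf_range[2], 0.10, 0.95),
    art_low = art_total * unif_frac(cfg$artifact_hf_range[1], cfg$artifact_hf_range[2], 0.05, 0.10),
    art_int = art_total * unif_frac(cfg$artifact_hf_range[1], cfg$artifact_hf_range[2], 0.10, 0.95)
  )
}

# solve for the log-scale intercept giving the target pooled marginal mean
calibrate_intercept <- function(target, slope, case_effect, f_case, age_range) {
  if (target <= 0) {
    abort("contamination exceeds the target class mean; reduce numt/artifact rates")
  }
  mix <- f_case * exp(case_effect) + (1 - f_case)
  log(target) - log(mix) - log(unif_mgf(slope, age_range[1], age_range[2]))
}

# position pools by required L-strand reference base, excluding the
# homopolymer mask, the placeholder and reserved (panel/NUMT) sites
position_pools <- function(annotation, exclude) {
  usable <- setdiff(callable_positions(annotation$genome), annotation$mask$positions)
  usable <- setdiff(usable, exclude)
  arcs <- arc_of(usable, annotation$arcs)
  bases <- annotation$genome$bases[usable]
  pools <- list()
  for (b in MT_BASES) {
    pools[[b]] <- list(
      major = usable[bases == b & arcs == "major"],
      minor = usable[bases == b & arcs == "minor"]
    )
  }
  pools
}

# The 4 transition types on the L-strand reference with their strand
# attribution under the pyrimidine convention. The replication-asymmetric
# pair is C>T-on-H (ref G) and T>C-on-L (ref T).
TRANSITION_TYPES <- data.frame(
  ref = c("G", "T", "C", "A"),
  alt = c("A", "C", "T", "G"),
  pyr_strand = c("H", "L", "L", "H"),
  biased = c(TRUE, TRUE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

# draw (ref, alt, pos) for n somatic heteroplasmies
draw_somatic_positions <- function(n, cfg, pools) {
  if (n == 0L) {
    return(tibble::tibble(
      pos = integer(0), ref = character(0), alt = character(0)
    ))
  }
  is_ts <- runif(n) < cfg$transition_fraction
  type_idx <- integer(n)
  biased <- runif(n) < cfg$signature_bias
  pick <- runif(n) < 0.5
  type_idx[is_ts] <- ifelse(biased[is_ts], ifelse(pick[is_ts], 1L, 2L),
    ifelse(pick[is_ts], 3L, 4L)
  )
  ref <- alt <- character(n)
  arc <- character(n)
  # transitions: type fixes ref/alt; arc drawn with major-arc enrichment for
  # the replication-asymmetric pair
  for (t in 1:4) {
    sel <- which(is_ts & type_idx == t)
    if (!length(sel)) next
    tr <- TRANSITION_TYPES[t, ]
    ref[sel] <- tr$ref
    alt[sel] <- tr$alt
    pool <- pools[[tr$ref]]
    s_major <- length(pool$major) / (length(pool$major) + length(pool$minor))
    p_major <- if (tr$biased) {
      cfg$major_arc_odds * s_major / (cfg$major_arc_odds * s_major + (1 - s_major))
    } else {
      s_major
    }
    arc[sel] <- ifelse(runif(length(sel)) < p_major, "major", "minor")
  }
  # transversions: uniform over the eight ref->alt pairs, arc by availability
  tv <- which(!is_ts)
  if (length(tv)) {
    tv_pairs <- expand.grid(ref = MT_BASES, alt = MT_BASES, stringsAsFactors = FALSE)
    tv_pairs <- tv_pairs[tv_pairs$ref != tv_pairs$alt &
      TRANSITION[tv_pairs$ref] != tv_pairs$alt, ]
    j <- sample.int(nrow(tv_pairs), length(tv), replace = TRUE)
    ref[tv] <- tv_pairs$ref[j]
    alt[tv] <- tv_pairs$alt[j]
    for (i in tv) {
      pool <- pools[[ref[i]]]
      s_major <- length(pool$major) / (length(pool$major) + length(pool$minor))
      arc[i] <- if (runif(1) < s_major) "major" else "minor"
    }
  }
  pos <- integer(n)
  for (b in MT_BASES) {
    for (a in c("major", "minor")) {
      sel <- which(ref == b & arc == a)
      if (!length(sel)) next
      pool <- pools[[b]][[a]]
      if (!length(pool)) pool <- c(pools[[b]]$major, pools[[b]]$minor)
      pos[sel] <- sample(pool, length(sel), replace = TRUE)
    }
  }
  tibble::tibble(pos = pos, ref = ref, alt = alt)
}

# per-call depth and strand-split alternative read counts
attach_reads <- function(df, sample_depth, cfg, strand_biased = FALSE) {
  n <- nrow(df)
  if (n == 0L) {
    return(dplyr::mutate(df,
      depth = integer(0), alt_fwd = integer(0), alt_rev = integer(0)
    ))
  }
  depth <- pmax(rnbinom(n, size = cfg$depth_size, mu = sample_depth), 50L)
  alt_total <- pmin(pmax(round(df$hf * depth), 1L), depth)
  if (strand_biased) {
    side <- runif(n) < 0.5
    alt_fwd <- ifelse(side, alt_total, 0L)
  } else {
    alt_fwd <- rbinom(n, alt_total, 0.5)
  }
  dplyr::mutate(df,
    depth = as.integer(depth),
    alt_fwd = as.integer(alt_fwd),
    alt_rev = as.integer(alt_total - alt_fwd)
  )
}

#' Generate a synthetic mtDNA heteroplasmy cohort
#'
#' Simulates per-sample variant calls, sample metadata, reference-panel
#' allele-frequency tables and conservation/pathogenicity score tables with
#' the structure the analysis pipeline assumes. Each sample receives (a) a
#' haplotype of shared homoplasmies (HF near 1), (b) Poisson numbers of
#' intermediate and low-level heteroplasmies with log-linear age and
#' case-control effects, placed under the strand/arc mutational signature,
#' (c) NUMT pseudo-heteroplasmies at fixed sites with near-constant HF
#' across carriers, and (d) artifact calls (homopolymer-tract or
#' strand-biased). Every call carries an `origin` truth label
#' (`inherited`, `somatic`, `numt`, `artifact`).
#'
#' @param config An [simulation_config()] object.
#' @param seed Integer seed; the same seed and config reproduce the cohort
#'   exactly.
#' @param annotation An [mt_annotation()]; defaults to the packaged one.
#' @return Object of class `mt_cohort`: list with `calls`, `samples`,
#'   `panel_afs` (two tibbles), `scores` (`phastcons`, `mutpred`), `truth`,
#'   `config`, `seed`.
#' @export
#' @examples
#' cohort <- generate_cohort(simulation_config(n_cases = 30, n_controls = 30), seed = 1)
#' nrow(cohort$samples)
generate_cohort <- function(config = simulation_config(), seed = 1L,
                            annotation = default_annotation()) {
  stopifnot(inherits(config, "mt_sim_config"))
  n <- config$n_cases + config$n_controls
  if (n == 0L) abort("degenerate config: cohort has zero samples")
  withr::with_seed(as.integer(seed), {
    cohort <- generate_cohort_impl(config, annotation)
  })
  cohort$seed <- as.integer(seed)
  cohort
}

generate_cohort_impl <- function(cfg, annotation) {
  n <- cfg$n_cases + cfg$n_controls
  genome <- annotation$genome

  ## ---- samples -----------------------------------------------------------
  is_case <- rep(c(TRUE, FALSE), c(cfg$n_cases, cfg$n_controls))
  dropout <- runif(n) < cfg$coverage_dropout_fraction
  samples <- tibble::tibble(
    sample_id = sprintf("S%05d", seq_len(n)),
    group = ifelse(is_case, cfg$case_group, "control"),
    age = runif(n, cfg$age_range[1], cfg$age_range[2]),
    sex = sample(c("F", "M"), n, replace = TRUE),
    mean_depth = pmax(rnorm(n, cfg$depth_mean, cfg$depth_between_sd), 200),
    mt_ancestry = sample(c("European", "African", "Asian"), n,
      replace = TRUE, prob = c(0.94, 0.03, 0.03)
    ),
    covered_fraction = ifelse(dropout, runif(n, 0.90, 0.949), runif(n, 0.955, 0.999)),
    sbp = ifelse(is_case, rnorm(n, 160, 15), NA_real_),
    dbp = ifelse(is_case, rnorm(n, 95, 10), NA_real_),
    smoker = ifelse(is_case, runif(n) < 0.3, NA)
  )
  # a sprinkling of missing optional covariates, as in real case metadata
  miss <- is_case & runif(n) < 0.1
  samples$sbp[miss] <- NA_real_
  samples$dbp[miss] <- NA_real_

  ## ---- haplotype homoplasmies -------------------------------------------
  usable <- setdiff(callable_positions(genome), annotation$mask$positions)
  panel_pos <- sort(sample(usable, cfg$n_panel_sites))
  backbone <- panel_pos[sort(sample.int(cfg$n_panel_sites, cfg$n_backbone_sites))]
  extras <- setdiff(panel_pos, backbone)
  panel_ref <- genome$bases[panel_pos]
  panel_is_ts <- runif(cfg$n_panel_sites) < cfg$transition_fraction
  panel_alt <- ifelse(panel_is_ts, TRANSITION[panel_ref],
    vapply(panel_ref, function(r) sample(setdiff(MT_BASES, c(r, TRANSITION[r])), 1), character(1))
  )
  names(panel_alt) <- NULL
  extra_w <- rbeta(length(extras), 0.5, 1.5) + 1e-4
  extra_mu <- max(cfg$mean_homoplasmies - cfg$n_backbone_sites, 0.1)
  hap_sizes <- pmin(
    rnbinom(cfg$n_haplotypes, mu = extra_mu, size = cfg$homoplasmy_size_dispersion),
    length(extras)
  )
  haplotypes <- lapply(hap_sizes, function(k) {
    c(backbone, if (k > 0) sample(extras, k, prob = extra_w))
  })
  hap_of <- sample.int(cfg$n_haplotypes, n, replace = TRUE)
  hom_sites <- haplotypes[hap_of]
  hom_n <- lengths(hom_sites)
  hom_pos <- unlist(hom_sites, use.names = FALSE)
  hom <- tibble::tibble(
    sample_id = rep(samples$sample_id, hom_n),
    pos = hom_pos,
    ref = genome$bases[hom_pos],
    alt = panel_alt[match(hom_pos, panel_pos)],
    hf = 0.95 + 0.05 * rbeta(length(hom_pos), cfg$hf_homoplasmy_beta[1], cfg$hf_homoplasmy_beta[2]),
    origin = "inherited"
  )
  hom <- attach_reads(hom, rep(samples$mean_depth, hom_n), cfg)

  ## ---- NUMT pseudo-heteroplasmies ---------------------------------------
  numt_pool <- setdiff(usable, panel_pos)
  numt_pos <- if (cfg$numt_sites > 0) sort(sample(numt_pool, cfg$numt_sites)) else integer(0)
  numt_ref <- genome$bases[numt_pos]
  numt_is_ts <- runif(cfg$numt_sites) < cfg$transition_fraction
  numt_alt <- ifelse(numt_is_ts, TRANSITION[numt_ref],
    vapply(numt_ref, function(r) sample(setdiff(MT_BASES, c(r, TRANSITION[r])), 1), character(1))
  )
  names(numt_alt) <- NULL
  numt_hf0 <- runif(cfg$numt_sites, cfg$numt_hf_range[1], cfg$numt_hf_range[2])
  numt <- purrr::map_dfr(seq_len(cfg$numt_sites), function(j) {
    carriers <- which(runif(n) < cfg$numt_carrier_fraction)
    if (!length(carriers)) return(NULL)
    tibble::tibble(
      sample_id = samples$sample_id[carriers],
      pos = numt_pos[j],
      ref = numt_ref[j],
      alt = numt_alt[j],
      hf = pmin(pmax(numt_hf0[j] + rnorm(length(carriers), 0, cfg$numt_hf_jitter), 0.051), 0.949),
      origin = "numt",
      .depth_mu = samples$mean_depth[carriers]
    )
  })
  if (nrow(numt)) {
    numt <- attach_reads(numt, numt$.depth_mu, cfg)
    numt$.depth_mu <- NULL
  } else {
    numt <- hom[0, ]
  }

  ## ---- somatic heteroplasmies -------------------------------------------
  contam <- contamination_means(cfg)
  f_case <- cfg$n_cases / n
  a_int <- cfg$intermediate_rate_intercept %||% calibrate_intercept(
    cfg$mean_intermediate - contam$numt_int - contam$art_int,
    cfg$intermediate_age_slope, cfg$case_effect_intermediate, f_case, cfg$age_range
  )
  a_low <- cfg$somatic_rate_intercept %||% calibrate_intercept(
    cfg$mean_low - contam$numt_low - contam$art_low,
    cfg$somatic_rate_age_slope, cfg$case_effect_low, f_case, cfg$age_range
  )
  is_case <- samples$group != "control"
  rate_int <- exp(a_int + cfg$intermediate_age_slope * samples$age +
    cfg$case_effect_intermediate * is_case)
  rate_low <- exp(a_low + cfg$somatic_rate_age_slope * samples$age +
    cfg$case_effect_low * is_case)
  n_int <- rpois(n, rate_int)
  n_low <- rpois(n, rate_low)
  pools <- position_pools(annotation, exclude = c(panel_pos, numt_pos))

  som_int <- draw_somatic_positions(sum(n_int), cfg, pools)
  som_int$sample_id <- rep(samples$sample_id, n_int)
  # realise the extra non-synonymous case effect: case placements are
  # redrawn onto a non-synonymous site with a small probability so that the
  # non-synonymous component carries exp(case_effect_nonsyn) while the total
  # keeps exp(case_effect_intermediate)
  delta <- cfg$case_effect_nonsyn - cfg$case_effect_intermediate
  if (delta > 0 && nrow(som_int)) {
    case_rows <- which(som_int$sample_id %in% samples$sample_id[is_case])
    if (length(case_rows)) {
      cons <- annotation$consequences[cbind(som_int$pos[case_rows],
        match(som_int$alt[case_rows], MT_BASES))]
      for (i in case_rows[which(cons != "non-synonymous")]) {
        b <- som_int$ref[i]
        pool <- c(pools[[b]]$major, pools[[b]]$minor)
        ns_pool <- pool[annotation$consequences[cbind(pool, match(som_int$alt[i], MT_BASES))] == "non-synonymous"]
        if (!length(ns_pool)) next
        p_ns <- length(ns_pool) / length(pool)
        q_flip <- p_ns * (exp(delta) - 1) / (1 - p_ns)
        if (runif(1) < q_flip) som_int$pos[i] <- sample(ns_pool, 1)
      }
    }
  }
  som_int$hf <- 0.10 + 0.85 * rbeta(nrow(som_int), cfg$hf_intermediate_beta[1], cfg$hf_intermediate_beta[2])

  som_low <- draw_somatic_positions(sum(n_low), cfg, pools)
  som_low$sample_id <- rep(samples$sample_id, n_low)
  som_low$hf <- 0.05 + 0.05 * rbeta(nrow(som_low), cfg$hf_low_beta[1], cfg$hf_low_beta[2])

  som <- dplyr::bind_rows(som_int, som_low)
  som$origin <- "somatic"
  som <- attach_reads(
    som, samples$mean_depth[match(som$sample_id, samples$sample_id)], cfg
  )

  ## ---- artifacts ---------------------------------------------------------
  n_art <- rpois(n, cfg$artifact_rate)
  total_art <- sum(n_art)
  if (total_art > 0) {
    biased <- runif(total_art) < cfg$artifact_strand_bias_fraction
    mask_pool <- intersect(annotation$mask$positions, callable_positions(genome))
    art_pos <- integer(total_art)
    art_pos[!biased] <- sample(mask_pool, sum(!biased), replace = TRUE)
    art_pos[biased] <- sample(setdiff(usable, c(panel_pos, numt_pos)), sum(biased), replace = TRUE)
    art_ref <- genome$bases[art_pos]
    art_is_ts <- runif(total_art) < cfg$transition_fraction
    art_alt <- ifelse(art_is_ts, TRANSITION[art_ref],
      vapply(art_ref, function(r) sample(setdiff(MT_BASES, c(r, TRANSITION[r])), 1), character(1))
    )
    names(art_alt) <- NULL
    art <- tibble::tibble(
      sample_id = rep(samples$sample_id, n_art),
      pos = art_pos,
      ref = art_ref,
      alt = art_alt,
      hf = runif(total_art, cfg$artifact_hf_range[1], cfg$artifact_hf_range[2]),
      origin = "artifact"
    )
    depth_mu <- samples$mean_depth[match(art$sample_id, samples$sample_id)]
    art_b <- attach_reads(art[biased, ], depth_mu[biased], cfg, strand_biased = TRUE)
    art_m <- attach_reads(art[!biased, ], depth_mu[!biased], cfg)
    art <- dplyr::bind_rows(art_m, art_b)
  } else {
    art <- hom[0, ]
  }

  calls <- dplyr::bind_rows(hom, numt, som, art) |>
    dplyr::distinct(.data$sample_id, .data$pos, .data$alt, .keep_all = TRUE) |>
    dplyr::arrange(.data$sample_id, .data$pos, .data$alt) |>
    dplyr::select(
      "sample_id", "pos", "ref", "alt", "hf", "depth",
      "alt_fwd", "alt_rev", "origin"
    )

  cohort <- structure(
    list(
      calls = calls,
      samples = samples,
      panel_afs = NULL,
      scores = NULL,
      truth = list(
        numt_sites = tibble::tibble(
          pos = numt_pos, ref = numt_ref, alt = numt_alt, shared_hf = numt_hf0
        ),
        backbone_sites = backbone,
        panel_sites = tibble::tibble(pos = panel_pos, ref = panel_ref, alt = panel_alt),
        intercepts = c(intermediate = a_int, low = a_low),
        discordant_sites = NULL
      ),
      config = cfg
    ),
    class = "mt_cohort"
  )
  cohort$panel_afs <- make_panel_afs(cohort, cfg$discordant_fraction, cfg$panel_noise_sd)
  cohort$truth$discordant_sites <- attr(cohort$panel_afs, "discordant")
  cohort$scores <- make_score_tables(
    cohort, cfg$high_path_fraction, cfg$pathogenic_hf_skew,
    annotation = annotation
  )
  cohort
}

#' @export
print.mt_cohort <- function(x, ...) {
  cat(sprintf(
    "<mt_cohort> %d samples (%d %s / %d control), %d calls (%s)\n",
    nrow(x$samples), x$config$n_cases, x$config$case_group, x$config$n_controls,
    nrow(x$calls),
    paste(sprintf("%s %d", names(table(x$calls$origin)), table(x$calls$origin)),
      collapse = ", "
    )
  ))
  invisible(x)
}

#' Emulated reference-panel allele-frequency tables
#'
#' Builds two panel tables (emulating an mtDNA GenBank panel and a 1000
#' Genomes panel) whose allele frequencies track the cohort's homoplasmic
#' allele frequencies up to noise, except at a configured fraction of sites
#' where the panel frequency is displaced by more than 0.9 — the situation
#' the panel-concordance QC filter is designed to catch. Discordant sites
#' are recorded in the `"discordant"` attribute.
#'
#' @param cohort An `mt_cohort`.
#' @param discordant_fraction Fraction of polymorphic (homoplasmy-carrying)
#'   sites made discordant.
#' @param noise_sd SD of panel-vs-cohort frequency noise.
#' @return List of two tibbles (`genbank`, `kgenomes`) with columns
#'   `pos`, `ref`, `alt`, `af`.
#' @export
make_panel_afs <- function(cohort, discordant_fraction = NULL, noise_sd = NULL) {
  cfg <- cohort$config
  discordant_fraction <- discordant_fraction %||% cfg$discordant_fraction
  noise_sd <- noise_sd %||% cfg$panel_noise_sd
  n <- nrow(cohort$samples)
  afs <- cohort$calls |>
    dplyr::group_by(.data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(af = sum(.data$hf > 0.95) / n, .groups = "drop")
  poly <- which(afs$af > 0)
  eligible <- intersect(poly, which(afs$af < 0.095 | afs$af > 0.905))
  n_disc <- min(round(discordant_fraction * length(poly)), length(eligible))
  disc <- if (n_disc > 0) sample(eligible, n_disc) else integer(0)
  mk_panel <- function() {
    af_p <- pmin(pmax(afs$af + rnorm(nrow(afs), 0, noise_sd), 0), 1)
    af_p[disc] <- ifelse(
      afs$af[disc] > 0.905,
      runif(length(disc), 0, pmax(afs$af[disc] - 0.905, 0)),
      runif(length(disc), afs$af[disc] + 0.905, 1)
    )
    tibble::tibble(pos = afs$pos, ref = afs$ref, alt = afs$alt, af = af_p)
  }
  out <- list(genbank = mk_panel(), kgenomes = mk_panel())
  attr(out, "discordant") <- afs[disc, c("pos", "alt")]
  out
}

#' Emulated conservation and pathogenicity score tables
#'
#' Produces a per-site conservation score surrogate (PhastCons-like, in
#' \[0,1\], with D-loop sites drawn lower on average than coding sites) and a
#' per-variant pathogenicity surrogate (MutPred-like, in \[0,1\]) for
#' non-synonymous variants, with a configured fraction scoring >= 0.7
#' ("high pathogenicity"). High scores are preferentially assigned to
#' variants observed at lower heteroplasmic fractions, emulating purifying
#' selection against damaging alleles.
#'
#' @param cohort An `mt_cohort`.
#' @param high_path_fraction Fraction of non-synonymous variants scoring
#'   >= 0.7.
#' @param pathogenic_hf_skew Weighting exponent coupling high scores to low
#'   HF (0 = uncoupled).
#' @param annotation An [mt_annotation()].
#' @return List with tibbles `phastcons` (`pos`, `score`) and `mutpred`
#'   (`pos`, `ref`, `alt`, `score`, `high_path`).
#' @export
make_score_tables <- function(cohort, high_path_fraction = NULL,
                              pathogenic_hf_skew = NULL,
                              annotation = default_annotation()) {
  cfg <- cohort$config
  high_path_fraction <- high_path_fraction %||% cfg$high_path_fraction
  pathogenic_hf_skew <- pathogenic_hf_skew %||% cfg$pathogenic_hf_skew
  dloop <- annotation$region_sets[["MT-DLOOP"]]
  score <- rbeta(MT_LENGTH, 3, 1.5)
  score[dloop] <- rbeta(length(dloop), 1.2, 3)
  phastcons <- tibble::tibble(pos = seq_len(MT_LENGTH), score = score)

  variants <- cohort$calls |>
    dplyr::group_by(.data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(mean_hf = mean(.data$hf), .groups = "drop")
  cat_idx <- cbind(variants$pos, match(variants$alt, MT_BASES))
  variants$category <- annotation$consequences[cat_idx]
  ns <- variants[!is.na(variants$category) & variants$category == "non-synonymous", ]
  n_high <- round(high_path_fraction * nrow(ns))
  mutpred <- NULL
  if (nrow(ns)) {
    w <- (1 - ns$mean_hf)^pathogenic_hf_skew + 1e-8
    high <- rep(FALSE, nrow(ns))
    if (n_high > 0) high[sample.int(nrow(ns), n_high, prob = w)] <- TRUE
    mutpred <- tibble::tibble(
      pos = ns$pos, ref = ns$ref, alt = ns$alt,
      score = ifelse(high, runif(nrow(ns), 0.7, 1), runif(nrow(ns), 0, 0.699)),
      high_path = high
    )
  } else {
    mutpred <- tibble::tibble(
      pos = integer(0), ref = character(0), alt = character(0),
      score = numeric(0), high_path = logical(0)
    )
  }
  list(phastcons = phastcons, mutpred = mutpred)
}

#' Packaged default annotation (cached)
#'
#' The [mt_annotation()] built on the packaged synthetic reference, computed
#' once per session.
#'
#' @return An `mt_annotation`.
#' @export
default_annotation <- function() {
  if (is.null(.mt_cache$annotation)) {
    .mt_cache$annotation <- mt_annotation()
  }
  .mt_cache$annotation
}
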