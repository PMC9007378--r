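# Negative binomial burden regression and the accompanying comparison
# statistics (Spearman concordance, Kolmogorov-Smirnov HF comparisons,
# Mann-Whitney / two-way ANOVA score tests) with Bonferroni handling.

#' Fit a negative binomial (NB2) burden model
#'
#' Fits counts ~ predictors with a log link under the NB2 parameterisation
#' (variance = mu + mu^2/theta). Coefficients are estimated by iteratively
#' reweighted least squares alternating with one-dimensional maximum
#' likelihood for the size parameter theta (the `MASS::glm.nb` algorithm);
#' Wald z p-values are reported per coefficient. When the estimated
#' dispersion vanishes (theta diverging, variance collapsing to the mean)
#' the fit falls back to a Poisson GLM and is flagged. Rank-deficient
#' designs are rejected.
#'
#' @param data Data frame holding the response and predictors.
#' @param formula Model formula, e.g. `n ~ group + age + sex`.
#' @param theta_poisson_limit Theta above which the NB fit is declared
#'   Poisson-limited (default 1e5).
#' @return Object of class `mt_nb_fit` with `tidy()`/`glance()` methods.
#' @export
#' @examples
#' d <- data.frame(n = rpois(100, 2), x = rnorm(100))
#' fit_nb_glm(d, n ~ x)
fit_nb_glm <- function(data, formula, theta_poisson_limit = 1e5) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- model.matrix(formula, mf)
  if (nrow(X) <= ncol(X)) {
    abort("more predictors than observations")
  }
  if (qr(X)$rank < ncol(X)) {
    abort("rank-deficient design (collinear or separated predictors)")
  }
  if (any(y < 0) || any(y != round(y))) abort("response must be non-negative counts")

  fallback <- FALSE
  nb <- withCallingHandlers(
    tryCatch(
      MASS::glm.nb(formula, data = data),
      error = function(e) NULL
    ),
    warning = function(w) invokeRestart("muffleWarning")
  )
  theta <- if (!is.null(nb)) nb$theta else Inf
  if (is.null(nb) || !is.finite(theta) || theta > theta_poisson_limit) {
    fallback <- TRUE
    model <- glm(formula, data = data, family = poisson())
    theta <- Inf
  } else {
    model <- nb
  }
  converged <- isTRUE(model$converged)
  if (!converged && !fallback) {
    # retry in the Poisson limit rather than returning silent garbage
    fallback <- TRUE
    model <- glm(formula, data = data, family = poisson())
    theta <- Inf
    converged <- isTRUE(model$converged)
  }
  structure(
    list(
      model = model,
      family = if (fallback) "poisson" else "negative binomial (NB2)",
      fallback = fallback,
      converged = converged,
      theta = theta,
      n_obs = length(y),
      formula = formula
    ),
    class = "mt_nb_fit"
  )
}

#' @export
print.mt_nb_fit <- function(x, ...) {
  cat(sprintf(
    "<mt_nb_fit> %s, n = %d, theta = %s%s\n",
    x$family, x$n_obs,
    if (is.finite(x$theta)) sprintf("%.3g", x$theta) else "Inf (Poisson limit)",
    if (!x$converged) " [NOT CONVERGED]" else ""
  ))
  print(tidy(x))
  invisible(x)
}

#' Tidy a negative binomial burden fit
#'
#' @param x An `mt_nb_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @exportS3Method generics::tidy
tidy.mt_nb_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = unname(s[, 1]),
    std.error = unname(s[, 2]),
    statistic = unname(s[, 3]),
    p.value = unname(s[, 4])
  )
}

#' Model-level summary of a burden fit
#'
#' @param x An `mt_nb_fit`.
#' @param ... Unused.
#' @return One-row tibble with `family`, `theta`, `converged`, `fallback`,
#'   `nobs`, `AIC`, `deviance`.
#' @exportS3Method generics::glance
glance.mt_nb_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    theta = x$theta,
    converged = x$converged,
    fallback = x$fallback,
    nobs = x$n_obs,
    AIC = stats::AIC(x$model),
    deviance = stats::deviance(x$model)
  )
}

#' Re-exported generics
#'
#' See [generics::tidy()] and [generics::glance()].
#' @importFrom generics tidy
#' @export tidy
#' @name tidy
#' @rdname reexports
NULL

#' @importFrom generics glance
#' @export glance
#' @name glance
#' @rdname reexports
NULL

# assemble one regression data set: per-sample counts of the requested
# class (optionally one functional category) joined to covariates, for a
# disease-vs-control contrast with treatment coding and documented
# reference levels (control, female, European)
burden_design <- function(burden, samples, het_class, category = NULL,
                          disease = NULL, covariates = c("age", "sex", "mean_depth", "mt_ancestry")) {
  b <- burden[burden$het_class == het_class, ]
  if (!is.null(category)) b <- b[b$category %in% category, ]
  counts <- b |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  d <- dplyr::inner_join(counts, samples, by = "sample_id")
  if (!is.null(disease)) {
    d <- d[d$group %in% c(disease, "control"), ]
    d$group <- stats::relevel(factor(d$group, levels = c("control", disease)), "control")
  }
  if ("sex" %in% covariates) d$sex <- factor(d$sex, levels = c("F", "M"))
  if ("mt_ancestry" %in% covariates) {
    d$mt_ancestry <- stats::relevel(
      factor(d$mt_ancestry, levels = c("European", "African", "Asian")), "European"
    )
    if (length(unique(d$mt_ancestry)) < 2) covariates <- setdiff(covariates, "mt_ancestry")
  }
  d <- d[complete.cases(d[, c("n", if (!is.null(disease)) "group", covariates)]), ]
  list(data = d, covariates = covariates)
}

#' Disease-association burden model
#'
#' Negative binomial regression of a per-individual burden count (one
#' heteroplasmy class, optionally restricted to one functional category) on
#' a disease-vs-control indicator plus covariates (defaults: age, sex, mean
#' read depth, mitochondrial ancestry; references: control, female,
#' European). Complete-case analysis per model.
#'
#' @param burden An `mt_burden` table from [individual_burden()].
#' @param samples Sample tibble.
#' @param het_class `"intermediate"`, `"low"` or `"homoplasmy"`.
#' @param disease Case group to contrast against controls, or `NULL` for no
#'   group term (e.g. pure age models).
#' @param category Optional functional category subset (e.g.
#'   `"non-synonymous"`).
#' @param covariates Covariate names found in `samples`.
#' @return An `mt_nb_fit`.
#' @export
burden_model <- function(burden, samples, het_class = "intermediate",
                         disease = "HTN", category = NULL,
                         covariates = c("age", "sex", "mean_depth", "mt_ancestry")) {
  des <- burden_design(burden, samples, het_class, category, disease, covariates)
  rhs <- c(if (!is.null(disease)) "group", des$covariates)
  f <- stats::reformulate(rhs, response = "n")
  fit <- fit_nb_glm(des$data, f)
  fit$het_class <- het_class
  fit$disease <- disease
  fit$category <- category
  fit
}

#' Pairwise disease-vs-control burden association suite
#'
#' Runs one negative binomial model per disease x heteroplasmy-class
#' combination (or per functional category when `categories` is given) and
#' attaches the Bonferroni threshold for the family of tests.
#'
#' @param burden An `mt_burden` table.
#' @param samples Sample tibble.
#' @param diseases Case groups present in `samples`.
#' @param het_classes Heteroplasmy classes to model.
#' @param categories Optional functional categories (runs disease x class x
#'   category models).
#' @param covariates Covariates for every model.
#' @param alpha Family-wise alpha for the Bonferroni threshold.
#' @return Tibble with one row per model (case-control term: `estimate`,
#'   `std.error`, `p.value`, fit flags) and attributes `m`, `threshold`,
#'   `threshold_echo` (one significant figure).
#' @export
burden_association_suite <- function(burden, samples,
                                     diseases = c("HTN", "IHD", "IS"),
                                     het_classes = c("intermediate", "low"),
                                     categories = NULL,
                                     covariates = c("age", "sex", "mean_depth", "mt_ancestry"),
                                     alpha = 0.05) {
  diseases <- intersect(diseases, unique(samples$group))
  grid <- tidyr::expand_grid(
    disease = diseases, het_class = het_classes,
    category = categories %||% list(NULL)
  )
  rows <- purrr::pmap_dfr(grid, function(disease, het_class, category) {
    fit <- burden_model(burden, samples, het_class, disease,
      category = if (is.null(category) || is.na(category)) NULL else category,
      covariates = covariates
    )
    td <- tidy(fit)
    case_row <- td[grepl("^group", td$term), ]
    tibble::tibble(
      disease = disease,
      het_class = het_class,
      category = if (is.null(category) || is.na(category)) NA_character_ else category,
      estimate = case_row$estimate,
      std.error = case_row$std.error,
      p.value = case_row$p.value,
      family = fit$family,
      converged = fit$converged,
      n_obs = fit$n_obs
    )
  })
  m <- nrow(rows)
  thr <- bonferroni_threshold(alpha, m)
  attr(rows, "m") <- m
  attr(rows, "alpha") <- alpha
  attr(rows, "threshold") <- thr
  attr(rows, "threshold_echo") <- signif(thr, 1)
  rows
}

#' Bonferroni-adjusted significance threshold
#'
#' `alpha / m` for a family of `m` tests. Reports echo the threshold to one
#' significant figure (e.g. 0.05/6 echoes as 0.008), full precision is kept
#' for computation.
#'
#' @param alpha Family-wise alpha (default 0.05).
#' @param m Number of tests (>= 1).
#' @return The threshold (full precision).
#' @export
#' @examples
#' bonferroni_threshold(0.05, 6)
#' signif(bonferroni_threshold(0.05, 6), 1)
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) abort("`m` must be >= 1")
  alpha / m
}

#' Spearman concordance of cohort and panel allele frequencies
#'
#' Rank correlation (average ranks on ties, two-sided p) between cohort
#' variant frequencies and a reference panel's frequencies over shared
#' sites.
#'
#' @param cohort_afs,panel_afs Tibbles with `pos`, `alt`, `af`.
#' @return One-row tibble with `rho`, `p.value`, `n_sites`.
#' @export
spearman_frequency_concordance <- function(cohort_afs, panel_afs) {
  shared <- dplyr::inner_join(
    cohort_afs, panel_afs,
    by = c("pos", "alt"), suffix = c("_cohort", "_panel")
  )
  if (nrow(shared) < 3) abort("need at least 3 shared sites")
  if (var(shared$af_cohort) == 0 || var(shared$af_panel) == 0) {
    abort("allele frequencies are constant; rank correlation undefined")
  }
  ct <- suppressWarnings(
    cor.test(shared$af_cohort, shared$af_panel, method = "spearman", exact = FALSE)
  )
  tibble::tibble(
    rho = unname(ct$estimate), p.value = ct$p.value, n_sites = nrow(shared)
  )
}

#' Kolmogorov-Smirnov comparison of HF distributions against the D-loop
#'
#' Two-sample, two-sided KS test (asymptotic p) of a heteroplasmic-fraction
#' sample against the D-loop HF distribution, which serves as the neutral
#' reference.
#'
#' @param class_hfs HF values of the class of interest.
#' @param dloop_hfs HF values of D-loop variants (the reference).
#' @return One-row tibble with `statistic` (D), `p.value`, `n_class`,
#'   `n_ref`.
#' @export
ks_hf_compare <- function(class_hfs, dloop_hfs) {
  if (!length(class_hfs) || !length(dloop_hfs)) {
    abort("both HF samples must be non-empty")
  }
  kt <- suppressWarnings(ks.test(class_hfs, dloop_hfs, exact = FALSE))
  tibble::tibble(
    statistic = unname(kt$statistic), p.value = kt$p.value,
    n_class = length(class_hfs), n_ref = length(dloop_hfs)
  )
}

#' Conservation and pathogenicity score comparisons
#'
#' Mann-Whitney U tests (two-sided, normal approximation with tie
#' correction) of a score between each disease group and controls, and a
#' two-way fixed-effects ANOVA of the score on group and heteroplasmy
#' class.
#'
#' @param data Data frame with columns `score`, `group` and (for the ANOVA)
#'   `het_class`.
#' @param control Label of the control group.
#' @return List with `mann_whitney` (tibble: one row per disease) and
#'   `anova` (tibble of the two-way ANOVA terms).
#' @export
score_comparisons <- function(data, control = "control") {
  groups <- unique(data$group)
  if (length(groups) < 2) abort("need at least two groups")
  if (!control %in% groups) abort(sprintf("no `%s` group present", control))
  if (var(data$score) == 0) {
    abort("scores are constant; comparisons are degenerate")
  }
  diseases <- setdiff(groups, control)
  mw <- purrr::map_dfr(diseases, function(dz) {
    x <- data$score[data$group == dz]
    y <- data$score[data$group == control]
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    tibble::tibble(
      disease = dz, statistic = unname(wt$statistic), p.value = wt$p.value,
      n_disease = length(x), n_control = length(y)
    )
  })
  anova_tbl <- NULL
  if ("het_class" %in% names(data)) {
    fit <- aov(score ~ group + het_class, data = data)
    s <- summary(fit)[[1]]
    anova_tbl <- tibble::tibble(
      term = trimws(rownames(s)),
      df = s[, "Df"],
      statistic = s[, "F value"],
      p.value = s[, "Pr(>F)"]
    )
  }
  list(mann_whitney = mw, anova = anova_tbl)
}
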