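# Shared fixtures: one medium synthetic cohort reused across test files
# (generation is deterministic, so caching is purely a speed matter).

.fixtures <- new.env(parent = emptyenv())

fixture_annotation <- function() {
  if (is.null(.fixtures$ann)) .fixtures$ann <- default_annotation()
  .fixtures$ann
}

# default-condition cohort at n = 800 for structural checks
fixture_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- generate_cohort(
      simulation_config(n_cases = 400, n_controls = 400),
      seed = 20240101
    )
  }
  .fixtures$cohort
}

# hand-built call tibble for boundary tests
make_call <- function(sample_id = "S1", pos = 5000L, ref = NULL, alt = NULL,
                      hf = 0.2, depth = 1000L, alt_fwd = NULL, alt_rev = NULL,
                      genome = fixture_annotation()$genome) {
  ref <- ref %||% genome$bases[pos]
  alt <- alt %||% setdiff(c("A", "C", "G", "T"), ref)[1]
  alt_total <- max(round(hf * depth), 2L)
  tibble::tibble(
    sample_id = sample_id, pos = as.integer(pos), ref = ref, alt = alt,
    hf = hf, depth = as.integer(depth),
    alt_fwd = as.integer(alt_fwd %||% (alt_total %/% 2L)),
    alt_rev = as.integer(alt_rev %||% (alt_total - alt_total %/% 2L))
  )
}

make_samples <- function(n, group = "control", covered = 0.99) {
  tibble::tibble(
    sample_id = sprintf("S%d", seq_len(n)),
    group = rep_len(group, n),
    age = seq(40, 80, length.out = n),
    sex = rep_len(c("F", "M"), n),
    mean_depth = 1000,
    mt_ancestry = "European",
    covered_fraction = rep_len(covered, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent full-likelihood NB2 fit by direct optimisation (oracle for
# the IRLS-based model fit)
oracle_nb2 <- function(y, X) {
  nll <- function(par) {
    beta <- par[seq_len(ncol(X))]
    theta <- exp(par[length(par)])
    mu <- drop(exp(X %*% beta))
    -sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
      theta * log(theta) + y * log(mu) - (y + theta) * log(mu + theta))
  }
  start <- c(unname(coef(glm.fit(X, y, family = poisson()))), 0)
  opt <- optim(start, nll,
    method = "L-BFGS-B",
    lower = c(rep(-20, ncol(X)), -10), upper = c(rep(20, ncol(X)), 10),
    control = list(maxit = 1000, factr = 1e4)
  )
  list(beta = opt$par[seq_len(ncol(X))], theta = exp(opt$par[length(opt$par)]))
}
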