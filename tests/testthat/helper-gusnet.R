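# Shared fixtures, built in code at test time.

quick_config <- function(seed, iterations = 4000L, burn_in = 800L,
                         chains = 2L) {
  mcmc_config(chains = chains, iterations = iterations, burn_in = burn_in,
              seed = seed)
}

# Two-device complete-pairing cohort: every respondent tests the reference
# and one comparator; the paired-difference mean is the conjugate oracle
# for the FE device effect.
two_device_records <- function(n = 30, effect = 4, tau = 5, seed = 1,
                               devices = c("Breezhaler", "Genuair")) {
  withr::with_seed(seed, {
    mu <- stats::rnorm(n, 25, 5)
    y1 <- mu + stats::rnorm(n, 0, tau)
    y2 <- mu + effect + stats::rnorm(n, 0, tau)
  })
  tibble::tibble(
    respondent_id = rep(sprintf("P%03d", seq_len(n)), each = 2),
    stratum = "experienced",
    group = 3,
    device = rep(devices, n),
    gus_total = pmin(50, pmax(0, round(as.vector(rbind(y1, y2)))))
  )
}

# A synthetic gus_fit skeleton carrying hand-built chains, for exercising
# diagnostics without running the sampler.
fake_fit <- function(chains_d, model = "FE") {
  n <- length(chains_d[[1]])
  structure(
    list(
      model = model,
      stratum = "experienced",
      devices = c("Breezhaler", "Genuair"),
      reference = "Breezhaler",
      chains = lapply(chains_d, function(x) {
        list(d = cbind(Breezhaler = rep(0, n), Genuair = x),
             mu = cbind(P001 = rep(25, n)),
             tau = rep(5, n), sigma = rep(0, n),
             deviance = rep(0, n), n_kept = n)
      }),
      data = list(respondents = "P001")
    ),
    class = "gus_fit"
  )
}

# Independent textbook split-Rhat, written separately from the package
# implementation so it can serve as an oracle.
oracle_split_rhat <- function(chains) {
  seqs <- unlist(lapply(chains, function(x) {
    h <- length(x) %/% 2L
    list(x[1:h], x[(length(x) - h + 1L):length(x)])
  }), recursive = FALSE)
  n <- length(seqs[[1]])
  m <- length(seqs)
  mns <- sapply(seqs, mean)
  W <- mean(sapply(seqs, var))
  B <- n / (m - 1) * sum((mns - mean(mns))^2)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Scheme with coarser box-5 granularity (two-point yes/no items), which
# makes some totals (e.g. 49) unattainable: used for the
# nearest-achievable warning path.
coarse_scheme <- function() {
  sch <- default_scheme()
  sch$boxes[[5]]$items <- sch$boxes[[5]]$items[1:5]
  for (i in 1:5) sch$boxes[[5]]$items[[i]]$options <- c(yes = 2, no = 0)
  validate_scheme(sch)
}
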