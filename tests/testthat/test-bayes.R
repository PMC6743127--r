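test_that("no contrast signal concentrates every effect at zero", {
  recs <- tibble::tibble(
    respondent_id = rep(sprintf("P%02d", 1:20), each = 2),
    stratum = "experienced", group = 3,
    device = rep(c("Breezhaler", "Genuair"), 20),
    gus_total = 30
  )
  fit <- suppressWarnings(
    fit_gus_model(recs, gus_model_spec("FE"), quick_config(seed = 2))
  )
  est <- tidy(fit)
  expect_lt(abs(est$estimate), 0.3)
  expect_true(all(abs(summarize_effects(fit)$mean - 30) < 0.3))
})

test_that("the FE posterior matches the paired-difference conjugate oracle", {
  recs <- two_device_records(n = 40, effect = 4, tau = 5, seed = 12)
  fit <- fit_gus_model(recs, gus_model_spec("FE"),
                       quick_config(seed = 12, iterations = 8000,
                                    burn_in = 1500))
  d <- gusnet:::combined_draws(fit, "d")[, "Genuair"]
  w <- tapply(recs$gus_total, recs$respondent_id,
              function(y) y[2] - y[1])  # Genuair - Breezhaler per pair
  ess <- fit$diagnostics$ess[fit$diagnostics$parameter == "d[Genuair]"]
  mcse <- stats::sd(d) / sqrt(ess)
  expect_lt(abs(mean(d) - mean(w)), 3 * mcse + 0.05)
})

test_that("fits are reproducible for a fixed seed and stable across seeds", {
  recs <- two_device_records(n = 25, effect = 3, tau = 4, seed = 5)
  f1 <- fit_gus_model(recs, gus_model_spec("FE"), quick_config(seed = 7))
  f2 <- fit_gus_model(recs, gus_model_spec("FE"), quick_config(seed = 7))
  expect_identical(f1$chains[[1]]$d, f2$chains[[1]]$d)
  expect_identical(f1$chains[[2]]$tau, f2$chains[[2]]$tau)

  f3 <- fit_gus_model(recs, gus_model_spec("FE"), quick_config(seed = 8))
  expect_false(identical(f1$chains[[1]]$d, f3$chains[[1]]$d))
  expect_lt(abs(tidy(f1)$estimate - tidy(f3)$estimate), 0.3)
})

test_that("fit preconditions are enforced", {
  recs <- two_device_records(n = 10, seed = 3)
  mixed <- recs
  mixed$stratum[1:2] <- "naive"
  expect_error(fit_gus_model(mixed, gus_model_spec("FE"),
                             quick_config(seed = 1)),
               class = "gusnet_precondition_error")

  disjoint <- tibble::tibble(
    respondent_id = rep(c("R1", "R2"), each = 2),
    stratum = "experienced", group = c(1, 1, 2, 2),
    device = c("Breezhaler", "Spiromax", "Diskus", "Turbohaler"),
    gus_total = 25
  )
  expect_error(fit_gus_model(disjoint, gus_model_spec("FE"),
                             quick_config(seed = 1)),
               class = "gusnet_precondition_error")

  # reference missing from the stratum
  no_ref <- tibble::tibble(
    respondent_id = rep("R1", 2), stratum = "experienced", group = 2,
    device = c("Diskus", "Turbohaler"), gus_total = c(20, 30)
  )
  expect_error(fit_gus_model(no_ref, gus_model_spec("FE"),
                             quick_config(seed = 1)),
               class = "gusnet_precondition_error")

  # single-device respondents are dropped with a warning, not modelled
  plus_single <- dplyr::bind_rows(
    recs,
    tibble::tibble(respondent_id = "LONER", stratum = "experienced",
                   group = 3, device = "Breezhaler", gus_total = 40)
  )
  expect_warning(
    fit <- fit_gus_model(plus_single, gus_model_spec("FE"),
                         quick_config(seed = 4)),
    class = "gusnet_single_device"
  )
  expect_false("LONER" %in% fit$data$respondents)
})

test_that("device summaries equal a direct recomputation from the draws", {
  recs <- two_device_records(n = 20, effect = 5, seed = 9)
  fit <- fit_gus_model(recs, gus_model_spec("FE"), quick_config(seed = 9))
  s <- summarize_effects(fit)

  # brute-force oracle straight from the stored matrices
  d <- do.call(rbind, lapply(fit$chains, `[[`, "d"))
  A <- rowMeans(do.call(rbind, lapply(fit$chains, `[[`, "mu")))
  for (dev in fit$devices) {
    G <- A + d[, dev]
    row <- s[s$device == dev, ]
    expect_equal(row$mean, mean(G))
    expect_equal(row$cri_low,
                 unname(stats::quantile(G, 0.025, names = FALSE)))
    expect_equal(row$cri_high,
                 unname(stats::quantile(G, 0.975, names = FALSE)))
  }

  # the reference summary is exactly the summary of the anchor
  ref <- s[s$device == fit$reference, ]
  expect_equal(ref$mean, mean(A))
})

test_that("rank probabilities equal brute-force counting on a toy matrix", {
  set.seed(404)
  G <- matrix(rnorm(100 * 4, mean = rep(c(30, 28, 28, 25), each = 100)),
              ncol = 4)
  colnames(G) <- c("Breezhaler", "Diskus", "Ellipta", "Genuair")
  rp <- rank_probabilities(G, min_draws = 50)

  brute <- matrix(0, 4, 4)
  for (i in 1:100) {
    r <- order(-G[i, ])
    for (pos in 1:4) brute[r[pos], pos] <- brute[r[pos], pos] + 1
  }
  expect_equal(unclass(rp), brute / 100, ignore_attr = TRUE)
  expect_equal(unname(rowSums(rp)), rep(1, 4))
  expect_equal(unname(colSums(rp)), rep(1, 4))

  # a strictly dominant device always ranks first
  G2 <- G; G2[, "Ellipta"] <- 99
  rp2 <- rank_probabilities(G2, min_draws = 50)
  expect_equal(rp2["Ellipta", "1"], 1)

  # mirror-image draws split rank 1 evenly
  set.seed(17)
  x <- rnorm(4000)
  G3 <- cbind(Breezhaler = x, Diskus = -x)
  rp3 <- rank_probabilities(G3)
  expect_lt(abs(rp3["Breezhaler", "1"] - 0.5), 0.05)

  # exact ties break by canonical (column) order
  G4 <- matrix(5, nrow = 1200, ncol = 2,
               dimnames = list(NULL, c("Breezhaler", "Diskus")))
  rp4 <- rank_probabilities(G4)
  expect_equal(rp4["Breezhaler", "1"], 1)
  expect_equal(rp4["Diskus", "2"], 1)

  expect_error(rank_probabilities(G[1:30, ]),
               class = "gusnet_precondition_error")
})

test_that("rank matrix is invariant to input record order", {
  recs <- two_device_records(n = 15, effect = 2, seed = 22)
  f1 <- fit_gus_model(recs, gus_model_spec("FE"), quick_config(seed = 2))
  shuffled <- withr::with_seed(1, recs[sample.int(nrow(recs)), ])
  f2 <- fit_gus_model(shuffled, gus_model_spec("FE"), quick_config(seed = 2))
  expect_equal(unclass(rank_probabilities(f1)),
               unclass(rank_probabilities(f2)))
})

test_that("DIC decomposition matches its brute-force deviance oracle", {
  recs <- two_device_records(n = 12, effect = 3, seed = 30)
  fit <- fit_gus_model(recs, gus_model_spec("FE"),
                       quick_config(seed = 30, iterations = 2000,
                                    burn_in = 400))
  dic <- compute_dic(fit)
  expect_equal(dic$DIC, dic$Dbar + dic$pD)

  # recompute the per-draw deviance in R from the stored parameter draws
  dat <- fit$data
  y <- dat$y
  base_of_rec <- dat$base_idx[dat$resp_idx + 1L]
  dev_oracle <- function(mu_row, d_row, tau) {
    off <- d_row[dat$dev_idx + 1L] - d_row[base_of_rec + 1L]
    r <- y - mu_row[dat$resp_idx + 1L] - off
    length(y) * log(2 * pi * tau^2) + sum(r^2) / tau^2
  }
  for (ch in fit$chains) {
    manual <- vapply(seq_len(nrow(ch$d)), function(i) {
      dev_oracle(ch$mu[i, ], ch$d[i, ], ch$tau[i])
    }, 0)
    expect_equal(manual, as.vector(ch$deviance), tolerance = 1e-10)
  }

  # RE: the stored deviance is marginal over the contrasts
  fre <- fit_gus_model(recs, gus_model_spec("RE"),
                       quick_config(seed = 30, iterations = 2000,
                                    burn_in = 400))
  is_base <- dat$dev_idx == base_of_rec
  for (ch in fre$chains) {
    manual <- vapply(seq_len(nrow(ch$d)), function(i) {
      off <- ch$d[i, ][dat$dev_idx + 1L] - ch$d[i, ][base_of_rec + 1L]
      r <- y - ch$mu[i, ][dat$resp_idx + 1L] - ifelse(is_base, 0, off)
      v <- ifelse(is_base, ch$tau[i]^2, ch$tau[i]^2 + ch$sigma[i]^2)
      sum(log(2 * pi * v) + r^2 / v)
    }, 0)
    expect_equal(manual, as.vector(ch$deviance), tolerance = 1e-10)
  }

  expect_error(compute_dic(fit, records = recs[1:3, ]),
               class = "gusnet_consistency_error")
})

test_that("a single-draw chain has zero effective parameters", {
  recs <- two_device_records(n = 10, seed = 44)
  expect_warning(
    fit <- fit_gus_model(recs, gus_model_spec("FE"),
                         mcmc_config(chains = 1, iterations = 1,
                                     burn_in = 0, seed = 5)),
    class = "gusnet_single_chain"
  )
  dic <- compute_dic(fit)
  expect_equal(dic$pD, 0, tolerance = 1e-8)
  expect_equal(dic$DIC, dic$Dbar, tolerance = 1e-8)
})

test_that("the DIC selection rule prefers the simpler model within 3 points", {
  dic_row <- function(model, val) {
    tibble::tibble(model = model, Dbar = NA_real_, pD = NA_real_, DIC = val)
  }
  # the two DIC pairs reported for the real cohorts both keep FE
  expect_equal(select_model(dic_row("FE", 53.512), dic_row("RE", 53.921)),
               "FE")
  expect_equal(select_model(dic_row("FE", 58.652), dic_row("RE", 58.702)),
               "FE")
  # RE needs a full 3-point advantage
  expect_equal(select_model(dic_row("FE", 60.0), dic_row("RE", 56.9)), "RE")
  expect_equal(select_model(dic_row("FE", 60.0), dic_row("RE", 57.1)), "FE")
  expect_equal(select_model(dic_row("FE", 60.0), dic_row("RE", 57.0)), "RE")
})

test_that("split-Rhat matches an independent implementation", {
  withr::with_seed(55, {
    good <- list(rnorm(2000), rnorm(2000))
    bad <- list(rnorm(2000, 0), rnorm(2000, 10))
  })
  fg <- fake_fit(good)
  diag_good <- diagnose(fg)
  rhat_d <- diag_good$rhat[diag_good$parameter == "d[Genuair]"]
  expect_equal(rhat_d, oracle_split_rhat(good), tolerance = 1e-12)
  expect_lt(rhat_d, 1.05)

  diag_bad <- diagnose(fake_fit(bad))
  expect_gt(diag_bad$rhat[diag_bad$parameter == "d[Genuair]"], 1.5)
  expect_false(attr(diag_bad, "converged"))

  single <- fake_fit(good[1])
  expect_error(diagnose(single), class = "gusnet_precondition_error")
})

test_that("heterogeneity is detected when present and shrinks when absent", {
  cfg <- quick_config(seed = 19, iterations = 6000, burn_in = 1200)
  co0 <- generate_cohort(paper_design(),
                         simulation_params(seed = 61, heterogeneity_sd = 0))
  co6 <- generate_cohort(paper_design(),
                         simulation_params(seed = 61, heterogeneity_sd = 6))
  r0 <- dplyr::filter(co0$records, .data$stratum == "experienced")
  r6 <- dplyr::filter(co6$records, .data$stratum == "experienced")
  f0 <- suppressWarnings(fit_gus_model(r0, gus_model_spec("RE"), cfg))
  f6 <- suppressWarnings(fit_gus_model(r6, gus_model_spec("RE"), cfg))
  s0 <- stats::median(gusnet:::combined_draws(f0, "sigma"))
  s6 <- stats::median(gusnet:::combined_draws(f6, "sigma"))
  expect_lt(s0, s6)
  expect_lt(s0, 3)   # near-collapse on homogeneous data
  expect_gt(s6, 3)   # clear heterogeneity signal
})
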