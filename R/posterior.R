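#' Deviance information criterion of a fitted model
#'
#' `Dbar` is the posterior mean of the deviance (-2 log-likelihood),
#' `Dhat` the deviance at the posterior means of the parameters, and
#' `pD = Dbar - Dhat` the effective number of parameters;
#' `DIC = Dbar + pD`. For the RE model the deviance is marginal over the
#' latent respondent-level contrasts (closed form: baseline arms have
#' variance `tau^2`, contrast arms `tau^2 + sigma^2`), so the FE and RE
#' deviances describe the same data distribution and their DICs are
#' directly comparable; a conditional (contrast-level) deviance would let
#' the random effects chase residual noise and systematically favour RE.
#'
#' @param fit A `gus_fit`.
#' @param records Optional records to check dimensional consistency
#'   against the fit (defaults to the records stored in the fit).
#' @return A one-row tibble of class `gus_dic` with columns `model`,
#'   `Dbar`, `pD`, `DIC`.
#' @export
compute_dic <- function(fit, records = NULL) {
  stopifnot(inherits(fit, "gus_fit"))
  if (!is.null(records) && nrow(records) != length(fit$data$y)) {
    stop_gusnet(
      sprintf("records (%d rows) do not match the fitted data (%d records)",
              nrow(records), length(fit$data$y)),
      class = "gusnet_consistency_error"
    )
  }
  y <- fit$data$y
  n <- length(y)
  mu_bar <- colMeans(combined_draws(fit, "mu"))
  tau_bar <- mean(combined_draws(fit, "tau"))
  d_bar <- colMeans(combined_draws(fit, "d"))
  off <- d_bar[fit$data$dev_idx + 1L] -
    d_bar[fit$data$base_idx[fit$data$resp_idx + 1L] + 1L]
  resid <- y - mu_bar[fit$data$resp_idx + 1L] - off
  if (fit$model == "FE") {
    Dhat <- n * log(2 * pi * tau_bar^2) + sum(resid^2) / tau_bar^2
  } else {
    sigma_bar <- mean(combined_draws(fit, "sigma"))
    is_base <- fit$data$dev_idx ==
      fit$data$base_idx[fit$data$resp_idx + 1L]
    v <- ifelse(is_base, tau_bar^2, tau_bar^2 + sigma_bar^2)
    Dhat <- sum(log(2 * pi * v) + resid^2 / v)
  }
  Dbar <- mean(combined_draws(fit, "deviance"))
  pD <- Dbar - Dhat
  structure(
    tibble::tibble(model = fit$model, Dbar = Dbar, pD = pD, DIC = Dbar + pD),
    class = c("gus_dic", class(tibble::tibble()))
  )
}

#' Select between the fixed- and random-effect model by DIC
#'
#' The simpler fixed-effect model is retained unless the random-effect
#' model improves the DIC by at least three points — small differences and
#' ties go to the simpler model.
#'
#' @param dic_fe,dic_re `gus_dic` rows for the FE and RE fits of the same
#'   records.
#' @param margin Required DIC advantage for the RE model (points).
#' @return `"FE"` or `"RE"`.
#' @export
#' @examples
#' fe <- tibble::tibble(model = "FE", Dbar = NA, pD = NA, DIC = 53.512)
#' re <- tibble::tibble(model = "RE", Dbar = NA, pD = NA, DIC = 53.921)
#' select_model(fe, re)
select_model <- function(dic_fe, dic_re, margin = 3) {
  stopifnot(is.data.frame(dic_fe), is.data.frame(dic_re))
  if (dic_re$DIC <= dic_fe$DIC - margin) "RE" else "FE"
}

#' Posterior device summaries on the absolute GUS scale
#'
#' Device effects are relative to the reference; to present them on the
#' absolute 0-50 GUS scale each iteration is anchored at that iteration's
#' mean respondent intercept `A = mean(mu_i)`, giving `G_k = A + d_k`. The
#' reference device's summary therefore equals the summary of `A` exactly.
#'
#' @param fit A `gus_fit`.
#' @param level Credible level of the central interval (default 0.95).
#' @return A tibble of class `gus_summary` (`device`, `mean`, `cri_low`,
#'   `cri_high`), sorted by descending posterior mean.
#' @export
summarize_effects <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "gus_fit"))
  G <- anchored_draws(fit)
  alpha <- (1 - level) / 2
  out <- tibble::tibble(
    device = colnames(G),
    mean = unname(colMeans(G)),
    cri_low = unname(apply(G, 2, stats::quantile, probs = alpha,
                           names = FALSE)),
    cri_high = unname(apply(G, 2, stats::quantile, probs = 1 - alpha,
                            names = FALSE))
  ) |>
    dplyr::arrange(dplyr::desc(.data$mean))
  class(out) <- c("gus_summary", class(out))
  out
}

# Per-iteration absolute GUS draws: G_k = mean(mu_i) + d_k.
anchored_draws <- function(fit) {
  d <- combined_draws(fit, "d")
  A <- rowMeans(combined_draws(fit, "mu"))
  G <- d + A
  colnames(G) <- colnames(d)
  G
}

#' Rank probabilities across MCMC iterations
#'
#' At each iteration the devices are ranked by their anchored GUS draws
#' (rank 1 = greatest usability); ties are broken by canonical device
#' order. Entry (k, r) of the returned matrix is the fraction of
#' iterations in which device k occupies rank r, so the matrix is doubly
#' stochastic up to Monte-Carlo error.
#'
#' @param fit A `gus_fit`, or a numeric matrix of per-iteration device
#'   scores (iterations x devices, columns named).
#' @param min_draws Minimum number of draws required (default 1000).
#' @return A `gus_rank_matrix`: devices x ranks probability matrix.
#' @export
rank_probabilities <- function(fit, min_draws = 1000L) {
  G <- if (inherits(fit, "gus_fit")) anchored_draws(fit) else as.matrix(fit)
  if (nrow(G) < min_draws) {
    stop_gusnet(
      sprintf("need at least %d post-burn-in draws, have %d",
              min_draws, nrow(G)),
      class = "gusnet_precondition_error"
    )
  }
  D <- ncol(G)
  counts <- matrix(0L, D, D,
                   dimnames = list(device = colnames(G),
                                   rank = as.character(seq_len(D))))
  # order() is stable, so exact ties fall back to column (canonical) order
  for (i in seq_len(nrow(G))) {
    ord <- order(-G[i, ])
    for (r in seq_len(D)) counts[ord[r], r] <- counts[ord[r], r] + 1L
  }
  structure(counts / nrow(G), class = "gus_rank_matrix")
}

#' @export
print.gus_rank_matrix <- function(x, ...) {
  cat("<gus_rank_matrix> P(device has rank r), rank 1 = highest GUS\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Rank matrix in tidy long format
#'
#' @param rank_matrix A `gus_rank_matrix`.
#' @return A tibble `device`, `rank`, `probability`.
#' @export
rank_long <- function(rank_matrix) {
  m <- unclass(rank_matrix)
  tibble::tibble(
    device = rep(rownames(m), times = ncol(m)),
    rank = rep(seq_len(ncol(m)), each = nrow(m)),
    probability = as.vector(m)
  ) |>
    dplyr::arrange(.data$device, .data$rank)
}

#' Convergence diagnostics for a fitted model
#'
#' Split-chain Gelman-Rubin statistics (each chain is halved, so C chains
#' give 2C sequences) and effective sample sizes, computed for the device
#' effects, the respondent intercepts and the sd parameters. The
#' convergence flag requires every split-Rhat below 1.05.
#'
#' @param fit A `gus_fit` with at least two chains.
#' @return A tibble `parameter`, `rhat`, `ess`, with attribute
#'   `converged`.
#' @export
diagnose <- function(fit) {
  stopifnot(inherits(fit, "gus_fit"))
  if (length(fit$chains) < 2L) {
    stop_gusnet("diagnostics require at least 2 chains",
                class = "gusnet_precondition_error")
  }
  pars <- list()
  d_all <- lapply(fit$chains, `[[`, "d")
  for (k in seq_along(fit$devices)) {
    if (fit$devices[k] == fit$reference) next
    pars[[paste0("d[", fit$devices[k], "]")]] <-
      lapply(d_all, function(m) m[, k])
  }
  mu_all <- lapply(fit$chains, `[[`, "mu")
  for (i in seq_along(fit$data$respondents)) {
    pars[[paste0("mu[", fit$data$respondents[i], "]")]] <-
      lapply(mu_all, function(m) m[, i])
  }
  pars[["tau"]] <- lapply(fit$chains, `[[`, "tau")
  if (fit$model == "RE") {
    pars[["sigma"]] <- lapply(fit$chains, `[[`, "sigma")
  }
  out <- purrr::imap_dfr(pars, function(chains, name) {
    tibble::tibble(parameter = name,
                   rhat = split_rhat(chains),
                   ess = ess_chains(chains))
  })
  attr(out, "converged") <- all(out$rhat < 1.05, na.rm = TRUE)
  out
}

# Split-chain Gelman-Rubin statistic on a list of per-chain draws.
split_rhat <- function(chains) {
  seqs <- split_halves(chains)
  n <- length(seqs[[1]])
  means <- vapply(seqs, mean, 0)
  vars <- vapply(seqs, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

split_halves <- function(chains) {
  unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[(length(x) - n + 1L):length(x)])
  }), recursive = FALSE)
}

# Effective sample size: multi-chain autocovariance estimator with Geyer's
# initial-positive-pair truncation.
ess_chains <- function(chains) {
  seqs <- split_halves(chains)
  m <- length(seqs)
  n <- length(seqs[[1]])
  means <- vapply(seqs, mean, 0)
  vars <- vapply(seqs, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  var_plus <- (n - 1) / n * W + B / n
  if (var_plus == 0) return(NA_real_)
  lag_max <- min(n - 2L, 500L)
  acov <- vapply(seqs, function(x) {
    stats::acf(x, lag.max = lag_max, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  }, numeric(lag_max + 1L))
  rho <- 1 - (W - rowMeans(acov)[-1]) / var_plus
  # sum lags while paired autocorrelations remain positive
  s <- 0
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2L
  }
  ess <- m * n / (1 + 2 * s)
  min(ess, m * n)
}

#' @rdname gusnet-broom
#' @method tidy gus_fit
#' @export
tidy.gus_fit <- function(x, level = 0.95, ...) {
  d <- combined_draws(x, "d")
  alpha <- (1 - level) / 2
  keep <- colnames(d) != x$reference
  tibble::tibble(
    term = paste0("d[", colnames(d)[keep], "]"),
    device = colnames(d)[keep],
    estimate = colMeans(d[, keep, drop = FALSE]),
    std.error = apply(d[, keep, drop = FALSE], 2, stats::sd),
    conf.low = apply(d[, keep, drop = FALSE], 2, stats::quantile,
                     probs = alpha, names = FALSE),
    conf.high = apply(d[, keep, drop = FALSE], 2, stats::quantile,
                      probs = 1 - alpha, names = FALSE)
  )
}

#' Broom-style accessors for fitted indirect-comparison models
#'
#' `tidy()` returns one row per non-reference device effect (posterior
#' mean, sd and central credible interval, relative to the reference
#' device); `glance()` returns a one-row model overview including the DIC.
#'
#' @param x A `gus_fit`.
#' @param level Credible level for `tidy()` intervals.
#' @param ... Unused.
#' @name gusnet-broom
NULL

#' @rdname gusnet-broom
#' @method glance gus_fit
#' @export
glance.gus_fit <- function(x, ...) {
  dic <- compute_dic(x)
  tibble::tibble(
    model = x$model,
    stratum = x$stratum,
    n_respondents = length(x$data$respondents),
    n_records = length(x$data$y),
    n_devices = length(x$devices),
    Dbar = dic$Dbar,
    pD = dic$pD,
    DIC = dic$DIC,
    rhat_max = if (!is.null(x$diagnostics)) max(x$diagnostics$rhat) else NA_real_,
    converged = x$converged
  )
}
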