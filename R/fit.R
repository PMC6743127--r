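#' Specify the Bayesian indirect-comparison model
#'
#' The model pools all within-patient device comparisons of one stratum into
#' a single joint model. Each respondent i contributes
#' `y_ik = mu_i + delta_ik + eps_ik` with `eps ~ N(0, tau^2)` and
#' `delta_i,base(i) = 0`. Under the fixed-effect (FE) model every
#' respondent estimates the same device effects:
#' `delta_ik = d_k - d_base(i)`. Under the random-effect (RE) model each
#' non-baseline contrast is an independent normal draw around those means,
#' `delta_ik ~ N(d_k - d_base(i), sigma^2)`, `sigma` measuring
#' between-respondent heterogeneity of the device effects. Keeping the
#' contrasts independent (rather than correlated through a shared
#' baseline) is what leaves `tau` and `sigma` jointly identified when
#' every respondent contributes a single replicate per device; see the
#' methods vignette.
#'
#' Priors are vague on the 0-50 bounded GUS scale:
#' `d_k ~ N(0, 100^2)`, `mu_i ~ N(25, 100^2)`, `tau ~ U(0, 50)`,
#' `sigma ~ U(0, 25)`.
#'
#' @param type `"FE"` or `"RE"`.
#' @param reference Reference device with `d == 0`; defaults to Breezhaler,
#'   the only device tested in all three design groups.
#' @param prior_d,prior_mu Named numeric vectors `c(mean=, sd=)`.
#' @param tau_upper,sigma_upper Upper bounds of the uniform priors on the
#'   residual and heterogeneity sds (points).
#' @return A `gus_model_spec` list.
#' @export
gus_model_spec <- function(type = c("FE", "RE"), reference = "Breezhaler",
                           prior_d = c(mean = 0, sd = 100),
                           prior_mu = c(mean = 25, sd = 100),
                           tau_upper = 50, sigma_upper = 25) {
  type <- match.arg(type)
  reference <- match_device(reference)
  if (prior_d[["sd"]] <= 0 || prior_mu[["sd"]] <= 0 ||
      tau_upper <= 0 || sigma_upper <= 0) {
    stop_gusnet("prior sds and uniform upper bounds must be positive",
                class = "gusnet_domain_error")
  }
  structure(
    list(type = type, reference = reference, prior_d = prior_d,
         prior_mu = prior_mu, tau_upper = tau_upper,
         sigma_upper = sigma_upper),
    class = "gus_model_spec"
  )
}

#' MCMC configuration
#'
#' @param chains Number of chains (>= 2 for convergence diagnostics; a
#'   single chain is allowed but [diagnose()] will refuse it).
#' @param iterations Iterations per chain, including burn-in.
#' @param burn_in Burn-in iterations discarded per chain.
#' @param thin Thinning interval.
#' @param seed Integer seed; mandatory.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(chains = 2L, iterations = 100000L,
                        burn_in = 20000L, thin = 1L, seed) {
  if (missing(seed)) {
    stop_gusnet("an explicit integer seed is required",
                class = "gusnet_domain_error")
  }
  chains <- as.integer(chains); iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in); thin <- as.integer(thin)
  if (chains < 1L || iterations <= burn_in || burn_in < 0L || thin < 1L) {
    stop_gusnet("need chains >= 1, iterations > burn_in >= 0, thin >= 1",
                class = "gusnet_domain_error")
  }
  structure(
    list(chains = chains, iterations = iterations, burn_in = burn_in,
         thin = thin, seed = as.integer(seed)),
    class = "mcmc_config"
  )
}

#' Fit the Bayesian indirect-comparison model to one stratum
#'
#' Runs the Gibbs sampler (exact conjugate updates throughout; the
#' uniform-on-sd priors yield truncated inverse-gamma draws for the
#' variances) on the GUS records of a single stratum. Respondents who
#' tested a single device carry no within-respondent contrast information
#' and are dropped with a warning; the stratum's evidence network must be
#' connected. Results are exactly reproducible for a fixed seed.
#'
#' @param records Tibble of GUS records for one stratum (`respondent_id`,
#'   `device`, `gus_total`, ...).
#' @param spec A [gus_model_spec()].
#' @param config An [mcmc_config()].
#' @return A `gus_fit` object holding per-chain posterior draws of the
#'   device effects `d_k` (reference fixed at 0), respondent intercepts
#'   `mu_i`, sds `tau` (and `sigma` for RE), the per-iteration deviance,
#'   and convergence diagnostics.
#' @export
#' @examples
#' cohort <- generate_cohort(paper_design(), simulation_params(seed = 7))
#' recs <- dplyr::filter(cohort$records, stratum == "experienced")
#' fit <- fit_gus_model(recs, gus_model_spec("FE"),
#'                      mcmc_config(iterations = 2000, burn_in = 500,
#'                                  seed = 7))
#' tidy(fit)
fit_gus_model <- function(records, spec = gus_model_spec(),
                          config = mcmc_config(seed = 1L)) {
  stopifnot(is.data.frame(records), inherits(spec, "gus_model_spec"),
            inherits(config, "mcmc_config"))
  records <- dplyr::mutate(records, device = match_device(.data$device))
  strata <- unique(records$stratum)
  if (length(strata) != 1L) {
    stop_gusnet(
      sprintf("records span %d strata (%s); fit one stratum at a time",
              length(strata), paste(strata, collapse = ", ")),
      class = "gusnet_precondition_error"
    )
  }
  if (any(records$gus_total < 0 | records$gus_total > 50)) {
    stop_gusnet("gus_total outside [0, 50]", class = "gusnet_domain_error")
  }

  # single-device respondents: no contrast information under this model
  n_per <- records |>
    dplyr::count(.data$respondent_id)
  dropped <- n_per$respondent_id[n_per$n < 2]
  if (length(dropped) > 0) {
    warn_gusnet(
      sprintf("dropping %d single-device respondent(s) from the fit: %s",
              length(dropped), paste(dropped, collapse = ", ")),
      class = "gusnet_single_device"
    )
    records <- dplyr::filter(records,
                             !.data$respondent_id %in% dropped)
  }
  if (nrow(records) == 0) {
    stop_gusnet("no multi-device respondents to fit",
                class = "gusnet_precondition_error")
  }

  net <- build_network(records)
  assert_connected(net, strata)

  devs <- intersect(dpi_devices(), unique(records$device))
  if (!spec$reference %in% devs) {
    stop_gusnet(
      sprintf("reference device %s not present in this stratum",
              sQuote(spec$reference)),
      class = "gusnet_precondition_error"
    )
  }
  resp_ids <- sort(unique(records$respondent_id))
  dev_idx <- match(records$device, devs) - 1L
  resp_idx <- match(records$respondent_id, resp_ids) - 1L
  ref <- match(spec$reference, devs) - 1L

  # baseline device of each respondent: first tested in canonical order
  base_dev <- records |>
    dplyr::group_by(.data$respondent_id) |>
    dplyr::summarise(base = devs[min(match(.data$device, devs))],
                     .groups = "drop")
  base_idx <- match(base_dev$base[match(resp_ids, base_dev$respondent_id)],
                    devs) - 1L

  y <- as.numeric(records$gus_total)
  priors <- list(d_mean = unname(spec$prior_d[["mean"]]),
                 d_sd = unname(spec$prior_d[["sd"]]),
                 mu_mean = unname(spec$prior_mu[["mean"]]),
                 mu_sd = unname(spec$prior_mu[["sd"]]),
                 tau_upper = spec$tau_upper,
                 sigma_upper = spec$sigma_upper)

  resp_means <- tapply(y, resp_idx, mean)
  sd0 <- stats::sd(y)
  if (!is.finite(sd0) || sd0 < 1) sd0 <- 1

  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    chains[[ch]] <- withr::with_seed(config$seed + ch - 1L, {
      # overdispersed starting points beyond the first chain
      jitter <- if (ch == 1L) 0 else 1
      init <- list(
        mu = as.numeric(resp_means) +
          jitter * stats::rnorm(length(resp_ids), 0, sd0),
        d = jitter * stats::rnorm(length(devs), 0, 5),
        tau = sd0 * stats::runif(1, if (ch == 1L) 1 else 0.3,
                                 if (ch == 1L) 1 else 3),
        sigma = stats::runif(1, 0.5, if (ch == 1L) 1 else 5)
      )
      init$d[ref + 1L] <- 0
      draws <- gibbs_ic_cpp(y, resp_idx, dev_idx, base_idx,
                            length(resp_ids), length(devs), ref,
                            spec$type == "RE", priors, init,
                            config$iterations, config$burn_in, config$thin)
      colnames(draws$d) <- devs
      colnames(draws$mu) <- resp_ids
      draws
    })
  }

  delta_bar <- Reduce(`+`, lapply(chains, `[[`, "delta_bar")) / length(chains)

  fit <- structure(
    list(
      model = spec$type,
      stratum = strata,
      devices = devs,
      reference = spec$reference,
      spec = spec,
      config = config,
      chains = chains,
      delta_bar = delta_bar,
      data = list(y = y, resp_idx = resp_idx, dev_idx = dev_idx,
                  base_idx = base_idx, respondents = resp_ids,
                  records = records, dropped = dropped),
      diagnostics = NULL,
      converged = NA
    ),
    class = "gus_fit"
  )

  if (config$chains >= 2L) {
    diag <- diagnose(fit)
    fit$diagnostics <- diag
    fit$converged <- all(diag$rhat < 1.05, na.rm = TRUE)
    if (!fit$converged) {
      warn_gusnet(
        sprintf("possible non-convergence: max split-Rhat %.3f (threshold 1.05)",
                max(diag$rhat, na.rm = TRUE)),
        class = "gusnet_nonconvergence"
      )
    }
  } else {
    warn_gusnet("single chain: convergence diagnostics unavailable",
                class = "gusnet_single_chain")
  }
  fit
}

#' @export
print.gus_fit <- function(x, ...) {
  cat(sprintf("<gus_fit> %s model, stratum %s\n", x$model, x$stratum))
  cat(sprintf("  %d respondents, %d records, %d devices (reference %s)\n",
              length(x$data$respondents), length(x$data$y),
              length(x$devices), x$reference))
  cat(sprintf("  %d chain(s) x %d kept draws; converged: %s\n",
              length(x$chains), x$chains[[1]]$n_kept,
              format(x$converged)))
  invisible(x)
}

# Stack one parameter's draws across chains into a single matrix / vector.
combined_draws <- function(fit, par = c("d", "mu", "tau", "sigma",
                                        "deviance")) {
  par <- match.arg(par)
  out <- lapply(fit$chains, `[[`, par)
  if (is.matrix(out[[1]])) do.call(rbind, out) else do.call(c, out)
}
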