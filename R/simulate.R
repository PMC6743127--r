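#' The study's incomplete-block cohort design
#'
#' The fixed design of the usability study the package emulates: 103 COPD
#' respondents split into 74 DPI-experienced and 29 DPI-naive, allocated to
#' three groups. Group 1 (n = 36: 27 experienced / 9 naive) tests
#' Breezhaler, Spiromax, Nexthaler and Ellipta; Group 2 (n = 37: 28/9)
#' tests Breezhaler, Spiromax, Diskus and Turbohaler; Group 3 (n = 30:
#' 19/11) tests Breezhaler and Genuair. Breezhaler is tested in every
#' group, which keeps the evidence network connected in both strata.
#'
#' @return A `cohort_design` object: a list with a `groups` tibble
#'   (`group`, `devices` list-column, `n_experienced`, `n_naive`).
#' @export
#' @examples
#' d <- paper_design()
#' sum(d$groups$n_experienced)  # 74
paper_design <- function() {
  groups <- tibble::tibble(
    group = 1:3,
    devices = list(
      c("Breezhaler", "Spiromax", "Nexthaler", "Ellipta"),
      c("Breezhaler", "Spiromax", "Diskus", "Turbohaler"),
      c("Breezhaler", "Genuair")
    ),
    n_experienced = c(27L, 28L, 19L),
    n_naive = c(9L, 9L, 11L)
  )
  cohort_design(groups)
}

#' Construct a cohort design
#'
#' @param groups A tibble with columns `group`, `devices` (list-column of
#'   device names), `n_experienced`, `n_naive`.
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(groups) {
  stopifnot(is.data.frame(groups),
            all(c("group", "devices", "n_experienced", "n_naive") %in%
                  names(groups)))
  groups$devices <- lapply(groups$devices, match_device)
  if (any(groups$n_experienced < 0) || any(groups$n_naive < 0)) {
    stop_gusnet("group sizes must be non-negative", class = "gusnet_domain_error")
  }
  structure(list(groups = tibble::as_tibble(groups)), class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design>\n")
  g <- x$groups
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  group %d: %s (experienced %d, naive %d)\n",
                g$group[i], paste(g$devices[[i]], collapse = ", "),
                g$n_experienced[i], g$n_naive[i]))
  }
  cat(sprintf("  total: %d experienced, %d naive, %d overall\n",
              sum(g$n_experienced), sum(g$n_naive),
              sum(g$n_experienced) + sum(g$n_naive)))
  invisible(x)
}

#' Simulation parameters for a synthetic cohort
#'
#' Ground-truth parameters for [generate_cohort()]. `true_effects` are the
#' seven device effects on the GUS scale, in canonical device order,
#' expressed relative to the reference device Breezhaler (whose entry must
#' be 0); the reference's absolute level is `anchor`. A respondent's score
#' for device k is
#' `y = clamp(round(mu_i + e_k + eta_ik + eps_ik), 0, 50)` with
#' `mu_i ~ N(anchor, respondent_sd^2)` and `eps ~ N(0, residual_sd^2)`.
#' `eta_ik ~ N(0, heterogeneity_sd^2)` perturbs the respondent's
#' *relative* device effects and is therefore zero on the reference
#' device (0 everywhere gives fixed-effect truth): heterogeneity that hit
#' every arm equally — the reference included — would be indistinguishable
#' from residual noise and is not a separate quantity.
#'
#' @param true_effects Numeric vector of 7 device effects (canonical order
#'   or named by device); reference entry 0.
#' @param respondent_sd Between-respondent sd of the overall level (points).
#' @param residual_sd Measurement noise sd (points).
#' @param heterogeneity_sd Respondent-level device-effect sd (points); 0
#'   simulates fixed-effect truth.
#' @param anchor Absolute GUS level of the reference device (points);
#'   mid-scale 25 keeps truncation negligible for |effect| <= 15.
#' @param rounding `"integer"` (default; sub-scores are integer point
#'   awards), `"half-point"`, or `"none"`.
#' @param seed Integer seed; mandatory for reproducibility.
#' @return A `sim_params` list.
#' @export
simulation_params <- function(true_effects = c(0, 2, 10, -4, 4, 6, 8),
                              respondent_sd = 5,
                              residual_sd = 5,
                              heterogeneity_sd = 0,
                              anchor = 25,
                              rounding = c("integer", "half-point", "none"),
                              seed = 1L) {
  rounding <- match.arg(rounding)
  if (length(true_effects) != 7L) {
    stop_gusnet("true_effects must have length 7", class = "gusnet_domain_error")
  }
  if (is.null(names(true_effects))) names(true_effects) <- dpi_devices()
  true_effects <- true_effects[dpi_devices()]
  if (abs(true_effects[["Breezhaler"]]) > 1e-12) {
    stop_gusnet("the reference device (Breezhaler) must have effect 0",
                class = "gusnet_domain_error")
  }
  if (respondent_sd < 0 || residual_sd < 0 || heterogeneity_sd < 0) {
    stop_gusnet("sds must be non-negative", class = "gusnet_domain_error")
  }
  structure(
    list(true_effects = true_effects, respondent_sd = respondent_sd,
         residual_sd = residual_sd, heterogeneity_sd = heterogeneity_sd,
         anchor = anchor, rounding = rounding, seed = as.integer(seed)),
    class = "sim_params"
  )
}

round_scores <- function(y, rounding) {
  switch(rounding,
         "integer" = round(y),
         "half-point" = round(y * 2) / 2,
         "none" = y)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Simulates per-respondent, per-device GUS totals under the model described
#' in [simulation_params()], on any [cohort_design()]. Scores are rounded
#' and clamped to the 0-50 scale; the latent (pre-rounding, pre-clamping)
#' draws are returned alongside so downstream estimates can be checked
#' against truth.
#'
#' @param design A `cohort_design`; defaults to [paper_design()].
#' @param params A `sim_params` object.
#' @return A list of class `gus_cohort` with elements `records` (tibble:
#'   `respondent_id`, `stratum`, `group`, `device`, `gus_total`) and
#'   `truth` (true effects, respondent intercepts, latent draws, truncation
#'   rate, and the parameters used).
#' @export
#' @examples
#' cohort <- generate_cohort(paper_design(), simulation_params(seed = 42))
#' nrow(cohort$records)
generate_cohort <- function(design = paper_design(), params = simulation_params()) {
  stopifnot(inherits(design, "cohort_design"), inherits(params, "sim_params"))
  if (any(abs(params$true_effects) + params$anchor > 50 |
          params$anchor + params$true_effects < 0)) {
    warn_gusnet(
      "some true device means fall outside [0, 50]; truncation will bias them",
      class = "gusnet_truncation"
    )
  }

  roster <- design$groups |>
    tidyr::pivot_longer(c("n_experienced", "n_naive"),
                        names_to = "stratum", values_to = "n") |>
    dplyr::mutate(stratum = sub("^n_", "", .data$stratum)) |>
    dplyr::filter(.data$n > 0)

  withr::with_seed(params$seed, {
    respondents <- purrr::pmap_dfr(roster, function(group, devices, stratum, n) {
      tibble::tibble(group = group, stratum = stratum,
                     devices = rep(list(devices), n))
    })
    respondents$respondent_id <- sprintf("R%03d", seq_len(nrow(respondents)))
    respondents$mu <- stats::rnorm(nrow(respondents), params$anchor,
                                   params$respondent_sd)

    latent <- respondents |>
      dplyr::select("respondent_id", "stratum", "group", "devices", "mu") |>
      tidyr::unnest_longer("devices", values_to = "device") |>
      dplyr::mutate(
        effect = params$true_effects[.data$device],
        eta = stats::rnorm(dplyr::n(), 0, params$heterogeneity_sd) *
          (.data$device != "Breezhaler"),
        eps = stats::rnorm(dplyr::n(), 0, params$residual_sd),
        y_latent = .data$mu + .data$effect + .data$eta + .data$eps,
        y = pmin(50, pmax(0, round_scores(.data$y_latent, params$rounding)))
      )
  })

  trunc_rate <- mean(latent$y_latent < 0 | latent$y_latent > 50)
  if (trunc_rate > 0.05) {
    warn_gusnet(
      sprintf("%.1f%% of latent scores were truncated at the 0/50 bounds",
              100 * trunc_rate),
      class = "gusnet_truncation"
    )
  }

  records <- latent |>
    dplyr::transmute(.data$respondent_id, .data$stratum, .data$group,
                     .data$device, gus_total = .data$y)

  structure(
    list(
      records = records,
      truth = list(
        true_effects = params$true_effects,
        anchor = params$anchor,
        respondents = dplyr::select(respondents, "respondent_id", "stratum",
                                    "group", "mu"),
        latent = dplyr::select(latent, "respondent_id", "device", "eta",
                               "eps", "y_latent"),
        truncation_rate = trunc_rate,
        params = params
      )
    ),
    class = "gus_cohort"
  )
}

#' @export
print.gus_cohort <- function(x, ...) {
  cat("<gus_cohort>", nrow(x$truth$respondents), "respondents,",
      nrow(x$records), "records\n")
  cat(sprintf("  truncation rate %.3f, seed %d\n",
              x$truth$truncation_rate, x$truth$params$seed))
  invisible(x)
}

#' Reconstruct questionnaire answers that score to given totals
#'
#' For each GUS record, builds a full set of item answers whose score under
#' `scheme` equals the record's `gus_total` exactly (the round-trip
#' property `compute_gus(inverse_questionnaire(r)) == r`). Used to exercise
#' the scoring engine end-to-end on synthetic cohorts. When a total is not
#' attainable under the scheme's point granularity, the nearest attainable
#' total is used and a warning raised.
#'
#' @param records A tibble with `respondent_id`, `stratum`, `group`,
#'   `device`, `gus_total`.
#' @param scheme A validated `gus_scheme` with integer item points.
#' @param seed Integer seed controlling which of the (generally many) valid
#'   answer decompositions is chosen.
#' @return A long-format answers tibble for [compute_gus()].
#' @export
inverse_questionnaire <- function(records, scheme = default_scheme(),
                                  seed = 1L) {
  validate_scheme(scheme)
  items <- purrr::map(scheme$boxes, function(box) {
    purrr::map(box$items, function(item) {
      pts <- if (item$kind == "categorical") unname(item$options) else item$points
      list(box_id = box$box_id, item = item,
           points = sort(unique(as.numeric(pts))))
    })
  })
  items <- purrr::flatten(items)
  all_pts <- unlist(purrr::map(items, "points"))
  if (any(abs(all_pts - round(all_pts)) > 1e-9)) {
    stop_gusnet("inverse_questionnaire requires integer item points",
                class = "gusnet_domain_error")
  }

  n_items <- length(items)
  max_total <- sum(vapply(items, function(it) max(it$points), 0))
  # reach[i, t+1]: can items i..n sum to t?  (backward subset-sum table)
  reach <- matrix(FALSE, n_items + 1L, max_total + 1L)
  reach[n_items + 1L, 1L] <- TRUE
  for (i in n_items:1) {
    suffix_max <- sum(vapply(items[i:n_items], function(it) max(it$points), 0))
    for (t in 0:suffix_max) {
      for (p in items[[i]]$points) {
        if (p <= t && reach[i + 1L, t - p + 1L]) {
          reach[i, t + 1L] <- TRUE
          break
        }
      }
    }
  }
  achievable <- which(reach[1L, ]) - 1L

  withr::with_seed(seed, {
    purrr::pmap_dfr(records[, c("respondent_id", "stratum", "group", "device",
                                "gus_total")],
                    function(respondent_id, stratum, group, device, gus_total) {
      target <- gus_total
      if (!(target %in% achievable)) {
        nearest <- achievable[which.min(abs(achievable - target))]
        warn_gusnet(
          sprintf("total %g not attainable under the scheme; using nearest attainable %g (respondent %s, device %s)",
                  target, nearest, respondent_id, device),
          class = "gusnet_nearest_achievable"
        )
        target <- nearest
      }
      remaining <- target
      rows <- vector("list", n_items)
      for (i in seq_len(n_items)) {
        opts <- items[[i]]$points
        opts <- opts[opts <= remaining]
        opts <- opts[sample.int(length(opts))]  # seeded variety across valid decompositions
        for (p in opts) {
          if (reach[i + 1L, remaining - p + 1L]) {
            rows[[i]] <- tibble::tibble(
              respondent_id = respondent_id, stratum = stratum, group = group,
              device = device, box_id = items[[i]]$box_id,
              item = items[[i]]$item$id,
              value = answer_for_points(items[[i]]$item, p)
            )
            remaining <- remaining - p
            break
          }
        }
      }
      dplyr::bind_rows(rows)
    })
  })
}
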