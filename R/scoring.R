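#' Score a nurse measurement against a threshold rule
#'
#' Threshold rules map a count (critical issues, actuation attempts) or a
#' time in seconds onto points via half-open intervals `[lo, hi)`: a value
#' exactly on a boundary belongs to the interval whose lower edge it is. The
#' mapping is monotone non-increasing, so fewer attempts / less time never
#' scores fewer points.
#'
#' @param value A non-negative count or time in seconds.
#' @param rule An item rule of kind `count-threshold` or `time-threshold`
#'   (an element of a box's `items`).
#' @return Points awarded (scalar).
#' @export
#' @examples
#' sch <- default_scheme()
#' rule <- sch$boxes[[3]]$items$actuation_attempts
#' score_measurement(1, rule)  # first attempt: full points
#' score_measurement(5, rule)
score_measurement <- function(value, rule) {
  if (!rule$kind %in% c("count-threshold", "time-threshold")) {
    stop_gusnet("rule is not a measurement rule", class = "gusnet_domain_error")
  }
  if (!is.numeric(value) || is.na(value) || value < 0) {
    stop_gusnet(
      sprintf("measurement value must be a non-negative number, got %s",
              deparse(value)),
      class = "gusnet_domain_error"
    )
  }
  if (value < rule$breaks[1]) {
    stop_gusnet(
      sprintf("value %g below the rule's domain (first break %g)",
              value, rule$breaks[1]),
      class = "gusnet_domain_error"
    )
  }
  # [lo, hi) intervals: findInterval with left-closed edges
  idx <- findInterval(value, rule$breaks, left.open = FALSE)
  rule$points[idx]
}

score_categorical <- function(value, rule) {
  pts <- rule$options[as.character(value)]
  if (is.na(pts)) {
    stop_gusnet(
      sprintf("answer %s is not an option of item %s (options: %s)",
              sQuote(value), sQuote(rule$id),
              paste(names(rule$options), collapse = ", ")),
      class = "gusnet_domain_error"
    )
  }
  unname(pts)
}

score_item <- function(value, rule) {
  if (rule$kind == "categorical") {
    score_categorical(value, rule)
  } else {
    score_measurement(as.numeric(value), rule)
  }
}

#' Score one questionnaire box
#'
#' Sums the item points of a single box for one respondent-device pair. All
#' of the box's items must be answered: missing answers are an error, never
#' imputed, because the questionnaire is administered under nurse
#' supervision and arrives complete.
#'
#' @param answers A data frame with columns `item` and `value`, one row per
#'   item of this box.
#' @param box A box of a `gus_scheme` (an element of `scheme$boxes`).
#' @return The box sub-score (scalar), in `[0, box$max_points]`.
#' @export
score_box <- function(answers, box) {
  required <- names(box$items)
  missing <- setdiff(required, answers$item)
  if (length(missing) > 0) {
    stop_gusnet(
      sprintf("box %d: missing answer(s) for item(s) %s",
              box$box_id, paste(sQuote(missing), collapse = ", ")),
      class = "gusnet_missing_data"
    )
  }
  dup <- answers$item[duplicated(answers$item)]
  if (length(dup) > 0) {
    stop_gusnet(
      sprintf("box %d: duplicated answer(s) for item(s) %s",
              box$box_id, paste(sQuote(unique(dup)), collapse = ", ")),
      class = "gusnet_duplicate_observation"
    )
  }
  pts <- vapply(required, function(id) {
    v <- answers$value[answers$item == id]
    score_item(v, box$items[[id]])
  }, 0)
  sum(pts)
}

#' Compute Global Usability Scores from long-format answers
#'
#' Turns raw questionnaire answers (one row per respondent x device x item)
#' into one GUS record per respondent-device pair: the five box sub-scores
#' and their 0-50 total. Each respondent's tested devices must be a subset
#' of their group's device set under the study design.
#'
#' @param answers A data frame with columns `respondent_id`, `stratum`,
#'   `group`, `device`, `box_id`, `item`, `value`.
#' @param scheme A validated `gus_scheme`; defaults to [default_scheme()].
#' @param design A cohort design (see [paper_design()]) defining each
#'   group's device set; `NULL` skips the design-membership check.
#' @return A tibble with columns `respondent_id`, `stratum`, `group`,
#'   `device`, `subscore_1` .. `subscore_5`, `gus_total`.
#' @export
#' @examples
#' sch <- default_scheme()
#' ans <- extreme_answers(sch, which = "best", respondent_id = "R001",
#'                        stratum = "experienced", group = 3,
#'                        device = "Breezhaler")
#' compute_gus(ans, sch)
compute_gus <- function(answers, scheme = default_scheme(),
                        design = paper_design()) {
  stopifnot(is.data.frame(answers))
  needed <- c("respondent_id", "stratum", "group", "device", "box_id",
              "item", "value")
  miss <- setdiff(needed, names(answers))
  if (length(miss) > 0) {
    stop_gusnet(
      sprintf("answers is missing column(s): %s", paste(miss, collapse = ", ")),
      class = "gusnet_parse_error"
    )
  }
  validate_scheme(scheme)
  answers <- dplyr::mutate(answers, device = match_device(.data$device))

  if (!is.null(design)) {
    sets <- design$groups
    bad <- answers |>
      dplyr::distinct(.data$respondent_id, .data$group, .data$device) |>
      dplyr::rowwise() |>
      dplyr::filter(!.data$device %in% sets$devices[[match(.data$group, sets$group)]]) |>
      dplyr::ungroup()
    if (nrow(bad) > 0) {
      stop_gusnet(
        sprintf("design violation: respondent %s (group %s) has record(s) for %s, outside the group's device set",
                bad$respondent_id[1], bad$group[1], sQuote(bad$device[1])),
        class = "gusnet_design_violation"
      )
    }
  }

  per_device <- answers |>
    dplyr::group_by(.data$respondent_id, .data$stratum, .data$group,
                    .data$device)
  n_dev <- answers |>
    dplyr::distinct(.data$respondent_id, .data$device) |>
    dplyr::count(.data$respondent_id)
  if (any(n_dev$n > 4)) {
    stop_gusnet("a respondent may test at most 4 devices in a session",
                class = "gusnet_design_violation")
  }

  scored <- per_device |>
    dplyr::group_modify(function(df, key) {
      sub <- vapply(scheme$boxes, function(box) {
        box_answers <- df[df$box_id == box$box_id, c("item", "value")]
        tryCatch(
          score_box(box_answers, box),
          gusnet_missing_data = function(e) {
            stop_gusnet(
              sprintf("respondent %s, device %s: %s",
                      key$respondent_id, key$device, conditionMessage(e)),
              class = "gusnet_missing_data"
            )
          }
        )
      }, 0)
      out <- as.list(sub)
      names(out) <- paste0("subscore_", vapply(scheme$boxes, `[[`, 0L, "box_id"))
      out$gus_total <- sum(sub)
      tibble::as_tibble(out)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$respondent_id, device_factor(.data$device))
  scored
}

#' Build an all-best or all-worst answer set
#'
#' Constructs the long-format answers a respondent would give if every item
#' were answered at its best (or worst) option — the questionnaire that
#' scores exactly 50 (or 0) under any valid scheme.
#'
#' @param scheme A validated `gus_scheme`.
#' @param which `"best"` or `"worst"`.
#' @param respondent_id,stratum,group,device Identifiers stamped on the rows.
#' @return A long-format answers tibble suitable for [compute_gus()].
#' @export
extreme_answers <- function(scheme, which = c("best", "worst"),
                            respondent_id = "R001",
                            stratum = "experienced",
                            group = 3,
                            device = "Breezhaler") {
  which <- match.arg(which)
  validate_scheme(scheme)
  purrr::map_dfr(scheme$boxes, function(box) {
    purrr::map_dfr(box$items, function(rule) {
      target <- if (which == "best") item_max(rule) else item_min(rule)
      ans <- answer_for_points(rule, target)
      tibble::tibble(
        respondent_id = respondent_id,
        stratum = stratum,
        group = group,
        device = device,
        box_id = box$box_id,
        item = rule$id,
        value = ans
      )
    })
  })
}

# Inverse of score_item for a single attainable point value: returns an
# answer string that scores exactly `pts` under the item's rule.
answer_for_points <- function(item, pts) {
  if (item$kind == "categorical") {
    hit <- names(item$options)[which(item$options == pts)]
    if (length(hit) == 0) {
      stop_gusnet(
        sprintf("item %s cannot award %g points", sQuote(item$id), pts),
        class = "gusnet_domain_error"
      )
    }
    hit[1]
  } else {
    i <- which(item$points == pts)
    if (length(i) == 0) {
      stop_gusnet(
        sprintf("item %s cannot award %g points", sQuote(item$id), pts),
        class = "gusnet_domain_error"
      )
    }
    i <- i[1]
    lo <- item$breaks[i]
    hi <- if (i < length(item$breaks)) item$breaks[i + 1] else NA_real_
    rep_val <- if (item$kind == "count-threshold") {
      lo
    } else if (is.na(hi)) {
      lo + 1   # unbounded top interval for times
    } else {
      (lo + hi) / 2
    }
    # time > 0 invariant: nudge a zero representative inside its interval
    if (item$kind == "time-threshold" && rep_val <= 0) rep_val <- min(1, hi / 2)
    as.character(rep_val)
  }
}
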