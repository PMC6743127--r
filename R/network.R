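#' Build the device-comparison evidence network
#'
#' Every respondent who tested devices a and b contributes one direct
#' within-patient comparison of that pair; the evidence network collects
#' these counts per stratum on the edges of a graph whose nodes are the
#' devices. Respondents who tested a single device contribute a node but no
#' edge.
#'
#' @param records A tibble of GUS records (`respondent_id`, `stratum`,
#'   `group`, `device`, ...), one row per respondent-device observation.
#' @return An `evidence_network` object: list with `nodes` (character),
#'   `edges` (tibble `device_a`, `device_b`, `stratum`, `n`; pairs in
#'   canonical order, `device_a < device_b`), and `groups` (per-group,
#'   per-stratum respondent counts).
#' @export
#' @examples
#' cohort <- generate_cohort(paper_design(), simulation_params(seed = 1))
#' net <- build_network(cohort$records)
#' net$edges
build_network <- function(records) {
  stopifnot(is.data.frame(records))
  records <- dplyr::mutate(records, device = match_device(.data$device))

  dup <- records |>
    dplyr::count(.data$respondent_id, .data$device) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_gusnet(
      sprintf("duplicate observation: respondent %s has %d records for device %s",
              dup$respondent_id[1], dup$n[1], sQuote(dup$device[1])),
      class = "gusnet_duplicate_observation"
    )
  }

  per_resp <- records |>
    dplyr::group_by(.data$respondent_id, .data$stratum, .data$group) |>
    dplyr::summarise(devices = list(sort(unique(.data$device))),
                     .groups = "drop")

  empty_edges <- tibble::tibble(device_a = character(),
                                device_b = character(),
                                stratum = character(), n = integer())
  edges <- if (nrow(per_resp) == 0) empty_edges else per_resp |>
    dplyr::mutate(pairs = purrr::map(.data$devices, function(d) {
      if (length(d) < 2) return(tibble::tibble(device_a = character(),
                                               device_b = character()))
      cmb <- utils::combn(d, 2)
      tibble::tibble(device_a = cmb[1, ], device_b = cmb[2, ])
    })) |>
    dplyr::select("stratum", "pairs") |>
    tidyr::unnest("pairs") |>
    dplyr::count(.data$device_a, .data$device_b, .data$stratum, name = "n") |>
    dplyr::arrange(device_factor(.data$device_a), device_factor(.data$device_b),
                   .data$stratum)

  groups <- per_resp |>
    dplyr::count(.data$group, .data$stratum, name = "n") |>
    dplyr::arrange(.data$group, .data$stratum)

  structure(
    list(nodes = sort(unique(records$device)), edges = edges,
         groups = groups, respondents = per_resp),
    class = "evidence_network"
  )
}

#' @export
print.evidence_network <- function(x, ...) {
  cat("<evidence_network>", length(x$nodes), "devices,",
      nrow(x$edges), "stratum-edges\n")
  print(x$edges, n = Inf)
  invisible(x)
}

#' Check that a stratum's evidence network is connected
#'
#' A single joint indirect-comparison model is identifiable only if every
#' device is reachable from every other through direct comparisons, i.e. the
#' stratum's network is connected. Under the study design Breezhaler is
#' tested in all three groups, which guarantees connectivity.
#'
#' @param network An `evidence_network`.
#' @param stratum Stratum label, e.g. `"experienced"` or `"naive"`.
#' @param error If `TRUE` (default) a disconnected network raises an
#'   analysis-precondition error listing the components; if `FALSE` the
#'   function just returns `FALSE`.
#' @return `TRUE` if connected (invisibly when `error = TRUE`).
#' @export
assert_connected <- function(network, stratum, error = TRUE) {
  stopifnot(inherits(network, "evidence_network"))
  nodes <- network$respondents |>
    dplyr::filter(.data$stratum == !!stratum) |>
    dplyr::pull("devices") |>
    unlist() |>
    unique() |>
    sort()
  if (length(nodes) == 0) {
    stop_gusnet(sprintf("no records in stratum %s", sQuote(stratum)),
                class = "gusnet_precondition_error")
  }
  edges <- dplyr::filter(network$edges, .data$stratum == !!stratum,
                         .data$n > 0)

  # breadth-first search from the first node over the undirected edge list
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (start in nodes) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    queue <- start
    comp[start] <- cid
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- c(edges$device_b[edges$device_a == v],
              edges$device_a[edges$device_b == v])
      nb <- unique(nb[is.na(comp[nb])])
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  connected <- cid == 1L
  if (!connected && error) {
    parts <- split(names(comp), comp)
    stop_gusnet(
      sprintf("evidence network for stratum %s is disconnected: components %s",
              sQuote(stratum),
              paste(vapply(parts, function(p) paste0("{", paste(p, collapse = ", "), "}"), ""),
                    collapse = " ")),
      class = "gusnet_precondition_error"
    )
  }
  if (error) invisible(TRUE) else connected
}

#' Per-group, per-stratum design summary
#'
#' @param network An `evidence_network`.
#' @return A tibble with one row per group x stratum plus per-stratum and
#'   overall totals (`group = "total"`).
#' @export
design_summary <- function(network) {
  stopifnot(inherits(network, "evidence_network"))
  g <- network$groups
  if (nrow(g) == 0) {
    return(tibble::tibble(group = character(), stratum = character(),
                          n = integer()))
  }
  per_group <- g |>
    dplyr::mutate(group = as.character(.data$group))
  strata_totals <- g |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::mutate(group = "total")
  overall <- tibble::tibble(group = "total", stratum = "all", n = sum(g$n))
  dplyr::bind_rows(per_group, strata_totals, overall) |>
    dplyr::select("group", "stratum", "n")
}

#' Export a network's edge list
#'
#' Writes the per-stratum edge counts as a CSV (`device_a`, `device_b`,
#' `stratum`, `n`), mirroring the labelled evidence-network figure of a
#' usability study report.
#'
#' @param network An `evidence_network`.
#' @param path Output CSV path.
#' @return The edge tibble, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "evidence_network"))
  readr::write_csv(network$edges, path)
  invisible(network$edges)
}
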