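#' Read a GUS scoring scheme from JSON
#'
#' A scoring scheme describes how raw questionnaire answers and nurse
#' measurements are turned into the five box sub-scores whose sum is the
#' 0-50 Global Usability Score (GUS). The JSON layout is
#' `boxes -> items -> mapping`, where each item is either
#'
#' * `categorical`: a named `options` map from answer label to points, or
#' * `count-threshold` / `time-threshold`: ascending `breaks` (lower edges of
#'   half-open intervals `[lo, hi)`, the last interval unbounded above) with a
#'   parallel `points` vector that must be non-increasing — more attempts or
#'   more time can never score higher.
#'
#' @param path Path to a JSON scheme file.
#' @return A validated `gus_scheme` object.
#' @seealso [default_scheme()], [validate_scheme()]
#' @export
read_scheme <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  scheme <- structure(
    list(
      version = raw$version %||% "unversioned",
      boxes = lapply(raw$boxes, parse_box)
    ),
    class = "gus_scheme"
  )
  validate_scheme(scheme)
}

parse_box <- function(b) {
  items <- lapply(b$items, function(it) {
    kind <- it$kind
    if (kind == "categorical") {
      list(id = it$id, kind = kind,
           options = unlist(it$options))
    } else {
      list(id = it$id, kind = kind,
           breaks = as.numeric(unlist(it$breaks)),
           points = as.numeric(unlist(it$points)))
    }
  })
  names(items) <- vapply(items, `[[`, "", "id")
  list(box_id = as.integer(b$box_id),
       label = b$label %||% paste("Box", b$box_id),
       max_points = as.numeric(b$max_points),
       items = items)
}

#' The package's default scoring scheme
#'
#' A synthetic placeholder scheme shipped with the package: five boxes with
#' maxima (10, 10, 10, 10, 10), preference-at-glance answers in box 1,
#' nurse-measured critical issues / actuation attempts / time to autonomy in
#' boxes 2-4, and ten yes/no acceptance questions in box 5. The weights of
#' the validated GUS instrument are not publicly deposited, so this scheme is
#' a structurally faithful stand-in, never the authors' weighting.
#'
#' @return A validated `gus_scheme` object.
#' @export
#' @examples
#' sch <- default_scheme()
#' scheme_max_total(sch)
default_scheme <- function() {
  read_scheme(system.file("extdata", "default_scheme.json", package = "gusnet"))
}

item_max <- function(item) {
  if (item$kind == "categorical") max(item$options) else max(item$points)
}

item_min <- function(item) {
  if (item$kind == "categorical") min(item$options) else min(item$points)
}

box_max <- function(box) sum(vapply(box$items, item_max, 0))

#' Maximum attainable GUS total under a scheme
#'
#' @param scheme A `gus_scheme`.
#' @return The sum of the box maxima (50 for any valid scheme).
#' @export
scheme_max_total <- function(scheme) {
  sum(vapply(scheme$boxes, box_max, 0))
}

#' Validate a scoring scheme
#'
#' Checks every structural invariant of a scheme: exactly five boxes, box
#' maxima consistent with their items and summing to 50, non-negative item
#' points, strictly ascending threshold breaks, and monotone non-increasing
#' measurement mappings (a slower or more error-prone performance can never
#' be awarded more points).
#'
#' @param scheme A `gus_scheme` as returned by [read_scheme()].
#' @return The scheme, unchanged, if valid; otherwise an error of class
#'   `gusnet_invalid_scheme`.
#' @export
validate_scheme <- function(scheme) {
  if (!inherits(scheme, "gus_scheme")) {
    stop_gusnet("not a gus_scheme object", class = "gusnet_invalid_scheme")
  }
  boxes <- scheme$boxes
  if (length(boxes) != 5L) {
    stop_gusnet(
      sprintf("a scheme must have exactly 5 boxes, found %d", length(boxes)),
      class = "gusnet_invalid_scheme"
    )
  }
  ids <- vapply(boxes, `[[`, 0L, "box_id")
  if (!identical(sort(ids), 1:5)) {
    stop_gusnet("box ids must be exactly 1-5", class = "gusnet_invalid_scheme")
  }
  for (box in boxes) {
    for (item in box$items) {
      if (item$kind == "categorical") {
        if (any(item$options < 0)) {
          stop_gusnet(
            sprintf("item %s awards negative points", sQuote(item$id)),
            class = "gusnet_invalid_scheme"
          )
        }
      } else if (item$kind %in% c("count-threshold", "time-threshold")) {
        if (length(item$breaks) != length(item$points)) {
          stop_gusnet(
            sprintf("item %s: breaks and points lengths differ", sQuote(item$id)),
            class = "gusnet_invalid_scheme"
          )
        }
        if (is.unsorted(item$breaks, strictly = TRUE)) {
          stop_gusnet(
            sprintf("item %s: interval breaks must be strictly ascending",
                    sQuote(item$id)),
            class = "gusnet_invalid_scheme"
          )
        }
        if (any(diff(item$points) > 0)) {
          stop_gusnet(
            sprintf(paste0("item %s: measurement mapping is not monotone ",
                           "non-increasing (a worse performance scores more)"),
                    sQuote(item$id)),
            class = "gusnet_invalid_scheme"
          )
        }
        if (any(item$points < 0)) {
          stop_gusnet(
            sprintf("item %s awards negative points", sQuote(item$id)),
            class = "gusnet_invalid_scheme"
          )
        }
      } else {
        stop_gusnet(
          sprintf("item %s has unknown kind %s", sQuote(item$id),
                  sQuote(item$kind)),
          class = "gusnet_invalid_scheme"
        )
      }
    }
    attainable <- box_max(box)
    if (!isTRUE(all.equal(attainable, box$max_points))) {
      stop_gusnet(
        sprintf("box %d declares max_points %g but its items attain %g",
                box$box_id, box$max_points, attainable),
        class = "gusnet_invalid_scheme"
      )
    }
  }
  total <- sum(vapply(boxes, `[[`, 0, "max_points"))
  if (!isTRUE(all.equal(total, 50))) {
    stop_gusnet(
      sprintf("box maxima must sum to 50, found %g", total),
      class = "gusnet_invalid_scheme"
    )
  }
  scheme
}

#' @export
print.gus_scheme <- function(x, ...) {
  cat("<gus_scheme>", x$version, "\n")
  for (box in x$boxes) {
    cat(sprintf("  box %d (%s): %d item(s), max %g points\n",
                box$box_id, box$label, length(box$items), box$max_points))
  }
  cat(sprintf("  total: 0-%g points\n", scheme_max_total(x)))
  invisible(x)
}

#' Items of a scheme as a tibble
#'
#' One row per item with its box, kind and attainable point range; handy for
#' inspecting a scheme or joining against long-format answers.
#'
#' @param scheme A `gus_scheme`.
#' @return A tibble with columns `box_id`, `item`, `kind`, `min_points`,
#'   `max_points`.
#' @export
scheme_items <- function(scheme) {
  purrr::map_dfr(scheme$boxes, function(box) {
    tibble::tibble(
      box_id = box$box_id,
      item = names(box$items),
      kind = vapply(box$items, `[[`, "", "kind"),
      min_points = vapply(box$items, item_min, 0),
      max_points = vapply(box$items, item_max, 0)
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
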