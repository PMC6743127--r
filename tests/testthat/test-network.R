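test_that("edge counts reproduce the incomplete-block design", {
  cohort <- generate_cohort(paper_design(), simulation_params(seed = 21))
  net <- build_network(cohort$records)

  # Group 3's experienced stratum is the only source of this comparison
  bg <- dplyr::filter(net$edges, .data$device_a == "Breezhaler",
                      .data$device_b == "Genuair")
  expect_equal(bg$n[bg$stratum == "experienced"], 19L)
  expect_equal(bg$n[bg$stratum == "naive"], 11L)

  # Breezhaler-Spiromax is compared in groups 1 and 2 (both strata: 73)
  bs <- dplyr::filter(net$edges, .data$device_a == "Breezhaler",
                      .data$device_b == "Spiromax")
  expect_equal(sum(bs$n), 73L)
  expect_equal(bs$n[bs$stratum == "experienced"], 27L + 28L)

  # brute-force oracle: count pairs directly from the respondent roster
  brute <- table(unlist(lapply(
    split(cohort$records$device, cohort$records$respondent_id),
    function(d) if (length(d) >= 2) apply(utils::combn(sort(d), 2), 2,
                                          paste, collapse = "|")
  )))
  both <- dplyr::summarise(
    dplyr::group_by(net$edges, .data$device_a, .data$device_b),
    n = sum(.data$n), .groups = "drop"
  )
  expect_equal(both$n,
               as.integer(brute[paste(both$device_a, both$device_b,
                                      sep = "|")]))
})

test_that("degenerate record sets are handled", {
  one <- tibble::tibble(respondent_id = "R1", stratum = "experienced",
                        group = 3, device = "Breezhaler", gus_total = 30)
  net <- build_network(one)
  expect_equal(net$nodes, "Breezhaler")
  expect_equal(nrow(net$edges), 0L)

  dup <- dplyr::bind_rows(one, one)
  expect_error(build_network(dup), class = "gusnet_duplicate_observation")

  empty <- one[0, ]
  expect_equal(nrow(design_summary(build_network(empty))), 0L)
})

test_that("connectivity is assessed per stratum", {
  cohort <- generate_cohort(paper_design(), simulation_params(seed = 3))
  net <- build_network(cohort$records)
  expect_true(assert_connected(net, "experienced"))
  expect_true(assert_connected(net, "naive"))

  # two disjoint comparison groups are not a single evidence base
  disjoint <- tibble::tibble(
    respondent_id = rep(c("R1", "R2"), each = 2),
    stratum = "experienced", group = c(1, 1, 2, 2),
    device = c("Breezhaler", "Spiromax", "Diskus", "Turbohaler"),
    gus_total = 25
  )
  dnet <- build_network(disjoint)
  expect_false(assert_connected(dnet, "experienced", error = FALSE))
  err <- expect_error(assert_connected(dnet, "experienced"),
                      class = "gusnet_precondition_error")
  expect_match(conditionMessage(err), "Diskus")

  # a single group testing all seven devices is trivially connected
  all7 <- tibble::tibble(respondent_id = "R1", stratum = "naive", group = 1,
                         device = dpi_devices(), gus_total = 25)
  expect_true(assert_connected(build_network(all7), "naive", error = FALSE))
})

test_that("design summaries add up across groups and strata", {
  cohort <- generate_cohort(paper_design(), simulation_params(seed = 8))
  net <- build_network(cohort$records)
  s <- design_summary(net)
  expect_equal(s$n[s$group == "total" & s$stratum == "experienced"], 74L)
  expect_equal(s$n[s$group == "total" & s$stratum == "naive"], 29L)
  expect_equal(s$n[s$group == "total" & s$stratum == "all"], 103L)
  # per-group counts match the generator's ground-truth roster
  roster <- dplyr::count(cohort$truth$respondents, .data$group,
                         .data$stratum)
  per_group <- dplyr::filter(s, .data$group != "total")
  expect_equal(per_group$n[order(per_group$group, per_group$stratum)],
               roster$n[order(roster$group, roster$stratum)])
})

test_that("removing a respondent decrements exactly their pair counts", {
  cohort <- generate_cohort(paper_design(), simulation_params(seed = 13))
  recs <- cohort$records
  victim <- "R005"   # a group-1 respondent testing four devices
  tested <- sort(recs$device[recs$respondent_id == victim])
  expect_equal(length(tested), 4L)
  st <- recs$stratum[recs$respondent_id == victim][1]

  before <- build_network(recs)$edges
  after <- build_network(dplyr::filter(recs,
                                       .data$respondent_id != victim))$edges
  merged <- dplyr::full_join(
    before, after, by = c("device_a", "device_b", "stratum"),
    suffix = c("_b", "_a")
  )
  merged$n_a[is.na(merged$n_a)] <- 0L
  merged$drop <- merged$n_b - merged$n_a
  in_pair <- merged$device_a %in% tested & merged$device_b %in% tested &
    merged$stratum == st
  expect_true(all(merged$drop[in_pair] == 1L))
  expect_true(all(merged$drop[!in_pair] == 0L))
})
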