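test_that("unit aggregation takes the mean of non-NA answers", {
  instr <- mini_instrument(weights = c(4L, 2L), form = "room",
                           na_allowed = TRUE)
  forms <- forms_from_values(tibble::tibble(
    form_type = "room",
    unit_id = rep(paste0("room0", 1:3), each = 2),
    descriptor_id = rep(c("d1", "d2"), 3),
    value = c(2L, 2L, 2L, NA, 1L, NA)))
  eff <- aggregate_units(forms, instr)
  expect_equal(eff$value[eff$descriptor_id == "d1"], 5 / 3)
  expect_equal(eff$value[eff$descriptor_id == "d2"], 2)
  expect_equal(eff$n_units[eff$descriptor_id == "d2"], 1)

  # all units NA -> stays excluded
  all_na <- forms_from_values(tibble::tibble(
    form_type = "room", unit_id = c("room01", "room02"),
    descriptor_id = "d2", value = c(NA_integer_, NA_integer_)))
  expect_true(is.na(aggregate_units(all_na, instr)$value))

  # a single site form passes through unchanged
  site_instr <- mini_instrument(weights = 3L, form = "site")
  site <- forms_from_values(tibble::tibble(
    form_type = "site", unit_id = "site", descriptor_id = "d1",
    value = 1L))
  expect_equal(aggregate_units(site, site_instr)$value, 1)

  expect_error(aggregate_units(dplyr::bind_rows(forms, site), instr),
               "mixed")
})

test_that("per-room penalties are capped within the room, then averaged", {
  instr <- pwat_instrument(tibble::tibble(
    id = c("s1", "pen"), label = c("std", "penalty"),
    category = "behavioural", subcategory = "social behaviour",
    form = "room", weight = c(5L, 5L),
    response_kind = c("graded", "binary"),
    modifier = c("standard", "penalty")))
  forms <- forms_from_values(tibble::tibble(
    form_type = "room",
    unit_id = rep(c("room01", "room02"), each = 2),
    descriptor_id = rep(c("s1", "pen"), 2),
    value = c(2L, NA, 2L, NA),
    penalty_count = c(NA, 50L, NA, 4L)))
  eff <- aggregate_units(forms, instr)
  # room01 capped at 20, room02 at 4: mean 12 (not min(27, 20))
  expect_equal(attr(eff, "penalty"), 12)
  expect_false("pen" %in% eff$descriptor_id)
})

test_that("assess_facility scores a maximal facility at 100/600", {
  instr <- canonical_instrument()
  a <- suppressWarnings(assess_facility(maximal_forms(instr), instr))
  cats <- a$scores[a$scores$scope_kind == "category", ]
  expect_equal(nrow(cats), 6)
  expect_true(all(cats$percentage == 100))
  expect_equal(a$relative_total, 600)
  expect_equal(a$overall_percentage, 100)
  expect_equal(sum(a$relative$relative_score), a$relative_total)
})

test_that("duplicating every room form leaves the assessment unchanged", {
  instr <- canonical_instrument()
  set.seed(11)
  forms <- simulate_campaign(
    facility_profile("F1", theta = 0.55, n_rooms = 30, n_personnel = 30),
    instr, periods = "2022-Q1", seed = 11)
  rooms <- forms[forms$form_type == "room", ]
  dup <- dplyr::bind_rows(
    forms,
    rooms |> dplyr::mutate(unit_id = paste0(unit_id, "-copy")))
  a1 <- suppressWarnings(assess_facility(forms, instr))
  a2 <- suppressWarnings(assess_facility(dup, instr))
  expect_equal(a1$scores, a2$scores)
  expect_equal(a1$relative_total, a2$relative_total)
  expect_equal(a1$penalty, a2$penalty)
})

test_that("3 identical rooms assess the same as 1 such room", {
  instr <- canonical_instrument()
  one <- maximal_forms(instr, n_rooms = 1)
  room <- one[one$form_type == "room", ]
  three <- dplyr::bind_rows(
    one,
    room |> dplyr::mutate(unit_id = "room02"),
    room |> dplyr::mutate(unit_id = "room03"))
  a1 <- suppressWarnings(assess_facility(one, instr))
  a3 <- suppressWarnings(assess_facility(three, instr))
  expect_equal(a1$scores, a3$scores)
})

test_that("missing form types exclude their descriptors with a warning", {
  instr <- canonical_instrument()
  site_only <- maximal_forms(instr) |>
    dplyr::filter(form_type == "site")
  expect_warning(expect_warning(a <- assess_facility(site_only, instr),
                                "room"),
                 "unanswered")
  # culture of care is interview-only: undefined
  coc <- a$scores[a$scores$scope_kind == "category" &
                    a$scores$scope_name == "culture_of_care", ]
  expect_true(is.na(coc$percentage))
  expect_true(is.na(a$relative_total))
  expect_error(assess_facility(site_only[0, ], instr), "no forms")
})

test_that("with no NAs, scoring aggregated answers equals averaging per-room points", {
  set.seed(55)
  for (i in 1:20) {
    instr <- random_mini_instrument()
    x <- tibble::as_tibble(instr)
    x$form <- "room"
    instr <- pwat_instrument(x, penalty_config = attr(instr, "penalty_config"))
    n_rooms <- sample(2:4, 1)
    forms <- purrr::map(seq_len(n_rooms), function(r) {
      ans <- random_answers(instr, na_rate = 0)
      forms_from_values(tibble::tibble(
        form_type = "room", unit_id = sprintf("room%02d", r),
        descriptor_id = ans$descriptor_id, value = as.integer(ans$value)))
    }) |> dplyr::bind_rows()
    eff <- aggregate_units(forms, instr)
    pooled <- score_scope(eff, instr)
    per_room <- purrr::map_dbl(split(forms, forms$unit_id), function(rf) {
      oracle_breakdown(tibble::tibble(descriptor_id = rf$descriptor_id,
                                      value = rf$value), instr)$earned
    })
    expect_equal(pooled$earned, mean(per_room))
  }
})

test_that("benchmarking averages periods and passes single assessments through", {
  instr <- canonical_instrument()
  forms <- simulate_campaign(
    facility_profile("F1", theta = 0.6, n_rooms = 40, n_personnel = 40),
    instr, periods = c("2022-Q1", "2022-Q3"), seed = 2)
  a1 <- suppressWarnings(assess_facility(
    forms[forms$period == "2022-Q1", ], instr))
  a2 <- suppressWarnings(assess_facility(
    forms[forms$period == "2022-Q3", ], instr))

  bm <- benchmark_year(list(a1, a2))
  expect_equal(bm$overall_percentage,
               mean(c(a1$overall_percentage, a2$overall_percentage)))
  # metric-wise, the benchmark lies between the periods' min and max
  merged <- bm$scores |>
    dplyr::left_join(a1$scores |> dplyr::select(scope_kind, scope_name,
                                                p1 = percentage),
                     by = c("scope_kind", "scope_name")) |>
    dplyr::left_join(a2$scores |> dplyr::select(scope_kind, scope_name,
                                                p2 = percentage),
                     by = c("scope_kind", "scope_name")) |>
    dplyr::filter(!is.na(percentage))
  expect_true(all(merged$percentage >= pmin(merged$p1, merged$p2) - 1e-9))
  expect_true(all(merged$percentage <= pmax(merged$p1, merged$p2) + 1e-9))

  # single assessment passes through unchanged
  solo <- benchmark_year(a1)
  expect_equal(solo$overall_percentage, a1$overall_percentage)
  expect_equal(solo$relative_total, a1$relative_total)
  expect_equal(solo$contributing_periods, "2022-Q1")

  # idempotence on identical inputs
  twin <- benchmark_year(list(a1, a1))
  expect_equal(twin$overall_percentage, a1$overall_percentage)
  expect_equal(sort(twin$scores$percentage), sort(a1$scores$percentage))
  expect_error(benchmark_year(list()), "no assessments")
})

test_that("cross-site summary means lie within min-max and ignore order", {
  instr <- canonical_instrument()
  profs <- dplyr::bind_rows(
    facility_profile("FA", theta = 0.4, n_rooms = 30, n_personnel = 30),
    facility_profile("FB", theta = 0.7, n_rooms = 30, n_personnel = 30),
    facility_profile("FC", theta = 0.85, n_rooms = 30, n_personnel = 30))
  forms <- simulate_campaign(profs, instr, "2022-Q1", seed = 9)
  bms <- purrr::map(split(forms, forms$facility_id), function(ff) {
    benchmark_year(suppressWarnings(assess_facility(ff, instr)))
  })
  cs <- cross_site_summary(unname(bms))
  ok <- !is.na(cs$summary$mean)
  expect_true(all(cs$summary$mean[ok] >= cs$summary$min[ok] - 1e-9))
  expect_true(all(cs$summary$mean[ok] <= cs$summary$max[ok] + 1e-9))
  expect_equal(sort(cs$facilities$facility), c("A", "B", "C"))

  cs_perm <- cross_site_summary(unname(bms)[c(3, 1, 2)])
  expect_equal(dplyr::arrange(cs_perm$summary, scope_kind, scope_name),
               dplyr::arrange(cs$summary, scope_kind, scope_name))

  solo <- cross_site_summary(bms[[1]])
  expect_equal(solo$summary$mean, solo$summary$min)
})

test_that("room prevalence counts answering rooms only", {
  instr <- mini_instrument(weights = 3L, form = "room", na_allowed = TRUE)
  forms <- forms_from_values(tibble::tibble(
    form_type = "room", unit_id = sprintf("room%02d", 1:5),
    descriptor_id = "d1", value = c(2L, 1L, 0L, 2L, NA)))
  expect_equal(room_prevalence(forms, "d1"), 2 / 4)
  expect_equal(room_prevalence(forms, "d1", ~ .x == 0), 1 / 4)

  # 19 of 60 answering rooms show the finding: 31.7% at one decimal
  many <- forms_from_values(tibble::tibble(
    form_type = "room", unit_id = sprintf("room%02d", 1:60),
    descriptor_id = "d1", value = c(rep(1L, 19), rep(2L, 41))))
  expect_equal(round(100 * room_prevalence(many, "d1"), 1), 31.7)

  all_na <- forms_from_values(tibble::tibble(
    form_type = "room", unit_id = "room01", descriptor_id = "d1",
    value = NA_integer_))
  expect_true(is.na(room_prevalence(all_na, "d1")))
})
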