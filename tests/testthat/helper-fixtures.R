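# shared fixture builders: mini-instruments, random cases, and an
# independent brute-force scoring oracle used to cross-check score_scope

mini_instrument <- function(weights = c(5L, 3L),
                            category = "physical",
                            subcategory = "general body condition",
                            form = "room", na_allowed = FALSE, ...) {
  n <- length(weights)
  pwat_instrument(tibble::tibble(
    id = paste0("d", seq_len(n)),
    label = paste("descriptor", seq_len(n)),
    category = category, subcategory = subcategory,
    form = form, weight = weights, na_allowed = na_allowed), ...)
}

# a random valid instrument of at most `max_n` descriptors spanning up to
# three categories, with occasional bonus descriptors
random_mini_instrument <- function(max_n = 12) {
  n <- sample(2:max_n, 1)
  cats <- sample(pwat_categories, sample(1:3, 1))
  category <- sample(cats, n, replace = TRUE)
  subcategory <- paste0(category, "-sub", sample(1:2, n, replace = TRUE))
  modifier <- sample(c("standard", "bonus"), n, replace = TRUE,
                     prob = c(0.85, 0.15))
  if (!any(modifier == "standard")) modifier[1] <- "standard"
  pwat_instrument(tibble::tibble(
    id = paste0("d", seq_len(n)),
    label = paste("descriptor", seq_len(n)),
    category = category, subcategory = subcategory,
    form = sample(pwat_form_types, n, replace = TRUE),
    weight = sample(1:5, n, replace = TRUE),
    response_kind = sample(c("graded", "binary"), n, replace = TRUE),
    modifier = modifier,
    na_allowed = TRUE))
}

# random effective answers for an instrument (values may be fractional, as
# produced by across-room aggregation)
random_answers <- function(instrument, na_rate = 0.2,
                           fractional = FALSE) {
  x <- tibble::as_tibble(instrument)
  v <- if (fractional) stats::runif(nrow(x), 0, 2) else
    sample(0:2, nrow(x), replace = TRUE)
  v[x$response_kind == "binary" & !fractional] <-
    sample(c(0, 2), sum(x$response_kind == "binary"), replace = TRUE)
  v[stats::runif(nrow(x)) < na_rate] <- NA_real_
  tibble::tibble(descriptor_id = x$id, value = v)
}

# independent oracle: plain loop over descriptor rows, no shared code path
oracle_breakdown <- function(answers, instrument, ids_in_scope = NULL,
                             penalty = 0) {
  x <- as.data.frame(instrument)
  if (!is.null(ids_in_scope)) x <- x[x$id %in% ids_in_scope, ]
  earned <- 0; possible <- 0; bonus <- 0
  for (i in seq_len(nrow(x))) {
    v <- answers$value[match(x$id[i], answers$descriptor_id)]
    if (length(v) == 0 || is.na(v)) next
    if (x$modifier[i] == "standard") {
      earned <- earned + v * x$weight[i]
      possible <- possible + 2 * x$weight[i]
    } else if (x$modifier[i] == "bonus") {
      bonus <- bonus + v * x$weight[i]
    }
  }
  pct <- if (possible > 0) 100 * (earned + bonus - penalty) / possible
         else NA_real_
  list(earned = earned, possible = possible, bonus = bonus,
       percentage = pct)
}

# a full set of forms with every standard descriptor at its maximum and
# bonus/penalty descriptors unanswered
maximal_forms <- function(instrument, facility_id = "FMAX",
                          period = "2022-Q1", n_rooms = 1,
                          n_interviews = 3) {
  std <- dplyr::filter(tibble::as_tibble(instrument),
                       modifier == "standard")
  units <- dplyr::bind_rows(
    tibble::tibble(form_type = "room",
                   unit_id = sprintf("room%02d", seq_len(n_rooms))),
    tibble::tibble(form_type = "site", unit_id = "site"),
    tibble::tibble(form_type = "interview",
                   unit_id = sprintf("interview%02d",
                                     seq_len(n_interviews))))
  dplyr::inner_join(units,
                    dplyr::select(std, id, form_type = form),
                    by = "form_type", relationship = "many-to-many") |>
    dplyr::transmute(facility_id = facility_id, period = period,
                     form_type, unit_id, descriptor_id = id, value = 2L,
                     penalty_count = NA_integer_)
}

# forms built from an explicit per-unit answer table
forms_from_values <- function(values, facility_id = "F1",
                              period = "2022-Q1") {
  tibble::as_tibble(values) |>
    dplyr::mutate(facility_id = facility_id, period = period,
                  penalty_count = if ("penalty_count" %in% names(values))
                    penalty_count else NA_integer_,
                  .before = 1) |>
    dplyr::select(facility_id, period, form_type, unit_id, descriptor_id,
                  value, penalty_count)
}
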