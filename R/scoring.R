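#' Map an observed prevalence to the 0/1/2 graded score
#'
#' Graded descriptors are answered from the prevalence of the item or
#' activity: rarely present (< 25%) scores 0, moderately present (25-75%)
#' scores 1, obviously present (> 75%) scores 2. The middle band is closed
#' at both ends, so 0.25 and 0.75 both score 1.
#'
#' @param p Numeric vector of prevalences in `[0, 1]`.
#' @return Integer vector of scores in `{0, 1, 2}`.
#' @export
#' @examples
#' proportion_to_score(c(0.1, 0.5, 0.9))
proportion_to_score <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("prevalence must be numeric within [0, 1]")
  }
  ifelse(p < 0.25, 0L, ifelse(p <= 0.75, 1L, 2L))
}

#' Points contributed by one answered descriptor
#'
#' The scoring rule multiplies the answer by the descriptor's welfare
#' weight. A non-applicable (NA) answer is excluded: it contributes to
#' neither the earned points nor the possible-points denominator, which this
#' function signals by returning NA. The penalty descriptor is never scored
#' here; use [penalty_points()].
#'
#' @param value Answer values (0, 1, 2, or NA), recycled with `weight`.
#' @param weight Welfare weights (1-5).
#' @param modifier Descriptor modifiers; an error if any is `"penalty"`.
#' @return Numeric vector: `value * weight`, NA where excluded.
#' @export
#' @examples
#' descriptor_points(c(2, NA, 0), c(5, 4, 3))
descriptor_points <- function(value, weight, modifier = "standard") {
  if (any(modifier == "penalty")) {
    abort("the penalty descriptor is not scored by answer × weight; use penalty_points()")
  }
  as.numeric(value) * as.numeric(weight)
}

#' Capped score reduction for singly housed animals
#'
#' The single penalty descriptor subtracts points from the final score in
#' proportion to the number of singly housed animals in a room, with the
#' maximum reduction capped (20 points by default).
#'
#' @param n_singly_housed Non-negative integer vector of singly housed
#'   animals per room.
#' @param rate Points subtracted per animal (default 1).
#' @param cap Maximum reduction per room (default 20).
#' @return Numeric vector of reductions, each in `[0, cap]`.
#' @export
#' @examples
#' penalty_points(c(0, 7, 50))
penalty_points <- function(n_singly_housed, rate = 1, cap = 20) {
  if (any(is.na(n_singly_housed)) || any(n_singly_housed < 0)) {
    abort("the singly-housed count must be a non-negative number")
  }
  pmin(n_singly_housed * rate, cap)
}

#' Score one scope from effective answers
#'
#' Computes the score breakdown for a subcategory, a category, or the whole
#' instrument from per-descriptor effective answers (raw 0/1/2 answers, or
#' the fractional across-unit means produced by [aggregate_units()]; NA
#' means excluded). Earned points sum `value * weight` over the scope's
#' standard descriptors; possible points sum `weight * 2` over the
#' non-excluded standard descriptors; bonus descriptors add points without
#' enlarging the denominator (so percentages above 100 are possible); the
#' penalty, if given, is subtracted from the numerator. A scope whose
#' possible points are 0 reports an NA percentage rather than an error.
#'
#' @param answers Tibble with columns `descriptor_id` and `value`
#'   (numeric; NA = excluded/non-applicable).
#' @param instrument A [pwat_instrument()].
#' @param scope_kind `"total"`, `"category"` or `"subcategory"`.
#' @param scope_name Category or subcategory name (for non-total scopes).
#' @param penalty Points already capped (see [penalty_points()]) to subtract
#'   at this scope; default 0.
#' @return One-row tibble: `scope_kind`, `scope_name`, `earned`, `possible`,
#'   `bonus`, `penalty`, `percentage` (full precision; NA when undefined).
#' @export
#' @examples
#' instr <- pwat_instrument(tibble::tibble(
#'   id = c("a", "b"), label = c("first", "second"),
#'   category = "physical", subcategory = "general body condition",
#'   form = "room", weight = c(5L, 3L)))
#' score_scope(tibble::tibble(descriptor_id = c("a", "b"), value = c(2, 1)),
#'             instr)  # earned 13 of 16: 81.25%
score_scope <- function(answers, instrument,
                        scope_kind = c("total", "category", "subcategory"),
                        scope_name = NULL, penalty = 0) {
  scope_kind <- match.arg(scope_kind)
  sc <- scope_descriptors(instrument, scope_kind, scope_name)
  instr_ids <- tibble::as_tibble(instrument)$id
  stray <- setdiff(answers$descriptor_id, instr_ids)
  if (length(stray) > 0) {
    warn(paste0("ignoring answers for descriptor(s) not in the instrument: ",
                paste(stray, collapse = ", ")))
  }
  joined <- sc |>
    dplyr::select("id", "weight", "modifier") |>
    dplyr::left_join(answers |> dplyr::select("descriptor_id", "value"),
                     by = c(id = "descriptor_id"))

  std <- joined |> dplyr::filter(.data$modifier == "standard")
  bon <- joined |> dplyr::filter(.data$modifier == "bonus")
  earned <- sum(std$value * std$weight, na.rm = TRUE)
  possible <- sum(2 * std$weight[!is.na(std$value)])
  bonus <- sum(bon$value * bon$weight, na.rm = TRUE)
  pct <- if (possible > 0) {
    100 * (earned + bonus - penalty) / possible
  } else {
    NA_real_
  }
  tibble::tibble(scope_kind = scope_kind,
                 scope_name = scope_name %||% "total",
                 earned = earned, possible = as.numeric(possible),
                 bonus = bonus, penalty = as.numeric(penalty),
                 percentage = pct)
}

# breakdowns for every subcategory, category, and the total, applying the
# configured penalty at the scopes named in penalty_config$apply_to
score_all_scopes <- function(answers, instrument, penalty = 0) {
  x <- tibble::as_tibble(instrument)
  cfg <- attr(instrument, "penalty_config") %||% list(apply_to = "total")
  apply_to <- cfg$apply_to %||% "total"
  pen_for <- function(kind, name) {
    if ((kind == "total" && "total" %in% apply_to) ||
        (kind == "category" && name %in% apply_to)) penalty else 0
  }
  subcats <- x |> dplyr::distinct(.data$category, .data$subcategory)
  sub_rows <- purrr::map2(subcats$category, subcats$subcategory,
                          function(cat, sub) {
    score_scope(answers, instrument, "subcategory", sub,
                penalty = pen_for("subcategory", sub)) |>
      dplyr::mutate(category = cat)
  }) |> dplyr::bind_rows()
  cats <- intersect(pwat_categories, unique(x$category))
  cat_rows <- purrr::map(cats, function(cat) {
    score_scope(answers, instrument, "category", cat,
                penalty = pen_for("category", cat)) |>
      dplyr::mutate(category = cat)
  }) |> dplyr::bind_rows()
  tot <- score_scope(answers, instrument, "total",
                     penalty = pen_for("total", "total")) |>
    dplyr::mutate(category = NA_character_)
  dplyr::bind_rows(sub_rows, cat_rows, tot) |>
    dplyr::relocate("category", .after = "scope_name")
}
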