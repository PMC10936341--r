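#' Number of rooms to assess for a facility
#'
#' Facilities assess approximately 10% of their occupied primate rooms, with
#' a minimum of three and a maximum of ten. The 10% is rounded half-up and
#' clamped to `[3, 10]`; a facility with fewer than three occupied rooms
#' assesses all of them (with a warning, since the stated minimum cannot be
#' met).
#'
#' @param n_occupied_rooms Positive integer vector of occupied room counts.
#' @return Integer vector of rooms to assess.
#' @export
#' @examples
#' plan_room_sample(c(12, 60, 200))  # 3, 6, 10
plan_room_sample <- function(n_occupied_rooms) {
  if (any(is.na(n_occupied_rooms)) || any(n_occupied_rooms <= 0)) {
    abort("the occupied room count must be a positive integer")
  }
  n <- as.integer(n_occupied_rooms)
  out <- pmin(pmax(round_half_up(0.10 * n), 3L), 10L)
  small <- n < 3L
  if (any(small)) {
    warn(paste0("facility has fewer than 3 occupied rooms; ",
                "assessing all of them"))
    out[small] <- n[small]
  }
  as.integer(out)
}

#' Number of culture-of-care interviews to conduct
#'
#' Between three and six interviews are conducted depending on the number of
#' personnel working with primates. The tier rule is `ceiling(n / 10)`
#' clamped to `[3, 6]` — monotone in the personnel count and reaching both
#' endpoints. With fewer than three eligible personnel, everyone is
#' interviewed (with a warning).
#'
#' @param n_personnel Positive integer vector of personnel counts.
#' @param per_tier Personnel per additional interview (default 10).
#' @return Integer vector of interviews to conduct.
#' @export
#' @examples
#' plan_interviews(c(5, 35, 100))  # 3, 4, 6
plan_interviews <- function(n_personnel, per_tier = 10) {
  if (any(is.na(n_personnel)) || any(n_personnel <= 0)) {
    abort("the personnel count must be a positive integer")
  }
  n <- as.integer(n_personnel)
  out <- pmin(pmax(ceiling(n / per_tier), 3L), 6L)
  small <- n < 3L
  if (any(small)) {
    warn("facility has fewer than 3 eligible personnel; interviewing all of them")
    out[small] <- n[small]
  }
  as.integer(out)
}

#' Sampling plan for a table of facilities
#'
#' Applies [plan_room_sample()] and [plan_interviews()] to facility
#' metadata. Which rooms to pick is a human decision — the plan carries a
#' reminder to cover a variety of housing types, animal purposes and study
#' types.
#'
#' @param facilities Data frame with columns `facility_id`,
#'   `n_occupied_rooms`, `n_personnel`.
#' @return Tibble with `facility_id`, `rooms_to_assess`,
#'   `interviews_to_conduct`, and a `note` column.
#' @export
plan_campaign <- function(facilities) {
  x <- tibble::as_tibble(facilities)
  required <- c("facility_id", "n_occupied_rooms", "n_personnel")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("facility table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  x |>
    dplyr::transmute(
      facility_id = .data$facility_id,
      rooms_to_assess = plan_room_sample(.data$n_occupied_rooms),
      interviews_to_conduct = plan_interviews(.data$n_personnel),
      note = paste("select rooms covering a variety of housing types,",
                   "animal purposes, study types and study lengths"))
}
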