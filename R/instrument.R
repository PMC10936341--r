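#' Build an instrument from a descriptor table
#'
#' An instrument is the versioned registry of weighted welfare descriptors,
#' together with the single-housing penalty configuration and (optionally)
#' the declared per-subcategory maxima used as a validation cross-check.
#' It is represented as a tibble of descriptors (one row per descriptor)
#' carrying the version, penalty configuration and maxima as attributes, so
#' it pipes directly into `dplyr` verbs.
#'
#' @param descriptors Data frame with columns `id`, `label`, `category`,
#'   `subcategory`, `form`, `weight` and optionally `response_kind`
#'   (default `"graded"`), `modifier` (default `"standard"`) and
#'   `na_allowed` (default `FALSE`).
#' @param version Version string stored with the instrument.
#' @param penalty_config List with elements
#'   `points_per_singly_housed_animal` (default 1), `cap_points` (default 20)
#'   and `apply_to` (scopes the penalty is subtracted at; default `"total"`,
#'   may also include a category name such as `"behavioural"`).
#' @param subcategory_maxima Optional named numeric vector (or NULL) mapping
#'   subcategory to its declared maximum points; validated against
#'   `sum(weight * 2)` over the subcategory's standard descriptors.
#' @param validate If TRUE (default) abort when [validate_instrument()]
#'   reports violations.
#'
#' @return A `pwat_instrument`: a tibble of descriptors with attributes
#'   `version`, `penalty_config` and `subcategory_maxima`.
#' @seealso [load_instrument()], [canonical_instrument()],
#'   [validate_instrument()], [max_points()]
#' @export
#' @examples
#' mini <- pwat_instrument(tibble::tibble(
#'   id = c("a", "b"), label = c("first", "second"),
#'   category = "physical", subcategory = "general body condition",
#'   form = "room", weight = c(5L, 3L)))
#' max_points(mini)  # (5 + 3) * 2
pwat_instrument <- function(descriptors, version = "custom",
                            penalty_config = list(),
                            subcategory_maxima = NULL,
                            validate = TRUE) {
  descriptors <- tibble::as_tibble(descriptors)
  required <- c("id", "label", "category", "subcategory", "form", "weight")
  missing <- setdiff(required, names(descriptors))
  if (length(missing) > 0) {
    abort(paste0("descriptor table lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"response_kind" %in% names(descriptors)) descriptors$response_kind <- "graded"
  if (!"modifier" %in% names(descriptors)) descriptors$modifier <- "standard"
  if (!"na_allowed" %in% names(descriptors)) descriptors$na_allowed <- FALSE
  descriptors <- descriptors |>
    dplyr::mutate(
      dplyr::across(c("id", "label", "category", "subcategory", "form",
                      "response_kind", "modifier"), as.character),
      weight = as.integer(.data$weight),
      na_allowed = as.logical(.data$na_allowed)
    ) |>
    dplyr::select(dplyr::all_of(c(required, "response_kind", "modifier",
                                  "na_allowed")))

  cfg <- penalty_config
  cfg$points_per_singly_housed_animal <-
    cfg$points_per_singly_housed_animal %||% 1
  cfg$cap_points <- cfg$cap_points %||% 20
  cfg$apply_to <- cfg$apply_to %||% "total"

  maxima <- subcategory_maxima
  if (!is.null(maxima)) {
    maxima <- setNames(as.numeric(maxima), names(maxima))
  }

  instr <- structure(descriptors,
                     version = version,
                     penalty_config = cfg,
                     subcategory_maxima = maxima,
                     class = c("pwat_instrument", class(tibble::tibble())))
  if (validate) {
    report <- validate_instrument(instr)
    if (nrow(report) > 0) {
      abort(paste0("invalid instrument:\n",
                   paste0("- ", report$message, collapse = "\n")))
    }
  }
  instr
}

#' @export
print.pwat_instrument <- function(x, ...) {
  cfg <- attr(x, "penalty_config")
  cat(sprintf("<pwat_instrument v%s: %d descriptors, %d categories, %d subcategories>\n",
              attr(x, "version"), nrow(x),
              dplyr::n_distinct(x$category), dplyr::n_distinct(x$subcategory)))
  cat(sprintf("  penalty: %g point(s)/singly housed animal, capped at %g; applied to: %s\n",
              cfg$points_per_singly_housed_animal, cfg$cap_points,
              paste(cfg$apply_to, collapse = ", ")))
  NextMethod()
}

#' Load an instrument definition file
#'
#' Reads an instrument from JSON (one object with `version`,
#' `penalty_config`, optional `subcategory_maxima`, and a `descriptors`
#' array) or from the flat CSV dialect (one row per descriptor, fixed header
#' `id,label,category,subcategory,form,weight,response_kind,modifier,na_allowed`;
#' CSV carries no penalty configuration or maxima, so defaults apply).
#' Descriptors keep file order. The file is validated on load and malformed
#' or rule-violating content is an error naming the offending record.
#'
#' @param path Path to the instrument file.
#' @param format `"json"`, `"csv"`, or `"auto"` (default; by extension).
#' @return A [pwat_instrument()].
#' @export
load_instrument <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) abort(paste0("no such instrument file: ", path))
  if (format == "json") {
    obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e) abort(paste0(
                      "cannot parse instrument JSON '", path, "': ",
                      conditionMessage(e))))
    if (is.null(obj$descriptors)) {
      abort(paste0("instrument JSON '", path, "' has no 'descriptors' array"))
    }
    maxima <- obj$subcategory_maxima
    if (!is.null(maxima)) maxima <- unlist(maxima)
    pwat_instrument(tibble::as_tibble(obj$descriptors),
                    version = obj$version %||% "unversioned",
                    penalty_config = as.list(obj$penalty_config),
                    subcategory_maxima = maxima)
  } else {
    descriptors <- tryCatch(
      readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
      error = function(e) abort(paste0("cannot parse instrument CSV '", path,
                                       "': ", conditionMessage(e))))
    pwat_instrument(descriptors, version = "unversioned")
  }
}

#' Write an instrument definition file
#'
#' The JSON format round-trips all fields (version, penalty configuration,
#' subcategory maxima, descriptors in order); the CSV dialect writes the
#' descriptor table only.
#'
#' @param instrument A [pwat_instrument()].
#' @param path Output path.
#' @param format `"json"`, `"csv"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_instrument <- function(instrument, path,
                             format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    maxima <- attr(instrument, "subcategory_maxima")
    obj <- list(
      version = attr(instrument, "version"),
      penalty_config = attr(instrument, "penalty_config"),
      subcategory_maxima = if (is.null(maxima)) NULL else as.list(maxima),
      descriptors = tibble::as_tibble(instrument)
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
  } else {
    readr::write_csv(tibble::as_tibble(instrument), path, progress = FALSE)
  }
  invisible(path)
}

#' The canonical 133-descriptor instrument shipped with the package
#'
#' Loads the packaged instrument definition: 133 weighted descriptors in six
#' categories (physical, behavioural, environmental, training, procedural,
#' culture of care) split across room, site and interview forms, with four
#' bonus descriptors, the single capped single-housing penalty descriptor,
#' and self-consistent subcategory maxima. The descriptor wording is a
#' synthetic transcription: it mirrors the published instrument's structure,
#' weights range and scoring semantics, while the per-item text is authored
#' for this package (the original table is not redistributable).
#'
#' @return A [pwat_instrument()] with 133 descriptors.
#' @export
canonical_instrument <- function() {
  load_instrument(system.file("extdata", "pwat_instrument_synthetic.json",
                              package = "pwat", mustWork = TRUE))
}

#' Validate an instrument
#'
#' Pure check returning a tibble of violations (empty means valid): weights
#' within 1-5, known categories and forms, known response kinds and
#' modifiers, binary descriptors never graded-only values, unique ids, at
#' most one penalty descriptor, and — where subcategory maxima are declared —
#' agreement of each maximum with `sum(weight * 2)` over that subcategory's
#' standard descriptors.
#'
#' @param instrument A [pwat_instrument()] (or plain descriptor tibble).
#' @return Tibble with columns `rule`, `where`, `message`; zero rows if valid.
#' @export
validate_instrument <- function(instrument) {
  x <- tibble::as_tibble(instrument)
  v <- list()
  bad_row <- function(rule, where, message) {
    tibble::tibble(rule = rule, where = where, message = message)
  }

  miss <- x |>
    dplyr::filter(is.na(.data$id) | is.na(.data$weight) |
                    is.na(.data$category) | is.na(.data$form))
  if (nrow(miss) > 0) {
    v[[length(v) + 1]] <- bad_row(
      "missing field", miss$id,
      paste0("descriptor '", miss$id, "' has missing required fields"))
  }

  bad_w <- x |> dplyr::filter(!.data$weight %in% 1:5)
  if (nrow(bad_w) > 0) {
    v[[length(v) + 1]] <- bad_row(
      "weight range", bad_w$id,
      paste0("descriptor '", bad_w$id, "' has weight ", bad_w$weight,
             " outside 1-5"))
  }

  bad_cat <- x |> dplyr::filter(!.data$category %in% pwat_categories)
  if (nrow(bad_cat) > 0) {
    v[[length(v) + 1]] <- bad_row(
      "unknown category", bad_cat$id,
      paste0("descriptor '", bad_cat$id, "' has unknown category '",
             bad_cat$category, "'"))
  }

  bad_form <- x |> dplyr::filter(!.data$form %in% pwat_form_types)
  if (nrow(bad_form) > 0) {
    v[[length(v) + 1]] <- bad_row(
      "unknown form", bad_form$id,
      paste0("descriptor '", bad_form$id, "' has unknown form '",
             bad_form$form, "'"))
  }

  bad_rk <- x |> dplyr::filter(!.data$response_kind %in% c("graded", "binary"))
  if (nrow(bad_rk) > 0) {
    v[[length(v) + 1]] <- bad_row(
      "unknown response kind", bad_rk$id,
      paste0("descriptor '", bad_rk$id, "' has unknown response_kind '",
             bad_rk$response_kind, "'"))
  }

  bad_mod <- x |>
    dplyr::filter(!.data$modifier %in% c("standard", "bonus", "penalty"))
  if (nrow(bad_mod) > 0) {
    v[[length(v) + 1]] <- bad_row(
      "unknown modifier", bad_mod$id,
      paste0("descriptor '", bad_mod$id, "' has unknown modifier '",
             bad_mod$modifier, "'"))
  }

  dup <- x$id[duplicated(x$id)]
  if (length(dup) > 0) {
    dup <- unique(dup)
    v[[length(v) + 1]] <- bad_row(
      "duplicate id", dup, paste0("duplicate descriptor id '", dup, "'"))
  }

  n_pen <- sum(x$modifier == "penalty", na.rm = TRUE)
  if (n_pen > 1) {
    v[[length(v) + 1]] <- bad_row(
      "multiple penalties", "<instrument>",
      paste0(n_pen, " penalty descriptors present; at most one is allowed"))
  }

  maxima <- attr(instrument, "subcategory_maxima")
  if (!is.null(maxima) && length(maxima) > 0) {
    computed <- x |>
      dplyr::filter(.data$modifier == "standard") |>
      dplyr::group_by(.data$subcategory) |>
      dplyr::summarise(max_points = sum(.data$weight * 2), .groups = "drop")
    decl <- tibble::tibble(subcategory = names(maxima),
                           declared = as.numeric(maxima))
    mism <- decl |>
      dplyr::left_join(computed, by = "subcategory") |>
      dplyr::mutate(max_points = dplyr::coalesce(.data$max_points, 0)) |>
      dplyr::filter(.data$declared != .data$max_points)
    if (nrow(mism) > 0) {
      v[[length(v) + 1]] <- bad_row(
        "maximum mismatch", mism$subcategory,
        paste0("subcategory '", mism$subcategory, "' declares maximum ",
               mism$declared, " but standard descriptors sum to ",
               mism$max_points))
    }
  }

  if (length(v) == 0) {
    tibble::tibble(rule = character(), where = character(),
                   message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Maximum achievable points for a scope
#'
#' The possible-points denominator: `sum(weight * 2)` over the scope's
#' standard descriptors restricted to the applicable set. Bonus and penalty
#' descriptors never enter the denominator, and descriptors answered
#' non-applicable are removed from it (pass the applicable ids).
#'
#' @param instrument A [pwat_instrument()].
#' @param scope_kind `"total"`, `"category"` or `"subcategory"`.
#' @param scope_name Category or subcategory name (ignored for `"total"`).
#' @param applicable_ids Descriptor ids counted as applicable; default all.
#' @return Non-negative number of points.
#' @export
max_points <- function(instrument, scope_kind = c("total", "category",
                                                  "subcategory"),
                       scope_name = NULL, applicable_ids = NULL) {
  scope_kind <- match.arg(scope_kind)
  x <- scope_descriptors(instrument, scope_kind, scope_name)
  if (is.null(applicable_ids)) applicable_ids <- x$id
  x |>
    dplyr::filter(.data$modifier == "standard",
                  .data$id %in% applicable_ids) |>
    dplyr::summarise(p = sum(.data$weight * 2)) |>
    dplyr::pull("p") |>
    (\(p) if (length(p) == 0 || is.na(p)) 0 else as.numeric(p))()
}

# restrict a descriptor table to one scope; unknown names are an error
scope_descriptors <- function(instrument, scope_kind, scope_name) {
  x <- tibble::as_tibble(instrument)
  if (scope_kind == "total") return(x)
  if (is.null(scope_name)) {
    abort(paste0("scope_name is required for scope_kind = '", scope_kind, "'"))
  }
  col <- if (scope_kind == "category") x$category else x$subcategory
  if (!scope_name %in% col) {
    abort(paste0("unknown ", scope_kind, " '", scope_name, "'"))
  }
  x[col == scope_name, ]
}
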