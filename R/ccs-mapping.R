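#' Normalize an ICD code string
#'
#' Strips dots and upper-cases, reconciling the "250.00"/"25000" dialects
#' found in the wild. Used for both code-map keys and event codes before
#' lookup.
#'
#' @param code Character vector of ICD codes.
#' @return Normalized character vector.
#' @export
normalize_icd <- function(code) {
  toupper(gsub(".", "", code, fixed = TRUE))
}

#' Load an ICD-to-CCS code map
#'
#' Reads a comma-separated mapping table with columns `icd_code`, `ccs_id`,
#' `ccs_label` describing the many-to-one grouping of ICD-9/ICD-10 diagnosis
#' codes into single-level CCS categories. Keys are normalized with
#' [normalize_icd()]; rows whose normalized keys collide with conflicting
#' `ccs_id` values are rejected (the licensed HCUP tables are not bundled —
#' users supply their own extract, or use the synthetic map emitted by
#' [generate_cohort()]).
#'
#' @param path Path to the delimited mapping file.
#' @return A `code_map` tibble with columns `icd_code` (normalized),
#'   `ccs_id`, `ccs_label`.
#' @export
load_code_map <- function(path) {
  raw <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character())))
  missing <- setdiff(c("icd_code", "ccs_id", "ccs_label"), names(raw))
  if (length(missing) > 0)
    abort(paste0("code map ", path, " lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "comorbidnet_format_error")
  as_code_map(raw)
}

#' Coerce a data frame to a validated code map
#'
#' @param x Data frame with columns `icd_code`, `ccs_id`, `ccs_label`.
#' @return A `code_map` tibble with normalized keys.
#' @export
as_code_map <- function(x) {
  cm <- tibble::as_tibble(x) |>
    dplyr::mutate(icd_code = normalize_icd(.data$icd_code)) |>
    dplyr::distinct()
  if (any(is.na(cm$ccs_id)) || any(cm$ccs_id == ""))
    abort("code map contains empty ccs_id entries",
          class = "comorbidnet_format_error")
  conflicts <- cm |>
    dplyr::distinct(.data$icd_code, .data$ccs_id) |>
    dplyr::count(.data$icd_code) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflicts) > 0)
    abort(paste0("conflicting CCS assignments for normalized ICD code(s): ",
                 paste(conflicts$icd_code, collapse = ", ")),
          class = "comorbidnet_mapping_conflict")
  cm <- dplyr::distinct(cm, .data$icd_code, .keep_all = TRUE)
  class(cm) <- c("code_map", class(cm))
  cm
}

#' Map ICD-coded events to CCS categories
#'
#' Replaces each event's ICD code by its single-level CCS category, preserving
#' patient, date and event order. Distinct unmapped codes are tallied into a
#' report attached as the `"unmapped"` attribute (see [unmapped_report()]).
#'
#' @param events Tibble of ICD-coded diagnosis events.
#' @param code_map A `code_map` from [load_code_map()] / [as_code_map()].
#' @param unmapped_policy `"drop"` silently drops events whose code has no
#'   mapping (tallied in the report); `"error"` fails on the first offender.
#' @return The CCS-coded events tibble (`code_system = "CCS"`), with the
#'   unmapped report as attribute.
#' @export
map_events <- function(events, code_map, unmapped_policy = c("drop", "error")) {
  unmapped_policy <- match.arg(unmapped_policy)
  if (!inherits(code_map, "code_map")) code_map <- as_code_map(code_map)

  key <- normalize_icd(events$code)
  idx <- match(key, code_map$icd_code)
  miss <- is.na(idx)
  if (any(miss) && unmapped_policy == "error")
    abort(paste0("unmapped ICD code: ", key[which(miss)[1]]),
          class = "comorbidnet_unmapped_error")
  report <- tibble::tibble(code = key[miss]) |>
    dplyr::count(.data$code, name = "n_events") |>
    dplyr::arrange(.data$code)

  out <- events[!miss, , drop = FALSE]
  out$code <- code_map$ccs_id[idx[!miss]]
  out$code_system <- rep("CCS", nrow(out))
  out <- tibble::as_tibble(out)
  attr(out, "unmapped") <- report
  out
}

#' @rdname map_events
#' @param mapped Result of [map_events()].
#' @export
unmapped_report <- function(mapped) {
  rep <- attr(mapped, "unmapped")
  if (is.null(rep)) tibble::tibble(code = character(), n_events = integer())
  else rep
}

#' Rank CCS categories by patient prevalence
#'
#' Prevalence is the number of DISTINCT patients with at least one event of
#' the code — repeat diagnoses never inflate it — reported with the percentage
#' relative to all distinct patients in the input. Ordered by descending
#' patient count, ties broken by ascending code so the top-k boundary is
#' deterministic.
#'
#' @param events CCS-coded events tibble.
#' @param k Number of top categories to keep.
#' @return Tibble `code`, `n_patients`, `pct_patients` with at most `k` rows.
#' @export
top_k_prevalence <- function(events, k = 50) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1)
    abort("`k` must be a positive integer", class = "comorbidnet_param_error")
  n_total <- dplyr::n_distinct(events$patient_id)
  events |>
    dplyr::distinct(.data$patient_id, .data$code) |>
    dplyr::count(.data$code, name = "n_patients") |>
    dplyr::arrange(dplyr::desc(.data$n_patients), .data$code) |>
    dplyr::mutate(pct_patients = 100 * .data$n_patients / n_total) |>
    head(n = k)
}

#' Select the analysis cohort
#'
#' Applies the two cohort filters in order: keep patients with at least one
#' event of a top-prevalence code, then keep those with strictly more than
#' `min_unique` distinct CCS codes over ALL their events (so `min_unique = 5`
#' retains patients with >= 6 distinct codes; a patient with exactly 5 is
#' excluded). Returns the retained patients' full event streams.
#'
#' @param events CCS-coded events tibble.
#' @param top_codes Character vector of top-prevalence codes (e.g. the `code`
#'   column of [top_k_prevalence()]).
#' @param min_unique Exclusive lower bound on distinct codes per patient.
#' @param unique_within_top If `TRUE`, count uniqueness only over top-code
#'   events instead of all events (the alternative reading; default `FALSE`).
#' @return `cohort_selection`: the retained events tibble, with attributes
#'   `retained_patients`, `top_codes` and `filter_params`.
#' @export
filter_cohort <- function(events, top_codes, min_unique = 5,
                          unique_within_top = FALSE) {
  if (length(top_codes) == 0)
    abort("`top_codes` must be non-empty", class = "comorbidnet_param_error")

  has_top <- events |>
    dplyr::filter(.data$code %in% top_codes) |>
    dplyr::distinct(.data$patient_id)

  uniq_base <- if (unique_within_top)
    dplyr::filter(events, .data$code %in% top_codes) else events
  enough <- uniq_base |>
    dplyr::filter(.data$patient_id %in% has_top$patient_id) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_codes = dplyr::n_distinct(.data$code), .groups = "drop") |>
    dplyr::filter(.data$n_codes > min_unique)

  retained <- sort(enough$patient_id)
  out <- dplyr::filter(events, .data$patient_id %in% retained)
  attr(out, "retained_patients") <- retained
  attr(out, "top_codes") <- top_codes
  attr(out, "filter_params") <- list(k = length(top_codes),
                                     min_unique_exclusive = min_unique,
                                     unique_within_top = unique_within_top)
  class(out) <- c("cohort_selection", class(out))
  out
}

#' @export
print.cohort_selection <- function(x, ...) {
  p <- attr(x, "filter_params")
  cat("<cohort_selection> ", length(attr(x, "retained_patients")),
      " patients retained (top-", p$k, " membership, > ",
      p$min_unique_exclusive, " unique codes), ", nrow(x), " events\n",
      sep = "")
  NextMethod()
}
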