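#' Configure a synthetic longitudinal diagnosis cohort
#'
#' Builds and validates the configuration for [generate_cohort()]. The
#' generator emulates the structure of an outpatient EHR registry: per-patient
#' visit streams over a follow-up of median ~3 years (sd ~0.5 years), latent
#' comorbidity clusters with elevated within-cluster co-occurrence, synthetic
#' ICD child codes with many-to-one grouping into CCS-style categories, and
#' directional inter-diagnosis lags with a same-day probability atom.
#'
#' @param n_patients Number of patients to simulate.
#' @param n_ccs_codes Number of CCS-style category codes (`"C01"`, `"C02"`, ...).
#' @param icd_per_ccs Number of synthetic ICD child codes per category
#'   (children are named `"<code>.<k>"`).
#' @param n_clusters Number of planted comorbidity clusters; codes are split
#'   into contiguous, near-equal blocks.
#' @param within_cluster_co_prob Probability that a patient carrying one
#'   cluster disease also receives each other disease of the same cluster.
#' @param background_rate Mean number of random noise diagnoses per patient
#'   (Poisson). Noise codes are drawn from codes not named in `lag_specs`, so
#'   planted first-occurrence lags stay exact.
#' @param lag_specs Optional tibble/data frame with columns `code_a`, `code_b`,
#'   `mean_lag_days`, `sd_lag_days`, `direction_prob`. For patients carrying
#'   both codes, the signed lag (first `code_b` minus first `code_a`, days) is
#'   `+N(mean, sd)` with probability `direction_prob` and `-N(mean, sd)`
#'   otherwise, with an atom of mass `same_day_prob` at exactly 0 days.
#'   Both codes of a pair must lie in the same planted cluster.
#' @param followup_median_years,followup_sd_years Follow-up length law:
#'   normal, truncated below at 0.5 years.
#' @param same_day_prob Probability that a planted pair is first diagnosed on
#'   the same day.
#' @param seed Integer seed for the root generator; per-patient substreams are
#'   derived deterministically so patient-level draws are reproducible.
#'
#' @return A `generator_config` list.
#' @export
#' @examples
#' cfg <- generator_config(n_patients = 50, seed = 1)
#' cohort <- generate_cohort(cfg)
#' cohort$events
generator_config <- function(n_patients,
                             n_ccs_codes = 30,
                             icd_per_ccs = 3,
                             n_clusters = 5,
                             within_cluster_co_prob = 0.8,
                             background_rate = 3,
                             lag_specs = NULL,
                             followup_median_years = 3,
                             followup_sd_years = 0.5,
                             same_day_prob = 0.05,
                             seed = 1L) {
  chk_count <- function(x, name, min = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
      abort(paste0("invalid generator configuration: `", name,
                   "` must be an integer >= ", min),
            class = "comorbidnet_config_error")
  }
  chk_prob <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      abort(paste0("invalid generator configuration: `", name,
                   "` must be a probability in [0, 1]"),
            class = "comorbidnet_config_error")
  }
  chk_count(n_patients, "n_patients", min = 0)
  chk_count(n_ccs_codes, "n_ccs_codes")
  chk_count(icd_per_ccs, "icd_per_ccs")
  chk_count(n_clusters, "n_clusters")
  chk_prob(within_cluster_co_prob, "within_cluster_co_prob")
  chk_prob(same_day_prob, "same_day_prob")
  if (!is.numeric(background_rate) || background_rate < 0)
    abort("invalid generator configuration: `background_rate` must be >= 0",
          class = "comorbidnet_config_error")
  if (followup_median_years <= 0 || followup_sd_years < 0)
    abort(paste0("invalid generator configuration: `followup_median_years` must",
                 " be positive and `followup_sd_years` non-negative"),
          class = "comorbidnet_config_error")
  if (n_clusters > n_ccs_codes)
    abort("invalid generator configuration: `n_clusters` exceeds `n_ccs_codes`",
          class = "comorbidnet_config_error")

  codes <- sprintf("C%02d", seq_len(n_ccs_codes))
  if (!is.null(lag_specs)) {
    lag_specs <- tibble::as_tibble(lag_specs)
    need <- c("code_a", "code_b", "mean_lag_days", "sd_lag_days", "direction_prob")
    if (!all(need %in% names(lag_specs)))
      abort(paste0("invalid generator configuration: `lag_specs` must have columns ",
                   paste(need, collapse = ", ")),
            class = "comorbidnet_config_error")
    bad <- setdiff(c(lag_specs$code_a, lag_specs$code_b), codes)
    if (length(bad) > 0)
      abort(paste0("invalid generator configuration: `lag_specs` names unknown ",
                   "codes: ", paste(bad, collapse = ", ")),
            class = "comorbidnet_config_error")
    if (any(lag_specs$sd_lag_days < 0) ||
        any(lag_specs$direction_prob < 0 | lag_specs$direction_prob > 1))
      abort(paste0("invalid generator configuration: `lag_specs` needs ",
                   "sd_lag_days >= 0 and direction_prob in [0, 1]"),
            class = "comorbidnet_config_error")
  }

  structure(
    list(n_patients = as.integer(n_patients),
         n_ccs_codes = as.integer(n_ccs_codes),
         icd_per_ccs = as.integer(icd_per_ccs),
         n_clusters = as.integer(n_clusters),
         within_cluster_co_prob = within_cluster_co_prob,
         background_rate = background_rate,
         lag_specs = lag_specs,
         followup_median_years = followup_median_years,
         followup_sd_years = followup_sd_years,
         same_day_prob = same_day_prob,
         seed = as.integer(seed),
         codes = codes),
    class = "generator_config")
}

# contiguous near-equal cluster blocks over the code list
cluster_assignment <- function(codes, n_clusters) {
  n <- length(codes)
  sizes <- rep(n %/% n_clusters, n_clusters)
  extra <- n %% n_clusters
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  stats::setNames(rep(seq_len(n_clusters), times = sizes), codes)
}

# deterministic per-patient substream seed derived from the root seed
patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed %% 100000L) * 2654435761 + as.numeric(i) * 97561) %%
               2147483629) + 1L
}

empty_events <- function() {
  tibble::tibble(patient_id = character(), date = as.Date(character()),
                 code = character(), code_system = character())
}

#' Generate a synthetic cohort with planted comorbidity and lag structure
#'
#' Simulates per-patient diagnosis streams. Each patient draws a follow-up
#' length from a truncated normal law, seeds one disease uniformly at random,
#' acquires each other disease of the seed's cluster with probability
#' `within_cluster_co_prob`, receives Poisson background noise diagnoses at
#' uniform dates, and — for every configured lag pair the patient carries —
#' has first-diagnosis dates placed according to the directional lag law.
#' A parallel ICD-level stream replaces each category code with a uniformly
#' chosen synthetic child code, so that grouping the ICD stream through the
#' returned code map recovers the category stream event-for-event.
#'
#' @param config A [generator_config()].
#' @return An `ehr_cohort` list with elements
#'   \describe{
#'     \item{events}{tibble of category-level diagnosis events
#'       (`patient_id`, `date`, `code`, `code_system = "CCS"`).}
#'     \item{icd_events}{the same events at ICD child-code granularity.}
#'     \item{demographics}{one row per patient: age, sex, follow-up window.}
#'     \item{code_map}{tibble `icd_code`, `ccs_id`, `ccs_label` for the
#'       synthetic children.}
#'     \item{ground_truth}{list with `cluster_of` (named vector code ->
#'       cluster id) and `lag_specs` (the planted pairs).}
#'   }
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config"))
    abort("`config` must be built with generator_config()",
          class = "comorbidnet_config_error")

  codes <- config$codes
  cluster_of <- cluster_assignment(codes, config$n_clusters)
  lag_specs <- config$lag_specs
  if (!is.null(lag_specs)) {
    cross <- cluster_of[lag_specs$code_a] != cluster_of[lag_specs$code_b]
    if (any(cross))
      abort(paste0("invalid generator configuration: `lag_specs` pairs must lie ",
                   "within one planted cluster: ",
                   paste(lag_specs$code_a[cross], lag_specs$code_b[cross],
                         sep = "-", collapse = ", ")),
            class = "comorbidnet_config_error")
  }
  lag_codes <- if (is.null(lag_specs)) character() else
    unique(c(lag_specs$code_a, lag_specs$code_b))
  noise_alphabet <- setdiff(codes, lag_codes)

  code_map <- tidyr::expand_grid(ccs_id = codes,
                                 k = seq_len(config$icd_per_ccs)) |>
    dplyr::mutate(icd_code = paste0(.data$ccs_id, ".", .data$k),
                  ccs_label = paste("Synthetic condition", .data$ccs_id)) |>
    dplyr::select("icd_code", "ccs_id", "ccs_label")
  children <- split(code_map$icd_code, code_map$ccs_id)

  ground_truth <- list(cluster_of = cluster_of,
                       lag_specs = lag_specs,
                       seed = config$seed)

  if (config$n_patients == 0) {
    return(structure(
      list(events = empty_events(), icd_events = empty_events(),
           demographics = tibble::tibble(patient_id = character(),
                                         age = integer(), sex = character(),
                                         followup_start = as.Date(character()),
                                         followup_days = integer()),
           code_map = code_map, ground_truth = ground_truth,
           config = config),
      class = "ehr_cohort"))
  }

  origin <- as.Date("2012-01-01")
  per_patient <- vector("list", config$n_patients)
  demo <- vector("list", config$n_patients)

  for (i in seq_len(config$n_patients)) {
    res <- withr::with_seed(patient_seed(config$seed, i), {
      pid <- sprintf("P%06d", i)
      fy <- max(0.5, rnorm(1, config$followup_median_years,
                           config$followup_sd_years))
      L <- max(2L, as.integer(round(fy * 365.25)))
      start <- origin + sample.int(1461L, 1L) - 1L

      # planted disease set: one uniform seed code + cluster co-occurrence
      seed_code <- sample(codes, 1L)
      mates <- codes[cluster_of == cluster_of[[seed_code]] & codes != seed_code]
      carried <- c(seed_code,
                   mates[runif(length(mates)) < config$within_cluster_co_prob])
      day_of <- stats::setNames(sample.int(L, length(carried),
                                           replace = TRUE) - 1L, carried)

      # enforce the directional lag law for carried pairs
      if (!is.null(lag_specs)) {
        for (r in seq_len(nrow(lag_specs))) {
          a <- lag_specs$code_a[r]; b <- lag_specs$code_b[r]
          if (!(a %in% carried && b %in% carried)) next
          if (runif(1) < config$same_day_prob) {
            delta <- 0L
          } else {
            sign <- if (runif(1) < lag_specs$direction_prob[r]) 1L else -1L
            mag <- max(0L, as.integer(round(
              rnorm(1, lag_specs$mean_lag_days[r], lag_specs$sd_lag_days[r]))))
            if (mag > L - 1L) mag <- L - 1L
            delta <- sign * mag
          }
          anchor <- sample.int(L - abs(delta), 1L) - 1L
          if (delta >= 0L) {          # a first, b delta days later
            day_of[[a]] <- anchor
            day_of[[b]] <- anchor + delta
          } else {
            day_of[[b]] <- anchor
            day_of[[a]] <- anchor - delta
          }
        }
      }

      ev_code <- names(day_of)
      ev_day <- unname(day_of)

      n_noise <- if (config$background_rate > 0) rpois(1, config$background_rate) else 0L
      if (n_noise > 0 && length(noise_alphabet) > 0) {
        ev_code <- c(ev_code, sample(noise_alphabet, n_noise, replace = TRUE))
        ev_day <- c(ev_day, sample.int(L, n_noise, replace = TRUE) - 1L)
      }

      icd <- vapply(ev_code, function(cc) {
        kids <- children[[cc]]
        kids[[sample.int(length(kids), 1L)]]
      }, character(1), USE.NAMES = FALSE)

      age <- as.integer(round(min(max(rnorm(1, 50, 22), 0), 100)))
      sex <- sample(c("female", "male"), 1L, prob = c(0.573, 0.427))

      list(events = tibble::tibble(patient_id = pid, date = start + ev_day,
                                   code = ev_code, icd = icd),
           demo = tibble::tibble(patient_id = pid, age = age, sex = sex,
                                 followup_start = start,
                                 followup_days = L))
    })
    per_patient[[i]] <- res$events
    demo[[i]] <- res$demo
  }

  all_ev <- dplyr::bind_rows(per_patient) |>
    dplyr::arrange(.data$patient_id, .data$date, .data$code)

  events <- dplyr::transmute(all_ev, patient_id = .data$patient_id,
                             date = .data$date, code = .data$code,
                             code_system = "CCS")
  icd_events <- dplyr::transmute(all_ev, patient_id = .data$patient_id,
                                 date = .data$date, code = .data$icd,
                                 code_system = "ICD10")

  structure(
    list(events = events, icd_events = icd_events,
         demographics = dplyr::bind_rows(demo),
         code_map = code_map, ground_truth = ground_truth, config = config),
    class = "ehr_cohort")
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat("<ehr_cohort> ", nrow(x$demographics), " patients, ",
      nrow(x$events), " events, ",
      length(unique(x$events$code)), " codes, ",
      x$config$n_clusters, " planted clusters\n", sep = "")
  invisible(x)
}

#' Write / read diagnosis event tables
#'
#' Events are serialized as comma-separated text with columns
#' `patient_id,date,code,code_system` and ISO-8601 dates, the package's
#' interchange format for diagnosis streams.
#'
#' @param events Tibble of diagnosis events.
#' @param path File path.
#' @return `write_events()` returns `path` invisibly; `read_events()` returns
#'   the events tibble.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("patient_id", "date", "code", "code_system") %in% names(events)))
  readr::write_csv(events[, c("patient_id", "date", "code", "code_system")], path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    date = readr::col_date(format = "%Y-%m-%d"),
    code = readr::col_character(),
    code_system = readr::col_character())))
  probs <- readr::problems(ev)
  if (nrow(probs) > 0)
    abort(paste0("malformed event row(s) at line(s) ",
                 paste(unique(probs$row), collapse = ", "), " in ", path),
          class = "comorbidnet_parse_error")
  missing <- setdiff(c("patient_id", "date", "code", "code_system"), names(ev))
  if (length(missing) > 0)
    abort(paste0("event file ", path, " lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "comorbidnet_parse_error")
  ev
}
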