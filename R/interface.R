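#' Configure an end-to-end pipeline run
#'
#' Collects every stage parameter with the analysis defaults: top 50
#' prevalent categories, more-than-5 unique-code cohort filter, 32-dimensional
#' CBOW embeddings with window 5 and min_count 1, correlation threshold 0.5
#' at category (CCS) granularity or 0.8 at ICD granularity, and 9
#' hierarchical clusters.
#'
#' @param granularity `"CCS"` (category-level analysis) or `"ICD"`
#'   (fine-grained code-level analysis).
#' @param top_k Number of top-prevalence categories defining cohort
#'   membership.
#' @param min_unique Exclusive lower bound on distinct categories per
#'   retained patient.
#' @param dim,window,min_count,negative,epochs Embedding hyperparameters
#'   (see [train_cbow()]).
#' @param ccs_threshold,icd_threshold Inclusive correlation thresholds for
#'   the edge list at each granularity.
#' @param k_clusters Number of hierarchical clusters.
#' @param seed Integer seed driving simulation and training.
#' @param simulate Optional named list of [generator_config()] arguments;
#'   when present the pipeline simulates its input cohort.
#' @param events_path,codemap_path Input paths used when `simulate` is
#'   `NULL`: a diagnosis event table (see [read_events()]) and, for
#'   ICD-coded input, an ICD-to-CCS map (see [load_code_map()]).
#' @param icd_allowlist Optional character vector restricting the ICD-level
#'   analysis to a subset of codes (default: all mapped codes).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(granularity = c("CCS", "ICD"),
                            top_k = 50, min_unique = 5,
                            dim = 32, window = 5, min_count = 1,
                            negative = 5, epochs = 5,
                            ccs_threshold = 0.5, icd_threshold = 0.8,
                            k_clusters = 9, seed = 1L,
                            simulate = NULL,
                            events_path = NULL, codemap_path = NULL,
                            icd_allowlist = NULL) {
  granularity <- match.arg(granularity)
  if (is.null(simulate) && is.null(events_path))
    abort("either `simulate` or `events_path` must be given",
          class = "comorbidnet_config_error")
  structure(
    list(granularity = granularity, top_k = top_k, min_unique = min_unique,
         dim = dim, window = window, min_count = min_count,
         negative = negative, epochs = epochs,
         ccs_threshold = ccs_threshold, icd_threshold = icd_threshold,
         k_clusters = k_clusters, seed = as.integer(seed),
         simulate = simulate, events_path = events_path,
         codemap_path = codemap_path, icd_allowlist = icd_allowlist),
    class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML round trip is exact: `read_pipeline_config(write_pipeline_config(x))`
#' reproduces `x`.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  if (!is.null(x$simulate) && !is.null(x$simulate$lag_specs))
    x$simulate$lag_specs <- purrr::transpose(as.list(
      tibble::as_tibble(x$simulate$lag_specs)))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$simulate) && !is.null(x$simulate$lag_specs))
    x$simulate$lag_specs <- dplyr::bind_rows(
      lapply(x$simulate$lag_specs, tibble::as_tibble))
  do.call(pipeline_config, x)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
          class = "comorbidnet_stage_error", parent = e))
}

#' Run the full comorbidity-discovery pipeline
#'
#' Executes the stages in order — simulate/ingest, ICD-to-CCS mapping,
#' prevalence ranking, cohort filtering, sentence building, CBOW embedding,
#' association analysis, and per-edge time-delay analysis — writing every
#' stage artifact plus a run manifest into `out_dir`. Reruns with the same
#' configuration and seed reproduce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list of in-memory stage results (`cohort`, `events`,
#'   `prevalence`, `selection`, `model`, `assoc`, `delays`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config"))
    abort("`config` must be built with pipeline_config()",
          class = "comorbidnet_config_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(out_dir, f)

  # --- ingest -----------------------------------------------------------
  cohort <- NULL; code_map <- NULL
  if (!is.null(config$simulate)) {
    cohort <- run_stage("simulate", {
      sim <- config$simulate
      sim$seed <- sim$seed %||% config$seed
      generate_cohort(do.call(generator_config, sim))
    })
    ccs_events <- cohort$events
    icd_events <- cohort$icd_events
    code_map <- cohort$code_map
    write_events(icd_events, art("events_icd.csv"))
    readr::write_csv(cohort$demographics, art("demographics.csv"))
    readr::write_csv(code_map, art("code_map.csv"))
    jsonlite::write_json(
      list(cluster_of = as.list(cohort$ground_truth$cluster_of),
           lag_specs = cohort$ground_truth$lag_specs,
           seed = cohort$ground_truth$seed),
      art("ground_truth.json"), auto_unbox = TRUE, digits = NA)
  } else {
    raw <- run_stage("ingest", read_events(config$events_path))
    if (any(raw$code_system != "CCS")) {
      code_map <- run_stage("ingest", {
        if (is.null(config$codemap_path))
          abort("ICD-coded input requires `codemap_path`")
        load_code_map(config$codemap_path)
      })
      icd_events <- raw
      ccs_events <- run_stage("map", map_events(raw, code_map, "drop"))
    } else {
      ccs_events <- raw
      icd_events <- raw
    }
  }
  write_events(ccs_events, art("events_ccs.csv"))

  # --- cohort selection (always at category level) ----------------------
  prevalence <- run_stage("prevalence",
                          top_k_prevalence(ccs_events, config$top_k))
  readr::write_csv(prevalence, art("prevalence.csv"))
  selection <- if (nrow(prevalence) == 0) {
    out <- ccs_events[0, , drop = FALSE]
    attr(out, "retained_patients") <- character()
    out
  } else {
    run_stage("filter",
              filter_cohort(ccs_events, prevalence$code, config$min_unique))
  }
  write_events(selection, art("cohort_events.csv"))

  # --- analysis granularity --------------------------------------------
  retained <- attr(selection, "retained_patients")
  if (config$granularity == "ICD") {
    ana_events <- dplyr::filter(icd_events, .data$patient_id %in% retained)
    if (!is.null(config$icd_allowlist))
      ana_events <- dplyr::filter(ana_events,
                                  .data$code %in% config$icd_allowlist)
    threshold <- config$icd_threshold
  } else {
    ana_events <- selection
    threshold <- config$ccs_threshold
  }

  empty_run <- nrow(ana_events) == 0
  sentences <- if (!empty_run)
    run_stage("sentences", build_sentences(ana_events)) else NULL
  trainable <- !empty_run && any(lengths(sentences$tokens) >= 2) &&
    dplyr::n_distinct(unlist(sentences$tokens)) >= 2

  model <- NULL; assoc <- NULL; delays <- NULL
  if (trainable) {
    model <- run_stage("embed",
                       train_cbow(sentences, dim = config$dim,
                                  window = config$window,
                                  min_count = config$min_count,
                                  negative = config$negative,
                                  epochs = config$epochs,
                                  seed = config$seed))
    write_cbow(model, art("model.txt"))
    k <- min(config$k_clusters, nrow(model$vocab))
    assoc <- run_stage("associate",
                       analyze_associations(model, threshold = threshold,
                                            k = k))
    write_corr_csv(assoc$corr, art("correlation.csv"))
    readr::write_csv(assoc$clusters, art("clusters.csv"))
    readr::write_csv(assoc$projection, art("projection.csv"))
    write_edges_csv(assoc$edges, art("edges.csv"))
    write_edges_sif(assoc$edges, art("edges.sif"))
    if (nrow(assoc$edges) > 0)
      write_edges_graphml(assoc$edges, art("edges.graphml"))
    delays <- run_stage("delays", delays_for_edges(ana_events, assoc$edges))
    readr::write_csv(delays, art("delay_summaries.csv"))
    if (nrow(delays) > 0)
      write_delay_graphml(delays, art("delay_network.graphml"))
  } else {
    # degenerate cohort: emit empty artifacts so report() stays total
    readr::write_csv(tibble::tibble(code_a = character(), code_b = character(),
                                    r = numeric()), art("edges.csv"))
    readr::write_csv(tibble::tibble(code = character(), cluster = integer()),
                     art("clusters.csv"))
    readr::write_csv(tibble::tibble(code_a = character(), code_b = character(),
                                    n_patients = integer()),
                     art("delay_summaries.csv"))
  }

  manifest <- list(
    package = "comorbidnet",
    version = as.character(utils::packageVersion("comorbidnet")),
    seed = config$seed,
    granularity = config$granularity,
    config = unclass(config)[c("granularity", "top_k", "min_unique", "dim",
                               "window", "min_count", "negative", "epochs",
                               "ccs_threshold", "icd_threshold", "k_clusters",
                               "seed")],
    config_hash = rlang::hash(unclass(config)),
    n_patients_input = dplyr::n_distinct(ccs_events$patient_id),
    n_patients_retained = length(retained),
    n_events_analysed = nrow(ana_events),
    stages_run = if (trainable)
      c("ingest", "prevalence", "filter", "sentences", "embed", "associate",
        "delays")
    else c("ingest", "prevalence", "filter"),
    artifacts = sort(setdiff(list.files(out_dir), "manifest.json")))
  jsonlite::write_json(manifest, art("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, events = ccs_events,
                 prevalence = prevalence, selection = selection,
                 model = model, assoc = assoc, delays = delays,
                 manifest = manifest))
}

#' Summarise a completed pipeline run
#'
#' Recomputes headline counts from the stage artifacts of a run directory:
#' cohort sizes, demographics, top-prevalence table, edge count at the run's
#' threshold, cluster table and per-pair delay summaries. Missing artifacts
#' are listed rather than raised as errors.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return A `pipeline_report` list.
#' @export
report <- function(run_dir) {
  want <- c("manifest.json", "events_ccs.csv", "prevalence.csv",
            "cohort_events.csv", "edges.csv", "clusters.csv",
            "delay_summaries.csv")
  present <- file.exists(file.path(run_dir, want))
  missing <- want[!present]

  get_csv <- function(f, ...) {
    p <- file.path(run_dir, f)
    if (!file.exists(p)) return(NULL)
    suppressWarnings(readr::read_csv(p, show_col_types = FALSE, ...))
  }
  manifest <- if (file.exists(file.path(run_dir, "manifest.json")))
    jsonlite::read_json(file.path(run_dir, "manifest.json"),
                        simplifyVector = TRUE) else NULL
  events <- get_csv("events_ccs.csv")
  cohort_events <- get_csv("cohort_events.csv")
  demo <- get_csv("demographics.csv")

  demo_summary <- if (!is.null(demo) && nrow(demo) > 0)
    tibble::tibble(n_patients = nrow(demo),
                   mean_age = mean(demo$age),
                   pct_female = 100 * mean(demo$sex == "female"),
                   median_followup_years = median(demo$followup_days) / 365.25)
  else tibble::tibble(n_patients = if (is.null(demo)) NA_integer_ else 0L,
                      mean_age = NA_real_, pct_female = NA_real_,
                      median_followup_years = NA_real_)

  edges <- get_csv("edges.csv")
  clusters <- get_csv("clusters.csv")
  delays <- get_csv("delay_summaries.csv")

  structure(
    list(manifest = manifest,
         missing_artifacts = missing,
         n_patients_input = if (is.null(events)) 0L else
           dplyr::n_distinct(events$patient_id),
         n_events_input = if (is.null(events)) 0L else nrow(events),
         n_patients_retained = if (is.null(cohort_events)) 0L else
           dplyr::n_distinct(cohort_events$patient_id),
         demographics = demo_summary,
         prevalence = get_csv("prevalence.csv"),
         n_edges = if (is.null(edges)) 0L else nrow(edges),
         edges = edges,
         clusters = clusters,
         n_clusters = if (is.null(clusters) || nrow(clusters) == 0) 0L else
           dplyr::n_distinct(clusters$cluster),
         delay_summaries = delays),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("  patients (input/retained): ", x$n_patients_input, " / ",
      x$n_patients_retained, "\n", sep = "")
  cat("  events: ", x$n_events_input, "\n", sep = "")
  cat("  edges at threshold: ", x$n_edges, "; clusters: ", x$n_clusters,
      "\n", sep = "")
  if (length(x$missing_artifacts) > 0)
    cat("  MISSING artifacts: ", paste(x$missing_artifacts, collapse = ", "),
        "\n", sep = "")
  invisible(x)
}
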