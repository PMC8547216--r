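mk_events <- function(...) {
  rows <- list(...)
  tibble::tibble(
    patient_id = vapply(rows, `[[`, character(1), 1),
    date = as.Date(vapply(rows, `[[`, character(1), 2)),
    code = vapply(rows, `[[`, character(1), 3),
    code_system = "CCS")
}

test_that("delays subtract first occurrences, day-resolved", {
  ev <- mk_events(c("P1", "2015-01-10", "A"), c("P1", "2015-11-06", "B"),
                  c("P1", "2016-01-01", "A"),   # repeat A ignored (first used)
                  c("P2", "2015-05-05", "A"), c("P2", "2015-05-05", "B"),
                  c("P3", "2015-02-02", "A"))   # lacks B: excluded
  pd <- pair_delays(ev, "A", "B")
  expect_equal(pd$patient_id, c("P1", "P2"))
  expect_equal(pd$delta_days, c(300L, 0L))
  expect_error(pair_delays(ev, "A", "A"), class = "comorbidnet_param_error")
})

test_that("swapping the pair negates every delay elementwise", {
  co <- generate_cohort(generator_config(n_patients = 150, seed = 51))
  ab <- pair_delays(co$events, "C01", "C02")
  ba <- pair_delays(co$events, "C02", "C01")
  expect_equal(ab$patient_id, ba$patient_id)
  expect_equal(ab$delta_days, -ba$delta_days)
})

test_that("the directional summary matches hand enumeration", {
  s <- structure(tibble::tibble(patient_id = paste0("P", 1:4),
                                delta_days = c(10L, -20L, 0L, 30L)),
                 code_a = "A", code_b = "B",
                 class = c("pair_delay_sample", "tbl_df", "tbl", "data.frame"))
  out <- delay_summary(s)
  expect_equal(out$pct_a_earlier, 50)
  expect_equal(out$pct_b_earlier, 25)
  expect_equal(out$pct_same_day, 25)
  expect_equal(out$median_days_a_earlier, 20)
  expect_equal(out$median_days_b_earlier, 20)
  expect_equal(out$pct_a_earlier + out$pct_b_earlier + out$pct_same_day, 100)
})

test_that("all-same-day pairs yield undefined medians, not zeros", {
  s <- structure(tibble::tibble(patient_id = paste0("P", 1:3),
                                delta_days = c(0L, 0L, 0L)),
                 code_a = "A", code_b = "B",
                 class = c("pair_delay_sample", "tbl_df", "tbl", "data.frame"))
  out <- delay_summary(s)
  expect_equal(out$pct_same_day, 100)
  expect_true(is.na(out$median_days_a_earlier))
  expect_true(is.na(out$median_days_b_earlier))
  expect_error(delay_summary(s[0, ]), class = "comorbidnet_param_error")
})

test_that("summaries of (a,b) and (b,a) swap percentages and medians", {
  co <- generate_cohort(generator_config(
    n_patients = 300, n_ccs_codes = 10, n_clusters = 2,
    within_cluster_co_prob = 1, seed = 53,
    lag_specs = small_lag_spec("C01", "C02", 200, 80, 0.7)))
  ab <- delay_summary(pair_delays(co$events, "C01", "C02"))
  ba <- delay_summary(pair_delays(co$events, "C02", "C01"))
  expect_equal(ab$pct_a_earlier, ba$pct_b_earlier)
  expect_equal(ab$pct_b_earlier, ba$pct_a_earlier)
  expect_equal(ab$pct_same_day, ba$pct_same_day)
  expect_equal(ab$median_days_a_earlier, ba$median_days_b_earlier)
  expect_equal(ab$median_days_b_earlier, ba$median_days_a_earlier)
  expect_equal(ab$pct_a_earlier + ab$pct_b_earlier + ab$pct_same_day, 100,
               tolerance = 1e-9)
})

test_that("planted directional lags are recovered within sampling error", {
  co <- generate_cohort(generator_config(
    n_patients = 600, n_ccs_codes = 10, n_clusters = 2,
    within_cluster_co_prob = 1, same_day_prob = 0, seed = 57,
    lag_specs = small_lag_spec("C01", "C02", 300, 50, 1)))
  pd <- pair_delays(co$events, "C01", "C02")
  m <- nrow(pd)
  expect_gt(m, 100)
  expect_true(all(pd$delta_days > 0))
  expect_lt(abs(mean(pd$delta_days) - 300), 2 * 50 / sqrt(m))
})

test_that("the delay KDE matches the direct Gaussian sum and normalizes", {
  s <- structure(tibble::tibble(patient_id = paste0("P", 1:7),
                                delta_days = c(120L, 150L, 90L, -40L, -60L,
                                               200L, 130L)),
                 code_a = "A", code_b = "B",
                 class = c("pair_delay_sample", "tbl_df", "tbl", "data.frame"))
  k <- delay_kde(s)
  bws <- attr(k, "bandwidth")
  for (dir in unique(k$direction)) {
    cur <- k[k$direction == dir, ]
    x <- if (dir == "a_earlier") s$delta_days[s$delta_days > 0]
         else -s$delta_days[s$delta_days < 0]
    expect_equal(cur$density, bf_kde(x, cur$grid_days, bws[[dir]]),
                 tolerance = 1e-10)
    trap <- sum(diff(cur$grid_days) *
                  (head(cur$density, -1) + cur$density[-1]) / 2)
    expect_lt(abs(trap - 1), 1e-3)
    expect_true(all(cur$density >= 0))
  }
})

test_that("a point mass peaks at the nearest grid point and lone directions warn", {
  s <- structure(tibble::tibble(patient_id = paste0("P", 1:5),
                                delta_days = rep(100L, 5)),
                 code_a = "A", code_b = "B",
                 class = c("pair_delay_sample", "tbl_df", "tbl", "data.frame"))
  expect_warning(k <- delay_kde(s, bandwidth = 10), "b_earlier")
  expect_equal(unique(k$direction), "a_earlier")
  peak <- k$grid_days[which.max(k$density)]
  expect_equal(peak, k$grid_days[which.min(abs(k$grid_days - 100))])

  zeros <- structure(tibble::tibble(patient_id = "P1", delta_days = 0L),
                     code_a = "A", code_b = "B",
                     class = c("pair_delay_sample", "tbl_df", "tbl",
                               "data.frame"))
  expect_error(delay_kde(zeros), class = "comorbidnet_param_error")
})

test_that("edge-wise delay tables cover every edge and export as GraphML", {
  co <- generate_cohort(generator_config(n_patients = 200, seed = 59))
  edges <- tibble::tibble(code_a = c("C01", "C05"), code_b = c("C02", "C28"))
  tab <- delays_for_edges(co$events, edges)
  expect_equal(nrow(tab), 2)
  ok <- tab$n_patients > 0
  expect_equal(tab$pct_a_earlier[ok] + tab$pct_b_earlier[ok] +
                 tab$pct_same_day[ok], rep(100, sum(ok)))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_delay_graphml(tab, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), 2)
})
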