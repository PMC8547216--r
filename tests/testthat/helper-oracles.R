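# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Pearson r by the textbook formula sum((x-xbar)(y-ybar)) / ((n-1) sx sy)
bf_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    ((n - 1) * sqrt(sum((x - mean(x))^2) / (n - 1)) *
       sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# distinct-patient prevalence tally by explicit loops over patients
bf_prevalence <- function(events) {
  codes <- sort(unique(events$code))
  pats <- unique(events$patient_id)
  counts <- vapply(codes, function(cc) {
    sum(vapply(pats, function(p)
      any(events$code[events$patient_id == p] == cc), logical(1)))
  }, integer(1))
  data.frame(code = codes, n_patients = counts)
}

# two-pass cohort filter: top-code membership, then > min_unique distinct codes
bf_filter <- function(events, top_codes, min_unique) {
  pats <- unique(events$patient_id)
  keep <- vapply(pats, function(p) {
    mine <- events$code[events$patient_id == p]
    any(mine %in% top_codes) && length(unique(mine)) > min_unique
  }, logical(1))
  sort(pats[keep])
}

# direct Gaussian kernel sum (1/mh) sum phi((g - x_i)/h)
bf_kde <- function(x, grid, h) {
  sapply(grid, function(g) sum(exp(-((g - x) / h)^2 / 2) /
                                 sqrt(2 * pi)) / (length(x) * h))
}

# co-occurring unordered code pairs per patient, tallied by explicit loops
bf_cooccurrence_pairs <- function(events) {
  out <- list()
  for (p in unique(events$patient_id)) {
    codes <- sort(unique(events$code[events$patient_id == p]))
    if (length(codes) < 2) next
    prs <- t(utils::combn(codes, 2))
    out[[p]] <- data.frame(code_a = prs[, 1], code_b = prs[, 2])
  }
  do.call(rbind, out)
}

# a tiny deterministic hand-built embedding model for unit tests
fake_model <- function(vectors) {
  structure(
    list(vocab = tibble::tibble(token = rownames(vectors),
                                count = rep(1L, nrow(vectors))),
         in_vectors = vectors, out_vectors = vectors * 0,
         params = list(dim = ncol(vectors), window = 5, min_count = 1,
                       algorithm = "CBOW", negative = 5, epochs = 0,
                       initial_lr = 0.025, final_lr = 1e-4,
                       noise_exponent = 0.75, seed = 0L)),
    class = "cbow_model")
}

small_lag_spec <- function(code_a = "C01", code_b = "C02", mean = 300,
                           sd = 50, direction_prob = 1) {
  tibble::tibble(code_a = code_a, code_b = code_b, mean_lag_days = mean,
                 sd_lag_days = sd, direction_prob = direction_prob)
}
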