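#' Build chronological per-patient code sentences
#'
#' One "sentence" per patient: the patient's diagnosis codes ordered by date,
#' with the code string as deterministic same-day tie-break. Repeat diagnoses
#' are kept as repeated tokens — repetition is the co-occurrence information
#' the embedding consumes. Patients with zero events are omitted.
#'
#' @param events CCS-coded events tibble.
#' @param dedupe_per_day If `TRUE`, collapse repeats of a code within one
#'   patient-day to a single token.
#' @return Tibble `patient_id`, `tokens` (list-column of character vectors).
#' @export
build_sentences <- function(events, dedupe_per_day = FALSE) {
  ev <- tibble::as_tibble(events)
  if (dedupe_per_day)
    ev <- dplyr::distinct(ev, .data$patient_id, .data$date, .data$code)
  ev |>
    dplyr::arrange(.data$patient_id, .data$date, .data$code) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(tokens = list(.data$code), .groups = "drop")
}

#' Train a CBOW word2vec model over code sentences
#'
#' From-scratch continuous-bag-of-words trainer with negative sampling, the
#' package's core learner. For each position the context is up to `window`
#' tokens on each side (truncated at sentence edges); the hidden vector is
#' the mean of the context input vectors; the loss per example is
#' \deqn{-\log\sigma(h \cdot v'_t) - \sum_{j=1}^{negative} \log\sigma(-h \cdot v'_{n_j})}
#' with noise tokens drawn from the unigram distribution raised to
#' `noise_exponent`. Plain SGD with a linear learning-rate decay from
#' `initial_lr` to `final_lr` over the total number of token updates. Input
#' vectors are initialized uniform in \eqn{[-0.5/dim, 0.5/dim]} and output
#' vectors at zero, from a generator seeded by `seed`; training is
#' single-threaded and bitwise deterministic for a fixed seed.
#'
#' @param sentences Tibble from [build_sentences()] (or any tibble with a
#'   `tokens` list-column).
#' @param dim Embedding dimension.
#' @param window Maximum distance between target and context tokens.
#' @param min_count Minimum corpus frequency for a token to enter the
#'   vocabulary; rarer tokens are removed from sentences before training.
#' @param negative Number of noise tokens per positive example.
#' @param epochs Passes over the corpus.
#' @param initial_lr,final_lr Linear learning-rate schedule endpoints.
#' @param noise_exponent Exponent applied to unigram counts for the noise
#'   distribution (0.75 flattens the head, the standard choice).
#' @param seed Integer seed.
#' @return A `cbow_model`: list with `vocab` (tibble `token`, `count`),
#'   `in_vectors` and `out_vectors` (token-by-`dim` matrices with token
#'   rownames; the input vectors are the downstream representation), and
#'   `params`.
#' @export
train_cbow <- function(sentences, dim = 32, window = 5, min_count = 1,
                       negative = 5, epochs = 5,
                       initial_lr = 0.025, final_lr = 1e-4,
                       noise_exponent = 0.75, seed = 1L) {
  if (dim < 1 || window < 1 || min_count < 1 || negative < 1 || epochs < 1)
    abort("dim, window, min_count, negative and epochs must all be >= 1",
          class = "comorbidnet_param_error")
  if (!(final_lr > 0 && final_lr <= initial_lr))
    abort("need 0 < final_lr <= initial_lr", class = "comorbidnet_param_error")

  toks <- if (is.data.frame(sentences)) sentences$tokens else sentences
  counts <- table(unlist(toks))
  counts <- counts[counts >= min_count]
  if (length(counts) == 0)
    abort("empty vocabulary after min_count pruning",
          class = "comorbidnet_training_error")
  # vocabulary ordered by descending count, ties by token, for determinism
  vocab <- tibble::tibble(token = names(counts), count = as.integer(counts)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$token)

  idx_of <- stats::setNames(seq_len(nrow(vocab)) - 1L, vocab$token)
  sent_idx <- lapply(toks, function(tt) {
    ii <- idx_of[tt[tt %in% vocab$token]]
    as.integer(unname(ii))
  })
  sent_idx <- sent_idx[lengths(sent_idx) > 0]
  if (!any(lengths(sent_idx) >= 2))
    abort("training needs at least one sentence with >= 2 in-vocabulary tokens",
          class = "comorbidnet_training_error")

  noise <- vocab$count^noise_exponent
  fit <- cbow_train_cpp(sent_idx, nrow(vocab), noise / sum(noise),
                        as.integer(dim), as.integer(window),
                        as.integer(negative), as.integer(epochs),
                        initial_lr, final_lr, as.integer(seed))

  in_vectors <- t(fit$in_mat)
  out_vectors <- t(fit$out_mat)
  rownames(in_vectors) <- rownames(out_vectors) <- vocab$token

  structure(
    list(vocab = vocab, in_vectors = in_vectors, out_vectors = out_vectors,
         params = list(dim = dim, window = window, min_count = min_count,
                       algorithm = "CBOW", negative = negative,
                       epochs = epochs, initial_lr = initial_lr,
                       final_lr = final_lr, noise_exponent = noise_exponent,
                       seed = as.integer(seed),
                       total_updates = fit$total_updates)),
    class = "cbow_model")
}

#' @export
print.cbow_model <- function(x, ...) {
  cat("<cbow_model> ", nrow(x$vocab), " tokens x ", x$params$dim,
      " dimensions (window ", x$params$window, ", negative ",
      x$params$negative, ", epochs ", x$params$epochs, ", seed ",
      x$params$seed, ")\n", sep = "")
  invisible(x)
}

#' @describeIn train_cbow One row per vocabulary token: `token`, `count`, and
#'   the input-vector coordinates `d1..d<dim>`.
#' @param x A `cbow_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cbow_model <- function(x, ...) {
  vec <- tibble::as_tibble(x$in_vectors, .name_repair = ~ paste0("d", seq_along(.x)))
  dplyr::bind_cols(x$vocab, vec)
}

#' @describeIn train_cbow One-row model summary.
#' @exportS3Method generics::glance
glance.cbow_model <- function(x, ...) {
  tibble::tibble(n_tokens = nrow(x$vocab), dim = x$params$dim,
                 window = x$params$window, negative = x$params$negative,
                 epochs = x$params$epochs,
                 total_updates = x$params$total_updates,
                 seed = x$params$seed)
}

model_vectors <- function(model, codes = NULL) {
  v <- model$in_vectors
  if (is.null(codes)) return(v)
  missing <- setdiff(codes, rownames(v))
  if (length(missing) > 0)
    abort(paste0("token(s) not in vocabulary: ", paste(missing, collapse = ", ")),
          class = "comorbidnet_lookup_error")
  v[codes, , drop = FALSE]
}

#' Pearson correlation between the embedding vectors of token pairs
#'
#' Computes, for each requested pair, the Pearson correlation between the two
#' tokens' input vectors across the embedding dimensions — the association
#' score used throughout the downstream network analysis.
#'
#' @param model A `cbow_model`.
#' @param token_pairs Two-column data frame (or 2-column character matrix) of
#'   token pairs.
#' @return Tibble `token_a`, `token_b`, `r`.
#' @export
similarity_check <- function(model, token_pairs) {
  tp <- as.data.frame(token_pairs, stringsAsFactors = FALSE)
  a <- as.character(tp[[1]]); b <- as.character(tp[[2]])
  va <- model_vectors(model, a)
  vb <- model_vectors(model, b)
  r <- vapply(seq_along(a), function(i) cor(va[i, ], vb[i, ]), numeric(1))
  tibble::tibble(token_a = a, token_b = b, r = r)
}

#' Write / read an embedding model as delimited text
#'
#' The vector table uses the word2vec text format: a header line
#' `"<n_tokens> <dim>"` followed by one space-separated row per token. A JSON
#' sidecar (`<path>.json`) records the vocabulary counts, hyperparameters and
#' seed; [read_cbow()] restores a full `cbow_model` when the sidecar is
#' present (output vectors are stored in the sidecar too).
#'
#' @param model A `cbow_model`.
#' @param path Output path for the vector table.
#' @return `write_cbow()` returns `path` invisibly; `read_cbow()` a
#'   `cbow_model`.
#' @export
write_cbow <- function(model, path) {
  v <- model$in_vectors
  lines <- c(paste(nrow(v), ncol(v)),
             vapply(seq_len(nrow(v)), function(i)
               paste(rownames(v)[i],
                     paste(formatC(v[i, ], format = "g", digits = 17),
                           collapse = " ")),
               character(1)))
  writeLines(lines, path)
  sidecar <- list(vocab = model$vocab, params = model$params,
                  out_vectors = apply(model$out_vectors, 1, identity,
                                      simplify = FALSE))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cbow
#' @export
read_cbow <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  n <- hdr[1]; d <- hdr[2]
  parts <- strsplit(lines[1 + seq_len(n)], " ", fixed = TRUE)
  tokens <- vapply(parts, `[[`, character(1), 1)
  v <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  rownames(v) <- tokens

  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    abort(paste0("missing model sidecar: ", sidecar_path),
          class = "comorbidnet_parse_error")
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  out_v <- do.call(rbind, side$out_vectors)
  rownames(out_v) <- names(side$out_vectors)

  structure(list(vocab = tibble::as_tibble(side$vocab),
                 in_vectors = v, out_vectors = out_v[tokens, , drop = FALSE],
                 params = side$params),
            class = "cbow_model")
}
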