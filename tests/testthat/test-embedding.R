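test_that("sentences are chronological with code as same-day tie-break, repeats kept", {
  ev <- tibble::tibble(patient_id = "P1",
                       date = as.Date(c("2015-01-02", "2015-01-02", "2015-02-01")),
                       code = c("B", "A", "A"), code_system = "CCS")
  s <- build_sentences(ev)
  expect_equal(s$tokens[[1]], c("A", "B", "A"))

  single <- build_sentences(ev[3, ])
  expect_equal(lengths(single$tokens), 1L)

  dedup <- build_sentences(dplyr::bind_rows(ev, ev[2, ]), dedupe_per_day = TRUE)
  expect_equal(dedup$tokens[[1]], c("A", "B", "A"))
})

test_that("per-sentence token multisets equal per-patient event code multisets", {
  co <- generate_cohort(generator_config(n_patients = 100, seed = 19))
  s <- build_sentences(co$events)
  expect_equal(nrow(s), dplyr::n_distinct(co$events$patient_id))
  for (i in seq_len(nrow(s))) {
    mine <- co$events$code[co$events$patient_id == s$patient_id[i]]
    expect_equal(sort(s$tokens[[i]]), sort(mine))
  }
})

test_that("the example loss matches the negative-sampling formula", {
  set.seed(4)
  dim <- 6; vocab <- 9
  inm <- matrix(rnorm(dim * vocab, sd = 0.5), dim, vocab)
  outm <- matrix(rnorm(dim * vocab, sd = 0.5), dim, vocab)
  ctx <- c(0L, 2L, 7L); tgt <- 4L; negs <- c(1L, 3L, 8L)
  sig <- function(x) 1 / (1 + exp(-x))
  h <- rowMeans(inm[, ctx + 1])
  expected <- -log(sig(sum(h * outm[, tgt + 1]))) -
    sum(vapply(negs + 1, function(j) log(sig(-sum(h * outm[, j]))), numeric(1)))
  expect_equal(comorbidnet:::cbow_example_loss_cpp(inm, outm, ctx, tgt, negs),
               expected, tolerance = 1e-14)
})

test_that("analytic gradients match central differences on randomized models", {
  for (seed in 1:4) {
    set.seed(seed)
    dim <- sample(3:8, 1); vocab <- sample(6:12, 1)
    inm <- matrix(rnorm(dim * vocab, sd = 0.5), dim, vocab)
    outm <- matrix(rnorm(dim * vocab, sd = 0.5), dim, vocab)
    n_ctx <- sample(1:4, 1)
    ids <- sample(0:(vocab - 1), n_ctx + 4)  # distinct context/target/negatives
    ctx <- ids[seq_len(n_ctx)]
    tgt <- ids[n_ctx + 1]
    negs <- ids[(n_ctx + 2):(n_ctx + 4)]
    g <- comorbidnet:::cbow_example_grad_cpp(inm, outm, ctx, tgt, negs)
    loss <- function(im, om)
      comorbidnet:::cbow_example_loss_cpp(im, om, ctx, tgt, negs)
    eps <- 1e-6

    num_in <- vapply(seq_len(dim), function(d) {
      ip <- inm; ip[d, ctx[1] + 1] <- ip[d, ctx[1] + 1] + eps
      im <- inm; im[d, ctx[1] + 1] <- im[d, ctx[1] + 1] - eps
      (loss(ip, outm) - loss(im, outm)) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(num_in - g$grad_in_context) /
                    pmax(abs(num_in), 1e-6)), 1e-4)

    for (k in 0:3) {
      o <- if (k == 0) tgt else negs[k]
      num_out <- vapply(seq_len(dim), function(d) {
        op <- outm; op[d, o + 1] <- op[d, o + 1] + eps
        om <- outm; om[d, o + 1] <- om[d, o + 1] - eps
        (loss(inm, op) - loss(inm, om)) / (2 * eps)
      }, numeric(1))
      expect_lt(max(abs(num_out - g$grad_out[, k + 1]) /
                      pmax(abs(num_out), 1e-6)), 1e-4)
    }
  }
})

test_that("training is bitwise deterministic under a fixed seed", {
  co <- generate_cohort(generator_config(n_patients = 60, seed = 2))
  s <- build_sentences(co$events)
  m1 <- train_cbow(s, dim = 8, epochs = 2, seed = 99)
  m2 <- train_cbow(s, dim = 8, epochs = 2, seed = 99)
  expect_identical(m1$in_vectors, m2$in_vectors)
  expect_identical(m1$out_vectors, m2$out_vectors)
  m3 <- train_cbow(s, dim = 8, epochs = 2, seed = 100)
  expect_false(identical(m1$in_vectors, m3$in_vectors))
})

test_that("training raises the target's predicted probability above initialization", {
  s <- tibble::tibble(patient_id = as.character(1:200),
                      tokens = rep(list(c("A", "B")), 200))
  m <- train_cbow(s, dim = 4, window = 5, epochs = 5, seed = 3)
  sig <- function(x) 1 / (1 + exp(-x))
  # at initialization out vectors are zero, so sigma(h . v'_B) = 0.5
  expect_gt(sig(sum(m$in_vectors["A", ] * m$out_vectors["B", ])), 0.5)
})

test_that("co-occurring tokens embed closer than independent ones across seeds", {
  wins <- 0L
  for (seed in 1:10) {
    sents <- withr::with_seed(seed, {
      # A and B always share a sentence (and its contexts); C0 lives in
      # sentences with a disjoint filler alphabet, so it shares no context
      lapply(1:200, function(i) {
        if (i %% 2 == 0) sample(c("A", "B", sample(c("D", "E", "F"), 2)))
        else sample(c("C0", sample(c("X", "Y", "Z"), 2)))
      })
    })
    m <- train_cbow(tibble::tibble(tokens = sents), dim = 8, epochs = 10,
                    seed = seed)
    r <- similarity_check(m, data.frame(a = c("A", "A"), b = c("B", "C0")))
    if (r$r[1] > r$r[2]) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("vocabulary pruning and degenerate corpora raise training errors", {
  s <- tibble::tibble(tokens = list(c("A", "B"), "C"))
  expect_error(train_cbow(s, min_count = 5),
               class = "comorbidnet_training_error")
  expect_error(train_cbow(tibble::tibble(tokens = list("A", "B"))),
               class = "comorbidnet_training_error")
  expect_error(train_cbow(s, dim = 0), class = "comorbidnet_param_error")
  expect_error(train_cbow(s, final_lr = 0.5, initial_lr = 0.1),
               class = "comorbidnet_param_error")
})

test_that("pairwise vector correlation follows the covariance formula", {
  v <- rbind(A = c(1, 2, 3, 4), B = c(2, 4, 6, 8.5), C = c(4, 3, 2, 1))
  m <- fake_model(v)
  r <- similarity_check(m, data.frame(a = c("A", "A", "B"),
                                      b = c("A", "C", "C")))
  expect_equal(r$r[1], 1.0)
  expect_equal(r$r[2], -1.0)
  expect_equal(r$r[3], bf_pearson(v["B", ], v["C", ]), tolerance = 1e-14)
  # constructed v and -v
  m2 <- fake_model(rbind(X = c(1, -2, 0.5, 3), Y = -c(1, -2, 0.5, 3)))
  expect_equal(similarity_check(m2, data.frame(a = "X", b = "Y"))$r, -1.0)
  expect_error(similarity_check(m, data.frame(a = "A", b = "ZZ")),
               class = "comorbidnet_lookup_error")
})

test_that("models round trip through the text format with sidecar", {
  co <- generate_cohort(generator_config(n_patients = 50, seed = 6))
  m <- train_cbow(build_sentences(co$events), dim = 5, epochs = 1, seed = 6)
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_cbow(m, tmp)
  m2 <- read_cbow(tmp)
  expect_equal(m2$in_vectors, m$in_vectors)
  expect_equal(m2$out_vectors, m$out_vectors)
  expect_equal(m2$vocab, m$vocab)
  expect_equal(m2$params$seed, m$params$seed)
})
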