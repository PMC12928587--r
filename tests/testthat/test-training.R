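# Fast structural checks of the mask-learning loop on a deliberately tiny
# model and corpus; the scientific end-to-end behaviour is exercised in
# test-acceptance.R on the full toy pipeline.

tiny_pipeline_inputs <- function(n_per_class = 12, seed = 77) {
  spec <- synthetic_spec(n_per_class = n_per_class,
                         length_range = c(20L, 30L), seed = seed)
  corpus <- generate_corpus(spec)
  model <- build_toy_model(depth = 1L, width = 8L, heads = 2L, max_len = 64L,
                           seed = 13)
  part <- build_partition(corpus, suppression_spec("sequence", "1", "Class"))
  split <- split_dataset(corpus, seed = 3)
  list(corpus = corpus, model = model, part = part, split = split)
}

fast_config <- function(...) {
  args <- utils::modifyList(
    list(max_steps = 6L, batch_size = 2L, snapshot_every = 3L, eval_size = 4L),
    list(...))
  do.call(train_config, args)
}

test_that("mask training is deterministic and leaves weights frozen", {
  inp <- tiny_pipeline_inputs()
  fp <- weights_fingerprint(inp$model)
  fit1 <- train_subnetwork(inp$model, inp$corpus, inp$part, inp$split,
                           fast_config())
  fit2 <- train_subnetwork(inp$model, inp$corpus, inp$part, inp$split,
                           fast_config())
  expect_identical(fit1$mask$logits, fit2$mask$logits)
  expect_identical(fit1$m, fit2$m)
  expect_identical(weights_fingerprint(inp$model), fp)
  # different data seed changes the trajectory
  fit3 <- train_subnetwork(inp$model, inp$corpus, inp$part, inp$split,
                           fast_config(seed_data = 99L))
  expect_false(identical(fit1$mask$logits, fit3$mask$logits))
})

test_that("zero training steps return the initialization", {
  inp <- tiny_pipeline_inputs()
  fit <- train_subnetwork(inp$model, inp$corpus, inp$part, inp$split,
                          fast_config(max_steps = 0L))
  expect_equal(sparsity(fit$m), 0)
  expect_true(all(fit$mask$logits == -5))
})

test_that("training logs loss components and sparsity per step", {
  inp <- tiny_pipeline_inputs()
  fit <- train_subnetwork(inp$model, inp$corpus, inp$part, inp$split,
                          fast_config())
  expect_identical(nrow(fit$step_log), 6L)
  expect_true(all(c("loss_supp", "loss_maint", "loss_mlm", "loss_total",
                    "sparsity") %in% names(fit$step_log)))
  expect_true(all(is.finite(fit$step_log$loss_total)))
  expect_true(all(fit$step_log$loss_supp >= 0))
  expect_true(all(fit$step_log$loss_maint >= 0))
  # serialized config travels with the fit
  expect_identical(fit$config$max_steps, 6L)
})

test_that("the returned snapshot maximizes the validation composite score", {
  inp <- tiny_pipeline_inputs(n_per_class = 16)
  fit <- train_subnetwork(inp$model, inp$corpus, inp$part, inp$split,
                          fast_config(max_steps = 12L))
  expect_gte(nrow(fit$log), 2L)
  best_row <- fit$log[which.max(fit$log$score), ]
  expect_identical(fit$best_step, best_row$step)
})

test_that("empty partition sides are rejected", {
  inp <- tiny_pipeline_inputs()
  # a partition whose suppressed side misses the training split entirely
  part <- inp$part
  part$suppressed <- character(0)
  part$maintained <- inp$corpus$id
  expect_error(
    train_subnetwork(inp$model, inp$corpus, part, inp$split, fast_config()),
    "empty suppression"
  )
})

test_that("one suppression-only step does not increase the suppression loss", {
  # lambda = (1,0,0), small learning rate: the first step can only flip
  # mask bits that reduce the KL-to-uniform under the same noise draw
  inp <- tiny_pipeline_inputs()
  cfg1 <- fast_config(max_steps = 1L, lambda = c(1, 0, 0), lr = 1e-3,
                      snapshot_every = 1L)
  fit <- train_subnetwork(inp$model, inp$corpus, inp$part, inp$split, cfg1)
  # compare the masks sampled under the same noise before and after the step
  state2 <- fit$mask
  ns <- asNamespace("subnetlm")
  set.seed(ns$derive_seed(cfg1$seed_noise, 1L))
  u <- runif(length(state2$logits))
  s_before <- sample_scores(rep(cfg1$init_logit, length(u)), cfg1$tau, u)
  s_after <- sample_scores(state2$logits, cfg1$tau, u)
  m_before <- binarize(s_before, cfg1$threshold)
  m_after <- binarize(s_after, cfg1$threshold)
  eval_loss <- function(m) {
    ids <- intersect(inp$part$suppressed, split_ids(inp$split, "train"))
    tot <- 0; np <- 0
    for (id in ids[1:2]) {
      tk <- tokenize(inp$corpus$sequence[inp$corpus$id == id])
      p <- plm_forward(inp$model, tk, m = m)
      tot <- tot + suppression_loss(p) * length(tk); np <- np + length(tk)
    }
    tot / np
  }
  expect_lte(eval_loss(m_after), eval_loss(m_before) + 1e-10)
})

test_that("random-sequence controls are reproducible and bounded", {
  rec <- random_records(10, seed = 5)
  a <- make_control_spec(rec, "random_sequences", n = 5, seed = 4)
  b <- make_control_spec(rec, "random_sequences", n = 5, seed = 4)
  expect_identical(a$suppressed, b$suppressed)
  expect_length(a$suppressed, 5)
  expect_setequal(c(a$suppressed, a$maintained), rec$id)
  expect_error(make_control_spec(rec, "random_sequences", n = 11, seed = 1),
               "exceeds pool")
})

test_that("random-residue controls hit the requested fraction on average", {
  rec <- domain_records("x", paste(rep("A", 50), collapse = ""))
  f <- 0.3
  sizes <- vapply(1:1000, function(s) {
    length(make_control_spec(rec, "random_residues", fraction = f,
                             seed = s)$positions[["x"]])
  }, numeric(1))
  expect_lt(abs(mean(sizes) - f * 50), 3 * sqrt(50 * f * (1 - f) / 1000))
  expect_error(make_control_spec(rec, "random_residues", fraction = 1.2),
               "fraction")
})
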