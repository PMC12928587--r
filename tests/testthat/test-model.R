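test_that("maskable slot count matches the analytic projection count", {
  # per block: 4 attention projections (d x d) + feed-forward (d x 4d, 4d x d)
  model <- build_toy_model(depth = 2, width = 32, heads = 4)
  K_expected <- as.integer(2 * (4 * 32 * 32 + 2 * 32 * 128))
  expect_identical(n_maskable(model), K_expected)
  man <- maskable_index(model)
  expect_setequal(unique(man$module), c("Wq", "Wk", "Wv", "Wo", "W1", "W2"))
  expect_identical(sum(man$length), K_expected)
  # embeddings, biases and normalization never appear in the manifest
  expect_false(any(grepl("emb|^b|ln", man$module)))
})

test_that("slot_info maps flat indices to tensor coordinates", {
  model <- small_model()
  info1 <- slot_info(model, 1L)
  expect_identical(info1$layer, 1L)
  expect_identical(info1$module, "Wq")
  expect_identical(c(info1$row, info1$col), c(1L, 1L))
  K <- n_maskable(model)
  infoK <- slot_info(model, K)
  expect_identical(infoK$layer, model$hyper$depth)
  expect_identical(infoK$module, "W2")
  expect_error(slot_info(model, K + 1L), "out of range")
})

test_that("model construction is deterministic and validates inputs", {
  a <- build_toy_model(seed = 5)
  b <- build_toy_model(seed = 5)
  expect_identical(a$params, b$params)
  expect_error(build_toy_model(depth = 0), "positive")
  vocab_no_mask <- plm_vocab()
  vocab_no_mask$tokens <- setdiff(vocab_no_mask$tokens, "<mask>")
  vocab_no_mask$mask_id <- NULL
  expect_error(build_toy_model(vocab = vocab_no_mask), "<mask>")
})

test_that("forward with an all-ones mask is bit-identical to no mask", {
  model <- small_model()
  tokens <- tokenize("ALEKRQVIFYGPSNDHWTCM")
  p0 <- plm_forward(model, tokens)
  p1 <- plm_forward(model, tokens, m = rep(1, n_maskable(model)))
  expect_identical(p0, p1)
  expect_identical(dim(p0), c(20L, 20L))
  expect_equal(rowSums(p0), rep(1, 20), tolerance = 1e-12)
})

test_that("masking one slot zeroes exactly that effective weight", {
  model <- small_model()
  K <- n_maskable(model)
  i <- 37L
  m <- rep(1, K); m[i] <- 0
  eff <- subnetlm:::masked_params(apply_mask(model, NULL), m)
  info <- slot_info(model, i)
  W_eff <- eff$blocks[[info$layer]][[info$module]]
  W_orig <- model$params$blocks[[info$layer]][[info$module]]
  expect_identical(W_eff[info$row, info$col], 0)
  W_eff[info$row, info$col] <- W_orig[info$row, info$col]
  expect_identical(W_eff, W_orig)
  # everything outside the manifest untouched
  expect_identical(eff$tok_emb, model$params$tok_emb)
  expect_identical(eff$blocks[[1]]$ln1_g, model$params$blocks[[1]]$ln1_g)
  expect_error(plm_forward(model, tokenize("ALEK"), m = m[-1]), "does not match K")
})

test_that("model checkpoints round-trip", {
  model <- small_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$params, model$params)
  expect_identical(manifest_fingerprint(back), manifest_fingerprint(model))
  saveRDS(list(oops = 1), path)
  expect_error(load_model(path), "not a toy_plm")
})

test_that("backward gradients match central differences", {
  ns <- asNamespace("subnetlm")
  model <- build_toy_model(depth = 2, width = 16, heads = 2, max_len = 64,
                           seed = 7)
  set.seed(42)
  tokens <- sample.int(20, 15)
  plan <- make_corruption_plan(15, seed = 3)
  corrupted <- apply_corruption(tokens, plan)
  scored <- plan$positions[tokens[plan$positions] <= 20]
  skip_if(length(scored) == 0)
  loss_fn <- function(params) {
    fwd <- ns$toy_forward(params, model$hyper, corrupted)
    mean(-log(fwd$probs[cbind(scored, tokens[scored])]))
  }
  fwd <- ns$toy_forward(model$params, model$hyper, corrupted, want_cache = TRUE)
  dlogits <- matrix(0, 15, 20)
  dlogits[scored, ] <- fwd$probs[scored, , drop = FALSE] / length(scored)
  hit <- cbind(scored, tokens[scored])
  dlogits[hit] <- dlogits[hit] - 1 / length(scored)
  g <- ns$toy_backward(model$hyper, fwd$cache, dlogits)
  eps <- 1e-5
  check_leaf <- function(path_get, path_set, grad) {
    idx <- sample(length(grad), min(4, length(grad)))
    for (i in idx) {
      p_hi <- path_set(model$params, i, +eps)
      p_lo <- path_set(model$params, i, -eps)
      fd <- (loss_fn(p_hi) - loss_fn(p_lo)) / (2 * eps)
      expect_equal(grad[i], fd, tolerance = 1e-5)
    }
  }
  bump <- function(get, put) function(p, i, d) { v <- get(p); v[i] <- v[i] + d; put(p, v) }
  check_leaf(NULL, bump(function(p) p$blocks[[1]]$Wq,
                        function(p, v) { p$blocks[[1]]$Wq[] <- v; p }),
             g$blocks[[1]]$Wq)
  check_leaf(NULL, bump(function(p) p$blocks[[2]]$W2,
                        function(p, v) { p$blocks[[2]]$W2[] <- v; p }),
             g$blocks[[2]]$W2)
  check_leaf(NULL, bump(function(p) p$blocks[[1]]$ln2_g,
                        function(p, v) { p$blocks[[1]]$ln2_g[] <- v; p }),
             g$blocks[[1]]$ln2_g)
  check_leaf(NULL, bump(function(p) p$tok_emb,
                        function(p, v) { p$tok_emb[] <- v; p }),
             g$tok_emb)
  check_leaf(NULL, bump(function(p) p$W_head,
                        function(p, v) { p$W_head[] <- v; p }),
             g$W_head)
})
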