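# Pretraining of the toy masked LM on a (synthetic) corpus, and shared
# helpers for turning records into token sequences and scoring masked-token
# negative log-likelihoods.

# Named list of token vectors for a set of records.
tokenize_records <- function(records, vocab = plm_vocab()) {
  toks <- lapply(records$sequence, tokenize, vocab = vocab)
  names(toks) <- records$id
  toks
}

# Batched forward: list of probability matrices, one per sequence.
forward_probs_batch <- function(model, tokens_list, m = NULL) {
  params <- masked_params(model, m)
  out <- toy_forward_batch(params, model$hyper, tokens_list)
  lapply(out$rows, function(rr) out$probs[rr, , drop = FALSE])
}

# Per-position NLLs of the true tokens at the corrupted positions of one
# sequence. Returns the scored positions and their NLLs; positions whose
# true token is outside the 20-letter support are never scored.
masked_nll_one <- function(model, tokens, plan, m = NULL, vocab = plm_vocab()) {
  corrupted <- apply_corruption(tokens, plan, vocab)
  p <- plm_forward(model, corrupted, m = m)
  scored <- plan$positions[tokens[plan$positions] <= vocab$n_aa]
  if (!length(scored)) return(list(positions = integer(0), nll = numeric(0)))
  list(positions = scored,
       nll = -log(pmax(p[cbind(scored, tokens[scored])], LOG_EPS)))
}

# Pooled masked-token NLLs over a list of token vectors, with `reps`
# independent corruption draws per sequence. Deterministic in `seed`.
# `restrict` optionally maps each sequence name to the positions that may
# be scored (residue-level strata).
masked_nll_set <- function(model, tokens_list, m = NULL, rate = 0.15,
                           reps = 1L, seed = 17L, restrict = NULL,
                           vocab = plm_vocab()) {
  if (!length(tokens_list)) return(numeric(0))
  ids <- names(tokens_list)
  out <- numeric(0)
  for (r in seq_len(reps)) {
    plans <- lapply(seq_along(tokens_list), function(i) {
      make_corruption_plan(length(tokens_list[[i]]), rate = rate,
                           seed = derive_seed(seed, i * 131L + r))
    })
    corrupted <- Map(apply_corruption, tokens_list, plans,
                     MoreArgs = list(vocab = vocab))
    probs <- forward_probs_batch(model, corrupted, m = m)
    for (i in seq_along(tokens_list)) {
      toks <- tokens_list[[i]]
      scored <- plans[[i]]$positions[toks[plans[[i]]$positions] <= vocab$n_aa]
      if (!is.null(restrict)) scored <- intersect(scored, restrict[[ids[i]]])
      if (!length(scored)) next
      out <- c(out, -log(pmax(probs[[i]][cbind(scored, toks[scored])], LOG_EPS)))
    }
  }
  out
}

#' Held-out masked-token perplexity
#'
#' Corrupts each sequence with the standard 15% / 80-10-10 scheme and
#' reports the perplexity of the true tokens at the selected positions.
#'
#' @param model A `toy_plm` (a mask attached with [apply_mask()] is used).
#' @param records A [domain_records()] object.
#' @param m Optional explicit binary mask.
#' @param rate Corruption rate.
#' @param reps Corruption replicates per sequence.
#' @param seed Seed for the corruption draws.
#' @return Scalar perplexity.
#' @export
mlm_perplexity <- function(model, records, m = NULL, rate = 0.15, reps = 1L,
                           seed = 17L) {
  toks <- tokenize_records(records, model$vocab)
  nll <- masked_nll_set(model, toks, m = m %||% model$mask, rate = rate,
                        reps = reps, seed = seed, vocab = model$vocab)
  perplexity(nll)
}

# Unigram perplexity of a corpus under its own pooled residue frequencies
# (a context-free reference the pretrained model should beat).
unigram_perplexity <- function(records) {
  chars <- strsplit(paste(records$sequence, collapse = ""), "")[[1]]
  counts <- table(factor(chars, levels = aa_alphabet()))
  p <- (as.numeric(counts) + 0.5) / sum(counts + 0.5)
  freq <- as.numeric(counts) / sum(counts)
  exp(-sum(freq * log(p)))
}

#' Pretrain the toy masked language model
#'
#' Standard masked-language-model training: at each step a minibatch of
#' sequences is corrupted with the 15% / 80-10-10 scheme and all model
#' weights are updated by Adam on the mean NLL of the true tokens at the
#' selected positions. Deterministic for fixed seeds.
#'
#' @param model A freshly built [build_toy_model()].
#' @param records Training corpus as [domain_records()].
#' @param steps Number of optimization steps (> 0).
#' @param batch_size Sequences per step.
#' @param lr Adam learning rate.
#' @param lr_end Optional final learning rate; when given, the rate decays
#'   linearly from `lr` to `lr_end` over the run.
#' @param rate Corruption rate.
#' @param seed Seed controlling data order and corruption.
#' @param verbose Print running loss every 100 steps.
#' @return The trained `toy_plm`, with a `train_log` data frame attached
#'   (`step`, `loss`).
#' @export
pretrain_toy <- function(model, records, steps = 600L, batch_size = 16L,
                         lr = 2e-3, lr_end = NULL, rate = 0.15, seed = 1L,
                         verbose = FALSE) {
  stopifnot(inherits(model, "toy_plm"))
  if (steps <= 0L) stop("steps must be positive", call. = FALSE)
  if (!nrow(records)) stop("empty corpus", call. = FALSE)
  vocab <- model$vocab
  toks <- tokenize_records(records, vocab)
  n <- length(toks)
  params <- model$params
  opt <- adam_init(params)
  log_steps <- integer(0); log_loss <- numeric(0)
  for (t in seq_len(steps)) {
    set.seed(derive_seed(seed, t))
    batch <- sample.int(n, min(batch_size, n))
    plan_seeds <- sample.int(2147483646L, length(batch))
    plans <- lapply(seq_along(batch), function(j) {
      make_corruption_plan(length(toks[[batch[j]]]), rate = rate,
                           seed = plan_seeds[j])
    })
    corrupted <- Map(apply_corruption, toks[batch], plans,
                     MoreArgs = list(vocab = vocab))
    fwd <- toy_forward_batch(params, model$hyper, corrupted, want_cache = TRUE)
    # stacked scored positions and targets
    scored_rows <- integer(0); targets <- integer(0)
    for (j in seq_along(batch)) {
      tk <- toks[[batch[j]]]
      sc <- plans[[j]]$positions[tk[plans[[j]]$positions] <= vocab$n_aa]
      scored_rows <- c(scored_rows, fwd$rows[[j]][sc])
      targets <- c(targets, tk[sc])
    }
    if (!length(scored_rows)) next
    dlogits <- matrix(0, nrow(fwd$probs), vocab$n_aa)
    dlogits[scored_rows, ] <- fwd$probs[scored_rows, , drop = FALSE]
    hit <- cbind(scored_rows, targets)
    dlogits[hit] <- dlogits[hit] - 1
    dlogits <- dlogits / length(scored_rows)
    loss <- mean(-log(pmax(fwd$probs[hit], LOG_EPS)))
    grads <- toy_backward_batch(model$hyper, fwd$cache, dlogits)
    lr_t <- if (is.null(lr_end)) lr else
      lr + (lr_end - lr) * (t - 1) / max(1L, steps - 1L)
    step_res <- adam_step_tree(params, grads, opt, lr_t)
    params <- step_res$params
    opt <- step_res$state
    log_steps <- c(log_steps, t)
    log_loss <- c(log_loss, loss)
    if (verbose && t %% 100L == 0L) {
      message(sprintf("step %d: mlm nll %.4f", t, loss))
    }
  }
  model$params <- params
  model$train_log <- data.frame(step = log_steps, loss = log_loss)
  model
}
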