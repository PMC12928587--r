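#' Configuration for subnetwork (mask) training
#'
#' Defaults: Adam on the mask logits with learning rate 0.05, equal loss
#' weights `lambda = (1, 1, 1)`, Gumbel-sigmoid temperature 0.5, threshold
#' 0.5, all logits initialized at -5 (start from the full model), batch
#' size 8 per side, up to 600 steps with a validation snapshot every 50
#' steps, and early stopping on the composite score
#' `suppression perplexity - maint_penalty * max(0, maintenance perplexity - baseline)`.
#'
#' @param lambda Nonnegative weights of (suppression, maintenance-KL,
#'   maintenance-MLM).
#' @param tau Gumbel-sigmoid temperature.
#' @param threshold Binarization threshold T.
#' @param init_logit Initial mask logit.
#' @param lr Adam learning rate on the logits.
#' @param optimizer Optimizer name (only `"adam"` is implemented).
#' @param max_steps Maximum optimization steps.
#' @param batch_size Sequences per minibatch (per side).
#' @param rate MLM corruption rate.
#' @param supp_scope Positions scored by the suppression KL:
#'   `"corrupted"` (default) scores the corruption-selected positions,
#'   targeting the context-driven masked-token predictions that perplexity
#'   evaluation measures; `"all"` scores every position of the suppressed
#'   input.
#' @param snapshot_every Validation snapshot cadence in steps.
#' @param patience Snapshots without improvement before early stop.
#' @param maint_penalty Weight of maintenance degradation in the composite
#'   early-stop score.
#' @param eval_size Max validation sequences per side per snapshot.
#' @param eval_reps Corruption replicates per validation sequence.
#' @param seed_mask,seed_noise,seed_data Seeds for mask initialization,
#'   Gumbel noise, and data order / corruption.
#' @return A `train_config` list, fully serialized into every run's output.
#' @export
train_config <- function(lambda = c(1, 1, 1), tau = 0.5, threshold = 0.5,
                         init_logit = -5, lr = 0.05, optimizer = "adam",
                         max_steps = 600L, batch_size = 8L, rate = 0.15,
                         supp_scope = c("corrupted", "all"),
                         snapshot_every = 50L, patience = 6L,
                         maint_penalty = 10, eval_size = 24L, eval_reps = 1L,
                         seed_mask = 1L, seed_noise = 2L, seed_data = 3L) {
  if (any(lambda < 0) || all(lambda == 0)) stop("invalid lambda", call. = FALSE)
  if (tau <= 0 || lr <= 0 || max_steps < 0L || batch_size <= 0L) {
    stop("tau, lr, batch_size must be positive and max_steps nonnegative",
         call. = FALSE)
  }
  if (optimizer != "adam") stop("unknown optimizer: ", optimizer, call. = FALSE)
  supp_scope <- match.arg(supp_scope)
  structure(
    list(lambda = lambda, tau = tau, threshold = threshold,
         init_logit = init_logit, lr = lr, optimizer = optimizer,
         max_steps = as.integer(max_steps), batch_size = as.integer(batch_size),
         rate = rate, supp_scope = supp_scope,
         snapshot_every = as.integer(snapshot_every),
         patience = as.integer(patience), maint_penalty = maint_penalty,
         eval_size = as.integer(eval_size), eval_reps = as.integer(eval_reps),
         seed_mask = as.integer(seed_mask), seed_noise = as.integer(seed_noise),
         seed_data = as.integer(seed_data)),
    class = "train_config"
  )
}

# Ids (sequence level) or restriction lists (residue level) for one side of
# a partition, limited to the given id pool.
partition_side <- function(partition, side = c("suppressed", "maintained"),
                           ids = NULL) {
  side <- match.arg(side)
  if (partition$level == "sequence") {
    out <- if (side == "suppressed") partition$suppressed else partition$maintained
    if (!is.null(ids)) out <- intersect(out, ids)
    out
  } else {
    pos <- if (side == "suppressed") partition$positions else partition$complement
    if (!is.null(ids)) pos <- pos[intersect(names(pos), ids)]
    pos[lengths(pos) > 0L]
  }
}

#' Train a suppressive subnetwork mask
#'
#' The mask-learning loop: model weights stay frozen; only the mask logits
#' are optimized. At each step, fresh logistic noise turns the logits into
#' continuous scores, the scores are binarized with a straight-through
#' estimator, and one suppression and one maintenance minibatch are scored
#' under the masked model. All three loss components see inputs corrupted
#' by the 15% / 80-10-10 scheme, aligning the training signal with
#' masked-token evaluation: the suppression term is the KL to uniform over
#' the suppressed positions, the maintenance-KL term matches the unmasked
#' baseline on maintained positions, and the maintenance-MLM term is the
#' NLL of the true residues at the corrupted maintained positions.
#' Validation perplexities are logged at every snapshot and the snapshot
#' with the best composite score is returned.
#'
#' @param model A pretrained `toy_plm` (weights are never updated).
#' @param records The corpus as [domain_records()].
#' @param partition A [build_partition()] or [make_control_spec()] result.
#' @param split Optional [split_dataset()] assignment; training minibatches
#'   come from the train partition and snapshots are scored on the
#'   validation partition. Without it, all records train and a held-back
#'   fifth of them is used for snapshots.
#' @param config A [train_config()].
#' @return A list of class `subnet_fit`: `mask` (the best [mask_state()]),
#'   `m` (its deterministic binary mask), `log` (per-snapshot data frame),
#'   `step_log` (per-step loss components and sparsity), `baseline`
#'   (validation perplexities of the unmasked model), and `config`.
#' @export
train_subnetwork <- function(model, records, partition, split = NULL,
                             config = train_config()) {
  stopifnot(inherits(model, "toy_plm"),
            inherits(partition, "suppression_partition"),
            inherits(config, "train_config"))
  vocab <- model$vocab
  fp_before <- weights_fingerprint(model)
  if (is.null(split)) split <- split_dataset(records, seed = config$seed_data)
  train_ids <- split_ids(split, "train")
  val_ids <- split_ids(split, "validation")
  if (!length(val_ids)) val_ids <- train_ids
  toks <- tokenize_records(records, vocab)

  seq_level <- partition$level == "sequence"
  if (seq_level) {
    supp_train <- partition_side(partition, "suppressed", train_ids)
    maint_train <- partition_side(partition, "maintained", train_ids)
    supp_val <- utils::head(partition_side(partition, "suppressed", val_ids),
                            config$eval_size)
    maint_val <- utils::head(partition_side(partition, "maintained", val_ids),
                             config$eval_size)
    val_restrict_supp <- NULL; val_restrict_maint <- NULL
  } else {
    supp_pos <- partition_side(partition, "suppressed", train_ids)
    maint_pos <- partition_side(partition, "maintained", train_ids)
    supp_train <- names(supp_pos); maint_train <- names(maint_pos)
    supp_val <- utils::head(intersect(val_ids, names(partition$positions)),
                            config$eval_size)
    maint_val <- supp_val
    val_restrict_supp <- partition$positions
    val_restrict_maint <- partition$complement
  }
  if (!length(supp_train) || !length(maint_train)) {
    stop("empty suppression or maintenance side in the training split",
         call. = FALSE)
  }

  state <- mask_state(model, init_logit = config$init_logit, tau = config$tau,
                      threshold = config$threshold,
                      noise_seed = config$seed_noise)
  K <- length(state$logits)
  opt <- adam_init_flat(K)
  lam <- config$lambda

  eval_side <- function(m, ids, restrict) {
    nll <- masked_nll_set(model, toks[ids], m = m, rate = config$rate,
                          reps = config$eval_reps, seed = 1719L,
                          restrict = restrict, vocab = vocab)
    if (!length(nll)) NA_real_ else perplexity(nll)
  }
  base_supp_ppl <- eval_side(NULL, supp_val, val_restrict_supp)
  base_maint_ppl <- eval_side(NULL, maint_val, val_restrict_maint)

  # one optimization step's losses and weight-space grads, each side as a
  # single batched forward/backward pass
  step_losses <- function(params_eff, supp_batch, maint_batch, plan_seeds) {
    V <- vocab$n_aa
    corrupt_batch <- function(ids, seeds) {
      plans <- lapply(seq_along(ids), function(j) {
        make_corruption_plan(length(toks[[ids[j]]]), rate = config$rate,
                             seed = seeds[j])
      })
      list(plans = plans,
           tokens = Map(apply_corruption, toks[ids], plans,
                        MoreArgs = list(vocab = vocab)))
    }
    # suppression side: KL to uniform over the suppressed positions
    cb_s <- corrupt_batch(supp_batch, plan_seeds[seq_along(supp_batch)])
    fwd_s <- toy_forward_batch(params_eff, model$hyper, cb_s$tokens,
                               want_cache = TRUE)
    sel_rows <- unlist(lapply(seq_along(supp_batch), function(j) {
      sel <- if (seq_level) seq_along(toks[[supp_batch[j]]]) else
        partition$positions[[supp_batch[j]]]
      if (config$supp_scope == "corrupted") {
        sel <- intersect(sel, cb_s$plans[[j]]$positions)
      }
      fwd_s$rows[[j]][sel]
    }))
    if (!length(sel_rows)) sel_rows <- fwd_s$rows[[1L]][1L]
    p <- fwd_s$probs
    logp <- log(pmax(p, LOG_EPS))
    kl_rows <- rowSums(p * logp) + log(V)   # KL(p || uniform) per position
    l_supp <- mean(kl_rows[sel_rows])
    dlog_s <- matrix(0, nrow(p), V)
    dlog_s[sel_rows, ] <- p[sel_rows, , drop = FALSE] *
      (logp[sel_rows, , drop = FALSE] - (kl_rows[sel_rows] - log(V)))
    g_total <- toy_backward_batch(model$hyper, fwd_s$cache,
                                  dlog_s * (lam[1] / length(sel_rows)))
    # maintenance side: KL to the unmasked baseline + MLM, one backward
    cb_m <- corrupt_batch(maint_batch,
                          plan_seeds[length(supp_batch) + seq_along(maint_batch)])
    fwd_m <- toy_forward_batch(params_eff, model$hyper, cb_m$tokens,
                               want_cache = TRUE)
    q <- toy_forward_batch(model$params, model$hyper, cb_m$tokens)$probs
    kl_sel_rows <- unlist(lapply(seq_along(maint_batch), function(j) {
      sel <- if (seq_level) seq_along(toks[[maint_batch[j]]]) else
        partition$complement[[maint_batch[j]]]
      fwd_m$rows[[j]][sel]
    }))
    scored_rows <- integer(0); targets <- integer(0)
    for (j in seq_along(maint_batch)) {
      tk <- toks[[maint_batch[j]]]
      sc <- cb_m$plans[[j]]$positions[tk[cb_m$plans[[j]]$positions] <= V]
      if (!seq_level) sc <- intersect(sc, partition$complement[[maint_batch[j]]])
      scored_rows <- c(scored_rows, fwd_m$rows[[j]][sc])
      targets <- c(targets, tk[sc])
    }
    pm <- fwd_m$probs
    logpm <- log(pmax(pm, LOG_EPS))
    r <- logpm - log(pmax(q, LOG_EPS))
    klq_rows <- rowSums(pm * r)
    l_kl <- if (length(kl_sel_rows)) mean(klq_rows[kl_sel_rows]) else 0
    dlog_m <- matrix(0, nrow(pm), V)
    if (length(kl_sel_rows)) {
      dlog_m[kl_sel_rows, ] <- (pm[kl_sel_rows, , drop = FALSE] *
        (r[kl_sel_rows, , drop = FALSE] - klq_rows[kl_sel_rows])) *
        (lam[2] / length(kl_sel_rows))
    }
    l_mlm <- 0
    if (length(scored_rows)) {
      hit <- cbind(scored_rows, targets)
      l_mlm <- mean(-log(pmax(pm[hit], LOG_EPS)))
      dmlm <- pm[scored_rows, , drop = FALSE]
      dmlm[cbind(seq_along(scored_rows), targets)] <-
        dmlm[cbind(seq_along(scored_rows), targets)] - 1
      dlog_m[scored_rows, ] <- dlog_m[scored_rows, ] +
        dmlm * (lam[3] / length(scored_rows))
    }
    g_total <- add_grads(g_total,
                         toy_backward_batch(model$hyper, fwd_m$cache, dlog_m))
    list(grads = g_total, losses = c(supp = l_supp, maint = l_kl, mlm = l_mlm))
  }

  snap_rows <- list(); step_rows <- list()
  best <- list(score = -Inf, logits = state$logits, step = 0L)
  since_improve <- 0L
  take_snapshot <- function(t, losses) {
    m_eval <- eval_mask(state)
    supp_ppl <- eval_side(m_eval, supp_val, val_restrict_supp)
    maint_ppl <- eval_side(m_eval, maint_val, val_restrict_maint)
    score <- supp_ppl - config$maint_penalty * max(0, maint_ppl - base_maint_ppl)
    list(row = data.frame(step = t, sparsity = sparsity(m_eval),
                          val_supp_ppl = supp_ppl, val_maint_ppl = maint_ppl,
                          score = score),
         score = score)
  }

  t <- 0L
  while (t < config$max_steps) {
    t <- t + 1L
    set.seed(derive_seed(config$seed_noise, t))
    u <- stats::runif(K)
    s <- sample_scores(state$logits, state$tau, u)
    m <- binarize(s, state$threshold)
    set.seed(derive_seed(config$seed_data, t))
    supp_batch <- sample(supp_train, min(config$batch_size, length(supp_train)))
    maint_batch <- sample(maint_train, min(config$batch_size, length(maint_train)))
    plan_seeds <- sample.int(2147483646L,
                             length(supp_batch) + length(maint_batch))
    params_eff <- masked_params(model, m)
    res <- step_losses(params_eff, supp_batch, maint_batch, plan_seeds)
    total <- combine_losses(res$losses, lam)
    if (!is.finite(total)) {
      stop("non-finite loss at step ", t, " (components: ",
           paste(sprintf("%.4g", res$losses), collapse = ", "), ")",
           call. = FALSE)
    }
    grad_m <- mask_grad_from_weight_grads(model, res$grads)
    grad_l <- straight_through_grad(grad_m, s, state$tau)
    upd <- adam_step_flat(state$logits, grad_l, opt, config$lr)
    state$logits <- upd$x
    opt <- upd$state
    step_rows[[t]] <- data.frame(step = t, loss_supp = res$losses[["supp"]],
                                 loss_maint = res$losses[["maint"]],
                                 loss_mlm = res$losses[["mlm"]],
                                 loss_total = total,
                                 sparsity = sparsity(m))
    if (t %% config$snapshot_every == 0L || t == config$max_steps) {
      snap <- take_snapshot(t, res$losses)
      snap_rows[[length(snap_rows) + 1L]] <- snap$row
      if (is.finite(snap$score) && snap$score > best$score) {
        best <- list(score = snap$score, logits = state$logits, step = t)
        since_improve <- 0L
      } else {
        since_improve <- since_improve + 1L
        if (since_improve >= config$patience) break
      }
    }
  }
  if (config$max_steps == 0L) {
    snap <- take_snapshot(0L, c(supp = NA, maint = NA, mlm = NA))
    snap_rows[[1L]] <- snap$row
    best <- list(score = snap$score, logits = state$logits, step = 0L)
  }

  fp_after <- weights_fingerprint(model)
  if (!identical(fp_before, fp_after)) {
    stop("model weights changed during mask training", call. = FALSE)
  }
  state$logits <- best$logits
  structure(
    list(mask = state, m = eval_mask(state),
         log = do.call(rbind, snap_rows),
         step_log = do.call(rbind, step_rows),
         baseline = c(supp_ppl = base_supp_ppl, maint_ppl = base_maint_ppl),
         best_step = best$step, config = config),
    class = "subnet_fit"
  )
}

#' @export
print.subnet_fit <- function(x, ...) {
  last <- x$log[which.max(x$log$score), ]
  cat("<subnet_fit> best step ", x$best_step,
      sprintf(": sparsity %.2f%%, val supp ppl %.2f (baseline %.2f), val maint ppl %.2f (baseline %.2f)\n",
              sparsity(x$m), last$val_supp_ppl, x$baseline[["supp_ppl"]],
              last$val_maint_ppl, x$baseline[["maint_ppl"]]), sep = "")
  invisible(x)
}

#' Control suppression partitions
#'
#' Builds the two control targets used to check that suppression draws on
#' shared structure rather than optimization slack: suppressing `n`
#' randomly chosen sequences, or a random fraction of positions in every
#' sequence. Deterministic for a fixed seed.
#'
#' @param records A [domain_records()] object.
#' @param kind `"random_sequences"` or `"random_residues"`.
#' @param n Number of sequences to suppress (sequence control).
#' @param fraction Per-sequence fraction of positions to suppress, in
#'   (0, 1) (residue control); each position is drawn independently with
#'   this probability.
#' @param seed Integer seed.
#' @return A `suppression_partition`, interchangeable with
#'   [build_partition()] output.
#' @export
make_control_spec <- function(records,
                              kind = c("random_sequences", "random_residues"),
                              n = NULL, fraction = NULL, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(records, "domain_records"))
  if (kind == "random_sequences") {
    if (is.null(n)) stop("random_sequences control needs n", call. = FALSE)
    if (n > nrow(records)) {
      stop("n = ", n, " exceeds pool size ", nrow(records), call. = FALSE)
    }
    supp <- with_seed(seed, sample(records$id, n))
    structure(list(level = "sequence",
                   spec = list(level = "sequence", target_label = "<random>",
                               cath_level = NA_character_),
                   suppressed = supp,
                   maintained = setdiff(records$id, supp)),
              class = "suppression_partition")
  } else {
    if (is.null(fraction) || fraction <= 0 || fraction >= 1) {
      stop("random_residues control needs fraction in (0,1)", call. = FALSE)
    }
    lens <- nchar(records$sequence)
    pos <- with_seed(seed, lapply(lens, function(L) which(stats::runif(L) < fraction)))
    comp <- Map(function(L, p) setdiff(seq_len(L), p), lens, pos)
    names(pos) <- names(comp) <- records$id
    structure(list(level = "residue",
                   spec = list(level = "residue", target_label = "<random>"),
                   positions = pos, complement = comp),
              class = "suppression_partition")
  }
}
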