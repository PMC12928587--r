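#' Initialize a mask state
#'
#' The learnable mask over a model's K maskable slots: one real logit per
#' slot, a Gumbel-sigmoid temperature, and a binarization threshold. All
#' logits start at `init_logit` (default -5), which puts every noise-free
#' score near 1 so the initial subnetwork keeps essentially every weight
#' (sparsity ~ 0%): mask learning starts from the full model.
#'
#' Sign convention: a *larger* logit gives a *lower* score, so slots whose
#' logits rise during training are the ones that get pruned.
#'
#' @param model A `toy_plm` (supplies K and the manifest fingerprint).
#' @param init_logit Initial value for every logit.
#' @param tau Positive Gumbel-sigmoid temperature.
#' @param threshold Binarization threshold T in (0, 1).
#' @param noise_seed Integer seed for the per-step logistic noise.
#' @return An object of class `mask_state`.
#' @export
mask_state <- function(model, init_logit = -5, tau = 0.5, threshold = 0.5,
                       noise_seed = 1L) {
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0,1)", call. = FALSE)
  K <- n_maskable(model)
  structure(
    list(logits = rep(as.numeric(init_logit), K), tau = tau,
         threshold = threshold, noise_seed = as.integer(noise_seed),
         fingerprint = manifest_fingerprint(model)),
    class = "mask_state"
  )
}

#' @export
print.mask_state <- function(x, ...) {
  m <- eval_mask(x)
  cat("<mask_state> K = ", length(x$logits), ", tau = ", x$tau,
      ", T = ", x$threshold,
      sprintf(", deterministic sparsity %.2f%%\n", sparsity(m)), sep = "")
  invisible(x)
}

#' Gumbel-sigmoid mask scores
#'
#' Transforms logits into continuous mask scores in (0, 1):
#' `s_i = sigmoid( -(1/tau) * (l_i + log(u_i / (1 - u_i))) )`,
#' where `u_i` is standard-uniform noise. The added logistic noise makes
#' different binary mask configurations visible during training. For fixed
#' noise, scores are strictly decreasing in the logit, and over noise draws
#' `P(s_i > 1/2) = sigmoid(-l_i)`. Noise values at exactly 0 or 1 are
#' clamped to `[1e-6, 1 - 1e-6]` with a warning.
#'
#' @param logits Numeric vector of logits.
#' @param tau Positive temperature.
#' @param u Uniform noise in (0, 1), same length as `logits`.
#' @return Numeric vector of scores in (0, 1).
#' @export
sample_scores <- function(logits, tau, u) {
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  if (length(u) != length(logits)) stop("noise and logits lengths differ", call. = FALSE)
  eps <- 1e-6
  if (any(u <= 0 | u >= 1)) {
    warning("uniform noise clamped away from {0,1}")
    u <- pmin(pmax(u, eps), 1 - eps)
  }
  sigmoid(-(logits + log(u / (1 - u))) / tau)
}

#' Binarize mask scores
#'
#' Forward value of the straight-through estimator: `m_i = 1` when
#' `s_i > T` (strict), else 0. During training, gradients with respect to
#' `m` are passed through unchanged to `s` (see
#' [straight_through_grad()]).
#'
#' @param s Scores in `[0, 1]`.
#' @param threshold Threshold T.
#' @return Numeric 0/1 vector.
#' @export
binarize <- function(s, threshold = 0.5) {
  as.numeric(s > threshold)
}

#' Straight-through gradient to the logits
#'
#' Implements the straight-through estimator: the gradient of the loss with
#' respect to the binary mask `m` is taken as the gradient with respect to
#' the continuous score `s` (identity pass-through), then chained through
#' the Gumbel-sigmoid: `dL/dl_i = dL/dm_i * s_i (1 - s_i) * (-1/tau)`.
#'
#' @param grad_m Gradient of the loss w.r.t. the binary mask entries.
#' @param s The continuous scores used in the same step.
#' @param tau The temperature used in the same step.
#' @return Gradient w.r.t. the logits.
#' @export
straight_through_grad <- function(grad_m, s, tau) {
  grad_m * s * (1 - s) * (-1 / tau)
}

#' Deterministic evaluation-time mask
#'
#' The noise-free binarization used at evaluation time:
#' `m_i = 1( sigmoid(-l_i / tau) > T )`.
#'
#' @param state A [mask_state()].
#' @return Numeric 0/1 vector of length K.
#' @export
eval_mask <- function(state) {
  stopifnot(inherits(state, "mask_state"))
  binarize(sigmoid(-state$logits / state$tau), state$threshold)
}

#' Mask sparsity
#'
#' Percentage of mask entries equal to zero, i.e. of maskable parameters
#' ablated from the subnetwork.
#'
#' @param m Binary mask vector.
#' @return A percentage in `[0, 100]`.
#' @export
sparsity <- function(m) {
  if (!length(m)) stop("empty mask", call. = FALSE)
  if (!all(m %in% c(0, 1))) stop("mask must be binary", call. = FALSE)
  100 * sum(m == 0) / length(m)
}

#' Save / load a mask checkpoint
#'
#' A mask checkpoint is a self-describing RDS file holding the logits,
#' temperature, threshold, noise seed, the derived deterministic binary
#' mask, and the manifest fingerprint of the model the mask was trained
#' for. Loading against a model whose manifest fingerprint differs is an
#' error.
#'
#' @param state A [mask_state()].
#' @param path Checkpoint path.
#' @param model The model the mask must match.
#' @return `load_mask()` returns the `mask_state`.
#' @export
save_mask <- function(state, path) {
  stopifnot(inherits(state, "mask_state"))
  obj <- unclass(state)
  obj$mask <- eval_mask(state)
  obj$format <- "subnetlm-mask-1"
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_mask
#' @export
load_mask <- function(path, model = NULL) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read mask checkpoint '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$format, "subnetlm-mask-1")) {
    stop("not a subnetlm mask checkpoint: ", path, call. = FALSE)
  }
  state <- structure(obj[c("logits", "tau", "threshold", "noise_seed",
                           "fingerprint")],
                     class = "mask_state")
  if (!is.null(model)) {
    fp <- manifest_fingerprint(model)
    if (!identical(fp, state$fingerprint)) {
      stop("mask/model manifest fingerprint mismatch: mask was trained for a ",
           "different maskable structure", call. = FALSE)
    }
  }
  state
}
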