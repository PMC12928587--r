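# The three loss components of subnetwork training, the MLM corruption
# scheme, and perplexity. All distributions live on the 20-letter
# amino-acid support; all losses are arithmetic means over their included
# positions, in nats.

LOG_EPS <- 1e-9

check_rows_normalized <- function(p, what) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  if (any(p < 0)) stop(what, " has negative probabilities", call. = FALSE)
  bad <- abs(rowSums(p) - 1) > 1e-6
  if (any(bad)) {
    stop(what, " rows not normalized (row ", which(bad)[1], ")", call. = FALSE)
  }
  p
}

#' Suppression loss: KL to the uniform reference
#'
#' Mean over the included positions of `KL(p || U)` where `U` is uniform
#' over the 20 amino acids. Minimizing it pushes the subnetwork's
#' predictive distribution on suppressed inputs toward uniform guessing.
#' Sequence-level suppression includes every position of a suppressed
#' sequence; residue-level suppression includes only the suppressed
#' positions J* (pass them via `positions`).
#'
#' @param p Matrix of predictive distributions, one row per position,
#'   20 columns, rows summing to 1 (tolerance 1e-6).
#' @param positions Optional 1-based row subset to include (default: all).
#' @return Mean KL divergence in nats (0 when `p` is uniform everywhere,
#'   `log(20)` for one-hot rows).
#' @export
suppression_loss <- function(p, positions = NULL) {
  p <- check_rows_normalized(p, "predictive distribution")
  if (!is.null(positions)) p <- p[positions, , drop = FALSE]
  if (!nrow(p)) stop("no positions to score", call. = FALSE)
  V <- ncol(p)
  kl <- rowSums(p * log(pmax(p, LOG_EPS))) + log(V)
  mean(kl)
}

#' Maintenance loss: KL to the baseline model
#'
#' Mean over the included positions of `KL(p_subnet || p_baseline)`, the
#' baseline being the unmasked model's predictive distribution on the same
#' inputs (treated as a constant). Zeros in the baseline are floored at
#' 1e-9 so the divergence stays finite.
#'
#' @param p Subnetwork predictive distributions (rows = positions).
#' @param q Baseline predictive distributions, same shape.
#' @param positions Optional 1-based row subset to include.
#' @return Mean KL divergence in nats.
#' @export
maintenance_kl <- function(p, q, positions = NULL) {
  p <- check_rows_normalized(p, "subnetwork distribution")
  q <- check_rows_normalized(q, "baseline distribution")
  if (!all(dim(p) == dim(q))) stop("subnetwork/baseline shape mismatch", call. = FALSE)
  if (!is.null(positions)) {
    p <- p[positions, , drop = FALSE]
    q <- q[positions, , drop = FALSE]
  }
  if (!nrow(p)) stop("no positions to score", call. = FALSE)
  kl <- rowSums(p * (log(pmax(p, LOG_EPS)) - log(pmax(q, LOG_EPS))))
  mean(kl)
}

#' Plan MLM corruption for one sequence
#'
#' Implements the standard masked-LM corruption: each position is selected
#' independently with probability `rate` (default 15%); each selected
#' position is assigned an action — replace with the mask token (80%),
#' replace with a random amino acid (10%), or keep unchanged (10%).
#' Deterministic for a fixed seed.
#'
#' @param len Sequence length.
#' @param rate Selection probability in (0, 1).
#' @param action_mix Probabilities of `(mask, mutate, keep)`, summing to 1.
#' @param seed Integer seed.
#' @return An object of class `corruption_plan`: `positions` (1-based
#'   selected set M), `actions` (character, one of mask/mutate/keep per
#'   selected position), `replacements` (amino-acid letters for mutate
#'   actions, `NA` otherwise), and `complement` (the unselected M').
#' @export
make_corruption_plan <- function(len, rate = 0.15,
                                 action_mix = c(mask = 0.8, mutate = 0.1, keep = 0.1),
                                 seed = 1L) {
  if (rate <= 0 || rate >= 1) stop("rate must lie in (0,1)", call. = FALSE)
  if (length(action_mix) != 3L || any(action_mix < 0) ||
      abs(sum(action_mix) - 1) > 1e-8) {
    stop("action_mix must be three nonnegative numbers summing to 1", call. = FALSE)
  }
  len <- as.integer(len)
  if (len < 0L) stop("negative length", call. = FALSE)
  with_seed(seed, {
    sel <- which(stats::runif(len) < rate)
    acts <- if (length(sel)) {
      sample(c("mask", "mutate", "keep"), length(sel), replace = TRUE,
             prob = action_mix)
    } else character(0)
    repl <- rep(NA_character_, length(sel))
    mut <- acts == "mutate"
    if (any(mut)) repl[mut] <- sample(aa_alphabet(), sum(mut), replace = TRUE)
    structure(
      list(positions = sel, actions = acts, replacements = repl,
           complement = setdiff(seq_len(len), sel), len = len),
      class = "corruption_plan"
    )
  })
}

#' @export
print.corruption_plan <- function(x, ...) {
  cat("<corruption_plan> ", length(x$positions), "/", x$len,
      " positions selected (",
      paste(names(table(x$actions)), as.integer(table(x$actions)),
            sep = ":", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Apply a corruption plan to a token sequence
#'
#' @param tokens Integer token ids.
#' @param plan A [make_corruption_plan()] for the same length.
#' @param vocab A [plm_vocab()].
#' @return The corrupted integer token vector.
#' @export
apply_corruption <- function(tokens, plan, vocab = plm_vocab()) {
  stopifnot(inherits(plan, "corruption_plan"))
  if (plan$len != length(tokens)) {
    stop("plan length ", plan$len, " does not match sequence length ",
         length(tokens), call. = FALSE)
  }
  out <- tokens
  for (k in seq_along(plan$positions)) {
    i <- plan$positions[k]
    out[i] <- switch(plan$actions[k],
                     mask = vocab$mask_id,
                     mutate = match(plan$replacements[k], vocab$tokens),
                     keep = out[i])
  }
  out
}

#' Maintenance MLM loss
#'
#' Mean negative log-probability of the true residue at the scored
#' positions of a corrupted sequence: the selected set M at sequence level,
#' or M with the suppressed residue positions J removed
#' (i.e. the intersection of M with the maintained positions J') at
#' residue level. Positions whose true token is not one of the 20 amino
#' acids (e.g. unknown residues) are never scored. An empty scored set
#' returns 0 with a warning.
#'
#' @param p Predictive distributions on the corrupted input (rows =
#'   positions of the full sequence, 20 columns).
#' @param truth Integer token ids of the uncorrupted sequence.
#' @param plan The [make_corruption_plan()] used to corrupt the input.
#' @param exclude_positions Optional 1-based positions to exclude from
#'   scoring (the suppressed residue set J for residue-level training).
#' @return Mean NLL in nats over the scored positions.
#' @export
mlm_loss <- function(p, truth, plan, exclude_positions = NULL) {
  stopifnot(inherits(plan, "corruption_plan"))
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  if (nrow(p) != length(truth)) stop("p/truth length mismatch", call. = FALSE)
  if (length(plan$positions) && max(plan$positions) > nrow(p)) {
    stop("corruption position out of range", call. = FALSE)
  }
  scored <- setdiff(plan$positions, exclude_positions)
  scored <- scored[truth[scored] <= ncol(p)]
  if (!length(scored)) {
    warning("empty scored set; MLM loss is 0")
    return(0)
  }
  nll <- -log(pmax(p[cbind(scored, truth[scored])], LOG_EPS))
  mean(nll)
}

#' Combine the loss components
#'
#' The weighted training objective
#' `L = lambda1 * L_supp + lambda2 * L_maint + lambda3 * L_mlm`,
#' with every component oriented so that joint minimization suppresses the
#' target category while maintaining everything else.
#'
#' @param losses Numeric length-3 vector `(L_supp, L_maint, L_mlm)`.
#' @param lambda Nonnegative length-3 weights, not all zero.
#' @return The scalar combined loss.
#' @export
combine_losses <- function(losses, lambda = c(1, 1, 1)) {
  if (length(losses) != 3L || length(lambda) != 3L) {
    stop("losses and lambda must have length 3", call. = FALSE)
  }
  if (any(lambda < 0)) stop("negative loss weight", call. = FALSE)
  if (all(lambda == 0)) stop("all loss weights are zero", call. = FALSE)
  sum(lambda * losses)
}

#' Perplexity
#'
#' The exponential of the mean per-position negative log-likelihood (in
#' nats). A uniform predictor over the 20 amino acids scores exactly 20; a
#' perfect predictor scores 1.
#'
#' @param nll Numeric vector of per-position negative log-likelihoods.
#' @return The scalar perplexity.
#' @export
perplexity <- function(nll) {
  if (!length(nll)) stop("empty NLL vector", call. = FALSE)
  exp(mean(nll))
}
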