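#' Build the bundled toy masked language model
#'
#' A small bidirectional transformer encoder with an MLM head, satisfying
#' the package's model contract: `plm_forward()` returns per-position
#' predictive distributions over the 20 amino acids, and
#' [maskable_index()] is an ordered manifest of the K maskable weight
#' slots. Following the usual subnetwork masking scope, only the
#' attention and feed-forward projection weight matrices are maskable;
#' embeddings, biases and layer-normalization parameters are excluded from
#' the manifest and are never altered by a mask.
#'
#' Architecture: learned token + position embeddings, `depth` pre-norm
#' blocks (multi-head self-attention + GELU feed-forward of width
#' `ff_mult * width`), a final layer norm, and a linear head over the
#' 20-letter support. Weights use Xavier-style initialization.
#'
#' @param vocab A [plm_vocab()]; must contain the `<mask>` token.
#' @param depth Number of transformer blocks.
#' @param width Model (embedding) dimension; must be divisible by `heads`.
#' @param heads Number of attention heads.
#' @param ff_mult Feed-forward expansion factor.
#' @param max_len Maximum sequence length (position-embedding rows).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `toy_plm`.
#' @export
build_toy_model <- function(vocab = plm_vocab(), depth = 2L, width = 32L,
                            heads = 4L, ff_mult = 4L, max_len = 1024L,
                            seed = 1L) {
  if (depth <= 0L || width <= 0L) stop("depth and width must be positive", call. = FALSE)
  if (width %% heads != 0L) stop("width must be divisible by heads", call. = FALSE)
  if (is.null(vocab$mask_id) || !"<mask>" %in% vocab$tokens) {
    stop("vocabulary must contain a <mask> token", call. = FALSE)
  }
  d <- as.integer(width); ff <- as.integer(ff_mult * width)
  V <- length(vocab$tokens); n_out <- vocab$n_aa
  xavier <- function(nr, nc) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
  }
  params <- with_seed(seed, {
    blocks <- lapply(seq_len(depth), function(b) {
      list(
        ln1_g = rep(1, d), ln1_b = rep(0, d),
        Wq = xavier(d, d), bq = rep(0, d),
        Wk = xavier(d, d), bk = rep(0, d),
        Wv = xavier(d, d), bv = rep(0, d),
        Wo = xavier(d, d), bo = rep(0, d),
        ln2_g = rep(1, d), ln2_b = rep(0, d),
        W1 = xavier(d, ff), b1 = rep(0, ff),
        W2 = xavier(ff, d), b2 = rep(0, d)
      )
    })
    list(
      tok_emb = matrix(stats::rnorm(V * d, sd = 0.02), V, d),
      pos_emb = sinusoidal_embedding(max_len, d),
      blocks = blocks,
      lnf_g = rep(1, d), lnf_b = rep(0, d),
      W_head = xavier(d, n_out), b_head = rep(0, n_out)
    )
  })
  hyper <- list(depth = as.integer(depth), width = d, heads = as.integer(heads),
                ff = ff, max_len = as.integer(max_len), n_out = n_out,
                seed = as.integer(seed))
  model <- structure(list(params = params, hyper = hyper, vocab = vocab),
                     class = "toy_plm")
  model$manifest <- build_manifest(model)
  model
}

# Fixed-frequency sinusoidal position embeddings (trainable after init).
# Sinusoids make relative offsets linearly decodable, which speeds up
# learning of local sequence patterns at small scale.
sinusoidal_embedding <- function(max_len, d, scale = 0.1) {
  pos <- seq_len(max_len) - 1L
  out <- matrix(0, max_len, d)
  half <- d %/% 2L
  for (j in seq_len(half)) {
    freq <- 1 / (10000^(2 * (j - 1) / d))
    out[, 2L * j - 1L] <- sin(pos * freq)
    out[, 2L * j] <- cos(pos * freq)
  }
  out * scale
}

# Ordered manifest of maskable slots: the projection weight matrices of each
# block, flattened column-major. One row per tensor; `offset`/`length` give
# the slot range inside the flat mask vector.
build_manifest <- function(model) {
  h <- model$hyper
  modules <- c("Wq", "Wk", "Wv", "Wo", "W1", "W2")
  rows <- list()
  off <- 0L
  for (b in seq_len(h$depth)) {
    for (mod in modules) {
      W <- model$params$blocks[[b]][[mod]]
      len <- length(W)
      rows[[length(rows) + 1L]] <- data.frame(
        layer = b, module = mod, nrow = nrow(W), ncol = ncol(W),
        offset = off, length = len
      )
      off <- off + len
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "K") <- off
  out
}

#' Manifest of maskable weight slots
#'
#' One row per maskable tensor (layer, module, shape, and the slot range it
#' occupies in the flat mask vector); the total slot count K is
#' `n_maskable()`.
#'
#' @param model A `toy_plm`.
#' @return Data frame with columns `layer`, `module`, `nrow`, `ncol`,
#'   `offset`, `length`.
#' @export
maskable_index <- function(model) {
  stopifnot(inherits(model, "toy_plm"))
  model$manifest
}

#' @rdname maskable_index
#' @return `n_maskable()` returns the integer K.
#' @export
n_maskable <- function(model) {
  attr(maskable_index(model), "K")
}

#' @rdname maskable_index
#' @param i Slot index in `1..K`.
#' @return `slot_info()` returns a one-row data frame with the layer,
#'   module and within-tensor `(row, col)` coordinate of slot `i`.
#' @export
slot_info <- function(model, i) {
  man <- maskable_index(model)
  if (i < 1L || i > attr(man, "K")) stop("slot index out of range", call. = FALSE)
  r <- man[man$offset < i & i <= man$offset + man$length, , drop = FALSE]
  j <- i - r$offset
  data.frame(layer = r$layer, module = r$module,
             row = (j - 1L) %% r$nrow + 1L,
             col = (j - 1L) %/% r$nrow + 1L)
}

#' Fingerprints of the maskable manifest and of the model weights
#'
#' `manifest_fingerprint()` hashes the slot manifest (architecture shape);
#' it is stored in mask checkpoints so a mask can never be loaded against a
#' model with a different maskable structure. `weights_fingerprint()`
#' hashes all parameter values and is used to assert that mask training
#' leaves the model weights untouched.
#'
#' @param model A `toy_plm`.
#' @return A single md5 string.
#' @export
manifest_fingerprint <- function(model) {
  man <- maskable_index(model)
  object_md5(man[, c("layer", "module", "nrow", "ncol", "offset", "length")])
}

#' @rdname manifest_fingerprint
#' @export
weights_fingerprint <- function(model) {
  object_md5(model$params)
}

# Effective parameters under a binary mask: maskable tensors are multiplied
# elementwise by their mask segment; everything else is untouched.
masked_params <- function(model, m) {
  if (is.null(m)) return(model$params)
  man <- maskable_index(model)
  K <- attr(man, "K")
  if (length(m) != K) {
    stop("mask length ", length(m), " does not match K = ", K, call. = FALSE)
  }
  params <- model$params
  for (r in seq_len(nrow(man))) {
    seg <- m[man$offset[r] + seq_len(man$length[r])]
    if (all(seg == 1)) next
    W <- params$blocks[[man$layer[r]]][[man$module[r]]]
    params$blocks[[man$layer[r]]][[man$module[r]]] <-
      W * matrix(seg, man$nrow[r], man$ncol[r])
  }
  params
}

#' Attach a binary mask to a model
#'
#' Returns a model whose forward pass multiplies each maskable weight slot
#' by its mask entry (Hadamard product between the mask and the pretrained
#' weights). The stored weights themselves are never modified, so applying
#' an all-ones mask afterwards restores baseline behavior exactly.
#'
#' @param model A `toy_plm`.
#' @param m Binary vector of length [n_maskable()] (or `NULL` to detach).
#' @return The model with the mask attached.
#' @export
apply_mask <- function(model, m) {
  stopifnot(inherits(model, "toy_plm"))
  if (!is.null(m)) {
    if (length(m) != n_maskable(model)) {
      stop("mask length ", length(m), " does not match K = ",
           n_maskable(model), call. = FALSE)
    }
    if (!all(m %in% c(0, 1))) stop("mask must be binary", call. = FALSE)
    m <- as.numeric(m)
  }
  model$mask <- m
  model
}

#' Model forward pass
#'
#' Runs the encoder on one token sequence and returns the per-position
#' predictive distribution over the 20 amino acids. A mask supplied here
#' (or previously attached with [apply_mask()]) multiplies the maskable
#' weights; an all-ones mask is bit-identical to no mask.
#'
#' @param model A `toy_plm`.
#' @param tokens Integer token ids (from [tokenize()]).
#' @param m Optional binary mask of length [n_maskable()]; overrides any
#'   attached mask.
#' @return A `length(tokens) x 20` matrix of probabilities, rows summing
#'   to 1.
#' @export
plm_forward <- function(model, tokens, m = NULL) {
  stopifnot(inherits(model, "toy_plm"))
  if (is.null(m)) m <- model$mask
  params <- masked_params(model, m)
  toy_forward(params, model$hyper, tokens, want_cache = FALSE)$probs
}

#' @export
print.toy_plm <- function(x, ...) {
  h <- x$hyper
  cat("<toy_plm> depth ", h$depth, ", width ", h$width, ", ", h$heads,
      " heads, ff ", h$ff, "; K = ", n_maskable(x), " maskable slots",
      if (!is.null(x$mask)) sprintf("; mask attached (%.1f%% pruned)",
                                    sparsity(x$mask)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are self-describing RDS files holding the architecture
#' hyperparameters, vocabulary, weights and the maskable-slot manifest.
#'
#' @param model A `toy_plm`.
#' @param path Checkpoint path.
#' @return `load_model()` returns the `toy_plm`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "toy_plm"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!all(c("params", "hyper", "vocab", "manifest") %in% names(obj))) {
    stop("not a toy_plm checkpoint: ", path, call. = FALSE)
  }
  structure(obj, class = "toy_plm")
}
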