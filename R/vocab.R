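#' The 20-letter amino-acid alphabet
#'
#' Canonical one-letter amino-acid codes in the fixed order used by every
#' model and loss in the package. All predictive distributions are defined
#' over this support.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Model vocabulary
#'
#' The token inventory of the bundled masked language model: the 20 amino
#' acids followed by the special tokens `<mask>`, `<pad>` and `<unk>`.
#' Special tokens are legal model inputs but are excluded from the predictive
#' support: perplexity, KL and MLM losses are computed over the 20
#' amino-acid letters only.
#'
#' @return An object of class `plm_vocab`: a list with `tokens` (ordered
#'   character vector), `n_aa` (20), and the integer ids `mask_id`, `pad_id`,
#'   `unk_id`.
#' @export
plm_vocab <- function() {
  tokens <- c(aa_alphabet(), "<mask>", "<pad>", "<unk>")
  structure(
    list(
      tokens = tokens,
      n_aa = 20L,
      mask_id = 21L,
      pad_id = 22L,
      unk_id = 23L
    ),
    class = "plm_vocab"
  )
}

#' @export
print.plm_vocab <- function(x, ...) {
  cat("<plm_vocab> ", length(x$tokens), " tokens (", x$n_aa,
      " amino acids + <mask>, <pad>, <unk>)\n", sep = "")
  invisible(x)
}

#' Tokenize an amino-acid sequence
#'
#' Maps a sequence string to integer token ids. Noncanonical letters
#' (X, B, Z, U, O, and anything else outside the 20-letter alphabet) are
#' handled according to `noncanonical`: the default maps them to the
#' `<unk>` token, whose positions are excluded from every loss downstream;
#' `"reject"` raises an error instead.
#'
#' @param sequence A single amino-acid string.
#' @param vocab A [plm_vocab()].
#' @param noncanonical Either `"unk"` (default) or `"reject"`.
#' @return Integer vector of token ids (1-based into `vocab$tokens`).
#' @export
tokenize <- function(sequence, vocab = plm_vocab(), noncanonical = c("unk", "reject")) {
  noncanonical <- match.arg(noncanonical)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  ids <- match(chars, vocab$tokens[seq_len(vocab$n_aa)])
  bad <- is.na(ids)
  if (any(bad)) {
    if (noncanonical == "reject") {
      stop("noncanonical residue(s) ",
           paste(unique(chars[bad]), collapse = ", "),
           " at position(s) ", paste(utils::head(which(bad), 5L), collapse = ", "),
           call. = FALSE)
    }
    ids[bad] <- vocab$unk_id
  }
  ids
}

#' @rdname tokenize
#' @param ids Integer token ids.
#' @return `detokenize()` returns the corresponding string.
#' @export
detokenize <- function(ids, vocab = plm_vocab()) {
  paste(vocab$tokens[ids], collapse = "")
}
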