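# Synthetic classed-sequence corpus: a desk-scale stand-in for a CATH-style
# dataset. Each class gets its own residue-frequency profile and short
# sequence motifs (the sequence-level signal); planted 3-state annotations
# modulate local composition (the residue-level signal).

state_profiles <- function() {
  aa <- aa_alphabet()
  mk <- function(fav) {
    p <- rep(0.2 / (20 - length(fav)), 20)
    p[match(fav, aa)] <- 0.8 / length(fav)
    names(p) <- aa
    p
  }
  list(
    H = mk(c("A", "L", "E", "K", "M", "Q", "R")),
    E = mk(c("V", "I", "F", "Y", "W", "T", "C")),
    L = mk(c("G", "P", "S", "N", "D"))
  )
}

default_class_profiles <- function(n_classes, concentration = 0.85) {
  aa <- aa_alphabet()
  sets <- list(
    c("A", "L", "E", "K", "R", "Q"),
    c("V", "I", "F", "Y", "T", "W"),
    c("G", "P", "S", "N", "D", "H")
  )
  profs <- matrix(0, n_classes, 20, dimnames = list(NULL, aa))
  for (c_i in seq_len(n_classes)) {
    fav <- if (c_i <= length(sets)) sets[[c_i]] else {
      aa[((c_i - 1L) * 7L + seq_len(6L) - 1L) %% 20L + 1L]
    }
    p <- rep((1 - concentration) / (20 - length(fav)), 20)
    p[match(fav, aa)] <- concentration / length(fav)
    profs[c_i, ] <- p
  }
  profs
}

default_class_motifs <- function(n_classes) {
  base <- list(
    c("ALEKRQALEK", "KEQRLAKEQR", "QRALEKQRAL"),
    c("VIFYTWVIFY", "YTWVIFYTWV", "TWVIYFTWVI"),
    c("GPSNDHGPSN", "NDHGPSNDHG", "SNGPDHSNGP")
  )
  lapply(seq_len(n_classes), function(c_i) {
    if (c_i <= length(base)) base[[c_i]] else {
      prof <- default_class_profiles(n_classes)[c_i, ]
      paste(rep(names(sort(prof, decreasing = TRUE))[1:5], 2), collapse = "")
    }
  })
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

#' Specify a synthetic classed corpus
#'
#' Defines the generating process for a synthetic corpus of protein-like
#' sequences: `n_classes` sequence-level categories (standing in for CATH
#' classes), each with a distinct residue-frequency profile and short
#' class-specific motifs, plus planted per-residue 3-state annotations
#' (standing in for DSSP helix/strand/loop) drawn from a segment process
#' with state-specific local composition.
#'
#' Per-position emission probabilities are the mixture
#' `(1 - state_mix) * class_profile + state_mix * state_profile`, after
#' which class motifs are stamped over a few random windows. With
#' `state_mix = 0` and `motifs = NULL` the per-class empirical residue
#' frequencies converge to `profiles` as the corpus grows.
#'
#' @param n_classes Number of sequence-level classes.
#' @param n_per_class Sequences generated per class.
#' @param length_range Inclusive range of sequence lengths.
#' @param profiles Optional `n_classes x 20` matrix of residue frequencies
#'   (rows sum to 1, columns in [aa_alphabet()] order).
#' @param motifs Optional list (length `n_classes`) of character vectors of
#'   class motifs; `NULL` disables motif planting, missing uses defaults.
#' @param motifs_per_seq Integer range of motif copies stamped per sequence.
#' @param state_mix Mixture weight of the secondary-structure-state profile
#'   in the per-position emission (0 disables the residue-level signal).
#' @param min_tv Minimum pairwise total-variation distance required between
#'   class profiles, so that sequence-level suppression has a learnable
#'   signal.
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 3L, n_per_class = 150L,
                           length_range = c(64L, 96L),
                           profiles = NULL,
                           motifs = default_class_motifs(n_classes),
                           motifs_per_seq = c(3L, 5L),
                           state_mix = 0.25,
                           min_tv = 0.2,
                           seed = 1L) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 1L) stop("n_classes must be >= 1", call. = FALSE)
  if (is.null(profiles)) profiles <- default_class_profiles(n_classes)
  profiles <- as.matrix(profiles)
  if (nrow(profiles) != n_classes || ncol(profiles) != 20L) {
    stop("profiles must be an n_classes x 20 matrix", call. = FALSE)
  }
  if (any(profiles < 0) || any(rowSums(profiles) <= 0)) {
    stop("degenerate class profile: zero or negative mass", call. = FALSE)
  }
  profiles <- profiles / rowSums(profiles)
  if (n_classes > 1L) {
    for (a in seq_len(n_classes - 1L)) {
      for (b in seq(a + 1L, n_classes)) {
        tv <- total_variation(profiles[a, ], profiles[b, ])
        if (tv < min_tv) {
          stop(sprintf("class profiles %d and %d are too similar (TV %.3f < %.3f)",
                       a, b, tv, min_tv), call. = FALSE)
        }
      }
    }
  }
  if (!is.null(motifs) && length(motifs) != n_classes) {
    stop("motifs must have one entry per class (or be NULL)", call. = FALSE)
  }
  if (length(length_range) != 2L || length_range[1] > length_range[2] ||
      length_range[1] < 1L) {
    stop("invalid length_range", call. = FALSE)
  }
  structure(
    list(n_classes = n_classes, n_per_class = as.integer(n_per_class),
         length_range = as.integer(length_range), profiles = profiles,
         motifs = motifs, motifs_per_seq = as.integer(motifs_per_seq),
         state_mix = state_mix, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# One planted 3-state annotation string: alternating segments with
# state-typical lengths (helices longest, loops shortest).
plant_ss3 <- function(len) {
  states <- character(0)
  while (length(states) < len) {
    st <- sample(c("H", "E", "L"), 1L, prob = c(0.38, 0.3, 0.32))
    seg <- switch(st,
                  H = sample(4:12, 1L),
                  E = sample(3:8, 1L),
                  L = sample(2:6, 1L))
    states <- c(states, rep(st, seg))
  }
  states[seq_len(len)]
}

#' Generate a synthetic classed corpus
#'
#' Draws the corpus described by a [synthetic_spec()]: deterministic for a
#' fixed spec (including its seed). Each record carries a synthetic 4-field
#' CATH-style label whose Class field is the class index (so Class-level
#' suppression of class `c` targets label `"c"`), and a full-length planted
#' 3-state annotation.
#'
#' @param spec A [synthetic_spec()].
#' @return A [domain_records()] object with `n_classes * n_per_class` rows.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  aa <- aa_alphabet()
  st_prof <- state_profiles()
  with_seed(spec$seed, {
    ids <- character(0); seqs <- character(0); labs <- character(0); sss <- character(0)
    for (c_i in seq_len(spec$n_classes)) {
      class_p <- spec$profiles[c_i, ]
      for (r in seq_len(spec$n_per_class)) {
        len <- sample(seq(spec$length_range[1], spec$length_range[2]), 1L)
        ss <- plant_ss3(len)
        chars <- character(len)
        for (st in c("H", "E", "L")) {
          at <- which(ss == st)
          if (!length(at)) next
          p <- (1 - spec$state_mix) * class_p + spec$state_mix * st_prof[[st]]
          chars[at] <- sample(aa, length(at), replace = TRUE, prob = p)
        }
        if (!is.null(spec$motifs)) {
          n_mot <- sample(seq(spec$motifs_per_seq[1], spec$motifs_per_seq[2]), 1L)
          for (k in seq_len(n_mot)) {
            mot <- strsplit(sample(spec$motifs[[c_i]], 1L), "")[[1]]
            if (len >= length(mot)) {
              start <- sample(seq_len(len - length(mot) + 1L), 1L)
              chars[start + seq_along(mot) - 1L] <- mot
            }
          }
        }
        ids <- c(ids, sprintf("syn%d_%04d", c_i, r))
        seqs <- c(seqs, paste(chars, collapse = ""))
        labs <- c(labs, sprintf("%d.1.1.1", c_i))
        sss <- c(sss, paste(ss, collapse = ""))
      }
    }
    domain_records(ids, seqs, labs, sss)
  })
}
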