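# Small fixtures built in code, shared across test files.

# A handful of records with full annotations.
tiny_records <- function() {
  domain_records(
    id = c("a", "b", "c", "d"),
    sequence = c("ALEKRQALEK", "VIFYTWVIFY", "GPSNDHGPSN", "ALEKVIFYGP"),
    cath_label = c("1.10.8.10", "2.40.50.140", "3.40.50.720", "1.20.5.110"),
    ss3 = c("HHHHHHHHHH", "EEEEEEEEEE", "LLLLLLLLLL", "HHHHEEEELL")
  )
}

# Random records with uniform sequences and random annotations.
random_records <- function(n, len_range = c(10L, 30L), n_class = 3L,
                           seed = 1L) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
    domain_records(
      id = sprintf("r%03d", seq_len(n)),
      sequence = vapply(lens, function(L)
        paste(sample(aa_alphabet(), L, replace = TRUE), collapse = ""),
        character(1)),
      cath_label = sprintf("%d.%d.%d.%d",
                           sample.int(n_class, n, replace = TRUE),
                           sample.int(3, n, replace = TRUE),
                           sample.int(3, n, replace = TRUE),
                           sample.int(3, n, replace = TRUE)),
      ss3 = vapply(lens, function(L)
        paste(sample(c("H", "E", "L"), L, replace = TRUE), collapse = ""),
        character(1))
    )
  })
}

# A very small model for fast structural tests.
small_model <- function(depth = 2L, width = 16L, heads = 2L, seed = 7L) {
  build_toy_model(depth = depth, width = width, heads = heads,
                  max_len = 128L, seed = seed)
}

subset_records <- function(records, ids) {
  out <- records[records$id %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("domain_records", "data.frame")
  out
}
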