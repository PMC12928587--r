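test_that("DSSP 8-state strings reduce to 3 states by the standard mapping", {
  expect_identical(reduce_dssp("HGIEBTS-"), "HHHEELLL")
  expect_identical(reduce_dssp("TTEEHH"), "LLEEHH")
  expect_identical(reduce_dssp(""), "")
  expect_identical(reduce_dssp(c("HG", "EB")), c("HH", "EE"))
  expect_error(reduce_dssp("HGX"), "unknown DSSP state 'X' at position 3")
  # H and E are fixed points of the mapping (idempotence on its own output)
  out <- reduce_dssp("HGIEB")
  expect_identical(reduce_dssp(gsub("L", "", out)), gsub("L", "", out))
})

test_that("CATH labels truncate to the requested hierarchy level", {
  expect_identical(truncate_cath("3.40.50.720", "Class"), "3")
  expect_identical(truncate_cath("3.40.50.720", "Architecture"), "3.40")
  expect_identical(truncate_cath("3.40.50.720", "Topology"), "3.40.50")
  expect_identical(truncate_cath("3.40.50.720", "HomologousSuperfamily"),
                   "3.40.50.720")
  # short labels are fine when the level is available, an error otherwise
  expect_identical(truncate_cath("3.40", "Architecture"), "3.40")
  expect_error(truncate_cath("3.40", "HomologousSuperfamily"), "needs 4")
})

test_that("domain_records validates annotation consistency", {
  expect_error(domain_records("a", "ALEK", ss3 = "HH"), "ss3 length")
  expect_error(domain_records(c("a", "a"), c("ALEK", "GPSN")), "duplicate")
  expect_error(domain_records("a", "ALEK", ss3 = "HHXX"), "outside")
  rec <- domain_records("a", "alek")
  expect_identical(rec$sequence, "ALEK")
})

test_that("sequence-level partitions match truncated labels", {
  rec <- domain_records(c("a", "b", "c"), c("AAAA", "CCCC", "DDDD"),
                        cath_label = c("1.10", "2.40", "1.20"))
  part <- build_partition(rec, suppression_spec("sequence", "1", "Class"))
  expect_setequal(part$suppressed, c("a", "c"))
  expect_identical(part$maintained, "b")
  expect_error(
    build_partition(rec, suppression_spec("sequence", "9", "Class")),
    "no record matches"
  )
  rec$cath_label[2] <- NA
  class(rec) <- c("domain_records", "data.frame")
  expect_error(build_partition(rec, suppression_spec("sequence", "1", "Class")),
               "missing cath_label: b")
})

test_that("residue-level partitions index target-state positions", {
  rec <- domain_records("a", "ALEKRQ", ss3 = "HHLLEE")
  part <- build_partition(rec, suppression_spec("residue", "E"))
  expect_identical(part$positions[["a"]], c(5L, 6L))
  expect_identical(part$complement[["a"]], 1:4)
  expect_error(build_partition(rec, suppression_spec("residue", "X")),
               "H, E, L")
})

test_that("partitions are disjoint and exhaustive on random record sets", {
  for (seed in 1:5) {
    rec <- random_records(20, seed = seed)
    part <- build_partition(rec, suppression_spec("sequence", "1", "Class"))
    expect_length(intersect(part$suppressed, part$maintained), 0)
    expect_setequal(c(part$suppressed, part$maintained), rec$id)
    for (state in c("H", "E", "L")) {
      rp <- build_partition(rec, suppression_spec("residue", state))
      for (id in rec$id) {
        L <- nchar(rec$sequence[rec$id == id])
        expect_length(intersect(rp$positions[[id]], rp$complement[[id]]), 0)
        expect_setequal(c(rp$positions[[id]], rp$complement[[id]]), seq_len(L))
      }
    }
  }
})

test_that("suppression_spec validates label granularity", {
  expect_error(suppression_spec("sequence", "1.10", "Class"), "requires 1")
  expect_error(suppression_spec("sequence", "1", "Architecture"), "requires 2")
  s <- suppression_spec("sequence", "3.40.50", "Topology")
  expect_identical(s$target_label, "3.40.50")
})

test_that("length filtering keeps both bounds inclusively", {
  rec <- domain_records(
    sprintf("s%d", 1:5),
    vapply(c(63, 64, 500, 1024, 1025), function(L)
      paste(rep("A", L), collapse = ""), character(1))
  )
  kept <- filter_by_length(rec)
  expect_identical(nchar(kept$sequence), c(64L, 500L, 1024L))
  expect_identical(nrow(filter_by_length(rec[0, ])), 0L)
  expect_identical(filter_by_length(rec, 0, Inf)$id, rec$id)
  expect_error(filter_by_length(rec, 10, 5), "exceeds")
})

test_that("dataset splits are 70/20/10 with remainder to train", {
  rec <- random_records(10)
  sp <- split_dataset(rec, seed = 3)
  counts10 <- table(factor(sp$partition, c("train", "validation", "test")))
  expect_identical(as.integer(counts10), c(7L, 2L, 1L))
  # floor allocation + remainder-to-train for every n up to 200
  for (n in 1:200) {
    n_val <- as.integer(floor(0.2 * n)); n_test <- as.integer(floor(0.1 * n))
    rec_n <- domain_records(sprintf("x%03d", 1:n), rep("ACDE", n))
    sp_n <- split_dataset(rec_n, seed = 1)
    counts <- table(factor(sp_n$partition, c("train", "validation", "test")))
    expect_identical(as.integer(counts),
                     c(n - n_val - n_test, n_val, n_test))
  }
})

test_that("splits are deterministic, disjoint and exhaustive", {
  rec <- random_records(57, seed = 2)
  a <- split_dataset(rec, seed = 42)
  b <- split_dataset(rec, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_setequal(a$id, rec$id)
  expect_false(identical(as.data.frame(a),
                         as.data.frame(split_dataset(rec, seed = 43))))
  expect_error(split_dataset(rec, fractions = c(0.5, 0.5, 0.2)), "sum to 1")
  expect_error(split_dataset(rec, fractions = c(0.9, 0.2, -0.1)), "positive")
})

test_that("stratified splitting balances classes across partitions", {
  rec <- random_records(90, n_class = 3, seed = 4)
  sp <- split_dataset(rec, seed = 7, stratify_by_class = TRUE)
  cls <- truncate_cath(rec$cath_label[match(sp$id, rec$id)], "Class")
  tab <- table(cls, sp$partition)
  # every class appears in train, and per-class train share is close to 70%
  for (k in rownames(tab)) {
    frac <- tab[k, "train"] / sum(tab[k, ])
    expect_gt(frac, 0.6)
    expect_lt(frac, 0.85)
  }
})
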