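test_that("an all-ones mask reproduces the baseline column exactly", {
  rec <- random_records(8, len_range = c(15L, 25L), seed = 21)
  model <- small_model()
  part <- build_partition(rec, suppression_spec("sequence", "1", "Class"))
  rep_all1 <- stratified_perplexity(model, rep(1, n_maskable(model)), rec,
                                    part, reps = 1)
  tab <- rep_all1$table
  for (st in c("suppression", "maintenance")) {
    sub <- tab$perplexity[tab$stratum == st & tab$model == "subnetwork"]
    base <- tab$perplexity[tab$stratum == st & tab$model == "baseline"]
    expect_identical(sub, base)
  }
  expect_equal(rep_all1$sparsity, 0)
})

test_that("perplexity cells match independently pooled NLLs", {
  ns <- asNamespace("subnetlm")
  rec <- random_records(6, len_range = c(15L, 20L), seed = 31)
  model <- small_model()
  part <- build_partition(rec, suppression_spec("residue", "E"))
  rep_res <- stratified_perplexity(model, NULL, rec, part, reps = 1, seed = 5)
  # oracle: recompute pooled NLLs with the same plans and split them by J*
  nll_supp <- c(); nll_maint <- c()
  for (i in seq_len(nrow(rec))) {
    tk <- tokenize(rec$sequence[i])
    plan <- make_corruption_plan(length(tk),
                                 seed = ns$derive_seed(5, i * 257L + 1L))
    res <- ns$masked_nll_one(model, tk, plan)
    hit <- res$positions %in% part$positions[[rec$id[i]]]
    nll_supp <- c(nll_supp, res$nll[hit])
    nll_maint <- c(nll_maint, res$nll[!hit])
  }
  tab <- rep_res$table
  expect_equal(tab$perplexity[tab$stratum == "suppression" &
                                tab$model == "baseline"],
               perplexity(nll_supp), tolerance = 1e-12)
  expect_equal(tab$perplexity[tab$stratum == "maintenance" &
                                tab$model == "baseline"],
               perplexity(nll_maint), tolerance = 1e-12)
  expect_identical(tab$n_positions[tab$stratum == "suppression" &
                                     tab$model == "baseline"],
                   length(nll_supp))
})

test_that("empty strata are reported as absent rather than zero", {
  rec <- domain_records(c("a", "b"), c("ALEKRQALEKRQ", "VIFYTWVIFYTW"),
                        cath_label = c("1.10.8.10", "1.20.5.110"),
                        ss3 = c("HHHHHHHHHHHH", "EEEEEEEEEEEE"))
  model <- small_model()
  part <- build_partition(rec, suppression_spec("sequence", "1.10",
                                                "Architecture"))
  split <- structure(
    data.frame(id = c("a", "b"), partition = c("train", "train")),
    class = c("split_assignment", "data.frame"))
  out <- stratified_perplexity(model, NULL, rec, part, split = split, reps = 1)
  val_rows <- out$table[out$table$split == "validation", ]
  expect_true(all(is.na(val_rows$perplexity)))
  expect_true(all(val_rows$n_positions == 0))
})

test_that("per-layer pruning fractions aggregate to the overall sparsity", {
  model <- small_model()
  man <- maskable_index(model)
  K <- n_maskable(model)
  expect_true(all(per_layer_pruning(rep(1, K), man)$pruned_pct == 0))
  # zero exactly half of layer 2's slots
  l2 <- man[man$layer == 2, ]
  idx2 <- unlist(lapply(seq_len(nrow(l2)), function(r)
    l2$offset[r] + seq_len(l2$length[r])))
  m <- rep(1, K)
  m[idx2[seq_len(length(idx2) / 2)]] <- 0
  tab <- per_layer_pruning(m, man)
  expect_equal(tab$pruned_pct[tab$layer == 2], 50)
  expect_equal(tab$pruned_pct[tab$layer == 1], 0)
  # slot-weighted mean equals overall sparsity for random masks
  set.seed(9)
  for (rep_i in 1:5) {
    mr <- as.numeric(rbinom(K, 1, runif(1, 0.5, 1)))
    tr <- per_layer_pruning(mr, man)
    expect_equal(sum(tr$pruned_pct * tr$n_slots) / K, sparsity(mr),
                 tolerance = 1e-12)
  }
  expect_error(per_layer_pruning(rep(1, K - 1), man), "does not match")
})

# brute-force oracles for the paired statistics
oracle_paired_t <- function(x, y) {
  d <- x - y; n <- length(d)
  t_stat <- mean(d) / (stats::sd(d) / sqrt(n))
  list(statistic = t_stat, p.value = 2 * stats::pt(-abs(t_stat), n - 1))
}
oracle_ks <- function(x, y) {
  v <- sort(c(x, y))
  D <- max(abs(vapply(v, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
  pool <- c(x, y)
  splits <- utils::combn(length(pool), length(x))
  Dperm <- apply(splits, 2, function(ix) {
    a <- pool[ix]; b <- pool[-ix]
    max(abs(vapply(v, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
  })
  list(statistic = D, p.value = mean(Dperm >= D - 1e-12))
}

delta_table <- function(supp_sub, supp_base, maint_sub, maint_base,
                        metric = "RMSD") {
  data.frame(
    id = sprintf("d%02d", seq_len(length(supp_sub) + length(maint_sub))),
    set_label = rep(c("suppression", "maintenance"),
                    c(length(supp_sub), length(maint_sub))),
    metric_name = metric,
    value_subnet = c(supp_sub, maint_sub),
    value_baseline = c(supp_base, maint_base)
  )
}

test_that("identical subnet and baseline metrics give zero deltas", {
  set.seed(2)
  v_s <- rnorm(5); v_m <- rnorm(6)
  rep0 <- delta_metric_stats(delta_table(v_s, v_s, v_m, v_m))
  expect_equal(rep0$t_supp, 0)
  expect_equal(rep0$t_maint, 0)
  expect_equal(rep0$p_supp, 1)
  expect_true(all(attr(rep0, "deltas")$delta == 0))
})

test_that("paired t and KS agree with brute-force oracles on small fixtures", {
  set.seed(14)
  for (fix in 1:100) {
    n <- 5
    tab <- delta_table(rnorm(n, 0.5), rnorm(n), rnorm(n, 0.1), rnorm(n))
    out <- delta_metric_stats(tab)
    supp <- tab[tab$set_label == "suppression", ]
    maint <- tab[tab$set_label == "maintenance", ]
    ot_s <- oracle_paired_t(supp$value_subnet, supp$value_baseline)
    ot_m <- oracle_paired_t(maint$value_subnet, maint$value_baseline)
    ok <- oracle_ks(abs(supp$value_subnet - supp$value_baseline),
                    abs(maint$value_subnet - maint$value_baseline))
    expect_equal(out$t_supp, ot_s$statistic, tolerance = 1e-8)
    expect_equal(out$p_supp, ot_s$p.value, tolerance = 1e-8)
    expect_equal(out$t_maint, ot_m$statistic, tolerance = 1e-8)
    expect_equal(out$p_maint, ot_m$p.value, tolerance = 1e-8)
    expect_equal(out$ks_stat, ok$statistic, tolerance = 1e-8)
    expect_equal(out$ks_p, ok$p.value, tolerance = 1e-8)
    expect_equal(out$mean_abs_diff,
                 mean(abs(supp$value_subnet - supp$value_baseline)) -
                   mean(abs(maint$value_subnet - maint$value_baseline)),
                 tolerance = 1e-12)
  }
})

test_that("the KS statistic is invariant under monotone transforms", {
  set.seed(8)
  for (rep_i in 1:10) {
    x <- abs(rnorm(12)); y <- abs(rnorm(15, 0.5))
    base <- suppressWarnings(stats::ks.test(x, y)$statistic)
    trans <- function(v) log1p(v)^3
    after <- suppressWarnings(stats::ks.test(trans(x), trans(y))$statistic)
    expect_equal(unname(base), unname(after), tolerance = 1e-12)
  }
})

test_that("degenerate delta tables are rejected with informative errors", {
  tab <- delta_table(rnorm(1), rnorm(1), rnorm(5), rnorm(5))
  expect_error(delta_metric_stats(tab), "at least 2")
  tab2 <- delta_table(rnorm(3), rnorm(3), rnorm(3), rnorm(3))
  tab2$value_subnet[2] <- NA
  expect_error(delta_metric_stats(tab2), "unpaired.*d02")
  tab3 <- delta_table(rnorm(3), rnorm(3), rnorm(3), rnorm(3))
  tab3$set_label[1] <- "other"
  expect_error(delta_metric_stats(tab3), "unknown set_label")
})

test_that("reports serialize to JSON and TSV", {
  set.seed(4)
  tab <- delta_table(rnorm(4, 1), rnorm(4), rnorm(4), rnorm(4))
  rep_d <- delta_metric_stats(tab)
  json <- withr::local_tempfile(fileext = ".json")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(rep_d, json, tsv)
  parsed <- jsonlite::read_json(json)
  expect_equal(parsed$stats[[1]]$ks_stat, rep_d$ks_stat, tolerance = 1e-12)
  flat <- utils::read.delim(tsv)
  expect_equal(flat$t_supp, rep_d$t_supp, tolerance = 1e-12)
})
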