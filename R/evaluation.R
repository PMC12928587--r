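#' Stratified perplexity report
#'
#' Evaluates the subnetwork and the unmasked baseline on identical
#' corrupted inputs, stratified by suppression/maintenance side and by
#' dataset split. For a sequence-level partition, a record's selected
#' corrupted positions all score in its own side's cell; for a
#' residue-level partition every record contributes its suppressed
#' positions (J*) to the suppression cell and its complement (J') to the
#' maintenance cell. Empty strata are reported as absent (`NA` with
#' `n_positions = 0`).
#'
#' @param model A `toy_plm`.
#' @param m Binary mask of the subnetwork (e.g. `fit$m`); `NULL` gives a
#'   baseline-only report.
#' @param records A [domain_records()] object.
#' @param partition A `suppression_partition`.
#' @param split Optional [split_dataset()] assignment; without it all
#'   records form a single `"all"` split.
#' @param rate Corruption rate used for evaluation.
#' @param reps Corruption replicates per sequence.
#' @param seed Seed for the evaluation corruption draws.
#' @return An object of class `eval_report`: `table` (split x stratum x
#'   model perplexities with position counts), `sparsity`, and `per_layer`
#'   (see [per_layer_pruning()]).
#' @export
stratified_perplexity <- function(model, m, records, partition, split = NULL,
                                  rate = 0.15, reps = 2L, seed = 17L) {
  stopifnot(inherits(model, "toy_plm"),
            inherits(partition, "suppression_partition"))
  vocab <- model$vocab
  toks <- tokenize_records(records, vocab)
  splits <- if (is.null(split)) {
    list(all = records$id)
  } else {
    sapply(c("train", "validation", "test"), function(p) split_ids(split, p),
           simplify = FALSE)
  }
  seq_level <- partition$level == "sequence"
  rows <- list()
  for (sp in names(splits)) {
    ids <- intersect(splits[[sp]], names(toks))
    pools <- list(
      suppression = list(sub = numeric(0), base = numeric(0)),
      maintenance = list(sub = numeric(0), base = numeric(0))
    )
    for (r in seq_len(reps)) {
      if (!length(ids)) break
      plans <- lapply(ids, function(id) {
        make_corruption_plan(nchar(records$sequence[records$id == id]),
                             rate = rate,
                             seed = derive_seed(seed, match(id, records$id) * 257L + r))
      })
      corrupted <- Map(apply_corruption, toks[ids], plans,
                       MoreArgs = list(vocab = vocab))
      probs_sub <- forward_probs_batch(model, corrupted, m = m)
      probs_base <- if (is.null(m)) probs_sub else
        forward_probs_batch(model, corrupted, m = NULL)
      for (i in seq_along(ids)) {
        id <- ids[i]
        tk <- toks[[id]]
        scored <- plans[[i]]$positions[tk[plans[[i]]$positions] <= vocab$n_aa]
        if (!length(scored)) next
        nll_sub <- -log(pmax(probs_sub[[i]][cbind(scored, tk[scored])], LOG_EPS))
        nll_base <- -log(pmax(probs_base[[i]][cbind(scored, tk[scored])], LOG_EPS))
        if (seq_level) {
          side <- if (id %in% partition$suppressed) "suppression" else "maintenance"
          pools[[side]]$sub <- c(pools[[side]]$sub, nll_sub)
          pools[[side]]$base <- c(pools[[side]]$base, nll_base)
        } else {
          in_supp <- scored %in% partition$positions[[id]]
          pools$suppression$sub <- c(pools$suppression$sub, nll_sub[in_supp])
          pools$suppression$base <- c(pools$suppression$base, nll_base[in_supp])
          pools$maintenance$sub <- c(pools$maintenance$sub, nll_sub[!in_supp])
          pools$maintenance$base <- c(pools$maintenance$base, nll_base[!in_supp])
        }
      }
    }
    for (side in names(pools)) {
      for (mdl in c("subnetwork", "baseline")) {
        nll <- if (mdl == "subnetwork") pools[[side]]$sub else pools[[side]]$base
        rows[[length(rows) + 1L]] <- data.frame(
          split = sp, stratum = side, model = mdl,
          n_positions = length(nll),
          perplexity = if (length(nll)) perplexity(nll) else NA_real_
        )
      }
    }
  }
  table <- do.call(rbind, rows)
  structure(
    list(table = table,
         sparsity = if (is.null(m)) 0 else sparsity(m),
         per_layer = if (is.null(m)) NULL else
           per_layer_pruning(m, maskable_index(model))),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> sparsity ", sprintf("%.2f%%", x$sparsity), "\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Per-layer pruning profile
#'
#' For each transformer layer, the percentage of that layer's maskable
#' slots set to zero. The slot-weighted mean across layers equals the
#' overall sparsity.
#'
#' @param m Binary mask vector.
#' @param manifest A [maskable_index()] manifest tagging every slot with a
#'   layer.
#' @return Data frame with columns `layer`, `n_slots`, `n_pruned`,
#'   `pruned_pct`.
#' @export
per_layer_pruning <- function(m, manifest) {
  K <- attr(manifest, "K") %||% sum(manifest$length)
  if (length(m) != K) {
    stop("mask length ", length(m), " does not match manifest (", K, ")",
         call. = FALSE)
  }
  layers <- sort(unique(manifest$layer))
  out <- do.call(rbind, lapply(layers, function(l) {
    rows <- manifest[manifest$layer == l, , drop = FALSE]
    idx <- unlist(lapply(seq_len(nrow(rows)), function(r) {
      rows$offset[r] + seq_len(rows$length[r])
    }))
    data.frame(layer = l, n_slots = length(idx),
               n_pruned = sum(m[idx] == 0),
               pruned_pct = 100 * sum(m[idx] == 0) / length(idx))
  }))
  out
}

# Guarded paired t-test: identical pairs give a zero statistic rather than
# an error, matching the "no change" reading of a degenerate comparison.
paired_t <- function(x, y) {
  d <- x - y
  if (length(d) < 2L) stop("paired t-test needs at least 2 pairs", call. = FALSE)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(statistic = 0, p.value = 1))
    return(list(statistic = sign(mean(d)) * Inf, p.value = 0))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

# Two-sample KS: exact null distribution up to 25 observations per sample,
# asymptotic beyond.
two_sample_ks <- function(x, y) {
  if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) {
    return(list(statistic = 0, p.value = 1))
  }
  exact <- length(x) <= 25L && length(y) <= 25L
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Paired-difference statistics for structure metrics
#'
#' Consumes a table of externally computed structure metrics (e.g. RMSD,
#' TM-score, pLDDT from a folding pipeline) for the subnetwork and the
#' baseline model on the same inputs, and reports, per metric: the paired
#' t-test on `metric_subnet - metric_baseline` separately for the
#' suppression and maintenance sets, the two-sample Kolmogorov-Smirnov
#' test comparing the magnitude distributions `|delta_supp|` vs
#' `|delta_maint|`, and the difference of mean magnitudes. Tests are
#' two-sided; KS p-values are exact for small samples (per
#' `stats::ks.test`) and asymptotic otherwise.
#'
#' @param metrics Data frame with columns `id`, `set_label` (values
#'   `suppression` / `maintenance`), `metric_name`, `value_subnet`,
#'   `value_baseline`.
#' @return An object of class `delta_metric_report`: a data frame with one
#'   row per metric (`t_supp`, `p_supp`, `t_maint`, `p_maint`, `ks_stat`,
#'   `ks_p`, `mean_abs_delta_supp`, `mean_abs_delta_maint`,
#'   `mean_abs_diff`), with the per-input deltas attached as attribute
#'   `deltas`.
#' @export
delta_metric_stats <- function(metrics) {
  need <- c("id", "set_label", "metric_name", "value_subnet", "value_baseline")
  if (!all(need %in% names(metrics))) {
    stop("metrics table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad_label <- setdiff(unique(metrics$set_label), c("suppression", "maintenance"))
  if (length(bad_label)) {
    stop("unknown set_label(s): ", paste(bad_label, collapse = ", "), call. = FALSE)
  }
  unpaired <- metrics$id[is.na(metrics$value_subnet) | is.na(metrics$value_baseline)]
  if (length(unpaired)) {
    stop("unpaired input(s) (missing subnet or baseline value): ",
         paste(unique(unpaired), collapse = ", "), call. = FALSE)
  }
  metrics$delta <- metrics$value_subnet - metrics$value_baseline
  rows <- lapply(split(metrics, metrics$metric_name), function(df) {
    supp <- df[df$set_label == "suppression", ]
    maint <- df[df$set_label == "maintenance", ]
    if (nrow(supp) < 2L || nrow(maint) < 2L) {
      stop("metric '", df$metric_name[1],
           "' needs at least 2 paired rows per set", call. = FALSE)
    }
    ts <- paired_t(supp$value_subnet, supp$value_baseline)
    tm <- paired_t(maint$value_subnet, maint$value_baseline)
    ks <- two_sample_ks(abs(supp$delta), abs(maint$delta))
    data.frame(
      metric = df$metric_name[1],
      n_supp = nrow(supp), n_maint = nrow(maint),
      t_supp = ts$statistic, p_supp = ts$p.value,
      t_maint = tm$statistic, p_maint = tm$p.value,
      ks_stat = ks$statistic, ks_p = ks$p.value,
      mean_abs_delta_supp = mean(abs(supp$delta)),
      mean_abs_delta_maint = mean(abs(maint$delta)),
      mean_abs_diff = mean(abs(supp$delta)) - mean(abs(maint$delta))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, deltas = metrics[, c("id", "set_label", "metric_name", "delta")],
            class = c("delta_metric_report", "data.frame"))
}

#' Write an evaluation report as JSON plus a flat TSV twin
#'
#' @param report An [stratified_perplexity()] or [delta_metric_stats()]
#'   result.
#' @param json Output JSON path.
#' @param tsv Optional output TSV path (the flat table).
#' @return Invisibly, the report.
#' @export
write_eval_report <- function(report, json, tsv = NULL) {
  if (inherits(report, "eval_report")) {
    payload <- list(sparsity = report$sparsity, perplexity = report$table,
                    per_layer = report$per_layer)
    flat <- report$table
  } else if (inherits(report, "delta_metric_report")) {
    payload <- list(stats = as.data.frame(report))
    flat <- as.data.frame(report)
  } else {
    stop("unsupported report type", call. = FALSE)
  }
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  if (!is.null(tsv)) {
    utils::write.table(flat, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}

#' Plot a stratified perplexity report
#'
#' Dot plot of perplexity by stratum and model, faceted by split, in the
#' style of subnetwork-vs-baseline evaluation figures. Requires ggplot2.
#'
#' @param report An [stratified_perplexity()] result.
#' @return A ggplot object.
#' @export
plot_eval_report <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_eval_report requires ggplot2", call. = FALSE)
  }
  df <- report$table[!is.na(report$table$perplexity), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$perplexity,
                                   colour = .data$model)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::facet_wrap(~split) +
    ggplot2::geom_hline(yintercept = 20, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "perplexity",
                  caption = "dashed line: uniform guessing over 20 amino acids") +
    ggplot2::theme_minimal()
}
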