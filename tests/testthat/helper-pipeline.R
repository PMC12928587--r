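# The reference toy pipeline (corpus -> pretrained model -> trained
# subnetwork), built lazily once per test run and shared across test files.
# Sizes match the package's reference configuration: 3 classes x 150
# sequences of 64-96 residues, a width-64 two-block encoder pretrained for
# 3000 steps, and the default mask-training configuration.

.pipeline_cache <- new.env(parent = emptyenv())

pipeline_corpus <- function() {
  if (is.null(.pipeline_cache$corpus)) {
    .pipeline_cache$corpus <- generate_corpus(synthetic_spec(seed = 11))
    .pipeline_cache$split <- split_dataset(.pipeline_cache$corpus, seed = 5)
  }
  list(corpus = .pipeline_cache$corpus, split = .pipeline_cache$split)
}

pipeline_model <- function() {
  if (is.null(.pipeline_cache$model)) {
    cs <- pipeline_corpus()
    train <- subset_records(cs$corpus, split_ids(cs$split, "train"))
    model <- build_toy_model(width = 64L, heads = 4L, max_len = 128L,
                             seed = 21)
    .pipeline_cache$init_model <- model
    .pipeline_cache$model <- pretrain_toy(model, train, steps = 3000L,
                                          lr = 2e-3, lr_end = 2e-4, seed = 9)
  }
  .pipeline_cache$model
}

pipeline_init_model <- function() {
  pipeline_model()
  .pipeline_cache$init_model
}

pipeline_fit <- function() {
  if (is.null(.pipeline_cache$fit)) {
    cs <- pipeline_corpus()
    part <- build_partition(cs$corpus,
                            suppression_spec("sequence", "1", "Class"))
    .pipeline_cache$part <- part
    .pipeline_cache$fit <- train_subnetwork(pipeline_model(), cs$corpus, part,
                                            cs$split, train_config())
  }
  list(fit = .pipeline_cache$fit, part = .pipeline_cache$part)
}

# Random-sequence control matched in size to the class-1 suppression set.
pipeline_control_fit <- function() {
  if (is.null(.pipeline_cache$control_fit)) {
    cs <- pipeline_corpus()
    n_class1 <- sum(startsWith(cs$corpus$id, "syn1"))
    ctrl <- make_control_spec(cs$corpus, "random_sequences", n = n_class1,
                              seed = 41)
    .pipeline_cache$ctrl <- ctrl
    .pipeline_cache$control_fit <- train_subnetwork(pipeline_model(),
                                                    cs$corpus, ctrl,
                                                    cs$split, train_config())
  }
  list(fit = .pipeline_cache$control_fit, part = .pipeline_cache$ctrl)
}

# Test-set perplexity ratio (subnetwork / baseline) per stratum.
stratum_ppl <- function(report, stratum, model, split = "test") {
  tab <- report$table
  tab$perplexity[tab$split == split & tab$stratum == stratum &
                   tab$model == model]
}
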