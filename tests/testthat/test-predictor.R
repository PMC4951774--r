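# A tiny separable training table used across the predictor tests.
separable_features <- function(n = 60L) {
  withr::with_seed(9, {
    pos <- data.table::data.table(
      distance = runif(n, 0, 3e4), css = runif(n, 0.6, 1),
      fss = runif(n, 0.5, 1), correlation = runif(n, 0.2, 0.9),
      label = "positive")
    neg <- data.table::data.table(
      distance = runif(n, 4e5, 2e6), css = runif(n, 0, 0.3),
      fss = runif(n, 0, 0.3), correlation = runif(n, -0.5, 0.1),
      label = "negative")
    data.table::rbindlist(list(pos, neg))
  })
}

test_that("negative sampling avoids known targets and is seed-reproducible", {
  enh <- data.table::data.table(enhancer_id = "e1", chrom = "chr1",
                                start = 1000, end = 2000)
  genes <- data.table::data.table(gene_id = c("g1", "g2", "g3"),
                                  chrom = "chr1", tss = c(5000, 9000, 12000),
                                  strand = "+", name = NA_character_)
  pos <- data.table::data.table(enhancer_id = "e1", gene_id = "g1")
  neg <- sample_negatives(pos, enh, genes, 2L, etg_params(), seed = 5)
  expect_setequal(neg$gene_id, c("g2", "g3"))  # forced outcome
  expect_error(sample_negatives(pos, enh, genes, 3L, etg_params(), seed = 5),
               "only 2 eligible")
  fx <- default_bundle()$fx
  n1 <- sample_negatives(fx$truth, fx$enhancers, fx$genes, 100L,
                         etg_params(), seed = 11)
  n2 <- sample_negatives(fx$truth, fx$enhancers, fx$genes, 100L,
                         etg_params(), seed = 11)
  expect_identical(n1, n2)
  expect_equal(nrow(fx$truth[n1, on = c("enhancer_id", "gene_id"),
                             nomatch = NULL]), 0L)
})

test_that("training is deterministic and separable data yield AUC 1", {
  feats <- separable_features()
  p <- etg_params(n_trees = 101L)
  m1 <- train_model(feats, p, seed = 21)
  m2 <- train_model(feats, p, seed = 21)
  expect_equal(m1$forest$ntree, 101L)
  probe <- separable_features(20L)
  expect_identical(score_pairs(m1, probe), score_pairs(m2, probe))
  expect_equal(roc_auc(score_pairs(m1, feats), feats$label), 1.0)
  expect_error(train_model(feats[label == "positive"], p), "both classes")
})

test_that("feature-subset models ignore the excluded feature entirely", {
  feats <- separable_features()
  p <- etg_params(n_trees = 101L)
  m <- train_model(feats, p,
                   feature_subset = c("distance", "css", "fss"), seed = 3)
  probe <- separable_features(20L)
  shuffled <- data.table::copy(probe)[, correlation := rev(correlation)]
  expect_identical(score_pairs(m, probe), score_pairs(m, shuffled))
  probe2 <- data.table::copy(probe)[, correlation := NULL]
  expect_identical(score_pairs(m, probe), score_pairs(m, probe2))
  expect_error(score_pairs(train_model(feats, p, seed = 3), probe2),
               "correlation")
})

test_that("scores are probabilities and predictions are monotone in cutoff", {
  feats <- separable_features()
  p <- etg_params(n_trees = 101L)
  m <- train_model(feats, p, seed = 7)
  withr::with_seed(8, probe <- data.table::data.table(
    distance = runif(50, 0, 2e6), css = runif(50), fss = runif(50),
    correlation = runif(50, -1, 1)))
  sc <- score_pairs(m, probe)
  expect_true(all(sc >= 0 & sc <= 1))
  prev <- NULL
  for (cut in c(0.999999, 0.95, 0.5, 0.25, 1e-9)) {
    pred <- predict_targets(m, probe, etg_params(score_cutoff = cut,
                                                 n_trees = 101L))
    if (!is.null(prev)) {
      # lowering the cutoff never removes a predicted pair
      expect_true(all(prev$score %in% pred$score))
      expect_gte(nrow(pred), nrow(prev))
    }
    prev <- pred
  }
  expect_equal(nrow(predict_targets(m, probe[0], p)), 0L)
})

test_that("model bundles round-trip and refuse malformed files", {
  feats <- separable_features()
  m <- train_model(feats, etg_params(n_trees = 51L), seed = 1)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$feature_subset, m$feature_subset)
  expect_identical(score_pairs(m2, feats), score_pairs(m, feats))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_model(bad), "model bundle")
})

test_that("information gain matches the exact entropy oracle on toy tables", {
  h <- function(y) { p <- table(y) / length(y); -sum(p * log(p)) }
  # binary feature identical to the label: gain equals the label entropy
  y <- rep(c("positive", "negative"), c(6, 4))
  x <- as.numeric(y == "positive")
  expect_equal(etgpair:::information_gain(x, y), h(y))
  # exact conditional-entropy oracle on a random discrete table
  withr::with_seed(13, {
    for (rep in 1:10) {
      x <- sample(1:4, 40, replace = TRUE)
      y <- factor(sample(c("a", "b"), 40, replace = TRUE))
      cond <- sum(vapply(unique(x), function(v) {
        mean(x == v) * h(y[x == v])
      }, numeric(1)))
      expect_equal(etgpair:::information_gain(x, y), h(y) - cond,
                   tolerance = 1e-12)
    }
  })
  # constant features carry no information
  expect_equal(etgpair:::information_gain(rep(1, 10), y[1:10]), 0)
})

test_that("feature ranking orders signal above noise in every method", {
  withr::with_seed(19, {
    n <- 300L
    y <- rep(c("positive", "negative"), each = n / 2)
    feats <- data.table::data.table(
      distance = ifelse(y == "positive", runif(n, 0, 1e4),
                        runif(n, 0, 2e6)),
      css = runif(n),                       # pure noise
      fss = runif(n),                       # pure noise
      correlation = rep(0.5, n),            # constant
      label = y
    )
  })
  methods <- c("infogain", "rf", "svm", "lasso")
  r <- rank_features(feats, methods = methods, p = etg_params(n_trees = 101L),
                     seed = 23)
  for (m in methods) {
    rm <- r[method == m]
    expect_setequal(rm$feature, c("distance", "css", "fss", "correlation"))
    expect_equal(rm[rank == 1, feature], "distance")
    # the constant feature has importance 0 and ranks last
    expect_equal(rm[feature == "correlation", importance], 0)
    expect_equal(rm[feature == "correlation", rank], 4L)
  }
})
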