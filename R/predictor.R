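# Training-set assembly, random-forest model and feature ranking.

FEATURES <- c("distance", "css", "fss", "correlation")

#' Sample negative enhancer-gene pairs
#'
#' Draws `n` distinct (enhancer, gene) pairs uniformly without replacement
#' from all candidate pairs within the window whose gene is not a known
#' target of the enhancer.
#'
#' @param positives Known pair table (`enhancer_id`, `gene_id`).
#' @param enhancers,genes Annotation tables.
#' @param n Number of negatives to draw.
#' @param p An [etg_params()] object.
#' @param seed Integer seed for reproducible draws.
#' @return `data.table` with `enhancer_id`, `gene_id`, `distance`.
#' @export
sample_negatives <- function(positives, enhancers, genes, n,
                             p = etg_params(), seed = NULL) {
  positives <- as.data.table(positives)
  cand <- enumerate_candidates(enhancers, genes, p)
  eligible <- cand[!positives, on = c("enhancer_id", "gene_id")]
  if (nrow(eligible) < n) {
    stop(sprintf("only %d eligible negative pairs, %d requested",
                 nrow(eligible), n))
  }
  draw <- function() eligible[sample(.N, n)]
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  setorder(out, enhancer_id, gene_id)
  out[]
}

#' Train the random-forest pair classifier
#'
#' Fits a forest of `p$n_trees` classification trees (library defaults for
#' the remaining hyperparameters) on the requested feature subset.
#'
#' @param features Labeled feature table (`label` column with values
#'   `"positive"`/`"negative"`, plus the feature columns).
#' @param p An [etg_params()] object.
#' @param feature_subset Features to train on.
#' @param seed Integer seed; fixed data and seed give bit-identical scores.
#' @return Object of class `etg_model`.
#' @export
train_model <- function(features, p = etg_params(),
                        feature_subset = FEATURES, seed = NULL) {
  features <- as.data.table(features)
  feature_subset <- match.arg(feature_subset, FEATURES, several.ok = TRUE)
  missing <- setdiff(feature_subset, names(features))
  if (length(missing) > 0L) {
    stop("missing feature columns: ", paste(missing, collapse = ", "))
  }
  if (!"label" %in% names(features)) stop("training table needs a label column")
  y <- factor(features$label, levels = c("negative", "positive"))
  if (any(is.na(y))) stop("labels must be 'positive' or 'negative'")
  if (length(unique(y)) < 2L) stop("training set must contain both classes")
  x <- as.data.frame(features[, feature_subset, with = FALSE])
  if (any(!vapply(x, is.numeric, logical(1))) || any(!is.finite(as.matrix(x)))) {
    stop("feature values must be finite numerics")
  }
  fit <- function() randomForest::randomForest(x, y, ntree = p$n_trees)
  forest <- if (is.null(seed)) fit() else withr::with_seed(seed, fit())
  structure(
    list(forest = forest, feature_subset = feature_subset,
         n_trees = p$n_trees, seed = seed, n_train = nrow(x),
         package_version = as.character(utils::packageVersion("etgpair")),
         format_version = 1L),
    class = "etg_model"
  )
}

#' @export
print.etg_model <- function(x, ...) {
  cat(sprintf("ETG random-forest model: %d trees, features [%s], n_train=%d\n",
              x$n_trees, paste(x$feature_subset, collapse = ", "), x$n_train))
  invisible(x)
}

#' Score enhancer-gene pairs
#'
#' The score of a pair is the fraction of trees voting it a true target,
#' in \[0, 1\].
#'
#' @param model An `etg_model`.
#' @param features Feature table containing the model's feature columns.
#' @return Numeric vector of scores.
#' @export
score_pairs <- function(model, features) {
  stopifnot(inherits(model, "etg_model"))
  features <- as.data.table(features)
  missing <- setdiff(model$feature_subset, names(features))
  if (length(missing) > 0L) {
    stop("missing feature columns: ", paste(missing, collapse = ", "))
  }
  x <- as.data.frame(features[, model$feature_subset, with = FALSE])
  if (nrow(x) == 0L) return(numeric(0))
  as.numeric(predict(model$forest, x, type = "prob")[, "positive"])
}

#' Predict target genes at the score cutoff
#'
#' @param model An `etg_model`.
#' @param features Candidate feature table.
#' @param p An [etg_params()] object (`score_cutoff`).
#' @return Candidates with score >= cutoff, scores attached, sorted by
#'   decreasing score.
#' @export
predict_targets <- function(model, features, p = etg_params()) {
  features <- as.data.table(features)
  out <- copy(features)
  out[, score := score_pairs(model, features)]
  out <- out[score >= p$score_cutoff]
  setorder(out, -score)
  out[]
}

#' Save / load a fitted model bundle
#'
#' Single-file bundle holding the forest, feature list, tree count and
#' version metadata; loading refuses bundles without them.
#'
#' @param model An `etg_model`.
#' @param path Bundle path.
#' @return `path` invisibly ([save_model()]); the model ([load_model()]).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "etg_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "etg_model") || is.null(model$feature_subset) ||
      is.null(model$format_version)) {
    stop("not a valid model bundle: ", path)
  }
  model
}

entropy_nats <- function(y) {
  pr <- table(y) / length(y)
  pr <- pr[pr > 0]
  -sum(pr * log(pr))
}

# Information gain of one feature for the label, with equal-frequency
# discretization (discrete features with few levels are used as-is).
information_gain <- function(x, y, n_bins = 10L) {
  if (length(unique(x)) <= n_bins) {
    bins <- factor(x)
  } else {
    breaks <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(breaks) < 2L) return(0)
    bins <- cut(x, breaks, include.lowest = TRUE)
  }
  if (nlevels(droplevels(bins)) < 2L) return(0)
  h <- entropy_nats(y)
  cond <- sum(vapply(levels(bins), function(b) {
    sel <- bins == b
    if (!any(sel)) return(0)
    mean(sel) * entropy_nats(y[sel])
  }, numeric(1)))
  h - cond
}

#' Rank features by importance
#'
#' Native methods: `"infogain"` (entropy reduction after 10-bin
#' equal-frequency discretization) and `"rf"` (random-forest impurity
#' importance, mean Gini decrease). `"svm"` (absolute weights of a linear
#' SVM on standardised features) and `"lasso"` (L1 path order of entry) are
#' optional hooks requiring \pkg{e1071} / \pkg{glmnet}. Constant features
#' get importance 0 and rank last.
#'
#' @param features Labeled feature table.
#' @param methods Ranking methods to run.
#' @param p An [etg_params()] object (tree count for `"rf"`).
#' @param feature_subset Features to rank.
#' @param seed Integer seed.
#' @param n_bins Bin count for `"infogain"`.
#' @return `data.table` with `method`, `feature`, `importance`, `rank`
#'   (1 = most important).
#' @export
rank_features <- function(features, methods = c("infogain", "rf"),
                          p = etg_params(), feature_subset = FEATURES,
                          seed = NULL, n_bins = 10L) {
  features <- as.data.table(features)
  feature_subset <- intersect(feature_subset, names(features))
  if (length(feature_subset) < 2L) stop("need >= 2 features to rank")
  y <- factor(features$label, levels = c("negative", "positive"))
  x <- as.data.frame(features[, feature_subset, with = FALSE])
  imp_of <- function(method) {
    switch(
      method,
      infogain = vapply(x, information_gain, numeric(1), y = y,
                        n_bins = n_bins),
      rf = {
        fit <- function() randomForest::randomForest(x, y, ntree = p$n_trees)
        forest <- if (is.null(seed)) fit() else withr::with_seed(seed, fit())
        setNames(forest$importance[, "MeanDecreaseGini"], feature_subset)
      },
      svm = {
        if (!requireNamespace("e1071", quietly = TRUE)) {
          stop("the 'svm' ranking hook requires the e1071 package")
        }
        keep <- vapply(x, function(v) var(v) > 0, logical(1))
        w <- setNames(rep(0, ncol(x)), feature_subset)
        fit <- e1071::svm(scale(as.matrix(x[, keep, drop = FALSE])), y,
                          kernel = "linear", scale = FALSE)
        w[keep] <- abs(as.numeric(t(fit$coefs) %*% fit$SV))
        w
      },
      lasso = {
        if (!requireNamespace("glmnet", quietly = TRUE)) {
          stop("the 'lasso' ranking hook requires the glmnet package")
        }
        fit <- glmnet::glmnet(as.matrix(x), y, family = "binomial",
                              standardize = TRUE)
        beta <- as.matrix(fit$beta)
        vapply(feature_subset, function(f) {
          nz <- which(abs(beta[f, ]) > 0)
          if (length(nz) == 0L) 0 else fit$lambda[min(nz)]
        }, numeric(1))
      },
      stop("unknown ranking method: ", method)
    )
  }
  out <- rbindlist(lapply(methods, function(m) {
    imp <- imp_of(m)
    dt <- data.table(method = m, feature = feature_subset,
                     importance = as.numeric(imp))
    dt[, rank := frank(-importance, ties.method = "first")]
    dt
  }))
  setorder(out, method, rank)
  out[]
}
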