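# Orchestration: the staged workflow (simulate -> features -> train ->
# predict -> evaluate / rank-features) as plain functions, plus a YAML run
# configuration. The command-line entry point in inst/cli/etgpair.R is a
# thin wrapper over these.

#' Read and validate a run configuration (YAML)
#'
#' @param path Path to a YAML file. Unknown keys are rejected; referenced
#'   input paths must exist.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("input_dir", "features_file", "model_file", "predictions_file",
             "out_dir", "out_file", "seed", "feature_subset", "mode",
             "n_negatives", "read_cutoff", "params", "fixture")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  for (key in c("input_dir", "features_file", "model_file",
                "predictions_file")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("configured path does not exist: ", cfg[[key]])
    }
  }
  cfg
}

params_from_config <- function(cfg) {
  if (is.null(cfg$params)) etg_params() else do.call(etg_params, cfg$params)
}

log_stage <- function(stage, ...) {
  kv <- list(...)
  message(sprintf("[%s] %s", stage,
                  paste(sprintf("%s=%s", names(kv),
                                vapply(kv, format, character(1))),
                        collapse = " ")))
}

with_cleanup <- function(out_file, expr) {
  tryCatch(expr, error = function(e) {
    if (file.exists(out_file)) unlink(out_file)
    stop(e)
  })
}

#' Derived feature inputs for a fixture dataset
#'
#' Runs the shared feature-computation core on a loaded fixture: motif scan
#' of the enhancer sequences, module discovery, IC computation and enhancer
#' GO assignment.
#'
#' @param fx A loaded fixture from [read_fixture()].
#' @param p An [etg_params()] object.
#' @return List with `occ`, `modules`, `dag` (IC-annotated),
#'   `enhancer_terms`, `gene_terms`.
#' @export
fixture_feature_inputs <- function(fx, p = etg_params()) {
  seqs <- enhancer_sequences(fx$genome_path, fx$enhancers)
  occ <- scan_motifs(seqs, fx$pwms)
  modules <- discover_modules(occ,
                              min_support = max(5L, round(0.05 * nrow(occ))))
  dag <- compute_ic(fx$dag, fx$ann)
  enhancer_terms <- assign_enhancer_go(occ, modules, fx$enhancers, fx$genes,
                                       fx$ann, dag, p)
  list(occ = occ, modules = modules, dag = dag,
       enhancer_terms = enhancer_terms, gene_terms = gene_term_sets(fx$ann))
}

#' Pair/feature table for a fixture dataset
#'
#' Builds the labeled training table (planted truth plus sampled
#' negatives) or the unlabeled candidate table of a loaded fixture.
#'
#' @param fx A loaded fixture from [read_fixture()].
#' @param p An [etg_params()] object.
#' @param mode `"training"` or `"candidates"`.
#' @param n_negatives Negatives to sample in training mode (default three
#'   per positive).
#' @param seed Seed for negative sampling.
#' @param inputs Optional precomputed [fixture_feature_inputs()].
#' @return Feature `data.table`.
#' @export
fixture_feature_table <- function(fx, p = etg_params(),
                                  mode = c("training", "candidates"),
                                  n_negatives = NULL, seed = 1L,
                                  inputs = NULL) {
  mode <- match.arg(mode)
  if (is.null(inputs)) inputs <- fixture_feature_inputs(fx, p)
  if (mode == "training") {
    pos <- fx$truth[, .(enhancer_id, gene_id, label = "positive")]
    if (is.null(n_negatives)) n_negatives <- 3L * nrow(pos)
    neg <- sample_negatives(fx$truth, fx$enhancers, fx$genes, n_negatives,
                            p, seed = seed)
    pairs <- rbindlist(list(pos, neg[, .(enhancer_id, gene_id,
                                         label = "negative")]))
  } else {
    pairs <- enumerate_candidates(fx$enhancers, fx$genes, p)[,
      .(enhancer_id, gene_id)]
  }
  compute_pair_features(pairs, fx$enhancers, fx$genes, p,
                        blocks = fx$blocks, phi = fx$phi,
                        enhancer_terms = inputs$enhancer_terms,
                        gene_terms = inputs$gene_terms, dag = inputs$dag,
                        tracks = fx$tracks)
}

#' Pipeline stage: simulate a fixture dataset
#'
#' @param out_dir Output directory for the bundle.
#' @param seed Master seed.
#' @param config Named list of [fixture_config()] overrides.
#' @return The `etg_fixture` bundle, invisibly.
#' @export
run_simulate <- function(out_dir, seed = 1L, config = list()) {
  cfg <- do.call(fixture_config, c(list(seed = as.integer(seed)), config))
  bundle <- generate_fixture(cfg, out_dir)
  log_stage("simulate", out_dir = out_dir, seed = seed,
            true_pairs = nrow(bundle$truth))
  invisible(bundle)
}

#' Pipeline stage: compute the pair/feature table
#'
#' @param input_dir Fixture-style input directory.
#' @param out_file Output TSV.
#' @param p An [etg_params()] object.
#' @param mode `"training"` (planted truth + sampled negatives, labeled) or
#'   `"candidates"` (all pairs within the window, unlabeled).
#' @param n_negatives Negatives to sample in training mode.
#' @param seed Seed for negative sampling.
#' @return The feature table, invisibly.
#' @export
run_features <- function(input_dir, out_file, p = etg_params(),
                         mode = "training", n_negatives = NULL, seed = 1L) {
  with_cleanup(out_file, {
    fx <- read_fixture(input_dir)
    feats <- fixture_feature_table(fx, p, mode = mode,
                                   n_negatives = n_negatives, seed = seed)
    digests <- tools::md5sum(unlist(fx[c("genome_path")], use.names = FALSE))
    write_feature_table(feats, out_file, meta = c(
      stage = "features", mode = mode, seed = as.character(seed),
      input_dir = input_dir, genome_md5 = unname(digests[1])
    ))
    log_stage("features", out_file = out_file, mode = mode,
              n_pairs = nrow(feats), seed = seed)
    invisible(feats)
  })
}

#' Pipeline stage: train the forest
#'
#' @param features_file Labeled feature TSV from [run_features()].
#' @param model_file Output model bundle path.
#' @param p An [etg_params()] object.
#' @param feature_subset Features to train on.
#' @param seed Training seed.
#' @return The fitted `etg_model`, invisibly.
#' @export
run_train <- function(features_file, model_file, p = etg_params(),
                      feature_subset = FEATURES, seed = 1L) {
  with_cleanup(model_file, {
    feats <- read_feature_table(features_file)
    model <- train_model(feats, p, feature_subset, seed = seed)
    save_model(model, model_file)
    log_stage("train", model_file = model_file, n_trees = p$n_trees,
              features = paste(feature_subset, collapse = ","), seed = seed)
    invisible(model)
  })
}

#' Pipeline stage: score pairs and call targets
#'
#' @param model_file Model bundle from [run_train()].
#' @param features_file Feature TSV to score.
#' @param out_file Output TSV (filtered at the cutoff unless `keep_all`).
#' @param p An [etg_params()] object (`score_cutoff`).
#' @param keep_all Keep all scored pairs (adds a logical `predicted`
#'   column) instead of filtering.
#' @return The output table, invisibly.
#' @export
run_predict <- function(model_file, features_file, out_file,
                        p = etg_params(), keep_all = FALSE) {
  with_cleanup(out_file, {
    model <- load_model(model_file)
    feats <- read_feature_table(features_file)
    scored <- copy(feats)[, score := score_pairs(model, feats)]
    out <- if (keep_all) {
      scored[, target := score >= p$score_cutoff][]
    } else {
      scored[score >= p$score_cutoff]
    }
    setorder(out, -score)
    write_feature_table(out, out_file, meta = c(
      stage = "predict", cutoff = as.character(p$score_cutoff),
      model = model_file
    ))
    log_stage("predict", out_file = out_file, cutoff = p$score_cutoff,
              n_scored = nrow(scored), n_predicted = sum(scored$score >=
                                                           p$score_cutoff))
    invisible(out)
  })
}

#' Pipeline stage: evaluate predictions
#'
#' Confusion counts and recall/precision/F1 against the planted truth by
#' dual-region overlap; ROC AUC when the scored table is labeled; Hi-C
#' support of the predicted pairs versus seeded random pairs with the
#' binomial enrichment p-value; inconsecutiveness of the predicted targets.
#'
#' @param predictions_file Scored TSV from [run_predict()].
#' @param input_dir Fixture-style input directory (truth, contacts).
#' @param out_file Output JSON report.
#' @param p An [etg_params()] object.
#' @param read_cutoff Minimum Hi-C read count for support.
#' @param seed Seed for the random-pair null.
#' @return The report list, invisibly.
#' @export
run_evaluate <- function(predictions_file, input_dir, out_file,
                         p = etg_params(), read_cutoff = 5, seed = 1L) {
  with_cleanup(out_file, {
    fx <- read_fixture(input_dir)
    scored <- read_feature_table(predictions_file)
    predicted <- if ("target" %in% names(scored)) {
      scored[target == TRUE]
    } else scored
    pred_reg <- pair_regions(predicted, fx$enhancers, fx$genes, p)
    truth_reg <- pair_regions(fx$truth, fx$enhancers, fx$genes, p)
    cc <- confusion_counts(pred_reg, truth_reg)
    mets <- pair_metrics(cc)
    auc <- if ("label" %in% names(scored)) {
      roc_auc(scored$score, scored$label)
    } else NA_real_
    sup <- hic_support(predicted, fx$enhancers, fx$genes, fx$contacts,
                       read_cutoff, p)
    nulls <- random_pairs(fx$enhancers, fx$genes, p$candidate_window,
                          max(nrow(predicted), 1L), seed = seed)
    nsup <- hic_support(nulls, fx$enhancers, fx$genes, fx$contacts,
                        read_cutoff, p)
    null_rate <- nrow(nsup) / nrow(nulls)
    enr_p <- if (nrow(predicted) > 0L && null_rate > 0 && null_rate < 1) {
      binomial_enrichment(nrow(sup), nrow(predicted), null_rate)
    } else NA_real_
    inc <- inconsecutiveness(predicted, fx$enhancers, fx$genes, p)
    report <- list(
      n_known = cc$n_known, n_predicted = cc$n_predicted,
      n_known_predicted = cc$n_known_predicted,
      recall = mets$recall, precision = mets$precision, f1 = mets$f1,
      roc_auc = auc, read_cutoff = read_cutoff,
      n_supported = nrow(sup),
      support_rate = if (nrow(predicted) > 0L)
        nrow(sup) / nrow(predicted) else NA_real_,
      null_support_rate = null_rate,
      support_enrichment_p = enr_p,
      inconsecutive_fraction = inc$fraction
    )
    jsonlite::write_json(report, out_file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    log_stage("evaluate", out_file = out_file, recall = mets$recall,
              precision = mets$precision, read_cutoff = read_cutoff)
    invisible(report)
  })
}

#' Pipeline stage: rank feature importance
#'
#' @param features_file Labeled feature TSV.
#' @param out_file Output TSV.
#' @param methods Ranking methods (see [rank_features()]).
#' @param p An [etg_params()] object.
#' @param seed Seed for the forest-based ranking.
#' @return The ranking table, invisibly.
#' @export
run_rank_features <- function(features_file, out_file,
                              methods = c("infogain", "rf"),
                              p = etg_params(), seed = 1L) {
  with_cleanup(out_file, {
    feats <- read_feature_table(features_file)
    ranking <- rank_features(feats, methods = methods, p = p, seed = seed)
    write_feature_table(ranking, out_file,
                        meta = c(stage = "rank_features",
                                 methods = paste(methods, collapse = ",")))
    log_stage("rank_features", out_file = out_file,
              methods = paste(methods, collapse = ","))
    invisible(ranking)
  })
}
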