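# Evaluation harness: region-overlap confusion counts, recall/precision/F1,
# rank-statistic ROC AUC, Hi-C contact-matrix support, random-pair binomial
# nulls and the target-gene inconsecutiveness statistic.

#' Attach enhancer and promoter regions to a pair table
#'
#' @param pairs `data.table` with `enhancer_id`, `gene_id`.
#' @param enhancers,genes Annotation tables.
#' @param p An [etg_params()] object.
#' @return `pairs` with `enh_chrom`, `enh_start`, `enh_end`, `prom_chrom`,
#'   `prom_start`, `prom_end` and `distance` columns.
#' @export
pair_regions <- function(pairs, enhancers, genes, p = etg_params()) {
  pairs <- as.data.table(pairs)
  enhancers <- as.data.table(enhancers)
  genes <- as.data.table(genes)
  ei <- match(pairs$enhancer_id, enhancers$enhancer_id)
  gi <- match(pairs$gene_id, genes$gene_id)
  if (any(is.na(ei)) || any(is.na(gi))) stop("pairs reference unknown ids")
  prom <- promoter_of(genes[gi], p)
  out <- copy(pairs)
  out[, `:=`(enh_chrom = enhancers$chrom[ei], enh_start = enhancers$start[ei],
             enh_end = enhancers$end[ei], prom_chrom = prom$chrom,
             prom_start = prom$start, prom_end = prom$end,
             distance = distance_of(enhancers[ei], genes[gi]))]
  out[]
}

# Dual-region overlap matching between two region-pair tables (>= 1 shared
# bp on both the enhancer side and the promoter side).
match_pairs <- function(a, b) {
  a <- as.data.table(a); b <- as.data.table(b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.table(xid = integer(0), yid = integer(0)))
  }
  qa <- a[, .(xid = .I, chrom = enh_chrom, qs = enh_start, qe = enh_end - 1)]
  qb <- b[, .(yid = .I, chrom = enh_chrom, bs = enh_start, be = enh_end - 1)]
  setkey(qb, chrom, bs, be)
  hits <- foverlaps(qa, qb, by.x = c("chrom", "qs", "qe"),
                    by.y = c("chrom", "bs", "be"), nomatch = NULL)
  if (nrow(hits) == 0L) return(data.table(xid = integer(0), yid = integer(0)))
  ok <- a$prom_chrom[hits$xid] == b$prom_chrom[hits$yid] &
    a$prom_start[hits$xid] < b$prom_end[hits$yid] &
    b$prom_start[hits$yid] < a$prom_end[hits$xid]
  hits[ok, .(xid, yid)]
}

#' Confusion counts by dual-region overlap
#'
#' A prediction matches a known pair when its enhancer region overlaps the
#' known enhancer region and its promoter region overlaps the known
#' promoter region (>= 1 bp each). A known pair matched by several
#' predictions is recovered once, and one prediction matching several known
#' pairs counts once, so `tp + fn` equals the number of known positives.
#'
#' @param predicted,known_pos,known_neg Region-pair tables from
#'   [pair_regions()] (`known_neg` optional).
#' @return Object of class `etg_confusion` with `tp` (known positives
#'   recovered), `fp` (predictions matching no known positive), `fn`, `tn`,
#'   and the raw tallies `n_known`, `n_predicted`, `n_known_predicted`.
#' @export
confusion_counts <- function(predicted, known_pos, known_neg = NULL) {
  predicted <- as.data.table(predicted)
  known_pos <- as.data.table(known_pos)
  m <- match_pairs(predicted, known_pos)
  tp <- uniqueN(m$yid)
  matched_pred <- uniqueN(m$xid)
  fp <- nrow(predicted) - matched_pred
  fn <- nrow(known_pos) - tp
  tn <- NA_integer_
  if (!is.null(known_neg)) {
    known_neg <- as.data.table(known_neg)
    mn <- match_pairs(predicted, known_neg)
    tn <- nrow(known_neg) - uniqueN(mn$yid)
  }
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         n_known = nrow(known_pos), n_predicted = nrow(predicted),
         n_known_predicted = tp),
    class = "etg_confusion"
  )
}

#' @export
print.etg_confusion <- function(x, ...) {
  cat(sprintf("confusion: tp=%d fp=%d fn=%d tn=%s (known=%d predicted=%d)\n",
              x$tp, x$fp, x$fn, format(x$tn), x$n_known, x$n_predicted))
  invisible(x)
}

#' Recall, precision and F1 from confusion counts
#'
#' `recall = tp/(tp+fn)`, `precision = tp/(tp+fp)`,
#' `f1 = 2PR/(P+R)`; a zero denominator yields `NA` (undefined), never a
#' division by zero.
#'
#' @param x An `etg_confusion` object, or a list with `tp`, `fp`, `fn`
#'   (and optionally `tn`).
#' @return Object of class `etg_metrics`: `recall`, `precision`, `f1` plus
#'   the counts.
#' @export
pair_metrics <- function(x) {
  tp <- x$tp; fp <- x$fp; fn <- x$fn
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(recall) && !is.na(precision) && (recall + precision) > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  structure(
    list(recall = recall, precision = precision, f1 = f1,
         tp = tp, fp = fp, fn = fn, tn = x$tn %||% NA_integer_,
         n_known = x$n_known %||% (tp + fn),
         n_predicted = x$n_predicted %||% NA_integer_,
         n_known_predicted = x$n_known_predicted %||% tp),
    class = "etg_metrics"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Metrics from published-style tallies
#'
#' Convenience wrapper mapping (number of known pairs, number of predicted
#' pairs, number of known pairs predicted) to confusion counts and then to
#' [pair_metrics()].
#'
#' @param n_known,n_predicted,n_known_predicted Integer tallies.
#' @return An `etg_metrics` object.
#' @export
metrics_from_counts <- function(n_known, n_predicted, n_known_predicted) {
  pair_metrics(list(
    tp = n_known_predicted, fp = n_predicted - n_known_predicted,
    fn = n_known - n_known_predicted, tn = NA_integer_,
    n_known = n_known, n_predicted = n_predicted,
    n_known_predicted = n_known_predicted
  ))
}

#' @export
print.etg_metrics <- function(x, ...) {
  cat(sprintf("recall=%.3f precision=%.3f F1=%.3f (known=%s predicted=%s)\n",
              x$recall, x$precision, x$f1, format(x$n_known),
              format(x$n_predicted)))
  invisible(x)
}

#' ROC area under the curve
#'
#' Area under the TPR-vs-FPR curve over all score thresholds, computed in
#' the rank-statistic (Mann-Whitney) form so that tied scores contribute
#' half a concordance.
#'
#' @param scores Numeric scores.
#' @param labels Logical, 0/1, or `"positive"`/`"negative"` labels.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels) == "positive"
  }
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    stop("scores and labels must be complete and of equal length")
  }
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0L || nneg == 0L) stop("both classes required for ROC AUC")
  r <- rank(scores)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Read a sparse contact matrix
#'
#' Triplet TSV with columns `chrom`, `bin_i_start`, `bin_j_start`, `count`
#' (normalized read counts; bin starts must be multiples of the
#' resolution).
#'
#' @param path Path to the triplet TSV.
#' @param resolution Bin size in bp.
#' @return `data.table` with attribute `"resolution"`.
#' @export
read_contacts <- function(path, resolution = 5000) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  dt <- fread(path, header = identical(first[1], "chrom"), sep = "\t")
  if (ncol(dt) < 4L) stop("contact triplets need 4 columns: ", path)
  setnames(dt, seq_len(4L), c("chrom", "bin_i_start", "bin_j_start", "count"))
  if (dt[, any(count < 0)]) stop("negative contact counts in ", path)
  if (dt[, any(bin_i_start %% resolution != 0 | bin_j_start %% resolution != 0)]) {
    stop("bin starts are not multiples of the stated resolution")
  }
  setattr(dt, "resolution", resolution)
  dt[]
}

#' Hi-C support of enhancer-gene pairs
#'
#' A pair is supported when its enhancer-TSS distance is at least
#' `p$min_separation` and some contact triplet with count >= `read_cutoff`
#' has one bin overlapping the enhancer region and the other overlapping
#' the promoter region (in either orientation).
#'
#' @param pairs Pair table (`enhancer_id`, `gene_id`).
#' @param enhancers,genes Annotation tables.
#' @param contacts Contact table from [read_contacts()].
#' @param read_cutoff Minimum normalized read count.
#' @param p An [etg_params()] object (`hic_resolution`, `min_separation`).
#' @return The supported subset of `pairs`; the full logical vector is
#'   attached as attribute `"supported"`.
#' @export
hic_support <- function(pairs, enhancers, genes, contacts, read_cutoff,
                        p = etg_params()) {
  res <- attr(contacts, "resolution") %||% p$hic_resolution
  if (res != p$hic_resolution) {
    stop(sprintf("contact resolution %s does not match parameter %s",
                 format(res), format(p$hic_resolution)))
  }
  pr <- pair_regions(pairs, enhancers, genes, p)
  cm <- as.data.table(contacts)[count >= read_cutoff]
  # symmetrize so that (enhancer bin, promoter bin) can match either order
  cm <- unique(rbindlist(list(
    cm[, .(chrom, bi = bin_i_start, bj = bin_j_start)],
    cm[, .(chrom, bi = bin_j_start, bj = bin_i_start)]
  )))
  supported <- rep(FALSE, nrow(pr))
  if (nrow(cm) > 0L && nrow(pr) > 0L) {
    combos <- rbindlist(lapply(seq_len(nrow(pr)), function(i) {
      if (pr$distance[i] < p$min_separation || !is.finite(pr$distance[i])) {
        return(NULL)
      }
      eb <- seq(floor(pr$enh_start[i] / res), floor((pr$enh_end[i] - 1) / res))
      pb <- seq(floor(pr$prom_start[i] / res), floor((pr$prom_end[i] - 1) / res))
      CJ(i = i, chrom = pr$enh_chrom[i], bi = eb * res, bj = pb * res)
    }))
    if (!is.null(combos) && nrow(combos) > 0L) {
      hit <- cm[combos, on = c("chrom", "bi", "bj"), nomatch = NULL]
      supported[unique(hit$i)] <- TRUE
    }
  }
  out <- as.data.table(pairs)[supported]
  setattr(out, "supported", supported)
  out
}

#' Random enhancer-gene null pairs
#'
#' Uniform independent draws of (enhancer, gene within `window`); the null
#' counterpart of the predicted pair set.
#'
#' @param enhancers,genes Annotation tables.
#' @param window Neighbourhood size in bp.
#' @param n Number of pairs to draw.
#' @param seed Integer seed.
#' @return `data.table` with `enhancer_id`, `gene_id`, `distance`.
#' @export
random_pairs <- function(enhancers, genes, window, n, seed = NULL) {
  cand <- enumerate_candidates(enhancers, genes, etg_params(), window = window)
  if (nrow(cand) == 0L) stop("no eligible enhancer-gene pair within the window")
  draw <- function() cand[sample(.N, n, replace = TRUE)]
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out[]
}

#' Exact binomial enrichment p-value
#'
#' One-sided upper-tail probability of observing at least `k` supported
#' pairs among `n` under a null support rate `p0`.
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p0 Null success probability in (0, 1).
#' @return p-value.
#' @export
binomial_enrichment <- function(k, n, p0) {
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Inconsecutiveness of predicted target genes
#'
#' For each enhancer with >= 2 predicted targets, order its candidate genes
#' by TSS; the enhancer is inconsecutive when a non-target candidate lies
#' strictly between two targets in that order. Enhancers with fewer than
#' two targets are excluded from the denominator.
#'
#' @param predictions Predicted pair table (`enhancer_id`, `gene_id`).
#' @param enhancers,genes Annotation tables.
#' @param p An [etg_params()] object (candidate window).
#' @return List with `per_enhancer` (`enhancer_id`, `n_targets`,
#'   `inconsecutive`) and `fraction` (share of inconsecutive enhancers
#'   among those with >= 2 targets; `NaN` when none qualify).
#' @export
inconsecutiveness <- function(predictions, enhancers, genes, p = etg_params()) {
  predictions <- as.data.table(predictions)
  enhancers <- as.data.table(enhancers)
  genes <- as.data.table(genes)
  per <- rbindlist(lapply(unique(predictions$enhancer_id), function(e) {
    cand <- candidate_genes(enhancers[enhancer_id == e], genes, p)
    targets <- predictions[enhancer_id == e, gene_id]
    idx <- sort(match(targets, cand$gene_id))
    idx <- idx[!is.na(idx)]
    inc <- if (length(idx) >= 2L) (max(idx) - min(idx) + 1L) > length(idx) else NA
    data.table(enhancer_id = e, n_targets = length(idx), inconsecutive = inc)
  }))
  qual <- per[n_targets >= 2L]
  list(per_enhancer = per,
       fraction = if (nrow(qual) > 0L) mean(qual$inconsecutive) else NaN)
}
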