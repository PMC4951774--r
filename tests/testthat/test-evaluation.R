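regions_of <- function(pairs, enh, genes) {
  pair_regions(pairs, enh, genes, etg_params())
}

test_that("confusion counts match dual-region overlap semantics", {
  enh <- toy_enhancers(); genes <- toy_genes()
  known <- regions_of(data.table::data.table(
    enhancer_id = c("e1", "e2"), gene_id = c("g1", "g3")), enh, genes)
  # predictions identical to the positives
  cc <- confusion_counts(known, known)
  expect_equal(c(cc$tp, cc$fp, cc$fn), c(2L, 0L, 0L))
  # empty prediction set
  cc0 <- confusion_counts(known[0], known)
  expect_equal(c(cc0$tp, cc0$fp, cc0$fn), c(0L, 0L, 2L))
  # partial overlap still counts: shift the predicted enhancer by half its
  # width and the promoter match is by region, not identity
  shifted <- data.table::copy(known)[1, `:=`(enh_start = enh_start + 500,
                                             enh_end = enh_end + 500)]
  cc2 <- confusion_counts(shifted[1], known)
  expect_equal(cc2$tp, 1L)
  # brute-force all-pairs overlap oracle
  ov <- function(a, b, i, j) {
    a$enh_chrom[i] == b$enh_chrom[j] &&
      a$enh_start[i] < b$enh_end[j] && b$enh_start[j] < a$enh_end[i] &&
      a$prom_chrom[i] == b$prom_chrom[j] &&
      a$prom_start[i] < b$prom_end[j] && b$prom_start[j] < a$prom_end[i]
  }
  withr::with_seed(3, {
    pred <- regions_of(data.table::data.table(
      enhancer_id = sample(enh$enhancer_id, 5, replace = TRUE),
      gene_id = sample(genes$gene_id, 5, replace = TRUE)), enh, genes)
    cc3 <- confusion_counts(pred, known)
    hit_known <- vapply(seq_len(nrow(known)), function(j)
      any(vapply(seq_len(nrow(pred)), function(i) ov(pred, known, i, j),
                 logical(1))), logical(1))
    hit_pred <- vapply(seq_len(nrow(pred)), function(i)
      any(vapply(seq_len(nrow(known)), function(j) ov(pred, known, i, j),
                 logical(1))), logical(1))
    expect_equal(cc3$tp, sum(hit_known))
    expect_equal(cc3$fp, sum(!hit_pred))
    expect_equal(cc3$fn, sum(!hit_known))
  })
})

test_that("a prediction matching two known pairs is not double-counted", {
  enh <- data.table::data.table(enhancer_id = c("k1", "k2", "p"),
                                chrom = "chr1",
                                start = c(1000, 1200, 900),
                                end = c(1500, 1700, 1800))
  genes <- data.table::data.table(gene_id = "g1", chrom = "chr1",
                                  tss = 50000, strand = "+",
                                  name = NA_character_)
  known <- regions_of(data.table::data.table(enhancer_id = c("k1", "k2"),
                                             gene_id = "g1"), enh, genes)
  pred <- regions_of(data.table::data.table(enhancer_id = "p",
                                            gene_id = "g1"), enh, genes)
  cc <- confusion_counts(pred, known)
  expect_equal(cc$tp, 2L)   # both known pairs recovered ...
  expect_equal(cc$fp, 0L)   # ... by a single prediction, counted once
  expect_equal(cc$n_predicted, 1L)
})

test_that("metric identities hold exactly on integer counts", {
  withr::with_seed(41, {
    for (rep in 1:25) {
      tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
      m <- pair_metrics(list(tp = tp, fp = fp, fn = fn, tn = 0L))
      if (tp + fn > 0) expect_equal(m$recall, tp / (tp + fn))
      if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
      if (!is.na(m$f1)) {
        # harmonic-mean identity against rational arithmetic
        expect_equal(m$f1, 2 * tp / (2 * tp + fp + fn), tolerance = 1e-15)
        expect_lte(m$f1, 2 * min(m$precision, m$recall))
        expect_lte(m$f1, (m$precision + m$recall) / 2 * 2)
      }
    }
  })
  und <- pair_metrics(list(tp = 0L, fp = 0L, fn = 5L, tn = 0L))
  expect_true(is.na(und$precision))
})

test_that("ROC AUC equals the exact pairwise rank oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
  # six-point hand example with one tie
  s <- c(0.9, 0.7, 0.7, 0.5, 0.3, 0.1)
  y <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  expect_equal(roc_auc(s, y), auc_oracle(s, y))
  expect_equal(roc_auc(s, y), (3 + 2.5 + 1) / 9)  # hand count of pair wins
  withr::with_seed(47, {
    for (rep in 1:200) {
      n <- sample(4:50, 1)
      s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
      y <- runif(n) < 0.5
      if (!any(y) || all(y)) next
      expect_equal(roc_auc(s, y), auc_oracle(s, y), tolerance = 1e-12)
    }
  })
})

test_that("label-independent scores give AUC near one half", {
  withr::with_seed(53, {
    s <- runif(4000); y <- runif(4000) < 0.5
    expect_lt(abs(roc_auc(s, y) - 0.5), 0.03)
  })
})

hic_world <- function() {
  enh <- data.table::data.table(enhancer_id = "e1", chrom = "chr1",
                                start = 10100, end = 10400)
  genes <- data.table::data.table(gene_id = c("gfar", "gnear"),
                                  chrom = "chr1", tss = c(52000, 11500),
                                  strand = "+", name = NA_character_)
  contacts <- data.table::data.table(chrom = "chr1", bin_i_start = 10000,
                                     bin_j_start = 50000, count = 6)
  data.table::setattr(contacts, "resolution", 5000)
  list(enh = enh, genes = genes, contacts = contacts)
}

test_that("Hi-C support honours read cutoff, bin overlap and separation", {
  w <- hic_world(); p <- etg_params()
  pairs <- data.table::data.table(enhancer_id = "e1",
                                  gene_id = c("gfar", "gnear"))
  sup5 <- hic_support(pairs, w$enh, w$genes, w$contacts, 5, p)
  expect_equal(sup5$gene_id, "gfar")         # supported triplet, >= 5 kb
  sup10 <- hic_support(pairs, w$enh, w$genes, w$contacts, 10, p)
  expect_equal(nrow(sup10), 0L)              # cutoff above the count
  # close pairs are excluded regardless of contact counts
  close_contact <- data.table::data.table(chrom = "chr1",
                                          bin_i_start = 10000,
                                          bin_j_start = 10000, count = 50)
  data.table::setattr(close_contact, "resolution", 5000)
  supc <- hic_support(pairs[2], w$enh, w$genes, close_contact, 5, p)
  expect_equal(nrow(supc), 0L)
  # swapped bin order also matches
  swapped <- data.table::data.table(chrom = "chr1", bin_i_start = 50000,
                                    bin_j_start = 10000, count = 6)
  data.table::setattr(swapped, "resolution", 5000)
  expect_equal(hic_support(pairs, w$enh, w$genes, swapped, 5, p)$gene_id,
               "gfar")
  # resolution mismatch is an error
  data.table::setattr(w$contacts, "resolution", 1000)
  expect_error(hic_support(pairs, w$enh, w$genes, w$contacts, 5, p),
               "resolution")
})

test_that("Hi-C support is monotone non-increasing in the read cutoff", {
  fx <- default_bundle()$fx
  pairs <- fx$truth[1:200, .(enhancer_id, gene_id)]
  sizes <- vapply(c(1, 5, 10, 25, 60), function(cut) {
    nrow(hic_support(pairs, fx$enhancers, fx$genes, fx$contacts, cut,
                     etg_params()))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("random pairs are seed-deterministic and forced when unique", {
  enh <- data.table::data.table(enhancer_id = "e1", chrom = "chr1",
                                start = 1000, end = 2000)
  genes <- data.table::data.table(gene_id = "g1", chrom = "chr1", tss = 5000,
                                  strand = "+", name = NA_character_)
  rp <- random_pairs(enh, genes, 2e6, 3L, seed = 1)
  expect_equal(unique(rp$gene_id), "g1")
  fx <- default_bundle()$fx
  r1 <- random_pairs(fx$enhancers, fx$genes, 2e6, 50L, seed = 9)
  r2 <- random_pairs(fx$enhancers, fx$genes, 2e6, 50L, seed = 9)
  expect_identical(r1, r2)
  expect_error(random_pairs(enh, genes[0], 2e6, 3L, seed = 1), "eligible")
})

test_that("binomial enrichment equals the exact tail sum", {
  expect_equal(binomial_enrichment(10, 10, 0.5), 2^-10)
  expect_equal(binomial_enrichment(0, 10, 0.5), 1)
  # direct summation oracle
  k <- 7; n <- 10; p0 <- 0.102
  want <- sum(choose(n, k:n) * p0^(k:n) * (1 - p0)^(n - (k:n)))
  expect_equal(binomial_enrichment(k, n, p0), want, tolerance = 1e-12)
  expect_error(binomial_enrichment(11, 10, 0.5), "k must")
  expect_error(binomial_enrichment(2, 10, 0), "p0 must")
})

test_that("inconsecutiveness flags interrupted target runs only", {
  enh <- data.table::data.table(enhancer_id = c("eA", "eB", "eC"),
                                chrom = "chr1", start = 1000, end = 1300)
  genes <- data.table::data.table(gene_id = sprintf("g%d", 1:4),
                                  chrom = "chr1",
                                  tss = c(10000, 20000, 30000, 40000),
                                  strand = "+", name = NA_character_)
  pred <- data.table::data.table(
    enhancer_id = c("eA", "eA", "eB", "eB", "eC"),
    gene_id = c("g1", "g3", "g1", "g2", "g2"))
  inc <- inconsecutiveness(pred, enh, genes, etg_params())
  per <- inc$per_enhancer
  expect_true(per[enhancer_id == "eA", inconsecutive])   # g2 interrupts
  expect_false(per[enhancer_id == "eB", inconsecutive])  # adjacent run
  expect_true(is.na(per[enhancer_id == "eC", inconsecutive]))  # 1 target
  expect_equal(inc$fraction, 0.5)  # over the two enhancers with >= 2 targets
})
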