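empty_blocks <- function() {
  data.table::data.table(species = character(0), ref_chrom = character(0),
                         ref_start = numeric(0), ref_end = numeric(0),
                         tgt_chrom = character(0), tgt_start = numeric(0),
                         tgt_end = numeric(0), orientation = character(0))
}

mk_blocks <- function(...) {
  if (length(list(...)) == 0L) return(empty_blocks())
  data.table::rbindlist(lapply(list(...), function(r) {
    data.table::data.table(species = r[[1]], ref_chrom = r[[2]],
                           ref_start = as.numeric(r[[3]]),
                           ref_end = as.numeric(r[[4]]),
                           tgt_chrom = r[[5]],
                           tgt_start = as.numeric(r[[6]]),
                           tgt_end = as.numeric(r[[7]]),
                           orientation = r[[8]])
  }))
}

test_that("single-block lifting trims the target proportionally", {
  b <- mk_blocks(list("s", "chr1", 0, 1000, "t1", 5000, 7000, "+"))
  m <- map_region(b, list(chrom = "chr1", start = 250, end = 500))
  expect_equal(m$chrom, "t1")
  expect_equal(m$start, 5000 + 250 * 2)   # scale 2
  expect_equal(m$end, 5000 + 500 * 2)
  expect_null(map_region(b, list(chrom = "chr1", start = 2000, end = 2100)))
  expect_null(map_region(b, list(chrom = "chr9", start = 0, end = 100)))
})

test_that("majority target chromosome wins for split regions", {
  b <- mk_blocks(
    list("s", "chr1", 0, 800, "t1", 0, 800, "+"),
    list("s", "chr1", 800, 1000, "t2", 0, 200, "+")
  )
  # 80% of the query overlaps the t1 block, 20% the t2 block
  m <- map_region(b, list(chrom = "chr1", start = 0, end = 1000))
  expect_equal(m$chrom, "t1")
  expect_equal(c(m$start, m$end), c(0, 800))
})

test_that("minus-orientation blocks reflect the lifted interval", {
  b <- mk_blocks(list("s", "chr1", 0, 1000, "t1", 5000, 6000, "-"))
  m <- map_region(b, list(chrom = "chr1", start = 0, end = 100))
  expect_equal(c(m$start, m$end), c(5900, 6000))
})

test_that("species distance is a gap, zero on overlap, NA when unmapped", {
  p <- etg_params()
  e <- data.table::data.table(enhancer_id = "e", chrom = "chr1",
                              start = 100, end = 200)
  g <- data.table::data.table(gene_id = "g", chrom = "chr1", tss = 5000,
                              strand = "+")
  # promoter = [4000, 5100); enhancer and promoter lift 1:1
  b <- mk_blocks(
    list("s", "chr1", 100, 200, "t1", 0, 100, "+"),
    list("s", "chr1", 4000, 5100, "t1", 600, 1700, "+")
  )
  expect_equal(species_distance(b, e, g, p), 500)
  b2 <- mk_blocks(
    list("s", "chr1", 100, 200, "t1", 0, 100, "+"),
    list("s", "chr1", 4000, 5100, "t1", 50, 1150, "+")
  )
  expect_equal(species_distance(b2, e, g, p), 0)
  b3 <- mk_blocks(list("s", "chr1", 4000, 5100, "t1", 0, 1100, "+"))
  expect_true(is.na(species_distance(b3, e, g, p)))
  b4 <- mk_blocks(
    list("s", "chr1", 100, 200, "t1", 0, 100, "+"),
    list("s", "chr1", 4000, 5100, "t2", 0, 1100, "+")
  )
  expect_true(is.na(species_distance(b4, e, g, p)))
})

css_world <- function(d_by_species) {
  # builds blocks realizing the requested per-species distances (NA = absent)
  e <- data.table::data.table(enhancer_id = "e", chrom = "chr1",
                              start = 100, end = 200)
  g <- data.table::data.table(gene_id = "g", chrom = "chr1", tss = 5000,
                              strand = "+", name = NA_character_)
  rows <- list()
  for (s in names(d_by_species)) {
    d <- d_by_species[[s]]
    if (is.na(d)) next
    rows[[length(rows) + 1L]] <-
      list(s, "chr1", 100, 200, "t1", 0, 100, "+")
    rows[[length(rows) + 1L]] <-
      list(s, "chr1", 4000, 5100, "t1", 100 + d, 1200 + d, "+")
  }
  list(e = e, g = g, blocks = do.call(mk_blocks, rows))
}

test_that("CSS matches hand-computed values on worked examples", {
  p <- etg_params()
  phi5 <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
  w <- css_world(setNames(rep(0, 5), names(phi5)))
  expect_equal(as.numeric(css_score(w$e, w$g, w$blocks, phi5, p)), 1)
  w0 <- css_world(setNames(rep(NA_real_, 5), names(phi5)))
  expect_equal(as.numeric(css_score(w0$e, w0$g, w0$blocks, phi5, p)), 0)
  # phi = {1, 1}, d_A = 1 Mb, B absent, Theta = 2 Mb -> 0.25
  w2 <- css_world(c(A = 1e6, B = NA))
  expect_equal(as.numeric(css_score(w2$e, w2$g, w2$blocks, c(A = 1, B = 1), p)),
               0.25)
  expect_error(css_score(w2$e, w2$g, w2$blocks, numeric(0), p), "empty")
})

test_that("CSS is bounded, monotone in distance and scale-invariant in phi", {
  p <- etg_params()
  phi <- c(a = 0.4, b = 1.2, c = 2.5)
  withr::with_seed(99, {
    for (rep in 1:20) {
      d1 <- ifelse(runif(3) < 0.3, NA, runif(3, 0, 3e6))
      w1 <- css_world(setNames(d1, names(phi)))
      v1 <- as.numeric(css_score(w1$e, w1$g, w1$blocks, phi, p))
      expect_gte(v1, 0); expect_lte(v1, 1)
      # increasing any present distance cannot increase the score
      d2 <- d1 + ifelse(is.na(d1), 0, runif(3, 0, 1e6))
      w2 <- css_world(setNames(d2, names(phi)))
      v2 <- as.numeric(css_score(w2$e, w2$g, w2$blocks, phi, p))
      expect_lte(v2, v1 + 1e-12)
      # a previously absent species becoming syntenic cannot decrease it
      if (any(is.na(d1))) {
        d3 <- d1; d3[which(is.na(d1))[1]] <- 0
        w3 <- css_world(setNames(d3, names(phi)))
        v3 <- as.numeric(css_score(w3$e, w3$g, w3$blocks, phi, p))
        expect_gte(v3, v1 - 1e-12)
      }
      # uniform rescaling of phi leaves the score unchanged
      expect_equal(as.numeric(css_score(w1$e, w1$g, w1$blocks, phi * 7.3, p)),
                   v1)
    }
  })
})

test_that("vectorised CSS equals the per-species loop on random fixtures", {
  p <- etg_params()
  phi <- c(a = 0.4, b = 1.2, c = 2.5)
  withr::with_seed(123, {
    for (rep in 1:10) {
      d <- ifelse(runif(3) < 0.4, NA, runif(3, 0, 4e6))
      w <- css_world(setNames(d, names(phi)))
      single <- as.numeric(css_score(w$e, w$g, w$blocks, phi, p))
      batch <- etgpair:::compute_css(
        data.table::data.table(enhancer_id = "e", gene_id = "g"),
        w$e, w$g, w$blocks, phi, p
      )
      expect_equal(batch, single, tolerance = 1e-12)
      # brute-force oracle: independent per-species kernel evaluation
      cs <- ifelse(is.na(d), 0, pmax(0, 1 - d / p$theta))
      expect_equal(single, sum(phi * cs) / sum(phi), tolerance = 1e-9)
    }
  })
})

test_that("the indicator kernel scores any syntenic species fully", {
  p <- etg_params(css_kernel = "indicator")
  w <- css_world(c(A = 1e6, B = NA))
  expect_equal(as.numeric(css_score(w$e, w$g, w$blocks, c(A = 1, B = 1), p)),
               0.5)
})
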