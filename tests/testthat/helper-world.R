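# Shared in-code fixtures: a hand-sized genomic world, a toy ontology with
# known propagated counts, and a session-cached default synthetic bundle.

toy_enhancers <- function() {
  data.table::data.table(
    enhancer_id = c("e1", "e2", "e3"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000, 50000, 8000),
    end = c(2000, 50400, 8500)
  )
}

toy_genes <- function() {
  data.table::data.table(
    gene_id = sprintf("g%d", 1:6),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2"),
    tss = c(5000, 10000, 30000, 2500000, 9000, 400000),
    strand = c("+", "-", "+", "+", "-", "+"),
    name = sprintf("G%d", 1:6)
  )
}

# Linear-chain ontology with propagated counts 8 / 4 / 1 (IC 0, ln 2, ln 8)
# plus a sibling pair A/B under the middle term for the MICA checks.
toy_dag <- function() {
  obo <- c(
    "format-version: 1.2", "",
    "[Term]", "id: T0", "name: root", "namespace: biological_process", "",
    "[Term]", "id: T1", "name: mid", "namespace: biological_process",
    "is_a: T0 ! root", "",
    "[Term]", "id: T2", "name: deep", "namespace: biological_process",
    "is_a: T1 ! mid", "",
    "[Term]", "id: TA", "name: leaf a", "namespace: biological_process",
    "is_a: T1 ! mid", "",
    "[Term]", "id: TB", "name: leaf b", "namespace: biological_process",
    "is_a: T1 ! mid", ""
  )
  f <- withr::local_tempfile(fileext = ".obo", .local_envir = parent.frame())
  writeLines(obo, f)
  read_go_obo(f)
}

# Annotations giving propagated counts T0=8, T1=4, T2=1, TA=1, TB=1.
toy_ann <- function() {
  data.table::data.table(
    gene = c(sprintf("u%d", 1:4), "v1", "w", "a", "b"),
    term = c(rep("T0", 4), "T1", "T2", "TA", "TB")
  )
}

toy_dag_ic <- function() compute_ic(toy_dag(), toy_ann())

# The default synthetic bundle, generated once per test session.
default_bundle <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$bundle)) {
      dir <- file.path(tempdir(), "etgpair-default-fixture")
      cache$bundle <- generate_fixture(fixture_config(seed = 42), dir)
      cache$fx <- read_fixture(dir)
    }
    list(bundle = cache$bundle, fx = cache$fx)
  }
})

# Feature table of the default bundle, cached alongside it.
default_features <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$feats)) {
      fx <- default_bundle()$fx
      cache$feats <- fixture_feature_table(
        fx, etg_params(), n_negatives = 3L * nrow(fx$truth), seed = 4242
      )
    }
    cache$feats
  }
})
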