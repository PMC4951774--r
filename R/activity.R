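# Chromatin-activity correlation feature: mean per-bp DNase hypersensitivity
# signal of a region across a panel of cell types, compared by Spearman
# rank correlation between the enhancer and the candidate promoter.

#' Read a panel of signal tracks
#'
#' Loads one bedGraph per cell type. Input is either a manifest TSV with
#' columns `cell_type`, `path` (paths resolved relative to the manifest) or
#' a named character vector of bedGraph paths.
#'
#' @param x Manifest path or named vector of paths.
#' @return Object of class `signal_track_set`: named list of keyed
#'   data.tables (`chrom`, `start`, `end`, `value`).
#' @export
read_signal_tracks <- function(x) {
  if (length(x) == 1L && is.null(names(x))) {
    man <- fread(x, header = TRUE, sep = "\t")
    if (!all(c("cell_type", "path") %in% names(man))) {
      stop("track manifest needs columns cell_type, path")
    }
    paths <- setNames(file.path(dirname(x), man$path), man$cell_type)
  } else {
    if (is.null(names(x))) stop("track paths must be named by cell type")
    paths <- x
  }
  tracks <- lapply(paths, function(pth) {
    if (!file.exists(pth)) stop("bedGraph not found: ", pth)
    dt <- fread(pth, header = FALSE, sep = "\t")
    if (ncol(dt) < 4L) stop("bedGraph needs 4 columns: ", pth)
    setnames(dt, seq_len(4L), c("chrom", "start", "end", "value"))
    if (any(dt$value < 0)) stop("negative signal values in ", pth)
    dt[, `:=`(start = as.numeric(start), end = as.numeric(end),
              value = as.numeric(value))]
    dt[]
  })
  structure(tracks, class = "signal_track_set")
}

#' Mean per-bp signal over regions
#'
#' Sum of value times covered length over each region divided by the region
#' width; uncovered bases contribute 0.
#'
#' @param track One track (`data.table` with `chrom`, `start`, `end`,
#'   `value`).
#' @param regions Region table (`chrom`, `start`, `end`).
#' @return Numeric vector of mean signals, aligned with `regions`.
#' @export
region_signal <- function(track, regions) {
  regions <- as.data.table(regions)
  if (nrow(regions) == 0L) return(numeric(0))
  q <- data.table(idx = seq_len(nrow(regions)), chrom = regions$chrom,
                  qs = regions$start, qe = regions$end - 1,
                  q_start = regions$start, q_end = regions$end)
  b <- as.data.table(track)[, .(chrom, bs = start, be = end - 1,
                                t_start = start, t_end = end, value)]
  setkey(b, chrom, bs, be)
  hits <- foverlaps(q, b, by.x = c("chrom", "qs", "qe"),
                    by.y = c("chrom", "bs", "be"), nomatch = NULL)
  out <- numeric(nrow(regions))
  if (nrow(hits) > 0L) {
    hits[, ov := pmin(q_end, t_end) - pmax(q_start, t_start)]
    agg <- hits[, .(s = sum(value * ov)), by = idx]
    out[agg$idx] <- agg$s
  }
  out / (regions$end - regions$start)
}

# Region x cell-type matrix of mean signals.
activity_matrix <- function(tracks, regions) {
  stopifnot(inherits(tracks, "signal_track_set"))
  vapply(tracks, region_signal, numeric(nrow(as.data.table(regions))),
         regions = regions)
}

spearman_or_zero <- function(x, y) {
  if (var(x) == 0 || var(y) == 0) return(0)
  cor(x, y, method = "spearman")
}

#' Activity correlation of an enhancer and a gene promoter
#'
#' Spearman rank correlation (average ranks on ties) of the mean per-bp
#' signal of the enhancer region and of the gene's promoter across the cell
#' types of the panel. A constant activity vector has no defined rank
#' correlation and scores 0 so that the feature is always populated.
#'
#' @param enhancer Single enhancer row.
#' @param gene Single gene row.
#' @param tracks A `signal_track_set` with >= 3 cell types.
#' @param p An [etg_params()] object (promoter definition).
#' @return Correlation in \[-1, 1\].
#' @export
correlation_feature <- function(enhancer, gene, tracks, p = etg_params()) {
  stopifnot(inherits(tracks, "signal_track_set"))
  if (length(tracks) < 3L) stop("need >= 3 cell types for a defined correlation")
  e <- activity_matrix(tracks, as.data.table(enhancer)[, .(chrom, start, end)])
  g <- activity_matrix(tracks, promoter_of(gene, p))
  spearman_or_zero(as.numeric(e), as.numeric(g))
}

# Vectorised correlations for a pair table: ranks each region's activity
# vector once, then computes the Pearson correlation of ranks pairwise.
compute_correlations <- function(pairs, enhancers, genes, tracks,
                                 p = etg_params()) {
  stopifnot(inherits(tracks, "signal_track_set"))
  if (length(tracks) < 3L) stop("need >= 3 cell types for a defined correlation")
  pairs <- as.data.table(pairs)
  enhancers <- as.data.table(enhancers)
  genes <- as.data.table(genes)
  em <- activity_matrix(tracks, enhancers[, .(chrom, start, end)])
  gm <- activity_matrix(tracks, promoter_of(genes, p))
  if (is.null(dim(em))) em <- matrix(em, nrow = 1)
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1)
  rank_rows <- function(m) t(apply(m, 1, rank))
  er <- rank_rows(em); gr <- rank_rows(gm)
  ei <- match(pairs$enhancer_id, enhancers$enhancer_id)
  gi <- match(pairs$gene_id, genes$gene_id)
  vapply(seq_len(nrow(pairs)), function(i) {
    x <- er[ei[i], ]; y <- gr[gi[i], ]
    if (var(x) == 0 || var(y) == 0) return(0)
    cor(x, y)
  }, numeric(1))
}
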