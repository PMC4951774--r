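# Genomic primitives. All internal coordinates are 0-based half-open
# (BED convention): an interval [start, end) covers bases start .. end-1.

#' Read enhancers from a BED file
#'
#' Parses a BED file (>= 3 columns) into an enhancer table. Track, browser
#' and comment lines are skipped. Enhancer identifiers come from the fourth
#' column when present, otherwise `"chrom:start-end"`.
#'
#' @param path Path to a BED file.
#' @return A `data.table` with columns `enhancer_id`, `chrom`, `start`,
#'   `end` (0-based half-open), one row per input record, order preserved.
#' @export
read_enhancers <- function(path) {
  if (!file.exists(path)) stop("enhancer BED file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) &
                  !grepl("^(#|track\\b|browser\\b)", lines))
  if (length(keep) == 0L) stop("no enhancer records in ", path)
  recs <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 3L) {
      stop(sprintf("malformed BED line %d in %s: fewer than 3 columns", i, path))
    }
    if (!grepl("^[0-9]+$", f[2]) || !grepl("^[0-9]+$", f[3])) {
      stop(sprintf("malformed BED line %d in %s: non-numeric coordinates", i, path))
    }
    s <- as.numeric(f[2]); e <- as.numeric(f[3])
    if (s >= e) {
      stop(sprintf("malformed BED line %d in %s: start >= end", i, path))
    }
    id <- if (length(f) >= 4L && nzchar(f[4])) f[4] else
      sprintf("%s:%s-%s", f[1], f[2], f[3])
    recs[[j]] <- data.table(enhancer_id = id, chrom = f[1], start = s, end = e)
  }
  out <- rbindlist(recs)
  if (anyDuplicated(out$enhancer_id)) {
    stop("duplicate enhancer ids in ", path)
  }
  out[]
}

#' Read gene annotation
#'
#' Accepts GTF/GFF3 (by file extension, read through
#' [rtracklayer::import()]) or a 4/5-column tabular file
#' (`gene_id`, `chrom`, `tss`, `strand`[, `name`]). For GTF/GFF input only
#' records of type `gene` are used when that type is present. The TSS is the
#' printed feature start for `+` genes and the printed feature end minus one
#' for `-` genes.
#'
#' @param path Path to the annotation file.
#' @return A `data.table` with columns `gene_id`, `chrom`, `tss`, `strand`
#'   and `name`.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("gene annotation file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff", "gff3")) {
    gr <- rtracklayer::import(path)
    df <- as.data.frame(gr)
    if ("type" %in% names(df) && any(df$type == "gene")) {
      df <- df[df$type == "gene", , drop = FALSE]
    }
    strand <- as.character(df$strand)
    if (any(!strand %in% c("+", "-"))) {
      stop("unknown strand character in ", path, ": ",
           paste(unique(setdiff(strand, c("+", "-"))), collapse = ", "))
    }
    id <- if ("gene_id" %in% names(df)) df$gene_id else
      if ("ID" %in% names(df)) df$ID else
        stop("no gene_id/ID attribute in ", path)
    nm <- if ("gene_name" %in% names(df)) df$gene_name else
      if ("Name" %in% names(df)) df$Name else NA_character_
    out <- data.table(
      gene_id = as.character(id),
      chrom = as.character(df$seqnames),
      tss = ifelse(strand == "+", df$start, df$end - 1),
      strand = strand,
      name = as.character(nm)
    )
  } else {
    first <- readLines(path, n = 1L)
    f1 <- strsplit(first, "\t", fixed = TRUE)[[1]]
    has_header <- length(f1) >= 3L && !grepl("^[0-9]+$", f1[3])
    dt <- fread(path, header = has_header, sep = "\t")
    if (ncol(dt) < 4L) stop("tabular gene file needs >= 4 columns: ", path)
    setnames(dt, seq_len(4L), c("gene_id", "chrom", "tss", "strand"))
    if (ncol(dt) >= 5L) setnames(dt, 5L, "name") else dt[, name := NA_character_]
    out <- dt[, .(gene_id = as.character(gene_id), chrom = as.character(chrom),
                  tss = as.numeric(tss), strand = as.character(strand),
                  name = as.character(name))]
    if (any(!out$strand %in% c("+", "-"))) {
      stop("unknown strand character in ", path)
    }
  }
  if (any(out$tss < 0)) stop("negative TSS in ", path)
  out[]
}

#' Promoter window of one or more genes
#'
#' The promoter extends `promoter_upstream` bp upstream to
#' `promoter_downstream` bp downstream of the TSS (strand-aware), clamped at
#' position 0. With the defaults the window is 1 kb upstream to 100 bp
#' downstream, i.e. 1100 bp except at a chromosome edge.
#'
#' @param genes Gene table (rows with `chrom`, `tss`, `strand`).
#' @param p An [etg_params()] object.
#' @return A `data.table` with `chrom`, `start`, `end`, aligned row-wise
#'   with `genes`.
#' @export
promoter_of <- function(genes, p = etg_params()) {
  genes <- as.data.table(genes)
  up <- p$promoter_upstream
  dn <- p$promoter_downstream
  start <- ifelse(genes$strand == "+", genes$tss - up, genes$tss - dn)
  end <- ifelse(genes$strand == "+", genes$tss + dn, genes$tss + up)
  data.table(chrom = genes$chrom, start = pmax(0, start), end = end)
}

#' Enhancer-TSS distance
#'
#' Minimum distance between the enhancer endpoints (first and last covered
#' base, i.e. `start` and `end - 1`) and the TSS; 0 when the TSS lies inside
#' the enhancer. Pairs on different chromosomes get `Inf` (never candidates).
#'
#' @param enhancers Enhancer rows (`chrom`, `start`, `end`).
#' @param genes Gene rows (`chrom`, `tss`), recycled against `enhancers` if
#'   either side has a single row.
#' @return Numeric vector of distances in bp.
#' @export
distance_of <- function(enhancers, genes) {
  e <- as.data.table(enhancers)
  g <- as.data.table(genes)
  if (nrow(e) == 1L && nrow(g) > 1L) e <- e[rep(1L, nrow(g))]
  if (nrow(g) == 1L && nrow(e) > 1L) g <- g[rep(1L, nrow(e))]
  if (nrow(e) != nrow(g)) stop("row mismatch between enhancers and genes")
  d <- pmin(abs(e$start - g$tss), abs(e$end - 1 - g$tss))
  d[g$tss >= e$start & g$tss < e$end] <- 0
  d[e$chrom != g$chrom] <- Inf
  d
}

#' Candidate target genes of an enhancer
#'
#' All genes on the enhancer's chromosome whose [distance_of()] is at most
#' the candidate window (inclusive), sorted by TSS.
#'
#' @param enhancer A single enhancer row.
#' @param genes Gene table.
#' @param p An [etg_params()] object.
#' @return Subset of `genes` with an extra `distance` column.
#' @export
candidate_genes <- function(enhancer, genes, p = etg_params()) {
  enhancer <- as.data.table(enhancer)
  if (nrow(enhancer) != 1L) stop("candidate_genes expects a single enhancer")
  genes <- as.data.table(genes)
  g <- genes[chrom == enhancer$chrom]
  if (nrow(g) == 0L) return(cbind(g, data.table(distance = numeric(0))))
  d <- distance_of(enhancer, g)
  out <- cbind(g, data.table(distance = d))[distance <= p$candidate_window]
  setorder(out, tss)
  out[]
}

# All (enhancer, candidate gene) pairs within the window; the workhorse
# behind negative sampling, whole-dataset prediction and the
# inconsecutiveness statistic.
enumerate_candidates <- function(enhancers, genes, p = etg_params(),
                                 window = p$candidate_window) {
  enhancers <- as.data.table(enhancers)
  genes <- as.data.table(genes)
  out <- vector("list", 0L)
  for (ch in intersect(unique(enhancers$chrom), unique(genes$chrom))) {
    e <- enhancers[chrom == ch]
    g <- genes[chrom == ch]
    ij <- CJ(ei = seq_len(nrow(e)), gi = seq_len(nrow(g)))
    d <- pmin(abs(e$start[ij$ei] - g$tss[ij$gi]),
              abs(e$end[ij$ei] - 1 - g$tss[ij$gi]))
    inside <- g$tss[ij$gi] >= e$start[ij$ei] & g$tss[ij$gi] < e$end[ij$ei]
    d[inside] <- 0
    sel <- d <= window
    out[[length(out) + 1L]] <- data.table(
      enhancer_id = e$enhancer_id[ij$ei[sel]],
      gene_id = g$gene_id[ij$gi[sel]],
      distance = d[sel]
    )
  }
  if (length(out) == 0L) {
    return(data.table(enhancer_id = character(0), gene_id = character(0),
                      distance = numeric(0)))
  }
  res <- rbindlist(out)
  setorder(res, enhancer_id, gene_id)
  res[]
}
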