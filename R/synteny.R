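# Conserved synteny score (CSS). For each non-reference species we lift the
# enhancer and the candidate gene's promoter through a pairwise alignment
# block map and measure how far apart the two lifted regions are; closeness
# across species, weighted by phylogenetic distance phi from the reference,
# yields a score in [0, 1].

#' Read pairwise alignment block maps
#'
#' Block map TSV with columns `species`, `ref_chrom`, `ref_start`,
#' `ref_end`, `tgt_chrom`, `tgt_start`, `tgt_end`, `orientation`
#' (coordinates 0-based half-open, orientation `+`/`-`).
#'
#' @param path Path to the TSV (header optional).
#' @return A `data.table` of blocks for all species.
#' @export
read_block_maps <- function(path) {
  if (!file.exists(path)) stop("block map file not found: ", path)
  cols <- c("species", "ref_chrom", "ref_start", "ref_end",
            "tgt_chrom", "tgt_start", "tgt_end", "orientation")
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  dt <- fread(path, header = identical(first[1], "species"), sep = "\t")
  if (ncol(dt) < 8L) stop("block map needs 8 columns: ", path)
  setnames(dt, seq_len(8L), cols)
  dt[, `:=`(ref_start = as.numeric(ref_start), ref_end = as.numeric(ref_end),
            tgt_start = as.numeric(tgt_start), tgt_end = as.numeric(tgt_end))]
  if (dt[, any(ref_start >= ref_end | tgt_start >= tgt_end)]) {
    stop("degenerate block (start >= end) in ", path)
  }
  if (!all(dt$orientation %in% c("+", "-"))) {
    stop("orientation must be '+' or '-' in ", path)
  }
  dt[]
}

#' Read phylogenetic distances from the reference species
#'
#' Either a 2-column TSV (`species`, `phi`) or a Newick tree (patristic
#' distances from `reference` computed with \pkg{ape}).
#'
#' @param path Path to the TSV or Newick file.
#' @param reference Reference species tip label (Newick input only).
#' @return Named numeric vector of distances phi(r, s), reference excluded.
#' @export
read_phylo_distances <- function(path, reference = NULL) {
  if (!file.exists(path)) stop("phylogeny file not found: ", path)
  first <- trimws(readLines(path, n = 1L))
  if (startsWith(first, "(")) {
    if (is.null(reference)) stop("reference species required for Newick input")
    tree <- ape::read.tree(path)
    dm <- ape::cophenetic.phylo(tree)
    if (!reference %in% rownames(dm)) {
      stop("reference species '", reference, "' not in tree")
    }
    phi <- dm[reference, colnames(dm) != reference]
  } else {
    f1 <- strsplit(first, "\t", fixed = TRUE)[[1]]
    dt <- fread(path, header = !grepl("^[0-9.eE+-]+$", f1[2]), sep = "\t")
    setnames(dt, seq_len(2L), c("species", "phi"))
    phi <- setNames(as.numeric(dt$phi), dt$species)
  }
  if (length(phi) == 0L) stop("no species in ", path)
  if (any(phi <= 0) || anyDuplicated(names(phi))) {
    stop("phylogenetic distances must be positive with unique species names")
  }
  phi
}

# Lift a set of reference regions through one species' block map.
# regions: data.table(id, chrom, start, end). Returns one row per mapped
# region: id, tgt_chrom, tgt_start, tgt_end. Among blocks overlapping a
# region the target chromosome with the largest total reference overlap
# wins; the mapped span is the hull of the per-block interpolated pieces on
# that chromosome. Per-block pieces are trimmed proportionally to the
# overlapped fraction of the block (orientation-aware).
map_regions <- function(blocks, regions) {
  blocks <- as.data.table(blocks)
  regions <- as.data.table(regions)
  if (nrow(regions) == 0L || nrow(blocks) == 0L) {
    return(data.table(id = character(0), tgt_chrom = character(0),
                      tgt_start = numeric(0), tgt_end = numeric(0)))
  }
  b <- blocks[, .(ref_chrom, rs = ref_start, re = ref_end,
                  tgt_chrom, ts = tgt_start, te = tgt_end, orientation)]
  # closed-coordinate trick so that half-open adjacency does not count
  b[, `:=`(bs = rs, be = re - 1)]
  q <- regions[, .(id, ref_chrom = chrom, qs = start, qe = end - 1,
                   q_start = start, q_end = end)]
  setkey(b, ref_chrom, bs, be)
  hits <- foverlaps(q, b, by.x = c("ref_chrom", "qs", "qe"),
                    by.y = c("ref_chrom", "bs", "be"), nomatch = NULL)
  if (nrow(hits) == 0L) {
    return(data.table(id = character(0), tgt_chrom = character(0),
                      tgt_start = numeric(0), tgt_end = numeric(0)))
  }
  hits[, `:=`(os = pmax(q_start, rs), oe = pmin(q_end, re))]
  hits[, scale := (te - ts) / (re - rs)]
  hits[, `:=`(
    ms = ifelse(orientation == "+",
                ts + floor((os - rs) * scale),
                te - ceiling((oe - rs) * scale)),
    me = ifelse(orientation == "+",
                ts + ceiling((oe - rs) * scale),
                te - floor((os - rs) * scale))
  )]
  grp <- hits[, .(ov = sum(oe - os), tgt_start = min(ms), tgt_end = max(me)),
              by = .(id, tgt_chrom)]
  setorder(grp, id, -ov, tgt_chrom)
  grp[, head(.SD, 1L), by = id][, .(id, tgt_chrom, tgt_start, tgt_end)]
}

#' Lift one genomic interval through a species block map
#'
#' @param blocks Block rows of a single species (see [read_block_maps()]).
#' @param iv A list or single-row table with `chrom`, `start`, `end`.
#' @return `NULL` when no block overlaps, otherwise a list with
#'   `chrom`, `start`, `end` of the mapped span.
#' @export
map_region <- function(blocks, iv) {
  iv <- as.list(iv)
  res <- map_regions(blocks, data.table(id = "q", chrom = iv$chrom,
                                        start = iv$start, end = iv$end))
  if (nrow(res) == 0L) return(NULL)
  list(chrom = res$tgt_chrom, start = res$tgt_start, end = res$tgt_end)
}

#' Cross-species distance between an enhancer and a gene promoter
#'
#' Lifts both regions through one species' block map; returns `NA` when
#' either region is unmapped or the two map to different target
#' chromosomes, otherwise the gap in bp between the mapped spans (0 when
#' they touch or overlap).
#'
#' @param blocks Block rows of one species.
#' @param enhancer Single enhancer row.
#' @param gene Single gene row.
#' @param p An [etg_params()] object (promoter definition).
#' @return Distance in bp, or `NA_real_`.
#' @export
species_distance <- function(blocks, enhancer, gene, p = etg_params()) {
  enhancer <- as.data.table(enhancer)
  prom <- promoter_of(gene, p)
  a <- map_region(blocks, enhancer[, .(chrom, start, end)])
  b <- map_region(blocks, prom)
  if (is.null(a) || is.null(b) || a$chrom != b$chrom) return(NA_real_)
  max(0, a$start - b$end, b$start - a$end)
}

css_kernel_value <- function(d, theta, kernel) {
  if (kernel == "indicator") as.numeric(d <= theta) else pmax(0, 1 - d / theta)
}

#' Conserved synteny score of an enhancer-gene pair
#'
#' `CSS = sum_s phi(r,s) * c_s / sum_s phi(r,s)` over the species of `phi`,
#' where `c_s` decays with the cross-species distance `d_s` (linear decay
#' `max(0, 1 - d_s/theta)` by default, hard indicator `d_s <= theta`
#' optionally) and `c_s = 0` when the pair is not syntenic in species `s`.
#'
#' @param enhancer Single enhancer row.
#' @param gene Single gene row.
#' @param maps Block table covering all species (column `species`).
#' @param phi Named numeric vector from [read_phylo_distances()].
#' @param p An [etg_params()] object (`theta`, `css_kernel`).
#' @return CSS in \[0, 1\], with the per-species distances attached as
#'   attribute `"species_distance"`.
#' @export
css_score <- function(enhancer, gene, maps, phi, p = etg_params()) {
  if (length(phi) == 0L) stop("empty species set")
  maps <- as.data.table(maps)
  d <- vapply(names(phi), function(s) {
    species_distance(maps[species == s], enhancer, gene, p)
  }, numeric(1))
  cs <- ifelse(is.na(d), 0, css_kernel_value(d, p$theta, p$css_kernel))
  out <- sum(phi * cs) / sum(phi)
  attr(out, "species_distance") <- d
  out
}

# Vectorised CSS over a pair table. Lifts each distinct enhancer region and
# each distinct promoter once per species, then combines per pair.
compute_css <- function(pairs, enhancers, genes, maps, phi, p = etg_params()) {
  pairs <- as.data.table(pairs)
  enhancers <- as.data.table(enhancers)
  genes <- as.data.table(genes)
  maps <- as.data.table(maps)
  if (length(phi) == 0L) stop("empty species set")
  eregions <- enhancers[, .(id = enhancer_id, chrom, start, end)]
  proms <- promoter_of(genes, p)
  gregions <- data.table(id = genes$gene_id, proms)
  num <- rep(0, nrow(pairs))
  for (s in names(phi)) {
    bl <- maps[species == s]
    em <- map_regions(bl, eregions)
    gm <- map_regions(bl, gregions)
    em2 <- em[match(pairs$enhancer_id, em$id)]
    gm2 <- gm[match(pairs$gene_id, gm$id)]
    ok <- !is.na(em2$tgt_chrom) & !is.na(gm2$tgt_chrom) &
      em2$tgt_chrom == gm2$tgt_chrom
    d <- rep(NA_real_, nrow(pairs))
    d[ok] <- pmax(0, pmax(em2$tgt_start[ok] - gm2$tgt_end[ok],
                          gm2$tgt_start[ok] - em2$tgt_end[ok]))
    cs <- ifelse(is.na(d), 0, css_kernel_value(d, p$theta, p$css_kernel))
    num <- num + phi[[s]] * cs
  }
  num / sum(phi)
}
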