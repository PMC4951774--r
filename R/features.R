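# Assembly of the four-feature table for enhancer-gene pairs.

#' Compute feature vectors for enhancer-gene pairs
#'
#' Builds the pair/feature table consumed by the predictor: distance in bp,
#' conserved synteny score, function similarity score and activity
#' correlation. Any subset of features can be requested; the inputs needed
#' only for omitted features may be `NULL`.
#'
#' @param pairs `data.table` with `enhancer_id`, `gene_id` (extra columns
#'   such as `label` are carried through).
#' @param enhancers,genes Annotation tables.
#' @param p An [etg_params()] object.
#' @param blocks,phi Alignment block maps and phylogenetic distances
#'   (for `css`).
#' @param enhancer_terms Named list from [assign_enhancer_go()] (for `fss`).
#' @param gene_terms Named list of per-gene GO term sets (for `fss`);
#'   typically the direct annotations.
#' @param dag `go_dag` after [compute_ic()] (for `fss`).
#' @param tracks `signal_track_set` (for `correlation`).
#' @param features Features to compute.
#' @return `pairs` with one numeric column per requested feature.
#' @export
compute_pair_features <- function(pairs, enhancers, genes, p = etg_params(),
                                  blocks = NULL, phi = NULL,
                                  enhancer_terms = NULL, gene_terms = NULL,
                                  dag = NULL, tracks = NULL,
                                  features = c("distance", "css", "fss",
                                               "correlation")) {
  features <- match.arg(features, several.ok = TRUE)
  pairs <- as.data.table(pairs)
  enhancers <- as.data.table(enhancers)
  genes <- as.data.table(genes)
  missing_e <- setdiff(pairs$enhancer_id, enhancers$enhancer_id)
  missing_g <- setdiff(pairs$gene_id, genes$gene_id)
  if (length(missing_e) || length(missing_g)) {
    stop("pairs reference unknown ids: ",
         paste(c(missing_e, missing_g), collapse = ", "))
  }
  out <- copy(pairs)
  if ("distance" %in% features) {
    ei <- match(out$enhancer_id, enhancers$enhancer_id)
    gi <- match(out$gene_id, genes$gene_id)
    out[, distance := distance_of(enhancers[ei], genes[gi])]
  }
  if ("css" %in% features) {
    if (is.null(blocks) || is.null(phi)) stop("css requires blocks and phi")
    out[, css := compute_css(out, enhancers, genes, blocks, phi, p)]
  }
  if ("fss" %in% features) {
    if (is.null(enhancer_terms) || is.null(gene_terms) || is.null(dag)) {
      stop("fss requires enhancer_terms, gene_terms and dag")
    }
    # cache FSS per distinct (enhancer term set, gene term set) combination
    ekey <- vapply(enhancer_terms[out$enhancer_id], paste, character(1),
                   collapse = ",")
    gt <- gene_terms[out$gene_id]
    gt[vapply(gt, is.null, logical(1))] <- list(character(0))
    gkey <- vapply(gt, paste, character(1), collapse = ",")
    key <- paste(ekey, gkey, sep = "|")
    ucache <- new.env(parent = emptyenv())
    out[, fss := vapply(seq_len(.N), function(i) {
      k <- key[i]
      if (!is.null(ucache[[k]])) return(ucache[[k]])
      v <- fss_score(enhancer_terms[[out$enhancer_id[i]]], gt[[i]], dag)
      ucache[[k]] <- v
      v
    }, numeric(1))]
  }
  if ("correlation" %in% features) {
    if (is.null(tracks)) stop("correlation requires tracks")
    out[, correlation := compute_correlations(out, enhancers, genes, tracks, p)]
  }
  out[]
}

#' Write a pair/feature table as TSV
#'
#' Metadata (`# key: value`) lines precede a regular header row; these
#' comment lines are skipped on read.
#'
#' @param x Feature table.
#' @param path Output path.
#' @param meta Named character vector written as comment lines.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, meta = character(0)) {
  header <- c(sprintf("# %s: %s", names(meta), meta),
              paste(names(x), collapse = "\t"))
  writeLines(header, path)
  if (nrow(x) > 0L) {
    fwrite(x, path, sep = "\t", col.names = FALSE, append = TRUE)
  }
  invisible(path)
}

#' Read a pair/feature table written by [write_feature_table()]
#'
#' @param path Input path.
#' @return `data.table` of the table body.
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) stop("empty feature table: ", path)
  if (length(body) == 1L) {
    nm <- strsplit(body, "\t", fixed = TRUE)[[1]]
    return(setnames(as.data.table(
      lapply(nm, function(.) character(0))), nm))
  }
  fread(text = paste(body, collapse = "\n"), header = TRUE, sep = "\t")
}
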