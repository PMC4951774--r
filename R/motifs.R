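# Motif scanning and motif-module discovery. A motif module is a set of
# >= 2 motifs that co-occur in significantly many enhancers; modules are the
# bridge from enhancer sequence to enhancer function (GO terms).

#' Read position weight matrices (MEME minimal format)
#'
#' Parses `MOTIF` blocks with `letter-probability matrix:` sections over the
#' alphabet ACGT.
#'
#' @param path Path to the PWM text file.
#' @return Named list of 4 x L probability matrices (rows A, C, G, T).
#' @export
read_pwms <- function(path) {
  if (!file.exists(path)) stop("PWM file not found: ", path)
  lines <- readLines(path)
  motif_at <- grep("^MOTIF\\b", lines)
  if (length(motif_at) == 0L) stop("no MOTIF blocks in ", path)
  pwms <- list()
  for (k in seq_along(motif_at)) {
    i <- motif_at[k]
    id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
    stop_at <- if (k < length(motif_at)) motif_at[k + 1] - 1L else length(lines)
    hdr <- grep("letter-probability matrix", lines[i:stop_at]) + i - 1L
    if (length(hdr) == 0L) stop("no probability matrix for motif ", id)
    w <- suppressWarnings(as.integer(sub(".*w=\\s*([0-9]+).*", "\\1", lines[hdr[1]])))
    rows <- lines[(hdr[1] + 1L):stop_at]
    rows <- rows[nzchar(trimws(rows))]
    if (!is.na(w)) rows <- head(rows, w)
    mat <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                    numeric(4)))
    m <- t(mat)  # 4 x L
    rownames(m) <- c("A", "C", "G", "T")
    if (ncol(m) < 4L) stop("motif ", id, " shorter than 4 positions")
    if (any(abs(colSums(m) - 1) > 1e-6)) {
      stop("PWM columns of motif ", id, " do not sum to 1")
    }
    pwms[[id]] <- m
  }
  pwms
}

# Best log-odds score of one encoded strand (idx in 1..4, NA for non-ACGT,
# which contributes zero log-odds).
best_window_score <- function(idx, lo) {
  L <- ncol(lo)
  n <- length(idx)
  if (n < L) return(-Inf)
  s <- numeric(n - L + 1L)
  for (i in seq_len(L)) {
    v <- lo[, i][idx[i:(n - L + i)]]
    v[is.na(v)] <- 0
    s <- s + v
  }
  max(s)
}

#' Scan sequences for motif occurrences
#'
#' Scores every window of each sequence on both strands with the motif
#' log-odds (probabilities plus pseudocount 1e-3 against a uniform 0.25
#' background); a motif occurs in a sequence when its best score reaches
#' `threshold_frac` of the motif's maximal achievable log-odds. Non-ACGT
#' characters contribute zero log-odds; sequences shorter than a motif
#' never contain it.
#'
#' @param seqs Named character vector or `Biostrings::DNAStringSet` of
#'   enhancer sequences.
#' @param pwms List of PWMs from [read_pwms()].
#' @param threshold_frac Fraction of the maximal log-odds required,
#'   in (0, 1].
#' @return Binary integer matrix, enhancers x motifs.
#' @export
scan_motifs <- function(seqs, pwms, threshold_frac = 0.8) {
  if (threshold_frac <= 0 || threshold_frac > 1) {
    stop("threshold_frac must lie in (0, 1]")
  }
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs))) stop("sequences must be named by enhancer id")
  base <- c("A", "C", "G", "T")
  enc <- lapply(seqs, function(s) match(strsplit(toupper(s), "")[[1]], base))
  enc_rc <- lapply(enc, function(ix) rev(5L - ix))
  occ <- matrix(0L, nrow = length(seqs), ncol = length(pwms),
                dimnames = list(names(seqs), names(pwms)))
  for (m in names(pwms)) {
    lo <- log((pwms[[m]] + 1e-3) / 0.25)
    max_score <- sum(apply(lo, 2, max))
    thr <- threshold_frac * max_score
    for (i in seq_along(enc)) {
      sc <- max(best_window_score(enc[[i]], lo),
                best_window_score(enc_rc[[i]], lo))
      occ[i, m] <- as.integer(sc >= thr)
    }
  }
  occ
}

# Apriori candidate generation: join frequent (k-1)-sets sharing a prefix.
apriori_next <- function(freq_sets) {
  out <- list()
  n <- length(freq_sets)
  if (n < 2L) return(out)
  keys <- vapply(freq_sets, function(s) paste(head(s, -1L), collapse = "\r"),
                 character(1))
  for (key in unique(keys)) {
    grp <- freq_sets[keys == key]
    if (length(grp) < 2L) next
    lasts <- sort(vapply(grp, function(s) tail(s, 1L), character(1)))
    for (a in seq_along(lasts)) {
      for (b in seq_along(lasts)) {
        if (a < b) {
          out[[length(out) + 1L]] <- c(strsplit(key, "\r", fixed = TRUE)[[1]],
                                       lasts[a], lasts[b])
        }
      }
    }
  }
  out
}

#' Discover co-occurring motif modules
#'
#' Level-wise (Apriori) enumeration of motif sets with support at least
#' `min_support`. Each frequent set of size `min_size`..`max_size` is tested
#' with a one-sided binomial upper tail against the independence null
#' `p0 = prod(per-motif frequency)`; p-values are Bonferroni-corrected over
#' all tested sets, sets with corrected p <= `alpha` are kept, and only
#' maximal kept sets are reported.
#'
#' @param occ Binary occurrence matrix (enhancers x motifs).
#' @param min_size,max_size Module size bounds.
#' @param min_support Minimum number of enhancers containing the whole set.
#' @param alpha Significance level after Bonferroni correction.
#' @return `data.table` with `module_id`, `motif_ids` (comma-separated,
#'   sorted), `size`, `support`, `p_value` (raw), `p_adj`.
#' @export
discover_modules <- function(occ, min_size = 2L, max_size = 5L,
                             min_support = 5L, alpha = 0.01) {
  if (!is.matrix(occ) || nrow(occ) == 0L || ncol(occ) < 2L) {
    stop("occurrence matrix must have >= 1 enhancer and >= 2 motifs")
  }
  n <- nrow(occ)
  freq <- colSums(occ) / n
  motifs <- sort(colnames(occ))
  support_of <- function(set) sum(rowSums(occ[, set, drop = FALSE]) == length(set))
  level <- lapply(motifs[colSums(occ)[motifs] >= min_support], identity)
  tested <- list()
  k <- 1L
  while (k < max_size && length(level) > 0L) {
    cands <- apriori_next(level)
    k <- k + 1L
    level <- list()
    for (set in cands) {
      sup <- support_of(set)
      if (sup < min_support) next
      level[[length(level) + 1L]] <- set
      if (k >= min_size) {
        p0 <- prod(freq[set])
        pv <- pbinom(sup - 1L, n, p0, lower.tail = FALSE)
        tested[[length(tested) + 1L]] <-
          list(set = set, support = sup, p_value = pv)
      }
    }
  }
  empty <- data.table(module_id = character(0), motif_ids = character(0),
                      size = integer(0), support = integer(0),
                      p_value = numeric(0), p_adj = numeric(0))
  if (length(tested) == 0L) return(empty)
  res <- data.table(
    motifs = lapply(tested, `[[`, "set"),
    support = vapply(tested, `[[`, integer(1), "support"),
    p_value = vapply(tested, `[[`, numeric(1), "p_value")
  )
  res[, p_adj := pmin(1, p_value * length(tested))]
  res <- res[p_adj <= alpha]
  if (nrow(res) == 0L) return(empty)
  res[, size := vapply(motifs, length, integer(1))]
  setorder(res, -size)
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(res))) {
      if (i != j && keep[i] && keep[j] &&
          res$size[j] < res$size[i] &&
          all(res$motifs[[j]] %in% res$motifs[[i]])) {
        keep[j] <- FALSE
      }
    }
  }
  res <- res[keep]
  res[, motif_ids := vapply(motifs, function(s) paste(sort(s), collapse = ","),
                            character(1))]
  setorder(res, p_adj, -support, motif_ids)
  res[, module_id := sprintf("mod%02d", .I)]
  res[, .(module_id, motif_ids, size, support, p_value, p_adj)]
}

#' Enhancers containing each module
#'
#' An enhancer contains a module when it contains every member motif.
#'
#' @param occ Binary occurrence matrix.
#' @param modules Module table from [discover_modules()] or
#'   [read_motif_modules()].
#' @return `data.table` with `enhancer_id`, `module_id`.
#' @export
module_instances <- function(occ, modules) {
  modules <- as.data.table(modules)
  out <- lapply(seq_len(nrow(modules)), function(i) {
    set <- strsplit(modules$motif_ids[i], ",", fixed = TRUE)[[1]]
    missing <- setdiff(set, colnames(occ))
    if (length(missing) > 0L) {
      stop("module motifs absent from occurrence matrix: ",
           paste(missing, collapse = ", "))
    }
    hit <- rowSums(occ[, set, drop = FALSE]) == length(set)
    data.table(enhancer_id = rownames(occ)[hit],
               module_id = modules$module_id[i])
  })
  rbindlist(out)
}

#' Import externally discovered motif modules
#'
#' Accepts module lists produced by an external module-discovery run: a
#' module TSV (`module_id`, comma-separated `motif_ids`) and optionally an
#' instance TSV (`enhancer_id`, `module_id`).
#'
#' @param modules_path Module list TSV.
#' @param instances_path Optional instance list TSV.
#' @return List with elements `modules` (data.table) and `instances`
#'   (data.table or `NULL`).
#' @export
read_motif_modules <- function(modules_path, instances_path = NULL) {
  mods <- fread(modules_path, header = TRUE, sep = "\t")
  if (!all(c("module_id", "motif_ids") %in% names(mods))) {
    stop("module TSV needs columns module_id, motif_ids")
  }
  inst <- NULL
  if (!is.null(instances_path)) {
    inst <- fread(instances_path, header = TRUE, sep = "\t")
    if (!all(c("enhancer_id", "module_id") %in% names(inst))) {
      stop("instance TSV needs columns enhancer_id, module_id")
    }
  }
  list(modules = mods[], instances = if (is.null(inst)) NULL else inst[])
}
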