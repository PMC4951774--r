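#' Analysis parameter set
#'
#' Bundles the tunable constants of the prediction pipeline. Defaults follow
#' the published protocol: candidate genes are collected within 2 Mb of an
#' enhancer, the synteny decay cutoff Theta is 2 Mb, the promoter spans 1 kb
#' upstream to 100 bp downstream of the TSS, Hi-C matrices are binned at
#' 5 kb, the forest holds 500 trees, predicted pairs require a vote fraction
#' of at least 0.95, and Hi-C support requires an enhancer-TSS separation of
#' at least 5 kb.
#'
#' @param candidate_window Candidate-gene window around an enhancer, bp.
#' @param theta Synteny decay cutoff Theta, bp.
#' @param promoter_upstream Promoter extent upstream of the TSS, bp.
#' @param promoter_downstream Promoter extent downstream of the TSS, bp.
#' @param hic_resolution Contact-matrix bin size, bp.
#' @param score_cutoff Forest vote fraction required to call a target,
#'   in (0, 1).
#' @param n_trees Number of trees in the random forest.
#' @param min_separation Minimum enhancer-TSS distance for a pair to be
#'   eligible for Hi-C support, bp.
#' @param css_kernel Per-species synteny decay kernel: `"linear"` uses
#'   `max(0, 1 - d/theta)`, `"indicator"` scores 1 whenever `d <= theta`.
#' @return An object of class `etg_params` (a validated list).
#' @examples
#' p <- etg_params()
#' p$candidate_window
#' @export
etg_params <- function(candidate_window = 2e6,
                       theta = 2e6,
                       promoter_upstream = 1000,
                       promoter_downstream = 100,
                       hic_resolution = 5000,
                       score_cutoff = 0.95,
                       n_trees = 500L,
                       min_separation = 5000,
                       css_kernel = c("linear", "indicator")) {
  css_kernel <- match.arg(css_kernel)
  p <- list(
    candidate_window = as.numeric(candidate_window),
    theta = as.numeric(theta),
    promoter_upstream = as.numeric(promoter_upstream),
    promoter_downstream = as.numeric(promoter_downstream),
    hic_resolution = as.numeric(hic_resolution),
    score_cutoff = as.numeric(score_cutoff),
    n_trees = as.integer(n_trees),
    min_separation = as.numeric(min_separation),
    css_kernel = css_kernel
  )
  num <- p[setdiff(names(p), "css_kernel")]
  if (any(vapply(num, function(v) !is.finite(v) || v <= 0, logical(1)))) {
    stop("all numeric parameters must be positive and finite")
  }
  if (p$score_cutoff >= 1) stop("score_cutoff must lie in (0, 1)")
  structure(p, class = "etg_params")
}

#' @export
print.etg_params <- function(x, ...) {
  cat("ETG prediction parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
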