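# Independent reference implementations used to cross-check the package's
# algorithms. They share no code with the implementation paths they verify.

# Exhaustive itemset miner: enumerate every subset, exact binomial tail,
# Bonferroni over tested sets, maximality filter.
oracle_modules <- function(occ, min_size = 2L, max_size = 5L,
                           min_support = 5L, alpha = 0.01) {
  n <- nrow(occ)
  freq <- colSums(occ) / n
  tested <- list()
  for (k in min_size:min(max_size, ncol(occ))) {
    sets <- utils::combn(sort(colnames(occ)), k, simplify = FALSE)
    for (s in sets) {
      sup <- sum(rowSums(occ[, s, drop = FALSE]) == k)
      if (sup < min_support) next
      pv <- pbinom(sup - 1, n, prod(freq[s]), lower.tail = FALSE)
      tested[[length(tested) + 1L]] <- list(set = s, support = sup, p = pv)
    }
  }
  if (length(tested) == 0L) return(list())
  padj <- pmin(1, vapply(tested, `[[`, numeric(1), "p") * length(tested))
  kept <- tested[padj <= alpha]
  if (length(kept) == 0L) return(list())
  is_max <- vapply(seq_along(kept), function(i) {
    !any(vapply(seq_along(kept), function(j) {
      i != j && length(kept[[j]]$set) > length(kept[[i]]$set) &&
        all(kept[[i]]$set %in% kept[[j]]$set)
    }, logical(1)))
  }, logical(1))
  lapply(kept[is_max], function(x) {
    list(motifs = paste(x$set, collapse = ","), support = x$support)
  })
}

# Exact pairwise concordance AUC.
auc_oracle <- function(s, y) {
  pos <- s[y]; neg <- s[!y]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Exact entropy in nats.
entropy_oracle <- function(y) {
  p <- table(y) / length(y)
  p <- p[p > 0]
  -sum(p * log(p))
}
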