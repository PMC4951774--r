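# Gene Ontology machinery: OBO/GAF parsing, annotation propagation,
# information content, MICA-based term similarity, enhancer GO assignment
# via motif modules, and the function similarity score (FSS).

#' Read a GO DAG from an OBO file
#'
#' Parses `[Term]` stanzas (`id`, `name`, `namespace`, `is_a`); obsolete
#' terms are dropped. The graph must be acyclic.
#'
#' @param path Path to the OBO file.
#' @return An object of class `go_dag`: term ids, names, namespaces, parent
#'   lists and (after [compute_ic()]) annotation counts and information
#'   content.
#' @export
read_go_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path)
  starts <- grep("^\\[Term\\]$", lines)
  if (length(starts) == 0L) stop("no [Term] stanzas in ", path)
  ends <- c(grep("^\\[", lines)[-1] - 1L, length(lines))
  ends <- vapply(starts, function(s) min(ends[ends >= s]), numeric(1))
  ids <- character(0); nms <- character(0); ns <- character(0)
  parents <- list()
  for (k in seq_along(starts)) {
    chunk <- lines[starts[k]:ends[k]]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": *"), "", grep(paste0("^", key, ":"), chunk,
                                                 value = TRUE))
      if (length(v) == 0L) NA_character_ else v[1]
    }
    if (identical(get1("is_obsolete"), "true")) next
    id <- get1("id")
    if (is.na(id)) next
    isa <- grep("^is_a:", chunk, value = TRUE)
    isa <- trimws(sub("!.*$", "", sub("^is_a: *", "", isa)))
    ids <- c(ids, id)
    nms <- c(nms, get1("name"))
    ns <- c(ns, get1("namespace"))
    parents[[id]] <- isa
  }
  unknown <- setdiff(unlist(parents), ids)
  if (length(unknown) > 0L) {
    stop("is_a parents missing from the ontology: ",
         paste(unknown, collapse = ", "))
  }
  dag <- structure(
    list(terms = ids, name = setNames(nms, ids), namespace = setNames(ns, ids),
         parents = parents, ancestors = NULL, counts = NULL, ic = NULL,
         gene_terms = NULL),
    class = "go_dag"
  )
  dag$ancestors <- dag_ancestors(dag)  # errors on a cyclic graph
  dag
}

# Strict ancestor sets for every term (self excluded); Kahn-style
# topological pass that detects cycles.
dag_ancestors <- function(dag) {
  ids <- dag$terms
  pending <- setNames(rep(TRUE, length(ids)), ids)
  anc <- setNames(vector("list", length(ids)), ids)
  repeat {
    progressed <- FALSE
    for (id in ids[pending]) {
      ps <- dag$parents[[id]]
      if (all(!pending[ps])) {
        anc[[id]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
        pending[id] <- FALSE
        progressed <- TRUE
      }
    }
    if (!any(pending)) break
    if (!progressed) stop("cycle detected in the ontology graph")
  }
  anc
}

#' Read GO annotations (GAF 2.x)
#'
#' Keeps the gene identifier (column 2) and GO term (column 5); comment
#' lines (`!`) are skipped.
#'
#' @param path Path to the GAF file.
#' @return `data.table` with columns `gene`, `term` (unique rows).
#' @export
read_go_annotations <- function(path) {
  if (!file.exists(path)) stop("GAF file not found: ", path)
  dt <- fread(path, header = FALSE, sep = "\t", skip = "\t",
              fill = TRUE, quote = "")
  dt <- dt[!startsWith(as.character(dt[[1]]), "!")]
  if (ncol(dt) < 5L) stop("GAF file needs >= 5 columns: ", path)
  unique(data.table(gene = as.character(dt[[2]]), term = as.character(dt[[5]])))
}

#' Propagate annotations and compute information content
#'
#' Annotation counts are propagated to all ancestors (each gene counted
#' once per term); the information content of a term is
#' `IC(t) = -ln(n_t / n_root)` with `n_root` the propagated count of the
#' term's namespace root, so roots have IC 0 and unannotated terms have
#' undefined (`NA`) IC.
#'
#' @param dag A `go_dag` from [read_go_obo()].
#' @param ann Annotation table from [read_go_annotations()].
#' @return The `go_dag` with `counts`, `ic` and per-gene propagated term
#'   sets (`gene_terms`) filled in.
#' @export
compute_ic <- function(dag, ann) {
  stopifnot(inherits(dag, "go_dag"))
  ann <- unique(as.data.table(ann)[, .(gene, term)])
  bad <- setdiff(ann$term, dag$terms)
  if (length(bad) > 0L) {
    stop("annotated terms missing from the ontology: ",
         paste(bad, collapse = ", "))
  }
  anc <- dag$ancestors
  gene_terms <- lapply(split(ann$term, ann$gene), function(ts) {
    unique(c(ts, unlist(anc[ts], use.names = FALSE)))
  })
  tab <- table(unlist(gene_terms, use.names = FALSE))
  counts <- setNames(rep(0, length(dag$terms)), dag$terms)
  counts[names(tab)] <- as.numeric(tab)
  roots <- dag$terms[vapply(dag$parents[dag$terms], length, integer(1)) == 0L]
  root_of_ns <- setNames(roots, dag$namespace[roots])
  n_root <- counts[root_of_ns[dag$namespace[dag$terms]]]
  ic <- ifelse(counts > 0 & n_root > 0, -log(counts / n_root), NA_real_)
  names(ic) <- dag$terms
  # a child can never be annotated to more genes than its parent
  for (id in dag$terms) {
    for (pa in dag$parents[[id]]) {
      if (counts[id] > counts[pa]) stop("propagation invariant violated")
    }
  }
  dag$counts <- counts
  dag$ic <- ic
  dag$gene_terms <- gene_terms
  dag
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("GO DAG: %d terms, %d namespace(s)%s\n", length(x$terms),
              length(unique(x$namespace)),
              if (is.null(x$ic)) " (IC not computed)" else ""))
  invisible(x)
}

#' Semantic similarity of two GO terms
#'
#' The most informative common ancestor (MICA) is the shared ancestor
#' (either term included) with maximal IC. The default Lin form normalises
#' to `2 * IC(MICA) / (IC(t1) + IC(t2))` in \[0, 1\]; `"resnik"` returns
#' `IC(MICA)` unnormalised. Terms in different namespaces share no ancestor
#' and score 0.
#'
#' @param t1,t2 Term ids with defined IC.
#' @param dag A `go_dag` after [compute_ic()].
#' @param method `"lin"` (default) or `"resnik"`.
#' @return Similarity value.
#' @export
term_similarity <- function(t1, t2, dag, method = c("lin", "resnik")) {
  method <- match.arg(method)
  if (is.null(dag$ic)) stop("run compute_ic() before term_similarity()")
  for (t in c(t1, t2)) {
    if (!t %in% dag$terms) stop("unknown term: ", t)
    if (is.na(dag$ic[[t]])) stop("term has undefined IC: ", t)
  }
  common <- intersect(c(t1, dag$ancestors[[t1]]), c(t2, dag$ancestors[[t2]]))
  common <- common[!is.na(dag$ic[common])]
  if (length(common) == 0L) return(0)
  mica_ic <- max(dag$ic[common])
  if (method == "resnik") return(mica_ic)
  denom <- dag$ic[[t1]] + dag$ic[[t2]]
  if (denom == 0) return(0)
  2 * mica_ic / denom
}

# Pairwise similarity matrix over two term vectors.
term_sim_matrix <- function(terms1, terms2, dag, method = "lin") {
  m <- matrix(0, length(terms1), length(terms2),
              dimnames = list(terms1, terms2))
  for (i in seq_along(terms1)) {
    for (j in seq_along(terms2)) {
      m[i, j] <- term_similarity(terms1[i], terms2[j], dag, method)
    }
  }
  m
}

#' Assign GO terms to enhancers through their motif modules
#'
#' For every module with an instance in an enhancer: collect all enhancers
#' containing that module, collect all genes within the candidate window of
#' each collected enhancer, de-duplicate, and test every propagated GO term
#' for over-representation in that gene list against the full gene universe
#' (one-sided hypergeometric, Benjamini-Hochberg at `fdr`). An enhancer's
#' terms are the union of significant terms over its modules; enhancers
#' without module instances get an empty set.
#'
#' @param occ Occurrence matrix from [scan_motifs()].
#' @param modules Module table ([discover_modules()]).
#' @param enhancers,genes Annotation tables.
#' @param ann GO annotation table ([read_go_annotations()]).
#' @param dag `go_dag` after [compute_ic()].
#' @param p An [etg_params()] object (candidate window).
#' @param fdr BH false-discovery-rate threshold.
#' @param instances Optional externally supplied instance table
#'   (`enhancer_id`, `module_id`); defaults to [module_instances()].
#' @return Named list: enhancer id -> character vector of significant terms.
#' @export
assign_enhancer_go <- function(occ, modules, enhancers, genes, ann, dag,
                               p = etg_params(), fdr = 0.05,
                               instances = NULL) {
  if (is.null(dag$ic)) stop("run compute_ic() before assign_enhancer_go()")
  enhancers <- as.data.table(enhancers)
  genes <- as.data.table(genes)
  modules <- as.data.table(modules)
  if (is.null(instances)) instances <- module_instances(occ, modules)
  out <- setNames(vector("list", nrow(enhancers)), enhancers$enhancer_id)
  for (e in enhancers$enhancer_id) out[[e]] <- character(0)
  if (nrow(modules) == 0L || nrow(instances) == 0L) return(out)

  cand <- enumerate_candidates(enhancers, genes, p)
  # universe restricted to the study's gene annotation
  gt <- dag$gene_terms[intersect(names(dag$gene_terms), genes$gene_id)]
  n_universe <- nrow(genes)
  univ_counts <- table(unlist(gt, use.names = FALSE))

  for (m in unique(instances$module_id)) {
    enh_m <- instances[module_id == m, enhancer_id]
    gene_list <- unique(cand[enhancer_id %in% enh_m, gene_id])
    gl <- gt[intersect(gene_list, names(gt))]
    k <- length(gene_list)
    if (k == 0L || length(gl) == 0L) next
    q <- table(unlist(gl, use.names = FALSE))
    terms <- names(q)
    pv <- vapply(terms, function(t) {
      m_t <- as.numeric(univ_counts[t])
      phyper(q[[t]] - 1, m_t, n_universe - m_t, k, lower.tail = FALSE)
    }, numeric(1))
    padj <- p.adjust(pv, method = "BH")
    sig <- terms[padj <= fdr]
    if (length(sig) == 0L) next
    for (e in enh_m) out[[e]] <- union(out[[e]], sig)
  }
  out
}

#' Function similarity score of an enhancer and a gene
#'
#' Best-match average over the two GO term sets: each term is matched to
#' its most similar counterpart in the other set ([term_similarity()]),
#' the per-set means are averaged over both directions. Empty sets (or
#' sets with no IC-defined term) score 0.
#'
#' @param e_terms Character vector of the enhancer's GO terms.
#' @param g_terms Character vector of the gene's GO terms.
#' @param dag `go_dag` after [compute_ic()].
#' @param method Similarity form passed to [term_similarity()].
#' @return FSS in \[0, 1\] (for the Lin form).
#' @export
fss_score <- function(e_terms, g_terms, dag, method = "lin") {
  if (is.null(dag$ic)) stop("run compute_ic() before fss_score()")
  e_terms <- unique(e_terms[!is.na(dag$ic[e_terms])])
  g_terms <- unique(g_terms[!is.na(dag$ic[g_terms])])
  if (length(e_terms) == 0L || length(g_terms) == 0L) return(0)
  m <- term_sim_matrix(e_terms, g_terms, dag, method)
  (mean(apply(m, 1, max)) + mean(apply(m, 2, max))) / 2
}

# Direct (unpropagated) term sets per gene, for the gene side of the FSS.
gene_term_sets <- function(ann) {
  ann <- unique(as.data.table(ann)[, .(gene, term)])
  split(ann$term, ann$gene)
}
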