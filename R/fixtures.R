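# Seeded synthetic-data generator. Emits a complete, internally consistent
# toy dataset in every input format the package reads, with planted true
# enhancer-target pairs expressing all four feature signals. One
# pseudo-random stream per artifact (all derived from the master seed) so
# that, e.g., adding a cell type cannot perturb the gene layout.

FIXTURE_SPECIES <- c(chimpanzee = 0.04, mouse = 0.9, chicken = 1.9,
                     frog = 2.5, zebrafish = 3.2)

FIXTURE_MOTIFS <- c(M1 = "TGACTCAG", M2 = "CACGTGAC", M3 = "GGGCGGGA",
                    M4 = "TTCGCGAA", M5 = "AGATAAGC", M6 = "CCAATCAG")

FIXTURE_MODULES <- list(mod1 = c("M1", "M2"), mod2 = c("M3", "M4"))

# geometry constants of the toy world
FX_CHROM_LEN <- 1e6
FX_EDGE <- 30000
FX_ENH_LEN <- 300
FX_GENE_LEN <- 2000
FX_TGT_CHROMS <- c("tchr1", "tchr2")
FX_TGT_LEN <- 4e6

#' Configuration of the synthetic fixture
#'
#' Defines the study conditions of the toy world: its size, and the
#' strength of each planted signal (how much nearer, more syntenic, more
#' function-sharing, more activity-correlated and more contact-enriched
#' true pairs are than false pairs). Setting a `*_true` strength to zero
#' (or the decay scale to effectively infinite) disables that channel, the
#' documented null switch; otherwise every true strength must be at least
#' its false counterpart.
#'
#' @param n_chromosomes Number of reference chromosomes (1 Mb each).
#' @param n_enhancers Total number of enhancers.
#' @param genes_per_window Genes per candidate window (= per chromosome in
#'   this scaled world).
#' @param true_pairs_per_enhancer Planted targets per enhancer.
#' @param distance_decay_scale Exponential scale (bp) of the true-pair
#'   distance distribution.
#' @param synteny_true_prob Per-species probability that a true pair is
#'   planted syntenic (adjacent after lifting).
#' @param synteny_false_prob Per-species probability that a background
#'   element is mapped (at a random target location).
#' @param go_share_prob_true Probability that a target gene is annotated
#'   from its enhancer's module branch.
#' @param go_share_prob_false Probability that a background gene is
#'   annotated from some module branch (uniformly) rather than a
#'   background branch.
#' @param signal_correlation_true,signal_correlation_false Latent
#'   correlation of promoter and enhancer activity across cell types for
#'   targets / non-targets.
#' @param n_cell_types Number of DNase panels (bedGraph tracks).
#' @param hic_reads_true,hic_reads_false Poisson means of planted /
#'   background contact counts.
#' @param seed Master seed (all artifact streams derive from it).
#' @return Object of class `fixture_config`.
#' @export
fixture_config <- function(n_chromosomes = 4L, n_enhancers = 250L,
                           genes_per_window = 250L,
                           true_pairs_per_enhancer = 2L,
                           distance_decay_scale = 25000,
                           synteny_true_prob = 0.45,
                           synteny_false_prob = 0.5,
                           go_share_prob_true = 0.8,
                           go_share_prob_false = 0.10,
                           signal_correlation_true = 0.10,
                           signal_correlation_false = 0,
                           n_cell_types = 13L,
                           hic_reads_true = 30,
                           hic_reads_false = 2,
                           seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    n_enhancers = as.integer(n_enhancers),
    genes_per_window = as.integer(genes_per_window),
    true_pairs_per_enhancer = as.integer(true_pairs_per_enhancer),
    distance_decay_scale = as.numeric(distance_decay_scale),
    synteny_true_prob = as.numeric(synteny_true_prob),
    synteny_false_prob = as.numeric(synteny_false_prob),
    go_share_prob_true = as.numeric(go_share_prob_true),
    go_share_prob_false = as.numeric(go_share_prob_false),
    signal_correlation_true = as.numeric(signal_correlation_true),
    signal_correlation_false = as.numeric(signal_correlation_false),
    n_cell_types = as.integer(n_cell_types),
    hic_reads_true = as.numeric(hic_reads_true),
    hic_reads_false = as.numeric(hic_reads_false),
    seed = as.integer(seed)
  )
  probs <- cfg[c("synteny_true_prob", "synteny_false_prob",
                 "go_share_prob_true", "go_share_prob_false")]
  if (any(unlist(probs) < 0 | unlist(probs) > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (abs(cfg$signal_correlation_true) > 1 ||
      abs(cfg$signal_correlation_false) > 1) {
    stop("signal correlations must lie in [-1, 1]")
  }
  if (cfg$n_chromosomes < 1L || cfg$n_enhancers < 2L ||
      cfg$genes_per_window < 4L || cfg$true_pairs_per_enhancer < 1L ||
      cfg$distance_decay_scale <= 0 || cfg$n_cell_types < 3L ||
      cfg$hic_reads_true < 0 || cfg$hic_reads_false < 0) {
    stop("invalid fixture configuration")
  }
  # a planted 'true' signal, when enabled, must be at least as strong as
  # its false counterpart (zero disables the channel)
  if (cfg$go_share_prob_true > 0 &&
      cfg$go_share_prob_true < cfg$go_share_prob_false) {
    stop("go_share_prob_true must be >= go_share_prob_false (or 0)")
  }
  if (cfg$signal_correlation_true != 0 &&
      cfg$signal_correlation_true < cfg$signal_correlation_false) {
    stop("signal_correlation_true must be >= signal_correlation_false (or 0)")
  }
  if (cfg$hic_reads_true > 0 && cfg$hic_reads_true < cfg$hic_reads_false) {
    stop("hic_reads_true must be >= hic_reads_false (or 0)")
  }
  if (cfg$true_pairs_per_enhancer * cfg$n_enhancers >
      cfg$n_chromosomes * cfg$genes_per_window) {
    stop("not enough genes for the requested number of true pairs")
  }
  structure(cfg, class = "fixture_config")
}

#' Null (zero-effect) fixture configuration
#'
#' All planted channels disabled: true-pair distances are effectively
#' uniform and no synteny, GO, activity or contact signal distinguishes
#' true from false pairs.
#'
#' @param seed Master seed.
#' @param ... Further overrides passed to [fixture_config()].
#' @return A `fixture_config`.
#' @export
fixture_config_null <- function(seed = 1L, ...) {
  fixture_config(distance_decay_scale = 1e9, synteny_true_prob = 0,
                 go_share_prob_true = 0, signal_correlation_true = 0,
                 signal_correlation_false = 0, hic_reads_true = 0,
                 seed = seed, ...)
}

fx_stream <- function(cfg, k, expr) {
  # one stream per artifact; keep the derived seed well inside integer range
  withr::with_seed((cfg$seed %% 100000000L) * 7L + k, expr)
}

# -- layout: chromosomes, genes, enhancers, planted truth (stream 1) -------
fx_layout <- function(cfg) {
  fx_stream(cfg, 1L, {
    spacing <- (FX_CHROM_LEN - 2 * FX_EDGE) / cfg$genes_per_window
    genes <- list(); enhs <- list()
    n_e_chrom <- diff(round(seq(0, cfg$n_enhancers,
                                length.out = cfg$n_chromosomes + 1L)))
    gid <- 0L; eid <- 0L
    for (ci in seq_len(cfg$n_chromosomes)) {
      ch <- sprintf("chr%d", ci)
      grid <- FX_EDGE + spacing * (seq_len(cfg$genes_per_window) - 0.5)
      tss <- round(grid + runif(cfg$genes_per_window, -500, 500))
      strand <- sample(c("+", "-"), cfg$genes_per_window, replace = TRUE)
      genes[[ci]] <- data.table(
        gene_id = sprintf("g%04d", gid + seq_along(tss)),
        chrom = ch, tss = tss, strand = strand,
        name = sprintf("GENE%04d", gid + seq_along(tss))
      )
      gid <- gid + cfg$genes_per_window
      slots <- sort(sample(seq_len(cfg$genes_per_window - 1L), n_e_chrom[ci]))
      mid <- FX_EDGE + spacing * slots        # between-gene midpoints
      pos <- round(mid + runif(n_e_chrom[ci], -150, 150))
      enhs[[ci]] <- data.table(
        enhancer_id = sprintf("e%03d", eid + seq_along(pos)),
        chrom = ch, start = pos, end = pos + FX_ENH_LEN
      )
      eid <- eid + n_e_chrom[ci]
    }
    genes <- rbindlist(genes); enhancers <- rbindlist(enhs)
    # planted truth: targets drawn with exponential distance decay, each
    # gene the target of at most one enhancer
    taken <- character(0)
    truth <- list()
    for (i in seq_len(nrow(enhancers))) {
      e <- enhancers[i]
      g <- genes[chrom == e$chrom][!gene_id %in% taken]
      if (nrow(g) == 0L) next
      d <- distance_of(e, g)
      w <- exp(-d / cfg$distance_decay_scale)
      if (sum(w) == 0) w <- rep(1, length(w))
      k <- min(cfg$true_pairs_per_enhancer, nrow(g))
      pick <- sample(nrow(g), k, prob = w)
      taken <- c(taken, g$gene_id[pick])
      truth[[length(truth) + 1L]] <- data.table(
        enhancer_id = e$enhancer_id, gene_id = g$gene_id[pick],
        distance = d[pick]
      )
    }
    list(genes = genes, enhancers = enhancers, truth = rbindlist(truth))
  })
}

# -- sequences and motif content (stream 2) --------------------------------
fx_sequences <- function(cfg, layout) {
  fx_stream(cfg, 2L, {
    # module of a chromosome: modules alternate across chromosomes so that
    # each module occupies its own regulatory territory
    mod_names <- names(FIXTURE_MODULES)
    chrom_mod <- setNames(
      mod_names[(seq_len(cfg$n_chromosomes) - 1L) %% length(mod_names) + 1L],
      sprintf("chr%d", seq_len(cfg$n_chromosomes))
    )
    enh <- layout$enhancers
    has_mod <- runif(nrow(enh)) < 0.92
    enh_module <- ifelse(has_mod, chrom_mod[enh$chrom], NA_character_)
    base <- c("A", "C", "G", "T")
    chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
    seqs <- lapply(chroms, function(ch) sample(base, FX_CHROM_LEN, replace = TRUE))
    names(seqs) <- chroms
    insert <- function(ch, at, motif) {
      s <- strsplit(FIXTURE_MOTIFS[[motif]], "")[[1]]
      if (runif(1) < 0.3) s <- rev(c(A = "T", C = "G", G = "C", T = "A")[s])
      seqs[[ch]][(at + 1):(at + length(s))] <<- s
    }
    for (i in seq_len(nrow(enh))) {
      planted <- if (is.na(enh_module[i])) character(0) else
        FIXTURE_MODULES[[enh_module[i]]]
      noise <- names(FIXTURE_MOTIFS)[runif(length(FIXTURE_MOTIFS)) < 0.03]
      todo <- union(planted, noise)
      for (j in seq_along(todo)) {
        off <- 10 + (j - 1) * 60 + sample.int(40, 1L)
        insert(enh$chrom[i], enh$start[i] + off, todo[j])
      }
    }
    list(seqs = lapply(seqs, paste, collapse = ""),
         enh_module = setNames(enh_module, enh$enhancer_id),
         chrom_mod = chrom_mod)
  })
}

# -- synteny block maps (stream 3) -----------------------------------------
fx_synteny <- function(cfg, layout) {
  fx_stream(cfg, 3L, {
    p <- etg_params()
    proms <- promoter_of(layout$genes, p)
    elements <- rbindlist(list(
      data.table(id = layout$enhancers$enhancer_id,
                 chrom = layout$enhancers$chrom,
                 start = layout$enhancers$start, end = layout$enhancers$end),
      data.table(id = layout$genes$gene_id, chrom = proms$chrom,
                 start = proms$start, end = proms$end)
    ))
    widths <- setNames(elements$end - elements$start, elements$id)
    blocks <- list()
    for (s in names(FIXTURE_SPECIES)) {
      placed <- new.env(parent = emptyenv())
      place <- function(id, tchr, tstart) {
        assign(id, list(chrom = tchr, start = tstart,
                        end = tstart + widths[[id]]), envir = placed)
      }
      for (i in seq_len(nrow(layout$truth))) {
        if (runif(1) >= cfg$synteny_true_prob) next
        eid <- layout$truth$enhancer_id[i]
        gid <- layout$truth$gene_id[i]
        gap <- round(max(0, layout$truth$distance[i]) * runif(1, 0.8, 1.2))
        if (!exists(eid, envir = placed)) {
          place(eid, sample(FX_TGT_CHROMS, 1L),
                round(runif(1, 0, FX_TGT_LEN - 3e5)))
        }
        anchor <- get(eid, envir = placed)
        side <- sample(c(-1, 1), 1L)
        gstart <- if (side > 0) anchor$end + gap else
          max(0, anchor$start - gap - widths[[gid]])
        place(gid, anchor$chrom, gstart)
      }
      for (id in elements$id) {
        if (!exists(id, envir = placed) && runif(1) < cfg$synteny_false_prob) {
          place(id, sample(FX_TGT_CHROMS, 1L),
                round(runif(1, 0, FX_TGT_LEN - 3e5)))
        }
      }
      ids <- intersect(elements$id, ls(placed))
      if (length(ids) == 0L) next
      tgt <- rbindlist(lapply(ids, function(id) {
        x <- get(id, envir = placed)
        data.table(id = id, tgt_chrom = x$chrom, tgt_start = x$start,
                   tgt_end = x$end)
      }))
      ref <- elements[tgt, on = "id"]
      setorder(ref, chrom, start)
      # keep reference blocks non-overlapping (first wins)
      keep <- rep(TRUE, nrow(ref))
      last_end <- -1; last_chrom <- ""
      for (i in seq_len(nrow(ref))) {
        if (ref$chrom[i] == last_chrom && ref$start[i] < last_end) {
          keep[i] <- FALSE
        } else {
          last_end <- ref$end[i]; last_chrom <- ref$chrom[i]
        }
      }
      ref <- ref[keep]
      blocks[[s]] <- ref[, .(species = s, ref_chrom = chrom, ref_start = start,
                             ref_end = end, tgt_chrom, tgt_start, tgt_end,
                             orientation = "+")]
    }
    rbindlist(blocks)
  })
}

# -- ontology and annotations (stream 4) -----------------------------------
fx_go <- function(cfg, layout, seqinfo) {
  fx_stream(cfg, 4L, {
    n_branch <- 5L; n_leaf <- 5L
    branch_ids <- sprintf("GO:%07d", seq_len(n_branch) * 100)
    leaf_ids <- lapply(seq_len(n_branch), function(b) {
      sprintf("GO:%07d", b * 100 + seq_len(n_leaf))
    })
    module_branch <- setNames(seq_along(FIXTURE_MODULES),
                              names(FIXTURE_MODULES))
    n_mod_branch <- length(FIXTURE_MODULES)
    # branch of each gene's annotation
    truth <- layout$truth
    target_mod <- seqinfo$enh_module[truth$enhancer_id]
    gene_mod <- setNames(target_mod, truth$gene_id)  # NA for module-less
    draw_background <- function() {
      if (runif(1) < cfg$go_share_prob_false) {
        sample.int(n_mod_branch, 1L)
      } else {
        sample((n_mod_branch + 1L):n_branch, 1L)
      }
    }
    ann <- list()
    for (g in layout$genes$gene_id) {
      mod <- if (g %in% names(gene_mod)) gene_mod[[g]] else NA_character_
      branch <- if (!is.na(mod) && runif(1) < cfg$go_share_prob_true) {
        module_branch[[mod]]
      } else {
        draw_background()
      }
      terms <- sample(leaf_ids[[branch]], 2L)
      if (runif(1) < 0.3) {
        terms <- union(terms, sample(unlist(leaf_ids), 1L))
      }
      ann[[g]] <- data.table(gene = g, term = terms)
    }
    list(root = "GO:0000001", branches = branch_ids, leaves = leaf_ids,
         ann = rbindlist(ann))
  })
}

# -- DNase signal tracks (stream 5) ----------------------------------------
fx_signal <- function(cfg, layout) {
  fx_stream(cfg, 5L, {
    nc <- cfg$n_cell_types
    enh <- layout$enhancers
    z_e <- matrix(rnorm(nrow(enh) * nc), nrow(enh), nc,
                  dimnames = list(enh$enhancer_id, NULL))
    target_of <- setNames(layout$truth$enhancer_id, layout$truth$gene_id)
    genes <- layout$genes
    z_g <- matrix(0, nrow(genes), nc, dimnames = list(genes$gene_id, NULL))
    for (i in seq_len(nrow(genes))) {
      g <- genes$gene_id[i]
      if (g %in% names(target_of)) {
        rho <- cfg$signal_correlation_true
        anchor <- z_e[target_of[[g]], ]
      } else {
        rho <- cfg$signal_correlation_false
        near <- enh[chrom == genes$chrom[i]]
        anchor <- if (nrow(near) > 0L) {
          z_e[near$enhancer_id[which.min(abs(near$start - genes$tss[i]))], ]
        } else rep(0, nc)
      }
      z_g[i, ] <- rho * anchor + sqrt(1 - rho^2) * rnorm(nc)
    }
    list(enh_values = round(exp(z_e), 4), gene_values = round(exp(z_g), 4))
  })
}

# -- Hi-C contacts (stream 6) ----------------------------------------------
fx_hic <- function(cfg, layout) {
  fx_stream(cfg, 6L, {
    p <- etg_params()
    res <- p$hic_resolution
    enh <- layout$enhancers
    genes <- layout$genes
    emid <- setNames(floor((enh$start + enh$end) / 2 / res) * res,
                     enh$enhancer_id)
    echr <- setNames(enh$chrom, enh$enhancer_id)
    gbin <- setNames(floor(genes$tss / res) * res, genes$gene_id)
    rows <- list()
    if (cfg$hic_reads_true > 0) {
      tr <- layout$truth[distance >= p$min_separation]
      if (nrow(tr) > 0L) {
        cnt <- rpois(nrow(tr), cfg$hic_reads_true)
        rows[[1L]] <- data.table(
          chrom = echr[tr$enhancer_id], bin_i_start = emid[tr$enhancer_id],
          bin_j_start = gbin[tr$gene_id], count = cnt
        )
      }
    }
    n_bg <- 3L * nrow(layout$truth)
    cand <- enumerate_candidates(enh, genes, p)[distance >= p$min_separation]
    bg <- cand[!layout$truth, on = c("enhancer_id", "gene_id")]
    bg <- bg[sample(.N, min(n_bg, .N))]
    if (nrow(bg) > 0L && cfg$hic_reads_false > 0) {
      rows[[length(rows) + 1L]] <- data.table(
        chrom = echr[bg$enhancer_id], bin_i_start = emid[bg$enhancer_id],
        bin_j_start = gbin[bg$gene_id], count = rpois(nrow(bg),
                                                      cfg$hic_reads_false)
      )
    }
    if (length(rows) == 0L) {
      return(data.table(chrom = character(0), bin_i_start = numeric(0),
                        bin_j_start = numeric(0), count = numeric(0)))
    }
    out <- rbindlist(rows)[count > 0]
    out <- out[, .(count = max(count)), by = .(chrom, bin_i_start, bin_j_start)]
    setorder(out, chrom, bin_i_start, bin_j_start)
    out[]
  })
}

#' Generate the synthetic fixture bundle
#'
#' Writes `enhancers.bed`, `genes.gtf`, `genome.fa`, `blocks.tsv`,
#' `phylo.tsv`, `pwms.txt`, `go.obo`, `annotations.gaf`, one bedGraph per
#' cell type plus a `tracks.tsv` manifest, `contacts.tsv`,
#' `truth_pairs.tsv` and `config.yaml` into `dir`. Regeneration under the
#' same seed is byte-identical.
#'
#' @param cfg A [fixture_config()].
#' @param dir Output directory (created if needed).
#' @return Object of class `etg_fixture`: `dir`, file paths, the in-memory
#'   truth table and the config.
#' @export
generate_fixture <- function(cfg, dir) {
  stopifnot(inherits(cfg, "fixture_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layout <- fx_layout(cfg)
  seqinfo <- fx_sequences(cfg, layout)
  blocks <- fx_synteny(cfg, layout)
  go <- fx_go(cfg, layout, seqinfo)
  sig <- fx_signal(cfg, layout)
  hic <- fx_hic(cfg, layout)
  paths <- list()
  pth <- function(f) file.path(dir, f)

  # enhancers.bed
  fwrite(layout$enhancers[, .(chrom, start, end, enhancer_id)],
         pth("enhancers.bed"), sep = "\t", col.names = FALSE)
  paths$enhancers <- pth("enhancers.bed")

  # genes.gtf: printed start is the '+' TSS, printed end - 1 the '-' TSS
  g <- layout$genes
  gtf <- data.table(
    seqname = g$chrom, source = "synthetic", feature = "gene",
    start = ifelse(g$strand == "+", g$tss, g$tss + 1 - FX_GENE_LEN),
    end = ifelse(g$strand == "+", g$tss + FX_GENE_LEN, g$tss + 1),
    score = ".", strand = g$strand, frame = ".",
    attributes = sprintf('gene_id "%s"; gene_name "%s";', g$gene_id, g$name)
  )
  fwrite(gtf, pth("genes.gtf"), sep = "\t", col.names = FALSE, quote = FALSE)
  paths$genes <- pth("genes.gtf")

  # genome.fa
  writeLines(unlist(lapply(names(seqinfo$seqs), function(ch) {
    s <- seqinfo$seqs[[ch]]
    c(paste0(">", ch),
      substring(s, seq(1, nchar(s), 70), pmin(seq(1, nchar(s), 70) + 69,
                                              nchar(s))))
  })), pth("genome.fa"))
  paths$genome <- pth("genome.fa")

  # blocks.tsv + phylo.tsv
  fwrite(blocks, pth("blocks.tsv"), sep = "\t", col.names = TRUE)
  paths$blocks <- pth("blocks.tsv")
  fwrite(data.table(species = names(FIXTURE_SPECIES),
                    phi = unname(FIXTURE_SPECIES)),
         pth("phylo.tsv"), sep = "\t", col.names = TRUE)
  paths$phylo <- pth("phylo.tsv")

  # pwms.txt (MEME minimal)
  pwm_lines <- c("MEME version 4", "", "ALPHABET= ACGT", "")
  for (m in names(FIXTURE_MOTIFS)) {
    cons <- strsplit(FIXTURE_MOTIFS[[m]], "")[[1]]
    mat <- vapply(cons, function(b) {
      p <- rep(0.03, 4); p[match(b, c("A", "C", "G", "T"))] <- 0.91; p
    }, numeric(4))
    pwm_lines <- c(
      pwm_lines, paste("MOTIF", m),
      sprintf("letter-probability matrix: alength= 4 w= %d", length(cons)),
      apply(mat, 2, function(col) paste(sprintf("%.6f", col), collapse = " ")),
      ""
    )
  }
  writeLines(pwm_lines, pth("pwms.txt"))
  paths$pwms <- pth("pwms.txt")

  # go.obo + annotations.gaf
  obo <- c("format-version: 1.2", "")
  term_stanza <- function(id, name, parents) {
    c("[Term]", paste0("id: ", id), paste0("name: ", name),
      "namespace: biological_process",
      paste0("is_a: ", parents, recycle0 = TRUE), "")
  }
  obo <- c(obo, term_stanza(go$root, "biological_process", character(0)))
  for (b in seq_along(go$branches)) {
    obo <- c(obo, term_stanza(go$branches[b], sprintf("pathway family %d", b),
                              go$root))
    for (l in go$leaves[[b]]) {
      obo <- c(obo, term_stanza(l, sprintf("process %s", l), go$branches[b]))
    }
  }
  writeLines(obo, pth("go.obo"))
  paths$obo <- pth("go.obo")
  gaf <- go$ann[, .(db = "SYN", gene, symbol = gene, qualifier = "",
                    term, ref = "SYN:0001", evidence = "IEA", with = "",
                    aspect = "P", name = gene, synonym = "",
                    type = "protein", taxon = "taxon:0000",
                    date = "20260101", assigned_by = "SYN")]
  writeLines(c("!gaf-version: 2.1",
               do.call(paste, c(gaf, sep = "\t"))), pth("annotations.gaf"))
  paths$gaf <- pth("annotations.gaf")

  # signal tracks
  p <- etg_params()
  proms <- promoter_of(layout$genes, p)
  cells <- sprintf("cell%02d", seq_len(cfg$n_cell_types))
  track_files <- sprintf("dhs_%s.bedGraph", cells)
  for (k in seq_len(cfg$n_cell_types)) {
    bed <- rbindlist(list(
      data.table(chrom = layout$enhancers$chrom,
                 start = layout$enhancers$start,
                 end = layout$enhancers$end, value = sig$enh_values[, k]),
      data.table(chrom = proms$chrom, start = proms$start, end = proms$end,
                 value = sig$gene_values[, k])
    ))
    setorder(bed, chrom, start)
    fwrite(bed, pth(track_files[k]), sep = "\t", col.names = FALSE)
  }
  fwrite(data.table(cell_type = cells, path = track_files),
         pth("tracks.tsv"), sep = "\t", col.names = TRUE)
  paths$tracks <- pth("tracks.tsv")

  # contacts + truth
  fwrite(hic, pth("contacts.tsv"), sep = "\t", col.names = TRUE)
  paths$contacts <- pth("contacts.tsv")
  fwrite(layout$truth[, .(enhancer_id, gene_id)], pth("truth_pairs.tsv"),
         sep = "\t", col.names = TRUE)
  paths$truth <- pth("truth_pairs.tsv")

  yaml::write_yaml(unclass(cfg), pth("config.yaml"))
  paths$config <- pth("config.yaml")

  structure(list(dir = dir, paths = paths, truth = layout$truth,
                 config = cfg),
            class = "etg_fixture")
}

#' @export
print.etg_fixture <- function(x, ...) {
  cat(sprintf("synthetic fixture in %s: %d true pairs, seed %d\n",
              x$dir, nrow(x$truth), x$config$seed))
  invisible(x)
}

#' Read a fixture bundle through the package readers
#'
#' Round-trips every emitted file through the corresponding reader.
#'
#' @param dir Fixture directory.
#' @return List with `enhancers`, `genes`, `blocks`, `phi`, `pwms`,
#'   `tracks`, `dag`, `ann`, `contacts`, `truth`, `genome_path`, `config`.
#' @export
read_fixture <- function(dir) {
  cfgl <- yaml::read_yaml(file.path(dir, "config.yaml"))
  list(
    enhancers = read_enhancers(file.path(dir, "enhancers.bed")),
    genes = read_genes(file.path(dir, "genes.gtf")),
    blocks = read_block_maps(file.path(dir, "blocks.tsv")),
    phi = read_phylo_distances(file.path(dir, "phylo.tsv")),
    pwms = read_pwms(file.path(dir, "pwms.txt")),
    tracks = read_signal_tracks(file.path(dir, "tracks.tsv")),
    dag = read_go_obo(file.path(dir, "go.obo")),
    ann = read_go_annotations(file.path(dir, "annotations.gaf")),
    contacts = read_contacts(file.path(dir, "contacts.tsv")),
    truth = fread(file.path(dir, "truth_pairs.tsv"), sep = "\t"),
    genome_path = file.path(dir, "genome.fa"),
    config = do.call(fixture_config, cfgl)
  )
}

#' Extract enhancer sequences from a genome FASTA
#'
#' @param genome_path Path to the genome FASTA.
#' @param enhancers Enhancer table.
#' @return Named character vector of enhancer sequences.
#' @export
enhancer_sequences <- function(genome_path, enhancers) {
  enhancers <- as.data.table(enhancers)
  genome <- Biostrings::readDNAStringSet(genome_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing <- setdiff(unique(enhancers$chrom), names(genome))
  if (length(missing) > 0L) {
    stop("chromosomes absent from the genome FASTA: ",
         paste(missing, collapse = ", "))
  }
  out <- vapply(seq_len(nrow(enhancers)), function(i) {
    as.character(Biostrings::subseq(genome[[enhancers$chrom[i]]],
                                    start = enhancers$start[i] + 1L,
                                    end = enhancers$end[i]))
  }, character(1))
  setNames(out, enhancers$enhancer_id)
}

#' Planted-signal summary of a fixture
#'
#' Recomputes the four features through the package readers for the planted
#' true pairs and a seeded sample of false pairs, and reports per-feature
#' separation: means in both classes and the single-feature AUC (distance
#' oriented so that larger is better for true pairs).
#'
#' @param bundle An `etg_fixture` (or a fixture directory).
#' @param p An [etg_params()] object.
#' @param n_false Number of false pairs to sample (default: as many as
#'   there are true pairs).
#' @return `data.table` with `feature`, `mean_true`, `mean_false`, `gap`,
#'   `auc`.
#' @export
truth_metrics <- function(bundle, p = etg_params(), n_false = NULL) {
  dir <- if (inherits(bundle, "etg_fixture")) bundle$dir else bundle
  fx <- read_fixture(dir)
  if (is.null(n_false)) n_false <- nrow(fx$truth)
  feats <- fixture_feature_table(fx, p, n_negatives = n_false,
                                 seed = fx$config$seed + 1000L)
  rbindlist(lapply(FEATURES, function(f) {
    x <- feats[[f]]
    pos <- feats$label == "positive"
    sc <- if (f == "distance") -x else x
    data.table(feature = f, mean_true = mean(x[pos]),
               mean_false = mean(x[!pos]),
               gap = mean(x[pos]) - mean(x[!pos]),
               auc = roc_auc(sc, pos))
  }))
}
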