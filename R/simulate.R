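#' Simulation configuration
#'
#' Parameters of the synthetic experiment generator. Defaults mirror the
#' study design the pipeline targets: a 5-vs-4 two-group bulk RNA-seq
#' cohort, negative-binomial counts with dispersion 0.1, planted
#' differentially expressed genes with fold changes in the 2-8 range, and a
#' planted tripartite lncRNA-TF-target network whose members are co-located
#' (lncRNA within 100 kb of its TF) and co-expressed through a shared
#' latent factor calibrated to a target Pearson correlation of 0.95 on
#' log2(FPKM+1). Decoy lncRNAs are placed more than 200 kb from any TF.
#'
#' @param seed Integer seed; every simulator output is a pure function of
#'   the configuration.
#' @param n_case,n_control Samples per group (defaults 5 and 4). Recovery
#'   experiments use 20/20 (see [preset_config()]): at n = 9 the
#'   correlation thresholds leave little power, which is a property of the
#'   method, not of the generator.
#' @param n_genes Number of protein-coding genes (TF genes included).
#' @param n_lncrnas Number of candidate lncRNA genes (planted + decoys).
#' @param n_tfs Number of TF genes (all in the TF catalogue).
#' @param planted_triples Number of planted lncRNA-TF-target triples; must
#'   be a multiple of `targets_per_tf`.
#' @param targets_per_tf Planted targets per cis-regulated TF.
#' @param n_de_genes Decoy differentially expressed mRNAs.
#' @param de_fold_change Centre of the decoy DE fold-change range; each
#'   decoy draws `de_fold_change * 2^U(-j, j)` with `j = de_fc_jitter`
#'   (default span 2-8) and random direction.
#' @param de_fc_jitter Log2 half-width of the decoy fold-change jitter
#'   (default 1; set 0 for a fixed fold change).
#' @param network_fold_change Fold change of planted network members
#'   (default 8, the top of the range: the strong-signal recovery regime),
#'   all upregulated.
#' @param nb_dispersion Negative-binomial dispersion (0 gives Poisson).
#' @param planted_edge_r Target pooled Pearson correlation of planted
#'   edges on log2(FPKM+1), in (0, 1).
#' @param cis_fraction_within_window Fraction of decoy lncRNAs placed
#'   within the 100-kb window of a (non-TF) coding gene, exercising the
#'   co-located-but-uncorrelated branch of the intersection.
#' @param chrom_length_bp Length of the single simulated chromosome; an
#'   error is raised if the requested genes cannot be placed.
#' @param tool_error_rate Per-tool probability of flipping a
#'   coding/noncoding call.
#' @param n_db_decoys Decoy TF-target database pairs.
#' @param base_mean,base_sdlog Log-normal distribution of baseline gene
#'   means (counts scale).
#' @param depth_sdlog Log-normal spread of per-sample sequencing depth.
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(seed = 1L, n_case = 5L, n_control = 4L,
                       n_genes = 200L, n_lncrnas = 20L, n_tfs = 15L,
                       planted_triples = 9L, targets_per_tf = 3L,
                       n_de_genes = 40L, de_fold_change = 4,
                       de_fc_jitter = 1,
                       network_fold_change = 8, nb_dispersion = 0.1,
                       planted_edge_r = 0.95,
                       cis_fraction_within_window = 0.2,
                       chrom_length_bp = 3e8, tool_error_rate = 0,
                       n_db_decoys = 100L, base_mean = 150,
                       base_sdlog = 1, depth_sdlog = 0.1) {
  cfg <- list(seed = as.integer(seed), n_case = as.integer(n_case),
              n_control = as.integer(n_control),
              n_genes = as.integer(n_genes),
              n_lncrnas = as.integer(n_lncrnas),
              n_tfs = as.integer(n_tfs),
              planted_triples = as.integer(planted_triples),
              targets_per_tf = as.integer(targets_per_tf),
              n_de_genes = as.integer(n_de_genes),
              de_fold_change = de_fold_change,
              de_fc_jitter = de_fc_jitter,
              network_fold_change = network_fold_change,
              nb_dispersion = nb_dispersion,
              planted_edge_r = planted_edge_r,
              cis_fraction_within_window = cis_fraction_within_window,
              chrom_length_bp = chrom_length_bp,
              tool_error_rate = tool_error_rate,
              n_db_decoys = as.integer(n_db_decoys),
              base_mean = base_mean, base_sdlog = base_sdlog,
              depth_sdlog = depth_sdlog)
  stopifnot(cfg$n_case >= 2, cfg$n_control >= 2, cfg$n_genes > 0,
            cfg$n_lncrnas > 0, cfg$n_tfs > 0,
            cfg$planted_edge_r > 0, cfg$planted_edge_r < 1,
            cfg$planted_triples %% cfg$targets_per_tf == 0,
            cfg$tool_error_rate >= 0, cfg$tool_error_rate <= 1)
  k <- cfg$planted_triples %/% cfg$targets_per_tf
  if (k > cfg$n_tfs) stop("more planted cis pairs than TF genes")
  if (k > cfg$n_lncrnas) stop("more planted cis pairs than lncRNA genes")
  cfg$n_planted_pairs <- k
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Preset simulation configurations
#'
#' `"small-cohort"` keeps the 5-vs-4 cohort; `"recovery"` uses 20 samples
#' per group, the regime used for planted-network recovery experiments.
#'
#' @param preset `"small-cohort"` or `"recovery"`.
#' @param seed Seed passed to [sim_config()].
#' @param ... Further overrides for [sim_config()].
#' @return A `SimulationConfig`.
#' @export
preset_config <- function(preset = c("small-cohort", "recovery"), seed = 1L,
                          ...) {
  preset <- match.arg(preset)
  if (preset == "small-cohort") sim_config(seed = seed, ...)
  else sim_config(seed = seed, n_case = 20L, n_control = 20L, ...)
}

# random exon structure within a gene span: first exon starts at `start`,
# last ends at the span end, total exonic length tx_len
make_exons <- function(start, span, tx_len, n_ex) {
  n_ex <- max(1L, min(n_ex, tx_len %/% 60L))
  if (tx_len >= span) { tx_len <- span; n_ex <- 1L }
  if (n_ex == 1)
    return(data.frame(start = start, end = start + tx_len - 1L))
  w <- as.vector(stats::rmultinom(1, tx_len - 50L * n_ex, rep(1, n_ex))) +
    50L
  gaps <- as.vector(stats::rmultinom(1, span - tx_len - (n_ex - 1L),
                                     rep(1, n_ex - 1L))) + 1L
  st <- start + cumsum(c(0L, head(w, -1) + gaps))
  data.frame(start = as.integer(st), end = as.integer(st + w - 1L))
}

#' Simulate a genome annotation with planted cis structure
#'
#' Places protein-coding genes (including designated TF genes) along one
#' chromosome with inter-gene gaps of 150-250 kb. For every planted cis
#' pair, a lncRNA gene is inserted 5-50 kb from its partner TF (inside the
#' 100-kb co-location window, beyond the 1-kb proximity filter). Decoy
#' lncRNAs sit more than 200 kb from every other gene; a configurable
#' fraction is instead placed within the window of a non-TF coding gene.
#' Three structural-filter decoys are always added: a <200-nt transcript,
#' a lncRNA <1,000 bp from a coding gene, and a lncRNA overlapping a
#' coding gene on the same strand.
#'
#' The returned annotation carries a `role` column on `$genes` (`coding`,
#' `tf`, `tf_planted`, `lnc_planted`, `lnc_decoy`, `lnc_coloc`,
#' `lnc_short`, `lnc_close`, `lnc_overlap`) used by the other simulators.
#'
#' @param cfg A [sim_config()].
#' @return An [annotation_set()] with the extra `role` column.
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  k <- cfg$n_planted_pairs
  n_coloc <- round(cfg$cis_fraction_within_window * (cfg$n_lncrnas - k))
  n_far <- cfg$n_lncrnas - k - n_coloc
  if (n_far < 0) stop("n_lncrnas too small for planted + co-located decoys")
  items <- c(rep("coding", cfg$n_genes - cfg$n_tfs),
             rep("tf", cfg$n_tfs - k),
             sprintf("tf_planted:%d", seq_len(k)),
             rep("lnc_decoy", n_far),
             rep("lnc_coloc", n_coloc),
             "lnc_short", "lnc_close")
  # shuffle; decoys needing an upstream host are attached opportunistically
  items <- sample(items)
  items <- items[!items %in% c("lnc_coloc", "lnc_close")]
  need <- c(rep("lnc_coloc", n_coloc), "lnc_close")
  ids <- list(coding = 0L, tf = 0L, lncp = 0L, lncd = 0L, lncc = 0L)
  genes <- list(); exons <- list()
  cursor <- 1L
  place_gene <- function(gene_id, biotype, role, gap, span, tx_len, n_ex,
                         strand = sample(c("+", "-"), 1)) {
    start <- cursor + as.integer(gap)
    ex <- make_exons(start, as.integer(span), as.integer(tx_len),
                     as.integer(n_ex))
    genes[[length(genes) + 1L]] <<- data.frame(
      gene_id = gene_id, chrom = "chr1", start = min(ex$start),
      end = max(ex$end), strand = strand, biotype = biotype, role = role,
      stringsAsFactors = FALSE)
    exons[[length(exons) + 1L]] <<- data.frame(
      transcript_id = paste0(gene_id, ".t1"), gene_id = gene_id,
      chrom = "chr1", start = ex$start, end = ex$end, strand = strand,
      stringsAsFactors = FALSE)
    cursor <<- max(ex$end)
    invisible(NULL)
  }
  attach_after <- function(role) {
    # lncRNA placed close downstream of whatever was placed last
    if (role == "lnc_coloc") {
      ids$lncc <<- ids$lncc + 1L
      place_gene(sprintf("LNCC%02d", ids$lncc), "candidate", "lnc_coloc",
                 gap = runif(1, 20000, 60000), span = runif(1, 1500, 4000),
                 tx_len = runif(1, 300, 1500), n_ex = sample(1:2, 1))
    } else {
      place_gene("LNCCLOSE1", "candidate", "lnc_close",
                 gap = sample(100:900, 1), span = 1200,
                 tx_len = 600, n_ex = 1)
    }
  }
  pending <- need
  for (it in items) {
    if (startsWith(it, "tf_planted:")) {
      i <- as.integer(sub("tf_planted:", "", it))
      tfid <- sprintf("TF%02d", cfg$n_tfs - k + i)
      place_gene(tfid, "protein_coding", "tf_planted",
                 gap = runif(1, 150000, 250000),
                 span = runif(1, 5000, 25000),
                 tx_len = runif(1, 1000, 4000), n_ex = sample(2:4, 1))
      ids$lncp <- ids$lncp + 1L
      place_gene(sprintf("LNCP%02d", ids$lncp), "candidate",
                 "lnc_planted", gap = runif(1, 5000, 50000),
                 span = runif(1, 1500, 4500),
                 tx_len = runif(1, 300, 2000), n_ex = sample(1:2, 1))
      # guarantee the next gene stays outside the planted window
      cursor <- cursor + 150000L
    } else if (it == "tf") {
      ids$tf <- ids$tf + 1L
      place_gene(sprintf("TF%02d", ids$tf), "protein_coding", "tf",
                 gap = runif(1, 150000, 250000),
                 span = runif(1, 5000, 25000),
                 tx_len = runif(1, 1000, 4000), n_ex = sample(2:4, 1))
    } else if (it == "coding") {
      ids$coding <- ids$coding + 1L
      gid <- sprintf("GENE%03d", ids$coding)
      place_gene(gid, "protein_coding", "coding",
                 gap = runif(1, 150000, 250000),
                 span = runif(1, 5000, 30000),
                 tx_len = runif(1, 800, 4000), n_ex = sample(2:5, 1))
      if (length(pending) && runif(1) < 0.35) {
        attach_after(pending[1]); pending <- pending[-1]
      }
    } else if (it == "lnc_decoy") {
      ids$lncd <- ids$lncd + 1L
      place_gene(sprintf("LNCD%02d", ids$lncd), "candidate", "lnc_decoy",
                 gap = runif(1, 220000, 320000),
                 span = runif(1, 1500, 4000),
                 tx_len = runif(1, 300, 1500), n_ex = sample(1:2, 1))
      cursor <- cursor + 220000L
    } else if (it == "lnc_short") {
      place_gene("LNCSHORT1", "candidate", "lnc_short",
                 gap = runif(1, 220000, 300000), span = 150, tx_len = 150,
                 n_ex = 1)
      cursor <- cursor + 220000L
    }
  }
  # any attached decoys not yet placed go at the end, after a coding host
  for (role in pending) {
    ids$coding <- ids$coding + 1L
    place_gene(sprintf("GENE%03d", ids$coding), "protein_coding", "coding",
               gap = runif(1, 150000, 250000), span = runif(1, 5000, 30000),
               tx_len = runif(1, 800, 4000), n_ex = sample(2:5, 1))
    attach_after(role)
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)
  # overlap decoy: inside the span of the first-placed coding gene
  host <- genes[genes$role == "coding", ][1, ]
  ov_start <- host$start + 200L
  ov_ex <- data.frame(start = ov_start, end = ov_start + 399L)
  genes <- rbind(genes, data.frame(
    gene_id = "LNCOVER1", chrom = "chr1", start = ov_ex$start,
    end = ov_ex$end, strand = host$strand, biotype = "candidate",
    role = "lnc_overlap", stringsAsFactors = FALSE))
  exons <- rbind(exons, data.frame(
    transcript_id = "LNCOVER1.t1", gene_id = "LNCOVER1", chrom = "chr1",
    start = ov_ex$start, end = ov_ex$end, strand = host$strand,
    stringsAsFactors = FALSE))
  if (max(genes$end) > cfg$chrom_length_bp)
    stop("chrom_length_bp too small: need at least ", max(genes$end), " bp")
  tx_len <- tapply(exons$end - exons$start + 1L, exons$transcript_id, sum)
  transcripts <- data.frame(
    transcript_id = names(tx_len),
    gene_id = sub("\\.t1$", "", names(tx_len)),
    length_nt = as.integer(tx_len), stringsAsFactors = FALSE)
  genes$exon_length <- as.integer(
    tx_len[paste0(genes$gene_id, ".t1")])
  annotation_set(genes, transcripts, exons)
}

#' Ground truth of a simulated experiment
#'
#' Assigns planted cis pairs (lncRNA i with TF i), planted TF targets
#' (coding genes far from every lncRNA), the derived planted triple set,
#' and the differential-expression plan: network members upregulated at
#' `network_fold_change`, plus `n_de_genes` decoy DE mRNAs and up to five
#' decoy DE lncRNAs with random direction and fold change
#' `de_fold_change * 2^U(-1,1)`.
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation from [simulate_annotation()].
#' @return A `GroundTruth` list: `de_genes` (gene -> up/down), `de_fc`
#'   (gene -> linear fold change, case/control), `planted_cis_pairs`,
#'   `planted_tf_targets`, `planted_triples` (data.frames), and `factor_of`
#'   (gene -> planted-triple component index).
#' @export
simulate_truth <- function(cfg, ann) {
  stopifnot(inherits(cfg, "SimulationConfig"),
            inherits(ann, "AnnotationSet"))
  set.seed(cfg$seed + 1L)
  g <- ann$genes
  k <- cfg$n_planted_pairs
  lncs <- g$gene_id[g$role == "lnc_planted"]
  tfs <- g$gene_id[g$role == "tf_planted"]
  stopifnot(length(lncs) == k, length(tfs) == k)
  # pair lncRNA with the TF it was placed next to (genomic order)
  ord <- order(g[match(lncs, g$gene_id), "start"])
  lncs <- lncs[ord]
  tfs <- tfs[order(g[match(tfs, g$gene_id), "start"])]
  pool <- g$gene_id[g$role == "coding"]
  # targets must stay clear of all lncRNAs so no accidental cis edges form
  lnc_gr <- ann$gr[g$gene_id[grepl("^lnc", g$role)]]
  d <- GenomicRanges::distanceToNearest(ann$gr[pool], lnc_gr,
                                        ignore.strand = TRUE)
  dmin <- rep(Inf, length(pool))
  dmin[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
  pool_far <- pool[dmin > 150000]
  need <- k * cfg$targets_per_tf
  if (length(pool_far) < need + cfg$n_de_genes)
    stop("not enough coding genes for targets and DE decoys")
  targets <- sample(pool_far, need)
  planted_tf_targets <- data.frame(
    tf = rep(tfs, each = cfg$targets_per_tf), target = targets,
    stringsAsFactors = FALSE)
  planted_cis_pairs <- data.frame(lncrna = lncs, tf = tfs,
                                  stringsAsFactors = FALSE)
  planted_triples <- merge(planted_cis_pairs, planted_tf_targets,
                           by = "tf")[, c("lncrna", "tf", "target")]
  planted_triples <- planted_triples[order(planted_triples$lncrna,
                                           planted_triples$tf,
                                           planted_triples$target), ]
  rownames(planted_triples) <- NULL
  members <- c(lncs, tfs, targets)
  factor_of <- c(seq_len(k), seq_len(k),
                 rep(seq_len(k), each = cfg$targets_per_tf))
  names(factor_of) <- members
  de_genes <- setNames(rep("up", length(members)), members)
  de_fc <- setNames(rep(cfg$network_fold_change, length(members)), members)
  decoy_mrna <- sample(setdiff(pool_far, targets), cfg$n_de_genes)
  lnc_decoys <- g$gene_id[g$role %in% c("lnc_decoy", "lnc_coloc")]
  decoy_lnc <- sample(lnc_decoys, min(5L, length(lnc_decoys)))
  decoys <- c(decoy_mrna, decoy_lnc)
  dirs <- sample(c("up", "down"), length(decoys), replace = TRUE)
  fcs <- cfg$de_fold_change *
    2^runif(length(decoys), -cfg$de_fc_jitter, cfg$de_fc_jitter)
  fcs[dirs == "down"] <- 1 / fcs[dirs == "down"]
  de_genes <- c(de_genes, setNames(dirs, decoys))
  de_fc <- c(de_fc, setNames(fcs, decoys))
  structure(list(de_genes = de_genes, de_fc = de_fc,
                 planted_cis_pairs = planted_cis_pairs,
                 planted_tf_targets = planted_tf_targets,
                 planted_triples = planted_triples,
                 factor_of = factor_of),
            class = "GroundTruth")
}

# factor loading (log2 scale) for a planted triple: solve
#   r = (lambda^2 + shift_var) / (lambda^2 + shift_var + noise_var)
# where shift_var is the variance contributed by the shared DE shift and
# noise_var approximates Var(log2 NB count) = (1/mu + alpha) / ln(2)^2
factor_loading <- function(target_r, noise_var, shift_var) {
  lam2 <- target_r / (1 - target_r) * noise_var - shift_var
  sqrt(max(lam2, 0))
}

#' Simulate a fragment count matrix with planted structure
#'
#' Negative-binomial counts with log-normally distributed baseline means,
#' per-sample depth factors, a symmetric fold-change shift for planted DE
#' genes (`mu * fc^(+1/2)` in cases, `mu * fc^(-1/2)` in controls), and a
#' shared per-sample log-normal latent factor per planted triple whose
#' loading is solved in closed form so that the pooled Pearson correlation
#' of member genes on log2(FPKM+1) approximates `planted_edge_r` (the
#' calibration accounts for the correlation contributed by the shared DE
#' shift across the pooled groups).
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation from [simulate_annotation()].
#' @param truth Ground truth from [simulate_truth()].
#' @return An `ExpressionMatrix` of counts (samples `S01..`, cases first).
#' @export
simulate_counts <- function(cfg, ann, truth) {
  stopifnot(inherits(cfg, "SimulationConfig"),
            inherits(truth, "GroundTruth"))
  set.seed(cfg$seed + 2L)
  genes <- ann$genes$gene_id
  ns <- cfg$n_case + cfg$n_control
  samples <- sprintf("S%02d", seq_len(ns))
  groups <- setNames(rep(c("case", "control"),
                         c(cfg$n_case, cfg$n_control)), samples)
  x <- ifelse(groups == "case", 0.5, -0.5)
  vx <- mean((x - mean(x))^2)
  mu0 <- rlnorm(length(genes), meanlog = log(cfg$base_mean),
                sdlog = cfg$base_sdlog)
  names(mu0) <- genes
  d <- setNames(rep(0, length(genes)), genes)
  de <- names(truth$de_fc)
  d[de] <- log2(truth$de_fc[de])
  L <- outer(log2(mu0), rep(1, ns)) + outer(d, x)
  k <- if (length(truth$factor_of)) max(truth$factor_of) else 0L
  fac <- matrix(rnorm(k * ns), nrow = k)
  alpha <- cfg$nb_dispersion
  ln2sq <- log(2)^2
  for (t in seq_len(k)) {
    mem <- names(truth$factor_of)[truth$factor_of == t]
    dbar <- mean(d[mem])
    shift <- dbar^2 * vx
    # the DE shift moves half the samples below the baseline mean,
    # inflating the Poisson part of the log-scale noise by the design
    # factor mean(2^(-d x)); only this deterministic term is corrected
    # for -- chasing the stochastic factor's own tail contribution with a
    # fixed point overweights extreme samples and is left out
    infl <- mean(2^(-dbar * x))
    noise <- mean((infl / mu0[mem] + alpha) / ln2sq)
    lam <- factor_loading(cfg$planted_edge_r, noise, shift)
    L[mem, ] <- L[mem, ] + lam * matrix(fac[t, ], nrow = length(mem),
                                        ncol = ns, byrow = TRUE)
  }
  depth <- rlnorm(ns, 0, cfg$depth_sdlog)
  mu <- 2^L * matrix(depth, nrow = length(genes), ncol = ns, byrow = TRUE)
  counts <- if (alpha > 0) {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / alpha),
           nrow = length(genes))
  } else {
    matrix(stats::rpois(length(mu), lambda = mu), nrow = length(genes))
  }
  dimnames(counts) <- list(genes, samples)
  storage.mode(counts) <- "double"
  expression_matrix(counts, groups, unit = "counts")
}

#' Simulate four coding-potential call tables
#'
#' Emulates the output of four external predictors (CPC2, LGC, CNCI,
#' CPAT): every transcript of a protein-coding gene is truly coding, every
#' other transcript truly noncoding; each tool independently flips each
#' call with probability `tool_error_rate`.
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation from [simulate_annotation()].
#' @return Named list of four [tool_call_table()] objects.
#' @export
simulate_tool_calls <- function(cfg, ann) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed + 3L)
  tx <- ann$transcripts
  bio <- ann$genes[match(tx$gene_id, ann$genes$gene_id), "biotype"]
  truth <- ifelse(bio == "protein_coding", "coding", "noncoding")
  tools <- c("CPC2", "LGC", "CNCI", "CPAT")
  out <- lapply(tools, function(tool) {
    flip <- runif(nrow(tx)) < cfg$tool_error_rate
    lab <- ifelse(flip, ifelse(truth == "coding", "noncoding", "coding"),
                  truth)
    tool_call_table(tool, setNames(lab, tx$transcript_id))
  })
  names(out) <- tools
  out
}

#' TF catalogue of a simulated annotation
#'
#' @param ann Annotation from [simulate_annotation()].
#' @return Character vector of TF gene identifiers.
#' @export
simulate_tf_catalogue <- function(ann) {
  sort(ann$genes$gene_id[ann$genes$role %in% c("tf", "tf_planted")])
}

#' Simulate annotated TF-target database pairs
#'
#' All planted TF-target pairs are present, each supported by 1-3 of the
#' three emulated curated sources; `n_db_decoys` additional decoy pairs
#' link catalogue TFs to random non-network coding genes.
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation from [simulate_annotation()].
#' @param truth Ground truth from [simulate_truth()].
#' @return data.frame with columns tf, target, source_db.
#' @export
simulate_db_pairs <- function(cfg, ann, truth) {
  set.seed(cfg$seed + 4L)
  sources <- c("TFTG", "TRRUST", "ENCODE")
  pt <- truth$planted_tf_targets
  planted <- do.call(rbind, lapply(seq_len(nrow(pt)), function(i) {
    s <- sample(sources, sample(1:3, 1))
    data.frame(tf = pt$tf[i], target = pt$target[i], source_db = s,
               stringsAsFactors = FALSE)
  }))
  tf_all <- simulate_tf_catalogue(ann)
  pool <- setdiff(ann$genes$gene_id[ann$genes$role == "coding"],
                  pt$target)
  dec_tf <- sample(tf_all, cfg$n_db_decoys, replace = TRUE)
  dec_tg <- sample(pool, cfg$n_db_decoys, replace = TRUE)
  decoys <- data.frame(tf = dec_tf, target = dec_tg,
                       source_db = sample(sources, cfg$n_db_decoys,
                                          replace = TRUE),
                       stringsAsFactors = FALSE)
  keep <- !(paste(decoys$tf, decoys$target) %in% paste(pt$tf, pt$target))
  out <- rbind(planted, decoys[keep, ])
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Simulate toy term -> gene sets
#'
#' One term collecting the planted network targets plus TFs, and five
#' random terms over coding genes.
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation from [simulate_annotation()].
#' @param truth Ground truth from [simulate_truth()].
#' @return Named list of character vectors.
#' @export
simulate_terms <- function(cfg, ann, truth) {
  set.seed(cfg$seed + 5L)
  pool <- ann$genes$gene_id[ann$genes$biotype == "protein_coding"]
  terms <- list(TERM_NETWORK = sort(unique(
    c(truth$planted_tf_targets$target, truth$planted_tf_targets$tf))))
  for (i in 1:5)
    terms[[sprintf("TERM_RANDOM%d", i)]] <- sort(sample(pool, 15))
  terms
}

#' Simulate a complete experiment
#'
#' Runs every simulator with seeds derived from `cfg$seed` (each stage is
#' a pure function of the configuration) and returns all pipeline inputs
#' plus the ground truth.
#'
#' @param cfg A [sim_config()].
#' @return List with elements cfg, ann, truth, counts, tool_calls,
#'   tf_catalogue, db_pairs, terms.
#' @export
simulate_experiment <- function(cfg) {
  ann <- simulate_annotation(cfg)
  truth <- simulate_truth(cfg, ann)
  counts <- simulate_counts(cfg, ann, truth)
  tool_calls <- simulate_tool_calls(cfg, ann)
  list(cfg = cfg, ann = ann, truth = truth, counts = counts,
       tool_calls = tool_calls,
       tf_catalogue = simulate_tf_catalogue(ann),
       db_pairs = simulate_db_pairs(cfg, ann, truth),
       terms = simulate_terms(cfg, ann, truth))
}

#' Write a simulated experiment as a fixture bundle
#'
#' Emits every input file the pipeline consumes — GTF annotation, count
#' TSV, group labels, library sizes, four tool-call TSVs, TF catalogue,
#' TF-target pairs, GMT terms — plus a ground-truth JSON. Output is
#' byte-identical across runs for a fixed configuration.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the vector of written file paths.
#' @export
emit_fixture_bundle <- function(cfg, out_dir) {
  sim <- simulate_experiment(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wp <- function(name) {
    p <- file.path(out_dir, name); paths <<- c(paths, p); p
  }
  write_annotation(sim$ann, wp("annotation.gtf"))
  cm <- data.frame(gene_id = rownames(sim$counts$values),
                   sim$counts$values, check.names = FALSE)
  write.table(cm, wp("counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample_id = names(sim$counts$groups),
                         group = sim$counts$groups),
              wp("groups.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample_id = colnames(sim$counts$values),
                         library_size = colSums(sim$counts$values)),
              wp("library_sizes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (tool in names(sim$tool_calls)) {
    tc <- sim$tool_calls[[tool]]
    write.table(data.frame(transcript_id = names(tc$calls),
                           label = tc$calls),
                wp(paste0("tool_", tool, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  writeLines(sim$tf_catalogue, wp("tf_catalogue.tsv"))
  write.table(sim$db_pairs, wp("tf_targets.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  gmt <- vapply(names(sim$terms), function(tm)
    paste(c(tm, "synthetic", sim$terms[[tm]]), collapse = "\t"),
    character(1))
  writeLines(gmt, wp("terms.gmt"))
  jsonlite::write_json(
    list(de_genes = as.list(sim$truth$de_genes),
         de_fc = as.list(sim$truth$de_fc),
         planted_cis_pairs = sim$truth$planted_cis_pairs,
         planted_tf_targets = sim$truth$planted_tf_targets,
         planted_triples = sim$truth$planted_triples),
    wp("ground_truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Load a fixture bundle written by [emit_fixture_bundle()]
#'
#' @param dir Bundle directory.
#' @return List with the same pipeline-input elements as
#'   [simulate_experiment()] (ground truth reloaded from JSON).
#' @export
load_fixture_bundle <- function(dir) {
  ann <- read_annotation(file.path(dir, "annotation.gtf"))
  groups <- read_group_labels(file.path(dir, "groups.tsv"))
  counts <- expression_matrix(read_counts(file.path(dir, "counts.tsv")),
                              groups, unit = "counts")
  tools <- c("CPC2", "LGC", "CNCI", "CPAT")
  tool_calls <- lapply(tools, function(tool)
    read_tool_calls(file.path(dir, paste0("tool_", tool, ".tsv")), tool))
  names(tool_calls) <- tools
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  truth <- structure(
    list(de_genes = unlist(gt$de_genes), de_fc = unlist(gt$de_fc),
         planted_cis_pairs = gt$planted_cis_pairs,
         planted_tf_targets = gt$planted_tf_targets,
         planted_triples = gt$planted_triples),
    class = "GroundTruth")
  list(ann = ann, counts = counts, tool_calls = tool_calls,
       tf_catalogue = read_tf_catalogue(file.path(dir, "tf_catalogue.tsv")),
       db_pairs = read_tf_targets(file.path(dir, "tf_targets.tsv")),
       terms = read_gmt(file.path(dir, "terms.gmt")),
       library_sizes = read_library_sizes(
         file.path(dir, "library_sizes.tsv")),
       truth = truth)
}
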