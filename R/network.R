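#' Pearson correlation with a closed-form p-value
#'
#' Sample Pearson correlation of two vectors with a two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom; a
#' perfect correlation (|r| = 1) returns p = 0.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, each with nonzero
#'   variance.
#' @return List with elements `r`, `pvalue`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations, got ", n)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in input vector")
  r <- cor(x, y)
  if (abs(r) >= 1 - 1e-15) {
    return(list(r = sign(r), pvalue = 0, n = n))
  }
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, pvalue = 2 * pt(-abs(tt), df = n - 2), n = n)
}

# Vectorised cross-correlation of two gene sets over samples.
# m: samples x genes matrix (already transformed). Returns list(r, p) of
# |A| x |B| matrices.
cor_matrix_with_p <- function(m, set_a, set_b) {
  n <- nrow(m)
  r <- cor(m[, set_a, drop = FALSE], m[, set_b, drop = FALSE])
  r[r >= 1 - 1e-12] <- 1
  r[r <= -1 + 1e-12] <- -1
  r2 <- pmin(r^2, 1 - 1e-15)
  tt <- abs(r) * sqrt((n - 2) / (1 - r2))
  p <- 2 * pt(-tt, df = n - 2)
  p[abs(r) >= 1 - 1e-15] <- 0
  list(r = r, p = p, n = n)
}

# Expression values on the correlation scale: log2(x + 1) by default.
coexpr_values <- function(expr, transform = c("log2", "none")) {
  transform <- match.arg(transform)
  v <- t(expr$values)
  if (transform == "log2") v <- log2(v + 1)
  v
}

#' Co-expression pairs between two gene sets
#'
#' Computes Pearson correlations (by default on `log2(value + 1)` across
#' all samples, both groups pooled) for every cross pair between `set_a`
#' and `set_b` and retains pairs passing an absolute-correlation and
#' p-value screen. The correlation bound is strict (`|r| > min_abs_r`) for
#' the cis tier and inclusive (`|r| >= min_abs_r`) for the TF-DEG tier;
#' choose with `r_strict`. Constant-expression genes are skipped with a
#' message. Pairs are unordered and reported once.
#'
#' @param expr An `ExpressionMatrix`.
#' @param set_a,set_b Character vectors of gene_ids present in `expr`.
#' @param min_abs_r Absolute-correlation threshold.
#' @param max_p Inclusive p-value threshold (`p <= max_p`).
#' @param r_strict If `TRUE`, require `|r| > min_abs_r`, else `>=`.
#' @param transform `"log2"` (log2(x+1)) or `"none"`.
#' @return data.frame with columns gene_a, gene_b, r, pvalue, n.
#' @export
coexpression_pairs <- function(expr, set_a, set_b, min_abs_r, max_p,
                               r_strict = TRUE,
                               transform = c("log2", "none")) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            min_abs_r >= 0, min_abs_r <= 1, max_p >= 0, max_p <= 1)
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) == 0 || length(set_b) == 0)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      r = numeric(0), pvalue = numeric(0), n = integer(0)))
  miss <- setdiff(c(set_a, set_b), rownames(expr$values))
  if (length(miss))
    stop("genes absent from expression matrix: ",
         paste(miss, collapse = ", "))
  m <- coexpr_values(expr, transform)
  const <- colnames(m)[apply(m, 2, function(z) sd(z) == 0)]
  ndrop <- length(intersect(const, union(set_a, set_b)))
  if (ndrop > 0)
    message("skipping ", ndrop, " constant-expression gene(s)")
  set_a <- setdiff(set_a, const); set_b <- setdiff(set_b, const)
  if (length(set_a) == 0 || length(set_b) == 0)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      r = numeric(0), pvalue = numeric(0), n = integer(0)))
  cc <- cor_matrix_with_p(m, set_a, set_b)
  pass <- if (r_strict) abs(cc$r) > min_abs_r else abs(cc$r) >= min_abs_r
  pass <- pass & cc$p <= max_p
  idx <- which(pass, arr.ind = TRUE)
  out <- data.frame(
    gene_a = set_a[idx[, 1]],
    gene_b = set_b[idx[, 2]],
    r = cc$r[idx], pvalue = cc$p[idx],
    n = rep(cc$n, nrow(idx)),
    stringsAsFactors = FALSE)
  out <- out[out$gene_a != out$gene_b, , drop = FALSE]
  # unordered pair stored once
  key <- ifelse(out$gene_a < out$gene_b,
                paste(out$gene_a, out$gene_b),
                paste(out$gene_b, out$gene_a))
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cis targets of lncRNAs: co-location AND co-expression
#'
#' A differentially expressed mRNA is a cis target of a differentially
#' expressed lncRNA when (a) its span lies within `window_bp` of the lncRNA
#' span (co-location; strand-agnostic window both upstream and downstream)
#' and (b) the pair passes the co-expression screen (`|r| > min_abs_r`,
#' `p <= max_p`). The result is the intersection of the two sets.
#'
#' @param lnc_deg Character vector of DE lncRNA gene_ids.
#' @param mrna_deg Character vector of DE mRNA gene_ids.
#' @param ann An [annotation_set()].
#' @param expr An `ExpressionMatrix` (FPKM recommended).
#' @param window_bp Co-location window (default 100,000 bp).
#' @param min_abs_r Strict absolute-correlation threshold (default 0.6).
#' @param max_p Inclusive p-value threshold (default 0.01).
#' @param transform Correlation-scale transform, see
#'   [coexpression_pairs()].
#' @return data.frame with columns lncrna, target, r, pvalue, n.
#' @export
cis_targets <- function(lnc_deg, mrna_deg, ann, expr,
                        window_bp = 100000, min_abs_r = 0.6,
                        max_p = 0.01, transform = c("log2", "none")) {
  stopifnot(inherits(ann, "AnnotationSet"))
  if (length(lnc_deg) == 0 || length(mrna_deg) == 0)
    return(data.frame(lncrna = character(0), target = character(0),
                      r = numeric(0), pvalue = numeric(0), n = integer(0)))
  coloc <- do.call(rbind, lapply(lnc_deg, function(l) {
    nb <- genes_within_window(ann, l, window_bp)
    hit <- intersect(nb$gene_id, mrna_deg)
    if (length(hit) == 0) return(NULL)
    data.frame(lncrna = l, target = hit, stringsAsFactors = FALSE)
  }))
  if (is.null(coloc) || nrow(coloc) == 0)
    return(data.frame(lncrna = character(0), target = character(0),
                      r = numeric(0), pvalue = numeric(0), n = integer(0)))
  coex <- coexpression_pairs(expr, lnc_deg, mrna_deg,
                             min_abs_r = min_abs_r, max_p = max_p,
                             r_strict = TRUE, transform = transform)
  key_loc <- paste(coloc$lncrna, coloc$target)
  key_a <- paste(coex$gene_a, coex$gene_b)
  key_b <- paste(coex$gene_b, coex$gene_a)
  m <- match(key_loc, key_a)
  m2 <- match(key_loc, key_b)
  use <- ifelse(is.na(m), m2, m)
  keep <- !is.na(use)
  out <- data.frame(
    lncrna = coloc$lncrna[keep],
    target = coloc$target[keep],
    r = coex$r[use[keep]],
    pvalue = coex$pvalue[use[keep]],
    n = coex$n[use[keep]],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Restrict cis targets to a TF catalogue
#'
#' @param targets data.frame from [cis_targets()].
#' @param tf_catalogue Non-empty character vector of TF gene symbols.
#' @return Same shape with column `target` renamed to `tf`, keeping only
#'   rows whose target is in the catalogue.
#' @export
filter_tfs <- function(targets, tf_catalogue) {
  if (length(tf_catalogue) == 0) stop("TF catalogue is empty")
  out <- targets[targets$target %in% tf_catalogue, , drop = FALSE]
  names(out)[names(out) == "target"] <- "tf"
  rownames(out) <- NULL
  out
}

#' TF-DEG co-expression pairs supported by curated databases
#'
#' Second co-expression tier: pairs of cis-TFs and DEGs with
#' `|r| >= min_abs_r` (inclusive, default 0.8) and `p <= max_p` that are
#' also annotated as TF-target pairs in at least `min_sources` of the
#' supplied databases (union rule by default).
#'
#' @param cis_tfs Character vector of cis-regulated TF gene_ids.
#' @param degs Character vector of DE gene_ids (candidate targets).
#' @param expr An `ExpressionMatrix`.
#' @param db_pairs data.frame with columns tf, target, source_db; may be
#'   `NULL` to disable the database intersection.
#' @param min_abs_r,max_p Thresholds (defaults 0.8, 0.01).
#' @param min_sources Minimum number of distinct supporting databases.
#' @param transform Correlation-scale transform.
#' @return data.frame with columns tf, target, r, pvalue, n, db_sources
#'   (comma-separated; "" when intersection disabled).
#' @export
tf_deg_pairs <- function(cis_tfs, degs, expr, db_pairs,
                         min_abs_r = 0.8, max_p = 0.01,
                         min_sources = 1,
                         transform = c("log2", "none")) {
  degs <- setdiff(degs, cis_tfs)
  coex <- coexpression_pairs(expr, cis_tfs, degs,
                             min_abs_r = min_abs_r, max_p = max_p,
                             r_strict = FALSE, transform = transform)
  names(coex)[names(coex) == "gene_a"] <- "tf"
  names(coex)[names(coex) == "gene_b"] <- "target"
  if (is.null(db_pairs)) {
    coex$db_sources <- rep("", nrow(coex))
    return(coex)
  }
  key <- paste(coex$tf, coex$target)
  dbkey <- paste(db_pairs$tf, db_pairs$target)
  src <- tapply(db_pairs$source_db, dbkey,
                function(s) sort(unique(s)), simplify = FALSE)
  nsrc <- vapply(src[key], function(s) if (is.null(s)) 0L else length(s),
                 integer(1))
  keep <- nsrc >= min_sources
  coex <- coex[keep, , drop = FALSE]
  coex$db_sources <- vapply(src[key[keep]], paste, character(1),
                            collapse = ",")
  rownames(coex) <- NULL
  coex
}

#' Assemble the tripartite lncRNA-TF-DEG network
#'
#' Joins cis (lncRNA -> TF) edges with (TF -> DEG) edges on the shared TF:
#' every combination becomes one regulatory triple. Nodes are typed
#' `lncRNA`, `TF` or `DEG`.
#'
#' @param cis_edges data.frame from [filter_tfs()] (columns lncrna, tf, r,
#'   pvalue).
#' @param tf_deg_edges data.frame from [tf_deg_pairs()] (columns tf,
#'   target, r, pvalue, db_sources).
#' @return A `RegulatoryNetwork`: list with `triples` (data.frame: lncrna,
#'   tf, target, r_lnc_tf, p_lnc_tf, r_tf_target, p_tf_target, db_sources)
#'   and `graph` (an igraph object with a `type` vertex attribute).
#' @export
build_network <- function(cis_edges, tf_deg_edges) {
  shared <- intersect(cis_edges$tf, tf_deg_edges$tf)
  if (length(shared) == 0 || nrow(cis_edges) == 0 ||
      nrow(tf_deg_edges) == 0) {
    triples <- data.frame(
      lncrna = character(0), tf = character(0), target = character(0),
      r_lnc_tf = numeric(0), p_lnc_tf = numeric(0),
      r_tf_target = numeric(0), p_tf_target = numeric(0),
      db_sources = character(0), stringsAsFactors = FALSE)
  } else {
    a <- cis_edges[cis_edges$tf %in% shared, , drop = FALSE]
    b <- tf_deg_edges[tf_deg_edges$tf %in% shared, , drop = FALSE]
    triples <- merge(
      data.frame(lncrna = a$lncrna, tf = a$tf, r_lnc_tf = a$r,
                 p_lnc_tf = a$pvalue, stringsAsFactors = FALSE),
      data.frame(tf = b$tf, target = b$target, r_tf_target = b$r,
                 p_tf_target = b$pvalue,
                 db_sources = if ("db_sources" %in% names(b))
                   b$db_sources else "",
                 stringsAsFactors = FALSE),
      by = "tf")
    triples <- triples[, c("lncrna", "tf", "target", "r_lnc_tf",
                           "p_lnc_tf", "r_tf_target", "p_tf_target",
                           "db_sources")]
    triples <- triples[order(triples$lncrna, triples$tf, triples$target), ]
    rownames(triples) <- NULL
  }
  nodes <- unique(data.frame(
    name = c(triples$lncrna, triples$tf, triples$target),
    type = rep(c("lncRNA", "TF", "DEG"),
               times = rep(nrow(triples), 3)),
    stringsAsFactors = FALSE))
  edges <- unique(rbind(
    data.frame(from = triples$lncrna, to = triples$tf,
               r = triples$r_lnc_tf,
               tier = rep("cis", nrow(triples)),
               stringsAsFactors = FALSE),
    data.frame(from = triples$tf, to = triples$target,
               r = triples$r_tf_target,
               tier = rep("tf_target", nrow(triples)),
               stringsAsFactors = FALSE)))
  graph <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                         vertices = nodes)
  structure(list(triples = triples, graph = graph),
            class = "RegulatoryNetwork")
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  t <- x$triples
  cat("RegulatoryNetwork:", nrow(t), "triples |",
      length(unique(t$lncrna)), "lncRNA ->", length(unique(t$tf)),
      "TF ->", length(unique(t$target)), "targets\n")
  invisible(x)
}

#' Export a regulatory network
#'
#' Writes the triple table as TSV and/or the typed tripartite graph as
#' GraphML.
#'
#' @param net A `RegulatoryNetwork` from [build_network()].
#' @param tsv,graphml Output paths (either may be `NULL`).
#' @return Invisibly, `net`.
#' @export
write_network <- function(net, tsv = NULL, graphml = NULL) {
  stopifnot(inherits(net, "RegulatoryNetwork"))
  if (!is.null(tsv))
    write.table(net$triples, tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(graphml))
    igraph::write_graph(net$graph, graphml, format = "graphml")
  invisible(net)
}
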