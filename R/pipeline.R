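#' Run the full cis lncRNA-TF-target inference pipeline
#'
#' Chains every stage: FPKM quantification and detection; differential
#' expression with fold-change/FDR classification; candidate lncRNA
#' screening (four-tool consensus + structural filters); cis-target
#' calling as co-location within `window_bp` intersected with a strict
#' `|r| > cis_min_r`, `p <= cis_max_p` co-expression screen; restriction
#' to the TF catalogue; the inclusive `|r| >= tf_min_r`, `p <= tf_max_p`
#' TF-DEG tier intersected with the TF-target databases; and assembly of
#' the tripartite network.
#'
#' @param ann An [annotation_set()].
#' @param counts `ExpressionMatrix` of counts with group labels.
#' @param tool_calls List of four [tool_call_table()] objects.
#' @param tf_catalogue Character vector of TF gene symbols.
#' @param db_pairs data.frame (tf, target, source_db) or `NULL` to skip
#'   the database intersection.
#' @param library_sizes Optional named vector of total mapped fragments.
#' @param window_bp Co-location window (default 100,000).
#' @param cis_min_r,cis_max_p Cis-tier thresholds (defaults 0.6, 0.01;
#'   strict on r).
#' @param tf_min_r,tf_max_p TF-tier thresholds (defaults 0.8, 0.01;
#'   inclusive on r).
#' @param min_sources Minimum supporting databases per TF-target pair.
#' @param transform Correlation-scale transform (default log2(FPKM+1)).
#' @return A `PipelineResult` list: fpkm, detected, de, lnc_screen,
#'   lnc_genes, lnc_deg, mrna_deg, cis_edges, cis_tf_edges, tf_deg_edges,
#'   network.
#' @export
run_pipeline <- function(ann, counts, tool_calls, tf_catalogue,
                         db_pairs = NULL, library_sizes = NULL,
                         window_bp = 100000, cis_min_r = 0.6,
                         cis_max_p = 0.01, tf_min_r = 0.8,
                         tf_max_p = 0.01, min_sources = 1,
                         transform = "log2") {
  fpkm <- compute_fpkm(counts, ann, library_sizes)
  detected <- detected_genes(fpkm)
  de <- differential_expression(counts)
  deg <- de$gene_id[de$call != "none"]
  screen <- screen_lncrnas(tool_calls, ann)
  lnc_genes <- unique(screen$gene_id[screen$retained])
  biot <- ann$genes[match(de$gene_id, ann$genes$gene_id), "biotype"]
  mrna_deg <- intersect(de$gene_id[biot == "protein_coding"], deg)
  lnc_deg <- intersect(lnc_genes, deg)
  cis_edges <- cis_targets(lnc_deg, intersect(mrna_deg, detected), ann,
                           fpkm, window_bp = window_bp,
                           min_abs_r = cis_min_r, max_p = cis_max_p,
                           transform = transform)
  cis_tf_edges <- filter_tfs(cis_edges, tf_catalogue)
  tf_deg_edges <- tf_deg_pairs(unique(cis_tf_edges$tf),
                               intersect(mrna_deg, detected), fpkm,
                               db_pairs, min_abs_r = tf_min_r,
                               max_p = tf_max_p,
                               min_sources = min_sources,
                               transform = transform)
  network <- build_network(cis_tf_edges, tf_deg_edges)
  structure(list(fpkm = fpkm, detected = detected, de = de,
                 lnc_screen = screen, lnc_genes = lnc_genes,
                 lnc_deg = lnc_deg, mrna_deg = mrna_deg,
                 cis_edges = cis_edges, cis_tf_edges = cis_tf_edges,
                 tf_deg_edges = tf_deg_edges, network = network),
            class = "PipelineResult")
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("PipelineResult:\n")
  cat("  DE genes:", sum(x$de$call != "none"),
      "(", sum(x$de$call == "up"), "up /", sum(x$de$call == "down"),
      "down )\n")
  cat("  retained lncRNA genes:", length(x$lnc_genes),
      "| DE lncRNAs:", length(x$lnc_deg),
      "| DE mRNAs:", length(x$mrna_deg), "\n")
  cat("  cis edges:", nrow(x$cis_edges),
      "-> cis-TF edges:", nrow(x$cis_tf_edges),
      "| TF-DEG edges:", nrow(x$tf_deg_edges),
      "| triples:", nrow(x$network$triples), "\n")
  invisible(x)
}

#' Precision and recall of planted-network recovery
#'
#' Compares the triples recovered by [run_pipeline()] against the planted
#' ground truth.
#'
#' @param result A `PipelineResult` (or its `network` element).
#' @param truth A `GroundTruth` from [simulate_truth()].
#' @return List with n_true, n_found, n_correct, recall, precision
#'   (precision is `NA` when nothing was found).
#' @export
evaluate_recovery <- function(result, truth) {
  trip <- if (inherits(result, "PipelineResult"))
    result$network$triples else result$triples
  found <- paste(trip$lncrna, trip$tf, trip$target)
  want <- paste(truth$planted_triples$lncrna, truth$planted_triples$tf,
                truth$planted_triples$target)
  n_correct <- length(intersect(found, want))
  list(n_true = length(want), n_found = length(found),
       n_correct = n_correct,
       recall = n_correct / length(want),
       precision = if (length(found)) n_correct / length(found)
                   else NA_real_)
}
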