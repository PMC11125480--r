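#' Expression matrices with group labels
#'
#' Container for a genes-by-samples matrix of counts or FPKM together with
#' case/control labels.
#'
#' @param values Non-negative numeric matrix with gene_ids as rownames and
#'   sample_ids as colnames.
#' @param groups Named character vector (`sample_id` -> `case`/`control`)
#'   covering every column.
#' @param unit `"counts"` or `"fpkm"`.
#' @return An `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, groups, unit = c("counts", "fpkm")) {
  unit <- match.arg(unit)
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  if (is.null(rownames(values))) {
    if (nrow(values) > 0) stop("values must have gene_ids as rownames")
    rownames(values) <- character(0)
  }
  if (any(values < 0)) stop("expression values must be non-negative")
  if (anyDuplicated(rownames(values))) stop("duplicate gene_ids")
  miss <- setdiff(colnames(values), names(groups))
  if (length(miss))
    stop("samples without a group label: ", paste(miss, collapse = ", "))
  groups <- groups[colnames(values)]
  bad <- setdiff(unique(groups), c("case", "control"))
  if (length(bad))
    stop("group labels must be case/control; found: ",
         paste(bad, collapse = ", "))
  structure(list(values = values, groups = groups, unit = unit),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix [", x$unit, "]: ", nrow(x$values), " genes x ",
      ncol(x$values), " samples (case ", sum(x$groups == "case"),
      " / control ", sum(x$groups == "control"), ")\n", sep = "")
  invisible(x)
}

#' FPKM from fragment counts
#'
#' Fragments per kilobase of exon per million mapped fragments:
#' `fpkm[g,s] = counts[g,s] * 1e9 / (exon_length_bp(g) * library_size(s))`.
#' Exonic length is the union of the gene's exons from the annotation.
#' Library sizes should be total mapped fragments; when absent, column sums
#' of the count matrix are used as a fallback.
#'
#' @param counts An `ExpressionMatrix` with unit `"counts"`.
#' @param ann An [annotation_set()] covering every gene in `counts`.
#' @param library_sizes Optional named numeric vector of total mapped
#'   fragments per sample.
#' @return An `ExpressionMatrix` with unit `"fpkm"`.
#' @export
compute_fpkm <- function(counts, ann, library_sizes = NULL) {
  stopifnot(inherits(counts, "ExpressionMatrix"),
            inherits(ann, "AnnotationSet"))
  if (counts$unit != "counts") stop("compute_fpkm expects a counts matrix")
  miss <- setdiff(rownames(counts$values), ann$genes$gene_id)
  if (length(miss))
    stop("genes missing from annotation: ", paste(miss, collapse = ", "))
  if (is.null(library_sizes)) {
    library_sizes <- colSums(counts$values)
  } else {
    m2 <- setdiff(colnames(counts$values), names(library_sizes))
    if (length(m2))
      stop("samples without library size: ", paste(m2, collapse = ", "))
    library_sizes <- library_sizes[colnames(counts$values)]
  }
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  len <- ann$genes[rownames(counts$values), "exon_length"]
  fpkm <- counts$values * 1e9 /
    (len %o% as.numeric(library_sizes))
  dimnames(fpkm) <- dimnames(counts$values)
  expression_matrix(fpkm, counts$groups, unit = "fpkm")
}

#' Detected genes (FPKM > 0 in at least one sample)
#'
#' @param fpkm An `ExpressionMatrix` with unit `"fpkm"`.
#' @return Character vector of gene_ids.
#' @export
detected_genes <- function(fpkm) {
  stopifnot(inherits(fpkm, "ExpressionMatrix"))
  if (fpkm$unit != "fpkm") stop("detected_genes expects FPKM values")
  rownames(fpkm$values)[rowSums(fpkm$values > 0) >= 1]
}

# Median-of-ratios size factors (reference = geometric mean over samples,
# taken over genes expressed in all samples), normalised to geometric mean 1.
size_factors <- function(counts) {
  lg <- log(counts)
  lg[!is.finite(lg)] <- NA
  ref <- exp(rowMeans(lg))
  ok <- is.finite(ref) & ref > 0 & rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) return(setNames(rep(1, ncol(counts)), colnames(counts)))
  sf <- apply(counts[ok, , drop = FALSE], 2,
              function(cnt) median(cnt / ref[ok]))
  sf[!is.finite(sf) | sf <= 0] <- 1
  sf / exp(mean(log(sf)))
}

#' Differential expression by a simplified negative-binomial Wald test
#'
#' A desk-scale two-group test for RNA-seq counts: median-of-ratios size
#' factors; per-gene pooled method-of-moments dispersion on normalised
#' counts (floored at 1e-8); Wald statistic on the log2 fold change with a
#' delta-method plug-in variance; two-sided p-values from a t reference
#' with `n1 + n2 - 2` degrees of freedom (small-sample correction for the
#' plug-in variance); Benjamini-Hochberg FDR across all genes. Fold change
#' is case/control on normalised group means with a pseudo-count.
#'
#' @param counts An `ExpressionMatrix` with unit `"counts"`, at least two
#'   samples per group.
#' @param pseudo Pseudo-count added to normalised group means for the fold
#'   change (default 0.5).
#' @param fc_up,fc_down,max_fdr Classification thresholds passed to
#'   [classify_deg()].
#' @return data.frame with columns gene_id, mean_case, mean_control, fc,
#'   log2fc, pvalue, fdr, call.
#' @export
differential_expression <- function(counts, pseudo = 0.5,
                                    fc_up = 2, fc_down = 0.5,
                                    max_fdr = 0.05) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$unit != "counts")
    stop("differential_expression expects raw counts")
  m <- counts$values
  if (any(abs(m - round(m)) > 1e-6))
    stop("counts must be integer-valued")
  grp <- counts$groups
  i1 <- grp == "case"; i0 <- grp == "control"
  n1 <- sum(i1); n0 <- sum(i0)
  if (n1 < 2 || n0 < 2)
    stop("each group needs at least 2 samples (case ", n1,
         ", control ", n0, ")")
  sf <- size_factors(m)
  q <- sweep(m, 2, sf, "/")
  q1 <- q[, i1, drop = FALSE]; q0 <- q[, i0, drop = FALSE]
  m1 <- rowMeans(q1); m0 <- rowMeans(q0)
  v1 <- rowSums((q1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((q0 - m0)^2) / (n0 - 1)
  mpool <- (n1 * m1 + n0 * m0) / (n1 + n0)
  vpool <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  alpha <- (vpool - mpool) / mpool^2
  alpha[!is.finite(alpha)] <- 0
  alpha <- pmax(alpha, 1e-8)
  # Var(mean of normalised counts) per group under NB(mu, alpha):
  # (1/n^2) * sum_j (m/sf_j + alpha m^2)
  s1 <- sum(1 / sf[i1]); s0 <- sum(1 / sf[i0])
  var_m1 <- (m1 * s1 + alpha * m1^2 * n1) / n1^2
  var_m0 <- (m0 * s0 + alpha * m0^2 * n0) / n0^2
  fc <- (m1 + pseudo) / (m0 + pseudo)
  log2fc <- log2(fc)
  se <- sqrt(var_m1 / (m1 + pseudo)^2 + var_m0 / (m0 + pseudo)^2) / log(2)
  stat <- log2fc / se
  p <- 2 * pt(-abs(stat), df = n1 + n0 - 2)
  allzero <- rowSums(m) == 0
  p[allzero] <- 1
  fc[allzero] <- 1
  log2fc[allzero] <- 0
  p[!is.finite(p)] <- 1
  fdr <- p.adjust(p, method = "BH")
  data.frame(
    gene_id = rownames(m),
    mean_case = m1, mean_control = m0,
    fc = fc, log2fc = log2fc,
    pvalue = p, fdr = fdr,
    call = classify_deg(fc, fdr, fc_up = fc_up, fc_down = fc_down,
                        max_fdr = max_fdr),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify differential expression calls
#'
#' `up` iff `fc >= fc_up` and `fdr < max_fdr`; `down` iff `fc <= fc_down`
#' and `fdr < max_fdr`; otherwise `none`. Fold-change bounds are inclusive
#' and the FDR bound is strict.
#'
#' @param fc Positive fold change(s), case/control on the linear scale.
#' @param fdr FDR value(s) in \[0, 1\].
#' @param fc_up,fc_down,max_fdr Thresholds (defaults 2, 0.5, 0.05).
#' @return Character vector in `{up, down, none}`.
#' @export
classify_deg <- function(fc, fdr, fc_up = 2, fc_down = 0.5,
                         max_fdr = 0.05) {
  if (any(fc <= 0)) stop("fold change must be positive")
  if (any(fdr < 0 | fdr > 1)) stop("fdr must lie in [0, 1]")
  out <- rep("none", length(fc))
  out[fc >= fc_up & fdr < max_fdr] <- "up"
  out[fc <= fc_down & fdr < max_fdr] <- "down"
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' qRT-PCR fold change of a target gene in case vs control, normalised to a
#' reference gene (e.g. GAPDH):
#' `2^-((Ct_target,case - Ct_ref,case) - (Ct_target,ctrl - Ct_ref,ctrl))`.
#'
#' @param ct_target_case,ct_ref_case Ct values in the case sample.
#' @param ct_target_ctrl,ct_ref_ctrl Ct values in the control sample.
#' @return Fold change (1 = no change; one extra cycle of the target in the
#'   control direction doubles it).
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  stopifnot(is.finite(ct_target_case), is.finite(ct_ref_case),
            is.finite(ct_target_ctrl), is.finite(ct_ref_ctrl))
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
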