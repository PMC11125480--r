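# Shared fixtures: a random co-expression fixture with latent-factor
# planted correlations, its brute-force cis oracle, and the 10-transcript
# toy annotation exercising every lncRNA discard rule.

# annotation + FPKM matrix; every third gene loads on a shared factor
coexpr_fixture <- function(seed, n_genes = 24, n_samples = 12) {
  ann <- random_annotation(n_genes, seed = seed + 1000)
  set.seed(seed)
  f <- rnorm(n_samples)
  vals <- t(sapply(seq_len(n_genes), function(i) {
    lam <- if (i %% 3 == 0) runif(1, 1.5, 2.5) else 0
    2^(runif(1, 2, 6) + lam * f + rnorm(n_samples, sd = 0.5))
  }))
  dimnames(vals) <- list(ann$genes$gene_id, sprintf("S%02d", 1:n_samples))
  list(ann = ann, expr = make_expr(vals),
       lnc = ann$genes$gene_id[ann$genes$biotype == "lncRNA"],
       mrna = ann$genes$gene_id[ann$genes$biotype == "protein_coding"])
}

# definitional oracle: window scan intersected with per-pair correlation
brute_cis <- function(fix, window_bp = 100000, min_r = 0.6, max_p = 0.01) {
  lv <- log2(fix$expr$values + 1)
  out <- character(0)
  for (l in fix$lnc) for (m in fix$mrna) {
    if (!(m %in% brute_window(fix$ann$genes, l, window_bp))) next
    if (sd(lv[l, ]) == 0 || sd(lv[m, ]) == 0) next
    pp <- pearson_with_p(lv[l, ], lv[m, ])
    if (abs(pp$r) > min_r && pp$pvalue <= max_p)
      out <- c(out, paste(l, m))
  }
  sort(out)
}

# 10 candidate transcripts, 3 designed to pass every rule
# (c_anti: antisense overlap allowed; c_ok1; c_ok2)
toy_ann <- function() {
  make_ann(rbind(
    gene_row("COD1", 100000, 110000, strand = "+"),
    gene_row("COD2", 500000, 510000, strand = "+"),
    gene_row("c_short", 1, 150, biotype = "candidate"),
    gene_row("c_close", 110801, 111400, biotype = "candidate"),
    gene_row("c_overlap", 105000, 105999, strand = "+",
             biotype = "candidate"),
    gene_row("c_anti", 105000, 105499, strand = "-",
             biotype = "candidate"),
    gene_row("c_vote3", 700000, 701000, biotype = "candidate"),
    gene_row("c_allcod", 750000, 750800, biotype = "candidate"),
    gene_row("c_ok1", 800000, 801500, biotype = "candidate"),
    gene_row("c_ok2", 900000, 902000, biotype = "candidate"),
    gene_row("c_combo", 510801, 510950, biotype = "candidate"),
    gene_row("c_missing", 950000, 950900, biotype = "candidate")))
}

toy_tables <- function() {
  cand <- paste0(c("c_short", "c_close", "c_overlap", "c_anti", "c_vote3",
                   "c_ok1", "c_ok2", "c_combo", "c_missing"), ".t1")
  cod <- c("COD1.t1", "COD2.t1", "c_allcod.t1")
  t_full <- function(nm) vote_table(nm, cand, cod)
  t3 <- vote_table("CNCI", setdiff(cand, c("c_vote3.t1", "c_missing.t1")),
                   c(cod, "c_vote3.t1"))
  list(t_full("CPC2"), t_full("LGC"), t3, t_full("CPAT"))
}
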