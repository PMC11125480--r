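# Independent reference implementations used as oracles. These are kept
# deliberately naive (enumeration, literal textbook steps) and separate
# from the package code paths they check.

# literal Benjamini-Hochberg step-up
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# exact hypergeometric upper tail by integer combinatorics (exact in
# doubles for N <= 25 since all binomials are < 2^53)
hyper_exact <- function(N, K, n, k) {
  if (k <= 0) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# all permutations of 1..n (n <= 7)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

# exhaustive two-sided permutation p-value for the Pearson correlation
perm_pvalue <- function(x, y) {
  P <- all_perms(length(x))
  r0 <- abs(cor(x, y))
  rs <- abs(apply(P, 1, function(p) cor(x, y[p])))
  mean(rs >= r0 - 1e-12)
}

# brute-force window query over a plain gene table
brute_window <- function(genes, anchor, window_bp) {
  a <- genes[genes$gene_id == anchor, ]
  hit <- genes$chrom == a$chrom & genes$gene_id != a$gene_id &
    genes$start <= a$end + window_bp & genes$end >= a$start - window_bp
  sort(genes$gene_id[hit])
}

# simple annotation builder: one single-exon transcript per gene unless a
# tx_len below the span width is given (then a 2-exon transcript)
make_ann <- function(genes, tx_len = NULL) {
  exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    tl <- if (is.null(tx_len)) NA else tx_len[i]
    span <- g$end - g$start + 1
    if (is.na(tl) || tl >= span) {
      data.frame(transcript_id = paste0(g$gene_id, ".t1"),
                 gene_id = g$gene_id, chrom = g$chrom,
                 start = g$start, end = g$end, strand = g$strand)
    } else {
      half <- tl %/% 2
      data.frame(transcript_id = paste0(g$gene_id, ".t1"),
                 gene_id = g$gene_id, chrom = g$chrom,
                 start = c(g$start, g$end - (tl - half) + 1),
                 end = c(g$start + half - 1, g$end),
                 strand = g$strand)
    }
  }))
  tl <- tapply(exons$end - exons$start + 1, exons$transcript_id, sum)
  transcripts <- data.frame(
    transcript_id = names(tl),
    gene_id = sub("\\.t1$", "", names(tl)),
    length_nt = as.integer(tl), stringsAsFactors = FALSE)
  genes$exon_length <- as.integer(tl[paste0(genes$gene_id, ".t1")])
  annotation_set(genes, transcripts, exons)
}

gene_row <- function(gene_id, start, end, chrom = "chr1", strand = "+",
                     biotype = "protein_coding") {
  data.frame(gene_id = gene_id, chrom = chrom, start = start, end = end,
             strand = strand, biotype = biotype, stringsAsFactors = FALSE)
}

# random annotation on 1-2 chromosomes for property tests
random_annotation <- function(n_genes, seed) {
  set.seed(seed)
  chrom <- sample(c("chr1", "chr2"), n_genes, replace = TRUE)
  start <- sample.int(3e6, n_genes)
  width <- sample(200:20000, n_genes, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = chrom, start = start, end = start + width - 1,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    biotype = sample(c("protein_coding", "lncRNA"), n_genes,
                     replace = TRUE),
    stringsAsFactors = FALSE)
  make_ann(genes)
}

make_expr <- function(values, n_case = NULL, unit = "fpkm") {
  ns <- ncol(values)
  if (is.null(n_case)) n_case <- ceiling(ns / 2)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%02d", seq_len(ns))
  groups <- setNames(rep(c("case", "control"), c(n_case, ns - n_case)),
                     colnames(values))
  expression_matrix(values, groups, unit = unit)
}

# tool table voting "noncoding" for ids in nc, "coding" for ids in cod
vote_table <- function(name, nc, cod = character(0)) {
  tool_call_table(name, setNames(c(rep("noncoding", length(nc)),
                                   rep("coding", length(cod))),
                                 c(nc, cod)))
}
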