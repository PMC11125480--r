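fpkm_ann <- function(lens) {
  n <- length(lens)
  starts <- cumsum(c(1, rep(1e6, n - 1)))
  make_ann(do.call(rbind, lapply(seq_len(n), function(i)
    gene_row(names(lens)[i], starts[i], starts[i] + lens[i] - 1))))
}

test_that("FPKM follows counts * 1e9 / (length * library size)", {
  ann <- fpkm_ann(c(g1 = 1000L, g2 = 2500L))
  counts <- make_expr(matrix(c(10, 7, 0, 7, 10, 0, 10, 7, 0, 10, 7, 0),
                             nrow = 2, dimnames = list(c("g1", "g2"),
                                                       NULL))[, 1:4],
                      unit = "counts")
  libs <- setNames(c(1e6, 2e7, 1e6, 2e7), colnames(counts$values))
  fpkm <- compute_fpkm(counts, ann, libs)
  expect_equal(fpkm$values["g1", 1], 10)           # unit-scale case
  expect_equal(fpkm$values["g2", 2], 0.14)          # 7e9/(2500*2e7)
  expect_equal(fpkm$unit, "fpkm")
  zero <- counts; zero$values[] <- 0
  expect_true(all(compute_fpkm(zero, ann, libs)$values == 0))
})

test_that("FPKM is linear in counts and inverse in length and library size", {
  set.seed(9)
  lens <- setNames(sample(500:5000, 6), sprintf("g%d", 1:6))
  ann <- fpkm_ann(lens)
  m <- matrix(rpois(24, 50), nrow = 6,
              dimnames = list(names(lens), sprintf("S%02d", 1:4)))
  libs <- setNames(runif(4, 1e6, 5e6), colnames(m))
  f1 <- compute_fpkm(make_expr(m, unit = "counts"), ann, libs)$values
  f2 <- compute_fpkm(make_expr(3 * m, unit = "counts"), ann, libs)$values
  expect_equal(f2, 3 * f1)
  f3 <- compute_fpkm(make_expr(m, unit = "counts"), ann, 2 * libs)$values
  expect_equal(f3, f1 / 2)
  expect_equal(f1, m * 1e9 / (lens %o% libs))
})

test_that("FPKM errors name missing genes and reject zero library sizes", {
  ann <- fpkm_ann(c(g1 = 1000L))
  counts <- make_expr(matrix(1, 2, 4, dimnames = list(c("g1", "gX"), NULL)),
                      unit = "counts")
  expect_error(compute_fpkm(counts, ann), "gX")
  counts2 <- make_expr(matrix(1, 1, 4, dimnames = list("g1", NULL)),
                       unit = "counts")
  libs <- setNames(c(0, 1, 1, 1), colnames(counts2$values))
  expect_error(compute_fpkm(counts2, ann, libs), "positive")
})

test_that("detected genes require FPKM > 0 in at least one sample", {
  m <- matrix(c(0, 0, 0, 0,
                0, 0, 2.5, 0,
                1, 2, 3, 4), nrow = 3, byrow = TRUE,
              dimnames = list(c("zero", "once", "always"), NULL))
  expect_setequal(detected_genes(make_expr(m)), c("once", "always"))
  empty <- make_expr(matrix(0, 0, 4, dimnames = list(character(0), NULL)))
  expect_length(detected_genes(empty), 0)
})

test_that("DEG classification uses inclusive FC and strict FDR bounds", {
  expect_equal(classify_deg(2.5, 0.01), "up")
  expect_equal(classify_deg(0.4, 0.04), "down")
  expect_equal(classify_deg(1.5, 0.001), "none")
  expect_equal(classify_deg(2.0, 0.05), "none")   # FDR bound is strict
  expect_equal(classify_deg(2.0, 0.049), "up")    # FC bound is inclusive
  expect_equal(classify_deg(0.5, 0.049), "down")
  expect_equal(classify_deg(c(3, 0.2, 1), c(0.01, 0.01, 0.01)),
               c("up", "down", "none"))
  expect_error(classify_deg(-1, 0.01), "positive")
})

test_that("ddCt fold change doubles per cycle of relative shift", {
  expect_equal(ddct_fold_change(22, 20, 24, 21), 2)    # ddCt = -1
  expect_equal(ddct_fold_change(25, 20, 25, 20), 1)
  expect_equal(ddct_fold_change(24, 20, 22, 20), 0.25) # ddCt = +2
})

test_that("degenerate genes and groups are handled in the NB test", {
  m <- matrix(5, nrow = 3, ncol = 9,
              dimnames = list(c("flat", "zero", "var"), NULL))
  m["zero", ] <- 0
  set.seed(4); m["var", ] <- rpois(9, 40)
  de <- differential_expression(make_expr(m, n_case = 5, unit = "counts"))
  expect_gt(de$pvalue[de$gene_id == "flat"], 0.9)
  expect_equal(de$call[de$gene_id == "flat"], "none")
  expect_equal(de$pvalue[de$gene_id == "zero"], 1)
  expect_equal(de$fc[de$gene_id == "zero"], 1)
  one_per_group <- make_expr(m[, 1:3], n_case = 1, unit = "counts")
  expect_error(differential_expression(one_per_group), "at least 2")
})

test_that("the NB test is invariant to sample order and global count scale", {
  set.seed(21)
  m <- matrix(rnbinom(200 * 9, mu = 80, size = 10), nrow = 200,
              dimnames = list(sprintf("g%03d", 1:200),
                              sprintf("S%02d", 1:9)))
  de1 <- differential_expression(make_expr(m, n_case = 5, unit = "counts"))
  perm <- c(3, 1, 5, 2, 4, 8, 9, 6, 7)  # permutes within groups
  de2 <- differential_expression(
    expression_matrix(m[, perm],
                      setNames(rep(c("case", "control"), c(5, 4)),
                               colnames(m))[perm], unit = "counts"))
  expect_equal(de2$pvalue, de1$pvalue, tolerance = 1e-12)
  # doubling every count leaves normalised ratios essentially unchanged
  # (the pseudo-count on group means gives a sub-percent wobble)
  de3 <- differential_expression(make_expr(2 * m, n_case = 5,
                                           unit = "counts"))
  expect_equal(de3$log2fc, de1$log2fc, tolerance = 0.02)
  expect_gt(cor(de3$pvalue, de1$pvalue), 0.999)
})

test_that("type-I error is near nominal and BH calls nest in raw calls", {
  set.seed(77)
  G <- 2000
  mu <- exp(rnorm(G, log(100), 1))
  m <- matrix(rnbinom(G * 9, mu = rep(mu, 9), size = 10), nrow = G,
              dimnames = list(sprintf("g%04d", 1:G),
                              sprintf("S%02d", 1:9)))
  de <- differential_expression(make_expr(m, n_case = 5, unit = "counts"))
  frac <- mean(de$pvalue < 0.05)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
  expect_true(all(de$gene_id[de$fdr < 0.05] %in%
                  de$gene_id[de$pvalue < 0.05]))
})

test_that("planted four-fold changes are detected with high power", {
  set.seed(88)
  G <- 1000; nde <- 100
  mu <- rep(100, G)
  m <- matrix(rnbinom(G * 9, mu = rep(mu, 9), size = 1 / 0.05), nrow = G)
  dimnames(m) <- list(sprintf("g%04d", 1:G), sprintf("S%02d", 1:9))
  m[1:nde, 1:5] <- rnbinom(nde * 5, mu = 400, size = 1 / 0.05)
  de <- differential_expression(make_expr(m, n_case = 5, unit = "counts"))
  expect_gte(mean(de$call[1:nde] == "up"), 0.9)
})

test_that("log2FC estimates agree with DESeq2 on planted signal", {
  skip_if_not_installed("DESeq2")
  set.seed(13)
  G <- 300
  mu <- exp(rnorm(G, log(120), 0.8))
  fc <- rep(1, G); fc[1:30] <- 4; fc[31:60] <- 0.25
  m <- sapply(1:9, function(j) {
    f <- if (j <= 5) fc else 1
    rnbinom(G, mu = mu * f, size = 10)
  })
  dimnames(m) <- list(sprintf("g%03d", 1:G), sprintf("S%02d", 1:9))
  mine <- differential_expression(make_expr(m, n_case = 5,
                                            unit = "counts"))
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = round(m),
    colData = data.frame(condition = factor(
      rep(c("case", "control"), c(5, 4)), levels = c("control", "case"))),
    design = ~condition)
  res <- DESeq2::results(suppressMessages(DESeq2::DESeq(dds, quiet = TRUE)))
  expect_gt(cor(mine$log2fc, res$log2FoldChange, use = "complete.obs"),
            0.99)
  ds_sig <- !is.na(res$padj) & res$padj < 0.05 &
    abs(res$log2FoldChange) >= 1
  my_sig <- mine$call != "none"
  expect_gt(sum(ds_sig & my_sig) / sum(ds_sig | my_sig), 0.75)
})
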