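test_that("pearson_with_p handles exact, reversed and degenerate input", {
  x <- c(1, 4, 2, 8)
  expect_equal(pearson_with_p(x, x), list(r = 1, pvalue = 0, n = 4))
  expect_equal(pearson_with_p(c(1, 2, 3), c(3, 2, 1))$r, -1)
  expect_equal(pearson_with_p(c(1, 2, 3), c(3, 2, 1))$pvalue, 0)
  expect_error(pearson_with_p(c(1, 2), c(3, 4)), "at least 3")
  expect_error(pearson_with_p(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson_with_p(1:4, 1:3), "equal length")
})

test_that("closed-form p matches cor.test to 1e-10 on random vectors", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- pearson_with_p(x, y)
    ref <- cor.test(x, y)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
    expect_lt(abs(got$pvalue - ref$p.value), 1e-10)
  }
})

test_that("the t approximation tracks the exhaustive permutation oracle", {
  # the permutation p is discrete (granularity 1/n!), so the worst-case
  # deviation of the closed-form p shrinks as n grows; bands reflect the
  # measured discreteness at each n
  band <- c(`3` = 0.40, `4` = 0.52, `5` = 0.32, `6` = 0.25)
  set.seed(55)
  for (n in 3:6) {
    diffs <- replicate(40, {
      x <- rnorm(n); y <- rnorm(n)
      abs(pearson_with_p(x, y)$pvalue - perm_pvalue(x, y))
    })
    expect_lt(max(diffs), band[as.character(n)])
    expect_lt(mean(diffs), 0.12)
  }
  # worked 4-point case: r = 0.8, permutation p = 8/24
  x <- 1:4; y <- c(1, 3, 2, 4)
  pp <- pearson_with_p(x, y)
  expect_equal(pp$r, 0.8, tolerance = 1e-12)
  expect_equal(perm_pvalue(x, y), 1 / 3, tolerance = 1e-12)
  expect_lt(abs(pp$pvalue - 1 / 3), 5 / 24)
})

test_that("at n = 9 the p cutoff dominates the cis correlation cutoff", {
  tcrit <- qt(1 - 0.01 / 2, df = 7)
  r_implied <- tcrit / sqrt(tcrit^2 + 7)
  expect_gt(r_implied, 0.6)
  x <- seq_len(9)
  # a pair at exactly |r| slightly above 0.6 still fails p <= 0.01
  r <- 0.62
  p <- 2 * pt(-abs(r) * sqrt(7 / (1 - r^2)), df = 7)
  expect_gt(p, 0.01)
})

test_that("co-expression screening applies thresholds and strictness", {
  set.seed(7)
  f <- rnorm(20)
  a <- 2^(4 + 2 * f + rnorm(20, sd = 0.3))
  b <- 2^(5 + 2 * f + rnorm(20, sd = 0.3))
  c_ <- 2^(runif(20, 2, 6))
  vals <- rbind(A = a, B = b, C = c_)
  colnames(vals) <- sprintf("S%02d", 1:20)
  expr <- make_expr(vals)
  got <- coexpression_pairs(expr, "A", c("B", "C"), min_abs_r = 0.8,
                            max_p = 0.01, r_strict = FALSE)
  expect_equal(got$gene_b, "B")   # planted latent-factor pair only
  expect_gt(abs(got$r), 0.8)
  # exact collinearity is the only way past min_abs_r = 1 (inclusive)
  vals2 <- rbind(A = 1:10, B = 2 * (1:10), C = (1:10)^2)
  colnames(vals2) <- sprintf("S%02d", 1:10)
  got2 <- coexpression_pairs(make_expr(vals2), "A", c("B", "C"),
                             min_abs_r = 1, max_p = 1, r_strict = FALSE,
                             transform = "none")
  expect_equal(got2$gene_b, "B")
  got3 <- coexpression_pairs(make_expr(vals2), "A", c("B", "C"),
                             min_abs_r = 1, max_p = 1, r_strict = TRUE,
                             transform = "none")
  expect_equal(nrow(got3), 0L)
  # constant genes are skipped with a message
  vals3 <- rbind(A = 1:10, B = rep(3, 10))
  colnames(vals3) <- sprintf("S%02d", 1:10)
  expect_message(
    out <- coexpression_pairs(make_expr(vals3), "A", "B", 0, 1),
    "constant")
  expect_equal(nrow(out), 0L)
  expect_equal(nrow(coexpression_pairs(expr, character(0), "B", 0.5,
                                       0.05)), 0L)
})

test_that("cis targets are exactly co-location intersected with co-expression", {
  for (seed in 1:20) {
    fix <- coexpr_fixture(seed)
    got <- cis_targets(fix$lnc, fix$mrna, fix$ann, fix$expr)
    expect_equal(sort(paste(got$lncrna, got$target)), brute_cis(fix))
  }
})

test_that("cis calling needs both proximity and correlation", {
  f <- local({ set.seed(3); rnorm(16) })
  noise <- local({ set.seed(4); matrix(rnorm(4 * 16, sd = 0.3), 4) })
  vals <- 2^rbind(4 + 2 * f + noise[1, ], 5 + 2 * f + noise[2, ],
                  4 + noise[3, ] * 4, 5 + 2 * f + noise[4, ])
  rownames(vals) <- c("LNC1", "NEAR_COR", "NEAR_UNCOR", "FAR_COR")
  colnames(vals) <- sprintf("S%02d", 1:16)
  ann <- make_ann(rbind(
    gene_row("LNC1", 200000, 202000, biotype = "lncRNA"),
    gene_row("NEAR_COR", 150000, 160000),
    gene_row("NEAR_UNCOR", 240000, 250000),
    gene_row("FAR_COR", 700000, 710000)))
  got <- cis_targets("LNC1", c("NEAR_COR", "NEAR_UNCOR", "FAR_COR"),
                     ann, make_expr(vals))
  expect_equal(got$target, "NEAR_COR")
})

test_that("TF filtering restricts targets to the catalogue", {
  edges <- data.frame(lncrna = c("L1", "L1", "L2"),
                      target = c("TFA", "GENE1", "TFB"),
                      r = c(0.9, 0.8, -0.95), pvalue = c(0.001, 0.002,
                                                         0.001),
                      n = 9L)
  got <- filter_tfs(edges, c("TFA", "TFB"))
  expect_setequal(got$tf, c("TFA", "TFB"))
  expect_equal(nrow(filter_tfs(edges, "ZZZ")), 0L)
  expect_equal(nrow(filter_tfs(edges, unique(edges$target))), 3L)
  expect_error(filter_tfs(edges, character(0)), "empty")
})

test_that("TF-DEG pairs require correlation and database support", {
  set.seed(11)
  f <- rnorm(20)
  vals <- 2^rbind(TF1 = 5 + 2 * f + rnorm(20, sd = 0.3),
                  IN_DB = 4 + 2 * f + rnorm(20, sd = 0.3),
                  NO_DB = 6 + 2 * f + rnorm(20, sd = 0.3),
                  DB_UNCOR = 5 + rnorm(20, sd = 2))
  colnames(vals) <- sprintf("S%02d", 1:20)
  db <- data.frame(tf = c("TF1", "TF1", "TF1"),
                   target = c("IN_DB", "DB_UNCOR", "IN_DB"),
                   source_db = c("TRRUST", "ENCODE", "TFTG"))
  got <- tf_deg_pairs("TF1", c("IN_DB", "NO_DB", "DB_UNCOR"),
                      make_expr(vals), db)
  expect_equal(got$target, "IN_DB")
  expect_equal(got$db_sources, "TFTG,TRRUST")
  # two-source requirement
  got2 <- tf_deg_pairs("TF1", c("IN_DB", "NO_DB", "DB_UNCOR"),
                       make_expr(vals), db, min_sources = 2)
  expect_equal(got2$target, "IN_DB")
  # no database: correlation alone decides
  got3 <- tf_deg_pairs("TF1", c("IN_DB", "NO_DB", "DB_UNCOR"),
                       make_expr(vals), NULL)
  expect_setequal(got3$target, c("IN_DB", "NO_DB"))
})

test_that("triples join cis and TF-tier edges through the shared TF", {
  cis <- data.frame(lncrna = "L1", tf = "TF1", r = 0.9, pvalue = 1e-4)
  tfe <- data.frame(tf = c("TF1", "TF1"), target = c("G1", "G2"),
                    r = c(0.85, -0.9), pvalue = c(1e-3, 1e-4),
                    db_sources = "TRRUST")
  net <- build_network(cis, tfe)
  expect_equal(nrow(net$triples), 2L)
  expect_setequal(net$triples$target, c("G1", "G2"))
  expect_equal(igraph::vcount(net$graph), 4L)
  vt <- igraph::V(net$graph)$type
  expect_equal(as.vector(table(vt)[c("DEG", "TF", "lncRNA")]),
               c(2L, 1L, 1L))
  none <- build_network(cis, data.frame(tf = "TFX", target = "G1",
                                        r = 0.9, pvalue = 1e-3,
                                        db_sources = ""))
  expect_equal(nrow(none$triples), 0L)
})

test_that("tightening any threshold never adds an edge", {
  for (seed in 1:10) {
    fix <- coexpr_fixture(seed + 100)
    base <- cis_targets(fix$lnc, fix$mrna, fix$ann, fix$expr,
                        window_bp = 150000, min_abs_r = 0.5, max_p = 0.05)
    key <- function(d) paste(d$lncrna, d$target)
    for (args in list(list(min_abs_r = 0.8), list(max_p = 0.01),
                      list(window_bp = 20000),
                      list(min_abs_r = 0.9, max_p = 0.005,
                           window_bp = 10000))) {
      tight <- do.call(cis_targets,
                       c(list(fix$lnc, fix$mrna, fix$ann, fix$expr),
                         utils::modifyList(list(window_bp = 150000,
                                                min_abs_r = 0.5,
                                                max_p = 0.05), args)))
      expect_true(all(key(tight) %in% key(base)))
    }
    loose <- cis_targets(fix$lnc, fix$mrna, fix$ann, fix$expr,
                         window_bp = 500000, min_abs_r = 0.3, max_p = 0.2)
    expect_true(all(key(base) %in% key(loose)))
  }
})

test_that("network export writes a parsable edge table and GraphML", {
  cis <- data.frame(lncrna = "L1", tf = "TF1", r = 0.9, pvalue = 1e-4)
  tfe <- data.frame(tf = "TF1", target = "G1", r = 0.85, pvalue = 1e-3,
                    db_sources = "TRRUST")
  net <- build_network(cis, tfe)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, tsv = tsv, graphml = gml)
  back <- read.delim(tsv)
  expect_equal(back$lncrna, "L1")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
})
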