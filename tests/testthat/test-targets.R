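mk_lnc_tx <- function(id, chrom, start, end) {
  data.frame(transcript_id = id, gene_id = id, chrom = chrom,
             strand = "+", n_exons = 2L, spliced_length = 400L,
             span_start = start, span_end = end, stringsAsFactors = FALSE)
}

mk_gene_ann <- function(ids, chrom, starts, ends, strand = "+") {
  rows <- do.call(rbind, lapply(seq_along(ids), function(i)
    data.frame(chrom = chrom, start = starts[i], end = ends[i],
               strand = strand, gene_id = ids[i],
               transcript_id = paste0(ids[i], ".t1"))))
  annotation(rows)
}

test_that("cis window is boundary-inclusive on the gap between spans", {
  lnc <- mk_lnc_tx("L1", "c1", 500000L, 501000L)
  genes <- mk_gene_ann(c("gIn", "gEdge", "gOut", "gOverlap", "gLeft"),
                       "c1",
                       starts = c(601000L, 601001L, 601002L, 500500L,
                                  399000L),
                       ends = c(602000L, 602001L, 602002L, 500600L,
                                399999L))
  ct <- find_cis_targets(lnc, genes, window = 100000L)
  # gIn: gap 601000 - 501000 - 1 = 99,999; gEdge: exactly 100,000
  expect_setequal(ct$gene_id, c("gIn", "gEdge", "gOverlap", "gLeft"))
  expect_equal(ct$distance[ct$gene_id == "gIn"], 99999L)
  expect_equal(ct$distance[ct$gene_id == "gEdge"], 100000L)
  expect_equal(ct$side[ct$gene_id == "gEdge"], "downstream")
  expect_equal(ct$distance[ct$gene_id == "gOverlap"], 0L)
  expect_equal(ct$side[ct$gene_id == "gOverlap"], "overlapping")
  expect_equal(ct$distance[ct$gene_id == "gLeft"], -100000L)
  expect_equal(ct$side[ct$gene_id == "gLeft"], "upstream")
})

test_that("cis search matches an all-pairs scan and grows with the window", {
  set.seed(31)
  n <- 30
  gstart <- sample.int(900000L, n)
  genes <- mk_gene_ann(sprintf("g%02d", 1:n), "c1", gstart,
                       gstart + sample(500:5000, n, replace = TRUE))
  lstart <- sample.int(900000L, 8)
  lncs <- do.call(rbind, lapply(1:8, function(i)
    mk_lnc_tx(sprintf("L%d", i), "c1", lstart[i], lstart[i] + 800L)))
  for (w in c(20000L, 100000L)) {
    ct <- find_cis_targets(lncs, genes, window = w)
    got <- paste(ct$lncRNA_id, ct$gene_id)
    want <- character(0)
    gd <- genes$genes
    for (i in seq_len(nrow(lncs))) for (j in seq_len(nrow(gd))) {
      gap <- if (gd$span_start[j] > lncs$span_end[i])
        gd$span_start[j] - lncs$span_end[i] - 1L
      else if (gd$span_end[j] < lncs$span_start[i])
        lncs$span_start[i] - gd$span_end[j] - 1L
      else 0L
      if (gap <= w)
        want <- c(want, paste(lncs$transcript_id[i], gd$gene_id[j]))
    }
    expect_setequal(got, want)
  }
  small <- find_cis_targets(lncs, genes, window = 20000L)
  large <- find_cis_targets(lncs, genes, window = 100000L)
  expect_true(all(paste(small$lncRNA_id, small$gene_id) %in%
                    paste(large$lncRNA_id, large$gene_id)))
})

test_that("pearson_with_p gives the classical t-based p-value", {
  x <- c(1, 2, 3, 4, 5)
  res <- pearson_with_p(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_equal(res$p_value, 0)
  res2 <- pearson_with_p(x, -3 * x + 10)
  expect_equal(res2$r, -1)
  expect_equal(res2$p_value, 0)
  expect_error(pearson_with_p(x, rep(2, 5)), "zero variance")

  # engineered pair with r = 0.95 exactly at n = 5
  xc <- x - mean(x)
  e <- c(1, -1, 0, 1, -1)
  e <- e - mean(e)
  e <- e - sum(e * xc) / sum(xc^2) * xc   # orthogonal to x
  y <- 0.95 * xc / sd(xc) + sqrt(1 - 0.95^2) * e / sd(e)
  res3 <- pearson_with_p(x, y)
  expect_equal(res3$r, 0.95, tolerance = 1e-12)
  # numeric t-CDF oracle by quadrature of the t density
  tstat <- 0.95 * sqrt(3) / sqrt(1 - 0.95^2)
  p_oracle <- 2 * integrate(function(u) dt(u, df = 3), tstat, Inf,
                            rel.tol = 1e-12)$value
  expect_equal(res3$p_value, p_oracle, tolerance = 1e-10)
  expect_equal(signif(res3$p_value, 3), 0.0133)
  # cor.test agreement
  ct <- cor.test(x, y)
  expect_equal(res3$p_value, ct$p.value, tolerance = 1e-12)
})

test_that("pearson_with_p is symmetric and affine-invariant", {
  set.seed(17)
  for (k in 1:20) {
    x <- rnorm(5)
    y <- rnorm(5)
    a <- pearson_with_p(x, y)
    b <- pearson_with_p(y, x)
    expect_equal(a$r, b$r)
    expect_equal(a$p_value, b$p_value)
    c_ <- pearson_with_p(3 * x - 2, y)
    expect_equal(c_$r, a$r, tolerance = 1e-12)
  }
})

test_that("analytic p ranks pairs like the exact permutation null at n = 5", {
  set.seed(23)
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  stopifnot(nrow(perms) == 120)
  p_an <- p_perm <- numeric(60)
  for (k in 1:60) {
    x <- rnorm(5)
    y <- rnorm(5)
    res <- pearson_with_p(x, y)
    p_an[k] <- res$p_value
    r_perm <- apply(perms, 1, function(ix) cor(x, y[ix]))
    p_perm[k] <- mean(abs(r_perm) >= abs(res$r) - 1e-12)
  }
  expect_gt(cor(rank(p_an), rank(p_perm)), 0.95)
})

test_that("trans targets apply strict thresholds and record skips", {
  expr_l <- rbind(L1 = c(1, 2, 3, 4, 5), Lflat = rep(2, 5))
  expr_g <- rbind(gPos = c(2, 4, 6, 8, 10.2), gNeg = c(10, 8, 6.1, 4, 2),
                  gNoise = c(5, 1, 4, 2, 3))
  colnames(expr_l) <- colnames(expr_g) <- paste0("s", 1:5)
  expect_warning(tt <- find_trans_targets(expr_l, expr_g), "zero variance")
  expect_setequal(tt$gene_id, c("gPos", "gNeg"))
  expect_equal(tt$sign[tt$gene_id == "gPos"], "positive")
  expect_equal(tt$sign[tt$gene_id == "gNeg"], "negative")
  expect_equal(attr(tt, "n_skipped"), 3L)
  expect_equal(attr(tt, "n_positive"), 1L)
  # empty gene set
  empty <- find_trans_targets(expr_l, expr_g[0, , drop = FALSE])
  expect_equal(nrow(empty), 0L)
})

test_that("independent feature pairs are rarely called trans targets", {
  set.seed(41)
  n <- 1500
  hits <- 0
  for (k in seq_len(n)) {
    x <- rnbinom(5, size = 10, mu = 100)
    y <- rnbinom(5, size = 10, mu = 100)
    if (sd(x) == 0 || sd(y) == 0) next
    res <- pearson_with_p(x, y)
    if (abs(res$r) > 0.95 && res$p_value < 0.05) hits <- hits + 1
  }
  expect_lt(hits / n, 0.05)
})

test_that("planted trans pairs are recovered from the default bundle", {
  b <- default_bundle()
  gt <- b$ground_truth
  fpkm <- bundle_fpkm(b)
  known_tx <- b$known$transcripts
  gene_fpkm <- rowsum(fpkm[known_tx$transcript_id, , drop = FALSE],
                      known_tx$gene_id)
  del_ids <- gt$de$feature_id[gt$de$type == "lncRNA"]
  deg_gene <- gt$de$gene_id[gt$de$type == "gene"]
  tt <- suppressWarnings(find_trans_targets(
    fpkm[del_ids, , drop = FALSE],
    gene_fpkm[deg_gene, , drop = FALSE]))
  planted <- paste(gt$trans_pairs$lncRNA_id, gt$trans_pairs$gene_id)
  called <- paste(tt$lncRNA_id, tt$gene_id)
  expect_gte(mean(planted %in% called), 0.9)
  # planted pairs share the hub's DE sign: recovered ones are positive
  sgn <- tt$sign[match(intersect(planted, called), called)]
  expect_true(all(sgn == "positive"))
})

test_that("cis/trans overlap is a plain set intersection", {
  cis <- data.frame(lncRNA_id = "L", gene_id = c("a", "b", "c", "c"))
  trans <- data.frame(lncRNA_id = "L", gene_id = c("c", "d"))
  expect_equal(overlap_cis_trans(cis, trans), "c")
  expect_equal(overlap_cis_trans(cis, trans[0, , drop = FALSE]),
               character(0))
  expect_equal(overlap_cis_trans(cis, cis), c("a", "b", "c"))
  tri <- data.frame(lncRNA_id = "L",
                    gene_id = c("a", "b", "c", "x", "y"))
  expect_equal(overlap_cis_trans(cis, tri), c("a", "b", "c"))
})
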