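test_that("compute_fpkm implements the FPKM formula and is linear", {
  counts <- matrix(c(100, 0), 2, 1,
                   dimnames = list(c("a", "b"), "s1"))
  fp <- compute_fpkm(counts, c(a = 2000, b = 500), c(s1 = 5e6))
  expect_equal(fp["a", "s1"], 10.0)
  expect_equal(fp["b", "s1"], 0.0)
  # doubling the library size halves every FPKM
  fp2 <- compute_fpkm(counts, c(a = 2000, b = 500), c(s1 = 1e7))
  expect_equal(fp2, fp / 2)
  # linearity in counts
  fp3 <- compute_fpkm(3 * counts, c(a = 2000, b = 500), c(s1 = 5e6))
  expect_equal(fp3, 3 * fp)
  expect_error(compute_fpkm(counts, c(a = 0, b = 500), c(s1 = 5e6)), "> 0")
  expect_error(compute_fpkm(counts, c(a = 2000, b = 500), c(s1 = 0)), "> 0")
})

test_that("library summary reproduces the study's mapping arithmetic", {
  qc <- read.delim(system.file("extdata", "library_qc.tsv",
                               package = "lnclact"))
  sm <- summarize_libraries(qc)
  ps <- sm$per_sample
  expect_equal(ps$mapped_pct[ps$sample == "DP1"], 86.27)
  expect_equal(ps$mapped_pct,
               c(86.27, 86.32, 83.79, 86.48, 85.76))
  expect_equal(ps$unique_pct,
               c(79.06, 79.14, 77.09, 78.26, 79.88))
  expect_equal(sm$total_clean_million, 784.05)
  gt <- sm$group_totals
  expect_equal(gt$raw_million[gt$group == "DP"], 503.07)
  expect_equal(gt$raw_million[gt$group == "LP"], 299.23)
  # mapped == clean gives 100.00%
  qc2 <- qc
  qc2$total_mapped[1] <- qc2$clean_reads[1]
  expect_equal(summarize_libraries(qc2)$per_sample$mapped_pct[1], 100.00)
  # mapped > clean is a validation error
  qc3 <- qc
  qc3$total_mapped[2] <- qc3$clean_reads[2] + 1
  expect_error(summarize_libraries(qc3), "DP2")
})

test_that("dispersion estimation recovers phi and hits the Poisson floor", {
  grp <- factor(c("LP", "LP", "DP", "DP", "DP"), levels = c("LP", "DP"))
  lib <- rep(2e7, 5)
  set.seed(42)
  mu <- exp(rnorm(2000, log(100), 0.7))
  y <- matrix(rnbinom(2000 * 5, size = 1 / 0.1, mu = rep(mu, 5)), 2000, 5)
  est <- estimate_common_dispersion(y, grp, lib)
  expect_gte(est$phi, 0.05)
  expect_lte(est$phi, 0.2)
  # independent qCML implementation agrees closely
  dg <- edgeR::estimateCommonDisp(edgeR::DGEList(counts = y, group = grp))
  expect_lt(abs(est$phi - dg$common.dispersion), 0.01)

  yp <- matrix(rpois(2000 * 5, rep(mu, 5)), 2000, 5)
  expect_lt(estimate_common_dispersion(yp, grp, lib)$phi, 0.02)

  # identical counts in every sample: no overdispersion
  yc <- matrix(rep(c(5, 17, 40), 5), 3, 5)
  expect_equal(estimate_common_dispersion(yc, grp, lib)$phi, 0)
  expect_error(estimate_common_dispersion(matrix(0, 3, 5), grp, lib),
               "all-zero")
})

test_that("exact test reduces to the binomial in the Poisson 1-vs-1 limit", {
  grp <- factor(c("A", "B"))
  p <- nb_exact_test(c(0, 10), grp, c(1e6, 1e6), phi = 0)
  expect_equal(p, 2 * 0.5^10, tolerance = 1e-12)
  # modal split on a symmetric null has p = 1
  expect_equal(nb_exact_test(c(7, 7), grp, c(1e6, 1e6), phi = 0), 1)
  # S = 0 returns 1 by convention
  expect_equal(nb_exact_test(c(0, 0), grp, c(1e6, 1e6), phi = 0.1), 1)
})

test_that("exact test agrees with the convolution oracle on random cases", {
  grp <- factor(c("LP", "LP", "DP", "DP", "DP"), levels = c("LP", "DP"))
  lib <- rep(1e6, 5)
  set.seed(7)
  for (k in 1:60) {
    phi <- sample(c(0, 0.1, 0.5), 1)
    S <- sample.int(30, 1)
    a <- sample(0:S, 1)
    p <- nb_exact_test(split_counts(a, S), grp, lib, phi)
    expect_equal(p, oracle_exact_p(a, S, phi, 2, 3), tolerance = 1e-10)
  }
})

test_that("conditional null from full joint enumeration matches the test", {
  # every composition of S = 12 over 5 samples, joint NB likelihood,
  # aggregated to the group-sum distribution -- fully independent route
  S <- 12
  grp <- factor(c("LP", "LP", "DP", "DP", "DP"), levels = c("LP", "DP"))
  comp <- expand.grid(y1 = 0:S, y2 = 0:S, y3 = 0:S, y4 = 0:S)
  comp <- comp[rowSums(comp) <= S, ]
  comp$y5 <- S - rowSums(comp)
  for (phi in c(0.1, 0.5)) {
    jp <- apply(comp, 1, function(y)
      prod(dnbinom(y, size = 1 / phi, mu = 2.7)))
    a_of <- comp$y1 + comp$y2
    dist <- vapply(0:S, function(a) sum(jp[a_of == a]), 0)
    dist <- dist / sum(dist)
    for (a in 0:S) {
      p_exp <- sum(dist[dist <= dist[a + 1] * (1 + 1e-12)])
      p_got <- nb_exact_test(split_counts(a, S), grp, rep(1e6, 5), phi)
      expect_equal(p_got, p_exp, tolerance = 1e-10)
    }
  }
})

test_that("exact test matches edgeR's small-p exact test feature by feature", {
  grp <- factor(c("LP", "LP", "DP", "DP", "DP"), levels = c("LP", "DP"))
  set.seed(3)
  for (k in 1:25) {
    y <- rnbinom(5, size = 10, mu = sample(c(5, 30, 120), 1))
    p_mine <- nb_exact_test(y, grp, rep(1e6, 5), phi = 0.1)
    d <- edgeR::DGEList(counts = matrix(y, 1), group = grp,
                        lib.size = rep(1e6, 5))
    p_edger <- edgeR::exactTest(d, dispersion = 0.1,
                                rejection.region = "smallp")$table$PValue
    expect_equal(p_mine, p_edger, tolerance = 1e-9)
  }
})

test_that("exact test is symmetric in group labels and monotone to the mode", {
  grp <- factor(c("LP", "LP", "DP", "DP", "DP"), levels = c("LP", "DP"))
  grp_swapped <- factor(c("DP", "DP", "LP", "LP", "LP"),
                        levels = c("LP", "DP"))
  lib <- rep(1e6, 5)
  set.seed(8)
  for (k in 1:30) {
    y <- rnbinom(5, size = 5, mu = 20)
    p1 <- nb_exact_test(y, grp, lib, 0.2)
    p2 <- nb_exact_test(y, grp_swapped, lib, 0.2)
    expect_equal(p1, p2, tolerance = 1e-12)
    expect_gt(p1, 0)
    expect_lte(p1, 1)
  }
  # higher null probability of the observed split => larger p
  S <- 25
  d <- oracle_cond_dist(S, 0.1, 2, 3)
  ps <- vapply(0:S, function(a)
    nb_exact_test(split_counts(a, S), grp, lib, 0.1), 0)
  ord <- order(d)
  expect_true(all(diff(ps[ord]) >= -1e-12))
})

test_that("null features stay below the nominal false-positive budget", {
  grp <- factor(c("LP", "LP", "DP", "DP", "DP"), levels = c("LP", "DP"))
  lib <- rep(2e7, 5)
  set.seed(13)
  y <- matrix(rnbinom(1000 * 5, size = 1 / 0.1, mu = 50), 1000, 5)
  rownames(y) <- sprintf("f%04d", 1:1000)
  de <- call_differential(y, grp, lib, phi = 0.1)
  expect_gte(mean(!de$significant), 0.93)
})

test_that("planted DE features are recalled with matching direction", {
  recalls <- dirs <- numeric(0)
  for (s in 1:5) {
    cfg <- small_config(seed = s)
    g <- generate_genome_and_annotation(cfg)
    gt <- g$ground_truth
    counts <- simulate_counts(cfg, gt)
    grp <- factor(gt$samples$group, levels = c("LP", "DP"))
    lib <- setNames(gt$samples$library_size, gt$samples$sample)
    de <- call_differential(counts[, gt$samples$sample], grp, lib)
    called <- de$feature_id[de$significant]
    planted <- gt$de$feature_id
    recalls <- c(recalls, mean(planted %in% called))
    want <- ifelse(gt$de$log2fc > 0, "up", "down")
    got <- de$direction[match(planted, de$feature_id)]
    dirs <- c(dirs, mean(got == want))
  }
  expect_gte(mean(recalls), 0.9)
  expect_gte(mean(dirs), 0.95)
})

test_that("call_differential orders output, flags by both thresholds, and
           handles empty input", {
  grp <- factor(c("LP", "LP", "DP", "DP", "DP"), levels = c("LP", "DP"))
  lib <- rep(1e6, 5)
  y <- rbind(strong = c(400, 380, 50, 55, 60),
             flat = c(100, 100, 100, 100, 100))
  de <- call_differential(y, grp, lib, phi = 0.05)
  expect_equal(de$feature_id, c("strong", "flat"))
  expect_true(de$significant[1])
  expect_false(de$significant[2])
  expect_equal(de$direction[1], "up")
  expect_true(all(de$adj_p >= de$p_value))
  expect_equal(nrow(call_differential(y[0, , drop = FALSE], grp, lib,
                                      phi = 0.1)), 0L)
})
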