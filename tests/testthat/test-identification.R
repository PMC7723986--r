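test_that("longest_orf handles canonical and degenerate cases", {
  expect_equal(longest_orf("ATGAAATAG"), 9L)
  expect_equal(longest_orf("CCCCCC"), 0L)
  expect_equal(longest_orf("ATG"), 0L)           # no stop
  expect_equal(longest_orf("atgaaataa"), 9L)     # case-insensitive
  # ORF in a non-zero frame
  expect_equal(longest_orf("CATGAAATAGCC"), 9L)
  # an N codon inside the reading frame voids the ORF
  expect_equal(longest_orf("ATGNNNTAG"), 0L)
  expect_equal(longest_orf("ATGAANTAG"), 0L)
  # ...but an ORF before the N survives
  expect_equal(longest_orf("ATGAAATAGNNN"), 9L)
})

test_that("longest_orf matches an exhaustive per-ATG scan", {
  set.seed(21)
  for (k in 1:150) {
    n <- sample(c(60:120, 1000), 1)
    s <- paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
               collapse = "")
    expect_equal(longest_orf(s), naive_orf(s), info = paste("case", k))
  }
})

test_that("coding-potential threshold is inclusive at 300 nt", {
  cfg <- filter_config()
  seq299 <- paste0("ATG", strrep("AAA", 97), "TAA", strrep("C", 50))
  expect_equal(longest_orf(seq299), 297L)
  expect_equal(score_coding_potential("t", seq299, cfg)$verdict, "noncoding")
  seq300 <- paste0("ATG", strrep("AAA", 98), "TAA", strrep("C", 50))
  expect_equal(longest_orf(seq300), 300L)
  expect_equal(score_coding_potential("t", seq300, cfg)$verdict, "coding")
})

test_that("intersection mode removes a transcript if any evidence says coding", {
  cfg <- filter_config(evidence_mode = "intersection_with_external")
  ev <- data.frame(transcript_id = c("t1", "t1", "t2"),
                   tool = c("toolA", "toolB", "toolA"),
                   verdict = c("noncoding", "coding", "noncoding"))
  short <- strrep("C", 600)  # ORF 0: noncoding by the ORF rule
  expect_equal(score_coding_potential("t1", short, cfg, ev)$verdict,
               "coding")
  expect_equal(score_coding_potential("t2", short, cfg, ev)$verdict,
               "noncoding")
  # unknown transcript in a verdict file is an error at cascade level
  expect_error(
    lnclact:::check_external_verdicts(
      data.frame(transcript_id = "ghost", tool = "x",
                 verdict = "coding"), c("t1", "t2")),
    "unknown transcript")
})

# A tiny hand-built scene on an ORF-free genome (no ATG anywhere).
tiny_scene <- function() {
  genome <- Biostrings::DNAStringSet(c(chrU = strrep("C", 20000)))
  known <- annotation(data.frame(
    chrom = "chrU", start = c(1000L, 2000L), end = c(1400L, 2400L),
    strand = "+", gene_id = "gK", transcript_id = "gK.t1"))
  cand <- annotation(data.frame(
    chrom = rep("chrU", 5),
    start = c(5000L, 5400L, 8000L, 12000L, 1100L),
    end = c(5249L, 5649L, 13000L, 12180L, 1350L),
    strand = c("+", "+", "-", "-", "-"),
    gene_id = c("ok", "ok", "se", "ts", "ov"),
    transcript_id = c("ok", "ok", "se", "ts", "ov")))
  fpkm <- matrix(c(1, 10, 10, 10, 10, 1, 10, 10, 10, 10), ncol = 2,
                 dimnames = list(c("ok", "se", "ts", "ov", "zz"),
                                 c("s1", "s2")))
  list(genome = genome, known = known, cand = cand, fpkm = fpkm)
}

test_that("filter cascade records every failed rule without short-circuit", {
  sc <- tiny_scene()
  v <- run_filter_cascade(sc$cand, sc$known, sc$fpkm, sc$genome,
                          filter_config())
  v <- v[order(v$transcript_id), ]
  expect_setequal(v$transcript_id, c("ok", "se", "ts", "ov"))
  expect_true(v$passed[v$transcript_id == "ok"])
  expect_identical(v$failed_rules[v$transcript_id == "ok"], "")
  expect_identical(v$failed_rules[v$transcript_id == "se"], "single_exon")
  # 181-nt two-exon transcript fails only the length rule
  expect_identical(v$failed_rules[v$transcript_id == "ts"],
                   "single_exon,too_short")
  expect_identical(v$failed_rules[v$transcript_id == "ov"],
                   "single_exon,annotation_overlap")
  expect_true(all(is.na(v$class[!v$passed])))
  expect_equal(sum(v$passed) + sum(v$failed_rules != ""), nrow(v))
})

test_that("length rule is strict (> 200 nt) and FPKM rule inclusive (>= 0.5)", {
  genome <- Biostrings::DNAStringSet(c(chrU = strrep("C", 5000)))
  known <- annotation()
  cand <- annotation(data.frame(
    chrom = "chrU", start = c(100L, 300L, 1000L, 1200L),
    end = c(199L, 399L, 1100L, 1300L), strand = "+",
    gene_id = c("len200", "len200", "len202", "len202"),
    transcript_id = c("len200", "len200", "len202", "len202")))
  fpkm <- matrix(c(0.5, 0.49), ncol = 1,
                 dimnames = list(c("len200", "len202"), "s1"))
  v <- run_filter_cascade(cand, known, fpkm, genome, filter_config())
  expect_identical(v$failed_rules[v$transcript_id == "len200"], "too_short")
  expect_identical(v$failed_rules[v$transcript_id == "len202"], "low_fpkm")
})

test_that("missing FPKM rows are reported by transcript id", {
  sc <- tiny_scene()
  expect_error(
    run_filter_cascade(sc$cand, sc$known, sc$fpkm[c("se", "ts", "ov"), ],
                       sc$genome, filter_config()),
    "ok")
})

test_that("classification separates antisense from lincRNA by strand", {
  known <- annotation(data.frame(
    chrom = "chrU", start = c(1000L, 3000L), end = c(1500L, 3500L),
    strand = "+", gene_id = "gK", transcript_id = "gK.t1"))
  inside_minus <- list(chrom = "chrU", strand = "-",
                       exons = data.frame(start = 1600L, end = 2900L))
  expect_equal(classify_lncrna(inside_minus, known), "antisense")
  inside_plus <- list(chrom = "chrU", strand = "+",
                      exons = data.frame(start = 1600L, end = 2900L))
  expect_equal(classify_lncrna(inside_plus, known), "lincRNA")
  far <- list(chrom = "chrU", strand = "-",
              exons = data.frame(start = 53500L, end = 54000L))
  expect_equal(classify_lncrna(far, known), "lincRNA")
})

test_that("cascade is idempotent on its survivor set", {
  b <- default_bundle()
  v <- bundle_verdicts(b)
  surv <- v$transcript_id[v$passed]
  ex <- lnclact:::exon_table(b$candidates)
  surv_ann <- annotation(ex[ex$transcript_id %in% surv, ])
  v2 <- suppressMessages(run_filter_cascade(
    surv_ann, b$known, bundle_fpkm(b), b$genome, filter_config()))
  expect_setequal(v2$transcript_id[v2$passed], surv)
  expect_true(all(v2$passed))
})

test_that("class percentages reproduce the published split at 1 decimal", {
  n_linc <- 1374L
  n_anti <- 225L
  starts <- seq(1L, by = 1000L, length.out = n_linc + n_anti)
  ex <- data.frame(chrom = "chrV", start = starts, end = starts + 499L,
                   strand = "+",
                   gene_id = sprintf("L%04d", seq_along(starts)),
                   transcript_id = sprintf("L%04d", seq_along(starts)))
  ann <- annotation(ex)
  verdicts <- data.frame(
    transcript_id = ex$transcript_id, passed = TRUE, failed_rules = "",
    orf_length_nt = 90L,
    class = c(rep("lincRNA", n_linc), rep("antisense", n_anti)))
  sm <- summarize_lncrna_set(verdicts, ann)
  expect_equal(sm$class_summary$percent, c(85.9, 14.1))
  expect_equal(sm$n, 1599L)
  one <- summarize_lncrna_set(verdicts[1, ], ann)
  expect_equal(one$class_summary$percent[one$class_summary$class ==
                                           "lincRNA"], 100.0)
})

test_that("summary histograms match a hand count on 10 transcripts", {
  lens <- c(219L, 500L, 1999L, 2000L, 2001L, 3500L, 4100L, 6000L, 800L,
            1200L)
  starts <- seq(1L, by = 10000L, length.out = 10L)
  ex <- data.frame(chrom = "chrW", start = starts, end = starts + lens - 1L,
                   strand = "+", gene_id = sprintf("x%02d", 1:10),
                   transcript_id = sprintf("x%02d", 1:10))
  ann <- annotation(ex)
  verdicts <- data.frame(transcript_id = ex$transcript_id, passed = TRUE,
                         failed_rules = "",
                         orf_length_nt = c(30L, 49L, 50L, 51L, 99L, 100L,
                                           149L, 150L, 151L, 299L),
                         class = "lincRNA")
  sm <- summarize_lncrna_set(verdicts, ann)
  # bins [1,2000], [2001,4000], [4001,6000]
  expect_equal(sm$length_hist$count, c(6L, 2L, 2L))
  expect_equal(sm$length_hist$bin_start, c(1L, 2001L, 4001L))
  # ORF bins [1,50], [51,100], [101,150], [151,200], [251,300]
  expect_equal(sm$orf_hist$count, c(3L, 3L, 2L, 1L, 1L))
  expect_equal(sm$mean_exons, 1.00)
  expect_equal(sm$exon_hist$count, 10L)
})
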