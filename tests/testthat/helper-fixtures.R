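# Shared fixtures, built once per test run.

.cache <- new.env(parent = emptyenv())

# Default study bundle (seed 7), generated once and reused.
default_bundle <- function() {
  if (is.null(.cache$bundle)) {
    dir <- file.path(tempdir(), "lnclact-bundle-default")
    .cache$bundle <- suppressMessages(
      simulate_lnc_study(sim_config(seed = 7), dir))
  }
  .cache$bundle
}

bundle_fpkm <- function(b = default_bundle()) {
  if (is.null(.cache$fpkm)) {
    lens <- setNames(b$candidates$transcripts$spliced_length,
                     b$candidates$transcripts$transcript_id)
    lib <- setNames(b$ground_truth$samples$library_size,
                    b$ground_truth$samples$sample)
    .cache$fpkm <- compute_fpkm(
      b$counts[names(lens), b$ground_truth$samples$sample], lens, lib)
  }
  .cache$fpkm
}

bundle_verdicts <- function(b = default_bundle()) {
  if (is.null(.cache$verdicts)) {
    .cache$verdicts <- suppressMessages(run_filter_cascade(
      b$candidates, b$known, bundle_fpkm(b), b$genome, filter_config()))
  }
  .cache$verdicts
}

bundle_groups <- function(b = default_bundle()) {
  factor(b$ground_truth$samples$group, levels = c("LP", "DP"))
}

bundle_libs <- function(b = default_bundle()) {
  setNames(b$ground_truth$samples$library_size,
           b$ground_truth$samples$sample)
}

# A small simulation configuration for module-level tests.
small_config <- function(seed = 3, ...) {
  args <- list(seed = seed, n_chromosomes = 2L, chrom_length_bp = 250000L,
               n_coding_genes = 24L, n_lincrna = 8L, n_antisense = 3L,
               n_decoys_per_mode = 2L, n_trans_hubs = 2L,
               trans_genes_per_hub = 2L)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(sim_config, args)
}

# Random exon table -> annotation, for round-trip and overlap tests.
random_annotation <- function(n_tx = 10, seed = 1, chrom_len = 50000,
                              n_chrom = 2) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_tx)) {
    chrom <- sprintf("chrT%d", sample.int(n_chrom, 1))
    n_ex <- sample.int(4, 1)
    widths <- sample(20:200, n_ex, replace = TRUE)
    gaps <- if (n_ex > 1) sample(10:150, n_ex - 1, replace = TRUE)
      else integer(0)
    start <- sample.int(chrom_len - sum(widths) - sum(gaps) - 10, 1)
    starts <- start + cumsum(c(0L, widths[-n_ex] + gaps))
    rows[[i]] <- data.frame(
      chrom = chrom, start = starts, end = starts + widths - 1L,
      strand = sample(c("+", "-"), 1),
      gene_id = sprintf("g%02d", i),
      transcript_id = sprintf("t%02d", i), stringsAsFactors = FALSE)
  }
  annotation(do.call(rbind, rows))
}

random_genome <- function(chrom_len = 50000, n_chrom = 2, seed = 1) {
  set.seed(seed)
  seqs <- vapply(seq_len(n_chrom), function(i)
    paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
          collapse = ""), "")
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- sprintf("chrT%d", seq_len(n_chrom))
  g
}

# Independent brute-force ORF scan: walk codons from every ATG.
naive_orf <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  st <- 1L
  while (st + 2L <= n) {
    if (substring(s, st, st + 2L) == "ATG") {
      j <- st
      while (j + 5L <= n + 3L) {
        j <- j + 3L
        if (j + 2L > n) break
        cod <- substring(s, j, j + 2L)
        if (grepl("[^ACGT]", cod)) break
        if (cod %in% stops) {
          best <- max(best, j + 2L - st + 1L)
          break
        }
      }
    }
    st <- st + 1L
  }
  best
}

# Independent conditional-null oracle for the exact test: numeric
# convolution of per-sample pmfs, then the small-p two-sided rule.
oracle_cond_dist <- function(S, phi, nA, nB, mu = 1) {
  base <- if (phi == 0) dpois(0:S, mu) else
    dnbinom(0:S, size = 1 / phi, mu = mu)
  conv <- function(p, q) vapply(0:S, function(s)
    sum(p[1:(s + 1)] * q[(s + 1):1]), 0)
  pA <- base
  for (i in seq_len(nA - 1)) pA <- conv(pA, base)
  pB <- base
  for (i in seq_len(nB - 1)) pB <- conv(pB, base)
  w <- pA * rev(pB)
  w / sum(w)
}

oracle_exact_p <- function(a_obs, S, phi, nA, nB, mu = 1) {
  d <- oracle_cond_dist(S, phi, nA, nB, mu)
  sum(d[d <= d[a_obs + 1] * (1 + 1e-12)])
}

# 2-vs-3 count vector with group sums a and S - a.
split_counts <- function(a, S) {
  b <- S - a
  c(floor(a / 2), ceiling(a / 2),
    floor(b / 3), floor((b + 1) / 3), b - floor(b / 3) - floor((b + 1) / 3))
}
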