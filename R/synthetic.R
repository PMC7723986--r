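#' Simulation configuration
#'
#' Defines the synthetic study: a small diploid-agnostic genome, a known
#' coding-gene annotation, candidate transcripts containing planted true
#' lncRNAs (lincRNA and antisense) and decoys each violating exactly one
#' identification filter, negative-binomial counts for a 2-vs-3 two-group
#' design (LP = lactation period vs DP = dry period) with planted
#' differential expression, latent-factor trans-correlated pairs, a term
#' annotation with one planted enriched term, and Ct values consistent
#' with the planted fold changes.
#'
#' @param seed master seed; every generator stage derives its own RNG
#'   stream from it by stage name, so adding a stage never perturbs
#'   earlier stages' draws
#' @param n_chromosomes,chrom_length_bp genome shape
#' @param n_coding_genes known protein-coding genes (2-7 exons, planted
#'   ORF >= 300 nt)
#' @param n_lincrna,n_antisense planted true lncRNAs by class; antisense
#'   lncRNAs sit inside a host gene's intron on the opposite strand
#' @param n_decoys_per_mode decoys per failure mode (single-exon,
#'   length <= 200, FPKM < 0.5, exon overlap with known genes, long-ORF
#'   coding)
#' @param n_lp,n_dp group sizes (default 2 lactation vs 3 dry samples)
#' @param de_fraction fraction of true lncRNAs and of coding genes planted
#'   as differentially expressed
#' @param de_log2fc planted effect size |log2 fold change|
#' @param phi NB dispersion, Var = mu + phi * mu^2
#' @param library_sizes per-sample total mapped fragments (default around
#'   20 million with sample-to-sample variation)
#' @param n_terms number of annotation terms, one of which is planted
#'   enriched in the target genes
#' @param n_trans_hubs,trans_genes_per_hub planted trans structure: each
#'   hub lncRNA shares a latent expression factor with this many partner
#'   genes
#' @param latent_sdlog log-scale SD of an extra shared log-normal
#'   co-regulation factor on top of the shared NB mixing component (see
#'   [simulate_counts()]); together they put planted pair correlations
#'   above |r| = 0.95 in expectation at n = 5
#' @param qpcr_noise_sd Gaussian Ct noise (PCR cycles)
#' @param qpcr_panel_size number of planted DE lncRNAs on the qPCR panel
#' @param cis_window window for recording planted cis neighbors (bp)
#' @export
sim_config <- function(seed = 7L, n_chromosomes = 2L,
                       chrom_length_bp = 1000000L, n_coding_genes = 100L,
                       n_lincrna = 30L, n_antisense = 10L,
                       n_decoys_per_mode = 10L, n_lp = 2L, n_dp = 3L,
                       de_fraction = 0.3, de_log2fc = 2, phi = 0.1,
                       library_sizes = NULL, n_terms = 20L,
                       n_trans_hubs = 5L, trans_genes_per_hub = 3L,
                       latent_sdlog = 0.25, qpcr_noise_sd = 0.15,
                       qpcr_panel_size = 10L, cis_window = 100000L) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.integer(chrom_length_bp),
              n_coding_genes = as.integer(n_coding_genes),
              n_lincrna = as.integer(n_lincrna),
              n_antisense = as.integer(n_antisense),
              n_decoys_per_mode = as.integer(n_decoys_per_mode),
              n_lp = as.integer(n_lp), n_dp = as.integer(n_dp),
              de_fraction = de_fraction, de_log2fc = de_log2fc, phi = phi,
              n_terms = as.integer(n_terms),
              n_trans_hubs = as.integer(n_trans_hubs),
              trans_genes_per_hub = as.integer(trans_genes_per_hub),
              latent_sdlog = latent_sdlog, qpcr_noise_sd = qpcr_noise_sd,
              qpcr_panel_size = as.integer(qpcr_panel_size),
              cis_window = as.integer(cis_window))
  n_samples <- cfg$n_lp + cfg$n_dp
  if (is.null(library_sizes))
    library_sizes <- round(2e7 * seq(0.85, 1.15,
                                     length.out = max(n_samples, 2L)))[
                                       seq_len(n_samples)]
  cfg$library_sizes <- as.numeric(library_sizes)
  with(cfg, {
    if (phi < 0) stop("configuration error: phi must be >= 0")
    if (any(c(n_chromosomes, n_coding_genes, n_lincrna, n_antisense,
              n_decoys_per_mode, n_terms) < 0))
      stop("configuration error: counts must be >= 0")
    if (n_lp < 1 || n_dp < 1)
      stop("configuration error: both groups need >= 1 sample")
    if (length(cfg$library_sizes) != n_samples)
      stop("configuration error: need one library size per sample")
    if (n_coding_genes < n_antisense + n_decoys_per_mode)
      stop("configuration error: too few genes to host antisense lncRNAs ",
           "and overlap decoys")
  })
  structure(cfg, class = "lnc_sim_config")
}

#' Negative-binomial draws parameterized by mean and dispersion
#'
#' Var = mu + phi * mu^2 (the edgeR convention); phi = 0 gives Poisson.
#'
#' @param n number of draws
#' @param mu mean (vectorized)
#' @param phi dispersion >= 0
#' @export
rnb <- function(n, mu, phi) {
  if (phi < 0) stop("configuration error: phi must be >= 0")
  if (phi == 0) rpois(n, mu) else rnbinom(n, size = 1 / phi, mu = mu)
}

random_dna <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# sample() treats a length-1 numeric as 1:x; this keeps range draws safe
sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# Stop-codon cassette with TAG in all three reading frames: caps any ORF
# crossing it, so sequences built from <=240 nt random chunks separated by
# cassettes cannot contain an ORF of 300 nt.
.stop_cassette <- c("T", "A", "G", "A", "T", "A", "G", "A", "T", "A", "G", "A")

make_noncoding_seq <- function(L) {
  out <- character(0)
  left <- L
  while (left > 252L) {
    out <- c(out, random_dna(240L), .stop_cassette)
    left <- left - 252L
  }
  c(out, random_dna(left))
}

.stop_codons <- c("TAA", "TAG", "TGA")
.nonstop_codons <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  .stop_codons)

# Random sequence of length L with an ATG-initiated ORF of orf_len nt
# (multiple of 3, incl. stop) planted so that it ends on or before
# position max_end.
make_coding_seq <- function(L, orf_len, max_end = L) {
  stopifnot(orf_len %% 3 == 0, orf_len >= 9, orf_len <= max_end, max_end <= L)
  s <- random_dna(L)
  start <- if (max_end - orf_len >= 1)
    sample(seq_len(max_end - orf_len + 1L), 1L) else 1L
  orf <- c("A", "T", "G",
           unlist(strsplit(sample(.nonstop_codons, orf_len / 3L - 2L,
                                  replace = TRUE), "")),
           unlist(strsplit(sample(.stop_codons, 1L), "")))
  s[start:(start + orf_len - 1L)] <- orf
  s
}

# Write a designed spliced sequence (5'->3') into the chromosome character
# vector at the transcript's exon positions.
plant_sequence <- function(chrom_seq, exons, strand, seq_chars) {
  if (strand == "-")
    seq_chars <- rev(chartr("ACGT", "TGCA", seq_chars))
  pos <- unlist(mapply(seq.int, exons$start, exons$end, SIMPLIFY = FALSE))
  stopifnot(length(pos) == length(seq_chars))
  chrom_seq[pos] <- seq_chars
  chrom_seq
}

#' Generate the synthetic genome, annotations and ground truth
#'
#' Lays out coding genes, lincRNAs and intergenic decoys along the
#' chromosomes with randomized gaps (lincRNAs at least 100 bp from any
#' gene span), places antisense lncRNAs inside host-gene introns on the
#' opposite strand, and attaches exon-overlap decoys to host-gene 3'
#' exons on both strands.  Coding genes carry a planted ORF of at least
#' 300 nt; true lncRNAs and non-coding decoys are built from stop-cassette
#' sequence so their longest ORF is provably below 300 nt.
#'
#' @param config a [sim_config()]
#' @return list with `genome` ([Biostrings::DNAStringSet]), `known` and
#'   `candidates` ([annotation()]), and `ground_truth` (features table,
#'   planted DE, cis and trans pairs, qPCR panel, samples)
#' @export
generate_genome_and_annotation <- function(config) {
  stopifnot(inherits(config, "lnc_sim_config"))
  gt <- with_stage_seed(config$seed, "structure", sim_structure(config))
  genome <- with_stage_seed(config$seed, "genome", sim_genome(config, gt))
  known <- annotation(gt$exons[gt$exons$kind == "coding_gene",
                               c("chrom", "start", "end", "strand",
                                 "gene_id", "transcript_id")])
  candidates <- annotation(gt$exons[, c("chrom", "start", "end", "strand",
                                        "gene_id", "transcript_id")])
  list(genome = genome, known = known, candidates = candidates,
       ground_truth = gt$truth)
}

# -- structure stage ---------------------------------------------------------

sim_structure <- function(config) {
  n_g <- config$n_coding_genes
  n_li <- config$n_lincrna
  n_as <- config$n_antisense
  n_dk <- config$n_decoys_per_mode
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))

  # -- design intergenic items (genes + lincRNA-like loci) ----
  items <- list()
  add_item <- function(it) items[[length(items) + 1L]] <<- it

  host_idx <- seq_len(n_as)                    # antisense hosts
  ovl_idx <- n_as + seq_len(n_dk)              # exon-overlap decoy hosts
  for (i in seq_len(n_g)) {
    n_ex <- sample(2:7, 1)
    ex_len <- sample(150:400, n_ex, replace = TRUE)
    if (sum(ex_len) < 450L) ex_len[n_ex] <- ex_len[n_ex] + 450L - sum(ex_len)
    introns <- if (n_ex > 1) sample(200:1500, n_ex - 1, replace = TRUE)
      else integer(0)
    if (i %in% host_idx) introns[1] <- 4500L
    strand <- if (i %in% ovl_idx) "+" else sample(c("+", "-"), 1)
    add_item(list(id = sprintf("GENE%04d", i), kind = "coding_gene",
                  ex_len = ex_len, introns = introns, strand = strand,
                  tail_gap = if (i %in% ovl_idx) 1500L else 0L))
  }
  for (i in seq_len(n_li)) {
    n_ex <- sample(2:4, 1)
    L <- if (runif(1) < 0.7) sample(300:2000, 1) else sample(2000:6000, 1)
    ex_len <- pmax(100L, as.integer(round(L * as.vector(
      prop.table(runif(n_ex, 0.5, 1.5))))))
    introns <- sample(200:1200, n_ex - 1, replace = TRUE)
    add_item(list(id = sprintf("LNC_%06d", i), kind = "lincRNA",
                  ex_len = ex_len, introns = introns,
                  strand = sample(c("+", "-"), 1), tail_gap = 0L))
  }
  decoy_spec <- list(
    single_exon = function(i) list(
      id = sprintf("DECOY_SE_%02d", i), kind = "decoy_single_exon",
      ex_len = sample(400:2000, 1), introns = integer(0),
      strand = sample(c("+", "-"), 1), tail_gap = 0L),
    too_short = function(i) {
      L <- sample(150:200, 1)
      a <- sample(60:(L - 60L), 1)
      list(id = sprintf("DECOY_TS_%02d", i), kind = "decoy_too_short",
           ex_len = c(a, L - a), introns = sample(200:600, 1),
           strand = sample(c("+", "-"), 1), tail_gap = 0L)
    },
    low_fpkm = function(i) list(
      id = sprintf("DECOY_LF_%02d", i), kind = "decoy_low_fpkm",
      ex_len = sample(200:500, 2, replace = TRUE),
      introns = sample(200:800, 1), strand = sample(c("+", "-"), 1),
      tail_gap = 0L),
    coding = function(i) list(
      id = sprintf("DECOY_CP_%02d", i), kind = "decoy_coding",
      ex_len = sample(300:600, 2, replace = TRUE),
      introns = sample(200:800, 1), strand = sample(c("+", "-"), 1),
      tail_gap = 0L))
  for (mode in names(decoy_spec))
    for (i in seq_len(n_dk)) add_item(decoy_spec[[mode]](i))

  # -- place intergenic items on chromosomes ----
  order_ix <- sample(length(items))
  chrom_of <- rep(chroms, length.out = length(items))
  cursor <- setNames(rep(0L, length(chroms)), chroms)
  exon_rows <- list()
  placed <- list()
  for (j in seq_along(order_ix)) {
    it <- items[[order_ix[j]]]
    ch <- chrom_of[j]
    gap <- sample(300:2000, 1)
    start <- cursor[[ch]] + gap + 1L
    starts <- start + c(0L, cumsum(it$ex_len[-length(it$ex_len)] +
                                     it$introns))
    ends <- starts + it$ex_len - 1L
    span_end <- max(ends)
    if (span_end > config$chrom_length_bp - 2000L)
      stop("configuration error: chromosome ", ch,
           " too short for the requested features")
    cursor[[ch]] <- span_end + it$tail_gap
    tid <- if (it$kind == "coding_gene") paste0(it$id, ".t1") else it$id
    exon_rows[[length(exon_rows) + 1L]] <- data.frame(
      chrom = ch, start = starts, end = ends, strand = it$strand,
      gene_id = it$id, transcript_id = tid, kind = it$kind,
      stringsAsFactors = FALSE)
    placed[[it$id]] <- list(chrom = ch, start = start, end = span_end,
                            strand = it$strand, kind = it$kind,
                            ex_starts = starts, ex_ends = ends)
  }

  # -- antisense lncRNAs inside host-gene introns, opposite strand ----
  for (i in seq_len(n_as)) {
    host <- placed[[sprintf("GENE%04d", i)]]
    # first intron in genomic order (hosts have it sized 4500)
    in_start <- host$ex_ends[1] + 1L
    in_end <- host$ex_starts[2] - 1L
    ex_len <- sample(200:400, 2, replace = TRUE)
    intron <- sample(100:800, 1)
    span <- sum(ex_len) + intron
    slack <- (in_end - in_start + 1L) - span - 100L
    stopifnot(slack > 0)
    s1 <- in_start + 50L + sample(0:slack, 1)
    starts <- c(s1, s1 + ex_len[1] + intron)
    ends <- starts + ex_len - 1L
    id <- sprintf("LNC_%06d", n_li + i)
    strand <- if (host$strand == "+") "-" else "+"
    exon_rows[[length(exon_rows) + 1L]] <- data.frame(
      chrom = host$chrom, start = starts, end = ends, strand = strand,
      gene_id = id, transcript_id = id, kind = "antisense",
      stringsAsFactors = FALSE)
    placed[[id]] <- list(chrom = host$chrom, start = starts[1],
                         end = ends[2], strand = strand,
                         kind = "antisense", ex_starts = starts,
                         ex_ends = ends)
  }

  # -- exon-overlap decoys: share 50 bp of a host gene's 3'-most exon ----
  for (i in seq_len(n_dk)) {
    host <- placed[[sprintf("GENE%04d", n_as + i)]]
    last_end <- max(host$ex_ends)
    s1 <- last_end - 49L
    e1 <- last_end + 150L
    s2 <- e1 + sample(100:300, 1)
    e2 <- s2 + 299L
    id <- sprintf("DECOY_OV_%02d", i)
    strand <- if (i %% 2 == 0) "+" else "-"   # both orientations emitted
    exon_rows[[length(exon_rows) + 1L]] <- data.frame(
      chrom = host$chrom, start = c(s1, s2), end = c(e1, e2),
      strand = strand, gene_id = id, transcript_id = id,
      kind = "decoy_overlap", stringsAsFactors = FALSE)
    placed[[id]] <- list(chrom = host$chrom, start = s1, end = e2,
                         strand = strand, kind = "decoy_overlap",
                         ex_starts = c(s1, s2), ex_ends = c(e1, e2))
  }

  exons <- do.call(rbind, exon_rows)

  # -- feature table and planted truth ----
  ids <- names(placed)
  kind <- vapply(placed, `[[`, "", "kind")
  length_of <- vapply(ids, function(id) {
    p <- placed[[id]]
    sum(p$ex_ends - p$ex_starts + 1L)
  }, 0L)
  features <- data.frame(
    feature_id = ifelse(kind == "coding_gene", paste0(ids, ".t1"), ids),
    gene_id = ids, kind = unname(kind), chrom = vapply(placed, `[[`, "", "chrom"),
    span_start = vapply(placed, function(p) min(p$ex_starts), 0L),
    span_end = vapply(placed, function(p) max(p$ex_ends), 0L),
    strand = vapply(placed, `[[`, "", "strand"),
    length = unname(length_of), stringsAsFactors = FALSE)
  rownames(features) <- NULL

  truth <- plant_truth(config, features)
  truth$features <- features
  list(exons = exons, truth = truth, placed = placed)
}

# Planted DE, trans hubs, cis neighbors, qPCR panel.
plant_truth <- function(config, features) {
  lnc <- features[features$kind %in% c("lincRNA", "antisense"), ]
  gene <- features[features$kind == "coding_gene", ]
  n_del <- round(config$de_fraction * nrow(lnc))
  n_deg <- round(config$de_fraction * nrow(gene))
  del <- if (n_del) sort(sample(lnc$feature_id, n_del)) else character(0)
  deg <- if (n_deg) sort(sample(gene$feature_id, n_deg)) else character(0)
  sgn <- function(ids) if (length(ids))
    setNames(config$de_log2fc * rep_len(c(1, -1), length(ids)), ids)
    else setNames(numeric(0), character(0))
  de_lfc <- c(sgn(del), sgn(deg))

  n_hub <- min(config$n_trans_hubs, length(del))
  hubs <- if (n_hub) sample(del, n_hub) else character(0)
  n_part <- config$trans_genes_per_hub
  gene_of <- setNames(features$gene_id, features$feature_id)
  avail <- deg
  trans_pairs <- list()
  for (h in hubs) {
    take <- head(avail, n_part)
    avail <- setdiff(avail, take)
    if (length(take))
      trans_pairs[[h]] <- data.frame(lncRNA_id = h,
                                     gene_id = unname(gene_of[take]),
                                     feature_id = take,
                                     stringsAsFactors = FALSE)
  }
  trans_pairs <- if (length(trans_pairs)) do.call(rbind, trans_pairs) else
    data.frame(lncRNA_id = character(), gene_id = character(),
               feature_id = character(), stringsAsFactors = FALSE)
  rownames(trans_pairs) <- NULL
  # partner genes co-regulate with their hub: same DE sign, so the shared
  # expression state and the group effect pull the pair the same way
  if (nrow(trans_pairs))
    de_lfc[trans_pairs$feature_id] <- de_lfc[trans_pairs$lncRNA_id]

  # cis neighbors by a plain arithmetic scan (bases strictly between spans)
  cis <- list()
  for (i in seq_len(nrow(lnc))) {
    g <- gene[gene$chrom == lnc$chrom[i], ]
    if (!nrow(g)) next
    gap <- ifelse(g$span_start > lnc$span_end[i],
                  g$span_start - lnc$span_end[i] - 1L,
           ifelse(g$span_end < lnc$span_start[i],
                  -(lnc$span_start[i] - g$span_end - 1L), 0L))
    keep <- abs(gap) <= config$cis_window
    if (any(keep))
      cis[[length(cis) + 1L]] <- data.frame(
        lncRNA_id = lnc$feature_id[i], gene_id = g$gene_id[keep],
        distance = as.integer(gap[keep]), stringsAsFactors = FALSE)
  }
  cis <- if (length(cis)) do.call(rbind, cis) else
    data.frame(lncRNA_id = character(), gene_id = character(),
               distance = integer(), stringsAsFactors = FALSE)
  rownames(cis) <- NULL

  panel <- head(sort(del), config$qpcr_panel_size)

  samples <- data.frame(
    sample = c(sprintf("DP%d", seq_len(config$n_dp)),
               sprintf("LP%d", seq_len(config$n_lp))),
    group = c(rep("DP", config$n_dp), rep("LP", config$n_lp)),
    library_size = config$library_sizes[c(
      config$n_lp + seq_len(config$n_dp), seq_len(config$n_lp))],
    stringsAsFactors = FALSE)

  decoy_reason <- c(decoy_single_exon = "single_exon",
                    decoy_too_short = "too_short",
                    decoy_low_fpkm = "low_fpkm",
                    decoy_overlap = "annotation_overlap",
                    decoy_coding = "coding_potential")
  dk <- features[features$kind %in% names(decoy_reason), ]
  decoys <- data.frame(transcript_id = dk$feature_id,
                       reason = unname(decoy_reason[dk$kind]),
                       stringsAsFactors = FALSE)

  list(true_lncrnas = data.frame(transcript_id = lnc$feature_id,
                                 class = lnc$kind, stringsAsFactors = FALSE),
       decoys = decoys,
       de = data.frame(feature_id = names(de_lfc),
                       gene_id = unname(gene_of[names(de_lfc)]),
                       log2fc = unname(de_lfc),
                       type = ifelse(names(de_lfc) %in% lnc$feature_id,
                                     "lncRNA", "gene"),
                       stringsAsFactors = FALSE),
       trans_pairs = trans_pairs, cis_pairs = cis,
       qpcr_panel = panel, samples = samples)
}

# -- genome stage ------------------------------------------------------------

sim_genome <- function(config, st) {
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  seqs <- lapply(chroms, function(ch) random_dna(config$chrom_length_bp))
  names(seqs) <- chroms

  feats <- st$truth$features
  ord <- order(feats$feature_id)
  # coding sequences first, then non-coding (which may overwrite a host
  # gene's 3' tail or intron without touching its planted ORF)
  for (pass in c("coding", "noncoding")) {
    for (i in ord) {
      f <- feats[i, ]
      p <- st$placed[[f$gene_id]]
      ex <- data.frame(start = p$ex_starts, end = p$ex_ends)
      L <- f$length
      is_coding <- f$kind %in% c("coding_gene", "decoy_coding")
      if ((pass == "coding") != is_coding) next
      s <- if (f$kind == "coding_gene") {
        # ORF confined to the first 70% so overlap decoys on the 3' exon
        # tail cannot disturb it
        orf_max <- 3L * ((min(L - 60L, floor(0.7 * L))) %/% 3L)
        orf_len <- 3L * sample1(100:(orf_max %/% 3L))
        make_coding_seq(L, orf_len, max_end = orf_max)
      } else if (f$kind == "decoy_coding") {
        orf_len <- 3L * sample1(100:min(150L, (L - 9L) %/% 3L))
        make_coding_seq(L, orf_len)
      } else make_noncoding_seq(L)
      seqs[[f$chrom]] <- plant_sequence(seqs[[f$chrom]], ex, f$strand, s)
    }
  }
  Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
}

# -- counts stage ------------------------------------------------------------

#' Simulate the fragment-count table
#'
#' Draws NB(mu, phi) counts for every candidate transcript over the 5
#' samples.  Non-DE features share their mean across groups (scaled by
#' library size); planted DE features have group means separated by the
#' planted log2FC.  Trans-planted features are drawn hierarchically as
#' Poisson(mu * G * exp(z)) with the per-sample expression state
#' G ~ Gamma(1/phi, phi) and z ~ N(0, latent_sdlog) SHARED within a hub:
#' each member's marginal stays (essentially) NB(mu, phi) while the pair's
#' cross-sample correlation is limited only by Poisson noise and exceeds
#' 0.95 in expectation.  Low-FPKM decoys are drawn truncated below the
#' FPKM = 0.5 count threshold in every sample, and all other candidates
#' are conditioned on reaching it in at least one sample.
#'
#' @param config a [sim_config()]
#' @param ground_truth the `ground_truth` component of
#'   [generate_genome_and_annotation()]
#' @return matrix of counts (features x samples) with an attached
#'   `base_mean` attribute (named expected baseline means)
#' @export
simulate_counts <- function(config, ground_truth) {
  with_stage_seed(config$seed, "counts",
                  sim_counts_impl(config, ground_truth))
}

sim_counts_impl <- function(config, gt) {
  feats <- gt$features
  samples <- gt$samples
  nS <- nrow(samples)
  lib <- samples$library_size
  libfac <- lib / exp(mean(log(lib)))
  is_lp <- samples$group == "LP"

  lfc <- setNames(rep(0, nrow(feats)), feats$feature_id)
  lfc[gt$de$feature_id] <- gt$de$log2fc
  hub_of <- setNames(rep(NA_character_, nrow(feats)), feats$feature_id)
  if (nrow(gt$trans_pairs)) {
    hub_of[gt$trans_pairs$feature_id] <- gt$trans_pairs$lncRNA_id
    hub_of[unique(gt$trans_pairs$lncRNA_id)] <-
      unique(gt$trans_pairs$lncRNA_id)
  }

  base <- numeric(nrow(feats))
  for (i in seq_len(nrow(feats))) {
    k <- feats$kind[i]
    base[i] <- if (k == "coding_gene") exp(rnorm(1, log(200), 0.6))
      else if (k == "decoy_low_fpkm") 0   # set below from the threshold
      else exp(rnorm(1, log(80), 0.6))
  }
  names(base) <- feats$feature_id
  is_lnc <- feats$kind %in% c("lincRNA", "antisense")
  base[is_lnc] <- pmax(base[is_lnc], 30)
  # planted DE effects are kept in the detectable expression regime
  base[names(base) %in% gt$de$feature_id] <-
    pmax(base[names(base) %in% gt$de$feature_id], 50)
  base[!is.na(hub_of)] <- 500   # trans members: high expression

  # shared per-hub expression state: NB mixing gamma times a mild
  # log-normal co-regulation factor
  hub_state <- list()
  for (h in unique(hub_of[!is.na(hub_of)])) {
    G <- if (config$phi > 0)
      stats::rgamma(nS, shape = 1 / config$phi, scale = config$phi)
      else rep(1, nS)
    hub_state[[h]] <- G * exp(rnorm(nS, 0, config$latent_sdlog))
  }

  # count threshold at which FPKM reaches 0.5, per sample
  thr <- function(len) 0.5 * len * lib / 1e9

  counts <- matrix(0, nrow(feats), nS,
                   dimnames = list(feats$feature_id, samples$sample))
  for (i in seq_len(nrow(feats))) {
    id <- feats$feature_id[i]
    len <- feats$length[i]
    tv <- thr(len)
    if (feats$kind[i] == "decoy_low_fpkm") {
      y <- rnb(nS, pmax(tv / 4, 0.2), config$phi)
      counts[i, ] <- pmin(y, pmax(ceiling(tv) - 1, 0))
      next
    }
    grp <- ifelse(is_lp, 2^(lfc[id] / 2), 2^(-lfc[id] / 2))
    mu <- base[id] * grp * libfac
    draw <- function() {
      if (!is.na(hub_of[id])) rpois(nS, mu * hub_state[[hub_of[id]]])
      else rnb(nS, mu, config$phi)
    }
    y <- draw()
    # all non-low-FPKM candidates must clear FPKM >= 0.5 in >= 1 sample
    tries <- 0L
    while (all(y < tv) && tries < 20L) {
      y <- draw()
      tries <- tries + 1L
    }
    if (all(y < tv)) y[which.max(mu)] <- ceiling(max(tv))
    counts[i, ] <- y
  }
  storage.mode(counts) <- "integer"
  attr(counts, "base_mean") <- base
  counts
}

# -- terms stage -------------------------------------------------------------

#' Generate the gene-to-term annotation
#'
#' Every coding gene receives 1-5 of `n_terms` terms.  One planted term
#' covers at least 80% of the planted target genes (trans partners plus
#' differentially expressed cis neighbors of planted DE lncRNAs) and at
#' most 10% of the remaining background.  With a single term the term is
#' assigned to every gene and can never be enriched.
#'
#' @inheritParams simulate_counts
#' @return list with `term_map` (gene_id, term_id, term_name),
#'   `enriched_term` and `target_genes`
#' @export
generate_term_annotation <- function(config, ground_truth) {
  with_stage_seed(config$seed, "terms",
                  sim_terms_impl(config, ground_truth))
}

sim_terms_impl <- function(config, gt) {
  genes <- gt$features$gene_id[gt$features$kind == "coding_gene"]
  if (config$n_terms < 1) stop("configuration error: n_terms must be >= 1")
  terms <- sprintf("TERM%03d", seq_len(config$n_terms))
  del_ids <- gt$de$feature_id[gt$de$type == "lncRNA"]
  deg_gene_ids <- gt$de$gene_id[gt$de$type == "gene"]
  targets <- unique(c(
    gt$trans_pairs$gene_id,
    gt$cis_pairs$gene_id[gt$cis_pairs$lncRNA_id %in% del_ids &
                           gt$cis_pairs$gene_id %in% deg_gene_ids]))
  targets <- intersect(targets, genes)

  rows <- list()
  if (config$n_terms == 1L) {
    rows[[1]] <- data.frame(gene_id = genes, term_id = terms[1],
                            stringsAsFactors = FALSE)
    enriched <- terms[1]
  } else {
    enriched <- terms[1]
    others <- terms[-1]
    in_term <- character(0)
    if (length(targets)) {
      n_cov <- max(ceiling(0.9 * length(targets)), 1L)
      in_term <- sample(targets, n_cov)
    }
    bg <- setdiff(genes, targets)
    n_bg <- min(floor(0.08 * length(bg)), length(bg))
    if (n_bg > 0) in_term <- c(in_term, sample(bg, n_bg))
    if (length(in_term))
      rows[[1]] <- data.frame(gene_id = in_term, term_id = enriched,
                              stringsAsFactors = FALSE)
    for (g in genes) {
      k <- sample(1:min(5, length(others)), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, term_id = sort(sample(others, k)),
        stringsAsFactors = FALSE)
    }
  }
  tm <- do.call(rbind, rows)
  tm <- tm[order(tm$gene_id, tm$term_id), ]
  tm$term_name <- paste0("term ", sub("TERM0*", "", tm$term_id))
  rownames(tm) <- NULL
  list(term_map = tm, enriched_term = enriched, target_genes = targets)
}

# -- qPCR stage --------------------------------------------------------------

#' Simulate a qPCR Ct table for the planted panel
#'
#' Ct = intercept - log2(expected expression) + Gaussian noise; reference
#' genes (HMBS, YWHAZ) have constant expression across groups up to noise.
#' With zero noise the 2^-ddCt fold change equals 2^(planted log2FC)
#' exactly.
#'
#' @inheritParams simulate_counts
#' @param noise_sd Ct noise SD; defaults to the configured value
#' @return matrix of Ct values (panel + reference genes x samples)
#' @export
simulate_qpcr <- function(config, ground_truth,
                          noise_sd = config$qpcr_noise_sd) {
  with_stage_seed(config$seed, "qpcr",
                  sim_qpcr_impl(config, ground_truth, noise_sd))
}

sim_qpcr_impl <- function(config, gt, noise_sd) {
  samples <- gt$samples
  nS <- nrow(samples)
  is_lp <- samples$group == "LP"
  panel <- gt$qpcr_panel
  lfc <- setNames(gt$de$log2fc, gt$de$feature_id)
  rows <- c(panel, "HMBS", "YWHAZ")
  ct <- matrix(0, length(rows), nS,
               dimnames = list(rows, samples$sample))
  for (f in panel) {
    expr <- 100 * ifelse(is_lp, 2^(lfc[f] / 2), 2^(-lfc[f] / 2))
    ct[f, ] <- 30 - log2(expr) + rnorm(nS, 0, noise_sd)
  }
  ct["HMBS", ] <- 30 - log2(1000) + rnorm(nS, 0, noise_sd)
  ct["YWHAZ", ] <- 30 - log2(800) + rnorm(nS, 0, noise_sd)
  ct
}

# -- bundle writer -----------------------------------------------------------

#' Write the full synthetic input bundle
#'
#' Runs every generator stage and writes the files the pipeline consumes:
#' `genome.fa`, `known.gtf`, `candidates.gtf`, `counts.tsv`,
#' `samples.tsv`, `terms.tsv`, `qpcr_ct.tsv` and `ground_truth.json`.
#' Identical configurations (same seed) produce byte-identical files.
#'
#' @param config a [sim_config()]
#' @param dir output directory (created if needed)
#' @return invisible list with all file `paths`, the in-memory objects and
#'   the `ground_truth`
#' @export
simulate_lnc_study <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genome_and_annotation(config)
  gt <- gen$ground_truth
  counts <- simulate_counts(config, gt)
  trm <- generate_term_annotation(config, gt)
  ct <- simulate_qpcr(config, gt)

  paths <- list(
    genome = file.path(dir, "genome.fa"),
    known_gtf = file.path(dir, "known.gtf"),
    candidate_gtf = file.path(dir, "candidates.gtf"),
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    terms = file.path(dir, "terms.tsv"),
    qpcr = file.path(dir, "qpcr_ct.tsv"),
    ground_truth = file.path(dir, "ground_truth.json"))

  Biostrings::writeXStringSet(gen$genome, paths$genome, width = 80L)
  write_gtf(gen$known, paths$known_gtf)
  write_gtf(gen$candidates, paths$candidate_gtf)
  cdf <- data.frame(transcript_id = rownames(counts), counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(cdf, paths$counts)
  write_tsv(gt$samples, paths$samples)
  write_tsv(trm$term_map, paths$terms)
  qdf <- data.frame(feature_id = rownames(ct), round(ct, 4),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(qdf, paths$qpcr)
  gt_out <- gt
  gt_out$enriched_term <- trm$enriched_term
  gt_out$target_genes <- trm$target_genes
  jsonlite::write_json(gt_out, paths$ground_truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(paths = paths, genome = gen$genome, known = gen$known,
                 candidates = gen$candidates, counts = counts,
                 terms = trm, qpcr_ct = ct, ground_truth = gt_out))
}
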