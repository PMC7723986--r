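#' Filter cascade configuration
#'
#' Defaults implement the candidate-lncRNA exclusion criteria: single-exon
#' transcripts removed; length must exceed 200 nt (length exactly 200 is
#' removed); max FPKM across samples must be >= 0.5 (inclusive); transcripts
#' overlapping known exons (either strand) removed; transcripts whose
#' longest ORF reaches 300 nt (100 codons, the conventional lncRNA
#' heuristic) are classed as coding and removed.
#'
#' @param min_exons minimum exon count kept (default 2)
#' @param min_length_nt keep spliced length strictly greater than this
#' @param min_fpkm keep max-over-samples FPKM greater than or equal to this
#' @param coding_orf_threshold_nt ORF length (nt, incl. stop) at or above
#'   which a transcript is called coding
#' @param evidence_mode `"orf_only"` or `"intersection_with_external"`: in
#'   intersection mode a transcript is noncoding only if the ORF rule AND
#'   every supplied external verdict agree on noncoding
#' @export
filter_config <- function(min_exons = 2L, min_length_nt = 200L,
                          min_fpkm = 0.5, coding_orf_threshold_nt = 300L,
                          evidence_mode = c("orf_only",
                                            "intersection_with_external")) {
  evidence_mode <- match.arg(evidence_mode)
  stopifnot(min_exons > 0, min_length_nt > 0, min_fpkm > 0,
            coding_orf_threshold_nt > 0)
  structure(list(min_exons = as.integer(min_exons),
                 min_length_nt = as.integer(min_length_nt),
                 min_fpkm = min_fpkm,
                 coding_orf_threshold_nt = as.integer(coding_orf_threshold_nt),
                 evidence_mode = evidence_mode),
            class = "lnc_filter_config")
}

#' Longest open reading frame
#'
#' Length in nt (including the stop codon) of the longest ATG-initiated,
#' stop-terminated reading frame across the three forward frames of the
#' given (already strand-resolved) sequence; 0 if none.  A codon containing
#' an ambiguous base (N) never starts, extends or terminates an ORF: an ORF
#' whose span contains such a codon is discarded.
#'
#' @param sequence nucleotide string over A/C/G/T/N (case-insensitive)
#' @return integer ORF length in nt
#' @export
longest_orf <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < 6L) return(0L)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 1:3) {
    pos <- seq.int(frame, n - 2L, by = 3L)
    if (!length(pos)) next
    codons <- substring(s, pos, pos + 2L)
    is_start <- codons == "ATG"
    is_stop <- codons %in% stops
    has_n <- grepl("[^ACGT]", codons)
    starts <- which(is_start & !has_n)
    if (!length(starts)) next
    # blockers: a stop codon terminates an ORF; an ambiguous codon voids it
    blocker <- which(is_stop | has_n)
    if (!length(blocker)) next
    j <- findInterval(starts - 1L, blocker) + 1L  # first blocker >= start
    ok <- j <= length(blocker)
    if (!any(ok)) next
    b <- blocker[j[ok]]
    is_valid_stop <- is_stop[b] & !has_n[b]
    len <- (b - starts[ok] + 1L) * 3L
    len <- len[is_valid_stop]
    if (length(len)) best <- max(best, max(len))
  }
  as.integer(best)
}

#' Coding-potential verdict for one transcript
#'
#' In `orf_only` mode a transcript is coding iff its longest ORF reaches the
#' threshold.  In `intersection_with_external` mode a transcript is
#' noncoding only when the ORF rule and every supplied external tool verdict
#' agree on noncoding -- mirroring the joint use of several coding-potential
#' tools as an exclusion criterion; a single coding call from any source is
#' enough to remove it.
#'
#' @param transcript_id transcript id (for external verdict lookup)
#' @param sequence the spliced, strand-resolved sequence
#' @param config a [filter_config()]
#' @param external_verdicts optional data.frame with columns
#'   `transcript_id`, `tool`, `verdict` (`"coding"`/`"noncoding"`)
#' @return list with `verdict` (`"coding"` or `"noncoding"`) and
#'   `orf_length_nt`
#' @export
score_coding_potential <- function(transcript_id, sequence, config,
                                   external_verdicts = NULL) {
  orf <- longest_orf(sequence)
  coding <- orf >= config$coding_orf_threshold_nt
  if (config$evidence_mode == "intersection_with_external" &&
      !is.null(external_verdicts)) {
    ev <- external_verdicts[external_verdicts$transcript_id == transcript_id, ]
    if (nrow(ev) && any(ev$verdict == "coding")) coding <- TRUE
  }
  list(verdict = if (coding) "coding" else "noncoding",
       orf_length_nt = orf)
}

check_external_verdicts <- function(external_verdicts, candidate_ids) {
  if (is.null(external_verdicts)) return(invisible(NULL))
  stopifnot(all(c("transcript_id", "tool", "verdict") %in%
                  names(external_verdicts)))
  unknown <- setdiff(external_verdicts$transcript_id, candidate_ids)
  if (length(unknown))
    stop("external verdict references unknown transcript(s): ",
         paste(head(unknown, 5), collapse = ", "))
  invisible(NULL)
}

#' Run the lncRNA identification filter cascade
#'
#' Evaluates, for every candidate transcript, the five exclusion rules in
#' order -- `single_exon`, `too_short`, `low_fpkm`, `annotation_overlap`,
#' `coding_potential` -- recording ALL failed rules (no short-circuit, for
#' auditability).  A transcript passes iff it fails none; survivors are
#' classified into `lincRNA` / `antisense` against the known annotation.
#' The annotation-overlap rule is strand-agnostic at exon resolution;
#' classification uses opposite-strand overlap with known gene spans.
#'
#' Candidate ids also present in the known annotation are dropped (with a
#' message) before filtering: they are by definition not novel.
#'
#' @param candidates `lnc_annotation` of candidate transcripts
#' @param known `lnc_annotation` of the reference gene models
#' @param fpkm matrix/data.frame of FPKM values, rownames = transcript ids,
#'   covering every candidate
#' @param genome [Biostrings::DNAStringSet]
#' @param config a [filter_config()]
#' @param external_verdicts optional external coding-potential verdicts
#'   (see [score_coding_potential()])
#' @return data.frame of per-transcript verdicts: `transcript_id`, `passed`,
#'   `failed_rules` (comma-joined, in rule order), `orf_length_nt`, `class`
#'   (`lincRNA`/`antisense`/`NA`)
#' @export
run_filter_cascade <- function(candidates, known, fpkm, genome, config,
                               external_verdicts = NULL) {
  stopifnot(inherits(config, "lnc_filter_config"))
  ids <- transcript_ids(candidates)
  known_ids <- transcript_ids(known)
  dup <- intersect(ids, known_ids)
  if (length(dup)) {
    message("dropping ", length(dup),
            " candidate(s) already present in the known annotation")
    ids <- setdiff(ids, dup)
  }
  fpkm <- as.matrix(fpkm)
  missing <- setdiff(ids, rownames(fpkm))
  if (length(missing))
    stop("FPKM table is missing candidate transcript(s): ",
         paste(head(missing, 5), collapse = ", "))
  check_external_verdicts(external_verdicts, ids)

  if (!length(ids)) {
    return(data.frame(transcript_id = character(), passed = logical(),
                      failed_rules = character(), orf_length_nt = integer(),
                      class = character(), stringsAsFactors = FALSE))
  }

  known_exons <- known$exons
  gene_spans <- GenomicRanges::GRanges(
    known$genes$chrom,
    IRanges::IRanges(known$genes$span_start, known$genes$span_end),
    strand = known$genes$strand)

  res <- lapply(ids, function(id) {
    tx <- get_transcript(candidates, id)
    fails <- character()
    if (nrow(tx$exons) < config$min_exons) fails <- c(fails, "single_exon")
    if (tx$spliced_length <= config$min_length_nt)
      fails <- c(fails, "too_short")
    if (max(fpkm[id, ]) < config$min_fpkm) fails <- c(fails, "low_fpkm")

    tx_gr <- GenomicRanges::GRanges(
      tx$chrom, IRanges::IRanges(tx$exons$start, tx$exons$end))
    ov <- GenomicRanges::countOverlaps(tx_gr, known_exons,
                                       ignore.strand = TRUE)
    if (any(ov > 0)) fails <- c(fails, "annotation_overlap")

    seq <- spliced_sequence(tx, genome)
    cp <- score_coding_potential(id, seq, config, external_verdicts)
    if (cp$verdict == "coding") fails <- c(fails, "coding_potential")

    passed <- !length(fails)
    cls <- if (passed) classify_lncrna(tx, known, gene_spans) else NA_character_
    data.frame(transcript_id = id, passed = passed,
               failed_rules = paste(fails, collapse = ","),
               orf_length_nt = cp$orf_length_nt, class = cls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a surviving lncRNA as lincRNA or antisense
#'
#' `antisense` iff the transcript has any (exonic or intronic) overlap with
#' a known gene's span on the OPPOSITE strand; otherwise `lincRNA`.
#'
#' @param transcript a transcript as returned by [get_transcript()]
#' @param known `lnc_annotation` of reference gene models
#' @param gene_spans optional precomputed `GRanges` of gene spans
#' @return `"lincRNA"` or `"antisense"`
#' @export
classify_lncrna <- function(transcript, known, gene_spans = NULL) {
  if (is.null(gene_spans)) {
    gene_spans <- GenomicRanges::GRanges(
      known$genes$chrom,
      IRanges::IRanges(known$genes$span_start, known$genes$span_end),
      strand = known$genes$strand)
  }
  span <- GenomicRanges::GRanges(
    transcript$chrom,
    IRanges::IRanges(min(transcript$exons$start), max(transcript$exons$end)),
    strand = transcript$strand)
  hits <- GenomicRanges::findOverlaps(span, gene_spans, ignore.strand = TRUE)
  if (length(hits)) {
    ov_strands <- as.character(
      GenomicRanges::strand(gene_spans)[S4Vectors::subjectHits(hits)])
    if (any(ov_strands != transcript$strand)) return("antisense")
  }
  "lincRNA"
}

#' Summary statistics of an identified lncRNA set
#'
#' Reports class counts and percentages (1 decimal), a spliced-length
#' histogram (2,000 nt bins), an ORF-length histogram (50 bp bins), an
#' exon-count histogram, and the mean exon number (2 decimals) -- the
#' descriptive characterization conventionally reported for a discovered
#' lncRNA set.
#'
#' @param verdicts output of [run_filter_cascade()] (only `passed` rows are
#'   summarized)
#' @param candidates `lnc_annotation` containing the transcripts
#' @return list with `class_summary`, `length_hist`, `orf_hist`,
#'   `exon_hist`, `mean_exons`, `n`
#' @export
summarize_lncrna_set <- function(verdicts, candidates) {
  surv <- verdicts[verdicts$passed, , drop = FALSE]
  n <- nrow(surv)
  tx <- candidates$transcripts
  tx <- tx[match(surv$transcript_id, tx$transcript_id), , drop = FALSE]

  cls <- table(factor(surv$class, levels = c("lincRNA", "antisense")))
  class_summary <- data.frame(
    class = names(cls), count = as.integer(cls),
    percent = if (n) round(100 * as.integer(cls) / n, 1) else c(0, 0),
    stringsAsFactors = FALSE)

  hist_of <- function(x, width) {
    if (!length(x)) return(data.frame(bin_start = integer(), count = integer()))
    b <- (x - 1L) %/% width * width + 1L  # bins [1,w], [w+1,2w], ...
    tab <- table(b)
    data.frame(bin_start = as.integer(names(tab)), count = as.integer(tab))
  }
  length_hist <- hist_of(tx$spliced_length, 2000L)
  orf_hist <- hist_of(pmax(surv$orf_length_nt, 1L), 50L)
  exon_tab <- table(tx$n_exons)
  exon_hist <- data.frame(n_exons = as.integer(names(exon_tab)),
                          count = as.integer(exon_tab))

  list(class_summary = class_summary, length_hist = length_hist,
       orf_hist = orf_hist, exon_hist = exon_hist,
       mean_exons = if (n) round(mean(tx$n_exons), 2) else NA_real_,
       n = n)
}
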