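#' Cis target genes within a genomic window
#'
#' A gene is a cis target of a lncRNA when its span intersects the lncRNA
#' span extended by `window` bp on both sides, on the same chromosome,
#' strand-agnostic.  The boundary is inclusive: a gap of exactly `window`
#' is reported.  `distance` is the gap between the two spans (number of
#' bases strictly between them; 0 when they intersect or are adjacent),
#' signed negative when the gene lies left (upstream in genomic
#' coordinates) of the lncRNA.
#'
#' @param lncs `lnc_annotation` (or its `$transcripts` slice) of the
#'   differentially expressed lncRNAs; spans are taken per transcript
#' @param genes `lnc_annotation` of protein-coding gene models
#' @param window half-window in bp (default 100,000)
#' @return data.frame: `lncRNA_id`, `gene_id`, `distance`, `side`
#'   (`upstream`/`downstream`/`overlapping`), sorted by lncRNA then gene
#' @export
find_cis_targets <- function(lncs, genes, window = 100000L) {
  ltx <- if (inherits(lncs, "lnc_annotation")) lncs$transcripts else lncs
  gdf <- genes$genes
  empty <- data.frame(lncRNA_id = character(), gene_id = character(),
                      distance = integer(), side = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(ltx) || !nrow(gdf)) return(empty)

  lgr <- GenomicRanges::GRanges(
    ltx$chrom, IRanges::IRanges(ltx$span_start, ltx$span_end))
  ggr <- GenomicRanges::GRanges(
    gdf$chrom, IRanges::IRanges(gdf$span_start, gdf$span_end))
  # maxgap counts bases strictly between the ranges, matching `distance`
  hits <- GenomicRanges::findOverlaps(lgr, ggr, maxgap = window,
                                      ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  gap <- ifelse(gdf$span_start[si] > ltx$span_end[qi],
                gdf$span_start[si] - ltx$span_end[qi] - 1L,
         ifelse(gdf$span_end[si] < ltx$span_start[qi],
                -(ltx$span_start[qi] - gdf$span_end[si] - 1L), 0L))
  out <- data.frame(
    lncRNA_id = ltx$transcript_id[qi], gene_id = gdf$gene_id[si],
    distance = as.integer(gap),
    side = ifelse(gap > 0, "downstream",
                  ifelse(gap < 0, "upstream", "overlapping")),
    stringsAsFactors = FALSE)
  out <- out[abs(out$distance) <= window, , drop = FALSE]
  out <- out[order(out$lncRNA_id, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Pearson correlation with two-sided t-test p-value
#'
#' Sample Pearson r with the classical two-sided p from
#' t = r * sqrt(n - 2) / sqrt(1 - r^2) on n - 2 degrees of freedom
#' (the test behind `cor.test`).  r = +-1 returns p = 0.
#'
#' @param x,y numeric vectors, equal length n >= 3, non-zero variance
#' @return list with `r` and `p_value`
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3L)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  r <- cor(x, y)
  if (abs(r) >= 1) return(list(r = sign(r), p_value = 0))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p_value = 2 * pt(-abs(t), df = n - 2))
}

#' Trans target genes by co-expression
#'
#' Tests every lncRNA x gene pair across the shared sample columns and
#' keeps pairs with |r| > `r_threshold` (strict) and p < `p_threshold`
#' (strict).  Pairs where either profile has zero variance are skipped and
#' counted in the `n_skipped` attribute (with a warning) -- at n = 5 such
#' degenerate profiles are common and should not abort a run.
#'
#' @param del_expr matrix of lncRNA expression (rows = lncRNAs, columns =
#'   samples), typically FPKM
#' @param deg_expr matrix of gene expression over the same columns
#' @param r_threshold keep |r| strictly greater (default 0.95)
#' @param p_threshold keep p strictly smaller (default 0.05)
#' @param log_transform correlate log2(x + 1) instead of raw values
#' @return data.frame `lncRNA_id`, `gene_id`, `r`, `p_value`, `sign`
#'   (`positive`/`negative`), sorted; attributes `n_positive`,
#'   `n_negative`, `n_skipped`
#' @export
find_trans_targets <- function(del_expr, deg_expr, r_threshold = 0.95,
                               p_threshold = 0.05, log_transform = FALSE) {
  del_expr <- as.matrix(del_expr)
  deg_expr <- as.matrix(deg_expr)
  stopifnot(identical(colnames(del_expr), colnames(deg_expr)))
  if (log_transform) {
    del_expr <- log2(del_expr + 1)
    deg_expr <- log2(deg_expr + 1)
  }
  empty <- data.frame(lncRNA_id = character(), gene_id = character(),
                      r = numeric(), p_value = numeric(),
                      sign = character(), stringsAsFactors = FALSE)
  if (!nrow(del_expr) || !nrow(deg_expr)) {
    attr(empty, "n_positive") <- 0L
    attr(empty, "n_negative") <- 0L
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  skipped <- 0L
  rows <- list()
  for (i in seq_len(nrow(del_expr))) {
    x <- del_expr[i, ]
    if (sd(x) == 0) { skipped <- skipped + nrow(deg_expr); next }
    for (j in seq_len(nrow(deg_expr))) {
      y <- deg_expr[j, ]
      if (sd(y) == 0) { skipped <- skipped + 1L; next }
      ct <- pearson_with_p(x, y)
      if (abs(ct$r) > r_threshold && ct$p_value < p_threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          lncRNA_id = rownames(del_expr)[i], gene_id = rownames(deg_expr)[j],
          r = ct$r, p_value = ct$p_value,
          sign = if (ct$r > 0) "positive" else "negative",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (skipped)
    warning(skipped, " pair(s) skipped for zero variance", call. = FALSE)
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$lncRNA_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_positive") <- sum(out$sign == "positive")
  attr(out, "n_negative") <- sum(out$sign == "negative")
  attr(out, "n_skipped") <- skipped
  out
}

#' Genes targeted both in cis and in trans
#'
#' @param cis output of [find_cis_targets()]
#' @param trans output of [find_trans_targets()]
#' @return sorted character vector of gene ids in both sets
#' @export
overlap_cis_trans <- function(cis, trans) {
  sort(intersect(unique(cis$gene_id), unique(trans$gene_id)))
}
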