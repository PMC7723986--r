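#' Transcript annotation container
#'
#' An `lnc_annotation` bundles exon records grouped into transcripts and gene
#' models, with a per-chromosome interval index ([GenomicRanges::GRanges])
#' used by all window and overlap queries downstream.  Coordinates follow the
#' GTF convention throughout: 1-based, closed intervals.
#'
#' @param exons data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (`"+"` or `"-"`; `"."` is rejected because every downstream rule --
#'   antisense classification, ORF scoring -- is strand-dependent),
#'   `gene_id`, `transcript_id`.  Exons of one transcript must be pairwise
#'   disjoint.
#'
#' @return An object of class `lnc_annotation` with components
#'   \describe{
#'     \item{exons}{`GRanges` of exons carrying `transcript_id`, `gene_id`}
#'     \item{transcripts}{data.frame: `transcript_id`, `gene_id`, `chrom`,
#'       `strand`, `n_exons`, `spliced_length`, `span_start`, `span_end`}
#'     \item{genes}{data.frame: `gene_id`, `chrom`, `strand`, `span_start`,
#'       `span_end`, `n_transcripts`}
#'   }
#' @export
annotation <- function(exons = NULL) {
  cols <- c("chrom", "start", "end", "strand", "gene_id", "transcript_id")
  if (is.null(exons) || nrow(exons) == 0L) {
    exons <- data.frame(chrom = character(), start = integer(),
                        end = integer(), strand = character(),
                        gene_id = character(), transcript_id = character(),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(cols %in% names(exons)))
  exons <- exons[cols]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$start < 1L)) stop("exon start must be >= 1")
  if (any(exons$end < exons$start)) stop("exon end must be >= start")
  if (!all(exons$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' (unknown strand '.' is rejected)")

  exons <- exons[order(exons$chrom, exons$start, exons$end,
                       exons$transcript_id), , drop = FALSE]
  rownames(exons) <- NULL

  if (nrow(exons)) {
    by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
    for (idx in by_tx) {
      e <- exons[idx, ]
      if (length(unique(e$chrom)) != 1L || length(unique(e$strand)) != 1L ||
          length(unique(e$gene_id)) != 1L)
        stop("transcript '", e$transcript_id[1],
             "' has inconsistent chrom/strand/gene_id across exons")
      if (nrow(e) > 1L && any(e$start[-1] <= e$end[-nrow(e)]))
        stop("transcript '", e$transcript_id[1], "' has overlapping exons")
    }
    tx <- do.call(rbind, lapply(by_tx, function(idx) {
      e <- exons[idx, ]
      data.frame(transcript_id = e$transcript_id[1], gene_id = e$gene_id[1],
                 chrom = e$chrom[1], strand = e$strand[1],
                 n_exons = nrow(e),
                 spliced_length = sum(e$end - e$start + 1L),
                 span_start = min(e$start), span_end = max(e$end),
                 stringsAsFactors = FALSE)
    }))
    tx <- tx[order(tx$chrom, tx$span_start, tx$transcript_id), ]
    rownames(tx) <- NULL
    gn <- do.call(rbind, lapply(split(tx, tx$gene_id), function(g) {
      if (length(unique(g$chrom)) != 1L || length(unique(g$strand)) != 1L)
        stop("gene '", g$gene_id[1], "' spans chromosomes or strands")
      data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
                 strand = g$strand[1], span_start = min(g$span_start),
                 span_end = max(g$span_end), n_transcripts = nrow(g),
                 stringsAsFactors = FALSE)
    }))
    gn <- gn[order(gn$chrom, gn$span_start, gn$gene_id), ]
    rownames(gn) <- NULL
  } else {
    tx <- data.frame(transcript_id = character(), gene_id = character(),
                     chrom = character(), strand = character(),
                     n_exons = integer(), spliced_length = integer(),
                     span_start = integer(), span_end = integer(),
                     stringsAsFactors = FALSE)
    gn <- data.frame(gene_id = character(), chrom = character(),
                     strand = character(), span_start = integer(),
                     span_end = integer(), n_transcripts = integer(),
                     stringsAsFactors = FALSE)
  }

  gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = exons$start, end = exons$end),
    strand = exons$strand)
  S4Vectors::mcols(gr)$transcript_id <- exons$transcript_id
  S4Vectors::mcols(gr)$gene_id <- exons$gene_id

  structure(list(exons = gr, transcripts = tx, genes = gn),
            class = "lnc_annotation")
}

#' @export
print.lnc_annotation <- function(x, ...) {
  cat("lnc_annotation:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts,", length(x$exons), "exons\n")
  invisible(x)
}

#' @rdname annotation
#' @param ann an `lnc_annotation`
#' @export
transcript_ids <- function(ann) ann$transcripts$transcript_id

exon_table <- function(ann) {
  gr <- ann$exons
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             gene_id = S4Vectors::mcols(gr)$gene_id,
             transcript_id = S4Vectors::mcols(gr)$transcript_id,
             stringsAsFactors = FALSE)
}

#' Extract one transcript model
#'
#' @param ann an `lnc_annotation`
#' @param id transcript id
#' @return list with `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `spliced_length` and an `exons` data.frame (`start`, `end`, sorted).
#' @export
get_transcript <- function(ann, id) {
  row <- ann$transcripts[ann$transcripts$transcript_id == id, ]
  if (nrow(row) != 1L) stop("unknown transcript id: ", id)
  keep <- S4Vectors::mcols(ann$exons)$transcript_id == id
  gr <- ann$exons[keep]
  ex <- data.frame(start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr))
  ex <- ex[order(ex$start), , drop = FALSE]
  rownames(ex) <- NULL
  list(transcript_id = id, gene_id = row$gene_id, chrom = row$chrom,
       strand = row$strand, spliced_length = row$spliced_length,
       exons = ex)
}

#' Query the interval index
#'
#' Returns the transcript ids with at least one exon overlapping the query
#' interval (1-based, closed), in sorted order.
#'
#' @param ann an `lnc_annotation`
#' @param chrom chromosome name
#' @param start,end query interval, 1-based closed
#' @export
query_overlaps <- function(ann, chrom, start, end) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(q, ann$exons, ignore.strand = TRUE)
  sort(unique(S4Vectors::mcols(ann$exons)$transcript_id[
    S4Vectors::subjectHits(hits)]))
}

#' Read exon records from a GTF file
#'
#' Only `exon` feature lines are semantic; all other feature types are
#' ignored.  Attributes in both the GTF dialect (`key "value";`) and the
#' `key=value` dialect are accepted.  Malformed lines raise an error naming
#' the line number.
#'
#' @param path GTF file path
#' @return an [annotation()] object
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) return(annotation())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("malformed GTF line ", idx[which(nf != 9L)[1]],
         ": expected 9 tab-separated fields, got ", nf[nf != 9L][1])
  feat <- vapply(fields, `[[`, "", 3L)
  is_exon <- feat == "exon"
  if (!any(is_exon)) return(annotation())
  fields <- fields[is_exon]
  lineno <- idx[is_exon]

  get_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexec(
      paste0(key, '(?:\\s+"([^"]*)"|=\\s*"?([^";]*)"?)\\s*;?'), attrs))[[1]]
    if (length(m) < 2L) return(NA_character_)
    v <- m[-1][m[-1] != ""]
    if (!length(v)) NA_character_ else v[1]
  }

  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end))
      stop("malformed GTF line ", lineno[i], ": non-numeric coordinates")
    gid <- get_attr(f[9], "gene_id")
    tid <- get_attr(f[9], "transcript_id")
    if (is.na(tid))
      stop("malformed GTF line ", lineno[i], ": exon missing transcript_id")
    if (is.na(gid))
      stop("malformed GTF line ", lineno[i], ": exon missing gene_id")
    if (!f[7] %in% c("+", "-"))
      stop("malformed GTF line ", lineno[i],
           ": strand must be '+' or '-', got '", f[7], "'")
    data.frame(chrom = f[1], start = start, end = end, strand = f[7],
               gene_id = gid, transcript_id = tid, stringsAsFactors = FALSE)
  })
  annotation(do.call(rbind, rows))
}

#' Write an annotation as GTF exon lines
#'
#' Emits 1-based closed-interval `exon` lines in the quoted attribute
#' dialect, deterministically ordered by (chrom, start, transcript_id), so
#' that repeated runs are byte-identical.
#'
#' @param ann an `lnc_annotation`
#' @param path output path
#' @export
write_gtf <- function(ann, path) {
  ex <- exon_table(ann)
  if (nrow(ex)) {
    ex <- ex[order(ex$chrom, ex$start, ex$transcript_id, ex$end), ]
    lines <- sprintf(
      '%s\tlnclact\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
      ex$chrom, ex$start, ex$end, ex$strand, ex$gene_id, ex$transcript_id)
  } else lines <- character()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Spliced transcript sequence
#'
#' Concatenates the exon subsequences in genomic order; for minus-strand
#' transcripts the reverse complement of the concatenation is returned, so
#' the result always reads 5' to 3'.
#'
#' @param transcript a transcript as returned by [get_transcript()]
#' @param genome a [Biostrings::DNAStringSet] keyed by chromosome name
#' @return a character string of nucleotides
#' @export
spliced_sequence <- function(transcript, genome) {
  chrom <- transcript$chrom
  if (!chrom %in% names(genome))
    stop("chromosome '", chrom, "' not present in genome")
  chrlen <- Biostrings::width(genome[chrom])
  ex <- transcript$exons
  if (any(ex$start < 1L) || any(ex$end > chrlen))
    stop("exon coordinates out of range for '", transcript$transcript_id,
         "' on ", chrom, " (length ", chrlen, ")")
  parts <- Biostrings::extractAt(
    genome[[chrom]], IRanges::IRanges(ex$start, ex$end))
  s <- Biostrings::DNAString(paste(as.character(parts), collapse = ""))
  if (transcript$strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Spliced sequences for many transcripts
#'
#' @param ann an `lnc_annotation`
#' @param genome a [Biostrings::DNAStringSet]
#' @param ids transcript ids (default: all)
#' @return named character vector of spliced sequences
#' @export
spliced_sequences <- function(ann, genome, ids = transcript_ids(ann)) {
  setNames(vapply(ids, function(id)
    spliced_sequence(get_transcript(ann, id), genome), ""), ids)
}

#' Exon-level overlap between two transcripts
#'
#' TRUE iff some exon of `t1` shares at least one base with some exon of
#' `t2` (closed intervals), optionally requiring the same strand.  Introns
#' do not count.
#'
#' @param t1,t2 transcripts as returned by [get_transcript()]
#' @param same_strand if TRUE, transcripts on opposite strands never overlap
#' @export
exonic_overlap <- function(t1, t2, same_strand = FALSE) {
  if (t1$chrom != t2$chrom) return(FALSE)
  if (same_strand && t1$strand != t2$strand) return(FALSE)
  any(outer(t1$exons$start, t2$exons$end, `<=`) &
      outer(t1$exons$end, t2$exons$start, `>=`))
}

#' Read a genome FASTA
#'
#' @param path FASTA path
#' @return a [Biostrings::DNAStringSet]
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  # keep only the first word of each header as the chromosome name
  names(g) <- sub("\\s.*$", "", names(g))
  g
}
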