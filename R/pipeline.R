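#' Pipeline configuration
#'
#' Collects all input/output paths, stage thresholds and stage switches.
#' Threshold defaults are the study thresholds used throughout the
#' package: filter cascade (2 exons, >200 nt, FPKM >= 0.5, ORF < 300 nt),
#' DE (|log2FC| >= 1, p < 0.05), cis window 100 kb, trans |r| > 0.95 and
#' p < 0.05, enrichment overlap > 5 and p < 0.05.
#'
#' @param inputs named list of input paths: `genome`, `known_gtf`,
#'   `candidate_gtf`, `counts`, `samples`, `terms`, and optionally
#'   `qpcr`, `external_verdicts`
#' @param out_dir output directory
#' @param filter named list overriding [filter_config()] arguments
#' @param de named list: `lfc_threshold`, `p_threshold`
#' @param targets named list: `cis_window`, `r_threshold`, `p_threshold`,
#'   `log_transform`
#' @param enrichment named list: `min_count`, `p_threshold`,
#'   `use_adjusted`
#' @param qpcr named list: `reference_genes`, `calibrator_group`
#' @param network named list: `gene_whitelist` (character vector or NULL)
#' @param stages named logical: which of identify, de, targets, enrich,
#'   network, qpcr to run
#' @param seed seed recorded for stochastic stages (none in the analysis
#'   path itself)
#' @export
pipeline_config <- function(inputs, out_dir, filter = list(),
                            de = list(), targets = list(),
                            enrichment = list(), qpcr = list(),
                            network = list(), stages = NULL, seed = 1L) {
  defaults <- list(
    inputs = inputs, out_dir = out_dir,
    filter = list(min_exons = 2L, min_length_nt = 200L, min_fpkm = 0.5,
                  coding_orf_threshold_nt = 300L,
                  evidence_mode = "orf_only"),
    de = list(lfc_threshold = 1, p_threshold = 0.05),
    targets = list(cis_window = 100000L, r_threshold = 0.95,
                   p_threshold = 0.05, log_transform = FALSE),
    enrichment = list(min_count = 5L, p_threshold = 0.05,
                      use_adjusted = FALSE),
    qpcr = list(reference_genes = c("HMBS", "YWHAZ"),
                calibrator_group = "DP"),
    network = list(gene_whitelist = NULL),
    stages = list(identify = TRUE, de = TRUE, targets = TRUE,
                  enrich = TRUE, network = TRUE, qpcr = TRUE),
    seed = as.integer(seed))
  for (sec in c("filter", "de", "targets", "enrichment", "qpcr",
                "network")) {
    ov <- get(sec)
    for (k in names(ov)) defaults[[sec]][[k]] <- ov[[k]]
  }
  if (!is.null(stages))
    for (k in names(stages)) defaults$stages[[k]] <- stages[[k]]
  structure(defaults, class = "lnc_pipeline_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' The configuration round-trips losslessly through its file format.
#'
#' @param config a [pipeline_config()]
#' @param path YAML file path
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "lnc_pipeline_config")
}

read_counts_table <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full downstream lncRNA pipeline
#'
#' Stages in order: identify (filter cascade + classification), de (FPKM,
#' dispersion, exact tests for lncRNAs at transcript level and genes at
#' gene level), targets (cis window + trans co-expression), enrich
#' (hypergeometric tests of cis and trans target genes), network
#' (Cytoscape-loadable export), qpcr (2^-ddCt concordance).  Each stage
#' writes deterministic TSVs under `out_dir`; a manifest records the
#' configuration hash, input checksums and per-stage row counts.
#' Re-running on identical inputs yields byte-identical outputs (the
#' manifest's timestamp aside).
#'
#' @param config a [pipeline_config()]
#' @return invisible list with the per-stage results and the `manifest`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "lnc_pipeline_config"))
  inp <- config$inputs
  for (k in c("genome", "known_gtf", "candidate_gtf", "counts", "samples"))
    if (is.null(inp[[k]]) || !file.exists(inp[[k]]))
      stop("missing input '", k, "'", if (!is.null(inp[[k]]))
        paste0(": ", inp[[k]]))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  on <- function(s) isTRUE(config$stages[[s]])
  counts_stage <- list()
  res <- list()
  stage_counts <- list()
  n_warnings <- 0L
  with_warning_count <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      n_warnings <<- n_warnings + 1L
      invokeRestart("muffleWarning")
    })
  }

  any_on <- any(vapply(config$stages, isTRUE, TRUE))
  if (any_on) run_stage("load", {
    samples <- read_tsv(inp$samples)
    counts <- read_counts_table(inp$counts)
    counts <- counts[, samples$sample, drop = FALSE]
    groups <- factor(samples$group, levels = c("LP", "DP"))
    lib <- setNames(as.numeric(samples$library_size), samples$sample)

    known <- read_gtf(inp$known_gtf)
    candidates <- read_gtf(inp$candidate_gtf)
    genome <- read_genome(inp$genome)

    lengths_all <- setNames(candidates$transcripts$spliced_length,
                            candidates$transcripts$transcript_id)
    absent <- setdiff(names(lengths_all), rownames(counts))
    if (length(absent))
      stop("counts table is missing annotated transcript(s): ",
           paste(head(absent, 5), collapse = ", "))
    fpkm <- compute_fpkm(counts[names(lengths_all), , drop = FALSE],
                         lengths_all, lib)
    write_tsv(data.frame(transcript_id = rownames(fpkm), round(fpkm, 6),
                         check.names = FALSE), out("fpkm.tsv"))
  })

  verdicts <- NULL
  if (on("identify")) {
    verdicts <- run_stage("identify", {
      ev <- if (!is.null(inp$external_verdicts) &&
                file.exists(inp$external_verdicts))
        read_tsv(inp$external_verdicts) else NULL
      cfg <- do.call(filter_config, config$filter)
      run_filter_cascade(candidates, known, fpkm, genome, cfg, ev)
    })
    write_tsv(verdicts, out("verdicts.tsv"))
    surv <- verdicts$transcript_id[verdicts$passed]
    surv_ex <- exon_table(candidates)
    surv_ann <- annotation(surv_ex[surv_ex$transcript_id %in% surv, ])
    write_gtf(surv_ann, out("lncrna.gtf"))
    stage_counts$identify <- list(candidates = nrow(verdicts),
                                  survivors = length(surv))
    res$verdicts <- verdicts
    res$survivors <- surv
  }

  de_lnc <- de_genes <- NULL
  if (on("de") && !is.null(verdicts)) {
    de <- run_stage("de", {
      surv <- res$survivors
      known_tx <- known$transcripts
      gene_counts <- rowsum(counts[known_tx$transcript_id, , drop = FALSE],
                            group = known_tx$gene_id)
      lnc_counts <- counts[surv, , drop = FALSE]
      phi <- estimate_common_dispersion(
        rbind(gene_counts, lnc_counts), groups, lib)$phi
      list(
        lnc = call_differential(lnc_counts, groups, lib, phi,
                                config$de$lfc_threshold,
                                config$de$p_threshold),
        genes = call_differential(gene_counts, groups, lib, phi,
                                  config$de$lfc_threshold,
                                  config$de$p_threshold),
        phi = phi)
    })
    de_lnc <- de$lnc
    de_genes <- de$genes
    write_tsv(de_lnc, out("de_lncrna.tsv"))
    write_tsv(de_genes, out("de_genes.tsv"))
    stage_counts$de <- list(
      phi = de$phi,
      del = sum(de_lnc$significant),
      del_up = attr(de_lnc, "n_up"), del_down = attr(de_lnc, "n_down"),
      deg = sum(de_genes$significant),
      deg_up = attr(de_genes, "n_up"), deg_down = attr(de_genes, "n_down"))
    res$de_lnc <- de_lnc
    res$de_genes <- de_genes
  }

  cis <- trans <- NULL
  if (on("targets") && !is.null(de_lnc)) {
    tg <- run_stage("targets", {
      dels <- de_lnc$feature_id[de_lnc$significant]
      degs <- de_genes$feature_id[de_genes$significant]
      ltx <- candidates$transcripts[
        candidates$transcripts$transcript_id %in% dels, ]
      cis <- find_cis_targets(ltx, known, config$targets$cis_window)
      # gene-level FPKM: sum member transcripts
      known_tx <- known$transcripts
      gene_fpkm <- rowsum(fpkm[known_tx$transcript_id, , drop = FALSE],
                          group = known_tx$gene_id)
      trans <- with_warning_count(find_trans_targets(
        fpkm[dels, , drop = FALSE],
        gene_fpkm[intersect(degs, rownames(gene_fpkm)), , drop = FALSE],
        config$targets$r_threshold, config$targets$p_threshold,
        config$targets$log_transform))
      list(cis = cis, trans = trans)
    })
    cis <- tg$cis
    trans <- tg$trans
    both <- overlap_cis_trans(cis, trans)
    write_tsv(cis, out("cis_targets.tsv"))
    write_tsv(trans, out("trans_targets.tsv"))
    write_tsv(data.frame(gene_id = both), out("cis_trans_overlap.tsv"))
    stage_counts$targets <- list(
      cis_pairs = nrow(cis), cis_genes = length(unique(cis$gene_id)),
      trans_pairs = nrow(trans),
      trans_positive = attr(trans, "n_positive"),
      trans_negative = attr(trans, "n_negative"),
      overlap_genes = length(both))
    res$cis <- cis
    res$trans <- trans
  }

  if (on("enrich") && !is.null(cis) && !is.null(inp$terms) &&
      file.exists(inp$terms)) {
    enr <- run_stage("enrich", {
      term_map <- read_tsv(inp$terms)
      list(cis = enrich(unique(cis$gene_id), term_map,
                        min_count = config$enrichment$min_count,
                        p_threshold = config$enrichment$p_threshold,
                        use_adjusted = config$enrichment$use_adjusted),
           trans = enrich(unique(trans$gene_id), term_map,
                          min_count = config$enrichment$min_count,
                          p_threshold = config$enrichment$p_threshold,
                          use_adjusted = config$enrichment$use_adjusted))
    })
    write_tsv(enr$cis, out("enrichment_cis.tsv"))
    write_tsv(enr$trans, out("enrichment_trans.tsv"))
    stage_counts$enrich <- list(
      cis_significant = sum(enr$cis$significant),
      trans_significant = sum(enr$trans$significant))
    res$enrichment <- enr
  }

  if (on("network") && !is.null(cis)) {
    net <- run_stage("network", with_warning_count(
      build_network(cis, trans, de_lnc, de_genes,
                    config$network$gene_whitelist)))
    export_network(net, out("network"), "edge_tsv")
    export_network(net, out("network"), "sif")
    stage_counts$network <- list(nodes = nrow(net$nodes),
                                 edges = nrow(net$edges))
    res$network <- net
  }

  if (on("qpcr") && !is.null(inp$qpcr) && file.exists(inp$qpcr) &&
      !is.null(de_lnc)) {
    qp <- run_stage("qpcr", {
      ct <- read_counts_table(inp$qpcr)
      refs <- config$qpcr$reference_genes
      panel <- setdiff(rownames(ct), refs)
      grp <- setNames(samples$group, samples$sample)
      q_lfc <- vapply(panel, function(f)
        ddct_fold_change(ct, f, grp, refs,
                         config$qpcr$calibrator_group)$log2_fold_change, 0)
      r_lfc <- setNames(de_lnc$log2fc, de_lnc$feature_id)
      concordance_report(q_lfc, r_lfc,
                         intersect(panel, de_lnc$feature_id))
    })
    write_tsv(qp$table, out("qpcr_concordance.tsv"))
    stage_counts$qpcr <- list(features = nrow(qp$table),
                              sign_agreement = qp$sign_agreement)
    res$qpcr <- qp
  }

  cfg_file <- tempfile(fileext = ".yaml")
  write_pipeline_config(config, cfg_file)
  manifest <- list(
    tool = "lnclact",
    version = as.character(utils::packageVersion("lnclact")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = unname(tools::md5sum(cfg_file)),
    inputs = lapply(inp[!vapply(inp, is.null, TRUE)], function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    stage_counts = stage_counts,
    n_warnings = n_warnings)
  unlink(cfg_file)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
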