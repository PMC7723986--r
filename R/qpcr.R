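#' Relative quantification by the 2^-ddCt method
#'
#' For each sample, dCt = Ct(target) - mean(Ct of the two reference genes)
#' (arithmetic mean of Cts, equivalent to geometric-mean normalization of
#' expression); ddCt = dCt - mean dCt over the calibrator group; fold
#' change = 2^(-ddCt).  PCR efficiency is fixed at 2 (100%).  The group
#' summary is the mean fold change over the non-calibrator (test) group.
#'
#' @param ct matrix of Ct values (rows = features incl. the reference
#'   genes, columns = samples)
#' @param target feature id to quantify
#' @param groups named vector/factor mapping each sample column to its
#'   group
#' @param reference_genes two reference gene ids
#'   (default `c("HMBS", "YWHAZ")`)
#' @param calibrator_group group used as ddCt baseline (default `"DP"`,
#'   the dry period)
#' @return list: `per_sample` (fold change for every sample),
#'   `fold_change` (mean over test-group samples), `log2_fold_change`
#' @export
ddct_fold_change <- function(ct, target, groups,
                             reference_genes = c("HMBS", "YWHAZ"),
                             calibrator_group = "DP") {
  ct <- as.matrix(ct)
  if (!target %in% rownames(ct)) stop("target '", target, "' not in Ct table")
  missing_ref <- setdiff(reference_genes, rownames(ct))
  if (length(missing_ref))
    stop("reference gene(s) missing from Ct table: ",
         paste(missing_ref, collapse = ", "))
  groups <- setNames(as.character(groups),
                     names(groups) %||% colnames(ct))
  stopifnot(all(colnames(ct) %in% names(groups)))
  grp <- groups[colnames(ct)]
  if (!calibrator_group %in% grp)
    stop("calibrator group '", calibrator_group, "' has no samples")
  if (anyNA(ct[c(target, reference_genes), ]))
    stop("missing Ct value for target or reference gene")

  ref_mean <- colMeans(ct[reference_genes, , drop = FALSE])
  dct <- ct[target, ] - ref_mean
  ddct <- dct - mean(dct[grp == calibrator_group])
  fc <- 2^(-ddct)
  test <- grp != calibrator_group
  group_fc <- mean(fc[test])
  list(per_sample = fc, fold_change = group_fc,
       log2_fold_change = log2(group_fc))
}

#' qPCR / RNA-seq concordance report
#'
#' Pairs the qPCR log2 fold changes with the RNA-seq log2 fold changes for
#' a feature list and reports per-feature sign agreement plus the overall
#' agreement fraction -- the conventional validation summary for a
#' sequencing experiment.
#'
#' @param qpcr_log2fc named numeric vector of qPCR log2 fold changes
#' @param rnaseq_log2fc named numeric vector of RNA-seq log2 fold changes
#' @param features feature ids to compare (default: intersection)
#' @return list with `table` (feature, qpcr_log2fc, rnaseq_log2fc,
#'   sign_match) and `sign_agreement` fraction
#' @export
concordance_report <- function(qpcr_log2fc, rnaseq_log2fc,
                               features = intersect(names(qpcr_log2fc),
                                                    names(rnaseq_log2fc))) {
  if (!length(features)) stop("no features to compare")
  missing <- setdiff(features, intersect(names(qpcr_log2fc),
                                         names(rnaseq_log2fc)))
  if (length(missing))
    stop("features missing from one of the inputs: ",
         paste(head(missing, 5), collapse = ", "))
  tab <- data.frame(
    feature = features,
    qpcr_log2fc = unname(qpcr_log2fc[features]),
    rnaseq_log2fc = unname(rnaseq_log2fc[features]),
    stringsAsFactors = FALSE)
  tab$sign_match <- sign(tab$qpcr_log2fc) == sign(tab$rnaseq_log2fc)
  list(table = tab, sign_agreement = mean(tab$sign_match))
}
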