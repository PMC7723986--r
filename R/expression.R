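#' FPKM from fragment counts
#'
#' fpkm\[f, s\] = counts\[f, s\] * 1e9 / (length_nt\[f\] * library_size\[s\]):
#' fragments per kilobase of exon per million mapped fragments.  Plain
#' spliced length is used (no effective-length correction).
#'
#' @param counts matrix of non-negative fragment counts,
#'   rownames = feature ids
#' @param transcript_lengths named vector of spliced lengths (nt) covering
#'   all rows
#' @param library_sizes named vector of per-sample total mapped fragments
#'   covering all columns
#' @return matrix of FPKM values, same dimnames as `counts`
#' @export
compute_fpkm <- function(counts, transcript_lengths, library_sizes) {
  counts <- as.matrix(counts)
  len <- transcript_lengths[rownames(counts)]
  lib <- library_sizes[colnames(counts)]
  if (anyNA(len)) stop("transcript_lengths missing for some features")
  if (anyNA(lib)) stop("library_sizes missing for some samples")
  if (any(len <= 0)) stop("transcript lengths must be > 0")
  if (any(lib <= 0)) stop("library sizes must be > 0")
  counts * 1e9 / outer(as.numeric(len), as.numeric(lib))
}

#' Library summary arithmetic
#'
#' Reproduces the usual RNA-seq library summary table: per-sample mapping
#' and unique-mapping percentages (mapped/clean * 100, 2 decimals) and
#' per-group / overall read totals in millions (2 decimals).
#'
#' @param qc data.frame with columns `sample`, `group`, `raw_reads`,
#'   `clean_reads`, `total_mapped`, `uniquely_mapped` (and optionally
#'   `q30_pct`, `gc_pct`)
#' @return list with `per_sample` (adds `mapped_pct`, `unique_pct`),
#'   `group_totals` (raw/clean sums in millions per group) and
#'   `total_clean_million`, `total_raw_million`
#' @export
summarize_libraries <- function(qc) {
  need <- c("sample", "group", "raw_reads", "clean_reads",
            "total_mapped", "uniquely_mapped")
  stopifnot(all(need %in% names(qc)))
  if (any(qc$total_mapped > qc$clean_reads))
    stop("total_mapped exceeds clean_reads for sample(s): ",
         paste(qc$sample[qc$total_mapped > qc$clean_reads], collapse = ", "))
  per_sample <- qc
  per_sample$mapped_pct <- round(100 * qc$total_mapped / qc$clean_reads, 2)
  per_sample$unique_pct <- round(100 * qc$uniquely_mapped / qc$clean_reads, 2)
  gt <- do.call(rbind, lapply(split(qc, qc$group), function(g)
    data.frame(group = g$group[1],
               raw_million = round(sum(g$raw_reads) / 1e6, 2),
               clean_million = round(sum(g$clean_reads) / 1e6, 2),
               stringsAsFactors = FALSE)))
  rownames(gt) <- NULL
  list(per_sample = per_sample, group_totals = gt,
       total_raw_million = round(sum(qc$raw_reads) / 1e6, 2),
       total_clean_million = round(sum(qc$clean_reads) / 1e6, 2))
}

# Scale counts to the geometric-mean library size and round to
# pseudo-counts; the exact test and the dispersion estimator both condition
# on these equalized counts.
equalize_libraries <- function(counts, library_sizes) {
  counts <- as.matrix(counts)
  lib <- as.numeric(library_sizes)
  if (any(lib <= 0)) stop("library sizes must be > 0")
  ref <- exp(mean(log(lib)))
  round(sweep(counts, 2, ref / lib, `*`))
}

#' Common negative-binomial dispersion by conditional maximum likelihood
#'
#' Estimates a single dispersion phi (Var = mu + phi * mu^2) shared by all
#' features, by maximizing the within-group likelihood conditional on the
#' per-group totals, summed over features -- the standard small-sample
#' strategy when only a handful of replicates is available.  Counts are
#' library-size-equalized to the geometric mean first.  The search is a
#' bounded 1-D optimization on \[0, 10\]; when the unconstrained optimum
#' would be negative, 0 (Poisson) is returned.
#'
#' @param counts count matrix (features x samples)
#' @param groups factor/character of group labels per sample (2 groups)
#' @param library_sizes per-sample library sizes (default: column sums)
#' @return list with `phi` and `method`
#' @export
estimate_common_dispersion <- function(counts, groups,
                                       library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (all(counts == 0)) stop("all-zero count matrix")
  groups <- as.factor(groups)
  stopifnot(ncol(counts) == length(groups))
  y <- equalize_libraries(counts, library_sizes)
  grp_idx <- split(seq_len(ncol(y)), groups)

  cond_ll <- function(phi) {
    r <- 1 / phi
    ll <- 0
    for (idx in grp_idx) {
      n <- length(idx)
      if (n < 2L) next
      yg <- y[, idx, drop = FALSE]
      z <- rowSums(yg)
      keep <- z > 0
      if (!any(keep)) next
      yg <- yg[keep, , drop = FALSE]
      z <- z[keep]
      ll <- ll + sum(lgamma(yg + r)) - sum(keep) * n * lgamma(r) +
        sum(keep) * lgamma(n * r) - sum(lgamma(z + n * r))
    }
    ll
  }
  opt <- optimize(cond_ll, interval = c(1e-6, 10), maximum = TRUE,
                  tol = 1e-6)
  phi <- opt$maximum
  # boundary: if the likelihood at the smallest admissible phi beats the
  # interior optimum, the unconstrained optimum is at or below zero
  if (cond_ll(1e-6) >= opt$objective || phi < 1e-4) phi <- 0
  list(phi = phi, method = "conditional_ml_common")
}

#' Conditional negative-binomial exact test for one feature
#'
#' Two-group exact test: counts are equalized to the geometric-mean library
#' size, and, conditional on the total pseudo-count S, the null distribution
#' of the group-A sum is computed exactly (the group sums of i.i.d. NB
#' variables with common dispersion are NB with size n_g/phi; their
#' conditional law given S does not depend on the mean).  The two-sided
#' p-value is the total probability of all splits no more probable than the
#' observed one, capped at 1.  phi = 0 gives the binomial (Poisson-limit)
#' null.
#'
#' @param counts_feature vector of counts, one per sample
#' @param groups two-level factor/character per sample
#' @param library_sizes per-sample library sizes
#' @param phi common NB dispersion (>= 0)
#' @return p-value in (0, 1]; S = 0 returns 1 by convention
#' @export
nb_exact_test <- function(counts_feature, groups, library_sizes, phi) {
  stopifnot(phi >= 0, length(counts_feature) == length(groups),
            length(counts_feature) == length(library_sizes))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  y <- drop(equalize_libraries(matrix(counts_feature, nrow = 1),
                               library_sizes))
  nA <- sum(groups == levels(groups)[1])
  nB <- sum(groups == levels(groups)[2])
  a_obs <- sum(y[groups == levels(groups)[1]])
  S <- sum(y)
  if (S == 0) return(1)

  a <- 0:S
  if (phi == 0) {
    logp <- dbinom(a, S, nA / (nA + nB), log = TRUE)
  } else {
    rA <- nA / phi
    rB <- nB / phi
    logp <- lgamma(a + rA) - lgamma(a + 1) +
      lgamma(S - a + rB) - lgamma(S - a + 1)
    logp <- logp - logsumexp(logp)
  }
  p_obs <- logp[a_obs + 1]
  # numerical tolerance so ties in probability are counted symmetrically
  p <- sum(exp(logp[logp <= p_obs + 1e-10]))
  min(p, 1)
}

#' Two-group differential expression calls
#'
#' Applies [nb_exact_test()] per feature and flags significance by the
#' |log2 fold change| >= 1 AND p < 0.05 rule.  The fold change is
#' log2(groupA / groupB) of library-size-normalized group mean counts; a
#' pseudo-count of 0.5 is added to both means when either is zero (display
#' only -- the test never sees it).  Raw p-values drive the calls, exactly
#' as the thresholds state; a BH-adjusted column is reported alongside for
#' reference.
#'
#' @param counts count matrix (features x samples)
#' @param groups two-level factor; the FIRST level is the numerator of the
#'   fold change (`direction` is "up"/"down" with respect to it)
#' @param library_sizes per-sample library sizes (default column sums)
#' @param phi common dispersion; estimated by
#'   [estimate_common_dispersion()] when NULL
#' @param lfc_threshold minimum |log2FC| (default 1)
#' @param p_threshold p-value cutoff (default 0.05, strict)
#' @return data.frame sorted by p then id: `feature_id`, `baseMeanA`,
#'   `baseMeanB`, `log2fc`, `p_value`, `adj_p`, `significant`, `direction`
#' @export
call_differential <- function(counts, groups,
                              library_sizes = colSums(counts), phi = NULL,
                              lfc_threshold = 1, p_threshold = 0.05) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  if (any(table(groups) == 0)) stop("both groups must be non-empty")
  empty <- data.frame(feature_id = character(), baseMeanA = numeric(),
                      baseMeanB = numeric(), log2fc = numeric(),
                      p_value = numeric(), adj_p = numeric(),
                      significant = logical(), direction = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(counts)) return(empty)
  if (is.null(phi)) phi <- estimate_common_dispersion(
    counts, groups, library_sizes)$phi

  lib <- as.numeric(library_sizes)
  ref <- exp(mean(log(lib)))
  norm <- sweep(counts, 2, ref / lib, `*`)
  iA <- groups == levels(groups)[1]
  mA <- rowMeans(norm[, iA, drop = FALSE])
  mB <- rowMeans(norm[, !iA, drop = FALSE])
  zero <- mA == 0 | mB == 0
  log2fc <- log2(ifelse(zero, mA + 0.5, mA) / ifelse(zero, mB + 0.5, mB))

  p <- vapply(seq_len(nrow(counts)), function(i)
    nb_exact_test(counts[i, ], groups, library_sizes, phi), 0)

  out <- data.frame(
    feature_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    baseMeanA = mA, baseMeanB = mB, log2fc = log2fc, p_value = p,
    adj_p = p.adjust(p, "BH"),
    significant = abs(log2fc) >= lfc_threshold & p < p_threshold,
    direction = ifelse(log2fc >= 0, "up", "down"),
    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$feature_id), ]
  rownames(out) <- NULL
  attr(out, "phi") <- phi
  attr(out, "n_up") <- sum(out$significant & out$direction == "up")
  attr(out, "n_down") <- sum(out$significant & out$direction == "down")
  out
}
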