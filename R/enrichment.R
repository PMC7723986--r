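#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the over-representation
#' p-value for drawing k annotated genes in a query of size n from a
#' background of N genes of which K carry the term,
#' p = sum_{i=k}^{min(K,n)} C(K,i) C(N-K, n-i) / C(N,n),
#' accumulated in log space for stability.
#'
#' @param N background size
#' @param K term genes in background
#' @param n query size
#' @param k overlap
#' @return p-value in (0, 1]
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  stopifnot(N >= 0, K >= 0, n >= 0, k >= 0)
  if (k > K) stop("impossible configuration: k > K")
  if (k > n) stop("impossible configuration: k > n")
  if (K > N || n > N) stop("impossible configuration: K or n exceeds N")
  if (k == 0) return(1)
  i <- k:min(K, n)
  lo <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(exp(logsumexp(lo)), 1)
}

#' Term over-representation analysis
#'
#' One hypergeometric test per term with K >= 1 against the background of
#' all annotated genes in the supplied mapping.  A term is flagged
#' significant when the overlap k is strictly greater than `min_count` AND
#' p < `p_threshold`; BH-adjusted p-values are reported alongside (and can
#' be used as the filter instead via `use_adjusted`).  Query genes absent
#' from the annotation are dropped from n, with a message.  The rich
#' factor k/K is the conventional bubble-plot x-axis.
#'
#' @param query character vector of gene ids (e.g. cis or trans targets)
#' @param term_map data.frame `gene_id`, `term_id` and optionally
#'   `term_name`
#' @param background optional character vector; default = all annotated
#'   genes in `term_map`
#' @param min_count overlap must be strictly greater than this (default 5)
#' @param p_threshold significance cutoff (default 0.05, strict)
#' @param use_adjusted apply the cutoff to BH-adjusted p instead of raw p
#' @return data.frame sorted by p then term: `term_id`, `term_name`, `N`,
#'   `K`, `n`, `k`, `p_value`, `adjusted_p`, `rich_factor`, `significant`;
#'   attribute `n_dropped` counts unannotated query genes
#' @export
enrich <- function(query, term_map, background = NULL, min_count = 5L,
                   p_threshold = 0.05, use_adjusted = FALSE) {
  stopifnot(all(c("gene_id", "term_id") %in% names(term_map)))
  annotated <- unique(term_map$gene_id)
  if (is.null(background)) background <- annotated
  background <- unique(background)
  if (!length(background)) stop("empty background")
  term_map <- term_map[term_map$gene_id %in% background, , drop = FALSE]

  query <- unique(query)
  dropped <- setdiff(query, annotated)
  if (length(dropped))
    message(length(dropped), " query gene(s) not in the term annotation; ",
            "dropped from the query size")
  q <- intersect(query, intersect(annotated, background))

  N <- length(background)
  n <- length(q)
  terms <- sort(unique(term_map$term_id))
  name_of <- if ("term_name" %in% names(term_map)) {
    tn <- term_map[!duplicated(term_map$term_id), c("term_id", "term_name")]
    setNames(tn$term_name, tn$term_id)
  } else setNames(terms, terms)

  rows <- lapply(terms, function(tm) {
    genes <- unique(term_map$gene_id[term_map$term_id == tm])
    K <- length(genes)
    k <- length(intersect(genes, q))
    data.frame(term_id = tm, term_name = unname(name_of[tm]),
               N = N, K = K, n = n, k = k,
               p_value = hypergeom_upper_tail(N, K, n, k),
               rich_factor = if (K) k / K else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- p.adjust(out$p_value, "BH")
  p_used <- if (use_adjusted) out$adjusted_p else out$p_value
  out$significant <- out$k > min_count & p_used < p_threshold
  out <- out[order(out$p_value, out$term_id),
             c("term_id", "term_name", "N", "K", "n", "k", "p_value",
               "adjusted_p", "rich_factor", "significant")]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- length(dropped)
  out
}
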