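#' Build a lncRNA-gene regulatory network
#'
#' Assembles a bipartite directed network lncRNA -> gene from the cis and
#' trans target tables, restricted (optionally) to a whitelist of genes of
#' interest (e.g. lactation genes).  Node regulation directions come from
#' the differential-expression calls.  A pair supported both in cis and in
#' trans keeps two edges with distinct `mode` -- the two evidence kinds are
#' distinct claims.  Edge weight is r for trans edges and -distance for cis
#' edges.
#'
#' @param cis output of [find_cis_targets()] (may be NULL)
#' @param trans output of [find_trans_targets()] (may be NULL)
#' @param de_lnc DE table for lncRNAs ([call_differential()] output)
#' @param de_genes DE table for genes
#' @param gene_whitelist optional character vector of gene ids to keep;
#'   whitelist entries absent from the DE gene table are skipped with a
#'   warning
#' @return object of class `lnc_network`: list with `nodes` (id, kind,
#'   direction) and `edges` (lncRNA_id, gene_id, mode, weight)
#' @export
build_network <- function(cis = NULL, trans = NULL, de_lnc, de_genes,
                          gene_whitelist = NULL) {
  edge_rows <- list()
  if (!is.null(cis) && nrow(cis)) {
    edge_rows[[1]] <- data.frame(
      lncRNA_id = cis$lncRNA_id, gene_id = cis$gene_id, mode = "cis",
      weight = -abs(as.numeric(cis$distance)), stringsAsFactors = FALSE)
  }
  if (!is.null(trans) && nrow(trans)) {
    edge_rows[[2]] <- data.frame(
      lncRNA_id = trans$lncRNA_id, gene_id = trans$gene_id, mode = "trans",
      weight = trans$r, stringsAsFactors = FALSE)
  }
  edges <- if (length(edge_rows)) do.call(rbind, edge_rows) else
    data.frame(lncRNA_id = character(), gene_id = character(),
               mode = character(), weight = numeric(),
               stringsAsFactors = FALSE)

  if (!is.null(gene_whitelist)) {
    missing <- setdiff(gene_whitelist, de_genes$feature_id)
    if (length(missing))
      warning(length(missing), " whitelist gene(s) absent from DE genes, ",
              "skipped: ", paste(head(missing, 5), collapse = ", "),
              call. = FALSE)
    keep <- intersect(gene_whitelist, de_genes$feature_id)
    edges <- edges[edges$gene_id %in% keep, , drop = FALSE]
  }

  bad <- !(edges$lncRNA_id %in% de_lnc$feature_id) |
    !(edges$gene_id %in% de_genes$feature_id)
  if (any(bad)) {
    warning(sum(bad), " edge(s) with endpoints missing from DE results, ",
            "skipped", call. = FALSE)
    edges <- edges[!bad, , drop = FALSE]
  }

  dir_of <- function(ids, de) de$direction[match(ids, de$feature_id)]
  lnc_ids <- sort(unique(edges$lncRNA_id))
  gene_ids <- sort(unique(edges$gene_id))
  nodes <- rbind(
    data.frame(id = lnc_ids, kind = rep("lncRNA", length(lnc_ids)),
               direction = dir_of(lnc_ids, de_lnc),
               stringsAsFactors = FALSE),
    data.frame(id = gene_ids, kind = rep("gene", length(gene_ids)),
               direction = dir_of(gene_ids, de_genes),
               stringsAsFactors = FALSE))
  edges <- edges[order(edges$lncRNA_id, edges$gene_id, edges$mode), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "lnc_network")
}

#' @export
print.lnc_network <- function(x, ...) {
  cat("lnc_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges (",
      sum(x$edges$mode == "cis"), "cis /", sum(x$edges$mode == "trans"),
      "trans )\n")
  invisible(x)
}

#' Export a regulatory network for Cytoscape
#'
#' Writes Cytoscape-loadable files with deterministic ordering:
#' \describe{
#'   \item{sif}{`<prefix>.sif` (source, relation = mode, target) plus a
#'     node-attribute table `<prefix>.nodes.tsv`}
#'   \item{edge_tsv}{`<prefix>.edges.tsv` + `<prefix>.nodes.tsv`; the edge
#'     table round-trips through [read_network()]}
#'   \item{graphml}{`<prefix>.graphml`}
#' }
#'
#' @param network an `lnc_network`
#' @param prefix output path prefix
#' @param format one of `"sif"`, `"edge_tsv"`, `"graphml"`
#' @return character vector of files written
#' @export
export_network <- function(network, prefix,
                           format = c("edge_tsv", "sif", "graphml")) {
  format <- match.arg(format)
  nodes_path <- paste0(prefix, ".nodes.tsv")
  files <- character()
  if (format == "sif") {
    path <- paste0(prefix, ".sif")
    con <- file(path, "wb")
    writeLines(sprintf("%s\t%s\t%s", network$edges$lncRNA_id,
                       network$edges$mode, network$edges$gene_id),
               con, sep = "\n")
    close(con)
    write_tsv(network$nodes, nodes_path)
    files <- c(path, nodes_path)
  } else if (format == "edge_tsv") {
    path <- paste0(prefix, ".edges.tsv")
    write_tsv(network$edges, path)
    write_tsv(network$nodes, nodes_path)
    files <- c(path, nodes_path)
  } else {
    path <- paste0(prefix, ".graphml")
    esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="kind" for="node" attr.name="kind" attr.type="string"/>',
      '  <key id="direction" for="node" attr.name="direction" attr.type="string"/>',
      '  <key id="mode" for="edge" attr.name="mode" attr.type="string"/>',
      '  <key id="weight" for="edge" attr.name="weight" attr.type="double"/>',
      '  <graph edgedefault="directed">',
      sprintf('    <node id="%s"><data key="kind">%s</data><data key="direction">%s</data></node>',
              esc(network$nodes$id), network$nodes$kind,
              network$nodes$direction),
      sprintf('    <edge source="%s" target="%s"><data key="mode">%s</data><data key="weight">%s</data></edge>',
              esc(network$edges$lncRNA_id), esc(network$edges$gene_id),
              network$edges$mode, format(network$edges$weight, trim = TRUE)),
      '  </graph>', '</graphml>')
    con <- file(path, "wb")
    writeLines(lines, con, sep = "\n")
    close(con)
    files <- path
  }
  invisible(files)
}

#' Re-import a network exported as edge/node TSVs
#'
#' @param prefix the prefix passed to [export_network()] with
#'   `format = "edge_tsv"`
#' @return an `lnc_network`
#' @export
read_network <- function(prefix) {
  edges <- read_tsv(paste0(prefix, ".edges.tsv"))
  nodes <- read_tsv(paste0(prefix, ".nodes.tsv"))
  if (!nrow(edges))
    edges <- data.frame(lncRNA_id = character(), gene_id = character(),
                        mode = character(), weight = numeric(),
                        stringsAsFactors = FALSE)
  if (!nrow(nodes))
    nodes <- data.frame(id = character(), kind = character(),
                        direction = character(), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "lnc_network")
}
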