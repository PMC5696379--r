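#' Map differentially expressed mouse genes to human orthologs
#'
#' Keeps DE genes below `fdr_cut`, joins them to the mouse-to-human
#' ortholog map (one-to-many mappings expand to all pairs and are flagged
#' ambiguous), and reports unmapped genes in the `unmapped` attribute
#' rather than dropping them silently.
#'
#' @param de data.frame from [lrt_de()]/[treat_test()] (needs `gene_id`,
#'   `log2fc`, `fdr`)
#' @param ortholog_map data.frame with `mouse_id`, `human_id`
#' @param fdr_cut FDR cut-off (default 0.001)
#' @return data.frame with `mouse_id`, `human_id`, `log2fc`, `fdr`,
#'   `ambiguous`; attribute `unmapped` lists DE genes without an ortholog
#' @export
map_orthologs <- function(de, ortholog_map, fdr_cut = 0.001) {
  if (!nrow(ortholog_map)) stop("empty ortholog map")
  keep <- de[de$fdr < fdr_cut, , drop = FALSE]
  if (!nrow(keep)) {
    out <- data.frame(mouse_id = character(0), human_id = character(0),
                      log2fc = numeric(0), fdr = numeric(0),
                      ambiguous = logical(0))
    attr(out, "unmapped") <- character(0)
    return(out)
  }
  m <- merge(data.frame(mouse_id = keep$gene_id, log2fc = keep$log2fc,
                        fdr = keep$fdr),
             ortholog_map, by = "mouse_id")
  multi <- names(which(table(m$mouse_id) > 1))
  m$ambiguous <- m$mouse_id %in% multi
  m <- m[order(m$mouse_id, m$human_id),
         c("mouse_id", "human_id", "log2fc", "fdr", "ambiguous")]
  rownames(m) <- NULL
  attr(m, "unmapped") <- setdiff(keep$gene_id, ortholog_map$mouse_id)
  m
}

#' Build the DE-overlaid interaction subnetwork
#'
#' Induces the subgraph of the interaction edge list on the mapped human
#' ids (only direct interactions between DE genes are kept); isolated
#' nodes are retained with degree 0. Node direction comes from the sign of
#' the log2FC; a human id fed by multiple mouse genes with conflicting
#' signs is flagged `"ambiguous"`.
#'
#' @param mapped data.frame from [map_orthologs()]
#' @param edges data.frame with `from`, `to` human ids (deduplicated
#'   unordered pairs, as from [read_network_tables()])
#' @return an `annotated_network`: list with `nodes` (data.frame
#'   `human_id`, `mouse_ids`, `direction`, `fun`) and `edges`
#' @export
build_de_subnetwork <- function(mapped, edges) {
  if (!nrow(mapped)) stop("no mapped DE genes")
  ids <- sort(unique(mapped$human_id))
  direction <- vapply(ids, function(h) {
    sg <- unique(sign(mapped$log2fc[mapped$human_id == h]))
    sg <- sg[sg != 0]
    if (length(sg) > 1) "ambiguous"
    else if (!length(sg)) "flat"
    else if (sg > 0) "up" else "down"
  }, "")
  mouse_ids <- vapply(ids, function(h)
    paste(sort(unique(mapped$mouse_id[mapped$human_id == h])),
          collapse = ","), "")
  nodes <- data.frame(human_id = ids, mouse_ids = unname(mouse_ids),
                      direction = unname(direction),
                      fun = NA_character_, row.names = NULL)
  sub <- edges[edges$from %in% ids & edges$to %in% ids, , drop = FALSE]
  rownames(sub) <- NULL
  structure(list(nodes = nodes, edges = sub), class = "annotated_network")
}

#' @export
#' @method print annotated_network
print.annotated_network <- function(x, ...) {
  cat("annotated_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  invisible(x)
}

#' Annotate node function classes and extract the ST/TF view
#'
#' Assigns each node `ST` (signal transduction), `TF` (transcription
#' factor activity), `dual` (both) or `other` (neither) from the supplied
#' function map, and attaches the view restricted to ST/TF/dual nodes
#' (induced on the network's edges) as `$st_tf_view`.
#'
#' @param net an `annotated_network`
#' @param function_map data.frame with `human_id`, `class` (`ST`/`TF`)
#' @return the network with `nodes$fun` filled and `st_tf_view` attached
#' @export
classify_node_function <- function(net, function_map) {
  cls <- vapply(net$nodes$human_id, function(h) {
    k <- unique(function_map$class[function_map$human_id == h])
    if (all(c("ST", "TF") %in% k)) "dual"
    else if ("ST" %in% k) "ST"
    else if ("TF" %in% k) "TF"
    else "other"
  }, "")
  net$nodes$fun <- unname(cls)
  keep <- net$nodes$fun != "other"
  view_ids <- net$nodes$human_id[keep]
  view_edges <- net$edges[net$edges$from %in% view_ids &
                          net$edges$to %in% view_ids, , drop = FALSE]
  rownames(view_edges) <- NULL
  net$st_tf_view <- structure(
    list(nodes = net$nodes[keep, , drop = FALSE], edges = view_edges),
    class = "annotated_network")
  net
}

#' Export a network as node/edge TSVs plus SIF lines
#'
#' Writes `nodes.tsv`, `edges.tsv` and `network.sif`
#' (`idA<TAB>pp<TAB>idB`) into a directory.
#'
#' @param net an `annotated_network`
#' @param dir output directory (created if needed)
#' @export
export_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(net$nodes, file.path(dir, "nodes.tsv"))
  write_table(net$edges, file.path(dir, "edges.tsv"))
  sif <- if (nrow(net$edges))
    paste(net$edges$from, "pp", net$edges$to, sep = "\t")
  else character(0)
  writeLines(sif, file.path(dir, "network.sif"))
  invisible(NULL)
}

#' Re-import a network written by [export_network()]
#'
#' @param dir directory containing `nodes.tsv` and `edges.tsv`
#' @return an `annotated_network`
#' @export
import_network <- function(dir) {
  nodes <- utils::read.delim(file.path(dir, "nodes.tsv"),
                             colClasses = "character")
  edges <- utils::read.delim(file.path(dir, "edges.tsv"),
                             colClasses = "character")
  if (!nrow(edges))
    edges <- data.frame(from = character(0), to = character(0))
  structure(list(nodes = nodes, edges = edges),
            class = "annotated_network")
}
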