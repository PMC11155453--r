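## network_builder: turn learned path importance into intra-cell signaling
## networks, diagnose score quality against fold changes, call DEGs, and link
## cell types through ligand-receptor pairs into inter-cell networks.

new_comm_network <- function(nodes, edges, kind, cell_types) {
  setorder(edges, source, target)
  structure(list(nodes = nodes, edges = edges, kind = kind,
                 cell_types = cell_types),
            class = "comm_network")
}

#' @export
print.comm_network <- function(x, ...) {
  cat(sprintf("comm_network (%s%s): %d nodes, %d edges\n", x$kind,
              if (length(x$cell_types)) paste0(": ",
                paste(x$cell_types, collapse = " -> ")) else "",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

gene_role_string <- function(db, genes) {
  vapply(genes, function(g) {
    r <- names(db$roles)[vapply(db$roles, function(v) g %in% v, logical(1L))]
    if (length(r) == 0L) "signaling" else paste(r, collapse = ",")
  }, character(1L))
}

#' Merge the top-K paths into an intra-cell network
#'
#' Paths are ranked by mean importance (descending, ties broken by ascending
#' path id) and the edges of the top `K` paths are merged; each edge records
#' the ids of the selected paths supporting it.
#'
#' @param mean_I per-path importance (e.g. averaged over repeats)
#' @param path_list the `path_list` the scores index
#' @param db the `interaction_db` (for node roles)
#' @param K number of top paths to merge
#' @param cell_type optional cell-type label
#' @return a `comm_network` of kind "intra"
#' @export
extract_intra_network <- function(mean_I, path_list, db, K = 300L,
                                  cell_type = character()) {
  stopifnot(length(mean_I) == path_list$p)
  if (K <= 0L) stop("K must be positive", call. = FALSE)
  K <- min(as.integer(K), path_list$p)
  ord <- order(-mean_I, seq_along(mean_I))  # stable: ties by path id
  top <- sort(ord[seq_len(K)])
  edge_dt <- rbindlist(lapply(top, function(m) {
    gs <- path_list$paths[[m]]
    data.table(source = gs[-length(gs)], target = gs[-1L],
               category = path_list$edge_categories[[m]], path_id = m)
  }))
  edges <- edge_dt[, list(
    supporting_path_ids = paste(sort(unique(path_id)), collapse = ",")
  ), by = list(source, target, category)]
  genes <- sort(unique(c(edges$source, edges$target)))
  nodes <- data.table(gene = genes, roles = gene_role_string(db, genes))
  net <- new_comm_network(nodes, edges, "intra", cell_type)
  net$selected_paths <- top
  net
}

#' Compare fold-change levels of top-ranked vs remaining paths
#'
#' For each path, the mean absolute gene fold change is computed; the
#' function returns that quantity averaged over the `top_n` paths by
#' importance and over the remainder. A learned score that tracks
#' differential expression yields `top_mean > rest_mean`.
#'
#' @param path_list a `path_list`
#' @param fc named per-gene log fold change
#' @param mean_I per-path importance
#' @param top_n number of top paths (must be < p)
#' @return list with `top_mean` and `rest_mean`
#' @export
compare_top_paths_fc <- function(path_list, fc, mean_I, top_n = 200L) {
  stopifnot(length(mean_I) == path_list$p)
  if (top_n >= path_list$p) {
    stop("top_n must be smaller than the number of paths", call. = FALSE)
  }
  per_path <- vapply(path_list$paths, function(gs) mean(abs(fc[gs])),
                     numeric(1L))
  ord <- order(-mean_I, seq_along(mean_I))
  top <- ord[seq_len(top_n)]
  list(top_mean = mean(per_path[top]), rest_mean = mean(per_path[-top]))
}

#' Call differentially expressed genes
#'
#' Two-sided Wilcoxon rank-sum test per gene with Benjamini-Hochberg
#' adjustment; a gene is flagged iff its adjusted p-value is below `alpha`
#' and its absolute log fold change exceeds `fc_threshold`. Constant genes
#' get p = 1 by convention.
#'
#' @param expr cells x genes log-normalized matrix
#' @param labels per-cell condition labels
#' @param fc_threshold minimum absolute log fold change (default 0.25)
#' @param alpha BH-adjusted significance level (default 0.05)
#' @return a `deg_result` data.table: gene, fc, p, padj, is_deg
#' @export
call_deg <- function(expr, labels, fc_threshold = 0.25, alpha = 0.05) {
  y <- normalize_labels(labels)
  if (!all(c(1L, 2L) %in% y)) {
    stop("both conditions must be present", call. = FALSE)
  }
  fc <- compute_log_fold_change(expr, labels)
  pvals <- vapply(seq_len(ncol(expr)), function(j) {
    x <- expr[y == 2L, j]; z <- expr[y == 1L, j]
    if (var(c(x, z)) == 0) return(1)
    suppressWarnings(wilcox.test(x, z)$p.value)
  }, numeric(1L))
  out <- data.table(gene = colnames(expr), fc = unname(fc), p = pvals,
                    padj = p.adjust(pvals, method = "BH"))
  out[, is_deg := padj < alpha & abs(fc) > fc_threshold]
  structure(out, class = c("deg_result", class(out)))
}

#' Link a ligand cell's DEGs into a receptor cell's intra network
#'
#' Ligand candidates are the differentially expressed genes of the ligand
#' cell that hold the ligand role; every ligand-receptor edge of the
#' interaction graph whose ligand is a candidate and whose receptor is a
#' receptor-role node of the intra network is added. The result is the intra
#' network's edges plus those ligand-receptor links.
#'
#' @param ligand_deg a `deg_result` for the ligand cell type
#' @param receptor_intra a `comm_network` of kind "intra"
#' @param db an `interaction_db`
#' @param up_only restrict candidates to upregulated DEGs
#' @param ligand_cell_type optional label for the ligand cell type
#' @return a `comm_network` of kind "inter"
#' @export
build_inter_network <- function(ligand_deg, receptor_intra, db,
                                up_only = FALSE,
                                ligand_cell_type = "ligand_cell") {
  stopifnot(inherits(receptor_intra, "comm_network"),
            receptor_intra$kind == "intra",
            nrow(receptor_intra$edges) > 0L)
  degs <- ligand_deg$gene[ligand_deg$is_deg &
                            (!up_only | ligand_deg$fc > 0)]
  candidates <- intersect(degs, db$roles$ligand)
  rec_nodes <- receptor_intra$nodes$gene[
    grepl("receptor", receptor_intra$nodes$roles)]
  lr <- db$edges[category %in% c("LR_directional", "LR_bidirectional")]
  links <- lr[source %in% candidates & target %in% rec_nodes]
  ## a bidirectional pair may be stored receptor-first; check both ends
  bid <- db$edges[bidirectional == 1L &
                    target %in% candidates & source %in% rec_nodes]
  if (nrow(bid) > 0L) {
    links <- rbindlist(list(links, data.table(
      source = bid$target, target = bid$source,
      category = bid$category, bidirectional = 1L)))
  }
  links <- unique(links, by = c("source", "target"))
  if (nrow(links) == 0L) {
    pc_log("network_builder",
           "no qualifying ligand-receptor pair; inter network equals the intra network",
           level = "WARN")
  }
  new_edges <- if (nrow(links) > 0L) {
    data.table(source = links$source, target = links$target,
               category = links$category, supporting_path_ids = "")
  } else {
    receptor_intra$edges[0L]
  }
  edges <- rbindlist(list(receptor_intra$edges, new_edges), use.names = TRUE)
  edges <- unique(edges, by = c("source", "target", "category"))
  genes <- sort(unique(c(edges$source, edges$target)))
  nodes <- data.table(gene = genes, roles = gene_role_string(db, genes))
  new_comm_network(nodes, edges, "inter",
                   c(ligand_cell_type,
                     receptor_intra$cell_types %||% "receptor_cell"))
}

#' Write a network as SIF plus a JSON sidecar
#'
#' The SIF file holds `source<TAB>category<TAB>target`; the JSON sidecar
#' records node roles, supporting path ids and the network kind.
#'
#' @param net a `comm_network`
#' @param path output SIF path (sidecar gets extension .json)
#' @return `path`, invisibly
#' @export
write_sif <- function(net, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  e <- net$edges
  writeLines(paste(e$source, e$category, e$target, sep = "\t"), path)
  jsonlite::write_json(list(
    kind = net$kind,
    cell_types = net$cell_types,
    nodes = net$nodes,
    supporting_path_ids = e$supporting_path_ids %||% character()
  ), sub("\\.sif$", ".json", path), dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' Read the edge list of a SIF file
#' @param path SIF file
#' @return data.table with columns source, category, target
#' @export
read_sif <- function(path) {
  fread(path, header = FALSE, sep = "\t",
        col.names = c("source", "category", "target"))
}
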