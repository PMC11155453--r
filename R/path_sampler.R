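## path_sampler: build the predefined path list from the interaction graph.
## Paths are receptor-anchored node sequences with 3..10 nodes, plus the
## length-2 exception for direct receptor regulation edges.

PATH_MIN_LEN <- 3L
PATH_MAX_LEN <- 10L

path_key <- function(genes) paste(genes, collapse = "\r")

#' Construct a path list
#'
#' @param paths list of ordered gene-symbol vectors
#' @param edge_categories list of category vectors, each one shorter than its
#'   path
#' @return an object of class `path_list` with fields `paths`,
#'   `edge_categories`, `p` (path count), `k` (total node slots), `offsets`
#'   (1-based first slot of each path) and `flat` (data.table: path_id, pos,
#'   gene — the scatter index, path-major then position)
#' @export
new_path_list <- function(paths, edge_categories) {
  stopifnot(length(paths) == length(edge_categories))
  if (length(paths) > 0L) {
    stopifnot(all(lengths(paths) - 1L == lengths(edge_categories)))
  }
  lens <- lengths(paths)
  p <- length(paths)
  k <- sum(lens)
  offsets <- if (p > 0L) cumsum(c(1L, lens[-p])) else integer()
  flat <- data.table(
    path_id = rep(seq_len(p), lens),
    pos = unlist(lapply(lens, seq_len), use.names = FALSE) %||% integer(),
    gene = unlist(paths, use.names = FALSE) %||% character()
  )
  structure(list(paths = paths, edge_categories = edge_categories,
                 p = p, k = k, offsets = as.integer(offsets), flat = flat),
            class = "path_list")
}

#' @export
print.path_list <- function(x, ...) {
  cat(sprintf("path_list: %d paths over %d node slots (%d genes)\n",
              x$p, x$k, length(unique(x$flat$gene))))
  if (x$p > 0L) {
    cat(sprintf("  lengths: %s\n",
                paste(names(table(lengths(x$paths))),
                      table(lengths(x$paths)), sep = "x", collapse = ", ")))
  }
  invisible(x)
}

## deduplicate by gene sequence (first-seen labeling wins) and order
## deterministically by the gene-sequence tuple
finalize_paths <- function(paths, cats) {
  if (length(paths) == 0L) return(new_path_list(list(), list()))
  keys <- vapply(paths, path_key, character(1L))
  keep <- !duplicated(keys)
  paths <- paths[keep]; cats <- cats[keep]; keys <- keys[keep]
  ord <- order(keys, method = "radix")
  new_path_list(paths[ord], cats[ord])
}

## vertex sequences from igraph results across igraph versions
asp_vpaths <- function(res) res$vpaths %||% res$res

path_categories <- function(genes, catmap) {
  n <- length(genes)
  if (n < 2L) return(character())
  unname(catmap[paste(genes[-n], genes[-1L], sep = "\r")])
}

## every receptor_regulation edge as a length-2 path
receptor_regulation_paths <- function(db) {
  rr <- db$edges[category == "receptor_regulation"]
  list(paths = mapply(function(s, t) c(s, t), rr$source, rr$target,
                      SIMPLIFY = FALSE, USE.NAMES = FALSE),
       cats = rep(list("receptor_regulation"), nrow(rr)))
}

#' Enumerate all shortest paths from receptors
#'
#' For every receptor and every gene reachable from it, all tied-shortest
#' directed paths with node count in `[min_len, max_len]` are enumerated by
#' BFS. Every direct receptor-regulation edge additionally contributes its
#' length-2 path. Bidirectional ligand-receptor edges are traversable in both
#' directions; all other categories follow their stated direction.
#'
#' @param db an `interaction_db`
#' @param min_len,max_len inclusive node-count bounds (defaults 3 and 10)
#' @return a `path_list`, deterministically ordered
#' @export
sample_shortest_paths <- function(db, min_len = PATH_MIN_LEN,
                                  max_len = PATH_MAX_LEN) {
  receptors <- intersect(db$roles$receptor, db$genes)
  if (length(receptors) == 0L) {
    stop("interaction graph has no receptor", call. = FALSE)
  }
  g <- db_graph(db)
  catmap <- edge_category_lookup(db)
  paths <- list(); cats <- list()
  for (r in sort(receptors)) {
    res <- suppressWarnings(
      igraph::all_shortest_paths(g, from = r, to = igraph::V(g), mode = "out")
    )
    for (vp in asp_vpaths(res)) {
      genes <- igraph::as_ids(vp)
      if (length(genes) >= min_len && length(genes) <= max_len) {
        paths[[length(paths) + 1L]] <- genes
        cats[[length(cats) + 1L]] <- path_categories(genes, catmap)
      }
    }
  }
  rr <- receptor_regulation_paths(db)
  finalize_paths(c(paths, rr$paths), c(cats, rr$cats))
}

## default path endpoints: genes regulated by TFs that hold no
## ligand/receptor/TF role themselves
#' Default target genes for receptor-to-target path sampling
#' @param db an `interaction_db`
#' @return character vector of target genes
#' @export
default_path_targets <- function(db) {
  tf_targets <- unique(db$edges[category == "TF_regulation"]$target)
  sort(setdiff(tf_targets,
               c(db$roles$ligand, db$roles$receptor, db$roles$TF)))
}

#' Enumerate all simple receptor-to-target paths
#'
#' Depth-limited enumeration of every simple directed path from any receptor
#' to any target gene with node count in `[min_len, max_len]`; a direct
#' receptor-regulation edge onto a target is kept as a length-2 path. The
#' per-(receptor, target) enumeration is truncated at `cap_per_pair` with a
#' warning, since all-simple-paths enumeration is combinatorial.
#'
#' @param db an `interaction_db`
#' @param targets target gene symbols; defaults to [default_path_targets()]
#' @param min_len,max_len inclusive node-count bounds (defaults 3 and 10)
#' @param cap_per_pair truncation bound per receptor-target pair
#' @return a `path_list`, deterministically ordered
#' @export
sample_receptor_to_target_paths <- function(db, targets = NULL,
                                            min_len = PATH_MIN_LEN,
                                            max_len = PATH_MAX_LEN,
                                            cap_per_pair = 1000L) {
  receptors <- intersect(db$roles$receptor, db$genes)
  if (length(receptors) == 0L) {
    stop("interaction graph has no receptor", call. = FALSE)
  }
  targets <- targets %||% default_path_targets(db)
  targets <- intersect(targets, db$genes)
  if (length(targets) == 0L) {
    stop("no target gene is present in the interaction graph", call. = FALSE)
  }
  g <- db_graph(db)
  catmap <- edge_category_lookup(db)
  paths <- list(); cats <- list()
  capped <- FALSE
  for (r in sort(receptors)) {
    vps <- igraph::all_simple_paths(g, from = r, to = targets, mode = "out",
                                    cutoff = max_len - 1L)
    genes_l <- lapply(vps, igraph::as_ids)
    if (length(genes_l) == 0L) next
    ends <- vapply(genes_l, function(x) x[length(x)], character(1L))
    lens <- lengths(genes_l)
    cats_l <- lapply(genes_l, path_categories, catmap = catmap)
    keep <- (lens >= min_len) |
      (lens == 2L & vapply(cats_l, identical, logical(1L),
                           "receptor_regulation"))
    genes_l <- genes_l[keep]; cats_l <- cats_l[keep]; ends <- ends[keep]
    ## deterministic order, then cap per (receptor, target) pair
    keys <- vapply(genes_l, path_key, character(1L))
    ord <- order(keys, method = "radix")
    genes_l <- genes_l[ord]; cats_l <- cats_l[ord]; ends <- ends[ord]
    rank_in_pair <- stats::ave(seq_along(ends), ends, FUN = seq_along)
    if (any(rank_in_pair > cap_per_pair)) capped <- TRUE
    keep <- rank_in_pair <= cap_per_pair
    paths <- c(paths, genes_l[keep])
    cats <- c(cats, cats_l[keep])
  }
  if (capped) {
    pc_log("path_sampler",
           sprintf("path enumeration truncated at cap_per_pair = %d", cap_per_pair),
           level = "WARN")
  }
  finalize_paths(paths, cats)
}

#' Merge path lists, deduplicate and rebuild the scatter index
#'
#' @param ... `path_list` objects (or a single list of them)
#' @return a `path_list` holding the union of the inputs' unique gene
#'   sequences, with the first-seen edge-category labeling kept
#' @export
merge_and_index <- function(...) {
  lists <- list(...)
  if (length(lists) == 1L && !inherits(lists[[1L]], "path_list")) {
    lists <- lists[[1L]]
  }
  stopifnot(all(vapply(lists, inherits, logical(1L), "path_list")))
  finalize_paths(
    unlist(lapply(lists, `[[`, "paths"), recursive = FALSE),
    unlist(lapply(lists, `[[`, "edge_categories"), recursive = FALSE)
  )
}

#' Write a path list to disk
#'
#' Emits `paths.tsv` (path_id, comma-joined genes, comma-joined edge
#' categories) and `paths.json` (p, k, offsets).
#'
#' @param pl a `path_list`
#' @param dir output directory
#' @return the directory, invisibly
#' @export
write_path_list <- function(pl, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dt <- data.table(
    path_id = seq_len(pl$p),
    genes = vapply(pl$paths, paste, character(1L), collapse = ","),
    edge_categories = vapply(pl$edge_categories, paste, character(1L),
                             collapse = ",")
  )
  fwrite(dt, file.path(dir, "paths.tsv"), sep = "\t")
  jsonlite::write_json(list(p = pl$p, k = pl$k, offsets = pl$offsets),
                       file.path(dir, "paths.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a path list written by [write_path_list()]
#' @param dir directory holding `paths.tsv`
#' @return a `path_list`
#' @export
read_path_list <- function(dir) {
  dt <- fread(file.path(dir, "paths.tsv"),
              colClasses = list(character = c("genes", "edge_categories")))
  new_path_list(strsplit(dt$genes, ",", fixed = TRUE),
                strsplit(dt$edge_categories, ",", fixed = TRUE))
}
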