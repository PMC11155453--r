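## interaction_db: parse the three raw interaction resources and classify every
## edge into one of nine categories, producing the role-annotated directed gene
## graph that path sampling, modelling and network construction all consume.

#' The nine edge categories of the interaction graph
#' @export
EDGE_CATEGORIES <- c(
  "LR_directional", "LR_bidirectional",
  "ligand_regulation", "receptor_regulation", "TF_regulation",
  "receptor_TF", "receptor_signaling", "signaling_TF", "signaling_signaling"
)

## parse one delimited edge file: >=2 columns, extras ignored, optional header
## (detected by "source"/"from" in the first field), malformed rows skipped.
read_edge_table <- function(path, n_cols = 2L) {
  if (!file.exists(path)) {
    stop("interaction table not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.table(source = character(), target = character()))
  }
  fields <- strsplit(lines, "[\t,;]|[[:space:]]+")
  fields <- lapply(fields, function(f) trimws(f[nzchar(trimws(f))]))
  first <- tolower(fields[[1L]][1L] %||% "")
  if (first %in% c("source", "from", "ligand", "gene")) {
    fields <- fields[-1L]
  }
  ok <- vapply(fields, function(f) length(f) >= n_cols, logical(1L))
  if (any(!ok)) {
    pc_log("interaction_db",
           sprintf("skipped %d malformed row(s) in %s", sum(!ok), basename(path)),
           level = "WARN")
  }
  fields <- fields[ok]
  if (length(fields) == 0L) {
    return(data.table(source = character(), target = character()))
  }
  dt <- data.table(
    source = vapply(fields, `[`, character(1L), 1L),
    target = if (n_cols >= 2L) vapply(fields, `[`, character(1L), 2L) else NA_character_
  )
  dt
}

#' Load the raw interaction tables
#'
#' Reads the ligand-receptor, signaling and gene-regulation edge tables
#' (two-column delimited text, extra columns ignored, header auto-detected)
#' plus the transcription-factor list. Edge lists are deduplicated, symbols
#' whitespace-stripped with case preserved, and self-loops dropped.
#'
#' @param lr_path,signaling_path,regulation_path paths to two-column edge tables
#' @param tf_path path to a one-column gene list
#' @return an object of class `raw_interaction_tables`
#' @export
load_raw_tables <- function(lr_path, signaling_path, regulation_path, tf_path) {
  load_edges <- function(path, what) {
    dt <- read_edge_table(path)
    n0 <- nrow(dt)
    dt <- unique(dt)
    loops <- dt$source == dt$target
    if (any(loops)) {
      pc_log("interaction_db",
             sprintf("removed %d self-loop(s) from %s table", sum(loops), what),
             level = "WARN")
    }
    dt[!loops]
  }
  tf <- read_edge_table(tf_path, n_cols = 1L)
  structure(list(
    lr_edges         = load_edges(lr_path, "ligand-receptor"),
    signaling_edges  = load_edges(signaling_path, "signaling"),
    regulation_edges = load_edges(regulation_path, "regulation"),
    tf_list          = sort(unique(tf$source))
  ), class = "raw_interaction_tables")
}

#' Classify ligand-receptor edges as directional or bidirectional
#'
#' An interaction present in both directions is labelled bidirectional and
#' emitted once in canonical orientation (lexicographically smaller source
#' first); every other edge is directional.
#'
#' @param lr_edges data.table with columns source, target (deduplicated)
#' @return data.table with columns source, target, category, bidirectional
#' @export
classify_lr_directionality <- function(lr_edges) {
  if (nrow(lr_edges) == 0L) {
    return(data.table(source = character(), target = character(),
                      category = character(), bidirectional = integer()))
  }
  key  <- paste(lr_edges$source, lr_edges$target, sep = "\r")
  rkey <- paste(lr_edges$target, lr_edges$source, sep = "\r")
  bidir <- rkey %in% key
  out <- data.table(
    source = ifelse(bidir & lr_edges$source > lr_edges$target,
                    lr_edges$target, lr_edges$source),
    target = ifelse(bidir & lr_edges$source > lr_edges$target,
                    lr_edges$source, lr_edges$target),
    category = ifelse(bidir, "LR_bidirectional", "LR_directional"),
    bidirectional = as.integer(bidir)
  )
  unique(out)
}

#' Assign ligand/receptor/TF/signaling roles to genes
#'
#' Ligands are the sources and receptors the targets of the ligand-receptor
#' network (a gene may hold both roles); TFs are the supplied TF list minus
#' any gene already a ligand or receptor; every other gene appearing in any
#' edge table is a signaling gene.
#'
#' @param tables a `raw_interaction_tables` object
#' @return named list of sorted gene vectors: ligand, receptor, TF, signaling
#' @export
collect_roles <- function(tables) {
  ligands   <- sort(unique(tables$lr_edges$source))
  receptors <- sort(unique(tables$lr_edges$target))
  tfs       <- sort(setdiff(tables$tf_list, union(ligands, receptors)))
  all_genes <- unique(c(
    tables$lr_edges$source, tables$lr_edges$target,
    tables$signaling_edges$source, tables$signaling_edges$target,
    tables$regulation_edges$source, tables$regulation_edges$target
  ))
  signaling <- sort(setdiff(all_genes, c(ligands, receptors, tfs)))
  list(ligand = ligands, receptor = receptors, TF = tfs, signaling = signaling)
}

#' Classify gene-regulation edges by the role of their source
#'
#' An edge is kept iff its source is a ligand, receptor or TF; the category is
#' `<source-role>_regulation`. A source holding several roles resolves by the
#' priority receptor > ligand > TF.
#'
#' @param reg_edges data.table with columns source, target
#' @param roles role list from [collect_roles()]
#' @return data.table with columns source, target, category, bidirectional
#' @export
classify_regulation <- function(reg_edges, roles) {
  if (nrow(reg_edges) == 0L) {
    return(data.table(source = character(), target = character(),
                      category = character(), bidirectional = integer()))
  }
  is_rec <- reg_edges$source %in% roles$receptor
  is_lig <- reg_edges$source %in% roles$ligand
  is_tf  <- reg_edges$source %in% roles$TF
  multi <- (is_rec + is_lig + is_tf) > 1L
  if (any(multi)) {
    pc_log("interaction_db",
           sprintf("%d regulation edge(s) with multi-role source resolved by priority receptor > ligand > TF",
                   sum(multi)))
  }
  category <- rep(NA_character_, nrow(reg_edges))
  category[is_tf]  <- "TF_regulation"
  category[is_lig] <- "ligand_regulation"
  category[is_rec] <- "receptor_regulation"
  keep <- !is.na(category)
  data.table(source = reg_edges$source[keep], target = reg_edges$target[keep],
             category = category[keep], bidirectional = 0L)
}

#' Classify signaling-network edges
#'
#' Edges already present in the ligand-receptor or regulation sets are removed
#' first. The remainder are classified by endpoint roles: receptor source with
#' TF target is receptor-TF; receptor source otherwise is receptor-signaling;
#' non-receptor source with TF target is signaling-TF; an edge with neither
#' endpoint a receptor or TF is signaling-signaling; anything else is dropped.
#'
#' @param sig_edges data.table with columns source, target
#' @param roles role list from [collect_roles()]
#' @param used_edges data.table of finalized LR + regulation edges
#' @return data.table with columns source, target, category, bidirectional
#' @export
classify_signaling <- function(sig_edges, roles, used_edges) {
  empty <- data.table(source = character(), target = character(),
                      category = character(), bidirectional = integer())
  if (nrow(sig_edges) == 0L) return(empty)
  used_key <- used_edge_keys(used_edges)
  key <- paste(sig_edges$source, sig_edges$target, sep = "\r")
  sig <- sig_edges[!(key %in% used_key)]
  if (nrow(sig) == 0L) return(empty)
  src_rec <- sig$source %in% roles$receptor
  src_tf  <- sig$source %in% roles$TF
  tgt_rec <- sig$target %in% roles$receptor
  tgt_tf  <- sig$target %in% roles$TF
  category <- rep(NA_character_, nrow(sig))
  category[src_rec & tgt_tf]  <- "receptor_TF"
  category[src_rec & !tgt_tf] <- "receptor_signaling"
  category[!src_rec & tgt_tf] <- "signaling_TF"
  rest <- is.na(category) & !src_rec & !src_tf & !tgt_rec & !tgt_tf
  category[rest] <- "signaling_signaling"
  keep <- !is.na(category)
  data.table(source = sig$source[keep], target = sig$target[keep],
             category = category[keep], bidirectional = 0L)
}

## directed keys occupied by LR (both orientations for bidirectional) and
## regulation edges; used to enforce the no-overlap invariant
used_edge_keys <- function(edges) {
  if (nrow(edges) == 0L) return(character())
  key <- paste(edges$source, edges$target, sep = "\r")
  bid <- edges$bidirectional == 1L
  c(key, paste(edges$target[bid], edges$source[bid], sep = "\r"))
}

#' Build the role-annotated interaction graph
#'
#' Runs the full classification pipeline: ligand-receptor directionality,
#' role collection, regulation classification, and signaling classification
#' with overlap removal. The category partition and no-overlap invariants are
#' asserted on every build.
#'
#' @param tables a `raw_interaction_tables` object
#' @return an object of class `interaction_db` with fields `genes`, `roles`
#'   (named list of gene vectors) and `edges` (data.table: source, target,
#'   category, bidirectional)
#' @export
build_interaction_db <- function(tables) {
  lr    <- classify_lr_directionality(tables$lr_edges)
  roles <- collect_roles(tables)
  reg   <- classify_regulation(tables$regulation_edges, roles)
  used  <- rbindlist(list(lr, reg))
  sig   <- classify_signaling(tables$signaling_edges, roles, used)
  edges <- rbindlist(list(lr, reg, sig))
  ## LR takes precedence over a duplicate regulation edge on the same pair
  edges <- unique(edges, by = c("source", "target"))
  stopifnot(
    all(edges$category %in% EDGE_CATEGORIES),
    !any(edges$source == edges$target),
    length(intersect(
      paste(sig$source, sig$target, sep = "\r"),
      used_edge_keys(used)
    )) == 0L
  )
  genes <- sort(unique(c(edges$source, edges$target)))
  roles <- lapply(roles, intersect, genes)
  new_interaction_db(genes, roles, edges)
}

new_interaction_db <- function(genes, roles, edges) {
  setorder(edges, source, target)
  structure(list(genes = genes, roles = roles, edges = edges),
            class = "interaction_db")
}

#' @export
print.interaction_db <- function(x, ...) {
  cat(sprintf("interaction_db: %d genes, %d edges\n",
              length(x$genes), nrow(x$edges)))
  cat(sprintf("  roles: %d ligands, %d receptors, %d TFs, %d signaling\n",
              length(x$roles$ligand), length(x$roles$receptor),
              length(x$roles$TF), length(x$roles$signaling)))
  print(x$edges[, .N, by = category])
  invisible(x)
}

#' Restrict an interaction graph to a gene list
#'
#' Induced subgraph on the intersection of `gene_list` with the graph's genes;
#' roles and edge categories are preserved.
#'
#' @param db an `interaction_db`
#' @param gene_list character vector of gene symbols
#' @return an `interaction_db`
#' @export
restrict_to_genes <- function(db, gene_list) {
  stopifnot(length(gene_list) > 0L)
  keep_genes <- intersect(db$genes, gene_list)
  if (length(keep_genes) == 0L) {
    stop("no overlap between gene list and interaction graph", call. = FALSE)
  }
  edges <- db$edges[source %in% keep_genes & target %in% keep_genes]
  roles <- lapply(db$roles, intersect, keep_genes)
  new_interaction_db(keep_genes, roles, edges)
}

## directed edge list for traversal: bidirectional LR edges materialized as two
## directed edges flagged as one logical interaction
db_directed_edges <- function(db) {
  e <- db$edges
  bid <- e[bidirectional == 1L]
  if (nrow(bid) > 0L) {
    rev <- data.table(source = bid$target, target = bid$source,
                      category = bid$category, bidirectional = 1L)
    e <- rbindlist(list(e, rev))
  }
  unique(e, by = c("source", "target"))
}

## igraph over the directed edge expansion, category as edge attribute
db_graph <- function(db) {
  e <- db_directed_edges(db)
  g <- igraph::graph_from_data_frame(
    e[, list(from = source, to = target, category = category)],
    directed = TRUE,
    vertices = data.frame(name = db$genes)
  )
  g
}

## named lookup "u\rv" -> category over the directed expansion
edge_category_lookup <- function(db) {
  e <- db_directed_edges(db)
  setNames(e$category, paste(e$source, e$target, sep = "\r"))
}

#' Genes holding a given role
#' @param db an `interaction_db`
#' @param role one of "ligand", "receptor", "TF", "signaling"
#' @return character vector
#' @export
genes_with_role <- function(db, role) {
  stopifnot(role %in% names(db$roles))
  db$roles[[role]]
}

#' Write an interaction graph to disk
#'
#' Emits `interactions.tsv` (source, target, category, bidirectional) and
#' `roles.json` (role -> sorted gene list).
#'
#' @param db an `interaction_db`
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_interaction_db <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fwrite(db$edges, file.path(dir, "interactions.tsv"), sep = "\t")
  jsonlite::write_json(lapply(db$roles, sort), file.path(dir, "roles.json"),
                       pretty = TRUE)
  invisible(dir)
}

#' Read an interaction graph written by [write_interaction_db()]
#' @param dir directory holding `interactions.tsv` and `roles.json`
#' @return an `interaction_db`
#' @export
read_interaction_db <- function(dir) {
  edges <- fread(file.path(dir, "interactions.tsv"),
                 colClasses = list(character = c("source", "target", "category"),
                                   integer = "bidirectional"))
  roles <- jsonlite::read_json(file.path(dir, "roles.json"),
                               simplifyVector = TRUE)
  roles <- lapply(roles, as.character)
  genes <- sort(unique(c(edges$source, edges$target)))
  new_interaction_db(genes, lapply(roles, intersect, genes), edges)
}
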