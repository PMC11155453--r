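## cli_io: readers/writers for the on-disk formats, run configuration,
## variable-gene selection, and the end-to-end pipeline driver. A thin
## command-line wrapper over these functions ships in inst/cli/pathcomm.R.

#' Write a cells x genes expression matrix as TSV
#'
#' Cells are rows; the first column `cell` holds cell names and the remaining
#' header fields are gene names.
#'
#' @param expr cells x genes numeric matrix with dimnames
#' @param path output file
#' @return `path`, invisibly
#' @export
write_expression <- function(expr, path) {
  stopifnot(!is.null(colnames(expr)))
  dt <- data.table(cell = rownames(expr) %||%
                     sprintf("cell%04d", seq_len(nrow(expr))))
  dt <- cbind(dt, as.data.table(expr))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read an expression matrix
#'
#' Accepts a dense delimited matrix (cells x genes or genes x cells,
#' auto-oriented using the gene index when supplied or a `cell`/`gene` header
#' tag) or a matrix-market triplet with gene/cell index files. Returns the
#' matrix in cells x genes orientation.
#'
#' @param path dense CSV/TSV or .mtx file
#' @param genes_path,cells_path one-column index files (required for .mtx)
#' @return numeric matrix, cells x genes, with dimnames
#' @export
read_expression <- function(path, genes_path = NULL, cells_path = NULL) {
  if (grepl("\\.mtx$", path)) {
    stopifnot(!is.null(genes_path), !is.null(cells_path))
    m <- as.matrix(Matrix::readMM(path))
    genes <- read_edge_table(genes_path, n_cols = 1L)$source
    cells <- read_edge_table(cells_path, n_cols = 1L)$source
    if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
      m <- t(m)  # genes x cells on disk
    }
    stopifnot(nrow(m) == length(cells), ncol(m) == length(genes))
    dimnames(m) <- list(cells, genes)
  } else {
    dt <- fread(path)
    id_col <- names(dt)[1L]
    ids <- as.character(dt[[1L]])
    m <- as.matrix(dt[, -1L, with = FALSE])
    rownames(m) <- ids
    genes <- if (!is.null(genes_path)) {
      read_edge_table(genes_path, n_cols = 1L)$source
    } else NULL
    transposed <- if (!is.null(genes)) {
      ## orient by where the gene names live
      mean(ids %in% genes) > mean(colnames(m) %in% genes)
    } else {
      tolower(id_col) %in% c("gene", "genes", "symbol")
    }
    if (transposed) m <- t(m)
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate gene name(s): ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  }
  m
}

#' Select the most variable genes
#'
#' Genes are ranked by variance of their log-normalized expression; the top
#' `n_top` are kept in their original matrix order. Ties rank the
#' lexicographically smaller gene name first.
#'
#' @param expr cells x genes matrix
#' @param n_top number of genes to keep
#' @return character vector of selected gene names, in original column order
#' @export
select_variable_genes <- function(expr, n_top) {
  stopifnot(n_top <= ncol(expr))
  if (n_top <= 0L) stop("n_top must be positive", call. = FALSE)
  v <- apply(expr, 2L, var)
  ord <- order(-v, colnames(expr), method = "radix")
  keep <- colnames(expr)[sort(ord[seq_len(n_top)])]
  keep
}

## ---- run configuration ----------------------------------------------------

default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "pathcomm_run",
    log_level = "INFO",
    inputs = list(lr = NULL, signaling = NULL, regulation = NULL,
                  tf = NULL, expr = NULL, labels = NULL, targets = NULL),
    sampler = list(mode = "receptor_to_target", min_len = 3L, max_len = 10L,
                   cap_per_pair = 1000L),
    model = list(L = 6L, h_emb = 128L, h = 8L, r = 8L, dropout = 0.1,
                 max_degree_bucket = 64L, node_index_mode = "full",
                 low_rank_dim = 8L, layer_norm = TRUE),
    training = list(split = c(0.7, 0.1, 0.2), repeats = 5L, epochs = 30L,
                    lr = 5e-4, beta = 0.1, batch_size = 32L, mode = "deg",
                    reg_variant = "distribution"),
    extraction = list(top_k = 300L, diagnostic_top_n = 200L),
    deg = list(fc_threshold = 0.25, alpha = 0.05),
    n_variable_genes = NULL
  )
}

## recursive merge rejecting keys absent from the default schema
merge_config <- function(base, override, path = "") {
  for (k in names(override)) {
    if (!k %in% names(base)) {
      stop("unknown config key: ", paste0(path, k), call. = FALSE)
    }
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]],
                                paste0(path, k, "."))
    } else {
      base[k] <- list(override[[k]])  # [k]<- keeps explicit NULLs
    }
  }
  base
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to defaults.
#'
#' @param path YAML file
#' @return a `run_config` list
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path) %||% list()
  cfg <- merge_config(default_run_config(), user)
  structure(cfg, class = "run_config")
}

#' Write a run configuration as YAML
#' @param config a `run_config` (or plain list)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

run_manifest <- function(config, input_files, out_dir) {
  input_files <- Filter(function(f) !is.null(f) && file.exists(f),
                        input_files)
  hashes <- vapply(input_files,
                   function(f) unname(tools::md5sum(f)), character(1L))
  manifest <- list(
    package_version = as.character(utils::packageVersion("pathcomm")),
    config = unclass(config),
    input_md5 = as.list(hashes),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' Run the full pipeline
#'
#' build-db -> sample-paths -> train -> extract, driven by a [run_config]:
#' loads the interaction tables and expression, optionally restricts to the
#' top variable genes, samples paths, trains with the repeated protocol,
#' writes metrics, per-path scores, the top-K intra network and a manifest
#' with input hashes. Deterministic given the config seed.
#'
#' @param config a `run_config` from [read_run_config()] (or the same shape)
#' @return the output directory, invisibly
#' @export
run_pipeline <- function(config) {
  cfg <- config
  ins <- cfg$inputs
  needed <- c("lr", "signaling", "regulation", "tf", "expr", "labels")
  missing <- needed[vapply(ins[needed], is.null, logical(1L))]
  if (length(missing) > 0L) {
    stop("config lacks input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, f) {
    tryCatch(f(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  db <- stage("build-db", function() {
    tables <- load_raw_tables(ins$lr, ins$signaling, ins$regulation, ins$tf)
    build_interaction_db(tables)
  })
  expr <- stage("read-expression", function() read_expression(ins$expr))
  labels_dt <- fread(ins$labels)
  labels <- labels_dt[[ncol(labels_dt)]]
  if (!is.null(cfg$n_variable_genes)) {
    keep <- select_variable_genes(expr, cfg$n_variable_genes)
    expr <- expr[, keep, drop = FALSE]
    db <- restrict_to_genes(db, keep)
  } else {
    db <- restrict_to_genes(db, colnames(expr))
  }
  pl <- stage("sample-paths", function() {
    if (cfg$sampler$mode == "shortest") {
      sample_shortest_paths(db, cfg$sampler$min_len, cfg$sampler$max_len)
    } else {
      targets <- if (!is.null(ins$targets)) {
        read_edge_table(ins$targets, n_cols = 1L)$source
      } else NULL
      sample_receptor_to_target_paths(db, targets, cfg$sampler$min_len,
                                      cfg$sampler$max_len,
                                      cfg$sampler$cap_per_pair)
    }
  })
  write_interaction_db(db, out)
  write_path_list(pl, out)
  mcfg <- do.call(model_config, cfg$model)
  ctx <- graph_context(db, pl, mcfg$max_degree_bucket)
  protocol <- do.call(train_protocol,
                      c(cfg$training, list(seed = cfg$seed)))
  result <- stage("train", function() {
    run_experiment(expr, labels, ctx, mcfg, protocol)
  })
  jsonlite::write_json(list(
    metrics_mean = as.list(result$metrics_mean),
    metrics_sd = as.list(result$metrics_sd),
    repeats = lapply(result$repeats, function(r) as.list(r$metrics)),
    seeds = vapply(result$repeats, `[[`, numeric(1L), "seed")
  ), file.path(out, "metrics.json"), auto_unbox = TRUE, digits = NA)
  scores <- data.table(path_id = seq_len(pl$p))
  for (i in seq_along(result$repeats)) {
    scores[[sprintf("I_rep%d", i)]] <- result$repeats[[i]]$I
  }
  scores[["I_mean"]] <- result$mean_I
  fwrite(scores, file.path(out, "path_scores.tsv"), sep = "\t")
  net <- stage("extract", function() {
    extract_intra_network(result$mean_I, pl, db, cfg$extraction$top_k)
  })
  write_sif(net, file.path(out, "intra_network.sif"))
  run_manifest(cfg, ins, out)
  pc_log("pipeline", sprintf("run complete: %s", out))
  invisible(out)
}
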