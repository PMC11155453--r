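## In-code fixture builders shared across the test files.

## a 5-gene toy set of raw tables exercising every classification branch
toy_raw_tables <- function() {
  structure(list(
    lr_edges = data.table::data.table(
      source = c("L1", "L2", "R1"),
      target = c("R1", "R2", "L2")),   # (L2,R2)+(R2->L2 absent): directional
    signaling_edges = data.table::data.table(
      source = c("R1", "R1", "S1", "S2", "T1"),
      target = c("T1", "S1", "T1", "S1", "S2")),
    regulation_edges = data.table::data.table(
      source = c("R1", "L1", "T1", "S1"),
      target = c("X1", "X1", "X1", "X1")),
    tf_list = c("T1", "L1")
  ), class = "raw_interaction_tables")
}

## random role-consistent raw tables on <= n_nodes genes; used for
## property-style tests of classification and path sampling
random_raw_tables <- function(seed, n_nodes = 10L, edge_prob = 0.25) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_nodes))
  n_lig <- max(1L, rbinom(1L, 2L, 0.5) + 1L)
  n_rec <- max(1L, rbinom(1L, 2L, 0.5) + 1L)
  ligands <- genes[seq_len(n_lig)]
  receptors <- genes[n_lig + seq_len(n_rec)]
  rest <- setdiff(genes, c(ligands, receptors))
  tfs <- if (length(rest) > 2L) sample(rest, 2L) else character()
  pairs <- expand.grid(source = genes, target = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pick <- function(p) pairs[runif(nrow(pairs)) < p, ]
  lr <- pairs[pairs$source %in% ligands & pairs$target %in% receptors, ]
  lr <- lr[runif(nrow(lr)) < 0.6, ]
  structure(list(
    lr_edges = data.table::as.data.table(lr),
    signaling_edges = data.table::as.data.table(pick(edge_prob)),
    regulation_edges = data.table::as.data.table(pick(edge_prob / 2)),
    tf_list = tfs
  ), class = "raw_interaction_tables")
}

random_db <- function(seed, n_nodes = 10L, edge_prob = 0.25) {
  build_interaction_db(random_raw_tables(seed, n_nodes, edge_prob))
}

## tiny in-memory modelling setup reused by model/training tests
tiny_setup <- function(L = 2L, h_emb = 8L, h = 2L, r = 2L, dropout = 0,
                       seed = 7L) {
  db <- pathcomm:::tiny_graph()
  pl <- sample_receptor_to_target_paths(db)
  cfg <- model_config(L = L, h_emb = h_emb, h = h, r = r, dropout = dropout,
                      max_degree_bucket = 4L)
  ctx <- graph_context(db, pl, cfg$max_degree_bucket)
  params <- init_params(cfg, ctx, seed = seed)
  list(db = db, pl = pl, cfg = cfg, ctx = ctx, params = params)
}

## write a two-column TSV edge file
write_edges <- function(df, path, header = FALSE) {
  lines <- paste(df[[1L]], df[[2L]], sep = "\t")
  if (header) lines <- c("source\ttarget", lines)
  writeLines(lines, path)
  path
}
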