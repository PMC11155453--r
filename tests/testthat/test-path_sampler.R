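# helper: db from explicit typed edge tables
db_from <- function(lr = NULL, sig = NULL, reg = NULL, tf = character()) {
  empty <- data.table::data.table(source = character(), target = character())
  as_dt <- function(x) if (is.null(x)) empty else
    data.table::data.table(source = x[[1L]], target = x[[2L]])
  build_interaction_db(structure(list(
    lr_edges = as_dt(lr), signaling_edges = as_dt(sig),
    regulation_edges = as_dt(reg), tf_list = tf
  ), class = "raw_interaction_tables"))
}

test_that("length bounds apply, with the receptor-regulation length-2 exception", {
  ## chain R -> a -> b: only the 3-node path; [R, a] excluded
  db <- db_from(lr = list("L", "R"),
                sig = list(c("R", "a"), c("a", "b")))
  pl <- sample_shortest_paths(db)
  expect_equal(path_list_keys(pl), c("R>a", "R>a>b")[2L])
  ## a receptor_regulation edge contributes its 2-node path
  db2 <- db_from(lr = list("L", "R"),
                 sig = list(c("R", "a"), c("a", "b")),
                 reg = list("R", "x"))
  pl2 <- sample_shortest_paths(db2)
  expect_true("R>x" %in% path_list_keys(pl2))
})

test_that("tied shortest paths are all enumerated (diamond)", {
  db <- db_from(lr = list("L", "R"),
                sig = list(c("R", "R", "a", "b"), c("a", "b", "t", "t")))
  pl <- sample_shortest_paths(db)
  expect_true(all(c("R>a>t", "R>b>t") %in% path_list_keys(pl)))
  ## matches the brute-force shortest-path oracle exactly
  expect_equal(path_list_keys(pl), oracle_enumerate_paths(db, mode = "shortest"))
})

test_that("an 11-node chain yields at most 10-node paths", {
  genes <- c("R", paste0("s", 1:10))
  db <- db_from(lr = list("L", "R"),
                sig = list(genes[-11L], genes[-1L]))
  pl <- sample_shortest_paths(db)
  expect_equal(max(lengths(pl$paths)), 10L)
  pl2 <- sample_receptor_to_target_paths(db, targets = genes[-1L])
  expect_equal(max(lengths(pl2$paths)), 10L)
})

test_that("receptor-to-target enumeration is exhaustive, simple, and min-length filtered", {
  ## three routes R->t plus one direct 2-node edge that fails min_len
  db <- db_from(lr = list("L", "R"),
                sig = list(c("R", "a", "R", "b", "a"),
                           c("a", "t", "b", "t", "b")),
                reg = list("T0", "t"), tf = "T0")
  pl <- sample_receptor_to_target_paths(db, targets = "t")
  expect_equal(path_list_keys(pl),
               sort(c("R>a>t", "R>b>t", "R>a>b>t")))
  ## cycles never traversed
  dbc <- db_from(lr = list("L", "R"),
                 sig = list(c("R", "a", "b"), c("a", "b", "a")),
                 reg = list("R", "t"))
  plc <- sample_receptor_to_target_paths(dbc, targets = "t")
  expect_equal(path_list_keys(plc), "R>t")  # length-2 receptor regulation only
})

test_that("default targets are TF-regulated genes without other roles", {
  db <- db_from(lr = list("L", "R"),
                sig = list(c("R", "s"), c("s", "T0")),
                reg = list(c("T0", "T0"), c("t1", "R")), tf = "T0")
  expect_equal(default_path_targets(db), "t1")
})

test_that("sampler equals the brute-force enumerator on random digraphs", {
  checked <- 0L
  for (seed in 1:12) {
    db <- random_db(seed, n_nodes = 10L, edge_prob = 0.3)
    if (length(db$roles$receptor) == 0L) next
    pl <- sample_shortest_paths(db)
    expect_equal(path_list_keys(pl), oracle_enumerate_paths(db, mode = "shortest"),
                 info = paste("shortest, seed", seed))
    tg <- default_path_targets(db)
    if (length(intersect(tg, db$genes)) > 0L) {
      pl2 <- sample_receptor_to_target_paths(db, targets = tg)
      expect_equal(path_list_keys(pl2),
                   oracle_enumerate_paths(db, targets = tg),
                   info = paste("all-paths, seed", seed))
    }
    checked <- checked + 1L
  }
  expect_gte(checked, 5L)
})

test_that("every path starts at a receptor and length-2 paths are receptor regulations", {
  for (seed in 1:6) {
    db <- random_db(seed, n_nodes = 12L, edge_prob = 0.25)
    if (length(db$roles$receptor) == 0L) next
    pl <- sample_shortest_paths(db)
    if (pl$p == 0L) next
    expect_true(all(vapply(pl$paths, `[`, character(1L), 1L) %in%
                      db$roles$receptor))
    two <- lengths(pl$paths) == 2L
    expect_true(all(unlist(pl$edge_categories[two]) == "receptor_regulation"))
  }
})

test_that("the flat scatter index reconstructs paths and matches the worked example", {
  pl <- new_path_list(
    list(c("g1", "g3", "g4"), c("g2", "g3", "g4", "g5")),
    list(rep("signaling_signaling", 2L), rep("signaling_signaling", 3L)))
  expect_equal(pl$p, 2L)
  expect_equal(pl$k, 7L)
  ## third slot is the third gene of the first path
  expect_equal(pl$flat$gene[3L], "g4")
  expect_equal(pl$flat$path_id[3L], 1L)
  expect_equal(pl$flat$pos[3L], 3L)
  expect_equal(pl$offsets, c(1L, 4L))
  ## round-trip: rebuild gene sequences from the flat index
  rebuilt <- split(pl$flat$gene, pl$flat$path_id)
  expect_equal(unname(rebuilt), pl$paths)
})

test_that("merge_and_index is an idempotent union with recomputed indices", {
  db <- db_from(lr = list("L", "R"),
                sig = list(c("R", "a"), c("a", "b")))
  pl <- sample_shortest_paths(db)
  expect_equal(merge_and_index(pl, pl)$paths, pl$paths)
  other <- new_path_list(list(c("R", "a", "c")),
                         list(rep("signaling_signaling", 2L)))
  merged <- merge_and_index(pl, other)
  expect_equal(merged$p, pl$p + 1L)
  expect_equal(merged$k, pl$k + 3L)
})

test_that("path lists are deterministic and round-trip through disk", {
  db <- random_db(3L, n_nodes = 10L, edge_prob = 0.3)
  pl <- sample_shortest_paths(db)
  expect_identical(pl, sample_shortest_paths(db))
  d <- tempfile()
  write_path_list(pl, d)
  pl2 <- read_path_list(d)
  expect_equal(pl2$paths, pl$paths)
  expect_equal(pl2$edge_categories, pl$edge_categories)
  expect_equal(pl2$k, pl$k)
})
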