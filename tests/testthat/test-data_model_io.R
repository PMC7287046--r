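test_that("wide response tables round-trip through the reader", {
  vals <- matrix(c(0.1, 0.2, 0.3, 0.4,
                   0.5, 0.6, 0.7, 0.8,
                   0.15, 0.25, 0.35, 0.45), 3, 4, byrow = TRUE,
                 dimnames = list(c("dA", "dB", "dC"),
                                 c("c1", "c2", "c3", "c4")))
  path <- tempfile(fileext = ".tsv")
  write.table(data.frame(drug = rownames(vals), vals, check.names = FALSE),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  m <- read_response_table(path, "wide", "auc", min_cell_lines = 1)
  expect_equal(m$values, vals)
  expect_equal(sum(!is.na(m$values)), 12)
})

test_that("long reader deduplicates consistent entries and keeps NA", {
  tab <- data.frame(drug = c("dA", "dA", "dA", "dB", "dB", "dB"),
                    cell_line = c("c1", "c2", "c1", "c1", "c2", "c3"),
                    value = c(0.2, 0.4, 0.2, 0.6, NA, 0.5))
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_warning(
    m <- read_response_table(path, "long", "auc", min_cell_lines = 1),
    "deduplicated")
  expect_equal(m$values["dA", "c1"], 0.2)
  expect_true(is.na(m$values["dB", "c2"]))
})

test_that("reader rejects conflicting duplicates and out-of-range AUC", {
  tab <- data.frame(drug = c("dA", "dA"), cell_line = c("c1", "c1"),
                    value = c(0.2, 0.3))
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_response_table(path, "long", "auc", min_cell_lines = 1),
               "conflicting")
  tab2 <- data.frame(drug = c("dA", "dB"), cell_line = c("c1", "c1"),
                     value = c(1.2, 0.3))
  write.table(tab2, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_response_table(path, "long", "auc", min_cell_lines = 1),
               "AUC")
})

test_that("drugs below the coverage threshold are dropped with a warning", {
  vals <- matrix(runif(20, 0.2, 0.8), 2, 10,
                 dimnames = list(c("dA", "dB"), paste0("c", 1:10)))
  vals["dB", 3:10] <- NA
  path <- tempfile(fileext = ".tsv")
  write.table(data.frame(drug = rownames(vals), vals, check.names = FALSE),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_warning(m <- read_response_table(path, "wide", "auc",
                                          min_cell_lines = 5), "dropping")
  expect_equal(rownames(m$values), "dA")
})

test_that("multi-batch long tables trigger a bias warning only", {
  tab <- data.frame(drug = rep(c("dA", "dB"), each = 2),
                    cell_line = rep(c("c1", "c2"), 2),
                    value = c(0.2, 0.4, 0.6, 0.5),
                    batch = c("WTSI", "MGH", "WTSI", "MGH"))
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_warning(m <- read_response_table(path, "long", "auc",
                                          min_cell_lines = 1),
                 "batch")
  expect_equal(dim(m$values), c(2L, 2L))
})

test_that("synergy tables canonicalize pairs and reject duplicates", {
  st <- synergy_table(c("c1", "c1"), c("zeta", "alpha"), c("alpha", "beta"),
                      c(1, 0))
  expect_equal(st$drug_a, c("alpha", "alpha"))
  expect_equal(st$drug_b, c("zeta", "beta"))
  expect_error(synergy_table(c("c1", "c1"), c("b", "a"), c("a", "b"),
                             c(1, 0)), "duplicate")
  expect_error(synergy_table("c1", "a", "a", 1), "drug_a == drug_b")
})

test_that("checkerboard plate invariants are enforced", {
  V <- matrix(100, 3, 3)
  pl <- checkerboard_plate(c("a", "b"), list(c(0, 1, 2), c(0, 1, 2)), V)
  expect_s3_class(pl, "checkerboard_plate")
  V2 <- V; V2[1, 1] <- 80
  expect_error(checkerboard_plate(c("a", "b"),
                                  list(c(0, 1, 2), c(0, 1, 2)), V2),
               "untreated")
  expect_error(checkerboard_plate(c("a", "b"),
                                  list(c(0, 2, 1), c(0, 1, 2)), V),
               "increasing")
})

test_that("atlas geometry JSON round-trips and SVG has one path per drug", {
  tr <- random_tree(5, seed = 11)
  lay <- suppressWarnings(layout_voronoi_treemap(tr, seed = 2))
  lay <- border_weights(lay, tr)
  jpath <- tempfile(fileext = ".json")
  write_atlas_geometry(lay, jpath, "json")
  back <- read_atlas_geometry(jpath)
  expect_equal(names(back$cells), names(lay$cells))
  for (nm in names(lay$cells))
    expect_equal(back$cells[[nm]], unname(lay$cells[[nm]]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  spath <- tempfile(fileext = ".svg")
  write_atlas_geometry(lay, spath, "svg")
  svg <- readLines(spath)
  expect_equal(sum(grepl('class="cell"', svg)), 5)
  # empty layout is rejected
  empty <- lay; empty$cells <- list()
  expect_error(write_atlas_geometry(empty, jpath), "empty")
})

test_that("newick export encodes merge heights as branch lengths", {
  single <- structure(list(labels = "A"), class = "drug_tree")
  p1 <- tempfile(fileext = ".nwk")
  export_tree_newick(single, p1)
  expect_equal(readLines(p1), "A;")

  two <- drug_tree(rbind(c(-1L, -2L)), 2, c("A", "B"))
  p2 <- tempfile(fileext = ".nwk")
  export_tree_newick(two, p2)
  phy <- ape::read.tree(p2)
  expect_setequal(phy$tip.label, c("A", "B"))
  expect_equal(unname(phy$edge.length), c(2, 2))

  # 4-leaf caterpillar round-trips through an external Newick parser:
  # root-to-leaf path length must equal the root height for every leaf
  cat4 <- drug_tree(rbind(c(-1L, -2L), c(1L, -3L), c(2L, -4L)),
                    c(1, 2, 3), c("A", "B", "C", "D"))
  p3 <- tempfile(fileext = ".nwk")
  export_tree_newick(cat4, p3)
  phy <- ape::read.tree(p3)
  expect_setequal(phy$tip.label, c("A", "B", "C", "D"))
  depths <- ape::node.depth.edgelength(phy)[seq_len(4)]
  expect_equal(unname(depths), rep(3, 4))
  # leaf-to-leaf path distances on the parsed tree are twice the merge
  # heights (both leaves descend from the joining node)
  ct <- ape::cophenetic.phylo(phy)[c("A", "B", "C", "D"),
                                   c("A", "B", "C", "D")]
  cm <- cophenetic_distance(cat4, normalize = FALSE)
  expect_equal(ct, 2 * unclass(cm)[rownames(ct), colnames(ct)],
               ignore_attr = TRUE)
})
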