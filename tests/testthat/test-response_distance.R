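test_that("cosine dissimilarity matches hand-computed inner products", {
  # AUC = 1 - effect, so effect vectors are chosen directly
  eff <- rbind(dA = c(1, 0, 1), dB = c(1, 1, 0), dC = c(1, 0, 1))
  m <- make_response(1 - eff)
  colnames(m$values) <- c("c1", "c2", "c3")
  d <- cosine_dissimilarity(m, min_overlap = 2)
  expect_equal(d["dA", "dC"], 0)             # identical vectors
  expect_equal(d["dA", "dB"], 0.5)           # 1 - 1/2
  expect_equal(diag(d), setNames(rep(0, 3), rownames(eff)))
  expect_equal(d, t(d))

  orth <- make_response(1 - rbind(dA = c(1, 0), dB = c(0, 1)))
  expect_equal(cosine_dissimilarity(orth, min_overlap = 2)["dA", "dB"], 1)
})

test_that("degenerate cosine inputs error or go missing with warning", {
  zero <- make_response(rbind(dA = c(1, 1, 1), dB = c(0.2, 0.3, 0.1)))
  expect_error(cosine_dissimilarity(zero), "all-zero")

  vals <- rbind(dA = c(0.2, 0.3, NA, NA), dB = c(NA, NA, 0.4, 0.3))
  colnames(vals) <- paste0("c", 1:4)
  low <- make_response(vals)
  expect_warning(d <- cosine_dissimilarity(low, min_overlap = 2),
                 "min_overlap")
  expect_true(is.na(d["dA", "dB"]))
})

test_that("clustering is deterministic and finds the obvious structure", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"),
                                                    c("A", "B")))
  tr <- cluster_drugs(d, "average")
  expect_equal(tr$hclust$height, 0.4)

  d3 <- matrix(0.9, 3, 3, dimnames = list(c("A", "B", "C"),
                                          c("A", "B", "C")))
  diag(d3) <- 0
  d3["A", "B"] <- d3["B", "A"] <- 0.1
  tr3 <- cluster_drugs(d3, "average")
  # first merge must join A and B (both leaves, i.e. negative entries)
  expect_setequal(tr3$hclust$merge[1, ], c(-1L, -2L))
  expect_equal(tr3$hclust$height[1], 0.1)

  # permuting input rows leaves the merge heights invariant
  perm <- c("C", "A", "B")
  tr3p <- cluster_drugs(d3[perm, perm], "average")
  expect_equal(tr3p$hclust$height, tr3$hclust$height)
  expect_equal(cophenetic_distance(tr3p), cophenetic_distance(tr3))
})

test_that("missing distances are imputed by the matrix median with a message", {
  d <- matrix(c(0, 0.2, NA, 0.2, 0, 0.6, NA, 0.6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_message(tr <- cluster_drugs(d, "average"), "imputing")
  expect_s3_class(tr, "drug_tree")
})

test_that("cophenetic distances agree with a brute-force LCA oracle", {
  for (seed in 1:20) {
    n <- sample(3:32, 1)
    tr <- random_tree(n, seed = seed)
    cm <- cophenetic_distance(tr, normalize = FALSE)
    expect_equal(unclass(cm), brute_cophenetic(tr), ignore_attr = TRUE)
  }
})

test_that("three-leaf cophenetic heights and normalization behave", {
  tr <- three_leaf_tree(1, 2)
  cm <- cophenetic_distance(tr, normalize = FALSE)
  expect_equal(cm["A", "B"], 1)
  expect_equal(cm["A", "C"], 2)
  expect_equal(cm["B", "C"], 2)
  expect_equal(diag(cm), setNames(rep(0, 3), c("A", "B", "C")))
  cmn <- cophenetic_distance(tr, normalize = TRUE)
  expect_equal(max(cmn), 1)
  expect_equal(cmn["A", "B"], 0.5)
})

test_that("cophenetic matrices are exactly ultrametric", {
  for (seed in 1:5) {
    tr <- random_tree(16, seed = seed + 100)
    cm <- unclass(cophenetic_distance(tr, normalize = FALSE))
    n <- nrow(cm)
    for (j in seq_len(n)) {
      lhs <- cm                                  # d(i, k)
      rhs <- outer(cm[, j], cm[j, ], pmax)       # max(d(i,j), d(j,k))
      expect_true(all(lhs <= rhs + 1e-12))
    }
  }
})

test_that("average linkage reproduces an ultrametric input exactly", {
  tr0 <- random_tree(12, seed = 7)
  um <- unclass(cophenetic_distance(tr0, normalize = FALSE))
  tr <- cluster_drugs(um, "average")
  expect_equal(unclass(cophenetic_distance(tr, normalize = FALSE))[
    rownames(um), colnames(um)], um, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("cophenetic correlation equals an independent Pearson routine", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:12, 1)
    x <- matrix(runif(n * 6), n)
    rownames(x) <- sprintf("D%02d", seq_len(n))
    dm <- as.matrix(dist(x))
    tr <- cluster_drugs(dm, "average")
    rep <- cophenetic_correlation(dm, tr)
    expect_equal(rep$c, cor(rep$pairs$x, rep$pairs$t), tolerance = 1e-12)
    expect_equal(mean(rep$pairs$x), rep$x_bar)
  }
})

test_that("cophenetic correlation hits 1 on faithful trees, < 0 on anti-ordered", {
  tr <- random_tree(10, seed = 3)
  um <- cophenetic_distance(tr, normalize = FALSE)
  rep <- cophenetic_correlation(um, tr)
  expect_equal(rep$c, 1, tolerance = 1e-12)

  # anti-ordered toy: input distances reversed relative to tree heights
  tr3 <- three_leaf_tree(1, 2)
  anti <- matrix(c(0, 2, 1, 2, 0, 1, 1, 1, 0), 3,
                 dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_lt(cophenetic_correlation(anti, tr3)$c, 0)
})

test_that("constant cophenetic distances yield NA with a warning", {
  tr <- drug_tree(rbind(c(-1L, -2L)), 1, c("A", "B"))
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_warning(rep <- cophenetic_correlation(d, tr), "constant")
  expect_true(is.na(rep$c))
})

test_that("target distances average cross-drug cophenetic distances", {
  # leaves A, B, C with d(A,C) = 0.4, d(B,C) = 0.8 needs A,B merging low:
  # heights: A-B at 0.4? construct explicit: (A,C) at 0.4 impossible with
  # ultrametric d(B,C)=0.8 and d(A,B)=?; use A,C merge 0.4 then B at 0.8
  tr <- drug_tree(rbind(c(-1L, -3L), c(1L, -2L)), c(0.4, 0.8),
                  c("A", "B", "C"))
  cm <- cophenetic_distance(tr, normalize = FALSE)
  expect_equal(cm["A", "C"], 0.4)
  expect_equal(cm["B", "C"], 0.8)
  ann <- annotation(targets_of = list(A = "u", B = "u", C = "v"))
  td <- target_distance(tr, ann, normalize = FALSE)
  expect_equal(td["u", "v"], mean(c(0.4, 0.8)))      # hand average 0.6
  # two singleton targets: target distance = drug distance
  ann2 <- annotation(targets_of = list(A = "p", C = "q"))
  td2 <- target_distance(tr, ann2, normalize = FALSE)
  expect_equal(td2["p", "q"], 0.4)
  expect_equal(diag(td2), setNames(c(0, 0), c("p", "q")))
  # a single drug carrying both targets has no non-identical cross pair
  ann3 <- annotation(targets_of = list(A = c("x", "y")))
  td3 <- target_distance(tr, ann3, normalize = FALSE)
  expect_true(is.na(td3["x", "y"]))
})

test_that("pathway sets split within/between and drop cross-reactive drugs", {
  tr <- random_tree(4, seed = 21)
  labs <- tr$labels
  ann <- annotation(pathway_of = setNames(c("g1", "g1", "g2", "g2"), labs))
  ps <- pathway_distance_sets(tr, ann)
  expect_length(ps$within, 2)
  expect_length(ps$between, 4)

  ann_one <- annotation(pathway_of = setNames(rep("g1", 4), labs))
  expect_length(pathway_distance_sets(tr, ann_one)$between, 0)

  annx <- annotation(pathway_of = setNames(c("g1", "g1", "g2", "g2"), labs),
                     cross_reactive = labs[1])
  psx <- pathway_distance_sets(tr, annx)
  expect_length(psx$within, 1)
  expect_length(psx$between, 2)
})

test_that("cross-process drug pairs are farther than within-process pairs", {
  cfg <- sim_config(seed = 42)
  panel <- generate_panel(cfg)
  tr <- cluster_drugs(cosine_dissimilarity(panel$response), "ward_d2")
  cm <- cophenetic_distance(tr)
  pod <- panel$truth$process_of_drug
  prs <- t(combn(names(pod), 2))
  dd <- cm[prs]
  cross <- pod[prs[, 1]] != pod[prs[, 2]]
  expect_gt(mean(dd[cross]), mean(dd[!cross]))
})
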