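make_small_inputs <- function() {
  tr <- three_leaf_tree(0.5, 1, labels = c("dA", "dB", "dC"))
  dm <- cophenetic_distance(tr)
  sens <- data.frame(
    cell_line = rep(c("c1", "c2"), each = 3),
    drug = rep(c("dA", "dB", "dC"), 2),
    tissue = "brain",
    log2_ic50 = c(-1, 0, 1, 1, 0, -1))
  sens <- normalize_tissue(sens)
  ann <- annotation(targets_of = list(dA = "G1", dB = "G2", dC = "G3"),
                    mutated_in = list(c1 = "G1", c2 = "none"))
  list(dm = dm, sens = sens, ann = ann)
}

test_that("feature assembly yields one row per cell line and pair", {
  inp <- make_small_inputs()
  st1 <- synergy_table("c1", "dA", "dB", 1)
  rows1 <- assemble_features(inp$dm, inp$sens, inp$ann, st1)
  expect_equal(nrow(rows1), 1)
  expect_equal(rows1$t_a, 1)                  # dA targets G1 mutated in c1
  expect_equal(rows1$t_b, 0.01)
  expect_equal(rows1$t, 1)

  st6 <- synergy_table(rep(c("c1", "c2"), each = 3),
                       rep(c("dA", "dA", "dB"), 2),
                       rep(c("dB", "dC", "dC"), 2),
                       c(1, 0, 1, 0, 1, 0))
  rows6 <- assemble_features(inp$dm, inp$sens, inp$ann, st6)
  expect_equal(nrow(rows6), 6)                # C(3,2) x 2 cell lines
  expect_true(all(rows6$c == 1))
  expect_equal(rows6$d[rows6$drug_a == "dA" & rows6$drug_b == "dB"],
               rep(0.5, 2))
})

test_that("rows without a pair distance are dropped and C flags propagate", {
  inp <- make_small_inputs()
  st <- synergy_table(c("c1", "c1"), c("dA", "dA"), c("dB", "dX"), c(1, 0))
  expect_message(rows <- assemble_features(inp$dm, inp$sens, inp$ann, st),
                 "dropping 1")
  expect_equal(nrow(rows), 1)

  # strict mode: missing sensitivity for one drug zeroes C
  sens_miss <- inp$sens[!(inp$sens$cell_line == "c1" &
                            inp$sens$drug == "dB"), ]
  rows_s <- assemble_features(inp$dm, sens_miss, inp$ann,
                              synergy_table("c1", "dA", "dB", 1),
                              strict = TRUE)
  expect_equal(rows_s$c, 0L)
  rows_l <- assemble_features(inp$dm, sens_miss, inp$ann,
                              synergy_table("c1", "dA", "dB", 1),
                              strict = FALSE)
  expect_equal(rows_l$c, 1L)
})

test_that("objective values follow the closed form and its linearity", {
  rows <- data.frame(s_a = 1, s_b = 1, d = 0.5, t_a = 1, t_b = 0.01,
                     c = 1L)
  v <- eq_objective(rows, s = 1, d = 1, t = 1)
  expect_equal(as.numeric(v), -1 + 0.5 + 1.01)       # 0.51
  v2 <- eq_objective(rows, s = 2, d = 2, t = 2)
  expect_equal(as.numeric(v2), 2 * as.numeric(v))
  rows0 <- rows; rows0$c <- 0L
  expect_equal(as.numeric(eq_objective(rows0)), 0)
})

test_that("the simplistic score matches its arithmetic and logistic identity", {
  expect_equal(simplistic_theta(1, 0), 0.5)
  expect_equal(simplistic_theta(1, 1), exp(1) / (1 + exp(1)))
  expect_equal(simplistic_theta(0.01, 0), 0.01 / 1.01)
  # identity with the logistic inverse link of d + log t over a grid
  grid <- expand.grid(t = c(0.01, 1), d = seq(0, 3, by = 0.25))
  expect_equal(simplistic_theta(grid$t, grid$d),
               plogis(grid$d + log(grid$t)), tolerance = 1e-12)
  # monotone in d and t
  expect_true(all(diff(simplistic_theta(1, seq(0, 2, 0.1))) > 0))
  expect_gt(simplistic_theta(1, 0.5), simplistic_theta(0.01, 0.5))
})

test_that("pair averaging of the simplistic score uses all cell lines", {
  rows <- data.frame(drug_a = "dA", drug_b = "dB",
                     t = c(1, 0.01), d = c(0.5, 0.5))
  agg <- simplistic_pair_scores(rows)
  expect_equal(agg$theta,
               mean(simplistic_theta(c(1, 0.01), 0.5)))
  expect_equal(agg$n_cell_lines, 2)
})

test_that("balanced draws are exactly 1:1 within tissue", {
  set.seed(4)
  rows <- data.frame(tissue = rep(c("brain", "skin"), c(40, 30)),
                     label = rbinom(70, 1, 0.3))
  bal <- drugatlas:::balanced_draw(rows)
  for (ts in unique(bal$tissue)) {
    tb <- table(bal$label[bal$tissue == ts])
    expect_equal(unname(tb["1"]), unname(tb["0"]))
  }
})

test_that("null data yield near-zero coefficients", {
  rows <- simulate_pair_rows(1500, alpha = 0, beta = 0, delta = 0,
                             gamma = 0, seed = 5)
  fit <- fit_logistic(rows, "IIB", n_resamples = 20, seed = 6)
  expect_lt(max(abs(fit$coefficients[c("t", "d", "s_sum")])), 0.35)
})

test_that("model IIB recovers its generating coefficients", {
  rows <- simulate_pair_rows(4000, alpha = -1.5, beta = 2, delta = 3,
                             gamma = -1, seed = 7)
  fit <- fit_logistic(rows, "IIB", n_resamples = 20, seed = 8)
  cf <- fit$coefficients
  expect_equal(unname(cf["t"]), 2, tolerance = 0.2)
  expect_equal(unname(cf["d"]), 3, tolerance = 0.2)
  expect_equal(unname(cf["s_sum"]), -1, tolerance = 0.25)
  # determinism under the seed
  fit2 <- fit_logistic(rows, "IIB", n_resamples = 20, seed = 8)
  expect_identical(fit$coefficients, fit2$coefficients)
})

test_that("per-tissue fitting skips thin strata and still estimates", {
  rows <- simulate_pair_rows(3000, seed = 9)
  fit <- fit_logistic(rows, "IB", n_resamples = 10, seed = 10,
                      per_tissue = TRUE, min_pos = 5)
  expect_true(is.finite(fit$coefficients["d"]))
  expect_gt(fit$coefficients["d"], 0)
})

test_that("separated resamples are refit with a ridge, not dropped", {
  # perfectly separating covariate: d > 0.5 iff label = 1
  n <- 120
  d <- runif(n)
  rows <- data.frame(cell_line = paste0("c", 1:n), tissue = "brain",
                     drug_a = "dA", drug_b = "dB",
                     d = d, s_a = 0.5, s_b = 0.5, t_a = 0.01, t_b = 0.01,
                     t = 0.01, c = 1L, label = as.integer(d > 0.5))
  fit <- fit_logistic(rows, "IB", n_resamples = 5, seed = 11)
  expect_gt(fit$n_ridge, 0)
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("rank AUC matches exhaustive pair counting", {
  expect_equal(drugatlas:::auc_rank(rep(0.3, 8), rep(c(1, 0), 4)), 0.5)
  expect_equal(drugatlas:::auc_rank(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1)
  # 4 positives, 4 negatives, one inversion -> 15/16
  scores <- c(8, 7, 6, 4, 5, 3, 2, 1)
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_equal(drugatlas:::auc_rank(scores, labels), 15 / 16)
  skip_if_not_installed("pROC")
  set.seed(12)
  sc <- runif(60); lb <- rbinom(60, 1, 0.5)
  expect_equal(drugatlas:::auc_rank(sc, lb),
               as.numeric(suppressMessages(
                 pROC::auc(pROC::roc(lb, sc, levels = c(0, 1),
                                     direction = "<", quiet = TRUE)))))
})

test_that("cross-validated AUC keeps drug pairs within folds", {
  rows <- simulate_pair_rows(1200, seed = 13)
  fit <- fit_logistic(rows, "IIB", n_resamples = 10, seed = 14)
  ext <- evaluate_auc(fit, rows, "external")
  expect_gt(ext$auc, 0.7)
  cv <- evaluate_auc(fit, rows, "cv_kfold", k = 4, seed = 15,
                     n_resamples = 5)
  expect_gt(cv$auc, 0.65)
  expect_true(all(diff(cv$roc$fpr) >= 0))
  expect_error(evaluate_auc(fit, rows[rows$label == 1, ], "external"),
               "both")
})

test_that("distance and sensitivity add predictive power under their generator", {
  rows <- simulate_pair_rows(2500, alpha = -1.5, beta = 2, delta = 3,
                             gamma = -1.5, seed = 16)
  cc <- covariate_contribution(rows, n_resamples = 20, seed = 17)
  expect_gt(cc$auc_table["IB"], cc$auc_table["IA"])
  expect_gt(cc$auc_table["IIB"], cc$auc_table["IIA"])
  expect_lt(cc$contrasts$p_one_sided[1], 0.05)
  # distance-free generator: no gain from adding d
  rows0 <- simulate_pair_rows(2500, alpha = 0, beta = 2, delta = 0,
                              gamma = -1.5, seed = 18)
  cc0 <- covariate_contribution(rows0, n_resamples = 20, seed = 19)
  expect_lt(abs(cc0$auc_table["IB"] - cc0$auc_table["IA"]), 0.02)
})

test_that("prediction ranking is monotone in distance and tie-stable", {
  rows <- simulate_pair_rows(1000, seed = 20)
  fit <- fit_logistic(rows, "IB", n_resamples = 10, seed = 21)
  cand <- rows[1:8, ]
  cand$t <- 1; cand$s_a <- 0.5; cand$s_b <- 0.5
  cand$d <- seq(0.1, 0.8, 0.1)
  rk <- rank_predictions(fit, cand)
  expect_equal(rk$d, sort(cand$d, decreasing = fit$coefficients["d"] > 0))
  one <- rank_predictions(fit, cand[3, ])
  expect_equal(nrow(one), 1)
})

test_that("the bounded objective fit prefers distance when labels demand it", {
  rows <- simulate_pair_rows(1500, alpha = -1.5, beta = 0.5, delta = 4,
                             gamma = 0, seed = 22)
  diag <- eq_objective_minimize(rows)
  expect_true(all(c("s", "d", "t", "loss") %in% names(diag)))
  expect_true(all(diag$loss < 0.3))
})
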