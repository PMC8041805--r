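test_that("position splits hit the fractions and respect groups", {
  sp <- make_position_splits(1:100, seed = 7)
  expect_equal(as.integer(table(sp$split)[c("train", "validation", "test")]),
               c(70L, 15L, 15L))
  # co-mutated positions always share a split
  sp2 <- make_position_splits(1:20, co_mutation_groups = list(c(3L, 7L)),
                              seed = 11)
  expect_equal(sp2$split[sp2$position == 3], sp2$split[sp2$position == 7])
  for (s in 1:5) {
    spa <- make_position_splits(1:40, list(c(1L, 2L), c(5L, 9L)), seed = s)
    spb <- make_position_splits(1:40, list(c(1L, 2L), c(5L, 9L)), seed = s)
    expect_identical(spa, spb)
  }
})

make_planted_fm <- function(n = 300, sigma = 0.02, seed = 31) {
  set.seed(seed)
  f1 <- runif(n); f2 <- runif(n); f3 <- runif(n)
  y <- 0.6 * f1 - 0.3 * f2 + rnorm(n, 0, sigma)
  structure(list(
    features = cbind(f1 = f1, f2 = f2, f3 = f3),
    meta = data.frame(variant_id = sprintf("v%03d", 1:n),
                      position = seq_len(n), target = y,
                      label = as.numeric(y > stats::median(y)),
                      stringsAsFactors = FALSE),
    registry = {
      r <- data.frame(name = c("f1", "f2", "f3"), group = "structure",
                      kind = "numeric", stringsAsFactors = FALSE)
      attr(r, "version") <- "1"; r
    }), class = "feature_matrix")
}

test_that("training recovers a planted linear signal with early stopping", {
  fm <- make_planted_fm()
  sp <- make_position_splits(1:300, seed = 3)
  mod <- train_model(fm, sp)
  expect_lte(mod$booster$best_val_rmse, 2 * 0.02 + 0.02)
  expect_lte(mod$booster$n_rounds, 1000L)

  # nothing to learn: stops long before the round budget
  fm2 <- fm
  fm2$meta$target <- 0.5 + rnorm(300, 0, 1e-4)
  mod2 <- train_model(fm2, sp)
  expect_lt(mod2$booster$n_rounds, 100L)

  # deterministic retrain
  mod3 <- train_model(fm, sp)
  expect_identical(predict(mod, fm), predict(mod3, fm))
})

test_that("evaluate computes metrics on the test split only", {
  fm <- make_planted_fm()
  sp <- make_position_splits(1:300, seed = 3)
  mod <- train_model(fm, sp)
  ev <- evaluate(mod, fm, sp, edited_threshold = stats::median(fm$meta$target))
  expect_gte(ev$r2, 0.8)
  expect_lte(ev$r2, 1)
  expect_equal(ev$n_variants, sum(sp$split == "test"))
  expect_true(ev$auROC >= 0 && ev$auROC <= 1)
  expect_true(ev$auPR >= 0 && ev$auPR <= 1)

  # metric helpers against hand-computable cases
  expect_equal(editcode:::auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(editcode:::auroc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(editcode:::aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # perfect inverse ranking: AP = (1/3 + 2/4)/2
  expect_equal(editcode:::aupr(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)),
               (1 / 3 + 2 / 4) / 2)
})

test_that("binary objective trains and predicts probabilities", {
  fm <- make_planted_fm()
  sp <- make_position_splits(1:300, seed = 5)
  mod <- train_model(fm, sp, train_params(objective = "binary"))
  p <- predict(mod, fm)
  expect_true(all(p >= 0 & p <= 1))
  ev <- evaluate(mod, fm, sp, edited_threshold = stats::median(fm$meta$target))
  expect_gt(ev$auROC, 0.7)
})

test_that("SHAP attributions are additive and rank planted weights", {
  fm <- make_planted_fm()
  sp <- make_position_splits(1:300, seed = 3)
  mod <- train_model(fm, sp)
  sh <- explain(mod, fm, sp)
  # additivity: baseline + sum(attributions) = prediction, per row
  pred <- predict(mod, editcode:::subset_rows(fm, sh$rows))
  recon <- sh$baseline + rowSums(sh$values)
  expect_lt(max(abs(recon - pred)), 1e-6)
  # |w1| > |w2| >> 0: ranking follows
  fi <- sh$feature_importance
  expect_identical(fi$name[1], "f1")
  expect_identical(fi$name[2], "f2")
  # percent contributions sum to 100
  expect_equal(sum(fi$percent), 100, tolerance = 1e-9)
  expect_equal(sum(sh$group_contributions), 100, tolerance = 1e-9)

  # single-informative-feature model: that feature carries ~100%
  fm1 <- fm
  fm1$features <- fm$features[, "f1", drop = FALSE]
  fm1$registry <- fm$registry[1, , drop = FALSE]
  fm1$meta$target <- fm$features[, "f1"]
  mod1 <- train_model(fm1, sp)
  sh1 <- explain(mod1, fm1, sp)
  expect_equal(sh1$feature_importance$percent[1], 100, tolerance = 1e-9)
})

test_that("no-leakage assertion holds and catches violations", {
  fm <- fixture_matrix()
  sp <- library_splits(fixture_library(), seed = 2)
  expect_true(assert_no_leakage(fm, sp))
  bad <- sp
  # corrupt: move one position of a co-mutation group across splits
  grp <- Filter(function(g) length(g) > 1, attr(sp, "groups"))
  if (length(grp)) {
    p <- grp[[1]][1]
    bad$split[bad$position == p] <-
      setdiff(c("train", "test"), bad$split[bad$position == p])[1]
    expect_error(assert_no_leakage(fm, bad), "leakage|split across")
  }
})

test_that("cross-substrate evaluation aligns features by name", {
  fm <- make_planted_fm()
  sp <- make_position_splits(1:300, seed = 3)
  mod <- train_model(fm, sp)
  # sanity: evaluating the test rows through the cross-substrate path
  # reproduces evaluate()
  lab <- assign_rows(fm, sp)
  te <- which(lab == "test")
  cs <- cross_substrate_eval(mod, editcode:::subset_rows(fm, te))
  ev <- evaluate(mod, fm, sp)
  expect_equal(cs$r2, ev$r2, tolerance = 1e-12)
  # unshared features become missing; zero overlap errors
  fm_alien <- fm
  colnames(fm_alien$features) <- c("g1", "g2", "g3")
  expect_error(cross_substrate_eval(mod, fm_alien), "zero shared")
})
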