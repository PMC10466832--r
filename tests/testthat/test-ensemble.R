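test_that("balanced sampling probabilities follow inverse class sizes", {
  # real-world colorectal screen counts
  ds <- make_ds(matrix(runif(725 * 2), 725L),
                rep(1:3, times = c(134L, 451L, 140L)))
  plan <- sampling_plan(ds)
  expect_equal(plan$alphas, oracle_alphas(c(134, 451, 140)),
               tolerance = 1e-12)
  expect_equal(sum(plan$alphas), 1, tolerance = 1e-12)
  # every sample of one class shares one weight; weights sum to 1
  expect_equal(sum(plan$weights), 1)
  expect_length(unique(round(plan$weights[ds$labels == 1L], 15L)), 1L)

  bal <- make_ds(matrix(runif(60), 30L), rep(1:3, each = 10L))
  expect_equal(sampling_plan(bal)$alphas, rep(1 / 3, 3L))
})

test_that("balanced draws equalize realized class shares", {
  set.seed(31)
  ds <- make_ds(matrix(runif(200), 100L), rep(1:3, times = c(10L, 80L, 10L)))
  plan <- sampling_plan(ds, subset_size = 10000L)
  sub <- balanced_sample(ds, plan)
  shares <- sub$class_counts / 10000
  expect_true(all(abs(shares - 1 / 3) < 0.02))
  # chi-square goodness of fit against uniform must not reject hard
  expect_gt(stats::chisq.test(sub$class_counts)$p.value, 0.001)
})

test_that("the better of the candidate trees is retained", {
  set.seed(5)
  ds <- generate_synthetic(synth_config(n_samples = 150, n_drugs = 12L,
                                        signature_dim = 4L, seed = 2))
  model <- edst_fit(ds, edst_config(m = 1L, k = 8L, seed = 3))
  expect_length(model$dsts, 1L)
  expect_length(model$selection_scores, 2L)
  expect_equal(max(model$selection_scores),
               model$selection_scores[model$retained])
})

test_that("retained scores dominate every discarded candidate", {
  ds <- generate_synthetic(synth_config(n_samples = 200, n_drugs = 12L,
                                        signature_dim = 5L, seed = 4))
  model <- edst_fit(ds, edst_config(m = 3L, k = 10L, seed = 5))
  kept <- model$selection_scores[model$retained]
  dropped <- model$selection_scores[-model$retained]
  expect_gte(min(kept), max(dropped))
})

test_that("refits under one seed are identical; prediction is stable", {
  ds <- generate_synthetic(synth_config(n_samples = 120, n_drugs = 10L,
                                        signature_dim = 4L, seed = 6))
  m1 <- edst_fit(ds, edst_config(m = 2L, k = 8L, seed = 9))
  m2 <- edst_fit(ds, edst_config(m = 2L, k = 8L, seed = 9))
  expect_identical(m1, m2)
  pr <- edst_predict_proba(m1, ds$features)
  expect_equal(rowSums(pr), rep(1, nrow(ds$features)))
  expect_true(all(pr >= 0))
  expect_error(edst_predict_proba(m1, ds$features[, 1:3]), "features")
})

test_that("tied votes go to the rarer training class", {
  counts <- c(50L, 5L, 20L)
  pr <- rbind(c(0.5, 0.5, 0), c(0.2, 0.2, 0.6), c(1 / 3, 1 / 3, 1 / 3))
  picks <- edst:::argmax_rare(pr, counts)
  expect_equal(picks, c(2L, 3L, 2L))
})

test_that("importance counts node usage and honours the threshold", {
  cn <- c("A", "B")
  # hand-built model: 3 single-stump trees on features 3, 3, 1
  mk_tree <- function(feat) {
    structure(list(root = list(
      type = "node", feature = feat, breaks = 0.5, n = 10L,
      dist = c(0.5, 0.5),
      children = list(list(type = "leaf", prob = c(1, 0), majority = 1L,
                           n = 5L),
                      list(type = "leaf", prob = c(0, 1), majority = 2L,
                           n = 5L))),
      theta = 1L, max_depth = 10L, n_leaves = 2L, depth = 1L),
      class = "stump_tree")
  }
  model <- structure(list(
    dsts = list(fake_dst(list(mk_tree(3L), mk_tree(3L), mk_tree(1L)),
                         matrix(c(1L, 2L, 1L, 2L, 1L, 2L), 2L), cn)),
    selection = structure(list(selected = 1:4, scores = rep(1, 4)),
                          class = "feature_selection"),
    feature_names = paste("feature", 1:4),
    class_names = cn, class_counts = c(5L, 5L),
    scaler = NULL), class = "edst_model")
  fi <- feature_importance(model, threshold = 1.0)
  expect_equal(unname(fi$importance),  c(2 / 3, 1 / 3))
  expect_equal(names(fi$importance), c("feature 3", "feature 1"))
  expect_setequal(fi$top_set, c("feature 3", "feature 1"))
  # single-feature model concentrates all importance
  m1 <- model; m1$dsts <- list(fake_dst(list(mk_tree(3L)),
                                        matrix(c(1L, 2L), 2L), cn))
  expect_equal(feature_importance(m1)$importance,
               c("feature 3" = 1.0))
})

test_that("uniform usage needs ceil(threshold * k) features", {
  cn <- c("A", "B")
  mk_tree <- function(feat) {
    structure(list(root = list(
      type = "node", feature = feat, breaks = 0.5, n = 10L,
      dist = c(0.5, 0.5),
      children = list(list(type = "leaf", prob = c(1, 0), majority = 1L,
                           n = 5L),
                      list(type = "leaf", prob = c(0, 1), majority = 2L,
                           n = 5L))),
      theta = 1L, max_depth = 10L, n_leaves = 2L, depth = 1L),
      class = "stump_tree")
  }
  model <- structure(list(
    dsts = list(fake_dst(lapply(1:4, mk_tree),
                         matrix(rep(c(1L, 2L), 4L), 2L), cn)),
    selection = structure(list(selected = 1:4, scores = rep(1, 4)),
                          class = "feature_selection"),
    feature_names = paste("feature", 1:4),
    class_names = cn, class_counts = c(5L, 5L),
    scaler = NULL), class = "edst_model")
  fi <- feature_importance(model, threshold = 0.9)
  expect_length(fi$top_set, 4L)   # 4 x 0.25 needs all four to pass 0.9
})

test_that("complexity statistics match a recursive recount", {
  ds <- generate_synthetic(synth_config(n_samples = 150, n_drugs = 10L,
                                        signature_dim = 4L, seed = 8))
  model <- edst_fit(ds, edst_config(m = 2L, k = 8L, seed = 11))
  cs <- complexity_stats(model)
  manual_depth <- manual_leaves <- c()
  for (d in model$dsts) for (tr in d$trees) {
    st <- edst:::tree_stats_node(tr$root)
    manual_depth <- c(manual_depth, st[["depth"]])
    manual_leaves <- c(manual_leaves, st[["leaves"]])
    expect_equal(tr$depth, st[["depth"]])
    expect_equal(tr$n_leaves, st[["leaves"]])
  }
  expect_equal(cs$mean_max_depth, mean(manual_depth))
  expect_equal(cs$mean_leaf_count, mean(manual_leaves))
  expect_lte(cs$mean_max_depth, model$config$max_depth)
  # an all-leaf ensemble sits at depth 0, one leaf per tree
  leafy <- structure(list(dsts = list(fake_dst(
    list(fake_leaf_tree(c(0.5, 0.5))), matrix(c(1L, 2L), 2L),
    c("A", "B")))), class = "edst_model")
  cs0 <- complexity_stats(leafy$dsts[[1L]])
  expect_equal(c(cs0$mean_max_depth, cs0$mean_leaf_count), c(0, 1))
})
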