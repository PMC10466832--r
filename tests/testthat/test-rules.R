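test_that("rule extraction yields one rule per leaf with path conditions", {
  set.seed(13)
  ds <- make_ds(matrix(runif(80), 40L), rep(1:2, 20L))
  d <- dst_fit(ds)
  rules <- extract_rules(d)
  expect_length(rules, d$trees[[1L]]$n_leaves)
  n_cond <- vapply(rules, function(r) nrow(r$conditions), 1L)
  expect_true(all(n_cond <= d$trees[[1L]]$depth))
  expect_true(all(n_cond >= 1L | d$trees[[1L]]$depth == 0L))
})

test_that("each sample fires exactly one rule per tree, matching the tree", {
  set.seed(14)
  for (rep in 1:12) {
    n <- 60L
    X <- matrix(sample(seq(0, 1, 0.125), 3L * n, replace = TRUE), n, 3L)
    y <- 1L + as.integer(X[, 1L] + 0.4 * X[, 2L] +
                           0.15 * runif(n) > 0.7)
    if (length(unique(y)) < 2L) next
    ds <- make_ds(X, y)
    d <- dst_fit(ds, max_depth = 2L, leaf_frac = 0.1)
    rules <- extract_rules(d)
    tree <- d$trees[[1L]]
    probs <- edst:::tree_leaf_probs(tree, X)
    for (i in seq_len(n)) {
      fired <- Filter(function(r) {
        edst:::rule_matches(r, X[i, , drop = FALSE])
      }, rules)
      expect_length(fired, 1L)
      verdict <- fired[[1L]]$predict_class
      side <- if (probs[i, 1L] >= probs[i, 2L]) 1L else 2L
      expect_equal(verdict, d$class_names[d$pairs[side, 1L]])
    }
  }
})

test_that("coverage and accuracy count over the pairwise population", {
  # 8 pair samples; rule matches 4, 3 of them labeled as predicted
  X <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9), ncol = 1L)
  y <- c(1L, 1L, 1L, 2L, 1L, 2L, 2L, 2L)
  ds <- make_ds(X, y, class_names = c("A", "B"))
  r <- structure(list(
    conditions = data.frame(feature = 1L, name = "feature 1",
                            lo = -Inf, hi = 0.45),
    predict_class = "A", against_class = "B",
    provenance = c(dst = 1, tree = 1, leaf = 1),
    coverage = NA_real_, accuracy = NA_real_, score = NA_real_),
    class = "rule")
  r <- rule_metrics(r, ds)
  expect_equal(r$coverage, 0.5)
  expect_equal(r$accuracy, 0.75)
  expect_equal(r$score, rule_score(0.5, 0.75))
  # rule matching everything correctly
  r2 <- r
  r2$conditions$hi <- Inf
  r2$conditions$lo <- -Inf
  r2 <- rule_metrics(r2, ds)
  expect_equal(r2$coverage, 1.0)
  # rule matching nothing
  r3 <- r
  r3$conditions$lo <- 10
  r3$conditions$hi <- 20
  r3 <- rule_metrics(r3, ds)
  expect_equal(c(r3$coverage, r3$accuracy, r3$score), c(0, 0, 0))
})

test_that("the rule score is the harmonic mean with a zero limit", {
  expect_equal(rule_score(1, 1), 1)
  expect_equal(rule_score(0.5, 1.0), 2 / 3)
  expect_equal(rule_score(0, 0.7), 0)
  expect_equal(rule_score(0, 0), 0)
  grid <- expand.grid(a = seq(0, 1, 0.1), b = seq(0, 1, 0.1))
  expect_equal(rule_score(grid$a, grid$b), rule_score(grid$b, grid$a))
  expect_true(all(rule_score(grid$a, grid$b) <= pmin(1, (grid$a + grid$b))))
})

test_that("rendering follows the printed dialect, dropping infinite bounds", {
  mk_rule <- function(conds, pred, agst) {
    structure(list(conditions = conds, predict_class = pred,
                   against_class = agst,
                   provenance = c(dst = 1, tree = 1, leaf = 1),
                   coverage = NA_real_, accuracy = NA_real_,
                   score = NA_real_), class = "rule")
  }
  r1 <- mk_rule(data.frame(feature = c(1695L, 431L),
                           name = c("feature 1695", "feature 431"),
                           lo = c(0.59, 0.52), hi = c(0.66, 1.00)),
                "Additive", "Synergy")
  expect_equal(render_rule(r1),
               paste0("IF 0.59 < feature 1695 ≤ 0.66 AND ",
                      "0.52 < feature 431 ≤ 1.0 ",
                      "THEN PREDICT Additive THAN Synergy"))
  r2 <- mk_rule(data.frame(feature = 1604L, name = "feature 1604",
                           lo = -Inf, hi = 0.37), "Additive", "Antagonism")
  expect_equal(render_rule(r2),
               "IF feature 1604 ≤ 0.37 THEN PREDICT Additive THAN Antagonism")
  r3 <- mk_rule(data.frame(feature = 1850L, name = "feature 1850",
                           lo = 1.0, hi = Inf), "Synergy", "Antagonism")
  expect_equal(render_rule(r3),
               "IF 1.0 < feature 1850 THEN PREDICT Synergy THAN Antagonism")
})

test_that("parse is the exact inverse of render", {
  set.seed(15)
  for (rep in 1:25) {
    k <- sample(1:3, 1L)
    feats <- sample(1:2000, k)
    lo <- round(runif(k, -1, 0.4), 4L)
    hi <- lo + round(runif(k, 0.05, 1), 4L)
    drop_lo <- runif(k) < 0.3
    drop_hi <- !drop_lo & runif(k) < 0.3
    lo[drop_lo] <- -Inf
    hi[drop_hi] <- Inf
    r <- structure(list(
      conditions = data.frame(feature = feats,
                              name = paste("feature", feats),
                              lo = lo, hi = hi),
      predict_class = "Synergy", against_class = "Additive",
      provenance = c(dst = NA, tree = NA, leaf = NA),
      coverage = NA_real_, accuracy = NA_real_, score = NA_real_),
      class = "rule")
    back <- parse_rule(render_rule(r))
    expect_equal(back$conditions$feature, r$conditions$feature)
    expect_equal(back$conditions$lo, r$conditions$lo, tolerance = 1e-12)
    expect_equal(back$conditions$hi, r$conditions$hi, tolerance = 1e-12)
    expect_equal(back$predict_class, r$predict_class)
    expect_equal(back$against_class, r$against_class)
  }
})

test_that("malformed rule text raises a positioned syntax error", {
  expect_error(parse_rule("WHENEVER x THEN y"), "syntax error")
  expect_error(parse_rule("IF 0.5 < feature 3 THEN GUESS A THAN B"),
               "syntax error")
  expect_error(parse_rule(
    "IF banana THEN PREDICT A THAN B"), "condition 1")
})

test_that("ranking is by score with stable tie order", {
  set.seed(16)
  ds <- generate_synthetic(synth_config(n_samples = 150, n_drugs = 12L,
                                        signature_dim = 4L, seed = 17))
  model <- edst_fit(ds, edst_config(m = 2L, k = 8L, seed = 18))
  ranked <- rank_rules(model, ds)
  scores <- vapply(ranked, `[[`, numeric(1L), "score")
  expect_true(all(diff(scores) <= 1e-12))
  expect_true(all(scores >= 0 & scores <= 1))
  # rendered output parses back
  back <- parse_rule(render_rule(ranked[[1L]]))
  expect_s3_class(back, "rule")
})
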