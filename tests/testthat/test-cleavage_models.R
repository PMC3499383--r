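test_that("known-motif rule fires on dibasic and RxxR patterns only", {
  sites <- make_site_table(
    c(window_p421(p2 = "K", p1 = "R"),   # dibasic KR
      window_p421(p2 = "R", p1 = "K"),   # dibasic RK variant
      window_p421(p4 = "R", p1 = "R"),   # RxxR
      window_p421(p1 = "R"),             # single R
      window_p421(p1 = "K")),            # single K
    cleaved = rep(FALSE, 5))
  expect_identical(known_motif_predict(sites), c(1, 1, 1, 0, 0))
  scores <- predict_scores(known_motif_model(), sites)
  expect_true(all(scores %in% c(0, 1)))
  expect_identical(apply_threshold(scores, 0.5), scores == 1)
})

test_that("rule and motif taxonomy agree on random P1-P4 windows", {
  set.seed(11)
  combos <- expand.grid(p4 = c("R", "K", "A"), p3 = c("A", "K"),
                        p2 = c("R", "K", "A", "G"),
                        p1 = c("R", "K"), stringsAsFactors = FALSE)
  wins <- apply(combos, 1, function(r) {
    chars <- rep("A", 18)
    chars[6] <- r[["p4"]]; chars[7] <- r[["p3"]]
    chars[8] <- r[["p2"]]; chars[9] <- r[["p1"]]
    paste(chars, collapse = "")
  })
  sites <- make_site_table(wins, cleaved = rep(FALSE, length(wins)))
  hits <- known_motif_predict(sites) == 1
  dibasic <- combos$p1 %in% c("K", "R") & combos$p2 %in% c("K", "R")
  for (i in seq_along(wins)) {
    tags <- classify_motif(wins[i])
    expect_identical(hits[i],
                     length(intersect(tags, c("xxKR", "xxRR", "RxxR"))) > 0 ||
                       dibasic[i],
                     info = wins[i])
  }
})

test_that("logistic fit separates a separable toy set, matching a brute-force oracle", {
  set.seed(2)
  sites <- separable_sites(12)
  model <- train_logistic(sites, scheme = "AA", seed = 1)
  preds <- apply_threshold(predict_scores(model, sites), 0.5)
  expect_identical(mean(preds == sites$cleaved), 1.0)

  # brute-force oracle on the 1-feature reduction x = (P1 == 'R'):
  # grid search over (intercept, weight) for the best achievable CCR
  x <- sites$residue == "R"
  grid <- expand.grid(b = seq(-3, 3, by = 0.25), w = seq(-3, 3, by = 0.25))
  ccr_grid <- apply(grid, 1, function(g) {
    mean((plogis(g[["b"]] + g[["w"]] * x) >= 0.5) == sites$cleaved)
  })
  expect_identical(max(ccr_grid), 1.0)  # a 1-feature separator exists

  # independent oracle: base-R glm on the same reduction agrees
  glm_fit <- suppressWarnings(glm(sites$cleaved ~ x, family = binomial()))
  glm_preds <- predict(glm_fit, type = "response") >= 0.5
  expect_identical(unname(glm_preds), preds)
})

test_that("strong shrinkage drives fitted probabilities to the base rate", {
  set.seed(3)
  sites <- separable_sites(10)
  model <- train_logistic(sites, scheme = "AA", l2 = 1e6, seed = 1)
  p <- predict_scores(model, sites)
  expect_true(all(abs(p - mean(sites$cleaved)) < 0.01))
})

test_that("training is deterministic given inputs and seed", {
  set.seed(4)
  sites <- separable_sites(8)
  m1 <- train_logistic(sites, scheme = "AA", seed = 7)
  m2 <- train_logistic(sites, scheme = "AA", seed = 7)
  expect_identical(m1$parameters, m2$parameters)
  a1 <- train_ann(sites, scheme = "AA", hidden = 2, seed = 7,
                  max_epochs = 300)
  a2 <- train_ann(sites, scheme = "AA", hidden = 2, seed = 7,
                  max_epochs = 300)
  expect_identical(a1$parameters, a2$parameters)
})

test_that("duplicating every training example leaves the logistic fit unchanged", {
  set.seed(6)
  sites <- separable_sites(8)
  doubled <- rbind(sites, sites)
  attr(doubled, "site_config") <- attr(sites, "site_config")
  m1 <- train_logistic(sites, scheme = "AA", seed = 1)
  m2 <- train_logistic(doubled, scheme = "AA", seed = 1)
  expect_equal(m1$parameters$weights, m2$parameters$weights,
               tolerance = 1e-4)
  expect_equal(m1$parameters$intercept, m2$parameters$intercept,
               tolerance = 1e-4)
})

test_that("single-class input and bad thresholds are rejected", {
  sites <- make_site_table(rep(window_p421(p1 = "R"), 4),
                           cleaved = rep(TRUE, 4))
  expect_error(train_logistic(sites), "both")
  expect_error(train_ann(sites), "both")
  expect_error(apply_threshold(c(0.2, 0.8), 0), "between 0 and 1")
  expect_error(apply_threshold(c(0.2, 1.8), 0.5), "0, 1")
  expect_identical(apply_threshold(c(0.4, 0.5, 0.6), 0.5),
                   c(FALSE, TRUE, TRUE))
  expect_identical(apply_threshold(c(0, 0, 0), 0.5), rep(FALSE, 3))
})

test_that("a single hidden unit suffices for the separable toy set", {
  set.seed(8)
  sites <- separable_sites(10)
  model <- train_ann(sites, scheme = "AA", hidden = 1, seed = 1,
                     max_epochs = 2000)
  preds <- apply_threshold(predict_scores(model, sites), 0.5)
  expect_identical(mean(preds == sites$cleaved), 1.0)
})

test_that("the ANN solves an XOR window problem no linear model can", {
  # cleaved iff exactly one of (K at P2, K at P4); P1 = R throughout
  pats <- list(c(p2 = "K", p4 = "A"), c(p2 = "A", p4 = "K"),
               c(p2 = "K", p4 = "K"), c(p2 = "A", p4 = "A"))
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  wins <- rep(vapply(pats, function(p)
    window_p421(p4 = p[["p4"]], p2 = p[["p2"]], p1 = "R"),
    character(1)), each = 6)
  sites <- make_site_table(wins, cleaved = rep(lab, each = 6))

  # brute force: any additive (linear) score f2(P2) + f4(P4) over a grid
  # misclassifies at least one of the four patterns
  x2 <- rep(c(1, 0, 1, 0), each = 6)
  x4 <- rep(c(0, 1, 1, 0), each = 6)
  grid <- expand.grid(w2 = seq(-2, 2, 0.2), w4 = seq(-2, 2, 0.2),
                      b = seq(-2, 2, 0.2))
  best_linear <- max(apply(grid, 1, function(g) {
    mean(((g[["w2"]] * x2 + g[["w4"]] * x4 + g[["b"]]) >= 0) ==
           sites$cleaved)
  }))
  expect_lt(best_linear, 1.0)

  ccrs <- vapply(1:3, function(s) {
    m <- train_ann(sites, scheme = "AA", hidden = 2, seed = s,
                   max_epochs = 3000)
    mean(apply_threshold(predict_scores(m, sites), 0.5) == sites$cleaved)
  }, numeric(1))
  expect_identical(max(ccrs), 1.0)
})

test_that("scoring is stateless and scheme-checked", {
  set.seed(9)
  sites <- separable_sites(8)
  model <- train_logistic(sites, scheme = "AA_PROP", seed = 1)
  all_scores <- predict_scores(model, sites)
  halves <- c(predict_scores(model, sites[1:8, ]),
              predict_scores(model, sites[9:16, ]))
  expect_identical(all_scores, halves)

  short <- make_site_table(rep("AAAKRA", 2), cleaved = c(TRUE, FALSE),
                           upstream = 5, downstream = 1)
  expect_error(predict_scores(model, short), "mismatch")
})

test_that("a zero-weight logistic model scores 0.5 everywhere", {
  set.seed(10)
  sites <- separable_sites(4)
  model <- train_logistic(sites, scheme = "AA", seed = 1)
  model$parameters$weights[] <- 0
  model$parameters$intercept <- 0
  expect_identical(unique(predict_scores(model, sites)), 0.5)
})

test_that("model artifacts survive a serialisation round trip", {
  set.seed(12)
  sites <- separable_sites(8)
  for (maker in list(
    function() train_logistic(sites, scheme = "AA_PROP", seed = 2),
    function() train_ann(sites, scheme = "AA", hidden = 2, seed = 2,
                         max_epochs = 300),
    function() known_motif_model())) {
    model <- maker()
    f <- withr::local_tempfile(fileext = ".json")
    write_model(model, f)
    model2 <- read_model(f)
    expect_equal(predict_scores(model2, sites),
                 predict_scores(model, sites), tolerance = 1e-12)
  }
})
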