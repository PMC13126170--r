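test_that("classifier training rows follow the first-label rule and the cutoff", {
  set.seed(61)
  n <- c(12L, 11L, 4L)
  ids <- sprintf("d%02d", 1:27)
  subs <- c(rep(list(c("tryptophan", "serine")), 12),   # first label wins
            rep(list("serine"), 11), rep(list("valine"), 4))
  feats <- matrix(rnorm(27 * 6), 27)
  ds <- specificity_dataset(ids, subs, features = feats)
  trn <- build_classifier_training(ds, inclusion_cutoff = 10L)
  expect_equal(nrow(trn$X), 23L)                         # 12 + 11
  expect_setequal(levels(trn$y), c("tryptophan", "serine"))
  expect_equal(sum(trn$y == "tryptophan"), 12L)          # labelled by first
  trn_all <- build_classifier_training(ds, inclusion_cutoff = 1L)
  expect_equal(nrow(trn_all$X), 27L)
  expect_error(build_classifier_training(ds, inclusion_cutoff = 100L),
               "counts")
})

test_that("the classifier separates the planted signature rule on held-out data", {
  fx <- fix_dataset()
  plan <- fix_split()
  te <- dataset_subset(fx$dataset, plan$test_ids)
  model <- fix_classifier()
  pred <- predict_substrate(model, te$features)
  sc <- score_predictions(stats::setNames(pred$label, te$domain_id),
                          stats::setNames(te$substrates, te$domain_id))
  expect_gte(sc$accuracy, 0.95)
  expect_true(all(pred$confidence >= 0 & pred$confidence <= 1))
})

test_that("training and prediction are deterministic for a fixed seed", {
  fx <- fix_dataset()
  tr <- dataset_subset(fx$dataset, fix_split()$train_ids)
  trn <- build_classifier_training(tr, 1L)
  m1 <- train_substrate_classifier(trn$X[1:60, ], droplevels(trn$y[1:60]),
                                   n_trees = 50L, seed = 77L)
  m2 <- train_substrate_classifier(trn$X[1:60, ], droplevels(trn$y[1:60]),
                                   n_trees = 50L, seed = 77L)
  probe <- fx$dataset$features[101:120, ]
  expect_identical(predict_substrate(m1, probe), predict_substrate(m2, probe))
  expect_error(train_substrate_classifier(trn$X[1:5, ],
                                          factor(rep("tryptophan", 5)),
                                          n_trees = 10L, seed = 1L),
               "single class")
})

test_that("balanced sampling keeps minority-class recall near the majority's", {
  # 90:10 two-class problem; without balancing the minority class is
  # drowned out at the vote
  set.seed(83)
  n_major <- 180L; n_minor <- 20L
  mk <- function(n, mu) matrix(rnorm(n * 10, mu), n)
  X <- rbind(mk(n_major, 0), mk(n_minor, 2))
  y <- factor(rep(c("maj", "min"), c(n_major, n_minor)))
  test_X <- rbind(mk(60, 0), mk(60, 2))
  test_y <- rep(c("maj", "min"), each = 60)
  recalls <- function(balance) {
    m <- train_substrate_classifier(X, y, n_trees = 300L, seed = 7L,
                                    balance = balance)
    pred <- predict_substrate(m, test_X)
    c(maj = mean(pred$label[test_y == "maj"] == "maj"),
      min = mean(pred$label[test_y == "min"] == "min"))
  }
  rec_w <- recalls("weights")
  expect_gte(rec_w["min"], rec_w["maj"] - 0.1)
  rec_b <- recalls("bootstrap")
  expect_gte(rec_b["min"], rec_b["maj"] - 0.1)
})

test_that("interaction pairs are built 1:1 with the undersampled negatives", {
  set.seed(91)
  lib <- fix_library()
  ids <- sprintf("p%02d", 1:10)
  ds <- specificity_dataset(ids,
                            as.list(sample(rownames(lib$fp_matrix), 10,
                                           replace = TRUE)),
                            features = matrix(rnorm(10 * 8), 10))
  pr <- build_interaction_pairs(ds, lib, seed = 19L)
  expect_equal(nrow(pr$X), 20L)                      # 10 positives + 10 negatives
  expect_equal(as.vector(table(pr$y)), c(10L, 10L))
  expect_equal(ncol(pr$X), 8L + 1024L)
  # a promiscuous domain contributes one positive row per major substrate
  ds2 <- specificity_dataset(c(ids, "p11"),
                             c(ds$substrates, list(c("tryptophan", "serine"))),
                             features = rbind(ds$features, rnorm(8)))
  pr2 <- build_interaction_pairs(ds2, lib, seed = 19L)
  expect_equal(sum(pr2$pairs$domain_id == "p11" &
                     pr2$pairs$label == "interaction"), 2L)
  # fixed seed reproduces the exact negative sample
  pr3 <- build_interaction_pairs(ds, lib, seed = 19L)
  expect_identical(pr$pairs, pr3$pairs)
  # per-domain scope balances within each domain
  pr4 <- build_interaction_pairs(ds, lib, seed = 19L, scope = "per_domain")
  per <- table(pr4$pairs$domain_id, pr4$pairs$label)
  expect_true(all(per[, "interaction"] == per[, "no_interaction"]))
})

test_that("interaction model ranks the true substrate first on held-out domains", {
  fx <- fix_dataset()
  te <- dataset_subset(fx$dataset, fix_split()$test_ids)
  model <- fix_interaction()
  rks <- predict_interactions_batch(model, te$features, fix_library())
  truth <- stats::setNames(te$substrates, te$domain_id)
  expect_length(rks, length(te$domain_id))
  expect_gte(topk_accuracy(rks, truth, 1), 0.8)
  r1 <- rks[[1]]
  expect_equal(nrow(r1), 4L)                          # one entry per query
  expect_true(all(diff(r1$probability) <= 0))         # sorted
  expect_true(all(r1$probability >= 0 & r1$probability <= 1))
  expect_true(attr(r1, "advisory_cutoff") >= 0 && attr(r1, "advisory_cutoff") <= 1)
})

test_that("novel substrates are first-class queries with fingerprint invariance", {
  fx <- fix_dataset()
  te <- dataset_subset(fx$dataset, fix_split()$test_ids)
  model <- fix_interaction()
  feats <- te$features[1, ]
  # tryptophan respelled + a substrate absent from training + a broken one
  queries <- data.frame(
    name = c("trp_respelled", "histidine", "broken"),
    smiles = c("N[C@@H](Cc1c[nH]c2ccccc12)C(=O)O",
               "N[C@@H](Cc1cnc[nH]1)C(=O)O",
               "xx(("))
  rk <- predict_interactions(model, feats, queries)
  expect_setequal(rk$substrate, c("trp_respelled", "histidine"))
  expect_named(attr(rk, "errors"), "broken")
  rk_lib <- predict_interactions(model, feats, fix_library())
  expect_equal(rk$probability[rk$substrate == "trp_respelled"],
               rk_lib$probability[rk_lib$substrate == "tryptophan"])
})

test_that("model bundles round-trip through disk and reject corruption", {
  model <- fix_classifier()
  fx <- fix_dataset()
  probe <- fx$dataset$features[1:20, ]
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  loaded <- load_model(path)
  expect_identical(predict_substrate(loaded, probe),
                   predict_substrate(model, probe))
  expect_equal(loaded$seed, model$seed)
  expect_equal(loaded$inclusion_cutoff, model$inclusion_cutoff)
  writeBin(readBin(path, "raw", 50L), trunc_path <- tempfile())
  expect_error(load_model(trunc_path), "corrupt")
  # schema refusal: wrong feature width
  expect_error(predict_substrate(loaded, matrix(0, 1, 12)), "schema")
})

test_that("kingdom-scoped and full models coexist from one dataset", {
  fx <- fix_dataset()
  bact <- dataset_kingdom(fx$dataset, "Bacteria")
  expect_lt(length(bact$domain_id), length(fx$dataset$domain_id))
  trn <- build_classifier_training(bact, 1L)
  m <- train_substrate_classifier(trn$X, trn$y, n_trees = 50L, seed = 3L)
  expect_s3_class(m, "substrate_classifier")
  expect_setequal(unique(bact$taxonomy$kingdom), "Bacteria")
})
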