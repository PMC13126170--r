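pure_family_dataset <- function() {
  # 4 substrates x 4 substrate-pure families of 4 domains: an exact 3:1
  # family-atomic split exists (3 families train, 1 test per substrate)
  ids <- sprintf("d%03d", 1:64)
  subs <- rep(c("tryptophan", "serine", "valine", "alanine"), each = 16)
  fam <- sprintf("%s_f%d", substr(subs, 1, 3), rep(rep(1:4, each = 4), 4))
  tax <- data.frame(kingdom = "Bacteria", phylum = "p", class = "c",
                    order = "o", family = fam)
  specificity_dataset(ids, as.list(subs), taxonomy = tax)
}

test_that("taxonomy split is family-atomic and reaches exact 3:1 when possible", {
  ds <- pure_family_dataset()
  plan <- taxonomy_split(ds, seed = 2)
  expect_equal(plan$ratios$train / plan$ratios$test, rep(3, 4))
  fam <- ds$taxonomy$family
  fam_train <- unique(fam[match(plan$train_ids, ds$domain_id)])
  fam_test <- unique(fam[match(plan$test_ids, ds$domain_id)])
  expect_length(intersect(fam_train, fam_test), 0L)
  expect_setequal(c(plan$train_ids, plan$test_ids), ds$domain_id)
})

test_that("family atomicity and substrate coverage hold over random fixtures", {
  for (s in c(101, 202, 303)) {
    set.seed(s)
    n <- 80L
    subs <- sample(c("tryptophan", "serine", "valine"), n, replace = TRUE)
    tax <- data.frame(kingdom = "Bacteria", phylum = "p", class = "c",
                      order = "o",
                      family = sample(sprintf("fam%d", 1:10), n, replace = TRUE))
    ds <- specificity_dataset(sprintf("r%d_%03d", s, 1:n), as.list(subs),
                              taxonomy = tax)
    plan <- taxonomy_split(ds, seed = s)
    fam <- ds$taxonomy$family
    expect_length(intersect(unique(fam[match(plan$train_ids, ds$domain_id)]),
                            unique(fam[match(plan$test_ids, ds$domain_id)])),
                  0L)
    for (sub in unique(subs)) {
      ids_sub <- ds$domain_id[subs == sub]
      expect_gt(length(intersect(ids_sub, plan$train_ids)), 0L)
      expect_gt(length(intersect(ids_sub, plan$test_ids)), 0L)
    }
  }
})

test_that("a substrate confined to one family relaxes coverage with a warning", {
  ids <- sprintf("w%02d", 1:20)
  subs <- c(rep("tryptophan", 16), rep("serine", 4))
  fam <- c(sprintf("fam%d", rep(1:4, each = 4)), rep("fam_only", 4))
  tax <- data.frame(kingdom = "B", phylum = "p", class = "c", order = "o",
                    family = fam)
  ds <- specificity_dataset(ids, as.list(subs), taxonomy = tax)
  expect_warning(plan <- taxonomy_split(ds, seed = 1), "relaxed")
  ser_sides <- c(length(intersect(ids[17:20], plan$train_ids)) > 0,
                 length(intersect(ids[17:20], plan$test_ids)) > 0)
  expect_equal(sum(ser_sides), 1L)         # one side only
})

test_that("single-label substrate split hits per-class test counts to +-1", {
  set.seed(71)
  n_per <- 100L
  classes <- c("tryptophan", "serine", "valine", "alanine")
  ids <- sprintf("s%03d", seq_len(4L * n_per))
  subs <- rep(classes, each = n_per)
  ds <- specificity_dataset(ids, as.list(subs))
  plan <- substrate_split(ds, 0.25, multilabel = FALSE, seed = 13)
  test_subs <- subs[match(plan$test_ids, ids)]
  for (cls in classes)
    expect_lte(abs(sum(test_subs == cls) - 25L), 1L)
  # determinism
  plan2 <- substrate_split(ds, 0.25, multilabel = FALSE, seed = 13)
  expect_identical(plan$test_ids, plan2$test_ids)
})

test_that("iterative multilabel stratification keeps rare labels proportional", {
  set.seed(72)
  n <- 40L
  ids <- sprintf("m%02d", 1:n)
  labels <- lapply(sample(c("tryptophan", "serine"), n, replace = TRUE), identity)
  rare_holders <- sample(n, 4L)
  for (i in rare_holders) labels[[i]] <- c(labels[[i]], "ornithine")
  ds <- specificity_dataset(ids, labels)
  plan <- substrate_split(ds, 0.25, multilabel = TRUE, seed = 14)
  rare_test <- sum(vapply(labels[match(plan$test_ids, ids)],
                          function(x) "ornithine" %in% x, TRUE))
  expect_equal(rare_test, 1L)                         # 4 * 0.25
  single <- ds
  single$substrates[[1]] <- c(single$substrates[[1]], "lonely")
  expect_warning(substrate_split(single, 0.25, multilabel = TRUE, seed = 14),
                 "single example")
})

test_that("prediction scoring implements any-match and top1 policies", {
  truth <- list(a = c("tryptophan", "phenylalanine"), b = "serine",
                c = "valine")
  pred <- c(a = "phenylalanine", b = "serine", c = "serine")
  sc <- score_predictions(pred, truth, policy = "any_match")
  expect_equal(sc$accuracy, 2 / 3)
  expect_true(sc$correct[["a"]])                      # any listed substrate
  sc1 <- score_predictions(pred, truth, policy = "top1")
  expect_false(sc1$correct[["a"]])                    # first-listed only
  perfect <- c(a = "tryptophan", b = "serine", c = "valine")
  scp <- score_predictions(perfect, truth, policy = "top1")
  expect_equal(scp$accuracy, 1)
  expect_true(all(scp$per_substrate$f1[scp$per_substrate$support > 0] == 1))
  wrong <- c(a = "serine", b = "valine", c = "tryptophan")
  scw <- score_predictions(wrong, truth, policy = "top1")
  expect_equal(scw$accuracy, 0)
  expect_true(all(scw$per_substrate$recall[scw$per_substrate$support > 0] == 0))
  expect_error(score_predictions(c(x = "serine"), truth), "do not match")
})

test_that("top-k accuracy is consistent, exhaustive at full depth, monotone", {
  mk_rank <- function(order) {
    structure(data.frame(substrate = order,
                         probability = seq(1, 0.1, length.out = length(order))),
              class = c("interaction_ranking", "data.frame"))
  }
  rks <- list(a = mk_rank(c("serine", "tryptophan", "valine")),
              b = mk_rank(c("valine", "serine", "tryptophan")),
              c = mk_rank(c("tryptophan", "valine", "serine")))
  truth <- list(a = "tryptophan", b = "valine", c = "serine")
  expect_equal(topk_accuracy(rks, truth, 1), 1 / 3)
  expect_equal(topk_accuracy(rks, truth, 2), 2 / 3)
  expect_equal(topk_accuracy(rks, truth, 3), 1)       # truth within library
  ks <- vapply(1:3, topk_accuracy, 0, rankings = rks, truth = truth)
  expect_true(all(diff(ks) >= 0))
  # k = 1 agrees with top1 scoring of the rank-1 substrate
  top1 <- vapply(rks, function(r) r$substrate[1], "")
  sc <- score_predictions(top1, truth, policy = "top1")
  expect_equal(topk_accuracy(rks, truth, 1), sc$accuracy)
})

test_that("promiscuity categories use exact top-x set matching and partition", {
  mk_rank <- function(order) {
    structure(data.frame(substrate = order,
                         probability = seq(1, 0.1, length.out = length(order))),
              class = c("interaction_ranking", "data.frame"))
  }
  rks <- list(a = mk_rank(c("B", "A", "C")),          # truth {A,B}: exact
              b = mk_rank(c("A", "C", "B")),          # truth {A,B}: partial
              c = mk_rank(c("C", "A", "B")))          # truth {A}: miss
  truth <- list(a = c("A", "B"), b = c("A", "B"), c = "A")
  counts <- promiscuity_eval(rks, truth)
  expect_equal(unname(counts), c(1L, 1L, 1L))
  expect_equal(sum(counts), length(truth))
  expect_error(promiscuity_eval(rks, list(a = "A", b = "B", c = character())),
               "non-empty")
})

test_that("benchmark call labels and folded accuracy follow the verdict rules", {
  classes <- c("tryptophan", "serine", "valine")
  expect_equal(benchmark_label("tryptophan", c("tryptophan", "serine"), classes),
               "correct")
  expect_equal(benchmark_label("valine", "serine", classes), "incorrect")
  expect_equal(benchmark_label(NA, "serine", classes), "no_call")
  expect_equal(benchmark_label(NULL, "serine", classes), "no_call")
  expect_equal(benchmark_label("serine", "ornithine", classes), "not_in_model")
  expect_equal(benchmark_accuracy(c("correct", "correct", "incorrect",
                                    "no_call")), 0.5)
  expect_error(benchmark_accuracy("maybe"), "unknown verdict")
})

test_that("bootstrap comparison separates degenerate tools and not identical ones", {
  calls_a <- rep("correct", 100)
  calls_b <- rep("incorrect", 100)
  res <- bootstrap_compare(list(A = calls_a, B = calls_b), n_boot = 300,
                           seed = 9)
  expect_equal(unname(res$accuracy), c(1, 0))
  expect_true(res$pairwise$significant)
  expect_equal(res$n_comparisons, 1L)
  same <- bootstrap_compare(list(A = calls_a, B = calls_a), n_boot = 300,
                            seed = 9)
  expect_equal(nrow(same$pairwise), 0L)
  # resampling consistency: bootstrap mean tracks the point accuracy
  set.seed(10)
  mixed <- sample(c("correct", "incorrect"), 150, replace = TRUE,
                  prob = c(0.7, 0.3))
  res2 <- bootstrap_compare(list(A = mixed, B = rep("incorrect", 150)),
                            n_boot = 1000, seed = 11)
  expect_lt(abs(mean(res2$distributions[, "A"]) - mean(mixed == "correct")),
            0.02)
})
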