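# Train/test stratification. Two strategies: taxonomy-atomic splitting
# (whole taxonomic families on one side, per-substrate ratios pushed toward
# 3:1) and substrate stratification (single-label proportional, or
# iterative multilabel stratification).

new_split_plan <- function(train_ids, test_ids, strategy, seed, ratios) {
  stopifnot(!anyDuplicated(c(train_ids, test_ids)))
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 strategy = strategy, seed = seed, ratios = ratios),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan (%s): %d train / %d test, seed %d>\n",
              x$strategy, length(x$train_ids), length(x$test_ids), x$seed))
  invisible(x)
}

split_substrate_labels <- function(dataset, scope) {
  if (scope == "first") lapply(dataset$substrates, `[`, 1L) else dataset$substrates
}

#' Taxonomy-stratified train/test split
#'
#' Assigns whole taxonomic families to either the train or the test side,
#' so no family straddles the split; this probes generalisation to
#' phylogenetically distant sequences. The assignment is greedy: first
#' every in-scope substrate is guaranteed at least one example on each
#' side, then the remaining families are placed one at a time (largest
#' first), each on the side that minimises the summed absolute deviation
#' of the per-substrate train fraction from the target (3:1, i.e. 0.75).
#' Ties go to train. Domains of unknown origin form their own
#' pseudo-family (`"None"`).
#'
#' @param dataset A [specificity_dataset()] with taxonomy.
#' @param seed Integer seed (controls the order among equal-sized
#'   families).
#' @param train_ratio Target train:test ratio (default 3).
#' @param substrate_scope `"first"` (predominant label only, default) or
#'   `"all"` (all listed substrates).
#' @param inclusion_cutoff Substrates with fewer total examples than this
#'   are out of scope for the coverage/ratio objective (default 1: all in
#'   scope).
#' @return A `split_plan` with per-substrate train:test ratios attached.
#' @export
taxonomy_split <- function(dataset, seed, train_ratio = 3,
                           substrate_scope = c("first", "all"),
                           inclusion_cutoff = 1L) {
  substrate_scope <- match.arg(substrate_scope)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  target <- train_ratio / (train_ratio + 1)
  labels <- split_substrate_labels(dataset, substrate_scope)
  fam <- dataset$taxonomy$family
  fam[is.na(fam) | fam == ""] <- "None"
  counts <- table(unlist(labels))
  scoped <- names(counts)[counts >= inclusion_cutoff]
  # family x substrate count matrix over in-scope substrates
  fams <- unique(fam)
  fm <- matrix(0L, length(fams), length(scoped),
               dimnames = list(fams, scoped))
  for (i in seq_along(labels)) {
    s <- intersect(labels[[i]], scoped)
    fm[fam[i], s] <- fm[fam[i], s] + 1L
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  # deterministic-for-seed processing order: descending size, random within ties
  fam_size <- rowSums(fm)
  ord <- order(-fam_size, sample.int(length(fams)))
  fams <- fams[ord]; fm <- fm[ord, , drop = FALSE]

  side <- stats::setNames(rep(NA_character_, length(fams)), fams)
  train_cnt <- test_cnt <- stats::setNames(numeric(length(scoped)), scoped)
  assign_family <- function(f, s) {
    side[f] <<- s
    if (s == "train") train_cnt <<- train_cnt + fm[f, ]
    else test_cnt <<- test_cnt + fm[f, ]
  }
  # coverage pass: at least one example of each substrate on both sides,
  # built up from the rarest substrate
  for (s in scoped[order(counts[scoped])]) {
    holders <- fams[fm[, s] > 0 & is.na(side[fams])]
    covered_train <- train_cnt[s] > 0
    covered_test <- test_cnt[s] > 0
    if (!covered_train && !covered_test && length(holders) < 2L) {
      warning("substrate '", s, "' cannot be represented on both sides ",
              "(all examples in one family); coverage relaxed")
    }
    for (want in c("test", "train")) {
      have <- if (want == "train") train_cnt[s] > 0 else test_cnt[s] > 0
      holders <- fams[fm[, s] > 0 & is.na(side[fams])]
      if (!have && length(holders)) {
        # smallest holder, so large families stay free for ratio balancing
        f <- holders[which.min(rowSums(fm)[holders])]
        assign_family(f, want)
      }
    }
  }
  objective <- function(tr, te) {
    tot <- tr + te
    use <- tot > 0
    sum(abs(tr[use] / tot[use] - target))
  }
  for (f in fams[is.na(side[fams])]) {
    o_train <- objective(train_cnt + fm[f, ], test_cnt)
    o_test <- objective(train_cnt, test_cnt + fm[f, ])
    assign_family(f, if (o_train <= o_test) "train" else "test")
  }
  train <- dataset$domain_id[side[fam] == "train"]
  test <- dataset$domain_id[side[fam] == "test"]
  ratios <- data.frame(substrate = scoped, train = as.numeric(train_cnt),
                       test = as.numeric(test_cnt))
  new_split_plan(train, test, "taxonomy", seed, ratios)
}

#' Substrate-stratified train/test split
#'
#' Single-label mode stratifies on the predominant (first-listed)
#' substrate: each class contributes `round(n_class * test_fraction)`
#' examples to the test side. Multilabel mode runs iterative
#' stratification: examples of the currently rarest remaining label are
#' placed one by one on the side whose desired count for that label is
#' furthest from satisfied, which keeps every label proportionally
#' represented. Labels with a single example go to train with a warning.
#'
#' @param dataset A [specificity_dataset()].
#' @param test_fraction Fraction of examples for the test side (default
#'   0.25).
#' @param multilabel Use all listed substrates (`TRUE`) or the first only
#'   (`FALSE`, default).
#' @param seed Integer seed (mandatory).
#' @return A `split_plan`.
#' @export
substrate_split <- function(dataset, test_fraction = 0.25, multilabel = FALSE,
                            seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  ids <- dataset$domain_id
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (!multilabel) {
    first <- vapply(dataset$substrates, `[`, "", 1L)
    test_idx <- integer()
    for (cls in unique(first)) {
      members <- which(first == cls)
      if (length(members) == 1L) {
        warning("substrate '", cls, "' has a single example; placed in train")
        next
      }
      n_test <- round(length(members) * test_fraction)
      if (n_test > 0L)
        test_idx <- c(test_idx, sample(members, n_test))
    }
    return(new_split_plan(ids[-sort(test_idx)], ids[sort(test_idx)],
                          "substrate", seed, NULL))
  }
  labels <- dataset$substrates
  n <- length(ids)
  label_names <- unique(unlist(labels))
  singletons <- label_names[vapply(label_names, function(l)
    sum(vapply(labels, function(x) l %in% x, TRUE)), 1L) == 1L]
  if (length(singletons))
    warning("label(s) with a single example placed in train: ",
            paste(singletons, collapse = ", "))
  # desired per-side example counts, overall and per label
  desire <- c(train = n * (1 - test_fraction), test = n * test_fraction)
  lab_count <- vapply(label_names, function(l)
    sum(vapply(labels, function(x) l %in% x, TRUE)), 1L)
  lab_desire <- rbind(train = lab_count * (1 - test_fraction),
                      test = lab_count * test_fraction)
  side <- rep(NA_character_, n)
  remaining <- function() which(is.na(side))
  repeat {
    rem <- remaining()
    if (!length(rem)) break
    rem_count <- vapply(label_names, function(l)
      sum(vapply(labels[rem], function(x) l %in% x, TRUE)), 1L)
    active <- label_names[rem_count > 0]
    if (!length(active)) {            # label-free leftovers: fill by desire
      for (i in rem) {
        s <- if (desire["train"] >= desire["test"]) "train" else "test"
        side[i] <- s; desire[s] <- desire[s] - 1
      }
      break
    }
    l <- active[which.min(rem_count[active])]      # rarest remaining label
    if (l %in% singletons) {
      i <- rem[vapply(labels[rem], function(x) l %in% x, TRUE)][1]
      side[i] <- "train"
      desire["train"] <- desire["train"] - 1
      for (ll in labels[[i]]) lab_desire["train", ll] <- lab_desire["train", ll] - 1
      next
    }
    holders <- rem[vapply(labels[rem], function(x) l %in% x, TRUE)]
    for (i in sample(holders)) {
      d <- lab_desire[, l]
      s <- if (d["train"] > d["test"]) "train"
      else if (d["test"] > d["train"]) "test"
      else if (desire["train"] != desire["test"])    # tie: larger capacity
        names(which.max(desire))
      else sample(c("train", "test"), 1L)
      side[i] <- s
      desire[s] <- desire[s] - 1
      for (ll in labels[[i]]) lab_desire[s, ll] <- lab_desire[s, ll] - 1
    }
  }
  new_split_plan(ids[side == "train"], ids[side == "test"],
                 "substrate", seed, NULL)
}
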