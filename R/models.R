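# The two random-forest predictors. Both are 1000-tree forests (ranger,
# seeded, single-threaded for reproducibility); class balance is handled at
# the bootstrap level, and all confidences/probabilities are tree-vote
# fractions.

balance_weights <- function(y) {
  tab <- table(y)
  as.numeric(1 / tab[y]) * length(y) / length(tab)
}

fit_forest <- function(X, y, n_trees, seed, balance) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (nlevels(droplevels(y)) < 2L)
    stop("training data contains a single class", call. = FALSE)
  if (nrow(X) != length(y)) stop("rows and labels differ in length", call. = FALSE)
  dat <- as.data.frame(X)
  feature_names <- colnames(dat)
  dat$.label <- y
  args <- list(dependent.variable.name = ".label", data = dat,
               num.trees = n_trees, seed = seed, num.threads = 1L,
               keep.inbag = TRUE, importance = "impurity")
  if (balance == "weights") {
    args$case.weights <- balance_weights(y)
  } else {                               # balanced bootstrap
    tab <- table(y)
    args$sample.fraction <- rep(min(tab) / length(y), nlevels(y))
    args$replace <- TRUE
  }
  forest <- do.call(ranger::ranger, args)
  list(forest = forest, feature_names = feature_names)
}

vote_fractions <- function(forest, X) {
  dat <- as.data.frame(X)
  pred <- stats::predict(forest, dat, predict.all = TRUE, num.threads = 1L)
  lev <- forest$forest$levels
  t(apply(pred$predictions, 1L, function(v)
    tabulate(v, nbins = length(lev)) / length(v))) |>
    `colnames<-`(lev)
}

#' Train the single-label substrate classifier
#'
#' A 1000-tree random forest mapping a domain feature vector to one
#' substrate, with balanced sampling so rare substrate classes are not
#' drowned out by common ones. Training rows are kept in the model so that
#' information-gain feature inference can replay the forest.
#'
#' @param X Feature matrix (rows = domains), e.g. from
#'   [build_classifier_training()].
#' @param y Factor of substrate labels.
#' @param n_trees Number of trees (default 1000).
#' @param seed Integer seed (mandatory; recorded in the model).
#' @param balance `"weights"` (inverse-frequency bootstrap weights,
#'   default) or `"bootstrap"` (balanced per-class bootstrap).
#' @param inclusion_cutoff Metadata: the substrate inclusion cutoff used to
#'   build the training set.
#' @return Object of class `substrate_classifier`.
#' @export
train_substrate_classifier <- function(X, y, n_trees = 1000L, seed,
                                       balance = c("weights", "bootstrap"),
                                       inclusion_cutoff = NA_integer_) {
  balance <- match.arg(balance)
  y <- droplevels(factor(y))
  fit <- fit_forest(X, y, n_trees, seed, balance)
  structure(list(forest = fit$forest, classes = levels(y),
                 feature_names = fit$feature_names,
                 schema = list(kind = "substrate_classifier",
                               width = ncol(X), features = fit$feature_names),
                 X = as.matrix(X), y = y,
                 n_trees = n_trees, seed = seed, balance = balance,
                 inclusion_cutoff = inclusion_cutoff),
            class = "substrate_classifier")
}

#' @export
print.substrate_classifier <- function(x, ...) {
  cat(sprintf("<substrate_classifier: %d trees, %d classes, %d features, seed %d>\n",
              x$n_trees, length(x$classes), x$schema$width, x$seed))
  invisible(x)
}

check_schema <- function(model, X) {
  if (ncol(X) != model$schema$width)
    stop("feature width ", ncol(X), " does not match the model schema (",
         model$schema$width, ")", call. = FALSE)
}

#' Predict substrates with vote confidences
#'
#' Every query receives a label (the model never abstains): the plurality
#' vote over trees, with confidence equal to the fraction of trees voting
#' for it. Vote ties are broken alphabetically by substrate name and
#' flagged in the output. No confidence cutoff is applied.
#'
#' @param model A [train_substrate_classifier()] model.
#' @param features Feature vector or matrix (rows = queries).
#' @return Data.frame with columns `domain_id`, `label`, `confidence`,
#'   `tie`.
#' @export
predict_substrate <- function(model, features) {
  if (!is.matrix(features)) features <- matrix(features, nrow = 1L)
  check_schema(model, features)
  colnames(features) <- model$feature_names
  vf <- vote_fractions(model$forest, features)
  lab <- apply(vf, 1L, function(p) colnames(vf)[which.max(p)])  # ties: first name
  conf <- apply(vf, 1L, max)
  tie <- apply(vf, 1L, function(p) sum(p == max(p)) > 1L)
  ids <- rownames(features)
  data.frame(domain_id = if (is.null(ids)) sprintf("query%d", seq_len(nrow(vf))) else ids,
             label = unname(lab), confidence = unname(conf), tie = unname(tie))
}

#' Train the domain-substrate interaction model
#'
#' A binary 1000-tree random forest over concatenated domain features and
#' substrate fingerprints (default width 510 + 1024 = 1534), trained on
#' 1:1 under-sampled pairs from [build_interaction_pairs()]. An advisory
#' interaction-probability cutoff is estimated from the in-sample
#' interaction-probability distributions of true positives and false
#' positives (midpoint of their medians); it is reported alongside
#' predictions but never enforced.
#'
#' @param pairs Pair feature matrix.
#' @param labels Binary factor (`interaction` / `no_interaction`).
#' @param library The [substrate_library()] used to build the pairs
#'   (stored for querying).
#' @inheritParams train_substrate_classifier
#' @return Object of class `interaction_model`.
#' @export
train_interaction_model <- function(pairs, labels, library = NULL,
                                    n_trees = 1000L, seed,
                                    balance = c("weights", "bootstrap")) {
  balance <- match.arg(balance)
  labels <- droplevels(factor(labels))
  fit <- fit_forest(pairs, labels, n_trees, seed, balance)
  vf <- vote_fractions(fit$forest, pairs)
  prob <- vf[, "interaction"]
  tp <- prob[labels == "interaction"]
  fp <- prob[labels == "no_interaction" & prob > 0.5]
  cutoff <- if (length(fp)) (stats::median(tp) + stats::median(fp)) / 2 else
    stats::median(tp) / 2
  structure(list(forest = fit$forest,
                 feature_names = fit$feature_names,
                 schema = list(kind = "interaction_model",
                               width = ncol(pairs), features = fit$feature_names),
                 library = library,
                 X = as.matrix(pairs), y = labels,
                 n_trees = n_trees, seed = seed, balance = balance,
                 advisory_cutoff = unname(cutoff)),
            class = "interaction_model")
}

#' @export
print.interaction_model <- function(x, ...) {
  cat(sprintf(
    "<interaction_model: %d trees, %d pair features, seed %d, advisory cutoff %.2f>\n",
    x$n_trees, x$schema$width, x$seed, x$advisory_cutoff))
  invisible(x)
}

#' Rank substrates by interaction probability
#'
#' Queries the interaction model with one domain against a list of
#' substrates, returning one probability (tree-vote fraction) per
#' substrate, sorted descending. Substrates absent from training are
#' first-class queries: their fingerprints are computed on the fly from
#' SMILES. Substrates whose SMILES cannot be parsed are reported with an
#' error flag and the rest are still ranked.
#'
#' @param model A [train_interaction_model()] model.
#' @param domain_features Domain feature vector (width =
#'   `model$schema$width - n_bits`).
#' @param substrates A [substrate_library()], a list of
#'   [substrate_record()]s, or a data.frame with `name` and `smiles`.
#' @return Object of class `interaction_ranking`: data.frame `substrate`,
#'   `probability` (sorted non-increasing), attributes `errors` (named
#'   character) and `advisory_cutoff`.
#' @export
predict_interactions <- function(model, domain_features, substrates) {
  if (inherits(substrates, "substrate_library")) {
    fps <- lapply(seq_len(nrow(substrates$fp_matrix)), function(i)
      substrates$fp_matrix[i, ])
    nm <- rownames(substrates$fp_matrix)
  } else if (is.data.frame(substrates)) {
    fps <- ecfp_batch(substrates$smiles)
    nm <- substrates$name
  } else {                                   # list of substrate_record
    fps <- lapply(substrates, `[[`, "fingerprint")
    nm <- vapply(substrates, `[[`, "", "name")
  }
  bad <- vapply(fps, is.character, TRUE)
  errors <- if (any(bad)) stats::setNames(unlist(fps[bad]), nm[bad]) else
    stats::setNames(character(), character())
  fps <- fps[!bad]; nm <- nm[!bad]
  if (!length(fps))
    stop("no queryable substrate (all SMILES failed to parse)", call. = FALSE)
  fpm <- do.call(rbind, fps)
  X <- cbind(matrix(rep(as.numeric(domain_features), each = nrow(fpm)),
                    nrow = nrow(fpm)), fpm)
  check_schema(model, X)
  colnames(X) <- model$feature_names
  vf <- vote_fractions(model$forest, X)
  df <- data.frame(substrate = nm, probability = unname(vf[, "interaction"]))
  df <- df[order(-df$probability, df$substrate), ]
  rownames(df) <- NULL
  structure(df, class = c("interaction_ranking", "data.frame"),
            errors = errors, advisory_cutoff = model$advisory_cutoff)
}

#' Rank substrates for many domains at once
#'
#' @param model A [train_interaction_model()] model.
#' @param features Matrix of domain feature vectors (rows = domains,
#'   rownames = domain ids).
#' @param substrates As in [predict_interactions()].
#' @return Named list of `interaction_ranking` objects.
#' @export
predict_interactions_batch <- function(model, features, substrates) {
  if (inherits(substrates, "substrate_library")) {
    fpm <- substrates$fp_matrix
  } else if (is.data.frame(substrates)) {
    fps <- ecfp_batch(substrates$smiles)
    bad <- vapply(fps, is.character, TRUE)
    fpm <- do.call(rbind, fps[!bad])
    rownames(fpm) <- substrates$name[!bad]
  } else stop("substrates must be a substrate_library or data.frame", call. = FALSE)
  nd <- nrow(features); ns <- nrow(fpm)
  X <- cbind(features[rep(seq_len(nd), each = ns), , drop = FALSE],
             fpm[rep(seq_len(ns), nd), , drop = FALSE])
  check_schema(model, X)
  colnames(X) <- model$feature_names
  rownames(X) <- NULL
  vf <- vote_fractions(model$forest, X)
  ids <- rownames(features)
  if (is.null(ids)) ids <- sprintf("query%d", seq_len(nd))
  out <- lapply(seq_len(nd), function(i) {
    p <- vf[(i - 1L) * ns + seq_len(ns), "interaction"]
    df <- data.frame(substrate = rownames(fpm), probability = unname(p))
    df <- df[order(-df$probability, df$substrate), ]
    rownames(df) <- NULL
    structure(df, class = c("interaction_ranking", "data.frame"),
              errors = character(), advisory_cutoff = model$advisory_cutoff)
  })
  stats::setNames(out, ids)
}

#' @export
print.interaction_ranking <- function(x, ...) {
  cat(sprintf("<interaction_ranking: %d substrates, advisory cutoff %.2f>\n",
              nrow(x), attr(x, "advisory_cutoff")))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (length(attr(x, "errors")))
    cat("failed substrates:", paste(names(attr(x, "errors")), collapse = ", "), "\n")
  invisible(x)
}
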