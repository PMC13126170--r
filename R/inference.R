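# Feature inference on trained forests. Overall importance reuses the
# forest's impurity-based importances; substrate-specific importance
# replays the training data through every tree and evaluates the per-node
# binary (substrate vs rest) information gain.

#' Binary node entropy
#'
#' Shannon entropy (base 2) of a node with `n` domains of which `n_S`
#' carry substrate S: `H = -[p log2 p + (1-p) log2 (1-p)]` with
#' `0 * log2(0) = 0`, so pure nodes have entropy 0 and a balanced node
#' entropy 1.
#'
#' @param n_S Domains at the node recognizing the substrate.
#' @param n Total domains at the node (>= 1).
#' @return Entropy in `[0, 1]`.
#' @export
node_entropy <- function(n_S, n) {
  if (any(n < 1L)) stop("n must be >= 1", call. = FALSE)
  if (any(n_S < 0L) || any(n_S > n)) stop("need 0 <= n_S <= n", call. = FALSE)
  p <- n_S / n
  q <- 1 - p
  term <- function(x) ifelse(x == 0, 0, x * log2(x))
  -(term(p) + term(q))
}

#' Information gain of one tree node for one substrate
#'
#' `gain = H(t) - [ (n_L/n_t) H(t_L) + (n_R/n_t) H(t_R) ]`: the entropy of
#' the parent minus the child-count-weighted mean entropy of its two
#' children, all computed for the binary substrate-vs-rest labelling.
#'
#' @param stats List (or one-row data.frame) with fields `n_t`, `n_t_S`,
#'   `n_L`, `n_R`, `n_L_S`, `n_R_S`. Counts must satisfy
#'   `n_t == n_L + n_R` and `n_t_S == n_L_S + n_R_S`.
#' @return Non-negative gain (up to floating-point rounding).
#' @export
node_information_gain <- function(stats) {
  s <- as.list(stats)
  need <- c("n_t", "n_t_S", "n_L", "n_R", "n_L_S", "n_R_S")
  if (!all(need %in% names(s)))
    stop("stats needs fields ", paste(need, collapse = ", "), call. = FALSE)
  if (s$n_t != s$n_L + s$n_R || s$n_t_S != s$n_L_S + s$n_R_S)
    stop("inconsistent node counts (children must sum to the parent)",
         call. = FALSE)
  h_parent <- node_entropy(s$n_t_S, s$n_t)
  h_children <- 0
  if (s$n_L > 0) h_children <- h_children + s$n_L / s$n_t * node_entropy(s$n_L_S, s$n_L)
  if (s$n_R > 0) h_children <- h_children + s$n_R / s$n_t * node_entropy(s$n_R_S, s$n_R)
  h_parent - h_children
}

# ranger numeric splits send x <= splitval to the left child
route_tree <- function(ti, X, w) {
  n_nodes <- nrow(ti)
  idx_at <- vector("list", n_nodes)
  idx_at[[1]] <- which(w > 0)
  out <- vector("list", n_nodes)
  for (r in seq_len(n_nodes)) {
    node <- ti$nodeID[r]
    idx <- idx_at[[node + 1L]]
    if (ti$terminal[r] || is.null(idx)) next
    v <- ti$splitvarID[r] + 1L
    left <- idx[X[idx, v] <= ti$splitval[r]]
    right <- setdiff(idx, left)
    idx_at[[ti$leftChild[r] + 1L]] <- left
    idx_at[[ti$rightChild[r] + 1L]] <- right
    out[[r]] <- list(node = node, feature = v, idx = idx, left = left,
                     right = right)
  }
  out[!vapply(out, is.null, TRUE)]
}

#' Per-node class-count statistics of a trained forest
#'
#' Replays each tree's in-bag training sample (with bootstrap
#' multiplicities) through its splits and records, for every internal
#' node: the split feature, the number of domains seen by the node and by
#' each child, and the per-class domain counts. These counts house the
#' information-gain equations.
#'
#' @param model A [train_substrate_classifier()] or
#'   [train_interaction_model()] model (training rows are stored in the
#'   model).
#' @return Object of class `forest_node_stats`: data.frame `nodes` (tree,
#'   node, feature, n_t, n_L, n_R) plus class-count matrices `cls_t`,
#'   `cls_L`, `cls_R` (one column per class), and `classes`.
#' @export
forest_node_stats <- function(model) {
  forest <- model$forest
  X <- model$X
  y <- model$y
  classes <- levels(y)
  yid <- as.integer(y)
  rows <- list()
  cls_t <- cls_l <- cls_r <- list()
  for (t in seq_len(forest$num.trees)) {
    ti <- ranger::treeInfo(forest, t)
    w <- forest$inbag.counts[[t]]
    for (nd in route_tree(ti, X, w)) {
      cnt <- function(idx) {
        v <- numeric(length(classes))
        if (length(idx)) {
          tb <- tapply(w[idx], yid[idx], sum)
          v[as.integer(names(tb))] <- tb
        }
        v
      }
      ct <- cnt(nd$idx); cl <- cnt(nd$left); cr <- cnt(nd$right)
      rows[[length(rows) + 1L]] <- c(t, nd$node, nd$feature,
                                     sum(ct), sum(cl), sum(cr))
      cls_t[[length(cls_t) + 1L]] <- ct
      cls_l[[length(cls_l) + 1L]] <- cl
      cls_r[[length(cls_r) + 1L]] <- cr
    }
  }
  nodes <- as.data.frame(do.call(rbind, rows))
  names(nodes) <- c("tree", "node", "feature", "n_t", "n_L", "n_R")
  structure(list(nodes = nodes,
                 cls_t = do.call(rbind, cls_t),
                 cls_L = do.call(rbind, cls_l),
                 cls_R = do.call(rbind, cls_r),
                 classes = classes,
                 n_features = ncol(X),
                 feature_names = colnames(X)),
            class = "forest_node_stats")
}

#' Substrate-specific feature importance by information gain
#'
#' For one substrate, averages the per-node information gain (substrate vs
#' rest) over all nodes that split on a feature and saw at least one
#' domain of that substrate. Features used by fewer than `min_usage` such
#' nodes are zeroed: rarely used features that happen to resolve a leaf
#' can otherwise carry inflated gains. Usage is the number of qualifying
#' nodes splitting on the feature.
#'
#' @param model A trained model, or a precomputed [forest_node_stats()]
#'   (pass the latter when profiling several substrates).
#' @param substrate Substrate name; must be one of the forest's training
#'   classes.
#' @param min_usage Zeroing threshold on feature usage (default 0: no
#'   zeroing).
#' @return Object of class `importance_profile`: `substrate`,
#'   `per_feature_gain`, `usage_counts`, `per_residue` (for 510-wide
#'   sequence models), `min_usage`, `normalized = FALSE`.
#' @export
substrate_importance <- function(model, substrate, min_usage = 0L) {
  stats <- if (inherits(model, "forest_node_stats")) model else
    forest_node_stats(model)
  if (!substrate %in% stats$classes)
    stop("substrate '", substrate, "' is not among the forest's training classes",
         call. = FALSE)
  ci <- match(substrate, stats$classes)
  nts <- stats$cls_t[, ci]
  seen <- nts >= 1
  gains <- rep(NA_real_, nrow(stats$nodes))
  if (any(seen)) {
    nd <- stats$nodes[seen, ]
    h <- node_entropy(nts[seen], nd$n_t)
    hl <- ifelse(nd$n_L > 0, node_entropy(stats$cls_L[seen, ci], pmax(nd$n_L, 1)), 0)
    hr <- ifelse(nd$n_R > 0, node_entropy(stats$cls_R[seen, ci], pmax(nd$n_R, 1)), 0)
    gains[seen] <- h - (nd$n_L / nd$n_t) * hl - (nd$n_R / nd$n_t) * hr
  }
  p <- stats$n_features
  per_feature <- numeric(p)
  usage <- integer(p)
  f <- stats$nodes$feature
  agg <- tapply(gains[seen], f[seen], mean)
  usage_tab <- table(f[seen])
  usage[as.integer(names(usage_tab))] <- as.integer(usage_tab)
  per_feature[as.integer(names(agg))] <- as.numeric(agg)
  per_feature[usage < min_usage] <- 0
  names(per_feature) <- names(usage) <- stats$feature_names
  structure(list(substrate = substrate,
                 per_feature_gain = per_feature,
                 usage_counts = usage,
                 per_residue = if (p == 510L)
                   residue_means(per_feature) else NULL,
                 min_usage = as.integer(min_usage),
                 normalized = FALSE),
            class = "importance_profile")
}

residue_means <- function(per_feature) {
  stats::setNames(colMeans(matrix(per_feature, nrow = 15L)),
                  sprintf("res%02d", 1:34))
}

#' Per-residue importance from a feature profile
#'
#' Averages the 15 property features of each signature residue into one
#' value per residue (34 values).
#'
#' @param profile An [substrate_importance()] profile over the 510
#'   sequence features (or a bare numeric vector of length 510).
#' @return Named numeric vector of length 34.
#' @export
per_residue_importance <- function(profile) {
  v <- if (inherits(profile, "importance_profile")) profile$per_feature_gain
    else profile
  if (length(v) != 510L)
    stop("per-residue aggregation needs the 510 sequence features", call. = FALSE)
  residue_means(v)
}

#' Normalise residue importances across substrates
#'
#' Stacks per-residue profiles into a residue x substrate matrix and
#' max-normalises it so the largest cell equals 1, highlighting the
#' differential contribution of residues to specific substrates.
#'
#' @param profiles Named list of [substrate_importance()] profiles, or a
#'   34-row numeric matrix.
#' @return 34 x substrate matrix with maximum 1.
#' @export
normalize_importance <- function(profiles) {
  m <- if (is.matrix(profiles)) profiles else
    vapply(profiles, function(p) per_residue_importance(p), numeric(34L))
  mx <- max(m)
  if (mx > 0) m / mx else m
}

#' Overall residue importance of a model
#'
#' Sums the forest's impurity-based feature importances over the 15
#' features describing each signature residue.
#'
#' @param model A [train_substrate_classifier()] model over the 510
#'   sequence features.
#' @return Named non-negative vector of length 34 whose sum equals the
#'   total importance mass of the forest.
#' @export
overall_importance <- function(model) {
  imp <- model$forest$variable.importance
  if (length(imp) != 510L)
    stop("overall residue importance needs the 510 sequence features",
         call. = FALSE)
  stats::setNames(colSums(matrix(imp, nrow = 15L)), sprintf("res%02d", 1:34))
}

#' Write a per-residue attribution table
#'
#' TSV with one row per extended-signature residue: 1-based index, the
#' signature letter, the raw score and the max-normalised score. The table
#' is viewer-agnostic (e.g. for painting scores onto a structure).
#'
#' @param values Numeric vector of 34 residue scores.
#' @param signature 34-character extended signature (or an
#'   [active_site_signature()]).
#' @param path Output TSV.
#' @return The written data.frame, invisibly.
#' @export
export_residue_attribution <- function(values, signature, path) {
  if (inherits(signature, "active_site_signature")) signature <- signature$extended
  if (length(values) != 34L || nchar(signature) != 34L)
    stop("need 34 values and a 34-residue signature", call. = FALSE)
  mx <- max(values)
  df <- data.frame(residue_index = 1:34,
                   residue = strsplit(signature, "")[[1]],
                   score = as.numeric(values),
                   normalized_score = if (mx > 0) as.numeric(values) / mx
                     else as.numeric(values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
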