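# Evaluation semantics: any-match/top-1 scoring, top-k accuracy over
# interaction rankings, promiscuity (exact top-x set match) categories,
# benchmark call labelling (correct / incorrect / no call / not in model)
# and bootstrap tool comparison.

#' Score single-label predictions against ordered substrate lists
#'
#' Under the `any_match` policy a prediction is correct when the predicted
#' substrate is among the substrates listed for that domain; under `top1`
#' it must equal the predominant (first-listed) substrate. Per-substrate
#' precision/recall/F1 are computed one-vs-rest: precision over domains
#' predicted as the substrate, recall over domains annotated with it
#' (any-match) or predominantly it (top1).
#'
#' @param predictions Data.frame with `domain_id` and `label` (as from
#'   [predict_substrate()]), or a named character vector of labels.
#' @param truth Named list of ordered substrate vectors (names = domain
#'   ids).
#' @param policy `"any_match"` (default) or `"top1"`.
#' @return List with `accuracy`, logical `correct` per domain, and
#'   `per_substrate` (data.frame substrate, precision, recall, f1,
#'   support).
#' @export
score_predictions <- function(predictions, truth,
                              policy = c("any_match", "top1")) {
  policy <- match.arg(policy)
  if (is.data.frame(predictions))
    predictions <- stats::setNames(predictions$label, predictions$domain_id)
  if (is.null(names(predictions)) || is.null(names(truth)))
    stop("predictions and truth must be named by domain id", call. = FALSE)
  if (!setequal(names(predictions), names(truth)))
    stop("domain ids of predictions and truth do not match", call. = FALSE)
  truth <- truth[names(predictions)]
  correct <- vapply(seq_along(predictions), function(i) {
    if (policy == "any_match") predictions[[i]] %in% truth[[i]]
    else predictions[[i]] == truth[[i]][1]
  }, TRUE)
  names(correct) <- names(predictions)
  subs <- sort(unique(c(unlist(truth), predictions)))
  per <- do.call(rbind, lapply(subs, function(s) {
    in_truth <- vapply(truth, function(t)
      if (policy == "any_match") s %in% t else t[1] == s, TRUE)
    predicted <- predictions == s
    tp <- sum(predicted & correct & in_truth)
    precision <- if (sum(predicted)) tp / sum(predicted) else NA_real_
    recall <- if (sum(in_truth)) sum(predicted & in_truth & correct) / sum(in_truth)
      else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    data.frame(substrate = s, precision = precision, recall = recall,
               f1 = f1, support = sum(in_truth))
  }))
  list(accuracy = mean(correct), correct = correct, per_substrate = per)
}

ranking_top <- function(ranking, k) utils::head(ranking$substrate, k)

#' Top-k accuracy over interaction rankings
#'
#' Fraction of domains whose true substrate set intersects the top `k`
#' ranked substrates. Non-decreasing in `k` by construction.
#'
#' @param rankings Named list of `interaction_ranking` objects (names =
#'   domain ids).
#' @param truth Named list of true substrate vectors.
#' @param k Rank depth (k >= 1).
#' @return Fraction in `[0, 1]`.
#' @export
topk_accuracy <- function(rankings, truth, k = 1L) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (!setequal(names(rankings), names(truth)))
    stop("domain ids of rankings and truth do not match", call. = FALSE)
  hit <- vapply(names(rankings), function(id)
    length(intersect(ranking_top(rankings[[id]], k), truth[[id]])) > 0, TRUE)
  mean(hit)
}

#' Promiscuity evaluation by exact top-x set matching
#'
#' For each domain with `x` annotated substrates, compares the set of its
#' top-`x` ranked substrates with the truth set: exact equality is
#' `correct`, at least one shared substrate is `partially_correct`, no
#' overlap is `incorrect`. The three categories partition the domains.
#'
#' @inheritParams topk_accuracy
#' @return Named integer vector with counts `correct`,
#'   `partially_correct`, `incorrect`.
#' @export
promiscuity_eval <- function(rankings, truth) {
  if (!setequal(names(rankings), names(truth)))
    stop("domain ids of rankings and truth do not match", call. = FALSE)
  if (any(lengths(truth) < 1L))
    stop("every truth set must be non-empty", call. = FALSE)
  verdict <- vapply(names(rankings), function(id) {
    x <- length(unique(truth[[id]]))
    top <- ranking_top(rankings[[id]], x)
    if (setequal(top, truth[[id]])) "correct"
    else if (length(intersect(top, truth[[id]]))) "partially_correct"
    else "incorrect"
  }, "")
  counts <- table(factor(verdict,
                         levels = c("correct", "partially_correct", "incorrect")))
  stats::setNames(as.integer(counts), names(counts))
}

#' Label one benchmark prediction
#'
#' Benchmark call semantics: if none of the domain's true substrates is in
#' the tool's class list, the call is `not_in_model`; if the tool returned
#' nothing (or its own confidence threshold suppressed the prediction),
#' `no_call`; otherwise `correct`/`incorrect` by the overlap policy.
#'
#' @param prediction Predicted substrate(s) as a character vector, or
#'   `NA`/`NULL` when the tool made no call.
#' @param truth True substrate vector for the domain.
#' @param model_classes Substrates the tool can predict.
#' @return One of `"correct"`, `"incorrect"`, `"no_call"`,
#'   `"not_in_model"`.
#' @export
benchmark_label <- function(prediction, truth, model_classes) {
  if (!length(intersect(truth, model_classes))) return("not_in_model")
  if (is.null(prediction) || !length(prediction) || all(is.na(prediction)))
    return("no_call")
  if (length(intersect(prediction, truth))) "correct" else "incorrect"
}

#' Aggregate benchmark accuracy
#'
#' Folds `no_call` and `not_in_model` verdicts into `incorrect`, the
#' convention for cross-tool benchmark accuracy.
#'
#' @param calls Character vector of verdicts from [benchmark_label()].
#' @return Fraction of `correct` calls.
#' @export
benchmark_accuracy <- function(calls) {
  ok <- c("correct", "incorrect", "no_call", "not_in_model")
  if (!all(calls %in% ok))
    stop("unknown verdict(s): ", paste(setdiff(calls, ok), collapse = ", "),
         call. = FALSE)
  mean(calls == "correct")
}

#' Bootstrap comparison of benchmark accuracies across tools
#'
#' Generates a bootstrap distribution of (folded) benchmark accuracy for
#' each tool, runs a Kruskal-Wallis omnibus rank test across tools, and -
#' only when the omnibus is significant - pairwise Mann-Whitney U tests
#' with Bonferroni correction over the declared number of comparisons.
#'
#' @param calls_by_tool Named list of verdict vectors (aligned domain
#'   sets, one per tool).
#' @param n_boot Bootstrap iterations (default 1000).
#' @param seed Integer seed.
#' @param alpha Significance level (default 0.05).
#' @param n_comparisons Bonferroni denominator; defaults to the number of
#'   pairwise tests performed.
#' @return List: `accuracy` (point accuracies), `distributions` (matrix
#'   n_boot x tools), `omnibus_p`, and `pairwise` (data.frame tool_a,
#'   tool_b, p, p_adjusted, significant; empty when the omnibus is not
#'   significant).
#' @export
bootstrap_compare <- function(calls_by_tool, n_boot = 1000L, seed,
                              alpha = 0.05, n_comparisons = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  k <- length(calls_by_tool)
  if (k < 2L) stop("need at least two tools", call. = FALSE)
  n <- unique(lengths(calls_by_tool))
  if (length(n) != 1L)
    stop("tools must be evaluated on aligned domain sets", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  correct <- lapply(calls_by_tool, function(x) x == "correct")
  dist <- vapply(correct, function(cv)
    vapply(seq_len(n_boot), function(b) mean(cv[sample.int(n, n, replace = TRUE)]),
           0), numeric(n_boot))
  acc <- vapply(correct, mean, 0)
  flat <- data.frame(acc = as.vector(dist),
                     tool = factor(rep(names(calls_by_tool), each = n_boot)))
  omnibus_p <- if (stats::var(flat$acc) == 0) 1 else
    stats::kruskal.test(acc ~ tool, data = flat)$p.value
  pairs <- utils::combn(names(calls_by_tool), 2L)
  if (is.null(n_comparisons)) n_comparisons <- ncol(pairs)
  pairwise <- data.frame(tool_a = character(), tool_b = character(),
                         p = numeric(), p_adjusted = numeric(),
                         significant = logical())
  if (!is.na(omnibus_p) && omnibus_p < alpha) {
    pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- dist[, pairs[1, j]]; b <- dist[, pairs[2, j]]
      p <- if (identical(a, b)) 1 else
        suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
      data.frame(tool_a = pairs[1, j], tool_b = pairs[2, j], p = p,
                 p_adjusted = min(1, p * n_comparisons),
                 significant = min(1, p * n_comparisons) < alpha)
    }))
  }
  list(accuracy = acc, distributions = dist, omnibus_p = omnibus_p,
       pairwise = pairwise, n_comparisons = n_comparisons)
}
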