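#' Specificity dataset
#'
#' The unit of splitting, training and evaluation: one record per A domain
#' with its ordered substrate labels (first = predominant), taxonomy down
#' to family, and optionally its extracted signature and feature vector.
#'
#' @param domain_id Character vector of unique domain ids.
#' @param substrates List of character vectors, one per domain, predominant
#'   substrate first; every domain needs at least one.
#' @param taxonomy Optional data.frame with columns `kingdom`, `phylum`,
#'   `class`, `order`, `family` (missing ranks as `"None"`, the convention
#'   for domains of unknown, e.g. metagenomic, origin).
#' @param features Optional numeric matrix of domain features, one row per
#'   domain.
#' @param signatures Optional character vector of 34-residue extended
#'   signatures.
#' @param protein_id,domain_index,evidence Optional per-domain annotation
#'   columns carried through to TSV output.
#' @return Object of class `specificity_dataset`.
#' @export
specificity_dataset <- function(domain_id, substrates, taxonomy = NULL,
                                features = NULL, signatures = NULL,
                                protein_id = NULL, domain_index = NULL,
                                evidence = NULL) {
  n <- length(domain_id)
  if (anyDuplicated(domain_id)) stop("domain ids must be unique", call. = FALSE)
  if (!is.list(substrates) || length(substrates) != n)
    stop("substrates must be a list with one entry per domain", call. = FALSE)
  if (any(lengths(substrates) < 1L) ||
      any(!vapply(substrates, function(s) all(nzchar(s)), TRUE)))
    stop("every domain needs at least one non-empty substrate label", call. = FALSE)
  ranks <- c("kingdom", "phylum", "class", "order", "family")
  if (is.null(taxonomy)) {
    taxonomy <- as.data.frame(stats::setNames(
      replicate(5, rep("None", n), simplify = FALSE), ranks))
  }
  if (!all(ranks %in% names(taxonomy)) || nrow(taxonomy) != n)
    stop("taxonomy needs columns ", paste(ranks, collapse = ", "),
         " and one row per domain", call. = FALSE)
  if (!is.null(features)) {
    features <- as.matrix(features)
    if (nrow(features) != n)
      stop("features must have one row per domain", call. = FALSE)
    rownames(features) <- domain_id
  }
  structure(list(domain_id = as.character(domain_id),
                 substrates = substrates,
                 taxonomy = taxonomy[ranks],
                 features = features,
                 signatures = signatures,
                 protein_id = protein_id,
                 domain_index = domain_index,
                 evidence = evidence),
            class = "specificity_dataset")
}

#' @export
print.specificity_dataset <- function(x, ...) {
  cat(sprintf("<specificity_dataset: %d domains, %d substrates%s%s>\n",
              length(x$domain_id), length(unique(unlist(x$substrates))),
              if (is.null(x$features)) "" else
                sprintf(", %d features", ncol(x$features)),
              if (is.null(x$signatures)) "" else ", signatures"))
  invisible(x)
}

#' Subset a dataset by domain id or index
#'
#' @param dataset A [specificity_dataset()].
#' @param which Integer/logical index or character domain ids.
#' @return The subsetted `specificity_dataset`.
#' @export
dataset_subset <- function(dataset, which) {
  if (is.character(which)) which <- match(which, dataset$domain_id)
  if (anyNA(which)) stop("unknown domain id(s)", call. = FALSE)
  pickv <- function(x) if (is.null(x)) NULL else x[which]
  specificity_dataset(
    dataset$domain_id[which], dataset$substrates[which],
    taxonomy = dataset$taxonomy[which, , drop = FALSE],
    features = if (is.null(dataset$features)) NULL else
      dataset$features[which, , drop = FALSE],
    signatures = pickv(dataset$signatures),
    protein_id = pickv(dataset$protein_id),
    domain_index = pickv(dataset$domain_index),
    evidence = pickv(dataset$evidence))
}

#' Restrict a dataset to one kingdom
#'
#' Supports kingdom-scoped model training (e.g. a bacteria-only model next
#' to an all-kingdoms model from the same dataset).
#'
#' @param dataset A [specificity_dataset()].
#' @param kingdom Kingdom name to keep (matched case-insensitively).
#' @return The subsetted dataset.
#' @export
dataset_kingdom <- function(dataset, kingdom) {
  dataset_subset(dataset, tolower(dataset$taxonomy$kingdom) == tolower(kingdom))
}

DATASET_COLUMNS <- c("domain_id", "protein_id", "domain_index", "substrates",
                     "kingdom", "phylum", "class", "order", "family",
                     "evidence")

#' Write a dataset to its TSV form
#'
#' Substrate lists are pipe-separated with the predominant substrate first;
#' empty fields mean missing.
#'
#' @param dataset A [specificity_dataset()].
#' @param path Output TSV.
#' @return The path, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  n <- length(dataset$domain_id)
  orNA <- function(x, default) if (is.null(x)) rep(default, n) else x
  df <- data.frame(
    domain_id = dataset$domain_id,
    protein_id = orNA(dataset$protein_id, ""),
    domain_index = orNA(dataset$domain_index, ""),
    substrates = vapply(dataset$substrates, paste, "", collapse = "|"),
    dataset$taxonomy,
    evidence = orNA(dataset$evidence, ""))
  names(df) <- DATASET_COLUMNS
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dataset TSV
#'
#' @param path TSV with the exact header
#'   `domain_id protein_id domain_index substrates kingdom phylum class
#'   order family evidence`.
#' @return A [specificity_dataset()] (without features).
#' @export
read_dataset <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  if (!identical(names(df), DATASET_COLUMNS))
    stop("dataset TSV header must be exactly: ",
         paste(DATASET_COLUMNS, collapse = ", "), call. = FALSE)
  taxonomy <- df[c("kingdom", "phylum", "class", "order", "family")]
  taxonomy[taxonomy == ""] <- "None"
  specificity_dataset(
    df$domain_id,
    strsplit(df$substrates, "|", fixed = TRUE),
    taxonomy = taxonomy,
    protein_id = ifelse(df$protein_id == "", NA, df$protein_id),
    domain_index = suppressWarnings(as.integer(df$domain_index)),
    evidence = ifelse(df$evidence == "", NA, df$evidence))
}

#' Assemble the single-label training set
#'
#' One row per domain, labelled with its first-listed (predominant)
#' substrate. Domains whose predominant substrate occurs fewer than
#' `inclusion_cutoff` times (counting first labels) are excluded; a cutoff
#' of 1 keeps every domain ("all substrates" mode).
#'
#' @param dataset A [specificity_dataset()] with features.
#' @param inclusion_cutoff Minimum occurrences for a substrate class
#'   (default 10).
#' @return List with `X` (feature matrix), `y` (factor of substrate
#'   labels), and `domain_id`.
#' @export
build_classifier_training <- function(dataset, inclusion_cutoff = 10L) {
  if (is.null(dataset$features))
    stop("dataset has no feature matrix", call. = FALSE)
  first <- vapply(dataset$substrates, `[`, "", 1L)
  counts <- table(first)
  keep_labels <- names(counts)[counts >= inclusion_cutoff]
  keep <- first %in% keep_labels
  if (!any(keep)) {
    stop("no substrate meets the inclusion cutoff of ", inclusion_cutoff,
         "; counts: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
         call. = FALSE)
  }
  list(X = dataset$features[keep, , drop = FALSE],
       y = factor(first[keep], levels = sort(keep_labels)),
       domain_id = dataset$domain_id[keep])
}

#' Assemble domain-substrate interaction pairs
#'
#' Positives are every (domain, listed substrate) pair; negatives are
#' (domain, library substrate) pairs for substrates the domain is not
#' annotated with. The raw label ratio is heavily imbalanced (about 1:30
#' on realistic substrate libraries), so negatives are randomly
#' under-sampled to exactly the positive count whenever enough candidates
#' exist; otherwise all candidates are kept with a warning. Each row is
#' the domain feature vector followed by the substrate's 1024-bit
#' fingerprint.
#'
#' @param dataset A [specificity_dataset()] with features.
#' @param library A [substrate_library()] covering at least the labelled
#'   substrates to be used.
#' @param seed Integer seed for the undersampler (mandatory).
#' @param scope `"global"` (negatives sampled over all domains jointly,
#'   default) or `"per_domain"` (equal positive and negative counts within
#'   each domain).
#' @param exclude Optional list (named by domain id) of substrates to
#'   exclude from a domain's negative candidates, e.g. curated minor
#'   substrates removed upstream.
#' @return List with `X`, binary factor `y` (`interaction` /
#'   `no_interaction`), and `pairs` (data.frame domain_id, substrate,
#'   label).
#' @export
build_interaction_pairs <- function(dataset, library, seed,
                                    scope = c("global", "per_domain"),
                                    exclude = NULL) {
  scope <- match.arg(scope)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(dataset$features))
    stop("dataset has no feature matrix", call. = FALSE)
  lib_names <- rownames(library$fp_matrix)
  pos <- data.frame(
    domain = rep(seq_along(dataset$domain_id), lengths(dataset$substrates)),
    substrate = unlist(dataset$substrates))
  pos <- pos[pos$substrate %in% lib_names, , drop = FALSE]
  if (!nrow(pos))
    stop("no labelled substrate is covered by the library", call. = FALSE)
  neg <- do.call(rbind, lapply(seq_along(dataset$domain_id), function(i) {
    banned <- unique(c(dataset$substrates[[i]],
                       exclude[[dataset$domain_id[i]]]))
    cand <- setdiff(lib_names, banned)
    if (!length(cand)) return(NULL)
    data.frame(domain = i, substrate = cand)
  }))
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  n_pos <- nrow(pos)
  if (scope == "global") {
    if (is.null(neg) || nrow(neg) < n_pos) {
      warning("fewer candidate negatives than positives; keeping all")
    } else {
      neg <- withr_seed(neg[sample.int(nrow(neg), n_pos), , drop = FALSE])
    }
  } else {
    neg <- withr_seed(do.call(rbind, lapply(split(neg, neg$domain), function(nd) {
      want <- sum(pos$domain == nd$domain[1])
      if (nrow(nd) <= want) nd else nd[sample.int(nrow(nd), want), , drop = FALSE]
    })))
    if (nrow(neg) < n_pos) warning("fewer candidate negatives than positives; keeping all")
  }
  all_pairs <- rbind(cbind(pos, label = "interaction"),
                     cbind(neg, label = "no_interaction"))
  X <- cbind(dataset$features[all_pairs$domain, , drop = FALSE],
             library$fp_matrix[all_pairs$substrate, , drop = FALSE])
  dom_names <- colnames(dataset$features)
  if (is.null(dom_names))
    dom_names <- sprintf("dom%04d", seq_len(ncol(dataset$features)))
  colnames(X) <- c(dom_names,
                   sprintf("fp%04d", seq_len(ncol(library$fp_matrix))))
  rownames(X) <- NULL
  list(X = X,
       y = factor(all_pairs$label, levels = c("interaction", "no_interaction")),
       pairs = data.frame(domain_id = dataset$domain_id[all_pairs$domain],
                          substrate = all_pairs$substrate,
                          label = all_pairs$label))
}
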