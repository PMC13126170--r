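# Shared fixtures, built once per test run and memoised across test files.

.fix <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.fix[[key]])) .fix[[key]] <- fn()
  .fix[[key]]
}

fix_scaffold <- function() memo("scaffold", function() make_scaffold(seed = 42))

fix_dataset <- function() memo("dataset", function()
  make_dataset(fixture_spec(n_domains = 120L, n_substrate_classes = 4L,
                            seed = 7L), fix_scaffold()))

fix_library <- function() memo("library", function() {
  fx <- fix_dataset()
  substrate_library(fx$substrates$name, fx$substrates$smiles)
})

fix_split <- function() memo("split", function()
  substrate_split(fix_dataset()$dataset, 0.25, multilabel = FALSE, seed = 3))

fix_classifier <- function() memo("classifier", function() {
  fx <- fix_dataset()
  tr <- dataset_subset(fx$dataset, fix_split()$train_ids)
  trn <- build_classifier_training(tr, inclusion_cutoff = 1L)
  train_substrate_classifier(trn$X, trn$y, n_trees = 200L, seed = 11L,
                             inclusion_cutoff = 1L)
})

fix_interaction <- function() memo("interaction", function() {
  fx <- fix_dataset()
  tr <- dataset_subset(fx$dataset, fix_split()$train_ids)
  pairs <- build_interaction_pairs(tr, fix_library(), seed = 5L)
  train_interaction_model(pairs$X, pairs$y, library = fix_library(),
                          n_trees = 200L, seed = 13L)
})

fix_truth <- function() {
  fx <- fix_dataset()
  stats::setNames(fx$dataset$substrates, fx$dataset$domain_id)
}

# Independent oracle for position mapping: exhaustive global pairwise
# alignment of query against the scaffold reference (Biostrings Needleman-
# Wunsch, BLOSUM62), returning reference position -> query position or NA.
oracle_map <- function(query, scaffold) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(scaffold$reference_sequence),
    substitutionMatrix = BLOSUM62, gapOpening = 10, gapExtension = 0.5,
    type = "global")
  qa <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  rpos <- cumsum(ra != "-")
  qpos <- cumsum(qa != "-")
  cols <- which(ra != "-")
  map <- rep(NA_integer_, nchar(scaffold$reference_sequence))
  map[rpos[cols]] <- ifelse(qa[cols] != "-", qpos[cols], NA_integer_)
  map
}

oracle_signature <- function(query, scaffold) {
  map <- oracle_map(query, scaffold)
  qp <- map[scaffold$extended_positions]
  paste(vapply(qp, function(p) if (is.na(p)) "-" else substr(query, p, p), ""),
        collapse = "")
}

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "G", "S", "T", "P", "V", "N", "Q"), n, replace = TRUE),
        collapse = "")
}
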