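#' Read protein sequences from FASTA or GenBank
#'
#' FASTA parsing (wrapped lines tolerated) uses Biostrings; GenBank mode
#' extracts the `/translation` of every CDS feature, identified by its
#' `/locus_tag` (falling back to `/protein_id`, then a positional id).
#'
#' @param path Input file.
#' @param format `"fasta"` (default) or `"genbank"`.
#' @return List of [protein_record()]s.
#' @export
read_proteins <- function(path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty file: ", path, call. = FALSE)
  if (format == "fasta") {
    seqs <- Biostrings::readAAStringSet(path)
    if (!length(seqs)) stop("no sequences in ", path, call. = FALSE)
    ids <- sub("\\s.*$", "", names(seqs))
    dup <- ids[duplicated(ids)]
    if (length(dup))
      stop("duplicate protein id(s): ", paste(unique(dup), collapse = ", "),
           call. = FALSE)
    return(Map(protein_record, ids, as.character(seqs)))
  }
  parse_genbank_cds(readLines(path))
}

# minimal GenBank flat-file parser: CDS features with /translation
parse_genbank_cds <- function(lines) {
  records <- list()
  in_features <- FALSE
  i <- 1L
  current <- NULL
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$translation)) return(NULL)
    id <- cur$locus_tag %||% cur$protein_id %||%
      sprintf("CDS_%d", length(records) + 1L)
    protein_record(id, gsub("\\s", "", cur$translation))
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  while (i <= length(lines)) {
    line <- lines[i]
    if (grepl("^FEATURES", line)) in_features <- TRUE
    else if (grepl("^ORIGIN|^//", line)) {
      r <- flush(current); if (!is.null(r)) records[[length(records) + 1L]] <- r
      current <- NULL
      in_features <- FALSE
    } else if (in_features) {
      if (grepl("^ {5}CDS ", line)) {
        r <- flush(current); if (!is.null(r)) records[[length(records) + 1L]] <- r
        current <- list()
      } else if (grepl("^ {5}\\S", line)) {          # another feature key
        r <- flush(current); if (!is.null(r)) records[[length(records) + 1L]] <- r
        current <- NULL
      } else if (!is.null(current) && grepl("^ {21}/", line)) {
        qual <- sub("^ +/", "", line)
        key <- sub("=.*$", "", qual)
        val <- if (grepl("=", qual)) gsub("\"", "", sub("^[^=]+=", "", qual)) else TRUE
        if (key == "translation") {
          # value may continue over following lines until the closing quote
          txt <- sub("^[^=]+=\"?", "", qual)
          while (!grepl("\"\\s*$", lines[i]) && i < length(lines)) {
            i <- i + 1L
            txt <- paste0(txt, trimws(lines[i]))
          }
          current$translation <- gsub("\"", "", txt)
        } else if (key %in% c("locus_tag", "protein_id")) {
          current[[key]] <- val
        }
      }
    }
    i <- i + 1L
  }
  r <- flush(current); if (!is.null(r)) records[[length(records) + 1L]] <- r
  if (!length(records)) stop("no CDS translations found", call. = FALSE)
  records
}

# does `short` match a terminal truncation of `long`? exact containment, or
# a suffix-prefix overlap of at least `min_frac` of the shorter sequence
truncation_match <- function(a, b, min_frac = 0.8) {
  if (a == b) return(TRUE)
  short <- if (nchar(a) <= nchar(b)) a else b
  long <- if (nchar(a) <= nchar(b)) b else a
  if (grepl(short, long, fixed = TRUE)) return(TRUE)
  min_ov <- ceiling(min_frac * nchar(short))
  for (ov in seq(nchar(short), min_ov)) {
    if (substr(long, nchar(long) - ov + 1L, nchar(long)) ==
        substr(short, 1L, ov)) return(TRUE)
    if (substr(short, nchar(short) - ov + 1L, nchar(short)) ==
        substr(long, 1L, ov)) return(TRUE)
  }
  FALSE
}

#' Deduplicate domain records by sequence
#'
#' Two records merge when their sequences are identical or one is a
#' terminal truncation of the other (contained, or overlapping at an end
#' by at least 0.8x the shorter length). Merged records keep all protein
#' labels and the longest sequence. Records that would merge but carry
#' different substrate annotations are NOT merged silently: they are kept
#' separate and flagged for curation in the report.
#'
#' @param records Data.frame with columns `id`, `sequence` and optionally
#'   `substrates` (pipe-separated).
#' @param min_overlap Minimum overlap fraction of the shorter sequence
#'   (default 0.8).
#' @return List with `records` (deduplicated data.frame; `labels` collects
#'   merged ids) and `conflicts` (data.frame of flagged pairs).
#' @export
deduplicate <- function(records, min_overlap = 0.8) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  n <- nrow(records)
  subs <- if ("substrates" %in% names(records)) records$substrates
    else rep(NA_character_, n)
  group <- seq_len(n)
  conflicts <- list()
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    if (group[j] != j) next                       # already merged elsewhere
    if (truncation_match(records$sequence[i], records$sequence[j], min_overlap)) {
      same_sub <- is.na(subs[i]) || is.na(subs[j]) ||
        setequal(strsplit(subs[i], "|", fixed = TRUE)[[1]],
                 strsplit(subs[j], "|", fixed = TRUE)[[1]])
      if (same_sub) {
        group[j] <- group[i]
      } else {
        conflicts[[length(conflicts) + 1L]] <-
          data.frame(id_a = records$id[i], id_b = records$id[j],
                     substrates_a = subs[i], substrates_b = subs[j])
      }
    }
  }
  merged <- do.call(rbind, lapply(unique(group), function(g) {
    members <- which(group == g)
    longest <- members[which.max(nchar(records$sequence[members]))]
    data.frame(id = records$id[members[1]],
               labels = paste(records$id[members], collapse = "|"),
               sequence = records$sequence[longest],
               substrates = subs[members[1]])
  }))
  list(records = merged,
       conflicts = if (length(conflicts)) do.call(rbind, conflicts) else
         data.frame(id_a = character(), id_b = character(),
                    substrates_a = character(), substrates_b = character()))
}

MODEL_BUNDLE_VERSION <- 1L

#' Save a trained model bundle
#'
#' Writes a single-file bundle embedding the forest, feature schema,
#' substrate library (interaction models), seed and training metadata.
#'
#' @param model A `substrate_classifier` or `interaction_model`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, c("substrate_classifier", "interaction_model")))
    stop("model must be a trained substrate_classifier or interaction_model",
         call. = FALSE)
  saveRDS(list(bundle_version = MODEL_BUNDLE_VERSION,
               kind = class(model)[1], model = model), path)
  invisible(path)
}

#' Load a model bundle
#'
#' @param path Bundle written by [save_model()].
#' @return The model, predicting identically to the saved one.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model bundle not found: ", path, call. = FALSE)
  bundle <- tryCatch(suppressWarnings(readRDS(path)), error = function(e) NULL)
  if (is.null(bundle) || !is.list(bundle) ||
      !all(c("bundle_version", "kind", "model") %in% names(bundle)) ||
      !inherits(bundle$model, bundle$kind) ||
      is.null(bundle$model$forest))
    stop("corrupt model bundle: ", path, call. = FALSE)
  bundle$model
}
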