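# ECFP-4 substrate fingerprints, computed with RDKit through a batched
# `python` subprocess (one call per SMILES batch, results cached per
# session). Fingerprints are graph-derived, so any SMILES spelling of the
# same molecule maps to identical bits.

.fp_cache <- new.env(parent = emptyenv())

rdkit_available <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) return(FALSE)
  if (!is.null(.fp_cache$.rdkit_ok)) return(.fp_cache$.rdkit_ok)
  ok <- suppressWarnings(system2(py, c("-c", shQuote("import rdkit")),
                                 stdout = FALSE, stderr = FALSE)) == 0L
  .fp_cache$.rdkit_ok <- ok
  ok
}

# returns a list: one integer vector of 0/1 per SMILES, or the condition
# message string for unparseable input
ecfp_batch <- function(smiles, radius = 2L, n_bits = 1024L) {
  if (!rdkit_available())
    stop("fingerprinting needs 'python' with RDKit on PATH", call. = FALSE)
  key <- function(s) sprintf("%s|%d|%d", s, radius, n_bits)
  out <- vector("list", length(smiles))
  todo <- which(!vapply(smiles, function(s) !is.null(.fp_cache[[key(s)]]), TRUE))
  if (length(todo)) {
    infile <- tempfile(fileext = ".tsv")
    on.exit(unlink(infile))
    writeLines(sprintf("s%d\t%s", seq_along(todo), smiles[todo]), infile)
    script <- system.file("python", "ecfp.py", package = "adomain")
    res <- system2(Sys.which("python"),
                   c(shQuote(script), shQuote(infile), radius, n_bits),
                   stdout = TRUE, stderr = FALSE)
    parts <- strsplit(res, "\t")
    got <- stats::setNames(parts, vapply(parts, `[`, "", 1L))
    for (i in seq_along(todo)) {
      p <- got[[sprintf("s%d", i)]]
      if (is.null(p) || p[2] == "ERROR") {
        .fp_cache[[key(smiles[todo[i]])]] <-
          if (is.null(p)) "fingerprint helper returned nothing" else p[3]
      } else {
        v <- integer(n_bits)
        if (length(p) >= 3L && nzchar(p[3]))
          v[as.integer(strsplit(p[3], ",")[[1]]) + 1L] <- 1L
        .fp_cache[[key(smiles[todo[i]])]] <- v
      }
    }
  }
  for (i in seq_along(smiles)) out[[i]] <- .fp_cache[[key(smiles[i])]]
  out
}

#' Compute an ECFP-4 molecular fingerprint
#'
#' Hashes circular substructures of the molecule (Morgan algorithm, radius
#' 2 = ECFP-4) into a fixed-length bit vector. Deterministic, and invariant
#' under rewriting of the SMILES for the same molecule.
#'
#' @param smiles A single SMILES string.
#' @param radius Morgan radius (default 2, i.e. ECFP-4).
#' @param n_bits Fingerprint length (default 1024).
#' @return Integer vector of 0/1 of length `n_bits`.
#' @examples
#' \dontrun{sum(compute_fingerprint("NCC(=O)O"))  # glycine sets some bits}
#' @export
compute_fingerprint <- function(smiles, radius = 2L, n_bits = 1024L) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    stop("smiles must be a non-empty string", call. = FALSE)
  v <- ecfp_batch(smiles, radius, n_bits)[[1]]
  if (is.character(v)) stop(v, call. = FALSE)
  v
}

#' Substrate record: name, SMILES, fingerprint
#'
#' @param name Canonical substrate name (case-insensitively unique within a
#'   library).
#' @param smiles Isomeric SMILES for the substrate.
#' @param radius,n_bits Fingerprint parameters.
#' @return Object of class `substrate_record` with a 1024-bit `fingerprint`.
#' @export
substrate_record <- function(name, smiles, radius = 2L, n_bits = 1024L) {
  fp <- compute_fingerprint(smiles, radius, n_bits)
  structure(list(name = name, smiles = smiles, fingerprint = fp),
            class = "substrate_record")
}

#' Substrate library
#'
#' A named collection of [substrate_record()]s; the reference set of
#' substrates a model can be trained on or queried with. Fingerprints are
#' computed in one batch.
#'
#' @param names Character vector of substrate names.
#' @param smiles Character vector of SMILES, same length.
#' @param radius,n_bits Fingerprint parameters.
#' @return Object of class `substrate_library`: list of records, plus a
#'   fingerprint matrix `fp_matrix` (substrate x bit).
#' @export
substrate_library <- function(names, smiles, radius = 2L, n_bits = 1024L) {
  if (length(names) != length(smiles))
    stop("names and smiles must have the same length", call. = FALSE)
  if (anyDuplicated(tolower(names)))
    stop("substrate names must be case-insensitively unique", call. = FALSE)
  fps <- ecfp_batch(smiles, radius, n_bits)
  bad <- vapply(fps, is.character, TRUE)
  if (any(bad))
    stop("unparseable SMILES for: ",
         paste(sprintf("%s (%s)", names[bad], unlist(fps[bad])), collapse = "; "),
         call. = FALSE)
  records <- Map(function(n, s, f)
    structure(list(name = n, smiles = s, fingerprint = f),
              class = "substrate_record"),
    names, smiles, fps)
  m <- do.call(rbind, fps)
  rownames(m) <- names
  structure(list(records = records, fp_matrix = m, radius = radius,
                 n_bits = n_bits),
            class = "substrate_library")
}

#' @export
print.substrate_library <- function(x, ...) {
  cat(sprintf("<substrate_library: %d substrates, %d-bit ECFP-%d>\n",
              nrow(x$fp_matrix), x$n_bits, 2L * x$radius))
  invisible(x)
}

#' Read a substrate table (name, SMILES) from TSV
#'
#' @param path TSV with columns `name` and `smiles`.
#' @inheritParams substrate_library
#' @return A [substrate_library()].
#' @export
read_substrates <- function(path, radius = 2L, n_bits = 1024L) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, quote = "")
  if (!all(c("name", "smiles") %in% names(df)))
    stop("substrate table needs 'name' and 'smiles' columns", call. = FALSE)
  substrate_library(df$name, df$smiles, radius, n_bits)
}
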