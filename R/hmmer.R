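# Thin wrappers around the HMMER3 command-line tools. All profile models are
# HMMER ASCII files; alignments pass through temporary FASTA on disk.

hmmer_available <- function() {
  all(nzchar(Sys.which(c("hmmbuild", "hmmsearch", "hmmalign"))))
}

check_hmmer <- function() {
  if (!hmmer_available())
    stop("HMMER executables (hmmbuild/hmmsearch/hmmalign) not found on PATH",
         call. = FALSE)
}

write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  path
}

#' Build a profile HMM from an alignment
#'
#' @param alignment Named character vector of aligned sequences (equal
#'   lengths, `-` for gaps) or a path to an aligned FASTA file.
#' @param out Output path for the HMMER ASCII profile.
#' @param name Profile name recorded in the file.
#' @return `out`, invisibly.
#' @export
build_profile <- function(alignment, out, name = "profile") {
  check_hmmer()
  if (is.character(alignment) && length(alignment) == 1L && file.exists(alignment)) {
    aln_path <- alignment
  } else {
    if (length(unique(nchar(alignment))) != 1L)
      stop("aligned sequences must all have the same length", call. = FALSE)
    aln_path <- tempfile(fileext = ".afa")
    write_fasta(alignment, aln_path)
    on.exit(unlink(aln_path))
  }
  log <- system2("hmmbuild", c("--amino", "-n", name, shQuote(out), shQuote(aln_path)),
                 stdout = TRUE, stderr = TRUE)
  if (!file.exists(out))
    stop("hmmbuild failed:\n", paste(log, collapse = "\n"), call. = FALSE)
  invisible(out)
}

# Run hmmsearch and parse --domtblout. Returns one row per domain hit with
# 1-based envelope coordinates and the per-domain bit score.
run_hmmsearch <- function(profile, seqs, bitscore = 0) {
  check_hmmer()
  if (!file.exists(profile)) stop("profile not found: ", profile, call. = FALSE)
  fa <- tempfile(fileext = ".fasta")
  tbl <- tempfile(fileext = ".domtbl")
  on.exit(unlink(c(fa, tbl)))
  write_fasta(seqs, fa)
  system2("hmmsearch",
          c("--domtblout", shQuote(tbl), "-T", format(bitscore), "--domT",
            format(bitscore), shQuote(profile), shQuote(fa)),
          stdout = FALSE, stderr = FALSE)
  if (!file.exists(tbl)) stop("hmmsearch produced no output", call. = FALSE)
  lines <- readLines(tbl)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(protein_id = character(), score = numeric(),
                      start = integer(), end = integer()))
  f <- strsplit(trimws(lines), "\\s+")
  data.frame(protein_id = vapply(f, `[`, "", 1L),
             score = as.numeric(vapply(f, `[`, "", 14L)),
             start = as.integer(vapply(f, `[`, "", 20L)),
             end = as.integer(vapply(f, `[`, "", 21L)))
}

# Align sequences to a profile; returns the alignment as a list of
# per-sequence character vectors (upper/lower case residues, '-'/'.' gaps).
run_hmmalign <- function(profile, seqs) {
  check_hmmer()
  fa <- tempfile(fileext = ".fasta")
  out <- tempfile(fileext = ".afa")
  on.exit(unlink(c(fa, out)))
  write_fasta(seqs, fa)
  log <- system2("hmmalign", c("--outformat", "afa", "-o", shQuote(out),
                               shQuote(profile), shQuote(fa)),
                 stdout = TRUE, stderr = TRUE)
  if (!file.exists(out))
    stop("hmmalign failed:\n", paste(log, collapse = "\n"), call. = FALSE)
  aln <- Biostrings::readAAStringSet(out)
  stats::setNames(strsplit(as.character(aln), ""), names(aln))
}

# Best bit score of a query against a profile, NA when there is no hit.
profile_score <- function(profile, query) {
  hits <- run_hmmsearch(profile, c(query = query), bitscore = -1e6)
  if (!nrow(hits)) NA_real_ else max(hits$score)
}
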