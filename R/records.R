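#' Protein record
#'
#' A minimal validated container for one protein sequence. Sequences must be
#' uppercase amino-acid strings over the 20 canonical letters plus the
#' ambiguity codes `X`, `B`, `Z`, `U`.
#'
#' @param protein_id Accession-like identifier (GenBank/RefSeq/UniProt style).
#' @param sequence Amino-acid string, no whitespace, non-empty.
#' @return An object of class `protein_record` with fields `protein_id` and
#'   `sequence`.
#' @examples
#' protein_record("P0001", "MKTAYIAKQR")
#' @export
protein_record <- function(protein_id, sequence) {
  if (!is.character(protein_id) || length(protein_id) != 1L || !nzchar(protein_id))
    stop("protein_id must be a non-empty string", call. = FALSE)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty string", call. = FALSE)
  sequence <- toupper(sequence)
  if (grepl("\\s", sequence))
    stop("sequence must not contain whitespace", call. = FALSE)
  bad <- gsub(sprintf("[%sXBZU]", paste(AA_LETTERS, collapse = "")), "", sequence)
  if (nzchar(bad))
    stop("invalid residue letter(s) in sequence: ", substr(bad, 1, 5), call. = FALSE)
  structure(list(protein_id = protein_id, sequence = sequence),
            class = "protein_record")
}

# the 20 canonical amino-acid letters, alphabetical
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# letters recorded verbatim in signatures but featurised as gaps
AA_AMBIGUOUS <- c("X", "B", "Z", "U")

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record %s: %d aa>\n", x$protein_id, nchar(x$sequence)))
  invisible(x)
}

#' Reference scaffold for signature extraction
#'
#' The scaffold pins the active-site footprint: an A-domain reference
#' sequence (the role historically played by the Phe-activating A domain of
#' gramicidin S synthetase, GrsA) together with the 34 extended-signature
#' positions (the residues within 8 A of the bound phenylalanine substrate
#' in the reference crystal structure) and the 10 Stachelhaus-code
#' positions. Both position lists are 1-based indices into
#' `reference_sequence` and are configuration data: swap them to use a
#' different reference or footprint.
#'
#' Positions must be strictly increasing, except that the final Stachelhaus
#' position (the conserved terminal lysine, which lies beyond the N-terminal
#' subdomain) may break monotonicity as the last element only.
#'
#' @param reference_id Identifier of the reference domain.
#' @param reference_sequence Amino-acid sequence of the reference A domain.
#' @param extended_positions Integer vector, length 34.
#' @param stachelhaus_positions Integer vector, length 10.
#' @param profile Optional path to a HMMER ASCII profile for the scaffold
#'   family, used by `phmm`-mode position mapping and carried along for
#'   convenience.
#' @return An object of class `reference_scaffold`.
#' @export
reference_scaffold <- function(reference_id, reference_sequence,
                               extended_positions, stachelhaus_positions,
                               profile = NULL) {
  rec <- protein_record(reference_id, reference_sequence)
  ep <- as.integer(extended_positions)
  sp <- as.integer(stachelhaus_positions)
  n <- nchar(rec$sequence)
  if (length(ep) != 34L) stop("extended_positions must have length 34", call. = FALSE)
  if (length(sp) != 10L) stop("stachelhaus_positions must have length 10", call. = FALSE)
  if (any(ep < 1L) || any(ep > n) || any(sp < 1L) || any(sp > n))
    stop("signature positions must lie within the reference sequence", call. = FALSE)
  if (any(diff(ep) <= 0L))
    stop("extended_positions must be strictly increasing", call. = FALSE)
  # terminal lysine may break monotonicity, but only as the final element
  if (any(diff(sp[-10L]) <= 0L))
    stop("stachelhaus_positions 1-9 must be strictly increasing", call. = FALSE)
  structure(list(reference_id = rec$protein_id,
                 reference_sequence = rec$sequence,
                 extended_positions = ep,
                 stachelhaus_positions = sp,
                 profile = profile),
            class = "reference_scaffold")
}

#' @export
print.reference_scaffold <- function(x, ...) {
  cat(sprintf("<reference_scaffold %s: %d aa, 34+10 signature positions%s>\n",
              x$reference_id, nchar(x$reference_sequence),
              if (is.null(x$profile)) "" else ", profile attached"))
  invisible(x)
}

#' A-domain hit within a protein
#'
#' Coordinates are 1-based and inclusive. `subdomain_n` and `subdomain_c`
#' are `c(start, end)` pairs for the N- and C-terminal A subdomains;
#' `subdomain_c` is `NULL` when no C-subdomain match was paired.
#'
#' @param protein_id Parent protein identifier.
#' @param domain_index 1-based ordinal of the A domain within the protein,
#'   counted N- to C-terminally.
#' @param start,end Domain span within the protein.
#' @param sequence Excised domain sequence; must equal the substring of the
#'   parent protein.
#' @param subdomain_n,subdomain_c Subdomain coordinate pairs.
#' @return An object of class `domain_hit`. Its `domain_id` is
#'   `<protein_id>.A<domain_index>`.
#' @export
domain_hit <- function(protein_id, domain_index, start, end, sequence,
                       subdomain_n = c(start, end), subdomain_c = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || start > end)
    stop("need 1 <= start <= end", call. = FALSE)
  if (nchar(sequence) != end - start + 1L)
    stop("sequence length does not match coordinates", call. = FALSE)
  if (!is.null(subdomain_c) && subdomain_c[1] <= subdomain_n[2] &&
      subdomain_n[1] >= subdomain_c[1])
    stop("subdomain_n must precede subdomain_c", call. = FALSE)
  structure(list(domain_id = sprintf("%s.A%d", protein_id, domain_index),
                 protein_id = protein_id,
                 domain_index = as.integer(domain_index),
                 start = start, end = end,
                 subdomain_n = as.integer(subdomain_n),
                 subdomain_c = if (is.null(subdomain_c)) NULL else as.integer(subdomain_c),
                 sequence = sequence),
            class = "domain_hit")
}

#' @export
print.domain_hit <- function(x, ...) {
  cat(sprintf("<domain_hit %s: %d-%d (%d aa)%s>\n", x$domain_id, x$start,
              x$end, nchar(x$sequence),
              if (is.null(x$subdomain_c)) ", N-subdomain only" else ""))
  invisible(x)
}

#' Active-site signature of an A domain
#'
#' @param domain_id Domain identifier.
#' @param extended 34-character extended signature over the amino-acid
#'   alphabet plus `-` for unaligned positions.
#' @param stachelhaus 10-character Stachelhaus signature.
#' @return An object of class `active_site_signature` with a `gap_count`
#'   field (number of `-` in the extended signature).
#' @export
active_site_signature <- function(domain_id, extended, stachelhaus) {
  if (nchar(extended) != 34L)
    stop("extended signature must have length 34", call. = FALSE)
  if (nchar(stachelhaus) != 10L)
    stop("stachelhaus signature must have length 10", call. = FALSE)
  ok <- sprintf("^[%sXBZU-]+$", paste(AA_LETTERS, collapse = ""))
  if (!grepl(ok, extended) || !grepl(ok, stachelhaus))
    stop("signatures may only contain amino-acid letters and '-'", call. = FALSE)
  structure(list(domain_id = domain_id, extended = extended,
                 stachelhaus = stachelhaus,
                 gap_count = lengths(regmatches(extended, gregexpr("-", extended, fixed = TRUE)))),
            class = "active_site_signature")
}

#' @export
print.active_site_signature <- function(x, ...) {
  cat(sprintf("<signature %s: %s | %s (%d gaps)>\n", x$domain_id,
              x$extended, x$stachelhaus, x$gap_count))
  invisible(x)
}

#' Count identical aligned residues between two signatures
#'
#' Positions where both strings carry the same amino-acid letter are
#' counted; aligned gap pairs (`-`) do not count as matches. The two
#' best-known divergent tryptophan signatures, `DAWTVTGVGK` and
#' `DPTQAGEVVK`, share exactly 3 residues (the conserved Asp and Lys among
#' them).
#'
#' @param a,b Signature strings of equal length.
#' @return Integer match count.
#' @examples
#' signature_matches("DAWTVTGVGK", "DPTQAGEVVK")  # 3
#' @export
signature_matches <- function(a, b) {
  if (!is.character(a) || !is.character(b) || length(a) != 1L || length(b) != 1L)
    stop("a and b must be single strings", call. = FALSE)
  if (nchar(a) != nchar(b))
    stop("signature length mismatch: ", nchar(a), " vs ", nchar(b), call. = FALSE)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sum(av == bv & av != "-")
}

#' Write / read a reference scaffold as TSV
#'
#' Plain-text serialization of the scaffold configuration (sequence,
#' position lists, optional profile path) for use from the command line.
#'
#' @param scaffold A [reference_scaffold()].
#' @param path TSV file.
#' @return `path` (or the scaffold for the reader), invisibly.
#' @export
write_scaffold <- function(scaffold, path) {
  df <- data.frame(
    reference_id = scaffold$reference_id,
    reference_sequence = scaffold$reference_sequence,
    extended_positions = paste(scaffold$extended_positions, collapse = "|"),
    stachelhaus_positions = paste(scaffold$stachelhaus_positions, collapse = "|"),
    profile = if (is.null(scaffold$profile)) "" else scaffold$profile)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scaffold
#' @export
read_scaffold <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  reference_scaffold(
    df$reference_id, df$reference_sequence,
    as.integer(strsplit(df$extended_positions, "|", fixed = TRUE)[[1]]),
    as.integer(strsplit(df$stachelhaus_positions, "|", fixed = TRUE)[[1]]),
    profile = if (nzchar(df$profile)) df$profile else NULL)
}
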