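#' Profile-model set for A-domain detection
#'
#' Detection scans a protein with profile HMMs for the N-terminal A
#' subdomain (the adenylation core, which carries the substrate-binding
#' pocket) and optionally the small C-terminal subdomain. `n_profiles` is an
#' ordered vector of N-subdomain profiles tried in precedence order: an
#' NRPS-specific profile first, then more general AMP-binding family
#' profiles as fallback for divergent (e.g. fungal) domains. The first
#' profile that yields any hit for a protein is used for that protein.
#'
#' @param n_profiles Character vector of paths to HMMER ASCII profiles for
#'   the N-terminal subdomain, in precedence order.
#' @param c_profile Optional path to a C-terminal subdomain profile.
#' @param bitscore Minimum per-domain bit score for a match. The curated
#'   gathering threshold of a profile is the natural choice; the default of
#'   25 bits is conservative for the bundled synthetic profiles.
#' @param merge_gap Same-profile envelopes separated by at most this many
#'   residues are merged into one hit (divergent domains often match a
#'   profile as several split envelopes).
#' @return An object of class `a_domain_detectors`.
#' @export
a_domain_detectors <- function(n_profiles, c_profile = NULL, bitscore = 25,
                               merge_gap = 100L) {
  n_profiles <- as.character(n_profiles)
  if (!length(n_profiles))
    stop("at least one N-subdomain profile model is required", call. = FALSE)
  missing <- n_profiles[!file.exists(n_profiles)]
  if (!is.null(c_profile) && !file.exists(c_profile))
    missing <- c(missing, c_profile)
  if (length(missing))
    stop("profile model file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(list(n_profiles = n_profiles, c_profile = c_profile,
                 bitscore = bitscore, merge_gap = as.integer(merge_gap)),
            class = "a_domain_detectors")
}

#' Detect adenylation domains in protein sequences
#'
#' Runs the detector profiles over one or more proteins and returns
#' non-overlapping A-domain hits in N- to C-terminal order. Each N-subdomain
#' match is paired with its nearest unclaimed downstream C-subdomain match
#' (when a C profile is configured and a match exists); the domain then
#' spans from the N-subdomain start to the C-subdomain end, otherwise it
#' covers the N-subdomain alone.
#'
#' @param proteins A `protein_record` or list of them.
#' @param detectors An [a_domain_detectors()] object.
#' @return A list of [domain_hit()] objects sorted by protein and start;
#'   empty list when nothing is found.
#' @export
detect_a_domains <- function(proteins, detectors) {
  if (inherits(proteins, "protein_record")) proteins <- list(proteins)
  if (!length(proteins)) return(list())
  ok <- vapply(proteins, inherits, TRUE, "protein_record")
  if (!all(ok)) stop("proteins must be protein_record objects", call. = FALSE)
  if (!inherits(detectors, "a_domain_detectors"))
    stop("detectors must be built with a_domain_detectors(); none loaded",
         call. = FALSE)
  seqs <- stats::setNames(vapply(proteins, `[[`, "", "sequence"),
                          vapply(proteins, `[[`, "", "protein_id"))
  if (anyDuplicated(names(seqs)))
    stop("duplicate protein ids in input", call. = FALSE)

  # one hmmsearch call per profile over the whole batch
  n_hits <- lapply(detectors$n_profiles, run_hmmsearch, seqs = seqs,
                   bitscore = detectors$bitscore)
  c_hits <- if (is.null(detectors$c_profile)) NULL else
    run_hmmsearch(detectors$c_profile, seqs, bitscore = detectors$bitscore)

  out <- list()
  for (pid in names(seqs)) {
    nh <- NULL
    for (h in n_hits) {            # precedence: first profile with any hit
      hh <- h[h$protein_id == pid, , drop = FALSE]
      if (nrow(hh)) { nh <- hh; break }
    }
    if (is.null(nh)) next
    nh <- nh[order(nh$start), , drop = FALSE]
    # merge split envelopes (overlapping or within merge_gap) into one hit
    merged <- nh[1, , drop = FALSE]
    for (i in seq_len(nrow(nh))[-1]) {
      last <- nrow(merged)
      if (nh$start[i] <= merged$end[last] + detectors$merge_gap) {
        merged$end[last] <- max(merged$end[last], nh$end[i])
        merged$score[last] <- max(merged$score[last], nh$score[i])
      } else {
        merged <- rbind(merged, nh[i, , drop = FALSE])
      }
    }
    nh <- merged

    ch <- if (is.null(c_hits)) NULL else {
      x <- c_hits[c_hits$protein_id == pid, , drop = FALSE]
      x[order(x$start), , drop = FALSE]
    }
    used_c <- integer()
    for (i in seq_len(nrow(nh))) {
      cd <- NULL
      if (!is.null(ch) && nrow(ch)) {
        next_n <- if (i < nrow(nh)) nh$start[i + 1L] else nchar(seqs[[pid]]) + 1L
        cand <- which(ch$start > nh$end[i] & ch$end < next_n &
                        !(seq_len(nrow(ch)) %in% used_c))
        if (length(cand)) {
          j <- cand[which.min(ch$start[cand])]   # nearest downstream partner
          used_c <- c(used_c, j)
          cd <- c(ch$start[j], ch$end[j])
        }
      }
      dstart <- nh$start[i]
      dend <- if (is.null(cd)) nh$end[i] else cd[2]
      out[[length(out) + 1L]] <- domain_hit(
        protein_id = pid, domain_index = i, start = dstart, end = dend,
        sequence = substr(seqs[[pid]], dstart, dend),
        subdomain_n = c(nh$start[i], nh$end[i]), subdomain_c = cd)
    }
  }
  out
}

#' Write extracted signatures to a TSV file
#'
#' @param signatures List of `active_site_signature` objects.
#' @param hits Optional list of matching `domain_hit` objects (same order)
#'   supplying coordinates; coordinates are reported 1-based.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_signatures_tsv <- function(signatures, path, hits = NULL) {
  df <- data.frame(
    domain_id = vapply(signatures, `[[`, "", "domain_id"),
    protein_id = if (is.null(hits)) NA_character_ else
      vapply(hits, `[[`, "", "protein_id"),
    domain_index = if (is.null(hits)) NA_integer_ else
      vapply(hits, `[[`, 1L, "domain_index"),
    start = if (is.null(hits)) NA_integer_ else vapply(hits, `[[`, 1L, "start"),
    end = if (is.null(hits)) NA_integer_ else vapply(hits, `[[`, 1L, "end"),
    extended_signature = vapply(signatures, `[[`, "", "extended"),
    stachelhaus_signature = vapply(signatures, `[[`, "", "stachelhaus"),
    gap_count = vapply(signatures, function(s) as.integer(s$gap_count), 1L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
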