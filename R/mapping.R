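#' Map reference scaffold positions onto a query A domain
#'
#' Aligns the query and the scaffold reference sequence to the same profile
#' and reads the residue correspondence off the shared alignment columns.
#' In `phmm` mode the scaffold's own profile HMM is used; in `guided` mode a
#' profile is built from a user-supplied guide alignment (e.g. one derived
#' externally from superposed structures) and both sequences are aligned to
#' it. Either way the mapping is a function from every reference position to
#' a query position or to gap.
#'
#' @param query Excised A-domain sequence (character string).
#' @param scaffold A [reference_scaffold()].
#' @param mode `"phmm"` (default) or `"guided"`.
#' @param profile Profile HMM path for `phmm` mode; defaults to
#'   `scaffold$profile`.
#' @param guide Aligned-FASTA path (or named character vector of aligned
#'   sequences) for `guided` mode.
#' @param min_score Minimum profile bit score for the query; below it an
#'   alignment-failure error (condition class `adomain_alignment_error`)
#'   carrying the score is raised. `NULL` disables the check.
#' @return Integer vector of length `nchar(reference_sequence)`: entry `i`
#'   is the 1-based query position aligned to reference position `i`, or
#'   `NA` for gap. Mapped positions are strictly increasing.
#' @export
map_reference_positions <- function(query, scaffold, mode = c("phmm", "guided"),
                                    profile = NULL, guide = NULL,
                                    min_score = NULL) {
  mode <- match.arg(mode)
  if (!inherits(scaffold, "reference_scaffold"))
    stop("scaffold must be a reference_scaffold", call. = FALSE)
  query <- toupper(query)
  if (mode == "phmm") {
    if (is.null(profile)) profile <- scaffold$profile
    if (is.null(profile))
      stop("phmm mode needs a profile (argument or scaffold$profile)",
           call. = FALSE)
  } else {
    if (is.null(guide))
      stop("guided mode needs a guide alignment", call. = FALSE)
    profile <- tempfile(fileext = ".hmm")
    on.exit(unlink(profile))
    if (is.character(guide) && length(guide) == 1L && file.exists(guide)) {
      aln <- Biostrings::readAAStringSet(guide)
      guide <- stats::setNames(as.character(aln), names(aln))
    }
    build_profile(guide, profile, name = "guide")
  }
  if (!is.null(min_score)) {
    sc <- profile_score(profile, query)
    if (is.na(sc) || sc < min_score) {
      cond <- structure(class = c("adomain_alignment_error", "error", "condition"),
                        list(message = sprintf(
                          "query does not align to the profile (score %s < %s)",
                          ifelse(is.na(sc), "none", format(sc)), format(min_score)),
                          call = sys.call(-1), score = sc))
      stop(cond)
    }
  }
  aln <- run_hmmalign(profile, c(.ref = scaffold$reference_sequence,
                                 .query = query))
  r <- aln[[".ref"]]
  q <- aln[[".query"]]
  is_res <- function(x) x %in% c(LETTERS, letters)
  rpos <- cumsum(is_res(r))
  qpos <- cumsum(is_res(q))
  cols <- which(is_res(r))
  map <- ifelse(is_res(q)[cols], qpos[cols], NA_integer_)
  as.integer(map)
}

#' Extract active-site signatures from an A domain
#'
#' Reads the query residues at the scaffold's 34 extended and 10
#' Stachelhaus positions through the reference position map. Positions the
#' query does not cover become `-`. Ambiguous residues (X, B, Z, U) are
#' recorded verbatim (they featurise as gaps downstream).
#'
#' @param domain A [domain_hit()] or a plain character sequence.
#' @param scaffold A [reference_scaffold()].
#' @param mode,profile,guide,min_score Passed to
#'   [map_reference_positions()].
#' @param domain_id Identifier used when `domain` is a bare sequence.
#' @param min_length Minimum domain length (amino acids); shorter input is
#'   rejected (default 100).
#' @return An [active_site_signature()].
#' @export
extract_signature <- function(domain, scaffold, mode = c("phmm", "guided"),
                              profile = NULL, guide = NULL, min_score = NULL,
                              domain_id = "query", min_length = 100L) {
  mode <- match.arg(mode)
  if (inherits(domain, "domain_hit")) {
    domain_id <- domain$domain_id
    seqstr <- domain$sequence
  } else if (is.character(domain) && length(domain) == 1L) {
    seqstr <- toupper(domain)
  } else stop("domain must be a domain_hit or a sequence string", call. = FALSE)
  if (nchar(seqstr) < min_length)
    stop("domain too short for signature extraction (", nchar(seqstr),
         " aa < ", min_length, ")", call. = FALSE)
  map <- map_reference_positions(seqstr, scaffold, mode = mode,
                                 profile = profile, guide = guide,
                                 min_score = min_score)
  pick <- function(positions) {
    qp <- map[positions]
    res <- vapply(qp, function(p) if (is.na(p)) "-" else substr(seqstr, p, p), "")
    paste(res, collapse = "")
  }
  active_site_signature(domain_id,
                        extended = pick(scaffold$extended_positions),
                        stachelhaus = pick(scaffold$stachelhaus_positions))
}

#' Extract signatures for a batch of domains
#'
#' Batched variant of [extract_signature()]: one profile alignment call for
#' all domains rather than one per domain.
#'
#' @param domains List of [domain_hit()] objects.
#' @inheritParams extract_signature
#' @return List of [active_site_signature()] objects, one per domain.
#' @export
extract_signatures <- function(domains, scaffold, mode = c("phmm", "guided"),
                               profile = NULL, guide = NULL, min_score = NULL,
                               min_length = 100L) {
  mode <- match.arg(mode)
  if (!length(domains)) return(list())
  if (mode == "phmm" && is.null(profile)) profile <- scaffold$profile
  short <- vapply(domains, function(d) nchar(d$sequence) < min_length, TRUE)
  if (any(short))
    stop("domain(s) too short for signature extraction: ",
         paste(vapply(domains[short], `[[`, "", "domain_id"), collapse = ", "),
         call. = FALSE)
  if (mode == "guided") {
    return(lapply(domains, extract_signature, scaffold = scaffold,
                  mode = "guided", guide = guide, min_score = min_score,
                  min_length = min_length))
  }
  seqs <- c(.ref = scaffold$reference_sequence,
            stats::setNames(vapply(domains, `[[`, "", "sequence"),
                            vapply(domains, `[[`, "", "domain_id")))
  if (!is.null(min_score)) {
    for (d in domains) {
      sc <- profile_score(profile, d$sequence)
      if (is.na(sc) || sc < min_score)
        stop(sprintf("domain %s does not align to the profile (score %s)",
                     d$domain_id, ifelse(is.na(sc), "none", format(sc))),
             call. = FALSE)
    }
  }
  aln <- run_hmmalign(profile, seqs)
  is_res <- function(x) x %in% c(LETTERS, letters)
  r <- aln[[".ref"]]
  rpos <- cumsum(is_res(r))
  cols <- which(is_res(r))
  lapply(domains, function(d) {
    q <- aln[[d$domain_id]]
    qpos <- cumsum(is_res(q))
    map <- ifelse(is_res(q)[cols], qpos[cols], NA_integer_)
    pick <- function(positions) {
      qp <- map[positions]
      res <- vapply(qp, function(p) if (is.na(p)) "-" else
        substr(d$sequence, p, p), "")
      paste(res, collapse = "")
    }
    active_site_signature(d$domain_id,
                          extended = pick(scaffold$extended_positions),
                          stachelhaus = pick(scaffold$stachelhaus_positions))
  })
}
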