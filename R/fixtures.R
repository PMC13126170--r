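# Synthetic fixtures with recorded ground truth. The generator emulates the
# shape of real inputs end to end: scaffold proteins with an extractable
# A-domain region, signature residues that deterministically (plus
# configurable noise) encode a substrate, family-level taxonomy, a small
# library of genuine amino-acid SMILES, and toy PDB structures.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Build a synthetic reference scaffold with profile models
#'
#' Generates a ~450-residue A-domain-like sequence with 34 designated
#' extended-signature positions in the N-terminal subdomain and a
#' 10-position Stachelhaus subset whose terminal lysine sits in the
#' C-terminal subdomain, then builds profile HMMs (full-length,
#' N-subdomain, C-subdomain) from seeded mutants of it so that detection
#' and extraction run without any external profile downloads. Everything
#' is synthetic: the scaffold stands in for the GrsA-style reference used
#' on real data.
#'
#' @param seed Integer seed; the same seed reproduces the scaffold
#'   exactly.
#' @param dir Directory for the profile files (default: a fresh temporary
#'   directory).
#' @param length Scaffold length (default 450).
#' @return Object of class `fixture_scaffold`: `scaffold` (a
#'   [reference_scaffold()] with the full-length profile attached),
#'   `detectors` (an [a_domain_detectors()] over the subdomain profiles),
#'   `n_region`/`c_region` coordinate pairs and `dir`.
#' @export
make_scaffold <- function(seed, dir = tempfile("scaffold"), length = 450L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_region <- c(1L, 340L)
  c_region <- c(355L, length)
  res <- with_seed(seed, {
    chars <- sample(AA_LETTERS, length, replace = TRUE)
    ext <- sort(sample(60:320, 34L))
    stach <- c(ext[c(2L, 5L, 8L, 11L, 14L, 18L, 22L, 26L, 30L)],
               c_region[1] + 20L)            # terminal lysine, C-subdomain
    chars[stach[10]] <- "K"
    mutants <- vapply(1:12, function(i) {
      m <- chars
      pos <- sample(setdiff(seq_len(length), c(ext, stach)), round(length * 0.1))
      m[pos] <- sample(AA_LETTERS, base::length(pos), replace = TRUE)
      paste(m, collapse = "")
    }, "")
    list(chars = chars, ext = ext, stach = stach, mutants = mutants)
  })
  seqstr <- paste(res$chars, collapse = "")
  fam <- stats::setNames(c(seqstr, res$mutants), c("ref", sprintf("m%02d", 1:12)))
  full_hmm <- file.path(dir, "full.hmm")
  n_hmm <- file.path(dir, "n_subdomain.hmm")
  c_hmm <- file.path(dir, "c_subdomain.hmm")
  build_profile(fam, full_hmm, name = "adomain_full")
  build_profile(substr(fam, n_region[1], n_region[2]), n_hmm, name = "adomain_n")
  build_profile(substr(fam, c_region[1], c_region[2]), c_hmm, name = "adomain_c")
  scaffold <- reference_scaffold("SYN_REF", seqstr, res$ext, res$stach,
                                 profile = full_hmm)
  structure(list(scaffold = scaffold,
                 detectors = a_domain_detectors(n_hmm, c_hmm, bitscore = 25),
                 n_region = n_region, c_region = c_region,
                 dir = dir, seed = seed),
            class = "fixture_scaffold")
}

#' Fixture specification
#'
#' Bundles the knobs of the synthetic dataset generator. Classes are
#' encoded at two determinant positions of the extended signature: each
#' class owns a distinct residue pair, and a domain's signature carries its
#' class's pair unless noise flips it to a random class's pair (label
#' unchanged), so `noise_rate = 0` gives a perfectly separable dataset and
#' `noise_rate = 1` destroys the signature-label link entirely.
#'
#' @param n_domains Number of domains (default 200).
#' @param n_substrate_classes Number of substrate classes (2-8, default 4).
#' @param noise_rate Probability a domain's signature violates its class
#'   rule (default 0).
#' @param promiscuity_rate Fraction of domains given a second major
#'   substrate (default 0).
#' @param n_families Number of taxonomic families (default 8).
#' @param determinants Positions (1-34) of the two determinant residues in
#'   the extended signature (default 7 and 17).
#' @param seed Integer seed.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_domains = 200L, n_substrate_classes = 4L,
                         noise_rate = 0, promiscuity_rate = 0,
                         n_families = 8L, determinants = c(7L, 17L),
                         seed = 1L) {
  if (noise_rate < 0 || noise_rate > 1 || promiscuity_rate < 0 ||
      promiscuity_rate > 1)
    stop("noise_rate and promiscuity_rate must lie in [0, 1]", call. = FALSE)
  if (n_substrate_classes < 2L || n_substrate_classes > 8L)
    stop("n_substrate_classes must be between 2 and 8", call. = FALSE)
  if (length(determinants) != 2L || any(determinants < 1L | determinants > 34L))
    stop("determinants must be two positions in 1..34", call. = FALSE)
  structure(list(n_domains = as.integer(n_domains),
                 n_substrate_classes = as.integer(n_substrate_classes),
                 noise_rate = noise_rate, promiscuity_rate = promiscuity_rate,
                 n_families = as.integer(n_families),
                 determinants = as.integer(determinants),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

fixture_substrate_table <- function() {
  utils::read.table(system.file("extdata", "substrate_library.tsv",
                                package = "adomain"),
                    header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, quote = "")
}

# residue pairs available to encode classes at the two determinant positions
CLASS_RESIDUES <- rbind(c("D", "W"), c("A", "F"), c("S", "C"), c("L", "H"),
                        c("F", "E"), c("E", "M"), c("K", "Y"), c("G", "N"))

#' Generate a synthetic specificity dataset with known ground truth
#'
#' Each domain is a copy of the scaffold whose extended-signature positions
#' are randomised except the two determinant positions, which carry the
#' residue pair of the domain's substrate class (scrambled to a random
#' class's pair with probability `noise_rate`); 5% of non-signature
#' positions are mutated for realism. Substrates are drawn from the
#' bundled library of genuine amino-acid SMILES. Proteins embed each
#' domain between random flanking sequence so detection fixtures have
#' recorded true coordinates. Regenerating with the same spec is
#' byte-identical.
#'
#' @param spec A [fixture_spec()].
#' @param scaffold_fixture A [make_scaffold()] result.
#' @param dir Optional directory; when given, writes `proteins.fasta`,
#'   `dataset.tsv`, `substrates.tsv` and `manifest.tsv` there.
#' @param features Compute the 510-length signature feature matrix into
#'   the dataset (default TRUE).
#' @return Object of class `fixture_dataset`: `dataset` (a
#'   [specificity_dataset()] with signatures and features), `proteins`
#'   (list of [protein_record()]s with one embedded domain each),
#'   `substrates` (name/SMILES data.frame for the classes in use),
#'   `manifest` (per-domain ground truth: class, substrates, family,
#'   determinant residues, true embedding coordinates) and `spec`.
#' @export
make_dataset <- function(spec, scaffold_fixture, dir = NULL, features = TRUE) {
  stopifnot(inherits(spec, "fixture_spec"),
            inherits(scaffold_fixture, "fixture_scaffold"))
  sc <- scaffold_fixture$scaffold
  subs <- fixture_substrate_table()
  k <- spec$n_substrate_classes
  classes <- subs$name[seq_len(k)]
  pairs <- CLASS_RESIDUES[seq_len(k), , drop = FALSE]
  ref_chars <- strsplit(sc$reference_sequence, "")[[1]]
  ext <- sc$extended_positions
  det_pos <- ext[spec$determinants]
  gen <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_domains), function(i) {
      cls <- sample.int(k, 1L)
      chars <- ref_chars
      # randomise the non-determinant signature positions
      rand_pos <- setdiff(ext, det_pos)
      chars[rand_pos] <- sample(AA_LETTERS, length(rand_pos), replace = TRUE)
      shown <- if (stats::runif(1) < spec$noise_rate) sample.int(k, 1L) else cls
      chars[det_pos] <- pairs[shown, ]
      # light mutation away from the signature keeps profiles matching
      mut <- sample(setdiff(seq_along(chars), c(ext, sc$stachelhaus_positions)),
                    round(length(chars) * 0.05))
      chars[mut] <- sample(AA_LETTERS, length(mut), replace = TRUE)
      domain_seq <- paste(chars, collapse = "")
      labels <- classes[cls]
      if (stats::runif(1) < spec$promiscuity_rate)
        labels <- c(labels, sample(classes[-cls], 1L))
      flank_n <- paste(sample(AA_LETTERS, sample(20:60, 1L), replace = TRUE),
                       collapse = "")
      flank_c <- paste(sample(AA_LETTERS, sample(20:60, 1L), replace = TRUE),
                       collapse = "")
      list(class = cls, labels = labels, domain_seq = domain_seq,
           flank_n = flank_n, flank_c = flank_c,
           family = sprintf("fam%02d", sample.int(spec$n_families, 1L)),
           kingdom = if (stats::runif(1) < 0.85) "Bacteria" else "Fungi")
    })
  })
  ids <- sprintf("SYN%04d.A1", seq_along(gen))
  protein_ids <- sprintf("SYN%04d", seq_along(gen))
  signatures <- vapply(gen, function(g)
    paste(strsplit(g$domain_seq, "")[[1]][ext], collapse = ""), "")
  taxonomy <- data.frame(
    kingdom = vapply(gen, `[[`, "", "kingdom"),
    phylum = "SynPhylum", class = "SynClass", order = "SynOrder",
    family = vapply(gen, `[[`, "", "family"))
  feats <- if (features)
    featurise_signatures(stats::setNames(as.list(signatures), ids)) else NULL
  dataset <- specificity_dataset(
    ids, lapply(gen, `[[`, "labels"), taxonomy = taxonomy,
    features = feats, signatures = signatures,
    protein_id = protein_ids, domain_index = rep(1L, length(gen)),
    evidence = rep("synthetic", length(gen)))
  proteins <- lapply(seq_along(gen), function(i) {
    g <- gen[[i]]
    protein_record(protein_ids[i],
                   paste0(g$flank_n, g$domain_seq, g$flank_c))
  })
  manifest <- data.frame(
    domain_id = ids, protein_id = protein_ids,
    class = classes[vapply(gen, `[[`, 1L, "class")],
    substrates = vapply(gen, function(g) paste(g$labels, collapse = "|"), ""),
    family = taxonomy$family, kingdom = taxonomy$kingdom,
    true_start = vapply(gen, function(g) nchar(g$flank_n) + 1L, 1L),
    true_end = vapply(gen, function(g)
      nchar(g$flank_n) + nchar(g$domain_seq), 1L),
    determinant_positions = paste(spec$determinants, collapse = "|"),
    determinant_residues = vapply(gen, function(g)
      paste(strsplit(g$domain_seq, "")[[1]][det_pos], collapse = ""), ""))
  out <- structure(list(dataset = dataset, proteins = proteins,
                        substrates = subs[seq_len(k), ],
                        manifest = manifest, spec = spec),
                   class = "fixture_dataset")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(stats::setNames(vapply(proteins, `[[`, "", "sequence"),
                                protein_ids),
                file.path(dir, "proteins.fasta"))
    write_dataset(dataset, file.path(dir, "dataset.tsv"))
    utils::write.table(out$substrates, file.path(dir, "substrates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Write a toy PDB structure at exact coordinates
#'
#' Emits syntactically valid ATOM records for the given placements, so
#' voxelisation fixtures can put atoms at known grid coordinates.
#'
#' @param placements Data.frame with columns `x`, `y`, `z`, `elesy`
#'   (element symbol) and optionally `resid` (3-letter residue, default
#'   `ALA`) and `elety` (atom name, default the element symbol).
#' @param path Optional output file; when `NULL` the PDB text lines are
#'   returned.
#' @return The PDB lines (invisibly when written to `path`).
#' @export
make_toy_structure <- function(placements, path = NULL) {
  stopifnot(all(c("x", "y", "z", "elesy") %in% names(placements)))
  n <- nrow(placements)
  resid <- if ("resid" %in% names(placements)) placements$resid else rep("ALA", n)
  elety <- if ("elety" %in% names(placements)) placements$elety
    else placements$elesy
  lines <- vapply(seq_len(n), function(i) {
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, substr(elety[i], 1, 4), substr(resid[i], 1, 3), i,
            placements$x[i], placements$y[i], placements$z[i],
            placements$elesy[i])
  }, "")
  lines <- c(lines, "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
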