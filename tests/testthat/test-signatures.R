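test_that("signature match counting follows the aligned-identity rule", {
  # the two divergent tryptophan-activating signatures share 3 residues
  expect_equal(signature_matches("DAWTVTGVGK", "DPTQAGEVVK"), 3)
  expect_equal(signature_matches("DAWTIAAICK", "DAWTIAAICK"), 10)
  expect_equal(signature_matches("DAWTVTGVGK", "----------"), 0)
  # aligned gap pairs never count as matches
  expect_equal(signature_matches("D-WT", "D-WT"), 3)
  expect_error(signature_matches("DAWT", "DAW"), "length mismatch")
})

test_that("self-alignment maps every reference position to itself", {
  sc <- fix_scaffold()$scaffold
  map <- map_reference_positions(sc$reference_sequence, sc)
  expect_identical(map, seq_len(nchar(sc$reference_sequence)))
})

test_that("signature extraction recovers planted residues and survives indels", {
  sc <- fix_scaffold()$scaffold
  ref <- sc$reference_sequence
  chars <- strsplit(ref, "")[[1]]
  truth <- paste(chars[sc$extended_positions], collapse = "")

  sig <- extract_signature(ref, sc)
  expect_equal(sig$extended, truth)
  expect_equal(sig$gap_count, 0L)
  expect_equal(nchar(sig$stachelhaus), 10L)

  # 5-residue insertion between two signature positions: all 34 recovered
  at <- sc$extended_positions[10] + 2L
  q_ins <- paste0(substr(ref, 1, at), "GGGGG", substr(ref, at + 1, nchar(ref)))
  sig_ins <- extract_signature(q_ins, sc)
  expect_equal(sig_ins$extended, truth)
  expect_equal(sig_ins$extended, oracle_signature(q_ins, sc))

  # deleting one signature residue gaps that position, leaves the rest
  del <- sc$extended_positions[5]
  q_del <- paste0(substr(ref, 1, del - 1L), substr(ref, del + 1L, nchar(ref)))
  sig_del <- extract_signature(q_del, sc)
  expect_equal(substr(sig_del$extended, 5, 5), "-")
  expect_equal(signature_matches(sig_del$extended, truth), 33)
  expect_equal(sig_del$extended, oracle_signature(q_del, sc))
})

test_that("signatures are robust to random edits away from signature positions", {
  sc <- fix_scaffold()$scaffold
  ref <- sc$reference_sequence
  truth <- paste(strsplit(ref, "")[[1]][sc$extended_positions], collapse = "")
  guarded <- sort(unique(c(sc$extended_positions, sc$stachelhaus_positions)))
  set.seed(99)
  for (rep in 1:5) {
    chars <- strsplit(ref, "")[[1]]
    # up to 10 random substitutions plus a short indel, never at signatures
    sub_at <- sample(setdiff(seq_along(chars), guarded), sample(3:10, 1))
    chars[sub_at] <- sample(c("A", "G", "L", "S", "T"), length(sub_at),
                            replace = TRUE)
    q <- paste(chars, collapse = "")
    free <- setdiff(50:300, c(guarded, guarded - 1L))
    cut <- sample(free, 1)
    q <- if (rep %% 2 == 0)
      paste0(substr(q, 1, cut), "AGS", substr(q, cut + 1, nchar(q)))
    else q
    sig <- extract_signature(q, sc)
    expect_equal(sig$extended, truth, label = sprintf("edit replicate %d", rep))
    expect_equal(sig$extended, oracle_signature(q, sc))
  }
})

test_that("guided mode from a guide alignment matches phmm mode on the reference", {
  sf <- fix_scaffold()
  sc <- sf$scaffold
  # guide: the scaffold family itself (mutants are substitution-only, so the
  # ungapped family is a valid alignment)
  set.seed(5)
  chars <- strsplit(sc$reference_sequence, "")[[1]]
  guarded <- c(sc$extended_positions, sc$stachelhaus_positions)
  guide <- c(ref = sc$reference_sequence,
             vapply(1:6, function(i) {
               m <- chars
               at <- sample(setdiff(seq_along(m), guarded), 40)
               m[at] <- sample(c("A", "C", "D", "E", "F", "G"), 40, replace = TRUE)
               paste(m, collapse = "")
             }, ""))
  names(guide) <- c("ref", sprintf("g%d", 1:6))
  s_phmm <- extract_signature(sc$reference_sequence, sc, mode = "phmm")
  s_guided <- extract_signature(sc$reference_sequence, sc, mode = "guided",
                                guide = guide)
  expect_equal(s_guided$extended, s_phmm$extended)
  expect_equal(s_guided$stachelhaus, s_phmm$stachelhaus)
})

test_that("extraction from an excised hit equals extraction from the full protein", {
  sf <- fix_scaffold()
  sc <- sf$scaffold
  p <- protein_record("IDEM1", paste0(random_protein(45, seed = 8),
                                      sc$reference_sequence,
                                      random_protein(35)))
  hits <- detect_a_domains(p, sf$detectors)
  expect_length(hits, 1L)
  from_hit <- extract_signature(hits[[1]], sc)
  from_excision <- extract_signature(hits[[1]]$sequence, sc,
                                     domain_id = hits[[1]]$domain_id)
  expect_equal(from_hit$extended, from_excision$extended)
  expect_equal(from_hit$stachelhaus, from_excision$stachelhaus)
})

test_that("degenerate inputs keep the 34/10 length invariants or fail loudly", {
  sc <- fix_scaffold()$scaffold
  expect_error(extract_signature(substr(sc$reference_sequence, 1, 80), sc),
               "too short")
  # ambiguous residues are recorded verbatim
  chars <- strsplit(sc$reference_sequence, "")[[1]]
  chars[sc$extended_positions[3]] <- "X"
  sig <- extract_signature(paste(chars, collapse = ""), sc)
  expect_equal(substr(sig$extended, 3, 3), "X")
  expect_equal(nchar(sig$extended), 34L)
  # a heavily truncated but >100 aa fragment still yields full-length strings
  frag <- substr(sc$reference_sequence, 1, 150)
  sig2 <- extract_signature(frag, sc)
  expect_equal(nchar(sig2$extended), 34L)
  expect_equal(nchar(sig2$stachelhaus), 10L)
  expect_gt(sig2$gap_count, 0L)
})

test_that("alignment failure carries the profile score", {
  sc <- fix_scaffold()$scaffold
  junk <- paste(rep("GAGAGAGAGS", 15), collapse = "")
  err <- tryCatch(
    map_reference_positions(junk, sc, min_score = 1e6),
    adomain_alignment_error = function(e) e)
  expect_s3_class(err, "adomain_alignment_error")
  expect_true(is.numeric(err$score) || is.na(err$score))
})

test_that("scaffold configuration is validated", {
  expect_error(reference_scaffold("r", "ACDEFGHIKL", 1:34, 1:10),
               "within the reference")
  seq450 <- paste(rep("ACDEFGHIKL", 45), collapse = "")
  expect_error(reference_scaffold("r", seq450, c(2:34, 20), c(1:9, 400)),
               "strictly increasing")
  # terminal lysine may break monotonicity as the last element
  sc <- reference_scaffold("r", seq450, seq(10, 340, 10), c(seq(10, 90, 10), 50))
  expect_s3_class(sc, "reference_scaffold")
  scaffold_tsv <- tempfile(fileext = ".tsv")
  write_scaffold(sc, scaffold_tsv)
  sc2 <- read_scaffold(scaffold_tsv)
  expect_equal(sc2$extended_positions, sc$extended_positions)
  expect_equal(sc2$reference_sequence, sc$reference_sequence)
})
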