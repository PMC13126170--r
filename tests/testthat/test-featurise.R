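test_that("the property table is normalised to [0,1] with exact extremes", {
  tab <- default_property_table()
  expect_length(tab$properties, 15L)
  expect_equal(dim(tab$values), c(20L, 15L))
  expect_equal(unname(apply(tab$values, 2, min)), rep(0, 15))
  expect_equal(unname(apply(tab$values, 2, max)), rep(1, 15))
  expect_equal(unname(tab$gap_vector), rep(0, 15))
  # custom tables are validated
  bad <- data.frame(aa = c(LETTERS[1:20]), m = 1:20)
  expect_error(property_table(bad), "15 property columns")
})

test_that("signature featurisation tiles per-residue property vectors", {
  tab <- default_property_table()
  sig <- paste(rep("A", 34), collapse = "")
  v <- featurise_signature(sig, tab)
  expect_length(v, 510L)
  expect_equal(v, rep(unname(tab$values["A", ]), 34))
  expect_true(all(v >= 0 & v <= 1))
  # gaps and ambiguity codes featurise as zeros
  expect_equal(featurise_signature(paste(rep("-", 34), collapse = "")),
               rep(0, 510))
  mixed <- paste0("X", paste(rep("A", 33), collapse = ""))
  expect_equal(featurise_signature(mixed, tab)[1:15], rep(0, 15))
  m <- featurise_signatures(list(a = sig, b = mixed), tab)
  expect_equal(dim(m), c(2L, 510L))
  expect_equal(rownames(m), c("a", "b"))
})

test_that("ECFP-4 fingerprints are 1024-bit, non-trivial and spelling-invariant", {
  f <- compute_fingerprint("NCC(=O)O")        # glycine
  expect_length(f, 1024L)
  expect_gt(sum(f), 0)
  expect_true(all(f %in% 0:1))
  expect_identical(compute_fingerprint("OC(=O)CN"), f)
  # same molecule, very different isomeric spellings
  trp_a <- "C1=CC=C2C(=C1)C(=CN2)C[C@@H](C(=O)O)N"
  trp_b <- "N[C@@H](Cc1c[nH]c2ccccc12)C(=O)O"
  expect_identical(compute_fingerprint(trp_b), compute_fingerprint(trp_a))
  expect_error(compute_fingerprint("not_a_smiles"), "not_a_smiles")
})

test_that("substrate libraries validate names and batch fingerprints", {
  lib <- fix_library()
  expect_equal(nrow(lib$fp_matrix), 4L)
  expect_equal(ncol(lib$fp_matrix), 1024L)
  expect_error(substrate_library(c("Trp", "trp"),
                                 c("NCC(=O)O", "NCC(=O)O")),
               "unique")
  expect_error(substrate_library("bad", "xxxx##"), "unparseable")
})

test_that("voxelisation places atoms in hand-computed voxel/channel slots", {
  g <- voxel_grid(center = c(0, 0, 0), edge = 16, n = 20)
  expect_length(voxelise_structure(data.frame(), g), 56000L)
  expect_equal(sum(voxelise_structure(data.frame(), g)), 0L)

  # an aromatic carbon just past the centre lands in voxel (10,10,10):
  # flat voxel index 10 + 20*10 + 400*10 = 4210; aromatic channel = slot 1
  atoms <- data.frame(x = 0.1, y = 0.1, z = 0.1, elety = "CG", resid = "PHE",
                      elesy = "C")
  v <- voxelise_structure(atoms, g)
  expect_equal(which(v > 0), 4210L * 7L + 1L)
  expect_equal(sum(v), 1L)

  # two atoms in the same voxel, distinct channels within its 7-slot block
  atoms2 <- rbind(atoms,
                  data.frame(x = 0.2, y = 0.2, z = 0.2, elety = "O",
                             resid = "SER", elesy = "O"),
                  data.frame(x = 0.2, y = 0.1, z = 0.3, elety = "SD",
                             resid = "MET", elesy = "S"))
  v2 <- voxelise_structure(atoms2, g)
  nz <- which(v2 > 0)
  expect_equal(nz, 4210L * 7L + c(1L, 4L, 7L))   # aromatic, nonchg O, S
  expect_equal(sum(v2), 3L)

  # boundary atoms go to the lower-index voxel: x = 0 is the start of voxel 10
  vb <- voxelise_structure(data.frame(x = 0, y = 0, z = 0, elety = "C",
                                      resid = "GLY", elesy = "C"), g)
  expect_equal(which(vb > 0), 4210L * 7L + 2L)
})

test_that("voxel counts are conserved against a naive double-loop oracle", {
  g <- voxel_grid(center = c(1, -2, 0.5), edge = 10, n = 5)
  set.seed(17)
  for (rep in 1:3) {
    atoms <- data.frame(
      x = runif(60, -6, 8), y = runif(60, -9, 5), z = runif(60, -5, 6),
      elety = sample(c("C", "N", "O", "SD", "NZ"), 60, replace = TRUE),
      resid = sample(c("ALA", "LYS", "MET", "SER"), 60, replace = TRUE),
      elesy = "")
    atoms$elesy <- substr(gsub("[0-9]", "", atoms$elety), 1, 1)
    v <- voxelise_structure(atoms, g)
    # oracle: per-atom loop with independent in-grid / channel logic
    w <- g$edge / g$n
    lo <- g$center - g$edge / 2
    n_in <- 0L
    for (i in seq_len(nrow(atoms))) {
      p <- as.numeric(atoms[i, c("x", "y", "z")])
      ix <- floor((p - lo) / w)
      if (all(ix >= 0 & ix < g$n)) n_in <- n_in + 1L
    }
    expect_equal(sum(v), n_in)
    expect_true(all(v >= 0))
  }
})

test_that("pocket PCA keeps knee-selected components per group plus the full set", {
  set.seed(23)
  base <- matrix(rpois(40 * 30, 2), 40)
  shift <- matrix(0, 40, 30); shift[21:40, 1:5] <- 6
  vecs <- base + shift
  asg <- rep(c("small", "aromatic"), each = 20)
  m <- fit_pocket_pca(vecs, asg)
  retained <- vapply(m$projections, `[[`, 1L, "retained")
  expect_named(retained, c("aromatic", "small", "ALL"))
  expect_equal(m$total_components, sum(retained))       # bookkeeping identity
  s <- apply_pocket_pca(m, vecs[1, ])
  expect_length(s, m$total_components)
  expect_true(all(is.finite(s)))
  # centering: the group's mean projects to zero on its own components
  mu <- colMeans(vecs[asg == "small", ])
  s_mu <- apply_pocket_pca(m, mu)
  expect_equal(unname(s_mu[startsWith(names(s_mu), "small_")]),
               rep(0, retained["small"]), tolerance = 1e-9)
  # linearity: doubling a centred input doubles every score
  call <- m$projections$ALL$center
  s1 <- apply_pocket_pca(m, call + (vecs[3, ] - call))
  s2 <- apply_pocket_pca(m, call + 2 * (vecs[3, ] - call))
  all_idx <- startsWith(names(s1), "ALL_")
  expect_equal(unname(s2[all_idx]), 2 * unname(s1[all_idx]), tolerance = 1e-9)
})

test_that("degenerate PCA groups collapse to one component", {
  set.seed(29)
  vecs <- rbind(matrix(1, 4, 12), matrix(rnorm(8 * 12), 8))
  asg <- c(rep("flat", 4), rep("varied", 8))
  expect_warning(m <- fit_pocket_pca(rbind(vecs, matrix(0, 1, 12)),
                                     c(asg, "lonely")),
                 "fewer than 2")
  expect_false("lonely" %in% names(m$projections))
  expect_equal(m$projections$flat$retained, 1L)
  expect_equal(m$projections$flat$explained[1], 1, tolerance = 1e-9)
  # two-cluster group: PC1 separates the clusters deterministically
  cl <- rbind(matrix(rnorm(10 * 12, 0, 0.1), 10),
              matrix(rnorm(10 * 12, 4, 0.1), 10))
  m2 <- fit_pocket_pca(cl, rep("two", 20))
  sc <- apply_pocket_pca(m2, cl)
  pc1 <- sc[, "two_PC1"]
  expect_true(all(sign(pc1[1:10]) == sign(pc1[1])))
  expect_true(all(sign(pc1[11:20]) == -sign(pc1[1])))
})
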