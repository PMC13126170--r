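#' Amino-acid property table
#'
#' Validates and normalises a table of per-residue physicochemical
#' properties. Each of the 15 property columns is min-max normalised so
#' that, across the 20 canonical amino acids, its minimum is exactly 0 and
#' its maximum exactly 1. Gaps (and ambiguous residues X/B/Z/U) featurise
#' as the all-zero vector.
#'
#' @param values A data.frame with a character column `aa` holding the 20
#'   canonical amino-acid letters and 15 numeric property columns.
#' @return An object of class `property_table`: list with `properties`
#'   (column names), `values` (20 x 15 normalised matrix, rownames = amino
#'   acids) and `gap_vector` (15 zeros).
#' @seealso [default_property_table()]
#' @export
property_table <- function(values) {
  if (!is.data.frame(values) || !"aa" %in% names(values))
    stop("values must be a data.frame with an 'aa' column", call. = FALSE)
  props <- setdiff(names(values), "aa")
  if (length(props) != 15L)
    stop("exactly 15 property columns are required, got ", length(props),
         call. = FALSE)
  if (!setequal(values$aa, AA_LETTERS) || nrow(values) != 20L)
    stop("the 'aa' column must hold each of the 20 canonical amino acids once",
         call. = FALSE)
  m <- as.matrix(values[props])
  if (!is.numeric(m) || anyNA(m))
    stop("property columns must be numeric and complete", call. = FALSE)
  rownames(m) <- values$aa
  m <- m[AA_LETTERS, , drop = FALSE]
  rng <- apply(m, 2L, range)
  if (any(rng[2, ] - rng[1, ] == 0))
    stop("constant property column cannot be normalised", call. = FALSE)
  m <- sweep(sweep(m, 2L, rng[1, ]), 2L, rng[2, ] - rng[1, ], "/")
  structure(list(properties = props, values = m,
                 gap_vector = stats::setNames(rep(0, 15L), props)),
            class = "property_table")
}

#' The bundled 15-property table
#'
#' Loads the packaged table of 15 physicochemical properties per amino
#' acid: hydrophobicity (WOLS870101 plus three hydrophobicity slots filled
#' with Kyte-Doolittle, Hopp-Woods and Eisenberg scales as documented
#' stand-ins), size (WOLS870102, TSAJ990101), electronic state
#' (WOLS870103), hydrogen-bond donors (FAUJ880109), polarity (GRAR740102,
#' RADA880108, ZIMJ680103), secondary-structure propensities
#' (CHOP780201/02/03) and isoelectric point (ZIMJ680104). See the TSV at
#' `system.file("extdata", "aa_property_table.tsv", package = "adomain")`
#' for sources; supply your own table via [property_table()] to override.
#'
#' @return A `property_table`.
#' @export
default_property_table <- function() {
  path <- system.file("extdata", "aa_property_table.tsv", package = "adomain")
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  property_table(df)
}

#' Featurise an active-site signature
#'
#' Encodes the 34-residue extended signature as a numeric vector of length
#' 510: for each residue, its 15 normalised physicochemical property
#' values, residue-major (residue 1 properties 1-15, then residue 2, ...).
#' Gap and ambiguous positions contribute the all-zero gap vector.
#'
#' @param sig An [active_site_signature()] (or a bare 34-character string).
#' @param table A [property_table()]; the bundled default if omitted.
#' @return Numeric vector of length 510, values in `[0, 1]`.
#' @export
featurise_signature <- function(sig, table = default_property_table()) {
  if (inherits(sig, "active_site_signature")) sig <- sig$extended
  if (!is.character(sig) || length(sig) != 1L || nchar(sig) != 34L)
    stop("sig must be an active_site_signature or a 34-character string",
         call. = FALSE)
  if (!inherits(table, "property_table"))
    stop("table must be a property_table", call. = FALSE)
  letters34 <- strsplit(toupper(sig), "")[[1]]
  rows <- lapply(letters34, function(a) {
    if (a %in% AA_LETTERS) table$values[a, ] else table$gap_vector
  })
  v <- as.numeric(unlist(rows, use.names = FALSE))
  stopifnot(length(v) == 510L)
  v
}

#' Featurise many signatures into a matrix
#'
#' @param sigs List of signatures (or character vector of extended
#'   signature strings), optionally named by domain id.
#' @param table A [property_table()].
#' @return Numeric matrix, one row per signature, 510 columns named
#'   `res<i>_<property>`.
#' @export
featurise_signatures <- function(sigs, table = default_property_table()) {
  ids <- if (!is.null(names(sigs))) names(sigs) else
    vapply(seq_along(sigs), function(i) {
      s <- sigs[[i]]
      if (inherits(s, "active_site_signature")) s$domain_id else sprintf("sig%d", i)
    }, "")
  m <- t(vapply(sigs, featurise_signature, numeric(510L), table = table))
  rownames(m) <- ids
  colnames(m) <- sequence_feature_names(table)
  m
}

sequence_feature_names <- function(table = default_property_table()) {
  as.vector(t(outer(sprintf("res%02d", 1:34), table$properties, paste, sep = "_")))
}

# residue index (1..34) for each of the 510 sequence feature columns
residue_of_feature <- function(idx) ((as.integer(idx) - 1L) %/% 15L) + 1L
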