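# Dimensionality reduction of voxel features: one PCA per substrate
# category plus one over the full data set, each truncated at the knee of
# its scree curve, concatenated into a compact structural feature vector.

# Knee of a decreasing scree curve: the point with maximum perpendicular
# distance to the chord from the first to the last point (the kneedle
# idea). Always returns at least 1.
find_knee <- function(y) {
  k <- length(y)
  if (k <= 2L || diff(range(y)) == 0) return(1L)
  x <- seq_len(k)
  xn <- (x - 1) / (k - 1)
  yn <- (y - min(y)) / diff(range(y))
  # distance to the line through (0, yn[1]) and (1, yn[k])
  d <- abs((yn[k] - yn[1]) * xn - yn + yn[1]) / sqrt((yn[k] - yn[1])^2 + 1)
  max(1L, which.max(d))
}

#' Fit per-category principal components of pocket voxel features
#'
#' Runs one PCA per substrate category (data points whose substrates fall
#' in several categories join each of them) plus one PCA over all vectors.
#' Each projection keeps the number of components located at the knee of
#' its explained-variance scree curve. Applying every projection to a
#' voxel vector and concatenating the scores gives the structural feature
#' vector.
#'
#' @param vectors Numeric matrix (rows = domains) or list of voxel count
#'   vectors.
#' @param assignments List (one element per row) of category names for that
#'   data point, or a character vector for single-category points.
#' @param max_components Upper bound on components considered per group.
#' @return Object of class `pocket_pca`: per-group projections (center,
#'   rotation, retained count) for each non-empty group and the `ALL`
#'   group, plus `total_components`.
#' @export
fit_pocket_pca <- function(vectors, assignments, max_components = 20L) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  vectors <- as.matrix(vectors)
  if (is.character(assignments)) assignments <- as.list(assignments)
  if (length(assignments) != nrow(vectors))
    stop("one category assignment per data point is required", call. = FALSE)
  groups <- sort(unique(unlist(assignments)))
  members <- c(lapply(groups, function(g)
    which(vapply(assignments, function(a) g %in% a, TRUE))),
    list(seq_len(nrow(vectors))))
  names(members) <- c(groups, "ALL")
  projections <- list()
  for (g in names(members)) {
    idx <- members[[g]]
    if (length(idx) < 2L) {
      warning("category '", g, "' has fewer than 2 members; skipped")
      next
    }
    sub <- vectors[idx, , drop = FALSE]
    keep_cols <- which(apply(sub, 2L, stats::sd) > 0)
    ncomp <- min(max_components, length(idx) - 1L, max(1L, length(keep_cols)))
    if (!length(keep_cols)) {
      # all vectors in the group identical: degenerate single component
      projections[[g]] <- list(center = colMeans(sub),
                               rotation = matrix(0, ncol(sub), 1L),
                               sdev = 0, retained = 1L,
                               explained = 1)
      next
    }
    p <- stats::prcomp(sub[, keep_cols, drop = FALSE], center = TRUE,
                       scale. = FALSE, rank. = ncomp)
    var <- p$sdev[seq_len(min(ncomp, length(p$sdev)))]^2
    retained <- find_knee(var)
    rot <- matrix(0, ncol(sub), retained)
    rot[keep_cols, ] <- p$rotation[, seq_len(retained), drop = FALSE]
    center <- numeric(ncol(sub))
    center <- colMeans(sub)
    projections[[g]] <- list(center = center, rotation = rot,
                             sdev = p$sdev, retained = retained,
                             explained = var / sum(p$sdev^2))
  }
  structure(list(projections = projections,
                 total_components = sum(vapply(projections, `[[`, 1L, "retained"))),
            class = "pocket_pca")
}

#' Project a voxel vector through a fitted pocket PCA
#'
#' @param model A [fit_pocket_pca()] result.
#' @param vector A single voxel count vector, or a matrix of them (rows).
#' @return Numeric vector of length `model$total_components` (or a matrix
#'   with that many columns), the concatenated group scores. The map is
#'   linear in the (centered) input.
#' @export
apply_pocket_pca <- function(model, vector) {
  if (!inherits(model, "pocket_pca")) stop("model must be a pocket_pca", call. = FALSE)
  if (is.matrix(vector))
    return(t(apply(vector, 1L, apply_pocket_pca, model = model)))
  width <- nrow(model$projections[[1]]$rotation)
  if (length(vector) != width)
    stop("input length ", length(vector), " does not match model width ",
         width, call. = FALSE)
  scores <- lapply(names(model$projections), function(g) {
    p <- model$projections[[g]]
    s <- as.numeric((vector - p$center) %*% p$rotation)
    stats::setNames(s, sprintf("%s_PC%d", g, seq_along(s)))
  })
  unlist(scores)
}
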