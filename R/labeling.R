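#' Root-mean-square deviation between two coordinate sets
#' @param a,b m x 3 coordinate matrices.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

kabsch_rotation <- function(p, q) {
  # optimal rotation u minimizing ||p u - q|| for centered p, q
  cvm <- crossprod(p, q)
  sv <- svd(cvm)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Least-squares superposition of every frame onto a reference frame
#'
#' Each frame is fitted onto the reference by the optimal rigid motion
#' (Kabsch rotation plus translation). The fit never increases the RMSD to
#' the reference. Coordinate PCA without this step mixes rigid-body and
#' internal motion, so [pca_project()] expects a superposed ensemble.
#'
#' @param ensemble a `coordinate_ensemble`.
#' @param reference_frame 1-based index of the reference frame.
#' @return a superposed `coordinate_ensemble`.
#' @export
superpose <- function(ensemble, reference_frame = 1L) {
  nf <- n_frames(ensemble)
  if (reference_frame < 1L || reference_frame > nf)
    stop(sprintf("index error: reference frame %d out of range", reference_frame))
  ref <- frame_coords(ensemble, reference_frame)
  ref_c <- colMeans(ref)
  refc <- sweep(ref, 2L, ref_c)
  if (min(svd(crossprod(refc))$d) < 1e-10 * max(svd(crossprod(refc))$d, 1))
    warning("conditioning warning: reference frame is (near-)degenerate")
  coords <- ensemble$coords
  for (f in seq_len(nf)) {
    p <- frame_coords(ensemble, f)
    pc <- sweep(p, 2L, colMeans(p))
    u <- kabsch_rotation(pc, refc)
    coords[f, , ] <- sweep(pc %*% u, 2L, ref_c, `+`)
  }
  coordinate_ensemble(coords, times = ensemble$times,
                      atom_meta = ensemble$atom_meta,
                      source = sprintf("%s [superposed on frame %d]",
                                       ensemble$source, reference_frame))
}

#' Principal-component projection of an ensemble
#'
#' PCA of the `n_frames x 3m` flattened, mean-centered coordinate matrix;
#' scores are the projections onto the top `k` components. Component signs
#' are fixed so each component's largest-magnitude loading is positive,
#' making score plots reproducible. An ensemble of identical frames is
#' flagged degenerate (all scores zero, variance ratios `NA`).
#'
#' @param ensemble a superposed `coordinate_ensemble`.
#' @param k number of components to keep (default 2).
#' @return an object of class `projection_result` with fields `scores`
#'   (`n x k`), `explained_variance_ratio`, `components` (`k x 3m`),
#'   `mean_structure`, `degenerate`.
#' @export
pca_project <- function(ensemble, k = 2L) {
  nf <- n_frames(ensemble); m <- n_atoms(ensemble)
  if (k > min(nf - 1L, 3L * m))
    stop(sprintf("argument error: k = %d exceeds min(n_frames - 1, 3m) = %d",
                 k, min(nf - 1L, 3L * m)))
  x <- matrix(ensemble$coords, nrow = nf)   # columns: atom-major x,y,z blocks
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  tot <- sum(xc^2)
  if (tot < 1e-20) {
    return(structure(list(scores = matrix(0, nf, k),
                          explained_variance_ratio = rep(NA_real_, k),
                          components = matrix(NA_real_, k, 3L * m),
                          mean_structure = mu, degenerate = TRUE),
                     class = "projection_result"))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ratio <- pc$sdev^2 / sum(pc$sdev^2)
  comps <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(comps[, j]))
    if (comps[i, j] < 0) { comps[, j] <- -comps[, j]; scores[, j] <- -scores[, j] }
  }
  structure(list(scores = unname(scores),
                 explained_variance_ratio = ratio[seq_len(k)],
                 components = t(comps), mean_structure = mu,
                 degenerate = FALSE),
            class = "projection_result")
}

#' 2D kernel density of projection scores
#'
#' Gaussian-kernel density on a regular grid covering the (PC1, PC2) score
#' range, extended by one bandwidth of margin so the grid integral is
#' close to 1. Bandwidths default to the normal-reference rule per axis.
#'
#' @param scores n x 2 matrix of (PC1, PC2) scores, n >= 10.
#' @param grid_size grid nodes per axis (default 128).
#' @param bandwidths optional numeric length-2 bandwidths.
#' @return an object of class `density_field`: grid vectors `x`, `y`,
#'   density matrix `z`, `bandwidths`.
#' @export
estimate_density <- function(scores, grid_size = 128L, bandwidths = NULL) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 10L)
    stop("argument error: density estimation requires n >= 10 points")
  if (is.null(bandwidths))
    bandwidths <- c(MASS::bandwidth.nrd(scores[, 1]),
                    MASS::bandwidth.nrd(scores[, 2]))
  if (any(!is.finite(bandwidths)) || any(bandwidths <= 0))
    stop("bandwidth error: zero-variance axis, cannot select a bandwidth")
  lims <- c(range(scores[, 1]) + c(-1, 1) * bandwidths[1],
            range(scores[, 2]) + c(-1, 1) * bandwidths[2])
  kd <- MASS::kde2d(scores[, 1], scores[, 2], h = bandwidths,
                    n = grid_size, lims = lims)
  structure(list(x = kd$x, y = kd$y, z = kd$z, bandwidths = bandwidths),
            class = "density_field")
}

# 4-connected components of a logical grid mask; returns an integer
# matrix, 0 = below threshold.
grid_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- matrix(0L, nr, nc)
  cur <- 0L
  stack <- integer(sum(mask))
  for (start in which(mask)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    top <- 1L
    stack[1L] <- start
    comp[start] <- cur
    while (top > 0L) {
      cell <- stack[top]; top <- top - 1L
      r <- (cell - 1L) %% nr + 1L; cc <- (cell - 1L) %/% nr + 1L
      if (r > 1L)  { i <- cell - 1L;  if (mask[i] && comp[i] == 0L) { comp[i] <- cur; top <- top + 1L; stack[top] <- i } }
      if (r < nr)  { i <- cell + 1L;  if (mask[i] && comp[i] == 0L) { comp[i] <- cur; top <- top + 1L; stack[top] <- i } }
      if (cc > 1L) { i <- cell - nr;  if (mask[i] && comp[i] == 0L) { comp[i] <- cur; top <- top + 1L; stack[top] <- i } }
      if (cc < nc) { i <- cell + nr;  if (mask[i] && comp[i] == 0L) { comp[i] <- cur; top <- top + 1L; stack[top] <- i } }
    }
  }
  comp
}

#' Threshold a density field into labeled state regions
#'
#' Grid nodes with density above `threshold` are grouped into 4-connected
#' components; each component becomes one state region. Regions are named
#' either by `anchors` (one representative (PC1, PC2) point per state --
#' the reproducible stand-in for the expert assignment step; a region
#' containing no anchor is an error) or, when only `state_names` is given,
#' in order of decreasing peak density. Boundary polygons are traced at
#' the threshold level for export and plotting; containment tests use the
#' grid mask itself, which makes threshold monotonicity exact.
#'
#' @param field a `density_field`.
#' @param threshold density threshold (> 0), in probability-density units
#'   over the score plane.
#' @param state_names character vector of state names.
#' @param anchors optional named list of length-2 numeric (PC1, PC2)
#'   points, names matching `state_names`.
#' @return an object of class `state_regions` (possibly with 0 regions).
#' @export
extract_regions <- function(field, threshold, state_names = c("A", "B", "I"),
                            anchors = NULL) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("argument error: threshold must be > 0")
  mask <- field$z > threshold
  comp <- grid_components(mask)
  ncomp <- max(comp)
  dx <- diff(field$x[1:2]); dy <- diff(field$y[1:2])
  empty <- structure(list(components = comp, x = field$x, y = field$y,
                          threshold = threshold, labels = character(0),
                          polygons = list(), areas = numeric(0),
                          peaks = list()),
                     class = "state_regions")
  if (ncomp == 0L) return(empty)
  cells <- lapply(seq_len(ncomp), function(k) which(comp == k))
  centroids <- t(vapply(cells, function(cs) {
    r <- (cs - 1L) %% nrow(comp) + 1L; cc <- (cs - 1L) %/% nrow(comp) + 1L
    c(mean(field$x[r]), mean(field$y[cc]))
  }, numeric(2)))
  if (!is.null(anchors)) {
    lab <- rep(NA_character_, ncomp)
    for (nm in names(anchors)) {
      pt <- anchors[[nm]]
      r <- which.min(abs(field$x - pt[1])); cc <- which.min(abs(field$y - pt[2]))
      k <- comp[r, cc]
      if (k == 0L)
        stop(sprintf("labeling error: anchor '%s' falls outside every region", nm))
      lab[k] <- nm
    }
    if (anyNA(lab))
      stop(sprintf(
        "labeling error: %d region(s) have no anchor; centroids: %s",
        sum(is.na(lab)),
        paste(apply(centroids[is.na(lab), , drop = FALSE], 1L,
                    function(p) sprintf("(%.3g, %.3g)", p[1], p[2])),
              collapse = ", ")))
  } else {
    if (ncomp > length(state_names))
      stop(sprintf(
        "labeling error: %d regions found but only %d state names; centroids: %s",
        ncomp, length(state_names),
        paste(apply(centroids, 1L, function(p) sprintf("(%.3g, %.3g)", p[1], p[2])),
              collapse = ", ")))
    peak <- vapply(cells, function(cs) max(field$z[cs]), numeric(1))
    lab <- rep(NA_character_, ncomp)
    lab[order(peak, decreasing = TRUE)] <- state_names[seq_len(ncomp)]
  }
  cl <- grDevices::contourLines(field$x, field$y, field$z, levels = threshold)
  polys <- vector("list", ncomp)
  for (p in cl) {
    r <- which.min(abs(field$x - mean(p$x))); cc <- which.min(abs(field$y - mean(p$y)))
    k <- comp[r, cc]
    if (k > 0L && is.null(polys[[k]])) polys[[k]] <- cbind(p$x, p$y)
  }
  structure(list(components = comp, x = field$x, y = field$y,
                 threshold = threshold, labels = lab, polygons = polys,
                 areas = vapply(cells, length, integer(1)) * dx * dy,
                 peaks = lapply(cells, function(cs) max(field$z[cs]))),
            class = "state_regions")
}

#' @export
print.state_regions <- function(x, ...) {
  cat(sprintf("<state_regions> %d region(s) at threshold %g: %s\n",
              length(x$labels), x$threshold,
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Assign per-frame state labels from score-space regions
#'
#' A point inside a region (nearest grid node belongs to the region's
#' super-threshold component; boundary points therefore count as inside)
#' receives that region's label; all other points receive the non-state
#' label `"N"`. Total and deterministic: every frame gets exactly one
#' label.
#'
#' @param scores n x 2 matrix of (PC1, PC2) scores.
#' @param regions a `state_regions` object.
#' @return an object of class `state_label_series`: character labels plus
#'   the declared label set.
#' @export
assign_labels <- function(scores, regions) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  lab <- rep("N", n)
  if (length(regions$labels)) {
    gx <- regions$x; gy <- regions$y
    ix <- pmin(pmax(findInterval(scores[, 1],
                                 c(-Inf, gx[-length(gx)] + diff(gx) / 2)), 1L),
               length(gx))
    iy <- pmin(pmax(findInterval(scores[, 2],
                                 c(-Inf, gy[-length(gy)] + diff(gy) / 2)), 1L),
               length(gy))
    k <- regions$components[cbind(ix, iy)]
    lab[k > 0L] <- regions$labels[k[k > 0L]]
  }
  state_label_series(lab, label_set = unique(c(regions$labels, "N")))
}

#' Per-frame state labels
#' @param labels character vector of per-frame labels.
#' @param label_set declared label universe (defaults to observed values).
#' @return object of class `state_label_series`.
#' @export
state_label_series <- function(labels, label_set = unique(labels)) {
  labels <- as.character(labels)
  if (!all(labels %in% label_set))
    stop("validation error: labels outside the declared label set")
  structure(list(labels = labels, label_set = label_set),
            class = "state_label_series")
}

#' @export
print.state_label_series <- function(x, ...) {
  tb <- table(factor(x$labels, levels = x$label_set))
  cat("<state_label_series>", length(x$labels), "frames:",
      paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  invisible(x)
}

#' Write / read labels as a two-column delimited table
#' @param labels a `state_label_series`.
#' @param path file path.
#' @return `path` invisibly, or a `state_label_series`.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(frame_index = seq_along(labels$labels), label = labels$labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  state_label_series(df$label)
}

#' Export state regions as JSON polygons
#' @param regions a `state_regions`.
#' @param path output JSON path.
#' @return `path` invisibly.
#' @export
write_regions_json <- function(regions, path) {
  obj <- lapply(seq_along(regions$labels), function(k) {
    poly <- regions$polygons[[k]]
    list(label = regions$labels[k],
         area = regions$areas[k],
         polygon = if (is.null(poly)) list() else
           lapply(seq_len(nrow(poly)), function(i) as.numeric(poly[i, ])))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Scatter plot of projection scores colored by state label
#' @param scores n x 2 score matrix.
#' @param labels optional `state_label_series`.
#' @param file optional PNG path; when given the plot is written there.
#' @return `file` (or `NULL`) invisibly.
#' @export
plot_projection <- function(scores, labels = NULL, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 640)
    on.exit(grDevices::dev.off())
  }
  col <- "grey40"
  if (!is.null(labels)) {
    pal <- c(A = "#2166ac", B = "#e08214", I = "#d6604d", N = "grey70")
    lv <- labels$label_set
    extra <- setdiff(lv, names(pal))
    if (length(extra))
      pal <- c(pal, stats::setNames(grDevices::rainbow(length(extra)), extra))
    col <- pal[labels$labels]
  }
  plot(scores[, 1], scores[, 2], col = col, pch = 16, cex = 0.5,
       xlab = "PC1", ylab = "PC2", main = "Conformational landscape")
  invisible(file)
}
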