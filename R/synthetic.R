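#' Reference conformations of a two-state hinge peptide
#'
#' Builds an idealized alpha-carbon trace with 3.8 Angstrom consecutive
#' spacing laid out as a planar zig-zag (pseudo-bond angle 120 degrees, as
#' in a coarse extended chain; a perfectly straight trace would be
#' unrealistically sparse in contacts). The "open" reference (state `A`)
#' is the extended zig-zag; the "closed" reference (state `B`) is the same
#' chain with the second half rotated by `bend_angle` about the midpoint
#' hinge, which moves some cross-hinge residue pairs from beyond the
#' 10 Angstrom contact cutoff to within it.
#'
#' @param m number of residues (>= 8).
#' @param bend_angle hinge bend in degrees.
#' @return named list with `A` and `B`, each an `m x 3` matrix.
#' @export
default_hinge_references <- function(m = 40L, bend_angle = 60) {
  if (m < 8L) stop("argument error: m must be >= 8")
  spacing <- 3.8
  beta <- 30 * pi / 180      # half the zig-zag apex deviation
  dirs <- cbind(cos(beta),
                ifelse(seq_len(m - 1L) %% 2L == 1L, sin(beta), -sin(beta)),
                0)
  open <- rbind(c(0, 0, 0), apply(dirs * spacing, 2L, cumsum))
  h <- floor(m / 2)
  pivot <- open[h, ]
  th <- bend_angle * pi / 180
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  closed <- open
  if (h < m) {
    tail_idx <- (h + 1L):m
    closed[tail_idx, ] <- sweep(sweep(open[tail_idx, , drop = FALSE], 2L, pivot) %*% rot,
                                2L, pivot, `+`)
  }
  dmin <- function(x) {
    dm <- as.matrix(stats::dist(x))
    dm[abs(row(dm) - col(dm)) <= 1] <- Inf
    min(dm)
  }
  if (dmin(closed) < 2)
    stop(sprintf(
      "geometry error: bend of %g degrees self-intersects the chain (min non-consecutive distance %.2f A)",
      bend_angle, dmin(closed)))
  list(A = open, B = closed)
}

#' Specification of a synthetic multi-state conformational ensemble
#'
#' The stated world the generator emulates: two (or more) reference
#' conformations of an `m`-residue chain, per-frame state occupancies, a
#' linearly interpolated transition path between the first two states,
#' isotropic Gaussian coordinate noise, and a random rigid motion per
#' frame. The rigid motion is deliberate: it lets tests prove the graph
#' stage's rigid-motion invariance and forces the labeling stage to
#' superpose.
#'
#' @param m residues per chain.
#' @param references named list of `m x 3` reference coordinate sets
#'   (defaults to the open/closed hinge pair, states `A` and `B`).
#' @param occupancies named per-state fractions; together with
#'   `transition_fraction` they must sum to 1.
#' @param transition_fraction fraction of frames drawn along the
#'   interpolation path between the first two states.
#' @param noise_sigma isotropic Gaussian noise, Angstrom.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param bend_angle hinge bend used when `references` is not supplied.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(m = 40L, references = NULL,
                           occupancies = c(A = 0.45, B = 0.45),
                           transition_fraction = 0.10,
                           noise_sigma = 0.5, n_frames = 2000L, seed = 1L,
                           bend_angle = 60) {
  if (is.null(references)) references <- default_hinge_references(m, bend_angle)
  if (is.list(occupancies)) occupancies <- unlist(occupancies)
  if (m < 4L) stop("spec error: m must be >= 4")
  if (is.null(names(references)) || is.null(names(occupancies)))
    stop("spec error: references and occupancies must be named")
  if (!all(names(occupancies) %in% names(references)))
    stop("spec error: occupancy names must match reference names")
  if (abs(sum(occupancies) + transition_fraction - 1) > 1e-9)
    stop("spec error: occupancies + transition_fraction must sum to 1")
  if (noise_sigma < 0) stop("spec error: noise_sigma must be >= 0")
  for (r in references)
    if (!is.matrix(r) || nrow(r) != m || ncol(r) != 3L)
      stop("spec error: each reference must be an m x 3 matrix")
  structure(list(m = as.integer(m), references = references,
                 occupancies = occupancies,
                 transition_fraction = transition_fraction,
                 noise_sigma = noise_sigma, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; cc <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - cc^2 - d^2, 2 * (b * cc + a * d), 2 * (b * d - a * cc),
           2 * (b * cc - a * d), a^2 - b^2 + cc^2 - d^2, 2 * (cc * d + a * b),
           2 * (b * d + a * cc), 2 * (cc * d - a * b), a^2 - b^2 - cc^2 + d^2),
         3, 3)
}

#' Generate a synthetic labeled conformational ensemble
#'
#' Each frame is a sampled state's reference conformation (or an
#' interpolation point between the first two states for transition
#' frames) plus isotropic Gaussian noise, followed by a random rigid
#' motion. Labels are the generative assignments: state frames carry
#' their state's name; transition frames in the middle 60% of the path
#' are labeled `"I"`, while path endpoints (first/last 20%) fold into
#' their state cores. Fully deterministic under `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `ensemble` (a `coordinate_ensemble`), `labels` (a
#'   `state_label_series` of generative labels) and `meta` (data.frame
#'   with the drawn category and interpolation coordinate `t`).
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  nf <- spec$n_frames; m <- spec$m
  states <- names(spec$occupancies)
  cats <- c(states, if (spec$transition_fraction > 0) ".transition")
  probs <- c(as.numeric(spec$occupancies),
             if (spec$transition_fraction > 0) spec$transition_fraction)
  draw <- sample(cats, nf, replace = TRUE, prob = probs)
  tvals <- rep(NA_real_, nf)
  labels <- character(nf)
  ref_a <- spec$references[[states[1]]]
  ref_b <- spec$references[[if (length(states) > 1L) states[2] else states[1]]]
  coords <- array(0, dim = c(nf, m, 3L))
  for (f in seq_len(nf)) {
    if (draw[f] == ".transition") {
      t <- stats::runif(1)
      tvals[f] <- t
      base <- (1 - t) * ref_a + t * ref_b
      labels[f] <- if (t <= 0.2) states[1] else if (t >= 0.8) states[2] else "I"
    } else {
      base <- spec$references[[draw[f]]]
      labels[f] <- draw[f]
    }
    noisy <- base + matrix(stats::rnorm(m * 3L, 0, spec$noise_sigma), m, 3L)
    rot <- random_rotation()
    shift <- stats::runif(3, -20, 20)
    coords[f, , ] <- sweep(noisy %*% rot, 2L, shift, `+`)
  }
  label_set <- unique(c(states, if (spec$transition_fraction > 0) "I"))
  list(ensemble = coordinate_ensemble(coords, source = "synthetic hinge ensemble"),
       labels = state_label_series(labels, label_set = label_set),
       meta = data.frame(category = draw, t = tvals,
                         stringsAsFactors = FALSE))
}
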