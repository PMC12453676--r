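test_that("superposition is idempotent, recovers rigid motions, never hurts RMSD", {
  sim <- small_two_state(n_frames = 12, m = 14, seed = 17)
  ens <- sim$ensemble
  sup <- superpose(ens, 1)
  sup2 <- superpose(sup, 1)
  expect_equal(sup2$coords, sup$coords, tolerance = 1e-9)     # idempotence
  # a purely rotated copy of the reference is recovered exactly
  ref <- frame_coords(ens, 1)
  rot90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  arr <- array(0, c(2, nrow(ref), 3))
  arr[1, , ] <- ref
  arr[2, , ] <- ref %*% rot90
  two <- coordinate_ensemble(arr)
  fit <- superpose(two, 1)
  expect_lt(rmsd(frame_coords(fit, 2), frame_coords(fit, 1)), 1e-9)
  # random-noise ensemble: post-fit RMSD <= pre-fit RMSD for every frame
  for (f in seq_len(n_frames(ens))) {
    pre <- rmsd(frame_coords(ens, f), frame_coords(ens, 1))
    post <- rmsd(frame_coords(sup, f), frame_coords(sup, 1))
    expect_lte(post, pre + 1e-12)
  }
})

test_that("coordinate PCA recovers a 1-D hinge motion and obeys its contract", {
  # all-transition ensemble: frames sample the interpolation path uniformly
  sim <- generate_ensemble(synthetic_spec(
    m = 20, n_frames = 120, occupancies = c(A = 0, B = 0),
    transition_fraction = 1, noise_sigma = 0.3, seed = 23))
  sup <- superpose(sim$ensemble, 1)
  pr <- pca_project(sup, k = 2)
  expect_false(pr$degenerate)
  r <- stats::cor(pr$scores[, 1], sim$meta$t)
  expect_gt(abs(r), 0.9)
  expect_true(all(diff(pr$explained_variance_ratio) <= 1e-12))
  expect_true(all(pr$explained_variance_ratio >= 0 &
                  pr$explained_variance_ratio <= 1))
  expect_lte(sum(pr$explained_variance_ratio), 1 + 1e-9)
  # components orthonormal
  g <- unname(pr$components %*% t(pr$components))
  expect_equal(g, diag(2), tolerance = 1e-8)
  expect_error(pca_project(sup, k = 121), "argument error")
})

test_that("identical frames flag a degenerate projection", {
  x <- matrix(rnorm(30), 10, 3)
  ens <- coordinate_ensemble(array(rep(x, each = 5), c(5, 10, 3)))
  pr <- pca_project(ens, 2)
  expect_true(pr$degenerate)
  expect_true(all(pr$scores == 0))
  expect_true(all(is.na(pr$explained_variance_ratio)))
})

test_that("kernel density is normalized and finds the generative modes", {
  set.seed(5)
  one <- cbind(rnorm(500, 0, 0.5), rnorm(500, 0, 0.5))
  fld <- estimate_density(one, grid_size = 96)
  dx <- diff(fld$x[1:2]); dy <- diff(fld$y[1:2])
  expect_true(all(fld$z >= 0))
  expect_gt(sum(fld$z) * dx * dy, 0.98)
  expect_lt(sum(fld$z) * dx * dy, 1.02)
  pk <- arrayInd(which.max(fld$z), dim(fld$z))
  expect_lt(abs(fld$x[pk[1]]), 0.3)
  expect_lt(abs(fld$y[pk[2]]), 0.3)
  # two Gaussians 10 sigma apart -> two local maxima above half-max
  two <- rbind(cbind(rnorm(400, 0, 1), rnorm(400, 0, 1)),
               cbind(rnorm(400, 10, 1), rnorm(400, 0, 1)))
  fld2 <- estimate_density(two, grid_size = 96)
  mx <- fld2$z
  n_peaks <- 0
  for (i in 2:(nrow(mx) - 1)) for (j in 2:(ncol(mx) - 1)) {
    v <- mx[i, j]
    if (v > max(mx) / 2 &&
        v > mx[i - 1, j] && v > mx[i + 1, j] &&
        v > mx[i, j - 1] && v > mx[i, j + 1]) n_peaks <- n_peaks + 1
  }
  expect_equal(n_peaks, 2L)
  expect_error(estimate_density(cbind(rep(1, 50), rnorm(50))),
               "bandwidth error")
  expect_error(estimate_density(one[1:5, ]), "argument error")
})

test_that("region extraction counts components and respects naming rules", {
  set.seed(9)
  two <- rbind(cbind(rnorm(400, 0, 1), rnorm(400, 0, 1)),
               cbind(rnorm(200, 10, 1), rnorm(200, 0, 1)))
  fld <- estimate_density(two, grid_size = 96)
  # threshold at half the lower peak splits exactly two regions
  lower_peak <- max(fld$z[fld$x > 5, ])
  reg <- extract_regions(fld, lower_peak / 2, state_names = c("A", "B"))
  expect_length(reg$labels, 2L)
  expect_setequal(reg$labels, c("A", "B"))
  # peak-ordered naming: the denser basin gets the first name
  expect_equal(reg$labels[which.max(unlist(reg$peaks))], "A")
  # anchors override ordering
  reg2 <- extract_regions(fld, lower_peak / 2,
                          anchors = list(B = c(0, 0), A = c(10, 0)))
  expect_equal(reg2$labels[which.max(unlist(reg2$peaks))], "B")
  expect_error(extract_regions(fld, lower_peak / 2,
                               anchors = list(A = c(0, 0))),
               "labeling error")
  expect_error(extract_regions(fld, lower_peak / 2, state_names = "A"),
               "labeling error")
  # empty case: threshold above the global maximum
  expect_length(extract_regions(fld, max(fld$z) * 2)$labels, 0L)
  # three well-separated Gaussians, three names
  three <- rbind(cbind(rnorm(300, 0, 1), rnorm(300, 0, 1)),
                 cbind(rnorm(300, 12, 1), rnorm(300, 0, 1)),
                 cbind(rnorm(300, 6, 1), rnorm(300, 12, 1)))
  fld3 <- estimate_density(three, grid_size = 96)
  reg3 <- extract_regions(fld3, max(fld3$z) / 3, state_names = c("A", "B", "I"))
  expect_length(reg3$labels, 3L)
})

test_that("raising the threshold never grows any region", {
  set.seed(11)
  pts <- rbind(cbind(rnorm(400, 0, 1), rnorm(400, 0, 1)),
               cbind(rnorm(300, 8, 1.5), rnorm(300, 0, 1.5)))
  fld <- estimate_density(pts, grid_size = 96)
  thresholds <- max(fld$z) * c(0.1, 0.2, 0.35, 0.5, 0.7)
  prev <- NULL
  for (th in thresholds) {
    mask_area <- sum(fld$z > th)
    if (!is.null(prev)) expect_lte(mask_area, prev)
    prev <- mask_area
  }
})

test_that("label assignment is total, boundary-inclusive, and recovers cores", {
  set.seed(13)
  a <- cbind(rnorm(400, 0, 1), rnorm(400, 0, 1))
  b <- cbind(rnorm(400, 10, 1), rnorm(400, 0, 1))
  scores <- rbind(a, b)
  truth <- rep(c("A", "B"), each = 400)
  fld <- estimate_density(scores, grid_size = 96)
  lower_peak <- min(max(fld$z[fld$x < 5, ]), max(fld$z[fld$x > 5, ]))
  # anchors pin region identity (the reproducible expert-assignment step)
  reg <- extract_regions(fld, lower_peak / 2,
                         anchors = list(A = c(0, 0), B = c(10, 0)))
  labs <- assign_labels(scores, reg)
  expect_length(labs$labels, 800L)
  expect_true(all(labs$labels %in% c("A", "B", "N")))
  # centroid of each region gets the region label
  for (k in seq_along(reg$labels)) {
    cells <- which(reg$components == k, arr.ind = TRUE)
    ctr <- c(mean(reg$x[cells[, 1]]), mean(reg$y[cells[, 2]]))
    expect_equal(assign_labels(rbind(ctr), reg)$labels, reg$labels[k])
  }
  # far-away point is non-state
  expect_equal(assign_labels(rbind(c(100, 100)), reg)$labels, "N")
  # core points (within 1 sigma of their mode) recover their label >= 90%
  core_a <- rowSums(sweep(a, 2, c(0, 0))^2) < 1
  core_b <- rowSums(sweep(b, 2, c(10, 0))^2) < 1
  got_a <- labs$labels[seq_len(400)][core_a]
  got_b <- labs$labels[400 + seq_len(400)][core_b]
  expect_gte(mean(got_a == "A"), 0.9)
  expect_gte(mean(got_b == "B"), 0.9)
  # no confusion between the two cores
  expect_equal(sum(got_a == "B") + sum(got_b == "A"), 0L)
})

test_that("labels and regions round-trip through their text formats", {
  labs <- state_label_series(c("A", "B", "N", "A"), c("A", "B", "I", "N"))
  tmp <- tempfile(fileext = ".tsv")
  write_labels(labs, tmp)
  back <- read_labels(tmp)
  expect_identical(back$labels, labs$labels)
  expect_error(state_label_series(c("A", "Z"), c("A", "B")),
               "validation error")
})
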