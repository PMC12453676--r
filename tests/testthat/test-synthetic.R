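test_that("hinge references obey construction contracts", {
  refs0 <- default_hinge_references(40, 0)
  expect_equal(refs0$A, refs0$B)                       # bend 0 -> identical
  refs <- default_hinge_references(40, 60)
  for (r in refs) {
    gaps <- sqrt(rowSums(diff(r)^2))
    expect_equal(gaps, rep(3.8, 39), tolerance = 1e-9)
  }
  # m = 40, bend 60: contact-graph edge sets differ at cutoff 10
  ga <- build_contact_graph(oracle_distances(refs$A), 10)
  gb <- build_contact_graph(oracle_distances(refs$B), 10)
  ka <- paste(ga$edges$i, ga$edges$j); kb <- paste(gb$edges$i, gb$edges$j)
  expect_gt(length(union(setdiff(ka, kb), setdiff(kb, ka))), 0L)
  expect_error(default_hinge_references(40, 176), "geometry error")
  expect_error(default_hinge_references(6), "argument error")
})

test_that("zero-noise frames reproduce reference internal distances exactly", {
  sim <- generate_ensemble(synthetic_spec(
    m = 12, n_frames = 10, occupancies = c(A = 0.5, B = 0.5),
    transition_fraction = 0, noise_sigma = 0, seed = 41))
  refs <- default_hinge_references(12, 60)
  for (f in seq_len(10)) {
    dm <- pairwise_distances(sim$ensemble, f)$values
    want <- oracle_distances(refs[[sim$labels$labels[f]]])
    expect_equal(dm, want, tolerance = 1e-8)  # rigid motion leaves distances
  }
})

test_that("state counts follow the occupancies within the binomial bound", {
  sim <- generate_ensemble(synthetic_spec(
    m = 8, n_frames = 2000, occupancies = c(A = 0.5, B = 0.5),
    transition_fraction = 0, noise_sigma = 0.3, seed = 43))
  nA <- sum(sim$labels$labels == "A")
  expect_lt(abs(nA - 1000), 3 * sqrt(2000 * 0.25))
  # law of large numbers at n = 10,000 with a transition component
  sim2 <- generate_ensemble(synthetic_spec(
    m = 8, n_frames = 10000, occupancies = c(A = 0.4, B = 0.4),
    transition_fraction = 0.2, noise_sigma = 0.3, seed = 47))
  frac <- table(sim2$meta$category) / 10000
  for (nm in c("A", "B")) {
    expect_lt(abs(frac[[nm]] - 0.4), 3 * sqrt(0.4 * 0.6 / 10000))
  }
  expect_lt(abs(frac[[".transition"]] - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))
  # transition labels: middle 60% of the path is "I", endpoints fold to cores
  tt <- sim2$meta$t[sim2$meta$category == ".transition"]
  ll <- sim2$labels$labels[sim2$meta$category == ".transition"]
  expect_true(all(ll[tt > 0.2 & tt < 0.8] == "I"))
  expect_true(all(ll[tt <= 0.2] == "A"))
  expect_true(all(ll[tt >= 0.8] == "B"))
})

test_that("generation is deterministic under the seed and validates its spec", {
  s <- synthetic_spec(m = 10, n_frames = 20, seed = 53)
  a <- generate_ensemble(s); b <- generate_ensemble(s)
  expect_identical(a$ensemble$coords, b$ensemble$coords)
  expect_identical(a$labels$labels, b$labels$labels)
  expect_error(synthetic_spec(occupancies = c(A = 0.5, B = 0.3)),
               "spec error")
  expect_error(synthetic_spec(noise_sigma = -1), "spec error")
})

test_that("PCA on a generated two-state ensemble separates the state cores", {
  sim <- generate_ensemble(synthetic_spec(
    m = 24, n_frames = 300, occupancies = c(A = 0.5, B = 0.5),
    transition_fraction = 0, noise_sigma = 0.5, seed = 59))
  pr <- pca_project(superpose(sim$ensemble, 1), 2)
  fld <- estimate_density(pr$scores, grid_size = 96)
  # the two cores sit in distinct density regions at half the lower peak
  is_a <- sim$labels$labels == "A"
  peak_of <- function(keep) {
    mu <- colMeans(pr$scores[keep, , drop = FALSE])
    fld$z[which.min(abs(fld$x - mu[1])), which.min(abs(fld$y - mu[2]))]
  }
  th <- min(peak_of(is_a), peak_of(!is_a)) / 2
  mu_a <- colMeans(pr$scores[is_a, ]); mu_b <- colMeans(pr$scores[!is_a, ])
  reg <- extract_regions(fld, th, anchors = list(A = mu_a, B = mu_b))
  expect_length(reg$labels, 2L)
  labs <- assign_labels(pr$scores, reg)
  # core frames (scores within 1 sd of their state centroid) recover their
  # generative label; frames in the low-density fringe may fall to N
  sd_a <- sqrt(mean(rowSums(sweep(pr$scores[is_a, ], 2, mu_a)^2)))
  sd_b <- sqrt(mean(rowSums(sweep(pr$scores[!is_a, ], 2, mu_b)^2)))
  core_a <- is_a & rowSums(sweep(pr$scores, 2, mu_a)^2) < sd_a^2
  core_b <- !is_a & rowSums(sweep(pr$scores, 2, mu_b)^2) < sd_b^2
  expect_gte(mean(labs$labels[core_a] == "A"), 0.9)
  expect_gte(mean(labs$labels[core_b] == "B"), 0.9)
  # zero confusion between the two cores
  expect_equal(sum(labs$labels[core_a] == "B") +
               sum(labs$labels[core_b] == "A"), 0L)
})
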