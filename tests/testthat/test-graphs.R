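test_that("pairwise distances match geometry and the brute-force oracle", {
  x <- matrix(c(0, 0, 0, 3, 4, 0), 2, 3, byrow = TRUE)
  ens <- coordinate_ensemble(array(x, c(1, 2, 3)))
  dm <- pairwise_distances(ens, 1)
  expect_equal(dm$values[1, 2], 5.0)                 # 3-4-5 triangle
  # degenerate single atom
  one <- coordinate_ensemble(array(c(1, 2, 3), c(1, 1, 3)))
  expect_equal(pairwise_distances(one, 1)$values, matrix(0, 1, 1))
  # oracle equivalence on a random 10-atom frame
  ens10 <- random_ensemble(1, 10, seed = 2)
  got <- pairwise_distances(ens10, 1)$values
  expect_equal(got, oracle_distances(frame_coords(ens10, 1)), tolerance = 1e-10)
  expect_error(pairwise_distances(ens10, 5), "index error")
})

test_that("contact graph weights follow 1 - d/cutoff with a strict cutoff", {
  mk <- function(d) {
    v <- matrix(c(0, d, d, 0), 2, 2)
    build_contact_graph(v, cutoff = 10)
  }
  expect_equal(mk(5)$edges$weight, 0.5)
  expect_equal(nrow(mk(10)$edges), 0L)               # boundary excluded
  expect_equal(mk(0 + 1e-300)$edges$weight, 1.0)     # coincident atoms
  # 4-residue chain with consecutive distances 3.8 A and all other pairs
  # beyond the cutoff: exactly 3 edges of weight 0.62. (No Euclidean
  # embedding exists with i..i+2 > 10 when consecutive gaps are 3.8, so
  # the distance matrix is supplied directly.)
  dm <- matrix(11, 4, 4); diag(dm) <- 0
  dm[cbind(1:3, 2:4)] <- 3.8; dm[cbind(2:4, 1:3)] <- 3.8
  g <- build_contact_graph(dm, 10)
  expect_equal(nrow(g$edges), 3L)
  expect_equal(g$edges$weight, rep(0.62, 3), tolerance = 1e-12)
  expect_error(build_contact_graph(matrix(c(0, 1, 2, 0), 2, 2), 10),
               "integrity error")
  expect_error(build_contact_graph(matrix(0, 2, 2) - 1, 10), "integrity error")
})

test_that("graph series shares nodes/cutoff and is rigid-motion invariant", {
  ens <- random_ensemble(3, 12, seed = 4)
  gs <- build_graph_series(ens, 10)
  expect_length(gs$graphs, 3L)
  expect_true(all(vapply(gs$graphs, `[[`, 0L, "n_nodes") == 12L))
  set.seed(8)
  for (f in 1:3) {
    rot <- random_rotation_matrix()
    shift <- runif(3, -50, 50)
    moved <- sweep(frame_coords(ens, f) %*% rot, 2, shift, `+`)
    g2 <- build_contact_graph(oracle_distances(moved), 10)
    g1 <- gs$graphs[[f]]
    expect_identical(g2$edges[, c("i", "j")], g1$edges[, c("i", "j")])
    expect_equal(g2$edges$weight, g1$edges$weight, tolerance = 1e-9)
  }
})

test_that("increasing the cutoff keeps edges and strictly raises weights", {
  ens <- random_ensemble(1, 15, seed = 6)
  dm <- pairwise_distances(ens, 1)
  for (pair in list(c(5, 8), c(8, 12), c(12, 20))) {
    g1 <- build_contact_graph(dm, pair[1])
    g2 <- build_contact_graph(dm, pair[2])
    k1 <- paste(g1$edges$i, g1$edges$j)
    k2 <- paste(g2$edges$i, g2$edges$j)
    expect_true(all(k1 %in% k2))
    if (nrow(g1$edges))
      expect_true(all(g2$edges$weight[match(k1, k2)] > g1$edges$weight))
  }
})

test_that("edge-list text export round-trips a graph series", {
  sim <- small_two_state(n_frames = 4)
  gs <- build_graph_series(sim$ensemble, 10)
  tmp <- tempfile(fileext = ".txt")
  write_graph_series(gs, tmp)
  back <- read_graph_series(tmp)
  expect_equal(length(back$graphs), length(gs$graphs))
  for (f in seq_along(gs$graphs)) {
    expect_identical(back$graphs[[f]]$edges[, c("i", "j")],
                     gs$graphs[[f]]$edges[, c("i", "j")])
    expect_equal(back$graphs[[f]]$edges$weight, gs$graphs[[f]]$edges$weight,
                 tolerance = 1e-12)
  }
})
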