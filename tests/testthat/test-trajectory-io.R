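test_that("multi-model PDB loads with the forced counts and deterministically", {
  tmp <- tempfile(fileext = ".pdb")
  coords <- lapply(1:3, function(f) matrix(f + (1:15), 5, 3) * 1.0)
  write_pdb_fixture(tmp, coords)
  ens <- load_ensemble(tmp)
  expect_equal(n_frames(ens), 3L)
  expect_equal(n_atoms(ens), 5L)
  expect_equal(ens$atom_meta$res_index, 1:5)
  # determinism of file reading
  ens2 <- load_ensemble(tmp)
  expect_identical(ens$coords, ens2$coords)
  # coordinates survive the fixed-width PDB round trip at 1e-3
  expect_equal(frame_coords(ens, 2), coords[[2]], tolerance = 1e-9)
})

test_that("empty selection and unreadable files raise typed errors", {
  tmp <- tempfile(fileext = ".pdb")
  write_pdb_fixture(tmp, list(matrix(1:15, 5, 3) * 1.0))
  expect_error(load_ensemble(tmp, selection = "name CB"), "selection error")
  expect_error(load_ensemble("does-not-exist.pdb"), "format error")
  expect_error(load_ensemble(tmp, trajectory = "missing.dcd"), "format error")
})

test_that("GRO topology parses with nm -> Angstrom conversion", {
  tmp <- tempfile(fileext = ".gro")
  writeLines(c(
    "test peptide",
    "    3",
    "    1ALA     CA    1   0.000   0.000   0.000",
    "    2ALA     CA    2   0.380   0.000   0.000",
    "    3GLY     CA    3   0.760   0.000   0.000",
    "   5.0   5.0   5.0"), tmp)
  ens <- load_ensemble(tmp)
  expect_equal(n_atoms(ens), 3L)
  expect_equal(frame_coords(ens, 1)[, 1], c(0, 3.8, 7.6), tolerance = 1e-9)
  expect_equal(ens$atom_meta$res_name, c("ALA", "ALA", "GLY"))
})

test_that("striding keeps frames 1, 1+s, ... and composes multiplicatively", {
  ens <- random_ensemble(100, 4)
  s20 <- stride_ensemble(ens, 20)
  expect_equal(n_frames(s20), 5L)            # ceiling(100/20)
  expect_identical(stride_ensemble(ens, 1)$coords, ens$coords)
  # composition property: stride a then b == stride a*b
  for (ab in list(c(2, 5), c(3, 4), c(5, 2))) {
    lhs <- stride_ensemble(stride_ensemble(ens, ab[1]), ab[2])
    rhs <- stride_ensemble(ens, ab[1] * ab[2])
    expect_identical(lhs$coords, rhs$coords)
    expect_identical(lhs$times, rhs$times)
  }
  expect_error(stride_ensemble(ens, 0), "argument error")
  # 10 ps recording strided to 20 ps spacing halves the frame count
  expect_equal(n_frames(stride_ensemble(random_ensemble(1000, 2), 2)), 500L)
})

test_that("delimited ensemble format round-trips losslessly", {
  ens <- random_ensemble(4, 7, seed = 42)
  tmp <- tempfile(fileext = ".txt")
  write_ensemble(ens, tmp)
  back <- read_ensemble(tmp)
  expect_equal(back$coords, ens$coords, tolerance = 1e-6)
  expect_identical(back$atom_meta, ens$atom_meta)
  expect_identical(back$times, ens$times)
})

test_that("truncated and malformed ensemble files give parse errors with line numbers", {
  ens <- random_ensemble(3, 5)
  tmp <- tempfile(fileext = ".txt")
  write_ensemble(ens, tmp)
  lines <- readLines(tmp)
  trunc <- tempfile(); writeLines(lines[1:(length(lines) - 3)], trunc)
  expect_error(read_ensemble(trunc), "parse error at line")
  bad <- tempfile(); lines2 <- lines; lines2[12] <- "not a number at all"
  writeLines(lines2, bad)
  expect_error(read_ensemble(bad), "parse error at line")
})

test_that("degenerate ensembles are rejected at construction/write", {
  expect_error(coordinate_ensemble(array(0, c(0, 5, 3))), "integrity error")
  expect_error(coordinate_ensemble(array(NA_real_, c(1, 2, 3))), "integrity error")
  expect_error(coordinate_ensemble(array(0, c(2, 2, 3)), times = c(1, 1)),
               "integrity error")
})

test_that("single-frame PDB export re-imports", {
  ens <- random_ensemble(2, 6, seed = 9)
  tmp <- tempfile(fileext = ".pdb")
  export_frame_pdb(ens, 2, tmp)
  back <- load_ensemble(tmp)
  expect_equal(frame_coords(back, 1), frame_coords(ens, 2), tolerance = 1e-3)
})

test_that("DCD trajectories written by MDAnalysis are read back", {
  py <- Sys.which("python")
  expect_true(nzchar(py))  # guaranteed by the runtime image
  top <- tempfile(fileext = ".pdb")
  set.seed(3)
  coords <- lapply(1:4, function(f) matrix(rnorm(18) * 8, 6, 3))
  write_pdb_fixture(top, coords[1])
  dcd <- tempfile(fileext = ".dcd")
  script <- tempfile(fileext = ".py")
  ref <- tempfile(fileext = ".txt")
  writeLines(c(
    "import sys, numpy as np",
    "import MDAnalysis as mda",
    "top, dcd, ref = sys.argv[1], sys.argv[2], sys.argv[3]",
    "u = mda.Universe(top)",
    "rng = np.random.default_rng(7)",
    "frames = [rng.normal(size=(6,3)).astype(np.float32)*8 for _ in range(4)]",
    "with mda.Writer(dcd, 6) as w:",
    "    for fr in frames:",
    "        u.atoms.positions = fr",
    "        w.write(u.atoms)",
    "np.savetxt(ref, np.vstack(frames))"), script)
  st <- system2(py, c(script, top, dcd, ref), stdout = TRUE, stderr = TRUE)
  expect_false(isTRUE(attr(st, "status") > 0))
  ens <- load_ensemble(top, dcd)
  expect_equal(n_frames(ens), 4L)
  want <- matrix(scan(ref, quiet = TRUE), ncol = 3, byrow = TRUE)
  expect_equal(frame_coords(ens, 1), want[1:6, ], tolerance = 1e-4)
  expect_equal(frame_coords(ens, 4), want[19:24, ], tolerance = 1e-4)
})
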