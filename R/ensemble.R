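#' Coordinate ensembles
#'
#' A `coordinate_ensemble` is the trajectory abstraction used throughout the
#' package: an ordered set of frames holding the 3D coordinates (in Angstrom)
#' of one fixed atom selection, plus per-atom metadata and per-frame times
#' (in picoseconds).
#'
#' @param coords numeric array of dimension `n_frames x n_atoms x 3`, Angstrom.
#' @param times optional numeric vector of frame times (ps), strictly
#'   increasing. When absent, frame indices `0, 1, 2, ...` are used so that
#'   striding semantics still apply.
#' @param atom_meta optional data.frame with columns `res_index` (1-based
#'   integer), `res_name`, `atom_name`, one row per atom.
#' @param source provenance string.
#' @return an object of class `coordinate_ensemble`.
#' @export
coordinate_ensemble <- function(coords, times = NULL, atom_meta = NULL,
                                source = "memory") {
  d <- dim(coords)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("integrity error: coords must be an n_frames x n_atoms x 3 array")
  n_frames <- d[1]; n_atoms <- d[2]
  if (n_frames < 1L)
    stop("integrity error: ensemble must contain at least one frame")
  if (!all(is.finite(coords)))
    stop("integrity error: non-finite coordinates")
  if (is.null(times)) {
    times <- as.numeric(seq_len(n_frames) - 1L)
  } else {
    times <- as.numeric(times)
    if (length(times) != n_frames)
      stop("integrity error: times length must equal n_frames")
    if (n_frames > 1L && any(diff(times) <= 0))
      stop("integrity error: times must be strictly increasing")
  }
  if (is.null(atom_meta)) {
    atom_meta <- data.frame(res_index = seq_len(n_atoms),
                            res_name = rep("GLY", n_atoms),
                            atom_name = rep("CA", n_atoms),
                            stringsAsFactors = FALSE)
  }
  if (nrow(atom_meta) != n_atoms)
    stop("integrity error: atom_meta must have one row per atom")
  stopifnot(all(c("res_index", "res_name", "atom_name") %in% names(atom_meta)))
  structure(list(coords = coords, times = times,
                 atom_meta = atom_meta, source = source),
            class = "coordinate_ensemble")
}

#' @export
print.coordinate_ensemble <- function(x, ...) {
  cat(sprintf("<coordinate_ensemble> %d frames x %d atoms  [%s]\n",
              n_frames(x), n_atoms(x), x$source))
  invisible(x)
}

#' Number of frames / atoms in an ensemble
#' @param ensemble a `coordinate_ensemble`.
#' @return integer count.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(ensemble) dim(ensemble$coords)[2]

#' Extract one frame as an m x 3 coordinate matrix
#' @param ensemble a `coordinate_ensemble`.
#' @param frame_index 1-based frame index.
#' @return numeric matrix `n_atoms x 3`.
#' @export
frame_coords <- function(ensemble, frame_index) {
  nf <- n_frames(ensemble)
  if (frame_index < 1L || frame_index > nf)
    stop(sprintf("index error: frame %d out of range [1, %d]", frame_index, nf))
  matrix(ensemble$coords[frame_index, , ], ncol = 3L)
}

## ---- atom selection ---------------------------------------------------

#' Resolve an atom-selection expression against atom metadata
#'
#' The selection mini-language supports `"calpha"` (alpha carbons, the
#' default), `"all"`, `"name <ATOM>"`, and `"protein and name <ATOM>"`.
#' Matching atoms are returned ordered by residue index, ties broken by atom
#' name, so that node identity is stable across frames.
#'
#' @param atom_meta data.frame with `res_index`, `res_name`, `atom_name`.
#' @param expression selection string.
#' @return integer indices into `atom_meta`, in canonical node order.
#' @export
select_atoms <- function(atom_meta, expression = "calpha") {
  expr <- tolower(trimws(expression))
  keep <- if (expr %in% c("calpha", "name ca", "protein and name ca")) {
    toupper(trimws(atom_meta$atom_name)) == "CA"
  } else if (expr == "all") {
    rep(TRUE, nrow(atom_meta))
  } else if (grepl("^(protein and )?name \\S+$", expr)) {
    nm <- toupper(sub("^(protein and )?name ", "", expr))
    toupper(trimws(atom_meta$atom_name)) == nm
  } else {
    stop(sprintf("selection error: unsupported selection expression '%s'",
                 expression))
  }
  idx <- which(keep)
  if (length(idx) == 0L)
    stop(sprintf("selection error: expression '%s' matches no atoms", expression))
  nm <- atom_meta$atom_name[idx]
  idx[order(atom_meta$res_index[idx], nm)]
}

## ---- format readers ---------------------------------------------------

parse_pdb_models <- function(lines, path = "<pdb>") {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  has_model <- any(grepl("^MODEL", lines))
  model_id <- integer(length(lines))
  if (has_model) {
    cur <- 0L
    starts <- grepl("^MODEL", lines)
    model_id <- cumsum(starts)
    ends <- grepl("^ENDMDL", lines)
    # atoms before the first MODEL or after ENDMDL belong to no model
    open <- cumsum(starts) - cumsum(ends)
    model_id[open < 1L] <- 0L
    keep <- is_atom & model_id > 0L
  } else {
    keep <- is_atom
    model_id[keep] <- 1L
  }
  if (!any(keep))
    stop(sprintf("format error: no ATOM records in %s", path))
  al <- lines[keep]
  mid <- model_id[keep]
  atom_name <- trimws(substr(al, 13, 16))
  res_name  <- trimws(substr(al, 18, 20))
  res_index <- suppressWarnings(as.integer(substr(al, 23, 26)))
  x <- suppressWarnings(as.numeric(substr(al, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(al, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(al, 47, 54)))
  if (anyNA(x) || anyNA(y) || anyNA(z) || anyNA(res_index))
    stop(sprintf("format error: malformed ATOM record in %s", path))
  models <- sort(unique(mid))
  counts <- tabulate(match(mid, models))
  if (length(unique(counts)) != 1L)
    stop(sprintf("integrity error: atom count differs across models in %s", path))
  first <- mid == models[1]
  meta <- data.frame(res_index = res_index[first], res_name = res_name[first],
                     atom_name = atom_name[first], stringsAsFactors = FALSE)
  coords <- lapply(models, function(m) {
    sel <- mid == m
    cbind(x[sel], y[sel], z[sel])
  })
  list(atoms = meta, coords = coords)
}

parse_gro_frames <- function(lines, path = "<gro>") {
  frames <- list(); meta <- NULL
  i <- 1L; nl <- length(lines)
  while (i <= nl) {
    if (!nzchar(trimws(lines[i])) && i == nl) break
    if (i + 1L > nl) break
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 1L)
      stop(sprintf("format error: bad atom count at line %d in %s", i + 1L, path))
    if (i + 1L + nat + 1L > nl)
      stop(sprintf("format error: truncated frame in %s", path))
    al <- lines[(i + 2L):(i + 1L + nat)]
    res_index <- suppressWarnings(as.integer(substr(al, 1, 5)))
    res_name  <- trimws(substr(al, 6, 10))
    atom_name <- trimws(substr(al, 11, 15))
    x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
    y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
    z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
    if (anyNA(x) || anyNA(y) || anyNA(z))
      stop(sprintf("format error: malformed coordinate line in %s", path))
    if (is.null(meta)) {
      meta <- data.frame(res_index = res_index, res_name = res_name,
                         atom_name = atom_name, stringsAsFactors = FALSE)
    } else if (nat != nrow(meta)) {
      stop(sprintf("integrity error: atom count differs across frames in %s", path))
    }
    frames[[length(frames) + 1L]] <- cbind(x, y, z) * 10  # nm -> Angstrom
    i <- i + 1L + nat + 2L  # title + count + atoms + box line
  }
  if (length(frames) == 0L)
    stop(sprintf("format error: no frames in %s", path))
  list(atoms = meta, coords = frames)
}

read_dcd_coords <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  rd_int <- function(n, endian) readBin(con, "integer", n, size = 4L, endian = endian)
  endian <- "little"
  m <- rd_int(1L, endian)
  if (length(m) == 0L) stop(sprintf("format error: empty DCD file %s", path))
  if (m != 84L) {
    endian <- "big"
    seek(con, 0L)
    m <- rd_int(1L, endian)
    if (m != 84L) stop(sprintf("format error: %s is not a DCD file", path))
  }
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (magic != "CORD") stop(sprintf("format error: %s is not a CORD DCD file", path))
  icntrl <- rd_int(20L, endian)
  rd_int(1L, endian)                       # closing record marker
  has_cell <- icntrl[11] == 1L
  if (icntrl[12] == 1L) stop("format error: 4D DCD trajectories are unsupported")
  tlen <- rd_int(1L, endian)
  ntitle <- rd_int(1L, endian)
  if (ntitle > 0L) readBin(con, "raw", 80L * ntitle)
  rd_int(1L, endian)
  rd_int(1L, endian)
  natoms <- rd_int(1L, endian)
  rd_int(1L, endian)
  frames <- list()
  repeat {
    if (has_cell) {
      mm <- rd_int(1L, endian)
      if (length(mm) == 0L) break
      readBin(con, "double", 6L, size = 8L, endian = endian)
      rd_int(1L, endian)
    }
    mm <- rd_int(1L, endian)
    if (length(mm) == 0L) break
    xyz <- matrix(0, natoms, 3L)
    for (k in 1:3) {
      if (k > 1L) rd_int(1L, endian)
      v <- readBin(con, "double", natoms, size = 4L, endian = endian)
      if (length(v) < natoms)
        stop(sprintf("format error: truncated frame in %s", path))
      xyz[, k] <- v
      rd_int(1L, endian)
    }
    frames[[length(frames) + 1L]] <- xyz
  }
  if (length(frames) == 0L)
    stop(sprintf("format error: no frames in %s", path))
  frames
}

# XTC/TRR are compressed binary formats; decoding is delegated to the
# MDAnalysis bridge (python subprocess in the same environment).
read_traj_via_python <- function(topology, trajectory) {
  py <- Sys.which("python")
  if (!nzchar(py))
    stop("format error: XTC/TRR support requires a python interpreter with MDAnalysis")
  out <- tempfile(fileext = ".txt")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "import MDAnalysis as mda",
    "top, trj, out = sys.argv[1], sys.argv[2], sys.argv[3]",
    "u = mda.Universe(top, trj)",
    "with open(out, 'w') as fh:",
    "    fh.write('%d %d\\n' % (len(u.trajectory), len(u.atoms)))",
    "    for ts in u.trajectory:",
    "        for p in u.atoms.positions:",
    "            fh.write('%.8f %.8f %.8f\\n' % (p[0], p[1], p[2]))"
  ), script)
  st <- system2(py, c(script, shQuote(topology), shQuote(trajectory), shQuote(out)),
                stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(st, "status")) && attr(st, "status") != 0L)
    stop(sprintf("format error: MDAnalysis failed to read %s:\n%s",
                 trajectory, paste(st, collapse = "\n")))
  hdr <- scan(out, what = integer(), n = 2L, quiet = TRUE)
  dat <- matrix(scan(out, what = double(), skip = 1L, quiet = TRUE),
                ncol = 3L, byrow = TRUE)
  lapply(seq_len(hdr[1]), function(f)
    dat[((f - 1L) * hdr[2] + 1L):(f * hdr[2]), , drop = FALSE])
}

#' Load a trajectory into a coordinate ensemble
#'
#' Reads a topology (PDB or GRO) and optionally a coordinate trajectory
#' (multi-model PDB, multi-frame GRO, DCD, or XTC/TRR via the MDAnalysis
#' bridge), restricts atoms to `selection`, and returns a
#' [coordinate_ensemble()]. With no trajectory argument the topology's own
#' models/frames are used.
#'
#' @param topology path to a PDB or GRO file.
#' @param trajectory optional path to a trajectory file.
#' @param selection selection expression, see [select_atoms()].
#' @return a `coordinate_ensemble` with atoms in canonical node order.
#' @export
load_ensemble <- function(topology, trajectory = NULL, selection = "calpha") {
  if (!file.exists(topology))
    stop(sprintf("format error: topology file '%s' does not exist", topology))
  ext <- tolower(tools::file_ext(topology))
  top <- switch(ext,
    pdb = parse_pdb_models(readLines(topology, warn = FALSE), topology),
    gro = parse_gro_frames(readLines(topology, warn = FALSE), topology),
    stop(sprintf("format error: unsupported topology format '.%s'", ext)))
  frames <- top$coords
  if (!is.null(trajectory)) {
    if (!file.exists(trajectory))
      stop(sprintf("format error: trajectory file '%s' does not exist", trajectory))
    text <- tolower(tools::file_ext(trajectory))
    frames <- switch(text,
      pdb = parse_pdb_models(readLines(trajectory, warn = FALSE), trajectory)$coords,
      gro = parse_gro_frames(readLines(trajectory, warn = FALSE), trajectory)$coords,
      dcd = read_dcd_coords(trajectory),
      xtc = ,
      trr = read_traj_via_python(topology, trajectory),
      stop(sprintf("format error: unsupported trajectory format '.%s'", text)))
    nat <- unique(vapply(frames, nrow, integer(1)))
    if (length(nat) != 1L)
      stop("integrity error: atom count differs across trajectory frames")
    if (nat != nrow(top$atoms))
      stop(sprintf("integrity error: trajectory has %d atoms but topology has %d",
                   nat, nrow(top$atoms)))
  }
  idx <- select_atoms(top$atoms, selection)
  nf <- length(frames)
  coords <- array(0, dim = c(nf, length(idx), 3L))
  for (f in seq_len(nf)) coords[f, , ] <- frames[[f]][idx, , drop = FALSE]
  coordinate_ensemble(coords,
                      atom_meta = top$atoms[idx, , drop = FALSE],
                      source = paste(c(topology, trajectory), collapse = " + "))
}

## ---- striding ---------------------------------------------------------

#' Subsample an ensemble at a fixed frame interval
#'
#' Keeps frames `1, 1+stride, 1+2*stride, ...`. Times follow the kept frames
#' so label alignment by index is preserved.
#'
#' @param ensemble a `coordinate_ensemble`.
#' @param stride positive integer.
#' @return a strided `coordinate_ensemble`.
#' @export
stride_ensemble <- function(ensemble, stride) {
  if (length(stride) != 1L || is.na(stride) || stride < 1 ||
      stride != as.integer(stride))
    stop("argument error: stride must be a positive integer")
  idx <- seq(1L, n_frames(ensemble), by = as.integer(stride))
  coordinate_ensemble(ensemble$coords[idx, , , drop = FALSE],
                      times = ensemble$times[idx],
                      atom_meta = ensemble$atom_meta,
                      source = sprintf("%s [stride %d]", ensemble$source, stride))
}

## ---- internal delimited format ----------------------------------------

#' Write / read the package's delimited ensemble format
#'
#' A plain-text format chosen for diffability: a header block (frame and
#' atom counts, provenance, times), per-atom metadata lines, then one
#' `x y z` row per atom per frame. Round-trips coordinates to at least six
#' significant digits and metadata exactly.
#'
#' @param ensemble a `coordinate_ensemble`.
#' @param path file path.
#' @return `write_ensemble` returns `path` invisibly; `read_ensemble`
#'   returns a `coordinate_ensemble`.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "coordinate_ensemble"))
  nf <- n_frames(ensemble); na <- n_atoms(ensemble)
  if (nf < 1L) stop("integrity error: refusing to write an empty ensemble")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("#mdembed-ensemble v1",
               sprintf("nframes %d", nf),
               sprintf("natoms %d", na),
               sprintf("source %s", ensemble$source),
               paste(c("times", sprintf("%.10g", ensemble$times)), collapse = " ")),
             con)
  writeLines(sprintf("atom %d %s %s", ensemble$atom_meta$res_index,
                     ensemble$atom_meta$res_name, ensemble$atom_meta$atom_name),
             con)
  for (f in seq_len(nf)) {
    writeLines(sprintf("frame %d", f), con)
    m <- frame_coords(ensemble, f)
    writeLines(sprintf("%.10g %.10g %.10g", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  if (!file.exists(path))
    stop(sprintf("parse error: file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  fail <- function(ln, why) stop(sprintf("parse error at line %d: %s", ln, why))
  if (length(lines) < 5L || lines[1] != "#mdembed-ensemble v1")
    fail(1L, "missing '#mdembed-ensemble v1' header")
  get_kv <- function(ln, key) {
    parts <- strsplit(lines[ln], " ", fixed = TRUE)[[1]]
    if (parts[1] != key) fail(ln, sprintf("expected '%s'", key))
    parts[-1]
  }
  nf <- suppressWarnings(as.integer(get_kv(2L, "nframes")[1]))
  na <- suppressWarnings(as.integer(get_kv(3L, "natoms")[1]))
  if (is.na(nf) || is.na(na) || nf < 1L || na < 1L) fail(2L, "bad counts")
  src <- paste(get_kv(4L, "source"), collapse = " ")
  times <- suppressWarnings(as.numeric(get_kv(5L, "times")))
  if (length(times) != nf || anyNA(times)) fail(5L, "bad times vector")
  ln <- 6L
  am <- strsplit(lines[ln:(ln + na - 1L)], " ", fixed = TRUE)
  if (any(vapply(am, function(p) length(p) != 4L || p[1] != "atom", logical(1))))
    fail(ln, "malformed atom line")
  meta <- data.frame(
    res_index = as.integer(vapply(am, `[`, "", 2L)),
    res_name = vapply(am, `[`, "", 3L),
    atom_name = vapply(am, `[`, "", 4L), stringsAsFactors = FALSE)
  ln <- ln + na
  coords <- array(0, dim = c(nf, na, 3L))
  for (f in seq_len(nf)) {
    if (ln > length(lines) || lines[ln] != sprintf("frame %d", f))
      fail(min(ln, length(lines)), sprintf("expected 'frame %d'", f))
    if (ln + na > length(lines)) fail(length(lines), "truncated frame block")
    vals <- suppressWarnings(
      as.numeric(unlist(strsplit(lines[(ln + 1L):(ln + na)], " ", fixed = TRUE))))
    if (length(vals) != 3L * na || anyNA(vals))
      fail(ln + 1L, "malformed coordinate row")
    coords[f, , ] <- matrix(vals, ncol = 3L, byrow = TRUE)
    ln <- ln + na + 1L
  }
  coordinate_ensemble(coords, times = times, atom_meta = meta, source = src)
}

#' Export one frame as a single-model PDB file
#'
#' @param ensemble a `coordinate_ensemble`.
#' @param frame_index 1-based frame index.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_frame_pdb <- function(ensemble, frame_index, path) {
  m <- frame_coords(ensemble, frame_index)
  meta <- ensemble$atom_meta
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
    seq_len(nrow(m)), substr(meta$atom_name, 1, 4), substr(meta$res_name, 1, 3),
    meta$res_index, m[, 1], m[, 2], m[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}
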