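# Fixtures are built in code: no binary data ships with the package.

# random coordinate ensemble (frames x atoms x 3)
random_ensemble <- function(n_frames, n_atoms, scale = 10, seed = 1) {
  set.seed(seed)
  coordinate_ensemble(array(stats::rnorm(n_frames * n_atoms * 3) * scale,
                            c(n_frames, n_atoms, 3)))
}

# brute-force pairwise distance oracle (naive double loop)
oracle_distances <- function(x) {
  m <- nrow(x)
  out <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      out[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
    }
  }
  out
}

# brute-force contact graph oracle: exhaustive pair enumeration
oracle_graph_edges <- function(x, cutoff) {
  dm <- oracle_distances(x)
  m <- nrow(x)
  rows <- list()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (dm[i, j] < cutoff) {
        rows[[length(rows) + 1]] <-
          data.frame(i = i, j = j, weight = 1 - dm[i, j] / cutoff)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(i = integer(), j = integer(), weight = numeric()))
  do.call(rbind, rows)
}

# independent enumeration of the node2vec second-order bias rule
oracle_n2v_probs <- function(adj, prev, cur, p, q) {
  nbrs <- which(adj[cur, ] > 0)
  u <- numeric(length(nbrs))
  for (k in seq_along(nbrs)) {
    x <- nbrs[k]
    bias <- if (x == prev) 1 / p else if (adj[prev, x] > 0) 1 else 1 / q
    u[k] <- adj[cur, x] * bias
  }
  stats::setNames(u / sum(u), nbrs)
}

# small multi-model PDB text fixture, written on the fly
write_pdb_fixture <- function(path, coords_list, res_names = NULL) {
  m <- nrow(coords_list[[1]])
  if (is.null(res_names)) res_names <- rep("ALA", m)
  lines <- character(0)
  for (f in seq_along(coords_list)) {
    lines <- c(lines, sprintf("MODEL     %4d", f))
    xyz <- coords_list[[f]]
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(m), res_names, seq_len(m), xyz[, 1], xyz[, 2], xyz[, 3]))
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

random_rotation_matrix <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; cc <- q[3]; d <- q[4]
  matrix(c(a^2+b^2-cc^2-d^2, 2*(b*cc+a*d), 2*(b*d-a*cc),
           2*(b*cc-a*d), a^2-b^2+cc^2-d^2, 2*(cc*d+a*b),
           2*(b*d+a*cc), 2*(cc*d-a*b), a^2-b^2-cc^2+d^2), 3, 3)
}

# shared small two-state ensemble for embedding/classifier tests
small_two_state <- function(n_frames = 40, m = 16, seed = 5) {
  generate_ensemble(synthetic_spec(m = m, n_frames = n_frames,
                                   occupancies = c(A = 0.5, B = 0.5),
                                   transition_fraction = 0,
                                   noise_sigma = 0.4, seed = seed))
}

fast_n2v_config <- function(...) {
  embedding_config("node2vec", dimension = 6, seed = 7, num_walks = 3,
                   walk_length = 15, epochs = 2, window = 3, ...)
}
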