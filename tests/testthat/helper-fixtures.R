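# Shared fixtures, built once per test run. All generators are seeded, so
# everything here is deterministic.

fx <- new.env()

fx_ideal <- function() {
  if (is.null(fx$ideal)) fx$ideal <- build_ideal_helix()
  fx$ideal
}

fx_kinked30 <- function() {
  if (is.null(fx$kinked30)) {
    fx$kinked30 <- build_kinked_helix(kink = kink_spec(target_bend_deg = 30))
  }
  fx$kinked30
}

fx_frame <- function() membrane_frame()  # default +/-19 A phosphate planes

# small on-disk ensemble PDB, written once per run
tempfile_pdb <- function() {
  if (is.null(fx$pdb_path) || !file.exists(fx$pdb_path)) {
    fx$pdb_path <- file.path(tempdir(), "helixkink-test-ens.pdb")
    write_pdb_ensemble(sample_ensemble(fx_ideal(), 2, 3, seed = 42), fx$pdb_path)
  }
  fx$pdb_path
}

# random proper rotation matrix (seeded by caller)
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# independent brute-force Jarvis-Patrick join rule (set logic only), used
# as the oracle for the packaged implementation; neighbor lists include
# every item within the k-th smallest distance (ties kept)
jp_bruteforce <- function(D, k, kmin) {
  n <- nrow(D)
  nbrs <- lapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    dd <- vapply(others, function(j) D[i, j], numeric(1))
    cutoff <- sort(dd)[k]
    others[dd <= cutoff]
  })
  joined <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    joined[i, j] <- (j %in% nbrs[[i]]) && (i %in% nbrs[[j]]) &&
      sum(nbrs[[i]] %in% nbrs[[j]]) >= kmin
  }
  labels <- rep(-1L, n); cl <- 0L
  for (s in seq_len(n)) {
    if (labels[s] != -1L || !any(joined[s, ])) next
    cl <- cl + 1L
    comp <- s
    repeat {
      grow <- unique(unlist(lapply(comp, function(v) which(joined[v, ]))))
      grow <- setdiff(grow, comp)
      if (!length(grow)) break
      comp <- c(comp, grow)
    }
    labels[comp] <- cl
  }
  labels
}

# canonical form of a clustering partition (for order-invariance checks)
partition_sets <- function(labels) {
  noise <- which(labels == -1L)
  clusters <- lapply(unique(labels[labels > 0]), function(l) sort(which(labels == l)))
  clusters <- clusters[order(vapply(clusters, min, integer(1)))]
  list(noise = sort(noise), clusters = clusters)
}
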