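## Sparse ensemble selection against RDCs with a genetic algorithm, and
## Jarvis-Patrick clustering of the selected conformers.
##
## Fitness of a candidate subset is the Q-factor of a single SVD tensor fit
## to the subset-averaged design matrix (one alignment medium implies one
## tensor). The chromosome is a fixed-size index subset (binary mask with
## repair); selection is tournament (size 3), crossover is uniform on the
## mask, mutation swaps members in/out.

#' Genetic-algorithm selection of a sub-ensemble fitting RDCs
#'
#' @param pool a `StructureEnsemble` (the conformer pool).
#' @param rdcs data frame with columns `residue`, `d_exp`.
#' @param ensemble_size subset size to select.
#' @param population GA population size.
#' @param generations number of generations.
#' @param crossover_rate probability of uniform crossover per offspring.
#' @param mutation_rate per-slot probability of swapping a selected member
#'   for a random outside member (default 1/pool size).
#' @param elitism number of best individuals copied unchanged.
#' @param seed RNG seed; the result is reproducible bit-for-bit.
#' @return an `EnsembleFit`: list with `selected` (pool indices), `tensor`,
#'   `d_calc`, `d_exp`, `residues`, `q_factor`, and `history` (best Q per
#'   generation).
#' @export
ga_select_ensemble <- function(pool, rdcs, ensemble_size = 10,
                               population = 100, generations = 200,
                               crossover_rate = 0.8, mutation_rate = NULL,
                               elitism = 1, seed = 1) {
  members <- pool$members
  npool <- length(members)
  if (ensemble_size < 1 || ensemble_size > npool) {
    stop("need pool size >= ensemble_size >= 1")
  }
  if (population < 2 || generations < 1 || crossover_rate < 0 || crossover_rate > 1 ||
      elitism < 0 || elitism >= population) {
    stop("invalid GA parameters")
  }
  if (is.null(mutation_rate)) mutation_rate <- 1 / npool
  Ms <- ensemble_design_matrices(members, rdcs)
  d_exp <- attr(Ms, "d_exp"); residues <- attr(Ms, "residues")
  nres <- length(d_exp)
  # flatten: row c of Mflat is conformer c's design matrix, column-major
  Mflat <- t(vapply(Ms, as.numeric, numeric(nres * 5)))
  rms_d <- sqrt(sum(d_exp^2))

  fitness_of_masks <- function(masks) {
    # masks: population x npool 0/1 matrix with fixed row sums
    Avg <- (masks %*% Mflat) / ensemble_size
    vapply(seq_len(nrow(masks)), function(j) {
      M <- matrix(Avg[j, ], nres, 5)
      sv <- svd(M)
      keep <- sv$d > max(dim(M)) * .Machine$double.eps * sv$d[1]
      s <- sv$v[, keep, drop = FALSE] %*%
        (crossprod(sv$u[, keep, drop = FALSE], d_exp) / sv$d[keep])
      sqrt(sum((M %*% s - d_exp)^2)) / rms_d
    }, numeric(1))
  }

  repair <- function(mask) {
    k <- sum(mask)
    if (k > ensemble_size) {
      on <- which(mask == 1L)
      mask[sample(on, k - ensemble_size)] <- 0L
    } else if (k < ensemble_size) {
      off <- which(mask == 0L)
      mask[sample(off, ensemble_size - k)] <- 1L
    }
    mask
  }

  set.seed(seed)
  popm <- t(vapply(seq_len(population), function(j) {
    m <- integer(npool); m[sample.int(npool, ensemble_size)] <- 1L; m
  }, integer(npool)))
  fit <- fitness_of_masks(popm)
  best_mask <- popm[which.min(fit), ]; best_q <- min(fit)
  history <- numeric(generations)

  for (g in seq_len(generations)) {
    ord <- order(fit)
    newpop <- matrix(0L, population, npool)
    if (elitism > 0) newpop[seq_len(elitism), ] <- popm[ord[seq_len(elitism)], , drop = FALSE]
    for (j in seq(elitism + 1, population)) {
      # tournament selection, size 3
      pick <- function() {
        cand <- sample.int(population, 3)
        cand[which.min(fit[cand])]
      }
      p1 <- popm[pick(), ]; p2 <- popm[pick(), ]
      child <- if (stats::runif(1) < crossover_rate) {
        take <- stats::runif(npool) < 0.5
        ifelse(take, p1, p2)
      } else p1
      child <- repair(as.integer(child))
      # mutation: swap members in/out, preserving size
      nmut <- stats::rbinom(1, ensemble_size, min(1, mutation_rate * npool / ensemble_size))
      if (nmut > 0) {
        on <- which(child == 1L); off <- which(child == 0L)
        nmut <- min(nmut, length(on), length(off))
        if (nmut > 0) {
          child[sample(on, nmut)] <- 0L
          child[sample(off, nmut)] <- 1L
        }
      }
      newpop[j, ] <- child
    }
    popm <- newpop
    fit <- fitness_of_masks(popm)
    if (min(fit) < best_q) { best_q <- min(fit); best_mask <- popm[which.min(fit), ] }
    history[g] <- best_q
  }

  selected <- which(best_mask == 1L)
  sub <- fit_ensemble_rdc(members[selected], data.frame(residue = residues, d_exp = d_exp))
  structure(list(selected = selected, tensor = sub$tensor, d_calc = sub$d_calc,
                 d_exp = d_exp, residues = residues, q_factor = sub$q_factor,
                 history = history, params = list(ensemble_size = ensemble_size,
                                                  population = population,
                                                  generations = generations,
                                                  crossover_rate = crossover_rate,
                                                  mutation_rate = mutation_rate,
                                                  elitism = elitism, seed = seed)),
            class = "EnsembleFit")
}

#' @export
print.EnsembleFit <- function(x, ...) {
  cat(sprintf("<EnsembleFit: %d conformers selected, Q = %.4f>\n",
              length(x$selected), x$q_factor))
  invisible(x)
}

#' Q-factor of random subsets (baseline for the GA)
#'
#' Evaluates `n_subsets` uniformly drawn fixed-size subsets and returns the
#' best (smallest) Q observed, with the full sample as an attribute.
#'
#' @inheritParams ga_select_ensemble
#' @param n_subsets number of random subsets to score.
#' @return best Q (numeric scalar) with attribute `all`.
#' @export
random_subset_baseline <- function(pool, rdcs, ensemble_size = 10,
                                   n_subsets = 1000, seed = 1) {
  members <- pool$members
  Ms <- ensemble_design_matrices(members, rdcs)
  d_exp <- attr(Ms, "d_exp")
  nres <- length(d_exp)
  Mflat <- t(vapply(Ms, as.numeric, numeric(nres * 5)))
  rms_d <- sqrt(sum(d_exp^2))
  set.seed(seed)
  qs <- vapply(seq_len(n_subsets), function(k) {
    idx <- sample.int(length(members), ensemble_size)
    M <- matrix(colMeans(Mflat[idx, , drop = FALSE]), nres, 5)
    sv <- svd(M)
    keep <- sv$d > max(dim(M)) * .Machine$double.eps * sv$d[1]
    s <- sv$v[, keep, drop = FALSE] %*%
      (crossprod(sv$u[, keep, drop = FALSE], d_exp) / sv$d[keep])
    sqrt(sum((M %*% s - d_exp)^2)) / rms_d
  }, numeric(1))
  structure(min(qs), all = qs)
}

#' Pairwise superposed-RMSD matrix of an ensemble
#'
#' @param ensemble a `StructureEnsemble`.
#' @param selection as in [superpose()] (default backbone N, CA, C over all
#'   shared residues).
#' @return symmetric n x n matrix of RMSDs in Angstrom.
#' @export
rmsd_matrix <- function(ensemble, selection = NULL) {
  n <- n_members(ensemble)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      D[i, j] <- D[j, i] <- superpose(ensemble$members[[i]],
                                      ensemble$members[[j]], selection)$rmsd
    }
  }
  D
}

#' Jarvis-Patrick clustering
#'
#' Two items join the same cluster iff each is among the other's
#' `k_neighbors` nearest neighbors AND they share at least `k_min_shared`
#' of those neighbor lists; clusters are the connected components of the
#' resulting join graph. Items joining nothing are labeled -1
#' (singleton/noise). Items tied at the k-th neighbor distance are all
#' included in the neighbor list (so the result does not depend on input
#' order; in particular a set of identical conformers forms one cluster).
#'
#' @param x a `StructureEnsemble` (distances = pairwise superposed backbone
#'   RMSD over `selection`) or a precomputed symmetric distance matrix.
#' @param k_neighbors neighbor list length (must be < number of items).
#' @param k_min_shared minimum shared neighbors (<= k_neighbors).
#' @param selection passed to [rmsd_matrix()] when `x` is an ensemble.
#' @return a `ClusterResult`: list with `labels` (cluster id per item, -1 =
#'   noise), `k_neighbors`, `k_min_shared`.
#' @export
jarvis_patrick <- function(x, k_neighbors = 6, k_min_shared = 3,
                           selection = NULL) {
  D <- if (inherits(x, "StructureEnsemble")) rmsd_matrix(x, selection) else as.matrix(x)
  n <- nrow(D)
  if (n < 2) stop("need at least 2 items to cluster")
  if (k_min_shared > k_neighbors) stop("k_min_shared must be <= k_neighbors")
  if (k_neighbors >= n) stop("k_neighbors must be smaller than the number of items")
  # k nearest neighbors of each item (self excluded); all ties at the k-th
  # distance are included
  nbrs <- lapply(seq_len(n), function(i) {
    others <- seq_len(n)[-i]
    d <- D[i, others]
    thr <- sort(d)[k_neighbors]
    others[d <= thr]
  })
  join <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      mutual <- (j %in% nbrs[[i]]) && (i %in% nbrs[[j]])
      shared <- length(intersect(nbrs[[i]], nbrs[[j]]))
      join[i, j] <- join[j, i] <- mutual && shared >= k_min_shared
    }
  }
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != -1L || !any(join[i, ])) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(join[v, ] & labels == -1L)
      labels[nb] <- cl
      queue <- c(queue, nb)
    }
  }
  structure(list(labels = labels, k_neighbors = k_neighbors,
                 k_min_shared = k_min_shared),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  k <- length(unique(x$labels[x$labels > 0]))
  cat(sprintf("<ClusterResult: %d clusters, %d noise of %d items>\n",
              k, sum(x$labels == -1L), length(x$labels)))
  invisible(x)
}
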