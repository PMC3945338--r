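# N-H vectors, SVD tensor fit, Q-factor, GA selection and clustering.

test_that("N-H vectors use explicit hydrogens and rebuild stripped ones", {
  h <- fx_ideal()
  v <- nh_vectors(h)
  # explicit H: vector is exactly normalize(H - N)
  r <- v$resno[5]
  N <- helixkink:::get_atom(h, r, "N"); H <- helixkink:::get_atom(h, r, "H")
  expect_equal(v$vectors[5, ], (H - N) / sqrt(sum((H - N)^2)), tolerance = 1e-12)
  # unit length
  expect_equal(rowSums(v$vectors^2), rep(1, nrow(v$vectors)), tolerance = 1e-12)
  # strip H and rebuild: within 5 degrees for ideal geometry
  stripped <- h
  stripped$atoms <- stripped$atoms[stripped$atoms$atom != "H", ]
  v2 <- nh_vectors(stripped)
  expect_equal(v2$resno, v$resno)
  ang <- acos(pmin(1, rowSums(v$vectors * v2$vectors))) * 180 / pi
  expect_lt(max(ang), 5)
  # residue missing N is skipped, or an error in strict mode
  broken <- stripped
  broken$atoms <- broken$atoms[!(broken$atoms$resno == 705 & broken$atoms$atom == "N"), ]
  expect_false(705 %in% nh_vectors(broken)$resno)
  expect_error(nh_vectors(broken, strict = TRUE), "705")
})

test_that("noise-free synthetic couplings give exact tensor recovery", {
  h <- fx_ideal()
  truth <- random_tensor(3)
  sr <- synth_rdc(h, tensor = truth, noise_sigma = 0)
  v <- nh_vectors(h)
  V <- v$vectors[match(sr$records$residue, v$resno), ]
  expect_gte(nrow(V), 20)
  fit <- svd_fit_tensor(V, sr$records)
  expect_lt(max(abs(fit$saupe - truth$saupe)), 1e-8)
  expect_lt(abs(sum(diag(fit$saupe))), 1e-12)
  expect_lt(q_factor(backcalc_rdc(fit, V), sr$records$d_exp), 1e-8)
})

test_that("noisy couplings give a bounded Q and recover what the data determine", {
  h <- fx_ideal()
  truth <- random_tensor(6)
  clean <- synth_rdc(h, tensor = truth, noise_sigma = 0)
  sigma <- 0.1 * sqrt(mean(clean$d_true^2))
  sr <- synth_rdc(h, tensor = truth, noise_sigma = sigma, seed = 41)
  v <- nh_vectors(h)
  V <- v$vectors[match(sr$records$residue, v$resno), ]
  fit <- svd_fit_tensor(V, sr$records)
  q <- q_factor(backcalc_rdc(fit, V), sr$records$d_exp)
  expect_gt(q, 0.02)
  expect_lt(q, 0.2)
  # helix N-H vectors cluster in a cone, so the design matrix is poorly
  # conditioned and parts of the tensor are weakly determined; what the
  # data do determine - the noise-free couplings - comes back within 15%
  d_hat <- backcalc_rdc(fit, V)
  expect_lt(sqrt(mean((d_hat - clean$d_true)^2)) / sqrt(mean(clean$d_true^2)), 0.15)

  # with isotropically scattered bond vectors the tensor itself is
  # recovered within 15% at the same noise level
  set.seed(42)
  V2 <- matrix(rnorm(120), 40, 3); V2 <- V2 / sqrt(rowSums(V2^2))
  d_true <- backcalc_rdc(truth, V2)
  d_noisy <- d_true + rnorm(40, 0, 0.1 * sqrt(mean(d_true^2)))
  fit2 <- svd_fit_tensor(V2, d_noisy)
  expect_lt(norm(fit2$saupe - truth$saupe, "F") / norm(truth$saupe, "F"), 0.15)
})

test_that("tensor fit rejects too-few or degenerate inputs", {
  set.seed(1)
  V <- matrix(rnorm(12), 4, 3); V <- V / sqrt(rowSums(V^2))
  expect_error(svd_fit_tensor(V, rnorm(4)), "at least 5")
  # all vectors identical: rank deficient
  V1 <- matrix(rep(c(1, 0, 0), 8), 8, 3, byrow = TRUE)
  expect_error(svd_fit_tensor(V1, rnorm(8)), "rank")
})

test_that("back-calculation equals the explicit double sum", {
  set.seed(17)
  S <- random_tensor(17)$saupe
  V <- matrix(rnorm(30), 10, 3); V <- V / sqrt(rowSums(V^2))
  d <- backcalc_rdc(S, V)
  explicit <- sapply(seq_len(10), function(i) {
    acc <- 0
    for (k in 1:3) for (l in 1:3) acc <- acc + S[k, l] * V[i, k] * V[i, l]
    acc
  })
  expect_equal(d, explicit, tolerance = 1e-12)
  expect_equal(backcalc_rdc(matrix(0, 3, 3), V), rep(0, 10))
  # eigenvector case: coupling equals the eigenvalue
  e <- eigen(S, symmetric = TRUE)
  expect_equal(as.numeric(backcalc_rdc(S, t(e$vectors[, 1]))), e$values[1],
               tolerance = 1e-12)
})

test_that("Q-factor closed forms and scale invariance hold", {
  d <- c(1, -2, 3, 0.5)
  expect_equal(q_factor(d, d), 0)
  expect_equal(q_factor(rep(0, 4), d), 1)
  expect_equal(q_factor(2 * d, d), 1)
  expect_equal(q_factor(1.7 * c(2, 1), 1.7 * c(1, 1)), q_factor(c(2, 1), c(1, 1)),
               tolerance = 1e-12)
  expect_error(q_factor(d, rep(0, 4)), "zero")
  expect_error(q_factor(d, d[1:3]), "equal length")
})

test_that("refitting to back-calculated couplings is a projection", {
  h <- fx_ideal()
  sr <- synth_rdc(h, tensor = random_tensor(9), noise_sigma = 0.4, seed = 2)
  v <- nh_vectors(h)
  V <- v$vectors[match(sr$records$residue, v$resno), ]
  fit1 <- svd_fit_tensor(V, sr$records)
  d1 <- backcalc_rdc(fit1, V)
  fit2 <- svd_fit_tensor(V, d1)
  expect_lt(max(abs(fit1$saupe - fit2$saupe)), 1e-10)
})

test_that("RDC tables round-trip through TSV", {
  tb <- data.frame(residue = 700:710, d_exp = round(rnorm(11), 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rdc_table(tb, path)
  back <- read_rdc_table(path)
  expect_equal(back$residue, tb$residue)
  expect_equal(back$d_exp, tb$d_exp)
})

test_that("GA finds a planted generating structure among decoys", {
  h <- fx_ideal()
  decoys <- sample_ensemble(fx_kinked30(), 20, 6, seed = 3)$members
  pool <- structure_ensemble(c(list(h), decoys))
  sr <- synth_rdc(h, tensor = random_tensor(4), noise_sigma = 0)
  fit <- ga_select_ensemble(pool, sr$records, ensemble_size = 1,
                            population = 40, generations = 40, seed = 7)
  expect_equal(fit$selected, 1L)
  expect_lt(fit$q_factor, 1e-8)
})

test_that("GA beats a 10x random-subset budget and is seed-reproducible", {
  h <- fx_ideal()
  pool <- structure_ensemble(c(sample_ensemble(h, 15, 5, seed = 21)$members,
                               sample_ensemble(fx_kinked30(), 15, 5, seed = 22)$members))
  sr <- synth_rdc(list(h, fx_kinked30()), tensor = random_tensor(8),
                  mixture_weights = c(0.5, 0.5), noise_sigma = 0.05, seed = 5)
  fit <- ga_select_ensemble(pool, sr$records, ensemble_size = 4,
                            population = 20, generations = 30, seed = 10)
  baseline <- random_subset_baseline(pool, sr$records, ensemble_size = 4,
                                     n_subsets = 10 * 20 * 30, seed = 10)
  expect_lte(fit$q_factor, as.numeric(baseline) + 1e-12)
  # bit-for-bit reproducibility
  fit2 <- ga_select_ensemble(pool, sr$records, ensemble_size = 4,
                             population = 20, generations = 30, seed = 10)
  expect_identical(fit$selected, fit2$selected)
  expect_identical(fit$q_factor, fit2$q_factor)
  expect_identical(fit$history, fit2$history)
  # invalid parameters are rejected
  expect_error(ga_select_ensemble(pool, sr$records, ensemble_size = 100), "pool size")
  expect_error(ga_select_ensemble(pool, sr$records, population = 1), "GA parameters")
})

test_that("Jarvis-Patrick recovers well-separated groups and matches brute force", {
  g1 <- sample_ensemble(fx_ideal(), 5, 0.5, seed = 1)$members
  g2 <- sample_ensemble(build_kinked_helix(kink = kink_spec(target_bend_deg = 50)),
                        5, 0.5, seed = 2)$members
  cl <- jarvis_patrick(structure_ensemble(c(g1, g2)), k_neighbors = 4, k_min_shared = 2)
  expect_equal(length(unique(cl$labels)), 2)
  expect_equal(length(unique(cl$labels[1:5])), 1)
  expect_equal(length(unique(cl$labels[6:10])), 1)
  expect_true(cl$labels[1] != cl$labels[6])

  # brute-force oracle on random small distance matrices
  set.seed(33)
  for (rep in 1:8) {
    n <- sample(5:8, 1)
    P <- matrix(rnorm(n * 2), n, 2)
    D <- as.matrix(dist(P))
    k <- sample(2:(n - 2), 1); kmin <- sample(1:k, 1)
    mine <- jarvis_patrick(D, k, kmin)$labels
    oracle <- jp_bruteforce(D, k, kmin)
    expect_equal(partition_sets(mine), partition_sets(oracle))
  }

  # degenerate case: identical conformers form one cluster
  same <- matrix(0, 5, 5)
  cl0 <- jarvis_patrick(same, k_neighbors = 3, k_min_shared = 2)
  expect_equal(cl0$labels, rep(1L, 5))

  # argument errors
  expect_error(jarvis_patrick(same, k_neighbors = 5), "smaller")
  expect_error(jarvis_patrick(same, k_neighbors = 3, k_min_shared = 4), "<=")
})

test_that("Jarvis-Patrick partitions are invariant to input order", {
  set.seed(12)
  P <- rbind(matrix(rnorm(10, sd = 0.3), 5, 2),
             matrix(rnorm(10, mean = 6, sd = 0.3), 5, 2))
  D <- as.matrix(dist(P))
  base <- jarvis_patrick(D, 4, 2)$labels
  perm <- sample(10)
  permuted <- jarvis_patrick(D[perm, perm], 4, 2)$labels
  # map back to original indexing and compare partitions
  back <- integer(10); back[perm] <- permuted
  expect_equal(partition_sets(base), partition_sets(back))
})
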