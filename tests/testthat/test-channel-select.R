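test_that("the neighboring matrix caps shortest-path hops per the contract", {
  # path graph A-B-C
  pos3 <- data.frame(name = c("A", "B", "C"), x = c(0, 1, 2), y = 0)
  m3 <- montage_from_positions(pos3)
  d3 <- neighboring_matrix(m3, kappa_max = 2)
  expect_equal(diag(d3), rep(0L, 3), ignore_attr = TRUE)
  expect_equal(d3["A", "C"], 2L)
  expect_equal(d3["A", "B"], 1L)

  # path graph A-B-C-D with kappa_max = 2: A-D exceeds the cap -> 0
  pos4 <- data.frame(name = c("A", "B", "C", "D"), x = 0:3, y = 0)
  d4 <- neighboring_matrix(montage_from_positions(pos4), kappa_max = 2)
  expect_equal(d4["A", "D"], 0L)
  expect_equal(d4["A", "C"], 2L)

  # disconnected montage errors naming the isolated channels
  pos_bad <- data.frame(name = c("A", "B", "Z"), x = c(0, 1, 50), y = 0)
  expect_error(neighboring_matrix(montage_from_positions(pos_bad)), "Z")
})

test_that("hop counts agree with a brute-force BFS on random graphs", {
  set.seed(77)
  for (g in 1:50) {
    n <- sample(5:20, 1)
    adj <- random_connected_adj(n)
    montage <- structure(list(
      name = "toy", channel_names = paste0("c", seq_len(n)),
      positions = data.frame(name = paste0("c", seq_len(n)), x = 0, y = 0),
      adjacency = `dimnames<-`(adj, list(paste0("c", seq_len(n)),
                                         paste0("c", seq_len(n)))),
      spacing_factor = 1.1), class = "eeg_montage")
    kmax <- sample(1:4, 1)
    d <- neighboring_matrix(montage, kappa_max = kmax)
    ref <- bfs_hops(adj)
    ref[ref > kmax] <- 0
    diag(ref) <- 0
    expect_equal(unclass(d), ref, ignore_attr = TRUE)
  }
})

test_that("channel similarity is Pearson correlation on standardised features", {
  X <- matrix(rnorm(24), 4, 6, dimnames = list(paste0("c", 1:4), NULL))
  X[2, ] <- X[1, ]                          # duplicate channel
  S <- channel_similarity(X)
  expect_equal(S[1, 2], 1, tolerance = 1e-12)
  expect_equal(diag(S), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(S >= -1 - 1e-12 & S <= 1 + 1e-12))

  # direct evaluation of the correlation formula with the symmetric
  # denominator sqrt(Var(ci) Var(cj)) on the standardised feature matrix
  Z <- scale(X)
  for (i in 1:4) for (j in 1:4) {
    ci <- Z[i, ]; cj <- Z[j, ]
    ref <- sum((ci - mean(ci)) * (cj - mean(cj))) /
      sqrt(sum((ci - mean(ci))^2) * sum((cj - mean(cj))^2))
    expect_equal(S[i, j], ref, tolerance = 1e-12)
  }

  # anti-correlated channel pair (two channels: standardisation keeps the
  # exact sign flip)
  x <- c(-2.5, 1.3, -0.4, 2.2, -1.1, 0.6)
  S2 <- channel_similarity(rbind(a = x, b = -x))
  expect_equal(S2["a", "b"], -1, tolerance = 1e-12)

  # zero-variance channel flagged with zero similarities
  X3 <- rbind(flat = rep(3, 6), a = rnorm(6), b = rnorm(6))
  S3 <- channel_similarity(X3)
  expect_identical(attr(S3, "flagged"), "flat")
  expect_true(all(S3["flat", c("a", "b")] == 0))
})

test_that("affinity propagation recovers block structure and singletons", {
  # two well-separated pairs of near-identical channels; the cluster
  # signatures vary in sign across features so they survive the
  # cross-channel standardisation
  set.seed(14)
  base1 <- rnorm(10) * 3; base2 <- rnorm(10) * 3
  X <- rbind(a = base1, b = base1 + 0.05 * rnorm(10),
             c = base2, d = base2 + 0.05 * rnorm(10))
  S <- channel_similarity(X)
  cl <- affinity_propagation(S)
  expect_length(cl$exemplars, 2)
  expect_equal(cl$labels[["a"]], cl$labels[["b"]])
  expect_equal(cl$labels[["c"]], cl$labels[["d"]])
  expect_false(cl$labels[["a"]] == cl$labels[["c"]])

  # dominant preference: every point its own exemplar, L all zero
  n <- 5
  S0 <- matrix(0.1, n, n); diag(S0) <- 0
  dimnames(S0) <- list(letters[1:n], letters[1:n])
  cl0 <- affinity_propagation(S0, preference = 10)
  expect_length(cl0$exemplars, n)
  expect_true(all(cl0$L == 0))
})

test_that("co-membership matrices satisfy the exemplar-sharing contract", {
  set.seed(15)
  for (rep in 1:10) {
    X <- matrix(rnorm(8 * 12), 8, 12,
                dimnames = list(paste0("c", 1:8), NULL))
    cl <- affinity_propagation(channel_similarity(X))
    L <- cl$L
    expect_true(all(diag(L) == 0))
    expect_identical(L, t(L))
    # transitivity within clusters: L + I is block-diagonal under labels
    for (ex in unique(cl$labels)) {
      members <- names(cl$labels)[cl$labels == ex]
      if (length(members) > 1) {
        block <- L[members, members]
        expect_true(all(block[row(block) != col(block)] == 1))
      }
    }
    # every channel assigned to exactly one exemplar, all alpha_kk+rho_kk > 0
    expect_true(all(cl$labels %in% cl$exemplars))
    dAR <- diag(cl$availability) + diag(cl$responsibility)
    expect_true(all(dAR[match(cl$exemplars, rownames(L))] > 0))
  }
})

test_that("affinity propagation matches the reference implementation", {
  # AP net similarity of a labelling: sum of point-to-exemplar similarities
  # plus the preference paid per exemplar
  net_sim <- function(S, exemplars, pref) {
    idx <- match(exemplars, rownames(S))
    assigned <- idx[max.col(S[, idx, drop = FALSE], ties.method = "first")]
    assigned[idx] <- idx
    non_ex <- setdiff(seq_len(nrow(S)), idx)
    sum(S[cbind(non_ex, assigned[non_ex])]) + length(idx) * pref
  }
  set.seed(99)
  agree <- 0; not_worse <- 0; cases <- 12
  for (case in seq_len(cases)) {
    k <- sample(2:3, 1)
    ang0 <- stats::runif(1, 0, 2 * pi)
    centers <- 25 * cbind(cos(ang0 + 2 * pi * seq_len(k) / k),
                          sin(ang0 + 2 * pi * seq_len(k) / k))
    P <- NULL
    for (ci in seq_len(k)) {
      ang <- stats::runif(3, 0, 2 * pi)
      P <- rbind(P, centers[ci, , drop = FALSE],
                 sweep(1.8 * cbind(cos(ang), sin(ang)), 2, centers[ci, ], "+"))
    }
    n <- nrow(P)
    S <- -as.matrix(stats::dist(P))^2
    dimnames(S) <- list(paste0("p", 1:n), paste0("p", 1:n))
    ours <- affinity_propagation(S, damping = 0.9, preference = -50)
    out <- run_python(c(
      "import numpy as np",
      "from sklearn.cluster import AffinityPropagation",
      sprintf("P = np.array([%s]).reshape(%d, 2)",
              paste(sprintf("%.12g", t(P)), collapse = ","), n),
      "S = -((P[:,None,:] - P[None,:,:])**2).sum(-1)",
      "ap = AffinityPropagation(damping=0.9, affinity='precomputed',",
      "     preference=-50.0, random_state=0).fit(S)",
      "print(' '.join(str(i) for i in sorted(ap.cluster_centers_indices_)))"))
    ref_ex <- paste0("p", as.integer(strsplit(out[length(out)], " ")[[1]]) + 1)
    same <- identical(sort(ours$exemplars), sort(ref_ex))
    if (same) agree <- agree + 1
    # on any disagreement our solution must be at least as good under the
    # AP objective (both solvers can settle in different fixed points)
    if (same || net_sim(S, ours$exemplars, -50) >=
          net_sim(S, ref_ex, -50) - 1e-9) not_worse <- not_worse + 1
  }
  expect_gte(agree, 10)
  expect_equal(not_worse, cases)
})

test_that("permuting channels permutes the clustering identically", {
  set.seed(41)
  X <- matrix(rnorm(6 * 10), 6, 10, dimnames = list(paste0("c", 1:6), NULL))
  S <- channel_similarity(X)
  perm <- sample(6)
  Sp <- S[perm, perm]
  cl <- affinity_propagation(S)
  clp <- affinity_propagation(Sp)
  expect_setequal(clp$exemplars, cl$exemplars)
  expect_identical(clp$L[rownames(S), rownames(S)], cl$L)
})

test_that("co-activation edges blend similarity, membership and distance", {
  nm <- c("A", "B", "C")
  S <- matrix(c(1, 0.9, 0.8, 0.9, 1, -0.5, 0.8, -0.5, 1), 3, 3,
              dimnames = list(nm, nm))
  L <- matrix(c(0, 1, 1, 1, 0, 0, 1, 0, 0), 3, 3, dimnames = list(nm, nm))
  delta <- structure(matrix(c(0L, 1L, 0L, 1L, 0L, 2L, 0L, 2L, 0L), 3, 3,
                            dimnames = list(nm, nm)),
                     kappa_max = 2,
                     class = c("delta_matrix", "matrix", "array"))
  G <- build_coactivation_graph(S, L, delta)
  expect_equal(G["A", "B"], 0.9 * (1 / 3))    # adjacent pair discounted
  expect_equal(G["A", "C"], 0.8)              # beyond the cap: full weight
  expect_equal(G["B", "C"], 0)                # not co-clustered
  expect_equal(diag(G), rep(0, 3), ignore_attr = TRUE)
})

test_that("cross-epoch ranking retains consistent epochs and orders channels", {
  nm <- paste0("c", 1:4)
  mk_cl <- function(exemplar, members) {
    L <- matrix(0L, 4, 4, dimnames = list(nm, nm))
    L[members, members] <- 1L
    diag(L) <- 0L
    labels <- stats::setNames(rep(nm[1], 4), nm)
    labels[members] <- exemplar
    structure(list(exemplars = unique(c(exemplar, setdiff(nm, members))),
                   labels = labels, L = L, converged = TRUE),
              class = "ap_clustering")
  }
  G_hi <- matrix(0.8, 4, 4, dimnames = list(nm, nm)); diag(G_hi) <- 0
  cls <- list(mk_cl("c1", c("c1", "c2")), mk_cl("c1", c("c1", "c2")),
              mk_cl("c1", c("c1", "c2")), mk_cl("c3", c("c3", "c4")))
  graphs <- list(G_hi, G_hi, G_hi, G_hi * 0)
  r <- rank_channels(cls, graphs, alpha = 0.5)
  # the three identical epochs dominate the consensus and are retained
  expect_true(all(1:3 %in% r$retained_epochs))
  expect_equal(r$order[1], "c1")   # exemplar everywhere retained, max degree

  # all epochs identical: every epoch retained with consistency 1
  same <- list(mk_cl("c1", c("c1", "c2")), mk_cl("c1", c("c1", "c2")),
               mk_cl("c1", c("c1", "c2")))
  rs <- rank_channels(same, list(G_hi, G_hi, G_hi))
  expect_equal(rs$consistency, rep(1, 3))
  expect_length(rs$retained_epochs, 3)
})

test_that("top-fraction selection uses the ceiling rule deterministically", {
  set.seed(2)
  X <- matrix(rnorm(32 * 10), 32, 10, dimnames = list(paste0("c", 1:32), NULL))
  scores <- stats::setNames(sort(runif(32), decreasing = TRUE), paste0("c", 1:32))
  r <- structure(list(scores = scores, order = names(scores),
                      components = data.frame(channel = names(scores),
                                              exemplar_frequency = scores,
                                              functional_strength = scores)),
                 class = "channel_ranking")
  expect_length(select_top_fraction(r, 1), 32)
  expect_length(select_top_fraction(r, 0.1), 4)
  expect_identical(select_top_fraction(r, 0.1), select_top_fraction(r, 0.1))
  expect_error(select_top_fraction(r, 0), "fraction")
})

test_that("planted co-activating channels outrank the rest across seeds", {
  planted <- c("F3", "F4", "T7")
  wins <- 0
  n_seeds <- 10
  for (seed in seq_len(n_seeds)) {
    cfg <- synth_config(n_subjects = 1, n_trials = 1, fs_raw = 128,
                        duration = 20, effect_size = 3, seed = seed)
    ds <- generate_dataset(cfg)
    ep <- preprocess(ds$recordings[[1]][[1]], w = 2, ica = FALSE)
    ft <- extract_features(ep)
    delta <- neighboring_matrix(load_montage("standard_1020_32"), 2)
    r <- rank_trial_channels(ft, delta)
    mean_planted <- mean(match(planted, r$order))
    mean_rest <- mean(match(setdiff(r$order, planted), r$order))
    if (mean_planted < mean_rest) wins <- wins + 1
  }
  # sign test: 10/10 or 9/10 successes reject equal ranking at p < 0.05
  expect_gte(wins, 9)
})
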