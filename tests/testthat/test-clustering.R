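small_dm <- function(v) {
  structure(list(values = v,
                 frames = tibble::tibble(model = seq_len(nrow(v)),
                                         trajectory = "T1",
                                         frame = seq_len(nrow(v)))),
            class = "qg_distmat")
}

test_that("the distance matrix is symmetric, zero on the diagonal, and
           agrees with the pairwise RMSD kernel", {
  q <- ideal_quadruplex()
  ens <- perturb_ensemble(q, 0.3, 6, seed = 3)
  dm <- distance_matrix(ens)
  v <- dm$values
  expect_equal(diag(v), rep(0, 6))
  expect_equal(v, t(v), tolerance = 1e-12)
  a <- as.matrix(dplyr::filter(ens, model == 2)[, c("x", "y", "z")])
  b <- as.matrix(dplyr::filter(ens, model == 5)[, c("x", "y", "z")])
  expect_equal(v[2, 5], rmsd_coords(a, b, fit = TRUE), tolerance = 1e-12)
  # identical frames give the zero matrix
  same <- dplyr::bind_rows(purrr::map(1:3, function(m) {
    dplyr::mutate(q, model = as.integer(m))
  }))
  expect_equal(max(distance_matrix(same)$values), 0, tolerance = 1e-9)
})

test_that("k = n gives singleton clusters with populations 1/n", {
  set.seed(7)
  v <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  cl <- cluster_medoids(small_dm(v), k = 10, seed = 1)
  expect_identical(sort(unique(cl$labels)), 1:10)
  expect_equal(cl$populations, rep(0.1, 10))
  expect_equal(cl$objective, 0)
  expect_error(cluster_medoids(small_dm(v), k = 11), "between 1 and")
})

test_that("well-separated planted clusters are recovered exactly
           (adjusted Rand index 1) for any seed", {
  centers <- deformed_centers(3)
  sched <- list(rep(c(1, 2), each = 6), rep(3, 8))
  tr <- generate_trajectories(centers, sched, sigma = 0.05, seed = 11)
  dm <- distance_matrix(tr)
  truth <- attr(tr, "truth")$schedule$center
  parts <- purrr::map(c(1, 7, 42), function(s) {
    cl <- cluster_medoids(dm, 3, seed = s)
    expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1)
    cl$labels
  })
  # identical partitions across seeds (up to label names)
  expect_equal(mclust::adjustedRandIndex(parts[[1]], parts[[2]]), 1)
  expect_equal(mclust::adjustedRandIndex(parts[[1]], parts[[3]]), 1)
  # deterministic under a fixed seed
  expect_identical(cluster_medoids(dm, 3, seed = 7)$labels,
                   cluster_medoids(dm, 3, seed = 7)$labels)
})

test_that("the medoid objective matches exhaustive search for small n", {
  for (s in 1:5) {
    set.seed(s)
    v <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
    for (k in 2:3) {
      cl <- cluster_medoids(small_dm(v), k, seed = s)
      brute <- min(purrr::map_dbl(
        utils::combn(8, k, simplify = FALSE),
        function(m) sum(apply(v[, m, drop = FALSE], 1, min))))
      expect_equal(cl$objective, brute, tolerance = 1e-9)
    }
  }
})

test_that("every reported medoid minimises its own cluster's summed
           dissimilarity", {
  centers <- deformed_centers(3)
  tr <- generate_trajectories(centers, list(c(1, 1, 2, 3, 2, 1, 3, 3, 2)),
                              sigma = 0.1, seed = 13)
  dm <- distance_matrix(tr)
  cl <- cluster_medoids(dm, 3, seed = 5)
  for (c0 in 1:3) {
    members <- which(cl$labels == c0)
    sums <- colSums(dm$values[members, members, drop = FALSE])
    expect_equal(sum(dm$values[members, cl$medoid_indices[c0]]),
                 min(sums), tolerance = 1e-12)
    expect_true(cl$medoid_indices[c0] %in% members)
  }
  expect_equal(sum(cl$populations), 1, tolerance = 1e-12)
})

test_that("silhouette selection finds the planted k and flags weak
           structure", {
  centers <- deformed_centers(3)
  tr <- generate_trajectories(centers, list(rep(1:3, each = 6)),
                              sigma = 0.05, seed = 17)
  dm <- distance_matrix(tr)
  k <- select_k(dm, k_max = 10, seed = 2)
  expect_identical(as.integer(k), 3L)
  expect_false(attr(k, "weak_structure"))
  # a single diffuse blob has no structure
  blob <- generate_trajectories(centers[1], list(rep(1, 12)),
                                sigma = 0.3, seed = 19)
  kb <- select_k(distance_matrix(blob), k_max = 6, seed = 2)
  expect_true(attr(kb, "weak_structure"))
  # k_max = 2 forces k = 2
  expect_identical(as.integer(select_k(dm, k_max = 2, seed = 2)), 2L)
  expect_error(select_k(small_dm(matrix(0, 2, 2))), "at least 3")
})

test_that("transitions are counted within trajectories only", {
  # single trajectory labelled 1,1,2: one 1->2 transition
  cl <- structure(list(
    k = 2, labels = c(1L, 1L, 2L), medoid_indices = c(1L, 3L),
    populations = c(2 / 3, 1 / 3), objective = 0,
    frames = tibble::tibble(model = 1:3, trajectory = "T1",
                            frame = 1:3)), class = "qg_clusters")
  g <- transition_graph(cl)
  expect_identical(g$counts[1, 2], 1L)
  expect_identical(sum(g$counts), 1L)
  # two single-frame trajectories: no transition can be counted
  cl2 <- structure(list(
    k = 2, labels = c(1L, 2L), medoid_indices = 1:2,
    populations = c(0.5, 0.5), objective = 0,
    frames = tibble::tibble(model = 1:2, trajectory = c("T1", "T2"),
                            frame = c(1L, 1L))), class = "qg_clusters")
  expect_identical(sum(transition_graph(cl2)$counts), 0L)
})

test_that("planted switch schedules are counted exactly and survive
           trajectory permutation", {
  centers <- deformed_centers(3)
  sched <- list(c(1, 1, 2, 2, 3), c(3, 3, 3), c(2, 1, 2, 1))
  tr <- generate_trajectories(centers, sched, sigma = 0.05, seed = 23)
  dm <- distance_matrix(tr)
  cl <- cluster_medoids(dm, 3, seed = 1)
  expect_equal(mclust::adjustedRandIndex(
    cl$labels, attr(tr, "truth")$schedule$center), 1)
  g <- transition_graph(cl)
  expect_identical(sum(g$counts), attr(tr, "truth")$n_switches)
  # permuting whole-trajectory blocks leaves the total unchanged
  tr2 <- generate_trajectories(centers, sched[c(3, 1, 2)], sigma = 0.05,
                               seed = 23)
  cl2 <- cluster_medoids(distance_matrix(tr2), 3, seed = 1)
  expect_identical(sum(transition_graph(cl2)$counts),
                   attr(tr, "truth")$n_switches)
})

test_that("isolated clusters are those connected to at most one other", {
  mk <- function(counts) {
    structure(list(counts = counts,
                   edges = {
                     e <- which(counts > 0, arr.ind = TRUE)
                     tibble::tibble(from = as.integer(e[, 1]),
                                    to = as.integer(e[, 2]),
                                    count = counts[e])
                   },
                   k = nrow(counts)), class = "qg_transitions")
  }
  full <- matrix(1L, 4, 4); diag(full) <- 0L
  expect_identical(isolated_clusters(mk(full)), integer(0))
  star <- matrix(0L, 4, 4); star[1, 2:4] <- 1L
  expect_identical(isolated_clusters(mk(star)), 2:4)
  chain <- matrix(0L, 3, 3); chain[1, 2] <- 1L; chain[2, 3] <- 1L
  expect_identical(isolated_clusters(mk(chain)), c(1L, 3L))
})

test_that("tidy and glance expose the clustering in broom style", {
  centers <- deformed_centers(2)
  tr <- generate_trajectories(centers, list(c(1, 1, 2, 2)), sigma = 0.05,
                              seed = 29)
  cl <- cluster_medoids(distance_matrix(tr), 2, seed = 1)
  td <- tidy(cl)
  expect_identical(nrow(td), 4L)
  expect_identical(sum(td$is_medoid), 2L)
  gl <- glance(cl)
  expect_identical(gl$k, 2L)
  expect_identical(gl$n, 4L)
})
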