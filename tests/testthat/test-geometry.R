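test_that("dihedral matches an independent triple-product oracle and the
           IUPAC conventions", {
  # symmetry-forced values
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0),
                              c(1, 0, 0)), 0)
  expect_equal(dihedral_angle(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0),
                              c(1, 0, 0)), 180)
  set.seed(101)
  for (i in 1:100) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    # reject near-degenerate draws the same way the kernel would
    ok <- tryCatch({
      dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]); TRUE
    }, error = function(e) FALSE)
    if (!ok) next
    expect_equal(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
  }
  # range is (-180, 180]
  set.seed(5)
  vals <- replicate(200, {
    p <- matrix(rnorm(12), 4, 3)
    tryCatch(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
             error = function(e) NA_real_)
  })
  vals <- vals[!is.na(vals)]
  expect_true(all(vals > -180 & vals <= 180))
})

test_that("dihedral is invariant under rigid motions", {
  set.seed(7)
  for (i in 1:25) {
    p <- matrix(rnorm(12, sd = 4), 4, 3)
    ref <- tryCatch(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                    error = function(e) NA_real_)
    if (is.na(ref)) next
    r <- random_rotation_matrix()
    t0 <- rnorm(3, sd = 20)
    q <- sweep(p %*% r, 2, t0, `+`)
    expect_equal(dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ]), ref,
                 tolerance = 1e-9)
  }
})

test_that("dihedral rejects degenerate geometry", {
  expect_error(dihedral_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 1, 0)), "coincide")
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)), "collinear")
})

test_that("best-fit plane recovers analytic and noisy planes", {
  pts <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  pl <- best_fit_plane(pts)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-12)
  expect_equal(pl$centroid, c(0.5, 0.5, 0), tolerance = 1e-12)
  expect_equal(sqrt(sum(pl$normal^2)), 1, tolerance = 1e-9)

  # plane z = x has normal (1, 0, -1)/sqrt(2)
  xy <- cbind(runif(20, -2, 2), runif(20, -2, 2))
  pts2 <- cbind(xy[, 1], xy[, 2], xy[, 1])
  n2 <- best_fit_plane(pts2)$normal
  expect_equal(abs(sum(n2 * c(1, 0, -1) / sqrt(2))), 1, tolerance = 1e-9)

  set.seed(31)
  for (i in 1:10) {
    true_n <- rnorm(3); true_n <- true_n / sqrt(sum(true_n^2))
    basis <- perp_basis(true_n)
    uv <- matrix(runif(100, -3, 3), 50, 2)
    pts3 <- uv %*% basis + matrix(rnorm(150, sd = 0.05), 50, 3)
    nf <- best_fit_plane(pts3)$normal
    ang <- acos(min(1, abs(sum(nf * true_n)))) * 180 / pi
    expect_lt(ang, 2)
  }

  expect_error(best_fit_plane(cbind(1:5, 1:5, 1:5)), "collinear")
})

test_that("superposition recovers planted rigid motions exactly", {
  set.seed(13)
  ref <- matrix(rnorm(45, sd = 5), 15, 3)
  sp0 <- superpose(ref, ref)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-9)
  for (i in 1:20) {
    r <- random_rotation_matrix()
    t0 <- rnorm(3, sd = 15)
    mob <- sweep(ref %*% r, 2, t0, `+`)
    sp <- superpose(mob, ref)
    expect_lt(sp$rmsd, 1e-8)
    # recovered rotation inverts the applied one
    expect_equal(sp$rotation, t(r), tolerance = 1e-7)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
    expect_equal(apply_superposition(mob, sp), ref, tolerance = 1e-7)
  }
})

test_that("closed-form superposition beats a rotation grid search", {
  set.seed(17)
  a <- matrix(rnorm(12, sd = 3), 4, 3)
  b <- matrix(rnorm(12, sd = 3), 4, 3)
  closed <- superpose(a, b)$rmsd
  ca <- sweep(a, 2, colMeans(a))
  cb <- sweep(b, 2, colMeans(b))
  step <- 15 * pi / 180
  best <- Inf
  for (a1 in seq(0, 2 * pi - step, by = step)) {
    for (a2 in seq(0, pi, by = step)) {
      for (a3 in seq(0, 2 * pi - step, by = step)) {
        rz1 <- matrix(c(cos(a1), -sin(a1), 0, sin(a1), cos(a1), 0,
                        0, 0, 1), 3, 3, byrow = TRUE)
        ry <- matrix(c(cos(a2), 0, sin(a2), 0, 1, 0,
                       -sin(a2), 0, cos(a2)), 3, 3, byrow = TRUE)
        rz2 <- matrix(c(cos(a3), -sin(a3), 0, sin(a3), cos(a3), 0,
                        0, 0, 1), 3, 3, byrow = TRUE)
        r <- rz1 %*% ry %*% rz2
        v <- sqrt(mean(rowSums((ca %*% r - cb)^2)))
        if (v < best) best <- v
      }
    }
  }
  expect_lte(closed, best + 1e-12)
})

test_that("rmsd obeys its analytic cases and the fitting inequality", {
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd_coords(a, a), 0)
  b <- sweep(a, 2, c(3, 4, 0), `+`)
  expect_equal(rmsd_coords(a, b, fit = FALSE), 5, tolerance = 1e-12)
  set.seed(23)
  for (i in 1:100) {
    x <- matrix(rnorm(24), 8, 3)
    y <- matrix(rnorm(24), 8, 3)
    expect_lte(rmsd_coords(x, y, fit = TRUE),
               rmsd_coords(x, y, fit = FALSE) + 1e-12)
  }
  expect_error(rmsd_coords(a, a[1:5, ]), "pair")
})

test_that("superposition rmsd is symmetric and pre-rotation invariant", {
  set.seed(29)
  a <- matrix(rnorm(30, sd = 4), 10, 3)
  b <- matrix(rnorm(30, sd = 4), 10, 3)
  expect_equal(superpose(a, b)$rmsd, superpose(b, a)$rmsd,
               tolerance = 1e-9)
  r <- random_rotation_matrix()
  expect_equal(superpose(a %*% r, b)$rmsd, superpose(a, b)$rmsd,
               tolerance = 1e-9)
})
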