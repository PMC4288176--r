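# Shared fixtures, built in code. Expensive objects are memoised per
# test run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

ideal_quadruplex <- function() memo("quad", build_quadruplex())

ideal_quadruplex_ions <- function() {
  memo("quad_ions", build_quadruplex(place_channel_ions = TRUE))
}

# independent dihedral oracle: explicit triple-product / atan2 formula,
# written against the definition rather than sharing code with the
# package kernel
oracle_dihedral <- function(p1, p2, p3, p4) {
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cross(n1, n2) * b2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

random_rotation_matrix <- function() {
  q <- qr(matrix(rnorm(9), 3, 3))
  r <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

rigid_move <- function(atoms, rot = random_rotation_matrix(),
                       shift = rnorm(3, sd = 10)) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% rot
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}

random_torsion_table <- function(n) {
  tibble::tibble(
    alpha = runif(n, -179, 179), beta = runif(n, -179, 179),
    gamma = runif(n, -179, 179), delta = runif(n, -179, 179),
    epsilon = runif(n, -179, 179), zeta = runif(n, -179, 179),
    chi = runif(n, -179, 179))
}

wrap_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# distinct cluster centers that differ in internal geometry (fitted RMSD
# does not see rigid motions)
deformed_centers <- function(n_centers, sigma = 1.5) {
  q <- ideal_quadruplex()
  purrr::map(seq_len(n_centers), function(i) {
    dplyr::filter(perturb_ensemble(q, sigma, 2, seed = 1000 + i),
                  model == 1)
  })
}

# paths of deposited c-KIT entries; resolved from the local cache or, if
# absent, fetched (requires network)
deposited <- function(id) fetch_structure(id)

perp_basis <- function(n) {
  u <- c(1, 0, 0)
  if (abs(sum(u * n)) > 0.9) u <- c(0, 1, 0)
  u <- u - sum(u * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  rbind(u, v)
}

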