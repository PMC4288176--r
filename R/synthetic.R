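#' @importFrom rlang .data
#' @importFrom stats rnorm sd cor setNames optim
NULL

.quadgeom <- new.env(parent = emptyenv())

# template posed so the base ring best-fit plane is z = 0, ring centroid at
# the origin, with a deterministic in-plane orientation and ring
# circulation sign
aligned_template <- function(res) {
  key <- paste0("tmpl_", res)
  if (!is.null(.quadgeom[[key]])) return(.quadgeom[[key]])
  t <- NT_TEMPLATES[[res]]
  if (is.null(t)) stop("no template for ", res, call. = FALSE)
  xyz <- cbind(t$x, t$y, t$z)
  ring <- match(BASE_RING_ATOMS[[res]], t$atom)
  pl <- best_fit_plane(xyz[ring, ])
  # rotate normal onto +z
  n <- pl$normal
  v <- c(n[2], -n[1], 0)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    rot <- diag(3) * sign(n[3])
    if (n[3] < 0) rot <- diag(c(1, -1, -1))
  } else {
    v <- v / s
    ang <- acos(max(-1, min(1, n[3])))
    rot <- rotation_about(v, ang)
  }
  xyz <- sweep(xyz, 2, pl$centroid) %*% t(rot)
  # deterministic circulation: first->second ring bond turns positively
  a <- xyz[ring[1], ]; b <- xyz[ring[2], ]; c3 <- xyz[ring[3], ]
  zc <- (b[1] - a[1]) * (c3[2] - b[2]) - (b[2] - a[2]) * (c3[1] - b[1])
  if (zc < 0) xyz <- xyz %*% diag(c(1, -1, -1))
  # in-plane: ring-centroid -> first ring atom along +x
  th <- atan2(xyz[ring[1], 2], xyz[ring[1], 1])
  xyz <- xyz %*% t(rot_z(-th))
  out <- list(atom = t$atom, elem = t$elem, xyz = xyz, ring = ring)
  .quadgeom[[key]] <- out
  out
}

rotation_about <- function(axis, ang) {
  axis <- axis / sqrt(sum(axis^2))
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  c1 <- cos(ang); s1 <- sin(ang); t1 <- 1 - c1
  matrix(c(t1 * x * x + c1, t1 * x * y - s1 * z, t1 * x * z + s1 * y,
           t1 * x * y + s1 * z, t1 * y * y + c1, t1 * y * z - s1 * x,
           t1 * x * z - s1 * y, t1 * y * z + s1 * x, t1 * z * z + c1),
         3, 3, byrow = TRUE)
}

rot_z <- function(th) {
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

# Solve the in-plane placement of a guanine so that four copies related
# by 90 degree rotations about z close the Hoogsteen donor->acceptor
# cycle. With a rigid ideal base the achievable cycle geometries are
# discrete; the targets dist(N1_g, O6_h) = 2.8 A and dist(N2_g, N7_h) =
# 3.1 A (both within the 3.2 A builder contract) select the solution
# branch whose sugars point outward and whose symmetry copies stay at
# van-der-Waals separation. Cached after the first call.
guanine_quartet_pose <- function() {
  if (!is.null(.quadgeom$quartet_pose)) return(.quadgeom$quartet_pose)
  tm <- aligned_template("DG")
  idx <- match(c("N1", "O6", "N2", "N7", "N9"), tm$atom)
  base <- tm$xyz
  delta <- -90
  rn <- rot_z(delta * pi / 180)
  hb <- function(p) {
    g <- sweep(base, 2, c(p[1], p[2], 0), `+`)
    h <- g %*% t(rn)
    (sqrt(sum((g[idx[1], ] - h[idx[2], ])^2)) - 2.8)^2 +
      (sqrt(sum((g[idx[3], ] - h[idx[4], ])^2)) - 3.1)^2
  }
  dmin <- function(a, b) {
    min(sqrt(pmax(0, outer(rowSums(a^2), rowSums(b^2), `+`) -
                    2 * tcrossprod(a, b))))
  }
  best <- NULL
  for (r0 in seq(2, 7, by = 1.5)) {
    for (a0 in seq(0, 2 * pi, length.out = 9)[-9]) {
      sol <- optim(c(r0 * cos(a0), r0 * sin(a0)), hb,
                   method = "Nelder-Mead",
                   control = list(maxit = 3000, reltol = 1e-15))
      if (sol$value > 1e-12) next
      g <- sweep(base, 2, c(sol$par, 0), `+`)
      h <- g %*% t(rn)
      r6 <- sqrt(sum(g[idx[2], 1:2]^2))
      rn9 <- sqrt(sum(g[idx[5], 1:2]^2))
      if (rn9 > r6 && dmin(g, h) > 2.5 &&
          dmin(g, g %*% t(rot_z(pi))) > 2.5 &&
          (is.null(best) || sol$value < best$value)) {
        best <- list(value = sol$value, par = sol$par)
      }
    }
  }
  if (is.null(best)) {
    stop("guanine quartet placement did not converge (radius untunable)",
         call. = FALSE)
  }
  g <- sweep(base, 2, c(best$par, 0), `+`)
  out <- list(xyz = g, atom = tm$atom, elem = tm$elem, ring = tm$ring,
              neighbor_delta = delta)
  .quadgeom$quartet_pose <- out
  out
}

new_atom_rows <- function(xyz, atom, elem, resno, resname, chain = "A",
                          hetero = FALSE, b = 10, model = 1L) {
  tibble::tibble(model = as.integer(model), chain = chain,
                 resno = as.integer(resno), resname = resname,
                 atom = atom, elem = elem,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 occ = 1, b = b, hetero = hetero)
}

#' Build an idealized G-quadruplex with known ground truth
#'
#' Constructs a four-column stacked G-quartet core from the embedded
#' guanine template: four guanines per layer at 90 degree spacing, layer
#' `k` rotated by `k * twist` and raised by `k * rise` along +z, with the
#' Hoogsteen donor-acceptor cycle closed geometrically (N1-O6 and N2-N7
#' heavy-atom distances of 2.9 A). Loop nucleotides are appended between
#' columns with their base centroids planted at positions that realise a
#' prescribed orientation category (`"up"`, `"down"`, `"out"`, `"stack"`)
#' under the default thresholds of [classify_base_orientation()], and
#' channel cations can be placed on the axis midway between layers.
#' Everything about the construction (quartet membership, loop categories,
#' ion residues) is recorded in the `"truth"` attribute.
#'
#' The loop backbone is geometrically plausible but not energy-minimised;
#' it exists to exercise geometric classifiers, not force fields.
#'
#' @param n_layers Number of stacked quartets (>= 2; default 3).
#' @param twist Helical twist per layer, degrees (default 30).
#' @param rise Rise per layer, Angstrom (default 3.3, within the stacking
#'   window 2.8-4.5 A).
#' @param loops List of three `list(length =, category =)` entries, one
#'   per inter-column loop. Default: three single-residue `"out"` loops,
#'   the all-parallel propeller fold.
#' @param antiparallel If `TRUE`, columns 2 and 4 run 3' to 5' (their
#'   nucleotides are reflected through the quartet plane and the chain
#'   traverses them top-down), giving lateral loops and mixed strand
#'   senses.
#' @param place_channel_ions Place one K+ between each pair of layers.
#' @return Atom tibble (see [read_structures()]) with attribute `truth`.
#' @examples
#' q <- build_quadruplex()
#' nrow(detect_quartets(q))
#' @export
build_quadruplex <- function(n_layers = 3, twist = 30, rise = 3.3,
                             loops = rep(list(list(length = 1,
                                                   category = "out")), 3),
                             antiparallel = FALSE,
                             place_channel_ions = FALSE) {
  stopifnot(n_layers >= 2, rise >= 2.8, rise <= 4.5, length(loops) == 3)
  pose <- guanine_quartet_pose()
  dirs <- if (antiparallel) c(1, -1, 1, -1) else c(1, 1, 1, 1)
  rows <- list()
  truth_cols <- list()
  truth_loops <- list()
  resno <- 0L
  ring_centroid <- function(xyz) colMeans(xyz[pose$ring, ])
  top_z <- (n_layers - 1) * rise
  stack_targets <- list()  # top-layer guanine ring centroids per column
  for (j in 1:4) {
    g <- pose$xyz
    if (dirs[j] < 0) g <- g %*% diag(c(1, 1, -1))
    layer_seq <- if (dirs[j] > 0) 0:(n_layers - 1) else (n_layers - 1):0
    for (k in layer_seq) {
      resno <- resno + 1L
      xyz <- g %*% t(rot_z(((j - 1) * 90 + k * twist) * pi / 180))
      xyz[, 3] <- xyz[, 3] + k * rise
      rows[[length(rows) + 1]] <-
        new_atom_rows(xyz, pose$atom, pose$elem, resno, "DG")
      truth_cols[[length(truth_cols) + 1]] <-
        tibble::tibble(column = j, layer = k + 1L, resno = resno)
      if (k == n_layers - 1) stack_targets[[j]] <- ring_centroid(xyz)
    }
    if (j < 4) {
      lp <- loops[[j]]
      cat0 <- match.arg(lp$category, c("up", "down", "out", "stack"))
      for (q in seq_len(lp$length)) {
        resno <- resno + 1L
        tmpl <- aligned_template("DA")
        phi <- ((j - 1) * 90 + 45 + (q - 1) * 20) * pi / 180
        target <- if (q == 1) cat0 else "out"
        ctr <- switch(target,
          out = c(9 * cos(phi), 9 * sin(phi),
                  rise * round((n_layers - 1) / 2)),
          up = c(3.5 * cos(phi), 3.5 * sin(phi), top_z + 4.8),
          down = c(3.5 * cos(phi), 3.5 * sin(phi), -4.8),
          stack = stack_targets[[j]] + c(0.3, 0.3, 3.4))
        xyz <- tmpl$xyz %*% t(rot_z(phi))
        xyz <- sweep(xyz, 2, ctr - colMeans((tmpl$xyz %*%
                                               t(rot_z(phi)))[tmpl$ring, ]),
                     `+`)
        rows[[length(rows) + 1]] <-
          new_atom_rows(xyz, tmpl$atom, tmpl$elem, resno, "DA")
        truth_loops[[length(truth_loops) + 1]] <-
          tibble::tibble(loop = j, resno = resno, category = target)
      }
    }
  }
  ion_resnos <- integer(0)
  if (place_channel_ions) {
    for (k in seq_len(n_layers - 1)) {
      rno <- 100L + k
      rows[[length(rows) + 1]] <-
        new_atom_rows(matrix(c(0, 0, (k - 0.5) * rise), 1, 3),
                      "K", "K", rno, "K", hetero = TRUE, b = 15)
      ion_resnos <- c(ion_resnos, rno)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- list(
    columns = dplyr::bind_rows(truth_cols),
    loops = dplyr::bind_rows(truth_loops),
    ion_resnos = ion_resnos,
    n_layers = n_layers, twist = twist, rise = rise,
    antiparallel = antiparallel)
  out
}

#' Build an idealized B-form G:C duplex (negative control)
#'
#' A regular double helix (36 degree twist, 3.4 A rise) with a poly-dG
#' strand paired against poly-dC. Contains guanines with complete
#' Hoogsteen-edge atoms but no closed quartet cycle, so quartet detection
#' must return nothing.
#'
#' @param n_bp Number of base pairs (default 8).
#' @return Atom tibble.
#' @export
build_bdna_duplex <- function(n_bp = 8) {
  g <- aligned_template("DG")
  c0 <- aligned_template("DC")
  rows <- list()
  resno <- 0L
  for (k in 0:(n_bp - 1)) {
    resno <- resno + 1L
    xyz <- sweep(g$xyz, 2, c(4.3, 0, 0), `+`) %*% t(rot_z(k * 36 * pi / 180))
    xyz[, 3] <- xyz[, 3] + k * 3.4
    rows[[length(rows) + 1]] <- new_atom_rows(xyz, g$atom, g$elem,
                                              resno, "DG")
  }
  for (k in 0:(n_bp - 1)) {
    resno <- resno + 1L
    xyz <- c0$xyz %*% diag(c(1, -1, -1))       # flip for the second strand
    xyz <- sweep(xyz, 2, c(4.3, 0, 0), `+`) %*%
      t(rot_z((k * 36 + 180) * pi / 180))
    xyz[, 3] <- xyz[, 3] + k * 3.4
    rows[[length(rows) + 1]] <- new_atom_rows(xyz, c0$atom, c0$elem,
                                              resno, "DC", chain = "B")
  }
  dplyr::bind_rows(rows)
}

#' Build Cartesian coordinates from an internal-coordinate table
#'
#' Sequential natural-extension construction: each atom is placed from
#' three previously placed reference atoms at a stated bond length, bond
#' angle and dihedral. Row `i`'s references must precede it. For the
#' seeding rows, references may be `NA`: the first atom sits at the
#' origin, the second along +x, the third in the xy-plane.
#'
#' With references `(r1, r2, r3)` the new atom `X` satisfies
#' `|X - r1| = length`, `angle(X, r1, r2) = angle`, and
#' `dihedral_angle(r3, r2, r1, X) = dihedral`, so prescribed torsions are
#' recovered exactly by [dihedral_angle()] and [backbone_torsions()].
#'
#' @param ic Tibble with columns `atom`, `resno`, `resname`, `ref1`,
#'   `ref2`, `ref3` (row indices of previously placed atoms), `length`
#'   (Angstrom), `angle`, `dihedral` (degrees).
#' @return Atom tibble (single model, chain "A").
#' @seealso [ic_nucleotide_chain()] for a ready-made DNA backbone table.
#' @export
build_chain <- function(ic) {
  ic <- tibble::as_tibble(ic)
  n <- nrow(ic)
  xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    r1 <- ic$ref1[i]; r2 <- ic$ref2[i]; r3 <- ic$ref3[i]
    if (!is.na(r1) && r1 >= i) {
      stop("build_chain(): row ", i, " references a later atom",
           call. = FALSE)
    }
    if (i == 1 || is.na(r1)) {
      xyz[i, ] <- c(0, 0, 0)
    } else if (is.na(r2)) {
      xyz[i, ] <- xyz[r1, ] + c(ic$length[i], 0, 0)
    } else if (is.na(r3)) {
      a <- ic$angle[i] * pi / 180
      u <- xyz[r2, ] - xyz[r1, ]
      u <- u / sqrt(sum(u^2))
      # in-plane perpendicular within the xy-plane (or any perpendicular)
      p <- c(-u[2], u[1], 0)
      if (sum(p^2) < 1e-12) p <- c(1, 0, 0)
      p <- p / sqrt(sum(p^2))
      xyz[i, ] <- xyz[r1, ] + ic$length[i] * (cos(a) * u + sin(a) * p)
    } else {
      xyz[i, ] <- nerf_place(xyz[r1, ], xyz[r2, ], xyz[r3, ],
                             ic$length[i], ic$angle[i], ic$dihedral[i])
    }
  }
  new_atom_rows(xyz, ic$atom, guess_element(ic$atom), ic$resno, ic$resname)
}

# place X given refs a (bonded), b, c with |X-a| = L,
# angle(X,a,b) = A deg, dihedral_angle(c, b, a, X) = D deg
nerf_place <- function(a, b, c3, L, A, D) {
  A <- A * pi / 180; D <- D * pi / 180
  bc <- a - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - c3
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  a + L * (-cos(A) * bc + sin(A) * (cos(D) * m + sin(D) * n))
}

# standard bond geometry used by ic_nucleotide_chain (lengths A, angles deg)
IC_GEOM <- list(
  P_O3p = c(1.607, 119.7), O5p_P = c(1.593, 104.0),
  C5p_O5p = c(1.440, 120.9), C4p_C5p = c(1.510, 111.5),
  C3p_C4p = c(1.524, 115.5), O3p_C3p = c(1.423, 110.5),
  O4p_C4p = c(1.453, 109.0), C1p_O4p = c(1.414, 109.7),
  N9_C1p = c(1.473, 108.2), C4_N9 = c(1.374, 126.0),
  C8_N9 = c(1.371, 127.0))

#' Internal-coordinate table for a DNA chain with prescribed torsions
#'
#' Builds the [build_chain()] input for an `n`-residue purine chain whose
#' backbone torsions (alpha, beta, gamma, delta, epsilon, zeta) and
#' glycosidic chi take exactly the values supplied -- the independent
#' oracle for torsion analysis. The 5'-terminal residue has no phosphate,
#' so its alpha and beta do not exist; the 3'-terminal epsilon and zeta
#' are consumed only when a following phosphate exists.
#'
#' @param torsions Tibble/data frame with columns `alpha`, `beta`,
#'   `gamma`, `delta`, `epsilon`, `zeta`, `chi` (degrees), one row per
#'   residue. `alpha`/`beta` of row 1 and `epsilon`/`zeta` of the last
#'   row are ignored.
#' @return The internal-coordinate tibble, with the prescribed torsions
#'   stored in attribute `"torsions"`.
#' @export
ic_nucleotide_chain <- function(torsions) {
  torsions <- tibble::as_tibble(torsions)
  n <- nrow(torsions)
  stopifnot(n >= 1)
  rows <- list()
  idx <- list()   # per residue: named atom row numbers
  add <- function(atom, resno, ref, L, A, D) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      atom = atom, resno = resno, resname = "DG",
      ref1 = ref[1], ref2 = ref[2], ref3 = ref[3],
      length = L, angle = A, dihedral = D)
    length(rows)
  }
  for (i in seq_len(n)) {
    tt <- torsions[i, ]
    ii <- list()
    if (i == 1) {
      ii$`O5'` <- add("O5'", i, c(NA, NA, NA), NA, NA, NA)
      ii$`C5'` <- add("C5'", i, c(ii$`O5'`, NA, NA),
                      IC_GEOM$C5p_O5p[1], NA, NA)
      ii$`C4'` <- add("C4'", i, c(ii$`C5'`, ii$`O5'`, NA),
                      IC_GEOM$C4p_C5p[1], IC_GEOM$C4p_C5p[2], NA)
    } else {
      pr <- idx[[i - 1]]
      tp <- torsions[i - 1, ]
      ii$P <- add("P", i, c(pr$`O3'`, pr$`C3'`, pr$`C4'`),
                  IC_GEOM$P_O3p[1], IC_GEOM$P_O3p[2], tp$epsilon)
      ii$`O5'` <- add("O5'", i, c(ii$P, pr$`O3'`, pr$`C3'`),
                      IC_GEOM$O5p_P[1], IC_GEOM$O5p_P[2], tp$zeta)
      ii$`C5'` <- add("C5'", i, c(ii$`O5'`, ii$P, pr$`O3'`),
                      IC_GEOM$C5p_O5p[1], IC_GEOM$C5p_O5p[2], tt$alpha)
      ii$`C4'` <- add("C4'", i, c(ii$`C5'`, ii$`O5'`, ii$P),
                      IC_GEOM$C4p_C5p[1], IC_GEOM$C4p_C5p[2], tt$beta)
    }
    ii$`C3'` <- add("C3'", i, c(ii$`C4'`, ii$`C5'`, ii$`O5'`),
                    IC_GEOM$C3p_C4p[1], IC_GEOM$C3p_C4p[2], tt$gamma)
    ii$`O3'` <- add("O3'", i, c(ii$`C3'`, ii$`C4'`, ii$`C5'`),
                    IC_GEOM$O3p_C3p[1], IC_GEOM$O3p_C3p[2], tt$delta)
    ii$`O4'` <- add("O4'", i, c(ii$`C4'`, ii$`C5'`, ii$`O5'`),
                    IC_GEOM$O4p_C4p[1], IC_GEOM$O4p_C4p[2],
                    wrap_angle(tt$gamma - 121))
    ii$`C1'` <- add("C1'", i, c(ii$`O4'`, ii$`C4'`, ii$`C5'`),
                    IC_GEOM$C1p_O4p[1], IC_GEOM$C1p_O4p[2], -145)
    ii$N9 <- add("N9", i, c(ii$`C1'`, ii$`O4'`, ii$`C4'`),
                 IC_GEOM$N9_C1p[1], IC_GEOM$N9_C1p[2], -100)
    ii$C4 <- add("C4", i, c(ii$N9, ii$`C1'`, ii$`O4'`),
                 IC_GEOM$C4_N9[1], IC_GEOM$C4_N9[2], tt$chi)
    ii$C8 <- add("C8", i, c(ii$N9, ii$`C1'`, ii$`O4'`),
                 IC_GEOM$C8_N9[1], IC_GEOM$C8_N9[2],
                 wrap_angle(tt$chi + 180))
    idx[[i]] <- ii
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "torsions") <- torsions
  out
}

#' Gaussian-perturbed conformational ensemble with a prescribed
#' fluctuation profile
#'
#' Each member is the reference structure plus i.i.d. Gaussian noise per
#' coordinate, with a per-residue standard deviation. Since the noise is
#' isotropic, the expected per-atom RMSF about the mean is
#' `sigma * sqrt(3)`.
#'
#' @param ref Single-model atom tibble.
#' @param sigma Per-coordinate noise s.d. in Angstrom: a single number, or
#'   a data frame with columns `resno`, `sigma` (residues not listed get
#'   0).
#' @param n_members Number of ensemble members (>= 2).
#' @param seed Integer seed; identical seeds give identical ensembles.
#' @return Atom tibble with models `1..n_members`.
#' @export
perturb_ensemble <- function(ref, sigma, n_members, seed = 1) {
  ref <- check_atoms(ref)
  stopifnot(length(unique(ref$model)) == 1, n_members >= 2)
  if (is.data.frame(sigma)) {
    s <- sigma$sigma[match(ref$resno, sigma$resno)]
    s[is.na(s)] <- 0
  } else {
    s <- rep(sigma, length.out = 1)
    s <- rep(s, nrow(ref))
  }
  stopifnot(all(s >= 0))
  n_atoms <- nrow(ref)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  members <- purrr::map(seq_len(n_members), function(m) {
    noise <- matrix(rnorm(3 * n_atoms, 0, rep(s, 3)), ncol = 3)
    dplyr::mutate(ref, model = as.integer(m),
                  x = .data$x + noise[, 1],
                  y = .data$y + noise[, 2],
                  z = .data$z + noise[, 3])
  })
  dplyr::bind_rows(members)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Multi-trajectory frame sets with planted clusters and transitions
#'
#' Frame `t` of trajectory `r` is `centers[[schedule[[r]][t]]]` plus
#' isotropic Gaussian noise -- ground truth for medoid clustering
#' (partition = schedule values) and for transition counting (total
#' off-diagonal transitions = number of consecutive same-trajectory label
#' switches in the schedule).
#'
#' @param centers List of single-model atom tibbles with identical layout.
#' @param schedule List of integer vectors, one per trajectory, each value
#'   indexing `centers`.
#' @param sigma Per-coordinate noise s.d., Angstrom.
#' @param seed Integer seed.
#' @return Atom tibble with one model per frame and a `trajectory` column;
#'   attribute `truth` holds the schedule tibble and the planted switch
#'   count.
#' @export
generate_trajectories <- function(centers, schedule, sigma = 0.05,
                                  seed = 1) {
  stopifnot(length(centers) >= 1, length(schedule) >= 1)
  centers <- purrr::map(centers, check_atoms)
  bad <- purrr::map_lgl(schedule, function(sch) any(!sch %in%
                                                      seq_along(centers)))
  if (any(bad)) {
    stop("generate_trajectories(): schedule references a missing center",
         call. = FALSE)
  }
  n_atoms <- nrow(centers[[1]])
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  frames <- list()
  truth <- list()
  m <- 0L
  for (r in seq_along(schedule)) {
    sch <- schedule[[r]]
    for (t in seq_along(sch)) {
      m <- m + 1L
      ref <- centers[[sch[t]]]
      noise <- matrix(rnorm(3 * n_atoms, 0, sigma), ncol = 3)
      frames[[m]] <- dplyr::mutate(
        ref, model = m, trajectory = paste0("T", r),
        x = .data$x + noise[, 1], y = .data$y + noise[, 2],
        z = .data$z + noise[, 3])
      truth[[m]] <- tibble::tibble(model = m, trajectory = paste0("T", r),
                                   frame = t, center = sch[t])
    }
  }
  out <- dplyr::bind_rows(frames)
  tr <- dplyr::bind_rows(truth)
  switches <- sum(purrr::map_int(schedule,
                                 function(sch) sum(diff(sch) != 0)))
  attr(out, "truth") <- list(schedule = tr, n_switches = switches)
  out
}
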