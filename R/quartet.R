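ION_ELEMENTS <- c("K", "NA", "MG", "CA", "SR", "BA", "RB", "CS", "LI",
                  "TL", "ZN", "MN")

# ring-atom coordinates of one residue as a matrix (NULL if too few)
base_ring_xyz <- function(res_atoms) {
  code <- normalize_resname(res_atoms$resname[1])
  ring <- switch(code %||% "X",
                 G = BASE_RING_ATOMS$DG, A = BASE_RING_ATOMS$DA,
                 C = BASE_RING_ATOMS$DC, T = BASE_RING_ATOMS$DT,
                 U = BASE_RING_ATOMS$DC, NULL)
  if (is.null(ring)) return(NULL)
  sub <- res_atoms[res_atoms$atom %in% ring, c("x", "y", "z")]
  if (nrow(sub) < 3) return(NULL)
  as.matrix(sub)
}

split_residues <- function(atoms) {
  atoms <- check_atoms(atoms)
  split(atoms, paste(atoms$chain, atoms$resno, sep = "\r"))
}

#' Detect G-quartets from Hoogsteen hydrogen-bond cycles
#'
#' A quartet is a directed 4-cycle in the graph with an edge from guanine
#' `g` to guanine `h` whenever both heavy-atom Hoogsteen contacts are
#' made: `dist(N1(g), O6(h)) <= hbond_max` and
#' `dist(N2(g), N7(h)) <= hbond_max`. No hydrogen positions and no
#' angle term are used (crystal structures lack hydrogens), and sequence
#' order plays no role, so guanines outside contiguous G-tracts (snapback
#' guanines) are found like any other. Candidate cycles are filtered by
#' base-plane planarity and made disjoint greedily, most planar first.
#'
#' @param atoms Single-model atom tibble.
#' @param hbond_max Donor-acceptor heavy-atom distance cutoff, Angstrom
#'   (default 3.5).
#' @param planarity_max Maximum root-mean-square deviation of the 4 bases'
#'   ring atoms from their common best-fit plane, Angstrom (default 1.0).
#' @return A tibble of class `qg_quartets`, one row per quartet:
#'   `quartet` id, `members` (list of 4-row tibbles in Hoogsteen
#'   donor-to-acceptor cycle order, started at the 5'-most guanine),
#'   `centroid` and `normal` (list columns, ring-atom best-fit plane) and
#'   `planarity_rms`.
#' @examples
#' detect_quartets(build_quadruplex())
#' @export
detect_quartets <- function(atoms, hbond_max = 3.5, planarity_max = 1.0) {
  atoms <- check_atoms(atoms)
  if (length(unique(atoms$model)) > 1) {
    stop("detect_quartets(): one model at a time; use extract_chain() ",
         "or filter on `model`", call. = FALSE)
  }
  res <- split_residues(atoms)
  is_g <- purrr::map_lgl(res, function(r) {
    identical(normalize_resname(r$resname[1]), "G") && !r$hetero[1]
  })
  gres <- res[is_g]
  need <- c("N1", "N2", "O6", "N7")
  ok <- purrr::map_lgl(gres, function(r) all(need %in% r$atom))
  if (any(!ok)) {
    bad <- names(gres)[!ok]
    warning("detect_quartets(): skipping guanine(s) with missing base ",
            "atoms: ", paste(gsub("\r", ":", bad), collapse = ", "),
            call. = FALSE)
    gres <- gres[ok]
  }
  n <- length(gres)
  empty <- tibble::tibble(quartet = integer(), members = list(),
                          centroid = list(), normal = list(),
                          planarity_rms = numeric())
  class(empty) <- c("qg_quartets", class(empty))
  if (n < 4) return(empty)
  coord_of <- function(nm) {
    do.call(rbind, purrr::map(gres, function(r) {
      unlist(r[match(nm, r$atom), c("x", "y", "z")], use.names = FALSE)
    }))
  }
  n1 <- coord_of("N1"); n2 <- coord_of("N2")
  o6 <- coord_of("O6"); n7 <- coord_of("N7")
  pd <- function(a, b) {
    sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), `+`) -
                2 * tcrossprod(a, b), 0))
  }
  edge <- pd(n1, o6) <= hbond_max & pd(n2, n7) <= hbond_max
  diag(edge) <- FALSE
  adj <- purrr::map(seq_len(n), function(i) which(edge[i, ]))
  # directed 4-cycles, deduplicated by smallest starting vertex
  cycles <- list()
  for (i in seq_len(n)) {
    for (j in adj[[i]]) {
      if (j == i) next
      for (k in adj[[j]]) {
        if (k %in% c(i, j)) next
        for (l in adj[[k]]) {
          if (l %in% c(i, j, k)) next
          if (edge[l, i] && i < min(j, k, l)) {
            cycles[[length(cycles) + 1]] <- c(i, j, k, l)
          }
        }
      }
    }
  }
  if (!length(cycles)) return(empty)
  planes <- purrr::map(cycles, function(cy) {
    pts <- do.call(rbind, purrr::map(gres[cy], base_ring_xyz))
    best_fit_plane(pts)
  })
  rms <- purrr::map_dbl(planes, "rms")
  keep <- rms <= planarity_max
  cycles <- cycles[keep]; planes <- planes[keep]; rms <- rms[keep]
  if (!length(cycles)) return(empty)
  ord <- order(rms)
  used <- logical(n)
  rows <- list()
  for (ci in ord) {
    cy <- cycles[[ci]]
    if (any(used[cy])) next
    used[cy] <- TRUE
    # start the reported cycle at the 5'-most member, preserving direction
    info <- purrr::map_dfr(gres[cy], function(r) {
      tibble::tibble(chain = r$chain[1], resno = r$resno[1],
                     resname = r$resname[1])
    })
    s <- order(info$chain, info$resno)[1]
    rot <- c(seq(s, 4), seq_len(s - 1))
    rows[[length(rows) + 1]] <- tibble::tibble(
      members = list(dplyr::mutate(info[rot, ], position = 1:4)),
      centroid = list(planes[[ci]]$centroid),
      normal = list(planes[[ci]]$normal),
      planarity_rms = rms[ci])
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, quartet = dplyr::row_number(), .before = 1)
  class(out) <- c("qg_quartets", class(out))
  out
}

#' Assemble detected quartets into a stacked core with a channel axis
#'
#' Orders quartets along the best-fit line through their centroids,
#' requires consecutive centroid separations inside the stacking window
#' (2.8-4.5 Angstrom), and orients the axis from the layer containing the
#' 5'-most core guanine ("bottom") towards the opposite end ("top"), so
#' up/down calls are reproducible across files.
#'
#' @param quartets A `qg_quartets` tibble from [detect_quartets()] with
#'   at least 2 rows.
#' @return Object of class `qg_core`: list with `layers` (the quartet
#'   tibble, reordered, with a `layer` column; layer 1 is the bottom),
#'   `centroids` (matrix), `axis` (unit 3-vector, bottom to top),
#'   `origin` (bottom-layer centroid), `rise_per_layer` (consecutive
#'   centroid separations, Angstrom) and `n_layers`.
#' @export
build_core <- function(quartets) {
  if (nrow(quartets) < 2) {
    stop("build_core(): need at least 2 quartets", call. = FALSE)
  }
  ctr <- do.call(rbind, quartets$centroid)
  dir <- if (nrow(ctr) == 2) {
    d <- ctr[2, ] - ctr[1, ]; d / sqrt(sum(d^2))
  } else {
    x <- sweep(ctr, 2, colMeans(ctr))
    e <- eigen(crossprod(x), symmetric = TRUE)
    e$vectors[, 1]
  }
  t_axial <- as.numeric(ctr %*% dir)
  ord <- order(t_axial)
  gaps <- sqrt(rowSums((ctr[ord[-1], , drop = FALSE] -
                          ctr[ord[-length(ord)], , drop = FALSE])^2))
  if (any(gaps < 2.8 | gaps > 4.5)) {
    bad <- which(gaps < 2.8 | gaps > 4.5)[1]
    stop(sprintf(paste0("build_core(): stacking break between quartets ",
                        "%d and %d (centroid separation %.2f A outside ",
                        "2.8-4.5 A)"),
                 quartets$quartet[ord[bad]], quartets$quartet[ord[bad + 1]],
                 gaps[bad]), call. = FALSE)
  }
  # bottom = layer containing the 5'-most core guanine
  first_res <- purrr::map_dfr(quartets$members, function(m) {
    m[order(m$chain, m$resno)[1], c("chain", "resno")]
  })
  best <- order(first_res$chain, first_res$resno)[1]
  if (which(ord == best) > length(ord) / 2) {
    ord <- rev(ord)
    dir <- -dir
  }
  layers <- quartets[ord, ]
  layers$layer <- seq_len(nrow(layers))
  layers$normal <- purrr::map(layers$normal, function(nv) {
    if (sum(nv * dir) < 0) -nv else nv
  })
  structure(list(layers = layers,
                 centroids = ctr[ord, , drop = FALSE],
                 axis = dir,
                 origin = ctr[ord[1], ],
                 rise_per_layer = sqrt(rowSums(
                   (ctr[ord[-1], , drop = FALSE] -
                      ctr[ord[-length(ord)], , drop = FALSE])^2)),
                 n_layers = nrow(layers)),
            class = "qg_core")
}

#' @export
print.qg_core <- function(x, ...) {
  cat("<qg_core>", x$n_layers, "stacked G-quartets; rise",
      paste(sprintf("%.2f", x$rise_per_layer), collapse = ", "), "A\n")
  invisible(x)
}

core_resnos <- function(core) {
  dplyr::bind_rows(purrr::map2(core$layers$members, core$layers$layer,
                               function(m, l) dplyr::mutate(m, layer = l)))
}

axial_radial <- function(core, xyz) {
  v <- sweep(rbind3(xyz), 2, core$origin)
  ax <- as.numeric(v %*% core$axis)
  rad <- sqrt(pmax(0, rowSums(v^2) - ax^2))
  list(axial = ax, radial = rad)
}

#' Assign monatomic cations to the channel or the exterior
#'
#' A cation is a channel ion when its axial projection falls between the
#' bottom and top layer centroids (extended by half a mean rise at both
#' ends) and it lies within `radial_max` of the axis; anything else is
#' external and annotated with its nearest nucleotide.
#'
#' @param core A `qg_core` from [build_core()].
#' @param atoms The same single-model atom tibble the core was built from.
#' @param radial_max Maximum distance from the channel axis, Angstrom
#'   (default 2.5).
#' @return Tibble with one row per monatomic ion: `chain`, `resno`,
#'   `resname`, `elem`, `role` (`"channel"`/`"external"`), `layer_gap`
#'   (index of the inter-layer gap, `NA` for external), `nearest`
#'   (nearest-residue label for external ions), `axial`, `radial`.
#' @export
assign_ions <- function(core, atoms, radial_max = 2.5) {
  atoms <- check_atoms(atoms)
  res <- split_residues(atoms)
  ions <- purrr::keep(res, function(r) {
    nrow(r) == 1 && r$hetero[1] && toupper(r$elem[1]) %in% ION_ELEMENTS
  })
  if (!length(ions)) {
    return(tibble::tibble(chain = character(), resno = integer(),
                          resname = character(), elem = character(),
                          role = character(), layer_gap = integer(),
                          nearest = character(), axial = numeric(),
                          radial = numeric()))
  }
  pos <- do.call(rbind, purrr::map(ions, function(r) {
    c(r$x[1], r$y[1], r$z[1])
  }))
  ar <- axial_radial(core, pos)
  t_layers <- as.numeric(sweep(core$centroids, 2, core$origin) %*%
                           core$axis)
  half <- mean(core$rise_per_layer) / 2
  channel <- ar$axial >= min(t_layers) - half &
    ar$axial <= max(t_layers) + half & ar$radial <= radial_max
  gap_mid <- (t_layers[-1] + t_layers[-length(t_layers)]) / 2
  nuc <- dplyr::filter(atoms, !.data$hetero)
  labs <- residues(atoms)
  nearest_label <- function(p) {
    d2 <- (nuc$x - p[1])^2 + (nuc$y - p[2])^2 + (nuc$z - p[3])^2
    i <- which.min(d2)
    lab <- labs$label[labs$chain == nuc$chain[i] &
                        labs$resno == nuc$resno[i] & !labs$hetero]
    if (length(lab)) lab[1] else paste0(nuc$chain[i], ":", nuc$resno[i])
  }
  purrr::map_dfr(seq_along(ions), function(i) {
    r <- ions[[i]]
    tibble::tibble(
      chain = r$chain[1], resno = r$resno[1], resname = r$resname[1],
      elem = r$elem[1],
      role = if (channel[i]) "channel" else "external",
      layer_gap = if (channel[i]) which.min(abs(gap_mid - ar$axial[i]))
                  else NA_integer_,
      nearest = if (channel[i]) NA_character_
                else nearest_label(c(r$x[1], r$y[1], r$z[1])),
      axial = ar$axial[i], radial = ar$radial[i])
  })
}

#' Classify the fold topology of a quadruplex chain
#'
#' Groups the core guanines into four columns by stacking contact across
#' layers, derives each column's strand sense from the axial progression
#' of its C1' atoms along the chain direction, types the connecting loops
#' (propeller when the two anchoring core guanines sit on opposite faces
#' of the core; lateral/diagonal when they sit on the same face and the
#' columns are angularly adjacent/opposite), and flags snapback guanines
#' -- core members with no sequence neighbour in their own column.
#'
#' @param core A `qg_core`.
#' @param atoms Atom tibble containing the (single) chain that carries
#'   the core guanines.
#' @return Object of class `qg_topology`: list with `tracts` (tibble:
#'   column, start/end resno, sense, parallel), `loops` (tibble: residue
#'   range, type, anchor resnos), `strand_senses`, `snapback_residues`,
#'   `n_layers`.
#' @export
classify_topology <- function(core, atoms) {
  atoms <- check_atoms(atoms)
  cres <- core_resnos(core)
  ch <- unique(cres$chain)
  if (length(ch) != 1) {
    stop("classify_topology(): core spans chains ",
         paste(ch, collapse = ", "), "; analyse one chain at a time",
         call. = FALSE)
  }
  chain_atoms <- dplyr::filter(atoms, .data$chain == ch)
  if (!all(cres$resno %in% chain_atoms$resno)) {
    stop("classify_topology(): supplied chain lacks the core guanines",
         call. = FALSE)
  }
  res <- split_residues(chain_atoms)
  ring_ctr <- function(resno) {
    r <- res[[paste(ch, resno, sep = "\r")]]
    colMeans(base_ring_xyz(r))
  }
  cres$ctr <- purrr::map(cres$resno, ring_ctr)

  # columns: greedy layer-to-layer matching by ring-centroid distance
  layers <- split(cres, cres$layer)
  n_layers <- length(layers)
  perms <- permutations4()
  layers <- purrr::map(layers, function(l) {
    l$column <- NA_integer_
    l
  })
  layers[[1]]$column <- 1:4
  for (k in seq_len(n_layers - 1)) {
    prev <- layers[[k]]; cur <- layers[[k + 1]]
    d <- outer(seq_len(4), seq_len(4), Vectorize(function(i, j) {
      sqrt(sum((prev$ctr[[i]] - cur$ctr[[j]])^2))
    }))
    costs <- apply(perms, 1, function(p) sum(d[cbind(seq_len(4), p)]))
    p <- perms[which.min(costs), ]
    cur$column[p] <- prev$column
    layers[[k + 1]] <- cur
  }
  cres <- dplyr::bind_rows(layers)
  # column 1 = column holding the 5'-most core guanine; rest by sequence
  first_in_col <- tapply(cres$resno, cres$column, min)
  remap <- match(seq_along(first_in_col), order(first_in_col))
  cres$column <- remap[cres$column]

  # angular position of each column about the axis
  ang_of <- function(ctr) {
    v <- ctr - core$origin
    ax <- sum(v * core$axis)
    p <- v - ax * core$axis
    ref <- perp_ref(core$axis)
    atan2(sum(p * ref$v), sum(p * ref$u))
  }
  col_angle <- tapply(purrr::map_dbl(cres$ctr, ang_of), cres$column,
                      function(a) atan2(mean(sin(a)), mean(cos(a))))

  # strand sense from axial C1' progression of sequence-consecutive pairs
  axial_c1 <- function(resno) {
    r <- res[[paste(ch, resno, sep = "\r")]]
    i <- match("C1'", r$atom)
    if (is.na(i)) return(NA_real_)
    axial_radial(core, c(r$x[i], r$y[i], r$z[i]))$axial
  }
  cres$t_c1 <- purrr::map_dbl(cres$resno, axial_c1)
  sense_of <- function(d) {
    d <- d[order(d$resno), ]
    steps <- diff(d$t_c1) / diff(d$resno)
    steps <- steps[diff(d$resno) == 1]
    if (!length(steps) || all(is.na(steps))) NA_real_
    else sign(mean(steps, na.rm = TRUE))
  }
  senses <- purrr::map_dbl(split(cres, cres$column), sense_of)
  strand_senses <- tibble::tibble(
    column = as.integer(names(senses)),
    sense = ifelse(is.na(senses), NA, ifelse(senses > 0, "+", "-")),
    parallel = senses == senses[1])

  # snapback: no sequence neighbour within the same column
  is_core <- function(resno) resno %in% cres$resno
  snap <- purrr::map_lgl(seq_len(nrow(cres)), function(i) {
    r <- cres$resno[i]; col <- cres$column[i]
    nb <- cres$resno[cres$column == col]
    !any((r - 1) %in% nb | (r + 1) %in% nb)
  })
  snapback <- cres[snap, c("chain", "resno", "resname")]

  # tracts: maximal consecutive runs within each column
  tracts <- purrr::map_dfr(split(cres, cres$column), function(d) {
    r <- sort(d$resno)
    grp <- cumsum(c(1, diff(r) != 1))
    purrr::map_dfr(split(r, grp), function(run) {
      tibble::tibble(column = d$column[1], start = min(run), end = max(run))
    })
  })
  tracts <- dplyr::left_join(tracts, strand_senses, by = "column")

  # loops between consecutive core anchors along the sequence
  nuc <- dplyr::filter(residues(chain_atoms), !.data$hetero,
                       !is.na(.data$base))
  core_sorted <- sort(cres$resno)
  loops <- list()
  for (i in seq_len(length(core_sorted) - 1)) {
    a <- core_sorted[i]; b <- core_sorted[i + 1]
    between <- nuc$resno[nuc$resno > a & nuc$resno < b]
    if (!length(between)) next
    la <- cres$layer[cres$resno == a]; lb <- cres$layer[cres$resno == b]
    ca <- cres$column[cres$resno == a]; cb <- cres$column[cres$resno == b]
    face <- function(l) {
      if (l == 1) "bottom" else if (l == n_layers) "top" else "mid"
    }
    fa <- face(la); fb <- face(lb)
    dang <- abs(wrap_angle((col_angle[[ca]] - col_angle[[cb]]) * 180 / pi))
    type <- if (fa == "mid" || fb == "mid" || ca == cb) {
      "other"
    } else if (fa != fb) {
      "propeller"
    } else if (dang < 135) {
      "lateral"
    } else {
      "diagonal"
    }
    loops[[length(loops) + 1]] <- tibble::tibble(
      start = min(between), end = max(between),
      n_residues = length(between), type = type,
      anchor_5p = a, anchor_3p = b)
  }
  loops <- if (length(loops)) dplyr::bind_rows(loops) else
    tibble::tibble(start = integer(), end = integer(),
                   n_residues = integer(), type = character(),
                   anchor_5p = integer(), anchor_3p = integer())

  structure(list(chain = ch, tracts = tracts, loops = loops,
                 strand_senses = strand_senses,
                 snapback_residues = snapback,
                 columns = cres[, c("chain", "resno", "layer", "column")],
                 n_layers = n_layers),
            class = "qg_topology")
}

permutations4 <- function() {
  p <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  m <- as.matrix(p[apply(p, 1, function(r) length(unique(r)) == 4), ])
  dimnames(m) <- NULL
  m
}

perp_ref <- function(axis) {
  u <- c(1, 0, 0)
  if (abs(sum(u * axis)) > 0.9) u <- c(0, 1, 0)
  u <- u - sum(u * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  list(u = u, v = v)
}

#' @export
print.qg_topology <- function(x, ...) {
  cat("<qg_topology> chain", x$chain, "-", x$n_layers, "layers;",
      nrow(x$loops), "loops (",
      paste(x$loops$type, collapse = ", "), ");",
      nrow(x$snapback_residues), "snapback guanine(s)\n")
  invisible(x)
}
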