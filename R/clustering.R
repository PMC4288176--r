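#' Pairwise RMSD dissimilarity matrix of an ensemble
#'
#' Fitted (or in-place) RMSD between every pair of members over an atom
#' selection -- the metric under medoid clustering of conformational
#' ensembles. Frame labels carry the trajectory identity used later for
#' transition counting.
#'
#' @param atoms Multi-model atom tibble; an optional `trajectory` column
#'   (as produced by [generate_trajectories()]) labels the source run of
#'   each model.
#' @param resnos,atom_names Optional selection of residues/atom names
#'   entering the RMSD (default: all non-hetero atoms).
#' @param fit Superpose each pair before measuring (default `TRUE`).
#' @return Object of class `qg_distmat`: list with `values` (n x n
#'   symmetric matrix, zero diagonal, Angstrom) and `frames` (tibble:
#'   `model`, `trajectory`, `frame`).
#' @export
distance_matrix <- function(atoms, resnos = NULL, atom_names = NULL,
                            fit = TRUE) {
  atoms <- check_atoms(atoms)
  nuc <- dplyr::filter(atoms, !.data$hetero)
  models <- split(nuc, nuc$model)
  ref <- models[[1]]
  ok <- purrr::every(models, function(m) {
    nrow(m) == nrow(ref) && all(m$atom == ref$atom) &&
      all(m$resno == ref$resno)
  })
  if (!ok) {
    stop("distance_matrix(): members do not share an atom layout",
         call. = FALSE)
  }
  sel <- rep(TRUE, nrow(ref))
  if (!is.null(resnos)) sel <- sel & ref$resno %in% resnos
  if (!is.null(atom_names)) sel <- sel & ref$atom %in% atom_names
  if (sum(sel) < 3) {
    stop("distance_matrix(): selection has fewer than 3 atoms",
         call. = FALSE)
  }
  coords <- purrr::map(models, function(m) {
    as.matrix(m[sel, c("x", "y", "z")])
  })
  n <- length(coords)
  v <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v[i, j] <- v[j, i] <- rmsd_coords(coords[[i]], coords[[j]],
                                        fit = fit)
    }
  }
  traj <- if ("trajectory" %in% names(atoms)) {
    purrr::map_chr(models, function(m) {
      tr <- atoms$trajectory[atoms$model == m$model[1]]
      tr[1]
    })
  } else {
    rep("T1", n)
  }
  frames <- tibble::tibble(model = as.integer(names(models)),
                           trajectory = traj)
  frames <- dplyr::mutate(dplyr::group_by(frames, .data$trajectory),
                          frame = dplyr::row_number())
  frames <- dplyr::ungroup(frames)
  structure(list(values = v, frames = frames), class = "qg_distmat")
}

#' @export
print.qg_distmat <- function(x, ...) {
  cat("<qg_distmat>", nrow(x$values), "frames,",
      length(unique(x$frames$trajectory)), "trajectory(ies)\n")
  invisible(x)
}

#' PAM-style k-medoids clustering on a dissimilarity matrix
#'
#' Seeded greedy initialisation (a k-medoids++ analogue: the first medoid
#' is drawn uniformly, each next with probability proportional to the
#' squared dissimilarity to the nearest chosen medoid), followed by
#' alternating assignment and medoid update until the labels stop
#' changing. The medoid of each cluster is the member minimising the
#' summed within-cluster dissimilarity -- every medoid is a physical
#' frame. Deterministic for a fixed seed.
#'
#' @param dm A `qg_distmat` (or plain symmetric matrix).
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed Integer seed for the initialisation.
#' @param restarts Independent seeded restarts; the best objective wins
#'   (default 5).
#' @return Object of class `qg_clusters`: list with `k`, `labels`
#'   (per-frame cluster id), `medoid_indices`, `populations` (fractions
#'   summing to 1), `objective` (summed dissimilarity to assigned
#'   medoids), `frames`.
#' @export
cluster_medoids <- function(dm, k, seed = 1, restarts = 5) {
  v <- if (inherits(dm, "qg_distmat")) dm$values else as.matrix(dm)
  n <- nrow(v)
  k <- as.integer(k)
  if (k < 1 || k > n) {
    stop("cluster_medoids(): k must be between 1 and the frame count (",
         n, ")", call. = FALSE)
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  if (choose(n, k) <= 5000) {
    # small instance: the global optimum over all medoid subsets is
    # affordable, so solve the objective exactly
    best <- medoid_exhaustive(v, n, k)
  } else {
    best <- NULL
    for (r in seq_len(max(1, restarts))) {
      run <- medoid_run(v, n, k, seed + r - 1)
      if (is.null(best) || run$objective < best$objective - 1e-12) {
        best <- run
      }
    }
  }
  frames <- if (inherits(dm, "qg_distmat")) dm$frames else
    tibble::tibble(model = seq_len(n), trajectory = "T1",
                   frame = seq_len(n))
  structure(list(k = k, labels = best$labels,
                 medoid_indices = best$meds,
                 populations = as.numeric(table(
                   factor(best$labels, levels = seq_len(k))) / n),
                 objective = best$objective, frames = frames),
            class = "qg_clusters")
}

medoid_exhaustive <- function(v, n, k) {
  best <- NULL
  for (m in utils::combn(n, k, simplify = FALSE)) {
    o <- sum(apply(v[, m, drop = FALSE], 1, min))
    if (is.null(best) || o < best$objective - 1e-12) {
      labels <- apply(v[, m, drop = FALSE], 1, which.min)
      # report the canonical medoid of each realised cluster
      meds <- purrr::map_int(seq_len(k), function(cl) {
        members <- which(labels == cl)
        if (!length(members)) return(m[cl])
        members[which.min(colSums(v[members, members, drop = FALSE]))]
      })
      best <- list(labels = as.integer(labels), meds = meds,
                   objective = o)
    }
  }
  best
}

medoid_run <- function(v, n, k, seed) {
  set.seed(seed)
  meds <- integer(k)
  meds[1] <- sample.int(n, 1)
  if (k > 1) {
    for (i in 2:k) {
      d2 <- apply(v[, meds[seq_len(i - 1)], drop = FALSE], 1, min)^2
      if (sum(d2) < 1e-300) {
        cand <- setdiff(seq_len(n), meds[seq_len(i - 1)])
        meds[i] <- cand[sample.int(length(cand), 1)]
      } else {
        meds[i] <- sample.int(n, 1, prob = d2)
      }
    }
  }
  assign_to <- function(meds) {
    apply(v[, meds, drop = FALSE], 1, which.min)
  }
  labels <- assign_to(meds)
  # alternating assignment / medoid update
  for (iter in seq_len(200)) {
    new_meds <- purrr::map_int(seq_len(k), function(cl) {
      members <- which(labels == cl)
      if (!length(members)) return(meds[cl])
      within <- colSums(v[members, members, drop = FALSE])
      members[which.min(within)]
    })
    new_labels <- assign_to(new_meds)
    if (identical(new_meds, meds) && identical(new_labels, labels)) break
    meds <- new_meds
    labels <- new_labels
  }
  # PAM swap phase: exchange a medoid for a non-medoid while the total
  # dissimilarity decreases (escapes the local optima of plain
  # alternation)
  if (k < n) {
    repeat {
      dmk <- v[, meds, drop = FALSE]
      nearest <- apply(dmk, 1, which.min)
      dn <- dmk[cbind(seq_len(n), nearest)]
      ds <- if (k == 1) rep(Inf, n) else
        apply(dmk, 1, function(r) sort(r, partial = 2)[2])
      cur <- sum(dn)
      best_gain <- 0
      best_swap <- NULL
      for (j in seq_len(k)) {
        mine <- nearest == j
        for (x in setdiff(seq_len(n), meds)) {
          newd <- ifelse(mine, pmin(ds, v[, x]), pmin(dn, v[, x]))
          gain <- cur - sum(newd)
          if (gain > best_gain + 1e-12) {
            best_gain <- gain
            best_swap <- c(j, x)
          }
        }
      }
      if (is.null(best_swap)) break
      meds[best_swap[1]] <- best_swap[2]
      labels <- assign_to(meds)
    }
    # final per-cluster medoid polish after the swaps
    meds <- purrr::map_int(seq_len(k), function(cl) {
      members <- which(labels == cl)
      if (!length(members)) return(meds[cl])
      members[which.min(colSums(v[members, members, drop = FALSE]))]
    })
    labels <- assign_to(meds)
  }
  list(labels = as.integer(labels), meds = meds,
       objective = sum(v[cbind(seq_len(n), meds[labels])]))
}

#' @export
print.qg_clusters <- function(x, ...) {
  cat("<qg_clusters> k =", x$k, "; populations:",
      paste(sprintf("%.2f", x$populations), collapse = ", "), "\n")
  invisible(x)
}

# mean silhouette width for a labelled dissimilarity matrix
mean_silhouette <- function(v, labels) {
  n <- nrow(v)
  k <- length(unique(labels))
  if (k < 2) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) {
      s[i] <- 0
      next
    }
    a <- sum(v[i, own]) / (length(own) - 1)
    b <- min(purrr::map_dbl(setdiff(unique(labels), labels[i]),
                            function(cl) mean(v[i, labels == cl])))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Choose the cluster count by mean silhouette
#'
#' Runs [cluster_medoids()] for `k = 2 ... k_max` and returns the `k`
#' with the best mean silhouette width (ties towards smaller `k`). A
#' best silhouette below 0.25 is flagged as weak structure via the
#' `"weak_structure"` attribute.
#'
#' @param dm A `qg_distmat` (or symmetric matrix) with at least 3 frames.
#' @param k_max Largest k to consider (default 10).
#' @param seed Seed passed to each clustering run.
#' @return Integer k; attributes `silhouettes` (named vector) and
#'   `weak_structure` (logical).
#' @export
select_k <- function(dm, k_max = 10, seed = 1) {
  v <- if (inherits(dm, "qg_distmat")) dm$values else as.matrix(dm)
  n <- nrow(v)
  if (n < 3) stop("select_k(): need at least 3 frames", call. = FALSE)
  if (k_max < 2) stop("select_k(): k_max must be >= 2", call. = FALSE)
  ks <- 2:min(k_max, n - 1)
  sil <- purrr::map_dbl(ks, function(k) {
    cl <- cluster_medoids(dm, k, seed = seed)
    mean_silhouette(v, cl$labels)
  })
  best <- ks[which.max(sil)]          # which.max takes the first maximum
  structure(as.integer(best),
            silhouettes = setNames(sil, ks),
            weak_structure = max(sil) < 0.25)
}

#' Same-trajectory transition graph between clusters
#'
#' For each trajectory independently, every pair of consecutive frames
#' whose cluster assignments differ increments the directed transition
#' count; pairs spanning a trajectory boundary contribute nothing, so no
#' artificial transitions between independent runs are created.
#'
#' @param model A `qg_clusters` from [cluster_medoids()] (its `frames`
#'   carry the trajectory labels).
#' @return Object of class `qg_transitions`: list with `counts` (k x k
#'   integer matrix, zero diagonal), `edges` (tibble: from, to, count)
#'   and `k`.
#' @export
transition_graph <- function(model) {
  stopifnot(inherits(model, "qg_clusters"))
  fr <- model$frames
  if (nrow(fr) != length(model$labels)) {
    stop("transition_graph(): frame labels and cluster labels differ in ",
         "length", call. = FALSE)
  }
  k <- model$k
  counts <- matrix(0L, k, k)
  for (tr in unique(fr$trajectory)) {
    idx <- which(fr$trajectory == tr)
    idx <- idx[order(fr$frame[idx])]
    lab <- model$labels[idx]
    if (length(lab) < 2) next
    from <- lab[-length(lab)]
    to <- lab[-1]
    keep <- from != to
    for (i in which(keep)) {
      counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
    }
  }
  ed <- which(counts > 0, arr.ind = TRUE)
  edges <- tibble::tibble(from = as.integer(ed[, 1]),
                          to = as.integer(ed[, 2]),
                          count = counts[ed])
  structure(list(counts = counts, edges = edges, k = k),
            class = "qg_transitions")
}

#' @export
print.qg_transitions <- function(x, ...) {
  cat("<qg_transitions>", x$k, "clusters,",
      sum(x$counts), "transitions,",
      nrow(undirected_edges(x)), "undirected link(s)\n")
  invisible(x)
}

undirected_edges <- function(graph) {
  e <- graph$edges
  if (nrow(e) == 0) {
    return(tibble::tibble(a = integer(), b = integer(), count = integer()))
  }
  e <- dplyr::mutate(e, a = pmin(.data$from, .data$to),
                     b = pmax(.data$from, .data$to))
  dplyr::summarise(dplyr::group_by(e, .data$a, .data$b),
                   count = sum(.data$count), .groups = "drop")
}

#' Clusters connected to at most one other cluster
#'
#' Identifies isolated clusters in the (undirected) transition
#' connectivity -- conformational states that exchange with at most a
#' single neighbour.
#'
#' @param graph A `qg_transitions`.
#' @return Integer vector of cluster ids with undirected degree <= 1.
#' @export
isolated_clusters <- function(graph) {
  stopifnot(inherits(graph, "qg_transitions"))
  ue <- undirected_edges(graph)
  deg <- integer(graph$k)
  for (i in seq_len(nrow(ue))) {
    deg[ue$a[i]] <- deg[ue$a[i]] + 1L
    deg[ue$b[i]] <- deg[ue$b[i]] + 1L
  }
  which(deg <= 1)
}
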