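#' Per-residue crystallographic B-factor profile
#'
#' Unweighted mean of the atomic isotropic B factors over each residue
#' (optionally base atoms only), the per-residue summary used to compare
#' flexibility between crystal forms.
#'
#' @param atoms Single-model atom tibble with B factors.
#' @param atom_scope `"all"` atoms or `"base_only"` (ring + exocyclic
#'   base atoms).
#' @return A flexibility profile tibble of class `qg_profile`: `chain`,
#'   `resno`, `resname`, `label`, `value` (Angstrom^2), with attribute
#'   `source = "crystal_b"`. Hetero groups are excluded.
#' @export
residue_bfactors <- function(atoms, atom_scope = c("all", "base_only")) {
  atoms <- check_atoms(atoms)
  atom_scope <- match.arg(atom_scope)
  if (length(unique(atoms$model)) > 1) {
    stop("residue_bfactors(): one model at a time", call. = FALSE)
  }
  labs <- residues(atoms)
  nuc <- dplyr::filter(labs, !.data$hetero, !is.na(.data$base))
  sub <- dplyr::semi_join(dplyr::filter(atoms, !.data$hetero),
                          nuc, by = c("chain", "resno"))
  if (atom_scope == "base_only") {
    base_names <- unique(unlist(c(
      BASE_RING_ATOMS,
      list(c("O6", "N2", "N6", "N4", "O2", "O4", "C7")))))
    sub <- dplyr::filter(sub, .data$atom %in% base_names)
  }
  prof <- dplyr::summarise(
    dplyr::group_by(sub, .data$chain, .data$resno),
    value = mean(.data$b), .groups = "drop")
  prof <- dplyr::left_join(nuc[, c("chain", "resno", "resname", "label")],
                           prof, by = c("chain", "resno"))
  if (anyNA(prof$value)) {
    warning("residue_bfactors(): residue(s) with no atoms in scope: ",
            paste(prof$label[is.na(prof$value)], collapse = ", "),
            call. = FALSE)
  }
  new_profile(prof, source = "crystal_b")
}

new_profile <- function(tbl, source) {
  attr(tbl, "source") <- source
  class(tbl) <- c("qg_profile", class(tbl))
  tbl
}

#' Normalise a flexibility profile
#'
#' Z-scores the per-residue values over the chain (the default reading of
#' a "normalized" per-residue profile), or min-max scales them to [0, 1]
#' for figure-style replotting. A constant profile maps to all zeros.
#' The operation is idempotent on already-z-scored profiles.
#'
#' @param profile A `qg_profile` (or any tibble with a `value` column).
#' @param method `"zscore"` (default) or `"minmax"`.
#' @return The profile with an added/overwritten `normalized` column.
#' @export
normalize_profile <- function(profile, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  v <- profile$value
  if (length(v) < 2) {
    stop("normalize_profile(): need at least 2 residues", call. = FALSE)
  }
  mu <- mean(v, na.rm = TRUE)
  s <- sqrt(mean((v - mu)^2, na.rm = TRUE))  # population sd: [0,2]->[-1,1]
  profile$normalized <- if (is.na(s) || s < 1e-12) {
    rep(0, length(v))
  } else if (method == "zscore") {
    (v - mu) / s
  } else {
    (v - min(v, na.rm = TRUE)) / (max(v, na.rm = TRUE) - min(v, na.rm = TRUE))
  }
  profile
}

#' Per-residue RMSF of a conformational ensemble
#'
#' Superposes every member onto the ensemble mean structure over a fit
#' selection (default: all shared heavy atoms; pass the core guanines to
#' keep loop flexibility from being absorbed into the fit), refines the
#' mean once (mean, fit, re-mean, re-fit), then reports the
#' root-mean-square fluctuation about the final mean, averaged per
#' residue or kept per atom.
#'
#' @param atoms Multi-model atom tibble (>= 2 models, identical layout).
#' @param fit_resnos Residue numbers used for the superposition fit
#'   (default all non-hetero residues).
#' @param fit_atoms Atom names used for the fit within those residues
#'   (default all).
#' @param per `"residue"` (default) or `"atom"`.
#' @return A `qg_profile` tibble (`value` in Angstrom, source
#'   `"ensemble_rmsf"`); per-atom output adds an `atom` column.
#' @export
ensemble_rmsf <- function(atoms, fit_resnos = NULL, fit_atoms = NULL,
                          per = c("residue", "atom")) {
  atoms <- check_atoms(atoms)
  per <- match.arg(per)
  models <- split(dplyr::filter(atoms, !.data$hetero),
                  dplyr::filter(atoms, !.data$hetero)$model)
  if (length(models) < 2) {
    stop("ensemble_rmsf(): need an ensemble of at least 2 members",
         call. = FALSE)
  }
  ref <- models[[1]]
  n <- nrow(ref)
  ok <- purrr::every(models, function(m) {
    nrow(m) == n && all(m$atom == ref$atom) && all(m$resno == ref$resno) &&
      all(m$chain == ref$chain)
  })
  if (!ok) {
    stop("ensemble_rmsf(): members do not share an atom layout",
         call. = FALSE)
  }
  sel <- rep(TRUE, n)
  if (!is.null(fit_resnos)) sel <- sel & ref$resno %in% fit_resnos
  if (!is.null(fit_atoms)) sel <- sel & ref$atom %in% fit_atoms
  if (sum(sel) < 3) {
    stop("ensemble_rmsf(): fit selection has fewer than 3 atoms",
         call. = FALSE)
  }
  coords <- purrr::map(models, function(m) as.matrix(m[, c("x", "y", "z")]))
  fit_all <- function(coords, mean_xyz) {
    purrr::map(coords, function(co) {
      sp <- superpose(co[sel, , drop = FALSE],
                      mean_xyz[sel, , drop = FALSE])
      apply_superposition(co, sp)
    })
  }
  mean_of <- function(cs) Reduce(`+`, cs) / length(cs)
  m0 <- mean_of(coords)
  fitted <- fit_all(coords, m0)
  m1 <- mean_of(fitted)            # one refinement of the mean structure
  fitted <- fit_all(fitted, m1)
  m2 <- mean_of(fitted)
  dev2 <- Reduce(`+`, purrr::map(fitted, function(co) {
    rowSums((co - m2)^2)
  })) / length(fitted)
  rmsf <- sqrt(dev2)
  labs <- residues(dplyr::filter(atoms, .data$model == ref$model[1]))
  if (per == "atom") {
    out <- dplyr::mutate(ref[, c("chain", "resno", "resname", "atom")],
                         value = rmsf)
    out <- dplyr::left_join(out, labs[, c("chain", "resno", "label")],
                            by = c("chain", "resno"))
    return(new_profile(out, source = "ensemble_rmsf"))
  }
  out <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(ref, value = rmsf),
                    .data$chain, .data$resno, .data$resname),
    value = mean(.data$value), .groups = "drop")
  out <- dplyr::left_join(out, labs[, c("chain", "resno", "label")],
                          by = c("chain", "resno"))
  out <- dplyr::relocate(out, "chain", "resno", "resname", "label",
                         "value")
  new_profile(out, source = "ensemble_rmsf")
}

#' Theoretical B factor from an RMSF
#'
#' The isotropic conversion `B = (8 pi^2 / 3) * rmsf^2`, mapping ensemble
#' fluctuations onto the crystallographic B-factor scale.
#'
#' @param rmsf Numeric RMSF values, Angstrom (>= 0), or a `qg_profile`
#'   whose `value` column is an RMSF.
#' @return Numeric B factors in Angstrom^2, or a `qg_profile` with source
#'   `"theoretical_b"`.
#' @export
rmsf_to_bfactor <- function(rmsf) {
  if (inherits(rmsf, "qg_profile") || is.data.frame(rmsf)) {
    if (any(rmsf$value < 0, na.rm = TRUE)) {
      stop("rmsf_to_bfactor(): negative RMSF", call. = FALSE)
    }
    rmsf$value <- (8 * pi^2 / 3) * rmsf$value^2
    return(new_profile(rmsf, source = "theoretical_b"))
  }
  if (any(rmsf < 0, na.rm = TRUE)) {
    stop("rmsf_to_bfactor(): negative RMSF", call. = FALSE)
  }
  (8 * pi^2 / 3) * rmsf^2
}

#' Align flexibility profiles and correlate them
#'
#' Aligns profiles from different sources (crystal B, ensemble RMSF,
#' theoretical B) by sequential residue index, z-scores each, and reports
#' Spearman rank correlations for every pair -- the quantitative form of
#' "do the same residues come out flexible".
#'
#' @param profiles Named list of `qg_profile` tibbles.
#' @return List of class `qg_profile_comparison`: `table` (tibble:
#'   `index`, `label`, one normalized column per profile) and
#'   `correlations` (tibble: `profile_a`, `profile_b`, `spearman_rho`,
#'   `n`).
#' @export
compare_profiles <- function(profiles) {
  if (is.null(names(profiles)) || any(names(profiles) == "")) {
    stop("compare_profiles(): profiles must be named", call. = FALSE)
  }
  idx_of <- function(p) {
    if (!"index" %in% names(p)) {
      p$index <- seq_len(nrow(p))
    }
    p
  }
  normed <- purrr::imap(profiles, function(p, nm) {
    p <- idx_of(normalize_profile(p))
    tibble::tibble(index = p$index, label = p$label,
                   !!nm := p$normalized)
  })
  tab <- purrr::reduce(purrr::map(normed, function(p) {
    p[, setdiff(names(p), "label")]
  }), dplyr::full_join, by = "index")
  if (nrow(tab) == 0 || all(rowSums(!is.na(tab[, -1, drop = FALSE])) < 2)) {
    stop("compare_profiles(): profiles share no residue indices",
         call. = FALSE)
  }
  tab <- dplyr::arrange(tab, .data$index)
  lab <- normed[[1]][, c("index", "label")]
  tab <- dplyr::left_join(lab, tab, by = "index")
  nms <- names(profiles)
  pairs <- utils::combn(nms, 2, simplify = FALSE)
  cors <- purrr::map_dfr(pairs, function(pr) {
    a <- tab[[pr[1]]]; b <- tab[[pr[2]]]
    use <- stats::complete.cases(a, b)
    tibble::tibble(profile_a = pr[1], profile_b = pr[2],
                   spearman_rho = suppressWarnings(
                     cor(a[use], b[use], method = "spearman")),
                   n = sum(use))
  })
  structure(list(table = tab, correlations = cors),
            class = "qg_profile_comparison")
}

#' @export
print.qg_profile_comparison <- function(x, ...) {
  cat("<qg_profile_comparison>", nrow(x$table), "aligned residues\n")
  print(x$correlations)
  invisible(x)
}
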