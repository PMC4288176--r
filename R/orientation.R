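#' Classify extra-helical bases relative to the quartet core
#'
#' Each candidate base is tested for face-to-face stacking against the
#' core guanines and the other candidate bases: a partner whose ring
#' centroid lies within `stack_lateral_max` laterally (perpendicular to
#' the core axis) and inside `stack_axial_window` axially, with a
#' ring-plane angle of at most 30 degrees, makes the call `"stack"`.
#' Otherwise the elevation of the base centroid relative to its nearest
#' quartet layer decides: above `+elevation_cut` is `"up"` (towards the
#' top of the core axis as fixed by [build_core()]), below
#' `-elevation_cut` is `"down"`, and anything in between points `"out"`
#' into solvent. Up/down are global-axis calls, not per-face calls, so
#' they are deterministic across depositions.
#'
#' The published description of these four orientations gives no numeric
#' thresholds; the defaults here are canonical pi-stacking geometry
#' (3.0-4.2 Angstrom face separation, 2.5 Angstrom lateral slip) and are
#' explicit arguments so sensitivity can be scanned.
#'
#' @param atoms Single-model atom tibble containing the core chain.
#' @param core A `qg_core` from [build_core()].
#' @param bases Residue numbers to classify; default: every non-hetero
#'   nucleotide outside the core.
#' @param stack_lateral_max Maximum lateral centroid offset for stacking,
#'   Angstrom.
#' @param stack_axial_window Axial centroid separation window for
#'   stacking, Angstrom (length 2).
#' @param elevation_cut Elevation angle (degrees) separating up/down from
#'   out.
#' @param plane_angle_max Maximum angle between ring planes for stacking,
#'   degrees.
#' @return Tibble: `chain`, `resno`, `resname`, `label`, `category`
#'   (`up`/`down`/`out`/`stack`), `partner_resno`, `partner_label`,
#'   `axial`, `radial` (Angstrom), `elevation` (degrees).
#' @export
classify_base_orientation <- function(atoms, core, bases = NULL,
                                      stack_lateral_max = 2.5,
                                      stack_axial_window = c(3.0, 4.2),
                                      elevation_cut = 30,
                                      plane_angle_max = 30) {
  atoms <- check_atoms(atoms)
  if (length(unique(atoms$model)) > 1) {
    stop("classify_base_orientation(): one model at a time", call. = FALSE)
  }
  cres <- core_resnos(core)
  labs <- residues(atoms)
  nuc <- dplyr::filter(labs, !.data$hetero, !is.na(.data$base))
  if (is.null(bases)) {
    bases <- setdiff(nuc$resno, cres$resno)
  }
  res <- split_residues(atoms)
  ring_info <- function(chain, resno) {
    r <- res[[paste(chain, resno, sep = "\r")]]
    if (is.null(r)) return(NULL)
    xyz <- base_ring_xyz(r)
    if (is.null(xyz)) return(NULL)
    pl <- tryCatch(best_fit_plane(xyz), error = function(e) NULL)
    if (is.null(pl)) return(NULL)
    list(centroid = pl$centroid, normal = pl$normal)
  }
  # stacking candidates: core guanines + all classified bases
  cand <- dplyr::bind_rows(
    dplyr::mutate(cres[, c("chain", "resno")], core = TRUE),
    tibble::tibble(chain = nuc$chain[match(bases, nuc$resno)],
                   resno = bases, core = FALSE))
  cand <- dplyr::distinct(cand, .data$chain, .data$resno,
                          .keep_all = TRUE)
  cand$info <- purrr::map2(cand$chain, cand$resno, ring_info)
  cand <- cand[!purrr::map_lgl(cand$info, is.null), ]

  layer_t <- as.numeric(sweep(core$centroids, 2, core$origin) %*%
                          core$axis)
  out <- purrr::map_dfr(bases, function(b) {
    i <- which(!cand$core & cand$resno == b)
    if (!length(i)) {
      stop("classify_base_orientation(): residue ", b,
           " lacks ring atoms for classification", call. = FALSE)
    }
    i <- i[1]
    me <- cand$info[[i]]
    ar <- axial_radial(core, matrix(me$centroid, 1))
    # stacking search over every other candidate ring
    partner <- NA_integer_
    best_d <- Inf
    for (j in seq_len(nrow(cand))) {
      if (j == i) next
      other <- cand$info[[j]]
      dv <- me$centroid - other$centroid
      ax <- abs(sum(dv * core$axis))
      lat <- sqrt(max(0, sum(dv^2) - ax^2))
      pang <- acos(min(1, abs(sum(me$normal * other$normal)))) * 180 / pi
      if (lat <= stack_lateral_max && ax >= stack_axial_window[1] &&
          ax <= stack_axial_window[2] && pang <= plane_angle_max) {
        d <- sqrt(sum(dv^2))
        if (d < best_d) {
          best_d <- d
          partner <- j
        }
      }
    }
    nearest_layer <- which.min(abs(layer_t - ar$axial))
    v_ax <- ar$axial - layer_t[nearest_layer]
    elev <- atan2(v_ax, ar$radial) * 180 / pi
    category <- if (!is.na(partner)) "stack"
      else if (elev > elevation_cut) "up"
      else if (elev < -elevation_cut) "down"
      else "out"
    lab_of <- function(ch, rn) {
      l <- labs$label[labs$chain == ch & labs$resno == rn & !labs$hetero]
      if (length(l)) l[1] else NA_character_
    }
    tibble::tibble(
      chain = cand$chain[i], resno = b,
      resname = nuc$resname[match(b, nuc$resno)],
      label = lab_of(cand$chain[i], b),
      category = category,
      partner_resno = if (is.na(partner)) NA_integer_
                      else cand$resno[partner],
      partner_label = if (is.na(partner)) NA_character_
                      else lab_of(cand$chain[partner],
                                  cand$resno[partner]),
      axial = ar$axial, radial = ar$radial, elevation = elev)
  })
  out
}

#' Orientation occupancy across an ensemble
#'
#' Classifies the selected bases in every member of an ensemble (the
#' quartet core is re-detected per member) and tabulates the percentage
#' of members -- or of supplied weight mass, e.g. cluster populations
#' when summarising medoids -- in each orientation category.
#'
#' @param atoms Multi-model atom tibble.
#' @param bases Residue numbers to classify (as in
#'   [classify_base_orientation()]).
#' @param weights Optional per-model weights summing to 1 (default: equal
#'   weights).
#' @param ... Passed on to [classify_base_orientation()].
#' @return Tibble: `resno`, `label`, `category`, `occupancy` (percent;
#'   rows for a base sum to 100 within rounding).
#' @export
orientation_summary <- function(atoms, bases = NULL, weights = NULL, ...) {
  atoms <- check_atoms(atoms)
  models <- sort(unique(atoms$model))
  if (!is.null(weights)) {
    if (length(weights) != length(models)) {
      stop("orientation_summary(): need one weight per model",
           call. = FALSE)
    }
    if (abs(sum(weights) - 1) > 1e-6) {
      stop("orientation_summary(): weights must sum to 1", call. = FALSE)
    }
  } else {
    weights <- rep(1 / length(models), length(models))
  }
  calls <- purrr::map2_dfr(models, weights, function(m, w) {
    sub <- dplyr::filter(atoms, .data$model == m)
    core <- build_core(detect_quartets(sub))
    cl <- classify_base_orientation(sub, core, bases = bases, ...)
    dplyr::mutate(cl, weight = w)
  })
  tab <- dplyr::summarise(
    dplyr::group_by(calls, .data$resno, .data$label, .data$category),
    occupancy = 100 * sum(.data$weight), .groups = "drop")
  dplyr::arrange(tab, .data$resno, dplyr::desc(.data$occupancy))
}

#' Inter-strand phosphorus cleft width
#'
#' The cleft opening between two strands measured as the Euclidean
#' distance between the two backbone phosphorus atoms, the convention
#' used to size candidate small-molecule binding clefts.
#'
#' @param atoms Single-model atom tibble.
#' @param res_a,res_b Residue numbers (author numbering) of the two
#'   phosphate-bearing residues; alternatively sequential-index labels
#'   like `"G8"`.
#' @param chain Chain to measure in (default: the first chain).
#' @return Tibble: `chain`, `res_a`, `res_b`, `distance` (Angstrom,
#'   exact) and `distance_1dp` (1-decimal reporting convention).
#' @export
cleft_width <- function(atoms, res_a, res_b, chain = NULL) {
  atoms <- check_atoms(atoms)
  if (length(unique(atoms$model)) > 1) {
    atoms <- dplyr::filter(atoms, .data$model == min(.data$model))
  }
  if (is.null(chain)) chain <- sort(unique(atoms$chain))[1]
  sub <- dplyr::filter(atoms, .data$chain == !!chain)
  labs <- residues(sub)
  resolve <- function(r) {
    if (is.character(r)) {
      hit <- labs$resno[labs$label == r & !labs$hetero]
      if (!length(hit)) {
        stop("cleft_width(): no residue labelled '", r, "' in chain ",
             chain, call. = FALSE)
      }
      hit[1]
    } else {
      r
    }
  }
  ra <- resolve(res_a); rb <- resolve(res_b)
  p_of <- function(rn) {
    hit <- dplyr::filter(sub, .data$resno == rn, .data$atom == "P")
    if (nrow(hit) == 0) {
      stop("cleft_width(): residue ", rn, " has no phosphorus atom",
           call. = FALSE)
    }
    c(hit$x[1], hit$y[1], hit$z[1])
  }
  d <- sqrt(sum((p_of(ra) - p_of(rb))^2))
  tibble::tibble(chain = chain, res_a = ra, res_b = rb,
                 distance = d, distance_1dp = round(d, 1))
}
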