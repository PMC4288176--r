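#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one validated
#' list, with the defaults used throughout the package: 3.5 Angstrom
#' heavy-atom Hoogsteen cutoff, 1.0 Angstrom quartet planarity, canonical
#' pi-stacking windows for orientation calls, 2.5 Angstrom channel
#' radius, and silhouette-selected k-medoids with at most 10 clusters.
#'
#' @param hbond_max,planarity_max See [detect_quartets()].
#' @param stack_lateral_max,stack_axial_window,elevation_cut See
#'   [classify_base_orientation()].
#' @param radial_max See [assign_ions()].
#' @param k_max,seed,stride Clustering: maximum cluster count, seed, and
#'   frame stride applied before clustering.
#' @param normalization `"zscore"` or `"minmax"` profile normalisation.
#' @param atom_scope B-factor scope, `"all"` or `"base_only"`.
#' @return Named list of class `qg_config`.
#' @export
analysis_config <- function(hbond_max = 3.5, planarity_max = 1.0,
                            stack_lateral_max = 2.5,
                            stack_axial_window = c(3.0, 4.2),
                            elevation_cut = 30, radial_max = 2.5,
                            k_max = 10, seed = 1, stride = 1,
                            normalization = c("zscore", "minmax"),
                            atom_scope = c("all", "base_only")) {
  normalization <- match.arg(normalization)
  atom_scope <- match.arg(atom_scope)
  cfg <- list(hbond_max = hbond_max, planarity_max = planarity_max,
              stack_lateral_max = stack_lateral_max,
              stack_axial_window = stack_axial_window,
              elevation_cut = elevation_cut, radial_max = radial_max,
              k_max = k_max, seed = seed, stride = stride,
              normalization = normalization, atom_scope = atom_scope)
  nums <- unlist(cfg[c("hbond_max", "planarity_max", "stack_lateral_max",
                       "stack_axial_window", "elevation_cut",
                       "radial_max", "stride")])
  if (any(nums <= 0)) {
    stop("analysis_config(): thresholds must be positive", call. = FALSE)
  }
  if (k_max < 2) stop("analysis_config(): k_max must be >= 2",
                      call. = FALSE)
  structure(cfg, class = "qg_config")
}

fixed_json <- function(x, path) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 4, pretty = TRUE,
                          null = "null", na = "null")
  writeLines(txt, path)
  invisible(path)
}

#' Run the full structural-analysis pipeline on coordinate files
#'
#' For every input file: parse, and per model/chain detect the quartet
#' core, classify topology, assign ions, tabulate torsions, classify
#' extra-helical base orientations and per-residue B factors; for
#' multi-model inputs additionally compute ensemble RMSF and cluster the
#' members with same-trajectory transition counting. All results are
#' written as JSON (fixed key order, 4-decimal floats) and CSV files
#' under `out_dir`, together
#' with a run manifest (configuration, seed, package version). A failing
#' stage is recorded per input; the function errors only if every input
#' fails.
#'
#' @param inputs Character vector of coordinate file paths (PDB/mmCIF).
#' @param out_dir Output directory (created if needed).
#' @param config A [analysis_config()] list.
#' @return Invisibly, a tibble of produced files with columns `input`,
#'   `product`, `path`, `status`.
#' @export
analyze <- function(inputs, out_dir, config = analysis_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  note <- function(input, product, path, status = "ok") {
    results[[length(results) + 1]] <<- tibble::tibble(
      input = input, product = product, path = path, status = status)
  }
  for (input in inputs) {
    base <- sub("\\.(pdb|cif)(\\.gz)?$", "", basename(input),
                ignore.case = TRUE)
    step <- function(product, path, expr) {
      out <- tryCatch(list(ok = TRUE, value = expr),
                      error = function(e) list(ok = FALSE,
                                               msg = conditionMessage(e)))
      if (out$ok) note(input, product, path)
      else note(input, product, path, paste("failed:", out$msg))
      out$ok
    }
    atoms <- tryCatch(read_structures(input), error = function(e) e)
    if (inherits(atoms, "error")) {
      note(input, "parse", NA_character_,
           paste("failed:", conditionMessage(atoms)))
      next
    }
    models <- sort(unique(atoms$model))
    m1 <- dplyr::filter(atoms, .data$model == models[1])
    for (ch in sort(unique(m1$chain[!m1$hetero]))) {
      sub <- dplyr::filter(m1, .data$chain == ch)
      tag <- paste0(base, "_", ch)
      topo_path <- file.path(out_dir, paste0(tag, "_topology.json"))
      step("topology", topo_path, {
        qs <- detect_quartets(sub, hbond_max = config$hbond_max,
                              planarity_max = config$planarity_max)
        core <- build_core(qs)
        topo <- classify_topology(core, sub)
        ions <- assign_ions(core, sub, radial_max = config$radial_max)
        orient <- classify_base_orientation(
          sub, core,
          stack_lateral_max = config$stack_lateral_max,
          stack_axial_window = config$stack_axial_window,
          elevation_cut = config$elevation_cut)
        fixed_json(list(
          n_layers = topo$n_layers,
          rise_per_layer = core$rise_per_layer,
          planarity_rms = qs$planarity_rms,
          tracts = topo$tracts, loops = topo$loops,
          strand_senses = topo$strand_senses,
          snapback = topo$snapback_residues,
          ions = ions, orientations = orient), topo_path)
      })
      tors_path <- file.path(out_dir, paste0(tag, "_torsions.csv"))
      step("torsions", tors_path, {
        tt <- backbone_torsions(sub)
        utils::write.csv(
          dplyr::mutate(tt, dplyr::across(dplyr::where(is.numeric),
                                          function(x) round(x, 4))),
          tors_path, row.names = FALSE, na = "")
      })
      flex_path <- file.path(out_dir, paste0(tag, "_flexibility.csv"))
      step("flexibility", flex_path, {
        prof <- normalize_profile(
          residue_bfactors(sub, atom_scope = config$atom_scope),
          method = config$normalization)
        utils::write.csv(
          dplyr::mutate(prof, dplyr::across(dplyr::where(is.numeric),
                                            function(x) round(x, 4))),
          flex_path, row.names = FALSE, na = "")
      })
    }
    if (length(models) > 1) {
      rmsf_path <- file.path(out_dir, paste0(base, "_rmsf.csv"))
      step("rmsf", rmsf_path, {
        prof <- normalize_profile(ensemble_rmsf(atoms),
                                  method = config$normalization)
        utils::write.csv(
          dplyr::mutate(prof, dplyr::across(dplyr::where(is.numeric),
                                            function(x) round(x, 4))),
          rmsf_path, row.names = FALSE, na = "")
      })
      clus_path <- file.path(out_dir, paste0(base, "_clusters.json"))
      step("clusters", clus_path, {
        keep <- models[seq(1, length(models), by = config$stride)]
        sub <- dplyr::filter(atoms, .data$model %in% keep)
        dm <- distance_matrix(sub)
        k <- select_k(dm, k_max = min(config$k_max,
                                      nrow(dm$values) - 1),
                      seed = config$seed)
        cl <- cluster_medoids(dm, as.integer(k), seed = config$seed)
        gr <- transition_graph(cl)
        fixed_json(list(
          k = cl$k,
          silhouettes = attr(k, "silhouettes"),
          weak_structure = attr(k, "weak_structure"),
          populations = cl$populations,
          medoid_models = dm$frames$model[cl$medoid_indices],
          labels = cl$labels,
          edges = gr$edges,
          isolated = isolated_clusters(gr)), clus_path)
      })
    }
  }
  manifest <- list(
    package = "quadgeom",
    version = as.character(utils::packageVersion("quadgeom")),
    config = unclass(config),
    inputs = basename(inputs))
  fixed_json(manifest, file.path(out_dir, "manifest.json"))
  out <- dplyr::bind_rows(results)
  if (nrow(out) && all(grepl("^failed", out$status))) {
    stop("analyze(): every input failed; see the returned log",
         call. = FALSE)
  }
  invisible(out)
}
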