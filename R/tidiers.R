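#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a k-medoids clustering
#'
#' One row per frame: model number, trajectory, cluster assignment and
#' whether the frame is its cluster's medoid.
#'
#' @param x A `qg_clusters`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.qg_clusters <- function(x, ...) {
  fr <- x$frames
  dplyr::mutate(fr, cluster = x$labels,
                is_medoid = dplyr::row_number() %in% x$medoid_indices)
}

#' One-row summary of a k-medoids clustering
#'
#' @param x A `qg_clusters`.
#' @param ... Unused.
#' @return Tibble with `k`, `n`, `objective`, `max_population`,
#'   `min_population`.
#' @exportS3Method generics::glance
glance.qg_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$labels), objective = x$objective,
                 max_population = max(x$populations),
                 min_population = min(x$populations))
}

#' Tidy a transition graph
#'
#' @param x A `qg_transitions`.
#' @param ... Unused.
#' @return Edge tibble (`from`, `to`, `count`).
#' @exportS3Method generics::tidy
tidy.qg_transitions <- function(x, ...) x$edges

#' Tidy a topology report
#'
#' @param x A `qg_topology`.
#' @param ... Unused.
#' @return The loop table with tract/sense context columns.
#' @exportS3Method generics::tidy
tidy.qg_topology <- function(x, ...) x$loops

#' One-row summary of a topology report
#'
#' @param x A `qg_topology`.
#' @param ... Unused.
#' @return Tibble with `n_layers`, `n_tracts`, `n_loops`,
#'   `n_propeller`, `n_lateral`, `n_diagonal`, `n_snapback`,
#'   `all_parallel`.
#' @exportS3Method generics::glance
glance.qg_topology <- function(x, ...) {
  tibble::tibble(
    n_layers = x$n_layers,
    n_tracts = nrow(x$tracts),
    n_loops = nrow(x$loops),
    n_propeller = sum(x$loops$type == "propeller"),
    n_lateral = sum(x$loops$type == "lateral"),
    n_diagonal = sum(x$loops$type == "diagonal"),
    n_snapback = nrow(x$snapback_residues),
    all_parallel = all(x$strand_senses$parallel, na.rm = TRUE))
}

#' Tidy a quartet core
#'
#' @param x A `qg_core`.
#' @param ... Unused.
#' @return One row per core guanine with its layer assignment.
#' @exportS3Method generics::tidy
tidy.qg_core <- function(x, ...) core_resnos(x)
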