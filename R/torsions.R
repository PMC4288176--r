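PURINE_CODES <- c("A", "G")

#' Backbone and glycosidic torsions per nucleotide
#'
#' Computes the seven standard nucleic-acid torsions, in degrees on
#' `(-180, 180]`:
#' \describe{
#'   \item{alpha}{O3'(i-1)-P-O5'-C5'}
#'   \item{beta}{P-O5'-C5'-C4'}
#'   \item{gamma}{O5'-C5'-C4'-C3'}
#'   \item{delta}{C5'-C4'-C3'-O3'}
#'   \item{epsilon}{C4'-C3'-O3'-P(i+1)}
#'   \item{zeta}{C3'-O3'-P(i+1)-O5'(i+1)}
#'   \item{chi}{O4'-C1'-N9-C4 for purines, O4'-C1'-N1-C2 for pyrimidines}
#' }
#' An angle whose atoms are absent (5'-terminal alpha/beta, 3'-terminal
#' epsilon/zeta, or any missing atom) is `NA`, never an error, matching
#' how published torsion tables leave terminal cells blank.
#'
#' @param atoms Single-model atom tibble; each chain is processed
#'   independently in residue-number order.
#' @return Tibble: `chain`, `resno`, `resname`, `base`, `index`, `label`,
#'   `alpha` ... `zeta`, `chi` (degrees).
#' @examples
#' tor <- tibble::tibble(alpha = c(NA, -60), beta = c(NA, 180),
#'                       gamma = c(55, 55), delta = c(120, 120),
#'                       epsilon = c(-170, NA), zeta = c(-95, NA),
#'                       chi = c(-120, -120))
#' chain <- build_chain(ic_nucleotide_chain(tor))
#' backbone_torsions(chain)
#' @export
backbone_torsions <- function(atoms) {
  atoms <- check_atoms(atoms)
  if (length(unique(atoms$model)) > 1) {
    stop("backbone_torsions(): one model at a time", call. = FALSE)
  }
  labs <- residues(atoms)
  nuc <- dplyr::filter(labs, !.data$hetero, !is.na(.data$base))
  out <- list()
  for (ch in unique(nuc$chain)) {
    rn <- nuc[nuc$chain == ch, ]
    rn <- rn[order(rn$resno), ]
    res <- split_residues(dplyr::filter(atoms, .data$chain == ch))
    get <- function(resno, name) {
      r <- res[[paste(ch, resno, sep = "\r")]]
      if (is.null(r)) return(NULL)
      i <- match(name, r$atom)
      if (is.na(i)) return(NULL)
      c(r$x[i], r$y[i], r$z[i])
    }
    dih <- function(p1, p2, p3, p4) {
      if (is.null(p1) || is.null(p2) || is.null(p3) || is.null(p4)) {
        return(NA_real_)
      }
      tryCatch(dihedral_angle(p1, p2, p3, p4), error = function(e) NA_real_)
    }
    for (i in seq_len(nrow(rn))) {
      r <- rn$resno[i]
      # sequence neighbours must be the adjacent residues of the chain
      rp <- if (i > 1) rn$resno[i - 1] else NA
      rx <- if (i < nrow(rn)) rn$resno[i + 1] else NA
      P <- get(r, "P"); O5 <- get(r, "O5'"); C5 <- get(r, "C5'")
      C4 <- get(r, "C4'"); C3 <- get(r, "C3'"); O3 <- get(r, "O3'")
      O4 <- get(r, "O4'"); C1 <- get(r, "C1'")
      O3p <- if (!is.na(rp)) get(rp, "O3'") else NULL
      Pn <- if (!is.na(rx)) get(rx, "P") else NULL
      O5n <- if (!is.na(rx)) get(rx, "O5'") else NULL
      purine <- rn$base[i] %in% PURINE_CODES
      Ng <- get(r, if (purine) "N9" else "N1")
      Cg <- get(r, if (purine) "C4" else "C2")
      out[[length(out) + 1]] <- tibble::tibble(
        chain = ch, resno = r, resname = rn$resname[i],
        base = rn$base[i], index = rn$index[i], label = rn$label[i],
        alpha = dih(O3p, P, O5, C5),
        beta = dih(P, O5, C5, C4),
        gamma = dih(O5, C5, C4, C3),
        delta = dih(C5, C4, C3, O3),
        epsilon = dih(C4, C3, O3, Pn),
        zeta = dih(C3, O3, Pn, O5n),
        chi = dih(O4, C1, Ng, Cg))
    }
  }
  dplyr::bind_rows(out)
}

#' Side-by-side torsion comparison table across structures
#'
#' Builds the classic published layout -- one row per residue x angle,
#' one column per structure -- for comparing loop torsions across crystal
#' forms and NMR models.
#'
#' @param structures Named list of single-model atom tibbles (the names
#'   become columns).
#' @param residues Residue selection: labels (`"A1"`, `"C9"`; matched
#'   against the sequential-index label of each chain) or integer
#'   sequential indices. Must select at least one residue.
#' @param angles Which torsions to tabulate (default all seven).
#' @param digits Round to this many decimals (default 0, printed-table
#'   granularity); `NA` to disable.
#' @return Tibble: `label`, `angle`, then one numeric column per
#'   structure; undefined angles are `NA`.
#' @export
torsion_table <- function(structures, residues,
                          angles = c("alpha", "beta", "gamma", "delta",
                                     "epsilon", "zeta", "chi"),
                          digits = 0) {
  if (is.null(names(structures)) || any(names(structures) == "") ||
      anyDuplicated(names(structures))) {
    stop("torsion_table(): structures must be uniquely named",
         call. = FALSE)
  }
  if (length(residues) == 0) {
    stop("torsion_table(): empty residue selection", call. = FALSE)
  }
  angles <- match.arg(angles, several.ok = TRUE)
  long <- purrr::imap_dfr(structures, function(atoms, nm) {
    tt <- backbone_torsions(atoms)
    sel <- if (is.numeric(residues)) tt$index %in% residues
           else tt$label %in% residues
    tt <- tt[sel, c("label", "index", angles)]
    tt <- tidyr::pivot_longer(tt, dplyr::all_of(angles),
                              names_to = "angle", values_to = "value")
    tt$structure <- nm
    tt
  })
  wide <- tidyr::pivot_wider(long, id_cols = c("label", "index", "angle"),
                             names_from = "structure",
                             values_from = "value")
  wide <- dplyr::arrange(wide,
                         .data$index,
                         match(.data$angle, c("alpha", "beta", "gamma",
                                              "delta", "epsilon", "zeta",
                                              "chi")))
  wide$index <- NULL
  if (!is.na(digits)) {
    wide <- dplyr::mutate(wide, dplyr::across(
      dplyr::where(is.numeric), function(x) round(x, digits)))
  }
  wide
}
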