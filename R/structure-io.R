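#' Read atomic coordinates into a tidy atom table
#'
#' Parses a PDB or mmCIF coordinate file (single structures, multi-model
#' NMR bundles, or multi-model "trajectory" files) into one tibble with a
#' row per atom per model -- the common currency of every analysis in this
#' package. Parsing itself is delegated to \pkg{bio3d}.
#'
#' Alternate locations are resolved to the highest-occupancy conformer
#' (ties broken by file order). Waters and ions are retained with
#' `hetero = TRUE`. Primed-atom-name variants (`O5*`) and quoting
#' (`"O5'"`) are normalised to the plain primed form (`O5'`).
#'
#' @param path Path to a coordinate file.
#' @param format One of `"auto"` (by file extension), `"pdb"`, `"cif"`.
#' @param drop_hydrogens Drop H/D atoms on read (default `TRUE`; all
#'   downstream geometry is hydrogen-free so that crystal structures,
#'   which lack hydrogens, and NMR models are treated uniformly).
#' @return A tibble with columns `model` (integer), `chain`, `resno`
#'   (author numbering, preserved verbatim), `resname`, `atom`, `elem`,
#'   `x`, `y`, `z` (Angstrom), `occ`, `b` (Angstrom^2) and `hetero`
#'   (logical). Every `MODEL` record becomes one value of `model`.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' write_pdb(build_quadruplex(), pdb)
#' atoms <- read_structures(pdb)
#' dplyr::count(atoms, model)
#' @export
read_structures <- function(path, format = c("auto", "pdb", "cif"),
                            drop_hydrogens = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("read_structures(): file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "cif" else "pdb"
  }
  p <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    } else {
      suppressWarnings(bio3d::read.cif(path, multi = TRUE, rm.alt = FALSE,
                                       verbose = FALSE))
    },
    error = function(e) {
      stop("read_structures(): could not parse '", path, "': ",
           conditionMessage(e), call. = FALSE)
    })
  at <- p$atom
  if (is.null(at) || nrow(at) == 0) {
    stop("read_structures(): no atoms / zero models in ", path,
         call. = FALSE)
  }
  xyz <- p$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  n_atoms <- nrow(at)

  name <- normalize_atom_name(at$elety)
  elem <- at$elsy %||% at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, n_atoms)
  elem <- ifelse(is.na(elem) | elem == "", guess_element(name), toupper(elem))
  occ <- ifelse(is.na(at$o), 1, at$o)
  bfac <- ifelse(is.na(at$b), 0, at$b)
  chain <- ifelse(is.na(at$chain), "A", at$chain)
  insert <- at$insert
  insert <- ifelse(is.na(insert), "", insert)

  # altloc policy: highest occupancy wins, ties -> first in file
  alt <- at$alt
  keep <- rep(TRUE, n_atoms)
  if (any(!is.na(alt) & alt != "")) {
    key <- paste(chain, at$resno, insert, name, sep = "\r")
    ord <- order(key, -occ, seq_len(n_atoms))
    dup <- duplicated(key[ord])
    keep[ord[dup]] <- FALSE
  }

  one <- tibble::tibble(
    chain = chain, resno = as.integer(at$resno), resname = trimws(at$resid),
    atom = name, elem = elem, occ = occ, b = bfac,
    hetero = at$type == "HETATM")
  rows <- purrr::map(seq_len(n_models), function(m) {
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    dplyr::mutate(one, model = m, x = co[, 1], y = co[, 2], z = co[, 3],
                  .before = 1)[keep, ]
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::relocate(out, "model", "chain", "resno", "resname", "atom",
                         "elem", "x", "y", "z", "occ", "b", "hetero")
  if (drop_hydrogens) out <- dplyr::filter(out, !.data$elem %in% c("H", "D"))
  out                                   # file order preserved per model
}

normalize_atom_name <- function(x) {
  x <- gsub('"', "", trimws(x), fixed = TRUE)
  gsub("*", "'", x, fixed = TRUE)
}

guess_element <- function(name) {
  core <- sub("^[0-9']+", "", gsub("'", "", name))
  two <- toupper(substr(core, 1, 2))
  one <- toupper(substr(core, 1, 1))
  ifelse(two %in% c("BR", "CL", "MG", "MN", "ZN", "NA", "FE", "SR", "CS",
                    "RB", "BA", "TL"),
         two, one)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an atom table to a PDB file
#'
#' Writes fixed-column PDB (3-decimal coordinates) through
#' [bio3d::write.pdb()]. Multi-model tables become `MODEL`/`ENDMDL`
#' blocks; coordinates are taken from the first model's atom ordering, so
#' all models must share the same atom layout.
#'
#' @param atoms An atom tibble (see [read_structures()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path) {
  atoms <- check_atoms(atoms)
  models <- split(atoms, atoms$model)
  ref <- models[[1]]
  n <- nrow(ref)
  same <- purrr::every(models, function(m) {
    nrow(m) == n && all(m$atom == ref$atom) && all(m$resno == ref$resno)
  })
  if (!same) {
    stop("write_pdb(): all models must share the same atom layout",
         call. = FALSE)
  }
  xyz <- do.call(rbind, purrr::map(models, function(m) {
    as.numeric(t(as.matrix(m[, c("x", "y", "z")])))
  }))
  bio3d::write.pdb(file = path,
                   type = ifelse(ref$hetero, "HETATM", "ATOM"),
                   eleno = seq_len(n),
                   elety = ref$atom,
                   resid = ref$resname,
                   chain = ref$chain,
                   resno = ref$resno,
                   xyz = xyz,
                   o = ref$occ,
                   b = ref$b,
                   elesy = ref$elem)
  invisible(path)
}

check_atoms <- function(atoms) {
  need <- c("model", "chain", "resno", "resname", "atom", "elem",
            "x", "y", "z", "occ", "b", "hetero")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) {
    stop("not an atom table; missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(atoms)
}

# residue-name normalization so NMR (one-letter) and X-ray (DA/DG/...)
# depositions compare; modified BrU maps to U
RESNAME_MAP <- c(DA = "A", DG = "G", DC = "C", DT = "T", DU = "U",
                 A = "A", G = "G", C = "C", T = "T", U = "U",
                 ADE = "A", GUA = "G", CYT = "C", THY = "T", URA = "U",
                 BRU = "U", `5BU` = "U")

#' Normalise residue names to one-letter nucleotide codes
#'
#' Maps deposition dialects (`DG`, `GUA`, `G`, brominated `BRU`, ...) onto
#' one-letter codes so NMR and X-ray entries compare; anything unknown is
#' returned as `NA`.
#'
#' @param resname Character vector of residue names.
#' @return Character vector of one-letter codes or `NA`.
#' @export
normalize_resname <- function(resname) {
  unname(RESNAME_MAP[toupper(trimws(resname))])
}

#' Per-residue summary of an atom table
#'
#' One row per residue per model, with a derived sequential nucleotide
#' index (1 upward from the 5' end of each chain, hetero groups excluded)
#' and a paper-style label such as `"G2"` built from the one-letter code
#' and that index. Author `resno` is never altered.
#'
#' @param atoms An atom tibble.
#' @return Tibble with columns `model`, `chain`, `resno`, `resname`,
#'   `hetero`, `n_atoms`, `base` (one-letter code or `NA`), `index`
#'   (sequential nucleotide index, `NA` for hetero groups) and `label`.
#' @export
residues <- function(atoms) {
  atoms <- check_atoms(atoms)
  res <- dplyr::summarise(
    dplyr::group_by(atoms, .data$model, .data$chain, .data$resno,
                    .data$resname, .data$hetero),
    n_atoms = dplyr::n(), .groups = "drop")
  res <- dplyr::arrange(res, .data$model, .data$chain, .data$resno)
  res$base <- normalize_resname(res$resname)
  res <- dplyr::mutate(
    dplyr::group_by(res, .data$model, .data$chain),
    index = ifelse(!.data$hetero & !is.na(.data$base),
                   cumsum(!.data$hetero & !is.na(.data$base)), NA_integer_),
    .keep = "all")
  res <- dplyr::ungroup(res)
  res$label <- ifelse(is.na(res$index), res$resname,
                      paste0(res$base, res$index))
  res
}

#' Count residues of a chemical class
#'
#' @param atoms An atom tibble (typically one model; counts are taken over
#'   distinct `(model, chain, resno, resname)` and divided by the number
#'   of models so a homogeneous ensemble reports per-model counts).
#' @param class One of `"water"`, `"potassium"`, `"magnesium"`,
#'   `"nucleotide"`.
#' @return Integer count.
#' @examples
#' q <- build_quadruplex(place_channel_ions = TRUE)
#' count_residue_class(q, "potassium")
#' @export
count_residue_class <- function(atoms,
                                class = c("water", "potassium", "magnesium",
                                          "nucleotide")) {
  class <- match.arg(class)
  res <- residues(atoms)
  nm <- toupper(res$resname)
  hit <- switch(class,
    water = nm %in% c("HOH", "WAT", "H2O", "DOD"),
    potassium = nm %in% c("K", "K+"),
    magnesium = nm %in% c("MG", "MG2"),
    nucleotide = !res$hetero & !is.na(res$base))
  n_models <- length(unique(res$model))
  as.integer(sum(hit) / n_models)
}

#' Extract one chain of one model
#'
#' @param atoms An atom tibble.
#' @param model Model number (default 1).
#' @param chain Chain identifier.
#' @return Single-model, single-chain atom tibble with original numbering
#'   (hetero groups carried along with their chain).
#' @export
extract_chain <- function(atoms, chain, model = 1) {
  atoms <- check_atoms(atoms)
  if (!model %in% atoms$model) {
    stop("extract_chain(): no model ", model, "; available: ",
         paste(sort(unique(atoms$model)), collapse = ", "), call. = FALSE)
  }
  sub <- dplyr::filter(atoms, .data$model == !!model)
  if (!chain %in% sub$chain) {
    stop("extract_chain(): no chain '", chain, "'; available: ",
         paste(sort(unique(sub$chain)), collapse = ", "), call. = FALSE)
  }
  dplyr::filter(sub, .data$chain == !!chain)
}

#' Fetch a deposited PDB entry into a local cache
#'
#' Downloads the named entry from the RCSB file server the first time and
#' caches it; later calls read the cache. Useful for reproducing the
#' published c-KIT quadruplex analyses (entries 4WO2, 4WO3, 3QXR, 2O3M)
#' on a machine with network access.
#'
#' @param id Four-character PDB identifier.
#' @param dir Cache directory (default `tools::R_user_dir("quadgeom",
#'   "cache")`).
#' @return Path to the cached PDB file.
#' @export
fetch_structure <- function(id,
                            dir = tools::R_user_dir("quadgeom", "cache")) {
  id <- toupper(id)
  stopifnot(grepl("^[0-9][A-Z0-9]{3}$", id))
  dest <- file.path(dir, paste0(id, ".pdb"))
  if (!file.exists(dest)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    url <- paste0("https://files.rcsb.org/download/", id, ".pdb")
    ok <- tryCatch(
      utils::download.file(url, dest, quiet = TRUE, mode = "wb") == 0,
      error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok || !file.exists(dest) || file.size(dest) == 0) {
      unlink(dest)
      stop("fetch_structure(): deposited entry ", id,
           " is not cached and could not be downloaded", call. = FALSE)
    }
  }
  dest
}

#' JSON summary of an atom table
#'
#' @param atoms An atom tibble.
#' @return A JSON string (sorted keys) summarising models, chains and
#'   residue-class counts.
#' @export
structure_summary_json <- function(atoms) {
  atoms <- check_atoms(atoms)
  res <- residues(atoms)
  m1 <- dplyr::filter(atoms, .data$model == min(.data$model))
  out <- list(
    n_models = length(unique(atoms$model)),
    chains = sort(unique(atoms$chain)),
    n_atoms_per_model = nrow(m1),
    n_residues_per_model = nrow(dplyr::filter(
      res, .data$model == min(res$model))),
    counts = list(
      water = count_residue_class(atoms, "water"),
      potassium = count_residue_class(atoms, "potassium"),
      magnesium = count_residue_class(atoms, "magnesium"),
      nucleotide = count_residue_class(atoms, "nucleotide")))
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
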