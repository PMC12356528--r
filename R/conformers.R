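# Conformer generation and ingestion of externally determined coordinates.
#
# Protocol: seeded distance-geometry embedding (ETKDG, n_confs embeddings
# pruned at 0.5 Angstrom heavy-atom RMSD), per-conformer force-field
# minimization, and selection of the minimum-energy member. Embedding runs
# through the system RDKit (the only seedable distance-geometry engine on
# this stack; OpenBabel's builder draws unseedable random numbers), while
# minimization and scoring use OpenBabel MMFF94 with UFF as fallback for
# atoms MMFF94 cannot parameterize. The whole chain is byte-deterministic
# for a fixed seed. If no python/RDKit is available, a non-deterministic
# OpenBabel fallback (builder + systematic rotor walk) is used with a
# warning.

rdkit_available <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) return(FALSE)
  if (is.null(.rdkit_cache$ok)) {
    st <- suppressWarnings(system2(py, c("-c", shQuote("import rdkit")),
                                   stdout = FALSE, stderr = FALSE))
    .rdkit_cache$ok <- identical(st, 0L)
  }
  .rdkit_cache$ok
}

.rdkit_cache <- new.env(parent = emptyenv())

# Seeded multi-conformer distance-geometry embedding; returns an SDF path.
rdkit_embed <- function(smi, n_confs, seed, prune_rms = 0.5) {
  script <- system.file("python", "embed_confs.py", package = "exitvector",
                        mustWork = TRUE)
  inp <- tempfile(fileext = ".smi")
  out <- tempfile(fileext = ".sdf")
  writeLines(smi, inp)
  st <- suppressWarnings(system2(Sys.which("python"),
                                 c(script, inp, out, n_confs, seed,
                                   prune_rms),
                                 stdout = FALSE, stderr = FALSE))
  unlink(inp)
  if (!identical(st, 0L) || !file.exists(out) ||
      ob_count_records(out) < 1) {
    stop("distance-geometry embedding failed", call. = FALSE)
  }
  out
}

#' Generate and minimize a conformer ensemble
#'
#' Embeds up to `n_confs` distance-geometry conformers for the compound
#' (seeded, pruned at `prune_rms` heavy-atom RMSD), minimizes each with a
#' molecular-mechanics force field, scores it, and designates the
#' lowest-energy member (ties broken by the lowest index).
#'
#' @param compound An `ev_compound` row (or any list with `$structure` and
#'   `$product_id`); the structure may carry attachment-point annotations,
#'   which do not affect the geometry.
#' @param n_confs Number of embeddings attempted (default 200; after RMSD
#'   pruning the ensemble is usually much smaller for these rigid
#'   compounds).
#' @param seed Integer seed for the embedding.
#' @param forcefield Force field for minimization and scoring
#'   (`"MMFF94"`, falling back to `"UFF"` when parameterization fails).
#' @param steps Minimization step cap per conformer.
#' @param prune_rms RMSD pruning threshold in Angstrom (default 0.5).
#' @return An object of class `ev_ensemble`: a list with `compound_id`,
#'   `coordinates` (list of n_atoms x 3 matrices, Angstrom, atom order =
#'   order of appearance in the structure), `elements`, `energies`
#'   (kcal/mol), `lowest_index`, `source = "computed"` and a `method`
#'   provenance tag.
#' @examples
#' \donttest{
#' eth <- list(structure = "CC", product_id = "ethane")
#' ens <- embed_and_minimize(eth, n_confs = 5)
#' ens$energies[ens$lowest_index]
#' }
#' @export
embed_and_minimize <- function(compound, n_confs = 200, seed = 42,
                               forcefield = "MMFF94", steps = 500,
                               prune_rms = 0.5) {
  stopifnot(n_confs >= 1)
  smi <- compound$structure
  id <- if (!is.null(compound$product_id)) compound$product_id
  else compound$id
  if (rdkit_available()) {
    protocol <- "etkdg-dg-embedding"
    sdfc <- tryCatch(rdkit_embed(smi, n_confs, seed, prune_rms),
                     error = function(e) {
                       stop("3D embedding failed for '", id, "': ",
                            conditionMessage(e), call. = FALSE)
                     })
  } else {
    warning("no seedable embedding engine found (python/rdkit missing); ",
            "using the OpenBabel builder, which is not deterministic")
    protocol <- "builder+systematic-rotor-walk"
    sdf0 <- tryCatch(ob_gen3d(smi),
                     error = function(e) {
                       stop("3D embedding failed for '", id, "': ",
                            conditionMessage(e), call. = FALSE)
                     })
    sdfc <- ob_conformers(sdf0, nconf = n_confs)
  }
  sdfm <- ob_minimize(sdfc, forcefield = forcefield, steps = steps)
  ff <- forcefield
  energies <- tryCatch(ob_energies(sdfm, ff), error = function(e) NULL)
  if (is.null(energies) && forcefield == "MMFF94") {
    warning("MMFF94 could not parameterize '", id, "'; falling back to UFF")
    ff <- "UFF"
    sdfm <- ob_minimize(sdfc, forcefield = ff, steps = steps)
    energies <- ob_energies(sdfm, ff)
  }
  geo <- read_sdf_geometry(sdfm)
  keep <- seq_len(min(length(energies), n_confs))
  new_ensemble(id, geo$coordinates[keep], geo$elements[[1]],
               energies[keep], source = "computed",
               method = list(protocol = protocol, forcefield = ff,
                             n_confs_requested = n_confs,
                             n_confs = length(keep), seed = seed,
                             prune_rms = prune_rms,
                             minimizer_steps = steps))
}

#' Load externally supplied 3D coordinates
#'
#' Reads one or more 3D models from an SDF/MOL file (for example re-running
#' the exit-vector analysis on crystallographic coordinates) into a
#' conformer ensemble with energies marked absent. Multi-model files yield
#' one conformer per model, all of which are retained by the downstream
#' vector analysis.
#'
#' @param path Path to an SDF (V2000) file with explicit 3D coordinates.
#' @param compound_id Label for the ensemble (default: the file name).
#' @param mapping Optional named integer vector assigning the vector-
#'   defining atom roles, e.g. `c(c1 = 3, n2 = 1, blue = 7, red = 14)`
#'   (1-based atom indices into the file's atom block). Checked against the
#'   atom count.
#' @return An `ev_ensemble` with `source = "supplied_coordinates"`,
#'   `energies = NA` and `lowest_index = 1`; the `mapping` is carried in
#'   the `roles` field.
#' @export
load_coordinates <- function(path, compound_id = basename(path),
                             mapping = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  geo <- tryCatch(read_sdf_geometry(path),
                  error = function(e) stop("could not read any structure ",
                                           "from '", path, "'",
                                           call. = FALSE))
  if (length(geo$coordinates) == 0) {
    stop("could not read any structure from '", path, "'", call. = FALSE)
  }
  flat <- all(vapply(geo$coordinates,
                     function(m) all(abs(m[, 3]) < 1e-8), logical(1)))
  if (flat) {
    stop("'", path, "' contains 2D coordinates only (all z = 0); ",
         "the exit-vector analysis needs 3D models", call. = FALSE)
  }
  n_atoms <- nrow(geo$coordinates[[1]])
  if (!is.null(mapping)) {
    need <- c("c1", "n2", "blue", "red")
    if (!all(need %in% names(mapping))) {
      stop("mapping must name the roles ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (any(mapping < 1 | mapping > n_atoms)) {
      stop("mapping references atoms outside 1..", n_atoms, call. = FALSE)
    }
  }
  ens <- new_ensemble(compound_id, geo$coordinates, geo$elements[[1]],
                      rep(NA_real_, length(geo$coordinates)),
                      source = "supplied_coordinates",
                      method = list(protocol = "supplied", file = path))
  ens$roles <- mapping
  ens
}

new_ensemble <- function(compound_id, coordinates, elements, energies,
                         source, method) {
  stopifnot(length(coordinates) == length(energies),
            length(coordinates) >= 1)
  for (m in coordinates) {
    d <- stats::dist(m)
    if (any(d < 0.6)) {
      stop("conformer of '", compound_id, "' has an interatomic distance ",
           "below 0.6 Angstrom - degenerate geometry", call. = FALSE)
    }
  }
  lowest <- if (all(is.na(energies))) 1L else which.min(energies)
  structure(list(compound_id = compound_id, coordinates = coordinates,
                 elements = elements, energies = energies,
                 lowest_index = lowest, source = source, method = method),
            class = "ev_ensemble")
}

#' @export
print.ev_ensemble <- function(x, ...) {
  cat("<ev_ensemble> ", x$compound_id, ": ", length(x$coordinates),
      " conformer(s), ", nrow(x$coordinates[[1]]), " atoms, source = ",
      x$source, "\n", sep = "")
  if (!all(is.na(x$energies))) {
    cat("  energies [kcal/mol]: min ",
        round(min(x$energies), 3), " at #", x$lowest_index, "\n", sep = "")
  }
  invisible(x)
}

# Parse coordinates and elements from a (multi-record) V2000 SDF via
# ChemmineR; returns lists aligned with the records.
read_sdf_geometry <- function(path) {
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  coords <- list(); elements <- list()
  for (i in seq_along(ChemmineR::sdfid(sdfs))) {
    ab <- ChemmineR::atomblock(sdfs[[i]])
    m <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
    coords[[i]] <- m
    elements[[i]] <- sub("_.*$", "", rownames(ab))
  }
  list(coordinates = coords, elements = elements)
}

#' Write a conformer ensemble to a multi-record SDF
#'
#' Energies and the method tag are stored as SD data fields.
#'
#' @param ensemble An `ev_ensemble`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ensemble_sdf <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ensemble$coordinates)) {
    m <- ensemble$coordinates[[i]]
    el <- ensemble$elements
    lines <- c(
      paste0(ensemble$compound_id, "_conf", i),
      " exitvector", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(m), 0L),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              m[, 1], m[, 2], m[, 3], el),
      "M  END",
      "> <energy_kcal_mol>", as.character(ensemble$energies[i]), "",
      "> <method>",
      paste(names(ensemble$method),
            vapply(ensemble$method, function(x) paste(x, collapse = ","),
                   character(1)),
            sep = "=", collapse = "; "),
      "", "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}
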