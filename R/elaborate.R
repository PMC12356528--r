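# Virtual elaboration: aryl attachment at C1 (the design-phase surrogate of
# the Suzuki-Miyaura coupling of the boron handle) and N-capping at N2.
# Both are attachment-point graph edits - a single new bond formed at the
# annotated atoms, displacing one hydrogen on each side - not reaction
# template matching. The four vector-defining atoms are tracked by atom
# map through every edit: 1 = C1 (green), 2 = N2 (orange), 3 = the fragment
# atom bonded to C1 (blue), 4 = the cap atom bonded to N2 (red).

#' Attach an aryl fragment at the C1 handle
#'
#' Forms the C-C bond between the scaffold's C1 attachment carbon and the
#' fragment's annotated atom, displacing one hydrogen from each.
#' Stereocentres written in the scaffold are preserved (the coupling this
#' models is retentive). Attaching the [hydrogen_placeholder()] is a no-op.
#'
#' @param scaffold A one-row `ev_scaffolds` data.frame (or any list with
#'   `$structure` and `$id`).
#' @param fragment A one-row fragment registry entry (exactly one
#'   attachment annotation).
#' @return A one-row data.frame of class `ev_compound` with columns
#'   `structure` (annotated SMILES), `scaffold_id`, `fragment_id`, `cap_id`
#'   (`NA` until capped), and the tracked atom indices `atom_c1`,
#'   `atom_n2`, `atom_blue`, `atom_red` (order-of-appearance indices,
#'   matching the atom order of SDF output downstream).
#' @export
attach_fragment <- function(scaffold, fragment) {
  frag_structure <- fragment$structure
  if (is_hydrogen_entry(fragment)) {
    return(new_compound(scaffold$structure, scaffold$id, fragment$id, NA))
  }
  check_single_attachment(frag_structure, fragment$id)
  guest <- smi_set_map(frag_structure, 1, 3)
  s <- smi_attach(scaffold$structure, 1, guest, 3, "%93")
  new_compound(s, scaffold$id, fragment$id, NA)
}

#' Attach a capping group at the N2 handle
#'
#' Forms the N-X bond between the ring nitrogen and the cap's annotated
#' atom (sulfur for sulfonyl caps, the carbonyl carbon for acyl caps, a
#' carbon for alkyl/aryl caps). The nitrogen must still carry a hydrogen;
#' capping an already-capped compound is an error.
#'
#' @param compound An `ev_compound` row (or a scaffold row for capping
#'   before/without arylation).
#' @param cap A one-row cap registry entry.
#' @return The capped `ev_compound` row with `atom_red` recorded.
#' @export
attach_cap <- function(compound, cap) {
  structure <- compound$structure
  scaffold_id <- if (!is.null(compound$scaffold_id)) compound$scaffold_id
  else compound$id
  fragment_id <- if (!is.null(compound$fragment_id)) compound$fragment_id
  else NA_character_
  if (is_hydrogen_entry(cap)) {
    return(new_compound(structure, scaffold_id, fragment_id, cap$id))
  }
  check_single_attachment(cap$structure, cap$id)
  guest <- smi_set_map(cap$structure, 1, 4)
  s <- tryCatch(
    smi_attach(structure, 2, guest, 4, "%94"),
    error = function(e) {
      stop("cannot cap '", scaffold_id,
           "': the ring nitrogen has no free hydrogen (already capped?)",
           call. = FALSE)
    })
  new_compound(s, scaffold_id, fragment_id, cap$id)
}

check_single_attachment <- function(structure, id) {
  at <- smi_atoms(structure)
  n <- sum(!is.na(at$map) & at$map == 1)
  if (n != 1) {
    stop("substituent '", id, "' must have exactly one attachment ",
         "annotation (map 1), found ", n, call. = FALSE)
  }
}

new_compound <- function(structure, scaffold_id, fragment_id, cap_id) {
  at <- smi_atoms(structure)
  idx_of <- function(m) {
    i <- which(!is.na(at$map) & at$map == m)
    if (length(i) == 1) at$idx[i] else NA_integer_
  }
  ids <- c(scaffold_id, fragment_id, cap_id)
  out <- data.frame(
    product_id = paste(ids[!is.na(ids)], collapse = "."),
    scaffold_id = scaffold_id,
    fragment_id = if (is.null(fragment_id)) NA_character_ else fragment_id,
    cap_id = if (is.null(cap_id)) NA_character_ else cap_id,
    structure = structure,
    atom_c1 = idx_of(1), atom_n2 = idx_of(2),
    atom_blue = idx_of(3), atom_red = idx_of(4),
    stringsAsFactors = FALSE)
  class(out) <- c("ev_compound", "data.frame")
  out
}

#' Enumerate the virtual elaboration library
#'
#' Full Cartesian grid scaffolds x fragments x caps, each product built by
#' [attach_fragment()] then [attach_cap()], deduplicated on the
#' relative-stereochemistry identity key (so symmetric or meso scaffolds
#' cannot produce phantom duplicates), in deterministic order.
#'
#' @param scaffolds An `ev_scaffolds` data.frame.
#' @param fragments,caps Registry data.frames (one attachment annotation
#'   per entry).
#' @return An `ev_compound` data.frame, one row per distinct product, with
#'   provenance columns and the canonical (annotation-free) SMILES in
#'   `canonical` plus the identity `key`.
#' @examples
#' \donttest{
#' lib <- enumerate_library(augment_with_tropane(enumerate_scaffolds()),
#'                          load_registry("fragments"),
#'                          load_registry("caps"))
#' nrow(lib)  # 108 = 27 scaffolds x 1 fragment x 4 caps
#' }
#' @export
enumerate_library <- function(scaffolds, fragments, caps) {
  if (nrow(scaffolds) == 0 || nrow(fragments) == 0 || nrow(caps) == 0) {
    out <- new_compound("[H][H]", "x", NA, NA)[0, ]
    out$canonical <- character(0); out$key <- character(0)
    return(out)
  }
  rows <- list()
  for (i in seq_len(nrow(scaffolds))) {
    for (j in seq_len(nrow(fragments))) {
      core <- attach_fragment(scaffolds[i, ], fragments[j, ])
      for (k in seq_len(nrow(caps))) {
        rows[[length(rows) + 1]] <- attach_cap(core, caps[k, ])
      }
    }
  }
  lib <- do.call(rbind, rows)
  lib$canonical <- ob_canonical(smi_strip_maps(lib$structure))
  lib$key <- ob_relative_key(smi_strip_maps(lib$structure))
  lib <- lib[!duplicated(lib$key), , drop = FALSE]
  lib <- lib[order(lib$scaffold_id, lib$fragment_id, lib$cap_id), ,
             drop = FALSE]
  rownames(lib) <- NULL
  class(lib) <- c("ev_compound", "data.frame")
  lib
}

#' Write an elaborated library to disk
#'
#' @param library An `ev_compound` data.frame.
#' @param smi_path,csv_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the input.
#' @export
write_library <- function(library, smi_path = NULL, csv_path = NULL) {
  if (!is.null(smi_path)) {
    writeLines(paste(library$structure, library$product_id), smi_path)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(library), csv_path, row.names = FALSE)
  }
  invisible(library)
}
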