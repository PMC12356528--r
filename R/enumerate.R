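# Brute-force enumeration of bifunctional cyclopropane-amine scaffolds.
#
# The enumeration universe: a saturated cyclic amine (azetidine, pyrrolidine
# or piperidine) carrying a cyclopropane that is either fused across one of
# the ring's C-C bonds or spiro-linked at one of its ring carbons. The two
# variation points are C1 (a substitutable cyclopropane carbon, atom map 1)
# and N2 (the ring nitrogen, atom map 2). Raw placements - every edge, every
# spiro atom, every substitutable cyclopropane carbon, every realizable
# relative configuration - are generated as annotated SMILES and then
# deduplicated on a relative-stereochemistry InChI key of a brominated probe
# form, which keeps diastereomers distinct while collapsing enantiomeric
# pairs (scaffolds are treated as racemic or meso).
#
# Stereochemical conventions (validated geometrically in the test-suite):
#   - ring fusion is cis: a cyclopropane trans-fused to a 4-6-membered ring
#     is prohibitively strained and is excluded from the universe;
#   - a substituent replacing a ring-junction hydrogen inherits the single
#     orientation the cis fusion allows (no stereo choice at junctions);
#   - a substituent on the cyclopropane apex of a fused system is enumerated
#     exo (on the convex face, anti to the amine ring) by default; the endo
#     placement points over the amine ring and is excluded unless
#     apex_stereo = "both" is requested;
#   - both relative orientations of a substituent on a spiro cyclopropane
#     methylene (syn or anti to the ring nitrogen) are enumerated whenever
#     the spiro pattern makes them distinct diastereomers.

# Written-parity constants for the SMILES templates below. Junction parities
# encode the cis fusion; apex/spiro parities select the labelled face. They
# are tied to the exact neighbour ordering of the templates and are verified
# against 3D geometry in the tests.
.P_J1 <- "@"           # non-handle first junction, [C@H]2
.P_J2 <- "@"           # non-handle second junction, [C@H]
.P_J1_HANDLE <- "@@"   # explicit-H form of the first junction
.P_J2_HANDLE <- "@"    # explicit-H form of the second junction
.P_APEX_EXO <- "@@"    # apex parity placing the replaceable hydrogen exo
.P_SPIRO_ANTI <- c(spiro = "@", handle = "@")  # handle anti to the nitrogen

#' @keywords internal
fused_smiles <- function(ring_size, locant, handle = c("none", "j1", "j2", "apex"),
                         apex_parity = .P_APEX_EXO) {
  handle <- match.arg(handle)
  n <- ring_size; i <- locant
  stopifnot(i >= 2, i + 1 < n + 1, i + 1 <= n - 0)
  if (i + 1 >= n) stop("terminal fusion edges must be passed as their ",
                       "mirror-equivalent low-locant form", call. = FALSE)
  j1 <- if (handle == "j1") paste0("[C", .P_J1_HANDLE, ":1]2([H])")
  else paste0("[C", .P_J1, "H]2")
  j2 <- if (handle == "j2") paste0("[C", .P_J2_HANDLE, ":1]([H])")
  else paste0("[C", .P_J2, "H]")
  apex <- if (handle == "apex") paste0("([C", apex_parity, ":1]2([H])[H])")
  else "(C2)"
  paste0("[NH:2]1", strrep("C", i - 2), j1, j2, apex,
         strrep("C", n - i - 2), "C1")
}

#' @keywords internal
spiro_smiles <- function(ring_size, locant,
                         spiro_parity = "@", handle_parity = "@") {
  n <- ring_size; p <- locant
  stopifnot(p >= 2, p <= n)
  if (p == n) p <- 2  # mirror-equivalent low-locant form
  paste0("[NH:2]1", strrep("C", p - 2),
         "[C", spiro_parity, "]2([C", handle_parity, ":1]([H])([H])C2)",
         strrep("C", n - p - 1), "C1")
}

# The tropane augmentation: 8-azabicyclo[3.2.1]octane (a piperidine carrying
# a two-carbon ethano bridge) with a cyclopropane spiro-linked at the carbon
# para to nitrogen. The boron-handle carbon sits anti to the ethano bridge
# (the face the carbene adds to) with its substituent exo. The written
# parities are fixed by a geometric calibration mirrored in the tests.
TROPANE_SMILES <- "[NH:2]1[C@@H]2C[C@]3([C@@:1]([H])([H])C3)C[C@H]1CC2"

#' Enumerate bifunctional cyclopropane-amine scaffolds
#'
#' Generates every symmetry-distinct scaffold that combines a saturated
#' cyclic amine (ring sizes 4-6) with a fused or spirocyclic cyclopropane
#' bearing a substitutable handle carbon, under the package's documented
#' stereochemical conventions. Raw placements are deduplicated on a
#' relative-stereochemistry identity key, so enantiomeric pairs collapse to
#' one representative while diastereomers stay distinct.
#'
#' @param ring_sizes Integer vector, subset of `c(4, 5, 6)`: heavy-atom size
#'   of the amine ring (azetidine, pyrrolidine, piperidine).
#' @param topologies Character vector, subset of `c("fused", "spiro")`.
#' @param include_diastereomers Logical. If `TRUE` (default) every distinct
#'   relative configuration allowed by the conventions is kept; if `FALSE`,
#'   one representative per constitution (placement) is kept.
#' @param apex_stereo Placement convention for substituents on the
#'   cyclopropane apex of fused systems: `"exo"` (default, convex face only)
#'   or `"both"` (also enumerate the endo face).
#' @return A data.frame of class `ev_scaffolds` with one row per scaffold:
#'   `id`, `ring_size`, `topology`, `locants`, `handle_position`, `stereo`,
#'   `structure` (annotated SMILES, C1 = map 1, N2 = map 2), `key`
#'   (relative-stereo identity of the brominated probe form) and `racemic`.
#'   Rows are sorted deterministically by ring size, topology, locants,
#'   handle and key.
#' @examples
#' \donttest{
#' sc <- enumerate_scaffolds()
#' nrow(sc)  # 26 under the default conventions
#' table(sc$ring_size, sc$topology)
#' }
#' @export
enumerate_scaffolds <- function(ring_sizes = c(4, 5, 6),
                                topologies = c("fused", "spiro"),
                                include_diastereomers = TRUE,
                                apex_stereo = c("exo", "both")) {
  apex_stereo <- match.arg(apex_stereo)
  if (length(ring_sizes) > 0 && !all(ring_sizes %in% 4:6)) {
    stop("ring_sizes must be a subset of {4, 5, 6}", call. = FALSE)
  }
  if (length(topologies) > 0 &&
      !all(topologies %in% c("fused", "spiro"))) {
    stop("topologies must be a subset of {fused, spiro}", call. = FALSE)
  }
  cand <- list()
  push <- function(...) cand[[length(cand) + 1]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  for (n in sort(unique(as.integer(ring_sizes)))) {
    if ("fused" %in% topologies) {
      for (i in 2:(n - 1)) {                       # every C-C edge (i, i+1)
        ic <- min(i, n + 1 - i)                    # low-locant reading
        handles <- c("j1", "j2", "apex")
        for (h in handles) {
          aps <- if (h == "apex") {
            if (apex_stereo == "both") c(exo = .P_APEX_EXO,
                                         endo = flip_parity(.P_APEX_EXO))
            else c(exo = .P_APEX_EXO)
          } else c(none = .P_APEX_EXO)
          for (k in seq_along(aps)) {
            smi <- fused_smiles(n, ic, h, aps[[k]])
            push(ring_size = n, topology = "fused",
                 locants = paste0(ic, ",", ic + 1),
                 handle_position = c(j1 = "junction", j2 = "junction",
                                     apex = "apex")[[h]],
                 handle_locant = c(j1 = ic, j2 = ic + 1, apex = 0)[[h]],
                 stereo = if (h == "apex") names(aps)[k] else "cis-junction",
                 structure = smi)
          }
        }
      }
    }
    if ("spiro" %in% topologies) {
      for (p in 2:n) {                             # every ring carbon
        for (ps in c("@", "@@")) for (ph in c("@", "@@")) {
          smi <- spiro_smiles(n, p, ps, ph)
          push(ring_size = n, topology = "spiro",
               locants = as.character(min(p, n + 2 - p)),
               handle_position = "cyclopropane-methylene",
               handle_locant = 0,
               stereo = spiro_stereo_label(ps, ph),
               structure = smi)
        }
      }
    }
  }
  if (length(cand) == 0) return(empty_scaffolds())
  cand <- do.call(rbind, cand)
  cand$key <- scaffold_key(cand$structure)
  cand <- cand[!duplicated(cand$key), , drop = FALSE]
  # spiro cells whose two faces are equivalent collapse to one scaffold;
  # a syn/anti label is meaningless there
  constitution <- paste(cand$ring_size, cand$topology, cand$locants,
                        cand$handle_position, cand$handle_locant)
  singleton <- constitution %in% names(which(table(constitution) == 1))
  cand$stereo[singleton & cand$topology == "spiro"] <- "equiv-faces"
  if (!include_diastereomers) {
    constitution <- paste(cand$ring_size, cand$topology, cand$locants,
                          cand$handle_position, cand$handle_locant)
    cand <- cand[!duplicated(constitution), , drop = FALSE]
  }
  ord <- order(cand$ring_size, cand$topology, cand$locants,
               cand$handle_position, cand$handle_locant, cand$stereo)
  cand <- cand[ord, , drop = FALSE]
  cand$id <- scaffold_ids(cand)
  cand$racemic <- is_racemic_key(cand$structure)
  rownames(cand) <- NULL
  out <- cand[, c("id", "ring_size", "topology", "locants",
                  "handle_position", "stereo", "structure", "key",
                  "racemic")]
  class(out) <- c("ev_scaffolds", "data.frame")
  out
}

flip_parity <- function(p) if (identical(p, "@")) "@@" else "@"

# Relative-configuration label for the spiro templates. Whether a written
# parity pair places the handle substituent syn or anti to the nitrogen was
# calibrated once against 3D geometry; same-parity pairs put the handle
# substituent on the nitrogen side.
spiro_stereo_label <- function(spiro_parity, handle_parity) {
  if (identical(spiro_parity, handle_parity)) "syn-N" else "anti-N"
}

# Identity key of a scaffold: relative-stereo InChI of the structure with a
# bromine probe bonded at C1 (the probe makes the handle orientation part of
# the key even though the stored scaffold is hydrogen-capped there).
scaffold_key <- function(structures) {
  probes <- vapply(structures, function(s) {
    smi_attach(s, 1, "[BrH:9]", 9)
  }, character(1))
  ob_relative_key(smi_strip_maps(probes))
}

# A scaffold is racemic when its probe form is chiral, i.e. when the probe
# InChI of the structure differs from that of its mirror image.
is_racemic_key <- function(structures) {
  probes <- vapply(structures, function(s) smi_attach(s, 1, "[BrH:9]", 9),
                   character(1))
  a <- ob_inchi(smi_strip_maps(probes))
  b <- ob_inchi(smi_strip_maps(vapply(probes, smi_mirror, character(1))))
  a != b
}

scaffold_ids <- function(df) {
  base <- sprintf("%s-%d-c%s-%s", substr(df$topology, 1, 2), df$ring_size,
                  gsub(",", "", df$locants),
                  ifelse(df$handle_position == "junction",
                         paste0("j", df$handle_locant),
                         substr(df$handle_position, 1, 2)))
  suff <- ifelse(df$stereo %in% c("cis-junction", "none", "equiv-faces"), "",
                 paste0("-", sub("-N$", "", df$stereo)))
  paste0(base, suff)
}

empty_scaffolds <- function() {
  out <- data.frame(id = character(), ring_size = integer(),
                    topology = character(), locants = character(),
                    handle_position = character(), stereo = character(),
                    structure = character(), key = character(),
                    racemic = logical(), stringsAsFactors = FALSE)
  class(out) <- c("ev_scaffolds", "data.frame")
  out
}

#' Append the tropane scaffold to an enumerated set
#'
#' The tropane building block (a cyclopropane spiro-linked to
#' 8-azabicyclo[3.2.1]octane) sits outside the azetidine/pyrrolidine/
#' piperidine enumeration universe but is synthetically accessible and is
#' carried as a fixed augmentation. Idempotent: if the tropane scaffold is
#' already present it is not added again.
#'
#' @param scaffolds An `ev_scaffolds` data.frame (may be empty).
#' @return The input with the tropane scaffold appended (and deduplicated).
#' @export
augment_with_tropane <- function(scaffolds = empty_scaffolds()) {
  trop <- data.frame(
    id = "tropane-c3-cy", ring_size = 6L, topology = "tropane_spiro",
    locants = "3", handle_position = "cyclopropane-methylene",
    stereo = "anti-bridge-exo", structure = TROPANE_SMILES,
    key = scaffold_key(TROPANE_SMILES), racemic = is_racemic_key(TROPANE_SMILES),
    stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(scaffolds), trop)
  out <- out[!duplicated(out$key), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ev_scaffolds", "data.frame")
  out
}

#' Per-cell enumeration counts
#'
#' Cross-tabulates an enumerated scaffold set by ring size and topology -
#' the reconciliation table used to localize any disagreement between the
#' enumeration conventions and an external count.
#'
#' @param scaffolds An `ev_scaffolds` data.frame.
#' @return A data.frame with columns `ring_size`, `topology`, `n`.
#' @export
enumeration_cells <- function(scaffolds) {
  tab <- as.data.frame(table(ring_size = scaffolds$ring_size,
                             topology = scaffolds$topology),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab <- tab[tab$n > 0, , drop = FALSE]
  tab$ring_size <- as.integer(tab$ring_size)
  rownames(tab) <- NULL
  tab[order(tab$ring_size, tab$topology), ]
}

#' Match packaged building blocks to enumerated scaffolds
#'
#' Maps each building-block registry entry onto the enumerated scaffold with
#' the same relative-stereochemistry identity, and flags the scaffolds left
#' unmatched as virtual-only.
#'
#' @param scaffolds An `ev_scaffolds` data.frame.
#' @param registry A registry data.frame (see [load_registry()]) whose
#'   entries have role `"building_block"`.
#' @return A list with `matches` (data.frame: `block_id`, `scaffold_id`,
#'   `key`) and `virtual_only` (character vector of unmatched scaffold ids).
#' @export
match_named_blocks <- function(scaffolds, registry) {
  if (nrow(registry) == 0) {
    return(list(matches = data.frame(block_id = character(),
                                     scaffold_id = character(),
                                     key = character(),
                                     stringsAsFactors = FALSE),
                virtual_only = scaffolds$id))
  }
  keys <- scaffold_key(registry$structure)
  hit <- match(keys, scaffolds$key)
  if (anyNA(hit)) {
    stop("building block(s) with no enumerated counterpart: ",
         paste(registry$id[is.na(hit)], collapse = ", "),
         " - this signals an enumeration convention mismatch", call. = FALSE)
  }
  matches <- data.frame(block_id = registry$id,
                        scaffold_id = scaffolds$id[hit],
                        key = keys, stringsAsFactors = FALSE)
  if (anyDuplicated(matches$scaffold_id)) {
    dup <- matches$scaffold_id[duplicated(matches$scaffold_id)]
    stop("multiple registry entries map to the same scaffold: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  list(matches = matches,
       virtual_only = setdiff(scaffolds$id, matches$scaffold_id))
}

#' Write an enumerated scaffold set to disk
#'
#' Writes the annotated SMILES (one per line, id in the title field) and a
#' CSV with the scaffold descriptors.
#'
#' @param scaffolds An `ev_scaffolds` data.frame.
#' @param smi_path,csv_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the input.
#' @export
write_scaffolds <- function(scaffolds, smi_path = NULL, csv_path = NULL) {
  if (!is.null(smi_path)) {
    writeLines(paste(scaffolds$structure, scaffolds$id), smi_path)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(scaffolds), csv_path, row.names = FALSE)
  }
  invisible(scaffolds)
}
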