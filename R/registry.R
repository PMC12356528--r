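# Packaged structure registries and the randomized fixture generator.
#
# Registries are plain tab-separated files with columns id / role /
# structure / racemic / notes. Structures are annotated SMILES: building
# blocks carry two attachment annotations (atom map 1 = C1 handle, atom map
# 2 = N2 handle); fragments and caps carry a single annotation (atom map 1
# on the atom that forms the new bond). A replaceable hydrogen on a
# stereo-annotated attachment atom is written as an explicit ([H]) branch so
# that substitution is stereo-safe (see smiles.R).

REGISTRY_NAMES <- c("building_blocks", "fragments", "caps", "fraglite_aryls")

#' Load a packaged (or user-supplied) structure registry
#'
#' @param name One of `"building_blocks"` (the nine bifunctional
#'   cyclopropane building blocks), `"fragments"` (elaboration fragments;
#'   the default pyrimidin-5-yl), `"caps"` (the four N-capping groups:
#'   methanesulfonyl, acetyl, methyl, phenyl) or `"fraglite_aryls"`
#'   (aryl-bromide-derived fragments in the style of the FragLite screening
#'   set). Alternatively the path to a user registry file in the same
#'   tab-separated format.
#' @return A data.frame with columns `id`, `role`, `structure`, `racemic`,
#'   `notes`, validated (parseable structures, unique ids, correct number of
#'   attachment annotations per role).
#' @examples
#' \donttest{
#' blocks <- load_registry("building_blocks")
#' nrow(blocks)  # 9
#' }
#' @export
load_registry <- function(name) {
  path <- if (file.exists(name)) name
  else {
    if (!name %in% REGISTRY_NAMES) {
      stop("unknown registry '", name, "'; valid names are: ",
           paste(REGISTRY_NAMES, collapse = ", "),
           " (or the path to a registry file)", call. = FALSE)
    }
    system.file("extdata", paste0(name, ".tsv"), package = "exitvector",
                mustWork = TRUE)
  }
  reg <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("id", "role", "structure")
  if (!all(required %in% names(reg))) {
    stop("registry file must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (!"racemic" %in% names(reg)) reg$racemic <- NA
  if (!"notes" %in% names(reg)) reg$notes <- ""
  reg$racemic <- as.logical(reg$racemic)
  validate_registry(reg)
  reg[, c("id", "role", "structure", "racemic", "notes")]
}

validate_registry <- function(reg) {
  if (anyDuplicated(reg$id)) {
    stop("duplicate registry ids: ",
         paste(unique(reg$id[duplicated(reg$id)]), collapse = ", "),
         call. = FALSE)
  }
  for (k in seq_len(nrow(reg))) {
    at <- smi_atoms(reg$structure[k])
    maps <- at$map[!is.na(at$map)]
    want <- switch(reg$role[k],
                   building_block = c(1L, 2L),
                   fragment = 1L,
                   cap = 1L,
                   fixture = integer())
    if (is.null(want)) next
    if (!identical(sort(maps), sort(want))) {
      stop("registry entry '", reg$id[k], "' (", reg$role[k],
           ") must annotate attachment atom(s) with map(s) ",
           paste(want, collapse = ","), call. = FALSE)
    }
  }
  # every structure must survive a parse
  invisible(ob_canonical(smi_strip_maps(reg$structure)))
}

#' The hydrogen placeholder entry
#'
#' A pseudo-entry usable wherever a fragment or cap is expected; attaching
#' it is a no-op (the attachment point keeps its hydrogen). Useful for
#' elaborating only one of the two variation points.
#'
#' @return A one-row registry data.frame with id `"hydrogen"`.
#' @export
hydrogen_placeholder <- function() {
  data.frame(id = "hydrogen", role = "placeholder", structure = "[H][H]",
             racemic = FALSE, notes = "identity substituent",
             stringsAsFactors = FALSE)
}

is_hydrogen_entry <- function(entry) {
  identical(entry$id, "hydrogen") || identical(entry$structure, "[H][H]")
}

# Substituent alphabet for randomized fixtures (attachment annotated with
# map 9; all attach by displacing one hydrogen).
FIXTURE_GROUPS <- c(methyl = "[CH4:9]", fluoro = "[FH:9]",
                    amino = "[NH3:9]", methoxy = "C[OH:9]",
                    cyano = "[CH:9]#N", phenyl = "[cH:9]1ccccc1",
                    hydroxymethyl = "O[CH3:9]")

#' Generate randomized decorated-scaffold fixtures
#'
#' Draws random enumerated scaffolds and decorates their two variation
#' points with random small substituents, producing chemically valid
#' structures for stress-testing downstream modules. Byte-identical output
#' for a fixed seed.
#'
#' @param n_random Number of fixtures to generate (may be 0).
#' @param seed Integer seed.
#' @param ring_sizes Subset of `c(4, 5, 6)` passed to
#'   [enumerate_scaffolds()].
#' @return A registry-style data.frame with role `"fixture"` whose
#'   structures are fully decorated (no attachment annotations remain).
#' @export
generate_fixtures <- function(n_random, seed = 1L, ring_sizes = c(4, 5, 6)) {
  stopifnot(n_random >= 0)
  if (n_random == 0) {
    return(data.frame(id = character(), role = character(),
                      structure = character(), racemic = logical(),
                      notes = character(), stringsAsFactors = FALSE))
  }
  sc <- enumerate_scaffolds(ring_sizes = ring_sizes)
  if (nrow(sc) == 0) stop("no scaffolds available for the requested rings",
                          call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(n_random), function(k) {
    i <- sample.int(nrow(sc), 1)
    g1 <- sample(names(FIXTURE_GROUPS), 1)
    g2 <- sample(names(FIXTURE_GROUPS), 1)
    s <- smi_attach(sc$structure[i], 1, FIXTURE_GROUPS[[g1]], 9, "%93")
    s <- smi_attach(s, 2, FIXTURE_GROUPS[[g2]], 9, "%94")
    data.frame(id = sprintf("fx%03d", k), role = "fixture",
               structure = smi_strip_maps(s), racemic = NA,
               notes = sprintf("%s + %s at C1 / %s at N2",
                               sc$id[i], g1, g2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
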