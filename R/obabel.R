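# Thin wrappers around the OpenBabel command-line tools (obabel, obenergy).
# All conversions run in batch: one subprocess per call, molecules aligned by
# their title line. Every wrapper checks that no molecule was silently dropped.

ob_available <- function() {
  nzchar(Sys.which("obabel"))
}

assert_obabel <- function() {
  if (!ob_available()) {
    stop("OpenBabel ('obabel') was not found on the PATH; ",
         "it is required for structure handling.", call. = FALSE)
  }
}

ob_run <- function(args, ok_status = 0L) {
  assert_obabel()
  out <- suppressWarnings(system2("obabel", args, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != ok_status) {
    stop("obabel failed (status ", status, "): ",
         paste(utils::tail(out, 5), collapse = "; "), call. = FALSE)
  }
  out
}

# Convert SMILES to another line format; returns a character vector aligned
# with `smiles`. `to` is an output format known to OpenBabel ("can", "inchi",
# "smi"). Stereo warnings from the InChI library go to stderr and are dropped.
ob_line_convert <- function(smiles, to = "can", extra = character()) {
  if (length(smiles) == 0) return(character())
  ids <- sprintf("m%06d", seq_along(smiles))
  inp <- tempfile(fileext = ".smi")
  on.exit(unlink(inp), add = TRUE)
  writeLines(paste(smiles, ids), inp)
  args <- c(inp, paste0("-o", to), if (to == "inchi") "-xt", extra)
  out <- ob_run(args)
  keep <- grepl(if (to == "inchi") "^InChI=" else "\\S", out) &
    !grepl("molecules converted|Open Babel|^==|^\\*\\*\\*|^ ", out)
  out <- out[keep]
  # align on the embedded id token (robust to --append fields after it)
  res <- rep(NA_character_, length(smiles))
  for (line in out) {
    parts <- strsplit(trimws(line), "[ \t]+")[[1]]
    hit <- grep("^m[0-9]{6}$", parts)
    if (length(hit) == 0) next
    j <- match(parts[hit[1]], ids)
    if (!is.na(j)) res[j] <- paste(parts[-hit[1]], collapse = " ")
  }
  if (anyNA(res)) {
    bad <- which(is.na(res))
    stop("obabel could not convert structure(s): ",
         paste(smiles[bad], collapse = ", "), call. = FALSE)
  }
  res
}

ob_canonical <- function(smiles) ob_line_convert(smiles, "can")

ob_inchi <- function(smiles) ob_line_convert(smiles, "inchi")

# Identity key that keeps relative stereochemistry (diastereomers distinct)
# but collapses enantiomeric pairs: the InChI with its /m and /s layers
# (absolute parity) removed.
ob_relative_key <- function(smiles) {
  gsub("/[ms][0-9]+", "", ob_inchi(smiles))
}

# Molecular formula and OpenBabel's atom-contribution descriptors.
ob_descriptors <- function(smiles, descriptors = c("MW", "logP")) {
  if (length(smiles) == 0) {
    out <- as.data.frame(matrix(numeric(), 0, length(descriptors)))
    names(out) <- descriptors
    return(out)
  }
  txt <- ob_line_convert(smiles, "smi",
                         extra = c("--append", paste(descriptors, collapse = " ")))
  vals <- lapply(strsplit(txt, "[ \t]+"), function(p) {
    utils::tail(p, length(descriptors))
  })
  out <- as.data.frame(do.call(rbind, lapply(vals, as.numeric)))
  names(out) <- descriptors
  out
}

# 3D embedding: one call, multi-molecule. Returns the path to an SDF whose
# records appear in input order (OpenBabel preserves SMILES atom order:
# explicit atoms first, implicit hydrogens appended).
ob_gen3d <- function(smiles, out = tempfile(fileext = ".sdf")) {
  if (length(smiles) == 0) stop("no structures to embed", call. = FALSE)
  ids <- sprintf("m%06d", seq_along(smiles))
  inp <- tempfile(fileext = ".smi")
  on.exit(unlink(inp), add = TRUE)
  writeLines(paste(smiles, ids), inp)
  log <- ob_run(c(inp, "-O", out, "--gen3d"))
  n <- ob_count_records(out)
  if (n != length(smiles)) {
    got <- ob_sdf_titles(out)
    bad <- ids[!ids %in% got]
    stop("3D embedding failed for structure(s): ",
         paste(smiles[match(bad, ids)], collapse = ", "), call. = FALSE)
  }
  out
}

ob_count_records <- function(sdf) sum(readLines(sdf) == "$$$$")

ob_sdf_titles <- function(sdf) {
  lines <- readLines(sdf)
  ends <- which(lines == "$$$$")
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lines[starts]
}

# Torsion-driving conformer search (deterministic systematic rotor walk),
# writing every generated conformer as an SDF record.
ob_conformers <- function(sdf_in, nconf = 200,
                          out = tempfile(fileext = ".sdf")) {
  ob_run(c(sdf_in, "-O", out, "--conformer", "--systematic",
           "--nconf", as.character(nconf), "--writeconformers"))
  if (ob_count_records(out) < 1) {
    stop("conformer search produced no conformers", call. = FALSE)
  }
  out
}

# Per-record force-field minimization.
ob_minimize <- function(sdf_in, forcefield = "MMFF94", steps = 500,
                        out = tempfile(fileext = ".sdf")) {
  ob_run(c(sdf_in, "-O", out, "--minimize",
           "--ff", forcefield, "--steps", as.character(steps)))
  if (ob_count_records(out) != ob_count_records(sdf_in)) {
    stop("minimization dropped records", call. = FALSE)
  }
  out
}

# Force-field energies, one value per SDF record, in kcal/mol.
# (obenergy reports MMFF94 in kcal/mol and UFF/GAFF in kJ/mol.)
ob_energies <- function(sdf_in, forcefield = "MMFF94") {
  assert_obabel()
  out <- suppressWarnings(
    system2("obenergy", c("-ff", forcefield, sdf_in),
            stdout = TRUE, stderr = FALSE))
  lines <- grep("TOTAL ENERGY", out, value = TRUE)
  if (length(lines) != ob_count_records(sdf_in)) {
    stop("force field '", forcefield, "' could not score every conformer",
         call. = FALSE)
  }
  vals <- as.numeric(sub(".*=\\s*([-0-9.eE+]+)\\s*k.*", "\\1", lines))
  if (any(grepl("kJ/mol", lines))) vals <- vals / 4.184
  vals
}
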