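# End-to-end orchestration: enumerate -> elaborate -> conformers ->
# exit vectors -> property profile, with a JSON run manifest.

#' Assemble a pipeline configuration
#'
#' @param ring_sizes,topologies,include_diastereomers,apex_stereo Passed to
#'   [enumerate_scaffolds()].
#' @param add_tropane Append the tropane augmentation (default `TRUE`).
#' @param scaffold_registry Optional: restrict the run to the packaged
#'   building blocks by naming a registry (e.g. `"building_blocks"`) or a
#'   registry file path; `NULL` (default) enumerates the full theoretical
#'   set.
#' @param fragments,caps Registry names or file paths for the elaboration
#'   inputs.
#' @param n_confs,seed,forcefield Conformer settings, see
#'   [embed_and_minimize()].
#' @param theta_fold `"180"` (default) or `"90"`.
#' @param outdir Output directory (created if missing).
#' @return A list of class `ev_config`.
#' @export
ev_config <- function(ring_sizes = c(4, 5, 6),
                      topologies = c("fused", "spiro"),
                      include_diastereomers = TRUE,
                      apex_stereo = "exo",
                      add_tropane = TRUE,
                      scaffold_registry = NULL,
                      fragments = "fragments",
                      caps = "caps",
                      n_confs = 200, seed = 42, forcefield = "MMFF94",
                      theta_fold = "180",
                      outdir = "exitvector-run") {
  cfg <- list(ring_sizes = as.integer(ring_sizes), topologies = topologies,
              include_diastereomers = include_diastereomers,
              apex_stereo = apex_stereo, add_tropane = add_tropane,
              scaffold_registry = scaffold_registry,
              fragments = fragments, caps = caps,
              n_confs = as.integer(n_confs), seed = as.integer(seed),
              forcefield = forcefield, theta_fold = theta_fold,
              outdir = outdir)
  class(cfg) <- "ev_config"
  cfg
}

#' Read/write a pipeline configuration as YAML
#'
#' Round-trips losslessly through the file format.
#'
#' @param path YAML file path.
#' @return For `read_ev_config`, an `ev_config`; for `write_ev_config`,
#'   invisibly `path`.
#' @export
read_ev_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configurations requires the 'yaml' package",
         call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  do.call(ev_config, raw)
}

#' @rdname read_ev_config
#' @param cfg An `ev_config`.
#' @export
write_ev_config <- function(cfg, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("writing YAML configurations requires the 'yaml' package",
         call. = FALSE)
  }
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full design pipeline
#'
#' Executes enumeration (or loads a scaffold registry), tropane
#' augmentation, virtual elaboration, conformer generation, exit-vector
#' measurement and property profiling, writing all tables plus a JSON
#' manifest into `cfg$outdir`. Any stage failure aborts with the stage
#' name and the offending compound ids.
#'
#' @param cfg An [ev_config()].
#' @param quiet Suppress per-stage progress messages (stderr).
#' @return Invisibly, a list with `scaffolds`, `library`, `vectors`,
#'   `properties`, `manifest`.
#' @export
run_pipeline <- function(cfg = ev_config(), quiet = FALSE) {
  t_start <- Sys.time()
  say <- function(...) if (!quiet) message("[exitvector] ", ...)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  stage <- "enumerate"
  scaffolds <- with_stage(stage, {
    if (!is.null(cfg$scaffold_registry)) {
      reg <- load_registry(cfg$scaffold_registry)
      full <- augment_with_tropane(
        enumerate_scaffolds(cfg$ring_sizes, cfg$topologies,
                            cfg$include_diastereomers, cfg$apex_stereo))
      m <- match_named_blocks(full, reg)
      sc <- full[match(m$matches$scaffold_id, full$id), , drop = FALSE]
      sc$id <- m$matches$block_id  # keep the registry labels
      sc
    } else {
      sc <- enumerate_scaffolds(cfg$ring_sizes, cfg$topologies,
                                cfg$include_diastereomers, cfg$apex_stereo)
      if (cfg$add_tropane) sc <- augment_with_tropane(sc)
      sc
    }
  })
  say(stage, ": ", nrow(scaffolds), " scaffolds")
  write_scaffolds(scaffolds,
                  smi_path = file.path(cfg$outdir, "scaffolds.smi"),
                  csv_path = file.path(cfg$outdir, "scaffolds.csv"))

  stage <- "elaborate"
  fragments <- load_registry(cfg$fragments)
  caps <- load_registry(cfg$caps)
  library <- with_stage(stage, enumerate_library(scaffolds, fragments, caps))
  if (nrow(library) == 0) {
    stop("stage 'elaborate' produced an empty library (empty fragment or ",
         "cap registry?)", call. = FALSE)
  }
  say(stage, ": ", nrow(library), " products")
  write_library(library,
                smi_path = file.path(cfg$outdir, "library.smi"),
                csv_path = file.path(cfg$outdir, "library.csv"))

  stage <- "conformers"
  ensembles <- list()
  sdf_path <- file.path(cfg$outdir, "conformers.sdf")
  if (file.exists(sdf_path)) unlink(sdf_path)
  for (i in seq_len(nrow(library))) {
    id <- library$product_id[i]
    ens <- with_stage(paste0(stage, " (", id, ")"),
                      embed_and_minimize(library[i, ], cfg$n_confs,
                                         cfg$seed, cfg$forcefield))
    ensembles[[id]] <- ens
    append_lowest_conformer(ens, sdf_path)
  }
  say(stage, ": ", length(ensembles), " ensembles")

  stage <- "vectors"
  vectors <- with_stage(stage,
                        vectors_for_library(library, ensembles,
                                            fold = cfg$theta_fold))
  write_vectors(vectors, file.path(cfg$outdir, "exit_vectors.csv"))
  say(stage, ": r in [", round(min(vectors$r_angstrom), 2), ", ",
      round(max(vectors$r_angstrom), 2), "] Angstrom")

  stage <- "profile"
  properties <- with_stage(stage, profile_properties(library))
  utils::write.csv(properties, file.path(cfg$outdir, "properties.csv"),
                   row.names = FALSE)
  say(stage, ": ", sum(properties$leadlike_pass), "/", nrow(properties),
      " lead-like")

  manifest <- list(
    package = "exitvector",
    version = as.character(utils::packageVersion("exitvector")),
    seed = cfg$seed, config = unclass(cfg),
    counts = list(scaffolds = nrow(scaffolds),
                  enumerated = sum(scaffolds$topology != "tropane_spiro"),
                  library = nrow(library),
                  vector_records = nrow(vectors)),
    r_range_angstrom = c(min(vectors$r_angstrom), max(vectors$r_angstrom)),
    theta_range_degrees = c(min(vectors$theta_degrees),
                            max(vectors$theta_degrees)),
    wall_time_s = as.numeric(Sys.time() - t_start, units = "secs"))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(scaffolds = scaffolds, library = library,
                 vectors = vectors, properties = properties,
                 manifest = manifest))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

append_lowest_conformer <- function(ens, path) {
  tmp <- tempfile(fileext = ".sdf")
  low <- ens
  low$coordinates <- ens$coordinates[ens$lowest_index]
  low$energies <- ens$energies[ens$lowest_index]
  low$lowest_index <- 1L
  write_ensemble_sdf(low, tmp)
  cat(readLines(tmp), file = path, sep = "\n", append = TRUE)
  unlink(tmp)
}
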