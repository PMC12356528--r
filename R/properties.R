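# Physicochemical profiling and the two design filters.
#
# Descriptors are computed on the neutral parent structure: molecular
# weight from standard average atomic weights, clogP by OpenBabel's
# atom-contribution (Crippen-type) estimator, and Fsp3 as the fraction of
# carbons with only single bonds. Filter semantics follow the printed
# inequalities: the Rule-of-Two for building-block scaffolds is strict
# (MW < 200 and clogP < 2); lead-like space uses inclusive mass bounds and
# strict lipophilicity bounds (200 <= MW <= 350 and -1 < clogP < 3).

#' Profile molecular properties and design-filter outcomes
#'
#' @param structures Character vector of SMILES (attachment annotations are
#'   ignored), or a data.frame with a `structure` column and an id column
#'   (`product_id` or `id`).
#' @param ids Optional labels (default: the structures themselves).
#' @return A data.frame with `compound_id`, `mw` (Da), `clogp`, `fsp3`,
#'   `rule_of_two_pass`, `leadlike_pass`.
#' @examples
#' \donttest{
#' profile_properties("c1ccccc1", "benzene")  # fsp3 = 0
#' }
#' @export
profile_properties <- function(structures, ids = NULL) {
  if (is.data.frame(structures)) {
    if (is.null(ids)) {
      ids <- if ("product_id" %in% names(structures)) structures$product_id
      else structures$id
    }
    structures <- structures$structure
  }
  if (is.null(ids)) ids <- structures
  if (length(structures) == 0) {
    return(data.frame(compound_id = character(), mw = numeric(),
                      clogp = numeric(), fsp3 = numeric(),
                      rule_of_two_pass = logical(),
                      leadlike_pass = logical(), stringsAsFactors = FALSE))
  }
  smi <- smi_strip_maps(structures)
  desc <- ob_descriptors(smi, c("MW", "logP"))
  fsp3 <- fsp3_fraction(smi)
  out <- data.frame(compound_id = ids, mw = desc$MW, clogp = desc$logP,
                    fsp3 = fsp3, stringsAsFactors = FALSE)
  out$rule_of_two_pass <- out$mw < 200 & out$clogp < 2
  out$leadlike_pass <- out$clogp > -1 & out$clogp < 3 &
    out$mw >= 200 & out$mw <= 350
  out
}

# Fraction of sp3 carbons: carbons engaged only in single bonds, over all
# carbons, computed from the kekulized connection table.
fsp3_fraction <- function(smiles) {
  inp <- tempfile(fileext = ".smi")
  out <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(inp, out)), add = TRUE)
  writeLines(paste(smiles, sprintf("m%06d", seq_along(smiles))), inp)
  ob_run(c(inp, "-O", out))
  geo <- suppressWarnings(ChemmineR::read.SDFset(out))
  vapply(seq_along(smiles), function(i) {
    sdf <- geo[[i]]
    el <- sub("_.*$", "", rownames(ChemmineR::atomblock(sdf)))
    carbons <- which(el == "C")
    if (length(carbons) == 0) return(NA_real_)
    bb <- ChemmineR::bondblock(sdf)
    unsat <- unique(c(bb[bb[, 3] > 1, 1], bb[bb[, 3] > 1, 2]))
    sum(!(carbons %in% unsat)) / length(carbons)
  }, numeric(1))
}

#' Summary statistics for a property table
#'
#' Arithmetic means of MW, clogP and Fsp3, plus counts and fractions
#' passing each design filter.
#'
#' @param records A data.frame from [profile_properties()].
#' @return A list with `n`, `mean_mw`, `mean_clogp`, `mean_fsp3`,
#'   `n_rule_of_two`, `n_leadlike`, `frac_rule_of_two`, `frac_leadlike`.
#' @export
summarize_properties <- function(records) {
  if (nrow(records) == 0) stop("cannot summarize an empty property table",
                               call. = FALSE)
  list(n = nrow(records),
       mean_mw = mean(records$mw),
       mean_clogp = mean(records$clogp),
       mean_fsp3 = mean(records$fsp3),
       n_rule_of_two = sum(records$rule_of_two_pass),
       n_leadlike = sum(records$leadlike_pass),
       frac_rule_of_two = mean(records$rule_of_two_pass),
       frac_leadlike = mean(records$leadlike_pass))
}

#' Filter a property table by a named design filter
#'
#' @param records A data.frame from [profile_properties()].
#' @param filter_name `"rule_of_two"` (MW < 200 and clogP < 2, strict) or
#'   `"leadlike"` (-1 < clogP < 3 and 200 <= MW <= 350).
#' @return The passing subset, original order preserved.
#' @export
apply_property_filter <- function(records,
                                  filter_name = c("rule_of_two",
                                                  "leadlike")) {
  if (!filter_name[1] %in% c("rule_of_two", "leadlike")) {
    stop("unknown filter '", filter_name[1],
         "'; valid filters: rule_of_two, leadlike", call. = FALSE)
  }
  filter_name <- match.arg(filter_name)
  col <- if (filter_name == "rule_of_two") "rule_of_two_pass"
  else "leadlike_pass"
  records[records[[col]], , drop = FALSE]
}
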