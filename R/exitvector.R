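# Exit-vector geometry. For a bifunctional scaffold the two substituent
# vectors are n1 (from C1, the "green" variation point, towards the
# fragment attachment atom, "blue") and n2 (from N2, "orange", towards the
# cap attachment atom, "red"). Two parameters summarize the 3D display of
# the substituents:
#   r     - the through-space distance C1...N2 in Angstrom;
#   theta - the dihedral angle between the plane containing n1 and the
#           C1-N2 axis and the plane containing n2 and that axis,
#           equivalently the four-point torsion red-orange-green-blue,
#           reported unsigned in [0, 180] degrees (one enantiomeric series
#           per compound; signed torsions would split enantiomers).

#' Exit-vector parameters from four atomic positions
#'
#' @param red,orange,green,blue Numeric length-3 coordinates (Angstrom) of
#'   the cap attachment atom, N2, C1, and the fragment attachment atom.
#' @param fold Fold convention for theta: `"180"` (default, unsigned
#'   torsion in `[0, 180]`) or `"90"` (additionally folds the obtuse range
#'   back onto `[0, 90]`).
#' @return A list with `r` (Angstrom), `theta` (degrees), and the unit
#'   vectors `n1` (C1 towards blue) and `n2` (N2 towards red).
#' @examples
#' compute_exit_vector(red = c(0, 1, 0), orange = c(0, 0, 0),
#'                     green = c(1.5, 0, 0), blue = c(1.5, 1, 0))
#' @export
compute_exit_vector <- function(red, orange, green, blue,
                                fold = c("180", "90")) {
  fold <- match.arg(fold)
  red <- as.numeric(red); orange <- as.numeric(orange)
  green <- as.numeric(green); blue <- as.numeric(blue)
  stopifnot(length(red) == 3, length(orange) == 3,
            length(green) == 3, length(blue) == 3)
  axis <- green - orange
  r <- sqrt(sum(axis^2))
  if (r < 1e-6) stop("C1 and N2 coincide; r is undefined", call. = FALSE)
  # torsion red-orange-green-blue (praxeolitic formulation; the first
  # bond vector points back towards red so the projected half-planes open
  # from the rotation axis)
  b1 <- red - orange
  b2 <- axis
  b3 <- blue - green
  if (vec_norm(cross3(b1, b2)) < 1e-8 * vec_norm(b1) * vec_norm(b2) ||
      vec_norm(cross3(b2, b3)) < 1e-8 * vec_norm(b2) * vec_norm(b3)) {
    stop("degenerate exit-vector geometry: three of the defining atoms ",
         "are collinear, the dihedral plane is undefined", call. = FALSE)
  }
  b2u <- b2 / vec_norm(b2)
  v <- b1 - sum(b1 * b2u) * b2u
  w <- b3 - sum(b3 * b2u) * b2u
  theta <- abs(atan2(sum(cross3(b2u, v) * w), sum(v * w)) * 180 / pi)
  if (fold == "90" && theta > 90) theta <- 180 - theta
  list(r = r, theta = theta,
       n1 = (blue - green) / vec_norm(blue - green),
       n2 = (red - orange) / vec_norm(red - orange))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vec_norm <- function(v) sqrt(sum(v^2))

#' Exit-vector table for an elaborated library
#'
#' Measures (r, theta) for every compound: on the lowest-energy conformer
#' for computed ensembles, and on every model for ensembles built from
#' supplied coordinates (crystal structures can hold several distinct
#' conformations in the asymmetric unit, all of which belong on the plot).
#'
#' @param library An `ev_compound` data.frame with tracked atom indices.
#' @param ensembles A list of `ev_ensemble` objects named by `product_id`
#'   (or in library order).
#' @param fold Theta fold convention, see [compute_exit_vector()].
#' @return A data.frame with one row per measured conformer: `compound_id`,
#'   `scaffold_id`, `fragment_id`, `cap_id`, `conformer_index`,
#'   `r_angstrom`, `theta_degrees`, `source`; sorted by compound id.
#' @export
vectors_for_library <- function(library, ensembles, fold = "180") {
  if (nrow(library) == 0) {
    return(data.frame(compound_id = character(), scaffold_id = character(),
                      fragment_id = character(), cap_id = character(),
                      conformer_index = integer(), r_angstrom = numeric(),
                      theta_degrees = numeric(), source = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(names(ensembles))) {
    stopifnot(length(ensembles) == nrow(library))
    names(ensembles) <- library$product_id
  }
  missing <- setdiff(library$product_id, names(ensembles))
  if (length(missing) > 0) {
    stop("no conformer ensemble for compound(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(library))) {
    cmp <- library[i, ]
    if (anyNA(c(cmp$atom_c1, cmp$atom_n2, cmp$atom_blue, cmp$atom_red))) {
      stop("compound '", cmp$product_id, "' does not have all four ",
           "vector-defining atoms; elaborate both variation points before ",
           "the vector analysis", call. = FALSE)
    }
    ens <- ensembles[[cmp$product_id]]
    confs <- if (identical(ens$source, "supplied_coordinates")) {
      seq_along(ens$coordinates)
    } else ens$lowest_index
    for (ci in confs) {
      m <- ens$coordinates[[ci]]
      ev <- compute_exit_vector(red = m[cmp$atom_red, ],
                                orange = m[cmp$atom_n2, ],
                                green = m[cmp$atom_c1, ],
                                blue = m[cmp$atom_blue, ],
                                fold = fold)
      rows[[length(rows) + 1]] <- data.frame(
        compound_id = cmp$product_id, scaffold_id = cmp$scaffold_id,
        fragment_id = cmp$fragment_id, cap_id = cmp$cap_id,
        conformer_index = ci, r_angstrom = ev$r, theta_degrees = ev$theta,
        source = ens$source, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$compound_id, out$conformer_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Maximin selection of geometrically diverse compounds
#'
#' Selects `k` compounds spread out in normalized (r, theta) space: r is
#' scaled by its observed range and theta by 180 degrees. The objective is
#' maximin: maximize the smallest pairwise distance within the selected
#' subset. Small instances (up to `exact_limit` candidate subsets) are
#' solved exactly by exhaustive search; larger ones fall back to the usual
#' greedy construction whose first pick is the point closest to the
#' centroid. All ties break deterministically towards the
#' lexicographically smallest compound id (set).
#'
#' @param records An exit-vector table from [vectors_for_library()].
#' @param k Number of compounds to select, `0 <= k <= nrow(records)`.
#' @param exact_limit Maximum number of subsets evaluated exhaustively
#'   before switching to the greedy construction.
#' @return Character vector of `k` compound ids.
#' @export
diversity_select <- function(records, k, exact_limit = 1e5) {
  n <- nrow(records)
  stopifnot(k >= 0, k <= n)
  if (k == 0) return(character())
  rr <- records$r_angstrom
  rrange <- diff(range(rr))
  x <- if (rrange > 0) (rr - min(rr)) / rrange else rep(0, n)
  y <- records$theta_degrees / 180
  ids <- records$compound_id
  pts <- cbind(x, y)
  ctr <- colMeans(pts)
  d_ctr <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  ord <- order(ids)  # tie-break preference
  if (k == 1) return(ids[ord[which.min(d_ctr[ord])]])
  if (k == n) return(ids[ord])
  dm <- as.matrix(stats::dist(pts))
  if (choose(n, k) <= exact_limit) {
    # exhaustive maximin, deterministic tie-break on sorted id sets
    subsets <- utils::combn(ord, k, simplify = FALSE)
    best <- NULL; best_obj <- -Inf; best_key <- NULL
    for (s in subsets) {
      obj <- min(dm[s, s][upper.tri(diag(k))])
      key <- paste(sort(ids[s]), collapse = "\001")
      if (obj > best_obj + 1e-12 ||
          (obj > best_obj - 1e-12 && (is.null(best_key) || key < best_key))) {
        best <- s; best_obj <- obj; best_key <- key
      }
    }
    return(ids[best])
  }
  chosen <- ord[which.min(d_ctr[ord])]
  while (length(chosen) < k) {
    dmin <- apply(dm[, chosen, drop = FALSE], 1, min)
    dmin[chosen] <- -Inf
    cand <- which(dmin >= max(dmin) - 1e-12)
    chosen <- c(chosen, cand[order(ids[cand])][1])
  }
  ids[chosen]
}

#' Write an exit-vector table to CSV
#'
#' @param records Exit-vector table.
#' @param csv_path Output path.
#' @return Invisibly, the records.
#' @export
write_vectors <- function(records, csv_path) {
  utils::write.csv(records, csv_path, row.names = FALSE)
  invisible(records)
}
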