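# Exit-vector geometry and diverse-subset selection.

test_that("planar reference geometries give the textbook angles", {
  red <- c(0, 1, 0); orange <- c(0, 0, 0); green <- c(1.5, 0, 0)
  cis <- compute_exit_vector(red, orange, green, blue = c(1.5, 1, 0))
  expect_equal(cis$r, 1.5)
  expect_equal(cis$theta, 0)
  trans <- compute_exit_vector(red, orange, green, blue = c(1.5, -1, 0))
  expect_equal(trans$r, 1.5)
  expect_equal(trans$theta, 180)
  perp <- compute_exit_vector(red, orange, green, blue = c(1.5, 0, 1))
  expect_equal(perp$theta, 90)
  expect_equal(sqrt(sum(perp$n1^2)), 1, tolerance = 1e-9)
  expect_equal(sqrt(sum(perp$n2^2)), 1, tolerance = 1e-9)
})

test_that("theta matches an independent dihedral formulation", {
  set.seed(11)
  for (i in 1:1000) {
    pts <- matrix(stats::runif(12, -3, 3), 4, 3)
    # guard against near-collinear draws, which both routes reject
    ok <- tryCatch({
      ev <- compute_exit_vector(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
      TRUE
    }, error = function(e) FALSE)
    if (!ok) next
    oracle <- dihedral_oracle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    expect_equal(ev$theta, oracle, tolerance = 1e-6 / max(oracle, 1))
  }
})

test_that("(r, theta) is invariant under rigid motions and mirrors", {
  set.seed(12)
  base <- matrix(stats::runif(12, -2, 2), 4, 3)
  ref <- compute_exit_vector(base[1, ], base[2, ], base[3, ], base[4, ])
  for (i in 1:25) {
    rot <- random_rotation()
    shift <- stats::rnorm(3)
    moved <- sweep(base %*% t(rot), 2, shift, "+")
    ev <- compute_exit_vector(moved[1, ], moved[2, ], moved[3, ], moved[4, ])
    expect_equal(ev$r, ref$r, tolerance = 1e-9)
    expect_equal(ev$theta, ref$theta, tolerance = 1e-7)
  }
  mirrored <- base %*% diag(c(-1, 1, 1))
  ev <- compute_exit_vector(mirrored[1, ], mirrored[2, ], mirrored[3, ],
                            mirrored[4, ])
  expect_equal(ev$theta, ref$theta, tolerance = 1e-9)
})

test_that("degenerate inputs are rejected", {
  o <- c(0, 0, 0); g <- c(1, 0, 0)
  expect_error(compute_exit_vector(red = c(-1, 0, 0), orange = o,
                                   green = g, blue = c(2, 1, 0)),
               "collinear")
  expect_error(compute_exit_vector(red = c(0, 1, 0), orange = o,
                                   green = o, blue = c(0, 0, 1)),
               "coincide")
})

test_that("the 90-degree fold maps obtuse angles back", {
  red <- c(0, 1, 0); orange <- c(0, 0, 0); green <- c(1.5, 0, 0)
  tr <- compute_exit_vector(red, orange, green, blue = c(1.5, -1, 0.1),
                            fold = "90")
  expect_lte(tr$theta, 90)
})

test_that("library vectors use the lowest conformer, supplied use all", {
  cmp <- get_compound86()
  ens <- get_ensemble86()
  tab <- vectors_for_library(cmp, setNames(list(ens), cmp$product_id))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$conformer_index, ens$lowest_index)
  # supplied coordinates: every model is retained
  sup <- ens
  sup$source <- "supplied_coordinates"
  tab2 <- vectors_for_library(cmp, setNames(list(sup), cmp$product_id))
  expect_equal(nrow(tab2), length(ens$coordinates))
  expect_error(vectors_for_library(cmp, list(other = ens)), "no conformer")
  expect_equal(nrow(vectors_for_library(cmp[0, ], list())), 0L)
})

test_that("mirror-imaged conformer coordinates give identical (r, theta)", {
  cmp <- get_compound86()
  ens <- get_ensemble86()
  tab <- vectors_for_library(cmp, setNames(list(ens), cmp$product_id))
  flipped <- ens
  flipped$coordinates <- lapply(ens$coordinates,
                                function(m) m %*% diag(c(-1, 1, 1)))
  tab2 <- vectors_for_library(cmp, setNames(list(flipped), cmp$product_id))
  expect_equal(tab2$r_angstrom, tab$r_angstrom, tolerance = 1e-9)
  expect_equal(tab2$theta_degrees, tab$theta_degrees, tolerance = 1e-9)
})

test_that("maximin selection handles the edge and textbook cases", {
  rec <- ev_records(c(1, 2, 3), c(10, 20, 30), c("a", "b", "c"))
  expect_equal(diversity_select(rec, 0), character())
  expect_setequal(diversity_select(rec, 3), c("a", "b", "c"))
  # three collinear points, k = 2: the two extremes
  expect_setequal(diversity_select(rec, 2), c("a", "c"))
})

test_that("selection equals an independent exhaustive search for n <= 10", {
  set.seed(13)
  for (trial in 1:8) {
    n <- sample(4:10, 1)
    k <- sample(2:(n - 1), 1)
    rec <- ev_records(stats::runif(n, 1, 5), stats::runif(n, 0, 180))
    got <- diversity_select(rec, k)
    # brute force, written independently of the package implementation
    x <- (rec$r_angstrom - min(rec$r_angstrom)) /
      diff(range(rec$r_angstrom))
    y <- rec$theta_degrees / 180
    combos <- utils::combn(n, k, simplify = FALSE)
    objs <- vapply(combos, function(s) {
      min(stats::dist(cbind(x[s], y[s])))
    }, numeric(1))
    best <- max(objs)
    got_obj <- min(stats::dist(cbind(
      x[match(got, rec$compound_id)], y[match(got, rec$compound_id)])))
    expect_equal(got_obj, best, tolerance = 1e-9)
  }
})
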