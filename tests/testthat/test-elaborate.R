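# Virtual elaboration: graph edits at the annotated attachment points.

test_that("fragment attachment forms the C1 bond and tracks the atoms", {
  core <- attach_fragment(get_blocks()[1, ], get_fragments()[1, ])
  at <- smi_atoms(core$structure)
  heavy <- sum(at$elem != "H")
  expect_equal(heavy, 12L)  # 6 scaffold + 6 pyrimidinyl heavy atoms
  expect_equal(at$elem[core$atom_c1], "C")
  expect_equal(at$elem[core$atom_n2], "N")
  expect_equal(at$elem[core$atom_blue], "c")
  expect_true(is.na(core$cap_id))
})

test_that("capping forms the N bond for sulfonyl, acyl, alkyl, aryl caps", {
  core <- attach_fragment(get_blocks()[1, ], get_fragments()[1, ])
  attach_atom <- c(methanesulfonyl = "S", acetyl = "C",
                   methyl = "C", phenyl = "c")
  caps <- get_caps()
  for (cid in names(attach_atom)) {
    cmp <- attach_cap(core, caps[caps$id == cid, ])
    at <- smi_atoms(cmp$structure)
    expect_equal(at$elem[cmp$atom_red], attach_atom[[cid]])
    # red and orange atoms are bonded: verify on the embedded geometry
    expect_equal(cmp$cap_id, cid)
  }
})

test_that("the hydrogen placeholder is an identity for both edits", {
  h <- hydrogen_placeholder()
  sc <- get_blocks()[1, ]
  same <- attach_fragment(sc, h)
  expect_equal(same$structure, sc$structure)
  core <- attach_fragment(sc, get_fragments()[1, ])
  expect_equal(attach_cap(core, h)$structure, core$structure)
})

test_that("capping an already-capped nitrogen errors", {
  core <- attach_fragment(get_blocks()[1, ], get_fragments()[1, ])
  caps <- get_caps()
  once <- attach_cap(core, caps[1, ])
  expect_error(attach_cap(once, caps[2, ]), "no free hydrogen")
})

test_that("substituents with the wrong attachment arity are rejected", {
  bad <- data.frame(id = "bad", role = "fragment", structure = "c1ccccc1",
                    racemic = FALSE, notes = "", stringsAsFactors = FALSE)
  expect_error(attach_fragment(get_blocks()[1, ], bad),
               "exactly one attachment")
})

test_that("elaboration obeys mass balance", {
  # product MW = scaffold + fragment + cap - 2 x H2 (one H displaced on
  # each side of each new bond)
  bb <- get_blocks(); fr <- get_fragments(); cp <- get_caps()
  h2 <- 2 * 1.008
  for (i in c(1, 4, 7)) for (k in c(1, 3)) {
    cmp <- attach_cap(attach_fragment(bb[i, ], fr[1, ]), cp[k, ])
    mw <- profile_properties(cmp)$mw
    parts <- profile_properties(c(bb$structure[i], fr$structure[1],
                                  cp$structure[k]))$mw
    expect_equal(mw, sum(parts) - 2 * h2, tolerance = 1e-4)
  }
})

test_that("the full grid gives 108 distinct products with provenance", {
  lib <- fixture("library108",
                 enumerate_library(get_scaffolds27(), get_fragments(),
                                   get_caps()))
  expect_equal(nrow(lib), 27L * 1L * 4L)
  expect_false(anyDuplicated(lib$key) > 0)
  expect_equal(sort(unique(lib$cap_id)), sort(get_caps()$id))
  expect_equal(length(unique(lib$scaffold_id)), 27L)
  expect_false(any(is.na(lib$atom_c1) | is.na(lib$atom_n2) |
                     is.na(lib$atom_blue) | is.na(lib$atom_red)))
})

test_that("degenerate registries give an empty library", {
  sc <- get_scaffolds27()
  expect_equal(nrow(enumerate_library(sc, get_fragments(),
                                      get_caps()[0, ])), 0L)
  expect_equal(nrow(enumerate_library(sc[0, ], get_fragments(),
                                      get_caps())), 0L)
})

test_that("roles survive serialization and re-location", {
  # writing the annotated structure out and re-scanning it finds the same
  # four roles with the same elements
  cmp <- get_compound86()
  f <- tempfile(fileext = ".smi")
  writeLines(cmp$structure, f)
  back <- readLines(f)
  at <- smi_atoms(back)
  expect_equal(which(at$map == 1), cmp$atom_c1)
  expect_equal(which(at$map == 2), cmp$atom_n2)
  expect_equal(which(at$map == 3), cmp$atom_blue)
  expect_equal(which(at$map == 4), cmp$atom_red)
})
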