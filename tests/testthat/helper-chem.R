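# Shared fixtures and independent oracles for the test-suite.

.fixture_env <- new.env(parent = emptyenv())

# Memoized expensive fixtures (computed once per test run).
fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

get_scaffolds <- function() fixture("scaffolds", enumerate_scaffolds())

get_scaffolds27 <- function() {
  fixture("scaffolds27", augment_with_tropane(get_scaffolds()))
}

get_blocks <- function() fixture("blocks", load_registry("building_blocks"))
get_fragments <- function() fixture("fragments", load_registry("fragments"))
get_caps <- function() fixture("caps", load_registry("caps"))

# Compound 86 analogue: 1a scaffold + pyrimidin-5-yl + methanesulfonyl.
get_compound86 <- function() {
  fixture("compound86", {
    bb <- get_blocks()
    attach_cap(
      attach_fragment(list(structure = bb$structure[bb$id == "1a"],
                           id = "1a"),
                      get_fragments()[1, ]),
      get_caps()[get_caps()$id == "methanesulfonyl", ])
  })
}

get_ensemble86 <- function() {
  fixture("ensemble86", embed_and_minimize(get_compound86(), n_confs = 50))
}

# ---- independent oracles ----------------------------------------------------

# Unsigned dihedral of the sequence p1-p2-p3-p4 via plane normals and acos;
# an algebraic route independent of the atan2 formulation in the package.
dihedral_oracle <- function(p1, p2, p3, p4) {
  n1 <- pracma_cross(p2 - p1, p3 - p2)
  n2 <- pracma_cross(p3 - p2, p4 - p3)
  cosang <- sum(n1 * n2) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Random proper rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# RDKit (via the system python) as an independent structure-identity oracle:
# counts distinct relative-stereo identities among SMILES. Returns NA if the
# oracle toolchain is unavailable.
rdkit_distinct_count <- function(smiles) {
  py <- Sys.which("python")
  if (!nzchar(py)) return(NA_integer_)
  inp <- tempfile(fileext = ".smi")
  writeLines(smiles, inp)
  code <- paste(
    "import sys",
    "from rdkit import Chem",
    "from rdkit.Chem import inchi",
    "import re",
    "seen=set()",
    "for line in open(sys.argv[1]):",
    "    m=Chem.MolFromSmiles(line.strip())",
    "    if m is None: sys.exit(3)",
    "    i=inchi.MolToInchi(m)",
    "    seen.add(re.sub(r'/[ms][0-9]+','',i))",
    "print(len(seen))", sep = "\n")
  out <- suppressWarnings(system2(py, c("-c", shQuote(code), inp),
                                  stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) return(NA_integer_)
  as.integer(out[length(out)])
}

# Average atomic masses for the independent molecular-weight summation.
ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998403163, S = 32.06, Cl = 35.45, Br = 79.904,
                 P = 30.973761998, I = 126.90447)

mw_from_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  total <- 0
  for (t in toks) {
    el <- gsub("[0-9]", "", t)
    n <- gsub("[^0-9]", "", t)
    n <- if (n == "") 1 else as.integer(n)
    total <- total + ATOMIC_MASS[[el]] * n
  }
  total
}

# Molecular formula via obabel's title append (used only to feed the
# independent mass summation).
formula_of <- function(smiles) {
  inp <- tempfile(fileext = ".smi")
  writeLines(paste(smiles, seq_along(smiles)), inp)
  out <- suppressWarnings(system2("obabel", c(inp, "-osmi", "--append",
                                              "formula"),
                                  stdout = TRUE, stderr = FALSE))
  out <- out[grepl("\t", out)]
  vapply(strsplit(out, "[ \t]+"), function(p) p[length(p)], character(1))
}

# Minimal multi-model SDF writer for coordinate-ingestion tests.
write_test_sdf <- function(models, elements, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in models) {
    writeLines(c("test", " test", "",
                 sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                         nrow(m), 0L),
                 sprintf(
                   "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   m[, 1], m[, 2], m[, 3], elements),
                 "M  END", "$$$$"), con)
  }
  path
}

# Exit-vector-style records from bare (r, theta) points.
ev_records <- function(r, theta, ids = NULL) {
  data.frame(compound_id = ids %||% sprintf("p%02d", seq_along(r)),
             scaffold_id = "s", fragment_id = "f", cap_id = "c",
             conformer_index = 1L, r_angstrom = r, theta_degrees = theta,
             source = "computed", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
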