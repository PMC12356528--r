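# A minimal SMILES scanner used for the attachment-point bookkeeping.
#
# Structures in this package annotate their variation points with atom maps:
#   map 1 = C1, the cyclopropane carbon that receives the aryl fragment
#   map 2 = N2, the ring nitrogen that receives the capping group
#   map 3 = the fragment atom bonded to C1 ("blue" atom)
#   map 4 = the cap atom bonded to N2 ("red" atom)
# A replaceable hydrogen on a stereo-annotated attachment atom is written as
# its first explicit-([H]) branch, so that substitution preserves the written
# tetrahedral parity (the new neighbour occupies the hydrogen's slot in the
# neighbour ordering). The scanner is not a general SMILES parser: it only
# locates atom tokens in order of appearance (the order OpenBabel preserves
# when writing SDF) and performs the bonded substitutions used by the
# elaboration step.

ORGANIC_TWO <- c("Cl", "Br")
ORGANIC_ONE <- c("B", "C", "N", "O", "P", "S", "F", "I",
                 "b", "c", "n", "o", "s", "p")

# Scan a SMILES string; returns a data.frame with one row per atom in order
# of appearance: element, atom map (NA if unmapped), implicit bracket H count
# (NA outside brackets), character span of the token.
smi_atoms <- function(smi) {
  chars <- strsplit(smi, "")[[1]]
  n <- length(chars)
  rows <- list()
  i <- 1
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1
      if (j > n) stop("unbalanced bracket in SMILES: ", smi, call. = FALSE)
      tok <- substr(smi, i, j)
      inner <- substr(tok, 2, nchar(tok) - 1)
      map <- if (grepl(":[0-9]+$", inner)) {
        as.integer(sub(".*:([0-9]+)$", "\\1", inner))
      } else NA_integer_
      core <- sub(":[0-9]+$", "", inner)
      core <- sub("^[0-9]+", "", core)          # isotope
      elem <- sub("^(\\*|[A-Za-z][a-z]?).*", "\\1", core)
      # distinguish the H *atom* from an H *count*: element is whatever the
      # leading symbol is; "[H]" scans as element H.
      if (!elem %in% c("*", "H") && !elem %in% ORGANIC_TWO &&
          nchar(elem) == 2 && grepl("H$", elem)) {
        elem <- substr(elem, 1, 1)              # e.g. [CH3] -> C
      }
      rest <- substr(core, nchar(elem) + 1, nchar(core))
      hcount <- if (elem == "H") 0L
      else if (grepl("H[0-9]*", rest)) {
        hs <- sub(".*H([0-9]*).*", "\\1", rest)
        if (hs == "") 1L else as.integer(hs)
      } else 0L
      rows[[length(rows) + 1]] <- data.frame(
        elem = elem, map = map, hcount = hcount,
        start = i, end = j, bracket = TRUE, stringsAsFactors = FALSE)
      i <- j + 1
    } else if (i < n && substr(smi, i, i + 1) %in% ORGANIC_TWO) {
      rows[[length(rows) + 1]] <- data.frame(
        elem = substr(smi, i, i + 1), map = NA_integer_, hcount = NA_integer_,
        start = i, end = i + 1, bracket = FALSE, stringsAsFactors = FALSE)
      i <- i + 2
    } else if (ch %in% ORGANIC_ONE) {
      rows[[length(rows) + 1]] <- data.frame(
        elem = ch, map = NA_integer_, hcount = NA_integer_,
        start = i, end = i, bracket = FALSE, stringsAsFactors = FALSE)
      i <- i + 1
    } else {
      i <- i + 1  # bonds, digits, branches, dots
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(elem = character(), map = integer(), hcount = integer(),
                      start = integer(), end = integer(), bracket = logical())
  }
  out$idx <- seq_len(nrow(out))
  out
}

# Index (order of appearance, hydrogens included) of the atom carrying `map`.
smi_map_index <- function(smi, map) {
  at <- smi_atoms(smi)
  hit <- which(!is.na(at$map) & at$map == map)
  if (length(hit) != 1) {
    stop("expected exactly one atom with map ", map, " in ", smi, call. = FALSE)
  }
  at$idx[hit]
}

smi_strip_maps <- function(smi) gsub(":[0-9]+\\]", "]", smi)

# Mirror image: invert every tetrahedral parity marker (inside brackets only).
smi_mirror <- function(smi) {
  at <- smi_atoms(smi)
  br <- at[at$bracket, , drop = FALSE]
  if (nrow(br) == 0) return(smi)
  out <- smi
  for (k in rev(seq_len(nrow(br)))) {
    tok <- substr(out, br$start[k], br$end[k])
    tok <- gsub("@@", "\001", tok, fixed = TRUE)
    tok <- gsub("@", "@@", tok, fixed = TRUE)
    tok <- gsub("\001", "@", tok, fixed = TRUE)
    out <- paste0(substr(out, 1, br$start[k] - 1), tok,
                  substr(out, br$end[k] + 1, nchar(out)))
  }
  out
}

smi_set_map <- function(smi, from, to) {
  at <- smi_atoms(smi)
  hit <- which(!is.na(at$map) & at$map == from)
  if (length(hit) != 1) {
    stop("expected exactly one atom with map ", from, " in ", smi,
         call. = FALSE)
  }
  tok <- substr(smi, at$start[hit], at$end[hit])
  tok <- sub(paste0(":", from, "\\]"), paste0(":", to, "]"), tok)
  paste0(substr(smi, 1, at$start[hit] - 1), tok,
         substr(smi, at$end[hit] + 1, nchar(smi)))
}

# Open a new bond slot at the atom carrying `map`: either consume the first
# explicit "([H])" branch written directly after the atom's ring-closure
# digits (stereo-safe convention used throughout this package), or decrement
# the bracket hydrogen count. Returns the modified SMILES with the ring-bond
# label `digit` (e.g. "%95") inserted at the freed neighbour slot.
smi_open_bond <- function(smi, map, digit) {
  at <- smi_atoms(smi)
  hit <- which(!is.na(at$map) & at$map == map)
  if (length(hit) != 1) {
    stop("expected exactly one atom with map ", map, " in ", smi,
         call. = FALSE)
  }
  tok_end <- at$end[hit]
  # consume ring-closure digits following the token
  p <- tok_end + 1
  nch <- nchar(smi)
  while (p <= nch) {
    ch <- substr(smi, p, p)
    if (grepl("[0-9]", ch)) p <- p + 1
    else if (ch == "%" && p + 2 <= nch) p <- p + 3
    else break
  }
  if (substr(smi, p, p + 4) == "([H])") {
    return(paste0(substr(smi, 1, p - 1), digit,
                  substr(smi, p + 5, nch)))
  }
  tok <- substr(smi, at$start[hit], tok_end)
  hcount <- at$hcount[hit]
  if (is.na(hcount) || hcount < 1) {
    stop("atom with map ", map, " in ", smi,
         " has no substitutable hydrogen", call. = FALSE)
  }
  if (grepl("@", tok)) {
    stop("stereo atom with map ", map,
         " must expose its replaceable hydrogen as an explicit ([H]) branch",
         call. = FALSE)
  }
  newtok <- if (hcount == 1) sub("H(?=[^A-Za-z])", "", tok, perl = TRUE)
  else sub(paste0("H", if (hcount > 1) hcount else ""),
           if (hcount == 2) "H" else paste0("H", hcount - 1), tok)
  paste0(substr(smi, 1, at$start[hit] - 1), newtok, digit,
         substr(smi, tok_end + 1, nch))
}

# Join two annotated structures with a single bond between the atom mapped
# `host_map` in `host` and the atom mapped `guest_map` in `guest`.
smi_attach <- function(host, host_map, guest, guest_map, digit = "%95") {
  a <- smi_open_bond(host, host_map, digit)
  b <- smi_open_bond(guest, guest_map, digit)
  paste0(a, ".", b)
}
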