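#' Functional-group category labels
#'
#' The closed set of eight functional-group categories used to group reaction
#' rules and to define ranking priority: `alcohols`, `alkanes`, `alkenes`,
#' `amines`, `aromatics`, `esters`, `ethers`, and `others` (the catch-all for
#' chemistries outside the seven named ones).
#'
#' @return Character vector of the eight category labels, alphabetically
#'   ordered.
#' @export
#' @examples
#' group_categories()
group_categories <- function() {
  c("alcohols", "alkanes", "alkenes", "amines",
    "aromatics", "esters", "ethers", "others")
}

ob_canonical_smiles <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n")),
    error = function(e) ""
  )
  out <- sub("[\t ]*\n?$", "", out)
  out <- sub("\t.*$", "", out)
  if (!nzchar(out)) return(NA_character_)
  out
}

strip_stereo_smiles <- function(smiles) {
  gsub("[@/\\\\]", "", smiles)
}

#' Parse and sanitize a SMILES string
#'
#' Parses a SMILES string into a molecule object carrying the sanitized
#' canonical SMILES, a stereo-stripped canonical identity key, the heavy atom
#' count and the internal molecular graph. The identity key is what decides
#' whether two structures are "the same metabolite": it is the canonical
#' SMILES after removing stereo annotations, so enantiomers and E/Z isomers
#' collapse to one key (literature metabolite records frequently omit
#' stereocenters).
#'
#' @param smiles A single SMILES string.
#' @return An object of class `nc_molecule` with elements `input_smiles`,
#'   `canonical_smiles`, `canonical_key`, `heavy_atom_count` and `graph`.
#' @export
#' @examples
#' m <- parse_molecule("CCO")
#' m$heavy_atom_count
#' canonical_key(parse_molecule("OCC")) == m$canonical_key
parse_molecule <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    invalid_smiles(as.character(smiles)[1], "empty or not a single string")
  }
  smiles <- trimws(smiles)
  # strict syntax check first: OpenBabel silently repairs some malformed input
  parse_smiles_graph(smiles)
  can <- ob_canonical_smiles(smiles)
  if (is.na(can)) invalid_smiles(smiles, "rejected during sanitization")
  if (grepl("[@/\\\\]", can)) {
    key <- ob_canonical_smiles(strip_stereo_smiles(can))
    if (is.na(key)) invalid_smiles(smiles, "stereo-stripped form failed sanitization")
  } else {
    key <- can
  }
  g <- parse_smiles_graph(key)
  structure(list(
    input_smiles = smiles,
    canonical_smiles = can,
    canonical_key = key,
    heavy_atom_count = heavy_atom_count_graph(g),
    graph = g
  ), class = "nc_molecule")
}

is_molecule <- function(x) inherits(x, "nc_molecule")

as_molecule <- function(x) {
  if (is_molecule(x)) x else parse_molecule(x)
}

#' @export
print.nc_molecule <- function(x, ...) {
  cat("<molecule>", x$canonical_smiles, "\n")
  cat("  key:", x$canonical_key, "\n")
  cat("  heavy atoms:", x$heavy_atom_count, "\n")
  invisible(x)
}

#' Stereo-stripped canonical identity key
#'
#' @param mol An `nc_molecule` (or a SMILES string, which is parsed first).
#' @return The canonical identity key: equal structures give equal keys
#'   regardless of atom numbering, SMILES spelling or stereo annotation.
#' @export
canonical_key <- function(mol) {
  as_molecule(mol)$canonical_key
}

# Build a molecule object directly from an internal graph produced by the
# rule engine (avoids a redundant round trip; the graph is already
# stereo-free, so key == canonical form of the written SMILES).
molecule_from_graph <- function(g) {
  smi <- write_smiles_graph(g)
  can <- ob_canonical_smiles(smi)
  if (is.na(can)) return(NULL)
  g2 <- tryCatch(parse_smiles_graph(can), error = function(e) NULL)
  if (is.null(g2)) return(NULL)
  structure(list(
    input_smiles = smi,
    canonical_smiles = can,
    canonical_key = can,
    heavy_atom_count = heavy_atom_count_graph(g2),
    graph = g2
  ), class = "nc_molecule")
}

# Compiled detection patterns, built once at load time.
classifier_env <- new.env(parent = emptyenv())

classifier_patterns <- function() {
  if (is.null(classifier_env$pats)) {
    classifier_env$pats <- list(
      alcohols = parse_smarts_pattern("[CX4][OX2;H1]"),
      ester    = parse_smarts_pattern("[CX3](=[OX1])[OX2][#6]"),
      ether    = parse_smarts_pattern("[#6][OX2][#6]"),
      alkenes  = parse_smarts_pattern("[C]=[C]"),
      amine_n  = parse_smarts_pattern("[NX3]"),
      carbonyl_c = parse_smarts_pattern("[CX3]=[OX1]"),
      sp3_ch   = parse_smarts_pattern("[CX4;!H0]")
    )
  }
  classifier_env$pats
}

#' Classify the functional-group categories present in a molecule
#'
#' Detects which of the eight rule categories a structure exhibits. Detection
#' is substructure-based with two masking conventions: an ester's bridging
#' oxygen is not additionally counted as an ether, and an sp3 C-H center
#' counts toward `alkanes` only when no heteroatom lies within two bonds (so
#' ethanol is an alcohol, not an alkane). Nitrogen adjacent to a carbonyl
#' carbon (amide) is not an amine. `others` is returned exactly when none of
#' the seven named categories match.
#'
#' @param mol An `nc_molecule` or SMILES string.
#' @return Character vector: a subset of [group_categories()].
#' @export
#' @examples
#' classify_functional_groups("CCO")          # alcohols
#' classify_functional_groups("CC(=O)OC")     # esters
#' classify_functional_groups("COc1ccccc1")   # ethers, aromatics
classify_functional_groups <- function(mol) {
  mol <- as_molecule(mol)
  g <- mol$graph
  props <- mol_match_props(g)
  pats <- classifier_patterns()
  found <- character()

  if (any(props$arom)) found <- c(found, "aromatics")
  if (nrow(match_smarts(pats$alcohols, g, props))) found <- c(found, "alcohols")

  ester_m <- match_smarts(pats$ester, g, props)
  if (nrow(ester_m)) found <- c(found, "esters")
  # ether: C-O-C where neither carbon is a carbonyl carbon (masks esters and
  # anhydrides)
  carbonyl_c <- unique(match_smarts(pats$carbonyl_c, g, props)[, 1])
  ether_m <- match_smarts(pats$ether, g, props)
  if (nrow(ether_m)) {
    ok <- !(ether_m[, 1] %in% carbonyl_c) & !(ether_m[, 3] %in% carbonyl_c)
    if (any(ok)) found <- c(found, "ethers")
  }
  if (nrow(match_smarts(pats$alkenes, g, props))) found <- c(found, "alkenes")
  # amine: trivalent N bonded to carbon, not adjacent to a carbonyl carbon
  amine_m <- match_smarts(pats$amine_n, g, props)
  if (nrow(amine_m)) {
    adj <- adjacency_list(g)
    is_amine <- vapply(amine_m[, 1], function(a) {
      nb <- adj[[a]]
      any(props$elem[nb] == "C") && !any(nb %in% carbonyl_c)
    }, logical(1))
    if (any(is_amine)) found <- c(found, "amines")
  }
  # alkane: sp3 C-H with no heteroatom within two bonds
  ch_m <- match_smarts(pats$sp3_ch, g, props)
  if (nrow(ch_m)) {
    hetero <- which(!props$elem %in% c("C", "H"))
    if (!length(hetero)) {
      found <- c(found, "alkanes")
    } else {
      d <- graph_distance_to_set(g, hetero)
      if (any(d[ch_m[, 1]] > 2)) found <- c(found, "alkanes")
    }
  }

  if (!length(found)) return("others")
  intersect(group_categories(), unique(found))
}
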