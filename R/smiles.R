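# Minimal molecular-graph model with a strict SMILES reader and writer.
#
# The graph is the substrate for rule application and steric scoring; identity
# and sanitization are delegated to OpenBabel (see chem_core.R). The reader is
# deliberately strict: unbalanced parentheses, unmatched ring-closure digits
# and unknown characters are errors even where OpenBabel would silently
# "repair" the string.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_SYMBOLS <- c("b", "c", "n", "o", "p", "s")

ELEMENT_NUMBERS <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Si = 14,
  P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Fe = 26, Zn = 30, Se = 34,
  As = 33, Br = 35, I = 53
)

# Standard valences used for implicit hydrogen completion.
STANDARD_VALENCES <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L
)

new_mol_graph <- function(atoms, bonds) {
  structure(list(atoms = atoms, bonds = bonds), class = "mol_graph")
}

empty_bonds <- function() {
  data.frame(a1 = integer(), a2 = integer(), order = integer(),
             arom = logical())
}

n_atoms <- function(g) nrow(g$atoms)

heavy_atom_count_graph <- function(g) sum(g$atoms$elem != "H")

#' @noRd
parse_smiles_graph <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    invalid_smiles(as.character(smiles)[1], "empty or not a single string")
  }
  ch <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(ch)
  fail <- function(why) invalid_smiles(smiles, why)

  elem <- character(); arom <- logical(); charge <- integer()
  hcount <- integer()  # NA = implicit
  b1 <- integer(); b2 <- integer(); bord <- integer(); barom <- logical()

  prev <- NA_integer_
  pending <- NULL            # bond symbol awaiting next atom / ring closure
  stack <- integer()
  rings <- list()            # ring digit -> list(atom, sym)

  add_atom <- function(e, ar, q = 0L, h = NA_integer_) {
    elem[length(elem) + 1L] <<- e
    arom[length(arom) + 1L] <<- ar
    charge[length(charge) + 1L] <<- q
    hcount[length(hcount) + 1L] <<- h
    length(elem)
  }
  add_bond <- function(a, b, sym) {
    if (a == b) fail("self bond")
    if (is.null(sym)) {
      ar <- arom[a] && arom[b]
      o <- 1L
    } else {
      ar <- identical(sym, ":")
      o <- switch(sym, "-" = 1L, "=" = 2L, "#" = 3L, ":" = 1L,
                  "/" = 1L, "\\" = 1L, fail(paste("bad bond", sym)))
    }
    b1[length(b1) + 1L] <<- a; b2[length(b2) + 1L] <<- b
    bord[length(bord) + 1L] <<- o; barom[length(barom) + 1L] <<- ar
  }
  connect <- function(idx) {
    if (!is.na(prev)) add_bond(prev, idx, pending)
    pending <<- NULL
    prev <<- idx
  }
  ring_event <- function(num) {
    key <- as.character(num)
    if (is.null(rings[[key]])) {
      if (is.na(prev)) fail("ring closure before any atom")
      rings[[key]] <<- list(atom = prev, sym = pending)
      pending <<- NULL
    } else {
      open <- rings[[key]]
      sym <- pending
      if (!is.null(open$sym) && !is.null(sym) && !identical(open$sym, sym)) {
        fail("conflicting ring-closure bond symbols")
      }
      if (is.null(sym)) sym <- open$sym
      add_bond(open$atom, prev, sym)
      rings[[key]] <<- NULL
      pending <<- NULL
    }
  }

  i <- 1L
  while (i <= n) {
    c0 <- ch[i]
    if (c0 == "[") {
      j <- i + 1L
      # isotope (ignored)
      while (j <= n && grepl("[0-9]", ch[j])) j <- j + 1L
      if (j > n) fail("unterminated bracket atom")
      # element symbol
      e <- NULL; ar <- FALSE
      two <- if (j + 1L <= n) paste0(ch[j], ch[j + 1L]) else ""
      if (two %in% names(ELEMENT_NUMBERS) && grepl("^[A-Z][a-z]$", two)) {
        e <- two; j <- j + 2L
      } else if (ch[j] %in% AROMATIC_SYMBOLS) {
        e <- toupper(ch[j]); ar <- TRUE; j <- j + 1L
      } else if (grepl("[A-Z]", ch[j])) {
        e <- ch[j]; j <- j + 1L
      } else fail(sprintf("bad element in bracket at position %d", j))
      q <- 0L; h <- 0L
      while (j <= n && ch[j] != "]") {
        cj <- ch[j]
        if (cj == "@") {
          j <- j + 1L  # stereo ignored
        } else if (cj == "H") {
          j <- j + 1L
          d <- ""
          while (j <= n && grepl("[0-9]", ch[j])) { d <- paste0(d, ch[j]); j <- j + 1L }
          h <- if (nzchar(d)) as.integer(d) else 1L
        } else if (cj %in% c("+", "-")) {
          sign <- if (cj == "+") 1L else -1L
          j <- j + 1L
          d <- ""
          while (j <= n && grepl("[0-9]", ch[j])) { d <- paste0(d, ch[j]); j <- j + 1L }
          reps <- 1L
          while (j <= n && ch[j] == cj) { reps <- reps + 1L; j <- j + 1L }
          q <- q + sign * (if (nzchar(d)) as.integer(d) else reps)
        } else fail(sprintf("unsupported bracket token '%s'", cj))
      }
      if (j > n) fail("unterminated bracket atom")
      idx <- add_atom(e, ar, q, h)
      connect(idx)
      i <- j + 1L
    } else if (c0 %in% c("C", "B") && i < n && paste0(c0, ch[i + 1L]) %in% c("Cl", "Br")) {
      connect(add_atom(paste0(c0, ch[i + 1L]), FALSE))
      i <- i + 2L
    } else if (c0 %in% ORGANIC_SUBSET) {
      connect(add_atom(c0, FALSE))
      i <- i + 1L
    } else if (c0 %in% AROMATIC_SYMBOLS) {
      connect(add_atom(toupper(c0), TRUE))
      i <- i + 1L
    } else if (c0 %in% c("-", "=", "#", ":", "/", "\\")) {
      if (!is.null(pending)) fail("two bond symbols in a row")
      pending <- c0
      i <- i + 1L
    } else if (c0 == "(") {
      if (is.na(prev)) fail("branch before any atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (c0 == ")") {
      if (!length(stack)) fail("unbalanced ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", c0)) {
      ring_event(as.integer(c0))
      i <- i + 1L
    } else if (c0 == "%") {
      if (i + 2L > n || !grepl("[0-9]", ch[i + 1L]) || !grepl("[0-9]", ch[i + 2L])) {
        fail("bad %nn ring closure")
      }
      ring_event(as.integer(paste0(ch[i + 1L], ch[i + 2L])))
      i <- i + 3L
    } else if (c0 == ".") {
      prev <- NA_integer_
      pending <- NULL
      i <- i + 1L
    } else {
      fail(sprintf("unexpected character '%s' at position %d", c0, i))
    }
  }
  if (length(stack)) fail("unbalanced '('")
  if (length(rings)) fail("unmatched ring-closure digit")
  if (!is.null(pending)) fail("dangling bond symbol")
  if (!length(elem)) fail("no atoms")

  g <- new_mol_graph(
    data.frame(elem = elem, arom = arom, charge = charge, hcount = hcount),
    data.frame(a1 = b1, a2 = b2, order = bord, arom = barom)
  )
  # An aromatic bond must lie in a ring; a default bond between two aromatic
  # atoms across a ring-ring junction (biphenyl) is a single bond.
  if (any(g$bonds$arom)) {
    ring <- ring_membership(g)$bond
    demote <- g$bonds$arom & !ring
    if (any(demote)) {
      g$bonds$arom[demote] <- FALSE
      g$bonds$order[demote] <- 1L
    }
  }
  g
}

# Bond-order sum per atom, counting aromatic bonds as 1.5, rounded up.
atom_bond_valence <- function(g) {
  v <- numeric(n_atoms(g))
  if (nrow(g$bonds)) {
    w <- ifelse(g$bonds$arom, 1.5, g$bonds$order)
    for (k in seq_len(nrow(g$bonds))) {
      v[g$bonds$a1[k]] <- v[g$bonds$a1[k]] + w[k]
      v[g$bonds$a2[k]] <- v[g$bonds$a2[k]] + w[k]
    }
  }
  as.integer(ceiling(v - 1e-9))
}

implicit_h_for <- function(elem, charge, bondsum) {
  vals <- STANDARD_VALENCES[[elem]]
  if (is.null(vals)) return(0L)
  if (charge != 0L) {
    if (elem %in% c("N", "P") && charge > 0L) vals <- vals + charge
    else if (elem %in% c("O", "S") && charge < 0L) vals <- pmax(vals + charge, 0L)
    else if (elem == "C") vals <- vals - abs(charge)
    else return(0L)
  }
  ok <- vals[vals >= bondsum]
  if (!length(ok)) return(0L)
  as.integer(ok[1] - bondsum)
}

# Total hydrogen count per atom (explicit bracket count, or valence-implied).
total_h <- function(g) {
  bs <- atom_bond_valence(g)
  h <- g$atoms$hcount
  need <- is.na(h)
  if (any(need)) {
    h[need] <- mapply(implicit_h_for, g$atoms$elem[need], g$atoms$charge[need],
                      bs[need])
  }
  as.integer(h)
}

atom_degree <- function(g) {
  d <- integer(n_atoms(g))
  if (nrow(g$bonds)) {
    t1 <- tabulate(g$bonds$a1, nbins = n_atoms(g))
    t2 <- tabulate(g$bonds$a2, nbins = n_atoms(g))
    d <- t1 + t2
  }
  d
}

adjacency_list <- function(g) {
  adj <- vector("list", n_atoms(g))
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a1[k]; b <- g$bonds$a2[k]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

# Ring membership via bridge detection (an edge is in a ring iff it is not a
# bridge); atoms are in a ring iff incident to a ring edge.
ring_membership <- function(g) {
  na <- n_atoms(g)
  if (!nrow(g$bonds)) {
    return(list(bond = logical(0), atom = logical(na)))
  }
  ig <- igraph::graph_from_edgelist(as.matrix(g$bonds[, c("a1", "a2")]),
                                    directed = FALSE)
  if (igraph::vcount(ig) < na) ig <- igraph::add_vertices(ig, na - igraph::vcount(ig))
  br <- igraph::bridges(ig)
  bond_ring <- !(seq_len(nrow(g$bonds)) %in% as.integer(br))
  atom_ring <- logical(na)
  if (any(bond_ring)) {
    atom_ring[unique(c(g$bonds$a1[bond_ring], g$bonds$a2[bond_ring]))] <- TRUE
  }
  list(bond = bond_ring, atom = atom_ring)
}

graph_components <- function(g) {
  adj <- adjacency_list(g)
  seen <- logical(n_atoms(g))
  comps <- list()
  for (s in seq_len(n_atoms(g))) {
    if (seen[s]) next
    q <- s; seen[s] <- TRUE; comp <- integer()
    while (length(q)) {
      a <- q[1]; q <- q[-1]
      comp <- c(comp, a)
      for (b in adj[[a]]) if (!seen[b]) { seen[b] <- TRUE; q <- c(q, b) }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

subgraph_atoms <- function(g, atoms) {
  idx <- match(seq_len(n_atoms(g)), atoms)
  atab <- g$atoms[atoms, , drop = FALSE]
  rownames(atab) <- NULL
  if (nrow(g$bonds)) {
    keep <- !is.na(idx[g$bonds$a1]) & !is.na(idx[g$bonds$a2])
    bonds <- g$bonds[keep, , drop = FALSE]
    bonds$a1 <- idx[bonds$a1]; bonds$a2 <- idx[bonds$a2]
    rownames(bonds) <- NULL
  } else {
    bonds <- empty_bonds()
  }
  new_mol_graph(atab, bonds)
}

# Topological (bond count) distance from a set of atoms; Inf if disconnected.
graph_distance_to_set <- function(g, site) {
  adj <- adjacency_list(g)
  d <- rep(Inf, n_atoms(g))
  d[site] <- 0
  q <- site
  while (length(q)) {
    a <- q[1]; q <- q[-1]
    for (b in adj[[a]]) {
      if (d[b] > d[a] + 1) { d[b] <- d[a] + 1; q <- c(q, b) }
    }
  }
  d
}

atom_token <- function(g, i, h, bs) {
  e <- g$atoms$elem[i]
  ar <- g$atoms$arom[i]
  q <- g$atoms$charge[i]
  sym <- if (ar) tolower(e) else e
  bare_ok <- e %in% ORGANIC_SUBSET && q == 0L &&
    implicit_h_for(e, 0L, bs[i]) == h
  if (bare_ok) return(sym)
  qtok <- if (q > 0L) paste0("+", if (q > 1L) q else "") else
    if (q < 0L) paste0("-", if (q < -1L) abs(q) else "") else ""
  htok <- if (h == 1L) "H" else if (h > 1L) paste0("H", h) else ""
  paste0("[", sym, htok, qtok, "]")
}

bond_token <- function(g, k) {
  if (g$bonds$arom[k]) return("")
  o <- g$bonds$order[k]
  if (o == 2L) return("=")
  if (o == 3L) return("#")
  # explicit single between two aromatic atoms (e.g. biphenyl)
  if (g$atoms$arom[g$bonds$a1[k]] && g$atoms$arom[g$bonds$a2[k]]) return("-")
  ""
}

#' @noRd
write_smiles_graph <- function(g, visit_rank = NULL) {
  na <- n_atoms(g)
  if (is.null(visit_rank)) visit_rank <- seq_len(na)
  hs <- total_h(g)
  bs <- atom_bond_valence(g)
  # bond lookup
  bkey <- new.env(parent = emptyenv())
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      assign(paste(g$bonds$a1[k], g$bonds$a2[k]), k, envir = bkey)
      assign(paste(g$bonds$a2[k], g$bonds$a1[k]), k, envir = bkey)
    }
  }
  adj <- adjacency_list(g)
  adj <- lapply(adj, function(v) v[order(visit_rank[v])])
  visited <- logical(na)
  ring_counter <- 0L
  ring_open <- list()   # atom -> character vector of tokens to append
  ring_seen <- new.env(parent = emptyenv())  # "a b" pairs already assigned
  pieces <- character()

  # Pre-walk to find ring-closure edges and assign digits.
  assign_rings <- function(root) {
    st <- list(list(a = root, parent = NA_integer_))
    pre_visited <- logical(na)
    while (length(st)) {
      top <- st[[length(st)]]; st[[length(st)]] <- NULL
      a <- top$a
      if (pre_visited[a]) next
      pre_visited[a] <- TRUE
      nb <- adj[[a]]
      for (b in rev(nb)) {
        if (identical(b, top$parent)) next
        if (pre_visited[b]) {
          key <- paste(min(a, b), max(a, b))
          if (is.null(ring_seen[[key]])) {
            ring_counter <<- ring_counter + 1L
            ring_seen[[key]] <- ring_counter
          }
        } else {
          st[[length(st) + 1L]] <- list(a = b, parent = a)
        }
      }
    }
  }

  emit <- function(a, from_bond) {
    out <- if (is.na(from_bond)) "" else bond_token(g, from_bond)
    out <- paste0(out, atom_token(g, a, hs[a], bs))
    visited[a] <<- TRUE
    # ring closure digits at this atom
    nb <- adj[[a]]
    closure_tokens <- character()
    children <- integer()
    for (b in nb) {
      key <- paste(min(a, b), max(a, b))
      num <- ring_seen[[key]]
      if (!is.null(num)) {
        k <- get(paste(a, b), envir = bkey)
        tok <- if (num > 9L) paste0("%", num) else as.character(num)
        # bond symbol on the opening occurrence only
        if (!isTRUE(attr(ring_seen[[key]], "opened"))) {
          tok <- paste0(bond_token(g, k), tok)
          v <- ring_seen[[key]]; attr(v, "opened") <- TRUE
          ring_seen[[key]] <<- v
        }
        closure_tokens <- c(closure_tokens, tok)
      } else if (!visited[b]) {
        children <- c(children, b)
      }
    }
    out <- paste0(out, paste(closure_tokens, collapse = ""))
    if (length(children)) {
      # children may have been visited by an earlier sibling subtree
      children <- children[!visited[children]]
      nc <- length(children)
      for (ci in seq_along(children)) {
        b <- children[ci]
        if (visited[b]) next
        k <- get(paste(a, b), envir = bkey)
        sub <- emit(b, k)
        if (ci < nc) sub <- paste0("(", sub, ")")
        out <- paste0(out, sub)
      }
    }
    out
  }

  roots <- order(visit_rank)
  for (r in roots) {
    if (visited[r]) next
    assign_rings(r)
    pieces <- c(pieces, emit(r, NA_integer_))
  }
  paste(pieces, collapse = ".")
}

molecular_formula <- function(g) {
  hs <- total_h(g)
  counts <- tapply(rep(1L, n_atoms(g)), g$atoms$elem, sum)
  counts <- counts[order(names(counts))]
  htot <- sum(hs)
  parts <- character()
  if (!is.na(counts["C"])) {
    parts <- c(parts, paste0("C", if (counts["C"] > 1) counts["C"] else ""))
    counts <- counts[names(counts) != "C"]
  }
  if (htot > 0) parts <- c(parts, paste0("H", if (htot > 1) htot else ""))
  for (e in names(counts)) {
    parts <- c(parts, paste0(e, if (counts[e] > 1) counts[e] else ""))
  }
  paste(parts, collapse = "")
}
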