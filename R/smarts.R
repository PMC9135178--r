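# SMARTS-subset pattern engine and reaction-transform applicator.
#
# Supported atom primitives: element symbols (aliphatic uppercase / aromatic
# lowercase), #n atomic number, a / A / *, Xn (total connections), Dn (heavy
# degree), Hn (total hydrogen count), R / R0 (ring membership), +/- charge,
# :n atom maps. Logical operators !, & (and high), , (or), ; (and low).
# Bond expressions: - = # : ~ and the single-or-aromatic default.
# Not supported (load-time error): recursive $(...), stereo, isotope
# constraints, component-level grouping.

smarts_error <- function(smarts, why) {
  abort_ncm("smarts_error", sprintf("invalid SMARTS '%s': %s", smarts, why),
            smarts = smarts)
}

prim <- function(kind, value = NULL) list(op = "prim", kind = kind, value = value)

# --- atom expression parsing (inside or outside brackets) -------------------

# Parses the bracket body (without []) into an expression tree plus map.
parse_atom_expr <- function(body, smarts) {
  pos <- 1L
  nb <- nchar(body)
  map <- NA_integer_
  peek <- function() if (pos <= nb) substr(body, pos, pos) else ""
  take <- function() { c0 <- peek(); pos <<- pos + 1L; c0 }
  digits <- function() {
    d <- ""
    while (grepl("^[0-9]$", peek())) d <- paste0(d, take())
    d
  }
  parse_primary <- function() {
    c0 <- peek()
    if (c0 == "!") { take(); return(list(op = "not", x = parse_primary())) }
    if (c0 == "$") smarts_error(smarts, "recursive SMARTS $(...) not supported")
    if (c0 == "#") {
      take(); d <- digits()
      if (!nzchar(d)) smarts_error(smarts, "# without atomic number")
      num <- as.integer(d)
      sym <- names(ELEMENT_NUMBERS)[match(num, ELEMENT_NUMBERS)]
      if (is.na(sym)) smarts_error(smarts, paste("unknown atomic number", num))
      return(prim("elem", sym))
    }
    if (c0 == "*") { take(); return(prim("any")) }
    if (c0 == "a") { take(); return(prim("arom", TRUE)) }
    if (c0 == "A") { take(); return(prim("arom", FALSE)) }
    if (c0 == "X") { take(); d <- digits()
      return(prim("X", if (nzchar(d)) as.integer(d) else 1L)) }
    if (c0 == "D") { take(); d <- digits()
      return(prim("D", if (nzchar(d)) as.integer(d) else 1L)) }
    if (c0 == "H") { take(); d <- digits()
      return(prim("H", if (nzchar(d)) as.integer(d) else 1L)) }
    if (c0 == "R") { take(); d <- digits()
      if (nzchar(d) && as.integer(d) == 0L) return(prim("ring", FALSE))
      return(prim("ring", TRUE)) }
    if (c0 %in% c("+", "-")) {
      sgn <- if (c0 == "+") 1L else -1L
      take(); d <- digits()
      reps <- 1L
      while (peek() == c0) { reps <- reps + 1L; take() }
      return(prim("charge", sgn * (if (nzchar(d)) as.integer(d) else reps)))
    }
    if (c0 == "@") { take(); while (peek() == "@") take(); return(prim("any")) }
    # element symbol
    two <- if (pos + 1L <= nb) substr(body, pos, pos + 1L) else ""
    if (two %in% c("Cl", "Br", "Se", "Si", "As", "Na", "Mg", "Ca", "Fe", "Zn")) {
      pos <<- pos + 2L
      return(list(op = "and",
                  xs = list(prim("elem", two), prim("arom", FALSE))))
    }
    if (grepl("^[A-Z]$", c0) && c0 %in% names(ELEMENT_NUMBERS)) {
      take()
      return(list(op = "and", xs = list(prim("elem", c0), prim("arom", FALSE))))
    }
    if (c0 %in% AROMATIC_SYMBOLS) {
      take()
      return(list(op = "and",
                  xs = list(prim("elem", toupper(c0)), prim("arom", TRUE))))
    }
    smarts_error(smarts, sprintf("unsupported atom primitive '%s'", c0))
  }
  parse_and_high <- function() {
    xs <- list(parse_primary())
    repeat {
      c0 <- peek()
      if (c0 == "&") { take(); xs[[length(xs) + 1L]] <- parse_primary() }
      else if (!c0 %in% c("", ",", ";", ":")) {
        xs[[length(xs) + 1L]] <- parse_primary()  # juxtaposition = and
      } else break
    }
    if (length(xs) == 1L) xs[[1]] else list(op = "and", xs = xs)
  }
  parse_or <- function() {
    xs <- list(parse_and_high())
    while (peek() == ",") { take(); xs[[length(xs) + 1L]] <- parse_and_high() }
    if (length(xs) == 1L) xs[[1]] else list(op = "or", xs = xs)
  }
  parse_and_low <- function() {
    xs <- list(parse_or())
    while (peek() == ";") { take(); xs[[length(xs) + 1L]] <- parse_or() }
    if (length(xs) == 1L) xs[[1]] else list(op = "and", xs = xs)
  }
  expr <- parse_and_low()
  if (peek() == ":") {
    take(); d <- digits()
    if (!nzchar(d)) smarts_error(smarts, "atom map ':' without number")
    map <- as.integer(d)
  }
  if (pos <= nb) {
    smarts_error(smarts, sprintf("trailing '%s' in bracket atom",
                                 substr(body, pos, nb)))
  }
  list(expr = expr, map = map)
}

# --- full pattern parsing ---------------------------------------------------

#' @noRd
parse_smarts_pattern <- function(smarts) {
  ch <- strsplit(smarts, "", fixed = TRUE)[[1]]
  n <- length(ch)
  atoms <- list()          # list(expr, map)
  b1 <- integer(); b2 <- integer(); bsym <- character()  # NA = default
  prev <- NA_integer_
  pending <- NA_character_
  stack <- integer()
  rings <- list()
  ncomp <- 1L
  comp_of <- integer()

  add_atom <- function(expr, map) {
    atoms[[length(atoms) + 1L]] <<- list(expr = expr, map = map)
    comp_of[length(atoms)] <<- ncomp
    length(atoms)
  }
  add_bond <- function(a, b, sym) {
    b1[length(b1) + 1L] <<- a; b2[length(b2) + 1L] <<- b
    bsym[length(bsym) + 1L] <<- sym
  }
  connect <- function(idx) {
    if (!is.na(prev)) add_bond(prev, idx, pending)
    pending <<- NA_character_
    prev <<- idx
  }
  ring_event <- function(num) {
    key <- as.character(num)
    if (is.null(rings[[key]])) {
      if (is.na(prev)) smarts_error(smarts, "ring closure before any atom")
      rings[[key]] <<- list(atom = prev, sym = pending)
      pending <<- NA_character_
    } else {
      open <- rings[[key]]
      sym <- pending
      if (is.na(sym)) sym <- open$sym
      add_bond(open$atom, prev, sym)
      rings[[key]] <<- NULL
      pending <<- NA_character_
    }
  }

  i <- 1L
  while (i <= n) {
    c0 <- ch[i]
    if (c0 == "[") {
      depth <- 1L; j <- i + 1L
      while (j <= n && depth > 0L) {
        if (ch[j] == "[") depth <- depth + 1L
        if (ch[j] == "]") depth <- depth - 1L
        if (depth > 0L) j <- j + 1L
      }
      if (j > n) smarts_error(smarts, "unterminated bracket atom")
      body <- substr(smarts, i + 1L, j - 1L)
      pa <- parse_atom_expr(body, smarts)
      connect(add_atom(pa$expr, pa$map))
      i <- j + 1L
    } else if (c0 %in% c("C", "B") && i < n && paste0(c0, ch[i + 1L]) %in% c("Cl", "Br")) {
      e <- paste0(c0, ch[i + 1L])
      connect(add_atom(list(op = "and",
                            xs = list(prim("elem", e), prim("arom", FALSE))),
                       NA_integer_))
      i <- i + 2L
    } else if (c0 %in% ORGANIC_SUBSET) {
      connect(add_atom(list(op = "and",
                            xs = list(prim("elem", c0), prim("arom", FALSE))),
                       NA_integer_))
      i <- i + 1L
    } else if (c0 %in% AROMATIC_SYMBOLS) {
      connect(add_atom(list(op = "and",
                            xs = list(prim("elem", toupper(c0)),
                                      prim("arom", TRUE))),
                       NA_integer_))
      i <- i + 1L
    } else if (c0 == "a") {
      connect(add_atom(prim("arom", TRUE), NA_integer_)); i <- i + 1L
    } else if (c0 == "A") {
      connect(add_atom(prim("arom", FALSE), NA_integer_)); i <- i + 1L
    } else if (c0 == "*") {
      connect(add_atom(prim("any"), NA_integer_)); i <- i + 1L
    } else if (c0 %in% c("-", "=", "#", ":", "~")) {
      if (!is.na(pending)) smarts_error(smarts, "two bond symbols in a row")
      pending <- c0
      i <- i + 1L
    } else if (c0 == "(") {
      if (is.na(prev)) smarts_error(smarts, "branch before any atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (c0 == ")") {
      if (!length(stack)) smarts_error(smarts, "unbalanced ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", c0)) {
      ring_event(as.integer(c0)); i <- i + 1L
    } else if (c0 == "%") {
      if (i + 2L > n) smarts_error(smarts, "bad %nn ring closure")
      ring_event(as.integer(paste0(ch[i + 1L], ch[i + 2L])))
      i <- i + 3L
    } else if (c0 == ".") {
      prev <- NA_integer_; pending <- NA_character_
      ncomp <- ncomp + 1L
      i <- i + 1L
    } else if (c0 == "$") {
      smarts_error(smarts, "recursive SMARTS $(...) not supported")
    } else {
      smarts_error(smarts, sprintf("unexpected character '%s'", c0))
    }
  }
  if (length(stack)) smarts_error(smarts, "unbalanced '('")
  if (length(rings)) smarts_error(smarts, "unmatched ring-closure digit")
  if (!length(atoms)) smarts_error(smarts, "no atoms")
  structure(list(
    atoms = atoms,
    bonds = data.frame(a1 = b1, a2 = b2, sym = bsym, stringsAsFactors = FALSE),
    comp_of = comp_of,
    smarts = smarts
  ), class = "smarts_pattern")
}

# --- matching ---------------------------------------------------------------

# Per-atom match properties, computed once per molecule.
mol_match_props <- function(g) {
  deg <- atom_degree(g)
  th <- total_h(g)
  ring <- ring_membership(g)
  list(
    elem = g$atoms$elem,
    arom = g$atoms$arom,
    charge = g$atoms$charge,
    degree = deg,
    totalh = th,
    X = deg + th,
    inring = ring$atom,
    bond_ring = ring$bond
  )
}

eval_atom_expr <- function(expr, props, i) {
  switch(expr$op,
    prim = switch(expr$kind,
      any = TRUE,
      elem = props$elem[i] == expr$value,
      arom = props$arom[i] == expr$value,
      X = props$X[i] == expr$value,
      D = props$degree[i] == expr$value,
      H = props$totalh[i] == expr$value,
      ring = props$inring[i] == expr$value,
      charge = props$charge[i] == expr$value,
      FALSE),
    "not" = !eval_atom_expr(expr$x, props, i),
    "and" = all(vapply(expr$xs, eval_atom_expr, logical(1), props = props, i = i)),
    "or" = any(vapply(expr$xs, eval_atom_expr, logical(1), props = props, i = i)),
    FALSE
  )
}

bond_expr_match <- function(sym, order, arom) {
  if (is.na(sym)) return(arom || order == 1L)
  switch(sym,
    "-" = !arom && order == 1L,
    "=" = !arom && order == 2L,
    "#" = !arom && order == 3L,
    ":" = arom,
    "~" = TRUE,
    FALSE)
}

# All embeddings of a connected pattern into a molecule graph.
# Returns a matrix, one row per match, column j = molecule atom for pattern
# atom j; zero rows when unmatched.
#' @noRd
match_smarts <- function(pattern, g, props = NULL) {
  if (is.null(props)) props <- mol_match_props(g)
  np <- length(pattern$atoms)
  na <- n_atoms(g)
  if (na == 0L) return(matrix(integer(), 0, np))

  # candidate atoms per pattern atom
  cand <- lapply(pattern$atoms, function(a) {
    which(vapply(seq_len(na), function(i) eval_atom_expr(a$expr, props, i),
                 logical(1)))
  })
  if (any(!lengths(cand))) return(matrix(integer(), 0, np))

  # pattern adjacency
  padj <- vector("list", np)
  if (nrow(pattern$bonds)) {
    for (k in seq_len(nrow(pattern$bonds))) {
      a <- pattern$bonds$a1[k]; b <- pattern$bonds$a2[k]
      padj[[a]] <- rbind(padj[[a]], c(b, k))
      padj[[b]] <- rbind(padj[[b]], c(a, k))
    }
  }
  # visit order: DFS over the pattern graph (pattern must be connected)
  porder <- integer(0); seen <- logical(np)
  st <- 1L
  while (length(st)) {
    a <- st[length(st)]; st <- st[-length(st)]
    if (seen[a]) next
    seen[a] <- TRUE
    porder <- c(porder, a)
    if (!is.null(padj[[a]])) st <- c(st, rev(padj[[a]][, 1]))
  }
  if (any(!seen)) {
    smarts_error(pattern$smarts, "pattern template must be connected")
  }

  # molecule adjacency + bond lookup
  madj <- adjacency_list(g)
  bidx <- new.env(parent = emptyenv())
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      assign(paste(g$bonds$a1[k], g$bonds$a2[k]), k, envir = bidx)
      assign(paste(g$bonds$a2[k], g$bonds$a1[k]), k, envir = bidx)
    }
  }
  mol_bond <- function(a, b) {
    k <- bidx[[paste(a, b)]]
    if (is.null(k)) NULL else k
  }

  results <- list()
  assignment <- integer(np)
  used <- logical(na)

  search <- function(step) {
    if (step > np) {
      results[[length(results) + 1L]] <<- assignment
      return(invisible())
    }
    pa <- porder[step]
    anchors <- NULL
    if (!is.null(padj[[pa]])) {
      for (r in seq_len(nrow(padj[[pa]]))) {
        nb <- padj[[pa]][r, 1]
        if (assignment[nb] != 0L) anchors <- rbind(anchors, padj[[pa]][r, ])
      }
    }
    if (is.null(anchors)) {
      pool <- cand[[pa]]
    } else {
      pool <- intersect(madj[[assignment[anchors[1, 1]]]], cand[[pa]])
    }
    for (ma in pool) {
      if (used[ma]) next
      ok <- TRUE
      if (!is.null(anchors)) {
        for (r in seq_len(nrow(anchors))) {
          mb <- assignment[anchors[r, 1]]
          k <- mol_bond(ma, mb)
          if (is.null(k) ||
              !bond_expr_match(pattern$bonds$sym[anchors[r, 2]],
                               g$bonds$order[k], g$bonds$arom[k])) {
            ok <- FALSE; break
          }
        }
      }
      if (!ok) next
      assignment[pa] <<- ma
      used[ma] <<- TRUE
      search(step + 1L)
      assignment[pa] <<- 0L
      used[ma] <<- FALSE
    }
    invisible()
  }
  search(1L)
  if (!length(results)) return(matrix(integer(), 0, np))
  do.call(rbind, results)
}

# --- reaction transforms ----------------------------------------------------

# Collect the top-level AND primitives of a product-template atom expression.
flat_prims <- function(expr) {
  if (expr$op == "prim") return(list(expr))
  if (expr$op == "and") return(do.call(c, lapply(expr$xs, flat_prims)))
  list()
}

product_atom_spec <- function(expr) {
  ps <- flat_prims(expr)
  spec <- list(elem = NA_character_, arom = NA, hcount = NA_integer_,
               charge = NA_integer_)
  for (p in ps) {
    if (p$kind == "elem") spec$elem <- p$value
    if (p$kind == "arom") spec$arom <- p$value
    if (p$kind == "H") spec$hcount <- p$value
    if (p$kind == "charge") spec$charge <- p$value
  }
  spec
}

#' @noRd
parse_reaction_smarts <- function(rxn_smarts) {
  sides <- strsplit(rxn_smarts, ">>", fixed = TRUE)[[1]]
  if (length(sides) != 2L) {
    smarts_error(rxn_smarts, "reaction SMARTS must contain exactly one '>>'")
  }
  reactant <- parse_smarts_pattern(sides[1])
  if (max(reactant$comp_of) > 1L) {
    smarts_error(rxn_smarts, "only single-reactant templates are supported")
  }
  product <- parse_smarts_pattern(sides[2])
  rmaps <- vapply(reactant$atoms, function(a) a$map, integer(1))
  pmaps <- vapply(product$atoms, function(a) a$map, integer(1))
  rm <- rmaps[!is.na(rmaps)]
  pm <- pmaps[!is.na(pmaps)]
  if (anyDuplicated(rm)) smarts_error(rxn_smarts, "duplicate reactant atom map")
  if (anyDuplicated(pm)) smarts_error(rxn_smarts, "duplicate product atom map")
  if (length(setdiff(pm, rm))) {
    smarts_error(rxn_smarts, "product atom map absent from reactant template")
  }
  # product atoms without a map are new atoms and need a concrete element
  for (j in seq_along(product$atoms)) {
    if (is.na(pmaps[j])) {
      spec <- product_atom_spec(product$atoms[[j]]$expr)
      if (is.na(spec$elem)) {
        smarts_error(rxn_smarts, "unmapped product atom without an element")
      }
    }
  }
  structure(list(reactant = reactant, product = product,
                 rmaps = rmaps, pmaps = pmaps, smarts = rxn_smarts),
            class = "reaction_smarts")
}

product_bond_order <- function(sym, arom_pair) {
  if (is.na(sym)) {
    if (arom_pair) return(list(order = 1L, arom = TRUE))
    return(list(order = 1L, arom = FALSE))
  }
  switch(sym,
    "-" = list(order = 1L, arom = FALSE),
    "=" = list(order = 2L, arom = FALSE),
    "#" = list(order = 3L, arom = FALSE),
    ":" = list(order = 1L, arom = TRUE),
    list(order = 1L, arom = FALSE))
}

# Apply one reaction match; returns the edited (possibly multi-fragment)
# graph, or NULL if the edit is degenerate.
apply_reaction_match <- function(g, rxn, m) {
  na <- n_atoms(g)
  atoms <- g$atoms
  bonds <- g$bonds
  rmaps <- rxn$rmaps; pmaps <- rxn$pmaps
  # reactant pattern atom -> product pattern atom (0 = none)
  r2p <- integer(length(rmaps))
  for (i in seq_along(rmaps)) {
    r2p[i] <- if (is.na(rmaps[i])) 0L else {
      j <- match(rmaps[i], pmaps)
      if (is.na(j)) 0L else j
    }
  }
  keep <- rep(TRUE, na)
  changed <- rep(FALSE, na)
  keep[m[r2p == 0L]] <- FALSE

  bond_key <- function(a, b) paste(min(a, b), max(a, b))
  bmap <- new.env(parent = emptyenv())
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) assign(bond_key(bonds$a1[k], bonds$a2[k]), k, envir = bmap)
  }
  # product template bonds indexed by product-atom pair
  pb <- rxn$product$bonds
  pbond <- new.env(parent = emptyenv())
  if (nrow(pb)) {
    for (k in seq_len(nrow(pb))) assign(bond_key(pb$a1[k], pb$a2[k]), k, envir = pbond)
  }

  drop_bond <- integer()
  # 1. bonds between mapped reactant atoms: delete or retype per product
  rb <- rxn$reactant$bonds
  if (nrow(rb)) {
    for (k in seq_len(nrow(rb))) {
      i1 <- rb$a1[k]; i2 <- rb$a2[k]
      if (r2p[i1] == 0L || r2p[i2] == 0L) next  # deleted atom takes its bonds
      a <- m[i1]; b <- m[i2]
      kb <- bmap[[bond_key(a, b)]]
      if (is.null(kb)) next
      kp <- pbond[[bond_key(r2p[i1], r2p[i2])]]
      if (is.null(kp)) {
        drop_bond <- c(drop_bond, kb)
        changed[c(a, b)] <- TRUE
      } else {
        arom_pair <- atoms$arom[a] && atoms$arom[b]
        po <- product_bond_order(pb$sym[kp], arom_pair)
        if (po$order != bonds$order[kb] || po$arom != bonds$arom[kb]) {
          bonds$order[kb] <- po$order
          bonds$arom[kb] <- po$arom
          changed[c(a, b)] <- TRUE
        }
      }
    }
  }

  # 2. new product atoms
  p2mol <- integer(length(pmaps))
  for (j in seq_along(pmaps)) {
    if (!is.na(pmaps[j])) {
      i <- match(pmaps[j], rmaps)
      p2mol[j] <- m[i]
    }
  }
  for (j in seq_along(pmaps)) {
    if (p2mol[j] == 0L) {
      spec <- product_atom_spec(rxn$product$atoms[[j]]$expr)
      atoms <- rbind(atoms, data.frame(
        elem = spec$elem,
        arom = isTRUE(spec$arom),
        charge = if (is.na(spec$charge)) 0L else spec$charge,
        hcount = spec$hcount
      ))
      keep <- c(keep, TRUE)
      changed <- c(changed, FALSE)
      p2mol[j] <- nrow(atoms)
    }
  }

  # 3. product bonds not covered in step 1 (new-atom bonds, or bonds between
  # mapped atoms that the reactant template left unbonded)
  if (nrow(pb)) {
    for (k in seq_len(nrow(pb))) {
      a <- p2mol[pb$a1[k]]; b <- p2mol[pb$a2[k]]
      kb <- if (a <= na && b <= na) bmap[[bond_key(a, b)]] else NULL
      arom_pair <- atoms$arom[a] && atoms$arom[b]
      po <- product_bond_order(pb$sym[k], arom_pair)
      if (is.null(kb)) {
        bonds <- rbind(bonds, data.frame(a1 = a, a2 = b, order = po$order,
                                         arom = po$arom))
        if (a <= na) changed[a] <- TRUE
        if (b <= na) changed[b] <- TRUE
      }
    }
  }

  # 4. explicit H / charge on mapped product atoms; recompute implicit H on
  # any atom whose bonding changed
  for (j in seq_along(pmaps)) {
    if (is.na(pmaps[j])) next
    a <- p2mol[j]
    spec <- product_atom_spec(rxn$product$atoms[[j]]$expr)
    if (!is.na(spec$hcount)) {
      atoms$hcount[a] <- spec$hcount
    } else if (changed[a]) {
      atoms$hcount[a] <- NA_integer_
    }
    if (!is.na(spec$charge)) atoms$charge[a] <- spec$charge
  }
  if (length(drop_bond)) bonds <- bonds[-drop_bond, , drop = FALSE]
  # drop bonds touching deleted atoms, then reindex
  if (nrow(bonds)) {
    bonds <- bonds[keep[bonds$a1] & keep[bonds$a2], , drop = FALSE]
  }
  old2new <- cumsum(keep)
  old2new[!keep] <- NA_integer_
  if (nrow(bonds)) {
    bonds$a1 <- old2new[bonds$a1]
    bonds$a2 <- old2new[bonds$a2]
  }
  atoms <- atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  rownames(bonds) <- NULL
  if (!nrow(atoms)) return(NULL)
  new_mol_graph(atoms, bonds)
}
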