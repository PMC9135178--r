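# Candidate metabolite generation: apply reaction rules to a parent molecule
# and build the deduplicated candidate pool with provenance.

candidate_columns <- function() {
  c("product_smiles", "canonical_key", "rule_id", "category", "site_atoms",
    "heavy_atoms")
}

empty_candidates <- function() {
  data.frame(product_smiles = character(), canonical_key = character(),
             rule_id = character(), category = character(),
             site_atoms = character(), heavy_atoms = integer(),
             stringsAsFactors = FALSE)
}

#' Apply one reaction rule to a parent molecule
#'
#' Enumerates every embedding of the rule's reactant template in the parent,
#' performs the bond edits of the product template, splits multi-fragment
#' products and keeps each organic fragment with at least two heavy atoms.
#' Products that fail sanitization are dropped with a warning; products
#' identical to the parent are excluded. One row is returned per distinct
#' (product identity key, reaction-site atom set).
#'
#' @param parent An `nc_molecule` (or SMILES string).
#' @param rule A single rule from an `nc_ruleset`.
#' @return A data frame with columns `product_smiles`, `canonical_key`,
#'   `rule_id`, `category`, `site_atoms` (comma-separated parent atom indices
#'   matched by the reactant template), `heavy_atoms`. Zero rows when the
#'   rule does not apply.
#' @export
#' @examples
#' rs <- default_ruleset()
#' apply_rule(parse_molecule("CCOC(C)=O"), rs$rules$est01)
apply_rule <- function(parent, rule) {
  parent <- as_molecule(parent)
  g <- parent$graph
  props <- mol_match_props(g)
  ms <- match_smarts(rule$rxn$reactant, g, props)
  if (!nrow(ms)) return(empty_candidates())
  rows <- list()
  for (i in seq_len(nrow(ms))) {
    m <- ms[i, ]
    pg <- apply_reaction_match(g, rule$rxn, m)
    if (is.null(pg)) next
    site <- sort(unique(m))
    site_str <- paste(site, collapse = ",")
    for (comp in graph_components(pg)) {
      sg <- subgraph_atoms(pg, comp)
      if (heavy_atom_count_graph(sg) < 2L) next  # leaving group, not a metabolite
      pm <- molecule_from_graph(sg)
      if (is.null(pm)) {
        warning(sprintf("rule %s on %s: product fragment failed sanitization",
                        rule$rule_id, parent$canonical_smiles),
                call. = FALSE)
        next
      }
      if (pm$canonical_key == parent$canonical_key) next  # identity product
      rows[[length(rows) + 1L]] <- data.frame(
        product_smiles = pm$canonical_smiles,
        canonical_key = pm$canonical_key,
        rule_id = rule$rule_id,
        category = rule$category,
        site_atoms = site_str,
        heavy_atoms = pm$heavy_atom_count,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) return(empty_candidates())
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("canonical_key", "site_atoms")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate the deduplicated candidate-metabolite pool
#'
#' Runs every rule of the rule set against the parent (a single metabolic
#' step by default) and merges the results by product identity key. A product
#' reachable through several rules keeps: the full set of producing
#' categories (`categories`, used for ranking), a `provenance_count` of how
#' many rule applications produced it, the minimum steric-hindrance score
#' over all producing reaction sites, and as displayed provenance the rule
#' whose category ranks highest under `order`.
#'
#' @param parent An `nc_molecule` or SMILES string.
#' @param rules An `nc_ruleset`.
#' @param order A group order (see [group_order()]); used only to resolve
#'   displayed provenance for multi-rule products.
#' @param depth Number of metabolic steps (default 1). With `depth > 1` the
#'   rules are re-applied to each product; deeper products keep the steric
#'   score relative to their immediate precursor.
#' @param steric_radius,steric_weight Passed to [steric_hindrance_score()].
#' @return A data frame, one row per distinct product, with the columns of
#'   [apply_rule()] plus `categories` (comma-joined), `provenance_count` and
#'   `steric_score`.
#' @export
generate_candidates <- function(parent, rules, order = default_group_order(),
                                depth = 1L, steric_radius = 3L,
                                steric_weight = NULL) {
  parent <- as_molecule(parent)
  rules <- as_ruleset(rules)
  order <- group_order(order)
  pool <- list()
  for (r in rules$rules) {
    cand <- apply_rule(parent, r)
    if (nrow(cand)) {
      cand$steric_score <- vapply(
        strsplit(cand$site_atoms, ",", fixed = TRUE),
        function(s) steric_hindrance_score(parent, as.integer(s),
                                           radius = steric_radius,
                                           weight = steric_weight),
        numeric(1))
      pool[[length(pool) + 1L]] <- cand
    }
  }
  step1 <- dedup_candidates(if (length(pool)) do.call(rbind, pool) else
    empty_candidates_full(), order)

  if (depth > 1L && nrow(step1)) {
    deeper <- lapply(step1$product_smiles, function(s) {
      generate_candidates(s, rules, order = order, depth = depth - 1L,
                          steric_radius = steric_radius,
                          steric_weight = steric_weight)
    })
    all <- rbind(step1, do.call(rbind, deeper))
    all <- all[all$canonical_key != parent$canonical_key, , drop = FALSE]
    step1 <- dedup_candidates(all, order, prededuped = TRUE)
  }
  step1
}

empty_candidates_full <- function() {
  out <- empty_candidates()
  out$steric_score <- numeric(0)
  out
}

# Merge rows sharing a canonical key. `prededuped` marks input rows that
# already carry categories/provenance_count (depth > 1 merging).
dedup_candidates <- function(cand, order, prededuped = FALSE) {
  if (!nrow(cand)) {
    out <- empty_candidates_full()
    out$categories <- character(0)
    out$provenance_count <- integer(0)
    return(out[, candidate_order_cols()])
  }
  if (!prededuped) {
    cand$categories <- cand$category
    cand$provenance_count <- 1L
  }
  prio <- stats::setNames(seq_along(order), order)
  split_idx <- split(seq_len(nrow(cand)), cand$canonical_key)
  rows <- lapply(split_idx, function(ii) {
    sub <- cand[ii, , drop = FALSE]
    cats <- sort(unique(unlist(strsplit(sub$categories, ",", fixed = TRUE))))
    best_cat <- cats[which.min(prio[cats])]
    # displayed provenance: best-category rows, then least hindered site,
    # then lexicographic rule id (deterministic)
    cat_rows <- sub[sub$category == best_cat, , drop = FALSE]
    if (!nrow(cat_rows)) cat_rows <- sub
    cat_rows <- cat_rows[order(cat_rows$steric_score, cat_rows$rule_id), ,
                         drop = FALSE]
    rep <- cat_rows[1, , drop = FALSE]
    rep$category <- best_cat
    rep$categories <- paste(cats, collapse = ",")
    rep$provenance_count <- sum(sub$provenance_count)
    rep$steric_score <- min(sub$steric_score)
    rep
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$canonical_key), , drop = FALSE]
  rownames(out) <- NULL
  out[, candidate_order_cols()]
}

candidate_order_cols <- function() {
  c("product_smiles", "canonical_key", "rule_id", "category", "categories",
    "site_atoms", "steric_score", "provenance_count", "heavy_atoms")
}
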