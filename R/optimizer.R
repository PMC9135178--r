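# Exhaustive search over the 40,320 orderings of the eight functional-group
# categories. Candidate pools and steric scores are generated once per
# substrate; each ordering only re-sorts, which is exactly equivalent to
# re-running the full prediction (the rank keys - priority tier, steric
# score, canonical key - do not depend on the order except through the tier).

#' Enumerate all orderings of the eight categories
#'
#' @return A 40,320 x 8 character matrix; each row is one permutation of the
#'   category labels, rows in deterministic lexicographic sequence (row 1 is
#'   the alphabetical order).
#' @export
#' @examples
#' nrow(enumerate_orders())  # 40320
enumerate_orders <- function() {
  p <- permutations_lex(8L)
  m <- matrix(group_categories()[p], nrow = nrow(p))
  m
}

# All permutations of 1..n in lexicographic order, one per row.
permutations_lex <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_lex(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    idx <- row:(row + nrow(sub) - 1L)
    out[idx, 1L] <- i
    out[idx, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    row <- row + nrow(sub)
  }
  out
}

# Per-substrate candidate summaries for re-ranking: category-index sets,
# steric scores, canonical keys, and the true metabolite's position.
prepare_rerank_pools <- function(pairs, rules, ...) {
  cats <- group_categories()
  cache <- new.env(parent = emptyenv())
  pools <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    smi <- pairs$substrate_smiles[i]
    if (is.null(cache[[smi]])) {
      cand <- generate_candidates(smi, rules, ...)
      cache[[smi]] <- list(
        key = cand$canonical_key,
        steric = cand$steric_score,
        catsets = lapply(strsplit(cand$categories, ",", fixed = TRUE),
                         function(cc) match(cc, cats)),
        mask_id = vapply(strsplit(cand$categories, ",", fixed = TRUE),
                         function(cc) paste(sort(cc), collapse = "|"),
                         character(1))
      )
    }
    p <- cache[[smi]]
    mk <- canonical_key(pairs$metabolite_smiles[i])
    pools[[i]] <- c(p, list(true_idx = match(mk, p$key)))
  }
  pools
}

# Rank of each pair's true metabolite under every ordering in `pos`
# (a n_orders x 8 priority-position matrix). Returns a list of vectors.
rerank_true_ranks <- function(pools, pos) {
  m <- nrow(pos)
  lapply(pools, function(p) {
    t <- p$true_idx
    if (is.na(t) || !length(p$key)) return(NULL)
    tier_cache <- new.env(parent = emptyenv())
    tier_of <- function(j) {
      id <- p$mask_id[j]
      tv <- tier_cache[[id]]
      if (is.null(tv)) {
        cs <- p$catsets[[j]]
        tv <- pos[, cs[1]]
        if (length(cs) > 1L) for (c2 in cs[-1]) tv <- pmin(tv, pos[, c2])
        tier_cache[[id]] <- tv
      }
      tv
    }
    tt <- tier_of(t)
    rank <- rep(1, m)
    st <- p$steric[t]; kt <- p$key[t]
    for (j in seq_along(p$key)) {
      if (j == t) next
      beats_tie <- p$steric[j] < st ||
        (p$steric[j] == st && p$key[j] < kt)
      tj <- tier_of(j)
      rank <- rank + (tj < tt) + if (beats_tie) (tj == tt) else 0
    }
    rank
  })
}

order_objective_scores <- function(true_ranks, n_total, top_k, m) {
  nhit <- numeric(m); srecip <- numeric(m); top1 <- numeric(m)
  for (rk in true_ranks) {
    if (is.null(rk)) next
    hit <- rk <= top_k
    nhit <- nhit + hit
    srecip <- srecip + ifelse(hit, 1 / rk, 0)
    top1 <- top1 + (rk == 1)
  }
  cs <- ifelse(nhit > 0, 100 * (nhit / n_total) * (srecip / nhit), 0)
  list(cs = cs, top1 = top1, n_hit = nhit)
}

#' Search the orderings of the eight categories for the best ranking order
#'
#' Enumerates all 40,320 permutations (or a seeded random subsample, or an
#' explicit list) and scores each by re-sorting cached candidate pools,
#' returning the argmax with a deterministic lexicographic tie-break.
#'
#' @param pairs A `pair_dataset` (or data frame / CSV path).
#' @param rules An `nc_ruleset`.
#' @param objective `"cs"` (default) or `"top1"` (count of rank-1 hits).
#' @param top_k List cutoff (default 50).
#' @param sample Optional number of orderings to draw at random instead of
#'   the full enumeration.
#' @param seed Seed for the subsample draw (required when `sample` is set).
#' @param orders Optional explicit list of orderings (each acceptable to
#'   [group_order()]) to evaluate instead of the enumeration.
#' @param ... Passed to [generate_candidates()].
#' @return List of class `order_search_result`: `best_order`,
#'   `best_objective`, `objective_name`, `n_orders_evaluated`, and
#'   `per_order_scores` (data frame of every evaluated order and its score).
#' @export
optimize_order <- function(pairs, rules = default_ruleset(),
                           objective = c("cs", "top1"), top_k = 50L,
                           sample = NULL, seed = NULL, orders = NULL, ...) {
  objective <- match.arg(objective)
  if (is.character(pairs) && length(pairs) == 1L) pairs <- load_pairs(pairs)
  if (!inherits(pairs, "pair_dataset")) pairs <- pair_dataset(pairs)
  if (!nrow(pairs)) stop("pair dataset is empty")
  rules <- as_ruleset(rules)

  if (!is.null(orders)) {
    omat <- do.call(rbind, lapply(orders, function(o) unclass(group_order(o))))
  } else {
    omat <- enumerate_orders()
    if (!is.null(sample)) {
      if (is.null(seed)) stop("subsampled search needs an explicit seed")
      idx <- with_preserved_seed(seed, sort(sample.int(nrow(omat), sample)))
      omat <- omat[idx, , drop = FALSE]
    }
  }
  m <- nrow(omat)
  cats <- group_categories()
  pos <- matrix(0L, m, 8L)
  for (k in 1:8) pos[cbind(seq_len(m), match(omat[, k], cats))] <- k

  pools <- prepare_rerank_pools(pairs, rules, ...)
  ranks <- rerank_true_ranks(pools, pos)
  sc <- order_objective_scores(ranks, n_total = nrow(pairs), top_k = top_k,
                               m = m)
  score <- if (objective == "cs") sc$cs else sc$top1
  best <- which.max(score)  # first maximum = lexicographically smallest
  structure(list(
    best_order = group_order(omat[best, ]),
    best_objective = score[best],
    objective_name = objective,
    n_orders_evaluated = m,
    per_order_scores = data.frame(
      order = apply(omat, 1, paste, collapse = " > "),
      score = score, stringsAsFactors = FALSE)
  ), class = "order_search_result")
}

#' @export
print.order_search_result <- function(x, ...) {
  cat(sprintf("<order search> %d order(s) evaluated, objective '%s'\n",
              x$n_orders_evaluated, x$objective_name))
  cat("  best:", paste(unclass(x$best_order), collapse = " > "),
      sprintf(" (score %.4f)\n", x$best_objective))
  invisible(x)
}

#' Compare two priority orders on a dataset
#'
#' Evaluates the dataset under both orders, tabulates Top-N counts side by
#' side and tests the two rank distributions against each other (reciprocal
#' ranks, misses as 0).
#'
#' @param pairs A `pair_dataset`.
#' @param rules An `nc_ruleset`.
#' @param order_a,order_b Orders acceptable to [group_order()].
#' @param top_k List cutoff.
#' @param ... Passed to [evaluate_pairs()].
#' @return List of class `order_comparison`: the two orders verbatim, their
#'   `eval_result`s, a `topn_table`, and the `rank_test`.
#' @export
compare_orders <- function(pairs, rules = default_ruleset(), order_a, order_b,
                           top_k = 50L, ...) {
  order_a <- group_order(order_a); order_b <- group_order(order_b)
  ev_a <- evaluate_pairs(pairs, rules, order = order_a, top_k = top_k, ...)
  ev_b <- evaluate_pairs(pairs, rules, order = order_b, top_k = top_k, ...)
  grid <- names(ev_a$topn_counts)
  topn <- data.frame(N = as.integer(grid),
                     order_a = unname(ev_a$topn_counts),
                     order_b = unname(ev_b$topn_counts))
  structure(list(
    order_a = paste(unclass(order_a), collapse = " > "),
    order_b = paste(unclass(order_b), collapse = " > "),
    eval_a = ev_a, eval_b = ev_b,
    topn_table = topn,
    rank_test = compare_rank_distributions(ev_a$ranks, ev_b$ranks)
  ), class = "order_comparison")
}

#' @export
print.order_comparison <- function(x, ...) {
  cat("<order comparison>\n")
  cat("  A:", x$order_a, sprintf("  CS = %.2f\n", x$eval_a$CS))
  cat("  B:", x$order_b, sprintf("  CS = %.2f\n", x$eval_b$CS))
  print(x$topn_table, row.names = FALSE)
  cat(sprintf("  rank test: t = %.3f, p = %.3g%s\n", x$rank_test$statistic,
              x$rank_test$p_value,
              if (x$rank_test$degenerate) " (degenerate variance)" else ""))
  invisible(x)
}

# Run an expression under a temporary RNG state.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
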