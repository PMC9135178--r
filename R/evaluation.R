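# Evaluation: coverage C, sorting ability S, the combined CS score,
# Top-N tallies, accumulation curves and rank-distribution comparison.

pair_file_error <- function(path, lines, why) {
  abort_ncm("pair_file_error",
            sprintf("pair file '%s': %s (line%s %s)", path, why,
                    if (length(lines) > 1) "s" else "",
                    paste(lines, collapse = ", ")),
            path = path, lines = lines)
}

#' Build a substrate-metabolite pair dataset from a data frame
#'
#' @param df Data frame with columns `substrate_id`, `substrate_smiles`,
#'   `metabolite_smiles` and optionally `evidence`.
#' @param strict If `TRUE` (default) any invalid row (unparsable SMILES, or
#'   substrate and metabolite identical under the canonical key) is an error;
#'   otherwise invalid rows are dropped with a warning.
#' @param source Label used in error messages.
#' @return The validated data frame with an added `evidence` column, class
#'   `pair_dataset`.
#' @export
pair_dataset <- function(df, strict = TRUE, source = "<data.frame>") {
  need <- c("substrate_id", "substrate_smiles", "metabolite_smiles")
  if (!all(need %in% names(df))) {
    pair_file_error(source, 0L,
                    paste("missing column(s):",
                          paste(setdiff(need, names(df)), collapse = ", ")))
  }
  if (!"evidence" %in% names(df)) df$evidence <- ""
  bad <- integer(); why <- character()
  for (i in seq_len(nrow(df))) {
    msg <- tryCatch({
      ks <- canonical_key(df$substrate_smiles[i])
      km <- canonical_key(df$metabolite_smiles[i])
      if (ks == km) "substrate and metabolite are the same structure" else NA
    }, error = function(e) conditionMessage(e))
    if (!is.na(msg)) { bad <- c(bad, i); why <- c(why, msg) }
  }
  if (length(bad)) {
    if (strict) {
      pair_file_error(source, bad + 1L,  # +1: header line of the CSV
                      paste(unique(why), collapse = "; "))
    }
    warning(sprintf("%s: dropped %d invalid pair row(s): %s", source,
                    length(bad), paste(bad, collapse = ", ")), call. = FALSE)
    df <- df[-bad, , drop = FALSE]
  }
  if (!nrow(df)) pair_file_error(source, 0L, "no valid pairs")
  rownames(df) <- NULL
  class(df) <- c("pair_dataset", "data.frame")
  df
}

#' Load a substrate-metabolite pair CSV
#'
#' Expected columns: `substrate_id,substrate_smiles,metabolite_smiles`
#' (optional `evidence`). Offending rows are reported with their line
#' numbers; in strict mode they abort with a `pair_file_error`.
#'
#' @param path CSV file path.
#' @inheritParams pair_dataset
#' @return A `pair_dataset`.
#' @export
load_pairs <- function(path, strict = TRUE) {
  if (!file.exists(path)) pair_file_error(path, 0L, "file does not exist")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  pair_dataset(df, strict = strict, source = path)
}

#' Write a pair dataset to CSV
#' @param pairs A `pair_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.csv(as.data.frame(pairs), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Coverage: fraction of known metabolites recovered
#'
#' @param n_hit Number of correctly predicted known metabolites.
#' @param n_total Total number of known metabolites.
#' @return `n_hit / n_total`.
#' @export
#' @examples
#' coverage(578, 850)  # 0.68
coverage <- function(n_hit, n_total) {
  if (n_total < 1) stop("n_total must be >= 1")
  if (n_hit < 0 || n_hit > n_total) stop("n_hit must be in [0, n_total]")
  n_hit / n_total
}

#' Sorting ability: mean reciprocal rank of the correct metabolites
#'
#' @param hit_ranks Integer ranks (1-based) of each correctly predicted
#'   metabolite in its candidate list.
#' @return `(1/n) * sum(1/rank)` over the hits.
#' @export
#' @examples
#' sorting_ability(c(1, 2, 4))  # 0.58333...
sorting_ability <- function(hit_ranks) {
  if (!length(hit_ranks)) stop("no hits: sorting ability is undefined (report CS = 0)")
  if (any(hit_ranks < 1)) stop("ranks must be >= 1")
  mean(1 / hit_ranks)
}

#' Combined coverage-and-sorting score
#'
#' @param C Coverage in `[0, 1]`.
#' @param S Sorting ability in `[0, 1]`.
#' @return `100 * C * S`, in `[0, 100]`.
#' @export
#' @examples
#' cs_score(0.5, 0.5)  # 25
cs_score <- function(C, S) {
  if (C < 0 || C > 1 || S < 0 || S > 1) stop("C and S must be in [0, 1]")
  100 * C * S
}

topn_grid <- function(top_k) sort(unique(c(1L, 3L, 5L, 10L, 20L, 50L, top_k)))

# Assemble an eval_result from per-pair ranks (NA = miss).
build_eval_result <- function(ranks, n_total, top_k, s_denominator = "hits",
                              per_pair = NULL) {
  ranks[!is.na(ranks) & ranks > top_k] <- NA  # outside the list counts as miss
  hit_ranks <- ranks[!is.na(ranks)]
  n_hit <- length(hit_ranks)
  C <- coverage(n_hit, n_total)
  S <- if (!n_hit) 0 else if (s_denominator == "hits") {
    sorting_ability(hit_ranks)
  } else {
    sum(1 / hit_ranks) / n_total
  }
  grid <- topn_grid(top_k)
  grid <- grid[grid <= top_k]
  topn_counts <- stats::setNames(
    vapply(grid, function(N) sum(hit_ranks <= N), integer(1)),
    as.character(grid))
  structure(list(
    n_total = as.integer(n_total),
    n_hit = as.integer(n_hit),
    C = C, S = S, CS = cs_score(C, S),
    hit_ranks = as.integer(hit_ranks),
    ranks = ranks,
    topn_counts = topn_counts,
    top_k = as.integer(top_k),
    s_denominator = s_denominator,
    per_pair = per_pair
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<evaluation> %d/%d hits  C = %.4f  S = %.4f  CS = %.2f\n",
              x$n_hit, x$n_total, x$C, x$S, x$CS))
  cat("  Top-N counts:",
      paste(sprintf("Top-%s: %d", names(x$topn_counts), x$topn_counts),
            collapse = "  "), "\n")
  invisible(x)
}

#' Evaluate predictions on a pair dataset
#'
#' Runs [predict_metabolites()] on every substrate; a pair is a hit when the
#' known metabolite's identity key appears in the returned top-`top_k` list,
#' and its `Order_i` is the 1-based rank of that candidate.
#'
#' @param pairs A `pair_dataset` (or data frame / CSV path).
#' @param rules An `nc_ruleset`.
#' @param order A [group_order()].
#' @param top_k List cutoff (default 50).
#' @param s_denominator `"hits"` (default): the sorting-ability mean runs
#'   over the correctly predicted metabolites; `"all"`: over all known
#'   metabolites (misses contribute 0).
#' @param strict If `FALSE`, rows whose substrate fails to parse are excluded
#'   from `n_total` (lenient mode); if `TRUE` they abort.
#' @param ... Passed to [predict_metabolites()].
#' @return An `eval_result`: `n_total`, `n_hit`, `C`, `S`, `CS`,
#'   `hit_ranks`, `topn_counts`, and a `per_pair` table.
#' @export
evaluate_pairs <- function(pairs, rules = default_ruleset(),
                           order = default_group_order(), top_k = 50L,
                           s_denominator = c("hits", "all"), strict = TRUE,
                           ...) {
  s_denominator <- match.arg(s_denominator)
  if (is.character(pairs) && length(pairs) == 1L) pairs <- load_pairs(pairs)
  if (!inherits(pairs, "pair_dataset")) pairs <- pair_dataset(pairs)
  rules <- as_ruleset(rules)
  order <- group_order(order)

  # substrates repeat across pairs; predict each structure once
  cache <- new.env(parent = emptyenv())
  ranks <- rep(NA_integer_, nrow(pairs))
  ncand <- integer(nrow(pairs))
  ok <- rep(TRUE, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pred <- tryCatch({
      key <- pairs$substrate_smiles[i]
      if (is.null(cache[[key]])) {
        cache[[key]] <- predict_metabolites(key, rules, order = order,
                                            top_k = top_k, ...)
      }
      cache[[key]]
    }, error = function(e) {
      if (strict) stop(e)
      ok[i] <<- FALSE
      NULL
    })
    if (is.null(pred)) next
    mk <- canonical_key(pairs$metabolite_smiles[i])
    ncand[i] <- nrow(pred$candidates)
    r <- match(mk, pred$candidates$canonical_key)
    if (!is.na(r)) ranks[i] <- pred$candidates$rank[r]
  }
  per_pair <- data.frame(substrate_id = pairs$substrate_id,
                         rank = ranks, n_candidates = ncand,
                         included = ok, stringsAsFactors = FALSE)
  build_eval_result(ranks[ok], n_total = sum(ok), top_k = top_k,
                    s_denominator = s_denominator, per_pair = per_pair)
}

#' Score a list of printed ranks directly
#'
#' Computes C, S and CS from known-metabolite ranks alone, e.g. when scoring
#' another predictor's published per-compound ranking positions. Misses are
#' given as `NA` (or omitted, with `n_total` larger than the list).
#'
#' @param ranks Integer ranks, `NA` for a miss.
#' @param n_total Total number of known metabolites (defaults to
#'   `length(ranks)`).
#' @inheritParams evaluate_pairs
#' @return An `eval_result`.
#' @export
#' @examples
#' score_rank_list(c(1, 1, 1, 1, 1, 1, 2, 3, 7, NA, NA, NA, NA, NA))
score_rank_list <- function(ranks, n_total = length(ranks), top_k = 50L,
                            s_denominator = c("hits", "all")) {
  s_denominator <- match.arg(s_denominator)
  build_eval_result(as.numeric(ranks), n_total = n_total, top_k = top_k,
                    s_denominator = s_denominator)
}

#' Load an external predictor's ranked candidate lists
#'
#' Generic ingestion for Table-1-style comparisons: a CSV with columns
#' `substrate_id,rank,candidate_smiles` from any tool.
#'
#' @param path CSV path.
#' @return Data frame with those three columns.
#' @export
load_rank_list <- function(path) {
  if (!file.exists(path)) pair_file_error(path, 0L, "file does not exist")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("substrate_id", "rank", "candidate_smiles")
  if (!all(need %in% names(df))) {
    pair_file_error(path, 0L,
                    paste("missing column(s):",
                          paste(setdiff(need, names(df)), collapse = ", ")))
  }
  df$rank <- as.integer(df$rank)
  df
}

#' Score an external rank list against a pair dataset
#'
#' For each pair, the hit rank is the smallest listed rank whose candidate
#' structure matches the known metabolite under the canonical identity key.
#'
#' @param rank_list Data frame from [load_rank_list()].
#' @param pairs A `pair_dataset`.
#' @inheritParams evaluate_pairs
#' @return An `eval_result`.
#' @export
evaluate_rank_list <- function(rank_list, pairs, top_k = 50L,
                               s_denominator = c("hits", "all")) {
  s_denominator <- match.arg(s_denominator)
  if (!inherits(pairs, "pair_dataset")) pairs <- pair_dataset(pairs)
  key_cache <- new.env(parent = emptyenv())
  keyof <- function(s) {
    if (is.null(key_cache[[s]])) {
      key_cache[[s]] <- tryCatch(canonical_key(s),
                                 error = function(e) NA_character_)
    }
    key_cache[[s]]
  }
  ranks <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    sub <- rank_list[rank_list$substrate_id == pairs$substrate_id[i], ,
                     drop = FALSE]
    if (!nrow(sub)) next
    mk <- canonical_key(pairs$metabolite_smiles[i])
    cand_keys <- vapply(sub$candidate_smiles, keyof, character(1))
    hit <- which(!is.na(cand_keys) & cand_keys == mk)
    if (length(hit)) ranks[i] <- min(sub$rank[hit])
  }
  per_pair <- data.frame(substrate_id = pairs$substrate_id, rank = ranks,
                         stringsAsFactors = FALSE)
  build_eval_result(ranks, n_total = nrow(pairs), top_k = top_k,
                    s_denominator = s_denominator, per_pair = per_pair)
}

#' Cumulative Top-N coverage curve
#'
#' @param result An `eval_result`.
#' @param n_total Denominator; defaults to the result's own total.
#' @return Data frame with columns `N` (1 to the result's `top_k`) and
#'   `cumulative_coverage`, non-decreasing in `N`.
#' @export
topn_curve <- function(result, n_total = result$n_total) {
  N <- seq_len(result$top_k)
  cc <- vapply(N, function(k) sum(result$hit_ranks <= k) / n_total, numeric(1))
  data.frame(N = N, cumulative_coverage = cc)
}

#' Compare two rank distributions
#'
#' Two-sample Student t-test on reciprocal ranks; misses (rank `NA` or 0)
#' enter as reciprocal 0, so the statistic reflects both coverage and
#' top-heaviness.
#'
#' @param ranks_a,ranks_b Integer rank vectors; `NA` or 0 marks a miss.
#' @return List with `statistic`, `p_value`, `df` and a `degenerate` flag;
#'   when both samples have zero variance the test is reported degenerate
#'   with `statistic` 0 (equal means) and `p_value` 1 or 0.
#' @export
compare_rank_distributions <- function(ranks_a, ranks_b) {
  if (!length(ranks_a) || !length(ranks_b)) stop("both rank lists must be non-empty")
  rr <- function(r) ifelse(is.na(r) | r < 1, 0, 1 / r)
  a <- rr(ranks_a); b <- rr(ranks_b)
  va <- stats::var(a); vb <- stats::var(b)
  if ((is.na(va) || va == 0) && (is.na(vb) || vb == 0)) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (same) 0 else Inf,
                p_value = if (same) 1 else 0,
                df = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}
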