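# Shared helpers: SMILES respelling, a tiny mixed dataset, and an exhaustive
# permutation test used as an oracle for the rank-distribution comparison.

# Re-spell a molecule's SMILES by walking its graph in a random atom order;
# same structure, different string.
respell_smiles <- function(mol, seed) {
  g <- mol$graph
  rank <- with_seed_local(seed, sample(nrow(g$atoms)))
  ncmetab:::write_smiles_graph(g, visit_rank = rank)
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Five-pair mixed dataset used where a small deterministic set is enough.
small_mixed_pairs <- function() {
  pair_dataset(data.frame(
    substrate_id = sprintf("p%d", 1:5),
    substrate_smiles = c("CCOC(C)=O", "COc1ccccc1", "C=Cc1ccccc1",
                         "CC(C)O", "CC(=O)c1ccccc1"),
    metabolite_smiles = c("CC(=O)O", "Oc1ccccc1", "CCc1ccccc1",
                          "CC(C)=O", "CC(O)c1ccccc1"),
    stringsAsFactors = FALSE
  ), source = "small_mixed_pairs")
}

# Exhaustive two-sample permutation test on the difference of means of
# reciprocal ranks (misses as 0); the independent oracle for the t-based
# comparison.
perm_test_mean_diff <- function(ranks_a, ranks_b) {
  rr <- function(r) ifelse(is.na(r) | r < 1, 0, 1 / r)
  a <- rr(ranks_a); b <- rr(ranks_b)
  pooled <- c(a, b)
  na <- length(a)
  obs <- abs(mean(a) - mean(b))
  splits <- utils::combn(length(pooled), na)
  diffs <- apply(splits, 2, function(ii) {
    abs(mean(pooled[ii]) - mean(pooled[-ii]))
  })
  mean(diffs >= obs - 1e-12)
}
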