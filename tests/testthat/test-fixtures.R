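# Fixture datasets: closure of the planted ground truth and reproducibility.

test_that("the toy pair set covers every category with recoverable metabolites", {
  toy <- builtin_toy_pairs()
  expect_gte(nrow(toy), 16L)
  expect_true(all(table(toy$category) >= 2))
  expect_setequal(unique(toy$category), group_categories())
  # closure: each metabolite is in its substrate's candidate pool
  rs <- default_ruleset()
  for (i in seq_len(nrow(toy))) {
    cand <- generate_candidates(toy$substrate_smiles[i], rs)
    expect_true(canonical_key(toy$metabolite_smiles[i]) %in%
                  cand$canonical_key,
                info = toy$substrate_id[i])
  }
})

test_that("randomized fixtures are bit-reproducible and honor the category mix", {
  spec <- fixture_spec(seed = 42, n_pairs = 10,
                       category_mix = c(esters = 0.5, ethers = 0.5))
  d1 <- make_randomized_dataset(spec)
  d2 <- make_randomized_dataset(spec)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_true(all(d1$category %in% c("esters", "ethers")))

  pure <- make_randomized_dataset(
    fixture_spec(seed = 3, n_pairs = 8, category_mix = c(esters = 1)))
  rs <- default_ruleset()
  expect_true(all(ncmetab:::rule_categories(rs)[pure$rule_id] == "esters"))
})

test_that("planted metabolites are always recoverable (closure property)", {
  ds <- make_randomized_dataset(
    fixture_spec(seed = 9, n_pairs = 12,
                 category_mix = c(esters = 0.4, alkanes = 0.3, others = 0.3)))
  rs <- default_ruleset()
  for (i in seq_len(nrow(ds))) {
    cand <- generate_candidates(ds$substrate_smiles[i], rs)
    expect_true(canonical_key(ds$metabolite_smiles[i]) %in% cand$canonical_key)
  }
  ev <- evaluate_pairs(ds, rs)
  expect_identical(ev$C, 1)
})

test_that("fixture generation does not disturb the caller's RNG stream", {
  set.seed(1234)
  before <- .Random.seed
  invisible(make_randomized_dataset(fixture_spec(seed = 7, n_pairs = 3)))
  expect_identical(.Random.seed, before)
})

test_that("impossible category mixes fail loudly", {
  rs <- default_ruleset()
  ester_only <- ncmetab:::new_ruleset(
    rs$rules[ncmetab:::rule_categories(rs) == "esters"])
  expect_error(
    make_randomized_dataset(
      fixture_spec(seed = 1, n_pairs = 2, category_mix = c(amines = 1)),
      rules = ester_only),
    class = "scaffold_exhausted")
  expect_error(fixture_spec(seed = 1, n_pairs = 2,
                            category_mix = c(esters = 0.5)),
               "sum to 1")
  expect_error(fixture_spec(seed = 1, n_pairs = 2,
                            category_mix = c(Esters = 1)),
               "category labels")
})

test_that("the decoy cap attaches a reduced evaluation rule set", {
  ds <- make_randomized_dataset(
    fixture_spec(seed = 2, n_pairs = 4, category_mix = c(esters = 1),
                 decoy_rules_per_pair = 3))
  sub <- attr(ds, "evaluation_ruleset")
  expect_s3_class(sub, "nc_ruleset")
  cats <- ncmetab:::rule_categories(sub)
  expect_identical(sum(cats == "esters"), 2L)   # all target rules kept
  expect_identical(sum(cats != "esters"), 3L)   # plus three decoy rules
  ev <- evaluate_pairs(ds, sub)
  expect_identical(ev$C, 1)
})
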