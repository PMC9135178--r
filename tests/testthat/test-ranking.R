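# Priority ordering, steric fine sort, determinism and invariances.

site_of <- function(mol, elem = "O") which(mol$graph$atoms$elem == elem)

test_that("steric scores match hand-computed values", {
  m <- parse_molecule("CO")
  expect_equal(steric_hindrance_score(m, site_of(m)), 0.5)
  m <- parse_molecule("CCO")
  expect_equal(steric_hindrance_score(m, site_of(m)), 0.5 + 1 / 3)
  m <- parse_molecule("CC(C)(C)O")
  expect_equal(steric_hindrance_score(m, site_of(m)), 0.5 + 3 * (1 / 3))
  # branching increases hindrance
  e <- steric_hindrance_score(parse_molecule("CCO"),
                              site_of(parse_molecule("CCO")))
  t <- steric_hindrance_score(parse_molecule("CC(C)(C)O"),
                              site_of(parse_molecule("CC(C)(C)O")))
  expect_gt(t, e)
})

test_that("steric score honors the radius and weight settings", {
  m <- parse_molecule("CCCCCO")  # pentanol chain
  o <- site_of(m)
  expect_equal(steric_hindrance_score(m, o, radius = 1L), 0.5)
  expect_equal(steric_hindrance_score(m, o, radius = 2L), 0.5 + 1 / 3)
  expect_equal(steric_hindrance_score(m, o, radius = 3L,
                                      weight = function(d) 1),
               3)
  expect_error(steric_hindrance_score(m, 99L), class = "invalid_site")
  expect_error(steric_hindrance_score(m, integer()), class = "invalid_site")
})

test_that("steric score is invariant under SMILES respelling of the parent", {
  base <- parse_molecule("CC(C)C1CCC(C)CC1O")
  ref_site <- site_of(base)
  ref <- steric_hindrance_score(base, ref_site)
  for (s in 1:50) {
    m <- parse_molecule(respell_smiles(base, seed = s))
    expect_equal(steric_hindrance_score(m, site_of(m)), ref)
  }
})

test_that("ranking sorts by category tier, then steric, then key, and truncates", {
  cand <- data.frame(
    product_smiles = c("CCO", "CCC", "CCN", "CCOC"),
    canonical_key = c("CCO", "CCC", "CCN", "CCOC"),
    rule_id = "r", category = c("alcohols", "esters", "esters", "ethers"),
    categories = c("alcohols", "esters", "esters", "ethers"),
    site_atoms = "1", steric_score = c(0.1, 0.9, 0.4, 0.2),
    provenance_count = 1L, heavy_atoms = 3L, stringsAsFactors = FALSE
  )
  r <- rank_candidates(cand, default_group_order(), top_k = 50L)
  # esters tier first (steric 0.4 before 0.9), then ethers, then alcohols
  expect_identical(r$canonical_key, c("CCN", "CCC", "CCOC", "CCO"))
  expect_identical(r$rank, 1:4)
  # steric tie broken by lexicographic key
  cand$steric_score <- 0.5
  cand$category <- "esters"; cand$categories <- "esters"
  r2 <- rank_candidates(cand, default_group_order())
  expect_identical(r2$canonical_key, sort(cand$canonical_key))
  # truncation
  r3 <- rank_candidates(cand, default_group_order(), top_k = 2L)
  expect_identical(nrow(r3), 2L)
  # empty input
  r4 <- rank_candidates(cand[0, ], default_group_order())
  expect_identical(nrow(r4), 0L)
})

test_that("ranking is invariant to candidate input order", {
  cand <- generate_candidates("CC(=O)OCc1ccc(OC)cc1", default_ruleset())
  ref <- rank_candidates(cand, default_group_order())
  for (s in 1:10) {
    shuffled <- cand[with_seed_local(s, sample(nrow(cand))), ]
    expect_identical(rank_candidates(shuffled, default_group_order()), ref)
  }
})

test_that("promoting a category never demotes its candidates", {
  cand <- generate_candidates("CC(=O)OCc1ccc(OC)cc1", default_ruleset())
  base_order <- unclass(default_group_order())
  ref <- rank_candidates(cand, base_order)
  for (cat in setdiff(base_order, base_order[1])) {
    promoted <- group_order(c(cat, setdiff(base_order, cat)))
    moved <- rank_candidates(cand, promoted)
    for (k in moved$canonical_key[moved$category == cat]) {
      expect_lte(moved$rank[moved$canonical_key == k],
                 ref$rank[ref$canonical_key == k])
    }
  }
})

test_that("within one category, ranking reduces to steric-score order", {
  cand <- generate_candidates("C1CCC2CCCCC2C1", default_ruleset())
  one_cat <- cand[cand$categories == "alkanes", ]
  r <- rank_candidates(one_cat, default_group_order())
  # oracle: plain sort on (steric, key)
  o <- order(one_cat$steric_score, one_cat$canonical_key)
  expect_identical(r$canonical_key, one_cat$canonical_key[o])
})

test_that("the glycoside walk-through ranks the aglycone in the top 5", {
  pred <- predict_metabolites("c1ccccc1OC1OC(CO)C(O)C(O)C1O")
  r <- match(canonical_key("Oc1ccccc1"), pred$candidates$canonical_key)
  expect_lte(pred$candidates$rank[r], 5L)
})

test_that("prediction is deterministic and inert parents give empty lists", {
  out1 <- tempfile(fileext = ".csv"); out2 <- tempfile(fileext = ".csv")
  cmd_predict(smiles = "CC(=O)Oc1ccccc1C(=O)O", out = out1)
  cmd_predict(smiles = "CC(=O)Oc1ccccc1C(=O)O", out = out2)
  expect_identical(readBin(out1, "raw", file.size(out1)),
                   readBin(out2, "raw", file.size(out2)))
  # no rule matches a bare fluorinated methane
  pred <- predict_metabolites("FC(F)(F)F")
  expect_identical(nrow(pred$candidates), 0L)
})

test_that("isomer-only mode confines the steric sort to same-formula groups", {
  cand <- generate_candidates("CC(=O)OCc1ccc(OC)cc1", default_ruleset())
  r <- rank_candidates(cand, default_group_order(), isomer_only = TRUE)
  # same candidates, a legal permutation, ranks still 1..n
  expect_setequal(r$canonical_key, cand$canonical_key)
  expect_identical(r$rank, seq_len(nrow(r)))
})
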