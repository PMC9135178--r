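# Self-contained fixture datasets with planted ground truth: every pair's
# metabolite is reachable from its substrate by a shipped rule, so closure
# (coverage 1 under the generating rule set) holds by construction.

#' Hand-curated toy substrate-metabolite pairs
#'
#' Eighteen small pairs, at least two per functional-group category, each
#' metabolite the product of exactly one shipped rule applied to its
#' substrate (e.g. ethyl acetate to acetic acid for esters, a phenyl
#' glucoside to phenol for ethers - deglycosylation in miniature).
#'
#' @return A `pair_dataset` with a `category` column recording the planted
#'   producing category.
#' @export
builtin_toy_pairs <- function() {
  df <- data.frame(
    substrate_id = sprintf("toy%02d", 1:18),
    substrate_smiles = c(
      "CCOC(C)=O",                      # ethyl acetate
      "CC(=O)Oc1ccccc1C(=O)O",          # aspirin
      "Oc1ccc(OS(=O)(=O)O)cc1",         # hydroquinone monosulfate
      "c1ccccc1OC1OC(CO)C(O)C(O)C1O",   # phenyl glucoside
      "COc1ccccc1",                     # anisole
      "c1ccc2ccccc2c1",                 # naphthalene
      "Oc1ccccc1",                      # phenol
      "CNc1ccccc1",                     # N-methylaniline
      "Nc1ccc(C)cc1",                   # p-toluidine
      "C1CCCCC1",                       # cyclohexane
      "CCc1ccccc1",                     # ethylbenzene
      "C=Cc1ccccc1",                    # styrene
      "C1=CCCCC1",                      # cyclohexene
      "CCO",                            # ethanol
      "CC(C)O",                         # isopropanol
      "CC(=O)c1ccccc1",                 # acetophenone
      "OC(=O)Cc1ccccc1",                # phenylacetic acid
      "CC(=O)Nc1ccccc1"                 # acetanilide
    ),
    metabolite_smiles = c(
      "CC(=O)O",                        # acetic acid        (est01)
      "Oc1ccccc1C(=O)O",                # salicylic acid     (est01)
      "Oc1ccc(O)cc1",                   # hydroquinone       (est02)
      "Oc1ccccc1",                      # phenol             (eth01)
      "Oc1ccccc1",                      # phenol             (eth02)
      "Oc1ccc2ccccc2c1",                # 2-naphthol         (aro01)
      "c1ccccc1",                       # benzene            (aro02)
      "Nc1ccccc1",                      # aniline            (ami01)
      "Cc1ccc(NC(C)=O)cc1",             # acetamido-toluene  (ami02)
      "OC1CCCCC1",                      # cyclohexanol       (alk01)
      "C=Cc1ccccc1",                    # styrene            (alk02)
      "CCc1ccccc1",                     # ethylbenzene       (ene01)
      "OC1CCCCC1",                      # cyclohexanol       (ene02)
      "CC(=O)O",                        # acetic acid        (alc01)
      "CC(C)=O",                        # acetone            (alc02)
      "CC(O)c1ccccc1",                  # 1-phenylethanol    (oth01)
      "Cc1ccccc1",                      # toluene            (oth02)
      "Nc1ccccc1"                       # aniline            (oth03)
    ),
    evidence = "planted by construction",
    stringsAsFactors = FALSE
  )
  df$category <- c("esters", "esters", "esters", "ethers", "ethers",
                   "aromatics", "aromatics", "amines", "amines", "alkanes",
                   "alkanes", "alkenes", "alkenes", "alcohols", "alcohols",
                   "others", "others", "others")
  pair_dataset(df, source = "builtin_toy_pairs")
}

#' Embedded scaffold library for randomized fixtures
#'
#' About thirty natural-product-like small scaffolds (flavonoid-like cores,
#' a glycoside, terpenoid fragments, alkaloid-type amines, and
#' polyfunctional esters) chosen so every functional-group category has
#' substrates and every substrate generates decoy candidates from several
#' categories.
#'
#' @return Named character vector of SMILES.
#' @export
scaffold_library <- function() {
  c(
    # polyfunctional esters (each carries aromatic / ether / amine / alkene /
    # alcohol / ketone handles so non-ester decoys always arise)
    ester_amine    = "CC(=O)OCCN(C)C",
    ester_benzyl   = "CC(=O)OCc1ccc(OC)cc1",
    ester_allyl    = "C=CCOC(=O)CCO",
    ester_ketone   = "CC(=O)OC1CCC(=O)CC1",
    benzocaine     = "CCOC(=O)c1ccc(N)cc1",
    cinnamate      = "COc1ccc(C=CC(=O)OCC)cc1",
    ester_glycol   = "CC(O)COC(=O)c1ccccc1",
    ester_thf      = "CC(=O)OCC1CCCO1",
    eugenol_ester  = "CC(=O)Oc1ccc(CC=C)cc1",
    ester_amide    = "CC(=O)NC1CCC(OC(C)=O)CC1",
    aspirin        = "CC(=O)Oc1ccccc1C(=O)O",
    salicin_like   = "OCC1OC(Oc2ccccc2CO)C(O)C(O)C1O",
    # ethers and glycosides
    phenyl_gluc    = "c1ccccc1OC1OC(CO)C(O)C(O)C1O",
    anisole_acid   = "COc1ccc(CC(=O)O)cc1",
    guaiacol       = "COc1ccccc1O",
    dibenzyl_ether = "C(OCc1ccccc1)c1ccccc1",
    # aromatics / phenols
    flavanone_like = "O=C1CC(c2ccccc2)Oc2ccccc21",
    naphthol       = "Oc1ccc2ccccc2c1",
    cresol         = "Cc1ccc(O)cc1",
    # amines / alkaloid-like
    phenethylamine = "NCCc1ccccc1",
    n_methyl_amine = "CN(C)CCc1ccc(O)cc1",
    piperidine_arm = "OCCN1CCCCC1",
    # alkanes / terpenoid-like
    decalin        = "C1CCC2CCCCC2C1",
    pinane_frag    = "CC1(C)CCCC(C)C1",
    cyclohexane    = "C1CCCCC1",
    # alkenes
    limonene_like  = "CC(=C)C1CCC(C)=CC1",
    styrene_deriv  = "C=Cc1ccc(O)cc1",
    stilbene_like  = "C(=Cc1ccccc1)c1ccc(O)cc1",
    # alcohols
    menthol_like   = "CC(C)C1CCC(C)CC1O",
    geraniol_frag  = "CC(C)=CCCC(C)O",
    benzyl_alcohol = "OCc1ccccc1",
    # ketone / amide bearing (others)
    raspberry_ket  = "CC(=O)CCc1ccc(O)cc1",
    benzamide_like = "CC(=O)Nc1ccc(O)cc1"
  )
}

#' Fixture generation settings
#'
#' @param seed Integer seed; generation is bit-reproducible for a seed.
#' @param n_pairs Number of pairs to draw.
#' @param category_mix Named numeric vector of category proportions (must
#'   sum to 1); e.g. `c(esters = 1)` plants only ester-rule ground truth.
#' @param decoy_rules_per_pair Optional cap on how many non-target rules are
#'   kept as decoy sources (default: all shipped rules).
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, n_pairs,
                         category_mix = c(esters = 1),
                         decoy_rules_per_pair = NULL) {
  stopifnot(n_pairs >= 1)
  if (is.null(names(category_mix)) ||
      !all(names(category_mix) %in% group_categories())) {
    stop("category_mix must be named with category labels")
  }
  if (abs(sum(category_mix) - 1) > 1e-8) stop("category_mix must sum to 1")
  structure(list(seed = as.integer(seed), n_pairs = as.integer(n_pairs),
                 category_mix = category_mix,
                 decoy_rules_per_pair = decoy_rules_per_pair),
            class = "fixture_spec")
}

#' Generate a randomized pair dataset with planted ground truth
#'
#' Samples scaffolds from [scaffold_library()], applies a randomly chosen
#' applicable rule of the drawn category to create the "known metabolite",
#' and records the pair. The planted metabolite is always recoverable: it is
#' a member of the substrate's candidate pool under the generating rules.
#'
#' @param spec A [fixture_spec()].
#' @param rules An `nc_ruleset` (default the shipped set).
#' @return A `pair_dataset` with `category` and `rule_id` columns recording
#'   the planted provenance.
#' @export
make_randomized_dataset <- function(spec, rules = default_ruleset()) {
  stopifnot(inherits(spec, "fixture_spec"))
  rules <- as_ruleset(rules)
  scaffolds <- scaffold_library()

  # applicability table: per category, which scaffolds have >= 1 product
  by_cat <- split(rules$rules, rule_categories(rules))
  want <- names(spec$category_mix)[spec$category_mix > 0]
  options_by_cat <- list()
  for (cat in want) {
    rr <- by_cat[[cat]]
    if (is.null(rr)) {
      abort_ncm("scaffold_exhausted",
                sprintf("no rules of category '%s' in the rule set", cat))
    }
    opts <- list()
    for (s in names(scaffolds)) {
      parent <- parse_molecule(scaffolds[[s]])
      for (r in rr) {
        prods <- apply_rule(parent, r)
        if (nrow(prods)) {
          opts[[length(opts) + 1L]] <- list(
            scaffold = s, smiles = parent$canonical_smiles,
            rule_id = r$rule_id,
            products = unique(prods$product_smiles))
        }
      }
    }
    if (!length(opts)) {
      abort_ncm("scaffold_exhausted",
                sprintf("no scaffold supports category '%s'", cat))
    }
    options_by_cat[[cat]] <- opts
  }

  with_preserved_seed(spec$seed, {
    cats <- sample(want, spec$n_pairs, replace = TRUE,
                   prob = spec$category_mix[want])
    rows <- lapply(seq_len(spec$n_pairs), function(i) {
      opts <- options_by_cat[[cats[i]]]
      o <- opts[[sample.int(length(opts), 1L)]]
      met <- o$products[[sample.int(length(o$products), 1L)]]
      data.frame(substrate_id = sprintf("fx%03d", i),
                 substrate_smiles = o$smiles,
                 metabolite_smiles = met,
                 evidence = sprintf("planted:%s", o$scaffold),
                 category = cats[i], rule_id = o$rule_id,
                 stringsAsFactors = FALSE)
    })
    out <- pair_dataset(do.call(rbind, rows),
                        source = "make_randomized_dataset")
    # Optional decoy cap: a reduced evaluation rule set holding all
    # target-category rules plus a seeded sample of the other rules.
    if (!is.null(spec$decoy_rules_per_pair)) {
      target <- rule_categories(rules) %in% want
      other <- which(!target)
      keep <- sort(c(which(target),
                     other[sample.int(length(other),
                                      min(spec$decoy_rules_per_pair,
                                          length(other)))]))
      attr(out, "evaluation_ruleset") <- new_ruleset(rules$rules[keep])
    }
    out
  })
}
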