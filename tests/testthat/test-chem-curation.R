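# Standardization, identity keys, overlap control and the strict filter.

test_that("standardization canonicalizes, keys correctly, and rejects garbage", {
  r <- standardize_molecule("C1=CC=CC=C1", 0, "dude")
  expect_equal(nchar(r$inchikey), 27)
  expect_equal(lengths(regmatches(r$inchikey, gregexpr("-", r$inchikey))), 2,
               ignore_attr = TRUE)
  expect_equal(r$connectivity_key, substr(r$inchikey, 1, 14))
  expect_error(standardize_molecule("not_a_smiles", 0, "dude"),
               class = "unparsable_structure")
  # same molecule under SMILES rewrites -> identical keys
  a <- standardize_molecule("OCC", 0, "dude")
  b <- standardize_molecule("CCO", 0, "dude")
  expect_equal(a$inchikey, b$inchikey)
  expect_equal(a$connectivity_key, b$connectivity_key)
  expect_equal(a$smiles, b$smiles)
  # idempotence: standardizing the standardized SMILES changes nothing
  c <- standardize_molecule(a$smiles, 0, "dude")
  expect_equal(c$inchikey, a$inchikey)
  expect_equal(c$smiles, a$smiles)
})

test_that("label-source consistency is enforced and salts are stripped", {
  expect_error(standardize_molecule("CCO", 1, "dude"), class = "bad_config")
  r <- standardize_molecule("CCO", 1, "prodrug")
  expect_equal(r$label, 1L)
  # largest organic fragment wins over the counter-ion
  salt <- standardize_molecule("CC(=O)Oc1ccccc1C(=O)O.[Na]", 0, "chembl_random")
  plain <- standardize_molecule("CC(=O)Oc1ccccc1C(=O)O", 0, "chembl_random")
  expect_equal(salt$inchikey, plain$inchikey)
})

test_that("vectorized standardization excludes unparsables with a report", {
  df <- data.frame(smiles = c("CCO", "xx!bad", "c1ccccc1"),
                   label = 0L, source = "dude")
  expect_warning(out <- standardize_molecules(df), "unparsable")
  expect_equal(nrow(out), 2)
  expect_equal(nrow(attr(out, "rejected")), 1)
  expect_equal(attr(out, "rejected")$smiles, "xx!bad")
})

test_that("positive-overlap removal drops identical keys and flags stereo twins", {
  aspirin <- standardize_molecule("CC(=O)Oc1ccccc1C(=O)O", 0, "dude")
  ethanol <- standardize_molecule("CCO", 0, "dude")
  benzene <- standardize_molecule("c1ccccc1", 0, "dude")
  pos_aspirin <- standardize_molecule("CC(=O)Oc1ccccc1C(=O)O", 1, "prodrug")
  # identity removal
  expect_equal(nrow(remove_positive_overlap(aspirin, pos_aspirin)), 0)
  # disjoint sets survive untouched and unflagged
  kept <- remove_positive_overlap(ethanol, standardize_molecule("c1ccccc1", 1, "prodrug"))
  expect_equal(kept$inchikey, ethanol$inchikey)
  expect_false(kept$potential_duplicate)
  # enantiomer of a positive: same connectivity block, different full key ->
  # retained but flagged
  l_ala <- standardize_molecule("C[C@H](N)C(=O)O", 1, "prodrug")
  d_ala <- standardize_molecule("C[C@@H](N)C(=O)O", 0, "chembl_random")
  expect_false(l_ala$inchikey == d_ala$inchikey)
  expect_equal(l_ala$connectivity_key, d_ala$connectivity_key)
  out <- remove_positive_overlap(rbind(d_ala, benzene), l_ala)
  expect_equal(nrow(out), 2)
  expect_true(out$potential_duplicate[out$inchikey == d_ala$inchikey])
  expect_false(out$potential_duplicate[out$inchikey == benzene$inchikey])
  # idempotence and order preservation
  again <- remove_positive_overlap(out[names(d_ala)], l_ala)
  expect_equal(again$inchikey, out$inchikey)
  # empty inputs allowed
  expect_equal(nrow(remove_positive_overlap(aspirin[0, ], l_ala)), 0)
})

test_that("duplicate collapse keeps the first of each full InChIKey", {
  x <- standardize_molecule("CCO", 0, "dude", id = "first")
  x2 <- standardize_molecule("OCC", 0, "dude", id = "second")
  y <- standardize_molecule("c1ccccc1", 0, "dude")
  out <- collapse_duplicates(rbind(x, x2, y))
  expect_equal(nrow(out), 2)
  expect_equal(out$id[1], "first")
  expect_equal(nrow(collapse_duplicates(x[0, ])), 0)
  # hash-count oracle: survivors = number of distinct keys
  set.seed(5)
  smis <- sample(c("CCO", "OCC", "c1ccccc1", "CCC", "CCCC"), 10, replace = TRUE)
  pool <- do.call(rbind, lapply(seq_along(smis), function(i)
    standardize_molecule(smis[i], 0, "dude", id = as.character(i))))
  expect_equal(nrow(collapse_duplicates(pool)),
               length(unique(pool$inchikey)))
})

test_that("every shipped SMARTS rule fires on its positive exemplar and not its negative", {
  for (file in c("strict_filter_smarts.tsv", "alert_smarts.tsv")) {
    tab <- read.delim(system.file("extdata", file, package = "decoyscreen"),
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(tab))) {
      hit <- ChemmineOB::smartsSearch_OB(
        ChemmineOB::forEachMol("SMILES", tab$example_hit[i], identity),
        tab$smarts[i])
      miss <- ChemmineOB::smartsSearch_OB(
        ChemmineOB::forEachMol("SMILES", tab$example_miss[i], identity),
        tab$smarts[i])
      expect_gt(hit, 0, label = sprintf("%s hit count", tab$name[i]))
      expect_equal(miss, 0, ignore_attr = TRUE,
                   label = sprintf("%s miss count", tab$name[i]))
    }
  }
})

test_that("toy fixtures fail exactly their annotated rules", {
  cfg <- strict_filter_config()
  toys <- toy_smiles_fixtures()
  for (i in seq_len(nrow(toys))) {
    v <- strict_negative_filter(toys$smiles[i], cfg)
    expected <- toys$expected_rules[i]
    expected <- if (is.na(expected) || expected == "") character() else
      strsplit(expected, ",")[[1]]
    expect_setequal(v$failed_rules, expected)
    expect_equal(v$passed, length(expected) == 0,
                 label = toys$name[i])
  }
})

test_that("the filter verdict is audit-complete and the config validates", {
  v <- strict_negative_filter("CCOC(C)=O")
  expect_false(v$passed)
  expect_true("promoiety:ester" %in% v$failed_rules)
  expect_true("element_whitelist" %in%
                strict_negative_filter("CC[Se]CC")$failed_rules)
  vb <- strict_negative_filter("c1ccccc1")
  expect_true(vb$passed)
  expect_lte(vb$properties$mw, 500)
  expect_equal(vb$properties$hbd, 0, ignore_attr = TRUE)
  expect_equal(vb$properties$rotb, 0, ignore_attr = TRUE)
  expect_error(
    strict_filter_config(promoiety_smarts = data.frame(name = "bad",
                                                       smarts = "[[[")),
    class = "bad_config")
  expect_error(strict_filter_config(alert_catalogs = "NOPE"),
               class = "bad_config")
})

test_that("adding SMARTS rules is monotone: failures only accumulate", {
  base <- strict_filter_config(alert_catalogs = character())
  extended <- strict_filter_config(alert_catalogs = c("PAINS", "Brenk",
                                                      "NIH", "ZINC"))
  toys <- toy_smiles_fixtures()
  for (smi in toys$smiles[toys$set %in% c("promoiety", "warhead", "passer")]) {
    f_base <- strict_negative_filter(smi, base)$failed_rules
    f_ext <- strict_negative_filter(smi, extended)$failed_rules
    expect_true(all(f_base %in% f_ext), label = smi)
  }
})
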