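# Structure standardization, identity keys, overlap control and the strict
# high-confidence-negative rule engine.
#
# Backend: OpenBabel via ChemmineOB. Standardization takes the largest
# organic fragment (salt stripping) and canonicalizes; identity uses the full
# 27-character InChIKey, with the first 14-character connectivity block as a
# coarser key for stereo/tautomer collision flagging. cLogP throughout is
# the OpenBabel atom-contribution logP estimator; that choice is recorded in
# every filter config.

ob_convert <- function(from, to, source) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(from, to, source)),
    error = function(e) "")
  trimws(out)
}

# InChIKey via the obabel binary: the in-process converter does not perceive
# tetrahedral stereo from SMILES, so enantiomers would collide on the full
# key; the command-line reader applies stereo perception correctly.
ob_inchikey <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(system2("obabel",
                             c(shQuote(paste0("-:", smiles)), "-oinchikey"),
                             stdout = TRUE, stderr = FALSE)),
    error = function(e) character())
  out <- trimws(out[nzchar(trimws(out))])
  if (length(out) != 1L) "" else out
}

# Largest fragment by atom-heavy MW among dot-separated components.
largest_fragment <- function(canonical_smiles) {
  frags <- strsplit(canonical_smiles, ".", fixed = TRUE)[[1L]]
  if (length(frags) == 1L) return(frags)
  mw <- vapply(frags, function(f) {
    p <- tryCatch(ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", f, identity)),
                  error = function(e) NULL)
    if (is.null(p)) -1 else p$MW
  }, numeric(1))
  frags[which.max(mw)]
}

#' Standardize one molecule into a curated record
#'
#' Canonicalizes the SMILES (keeping the largest organic fragment), computes
#' the full 27-character InChIKey and its 14-character connectivity block,
#' and attaches label and source. Unparsable input raises an
#' `unparsable_structure` error: rejected molecules are excluded, never
#' silently kept. Standardization is idempotent: re-standardizing the
#' returned SMILES reproduces the same keys.
#'
#' @param smiles Input SMILES string.
#' @param label 0/1 class label (1 = positive).
#' @param source Source tag; a label of 1 requires source `"prodrug"`.
#' @param id Stable identifier (defaults to the InChIKey).
#' @return A one-row data.frame with columns `id`, `smiles`, `inchikey`,
#'   `connectivity_key`, `label`, `source`.
#' @export
standardize_molecule <- function(smiles, label = 0L, source = "chembl_random",
                                 id = NULL) {
  label <- as.integer(label)
  if (!label %in% c(0L, 1L)) ds_error("bad_config", "label must be 0 or 1")
  if (label == 1L && !identical(source, "prodrug"))
    ds_error("bad_config", "label 1 implies source 'prodrug'")
  can <- ob_convert("SMI", "CAN", smiles)
  if (!nzchar(can))
    ds_error("unparsable_structure",
             sprintf("cannot interpret '%s' as a molecule", smiles))
  can <- largest_fragment(can)
  can <- ob_convert("SMI", "CAN", can)
  key <- ob_inchikey(can)
  if (nchar(key) != 27L)
    ds_error("unparsable_structure",
             sprintf("no valid InChIKey for '%s'", smiles))
  data.frame(
    id = as.character(id %||% key),
    smiles = can,
    inchikey = key,
    connectivity_key = substr(key, 1L, 14L),
    label = label,
    source = source,
    stringsAsFactors = FALSE
  )
}

#' Standardize a table of molecules
#'
#' Vectorized [standardize_molecule()]: unparsable rows are dropped with a
#' warning and reported in the `rejected` attribute of the result.
#'
#' @param df Data.frame with columns `smiles`, `label`, `source` and
#'   optionally `id`.
#' @return Data.frame of standardized records; attribute `rejected` holds
#'   the input rows that failed to parse.
#' @export
standardize_molecules <- function(df) {
  stopifnot(is.data.frame(df), all(c("smiles", "label", "source") %in% names(df)))
  ids <- df$id %||% rep(NA_character_, nrow(df))
  out <- vector("list", nrow(df))
  bad <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    rec <- tryCatch(
      standardize_molecule(df$smiles[i], df$label[i], df$source[i],
                           id = if (is.na(ids[i])) NULL else ids[i]),
      decoyscreen_error = function(e) NULL)
    if (is.null(rec)) bad[i] <- TRUE else out[[i]] <- rec
  }
  res <- do.call(rbind, out[!bad])
  if (any(bad))
    warning(sprintf("%d unparsable structure(s) excluded", sum(bad)))
  attr(res, "rejected") <- df[bad, , drop = FALSE]
  res
}

#' Remove decoys that collide with the positive set
#'
#' Two-stage identity screen: decoys sharing a full 27-character InChIKey
#' with any positive are removed (label leakage); decoys sharing only the
#' 14-character connectivity block (stereo/tautomer collisions) are retained
#' but flagged `potential_duplicate`. Survivor order is preserved, and the
#' operation is idempotent. Flagged records are excluded from decoy pools by
#' default downstream (conservative), overridable via `keep_flagged` in the
#' pool assembly.
#'
#' @param decoys,positives Standardized record data.frames.
#' @return The surviving decoys with a logical `potential_duplicate` column.
#' @export
remove_positive_overlap <- function(decoys, positives) {
  if (NROW(decoys) == 0L) {
    decoys$potential_duplicate <- logical(0)
    return(decoys)
  }
  keep <- !(decoys$inchikey %in% positives$inchikey)
  out <- decoys[keep, , drop = FALSE]
  out$potential_duplicate <-
    out$connectivity_key %in% positives$connectivity_key
  rownames(out) <- NULL
  out
}

#' Collapse exact duplicates within a pool
#'
#' Keeps the first occurrence of each full InChIKey.
#'
#' @param pool Standardized record data.frame.
#' @return Pool with full-InChIKey uniqueness.
#' @export
collapse_duplicates <- function(pool) {
  if (NROW(pool) == 0L) return(pool)
  out <- pool[!duplicated(pool$inchikey), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- strict high-confidence-negative rule engine ---------------------------

default_allowed_elements <- function()
  c("C", "H", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si")

load_smarts_table <- function(file) {
  path <- system.file("extdata", file, package = "decoyscreen", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

compile_check_smarts <- function(patterns) {
  probe <- ChemmineOB::forEachMol("SMILES", "CCO", identity)
  for (i in seq_along(patterns)) {
    ok <- tryCatch({
      ChemmineOB::smartsSearch_OB(probe, patterns[i])
      TRUE
    }, error = function(e) FALSE)
    if (!ok)
      ds_error("bad_config",
               sprintf("SMARTS pattern does not compile: %s", patterns[i]))
  }
  invisible(TRUE)
}

#' Configuration of the strict negative filter
#'
#' The rule engine that derives high-confidence negatives: an element
#' whitelist, named promoiety SMARTS (labile masking groups such as esters
#' and phosphates whose presence marks a latent prodrug), named reactive
#' warhead SMARTS, structural-alert catalogs, and drug-likeness property
#' windows (Lipinski/Veber-like). The default SMARTS tables ship with the
#' package (versioned; the alert catalogs are abridged excerpts of the
#' published PAINS/Brenk/NIH/ZINC sets). All SMARTS are compile-checked at
#' construction.
#'
#' @param allowed_elements Permitted element symbols.
#' @param promoiety_smarts,warhead_smarts Data.frames with columns `name`,
#'   `smarts` (defaults: packaged tables).
#' @param alert_catalogs Catalogs to apply, subset of
#'   `c("PAINS", "Brenk", "NIH", "ZINC")` (default PAINS + Brenk).
#' @param windows Named list of property bounds: `mw`, `hbd`, `hba`
#'   (upper bounds), `clogp` (length-2 range), `tpsa`, `rotb` (upper
#'   bounds).
#' @return An object of class `strict_filter_config`.
#' @export
strict_filter_config <- function(allowed_elements = default_allowed_elements(),
                                 promoiety_smarts = NULL,
                                 warhead_smarts = NULL,
                                 alert_catalogs = c("PAINS", "Brenk"),
                                 windows = list(mw = 500, hbd = 5, hba = 10,
                                                clogp = c(-1, 5), tpsa = 140,
                                                rotb = 10)) {
  tab <- load_smarts_table("strict_filter_smarts.tsv")
  if (is.null(promoiety_smarts))
    promoiety_smarts <- tab[tab$rule_class == "promoiety",
                            c("name", "smarts"), drop = FALSE]
  if (is.null(warhead_smarts))
    warhead_smarts <- tab[tab$rule_class == "warhead",
                          c("name", "smarts"), drop = FALSE]
  bad <- setdiff(alert_catalogs, c("PAINS", "Brenk", "NIH", "ZINC"))
  if (length(bad) > 0L)
    ds_error("bad_config", sprintf("unknown alert catalog '%s'", bad[1L]))
  alerts <- load_smarts_table("alert_smarts.tsv")
  alerts <- alerts[alerts$catalog %in% alert_catalogs, , drop = FALSE]
  if (length(windows$clogp) != 2L || windows$clogp[1L] > windows$clogp[2L])
    ds_error("bad_config", "clogp window must be a lo <= hi range")
  for (w in c("mw", "hbd", "hba", "tpsa", "rotb"))
    if (!is.finite(windows[[w]]))
      ds_error("bad_config", sprintf("window '%s' must be finite", w))
  compile_check_smarts(c(promoiety_smarts$smarts, warhead_smarts$smarts,
                         alerts$smarts))
  structure(list(
    allowed_elements = allowed_elements,
    promoiety_smarts = promoiety_smarts,
    warhead_smarts = warhead_smarts,
    alert_catalogs = alert_catalogs,
    alert_smarts = alerts,
    windows = windows,
    clogp_method = "openbabel atom-contribution logP"
  ), class = "strict_filter_config")
}

rotatable_bond_smarts <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

parse_formula_elements <- function(formula) {
  m <- gregexpr("[A-Z][a-z]?", formula)[[1L]]
  unique(regmatches(formula, list(m))[[1L]])
}

#' Apply the strict negative filter to one record
#'
#' Evaluates every rule (no short-circuit) so the verdict is audit-complete:
#' `failed_rules` lists each violated rule as `element_whitelist`,
#' `promoiety:<name>`, `warhead:<name>`, `alert:<catalog>` or
#' `window:<property>`. `passed` is true iff `failed_rules` is empty.
#'
#' @param record One standardized record (data.frame row or list with
#'   `$smiles`), or a SMILES string.
#' @param cfg A [strict_filter_config()].
#' @return A list of class `filter_verdict`: `passed`, `failed_rules`, and
#'   the computed `properties`.
#' @export
strict_negative_filter <- function(record, cfg = strict_filter_config()) {
  stopifnot(inherits(cfg, "strict_filter_config"))
  smi <- if (is.character(record)) record else record$smiles[1L]
  mol <- tryCatch(ChemmineOB::forEachMol("SMILES", smi, identity),
                  error = function(e) NULL)
  props <- tryCatch(ChemmineOB::prop_OB(mol), error = function(e) NULL)
  if (is.null(mol) || is.null(props) || !nzchar(props$formula))
    ds_error("unparsable_structure", sprintf("cannot parse '%s'", smi))

  failed <- character()
  elements <- parse_formula_elements(props$formula)
  if (!all(elements %in% cfg$allowed_elements))
    failed <- c(failed, "element_whitelist")
  for (i in seq_len(nrow(cfg$promoiety_smarts)))
    if (ChemmineOB::smartsSearch_OB(mol, cfg$promoiety_smarts$smarts[i]) > 0)
      failed <- c(failed, paste0("promoiety:", cfg$promoiety_smarts$name[i]))
  for (i in seq_len(nrow(cfg$warhead_smarts)))
    if (ChemmineOB::smartsSearch_OB(mol, cfg$warhead_smarts$smarts[i]) > 0)
      failed <- c(failed, paste0("warhead:", cfg$warhead_smarts$name[i]))
  hit_catalogs <- character()
  for (i in seq_len(nrow(cfg$alert_smarts)))
    if (ChemmineOB::smartsSearch_OB(mol, cfg$alert_smarts$smarts[i]) > 0)
      hit_catalogs <- c(hit_catalogs, cfg$alert_smarts$catalog[i])
  if (length(hit_catalogs) > 0L)
    failed <- c(failed, paste0("alert:", unique(hit_catalogs)))

  rotb <- ChemmineOB::smartsSearch_OB(mol, rotatable_bond_smarts)
  vals <- list(mw = props$MW, hbd = props$HBD, hba = props$HBA1,
               clogp = props$logP, tpsa = props$TPSA, rotb = rotb)
  w <- cfg$windows
  if (vals$mw > w$mw) failed <- c(failed, "window:mw")
  if (vals$hbd > w$hbd) failed <- c(failed, "window:hbd")
  if (vals$hba > w$hba) failed <- c(failed, "window:hba")
  if (vals$clogp < w$clogp[1L] || vals$clogp > w$clogp[2L])
    failed <- c(failed, "window:clogp")
  if (vals$tpsa > w$tpsa) failed <- c(failed, "window:tpsa")
  if (vals$rotb > w$rotb) failed <- c(failed, "window:rotb")

  structure(list(passed = length(failed) == 0L, failed_rules = failed,
                 properties = vals),
            class = "filter_verdict")
}

#' @export
print.filter_verdict <- function(x, ...) {
  if (x$passed) cat("PASS (high-confidence negative)\n")
  else cat("FAIL:", paste(x$failed_rules, collapse = ", "), "\n")
  invisible(x)
}

#' Filter a pool of records
#'
#' Vectorized [strict_negative_filter()] returning one row per record with
#' the verdict and the concatenated failed rules.
#'
#' @param pool Standardized record data.frame.
#' @inheritParams strict_negative_filter
#' @return The pool with added `passed` (logical) and `failed_rules`
#'   (comma-separated character) columns.
#' @export
strict_filter_pool <- function(pool, cfg = strict_filter_config()) {
  verdicts <- lapply(pool$smiles, strict_negative_filter, cfg = cfg)
  pool$passed <- vapply(verdicts, `[[`, logical(1), "passed")
  pool$failed_rules <- vapply(verdicts, function(v)
    paste(v$failed_rules, collapse = ","), character(1))
  pool
}
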