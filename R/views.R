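# Feature views: named, ordered subsets of fingerprint bit slots.

#' Create a feature view
#'
#' A named, ordered subset of fingerprint bit slots. Bits may be given as
#' 0-based slot indices or as slot names (`"Avalon_FP_<i>"`); both are kept.
#'
#' @param name View name.
#' @param bits Integer vector of 0-based indices in `[0, nbits)`, or a
#'   character vector of slot names.
#' @param nbits Fingerprint length the indices refer to (default 2048).
#' @return An object of class `feature_view`.
#' @examples
#' feature_view("toy", c(0, 5, 17))
#' @export
feature_view <- function(name, bits, nbits = 2048L) {
  if (is.character(bits)) {
    idx <- suppressWarnings(as.integer(sub("^.*_", "", bits)))
    if (anyNA(idx))
      ds_error("bad_config", "unparsable bit names in feature view")
  } else {
    idx <- as.integer(bits)
  }
  if (length(idx) == 0L) ds_error("empty_view", "a feature view needs >= 1 bit")
  if (anyNA(idx) || any(idx < 0L) || any(idx >= nbits))
    ds_error("bad_config", sprintf("bit indices must lie in [0, %d)", nbits))
  if (anyDuplicated(idx))
    ds_error("bad_config", "bit indices must be unique")
  structure(
    list(name = as.character(name),
         bit_indices = idx,
         bit_names = paste0("Avalon_FP_", idx),
         nbits = as.integer(nbits)),
    class = "feature_view"
  )
}

#' @export
print.feature_view <- function(x, ...) {
  cat(sprintf("Feature view '%s': %d bits of %d\n", x$name,
              length(x$bit_indices), x$nbits))
  invisible(x)
}

#' @export
length.feature_view <- function(x) length(x$bit_indices)

# Subset the columns of a bit matrix by a view (1-based columns = index + 1).
view_columns <- function(X, view) {
  if (inherits(X, "fp_matrix")) X <- X$matrix
  X[, view$bit_indices + 1L, drop = FALSE]
}

#' Packaged selected feature sets
#'
#' The two published single-view fingerprint feature sets shipped with the
#' package (`list_1`, 40 bits; `list_2`, 55 bits), selected upstream by a
#' domain-bias-aware screen and confirmed under cross-decoy validation.
#' They double as fixtures for overlap statistics and ensemble wiring.
#'
#' @return A named list of two [feature_view()] objects.
#' @examples
#' v <- packaged_views()
#' view_overlap_stats(v$list_1, v$list_2)
#' @export
packaged_views <- function() {
  path <- system.file("extdata", "selected_feature_sets.tsv",
                      package = "decoyscreen", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(tab$bit_name, tab$view), function(bits) bits)
  views <- lapply(names(out), function(nm) feature_view(nm, out[[nm]]))
  names(views) <- names(out)
  # preserve within-view publication order
  for (nm in names(views)) {
    ord <- tab$bit_name[tab$view == nm]
    views[[nm]] <- feature_view(nm, ord)
  }
  views
}
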