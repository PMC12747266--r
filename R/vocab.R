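# Element-hybridization node vocabulary. The model's node identity is the
# (element, hybridization) tuple, so Csp3 and Csp2 are distinct node classes;
# anything outside the declared chemistry falls into one unknown bucket.

#' Build the element-hybridization atom vocabulary
#'
#' The vocabulary is the Cartesian product of an element set and a
#' hybridization-label set, in deterministic (element-major) order, plus a
#' single out-of-vocabulary bucket at the end. Atom identities are looked up
#' as (element, hybridization) pairs; unseen pairs map to the unknown index.
#'
#' @param elements character vector of element symbols (heavy atoms only).
#' @param hybridizations character vector of hybridization labels.
#' @return an object of class `atom_vocab`: a list with `entries` (data.frame
#'   of element/hybridization per index), `unknown_index` and `size`.
#' @examples
#' \dontrun{
#' v <- build_atom_vocab(c("C", "N"), c("SP2", "SP3"))
#' v$size  # 5: four tuples plus the unknown bucket
#' }
#' @export
build_atom_vocab <- function(elements = default_elements(),
                             hybridizations = default_hybridizations()) {
  if (length(elements) == 0L || length(hybridizations) == 0L) {
    stopf("element and hybridization sets must be non-empty")
  }
  if (anyDuplicated(elements)) stopf("duplicate element symbols in vocabulary")
  if (anyDuplicated(hybridizations)) stopf("duplicate hybridization labels in vocabulary")
  entries <- expand.grid(
    hybridization = hybridizations,
    element = elements,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )[, c("element", "hybridization")]
  vocab <- list(
    entries = entries,
    unknown_index = nrow(entries) + 1L,
    size = nrow(entries) + 1L
  )
  class(vocab) <- "atom_vocab"
  vocab
}

#' @export
print.atom_vocab <- function(x, ...) {
  cat(sprintf("<atom_vocab> %d element-hybridization tuples + 1 unknown bucket\n",
              nrow(x$entries)))
  invisible(x)
}

#' Default heavy-atom element set for drug-like chemistry
#' @return character vector of element symbols.
#' @export
default_elements <- function() {
  c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si", "Se")
}

#' Default hybridization label set
#'
#' RDKit hybridization states; anything else (e.g. UNSPECIFIED) is mapped to
#' `"OTHER"` before lookup.
#' @return character vector of labels.
#' @export
default_hybridizations <- function() {
  c("S", "SP", "SP2", "SP3", "SP3D", "SP3D2", "OTHER")
}

normalize_hyb_label <- function(hyb, vocab_labels) {
  ifelse(hyb %in% vocab_labels, hyb, "OTHER")
}

#' Look up vocabulary indices for (element, hybridization) pairs
#'
#' @param vocab an `atom_vocab`.
#' @param element character vector of element symbols.
#' @param hybridization character vector of hybridization labels (recycled
#'   against `element`).
#' @return integer vector of 1-based vocabulary indices; out-of-vocabulary
#'   pairs return `vocab$unknown_index`.
#' @export
vocab_lookup <- function(vocab, element, hybridization) {
  stopifnot(inherits(vocab, "atom_vocab"))
  labels <- unique(vocab$entries$hybridization)
  hybridization <- normalize_hyb_label(hybridization, labels)
  key <- paste(element, hybridization, sep = "|")
  table_key <- paste(vocab$entries$element, vocab$entries$hybridization, sep = "|")
  idx <- match(key, table_key)
  idx[is.na(idx)] <- vocab$unknown_index
  idx
}
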