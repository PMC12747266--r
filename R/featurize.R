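# Featurization: canonical SMILES -> molecular graph (11 node features,
# 5 edge features, directed edge list) and 544-dimensional descriptor vector
# (512 Morgan bits followed by 32 physicochemical descriptors).

N_NODE_FEATURES <- 11L
N_EDGE_FEATURES <- 5L
N_FP_BITS <- 512L
N_PHYSCHEM <- 32L
N_DESCRIPTORS <- N_FP_BITS + N_PHYSCHEM  # 544

NODE_FEATURE_NAMES <- c(
  "vocab_id", "atomic_num", "degree", "formal_charge", "total_h",
  "aromatic", "in_ring", "chiral_r", "chiral_s", "smallest_ring", "total_valence"
)
EDGE_FEATURE_NAMES <- c("bond_type", "conjugated", "in_ring", "aromatic", "stereo")

graph_from_record <- function(rec, vocab) {
  nf <- do.call(rbind, lapply(rec$node_feats, function(r) as.numeric(unlist(r))))
  vocab_id <- vocab_lookup(vocab, unlist(rec$element), unlist(rec$hybridization))
  node_features <- cbind(vocab_id, nf)
  colnames(node_features) <- NODE_FEATURE_NAMES
  n <- nrow(node_features)

  src <- as.integer(unlist(rec$bond_src)) + 1L
  dst <- as.integer(unlist(rec$bond_dst)) + 1L
  if (length(src)) {
    ef <- do.call(rbind, lapply(rec$bond_feats, function(r) as.numeric(unlist(r))))
    # each chemical bond becomes two directed entries with identical features
    edge_index <- rbind(c(src, dst), c(dst, src))
    edge_features <- rbind(ef, ef)
  } else {
    edge_index <- matrix(integer(0), nrow = 2)
    edge_features <- matrix(numeric(0), ncol = N_EDGE_FEATURES)
  }
  colnames(edge_features) <- EDGE_FEATURE_NAMES

  structure(
    list(
      n_nodes = n,
      node_vocab_ids = as.integer(vocab_id),
      node_features = node_features,
      edge_index = edge_index,
      edge_features = edge_features,
      mol_size = as.integer(rec$mol_size)
    ),
    class = "molecular_graph"
  )
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %d nodes, %d directed edges, mol_size %d\n",
              x$n_nodes, ncol(x$edge_index), x$mol_size))
  invisible(x)
}

#' Convert SMILES to hybridization-explicit molecular graphs
#'
#' Atoms become nodes and bonds become directed edge pairs (i to j and j to
#' i, identical features). Hydrogens are implicit: they are not nodes but are
#' counted in the total-hydrogen node feature. Node features, in order:
#' vocabulary id (element-hybridization tuple), atomic number, degree, formal
#' charge, total hydrogen count, aromatic flag, ring flag, R-chirality flag,
#' S-chirality flag, smallest-ring size (0 outside rings), total valence.
#' Edge features: bond-type code (1 single, 2 double, 3 triple, 4 aromatic),
#' conjugated, ring and aromatic flags, bond-stereo code (0 = none).
#'
#' @param smiles character vector of valid SMILES.
#' @param vocab an `atom_vocab`; defaults to the package vocabulary.
#' @return a list of `molecular_graph` objects (a single object if one
#'   SMILES was given and `simplify = TRUE`). `mol_size` is the sum of
#'   heavy-atom atomic numbers.
#' @param simplify return the bare graph for a single input.
#' @export
smiles_to_graph <- function(smiles, vocab = build_atom_vocab(), simplify = TRUE) {
  recs <- chem_featurize_raw(smiles)
  bad <- which(!vapply(recs, function(x) isTRUE(x$ok), logical(1)))
  if (length(bad)) stopf("featurization failed: %s", recs[[bad[1]]]$error)
  graphs <- lapply(recs, graph_from_record, vocab = vocab)
  if (simplify && length(graphs) == 1L) graphs[[1]] else graphs
}

#' Molecular size feature
#'
#' Sum of atomic numbers over heavy atoms (implicit hydrogens excluded);
#' the scalar size feature concatenated into the fused representation.
#'
#' @param smiles character vector of valid SMILES.
#' @return integer vector.
#' @export
molecular_size <- function(smiles) {
  recs <- chem_featurize_raw(smiles)
  bad <- which(!vapply(recs, function(x) isTRUE(x$ok), logical(1)))
  if (length(bad)) stopf("featurization failed: %s", recs[[bad[1]]]$error)
  vapply(recs, function(x) as.integer(x$mol_size), integer(1))
}

#' Physicochemical descriptor block
#'
#' Computes the package's 32-descriptor registry (lipophilicity, hydrogen
#' bonding, ring and shape counts, electronic and complexity descriptors) in
#' fixed declared order.
#'
#' @param smiles character vector of valid SMILES.
#' @return numeric matrix, one row per molecule, 32 named columns.
#' @export
compute_physchem <- function(smiles) {
  recs <- chem_featurize_raw(smiles)
  bad <- which(!vapply(recs, function(x) isTRUE(x$ok), logical(1)))
  if (length(bad)) stopf("descriptor computation failed: %s", recs[[bad[1]]]$error)
  out <- do.call(rbind, lapply(recs, function(x) as.numeric(unlist(x$physchem))))
  colnames(out) <- unlist(recs[[1]]$physchem_names)
  rownames(out) <- smiles
  out
}

#' Morgan circular fingerprint
#'
#' Radius-2 circular (Morgan) fingerprint folded to 512 bits.
#'
#' @param smiles character vector of valid SMILES.
#' @return integer matrix of 0/1, one row per molecule, 512 columns.
#' @export
compute_fingerprint <- function(smiles) {
  recs <- chem_featurize_raw(smiles)
  bad <- which(!vapply(recs, function(x) isTRUE(x$ok), logical(1)))
  if (length(bad)) stopf("fingerprint computation failed: %s", recs[[bad[1]]]$error)
  out <- matrix(0L, nrow = length(recs), ncol = N_FP_BITS)
  for (i in seq_along(recs)) {
    on <- as.integer(unlist(recs[[i]]$fp_on_bits)) + 1L
    out[i, on] <- 1L
  }
  colnames(out) <- paste0("fp", seq_len(N_FP_BITS) - 1L)
  rownames(out) <- smiles
  out
}

#' Combined 544-dimensional descriptor vectors
#'
#' Concatenation `[fingerprint (512) || physchem (32)]` per molecule.
#'
#' @param smiles character vector of valid SMILES.
#' @return numeric matrix with 544 named columns.
#' @export
compute_descriptors <- function(smiles) {
  recs <- chem_featurize_raw(smiles)
  bad <- which(!vapply(recs, function(x) isTRUE(x$ok), logical(1)))
  if (length(bad)) stopf("descriptor computation failed: %s", recs[[bad[1]]]$error)
  descriptors_from_records(recs, smiles)
}

descriptors_from_records <- function(recs, smiles) {
  fp <- matrix(0, nrow = length(recs), ncol = N_FP_BITS)
  for (i in seq_along(recs)) {
    on <- as.integer(unlist(recs[[i]]$fp_on_bits)) + 1L
    fp[i, on] <- 1
  }
  pc <- do.call(rbind, lapply(recs, function(x) as.numeric(unlist(x$physchem))))
  out <- cbind(fp, pc)
  colnames(out) <- c(paste0("fp", seq_len(N_FP_BITS) - 1L),
                     unlist(recs[[1]]$physchem_names))
  rownames(out) <- smiles
  out
}

#' Fit a z-score normalizer on training descriptors
#'
#' Per-dimension mean and population standard deviation over the training
#' vectors only; test and prediction inputs are always standardized with
#' these training statistics.
#'
#' @param x numeric matrix of descriptor vectors (rows = molecules).
#' @return an object of class `descriptor_normalizer`.
#' @export
fit_normalizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stopf("need at least 2 vectors to fit a normalizer")
  mu <- colMeans(x)
  # population (1/n) standard deviation; two points 0,2 give sd 1
  sdv <- sqrt(colMeans(sweep(x, 2, mu)^2))
  structure(
    list(means = mu, stds = sdv, fitted_on = nrow(x)),
    class = "descriptor_normalizer"
  )
}

#' @export
print.descriptor_normalizer <- function(x, ...) {
  cat(sprintf("<descriptor_normalizer> %d dimensions, fitted on %d samples (%d constant)\n",
              length(x$means), x$fitted_on, sum(x$stds == 0)))
  invisible(x)
}

#' Apply a fitted normalizer
#'
#' Standardizes as `(x - mean) / max(std, eps)` per dimension with
#' `eps = 1e-8`; dimensions that were constant in training map to 0
#' regardless of input (fingerprint bits that never fire on a small training
#' set must not divide by zero).
#'
#' @param norm a `descriptor_normalizer`.
#' @param x numeric matrix (or single vector) of descriptor vectors.
#' @return standardized numeric matrix of the same shape.
#' @export
apply_normalizer <- function(norm, x) {
  stopifnot(inherits(norm, "descriptor_normalizer"))
  single <- is.null(dim(x))
  x <- if (single) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != length(norm$means)) {
    stopf("descriptor length %d does not match normalizer length %d",
          ncol(x), length(norm$means))
  }
  eps <- 1e-8
  z <- sweep(sweep(x, 2, norm$means), 2, pmax(norm$stds, eps), "/")
  z[, norm$stds == 0] <- 0
  if (single) z[1, ] else z
}

#' Featurize a cleaned dataset for modelling
#'
#' Runs one batched chemistry call over the unique SMILES of a cleaned
#' activity table and assembles everything the model consumes: molecular
#' graphs, 544-vectors, molecular sizes, labels and target ids.
#'
#' @param data data.frame with columns `canonical_smiles`, `target_id` and
#'   (for training data) `log_ic50`; bare SMILES vectors are accepted for
#'   prediction.
#' @param vocab an `atom_vocab`.
#' @param normalizer optional fitted `descriptor_normalizer`; when supplied,
#'   `desc` is standardized with it (train statistics), otherwise `desc` is
#'   returned raw and a normalizer can be fitted on it afterwards.
#' @return an object of class `mol_features`: list with `graphs` (per row),
#'   `desc` (n x 544 matrix), `mol_size`, `smiles`, `target`, `y`, `vocab`,
#'   `normalizer`.
#' @export
featurize_dataset <- function(data, vocab = build_atom_vocab(), normalizer = NULL) {
  if (is.character(data)) {
    data <- data.frame(canonical_smiles = data, target_id = NA_character_,
                       stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(data), "canonical_smiles" %in% names(data))
  smi <- data$canonical_smiles
  uniq <- unique(smi)
  recs <- chem_featurize_raw(uniq)
  bad <- which(!vapply(recs, function(x) isTRUE(x$ok), logical(1)))
  if (length(bad)) stopf("featurization failed: %s", recs[[bad[1]]]$error)
  names(recs) <- uniq

  graphs_u <- lapply(recs, graph_from_record, vocab = vocab)
  desc_u <- descriptors_from_records(recs, uniq)
  size_u <- vapply(recs, function(x) as.numeric(x$mol_size), numeric(1))

  idx <- match(smi, uniq)
  desc <- desc_u[idx, , drop = FALSE]
  if (!is.null(normalizer)) desc <- apply_normalizer(normalizer, desc)
  out <- list(
    graphs = graphs_u[idx],
    desc = desc,
    mol_size = size_u[idx],
    smiles = smi,
    target = if ("target_id" %in% names(data)) data$target_id else rep(NA_character_, length(smi)),
    y = if ("log_ic50" %in% names(data)) data$log_ic50 else rep(NA_real_, length(smi)),
    vocab = vocab,
    normalizer = normalizer
  )
  class(out) <- "mol_features"
  out
}

#' @export
print.mol_features <- function(x, ...) {
  cat(sprintf("<mol_features> %d samples (%d unique molecules), %d descriptor dims, %s\n",
              length(x$smiles), length(unique(x$smiles)), ncol(x$desc),
              if (is.null(x$normalizer)) "raw descriptors" else "normalized descriptors"))
  invisible(x)
}

# subset rows of a mol_features object
feats_subset <- function(feats, i) {
  out <- feats
  out$graphs <- feats$graphs[i]
  out$desc <- feats$desc[i, , drop = FALSE]
  out$mol_size <- feats$mol_size[i]
  out$smiles <- feats$smiles[i]
  out$target <- feats$target[i]
  out$y <- feats$y[i]
  out
}

feats_n <- function(feats) length(feats$smiles)
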