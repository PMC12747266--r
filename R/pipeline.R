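# ChEMBL-style activity-table curation: validate SMILES, filter to numeric
# IC50 in recognised units, convert to nM, drop nonpositive values, collapse
# duplicate (compound, target) pairs to the median, log10-transform, and
# account for every dropped row in a provenance tally.

PROVENANCE_STAGES <- c("invalid_smiles", "bad_value", "bad_units",
                       "nonpositive", "duplicates")

#' Read a raw activity table
#'
#' Expects the column layout of ChEMBL web-service activity exports:
#' `smiles` (or `canonical_smiles`), `target_chembl_id` (or `target_id`),
#' `standard_value`, `standard_units`, `standard_type`.
#'
#' @param path CSV file path (UTF-8, header required).
#' @return data.frame of raw activity records, one per measurement.
#' @export
read_activity_csv <- function(path) {
  if (!file.exists(path)) stopf("activity file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", encoding = "UTF-8")
  nm <- names(raw)
  pick <- function(...) {
    cand <- c(...)
    hit <- cand[cand %in% nm]
    if (!length(hit)) stopf("missing required column (one of: %s)",
                            paste(cand, collapse = ", "))
    raw[[hit[1]]]
  }
  data.frame(
    smiles = pick("smiles", "canonical_smiles"),
    target_id = pick("target_chembl_id", "target_id"),
    standard_value = pick("standard_value"),
    standard_units = pick("standard_units"),
    standard_type = pick("standard_type"),
    stringsAsFactors = FALSE
  )
}

unit_to_nm_factor <- function(units) {
  u <- tolower(trimws(units))
  factor <- rep(NA_real_, length(u))
  factor[u == "nm"] <- 1
  factor[u %in% c("um", "µm", "μm")] <- 1000
  factor
}

#' Clean raw activity records into model-ready samples
#'
#' Applies, in order: (1) drop rows whose SMILES does not parse (multi-
#' fragment inputs are first reduced to their largest fragment, counted in
#' `provenance$multi_fragment` but not dropped); (2) drop rows with missing
#' or non-numeric `standard_value` or `standard_type` other than IC50;
#' (3) keep only nM and uM units and convert to nM; (4) drop IC50 <= 0;
#' (5) collapse duplicate (canonical SMILES, target) pairs to the median
#' IC50 in nM (mean of the two central values for even counts); (6) take
#' log10. Every dropped row is tallied by stage so that
#' `n_raw = nrow(clean) + sum(drops)` always holds.
#'
#' @param records data.frame of raw records as from [read_activity_csv()].
#' @return an object of class `clean_dataset`: a list with `samples`
#'   (data.frame `canonical_smiles`, `target_id`, `log_ic50`) and
#'   `provenance` (named drop counts plus `n_raw`, `n_clean`,
#'   `multi_fragment`).
#' @examples
#' \dontrun{
#' recs <- data.frame(smiles = c("CCO", "CCO"), target_id = "T1",
#'                    standard_value = c("100", "400"),
#'                    standard_units = "nM", standard_type = "IC50")
#' clean_activities(recs)$samples$log_ic50  # log10(250)
#' }
#' @export
clean_activities <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("smiles", "target_id", "standard_value", "standard_units", "standard_type")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) stopf("records lack columns: %s", paste(missing_cols, collapse = ", "))

  drops <- stats::setNames(rep(0L, length(PROVENANCE_STAGES)), PROVENANCE_STAGES)
  n_raw <- nrow(records)
  multi_fragment <- 0L

  if (n_raw == 0L) {
    return(new_clean_dataset(
      data.frame(canonical_smiles = character(0), target_id = character(0),
                 log_ic50 = numeric(0), stringsAsFactors = FALSE),
      c(n_raw = 0L, drops, multi_fragment = 0L, n_clean = 0L)
    ))
  }

  # stage 1: SMILES validation + canonicalization (largest fragment kept)
  canon <- canonicalize_smiles(records$smiles, largest_fragment = TRUE,
                               on_error = "na", details = TRUE)
  ok <- canon$ok
  drops["invalid_smiles"] <- sum(!ok)
  multi_fragment <- sum(canon$n_frags[ok] > 1L, na.rm = TRUE)
  df <- records[ok, , drop = FALSE]
  df$canonical_smiles <- canon$canonical[ok]

  # stage 2: numeric value and IC50 type
  value <- suppressWarnings(as.numeric(df$standard_value))
  type_ok <- toupper(trimws(df$standard_type)) == "IC50"
  keep <- !is.na(value) & type_ok
  drops["bad_value"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  value <- value[keep]

  # stage 3: recognised units, converted to nM
  factor_nm <- unit_to_nm_factor(df$standard_units)
  keep <- !is.na(factor_nm)
  drops["bad_units"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  ic50_nm <- value[keep] * factor_nm[keep]

  # stage 4: strictly positive concentrations only
  keep <- ic50_nm > 0
  drops["nonpositive"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  ic50_nm <- ic50_nm[keep]

  # stage 5: median per (canonical SMILES, target); stage 6: log10
  if (nrow(df)) {
    key <- paste(df$canonical_smiles, df$target_id, sep = "\r")
    med <- tapply(ic50_nm, key, stats::median)
    first <- !duplicated(key)
    drops["duplicates"] <- sum(!first)
    samples <- data.frame(
      canonical_smiles = df$canonical_smiles[first],
      target_id = df$target_id[first],
      log_ic50 = log10(as.numeric(med[key[first]])),
      stringsAsFactors = FALSE
    )
    samples <- samples[order(samples$target_id, samples$canonical_smiles), ]
    rownames(samples) <- NULL
  } else {
    samples <- data.frame(canonical_smiles = character(0), target_id = character(0),
                          log_ic50 = numeric(0), stringsAsFactors = FALSE)
  }

  new_clean_dataset(samples, c(n_raw = n_raw, drops,
                               multi_fragment = multi_fragment,
                               n_clean = nrow(samples)))
}

new_clean_dataset <- function(samples, provenance) {
  structure(list(samples = samples, provenance = as.list(provenance)),
            class = "clean_dataset")
}

#' @export
print.clean_dataset <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<clean_dataset> %d samples from %d raw rows (%d targets)\n",
              p$n_clean, p$n_raw, length(unique(x$samples$target_id))))
  dropped <- unlist(p[PROVENANCE_STAGES])
  cat("  dropped:", paste(sprintf("%s=%d", names(dropped), dropped), collapse = ", "), "\n")
  invisible(x)
}

#' Seeded train/test split of a cleaned dataset
#'
#' Record-level uniform random partition driven only by the seed: the same
#' seed always yields the same membership. Note the leakage caveat of
#' record-level splitting in multi-target data: the same compound may sit in
#' train for one target and in test for another; `by_compound = TRUE` splits
#' at the compound level instead.
#'
#' @param dataset a `clean_dataset` or its `samples` data.frame.
#' @param test_fraction fraction held out, in (0, 1); train size is
#'   `round((1 - test_fraction) * n)`.
#' @param seed integer seed.
#' @param by_compound split whole compounds rather than records.
#' @return list with class `split_dataset`: `train`, `test` (data.frames),
#'   `train_idx`, `test_idx`, `seed`, `test_fraction`.
#' @export
split_activities <- function(dataset, test_fraction = 0.2, seed = 42,
                             by_compound = FALSE) {
  samples <- if (inherits(dataset, "clean_dataset")) dataset$samples else dataset
  stopifnot(is.data.frame(samples))
  n <- nrow(samples)
  if (n < 2L) stopf("need at least 2 samples to split")
  if (!(test_fraction > 0 && test_fraction < 1)) stopf("test_fraction must be in (0, 1)")

  if (by_compound) {
    compounds <- unique(samples$canonical_smiles)
    k <- length(compounds)
    n_train_c <- round((1 - test_fraction) * k)
    perm <- with_seed(seed, sample.int(k))
    train_compounds <- compounds[perm[seq_len(n_train_c)]]
    train_idx <- which(samples$canonical_smiles %in% train_compounds)
    test_idx <- setdiff(seq_len(n), train_idx)
  } else {
    n_train <- round((1 - test_fraction) * n)
    perm <- with_seed(seed, sample.int(n))
    train_idx <- sort(perm[seq_len(n_train)])
    test_idx <- sort(perm[-seq_len(n_train)])
  }
  structure(
    list(
      train = samples[train_idx, , drop = FALSE],
      test = samples[test_idx, , drop = FALSE],
      train_idx = train_idx,
      test_idx = test_idx,
      seed = seed,
      test_fraction = test_fraction
    ),
    class = "split_dataset"
  )
}

#' @export
print.split_dataset <- function(x, ...) {
  cat(sprintf("<split_dataset> %d train / %d test (seed %d)\n",
              nrow(x$train), nrow(x$test), x$seed))
  invisible(x)
}

#' Oversample training records so every target contributes equally
#'
#' For each target, records are drawn with replacement (seeded) until every
#' target's count equals the maximum per-target count; all original records
#' are retained and the result is shuffled with the same seed. Applied to
#' the training set only.
#'
#' @param train data.frame of training samples (needs a `target_id` column).
#' @param seed integer seed.
#' @return data.frame with equal per-target counts.
#' @export
oversample_by_target <- function(train, seed = 42) {
  if (inherits(train, "clean_dataset")) train <- train$samples
  stopifnot(is.data.frame(train))
  if (nrow(train) == 0L) stopf("cannot oversample an empty training set")
  counts <- table(train$target_id)
  target_max <- max(counts)
  with_seed(seed, {
    extra_idx <- unlist(lapply(names(counts), function(tg) {
      rows <- which(train$target_id == tg)
      deficit <- target_max - length(rows)
      if (deficit > 0L) sample(rows, deficit, replace = TRUE) else integer(0)
    }), use.names = FALSE)
    out <- train[c(seq_len(nrow(train)), extra_idx), , drop = FALSE]
    out <- out[sample.int(nrow(out)), , drop = FALSE]
  })
  rownames(out) <- NULL
  out
}

#' Write a cleaned dataset plus provenance sidecar
#'
#' @param dataset a `clean_dataset`.
#' @param path output CSV path (`canonical_smiles`, `target_id`, `log_ic50`);
#'   a JSON provenance sidecar is written next to it as `<path>.provenance.json`.
#' @return invisibly, the paths written.
#' @export
write_clean_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "clean_dataset"))
  utils::write.csv(dataset$samples, path, row.names = FALSE)
  sidecar <- paste0(path, ".provenance.json")
  jsonlite::write_json(dataset$provenance, sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(path, sidecar))
}
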