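# Deterministic synthetic data: drug-like molecules assembled from a fixed
# fragment grammar (rings, chains, common substituents), and activity tables
# with a planted structure-activity signal, optional duplicate rows and
# deliberately invalid rows, so the whole pipeline is testable offline.

# Substituents valid in any SMILES context the templates use (chain prefix,
# parenthesised branch, chain suffix) ...
FRAGMENT_SUBS_ANY <- c("C", "CC", "CCC", "CCCC", "N", "O", "F", "Cl", "Br",
                       "C(=O)O", "OC", "CN", "CCO", "C(C)C")
# ... and substituents only valid as a branch/suffix (attachment atom first).
FRAGMENT_SUBS_TAIL <- c("C(F)(F)F", "C#N")

# Scaffold templates; slot contexts: "p" = prefix position (restricted set),
# "t" = branch/suffix position (full set).
FRAGMENT_TEMPLATES <- list(
  list(fmt = "%sc1ccccc1",             ctx = "p"),
  list(fmt = "%sc1ccc(%s)cc1",         ctx = c("p", "t")),
  list(fmt = "%sc1cccc(%s)c1",         ctx = c("p", "t")),
  list(fmt = "%sc1cc(%s)cc(%s)c1",     ctx = c("p", "t", "t")),
  list(fmt = "%sc1ccncc1",             ctx = "p"),
  list(fmt = "%sc1cccnc1",             ctx = "p"),
  list(fmt = "%sc1ccc(%s)nc1",         ctx = c("p", "t")),
  list(fmt = "%sc1ccco1",              ctx = "p"),
  list(fmt = "%sc1ccc(%s)o1",          ctx = c("p", "t")),
  list(fmt = "%sc1cccs1",              ctx = "p"),
  list(fmt = "%sC1CCCCC1",             ctx = "p"),
  list(fmt = "%sC1CCN(%s)CC1",         ctx = c("p", "p")),
  list(fmt = "%sC1CCOC1",              ctx = "p"),
  list(fmt = "%sCC%s",                 ctx = c("p", "t")),
  list(fmt = "%sCCC%s",                ctx = c("p", "t")),
  list(fmt = "%sCC(%s)C%s",            ctx = c("p", "t", "t")),
  list(fmt = "C[C@H](N)%s",            ctx = "t"),
  list(fmt = "C[C@@H](O)%s",           ctx = "t"),
  list(fmt = "%sc1ccc2ccccc2c1",       ctx = "p"),
  list(fmt = "O=C(%s)Nc1ccc(%s)cc1",   ctx = c("t", "t"))
)

#' Specification of a synthetic activity fixture
#'
#' Describes the study conditions a generated dataset emulates: how many
#' molecules and targets, the per-target size imbalance, the planted
#' structure-activity signal and its noise, and the rates of duplicate and
#' deliberately invalid rows used to exercise the cleaning pipeline.
#'
#' @param n_molecules number of distinct molecules.
#' @param n_targets number of target labels.
#' @param target_size_ratios positive relative group sizes (recycled/
#'   truncated to `n_targets`).
#' @param noise_sd Gaussian noise on log10 IC50 (log10 nM units).
#' @param signal_weights named weights over physicochemical descriptors
#'   (standardized within the generated set); the descriptor-planted signal.
#' @param target_offsets per-target additive shifts in log10 units; default
#'   an equispaced ladder in [-0.25, 0.25].
#' @param intercept mean log10 IC50 in nM (3 = 1 uM, a realistic potency
#'   midpoint).
#' @param signal_mode `"descriptor"` plants a descriptor-linear signal;
#'   `"substructure"` plants a fragment-indicator shift (presence of
#'   `substructure_marker`) that only the graph branch can see.
#' @param substructure_marker substituent whose presence shifts activity in
#'   substructure mode.
#' @param substructure_delta activity shift (log10 units) for marker-bearing
#'   molecules.
#' @param dup_fraction fraction of extra duplicate (compound, target) rows
#'   with jittered IC50.
#' @param dirty_fraction fraction of deliberately invalid rows (bad SMILES,
#'   nonpositive or missing values, unknown units, wrong assay type).
#' @param seed integer seed; the whole fixture is a pure function of the spec.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_molecules = 200,
                         n_targets = 3,
                         target_size_ratios = c(3, 2, 1),
                         noise_sd = 0.3,
                         signal_weights = c(LogP = 1.0, TPSA = -0.8, Rings = 0.5),
                         target_offsets = NULL,
                         intercept = 3,
                         signal_mode = c("descriptor", "substructure"),
                         substructure_marker = "Cl",
                         substructure_delta = 2,
                         dup_fraction = 0.05,
                         dirty_fraction = 0.1,
                         seed = 42) {
  signal_mode <- match.arg(signal_mode)
  stopifnot(n_molecules >= 1, n_targets >= 1,
            all(target_size_ratios > 0),
            dirty_fraction >= 0, dirty_fraction < 1,
            dup_fraction >= 0, noise_sd >= 0)
  target_size_ratios <- rep_len(target_size_ratios, n_targets)
  if (is.null(target_offsets)) {
    target_offsets <- if (n_targets == 1) 0 else seq(-0.25, 0.25, length.out = n_targets)
  }
  structure(
    list(
      n_molecules = as.integer(n_molecules),
      n_targets = as.integer(n_targets),
      target_size_ratios = target_size_ratios,
      noise_sd = noise_sd,
      signal_weights = signal_weights,
      target_offsets = rep_len(target_offsets, n_targets),
      intercept = intercept,
      signal_mode = signal_mode,
      substructure_marker = substructure_marker,
      substructure_delta = substructure_delta,
      dup_fraction = dup_fraction,
      dirty_fraction = dirty_fraction,
      seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

draw_substituent <- function(ctx, exclude = character(0), force = NULL) {
  pool <- if (ctx == "p") FRAGMENT_SUBS_ANY else c(FRAGMENT_SUBS_ANY, FRAGMENT_SUBS_TAIL)
  pool <- setdiff(pool, exclude)
  if (!is.null(force)) force else sample(pool, 1)
}

draw_molecule <- function(marker_policy = NULL, marker = "Cl") {
  tpl <- FRAGMENT_TEMPLATES[[sample.int(length(FRAGMENT_TEMPLATES), 1)]]
  k <- length(tpl$ctx)
  exclude <- if (identical(marker_policy, FALSE)) marker else character(0)
  subs <- vapply(tpl$ctx, draw_substituent, character(1), exclude = exclude)
  if (isTRUE(marker_policy)) subs[sample.int(k, 1)] <- marker
  do.call(sprintf, c(list(tpl$fmt), as.list(subs)))
}

#' Generate synthetic drug-like molecules
#'
#' Assembles SMILES from the fixed fragment grammar (benzene, pyridine,
#' furan, thiophene, naphthalene, saturated rings, chains and amides with
#' halogen/hydroxyl/amine/carboxyl/nitrile substituents), guaranteeing
#' parseability by construction. Molecules are unique as canonical SMILES;
#' with `dup_fraction > 0` in the spec, a controlled fraction of positions
#' repeat an earlier molecule to exercise deduplication.
#'
#' @param spec a [fixture_spec()].
#' @return character vector of `spec$n_molecules` SMILES; attribute
#'   `has_marker` flags molecules containing the substructure marker.
#' @export
generate_molecules <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    want <- spec$n_molecules
    smiles <- character(0)
    marker_policy <- NULL
    tries <- 0L
    while (length(smiles) < want && tries < 60L) {
      tries <- tries + 1L
      batch_n <- max(64L, 2L * (want - length(smiles)))
      policy <- if (spec$signal_mode == "substructure") {
        sample(c(TRUE, FALSE), batch_n, replace = TRUE)
      } else {
        rep(list(NULL), batch_n)
      }
      batch <- vapply(seq_len(batch_n), function(i) {
        draw_molecule(if (is.list(policy)) policy[[i]] else policy[i],
                      spec$substructure_marker)
      }, character(1))
      canon <- canonicalize_smiles(batch, on_error = "na")
      keep <- !is.na(canon) & !duplicated(canon) & !(canon %in% smiles)
      smiles <- c(smiles, canon[keep])
    }
    if (length(smiles) < want) {
      stopf("fragment grammar exhausted at %d unique molecules (%d requested)",
            length(smiles), want)
    }
    smiles <- smiles[seq_len(want)]
    if (spec$dup_fraction > 0 && want > 1) {
      n_dup <- floor(spec$dup_fraction * want)
      if (n_dup > 0) {
        pos <- sample(2:want, n_dup)
        for (p in pos) smiles[p] <- smiles[sample.int(p - 1L, 1)]
      }
    }
    structure(smiles,
              has_marker = grepl(spec$substructure_marker, smiles, fixed = TRUE))
  })
}

target_assignment <- function(n, ratios) {
  counts <- floor(n * ratios / sum(ratios))
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- n * ratios / sum(ratios) - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  sample(rep(sprintf("SYNTH%d", seq_along(ratios)), counts))
}

#' Generate a raw synthetic activity table
#'
#' Produces rows in the shape of a ChEMBL activity export (`smiles`,
#' `target_id`, `standard_value`, `standard_units`, `standard_type`) with a
#' planted signal: log10 IC50 (nM) = intercept + signal + target offset +
#' Gaussian noise, where the signal is either a linear combination of
#' standardized physicochemical descriptors (`"descriptor"` mode) or an
#' activity shift for molecules carrying a marker substructure
#' (`"substructure"` mode). Values are emitted in mixed nM/uM units;
#' duplicate (compound, target) rows carry jittered values; dirty rows
#' (malformed SMILES, nonpositive/missing values, unknown units, non-IC50
#' types) are appended at the spec'd rate.
#'
#' @param spec a [fixture_spec()].
#' @return data.frame of raw activity rows; column `row_kind` labels each
#'   row (`clean`, `duplicate`, or `dirty_<stage>` naming the cleaning stage
#'   expected to drop it); attribute `truth` holds the noiseless-duplicate
#'   clean table (`canonical_smiles`, `target_id`, `log_ic50`) the pipeline
#'   should recover, and attribute `molecules` the per-molecule signal parts.
#' @export
generate_activity_table <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  mols <- generate_molecules(spec)
  has_marker <- attr(mols, "has_marker")
  uniq <- unique(mols)
  physchem <- compute_physchem(uniq)

  with_seed(spec$seed + 1L, {
    target <- target_assignment(length(mols), spec$target_size_ratios)

    # planted signal on the unique molecules, then indexed per row
    if (spec$signal_mode == "descriptor") {
      w <- spec$signal_weights
      miss <- setdiff(names(w), colnames(physchem))
      if (length(miss)) stopf("unknown signal descriptors: %s", paste(miss, collapse = ", "))
      z <- scale(physchem[, names(w), drop = FALSE])
      z[is.nan(z)] <- 0
      signal_u <- as.vector(z %*% w)
    } else {
      signal_u <- spec$substructure_delta *
        as.numeric(grepl(spec$substructure_marker, uniq, fixed = TRUE))
      signal_u <- signal_u - mean(signal_u)
    }
    idx <- match(mols, uniq)
    log_ic50 <- spec$intercept + signal_u[idx] +
      spec$target_offsets[match(target, sprintf("SYNTH%d", seq_len(spec$n_targets)))] +
      stats::rnorm(length(mols), 0, spec$noise_sd)

    truth <- data.frame(
      canonical_smiles = mols, target_id = target, log_ic50 = log_ic50,
      stringsAsFactors = FALSE
    )
    # a molecule drawn twice for the same target deduplicates downstream;
    # keep the first occurrence as the expected clean row
    truth_key <- paste(truth$canonical_smiles, truth$target_id)
    truth <- truth[!duplicated(truth_key), ]

    emit_row <- function(smiles, target_id, ic50_nm, kind) {
      if (ic50_nm >= 1000) {
        data.frame(smiles = smiles, target_id = target_id,
                   standard_value = format(ic50_nm / 1000, digits = 10),
                   standard_units = "uM", standard_type = "IC50",
                   row_kind = kind, stringsAsFactors = FALSE)
      } else {
        data.frame(smiles = smiles, target_id = target_id,
                   standard_value = format(ic50_nm, digits = 10),
                   standard_units = "nM", standard_type = "IC50",
                   row_kind = kind, stringsAsFactors = FALSE)
      }
    }

    rows <- do.call(rbind, lapply(seq_along(mols), function(i) {
      emit_row(mols[i], target[i], 10^log_ic50[i],
               if (duplicated(truth_key)[i]) "duplicate" else "clean")
    }))

    n_dup <- floor(spec$dup_fraction * nrow(rows))
    if (n_dup > 0) {
      pick <- sample.int(nrow(rows), n_dup, replace = TRUE)
      dup_rows <- do.call(rbind, lapply(pick, function(i) {
        jitter <- 10^stats::rnorm(1, 0, 0.1)
        base <- as.numeric(rows$standard_value[i]) *
          ifelse(rows$standard_units[i] == "uM", 1000, 1)
        emit_row(rows$smiles[i], rows$target_id[i], base * jitter, "duplicate")
      }))
      rows <- rbind(rows, dup_rows)
    }

    n_dirty <- floor(spec$dirty_fraction * nrow(rows)) # nolint
    if (spec$dirty_fraction > 0) {
      n_dirty <- max(1L, floor(spec$dirty_fraction / (1 - spec$dirty_fraction) * nrow(rows)))
      kinds <- rep(c("dirty_invalid_smiles", "dirty_nonpositive",
                     "dirty_bad_units", "dirty_bad_value"),
                   length.out = n_dirty)
      dirty <- do.call(rbind, lapply(kinds, function(k) {
        tg <- sprintf("SYNTH%d", sample.int(spec$n_targets, 1))
        switch(k,
          dirty_invalid_smiles = data.frame(
            smiles = sample(c("C1CC", "not_a_smiles", "C(Q)C"), 1),
            target_id = tg, standard_value = "100",
            standard_units = "nM", standard_type = "IC50",
            row_kind = k, stringsAsFactors = FALSE),
          dirty_nonpositive = data.frame(
            smiles = sample(uniq, 1), target_id = tg,
            standard_value = sample(c("0", "-5"), 1),
            standard_units = "nM", standard_type = "IC50",
            row_kind = k, stringsAsFactors = FALSE),
          dirty_bad_units = data.frame(
            smiles = sample(uniq, 1), target_id = tg,
            standard_value = "10", standard_units = "ug.mL-1",
            standard_type = "IC50", row_kind = k, stringsAsFactors = FALSE),
          dirty_bad_value = data.frame(
            smiles = sample(uniq, 1), target_id = tg,
            standard_value = sample(c("", "n/a"), 1),
            standard_units = "nM",
            standard_type = sample(c("IC50", "Ki"), 1),
            row_kind = k, stringsAsFactors = FALSE)
        )
      }))
      rows <- rbind(rows, dirty)
    }

    rows <- rows[sample.int(nrow(rows)), ]
    rownames(rows) <- NULL
    attr(rows, "truth") <- truth
    attr(rows, "molecules") <- data.frame(
      canonical_smiles = uniq,
      signal = signal_u,
      has_marker = grepl(spec$substructure_marker, uniq, fixed = TRUE),
      stringsAsFactors = FALSE
    )
    rows
  })
}
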