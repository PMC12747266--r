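# Cleaning pipeline: canonicalization, filtering order, unit conversion,
# median deduplication, provenance accounting, splitting and oversampling.

make_records <- function(smiles, value, units = "nM", type = "IC50",
                         target = "T1") {
  data.frame(smiles = smiles, target_id = target,
             standard_value = as.character(value),
             standard_units = units, standard_type = type,
             stringsAsFactors = FALSE)
}

test_that("canonicalization maps equivalent SMILES together and is stable", {
  expect_identical(canonicalize_smiles("CCO"), canonicalize_smiles("CCO"))
  kek <- canonicalize_smiles(c("C1=CC=CC=C1", "c1ccccc1"))
  expect_identical(kek[1], kek[2])
  expect_identical(canonicalize_smiles("OCC"), canonicalize_smiles("CCO"))
  expect_error(canonicalize_smiles("C1CC"), "invalid SMILES")
  # largest-fragment option strips salts
  expect_identical(canonicalize_smiles("CCO.Cl", largest_fragment = TRUE),
                   canonicalize_smiles("CCO"))
})

test_that("duplicate measurements collapse to the median IC50", {
  # two measurements 100 and 400 nM -> midpoint 250 nM
  cd <- clean_activities(make_records(c("CCO", "OCC"), c(100, 400)))
  expect_equal(nrow(cd$samples), 1L)
  expect_equal(cd$samples$log_ic50, log10(250))
  expect_equal(cd$provenance$duplicates, 1L)
  # odd count -> middle value
  cd3 <- clean_activities(make_records(rep("CCO", 3), c(10, 1000, 100)))
  expect_equal(cd3$samples$log_ic50, 2)
})

test_that("values are log10-transformed in nM with unit conversion", {
  cd <- clean_activities(make_records("CCO", 1000))
  expect_equal(cd$samples$log_ic50, 3)
  # 2 uM = 2000 nM
  cd_um <- clean_activities(make_records("CCO", 2, units = "uM"))
  expect_equal(cd_um$samples$log_ic50, log10(2000))
  expect_equal(cd_um$samples$log_ic50, 3.30103, tolerance = 1e-6)
  # micro sign and case variants are recognised
  cd_mu <- clean_activities(make_records("CCO", 2, units = "µM"))
  expect_equal(cd_mu$samples$log_ic50, log10(2000))
  # multi-unit duplicates convert before the median: 100 nM and 0.4 uM -> 250
  cd_mix <- clean_activities(make_records(c("CCO", "CCO"), c(100, 0.4),
                                          units = c("nM", "uM")))
  expect_equal(cd_mix$samples$log_ic50, log10(250))
})

test_that("filters drop the right rows into the right provenance buckets", {
  recs <- rbind(
    make_records("CCO", 100),                       # clean
    make_records("C1CC", 100),                      # invalid smiles
    make_records("CCN", "abc"),                     # non-numeric value
    make_records("CCS", 100, type = "Ki"),          # wrong type
    make_records("CCF", 10, units = "ug/mL"),       # unknown units
    make_records("CCBr", 0),                        # nonpositive
    make_records("CCCl", -5)                        # nonpositive
  )
  cd <- clean_activities(recs)
  p <- cd$provenance
  expect_equal(p$invalid_smiles, 1L)
  expect_equal(p$bad_value, 2L)
  expect_equal(p$bad_units, 1L)
  expect_equal(p$nonpositive, 2L)
  expect_equal(nrow(cd$samples), 1L)
  expect_equal(p$n_raw,
               p$n_clean + p$invalid_smiles + p$bad_value + p$bad_units +
                 p$nonpositive + p$duplicates)
})

test_that("cleaning is idempotent and deduplicated", {
  tab <- dirty_table()
  cd <- clean_activities(tab)
  p <- cd$provenance
  dropped <- p$invalid_smiles + p$bad_value + p$bad_units + p$nonpositive + p$duplicates
  expect_equal(p$n_raw, p$n_clean + dropped)
  expect_equal(anyDuplicated(paste(cd$samples$canonical_smiles, cd$samples$target_id)), 0L)

  # feeding the cleaned output back through changes nothing
  again <- clean_activities(data.frame(
    smiles = cd$samples$canonical_smiles,
    target_id = cd$samples$target_id,
    standard_value = as.character(10^cd$samples$log_ic50),
    standard_units = "nM", standard_type = "IC50",
    stringsAsFactors = FALSE
  ))
  ord <- order(again$samples$target_id, again$samples$canonical_smiles)
  expect_equal(again$samples$canonical_smiles[ord], cd$samples$canonical_smiles)
  expect_equal(again$samples$log_ic50[ord], cd$samples$log_ic50, tolerance = 1e-12)
  expect_equal(again$provenance$n_clean, p$n_clean)
})

test_that("empty input yields an empty dataset with zeroed provenance", {
  cd <- clean_activities(data.frame(
    smiles = character(0), target_id = character(0),
    standard_value = character(0), standard_units = character(0),
    standard_type = character(0), stringsAsFactors = FALSE
  ))
  expect_equal(nrow(cd$samples), 0L)
  expect_equal(cd$provenance$n_raw, 0L)
  expect_equal(cd$provenance$n_clean, 0L)
})

test_that("split is a seeded partition with the stated sizes", {
  samples <- data.frame(canonical_smiles = sprintf("mol%02d", 1:10),
                        target_id = "T1", log_ic50 = rnorm(10),
                        stringsAsFactors = FALSE)
  sp <- split_activities(samples, 0.2, seed = 42)
  expect_equal(nrow(sp$train), 8L)
  expect_equal(nrow(sp$test), 2L)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0L)
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:10)

  # determinism: identical membership for identical seeds
  sp2 <- split_activities(samples, 0.2, seed = 42)
  expect_identical(sp$train_idx, sp2$train_idx)

  # different seeds give different memberships on 30 samples
  big <- data.frame(canonical_smiles = sprintf("mol%02d", 1:30),
                    target_id = "T1", log_ic50 = rnorm(30),
                    stringsAsFactors = FALSE)
  s42 <- split_activities(big, 0.2, seed = 42)
  s43 <- split_activities(big, 0.2, seed = 43)
  expect_false(identical(s42$train_idx, s43$train_idx))

  expect_error(split_activities(samples[1, ], 0.2), "at least 2")
  expect_error(split_activities(samples, 1.2), "test_fraction")
})

test_that("compound-level split keeps a compound on one side only", {
  samples <- data.frame(
    canonical_smiles = rep(sprintf("mol%02d", 1:10), each = 2),
    target_id = rep(c("T1", "T2"), 10),
    log_ic50 = rnorm(20), stringsAsFactors = FALSE
  )
  sp <- split_activities(samples, 0.3, seed = 1, by_compound = TRUE)
  expect_length(intersect(unique(sp$train$canonical_smiles),
                          unique(sp$test$canonical_smiles)), 0L)
})

test_that("oversampling equalizes per-target counts and keeps originals", {
  train <- data.frame(
    canonical_smiles = c(sprintf("a%02d", 1:10), sprintf("b%02d", 1:4)),
    target_id = rep(c("A", "B"), c(10, 4)),
    log_ic50 = rnorm(14), stringsAsFactors = FALSE
  )
  os <- oversample_by_target(train, seed = 42)
  expect_equal(unname(table(os$target_id)["A"]), 10)
  expect_equal(unname(table(os$target_id)["B"]), 10)
  # all originals retained; no new samples invented
  expect_true(all(paste(train$canonical_smiles, train$target_id) %in%
                  paste(os$canonical_smiles, os$target_id)))
  expect_setequal(unique(os$canonical_smiles), train$canonical_smiles)
  # deterministic under seed
  os2 <- oversample_by_target(train, seed = 42)
  expect_identical(os, os2)
  # balanced input is unchanged in counts; single target unchanged
  bal <- train[1:8, ]; bal$target_id <- rep(c("A", "B"), each = 4)
  expect_equal(nrow(oversample_by_target(bal, 1)), 8L)
  expect_equal(nrow(oversample_by_target(train[1:10, ], 1)), 10L)
})

test_that("activity CSV round-trips through read and write", {
  tab <- dirty_table()
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  raw <- read_activity_csv(f)
  expect_equal(nrow(raw), nrow(tab))
  expect_named(raw, c("smiles", "target_id", "standard_value",
                      "standard_units", "standard_type"))
  cd <- clean_activities(raw)
  out <- tempfile(fileext = ".csv")
  paths <- write_clean_csv(cd, out)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(out, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(cd$samples))
  prov <- jsonlite::read_json(paths[2])
  expect_equal(prov$n_clean, nrow(cd$samples))
  expect_error(read_activity_csv(tempfile()), "not found")
})
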