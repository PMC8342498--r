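# a small, fast configuration shared across generator tests
small_cfg <- function(...) {
  synth_config(seed = 42L, beers = default_beers()[1:8, ],
               n_barley_proteins = 8L, n_yeast_proteins = 5L,
               families_per_protein = 4L, ...)
}

test_that("generation is deterministic under a fixed seed", {
  b1 <- generate_dataset(small_cfg())
  b2 <- generate_dataset(small_cfg())
  expect_identical(b1$quant, b2$quant)
  expect_identical(b1$db, b2$db)
  expect_identical(b1$foam, b2$foam)
  expect_identical(b1$truth$occupancy, b2$truth$occupancy)
  # and the written bundle is byte-identical
  d1 <- tempfile(); d2 <- tempfile()
  write_bundle(b1, d1); write_bundle(b2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})

test_that("config invariants are enforced before any output", {
  expect_error(synth_config(replicate_cv = -1), "negative")
  expect_error(synth_config(fdr_good_frac = 1.5), "probabilities")
  expect_error(synth_config(n_yeast_proteins = 2), "counts")
  expect_error(synth_config(glycation_hex_weights = c(1, 1)), "Hex1-7")
  expect_error(generate_dataset(list()), "synth_config")
})

test_that("exactly one HexNAc-bearing N-glycoform exists in the bundle", {
  b <- generate_dataset(small_cfg())
  expect_equal(sum(grepl("HexNAc", unique(b$quant$mods))), 1L)
  expect_equal(sum(b$truth$families$has_nglyc), 1L)
  # and it sits on the sequon-bearing yeast protein
  acc <- b$quant$accession[grepl("HexNAc", b$quant$mods)][1]
  expect_equal(acc, "SYNY_PST1")
})

test_that("glycation Hex composition follows the planted 52:37 shape", {
  b <- generate_dataset(synth_config(seed = 7L))
  ev <- unique(b$quant[grepl("^Hex\\(\\d+\\)@K", b$quant$mods),
                       c("accession", "peptide", "mods")])
  hx <- as.integer(sub("^Hex\\((\\d+)\\).*", "\\1", ev$mods))
  expect_gt(length(hx), 30)
  w <- c(52, 37, 10, 6, 3, 2, 1) / 111
  p1 <- mean(hx == 1); p2 <- mean(hx == 2)
  # multinomial sampling error ~ 3 sd
  tol <- 3 * sqrt(w[1] * (1 - w[1]) / length(hx))
  expect_lt(abs(p1 - w[1]), tol)
  expect_lt(abs(p2 - w[2]), 3 * sqrt(w[2] * (1 - w[2]) / length(hx)))
  expect_true(all(hx >= 1 & hx <= 7))
})

test_that("every generated row parses with zero rejections (no decoys)", {
  b <- generate_dataset(small_cfg(decoys = FALSE))
  p <- parse_quant_table(b$quant, b$db, verbose = FALSE)
  expect_equal(nrow(p$rejected), 0L)
  # family assignment matches the generator's family ids
  fid <- p$forms$family_id[match(
    sprintf("%s:%d-%d|unmodified", b$truth$families$accession,
            b$truth$families$start, b$truth$families$end),
    p$forms$form_id)]
  expect_equal(fid, b$truth$families$family_id)
})

test_that("true proportions sum to one per family and beer", {
  b <- generate_dataset(small_cfg())
  s <- tapply(b$truth$proportions$true_proportion,
              paste(b$truth$proportions$family_id,
                    b$truth$proportions$sample_id), sum)
  expect_true(all(abs(s - 1) < 1e-9))
})

test_that("noise-free generation recovers planted occupancies exactly", {
  b <- generate_dataset(small_cfg(replicate_cv = 0, decoys = FALSE))
  res <- analyze_bundle(b)
  tc <- truth_check(b, res)
  for (k in c("glycosylation", "glycation", "proteolysis")) {
    expect_gt(tc$occupancy[[k]]$n, 0)
    expect_lt(tc$occupancy[[k]]$rmse, 1e-9)
  }
  expect_error(truth_check(b, modifyList(res, list(seed = 999L))),
               "seed mismatch")
})

test_that("decoy rows are present, parseable, and killed by the FDR filter", {
  b <- generate_dataset(small_cfg())
  expect_gt(length(b$truth$decoy_form_ids), 0)
  p <- parse_quant_table(b$quant, b$db, verbose = FALSE)
  q <- fdr_filter(p$quant, 0.01, verbose = FALSE)
  decoy_rows <- q$form_id %in% b$truth$decoy_form_ids
  expect_true(any(decoy_rows))
  expect_true(all(is.na(q$intensity[decoy_rows])))
})

test_that("dark beers rank lowest in total glycation, highest in average proteolysis", {
  b <- generate_dataset(synth_config(seed = 3L))
  res <- analyze_bundle(b)
  occ <- res$occupancy
  dark <- b$metadata$dark[match(occ$sample_id, b$metadata$sample_id)]
  gly <- occ$kind == "glycation"
  expect_lt(max(occ$total[gly & dark]), min(occ$total[gly & !dark]))
  pro <- occ$kind == "proteolysis"
  expect_gt(mean(occ$average[pro & dark]), mean(occ$average[pro & !dark]))
})

test_that("truth_check recovers planted effects on the default world", {
  b <- generate_dataset(synth_config(seed = 5L))
  res <- analyze_bundle(b)
  tc <- truth_check(b, res)
  expect_gt(tc$protein_log10_cor, 0.95)
  expect_gt(tc$yeast_scale_log10_diff, 0)       # planted independent shift
  expect_lt(tc$foam$slope, 0)                   # planted negative coupling
  for (k in c("glycosylation", "glycation", "proteolysis"))
    expect_lt(tc$occupancy[[k]]$rmse, 0.05)
})
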