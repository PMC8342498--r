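# minimal in-memory quant/form scaffolding for the normalization layer
mk_forms <- function(ids, family, cleavage = "full_tryptic", kind = NA) {
  data.frame(form_id = ids, family_id = family,
             cleavage = rep_len(cleavage, length(ids)),
             kind = rep_len(kind, length(ids)),
             accession = sub(":.*", "", family),
             stringsAsFactors = FALSE)
}
mk_quant <- function(form_id, sample_id, replicate, intensity, fdr = 0.001) {
  data.frame(form_id = form_id, sample_id = sample_id,
             replicate = replicate, intensity = intensity, fdr = fdr)
}

test_that("fdr_filter removes exactly the entries above the cutoff", {
  # derived by enumeration: 10 entries, q from 0.001 stepping ~0.011
  q <- mk_quant(paste0("f", 1:10), "s1", 1L, 100,
                fdr = 0.001 + 0.011 * (0:9))
  out <- fdr_filter(q, 0.01, verbose = FALSE)
  keep_brute <- q$fdr <= 0.01
  expect_identical(is.na(out$intensity), !keep_brute)
  expect_equal(attr(out, "n_removed"), sum(!keep_brute))
  expect_equal(sum(keep_brute), 1L)
  expect_error(fdr_filter(q, 0), "cutoff")
})

test_that("collapse_replicates averages observed values only", {
  q <- mk_quant(rep("f1", 3), "s1", 1:3, c(10, 20, 30))
  expect_equal(collapse_replicates(q, "mean")$intensity, 20)
  q2 <- mk_quant(rep("f1", 3), "s1", 1:3, c(1, 100, 100))
  expect_equal(collapse_replicates(q2, "median")$intensity, 100)
  q3 <- mk_quant(rep("f1", 3), "s1", 1:3, c(10, NA, 30))
  expect_equal(collapse_replicates(q3, "mean")$intensity, 20)
  q4 <- mk_quant(rep("f1", 2), "s1", 1:2, c(NA_real_, NA_real_))
  expect_true(is.na(collapse_replicates(q4, "mean")$intensity))
})

test_that("family_normalize computes within-family proportions", {
  forms <- mk_forms(c("u", "h1", "h2"), "P:1-10")
  ps <- data.frame(form_id = c("u", "h1", "h2"), sample_id = "s1",
                   intensity = c(80, 15, 5))
  ft <- family_normalize(ps, forms)
  expect_equal(ft$proportion[match(c("u", "h1", "h2"), ft$form_id)],
               c(0.80, 0.15, 0.05))
  expect_equal(unique(ft$family_total), 100)

  # family of only its anchor
  ft1 <- family_normalize(data.frame(form_id = "u", sample_id = "s1",
                                     intensity = 42),
                          mk_forms("u", "P:1-10"))
  expect_equal(ft1$proportion, 1.0)

  # all-zero family flagged undefined
  ps0 <- data.frame(form_id = c("u", "h1"), sample_id = "s1",
                    intensity = c(0, NA))
  ft0 <- family_normalize(ps0, mk_forms(c("u", "h1"), "P:1-10"))
  expect_false(any(ft0$defined))
  expect_true(all(is.na(ft0$proportion)))
})

test_that("proportions sum to 1 and match brute force on random tables", {
  set.seed(31)
  for (rep in 1:20) {
    nfam <- 20
    forms <- do.call(rbind, lapply(seq_len(nfam), function(f)
      mk_forms(sprintf("f%d_%d", f, 1:4), sprintf("P%d:1-10", f))))
    ps <- expand.grid(form_id = forms$form_id, sample_id = c("a", "b"),
                      stringsAsFactors = FALSE)
    ps$intensity <- rlnorm(nrow(ps), 8, 1)
    ps$intensity[sample(nrow(ps), 10)] <- NA
    ft <- family_normalize(ps, forms)
    sums <- tapply(ft$proportion[ft$defined],
                   paste(ft$family_id, ft$sample_id)[ft$defined], sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    # brute force a random cell
    i <- sample(which(ft$defined), 1)
    fam_rows <- ps$form_id %in% forms$form_id[forms$family_id ==
                                                ft$family_id[i]] &
      ps$sample_id == ft$sample_id[i]
    denom <- sum(ps$intensity[fam_rows], na.rm = TRUE)
    num <- ps$intensity[ps$form_id == ft$form_id[i] &
                          ps$sample_id == ft$sample_id[i]]
    num <- ifelse(is.na(num), 0, num)
    expect_equal(ft$proportion[i], num / denom)
  }
})

test_that("family proportions are invariant to per-sample scaling", {
  set.seed(5)
  forms <- mk_forms(paste0("f", 1:6), rep(c("P:1-9", "Q:2-12"), each = 3))
  ps <- expand.grid(form_id = forms$form_id, sample_id = c("a", "b"),
                    stringsAsFactors = FALSE)
  ps$intensity <- runif(12, 10, 1000)
  ft <- family_normalize(ps, forms)
  ps2 <- ps
  ps2$intensity[ps2$sample_id == "a"] <- ps2$intensity[ps2$sample_id == "a"] * 37.5
  ft2 <- family_normalize(ps2, forms)
  expect_equal(ft$proportion, ft2$proportion)
})

test_that("occupancy_summary sums and averages per-family occupancy", {
  forms <- rbind(
    mk_forms(c("a_u", "a_h1", "a_h2"), "P:1-10",
             kind = c(NA, "o_glyc_hex", "o_glyc_hex")),
    mk_forms(c("b_u", "b_h1"), "P:20-30", kind = c(NA, "o_glyc_hex")))
  ps <- data.frame(form_id = c("a_u", "a_h1", "a_h2", "b_u", "b_h1"),
                   sample_id = "s1", intensity = c(80, 15, 5, 60, 40))
  ft <- family_normalize(ps, forms)
  occ <- occupancy_summary(ft, forms, "glycosylation")
  expect_equal(occ$total, 0.20 + 0.40)
  expect_equal(occ$average, 0.30)
  expect_equal(occ$n_families, 2L)
  # no eligible family for glycation -> undefined with warning
  expect_warning(o2 <- occupancy_summary(ft, forms, "glycation"),
                 "eligible")
  expect_true(all(is.na(o2$total)))
})

test_that("occupancy matches brute force over many random families", {
  set.seed(91)
  nfam <- 1000
  forms <- do.call(rbind, lapply(seq_len(nfam), function(f) {
    n <- sample(2:5, 1)
    mk_forms(sprintf("f%d_%d", f, seq_len(n)), sprintf("P%d:1-10", f),
             cleavage = c("full_tryptic",
                          sample(c("full_tryptic", "semi_tryptic",
                                   "non_tryptic"), n - 1, replace = TRUE)))
  }))
  ps <- data.frame(form_id = forms$form_id, sample_id = "s1",
                   intensity = rlnorm(nrow(forms), 6, 1))
  ft <- family_normalize(ps, forms)
  occ <- occupancy_summary(ft, forms, "proteolysis")
  # brute force from the raw per-sample matrix
  clipped <- forms$form_id[forms$cleavage != "full_tryptic"]
  eligible <- unique(forms$family_id[forms$cleavage != "full_tryptic"])
  occs <- vapply(eligible, function(fid) {
    rows <- forms$family_id == fid
    tot <- sum(ps$intensity[rows])
    sum(ps$intensity[rows & ps$form_id %in% clipped]) / tot
  }, 0)
  expect_equal(occ$total, sum(occs))
  expect_equal(occ$average, mean(occs))
  expect_equal(occ$n_families, length(eligible))
})

test_that("high per-family clipping with few detected families: high average, low total", {
  # dark-beer-like contrast built directly: sample "porter" has 2 detected
  # clipped families at 0.8 occupancy; "pale" has 10 at 0.3
  forms <- do.call(rbind, lapply(1:10, function(f)
    mk_forms(sprintf("f%d_%d", f, 1:2), sprintf("P%d:1-10", f),
             cleavage = c("full_tryptic", "semi_tryptic"))))
  ps <- rbind(
    data.frame(form_id = forms$form_id, sample_id = "pale",
               intensity = rep(c(70, 30), 10)),
    data.frame(form_id = forms$form_id, sample_id = "porter",
               intensity = c(rep(c(20, 80), 2), rep(0, 16))))
  ft <- family_normalize(ps, forms)
  occ <- occupancy_summary(ft, forms, "proteolysis")
  pale <- occ[occ$sample_id == "pale", ]
  port <- occ[occ$sample_id == "porter", ]
  expect_gt(port$average, pale$average)   # 0.8 > 0.3
  expect_lt(port$total, pale$total)       # 1.6 < 3.0
})

test_that("protein_abundance normalizes by total or trypsin reference", {
  db <- protein_db(c("A1", "B1", "TRYP", "CONT"),
                   c("barley", "yeast", "trypsin", "contaminant"),
                   c("AKAK", "ARAR", "GKGK", "CACA"))
  forms <- data.frame(form_id = c("fa", "fb", "ft", "fc"),
                      accession = c("A1", "B1", "TRYP", "CONT"))
  ps <- data.frame(form_id = c("fa", "fb", "ft", "fc"), sample_id = "s1",
                   intensity = c(60, 40, 10, 5))
  pa <- protein_abundance(ps, forms, db, mode = "total")
  expect_equal(pa$norm_total[pa$accession == "A1"], 0.6)
  expect_equal(pa$norm_total[pa$accession == "B1"], 0.4)
  # trypsin and contaminant excluded from the denominator but present
  expect_equal(pa$norm_total[pa$accession == "TRYP"], 0.1)
  expect_equal(sum(pa$norm_total[pa$species %in% c("barley", "yeast")]), 1)

  pt <- protein_abundance(ps, forms, db, mode = "trypsin")
  expect_equal(pt$norm_trypsin[pt$accession == "A1"], 6)
  expect_equal(pt$norm_trypsin[pt$accession == "B1"], 4)
  expect_equal(pt$log10_norm[pt$accession == "A1"], log10(6))

  # trypsin mode without trypsin signal errors, naming the sample
  ps2 <- ps[ps$form_id != "ft", ]
  expect_error(protein_abundance(ps2, forms[forms$form_id != "ft", ], db,
                                 mode = "trypsin"), "s1")

  # single-protein sample
  p1 <- protein_abundance(data.frame(form_id = "fa", sample_id = "x",
                                     intensity = 7),
                          forms, db, mode = "total")
  expect_equal(p1$norm_total, 1.0)
})

test_that("norm_total is invariant to per-sample scaling; log floor holds", {
  db <- protein_db(c("A1", "B1"), c("barley", "yeast"), c("AKAK", "ARAR"))
  forms <- data.frame(form_id = c("fa", "fb"), accession = c("A1", "B1"))
  ps <- data.frame(form_id = c("fa", "fb"), sample_id = "s1",
                   intensity = c(60, 0))
  pa <- protein_abundance(ps, forms, db)
  ps$intensity <- ps$intensity * 1e3
  pa2 <- protein_abundance(ps, forms, db)
  expect_equal(pa$norm_total, pa2$norm_total)
  # zero normalized abundance -> NA log10, no pseudo-count
  expect_true(is.na(pa$log10_norm[pa$accession == "B1"]))
})
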