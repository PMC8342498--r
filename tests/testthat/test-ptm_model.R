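test_that("parse_mods validates the grammar and composition invariants", {
  ok <- parse_mods("Hex(3)@K2", "MKPCLTYVQGGPGPSGECCNGVR", "barley")
  expect_true(ok$ok)
  expect_equal(ok$rare$kind, "glycation_hex")
  expect_equal(ok$rare$hex, 3L)
  expect_equal(ok$canon, "Hex(3)@K2")

  und <- parse_mods("Hex(3)@undetermined", "VITGVPWYSTR", "yeast")
  expect_true(und$ok)
  expect_equal(und$rare$kind, "o_glyc_hex")
  expect_true(und$rare$undetermined)
  # same composition on a barley backbone reads as glycation
  expect_equal(parse_mods("Hex(3)@undetermined", "VITGVPWYSTR",
                          "barley")$rare$kind, "glycation_hex")

  ng <- parse_mods("HexNAc(1)@N7", "CDTLVGNLTIGGGLK", "yeast")
  expect_true(ng$ok)
  expect_equal(ng$rare$kind, "n_glyc")
  ng2 <- parse_mods("HexNAc(2)Hex(5)@N7", "CDTLVGNLTIGGGLK", "yeast")
  expect_true(ng2$ok)
  expect_equal(ng2$rare$hex, 5L)

  # invariant violations
  expect_false(parse_mods("Hex(11)@K2", "MKPC", "barley")$ok)
  expect_false(parse_mods("Hex(0)@K2", "MKPC", "barley")$ok)
  expect_false(parse_mods("HexNAc(3)@N7", "CDTLVGNLTIGGGLK", "yeast")$ok)
  # N-glycan outside a sequon
  expect_false(parse_mods("HexNAc(1)@N3", "AANAA", "yeast")$ok)
  # site residue mismatch and out of bounds
  expect_false(parse_mods("Hex(2)@K3", "MKPC", "barley")$ok)
  expect_false(parse_mods("Hex(2)@K99", "MKPC", "barley")$ok)
  # more than one rare modification
  expect_false(parse_mods("Hex(1)@K2;Hex(2)@K2", "MKPC", "barley")$ok)
  expect_false(parse_mods("gibberish", "MKPC", "barley")$ok)
})

test_that("common modifications are capped and excluded from the canon", {
  p <- parse_mods("Hex(2)@K2;Oxidation@M1;Deamidated@N20",
                  "MKPCLTYVQGGPGPSGECCNGVR", "barley")
  expect_true(p$ok)
  expect_equal(nrow(p$common), 2L)
  expect_equal(p$canon, "Hex(2)@K2")   # identity ignores common mods
  expect_false(parse_mods("Oxidation@M1;Oxidation@M1;Deamidated@N20",
                          "MNPCLTYVQGGPGPSGECCNGVM", "barley")$ok)
  expect_false(parse_mods("Deamidated@N20;Deamidated@N20",
                          "MKPCLTYVQGGPGPSGECCNGVR", "barley")$ok)
})

test_that("family_key picks the minimal containing full-tryptic anchor", {
  db <- fixture_db()
  # clipped forms map to the printed full tryptic peptide 56-80
  fk <- family_key(rep("GLT3_SYN", 3), c(56, 56, 56), c(80, 74, 69), db)
  expect_equal(unique(fk$family_id), "GLT3_SYN:56-80")
  # glycated missed-cleavage peptide anchors on itself
  fk2 <- family_key("NLTP1_SYN", 36, 58, db)
  expect_equal(fk2$family_id, "NLTP1_SYN:36-58")
  # idempotence: the key of an anchor is itself
  fk3 <- family_key("GLT3_SYN", fk$family_start[1], fk$family_end[1], db)
  expect_equal(fk3$family_id, fk$family_id[1])
  # no containing anchor within max_missed -> unassigned
  span <- nchar(db$sequence[db$accession == "GLT3_SYN"])
  expect_true(is.na(family_key("GLT3_SYN", 1, span, db, max_missed = 0)
                    $family_id))
})

test_that("random clippings anchor like a brute-force span search", {
  set.seed(23)
  aa <- strsplit(ptmfam:::PTMFAM_AA, "")[[1]]
  for (rep in 1:40) {
    s <- paste(sample(aa, 120, replace = TRUE), collapse = "")
    db <- protein_db("P1", "barley", s)
    d <- digest(s, 2)
    # clip a random tryptic peptide from either end
    i <- sample(nrow(d), 1)
    st <- d$start[i]; en <- d$end[i]
    if (en - st < 2) next
    if (runif(1) < 0.5) st <- st + sample(en - st, 1)
    else en <- en - sample(en - st, 1)
    got <- family_key("P1", st, en, db, max_missed = 2)
    # oracle: scan all full-tryptic spans, order by (missed, length, start)
    cand <- d[d$start <= st & d$end >= en, ]
    cand <- cand[order(cand$missed, cand$end - cand$start, cand$start), ]
    expect_equal(got$family_id,
                 sprintf("P1:%d-%d", cand$start[1], cand$end[1]))
  }
})

test_that("parse_quant_table locates, classifies and rejects correctly", {
  db <- fixture_db()
  q <- rbind(
    qrow("GLT3_SYN", "VVDQQLVGQLPWSTGLQMQ", "R", "C"),          # semi clip
    qrow("GLT3_SYN", "VVDQQLVGQLPWSTGLQMQCCQQLR", "R", "D"),    # anchor
    qrow("PAU15_SYN", "VITGVPWYSTR", "R", "L",
         mods = "Hex(3)@undetermined"),
    qrow("NLTP1_SYN", "MKPCLTYVQGGPGPSGECCNGVR", "K", "S",
         mods = "Hex(2)@K2"),
    qrow("NLTP1_SYN", "MKPCLTYVQGGPGPSGECCNGVR", "K", "S",
         mods = "Hex(11)@K2"),                                  # reject
    qrow("GLT3_SYN", "WWWWWW", "R", "D"),                       # reject
    qrow("GLT3_SYN", "VVDQQLVGQLPWSTGLQMQ", "A", "C"))          # reject
  expect_message(p <- parse_quant_table(q, db), "rejected 3")
  expect_equal(nrow(p$rejected), 3L)
  expect_setequal(
    sub(";.*", "", p$rejected$reason),
    c("Hex count outside 1-10: Hex(11)@K2", "peptide not found in protein",
      "flanking residues inconsistent with protein"))

  f <- p$forms
  clip <- f[f$peptide == "VVDQQLVGQLPWSTGLQMQ", ]
  expect_equal(clip$cleavage, "semi_tryptic")
  expect_equal(clip$start, 56L)
  expect_equal(clip$end, 74L)
  expect_equal(clip$family_id, "GLT3_SYN:56-80")
  pau <- f[f$accession == "PAU15_SYN", ]
  expect_equal(pau$kind, "o_glyc_hex")
  expect_true(pau$site_undetermined)
  expect_equal(pau$cleavage, "full_tryptic")
  nltp <- f[f$accession == "NLTP1_SYN", ]
  expect_equal(nltp$kind, "glycation_hex")
  expect_equal(nltp$family_id, "NLTP1_SYN:36-58")
})

test_that("common-mod variants collapse onto one form (summed, min q)", {
  db <- fixture_db()
  q <- rbind(
    qrow("NLTP1_SYN", "MKPCLTYVQGGPGPSGECCNGVR", "K", "S",
         mods = "Hex(2)@K2", intensity = 70, fdr = 0.004),
    qrow("NLTP1_SYN", "MKPCLTYVQGGPGPSGECCNGVR", "K", "S",
         mods = "Hex(2)@K2;Oxidation@M1", intensity = 30, fdr = 0.001))
  p <- parse_quant_table(q, db, verbose = FALSE)
  expect_equal(nrow(p$quant), 1L)
  expect_equal(p$quant$intensity, 100)
  expect_equal(p$quant$fdr, 0.001)
  expect_equal(nrow(p$forms), 1L)
})

test_that("ambiguous in-protein matches are rejected", {
  # peptide occurs twice with identical flanks
  s <- paste0("AAAR", "GGWGG", "R", "GGWGG", "RAAA")
  db <- protein_db("DUP", "barley", s)
  p <- parse_quant_table(qrow("DUP", "GGWGG", "R", "R"), db,
                         verbose = FALSE)
  expect_equal(p$rejected$reason, "ambiguous match within protein")
})
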