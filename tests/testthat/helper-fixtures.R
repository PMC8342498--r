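# Fixture builders. Protein sequences are synthetic stand-ins: published
# peptides are embedded at their published coordinates inside filler that
# contains no Lys/Arg (so the flanking cleavage structure is exact).

filler <- function(n) {
  base <- "ACDEFGHILMNPQSTVWY"   # 18 residues, no K/R
  paste(strsplit(strrep(base, ceiling(n / nchar(base))), "")[[1]][seq_len(n)],
        collapse = "")
}

# glutenin-like protein: full tryptic peptide V56..R80, preceded by R55,
# followed by D81
glt3_protein <- function() {
  pep <- "VVDQQLVGQLPWSTGLQMQCCQQLR"
  paste0(filler(54), "R", pep, "D", filler(40))
}

# mannoprotein-like: sequon-bearing peptide C51..K65 after R50, before T66
# (the published flank numbering puts the Arg at residue 50, Asn at 57)
pst1_protein <- function() {
  pep <- "CDTLVGNLTIGGGLK"
  paste0(filler(49), "R", pep, "T", filler(30))
}

# lipid-transfer-like: glycated peptide M36..R58 after K35, before S59
nltp1_protein <- function() {
  pep <- "MKPCLTYVQGGPGPSGECCNGVR"
  paste0(filler(34), "K", pep, "S", filler(40))
}

# seripauperin-like: O-glycopeptide V94..R104 after R93, before L105
pau15_protein <- function() {
  pep <- "VITGVPWYSTR"
  paste0(filler(92), "R", pep, "L", filler(30))
}

fixture_db <- function() {
  protein_db(
    accession = c("GLT3_SYN", "PST1_SYN", "NLTP1_SYN", "PAU15_SYN"),
    species = c("barley", "yeast", "barley", "yeast"),
    sequence = c(glt3_protein(), pst1_protein(), nltp1_protein(),
                 pau15_protein()))
}

# one quant row with defaults filled in
qrow <- function(accession, peptide, prev_aa, next_aa, mods = "unmodified",
                 sample_id = "s1", replicate = 1L, intensity = 100,
                 fdr = 0.001) {
  data.frame(sample_id = sample_id, replicate = replicate,
             accession = accession, peptide = peptide, prev_aa = prev_aa,
             next_aa = next_aa, mods = mods, intensity = intensity,
             fdr = fdr, stringsAsFactors = FALSE)
}

# independent O(n^3) complete-linkage oracle: recomputes every merge
# height as the max pairwise distance between cluster members, using the
# same lowest-index-first tie break on cluster creation order
brute_complete_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1L)
  merges <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(clusters)
    best <- NULL; bestd <- Inf
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      v <- max(d[clusters[[i]], clusters[[j]]])
      if (v < bestd) { bestd <- v; best <- c(i, j) }
    }
    heights[step] <- bestd
    merges[[step]] <- sort(c(clusters[[best[1L]]], clusters[[best[2L]]]))
    clusters[[best[1L]]] <- merges[[step]]
    clusters[[best[2L]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# member leaf sets of every internal node of an hclust tree
hclust_member_sets <- function(hc) {
  n <- length(hc$height) + 1L
  sets <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    grab <- function(x) if (x < 0L) -x else sets[[x]]
    sets[[s]] <- sort(c(grab(hc$merge[s, 1L]), grab(hc$merge[s, 2L])))
  }
  sets
}
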