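# Synthetic dataset generator: emits a FASTA + long quant table +
# metadata + foam table bundle with full ground truth, emulating the
# structure the analysis assumes: barley proteins carrying Lys glycation
# (Hex1-7, weighted toward Hex1/Hex2) and semi-tryptic clipped forms,
# yeast proteins carrying Ser/Thr O-glycosylation (Hex1-8) plus one
# HexNAc1 sequon event, brewery/style/scale abundance effects, technical
# replicate noise, a detection limit, decoy rows for FDR-filter testing,
# and foam variables linearly coupled to seripauperin/NLTP class sums.

# residue sampling frequencies: K+R ~ 10% so tryptic peptides average
# ~10 residues, S/T/N frequent enough to provide glyco sites
aa_freq <- function() {
  f <- c(A = 8.0, C = 1.5, D = 5.4, E = 6.5, F = 3.9, G = 7.0, H = 2.3,
         I = 5.8, K = 5.5, L = 9.5, M = 2.3, N = 4.3, P = 4.8, Q = 3.9,
         R = 4.5, S = 6.8, T = 5.5, V = 6.8, W = 1.1, Y = 3.0)
  f / sum(f)
}

#' Default beer layout for the synthetic generator
#'
#' Seven breweries (A-G), 23 beers across lagers, ales, and dark styles;
#' breweries B and D flagged multinational, the rest independent.
#' Porter, Dark Ale and Amber Ale are flagged dark.
#' @return data.frame `sample_id`, `brewery`, `style`, `scale`, `dark`.
#' @export
default_beers <- function() {
  b <- rbind(
    data.frame(brewery = "A", style = c("Session Ale", "Pale Ale", "IPA",
                                        "Porter", "Amber Ale", "Golden Ale")),
    data.frame(brewery = "B", style = c("Lager-1", "Lager-2", "Lager-3",
                                        "Pale Ale", "Dark Ale", "Porter")),
    data.frame(brewery = "C", style = c("Pale Ale", "IPA")),
    data.frame(brewery = "D", style = c("Lager-1", "Lager-2", "Lager-3",
                                        "Pale Ale-1", "Pale Ale-2")),
    data.frame(brewery = "E", style = "Pale Ale"),
    data.frame(brewery = "F", style = "Pale Ale"),
    data.frame(brewery = "G", style = c("IPA", "XPA")))
  b$sample_id <- paste0(b$brewery, "-", gsub(" ", "", b$style))
  b$scale <- ifelse(b$brewery %in% c("B", "D"), "multinational",
                    "independent")
  b$dark <- grepl("Porter|Dark|Amber", b$style)
  b[, c("sample_id", "brewery", "style", "scale", "dark")]
}

#' Generator configuration
#'
#' Defaults describe a realistic scaled-down beer proteome: 20 barley +
#' 8 yeast proteins, ~8 peptide families per protein, technical
#' triplicate with 20% intensity CV, log10 brewery/style effects of
#' 0.30/0.15, yeast proteins shifted up in independent-brewery beers,
#' glycation Hex weights proportional to 52:37 for Hex1:Hex2 with a
#' decaying tail over Hex3-7, O-glycan weights decaying over Hex1-8, and
#' a dark-beer rule (glycated-form proportions down, clipped-form
#' proportions up, clipped-family abundance down past the detection
#' limit). The seed fixes the whole bundle byte-for-byte.
#'
#' @param seed integer RNG seed.
#' @param beers beer metadata (see [default_beers()]).
#' @param n_barley_proteins,n_yeast_proteins protein counts (>= 6 / 5).
#' @param families_per_protein target peptide families per protein.
#' @param protein_length mean protein length.
#' @param replicates technical replicates per beer.
#' @param replicate_cv lognormal intensity CV across replicates.
#' @param log10_abundance_mean,log10_abundance_sd protein base abundance.
#' @param brewery_sd,style_sd per-protein effect SDs (log10).
#' @param yeast_independent_shift log10 shift of yeast proteins in
#'   independent-brewery beers (the planted scale contrast).
#' @param glycation_site_prob per internal Lys event probability in
#'   glycation-eligible families.
#' @param glycation_hex_weights sampling weights for Hex1..Hex7.
#' @param oglyc_site_prob per Ser/Thr event probability.
#' @param oglyc_hex_weights weights for Hex1..Hex8.
#' @param oglyc_undetermined_prob fraction of O-glyc events reported with
#'   undetermined site.
#' @param clip_family_prob probability a family carries clipped forms.
#' @param occupancy_shape Beta shape parameters for the per-family total
#'   modified proportion.
#' @param dark_glycation_factor,dark_clipping_factor,
#'   dark_clipped_abundance_factor the dark-beer rule multipliers.
#' @param lod detection limit on noise-free family abundance.
#' @param fdr_good_frac fraction of true rows passing the 1% cutoff.
#' @param decoys inject decoy rows? `n_decoys` how many.
#' @param n_decoys number of decoy rows.
#' @param foam_lifetime_r2,foam_small_r2 planted coefficients of
#'   determination for the seripauperin couplings (negative slopes).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         beers = default_beers(),
                         n_barley_proteins = 20L,
                         n_yeast_proteins = 8L,
                         families_per_protein = 8L,
                         protein_length = 300L,
                         replicates = 3L,
                         replicate_cv = 0.2,
                         log10_abundance_mean = 4.5,
                         log10_abundance_sd = 0.6,
                         brewery_sd = 0.30,
                         style_sd = 0.15,
                         yeast_independent_shift = 0.4,
                         glycation_site_prob = 0.7,
                         glycation_hex_weights = c(52, 37, 10, 6, 3, 2, 1),
                         oglyc_site_prob = 0.25,
                         oglyc_hex_weights = c(16, 12, 9, 7, 6, 4, 3, 3),
                         oglyc_undetermined_prob = 0.3,
                         clip_family_prob = 0.4,
                         occupancy_shape = c(2, 6),
                         dark_glycation_factor = 0.25,
                         dark_clipping_factor = 2.5,
                         dark_clipped_abundance_factor = 0.02,
                         lod = 1000,
                         fdr_good_frac = 0.99,
                         decoys = TRUE,
                         n_decoys = 30L,
                         foam_lifetime_r2 = 0.7,
                         foam_small_r2 = 0.38) {
  cfg <- as.list(environment())
  probs <- c(glycation_site_prob, oglyc_site_prob, oglyc_undetermined_prob,
             clip_family_prob, fdr_good_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (replicates < 1L || n_barley_proteins < 6L || n_yeast_proteins < 5L ||
      families_per_protein < 1L)
    stop("counts too small for a valid configuration")
  if (replicate_cv < 0 || lod < 0) stop("negative noise/lod parameter")
  if (length(glycation_hex_weights) != 7L ||
      length(oglyc_hex_weights) != 8L)
    stop("hex weight vectors must cover Hex1-7 (glycation) / Hex1-8 (O)")
  need <- c("sample_id", "brewery", "style", "scale", "dark")
  if (!all(need %in% names(beers))) stop("beers table missing columns")
  class(cfg) <- "synth_config"
  cfg
}

# is (peptide, flanks) a unique exact match in the protein?
locates_uniquely <- function(seq, pep, start) {
  L <- nchar(seq)
  starts <- gregexpr(pep, seq, fixed = TRUE)[[1]]
  if (length(starts) == 1L) return(TRUE)
  ends <- starts + nchar(pep) - 1L
  pa <- ifelse(starts == 1L, "-", substring(seq, starts - 1L, starts - 1L))
  na <- ifelse(ends == L, "-", substring(seq, ends + 1L, ends + 1L))
  want_pa <- if (start == 1L) "-" else substring(seq, start - 1L, start - 1L)
  want_end <- start + nchar(pep) - 1L
  want_na <- if (want_end == L) "-"
    else substring(seq, want_end + 1L, want_end + 1L)
  sum(pa == want_pa & na == want_na) == 1L
}

#' Generate a complete synthetic dataset bundle
#'
#' @param cfg a [synth_config()].
#' @param dir optional output directory; when given, writes
#'   `proteins.fasta`, `quant.tsv`, `metadata.tsv`, `foam.tsv` and a
#'   `provenance.json` sidecar.
#' @return list with `db` (protein database), `quant`, `metadata`,
#'   `foam` (data.frames) and `truth` (families, per-form true
#'   proportions, per-family occupancies, true protein abundances,
#'   planted foam coefficients, decoy row keys).
#' @export
generate_dataset <- function(cfg = synth_config(), dir = NULL) {
  if (!inherits(cfg, "synth_config")) stop("cfg must come from synth_config()")
  set.seed(cfg$seed)
  beers <- cfg$beers
  nb <- nrow(beers)
  freq <- aa_freq()
  rprot <- function(len) paste(sample(names(freq), len, TRUE, freq),
                               collapse = "")
  plen <- function(k) pmax(100L, round(stats::rnorm(k, cfg$protein_length,
                                                    40)))

  ## ---- protein database -------------------------------------------------
  n_b <- cfg$n_barley_proteins; n_y <- cfg$n_yeast_proteins
  barley_acc <- c(sprintf("SYNB_NLTP%d", 1:3), sprintf("SYNB_SRPZ%d", 1:3),
                  sprintf("SYNB_P%03d", seq_len(n_b - 6L)))
  n_pau <- min(4L, n_y - 1L)
  yeast_acc <- c(sprintf("SYNY_PAU%d", seq_len(n_pau)), "SYNY_PST1",
                 if (n_y - n_pau - 1L > 0)
                   sprintf("SYNY_Y%03d", seq_len(n_y - n_pau - 1L)))
  accs <- c(barley_acc, yeast_acc, "SYNT_TRYP1", "SYNC_KRT1")
  species <- c(rep("barley", n_b), rep("yeast", n_y), "trypsin",
               "contaminant")
  seqs <- vapply(plen(length(accs)), rprot, "")
  # splice one N-X-S/T sequon into SYNY_PST1 inside a tryptic peptide
  ipst <- which(accs == "SYNY_PST1")
  d0 <- digest(seqs[ipst], 0L)
  len0 <- d0$end - d0$start + 1L
  host <- d0[len0 >= 8L & len0 <= 26L, ][1L, ]
  if (is.na(host$start)) host <- d0[len0 >= 8L, ][1L, ]
  at <- host$start + 3L
  substr(seqs[ipst], at, at + 2L) <- "NGT"
  db <- protein_db(accs, species, seqs)
  beer_accs <- c(barley_acc, yeast_acc)

  ## ---- peptide families and their modified forms ------------------------
  fam <- list(); fi <- 0L
  add_family <- function(acc, sp, st, en, pep, anchor_missed) {
    fi <<- fi + 1L
    fam[[fi]] <<- list(accession = acc, species = sp, start = st, end = en,
                       peptide = pep, anchor_missed = anchor_missed,
                       forms = list())
  }
  for (k in seq_along(beer_accs)) {
    acc <- beer_accs[k]
    sp <- species[k]
    s <- seqs[k]
    d0 <- digest(s, 0L)
    d1 <- digest(s, 1L)
    ok_len <- function(d) d[(d$end - d$start + 1L) >= 6L &
                             (d$end - d$start + 1L) <= 26L, , drop = FALSE]
    c0 <- ok_len(d0)
    c0 <- c0[vapply(seq_len(nrow(c0)), function(i)
      locates_uniquely(s, c0$peptide[i], c0$start[i]), TRUE), , drop = FALSE]
    n_glycfam <- 0L
    picks <- NULL
    if (sp == "barley") {
      cg <- d1[d1$missed == 1L, , drop = FALSE]
      cg <- ok_len(cg)
      # internal Lys required (the glycated residue blocks cleavage)
      has_int_k <- vapply(seq_len(nrow(cg)), function(i) {
        p <- cg$peptide[i]
        any(substring(p, 1L, nchar(p) - 1L) |>
              strsplit("") |> unlist() == "K")
      }, TRUE)
      cg <- cg[has_int_k, , drop = FALSE]
      cg <- cg[vapply(seq_len(nrow(cg)), function(i)
        locates_uniquely(s, cg$peptide[i], cg$start[i]), TRUE), ,
        drop = FALSE]
      n_glycfam <- min(3L, nrow(cg))
      if (n_glycfam > 0L) {
        gi <- sample(nrow(cg), n_glycfam)
        for (i in gi) add_family(acc, sp, cg$start[i], cg$end[i],
                                 cg$peptide[i], 1L)
      }
    }
    n_base <- max(0L, cfg$families_per_protein - n_glycfam)
    n_base <- min(n_base, nrow(c0))
    if (n_base > 0L) picks <- sample(nrow(c0), n_base)
    if (acc == "SYNY_PST1") {
      # force-include the sequon-bearing peptide
      seq_i <- which(c0$start <= at & c0$end >= at + 2L)
      if (length(seq_i) && !(seq_i[1L] %in% picks))
        picks <- c(seq_i[1L], picks[-1L])
    }
    for (i in picks) add_family(acc, sp, c0$start[i], c0$end[i],
                                c0$peptide[i], 0L)
  }

  hexw_g <- cfg$glycation_hex_weights / sum(cfg$glycation_hex_weights)
  hexw_o <- cfg$oglyc_hex_weights / sum(cfg$oglyc_hex_weights)
  for (i in seq_along(fam)) {
    f <- fam[[i]]
    pep <- f$peptide; n <- nchar(pep)
    forms <- list(list(kind = NA_character_, canon = "unmodified",
                       start = f$start, end = f$end, peptide = pep,
                       clipped = FALSE))
    if (f$species == "barley" && f$anchor_missed == 1L) {
      ks <- find_modifiable_sites(substring(pep, 1L, n - 1L), "K")
      ks <- ks[stats::runif(length(ks)) < cfg$glycation_site_prob]
      for (k in utils::head(ks, 2L)) {
        h <- sample(7L, 1L, prob = hexw_g)
        forms[[length(forms) + 1L]] <- list(
          kind = "glycation_hex", canon = sprintf("Hex(%d)@K%d", h, k),
          start = f$start, end = f$end, peptide = pep, clipped = FALSE)
      }
    }
    if (f$species == "yeast") {
      sq <- find_sequons(pep)
      if (f$accession == "SYNY_PST1" && length(sq) &&
          (f$start <= at && f$end >= at + 2L)) {
        pos <- at - f$start + 1L
        if (pos %in% sq)
          forms[[length(forms) + 1L]] <- list(
            kind = "n_glyc", canon = sprintf("HexNAc(1)@N%d", pos),
            start = f$start, end = f$end, peptide = pep, clipped = FALSE)
      }
      st_sites <- find_modifiable_sites(pep, c("S", "T"))
      st_sites <- st_sites[stats::runif(length(st_sites)) <
                             cfg$oglyc_site_prob]
      seen_undet <- FALSE
      for (k in utils::head(st_sites, 2L)) {
        h <- sample(8L, 1L, prob = hexw_o)
        undet <- stats::runif(1) < cfg$oglyc_undetermined_prob
        if (undet && seen_undet) next
        canon <- if (undet) sprintf("Hex(%d)@undetermined", h)
          else sprintf("Hex(%d)@%s%d", h, substring(pep, k, k), k)
        if (undet) seen_undet <- TRUE
        if (any(vapply(forms, function(x) identical(x$canon, canon), TRUE)))
          next
        forms[[length(forms) + 1L]] <- list(
          kind = "o_glyc_hex", canon = canon,
          start = f$start, end = f$end, peptide = pep, clipped = FALSE)
      }
    }
    if (f$anchor_missed == 0L && n >= 10L &&
        stats::runif(1) < cfg$clip_family_prob) {
      for (ct in seq_len(sample(3L, 1L))) {
        if (stats::runif(1) < 0.5) {  # clip from the N-terminal side
          cs <- f$start + sample(3:(n - 4L), 1L)
          st2 <- cs; en2 <- f$end
        } else {                      # clip from the C-terminal side
          ce <- f$start + sample(3:(n - 4L), 1L)
          st2 <- f$start; en2 <- ce
        }
        pep2 <- substring(seqs[match(f$accession, accs)], st2, en2)
        if (!locates_uniquely(seqs[match(f$accession, accs)], pep2, st2))
          next
        canon_key <- sprintf("%d-%d", st2, en2)
        if (any(vapply(forms, function(x)
          x$clipped && identical(sprintf("%d-%d", x$start, x$end),
                                 canon_key), TRUE))) next
        forms[[length(forms) + 1L]] <- list(
          kind = NA_character_, canon = "unmodified",
          start = st2, end = en2, peptide = pep2, clipped = TRUE)
      }
    }
    fam[[i]]$forms <- forms
  }

  ## ---- per-beer true proportions & abundances ---------------------------
  fam_df <- do.call(rbind, lapply(seq_along(fam), function(i) {
    f <- fam[[i]]
    data.frame(family_id = sprintf("%s:%d-%d", f$accession, f$start, f$end),
               accession = f$accession, species = f$species,
               start = f$start, end = f$end, peptide = f$peptide,
               n_forms = length(f$forms),
               has_clip = any(vapply(f$forms, `[[`, TRUE, "clipped")),
               has_glycation = any(vapply(f$forms, function(x)
                 identical(x$kind, "glycation_hex"), TRUE)),
               has_oglyc = any(vapply(f$forms, function(x)
                 identical(x$kind, "o_glyc_hex"), TRUE)),
               has_nglyc = any(vapply(f$forms, function(x)
                 identical(x$kind, "n_glyc"), TRUE)))
  }))
  nf <- nrow(fam_df)
  theta <- stats::rbeta(nf, cfg$occupancy_shape[1L], cfg$occupancy_shape[2L])
  fam_df$theta <- theta

  base_p <- stats::setNames(stats::rnorm(length(beer_accs),
                                         cfg$log10_abundance_mean,
                                         cfg$log10_abundance_sd), beer_accs)
  brews <- unique(beers$brewery); styles <- unique(beers$style)
  brew_eff <- matrix(stats::rnorm(length(beer_accs) * length(brews), 0,
                                  cfg$brewery_sd),
                     length(beer_accs), length(brews),
                     dimnames = list(beer_accs, brews))
  style_eff <- matrix(stats::rnorm(length(beer_accs) * length(styles), 0,
                                   cfg$style_sd),
                      length(beer_accs), length(styles),
                      dimnames = list(beer_accs, styles))
  u_f <- stats::rnorm(nf, 0, 0.4)

  sdlog <- sqrt(log(1 + cfg$replicate_cv^2))
  quant <- vector("list", nf)
  prop_rows <- vector("list", nf)
  occ_rows <- vector("list", nf)
  prot_true <- matrix(0, length(beer_accs), nb,
                      dimnames = list(beer_accs, beers$sample_id))
  for (i in seq_len(nf)) {
    f <- fam[[i]]
    forms <- f$forms
    nfo <- length(forms)
    is_glyc <- vapply(forms, function(x) identical(x$kind, "glycation_hex"),
                      TRUE)
    is_ogly <- vapply(forms, function(x)
      identical(x$kind, "o_glyc_hex") || identical(x$kind, "n_glyc"), TRUE)
    is_clip <- vapply(forms, `[[`, TRUE, "clipped")
    w_mod <- rep(0, nfo)
    if (nfo > 1L) {
      raw <- stats::rexp(nfo - 1L)
      w_mod[-1L] <- theta[i] * raw / sum(raw)
    }
    form_ids <- vapply(forms, function(x)
      sprintf("%s:%d-%d|%s", f$accession, x$start, x$end, x$canon), "")
    qf <- list(); pr <- list(); oc <- list()
    for (b in seq_len(nb)) {
      v <- w_mod
      if (beers$dark[b]) {
        v[is_glyc] <- v[is_glyc] * cfg$dark_glycation_factor
        v[is_clip] <- v[is_clip] * cfg$dark_clipping_factor
      }
      sm <- sum(v)
      if (sm > 0.95) { v <- v * 0.95 / sm; sm <- 0.95 }
      p <- v; p[1L] <- 1 - sm
      logA <- base_p[f$accession] +
        brew_eff[f$accession, beers$brewery[b]] +
        style_eff[f$accession, beers$style[b]] + u_f[i] +
        (if (f$species == "yeast" && beers$scale[b] == "independent")
          cfg$yeast_independent_shift else 0) +
        (if (beers$dark[b] && any(is_clip))
          log10(cfg$dark_clipped_abundance_factor) else 0)
      A <- unname(10^logA)
      detected <- A >= cfg$lod
      pr[[b]] <- data.frame(family_id = fam_df$family_id[i],
                            form_id = form_ids,
                            sample_id = beers$sample_id[b],
                            true_proportion = p, detected = detected)
      oc[[b]] <- data.frame(family_id = fam_df$family_id[i],
                            sample_id = beers$sample_id[b],
                            glycation = sum(p[is_glyc]),
                            glycosylation = sum(p[is_ogly]),
                            proteolysis = sum(p[is_clip]),
                            detected = detected)
      if (!detected) next
      prot_true[f$accession, b] <- prot_true[f$accession, b] + A
      for (j in seq_len(nfo)) {
        if (p[j] <= 0) next
        ints <- A * p[j] * exp(stats::rnorm(cfg$replicates, 0, sdlog))
        good <- stats::runif(cfg$replicates) < cfg$fdr_good_frac
        fdr <- ifelse(good, stats::runif(cfg$replicates, 0, 0.01),
                      stats::runif(cfg$replicates, 0.011, 0.05))
        qf[[length(qf) + 1L]] <- data.frame(
          sample_id = beers$sample_id[b],
          replicate = seq_len(cfg$replicates),
          accession = f$accession, peptide = forms[[j]]$peptide,
          prev_aa = flank_of(seqs[match(f$accession, accs)],
                             forms[[j]]$start, "prev"),
          next_aa = flank_of(seqs[match(f$accession, accs)],
                             forms[[j]]$end, "next"),
          mods = forms[[j]]$canon, intensity = ints, fdr = fdr)
      }
    }
    quant[[i]] <- data.table::rbindlist(qf)
    prop_rows[[i]] <- data.table::rbindlist(pr)
    occ_rows[[i]] <- data.table::rbindlist(oc)
  }
  quant <- as.data.frame(data.table::rbindlist(quant))

  ## ---- trypsin self-digest and contaminant rows -------------------------
  extra <- list()
  for (tag in c("SYNT_TRYP1", "SYNC_KRT1")) {
    s <- seqs[match(tag, accs)]
    dd <- digest(s, 0L)
    dd <- dd[(dd$end - dd$start + 1L) >= 6L &
               (dd$end - dd$start + 1L) <= 26L, , drop = FALSE]
    dd <- dd[vapply(seq_len(nrow(dd)), function(i)
      locates_uniquely(s, dd$peptide[i], dd$start[i]), TRUE), , drop = FALSE]
    npep <- min(if (tag == "SYNT_TRYP1") 5L else 3L, nrow(dd))
    dd <- dd[sample(nrow(dd), npep), , drop = FALSE]
    lvl <- if (tag == "SYNT_TRYP1") 4.8 else 3.8
    for (i in seq_len(nrow(dd))) {
      pep_lvl <- lvl + stats::rnorm(1, 0, 0.2)
      for (b in seq_len(nb)) {
        ints <- 10^pep_lvl * exp(stats::rnorm(cfg$replicates, 0,
                                              sdlog + 0.02))
        extra[[length(extra) + 1L]] <- data.frame(
          sample_id = beers$sample_id[b], replicate = seq_len(cfg$replicates),
          accession = tag, peptide = dd$peptide[i], prev_aa = dd$prev_aa[i],
          next_aa = dd$next_aa[i], mods = "unmodified", intensity = ints,
          fdr = stats::runif(cfg$replicates, 0, 0.01))
      }
    }
  }
  quant <- rbind(quant, as.data.frame(data.table::rbindlist(extra)))

  ## ---- decoy rows (labelled only in the ground truth) -------------------
  decoy_keys <- character(0)
  if (isTRUE(cfg$decoys) && cfg$n_decoys > 0L) {
    used <- unique(paste(fam_df$accession, fam_df$peptide))
    pool <- list()
    for (k in seq_along(beer_accs)) {
      dd <- digest(seqs[k], 0L)
      dd <- dd[(dd$end - dd$start + 1L) >= 6L &
                 (dd$end - dd$start + 1L) <= 26L, , drop = FALSE]
      dd <- dd[!(paste(beer_accs[k], dd$peptide) %in% used), , drop = FALSE]
      if (nrow(dd))
        pool[[length(pool) + 1L]] <- cbind(accession = beer_accs[k], dd)
    }
    pool <- as.data.frame(data.table::rbindlist(pool))
    pool <- pool[vapply(seq_len(nrow(pool)), function(i)
      locates_uniquely(seqs[match(pool$accession[i], accs)],
                       pool$peptide[i], pool$start[i]), TRUE), ,
      drop = FALSE]
    nd <- min(cfg$n_decoys, nrow(pool))
    sel <- pool[sample(nrow(pool), nd), , drop = FALSE]
    drows <- data.frame(
      sample_id = sample(beers$sample_id, nd, replace = TRUE),
      replicate = sample(cfg$replicates, nd, replace = TRUE),
      accession = sel$accession, peptide = sel$peptide,
      prev_aa = sel$prev_aa, next_aa = sel$next_aa, mods = "unmodified",
      intensity = 10^stats::rnorm(nd, 3.5, 0.3),
      fdr = stats::runif(nd, 0.02, 0.5))
    decoy_keys <- sprintf("%s:%d-%d|unmodified", sel$accession, sel$start,
                          sel$end)
    quant <- rbind(quant, drows)
  }
  quant <- quant[order(quant$accession, quant$peptide, quant$mods,
                       quant$sample_id, quant$replicate), ]
  rownames(quant) <- NULL

  ## ---- true normalized protein abundance --------------------------------
  keep <- species[match(beer_accs, accs)] %in% c("barley", "yeast")
  denom <- colSums(prot_true[keep, , drop = FALSE])
  prot_norm <- sweep(prot_true, 2L, denom, "/")
  prot_df <- data.frame(
    accession = rep(rownames(prot_true), nb),
    sample_id = rep(colnames(prot_true), each = length(beer_accs)),
    true_raw = as.vector(prot_true),
    true_norm_total = as.vector(prot_norm))

  ## ---- foam table coupled to class abundances ---------------------------
  pau_acc <- grep("^SYNY_PAU", beer_accs, value = TRUE)
  nltp_acc <- grep("^SYNB_NLTP", beer_accs, value = TRUE)
  pau_x <- colSums(prot_norm[pau_acc, , drop = FALSE])
  nltp_x <- colSums(prot_norm[nltp_acc, , drop = FALSE])
  foam <- NULL; foam_truth <- NULL
  if (nb >= 3L && stats::sd(pau_x) > 0) {
    b_l <- -600; b_s <- -900
    sd_l <- abs(b_l) * stats::sd(pau_x) *
      sqrt((1 - cfg$foam_lifetime_r2) / cfg$foam_lifetime_r2)
    sd_s <- abs(b_s) * stats::sd(pau_x) *
      sqrt((1 - cfg$foam_small_r2) / cfg$foam_small_r2)
    foam <- data.frame(
      sample_id = beers$sample_id,
      max_foam_volume = pmax(0, 120 + 200 * nltp_x +
                               stats::rnorm(nb, 0, 25)),
      foam_lifetime = pmax(0, 300 + b_l * pau_x + stats::rnorm(nb, 0, sd_l)),
      drainage = pmax(0, stats::rnorm(nb, 1.2, 0.3)),
      bubbles_small = round(pmax(0, 420 + b_s * pau_x +
                                   stats::rnorm(nb, 0, sd_s))),
      bubbles_medium = round(pmax(0, stats::rnorm(nb, 250, 60))),
      bubbles_large = round(pmax(0, stats::rnorm(nb, 80, 25))))
    foam_truth <- list(lifetime_slope = b_l, lifetime_r2 = cfg$foam_lifetime_r2,
                       small_slope = b_s, small_r2 = cfg$foam_small_r2,
                       pau_abundance = stats::setNames(pau_x,
                                                       beers$sample_id),
                       nltp_abundance = stats::setNames(nltp_x,
                                                        beers$sample_id))
  }

  truth <- list(
    seed = cfg$seed,
    families = fam_df,
    proportions = as.data.frame(data.table::rbindlist(prop_rows)),
    occupancy = as.data.frame(data.table::rbindlist(occ_rows)),
    protein = prot_df,
    foam = foam_truth,
    decoy_form_ids = decoy_keys)
  bundle <- list(db = db, quant = quant, metadata = beers, foam = foam,
                 truth = truth, cfg = cfg)
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

flank_of <- function(seq, pos, side) {
  L <- nchar(seq)
  if (side == "prev") {
    if (pos == 1L) "-" else substring(seq, pos - 1L, pos - 1L)
  } else {
    if (pos == L) "-" else substring(seq, pos + 1L, pos + 1L)
  }
}

#' Write a generated bundle to disk
#' @param bundle from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_protein_fasta(bundle$db, file.path(dir, "proteins.fasta"))
  wq <- bundle$quant
  wq$intensity <- sprintf("%.6g", wq$intensity)
  wq$fdr <- sprintf("%.6g", wq$fdr)
  utils::write.table(wq, file.path(dir, "quant.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$foam)) {
    wf <- bundle$foam
    num <- vapply(wf, is.numeric, TRUE)
    wf[num] <- lapply(wf[num], function(v) sprintf("%.6g", v))
    utils::write.table(wf, file.path(dir, "foam.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(generator = "ptmfam", seed = bundle$cfg$seed,
         n_proteins = nrow(bundle$db),
         n_families = nrow(bundle$truth$families),
         n_quant_rows = nrow(bundle$quant)),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Compare pipeline estimates against the generator's ground truth
#'
#' @param bundle from [generate_dataset()].
#' @param results from [analyze_bundle()] on the same bundle (seeds must
#'   match).
#' @return list: per-kind occupancy `bias` and `rmse` (over detected,
#'   eligible family-beer cells), `protein_log10_cor` (Pearson, detected
#'   proteins), `yeast_scale_log10_diff` (mean yeast-protein log10
#'   difference, independent minus multinational; positive = planted
#'   direction recovered), `foam` (refit slope/R2 on estimated class
#'   abundance, when foam data exist), and per-kind occupancy tables.
#' @export
truth_check <- function(bundle, results) {
  if (!identical(results$seed, bundle$cfg$seed))
    stop("results were not produced from this bundle (seed mismatch)")
  forms <- results$forms
  ft <- results$family_table
  est <- list()
  for (kind in c("glycosylation", "glycation", "proteolysis")) {
    is_mod <- form_has_kind(forms, kind)
    eligible <- unique(forms$family_id[is_mod])
    dt <- data.table::as.data.table(ft)
    dt <- dt[family_id %in% eligible & defined]
    modset <- forms$form_id[is_mod]
    dt[, is_mod := form_id %in% modset]
    e <- dt[, .(est = sum(proportion[is_mod])), by = .(family_id, sample_id)]
    tr <- data.table::as.data.table(
      bundle$truth$occupancy)[detected == TRUE,
                              c("family_id", "sample_id", kind),
                              with = FALSE]
    data.table::setnames(tr, kind, "truth")
    m <- merge(e, tr, by = c("family_id", "sample_id"))
    est[[kind]] <- list(
      n = nrow(m),
      bias = mean(m$est - m$truth),
      rmse = sqrt(mean((m$est - m$truth)^2)),
      table = as.data.frame(m))
  }
  pa <- data.table::as.data.table(results$protein_abundance)
  tp <- data.table::as.data.table(bundle$truth$protein)
  m <- merge(pa[, .(accession, sample_id, norm_total)],
             tp[true_norm_total > 0], by = c("accession", "sample_id"))
  m <- m[norm_total > 0]
  prot_cor <- stats::cor(log10(m$norm_total), log10(m$true_norm_total))
  md <- bundle$metadata
  yeast_acc <- bundle$db$accession[bundle$db$species == "yeast"]
  pa2 <- merge(pa[accession %in% yeast_acc & norm_total > 0],
               data.table::as.data.table(md[, c("sample_id", "scale")]),
               by = "sample_id")
  grp <- pa2[, .(mu = mean(log10(norm_total))), by = .(accession, scale)]
  wide <- data.table::dcast(grp, accession ~ scale, value.var = "mu")
  yeast_diff <- if (all(c("independent", "multinational") %in% names(wide)))
    mean(wide$independent - wide$multinational, na.rm = TRUE) else NA_real_
  foam_rec <- NULL
  if (!is.null(bundle$foam)) {
    cm <- protein_class_map(bundle$db$accession)
    ca <- class_abundance(as.data.frame(pa), cm)
    x <- ca$abundance[ca$class == "seripauperin"]
    names(x) <- ca$sample_id[ca$class == "seripauperin"]
    y <- stats::setNames(bundle$foam$foam_lifetime, bundle$foam$sample_id)
    common <- intersect(names(x), names(y))
    fr <- foam_regression(x[common], y[common])
    foam_rec <- list(slope = fr$slope, r_squared = fr$r_squared,
                     p_value = fr$p_value,
                     planted_r2 = bundle$truth$foam$lifetime_r2)
  }
  list(occupancy = est, protein_log10_cor = prot_cor,
       yeast_scale_log10_diff = yeast_diff, foam = foam_rec)
}

#' Default accession-to-class map for the synthetic proteins
#' @param accessions accession vector.
#' @return named character vector for [class_abundance()]; NLTP, serpin
#'   and seripauperin classes keyed on accession keywords.
#' @export
protein_class_map <- function(accessions) {
  cls <- rep(NA_character_, length(accessions))
  cls[grepl("NLTP", accessions)] <- "NLTP"
  cls[grepl("SRPZ|SERP", accessions)] <- "serpin"
  cls[grepl("PAU", accessions)] <- "seripauperin"
  stats::setNames(cls, accessions)[!is.na(cls)]
}
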