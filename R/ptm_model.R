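# Modification grammar (semicolon-separated tokens):
#   "unmodified"
#   Hex(n)@K12 | Hex(n)@S5 | Hex(n)@undetermined         n in 1..10
#   HexNAc(n)@N7 | HexNAc(n)Hex(m)@N7                    n in 1..2, m in 0..10
#   Deamidated@N4 | Oxidation@M3                         common mods, count
#                                                        optional as Name(1)@..
# Kind resolution for Hex-only tokens: K site -> glycation; S/T site ->
# O-glycosylation; undetermined site -> by species (barley: glycation,
# otherwise O-glycosylation).

MOD_TOKEN_RE <- paste0(
  "^(?:(HexNAc)\\((\\d+)\\))?(?:(Hex)\\((\\d+)\\))?",
  "(Deamidated|Oxidation)?(?:\\((\\d+)\\))?",
  "@(?:([A-Z])(\\d+)|(undetermined))$")

#' Parse a modification annotation string
#'
#' Validates the token grammar and the composition/site invariants:
#' at most one rare (glyco/glycation) modification and at most two common
#' modifications per peptide; Hex counts 1-10 for Hex-only compositions;
#' HexNAc 1-2 with Hex 0-10 for N-glycans; glycation sites must be Lys,
#' O-glycosylation sites Ser/Thr, N-glycan sites must sit in an N-X-S/T
#' sequon of the peptide.
#'
#' @param mods modification string (see grammar above) or `"unmodified"`.
#' @param peptide the peptide backbone sequence (for site checks).
#' @param species species tag of the parent protein, used only to resolve
#'   the kind of a Hex-only modification at an undetermined site.
#' @param allow_proline_sequon sequon rule passed to [find_sequons()].
#' @return list with `ok` (logical), `reason` (string if not ok), `rare`
#'   (data.frame: kind, hex, hexnac, site, undetermined), `common`
#'   (data.frame: name, site), `canon` (canonical rare-mod string used as
#'   part of the form identity; common mods are excluded by design).
#' @export
parse_mods <- function(mods, peptide, species = "barley",
                       allow_proline_sequon = TRUE) {
  fail <- function(reason) list(ok = FALSE, reason = reason)
  empty_rare <- data.frame(kind = character(0), hex = integer(0),
                           hexnac = integer(0), site = integer(0),
                           undetermined = logical(0))
  empty_common <- data.frame(name = character(0), site = integer(0))
  mods <- trimws(mods)
  if (identical(mods, "") || identical(tolower(mods), "unmodified"))
    return(list(ok = TRUE, rare = empty_rare, common = empty_common,
                canon = "unmodified"))
  toks <- trimws(strsplit(mods, ";", fixed = TRUE)[[1]])
  rare <- empty_rare
  common <- empty_common
  plen <- nchar(peptide)
  for (tok in toks) {
    m <- regmatches(tok, regexec(MOD_TOKEN_RE, tok))[[1]]
    if (!length(m)) return(fail(paste0("unparseable modification: ", tok)))
    hexnac <- if (nzchar(m[3])) as.integer(m[3]) else 0L
    hex <- if (nzchar(m[5])) as.integer(m[5]) else 0L
    common_name <- m[6]
    common_count <- if (nzchar(m[7])) as.integer(m[7]) else 1L
    site_res <- m[8]
    site <- if (nzchar(m[9])) as.integer(m[9]) else NA_integer_
    undet <- nzchar(m[10])
    if (nzchar(common_name)) {
      if (hex > 0 || hexnac > 0)
        return(fail(paste0("mixed common/glyco token: ", tok)))
      if (undet) return(fail(paste0("common mod needs a site: ", tok)))
      common <- rbind(common, data.frame(
        name = rep(common_name, common_count), site = rep(site, common_count)))
      next
    }
    if (hex == 0 && hexnac == 0)
      return(fail(paste0("empty composition: ", tok)))
    if (!undet) {
      if (is.na(site) || site < 1L || site > plen)
        return(fail(paste0("site out of peptide bounds: ", tok)))
      actual <- substring(peptide, site, site)
      if (actual != site_res)
        return(fail(sprintf("site residue mismatch: %s is %s in peptide",
                            tok, actual)))
    }
    if (hexnac > 0) {            # N-glycan composition
      if (hexnac > 2L) return(fail(paste0("HexNAc count > 2: ", tok)))
      if (hex > 10L) return(fail(paste0("Hex count > 10: ", tok)))
      if (!undet) {
        if (site_res != "N")
          return(fail(paste0("N-glycan site must be Asn: ", tok)))
        if (!(site %in% find_sequons(peptide, allow_proline_sequon)))
          return(fail(paste0("N-glycan site not in a sequon: ", tok)))
      }
      kind <- "n_glyc"
    } else {                     # Hex-only: glycation or O-glycosylation
      if (hex < 1L || hex > 10L)
        return(fail(paste0("Hex count outside 1-10: ", tok)))
      if (undet) {
        kind <- if (identical(species, "barley")) "glycation_hex"
                else "o_glyc_hex"
      } else if (site_res == "K") {
        kind <- "glycation_hex"
      } else if (site_res %in% c("S", "T")) {
        kind <- "o_glyc_hex"
      } else {
        return(fail(paste0("Hex site must be K, S or T: ", tok)))
      }
    }
    rare <- rbind(rare, data.frame(kind = kind, hex = hex, hexnac = hexnac,
                                   site = site, undetermined = undet))
  }
  if (nrow(rare) > 1L)
    return(fail("more than one rare (glyco/glycation) modification"))
  if (nrow(common) > 2L)
    return(fail("more than two common modifications"))
  if (sum(common$name == "Deamidated") > 1L)
    return(fail("Deamidated allowed at most once"))
  canon <- if (nrow(rare) == 0L) "unmodified" else {
    r <- rare[1L, ]
    comp <- paste0(if (r$hexnac > 0) sprintf("HexNAc(%d)", r$hexnac) else "",
                   if (r$hex > 0) sprintf("Hex(%d)", r$hex) else "")
    site_txt <- if (r$undetermined) "undetermined"
      else paste0(substring(peptide, r$site, r$site), r$site)
    paste0(comp, "@", site_txt)
  }
  list(ok = TRUE, rare = rare, common = common, canon = canon)
}

#' Minimal full-tryptic anchor for a peptide span
#'
#' Finds, for each (accession, start, end), the minimal full-tryptic
#' peptide span containing it: fewest missed cleavages, then shortest
#' span, then smallest start. This anchor defines the peptide family to
#' which clipped, glycated and glycosylated forms are matched.
#'
#' @param accession,start,end vectors describing peptide spans.
#' @param db `protein_db`.
#' @param max_missed maximum missed cleavages of the anchor.
#' @param proline_rule passed to [digest()].
#' @return `data.frame` with `family_id` (`"ACC:start-end"`, `NA` when no
#'   containing anchor exists), `family_start`, `family_end`.
#' @export
family_key <- function(accession, start, end, db, max_missed = 2L,
                       proline_rule = FALSE) {
  n <- length(accession)
  fs <- fe <- rep(NA_integer_, n)
  seqs <- stats::setNames(db$sequence, db$accession)
  digs <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    acc <- accession[i]
    if (!acc %in% names(seqs)) next
    d <- get0(acc, envir = digs)
    if (is.null(d)) {
      d <- digest(seqs[[acc]], max_missed, proline_rule)
      assign(acc, d, envir = digs)
    }
    hit <- d$start <= start[i] & d$end >= end[i]
    if (!any(hit)) next
    cand <- d[hit, , drop = FALSE]
    cand <- cand[order(cand$missed, cand$end - cand$start, cand$start), ,
                 drop = FALSE]
    fs[i] <- cand$start[1L]
    fe[i] <- cand$end[1L]
  }
  data.frame(family_id = ifelse(is.na(fs), NA_character_,
                                sprintf("%s:%d-%d", accession, fs, fe)),
             family_start = fs, family_end = fe)
}

#' Parse a long-format quant table into peptide forms and intensities
#'
#' Input columns: `sample_id`, `replicate`, `accession`, `peptide`,
#' `prev_aa`, `next_aa`, `mods`, `intensity`, `fdr`. Each distinct
#' (accession, peptide, flanks, mods) combination is located in its
#' protein by exact string match consistent with the stated flanking
#' residues; rows that cannot be located, match ambiguously, or carry an
#' invariant-violating modification are rejected with a logged reason.
#' Forms differing only in common modifications (deamidation, oxidation)
#' are collapsed onto one form: intensities summed, q-value taken as the
#' minimum of the collapsed entries.
#'
#' @param quant data.frame or TSV path.
#' @param db `protein_db`.
#' @param max_missed anchor search depth for [family_key()].
#' @param proline_rule,allow_proline_sequon rule switches (see
#'   [digest()], [find_sequons()]).
#' @param verbose emit a message with rejection counts.
#' @return list with `forms` (one row per peptide form: identity,
#'   location, cleavage class, modification kind/composition, family
#'   assignment), `quant` (form_id x sample_id x replicate intensities
#'   and q-values) and `rejected` (reasons).
#' @export
parse_quant_table <- function(quant, db, max_missed = 2L,
                              proline_rule = FALSE,
                              allow_proline_sequon = TRUE,
                              verbose = TRUE) {
  if (is.character(quant))
    quant <- utils::read.delim(quant, stringsAsFactors = FALSE)
  quant <- data.table::as.data.table(quant)
  need <- c("sample_id", "replicate", "accession", "peptide",
            "prev_aa", "next_aa", "mods", "intensity", "fdr")
  miss <- setdiff(need, names(quant))
  if (length(miss))
    stop("quant table missing column(s): ", paste(miss, collapse = ", "))
  sp <- stats::setNames(db$species, db$accession)
  seqs <- stats::setNames(db$sequence, db$accession)

  combos <- unique(quant[, c("accession", "peptide", "prev_aa", "next_aa",
                             "mods")])
  nres <- nrow(combos)
  form_id <- rep(NA_character_, nres)
  reason <- rep(NA_character_, nres)
  forms <- vector("list", nres)
  for (i in seq_len(nres)) {
    acc <- combos$accession[i]; pep <- combos$peptide[i]
    if (!acc %in% names(seqs)) { reason[i] <- "unknown accession"; next }
    s <- seqs[[acc]]; L <- nchar(s)
    starts <- gregexpr(pep, s, fixed = TRUE)[[1]]
    if (starts[1L] == -1L) { reason[i] <- "peptide not found in protein"; next }
    ends <- starts + nchar(pep) - 1L
    prev_ok <- ifelse(starts == 1L, combos$prev_aa[i] == "-",
                      substring(s, starts - 1L, starts - 1L) ==
                        combos$prev_aa[i])
    next_ok <- ifelse(ends == L, combos$next_aa[i] == "-",
                      substring(s, ends + 1L, ends + 1L) == combos$next_aa[i])
    keep <- which(prev_ok & next_ok)
    if (length(keep) == 0L) {
      reason[i] <- "flanking residues inconsistent with protein"; next
    }
    if (length(keep) > 1L) {
      reason[i] <- "ambiguous match within protein"; next
    }
    st <- as.integer(starts[keep]); en <- as.integer(ends[keep])
    pm <- parse_mods(combos$mods[i], pep, species = sp[[acc]],
                     allow_proline_sequon = allow_proline_sequon)
    if (!pm$ok) { reason[i] <- pm$reason; next }
    cl <- classify_cleavage(st, en, s, proline_rule)
    fid <- sprintf("%s:%d-%d|%s", acc, st, en, pm$canon)
    form_id[i] <- fid
    r <- pm$rare
    forms[[i]] <- data.frame(
      form_id = fid, accession = acc, species = sp[[acc]], peptide = pep,
      start = st, end = en, prev_aa = combos$prev_aa[i],
      next_aa = combos$next_aa[i], cleavage = cl, mods_canon = pm$canon,
      kind = if (nrow(r)) r$kind else NA_character_,
      hex = if (nrow(r)) r$hex else 0L,
      hexnac = if (nrow(r)) r$hexnac else 0L,
      site = if (nrow(r)) r$site else NA_integer_,
      site_undetermined = if (nrow(r)) r$undetermined else FALSE,
      stringsAsFactors = FALSE)
  }
  ok <- !is.na(form_id)
  rejected <- cbind(combos[!ok, , drop = FALSE],
                    data.frame(reason = reason[!ok]))
  forms <- unique(data.table::rbindlist(forms[ok]))
  forms <- as.data.frame(forms)
  fam <- family_key(forms$accession, forms$start, forms$end, db,
                    max_missed = max_missed, proline_rule = proline_rule)
  forms <- cbind(forms, fam)

  key <- do.call(paste, c(combos[, c("accession", "peptide", "prev_aa",
                                     "next_aa", "mods")], sep = "\r"))
  map <- stats::setNames(form_id, key)
  qkey <- do.call(paste, c(quant[, c("accession", "peptide", "prev_aa",
                                     "next_aa", "mods")], sep = "\r"))
  quant[, form_id := map[qkey]]
  qok <- quant[!is.na(form_id)]
  qc <- if (nrow(qok)) {
    qok[, .(intensity = sum(intensity), fdr = min(fdr)),
        by = .(form_id, sample_id, replicate)]
  } else {
    data.table::data.table(form_id = character(0), sample_id = character(0),
                           replicate = integer(0), intensity = numeric(0),
                           fdr = numeric(0))
  }
  if (verbose && nrow(rejected))
    message(sprintf("parse_quant_table: rejected %d peptide form(s) (%s)",
                    nrow(rejected),
                    paste(names(sort(table(rejected$reason),
                                     decreasing = TRUE)), collapse = "; ")))
  list(forms = forms, quant = as.data.frame(qc),
       rejected = as.data.frame(rejected))
}
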