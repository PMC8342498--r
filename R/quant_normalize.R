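#' FDR refiltering of peptide intensities
#'
#' Entries whose peptide-level q-value exceeds the cutoff have their
#' intensity set to missing (`NA`); everything else is unchanged. The
#' number of removed entries is attached as attribute `n_removed`.
#'
#' @param quant long quant table (`form_id`, `sample_id`, `replicate`,
#'   `intensity`, `fdr`).
#' @param cutoff q-value cutoff in (0, 1]; default 0.01 (1% FDR).
#' @param verbose message the removal count.
#' @return the filtered quant table.
#' @export
fdr_filter <- function(quant, cutoff = 0.01, verbose = TRUE) {
  if (!(cutoff > 0 && cutoff <= 1)) stop("cutoff must be in (0, 1]")
  drop <- !is.na(quant$fdr) & quant$fdr > cutoff & !is.na(quant$intensity)
  quant$intensity[drop] <- NA_real_
  if (verbose)
    message(sprintf("fdr_filter: removed %d of %d intensities at q <= %g",
                    sum(drop), nrow(quant), cutoff))
  attr(quant, "n_removed") <- sum(drop)
  quant
}

#' Collapse technical replicates to one value per sample
#'
#' Mean (default) or median over the observed (non-missing) replicates;
#' a form with no observed replicate in a sample stays missing.
#'
#' @param quant long quant table after [fdr_filter()].
#' @param method `"mean"` or `"median"`.
#' @return data.frame `form_id`, `sample_id`, `intensity`.
#' @export
collapse_replicates <- function(quant, method = c("mean", "median")) {
  method <- match.arg(method)
  f <- if (method == "mean") mean else stats::median
  dt <- data.table::as.data.table(quant)
  out <- dt[, .(intensity = if (all(is.na(intensity))) NA_real_
                else f(intensity[!is.na(intensity)])),
            by = .(form_id, sample_id)]
  as.data.frame(out)
}

#' Within-family proportions (peptide-family normalization)
#'
#' For every (family, sample) the proportion of each member form is its
#' intensity divided by the family total, missing intensities counting 0
#' in the denominator. Families whose total is 0 (or all-missing) in a
#' sample are flagged undefined and carry `NA` proportions. Forms with no
#' family assignment are excluded.
#'
#' @param per_sample collapsed table from [collapse_replicates()].
#' @param forms form table from [parse_quant_table()] (needs `form_id`,
#'   `family_id`).
#' @return data.frame `family_id`, `form_id`, `sample_id`, `intensity`,
#'   `family_total`, `proportion`, `defined`.
#' @export
family_normalize <- function(per_sample, forms) {
  dt <- data.table::as.data.table(per_sample)
  fmap <- stats::setNames(forms$family_id, forms$form_id)
  dt[, family_id := fmap[form_id]]
  dt <- dt[!is.na(family_id)]
  dt[, intensity0 := data.table::fifelse(is.na(intensity), 0, intensity)]
  dt[, family_total := sum(intensity0), by = .(family_id, sample_id)]
  dt[, defined := family_total > 0]
  dt[, proportion := data.table::fifelse(defined, intensity0 / family_total,
                                         NA_real_)]
  out <- as.data.frame(dt[, .(family_id, form_id, sample_id, intensity,
                              family_total, proportion, defined)])
  class(out) <- c("family_table", "data.frame")
  out
}

#' Which PTM kind does a form carry?
#'
#' `glycosylation` covers O-linked oligohexose and N-glycans;
#' `glycation` covers oligohexose on Lys; `proteolysis` covers any
#' semi- or non-tryptic cleavage (physiological clipping).
#'
#' @param forms form table.
#' @param kind one of `"glycosylation"`, `"glycation"`, `"proteolysis"`.
#' @return logical vector along `forms`.
#' @export
form_has_kind <- function(forms, kind) {
  kind <- match.arg(kind, c("glycosylation", "glycation", "proteolysis"))
  switch(kind,
    glycosylation = !is.na(forms$kind) &
      forms$kind %in% c("o_glyc_hex", "n_glyc"),
    glycation = !is.na(forms$kind) & forms$kind == "glycation_hex",
    proteolysis = forms$cleavage != "full_tryptic")
}

#' Total and average PTM occupancy per sample
#'
#' Per family and sample, occupancy is the summed proportion of member
#' forms carrying the kind's modification. Families *eligible* for a
#' kind are those with at least one such member form anywhere in the
#' form table; totals and averages run over eligible families that are
#' detected (family total > 0) in the sample. `total` is the unweighted
#' sum of per-family occupancies (set `weighted = TRUE` for the
#' intensity-weighted alternative: sum of modified-form intensities over
#' summed eligible-family totals); `average` is their mean.
#'
#' @param ft family table from [family_normalize()].
#' @param forms form table.
#' @param kind PTM kind (see [form_has_kind()]).
#' @param weighted use the intensity-weighted total.
#' @return data.frame `sample_id`, `kind`, `total`, `average`,
#'   `n_families` (eligible and detected).
#' @export
occupancy_summary <- function(ft, forms,
                              kind = c("glycosylation", "glycation",
                                       "proteolysis"),
                              weighted = FALSE) {
  kind <- match.arg(kind)
  is_mod <- form_has_kind(forms, kind)
  eligible <- unique(forms$family_id[is_mod])
  eligible <- eligible[!is.na(eligible)]
  if (!length(eligible)) {
    warning("no families eligible for kind '", kind, "'")
    return(data.frame(sample_id = unique(ft$sample_id), kind = kind,
                      total = NA_real_, average = NA_real_, n_families = 0L))
  }
  dt <- data.table::as.data.table(ft)
  dt <- dt[family_id %in% eligible & defined]
  modset <- forms$form_id[is_mod]
  dt[, is_mod := form_id %in% modset]
  fam <- dt[, .(occ = sum(proportion[is_mod]),
                mod_int = sum(intensity[is_mod], na.rm = TRUE),
                fam_int = family_total[1L]),
            by = .(sample_id, family_id)]
  out <- fam[, .(kind = kind,
                 total = if (weighted) sum(mod_int) / sum(fam_int)
                 else sum(occ),
                 average = mean(occ),
                 n_families = .N),
             by = .(sample_id)]
  out <- as.data.frame(out)
  # samples where no eligible family was detected
  missing_samples <- setdiff(unique(ft$sample_id), out$sample_id)
  if (length(missing_samples))
    out <- rbind(out, data.frame(sample_id = missing_samples, kind = kind,
                                 total = 0, average = 0, n_families = 0L))
  out[order(out$sample_id), ]
}

#' Protein abundance with total- or trypsin-reference normalization
#'
#' Raw protein abundance is the sum of all retained peptide-form
#' intensities (modified and unmodified) of the accession in a sample.
#' `norm_total` divides by the summed abundance of all quantified
#' proteins in the sample, excluding contaminant and trypsin entries
#' from the denominator (configurable); `norm_trypsin` divides by the
#' summed intensity of trypsin self-digest peptides in the sample.
#'
#' @param per_sample collapsed table from [collapse_replicates()].
#' @param forms form table.
#' @param db `protein_db`.
#' @param mode `"total"` or `"trypsin"`; selects which normalized column
#'   feeds `log10_norm`.
#' @param exclude_from_total species excluded from the total-abundance
#'   denominator.
#' @return data.frame `accession`, `species`, `sample_id`, `raw_sum`,
#'   `norm_total`, `norm_trypsin` (NA in total mode), `log10_norm`
#'   (log10 of the selected normalized value, `NA` at zero — no
#'   pseudo-count).
#' @export
protein_abundance <- function(per_sample, forms, db,
                              mode = c("total", "trypsin"),
                              exclude_from_total = c("contaminant",
                                                     "trypsin")) {
  mode <- match.arg(mode)
  dt <- data.table::as.data.table(per_sample)
  amap <- stats::setNames(forms$accession, forms$form_id)
  dt[, accession := amap[form_id]]
  dt <- dt[!is.na(accession)]
  dt[, intensity0 := data.table::fifelse(is.na(intensity), 0, intensity)]
  pa <- dt[, .(raw_sum = sum(intensity0)), by = .(accession, sample_id)]
  smap <- stats::setNames(db$species, db$accession)
  pa[, species := smap[accession]]
  pa[, denom_total := sum(raw_sum[!species %in% exclude_from_total]),
     by = sample_id]
  pa[, norm_total := data.table::fifelse(denom_total > 0,
                                         raw_sum / denom_total, NA_real_)]
  if (mode == "trypsin") {
    tryp <- pa[species == "trypsin", .(tryp_sum = sum(raw_sum)),
               by = sample_id]
    pa <- merge(pa, tryp, by = "sample_id", all.x = TRUE)
    bad <- pa[is.na(tryp_sum) | tryp_sum <= 0, unique(sample_id)]
    if (length(bad))
      stop("no trypsin self-digest signal in sample(s): ",
           paste(bad, collapse = ", "))
    pa[, norm_trypsin := raw_sum / tryp_sum]
  } else {
    pa[, norm_trypsin := NA_real_]
  }
  sel <- if (mode == "total") pa$norm_total else pa$norm_trypsin
  pa[, log10_norm := data.table::fifelse(!is.na(sel) & sel > 0, log10(sel),
                                         NA_real_)]
  out <- as.data.frame(pa[, .(accession, species, sample_id, raw_sum,
                              norm_total, norm_trypsin, log10_norm)])
  out[order(out$accession, out$sample_id), ]
}

#' Pivot protein abundances (or any long table) to a feature matrix
#'
#' @param x long data.frame.
#' @param row,col,value column names for rows, columns and cell values.
#' @return numeric matrix with dimnames; absent combinations are `NA`.
#' @export
as_feature_matrix <- function(x, row, col, value) {
  dt <- data.table::as.data.table(x[, c(row, col, value)])
  data.table::setnames(dt, c(".r", ".c", ".v"))
  w <- data.table::dcast(dt, .r ~ .c, value.var = ".v")
  m <- as.matrix(w[, -1L])
  rownames(m) <- w$.r
  m
}
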