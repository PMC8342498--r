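#' Run the core analysis on an in-memory bundle
#'
#' Executes parse -> FDR refilter -> replicate collapse -> family
#' normalization -> occupancy summaries -> protein abundance on a
#' dataset bundle (as produced by [generate_dataset()], or assembled
#' from files).
#'
#' @param bundle list with `db`, `quant`, `metadata` (and optionally
#'   `foam`, `cfg`).
#' @param fdr_cutoff peptide q-value cutoff (default 0.01).
#' @param max_missed anchor search depth (default 2).
#' @param collapse replicate collapse rule (`"mean"`/`"median"`).
#' @param mode protein normalization mode (`"total"`/`"trypsin"`).
#' @param verbose forwarded to the parsing/filtering steps.
#' @return list: `forms`, `quant` (filtered), `per_sample`,
#'   `family_table`, `occupancy` (long, all three kinds),
#'   `protein_abundance`, `rejected`, `params`, `seed` (from
#'   `bundle$cfg`, if present).
#' @export
analyze_bundle <- function(bundle, fdr_cutoff = 0.01, max_missed = 2L,
                           collapse = "mean", mode = "total",
                           verbose = FALSE) {
  md <- bundle$metadata
  unknown <- setdiff(unique(bundle$quant$sample_id), md$sample_id)
  if (length(unknown))
    stop("quant table references sample(s) absent from metadata: ",
         paste(unknown, collapse = ", "))
  parsed <- parse_quant_table(bundle$quant, bundle$db,
                              max_missed = max_missed, verbose = verbose)
  q <- fdr_filter(parsed$quant, fdr_cutoff, verbose = verbose)
  if (all(is.na(q$intensity))) stop("no intensities left after FDR filter")
  ps <- collapse_replicates(q, collapse)
  ft <- family_normalize(ps, parsed$forms)
  occ <- do.call(rbind, lapply(
    c("glycosylation", "glycation", "proteolysis"),
    function(k) occupancy_summary(ft, parsed$forms, k)))
  pa <- protein_abundance(ps, parsed$forms, bundle$db, mode = mode)
  list(forms = parsed$forms, quant = q, per_sample = ps, family_table = ft,
       occupancy = occ, protein_abundance = pa, rejected = parsed$rejected,
       params = list(fdr_cutoff = fdr_cutoff, max_missed = max_missed,
                     collapse = collapse, mode = mode),
       seed = if (!is.null(bundle$cfg)) bundle$cfg$seed else NA_integer_)
}

#' Run the full pipeline from files to an output directory
#'
#' Reads the FASTA + quant + metadata (+ optional foam) inputs, runs
#' [analyze_bundle()], then the downstream multivariate and comparative
#' stages, and writes every result table (TSV), sample dendrogram
#' (Newick) and a provenance JSON into `outdir`.
#'
#' @param fasta,quant,metadata,foam input paths (`foam` optional).
#' @param outdir output directory.
#' @param fdr_cutoff,max_missed,collapse,mode,alpha analysis parameters;
#'   defaults follow the emulated study settings (1% FDR, two missed
#'   cleavages, total-abundance normalization, alpha 0.05).
#' @param n_components PCA components to report.
#' @param species_map optional accession-to-species sidecar for the
#'   FASTA reader.
#' @param verbose forwarded to inner steps.
#' @return (invisibly) the in-memory results list.
#' @export
run_pipeline <- function(fasta, quant, metadata, foam = NULL,
                         outdir = "ptmfam_out", fdr_cutoff = 0.01,
                         max_missed = 2L, collapse = "mean",
                         mode = "total", alpha = 0.05, n_components = 2L,
                         species_map = NULL, verbose = FALSE) {
  db <- read_protein_fasta(fasta, species_map)
  qt <- utils::read.delim(quant, stringsAsFactors = FALSE)
  md <- utils::read.delim(metadata, stringsAsFactors = FALSE)
  fm <- if (!is.null(foam)) utils::read.delim(foam,
                                              stringsAsFactors = FALSE)
  bundle <- list(db = db, quant = qt, metadata = md, foam = fm)
  res <- analyze_bundle(bundle, fdr_cutoff, max_missed, collapse, mode,
                        verbose = verbose)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    fmt_num(x), file.path(outdir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(res$family_table, "family_proportions.tsv")
  wt(res$occupancy, "occupancy_summary.tsv")
  wt(res$protein_abundance, "protein_abundance.tsv")
  if (nrow(res$rejected)) wt(res$rejected, "rejected_rows.tsv")

  m <- as_feature_matrix(res$protein_abundance, "accession", "sample_id",
                         "log10_norm")
  m <- m[rowSums(!is.na(m)) > 0L, , drop = FALSE]
  pc <- pca(m, n_components)
  sc <- data.frame(sample_id = rownames(pc$scores), pc$scores)
  wt(sc, "pca_scores.tsv")
  writeLines(sprintf("PC%d\t%s", seq_along(pc$explained_pct),
                     pc$explained_pct),
             file.path(outdir, "pca_explained.tsv"))
  hc <- hcluster(m, axis = "cols")
  write_newick(hc, file.path(outdir, "samples_dendrogram.tsv.nwk"))

  volc <- NULL
  if ("scale" %in% names(md) && length(unique(md$scale)) == 2L) {
    labels <- md$scale[match(colnames(m), md$sample_id)]
    volc <- volcano(m, labels, group1 = "independent", alpha = alpha)
    wt(volc, "volcano_scale.tsv")
  }
  foam_res <- NULL
  if (!is.null(fm)) {
    cm <- protein_class_map(db$accession)
    ca <- class_abundance(res$protein_abundance, cm)
    if (nrow(ca)) {
      wt(ca, "class_abundance.tsv")
      foam_vars <- setdiff(names(fm), "sample_id")
      rows <- list()
      for (cl in unique(ca$class)) for (v in foam_vars) {
        x <- ca$abundance[ca$class == cl]
        names(x) <- ca$sample_id[ca$class == cl]
        y <- stats::setNames(fm[[v]], fm$sample_id)
        common <- intersect(names(x), names(y))
        if (length(common) < 3L || stats::var(x[common]) == 0) next
        fr <- foam_regression(x[common], y[common])
        rows[[length(rows) + 1L]] <- data.frame(
          class = cl, foam_variable = v, slope = fr$slope,
          intercept = fr$intercept, r_squared = fr$r_squared,
          p_value = fr$p_value, n = fr$n)
      }
      foam_res <- do.call(rbind, rows)
      if (!is.null(foam_res)) wt(foam_res, "foam_regression.tsv")
    }
  }
  jsonlite::write_json(
    list(tool = "ptmfam", version = as.character(utils::packageVersion("ptmfam")),
         inputs = list(fasta = fasta, quant = quant, metadata = metadata,
                       foam = foam),
         params = res$params, alpha = alpha,
         n_rejected_forms = nrow(res$rejected),
         n_intensities_removed_by_fdr = attr(res$quant, "n_removed"),
         pca_explained = pc$explained_pct[
           seq_len(min(n_components, length(pc$explained_pct)))]),
    file.path(outdir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  res$pca <- pc
  res$dendrogram <- hc
  res$volcano <- volc
  res$foam_regression <- foam_res
  invisible(res)
}

# fixed-format numeric columns so reruns are byte-identical
fmt_num <- function(x) {
  num <- vapply(x, is.double, TRUE)
  x[num] <- lapply(x[num], function(v)
    ifelse(is.na(v), "NA", sprintf("%.10g", v)))
  x
}

#' Command-line entry point
#'
#' Subcommands: `generate` (write a synthetic bundle), `run` (full
#' pipeline), `occupancy`, `cluster`, `compare`, `foamreg` (single
#' stages). Shared flags: `--fasta`, `--quant`, `--metadata`, `--foam`,
#' `--out`, `--fdr`, `--mode`, `--seed`, `--kind`, `--groups`,
#' `--axis`, `--alpha`.
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`).
#' @return exit status (0 on success), invisibly.
#' @export
ptmfam_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: ptmfam <generate|run|occupancy|cluster|compare|foamreg>",
    "[--fasta F] [--quant Q] [--metadata M] [--foam B] [--out DIR]",
    "[--fdr 0.01] [--mode total|trypsin] [--seed N]",
    "[--kind glycosylation|glycation|proteolysis] [--groups COL]",
    "[--axis rows|cols] [--alpha 0.05]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]; args <- args[-1L]
  opt <- list(out = "ptmfam_out", fdr = 0.01, mode = "total", seed = 1L,
              kind = "glycosylation", groups = "scale", axis = "cols",
              alpha = 0.05, fasta = NULL, quant = NULL, metadata = NULL,
              foam = NULL)
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!startsWith(args[i], "--") || i == length(args) ||
        !key %in% names(opt)) {
      message("unknown or incomplete flag: ", args[i], "\n", usage)
      return(invisible(2L))
    }
    val <- args[i + 1L]
    opt[[key]] <- if (key %in% c("fdr", "alpha")) as.numeric(val)
      else if (key == "seed") as.integer(val) else val
    i <- i + 2L
  }
  need_inputs <- function() {
    if (is.null(opt$fasta) || is.null(opt$quant) || is.null(opt$metadata)) {
      stop("this subcommand needs --fasta, --quant and --metadata",
           call. = FALSE)
    }
    db <- read_protein_fasta(opt$fasta)
    list(db = db,
         quant = utils::read.delim(opt$quant, stringsAsFactors = FALSE),
         metadata = utils::read.delim(opt$metadata,
                                      stringsAsFactors = FALSE))
  }
  status <- tryCatch({
    switch(cmd,
      generate = {
        generate_dataset(synth_config(seed = opt$seed), dir = opt$out)
        message("wrote synthetic bundle to ", opt$out)
      },
      run = {
        if (is.null(opt$fasta)) stop("run needs --fasta/--quant/--metadata",
                                     call. = FALSE)
        run_pipeline(opt$fasta, opt$quant, opt$metadata, opt$foam,
                     outdir = opt$out, fdr_cutoff = opt$fdr,
                     mode = opt$mode, alpha = opt$alpha)
        message("pipeline results in ", opt$out)
      },
      occupancy = {
        b <- need_inputs()
        res <- analyze_bundle(b, fdr_cutoff = opt$fdr, mode = opt$mode)
        occ <- res$occupancy[res$occupancy$kind == opt$kind, ]
        dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(fmt_num(occ),
                           file.path(opt$out, "occupancy_summary.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      },
      cluster = {
        b <- need_inputs()
        res <- analyze_bundle(b, fdr_cutoff = opt$fdr, mode = opt$mode)
        m <- as_feature_matrix(res$protein_abundance, "accession",
                               "sample_id", "log10_norm")
        hc <- hcluster(m[rowSums(!is.na(m)) > 0L, , drop = FALSE],
                       axis = opt$axis)
        dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
        write_newick(hc, file.path(opt$out, "dendrogram.nwk"))
      },
      compare = {
        b <- need_inputs()
        res <- analyze_bundle(b, fdr_cutoff = opt$fdr, mode = opt$mode)
        m <- as_feature_matrix(res$protein_abundance, "accession",
                               "sample_id", "log10_norm")
        m <- m[rowSums(!is.na(m)) > 0L, , drop = FALSE]
        labels <- b$metadata[[opt$groups]][match(colnames(m),
                                                 b$metadata$sample_id)]
        v <- volcano(m, labels, alpha = opt$alpha)
        dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(fmt_num(v),
                           file.path(opt$out,
                                     paste0("volcano_", opt$groups, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      },
      foamreg = {
        b <- need_inputs()
        if (is.null(opt$foam)) stop("foamreg needs --foam", call. = FALSE)
        fm <- utils::read.delim(opt$foam, stringsAsFactors = FALSE)
        res <- analyze_bundle(b, fdr_cutoff = opt$fdr, mode = opt$mode)
        ca <- class_abundance(res$protein_abundance,
                              protein_class_map(b$db$accession))
        rows <- list()
        for (cl in unique(ca$class))
          for (v in setdiff(names(fm), "sample_id")) {
            x <- ca$abundance[ca$class == cl]
            names(x) <- ca$sample_id[ca$class == cl]
            y <- stats::setNames(fm[[v]], fm$sample_id)
            common <- intersect(names(x), names(y))
            if (length(common) < 3L || stats::var(x[common]) == 0) next
            fr <- foam_regression(x[common], y[common])
            rows[[length(rows) + 1L]] <- data.frame(
              class = cl, foam_variable = v, slope = fr$slope,
              r_squared = fr$r_squared, p_value = fr$p_value, n = fr$n)
          }
        dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(fmt_num(do.call(rbind, rows)),
                           file.path(opt$out, "foam_regression.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      },
      { message("unknown subcommand: ", cmd, "\n", usage)
        return(invisible(2L)) })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
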