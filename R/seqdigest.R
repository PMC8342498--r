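#' Protein database constructor
#'
#' Builds and validates the protein database used throughout the pipeline.
#' Species tags are carried from the source FASTA (or a sidecar mapping);
#' they are never inferred from the sequence itself.
#'
#' @param accession character vector of unique accessions.
#' @param species character vector; each one of `"barley"`, `"yeast"`,
#'   `"contaminant"`, `"trypsin"`.
#' @param sequence character vector of uppercase amino-acid sequences.
#' @return A `data.frame` of class `protein_db` with columns `accession`,
#'   `species`, `sequence`.
#' @export
protein_db <- function(accession, species, sequence) {
  accession <- as.character(accession)
  species <- as.character(species)
  sequence <- toupper(as.character(sequence))
  if (length(accession) != length(species) ||
      length(accession) != length(sequence))
    stop("accession, species and sequence must have equal length")
  if (anyDuplicated(accession))
    stop("duplicate accessions in protein database: ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "))
  bad_sp <- setdiff(unique(species), PTMFAM_SPECIES)
  if (length(bad_sp))
    stop("unknown species tag(s): ", paste(bad_sp, collapse = ", "))
  if (any(!nzchar(sequence)))
    stop("empty protein sequence for: ",
         paste(accession[!nzchar(sequence)], collapse = ", "))
  if (any(grepl(sprintf("[^%s]", PTMFAM_AA), sequence)))
    stop("sequence contains characters outside the 20-letter alphabet")
  db <- data.frame(accession = accession, species = species,
                   sequence = sequence, stringsAsFactors = FALSE)
  class(db) <- c("protein_db", "data.frame")
  db
}

PTMFAM_SPECIES <- c("barley", "yeast", "contaminant", "trypsin")
PTMFAM_AA <- "ACDEFGHIKLMNPQRSTVWY"

#' Read a protein FASTA into a protein database
#'
#' Headers follow `>ACCESSION species=TAG free text`; alternatively a
#' sidecar accession-to-species mapping can be supplied (named character
#' vector, or a two-column TSV path with columns accession, species),
#' which overrides any header tag.
#'
#' @param path FASTA file path (multi-record, wrapped lines supported).
#' @param species_map optional named character vector or TSV path.
#' @return `protein_db`.
#' @export
read_protein_fasta <- function(path, species_map = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  accession <- sub("\\s.*$", "", headers)
  species <- rep(NA_character_, length(headers))
  m <- regmatches(headers, regexpr("species=[A-Za-z]+", headers))
  has_tag <- grepl("species=", headers)
  species[has_tag] <- sub("^species=", "", m)
  if (!is.null(species_map)) {
    if (is.character(species_map) && length(species_map) == 1 &&
        file.exists(species_map)) {
      sm <- utils::read.delim(species_map, stringsAsFactors = FALSE)
      species_map <- stats::setNames(sm[[2]], sm[[1]])
    }
    hit <- accession %in% names(species_map)
    species[hit] <- unname(species_map[accession[hit]])
  }
  if (anyNA(species))
    stop("no species tag for: ",
         paste(utils::head(accession[is.na(species)], 5), collapse = ", "))
  protein_db(accession, species, as.character(aa))
}

#' Write a protein database as FASTA
#' @param db `protein_db`.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_protein_fasta <- function(db, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(db))) {
    writeLines(sprintf(">%s species=%s", db$accession[i], db$species[i]), con)
    s <- db$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to Lys/Arg and enumerates peptides with up to
#' `max_missed` internal missed cleavages. No length filter is applied;
#' that is a caller decision. With `proline_rule = TRUE` a Lys/Arg
#' followed by Pro is not a cleavage site (off by default: the search
#' settings emulated here state no proline exception).
#'
#' @param sequence a single protein sequence (uppercase string).
#' @param max_missed maximum internal missed cleavages (>= 0).
#' @param proline_rule suppress cleavage before proline.
#' @return `data.frame` with 1-based inclusive `start`, `end`, the
#'   `peptide` string, flanking residues `prev_aa`/`next_aa` (`"-"` at
#'   protein termini) and the internal `missed` cleavage count.
#' @examples
#' digest("AKGCRD", max_missed = 1)
#' @export
digest <- function(sequence, max_missed = 2L, proline_rule = FALSE) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("digest() needs one non-empty sequence")
  if (max_missed < 0) stop("max_missed must be >= 0")
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  cut <- which(res %in% c("K", "R"))
  if (proline_rule) cut <- cut[!(cut < L & res[cut + 1L] == "P")]
  bounds <- unique(c(0L, cut, L))  # cut after these positions
  n_seg <- length(bounds) - 1L
  out <- vector("list", as.integer(min(max_missed, n_seg - 1L)) + 1L)
  for (m in 0:min(max_missed, n_seg - 1L)) {
    i <- seq_len(n_seg - m)
    out[[m + 1L]] <- data.frame(start = bounds[i] + 1L,
                                end = bounds[i + 1L + m],
                                missed = m)
  }
  d <- do.call(rbind, out)
  d <- d[order(d$start, d$end), , drop = FALSE]
  rownames(d) <- NULL
  d$peptide <- substring(sequence, d$start, d$end)
  d$prev_aa <- ifelse(d$start > 1L, res[pmax(d$start - 1L, 1L)], "-")
  d$next_aa <- ifelse(d$end < L, res[pmin(d$end + 1L, L)], "-")
  d[, c("start", "end", "peptide", "prev_aa", "next_aa", "missed")]
}

#' Cleavage-class assignment
#'
#' A peptide terminus is tryptic when the preceding residue is Lys/Arg
#' (N-terminal side) or the terminal residue itself is Lys/Arg
#' (C-terminal side); protein termini count as tryptic. Vectorized over
#' positions.
#'
#' @param start,end 1-based inclusive residue coordinates in the protein.
#' @param sequence the protein sequence.
#' @param proline_rule suppress cleavage before proline (see [digest()]).
#' @return character vector: `"full_tryptic"`, `"semi_tryptic"` or
#'   `"non_tryptic"`.
#' @export
classify_cleavage <- function(start, end, sequence, proline_rule = FALSE) {
  L <- nchar(sequence)
  if (any(start < 1L | end > L | start > end))
    stop("inconsistent peptide location for protein of length ", L)
  prev_aa <- substring(sequence, start - 1L, start - 1L)
  last_aa <- substring(sequence, end, end)
  after_aa <- substring(sequence, end + 1L, end + 1L)
  n_ok <- start == 1L | prev_aa %in% c("K", "R")
  c_ok <- end == L | last_aa %in% c("K", "R")
  if (proline_rule) {
    first_aa <- substring(sequence, start, start)
    n_ok <- n_ok & (start == 1L | first_aa != "P")
    c_ok <- c_ok & (end == L | after_aa != "P")
  }
  ifelse(n_ok & c_ok, "full_tryptic",
         ifelse(n_ok | c_ok, "semi_tryptic", "non_tryptic"))
}

#' Find N-glycosylation sequons (N-X-S/T) in a peptide
#'
#' Positions are peptide-relative (1-based). Sequons truncated by the
#' peptide boundary are not reported. `allow_proline = FALSE` applies
#' the conventional X != P exclusion; the default keeps the literal
#' N-X-S/T rule.
#'
#' @param peptide peptide sequence.
#' @param allow_proline allow Pro at the X position (default TRUE).
#' @return integer vector of Asn positions (possibly empty).
#' @export
find_sequons <- function(peptide, allow_proline = TRUE) {
  res <- strsplit(peptide, "")[[1]]
  n <- length(res)
  if (n < 3L) return(integer(0))
  i <- seq_len(n - 2L)
  hit <- res[i] == "N" & res[i + 2L] %in% c("S", "T")
  if (!allow_proline) hit <- hit & res[i + 1L] != "P"
  i[hit]
}

#' Positions of modifiable residues in a peptide
#' @param peptide peptide sequence.
#' @param residues character vector of residues (e.g. `c("S","T")`).
#' @return integer vector of 1-based positions.
#' @export
find_modifiable_sites <- function(peptide, residues) {
  if (!length(residues)) return(integer(0))
  which(strsplit(peptide, "")[[1]] %in% residues)
}
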