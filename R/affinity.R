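# Curation of peptide competition-binding data and conversion of IC50
# measurements to binding free energies.

#' Gas constant, J mol-1 K-1
#' @export
GAS_CONSTANT <- 8.314462

#' Binding free energy from IC50
#'
#' At sufficiently low peptide concentration the IC50 of a competition
#' assay approximates the dissociation constant, giving
#' `dG_bind = R * T * ln(IC50)` with T in Kelvin and IC50 in molar;
#' the result is returned in kJ/mol (negative for sub-molar IC50).
#'
#' @param ic50 molar concentration(s), > 0
#' @param temperature assay temperature in degrees Celsius
#' @return kJ/mol, vectorised
#' @examples
#' deltaG_from_ic50(4.6e-9, 37)   # about -49.5 kJ/mol
#' @export
deltaG_from_ic50 <- function(ic50, temperature) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("ic50 must be positive and finite (molar)")
  }
  GAS_CONSTANT * (temperature + 273.15) * log(ic50) / 1000
}

.unit_factor <- function(unit) {
  switch(unit,
         "nM" = 1e-9, "uM" = 1e-6, "µM" = 1e-6, "mM" = 1e-3, "M" = 1,
         stop("unknown IC50 unit '", unit, "' (use nM, uM, mM or M)"))
}

#' Load a peptide binding table
#'
#' Reads a delimited table with columns `peptide`, `ic50` and `temperature`
#' (an optional `source` column is carried through), converts IC50 to molar
#' using the mandatory unit declaration, and derives `dg_bind` via
#' [deltaG_from_ic50()].  The unit must be declared per file because
#' published tables are inconsistent about what an "nmol" column means.
#' Rows duplicated in (peptide, ic50, temperature) are collapsed with a
#' warning; unparsable rows raise an error naming the row.
#'
#' @param tsv path to a TSV file, or its text content
#' @param unit one of `"nM"`, `"uM"`, `"mM"`, `"M"`
#' @param allele optional allele label stored on every record
#' @return data frame of binding records with columns peptide, ic50
#'   (molar), temperature (Celsius), dg_bind (kJ/mol), source, allele
#' @export
load_binding_table <- function(tsv, unit, allele = NA_character_) {
  if (missing(unit)) stop("the IC50 unit must be declared explicitly")
  fac <- .unit_factor(unit)
  if (length(tsv) == 1 && !grepl("\n", tsv) && file.exists(tsv)) {
    txt <- readLines(tsv, warn = FALSE)
  } else {
    txt <- unlist(strsplit(paste(tsv, collapse = "\n"), "\n", fixed = TRUE))
  }
  txt <- txt[!grepl("^\\s*#", txt) & nzchar(trimws(txt))]
  if (!length(txt)) {
    return(data.frame(peptide = character(0), ic50 = numeric(0),
                      temperature = numeric(0), dg_bind = numeric(0),
                      source = character(0), allele = character(0),
                      stringsAsFactors = FALSE))
  }
  tab <- utils::read.delim(text = paste(txt, collapse = "\n"),
                           stringsAsFactors = FALSE)
  need <- c("peptide", "ic50", "temperature")
  if (!all(need %in% names(tab))) {
    stop("binding table must have columns: ", paste(need, collapse = ", "))
  }
  ic <- suppressWarnings(as.numeric(tab$ic50))
  tmp <- suppressWarnings(as.numeric(tab$temperature))
  bad <- which(is.na(ic) | is.na(tmp) | !nzchar(trimws(tab$peptide)))
  if (length(bad)) stop("unparsable binding-table row(s): ", paste(bad, collapse = ", "))
  badaa <- which(!vapply(toupper(trimws(tab$peptide)),
                         function(p) all(strsplit(p, "")[[1]] %in% names(AA3)),
                         logical(1)))
  if (length(badaa)) {
    stop("non-standard amino-acid letters in row(s): ", paste(badaa, collapse = ", "))
  }
  rec <- data.frame(
    peptide = toupper(trimws(tab$peptide)),
    ic50 = ic * fac,
    temperature = tmp,
    source = if ("source" %in% names(tab)) tab$source else NA_character_,
    allele = allele,
    stringsAsFactors = FALSE
  )
  dupkey <- paste(rec$peptide, rec$ic50, rec$temperature)
  if (anyDuplicated(dupkey)) {
    warning("collapsing ", sum(duplicated(dupkey)),
            " duplicate (peptide, ic50, temperature) row(s)")
    rec <- rec[!duplicated(dupkey), , drop = FALSE]
  }
  rec$dg_bind <- deltaG_from_ic50(rec$ic50, rec$temperature)
  rownames(rec) <- NULL
  rec[, c("peptide", "ic50", "temperature", "dg_bind", "source", "allele")]
}

#' Keep only peptides of the reference length
#'
#' Threading requires the query peptide to match the reference peptide's
#' length exactly, so the binding set is filtered to length `L`
#' (order-preserving).
#'
#' @param records binding-record data frame
#' @param L required peptide length (> 0)
#' @return filtered records
#' @export
filter_by_length <- function(records, L) {
  stopifnot(L > 0)
  records[nchar(records$peptide) == L, , drop = FALSE]
}

#' Resolve peptides with multiple IC50 measurements
#'
#' Per peptide sequence at most one record is kept.  Policies:
#' `exclude` drops any peptide whose IC50 values disagree by more than
#' `fold_threshold` (the operational reading of "inexplicable discrepancy")
#' and otherwise merges by geometric mean; `geometric_mean` always merges;
#' `keep_first` keeps the first record in file order.
#'
#' @param records binding-record data frame
#' @param policy `"exclude"`, `"geometric_mean"` or `"keep_first"`
#' @param fold_threshold discrepancy ratio for `exclude` (default 10)
#' @return de-duplicated records, dg_bind recomputed where merged
#' @export
resolve_duplicates <- function(records, policy = c("exclude", "geometric_mean", "keep_first"),
                               fold_threshold = 10) {
  policy <- match.arg(policy)
  if (!nrow(records)) return(records)
  out <- lapply(split(seq_len(nrow(records)), records$peptide), function(idx) {
    idx <- sort(idx)
    sub <- records[idx, , drop = FALSE]
    if (nrow(sub) == 1) return(sub)
    ratio <- max(sub$ic50) / min(sub$ic50)
    if (policy == "keep_first") return(sub[1, , drop = FALSE])
    if (policy == "exclude" && ratio > fold_threshold) return(NULL)
    m <- sub[1, , drop = FALSE]
    m$ic50 <- exp(mean(log(sub$ic50)))
    m$temperature <- mean(sub$temperature)
    m$dg_bind <- deltaG_from_ic50(m$ic50, m$temperature)
    m
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(records[0, , drop = FALSE])
  # restore original file order by first occurrence
  out <- out[order(match(out$peptide, records$peptide)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
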