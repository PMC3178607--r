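# The three study workflows behind one roof: validation on native
# complexes, train/predict by threading a binding set onto one reference,
# and the reference-set combinatorics experiment.  Each stage exchanges
# plain data frames (TSV on disk at the CLI level) so every step is
# independently invocable and auditable.

.as_structures <- function(structures, chain_roles = NULL, prepare = TRUE) {
  out <- lapply(names(structures), function(id) {
    s <- structures[[id]]
    if (!inherits(s, "complex_structure")) {
      cr <- if (is.list(chain_roles)) chain_roles[[id]] else chain_roles
      if (is.null(cr)) stop("chain_roles needed to read structure ", id)
      s <- read_complex(s, cr, pdb_id = id)
    }
    if (prepare && any(is.na(s$atoms$class))) s <- prepare_complex(s)
    s
  })
  stats::setNames(out, names(structures))
}

#' Validation workflow: native complexes against experimental affinities
#'
#' Scores each native crystal complex with the five terms, calibrates the
#' coefficients by PLS and evaluates leave-one-out q2 / S_press; reports
#' per-peptide predicted binding free energies and their deviations from
#' experiment.
#'
#' @param structures named list of `complex_structure`s (or PDB paths,
#'   with `chain_roles`), keyed by complex id; at least 4
#' @param bindings data frame with columns `peptide` and `dg_bind`
#'   (kJ/mol) covering every native peptide
#' @param chain_roles chain-role map (single map or per-id list) used when
#'   `structures` holds paths
#' @param params term parameters
#' @param n_components PLS components (default `min(5, n - 2)`)
#' @param external_desolv optional named per-complex desolvation table
#' @return list of class `groove_report`: `table` (peptide, complex_id,
#'   dg_exp, dg_pred, deviation), `q2`, `s_press`, `model`, `terms`
#' @export
run_validate <- function(structures, bindings, chain_roles = NULL,
                         params = term_params(), n_components = NULL,
                         external_desolv = NULL) {
  structures <- .as_structures(structures, chain_roles)
  if (length(structures) < 4) {
    stop("validation needs at least 4 usable complexes, got ", length(structures))
  }
  backend <- if (is.null(external_desolv)) "sasa" else "external"
  tm <- do.call(rbind, lapply(structures, compute_terms, params = params,
                              backend = backend, external_table = external_desolv))
  peptides <- vapply(structures, function(s) s$peptide_sequence, character(1))
  dg <- bindings$dg_bind[match(peptides, bindings$peptide)]
  if (any(is.na(dg))) {
    stop("no experimental dG for native peptide(s): ",
         paste(peptides[is.na(dg)], collapse = ", "))
  }
  X <- as.matrix(tm[, c("HB", "LIPO", "BP", "ROT", "DESOLV")])
  rownames(X) <- names(structures)
  if (is.null(n_components)) n_components <- max(1L, min(5L, nrow(X) - 2L))
  cv <- loocv_pls(X, dg, n_components = n_components)
  model <- fit_pls(X, dg, n_components = n_components)
  structure(list(
    table = data.frame(peptide = unname(peptides),
                       complex_id = names(structures),
                       dg_exp = dg,
                       dg_pred = unname(cv$predictions),
                       deviation = unname(cv$predictions) - dg,
                       stringsAsFactors = FALSE),
    q2 = cv$q2, s_press = cv$s_press, model = model, terms = tm,
    workflow = "validate"
  ), class = "groove_report")
}

#' Train/predict workflow: thread a binding set onto one reference
#'
#' Filters the binding records to the reference peptide's length, threads
#' each surviving peptide into the reference groove, computes the terms
#' of every model, and calibrates/evaluates by PLS with leave-one-out
#' cross-validation.
#'
#' @param reference a prepared `complex_structure` (or a PDB path plus
#'   `chain_roles`)
#' @param bindings binding records (see [load_binding_table()])
#' @param chain_roles used when `reference` is a path
#' @param duplicate_policy passed to [resolve_duplicates()]
#' @inheritParams run_validate
#' @return `groove_report` with per-peptide predictions, `q2`, `s_press`,
#'   the final `model`, the `terms` matrix, and threading diagnostics
#' @export
run_train_predict <- function(reference, bindings, chain_roles = NULL,
                              params = term_params(), n_components = NULL,
                              duplicate_policy = "exclude",
                              external_desolv = NULL) {
  if (!inherits(reference, "complex_structure")) {
    reference <- read_complex(reference, chain_roles)
  }
  if (any(is.na(reference$atoms$class))) reference <- prepare_complex(reference)
  L <- nchar(reference$peptide_sequence)
  recs <- resolve_duplicates(filter_by_length(bindings, L), policy = duplicate_policy)
  if (!nrow(recs)) {
    stop("no peptides left after the length filter: only peptides with the ",
         "same length as the reference peptide (", L, ") can be threaded")
  }
  backend <- if (is.null(external_desolv)) "sasa" else "external"
  tm <- do.call(rbind, lapply(recs$peptide, function(p) {
    model <- prepare_complex(thread_peptide(reference, p))
    compute_terms(model, params, backend = backend, external_table = external_desolv)
  }))
  X <- as.matrix(tm[, c("HB", "LIPO", "BP", "ROT", "DESOLV")])
  rownames(X) <- recs$peptide
  if (is.null(n_components)) n_components <- max(1L, min(5L, nrow(X) - 2L))
  cv <- loocv_pls(X, recs$dg_bind, n_components = n_components)
  model <- fit_pls(X, recs$dg_bind, n_components = n_components)
  structure(list(
    table = data.frame(peptide = recs$peptide,
                       dg_exp = recs$dg_bind,
                       dg_pred = unname(cv$predictions),
                       deviation = unname(cv$predictions) - recs$dg_bind,
                       stringsAsFactors = FALSE),
    q2 = cv$q2, s_press = cv$s_press, model = model, terms = tm,
    reference = reference$pdb_id, workflow = "train_predict"
  ), class = "groove_report")
}

#' Reference-set workflow
#'
#' Enumerates the structure combinations, runs the native-mode experiment
#' and summarises the q2 distribution plus the structural-similarity
#' correlations.
#'
#' @param structure_table data frame with `pdb_id` and `peptide`
#' @param bindings binding records covering the native peptides
#' @param structures named list of prepared structures (or paths with
#'   `chain_roles`)
#' @inheritParams run_validate
#' @return `groove_report` with `results`, `correlations`, and a q2
#'   distribution summary (`n_sets`, `n_q2_gt_0.5`)
#' @export
run_refsets <- function(structure_table, bindings, structures,
                        chain_roles = NULL, params = term_params(),
                        n_components = NULL, external_desolv = NULL) {
  structures <- .as_structures(structures, chain_roles)
  sets <- enumerate_reference_sets(structure_table)
  ex <- run_refset_experiment(sets, bindings, structures, params = params,
                              n_components = n_components,
                              external_desolv = external_desolv)
  structure(list(
    results = ex$results, correlations = ex$correlations,
    n_sets = nrow(ex$results),
    n_q2_gt_0.5 = sum(ex$results$q2 > 0.5, na.rm = TRUE),
    workflow = "refsets"
  ), class = "groove_report")
}

#' @export
print.groove_report <- function(x, ...) {
  cat("<groove_report>", x$workflow, "\n")
  if (!is.null(x$q2)) {
    cat("  q2 =", format(x$q2, digits = 4),
        " S_press =", format(x$s_press, digits = 4), "kJ/mol\n")
  }
  if (!is.null(x$table)) print(x$table, digits = 4)
  if (!is.null(x$results)) {
    cat(" ", x$n_sets, "reference sets;", x$n_q2_gt_0.5, "with q2 > 0.5\n")
    print(x$correlations, digits = 3)
  }
  invisible(x)
}

#' Read a flat key-value run configuration
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments and
#' blank lines ignored.  Values containing commas are split into vectors.
#'
#' @param path config file
#' @return named list
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([^=:]+?)\\s*[=:]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("unparsable config line: ", ln)
    val <- trimws(m[3])
    if (grepl(",", val)) val <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(val))
    out[[trimws(m[2])]] <- if (!any(is.na(num))) num else val
  }
  out
}

#' Paths to the bundled study tables
#'
#' `"madden"`: the five HLA-A*0201 native complexes with experimental
#' binding free energies; `"dr15"`: twenty 14-mer HLA-DR15 binders with
#' IC50 (nM) and assay temperature; `"hla_a2"`: seventeen HLA-A2 crystal
#' structures sharing native peptides, for the reference-set experiment.
#'
#' @param which one of `"madden"`, `"dr15"`, `"hla_a2"`
#' @return file path of the bundled TSV
#' @export
bundled_table <- function(which = c("madden", "dr15", "hla_a2")) {
  which <- match.arg(which)
  f <- c(madden = "madden_dg.tsv", dr15 = "dr15_binding.tsv",
         hla_a2 = "hla_a2_structures.tsv")[which]
  system.file("extdata", f, package = "groovescore")
}
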