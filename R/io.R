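#' @title Paired quantification tables and cohort metadata
#' @name core-io
#' @description
#' dd-ABPP quantifies every peptide transition twice per biospecimen: once in
#' the untreated ("total") extract and once in the probe-treated,
#' bead-depleted ("depleted") extract. The long-format paired table is the
#' central data structure of the package; all downstream ratios are computed
#' over transitions observed in both extracts of the same sample.
NULL

.EXTRACT_LEVELS <- c("total", "depleted")
.TISSUE_LEVELS <- c("T", "N")
.SURVIVAL_LEVELS <- c("long", "short")
.EVIDENCE_LEVELS <- c("experimental", "predicted", "any")
.QUANT_COLS <- c("protein_id", "peptide_seq", "transition_id",
                 "sample_id", "extract", "intensity")

#' Construct a validated paired quantification table
#'
#' Validates a long-format table of transition intensities from paired
#' total/depleted extracts and attaches the `"paired_quant"` class.
#' Intensities are on the raw linear scale; missing measurements are `NA`,
#' never 0 (0 is a legal measured floor after imputation).
#'
#' @param x data.frame with columns `protein_id`, `peptide_seq`,
#'   `transition_id`, `sample_id`, `extract` (`"total"` or `"depleted"`),
#'   `intensity` (non-negative or `NA`) and optionally `decoy` (logical).
#' @return `x` with class `c("paired_quant", "data.frame")`.
#' @export
paired_quant <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.QUANT_COLS, names(x))
  if (length(missing_cols))
    stop("quant table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!"decoy" %in% names(x)) x$decoy <- FALSE
  x$extract <- as.character(x$extract)
  bad <- setdiff(unique(x$extract), .EXTRACT_LEVELS)
  if (length(bad))
    stop("unknown extract label(s): ", paste(bad, collapse = ", "),
         " (expected 'total'/'depleted')")
  x$intensity <- as.numeric(x$intensity)
  if (any(x$intensity < 0, na.rm = TRUE))
    stop("negative intensities are not allowed")
  key <- quant_key(x)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (protein, peptide, transition, sample, extract) key: ", dup)
  }
  x$decoy <- as.logical(x$decoy)
  class(x) <- unique(c("paired_quant", class(x)))
  x
}

quant_key <- function(x, cols = .QUANT_COLS[1:5]) {
  do.call(paste, c(unname(as.list(x[cols])), sep = "\r"))
}

#' Read a paired quantification table from TSV
#'
#' Reads an OpenSWATH/SWATH2stats-style long table. Exported column names
#' vary between tools, so a `col_map` dialect maps the file's header onto
#' the canonical names; extract labels are case-folded when
#' `fold_extract_case = TRUE`.
#'
#' @param path tab-separated file with a header.
#' @param col_map named character vector mapping canonical names
#'   (`protein_id`, `peptide_seq`, `transition_id`, `sample_id`, `extract`,
#'   `intensity`, optionally `decoy`) to the file's column names. `NULL`
#'   assumes canonical names.
#' @param fold_extract_case lower-case the extract column before validation.
#' @return a [paired_quant] table. Missing intensities (empty field or
#'   `"NA"`) are preserved as `NA`.
#' @export
read_quant_table <- function(path, col_map = NULL, fold_extract_case = TRUE) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), check.names = FALSE)
  if (!is.null(col_map)) {
    missing_src <- setdiff(unname(col_map), names(raw))
    if (length(missing_src))
      stop("column(s) named in col_map not found in file: ",
           paste(missing_src, collapse = ", "))
    for (canon in names(col_map)) names(raw)[names(raw) == col_map[[canon]]] <- canon
  }
  if (fold_extract_case && "extract" %in% names(raw))
    raw$extract <- tolower(raw$extract)
  paired_quant(raw)
}

#' Write a paired quantification table to TSV
#'
#' Canonical dialect: UTF-8, tab-separated, header, missing intensities as
#' empty fields. `read_quant_table(write_quant_table(x))` round-trips.
#'
#' @param x a [paired_quant] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(x, path) {
  utils::write.table(as.data.frame(x)[, c(.QUANT_COLS, "decoy")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Construct a cohort design
#'
#' One row per MS sample. Each patient contributes at most one tumor (`T`)
#' and one adjacent-tissue (`N`) sample; the analysis condition is the
#' tissue-by-survival combination (e.g. `T_long`), derived here.
#'
#' @param x data.frame with columns `sample_id`, `patient_id`, `tissue`
#'   (`T`/`N`), `survival` (`long`/`short`), `age`, `sex` (0/1),
#'   `smoking` (0/1) and optionally `tumor_cell_pct` (percent, `NA` for
#'   non-tumor samples).
#' @return `x` plus a derived `condition` column, classed `"cohort_design"`.
#' @export
cohort_design <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "tissue", "survival",
            "age", "sex", "smoking")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("design is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!"tumor_cell_pct" %in% names(x)) x$tumor_cell_pct <- NA_real_
  if (anyDuplicated(x$sample_id))
    stop("duplicated sample_id: ",
         paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(as.character(x$tissue)), .TISSUE_LEVELS)
  if (length(bad))
    stop("tissue outside {T, N}: ", paste(bad, collapse = ", "))
  miss_surv <- is.na(x$survival) | x$survival == ""
  if (any(miss_surv))
    stop("missing survival class for sample(s): ",
         paste(x$sample_id[miss_surv], collapse = ", "))
  bad <- setdiff(unique(as.character(x$survival)), .SURVIVAL_LEVELS)
  if (length(bad))
    stop("survival outside {long, short}: ", paste(bad, collapse = ", "))
  pt <- paste(x$patient_id, x$tissue)
  if (anyDuplicated(pt))
    stop("patient with more than one sample of the same tissue: ",
         paste(unique(pt[duplicated(pt)]), collapse = ", "))
  x$condition <- paste(x$tissue, x$survival, sep = "_")
  class(x) <- unique(c("cohort_design", class(x)))
  x
}

#' Read a cohort design table
#'
#' @param path TSV (or CSV, by extension) with the columns documented in
#'   [cohort_design].
#' @return a `cohort_design`.
#' @export
read_design <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  cohort_design(utils::read.table(path, header = TRUE, sep = sep,
                                  stringsAsFactors = FALSE,
                                  na.strings = c("NA", "")))
}

#' Construct an undirected protein-protein interaction set
#'
#' Edges are unordered and de-duplicated; self-edges are dropped with a
#' warning. Evidence tiers follow the reference-interactome convention
#' (`experimental`, `predicted`, `any`).
#'
#' @param x data.frame with columns `protein_a`, `protein_b`, `evidence`.
#' @return classed `"interaction_set"` data.frame with canonically ordered
#'   endpoints.
#' @export
interaction_set <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("protein_a", "protein_b", "evidence")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("edge list is missing columns: ", paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(as.character(x$evidence)), .EVIDENCE_LEVELS)
  if (length(bad))
    stop("unknown evidence tier(s): ", paste(bad, collapse = ", "))
  self <- x$protein_a == x$protein_b
  if (any(self)) {
    warning(sum(self), " self-edge(s) dropped")
    x <- x[!self, , drop = FALSE]
  }
  a <- pmin(x$protein_a, x$protein_b)
  b <- pmax(x$protein_a, x$protein_b)
  x$protein_a <- a
  x$protein_b <- b
  x <- x[!duplicated(paste(a, b, x$evidence, sep = "\r")), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- unique(c("interaction_set", class(x)))
  x
}

#' Read a protein-protein interaction edge list
#'
#' @param path TSV with columns `protein_a`, `protein_b`, `evidence`.
#' @return an [interaction_set].
#' @export
read_interactions <- function(path) {
  interaction_set(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Subset an interaction set by evidence tier
#'
#' @param graph an [interaction_set].
#' @param evidence tier to keep; `"any"` keeps all edges.
#' @return an [interaction_set].
#' @export
filter_evidence <- function(graph, evidence = "experimental") {
  if (evidence == "any") return(graph)
  interaction_set(as.data.frame(graph)[graph$evidence == evidence, ,
                                       drop = FALSE])
}

#' Construct an enzyme catalogue
#'
#' The query list of hydrolase identifiers with their class labels
#' (serine proteases, metabolic serine hydrolases, non-annotated cases and
#' inactive enzymes).
#'
#' @param x data.frame with columns `protein_id`, `class` (one of
#'   `serine_protease`, `metabolic_SH`, `non_annotated`, `inactive`) and
#'   optionally `catalytic_ok` (logical, default `TRUE` except for
#'   `inactive`).
#' @return classed `"enzyme_catalog"` data.frame.
#' @export
enzyme_catalog <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("protein_id", "class")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("catalog is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(x$protein_id))
    stop("duplicated catalogue protein_id")
  classes <- c("serine_protease", "metabolic_SH", "non_annotated", "inactive")
  bad <- setdiff(unique(as.character(x$class)), classes)
  if (length(bad))
    stop("unknown enzyme class(es): ", paste(bad, collapse = ", "))
  if (!"catalytic_ok" %in% names(x)) x$catalytic_ok <- x$class != "inactive"
  class(x) <- unique(c("enzyme_catalog", class(x)))
  x
}

#' Read an enzyme catalogue table
#'
#' @param path TSV with columns `protein_id`, `class` and optionally
#'   `catalytic_ok`.
#' @return an [enzyme_catalog].
#' @export
read_catalog <- function(path) {
  enzyme_catalog(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Check total/depleted pairing per sample
#'
#' For every sample, counts the transitions observed (non-missing) in both
#' extracts -- the set eligible for depletion-ratio computation -- and the
#' orphans seen in only one extract. A sample with zero matched transitions
#' is flagged unusable rather than raising an error. The matched set is
#' symmetric in extract order.
#'
#' @param quant a [paired_quant] table.
#' @param design a [cohort_design]; every (sample, extract) in `quant`
#'   must belong to a declared sample.
#' @return data.frame with one row per design sample: `sample_id`,
#'   `n_matched`, `n_orphan_total`, `n_orphan_depleted`, `usable`.
#' @export
validate_pairing <- function(quant, design) {
  undeclared <- setdiff(unique(quant$sample_id), design$sample_id)
  if (length(undeclared))
    stop("sample(s) in quant table not declared in design: ",
         paste(undeclared, collapse = ", "))
  obs <- quant[!is.na(quant$intensity) & !quant$decoy, , drop = FALSE]
  fkey <- paste(obs$protein_id, obs$peptide_seq, obs$transition_id, sep = "\r")
  res <- lapply(design$sample_id, function(s) {
    in_tot <- unique(fkey[obs$sample_id == s & obs$extract == "total"])
    in_dep <- unique(fkey[obs$sample_id == s & obs$extract == "depleted"])
    n_matched <- length(intersect(in_tot, in_dep))
    data.frame(sample_id = s, n_matched = n_matched,
               n_orphan_total = length(setdiff(in_tot, in_dep)),
               n_orphan_depleted = length(setdiff(in_dep, in_tot)),
               usable = n_matched > 0L, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Drop decoy transitions
#'
#' Decoy rows are accepted on input but excluded from all downstream
#' statistics by default.
#'
#' @param quant a [paired_quant] table.
#' @return the table without decoy rows.
#' @export
drop_decoys <- function(quant) {
  out <- quant[!quant$decoy, , drop = FALSE]
  rownames(out) <- NULL
  out
}
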