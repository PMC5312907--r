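#' Load a solvent dispersibility table
#'
#' Reads a comma-separated table of solvent records: one row per compound with
#' an integer `id`, a `name`, an optional `smiles` string, the maximum
#' dispersible SWCNT concentration `conc` in mg/mL, optionally the log10
#' endpoint `log_conc`, and a `split` flag (`"train"` or `"test"`).  When
#' `log_conc` is absent it is derived with [to_log_endpoint()].
#'
#' @param file Path or connection to a CSV file with a header row.
#' @param strict If `TRUE`, require exactly 29 rows with a 22/7 train/test
#'   split (the layout of the packaged study data).  Set to `FALSE` to read
#'   arbitrary solvent tables.
#' @return A `data.frame` of solvent records with class `"solvent_table"`.
#' @seealso [solvent_data()] for the packaged dataset, [split_dataset()].
#' @export
load_solvent_table <- function(file, strict = FALSE) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no rows in solvent table")
  required <- c("id", "name", "conc", "split")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("solvent table lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$id))
    stop("duplicate id in solvent table: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  bad <- which(!is.finite(df$conc) | df$conc <= 0)
  if (length(bad))
    stop("non-positive concentration at row ", bad[1L], " (id ", df$id[bad[1L]], ")")
  bad <- which(is.na(df$split) | !df$split %in% c("train", "test"))
  if (length(bad))
    stop("missing or unknown split flag at row ", bad[1L], " (id ", df$id[bad[1L]], ")")
  if (is.null(df$log_conc)) df$log_conc <- to_log_endpoint(df$conc)
  if (strict) {
    if (nrow(df) != 29L) stop("strict mode: expected 29 rows, got ", nrow(df))
    if (sum(df$split == "test") != 7L)
      stop("strict mode: expected 7 test rows, got ", sum(df$split == "test"))
  }
  df$id <- as.integer(df$id)
  class(df) <- c("solvent_table", "data.frame")
  df
}

#' Write a solvent table to CSV
#'
#' Inverse of [load_solvent_table()]; a write-then-read round trip is
#' value-identical.
#'
#' @param records A solvent table `data.frame`.
#' @param file Destination path.
#' @return `file`, invisibly.
#' @export
write_solvent_table <- function(records, file) {
  write.csv(as.data.frame(records), file, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' The packaged 29-solvent SWCNT dispersibility dataset
#'
#' Twenty-nine organic solvents with the maximum dispersible concentration of
#' single-walled carbon nanotubes (`conc`, mg/mL), its log10 transform
#' (`log_conc`), the calculated endpoint reported alongside the original data
#' (`log_conc_cal`, stored for reference only and used by no fit in this
#' package), an authored SMILES encoding of each structure, and the fixed
#' train/test split (22 training, 7 test compounds).
#'
#' @return A `solvent_table` data.frame with 29 rows.
#' @export
solvent_data <- function() {
  load_solvent_table(system.file("extdata", "solvents.csv", package = "cntdisp",
                                 mustWork = TRUE), strict = TRUE)
}

#' SMILES strings for the packaged solvents
#'
#' @return Named character vector of SMILES, names are compound ids ("1".."29").
#' @export
solvent_smiles <- function() {
  x <- read.delim(system.file("extdata", "solvents.smi", package = "cntdisp",
                              mustWork = TRUE),
                  header = FALSE, col.names = c("id", "smiles"),
                  stringsAsFactors = FALSE)
  setNames(x$smiles, x$id)
}

#' Log10 dispersibility endpoint
#'
#' Transforms a concentration in mg/mL to the log10 endpoint used as the
#' response of every model in the package.  The packaged endpoint column is
#' the base-10 logarithm of the concentration in mg/mL; no conversion to molar
#' units is performed (molecular weights are never used).
#'
#' @param conc Numeric vector of concentrations, mg/mL, strictly positive.
#' @return `log10(conc)`.
#' @export
to_log_endpoint <- function(conc) {
  if (any(!is.finite(conc) | conc <= 0))
    stop("concentration must be positive and finite")
  log10(conc)
}

#' Split solvent records into training and test sets
#'
#' Partitions records by their `split` flag, preserving input order.
#'
#' @param records A solvent table (or any data.frame with a `split` column).
#' @return A list with elements `train` and `test`.
#' @export
split_dataset <- function(records) {
  if (is.null(records$split)) stop("records have no split column")
  bad <- which(is.na(records$split) | !records$split %in% c("train", "test"))
  if (length(bad))
    stop("record id ", records$id[bad[1L]], " has a missing or unknown split flag")
  list(train = records[records$split == "train", , drop = FALSE],
       test  = records[records$split == "test", , drop = FALSE])
}

#' Reference descriptor table for the packaged solvents
#'
#' The six descriptor columns (SRW09, DipoleZ, piPC05, Ram, X0Av, ATS6m) as
#' printed in the original study, for all 29 compounds.  All columns carry
#' provenance `"supplied"`: these are the values the reference models were
#' fitted on, not values recomputed by this package (see
#' [verify_against_reference()] for the comparison).
#'
#' @return A [descriptor_matrix()] with 29 rows and six columns.
#' @export
reference_descriptors <- function() {
  df <- read.csv(system.file("extdata", "descriptor_reference.csv",
                             package = "cntdisp", mustWork = TRUE))
  cols <- df[, setdiff(names(df), "id"), drop = FALSE]
  descriptor_matrix(df$id, cols,
                    provenance = setNames(rep("supplied", ncol(cols)), names(cols)))
}

#' Reference descriptor correlation matrix
#'
#' The printed pairwise Pearson correlations among the six reference
#' descriptors and the calculated endpoint, kept for side-by-side comparison
#' with [correlation_matrix()].  The compound cohort behind these printed
#' values (all 29 vs the 22 training compounds) is not documented in the
#' source, so no agreement is asserted anywhere in the package.
#'
#' @return A 7x7 symmetric numeric matrix.
#' @export
reference_correlations <- function() {
  m <- as.matrix(read.csv(system.file("extdata", "reference_correlations.csv",
                                      package = "cntdisp", mustWork = TRUE),
                          row.names = 1))
  colnames(m) <- rownames(m)
  m
}

#' Construct a descriptor matrix
#'
#' A descriptor matrix is a data.frame of named numeric descriptor columns
#' keyed by compound id, with a per-column provenance tag: `"computed"`
#' (derived from structure by this package) or `"supplied"` (taken from an
#' external source, e.g. a quantum-chemistry code).
#'
#' @param compound_ids Integer vector of compound ids.
#' @param columns Named list (or data.frame) of numeric vectors, one per
#'   descriptor.
#' @param provenance Named character vector mapping column names to
#'   `"computed"` or `"supplied"`.
#' @return A data.frame with class `"descriptor_matrix"`, first column `id`,
#'   and attribute `provenance`.
#' @export
descriptor_matrix <- function(compound_ids, columns, provenance) {
  columns <- as.data.frame(columns, optional = TRUE)
  if (nrow(columns) != length(compound_ids))
    stop("descriptor columns must match the number of compounds")
  if (anyNA(columns)) stop("descriptor matrix must have no missing entries")
  stopifnot(all(names(columns) %in% names(provenance)),
            all(provenance %in% c("computed", "supplied")))
  out <- cbind(data.frame(id = as.integer(compound_ids)), columns)
  attr(out, "provenance") <- provenance[names(columns)]
  class(out) <- c("descriptor_matrix", "data.frame")
  out
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("Descriptor matrix: ", nrow(x), " compounds x ", length(prov),
      " descriptors\n", sep = "")
  cat("  computed: ", paste(names(prov)[prov == "computed"], collapse = ", "),
      "\n  supplied: ", paste(names(prov)[prov == "supplied"], collapse = ", "),
      "\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}
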