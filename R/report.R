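# Printed reference models and statistics for the packaged 29-solvent study.
# These are inputs (the published regression equations the package re-derives),
# kept verbatim with their source locations for the reproduction report.
.reference_models <- list(
  list(id = 1L, subset = c("SRW09"),
       coefficients = c(`(Intercept)` = -2.1522, SRW09 = 0.0020),
       halfwidths   = c(`(Intercept)` = 0.3620, SRW09 = 0.0008),
       train = c(R2 = 0.548, Q2 = 0.453, F = 24.249, s = 0.627,
                 SPRESS = 0.690, SDEP = 0.674),
       test = c(R2_test = 0.830, rm2_average = 0.773, rm2_delta = 0.112),
       source = "model 1 (single-descriptor equation)"),
  list(id = 2L, subset = c("SRW09", "DipoleZ"),
       coefficients = c(`(Intercept)` = -2.1228, SRW09 = 0.0019,
                        DipoleZ = 0.3809),
       halfwidths   = c(`(Intercept)` = 0.3149, SRW09 = 0.0007,
                        DipoleZ = 0.2865),
       train = c(R2 = 0.679, Q2 = 0.573, F = 20.080, s = 0.543,
                 SPRESS = 0.626, SDEP = 0.595),
       test = c(R2_test = 0.786, rm2_average = 0.717, rm2_delta = 0.137),
       source = "model 2 (two-descriptor equation)"),
  list(id = 3L, subset = c("Ram", "piPC05", "DipoleZ"),
       coefficients = c(`(Intercept)` = -2.3590, Ram = 0.8389,
                        piPC05 = -0.0209, DipoleZ = 0.3855),
       halfwidths   = c(`(Intercept)` = 0.4189, Ram = 0.2960,
                        piPC05 = 0.0122, DipoleZ = 0.2920),
       train = c(R2 = 0.736, Q2 = 0.601, F = 16.687, s = 0.506,
                 SPRESS = 0.621, SDEP = 0.575),
       test = c(R2_test = 0.813, rm2_average = 0.751, rm2_delta = 0.122),
       source = "model 3 (three-descriptor equation)"),
  list(id = 4L, subset = c("SRW09", "ATS6m", "X0Av", "DipoleZ"),
       coefficients = c(`(Intercept)` = -4.5062, SRW09 = 0.0022,
                        ATS6m = 4.0933, X0Av = -0.0832, DipoleZ = 0.5488),
       halfwidths   = c(`(Intercept)` = 1.9741, SRW09 = 0.0008,
                        ATS6m = 3.1813, X0Av = 0.0857, DipoleZ = 0.2716),
       train = c(R2 = 0.797, Q2 = 0.666, F = 16.722, s = 0.456,
                 SPRESS = 0.585, SDEP = 0.527),
       test = c(R2_test = 0.807, rm2_average = 0.744, rm2_delta = 0.125),
       source = "model 4 (four-descriptor equation)")
)

# Reference-table cells documented as irreproducible from the compounds'
# actual structures.  The pattern behind them (established by recomputation,
# see the methods vignette): rows 3 and 4 of the printed table are transposed
# for piPC05/Ram/X0Av, and rows 2, 5, 10, 14 and 16 print the descriptors of
# the des-methylated parent heterocycle (2-pyrrolidinone instead of NMP,
# imidazolidinone instead of its dimethyl derivative, tetrahydropyrimidinone
# instead of DMPU, formamide instead of DMF, acetonitrile instead of
# propionitrile) -- every such cell is reproduced exactly by the parent
# structure.  The printed ATS6m column matches no autocorrelation dialect
# (its scale is log-like; see ats_dialect_report()).
.known_discrepancies <- function(ref) {
  rbind(
    data.frame(id = c(5L, 10L), column = "SRW09"),
    data.frame(id = c(2L, 3L, 4L, 5L, 10L), column = "piPC05"),
    data.frame(id = c(2L, 3L, 4L, 5L, 10L, 14L), column = "Ram"),
    data.frame(id = c(2L, 3L, 4L, 5L, 10L, 14L, 16L), column = "X0Av"),
    data.frame(id = ref$id, column = "ATS6m")
  )
}

#' Refit the reference dispersibility models on the packaged data
#'
#' Re-derives the four published regression models from the packaged tables:
#' fits each printed descriptor subset by OLS on the 22 training compounds
#' using the printed descriptor columns, computes the full statistics suite
#' (R2, s, F, Q2, SPRESS, SDEP), evaluates the 7 test compounds, and compares
#' everything against the printed values.
#'
#' Hard comparisons (training R2/Q2/F and the descriptor spot-checks computed
#' from SMILES) carry pass flags at the stated tolerances.  Soft comparisons
#' (test-set metrics, SDEP conventions, the printed correlation matrix, the
#' printed calculated-endpoint column) are reported with their differences
#' but never flagged as failures, because their exact provenance is not
#' documented in the source (see the methods vignette).
#'
#' @param tol_r2 Tolerance on R2 and Q2 (default 0.01).
#' @param tol_f Tolerance on F (default 0.5).
#' @param coef_rel Relative coefficient tolerance; a coefficient passes when
#'   within `coef_rel` of the printed value or within the printed halfwidth,
#'   whichever is larger.
#' @return Object of class `"reference_report"` with elements `models`
#'   (comparison data.frame), `coefficients` (long data.frame),
#'   `spot_checks`, `descriptor_check` (from [verify_against_reference()]),
#'   `correlations` (computed, both cohorts, and printed),
#'   `hard_pass` (logical).
#' @export
refit_reference_models <- function(tol_r2 = 0.01, tol_f = 0.5,
                                   coef_rel = 0.05) {
  solv <- solvent_data()
  ref <- reference_descriptors()
  sp <- split_dataset(solv)
  tr_idx <- match(sp$train$id, ref$id)
  te_idx <- match(sp$test$id, ref$id)
  y_tr <- sp$train$log_conc
  y_te <- sp$test$log_conc

  model_rows <- list(); coef_rows <- list()
  for (m in .reference_models) {
    fit <- fit_ols(ref[tr_idx, m$subset, drop = FALSE], y_tr)
    val <- validation_report(fit, ref[te_idx, m$subset, drop = FALSE], y_te,
                             train_mean = mean(y_tr))
    got <- c(R2 = fit$stats$R2, Q2 = fit$stats$Q2, F = fit$stats$F,
             s = fit$stats$s, SPRESS = fit$stats$SPRESS,
             SDEP = fit$stats$SDEP,
             R2_test = val$R2_test, rm2_average = val$rm2_average,
             rm2_delta = val$rm2_delta)
    printed <- c(m$train, m$test)
    stat <- names(printed)
    hard <- stat %in% c("R2", "Q2", "F")
    tol <- ifelse(stat %in% c("R2", "Q2"), tol_r2,
                  ifelse(stat == "F", tol_f, NA_real_))
    model_rows[[length(model_rows) + 1L]] <- data.frame(
      model = m$id, source = m$source, statistic = stat,
      refit = unname(got[stat]), printed = unname(printed),
      abs_diff = abs(unname(got[stat]) - unname(printed)),
      hard = hard, tolerance = tol,
      pass = ifelse(hard, abs(got[stat] - printed) <= tol, NA))
    cn <- names(m$coefficients)
    refc <- fit$coefficients[cn]
    coef_rows[[length(coef_rows) + 1L]] <- data.frame(
      model = m$id, term = cn, refit = unname(refc),
      printed = unname(m$coefficients),
      se = unname(fit$se[cn]), printed_halfwidth = unname(m$halfwidths),
      pass = abs(refc - m$coefficients) <=
        pmax(coef_rel * abs(m$coefficients), m$halfwidths))
  }
  models <- do.call(rbind, model_rows)
  coefs <- do.call(rbind, coef_rows)

  # descriptor spot checks recomputed from the SMILES fixtures
  g <- lapply(setNames(solv$smiles, solv$id), parse_structure)
  spot <- data.frame(
    check = c("X0Av(formamide)", "X0Av(acetone)", "X0Av(chlorophenol)",
              "Ram(N-cyclohexyl-pyrrolidinone)", "Ram(toluene)",
              "piPC05(toluene)", "piPC05(benzyl alcohol)"),
    computed = c(round(chi0v_average(g[["28"]]), 3),
                 round(chi0v_average(g[["22"]]), 3),
                 round(chi0v_average(g[["21"]]), 3),
                 ram_index(g[["1"]]), ram_index(g[["26"]]),
                 multiple_path_count(g[["26"]], 5),
                 multiple_path_count(g[["29"]], 5)),
    expected = c(0.521, 0.727, 0.611, 3, 1, 44, 50))
  spot$pass <- spot$computed == spot$expected

  computed <- build_descriptor_matrix(solv)
  dcheck <- verify_against_reference(
    computed, ref,
    tolerance = c(X0Av = 0.002, Ram = 0.5, piPC05 = 0.5, SRW09 = 0.5,
                  ATS6m = 0.01),
    known_discrepancies = .known_discrepancies(ref))

  # correlation matrix under both plausible cohorts, printed for comparison
  cor_cols <- cbind(ref[setdiff(names(ref), "id")],
                    LogC_cal = solv$log_conc_cal)
  correlations <- list(all29 = correlation_matrix(cor_cols),
                       train22 = correlation_matrix(cor_cols[tr_idx, ]),
                       printed = reference_correlations())

  hard_pass <- all(models$pass[models$hard]) && all(spot$pass)
  structure(list(models = models, coefficients = coefs, spot_checks = spot,
                 descriptor_check = dcheck, correlations = correlations,
                 hard_pass = hard_pass),
            class = "reference_report")
}

#' @export
print.reference_report <- function(x, ...) {
  cat("Reference model refits on the packaged 29-solvent data\n")
  cat("------------------------------------------------------\n")
  hardm <- x$models[x$models$hard, ]
  for (mid in unique(hardm$model)) {
    r <- hardm[hardm$model == mid, ]
    cat(sprintf("model %d: %s\n", mid,
                paste(sprintf("%s refit %.3f / printed %.3f [%s]",
                              r$statistic, r$refit, r$printed,
                              ifelse(r$pass, "ok", "DIFFERS")),
                      collapse = "  ")))
  }
  cat("\nDescriptor spot checks (computed from SMILES):\n")
  print(x$spot_checks, row.names = FALSE)
  cat("\nDescriptor table: ", x$descriptor_check$n_flagged,
      " unexplained flagged cells, ",
      sum(x$descriptor_check$cells$flag & x$descriptor_check$cells$known),
      " documented discrepancies\n", sep = "")
  cat("\nSoft comparisons (reported, not asserted):\n")
  soft <- x$models[!x$models$hard, ]
  print(soft[, c("model", "statistic", "refit", "printed", "abs_diff")],
        row.names = FALSE, digits = 3)
  cat("\nOverall hard-target result: ",
      if (x$hard_pass) "PASS" else "FAIL (see differences above)", "\n",
      sep = "")
  invisible(x)
}

#' Run the full modeling pipeline
#'
#' Executes descriptor assembly, GA subset selection, per-size model fits and
#' external validation on a configured dataset, writing all artifacts (CSV /
#' JSON) plus a manifest and log to `out_dir`.  Deterministic for a fixed
#' seed.
#'
#' @param config A named list (or path to a DCF key-value file) with entries:
#'   `dataset` (`"packaged"`, the default, or `"synthetic"`), `seed`
#'   (default 1), `max_vars` (default 4), `min_vars` (default 1), `fitness`
#'   (`"Q2"` or `"R2"`), `population`, `generations`, and for the packaged
#'   dataset `use_reference_descriptors` (default `TRUE`: model on the
#'   printed descriptor table; otherwise descriptors are recomputed from
#'   SMILES with DipoleZ taken from the reference table).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest (list of artifact paths).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    raw <- read.dcf(config)
    config <- setNames(as.list(raw[1, ]), colnames(raw))
    for (k in intersect(names(config),
                        c("seed", "max_vars", "min_vars", "population",
                          "generations")))
      config[[k]] <- as.integer(config[[k]])
    if (!is.null(config$use_reference_descriptors))
      config$use_reference_descriptors <-
        as.logical(config$use_reference_descriptors)
  }
  defaults <- list(dataset = "packaged", seed = 1L, max_vars = 4L,
                   min_vars = 1L, fitness = "Q2", population = 100L,
                   generations = 120L, use_reference_descriptors = TRUE)
  config <- utils::modifyList(defaults, config)
  if (config$max_vars < 1L) stop("config error: max_vars must be >= 1")
  if (!config$dataset %in% c("packaged", "synthetic"))
    stop("config error: dataset must be 'packaged' or 'synthetic'")

  if (config$dataset == "packaged") {
    solv <- solvent_data()
    mat <- if (isTRUE(config$use_reference_descriptors)) {
      reference_descriptors()
    } else {
      ref <- reference_descriptors()
      build_descriptor_matrix(solv,
                              supplied = list(DipoleZ = setNames(ref$DipoleZ,
                                                                 ref$id)))
    }
  } else {
    ds <- generate_study_dataset(seed = config$seed)
    solv <- ds$records
    mat <- ds$matrix
  }
  sp <- split_dataset(solv)
  tr <- match(sp$train$id, mat$id); te <- match(sp$test$id, mat$id)
  pool <- mat[tr, setdiff(names(mat), "id"), drop = FALSE]
  cfg <- ga_config(population = config$population,
                   generations = config$generations,
                   max_vars = config$max_vars, min_vars = config$min_vars,
                   fitness = config$fitness, seed = config$seed)
  sel <- ga_select(pool, sp$train$log_conc, cfg)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(out_dir, f)
  write.csv(as.data.frame(mat), art("descriptor_matrix.csv"),
            row.names = FALSE)
  cand <- lapply(Filter(Negate(is.null), sel), function(b)
    list(subset = b$subset, fitness = b$fitness))
  jsonlite::write_json(cand, art("candidates.json"), auto_unbox = TRUE,
                       digits = NA)
  models <- list(); valids <- list()
  for (nm in names(sel)) {
    b <- sel[[nm]]
    if (is.null(b)) next
    models[[nm]] <- list(subset = b$subset,
                         coefficients = as.list(b$model$coefficients),
                         stats = b$model$stats)
    v <- validation_report(b$model, mat[te, b$subset, drop = FALSE],
                           sp$test$log_conc,
                           train_mean = mean(sp$train$log_conc))
    valids[[nm]] <- unclass(v)
  }
  jsonlite::write_json(models, art("models.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(valids, art("validation.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(artifacts = c("descriptor_matrix.csv", "candidates.json",
                                 "models.json", "validation.json"),
                   config = config,
                   package_version = as.character(utils::packageVersion("cntdisp")))
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE)
  writeLines(c(sprintf("cntdisp %s", manifest$package_version),
               sprintf("dataset: %s", config$dataset),
               sprintf("seed: %d", config$seed),
               sprintf("fitness: %s", config$fitness),
               sprintf("ga: population %d, generations %d, vars %d..%d",
                       config$population, config$generations,
                       config$min_vars, config$max_vars),
               sprintf("collinearity guard |r| >= %.2f", cfg$collinearity_r)),
             art("log.txt"))
  invisible(manifest)
}
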