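#' External R2 on a held-out test set
#'
#' Default (`"pearson"`) is the squared Pearson correlation between observed
#' and predicted values, which is invariant to affine rescaling of the
#' predictions.  The `"predictive"` variant is
#' `1 - sum((y - yhat)^2) / sum((y - mean(y_train))^2)`, the predictive R2
#' about the training mean, which penalizes bias; both are shown side by side
#' in [validation_report()] because published external R2 values rarely state
#' their definition.
#'
#' @param model An [fit_ols()] model.
#' @param X_test,y_test Held-out descriptors and response (>= 3 rows,
#'   disjoint from training).
#' @param method `"pearson"` or `"predictive"`.
#' @param train_mean Training-set response mean, required for
#'   `"predictive"`.
#' @return A single number.
#' @export
external_r2 <- function(model, X_test, y_test,
                        method = c("pearson", "predictive"),
                        train_mean = NULL) {
  method <- match.arg(method)
  if (length(y_test) < 3L) stop("need at least 3 test observations")
  pred <- predict(model, X_test)
  if (sd(y_test) == 0 || sd(pred) == 0)
    stop("degenerate variance in test observations or predictions")
  if (method == "pearson") {
    cor(y_test, pred)^2
  } else {
    if (is.null(train_mean)) stop("predictive R2 needs train_mean")
    1 - sum((y_test - pred)^2) / sum((y_test - train_mean)^2)
  }
}

#' Roy's rm2 external-validation metrics
#'
#' For observed/predicted pairs, computes `rm2 = r2 * (1 - sqrt(r2 - r0^2))`
#' where `r2` is the squared Pearson correlation and `r0^2` measures how much
#' is lost when the regression is forced through the origin; the reverse
#' metric swaps the roles of observed and predicted.  Well-behaved models
#' have a high average and a small difference of the two.
#'
#' Two `r0^2` conventions are provided, since the literature uses both:
#' `"origin-residual"` (default) takes the through-origin residual form
#' `1 - sum((a - k b)^2) / sum((a - mean(a))^2)` with slope
#' `k = sum(ab)/sum(b^2)`; `"origin-correlation"` takes the squared cosine
#' `sum(ab)^2 / (sum(a^2) sum(b^2))`.  `r2 - r0^2` is clipped at 0 before the
#' square root.
#'
#' @param obs,pred Numeric vectors (>= 3 points, non-degenerate).
#' @param variant `"origin-residual"` or `"origin-correlation"`.
#' @return list with `rm2`, `rm2_reverse`, `average`, `delta`.
#' @export
rm2_metrics <- function(obs, pred,
                        variant = c("origin-residual", "origin-correlation")) {
  variant <- match.arg(variant)
  stopifnot(length(obs) == length(pred))
  if (length(obs) < 3L) stop("need at least 3 points")
  if (sd(obs) == 0 || sd(pred) == 0) stop("degenerate input")
  r2 <- cor(obs, pred)^2
  r0sq <- function(a, b) {  # through-origin fit of a on b
    switch(variant,
      "origin-residual" = {
        k <- sum(a * b) / sum(b * b)
        1 - sum((a - k * b)^2) / sum((a - mean(a))^2)
      },
      "origin-correlation" = sum(a * b)^2 / (sum(a * a) * sum(b * b)))
  }
  rm2 <- r2 * (1 - sqrt(max(0, r2 - r0sq(obs, pred))))
  rm2r <- r2 * (1 - sqrt(max(0, r2 - r0sq(pred, obs))))
  list(rm2 = rm2, rm2_reverse = rm2r,
       average = (rm2 + rm2r) / 2, delta = abs(rm2 - rm2r))
}

#' External validation report
#'
#' Evaluates a fitted model on a held-out test set: external R2 (both
#' definitions), Roy's rm2 metrics, and the conventional acceptance flags
#' (average rm2 above 0.5, delta rm2 below 0.2).
#'
#' @param model An [fit_ols()] model.
#' @param X_test,y_test Held-out data.
#' @param train_mean Training response mean (enables the predictive R2).
#' @param variant rm2 variant, see [rm2_metrics()].
#' @return list of class `"validation_report"`: `R2_test`,
#'   `R2_test_predictive` (NA without `train_mean`), `rm2`, `rm2_reverse`,
#'   `rm2_average`, `rm2_delta`, `pass_average`, `pass_delta`, `n_test`.
#' @export
validation_report <- function(model, X_test, y_test, train_mean = NULL,
                              variant = "origin-residual") {
  pred <- predict(model, X_test)
  m <- rm2_metrics(y_test, pred, variant = variant)
  structure(list(
    R2_test = external_r2(model, X_test, y_test, "pearson"),
    R2_test_predictive = if (is.null(train_mean)) NA_real_ else
      external_r2(model, X_test, y_test, "predictive", train_mean),
    rm2 = m$rm2, rm2_reverse = m$rm2_reverse,
    rm2_average = m$average, rm2_delta = m$delta,
    pass_average = m$average > 0.5, pass_delta = m$delta < 0.2,
    n_test = length(y_test)), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("External validation (n = %d)\n", x$n_test))
  cat(sprintf("  R2_test = %.3f (Pearson)", x$R2_test))
  if (!is.na(x$R2_test_predictive))
    cat(sprintf("  %.3f (predictive)", x$R2_test_predictive))
  cat("\n")
  cat(sprintf("  rm2 = %.3f  reverse = %.3f  average = %.3f  delta = %.3f\n",
              x$rm2, x$rm2_reverse, x$rm2_average, x$rm2_delta))
  chk <- acceptance_check(x)
  cat("  ", if (chk$pass) "PASS" else "FAIL", ": ",
      paste(chk$reasons, collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' Acceptance check on a validation report
#'
#' A model is acceptable when average rm2 exceeds 0.5 and delta rm2 is below
#' 0.2.
#'
#' @param report A [validation_report()].
#' @return list with `pass` (logical) and `reasons` (character).
#' @export
acceptance_check <- function(report) {
  reasons <- c(
    sprintf("average rm2 %.3f %s 0.5", report$rm2_average,
            if (report$pass_average) ">" else "<="),
    sprintf("delta rm2 %.3f %s 0.2", report$rm2_delta,
            if (report$pass_delta) "<" else ">="))
  list(pass = report$pass_average && report$pass_delta, reasons = reasons)
}
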