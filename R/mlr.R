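#' Ordinary least squares with the QSPR statistics suite
#'
#' Fits `y ~ X` by least squares (through [stats::lm()]) and reports the
#' statistics conventionally quoted for QSPR models: R2, residual standard
#' error `s = sqrt(RSS / (n - p - 1))`, the Fisher statistic `F` with its
#' p-value, and (by default) the leave-one-out statistics PRESS, Q2, SPRESS
#' and SDEP from [loo_crossvalidate()].  Coefficient uncertainty is reported
#' both as the standard error and as the 95% confidence halfwidth, since
#' published "(+/- ...)" halfwidths rarely state their convention.
#'
#' @param X data.frame or matrix of descriptor columns (the selected subset).
#' @param y Numeric response vector (log10 dispersibility in this package).
#' @param loo Also compute leave-one-out statistics (default `TRUE`).
#' @param sdep_df Degrees-of-freedom convention for SDEP, see
#'   [loo_crossvalidate()].
#' @return Object of class `"mlr_fit"`: `descriptor_names`, `coefficients`
#'   (intercept first), `se`, `halfwidth_ci95`, `n`, `p`, `stats` (list with
#'   `R2`, `s`, `F`, `p_value` and, when `loo`, `PRESS`, `Q2`, `SPRESS`,
#'   `SDEP`), and the underlying `lm` object.
#' @export
fit_ols <- function(X, y, loo = TRUE, sdep_df = c("n-1", "n", "n-p-1")) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y), ncol(X) >= 1L)
  p <- ncol(X)
  n <- length(y)
  if (n <= p + 1L) stop("need n > p + 1 observations (n = ", n, ", p = ", p, ")")
  zv <- vapply(X, function(col) var(col) == 0, logical(1))
  if (any(zv))
    stop("zero-variance column(s): ", paste(names(X)[zv], collapse = ", "))
  dat <- cbind(data.frame(.y = y), X)
  fit <- lm(.y ~ ., data = dat)
  if (fit$rank < p + 1L) {
    dropped <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  fstat <- unname(sm$fstatistic)
  stats <- list(R2 = sm$r.squared, s = sm$sigma, F = fstat[1],
                p_value = pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  if (loo) stats <- c(stats, loo_crossvalidate(X, y, sdep_df = sdep_df))
  structure(list(descriptor_names = names(X),
                 coefficients = coef(fit),
                 se = sm$coefficients[, "Std. Error"],
                 halfwidth_ci95 = sm$coefficients[, "Std. Error"] *
                   qt(0.975, n - p - 1L),
                 n = n, p = p, stats = stats, lm = fit),
            class = "mlr_fit")
}

#' @importFrom stats qt
#' @export
print.mlr_fit <- function(x, digits = 4, ...) {
  cat("MLR model: y ~ ", paste(x$descriptor_names, collapse = " + "),
      "  (n = ", x$n, ")\n", sep = "")
  cf <- data.frame(coef = round(x$coefficients, digits),
                   se = round(x$se, digits),
                   ci95_halfwidth = round(x$halfwidth_ci95, digits))
  print(cf)
  s <- x$stats
  cat(sprintf("R2 = %.3f  s = %.3f  F = %.3f  p = %.3g\n",
              s$R2, s$s, s$F, s$p_value))
  if (!is.null(s$Q2))
    cat(sprintf("Q2 = %.3f  PRESS = %.3f  SPRESS = %.3f  SDEP = %.3f\n",
                s$Q2, s$PRESS, s$SPRESS, s$SDEP))
  invisible(x)
}

#' Leave-one-out cross-validation statistics
#'
#' Computes the predictive error sum of squares `PRESS = sum((y_i -
#' yhat_(-i))^2)`, the cross-validated `Q2 = 1 - PRESS/TSS` (TSS about the
#' training mean), `SPRESS = sqrt(PRESS / (n - p - 1))` and SDEP.  The default
#' SDEP denominator is `n - 1`; this is the convention consistent with the
#' printed SPRESS/SDEP pair of the packaged single-descriptor reference model
#' (the more common `n` is available via `sdep_df = "n"`).
#'
#' The default `"hat"` method uses the closed form `e_i / (1 - h_ii)` for the
#' deleted residuals; `"refit"` refits the model n times and exists as the
#' independent oracle (both agree to numerical precision).
#'
#' @param X data.frame/matrix of predictors.
#' @param y Response vector.
#' @param method `"hat"` or `"refit"`.
#' @param sdep_df SDEP denominator convention.
#' @return list with `PRESS`, `Q2`, `SPRESS`, `SDEP`.
#' @export
loo_crossvalidate <- function(X, y, method = c("hat", "refit"),
                              sdep_df = c("n-1", "n", "n-p-1")) {
  method <- match.arg(method)
  sdep_df <- match.arg(sdep_df)
  X <- as.data.frame(X)
  n <- length(y); p <- ncol(X)
  if (n < p + 3L) stop("need n >= p + 3 for leave-one-out")
  Xm <- cbind(`(Intercept)` = 1, as.matrix(X))
  if (method == "hat") {
    qx <- qr(Xm)
    if (qx$rank < ncol(Xm)) stop("rank-deficient design in leave-one-out")
    res <- y - Xm %*% qr.coef(qx, y)
    h <- rowSums(qr.Q(qx)^2)
    if (any(h > 1 - 1e-10)) stop("leverage 1 observation: leave-one-out fit ",
                                 "is singular for index ", which.max(h))
    del <- res / (1 - h)
  } else {
    del <- vapply(seq_len(n), function(i) {
      qx <- qr(Xm[-i, , drop = FALSE])
      if (qx$rank < ncol(Xm))
        stop("singular leave-one-out fit when omitting index ", i)
      y[i] - drop(Xm[i, ] %*% qr.coef(qx, y[-i]))
    }, numeric(1))
  }
  press <- sum(del^2)
  tss <- sum((y - mean(y))^2)
  denom <- switch(sdep_df, "n-1" = n - 1L, "n" = n, "n-p-1" = n - p - 1L)
  list(PRESS = press, Q2 = 1 - press / tss,
       SPRESS = sqrt(press / (n - p - 1L)), SDEP = sqrt(press / denom))
}

#' Pearson correlation matrix of descriptor columns
#'
#' Symmetric matrix of pairwise Pearson correlations; zero-variance columns
#' produce `NA` entries and a warning rather than an error, so a degenerate
#' column is flagged without aborting a report.
#'
#' @param columns data.frame or matrix of numeric columns (an `id` column, if
#'   present, is dropped).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(columns) {
  df <- as.data.frame(columns)
  df <- df[setdiff(names(df), "id")]
  if (nrow(df) < 3L) stop("need at least 3 observations")
  zv <- vapply(df, function(v) var(v) == 0, logical(1))
  if (any(zv))
    warning("zero-variance column(s) flagged NA: ",
            paste(names(df)[zv], collapse = ", "))
  m <- suppressWarnings(cor(df))
  diag(m) <- 1
  m
}

#' Predict from a fitted MLR model
#'
#' @param object An `mlr_fit`.
#' @param newdata data.frame containing the model's descriptor columns.
#' @param ... Unused.
#' @return Numeric vector `intercept + sum(coef * x)`.
#' @export
predict.mlr_fit <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$descriptor_names, names(newdata))
  if (length(missing))
    stop("newdata lacks column(s): ", paste(missing, collapse = ", "))
  Xm <- as.matrix(newdata[object$descriptor_names])
  drop(object$coefficients[1L] + Xm %*% object$coefficients[-1L])
}
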