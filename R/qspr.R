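## Two-descriptor multiple linear regression with the validation statistics
## customary in QSPR work: multiple correlation coefficient R (reported in
## square-root form, as is its cross-validated analogue), adjusted R,
## standard error of estimate, Fisher F, PRESS and leave-one-out
## cross-validation via the hat-matrix shortcut e_(-i) = e_i / (1 - h_ii).

#' Fit a multiple linear regression QSPR model
#'
#' Ordinary least squares of `property ~ descriptors` on a property table.
#' Rows with a missing response or descriptor are dropped (and counted).
#'
#' @param table Data frame holding descriptor and property columns.
#' @param property Name of the response column.
#' @param descriptors Character vector of descriptor column names
#'   (default `c("xp1", "xp2")`).
#' @return Object of class `qspr_model`: coefficients with standard errors,
#'   `n`, `r`, `r_adj`, `s_err`, `f_stat`, `press`, `q2`, `r_cv`, `are`
#'   (guarded average relative error of the fitted values, percent), plus the
#'   underlying `lm` fit.
#' @export
#' @examples
#' tab <- data.frame(xp1 = 1:10, xp2 = (1:10)^1.5)
#' tab$y <- 2 + 3 * tab$xp1 + 4 * tab$xp2
#' fit_mlr(tab, "y")
fit_mlr <- function(table, property, descriptors = c("xp1", "xp2")) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(c(property, descriptors), names(table))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  dat <- table[, c(property, descriptors), drop = FALSE]
  keep <- stats::complete.cases(dat)
  dat <- dat[keep, , drop = FALSE]
  n <- nrow(dat)
  p <- length(descriptors)
  if (n < p + 2)
    stop("need at least ", p + 2, " complete rows, have ", n)
  form <- stats::as.formula(paste(property, "~",
                                  paste(descriptors, collapse = " + ")))
  fit <- stats::lm(form, data = dat)
  if (fit$rank < p + 1) {
    alias <- colnames(stats::model.matrix(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(alias, collapse = ", "))
  }
  y <- dat[[property]]
  res <- stats::residuals(fit)
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  ssr <- sst - sse
  r2 <- 1 - sse / sst
  r <- sqrt(max(0, r2))
  r_adj <- sqrt(max(0, 1 - (1 - r2) * (n - 1) / (n - p - 1)))
  s_err <- sqrt(sse / (n - p - 1))
  f_stat <- (ssr / p) / (sse / (n - p - 1))
  h <- stats::hatvalues(fit)
  press <- press_statistic(fit, y, res, h)
  q2 <- 1 - press / sst
  are <- average_relative_error(y, stats::fitted(fit))
  structure(list(
    property = property, descriptors = descriptors,
    coefficients = stats::coef(fit),
    std_errors = summary(fit)$coefficients[, "Std. Error"],
    n = n, n_dropped = sum(!keep),
    r = r, r_adj = r_adj, s_err = s_err, f_stat = f_stat,
    press = press, q2 = q2, r_cv = sqrt(max(0, q2)),
    are = are$are,
    fit = fit
  ), class = "qspr_model")
}

## PRESS via the hat-matrix identity, falling back to an explicit refit for
## any row with leverage numerically equal to 1.
press_statistic <- function(fit, y, res, h) {
  loo <- press_residuals(fit, y, res, h)
  sum(loo^2)
}

press_residuals <- function(fit, y, res, h) {
  loo <- res / (1 - h)
  ones <- which(1 - h < 1e-10)
  if (length(ones)) {
    mm <- stats::model.matrix(fit)
    for (i in ones) {
      coef_i <- stats::lm.fit(mm[-i, , drop = FALSE], y[-i])$coefficients
      coef_i[is.na(coef_i)] <- 0
      loo[i] <- y[i] - sum(mm[i, ] * coef_i)
    }
  }
  loo
}

#' @export
print.qspr_model <- function(x, ...) {
  cat(sprintf("<qspr_model> %s ~ %s\n", x$property,
              paste(x$descriptors, collapse = " + ")))
  co <- x$coefficients; se <- x$std_errors
  for (k in seq_along(co))
    cat(sprintf("  %-12s %12.6g  (+/- %.6g)\n", names(co)[k], co[k], se[k]))
  cat(sprintf("  n = %d; R = %.4f; R_adj = %.4f; S = %.4f; F = %.4f\n",
              x$n, x$r, x$r_adj, x$s_err, x$f_stat))
  cat(sprintf("  PRESS = %.4f; r_cv = %.4f; ARE = %.2f%%\n",
              x$press, x$r_cv, x$are))
  invisible(x)
}

#' Predict properties from a fitted QSPR model
#'
#' @param object A `qspr_model`.
#' @param newdata Data frame with the model's descriptor columns, or a
#'   numeric vector/matrix of descriptor values in model order.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.qspr_model <- function(object, newdata, ...) {
  if (is.numeric(newdata)) {
    m <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
    if (ncol(m) != length(object$descriptors))
      stop("expected ", length(object$descriptors), " descriptor values")
    newdata <- as.data.frame(m)
    names(newdata) <- object$descriptors
  }
  missing_cols <- setdiff(object$descriptors, names(newdata))
  if (length(missing_cols))
    stop("missing descriptor column(s): ", paste(missing_cols, collapse = ", "))
  unname(stats::predict(object$fit, newdata = newdata))
}

#' Leave-one-out cross-validation of a QSPR model
#'
#' Each compound is removed in turn, the model refitted on the remainder and
#' the removed compound predicted.  Out-of-sample residuals come from the
#' hat-matrix identity `e_(-i) = e_i / (1 - h_ii)` (with an explicit refit
#' fallback when a leverage equals 1).  Reports `Ss` (RMS of
#' observed-vs-LOO-predicted differences), `Ds` (RMS of observed deviations
#' from the mean), `PRESS`, `q2 = 1 - PRESS/SST` and the cross-validated
#' correlation coefficient in square-root form `r_cv = sqrt(max(0, q2))`.
#'
#' @inheritParams fit_mlr
#' @return Object of class `qspr_cv` with fields `y_obs`, `y_pre`, `ss`,
#'   `ds`, `press`, `q2`, `r_cv`, `n`.
#' @export
loo_cv <- function(table, property, descriptors = c("xp1", "xp2")) {
  model <- fit_mlr(table, property, descriptors)
  fit <- model$fit
  y <- stats::model.response(stats::model.frame(fit))
  res <- stats::residuals(fit)
  h <- stats::hatvalues(fit)
  n <- length(y)
  if (n < length(descriptors) + 3)
    stop("need at least ", length(descriptors) + 3, " rows for LOO")
  loo_res <- press_residuals(fit, y, res, h)
  y_pre <- y - loo_res
  press <- sum(loo_res^2)
  sst <- sum((y - mean(y))^2)
  q2 <- 1 - press / sst
  structure(list(
    property = property, descriptors = descriptors,
    y_obs = as.numeric(y), y_pre = as.numeric(y_pre),
    ss = sqrt(sum((y - y_pre)^2) / (n - 1)),
    ds = sqrt(sst / (n - 1)),
    press = press, q2 = q2, r_cv = sqrt(max(0, q2)), n = n
  ), class = "qspr_cv")
}

#' @export
print.qspr_cv <- function(x, ...) {
  cat(sprintf("<qspr_cv> %s: n = %d; PRESS = %.4f; q2 = %.4f; r_cv = %.4f\n",
              x$property, x$n, x$press, x$q2, x$r_cv))
  cat(sprintf("  Ss = %.4f; Ds = %.4f\n", x$ss, x$ds))
  invisible(x)
}

#' Guarded average relative error
#'
#' `100/m * sum(|pre - obs| / |obs|)` over the rows whose reference value has
#' magnitude at least `eps`; rows below the guard are excluded and counted.
#'
#' @param y_cal Reference values.
#' @param y_pre Predicted values.
#' @param eps Exclusion threshold on `|y_cal|` (default 1e-6).
#' @return List with `are` (percent), `n_used`, `n_excluded`.
#' @export
#' @examples
#' average_relative_error(c(100, 0), c(101, 5))  # 1% over 1 used row
average_relative_error <- function(y_cal, y_pre, eps = 1e-6) {
  if (length(y_cal) != length(y_pre))
    stop("y_cal and y_pre must have equal length")
  use <- abs(y_cal) >= eps & !is.na(y_cal) & !is.na(y_pre)
  if (!any(use)) stop("all rows excluded by the |y_cal| >= eps guard")
  list(are = 100 * mean(abs(y_pre[use] - y_cal[use]) / abs(y_cal[use])),
       n_used = sum(use), n_excluded = sum(!use))
}

#' Relative property within isomer groups
#'
#' Within each group (same substituent count) the property is re-expressed
#' relative to the group's most stable member: `y_rel = y - min(y)`.  Groups
#' of size one get `NA` (a relative value is meaningless there).
#'
#' @param table Data frame.
#' @param property Property column name.
#' @param group Grouping column name (e.g. bromine count).
#' @return The table with an added column `<property>_rel`.
#' @export
relative_property <- function(table, property, group) {
  stopifnot(is.data.frame(table))
  if (!all(c(property, group) %in% names(table)))
    stop("missing column(s)")
  y <- table[[property]]
  g <- table[[group]]
  rel <- rep(NA_real_, length(y))
  for (gv in unique(g)) {
    idx <- which(g == gv & !is.na(y))
    if (length(idx) > 1) rel[idx] <- y[idx] - min(y[idx])
  }
  table[[paste0(property, "_rel")]] <- rel
  table
}
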