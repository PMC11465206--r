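#' Accuracy metrics between predictions and a reference
#'
#' Computes the four standard volumetric accuracy measures: root mean
#' squared error `RMSE`, mean absolute error `MAE`, peak signal-to-noise
#' ratio `PSNR = 20 log10(max_ref / RMSE)` (reported as `Inf` when
#' `RMSE = 0`), and mean relative absolute error
#' `MRAE = mean |error / reference|` (reference zeros are skipped and
#' counted).
#'
#' @param predicted,reference equal-length numeric vectors.  Pairs with a
#'   missing value (e.g. out-of-domain predictions) are dropped and counted.
#' @param max_ref peak reference value for the PSNR (default
#'   `max(abs(reference))`).
#' @return list `rmse`, `mae`, `psnr`, `mrae`, `n`, `n_zero_skipped`,
#'   `n_na_skipped`.
#' @export
accuracy_metrics <- function(predicted, reference, max_ref = NULL) {
  if (length(predicted) != length(reference)) stop("length mismatch")
  if (!length(predicted)) stop("empty input")
  ok <- !is.na(predicted) & !is.na(reference)
  n_na <- sum(!ok)
  predicted <- predicted[ok]; reference <- reference[ok]
  if (!length(predicted)) stop("no complete prediction/reference pairs")
  if (is.null(max_ref)) max_ref <- max(abs(reference))
  err <- predicted - reference
  rmse <- sqrt(mean(err^2))
  nz <- reference != 0
  list(rmse = rmse,
       mae = mean(abs(err)),
       psnr = if (rmse > 0) 20 * log10(max_ref / rmse) else Inf,
       mrae = mean(abs(err[nz] / reference[nz])),
       n = length(err), n_zero_skipped = sum(!nz), n_na_skipped = n_na)
}

#' Out-of-sample mean integrated squared error
#'
#' Approximates the MISE of a fit against the true function by the mean
#' squared difference over an independent in-domain evaluation grid.
#'
#' @param fit a [tpst()] fit.
#' @param truth function of an n x 3 matrix returning true values.
#' @param grid n x 3 matrix of in-domain evaluation points (independent of
#'   the training data).
#' @return scalar MISE estimate (out-of-domain grid points are excluded).
#' @export
mise <- function(fit, truth, grid) {
  if (is.null(dim(grid))) grid <- matrix(grid, ncol = 3L)
  if (!nrow(grid)) stop("empty evaluation grid")
  pred <- predict(fit, grid)
  ok <- !is.na(pred)
  if (!any(ok)) stop("no evaluation point falls inside the fitted domain")
  mean((pred[ok] - truth(grid[ok, , drop = FALSE]))^2)
}
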