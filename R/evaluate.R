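# Evaluation metrics: MSE of transformed dispersions, ROC points over a fixed
# significance grid with left-continuous step interpolation, partial AUC, and
# the benchmark driver that crosses settings x estimators x tests.

#' Default significance grid
#'
#' 400 log-spaced significance levels in [1e-6, 1], fixed so every ROC curve
#' in a study shares the same grid.
#'
#' @return Increasing numeric vector of length 400.
#' @export
default_alpha_grid <- function() exp(seq(log(1e-6), log(1), length.out = 400))

#' MSE of transformed dispersions
#'
#' Mean squared error after the bounded transform \code{t(phi) = phi/(1+phi)},
#' which maps dispersions to (0, 1) and makes the MSE robust to outlying
#' estimates. The result is always in [0, 1].
#'
#' @param phi_hat Estimated dispersions.
#' @param phi_true True dispersions, same length.
#' @return Scalar mean squared error of the transformed values.
#' @export
transformed_mse <- function(phi_hat, phi_true) {
  if (length(phi_hat) != length(phi_true))
    stop("'phi_hat' and 'phi_true' must have equal length")
  if (any(phi_hat < 0) || any(phi_true < 0))
    stop("dispersions must be non-negative")
  t1 <- phi_hat / (1 + phi_hat)
  t0 <- phi_true / (1 + phi_true)
  mean((t1 - t0)^2)
}

#' ROC points over a significance grid
#'
#' At each significance level alpha, \code{FP} is the number of EE genes and
#' \code{TP} the number of DE genes with p-value strictly below alpha;
#' \code{FPR = FP/EE} and \code{TPR = TP/DE}.
#'
#' @param p_values Per-gene p-values.
#' @param is_de Logical truth flags.
#' @param alpha_grid Increasing significance levels in (0, 1].
#' @param fpr_cutoff Partial-AUC cutoff on FPR.
#' @return A \code{roc_result}: \code{alphas}, \code{fpr}, \code{tpr},
#'   \code{pauc}, \code{fpr_cutoff}.
#' @export
roc_points <- function(p_values, is_de, alpha_grid = default_alpha_grid(),
                       fpr_cutoff = 0.1) {
  is_de <- as.logical(is_de)
  if (!any(is_de) || all(is_de))
    stop("need both EE and DE genes to build a ROC curve")
  if (any(p_values < 0 | p_values > 1 | is.na(p_values)))
    stop("p-values must be in [0, 1] with no missing values")
  n_de <- sum(is_de); n_ee <- sum(!is_de)
  p_de <- sort(p_values[is_de]); p_ee <- sort(p_values[!is_de])
  tp <- vapply(alpha_grid, function(a) sum(p_de < a), numeric(1))
  fp <- vapply(alpha_grid, function(a) sum(p_ee < a), numeric(1))
  out <- structure(list(alphas = alpha_grid, fpr = fp / n_ee, tpr = tp / n_de,
                        pauc = NA_real_, fpr_cutoff = fpr_cutoff),
                   class = "roc_result")
  out$pauc <- partial_auc(out)
  out
}

#' Partial AUC of a step-interpolated ROC curve
#'
#' Area under the left-continuous step function through the ROC points (each
#' interval contributes its width times the TPR at its left endpoint),
#' restricted to FPR at most \code{fpr_cutoff}. The curve starts at (0, 0)
#' and the last reached TPR extends to the cutoff, so a perfect classifier
#' attains exactly \code{fpr_cutoff}. The step area never exceeds the
#' trapezoidal area on the same points.
#'
#' @param roc A \code{roc_result}.
#' @return Scalar partial AUC in [0, \code{fpr_cutoff}].
#' @export
partial_auc <- function(roc) {
  cut <- roc$fpr_cutoff
  # collapse to unique FPR values with the highest TPR attained at each
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; y <- roc$tpr[o]
  keep <- !duplicated(x, fromLast = TRUE)
  x <- c(0, x[keep]); y <- c(0, y[keep])
  area <- 0
  for (i in seq_along(x)) {
    if (x[i] >= cut) break
    xr <- if (i < length(x)) min(x[i + 1], cut) else cut
    area <- area + (xr - x[i]) * y[i]
  }
  area
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC over", length(x$alphas), "significance levels; pAUC(FPR <=",
      paste0(x$fpr_cutoff, ")"), "=", signif(x$pauc, 4), "\n")
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s", xlab = "FPR", ylab = "TPR",
                 xlim = c(0, x$fpr_cutoff), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Run the simulation benchmark
#'
#' For each setting and replicate: generate a pseudo-dataset; for each
#' estimator record the transformed-dispersion MSE against the truth; for
#' each (estimator, test) combination record the partial AUC; and, as the
#' gold standard, run every test with the true simulated dispersions.
#'
#' @param settings Named list of \code{simulation_config} objects.
#' @param estimators Character vector of estimator names
#'   (see \code{\link{dispersion_methods}}).
#' @param tests Character vector of test names (see \code{\link{run_de_test}}).
#' @param n_reps Replicates per setting.
#' @param seed Master seed; replicate r of setting s uses a seed derived from
#'   it deterministically.
#' @param fpr_cutoff Partial-AUC cutoff.
#' @param include_truth Also evaluate every test at the true dispersions
#'   (estimator label \code{"true"}).
#' @return Long-format data frame with columns \code{setting, replicate,
#'   estimator, test, mse, pauc, error}; MSE rows have \code{test = NA},
#'   pAUC rows have \code{mse = NA}. Failures are recorded per row and the
#'   run continues.
#' @export
run_benchmark <- function(settings, estimators, tests, n_reps = 5L, seed = 1L,
                          fpr_cutoff = 0.1, include_truth = TRUE) {
  stopifnot(length(settings) > 0, length(estimators) > 0)
  if (is.null(names(settings)))
    names(settings) <- paste0("setting", seq_along(settings))
  rows <- list()
  add <- function(setting, rep, estimator, test, mse, pauc, error = NA_character_)
    rows[[length(rows) + 1L]] <<- data.frame(
      setting = setting, replicate = rep, estimator = estimator, test = test,
      mse = mse, pauc = pauc, error = error, stringsAsFactors = FALSE)
  for (s in names(settings)) {
    for (r in seq_len(n_reps)) {
      cfg <- settings[[s]]
      cfg$seed <- derive_seed(seed, 7919L * match(s, names(settings)) + r)
      sim <- generate_pseudo_dataset(cfg)
      fits <- list()
      for (est in estimators) {
        fit <- tryCatch(estimate_dispersions(sim$counts, sim$groups, est),
                        error = function(e) e)
        if (inherits(fit, "error")) {
          add(s, r, est, NA_character_, NA_real_, NA_real_,
              conditionMessage(fit))
          next
        }
        fits[[est]] <- fit
        add(s, r, est, NA_character_,
            transformed_mse(fit$phi, sim$truth$phi), NA_real_)
      }
      if (include_truth)
        fits[["true"]] <- new_dispersion_fit(sim$truth$phi, "true", "truth",
                                             gene_ids = rownames(sim$counts))
      for (est in names(fits)) {
        for (te in tests) {
          res <- tryCatch({
            tr <- run_de_test(sim$counts, sim$groups, fits[[est]], te)
            roc_points(tr$p_values, sim$truth$is_de,
                       fpr_cutoff = fpr_cutoff)$pauc
          }, error = function(e) e)
          if (inherits(res, "error"))
            add(s, r, est, te, NA_real_, NA_real_, conditionMessage(res))
          else add(s, r, est, te, NA_real_, res)
        }
      }
    }
  }
  do.call(rbind, rows)
}
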