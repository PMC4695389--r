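# Dose-response layer: four-parameter logistic (Hill) fits.
#
# Reporter-assay responses are modelled as
#   response(c) = bottom + (top - bottom) / (1 + (ec50 / c)^hill)
# with concentrations in molar. fit_dose_response() is the package's
# model-fitting entry point and returns a classed object with the usual
# print/summary/coef/predict/plot/residuals/simulate methods.

#' Four-parameter logistic response
#'
#' @param concentration positive molar concentration(s).
#' @param bottom,top response asymptotes (response units).
#' @param ec50 half-maximal concentration (molar).
#' @param hill Hill slope (dimensionless, > 0 for activating curves).
#' @return Predicted response(s). At `concentration == ec50` the response
#'   is `(top + bottom) / 2`.
#' @examples
#' hill_response(1e-5, bottom = 0, top = 1, ec50 = 1e-5, hill = 1)
#' @export
hill_response <- function(concentration, bottom, top, ec50, hill = 1) {
  if (inherits(bottom, "hill_fit")) {
    p <- coef(bottom)
    top <- p[["top"]]; ec50 <- p[["ec50"]]; hill <- p[["hill"]]
    bottom <- p[["bottom"]]
  }
  if (any(concentration <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  bottom + (top - bottom) / (1 + (ec50 / concentration)^hill)
}

#' Construct a dose-response curve
#'
#' @param receptor,ligand identifiers.
#' @param concentration molar concentrations (positive), one per
#'   measurement.
#' @param response measured responses (arbitrary units).
#' @param replicate optional replicate index per measurement.
#' @param control optional data frame of no-receptor control measurements
#'   with columns `concentration`, `response`.
#' @return An object of class `dose_response_curve`: a data frame of
#'   measurements sorted by concentration, with attributes `receptor`,
#'   `ligand`, `control`.
#' @export
dose_response_curve <- function(receptor, ligand, concentration, response,
                                replicate = NULL, control = NULL) {
  stopifnot(length(concentration) == length(response))
  if (any(concentration <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (is.null(replicate)) {
    replicate <- stats::ave(concentration, concentration,
                            FUN = seq_along)
  }
  d <- data.frame(concentration = concentration, response = response,
                  replicate = replicate)
  d <- d[order(d$concentration, d$replicate), , drop = FALSE]
  rownames(d) <- NULL
  structure(d, class = c("dose_response_curve", "data.frame"),
            receptor = receptor, ligand = ligand, control = control)
}

#' Normalize responses against no-receptor controls
#'
#' Expresses each measurement as fold over the mean control response at
#' the same concentration. Control variability is propagated to a
#' per-point standard error (delta method on the ratio of the measurement
#' to the control mean). Concentrations without a control measurement are
#' dropped with a warning.
#'
#' @param curve a [dose_response_curve()] whose `control` attribute is set.
#' @return A normalized `dose_response_curve` (responses are fold-over-
#'   control; extra column `se` holds the propagated uncertainty;
#'   attribute `normalized` is `TRUE`).
#' @export
normalize_responses <- function(curve) {
  stopifnot(inherits(curve, "dose_response_curve"))
  ctrl <- attr(curve, "control")
  if (is.null(ctrl) || !nrow(ctrl)) {
    stop("no control responses attached to the curve", call. = FALSE)
  }
  agg <- stats::aggregate(response ~ concentration, data = ctrl,
                          FUN = function(v) c(m = mean(v),
                                              s = stats::sd(v),
                                              n = length(v)))
  cm <- agg$response[, "m"]
  cs <- agg$response[, "s"]
  cn <- agg$response[, "n"]
  names(cm) <- names(cs) <- names(cn) <- as.character(agg$concentration)
  if (any(cm <= 0)) {
    stop("non-positive control mean; cannot normalize", call. = FALSE)
  }
  key <- as.character(curve$concentration)
  have <- key %in% names(cm)
  if (any(!have)) {
    warning(sum(!have), " point(s) without matching control dropped",
            call. = FALSE)
  }
  d <- curve[have, , drop = FALSE]
  key <- key[have]
  mu <- cm[key]
  fold <- d$response / mu
  # delta method: var(r / mu_c) ~= r^2 * var(mean control) / mu_c^4
  se_ctrl <- ifelse(is.na(cs[key]), 0, cs[key] / sqrt(cn[key]))
  d$se <- abs(d$response) * se_ctrl / mu^2
  d$response <- fold
  out <- structure(d, class = c("dose_response_curve", "data.frame"),
                   receptor = attr(curve, "receptor"),
                   ligand = attr(curve, "ligand"),
                   control = attr(curve, "control"), normalized = TRUE)
  rownames(out) <- NULL
  out
}

# deterministic initialization: asymptotes from the concentration-averaged
# response extremes; ec50 by log-linear interpolation at the half-range
.hill_init <- function(conc, resp) {
  avg <- tapply(resp, conc, mean)
  cc <- as.numeric(names(avg))
  o <- order(cc)
  cc <- cc[o]; avg <- as.numeric(avg)[o]
  bottom0 <- min(avg); top0 <- max(avg)
  half <- (bottom0 + top0) / 2
  lec50 <- mean(log10(range(cc)))
  if (top0 > bottom0) {
    cross <- which(avg[-length(avg)] < half & avg[-1] >= half)
    if (length(cross)) {
      k <- cross[1]
      f <- (half - avg[k]) / (avg[k + 1] - avg[k])
      lec50 <- log10(cc[k]) + f * (log10(cc[k + 1]) - log10(cc[k]))
    }
  }
  c(bottom = bottom0, top = top0, lec50 = lec50)
}

#' Fit a four-parameter logistic dose-response model
#'
#' Least-squares fit of the 4PL model by Levenberg-Marquardt, with a fixed
#' deterministic initialization rule (asymptotes from the concentration-
#' averaged response extremes, EC50 from log-linear interpolation at the
#' half-range crossing, Hill slope 1). The Hill slope is bounded in
#' (0, 10] and may be fixed to 1. Non-converged fits are flagged, never
#' silently returned; fits whose EC50 falls outside
#' `[min(conc)/100, max(conc)*100]` are flagged `extrapolated`; near-flat
#' data (fitted dynamic range below twice the residual scatter, or an
#' inverted fit) is flagged `degenerate`.
#'
#' @param curve a [dose_response_curve()] with at least 4 distinct
#'   concentrations.
#' @param fix_hill if `TRUE`, fixes the Hill slope at 1.
#' @param max_hill upper bound for the Hill slope.
#' @return An object of class `hill_fit` with coefficients `bottom`,
#'   `top`, `ec50` (molar), `hill`; standard errors on the log10-EC50
#'   scale; 95% Wald confidence interval for EC50; `flags` list
#'   (`converged`, `degenerate`, `extrapolated`); residual summary.
#' @export
fit_dose_response <- function(curve, fix_hill = FALSE, max_hill = 10) {
  stopifnot(inherits(curve, "dose_response_curve"))
  conc <- curve$concentration
  resp <- curve$response
  if (length(unique(conc)) < 4L) {
    stop("need at least 4 distinct concentrations to fit", call. = FALSE)
  }
  ini <- .hill_init(conc, resp)
  lc <- log10(conc)
  fit_fun <- function(bottom, top, lec50, hill) {
    bottom + (top - bottom) / (1 + 10^(hill * (lec50 - lc)))
  }
  span <- max(resp) - min(resp)
  start <- c(as.list(ini), list(hill = 1))
  lower <- c(bottom = min(resp) - 2 * span - 1e-9,
             top = min(resp) - 2 * span - 1e-9,
             lec50 = log10(min(conc)) - 6, hill = 1e-3)
  upper <- c(bottom = max(resp) + 2 * span + 1e-9,
             top = max(resp) + 2 * span + 1e-9,
             lec50 = log10(max(conc)) + 6, hill = max_hill)
  if (fix_hill) {
    start$hill <- NULL
    lower <- lower[names(lower) != "hill"]
    upper <- upper[names(upper) != "hill"]
    form <- resp ~ fit_fun(bottom, top, lec50, 1)
  } else {
    form <- resp ~ fit_fun(bottom, top, lec50, hill)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, start = start,
                      lower = unname(lower[names(start)]),
                      upper = unname(upper[names(start)]),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  converged <- !is.null(fit) && fit$convInfo$isConv
  if (is.null(fit)) {
    cf <- c(ini, hill = 1)
    est <- c(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
             lec50 = unname(cf["lec50"]), hill = 1)
    se <- c(bottom = NA_real_, top = NA_real_, lec50 = NA_real_,
            hill = NA_real_)
    sigma <- NA_real_
    vc <- NULL
  } else {
    cf <- stats::coef(fit)
    est <- c(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
             lec50 = unname(cf["lec50"]),
             hill = if (fix_hill) 1 else unname(cf["hill"]))
    vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
    se <- c(bottom = NA_real_, top = NA_real_, lec50 = NA_real_,
            hill = if (fix_hill) 0 else NA_real_)
    if (!is.null(vc)) {
      se[colnames(vc)] <- sqrt(pmax(diag(vc), 0))
    }
    sigma <- stats::sigma(fit)
  }
  ec50 <- 10^est[["lec50"]]
  fitted_vals <- hill_response(conc, est[["bottom"]], est[["top"]],
                               ec50, est[["hill"]])
  res <- resp - fitted_vals
  dyn <- est[["top"]] - est[["bottom"]]
  degenerate <- !converged && is.null(fit) ||
    dyn <= 0 || (is.finite(sigma) && dyn < 2 * sigma)
  extrapolated <- ec50 < min(conc) / 100 || ec50 > max(conc) * 100
  ci <- if (!is.na(se[["lec50"]])) {
    10^(est[["lec50"]] + c(-1, 1) * 1.96 * se[["lec50"]])
  } else c(NA_real_, NA_real_)
  structure(list(
    coefficients = c(bottom = est[["bottom"]], top = est[["top"]],
                     ec50 = ec50, hill = est[["hill"]]),
    log10_ec50 = est[["lec50"]],
    se = se, vcov = vc, sigma = sigma,
    ec50_ci = stats::setNames(ci, c("lower", "upper")),
    fitted.values = fitted_vals, residuals = res,
    flags = list(converged = converged, degenerate = degenerate,
                 extrapolated = extrapolated),
    data = curve, fix_hill = fix_hill,
    receptor = attr(curve, "receptor"), ligand = attr(curve, "ligand")
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("4PL dose-response fit: %s / %s\n",
              x$receptor %||% "?", x$ligand %||% "?"))
  cat(sprintf("  EC50 = %.4g M (95%% CI %.3g-%.3g), hill = %.3g\n",
              x$coefficients[["ec50"]], x$ec50_ci[["lower"]],
              x$ec50_ci[["upper"]], x$coefficients[["hill"]]))
  cat(sprintf("  bottom = %.4g, top = %.4g, residual sd = %.3g\n",
              x$coefficients[["bottom"]], x$coefficients[["top"]], x$sigma))
  fl <- x$flags
  bad <- c("not_converged", "degenerate",
           "extrapolated")[c(!fl$converged, fl$degenerate, fl$extrapolated)]
  if (length(bad)) cat("  flags:", paste(bad, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
summary.hill_fit <- function(object, ...) {
  out <- data.frame(
    estimate = object$coefficients,
    row.names = names(object$coefficients)
  )
  out$se <- c(object$se[["bottom"]], object$se[["top"]],
              log(10) * object$coefficients[["ec50"]] * object$se[["lec50"]],
              object$se[["hill"]])
  cat("Four-parameter logistic fit\n")
  print(out)
  cat(sprintf("log10 EC50 = %.4f (se %.4f)\n", object$log10_ec50,
              object$se[["lec50"]]))
  invisible(out)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$concentration else
    if (is.data.frame(newdata)) newdata$concentration else newdata
  p <- object$coefficients
  hill_response(conc, p[["bottom"]], p[["top"]], p[["ec50"]], p[["hill"]])
}

#' @export
residuals.hill_fit <- function(object, ...) object$residuals

#' @export
simulate.hill_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  s <- if (is.finite(object$sigma)) object$sigma else 0
  out <- replicate(nsim, mu + stats::rnorm(length(mu), 0, s),
                   simplify = FALSE)
  as.data.frame(stats::setNames(out, paste0("sim_", seq_len(nsim))))
}

#' @export
plot.hill_fit <- function(x, n_grid = 200, ...) {
  d <- x$data
  grid <- 10^seq(log10(min(d$concentration)), log10(max(d$concentration)),
                 length.out = n_grid)
  plot(d$concentration, d$response, log = "x",
       xlab = "concentration (M)", ylab = "response",
       main = sprintf("%s / %s", x$receptor %||% "?", x$ligand %||% "?"),
       ...)
  graphics::lines(grid, predict(x, grid), col = "firebrick", lwd = 2)
  graphics::abline(v = x$coefficients[["ec50"]], lty = 2, col = "grey40")
  invisible(x)
}

#' Relative potency of two fits
#'
#' @param fit_a,fit_b converged `hill_fit` objects.
#' @return Fold ratio `ec50_a / ec50_b` with a propagated 95% interval
#'   (attribute `ci`); attribute `flagged` is `TRUE` when either fit was
#'   flagged extrapolated.
#' @export
relative_potency <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "hill_fit"), inherits(fit_b, "hill_fit"))
  if (!fit_a$flags$converged || !fit_b$flags$converged) {
    stop("both fits must have converged", call. = FALSE)
  }
  lr <- fit_a$log10_ec50 - fit_b$log10_ec50
  se <- sqrt(sum(c(fit_a$se[["lec50"]], fit_b$se[["lec50"]])^2,
                 na.rm = TRUE))
  ratio <- 10^lr
  attr(ratio, "ci") <- 10^(lr + c(-1.96, 1.96) * se)
  attr(ratio, "flagged") <- fit_a$flags$extrapolated ||
    fit_b$flags$extrapolated
  ratio
}
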