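## Dose-response pharmacology: control-anchored normalization and
## variable-slope four-parameter logistic (4PL) fits on log10
## concentration, the standard model for this assay class.

#' Evaluate the four-parameter logistic
#'
#' \code{y = bottom + (top - bottom) / (1 + 10^(hill * (log10(ec50) -
#' log10(x))))}. At \code{x = ec50} the value is \code{(bottom + top) / 2}
#' for any hill slope.
#'
#' @param x concentrations (molar, > 0).
#' @param params named numeric or \linkS4class{FourPLFit}:
#'   \code{bottom}, \code{top}, \code{ec50}, \code{hill}.
#' @return response values.
#' @export
fourPL <- function(x, params) {
  if (is(params, "FourPLFit")) params <- params@coefficients
  b <- params[["bottom"]]; t <- params[["top"]]
  e <- params[["ec50"]]; h <- params[["hill"]]
  b + (t - b) / (1 + 10^(h * (log10(e) - log10(x))))
}

#' Normalize raw signals to the reference-ligand window
#'
#' Subtractive (default): \code{100 * (x - mean(neg)) / (mean(pos) -
#' mean(neg))}, anchoring the negative controls at 0\% and the reference
#' ligand at 100\%. \code{method = "ratio"} reports the plain percentage of
#' the positive-control mean instead.
#'
#' @param drc data.frame with columns \code{compound_id},
#'   \code{conc_molar}, \code{replicate}, \code{value}, \code{role}
#'   (\code{role} containing at least one \code{pos} and one \code{neg}
#'   row).
#' @param method \code{"subtractive"} or \code{"ratio"}.
#' @return the table with \code{value} replaced by the percent response
#'   (control rows included, normalized on the same scale).
#' @examples
#' raw <- simulateDoseResponse(c(bottom = 0, top = 50, ec50 = 1e-5,
#'                               hill = 1), noiseCv = 0, seed = 1L)
#' head(normalizeToReference(raw))
#' @export
normalizeToReference <- function(drc, method = c("subtractive", "ratio")) {
  method <- match.arg(method)
  need <- c("value", "role")
  if (!all(need %in% names(drc)))
    stop("dose-response table needs 'value' and 'role' columns", call. = FALSE)
  posMean <- mean(drc$value[drc$role == "pos"])
  negMean <- mean(drc$value[drc$role == "neg"])
  if (!is.finite(posMean) || !is.finite(negMean))
    stop("need at least one positive and one negative control row",
         call. = FALSE)
  if (posMean == negMean)
    stop("degenerate controls: positive and negative means are equal",
         call. = FALSE)
  out <- drc
  out$value <- if (method == "subtractive")
    100 * (drc$value - negMean) / (posMean - negMean)
  else 100 * drc$value / posMean
  out
}

.fit4plEngine <- function(conc, resp, model) {
  ok <- is.finite(conc) & conc > 0 & is.finite(resp)
  conc <- conc[ok]; resp <- resp[ok]
  if (length(unique(conc)) < 4L)
    stop("need at least 4 distinct concentrations", call. = FALSE)
  lx <- log10(conc)
  agg <- tapply(resp, lx, mean)
  lvl <- as.numeric(names(agg))
  ## quantile-based initialization
  bottom0 <- as.numeric(quantile(resp, 0.05))
  top0 <- as.numeric(quantile(resp, 0.95))
  if (model == "inhibition") { tmp <- bottom0; bottom0 <- top0; top0 <- tmp }
  half <- (bottom0 + top0) / 2
  le0 <- lvl[which.min(abs(agg - half))]
  h0 <- if (model == "inhibition") -1 else 1
  df <- data.frame(lx = lx, y = resp)
  lower <- c(bottom = -Inf, top = -Inf, le = min(lx) - 4, hill = 1e-3)
  upper <- c(bottom = Inf, top = Inf, le = max(lx) + 4, hill = 20)
  if (model == "inhibition") {
    lower["hill"] <- -20; upper["hill"] <- -1e-3; h0 <- -1
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^(hill * (le - lx))),
      data = df,
      start = list(bottom = bottom0, top = top0, le = le0, hill = h0),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  n <- length(resp)
  if (is.null(fit)) {
    co <- c(bottom = NA_real_, top = NA_real_, ec50 = NA_real_,
            hill = NA_real_)
    return(new("FourPLFit", coefficients = co, se = co, rss = NA_real_,
               converged = FALSE, model = model, nPoints = as.integer(n)))
  }
  cf <- coef(fit)
  co <- c(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
          ec50 = unname(10^cf["le"]), hill = unname(cf["hill"]))
  se <- tryCatch({
    s <- summary(fit)$coefficients[, "Std. Error"]
    c(bottom = unname(s["bottom"]), top = unname(s["top"]),
      ec50 = unname(s["le"] * log(10) * 10^cf["le"]),  # delta method
      hill = unname(s["hill"]))
  }, error = function(e) c(bottom = NA_real_, top = NA_real_,
                           ec50 = NA_real_, hill = NA_real_))
  rss <- sum(residuals(fit)^2)
  conv <- isTRUE(fit$convInfo$isConv)
  ## honesty checks: a flat or unresolved curve is flagged, not reported as
  ## a clean fit
  span <- abs(co[["top"]] - co[["bottom"]])
  rse <- sqrt(rss / max(1L, n - 4L))
  if (span < 1e-8 || (rse > 0 && span < 2 * rse)) conv <- FALSE
  if (co[["ec50"]] < min(conc) / 1e3 || co[["ec50"]] > max(conc) * 1e3)
    conv <- FALSE
  new("FourPLFit", coefficients = co, se = se, rss = rss, converged = conv,
      model = model, nPoints = as.integer(n))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares variable-slope 4PL on log10 concentration
#' (Levenberg-Marquardt), initialized from data quantiles. The convergence
#' flag is honest: non-convergence, a flat fitted span (relative to the
#' residual scale) or a midpoint far outside the tested range all clear
#' it.
#'
#' @param curve normalized dose-response table (\code{role == "sample"}
#'   rows are fitted) or a data.frame with \code{conc_molar} and
#'   \code{value}.
#' @return a \linkS4class{FourPLFit} (EC50 in molar; \code{top} is the
#'   fitted maximal response, i.e. the E\eqn{_{max}} on the reference
#'   scale).
#' @examples
#' drc <- simulateDoseResponse(c(bottom = 0, top = 100, ec50 = 1e-5,
#'                               hill = 1), noiseCv = 0, seed = 1L)
#' fit4PL(normalizeToReference(drc))
#' @export
fit4PL <- function(curve) {
  d <- if ("role" %in% names(curve)) curve[curve$role == "sample", ] else curve
  .fit4plEngine(d$conc_molar, d$value, "agonist")
}

#' @rdname fit4PL
#' @export
fitInhibition <- function(curve) {
  d <- if ("role" %in% names(curve)) curve[curve$role == "sample", ] else curve
  .fit4plEngine(d$conc_molar, d$value, "inhibition")
}

#' Potentiation of a reference-ligand response by a modulator
#'
#' Fits the baseline curve and each modulated curve (same normalization
#' scale) and reports the percent change of the fitted top:
#' \code{100 * (top_mod - top_base) / top_base}.
#'
#' @param baselineCurve normalized dose-response table of the reference
#'   ligand alone.
#' @param modulatedCurves named list of normalized tables, one per
#'   modulator concentration; names are parsed as molar concentrations
#'   when numeric.
#' @return data.frame: \code{modulator_conc}, \code{baseline_top},
#'   \code{modulated_top}, \code{potentiation_pct}, \code{converged}.
#' @export
potentiationAnalysis <- function(baselineCurve, modulatedCurves) {
  base <- fit4PL(baselineCurve)
  topBase <- base@coefficients[["top"]]
  if (!is.finite(topBase) || topBase <= 0)
    stop("baseline top must be positive for potentiation analysis",
         call. = FALSE)
  nm <- names(modulatedCurves)
  if (is.null(nm)) nm <- as.character(seq_along(modulatedCurves))
  out <- lapply(seq_along(modulatedCurves), function(i) {
    f <- fit4PL(modulatedCurves[[i]])
    topMod <- f@coefficients[["top"]]
    data.frame(modulator_conc = suppressWarnings(as.numeric(nm[i])),
               baseline_top = topBase, modulated_top = topMod,
               potentiation_pct = 100 * (topMod - topBase) / topBase,
               converged = f@converged && base@converged)
  })
  do.call(rbind, out)
}
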