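#' Steady-state fraction of channel block
#'
#' The pore-block model used throughout the package:
#' \deqn{f = \frac{1}{1 + IC_{50}/[C]}}
#' the steady-state proportion of a current eliminated at drug concentration
#' \eqn{C}. Channel kinetics are assumed unchanged, so block enters purely as
#' a conductance rescaling \eqn{g \to g (1 - f)}.
#'
#' @param C drug concentration (µM, >= 0)
#' @param IC50 half-maximal inhibitory concentration (µM, > 0)
#' @return block fraction in \[0, 1); vectorized. `f(IC50) = 0.5` exactly and
#'   `f(0) = 0`.
#' @examples
#' fraction_block(2.5, 2.5)   # 50% block of I_Kr at 2.5 uM chloroquine
#' fraction_block(8.7, 1.0)   # ~90% block at the top of the I_K1/I_KACh sweep
#' @export
fraction_block <- function(C, IC50) {
  if (any(IC50 <= 0)) stop("IC50 must be positive")
  if (any(C < 0)) stop("concentration must be non-negative")
  1 / (1 + IC50 / C) * (C > 0)  # C = 0 handled as the limit 0
}

#' Chloroquine IC50 presets
#'
#' Two named sets of half-maximal inhibitory concentrations (µM) for
#' chloroquine block of the three potassium currents:
#' \describe{
#'   \item{simulation}{the values driving the cell/tissue simulations: 0.97
#'     (\eqn{I_{K1}}), 1.0 (\eqn{I_{KACh}}), 2.5 (\eqn{I_{Kr}}).}
#'   \item{patch_clamp}{the variable-slope fits to the whole-cell recordings:
#'     1.3 (\eqn{I_{K1}}), 1.2 (\eqn{I_{KACh}}), 2.5 (\eqn{I_{Kr}}).}
#' }
#'
#' @param preset `"simulation"` (default) or `"patch_clamp"`
#' @return named numeric vector with entries `IK1`, `IKACh`, `IKr`
#' @export
chloroquine_ic50 <- function(preset = c("simulation", "patch_clamp")) {
  preset <- match.arg(preset)
  switch(preset,
         simulation = c(IK1 = 0.97, IKACh = 1.0, IKr = 2.5),
         patch_clamp = c(IK1 = 1.3, IKACh = 1.2, IKr = 2.5))
}

#' Drug block profile
#'
#' Describes a steady-state multichannel block: the drug concentration, the
#' per-current IC50 values, and which currents are enabled for block. The
#' per-current block fractions are derived on construction.
#'
#' @param concentration drug concentration (µM, >= 0)
#' @param currents character vector naming the blocked currents; any subset of
#'   `"IK1"`, `"IKACh"`, `"IKr"`
#' @param ic50 named IC50 vector (µM), see [chloroquine_ic50()]
#' @return an object of class `drug_block_profile` with a `fraction` element
#' @export
drug_block_profile <- function(concentration,
                               currents = c("IK1", "IKACh", "IKr"),
                               ic50 = chloroquine_ic50()) {
  stopifnot(concentration >= 0)
  currents <- as.character(currents)
  bad <- setdiff(currents, c("IK1", "IKACh", "IKr"))
  if (length(bad)) stop("unknown current(s): ", paste(bad, collapse = ", "))
  missing_ic50 <- setdiff(currents, names(ic50))
  if (length(missing_ic50))
    stop("no IC50 supplied for: ", paste(missing_ic50, collapse = ", "))
  f <- setNames(numeric(length(currents)), currents)
  for (cur in currents) f[cur] <- fraction_block(concentration, ic50[[cur]])
  structure(list(concentration = concentration, currents = currents,
                 ic50 = ic50, fraction = f),
            class = "drug_block_profile")
}

#' @export
print.drug_block_profile <- function(x, ...) {
  cat(sprintf("drug block at C = %g uM:\n", x$concentration))
  if (!length(x$currents)) cat("  (no currents enabled)\n")
  for (cur in x$currents)
    cat(sprintf("  %-6s IC50 = %.3g uM, f = %.4f\n", cur, x$ic50[[cur]],
                x$fraction[[cur]]))
  invisible(x)
}

#' Apply steady-state drug block to cell parameters
#'
#' Rescales the enabled currents' maximal conductances by \eqn{(1 - f)};
#' channel kinetics are untouched, so block commutes with
#' [apply_remodeling()].
#'
#' @param params a [cell_params()]
#' @param profile a [drug_block_profile()]
#' @return a new `cell_params`
#' @export
apply_block <- function(params, profile) {
  stopifnot(inherits(params, "cell_params"),
            inherits(profile, "drug_block_profile"))
  p <- params
  map <- c(IK1 = "gK1", IKACh = "gKACh", IKr = "gKr")
  for (cur in profile$currents)
    p[[map[[cur]]]] <- p[[map[[cur]]]] * (1 - profile$fraction[[cur]])
  p
}

#' Variable-slope concentration-response curve
#'
#' \deqn{Y = \frac{1}{1 + 10^{(LogIC_{50} - X)\,Slope}}}
#' where \eqn{X} is log10 concentration. `Y(X = logIC50) = 0.5` for any slope;
#' with a negative slope the remaining current falls as concentration rises.
#' With `slope = -1`, `1 - hill_response(log10(C), log10(IC50), -1)` equals
#' [fraction_block()] for all concentrations.
#'
#' @param X log10 concentration (log10 µM)
#' @param logIC50 log10 of the IC50 (log10 µM)
#' @param slope signed Hill slope (dimensionless)
#' @return response in (0, 1); vectorized
#' @export
hill_response <- function(X, logIC50, slope) {
  1 / (1 + 10^((logIC50 - X) * slope))
}

#' Concentration-response data
#'
#' @param concentration concentrations (µM, all > 0)
#' @param response normalized remaining current (dimensionless; values
#'   moderately outside \[0, 1\] are tolerated as noise)
#' @param replicate optional replicate identifier
#' @return an object of class `conc_response` (a data frame)
#' @export
conc_response <- function(concentration, response, replicate = NULL) {
  if (any(concentration <= 0)) stop("concentrations must be positive")
  if (length(concentration) != length(response))
    stop("concentration and response lengths differ")
  if (!all(is.finite(response))) stop("non-finite response values")
  d <- data.frame(concentration = concentration, response = response)
  if (!is.null(replicate)) d$replicate <- replicate
  class(d) <- c("conc_response", "data.frame")
  d
}

#' Fit a variable-slope Hill curve to concentration-response data
#'
#' Nonlinear least squares of [hill_response()] against
#' (log10 concentration, response), via Levenberg-Marquardt with three
#' starting points spread across the data's concentration range (the fit
#' surface is mildly multimodal in the slope sign).
#'
#' @param data a [conc_response()] object or a data frame with columns
#'   `concentration` (µM) and `response`
#' @return an object of class `hill_fit`: `logIC50`, `IC50`, `slope`,
#'   `r_squared`, and `fitted(X)` evaluating the fitted curve at log10
#'   concentrations
#' @export
fit_hill <- function(data) {
  if (!is.data.frame(data) ||
      !all(c("concentration", "response") %in% names(data)))
    stop("data must have columns 'concentration' and 'response'")
  if (any(data$concentration <= 0)) stop("concentrations must be positive")
  X <- log10(data$concentration)
  Y <- data$response
  if (length(unique(signif(data$concentration, 12))) < 4)
    stop("at least 4 distinct concentrations are required")
  if (sd(Y) < 1e-9)
    stop("degenerate data: constant response, IC50 unidentifiable")

  d <- data.frame(X = X, Y = Y)
  starts <- expand.grid(logIC50 = c(min(X), mean(range(X)), max(X)),
                        slope = c(-1, 1))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(Y ~ 1 / (1 + 10^((logIC50 - X) * slope)),
                        data = d,
                        start = as.list(starts[i, ]),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("Hill fit failed to converge from any start")
  cf <- coef(best$fit)
  ss_tot <- sum((Y - mean(Y))^2)
  r2 <- 1 - best$rss / ss_tot
  out <- list(logIC50 = unname(cf[["logIC50"]]),
              IC50 = 10^unname(cf[["logIC50"]]),
              slope = unname(cf[["slope"]]),
              r_squared = r2,
              fitted = function(X) hill_response(X, cf[["logIC50"]],
                                                 cf[["slope"]]),
              data = d)
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: IC50 = %.4g uM (logIC50 = %.4f), slope = %.3f, R^2 = %.4f\n",
              x$IC50, x$logIC50, x$slope, x$r_squared))
  invisible(x)
}

#' @importFrom stats residuals
NULL
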