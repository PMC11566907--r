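# Four-parameter logistic dose-response fitting across replicates, IC50
# capping to the measured concentration range, and potency classification.

#' Four-parameter logistic function
#'
#' `f(x) = A + (D - A) / (1 + (x / C)^B)`: `D` is the response as `x -> 0`,
#' `A` the response as `x -> Inf`, `B` the Hill slope and `C` the
#' inflection (half-maximal) concentration.
#'
#' @param x concentration (uM), positive.
#' @param A,B,C,D curve parameters; `C > 0`.
#' @return response value(s).
#' @export
four_pl <- function(x, A, B, C, D) {
  if (any(x <= 0)) stop("concentration x must be > 0", call. = FALSE)
  if (any(C <= 0)) stop("inflection C must be > 0", call. = FALSE)
  A + (D - A) / (1 + (x / C)^B)
}

#' pIC50 from a micromolar IC50
#'
#' `-log10(IC50 in molar)`; 30 uM maps to ~4.52, 1 uM to exactly 6.
#'
#' @param ic50 IC50 in uM, positive.
#' @return pIC50.
#' @export
pic50 <- function(ic50) {
  if (any(ic50 <= 0)) stop("ic50 must be > 0", call. = FALSE)
  -log10(ic50 * 1e-6)
}

#' Potency class from pIC50
#'
#' Micromolar: pIC50 < 6; high nanomolar: 6 <= pIC50 < 7; nanomolar:
#' pIC50 >= 7. The union of the upper two classes is conventionally called
#' sub-micromolar.
#'
#' @param pic50 numeric vector of pIC50 values.
#' @return character vector of class labels.
#' @export
classify_activity <- function(pic50) {
  if (any(!is.finite(pic50))) stop("pic50 must be finite", call. = FALSE)
  ifelse(pic50 < 6, "micromolar",
         ifelse(pic50 < 7, "high_nanomolar", "nanomolar"))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit over all replicate points jointly
#' (Levenberg-Marquardt via `minpack.lm::nls.lm`), with analytic initialization (asymptotes from the
#' extreme-concentration responses, `C` at the half-range crossing, `B = 1`)
#' and restarts from perturbed initializations, keeping the best residual.
#' The reported IC50 is the fitted inflection `C` capped into the measured
#' concentration range; erroneous fits (non-convergence, inflection above
#' the top tested dose, or a near-flat fitted curve) are set to the highest
#' tested concentration and flagged `capped`.
#'
#' @param measurements data frame for one compound: `conc_uM`, `response`
#'   (replicate points are simply additional rows).
#' @param flat_tol fits whose dynamic range `|A - D|` is below this
#'   fraction of the observed response spread are treated as erroneous.
#' @return object of class `four_pl_fit`: list with `A`, `B`, `C`, `D`,
#'   `ic50`, `pic50`, `capped`, `activity_class`, `rmse`, `converged`.
#' @export
fit_dose_response <- function(measurements, flat_tol = 0.1) {
  x <- measurements$conc_uM
  y <- measurements$response
  if (any(x <= 0)) stop("non-positive concentrations", call. = FALSE)
  concs <- sort(unique(x))
  if (length(concs) < 4L)
    stop("insufficient data: need >= 4 distinct concentrations, got ",
         length(concs), call. = FALSE)
  top <- max(concs); bottom <- min(concs)

  finish <- function(A, B, C, D, converged, rmse) {
    capped <- FALSE
    ic50 <- C
    if (!converged || !is.finite(ic50) || ic50 > top ||
        abs(A - D) < flat_tol * max(diff(range(y)), 1e-9)) {
      ic50 <- top; capped <- TRUE
    } else if (ic50 < bottom) {
      ic50 <- bottom; capped <- TRUE
    }
    p <- pic50(ic50)
    structure(list(A = A, B = B, C = C, D = D, ic50 = ic50, pic50 = p,
                   capped = capped, activity_class = classify_activity(p),
                   rmse = rmse, converged = converged),
              class = "four_pl_fit")
  }

  if (diff(range(y)) < 1e-12)   # flat curve: no dose dependence measurable
    return(finish(y[1], 1, Inf, y[1], converged = FALSE, rmse = 0))

  mean_by_conc <- tapply(y, x, mean)
  lo_resp <- mean_by_conc[[as.character(bottom)]]
  hi_resp <- mean_by_conc[[as.character(top)]]
  half <- (lo_resp + hi_resp) / 2
  c0 <- concs[which.min(abs(mean_by_conc[as.character(concs)] - half))]
  c0 <- min(max(c0, bottom), top)
  starts <- list(c(C = c0, B = 1), c(C = c0 * 0.3, B = 0.7),
                 c(C = min(c0 * 3, top), B = 1.5))

  resid_fn <- function(par)
    y - (par[["A"]] + (par[["D"]] - par[["A"]]) /
           (1 + (x / par[["C"]])^par[["B"]]))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(A = hi_resp, B = st[["B"]], C = st[["C"]], D = lo_resp),
        fn = resid_fn,
        lower = c(A = -Inf, B = -10, C = bottom / 100, D = -Inf),
        upper = c(A = Inf, B = 10, C = top * 100, D = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    # info 1-4: converged; 5: iteration cap hit with best-found parameters
    # still usable (LM monotonically reduces the residual)
    if (is.null(fit) || !fit$info %in% 1:5) next
    rss <- fit$deviance
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(finish(hi_resp, 1, Inf, lo_resp, converged = FALSE,
                  rmse = stats::sd(y)))

  p <- best$fit$par
  A <- p[["A"]]; B <- p[["B"]]; C <- p[["C"]]; D <- p[["D"]]
  if (B < 0) { tmp <- A; A <- D; D <- tmp; B <- -B }  # equivalent reparam
  finish(A, B, C, D, converged = TRUE,
         rmse = sqrt(best$rss / length(y)))
}

#' @export
print.four_pl_fit <- function(x, ...) {
  cat(sprintf("4PL fit: IC50 %.4g uM (pIC50 %.2f%s), class %s, rmse %.3g\n",
              x$ic50, x$pic50, if (x$capped) ", capped" else "",
              x$activity_class, x$rmse))
  invisible(x)
}

#' Fit dose-response curves for every compound in a measurement table
#'
#' @param measurements data frame with `compound_id`, `conc_uM`,
#'   `response`.
#' @param ... passed to [fit_dose_response()].
#' @return data frame, one row per compound: parameters, `ic50_uM`,
#'   `pic50`, `capped`, `activity_class`, `rmse`.
#' @export
fit_dose_response_all <- function(measurements, ...) {
  rows <- lapply(split(measurements, measurements$compound_id), function(df) {
    f <- fit_dose_response(df, ...)
    data.frame(compound_id = df$compound_id[1], A = f$A, B = f$B, C = f$C,
               D = f$D, ic50_uM = f$ic50, pic50 = f$pic50, capped = f$capped,
               activity_class = f$activity_class, rmse = f$rmse,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
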