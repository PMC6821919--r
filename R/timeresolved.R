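#' @include idf.R
NULL

# Log-linear slope of a tail segment; returns c(alpha, tau) or NULL.
.tailEstimate <- function(t, y) {
  pos <- y > 0
  if (sum(pos) < 3L) return(NULL)
  fit <- stats::lm(log(y[pos]) ~ t[pos])
  slope <- stats::coef(fit)[2L]
  if (!is.finite(slope) || slope >= 0) return(NULL)
  c(alpha = exp(unname(stats::coef(fit)[1L])), tau = -1 / unname(slope))
}

#' Fit a multiexponential fluorescence decay
#'
#' Weighted least squares of
#' \deqn{I(t) = \sum_{i=1}^{n} \alpha_i e^{-t/\tau_i}}
#' to a background-subtracted TCSPC trace, with Poisson-motivated weights
#' \eqn{1/\max(\mathrm{counts}, 1)}. Fitting starts at the peak channel
#' (tail fitting; no instrument-response deconvolution). Initial values are
#' deterministic: the log-linear slope of the late tail seeds the long
#' component, the early residual seeds the short one. Amplitudes are
#' normalised to sum to 1 on output and components are ordered by
#' descending lifetime. Only one- and two-component models are supported;
#' asking for more is an error, not a silent extension.
#'
#' @param trace a [DecayTrace-class] with at least 10 points past the peak
#'   spanning several lifetimes.
#' @param nComponents 1 or 2.
#' @return a [DecayFit-class].
#' @examples
#' t <- seq(0, 50, by = 0.1)
#' tr <- DecayTrace(t, 1e4 * exp(-t / 6.71))
#' fitDecay(tr, 1)
#' @export
fitDecay <- function(trace, nComponents = 1) {
  stopifnot(is(trace, "DecayTrace"))
  if (!nComponents %in% c(1, 2))
    stop("only 1- or 2-component decays are supported")
  if (all(trace@counts == 0)) stop("decay trace holds no counts")
  peak <- which.max(trace@counts)
  t <- trace@timeNs[peak:length(trace@timeNs)]
  y <- trace@counts[peak:length(trace@counts)]
  t <- t - t[1L]
  if (length(t) < 10L)
    stop("decay fitting requires at least 10 points past the peak")
  wts <- 1 / pmax(y, 1)

  tailIdx <- seq(max(1L, floor(length(t) * 0.5)), length(t))
  long <- .tailEstimate(t[tailIdx], y[tailIdx])
  if (is.null(long)) long <- c(alpha = max(y), tau = max(t) / 3)
  if (nComponents == 1L) {
    p0 <- c(log(long[["alpha"]]), log(long[["tau"]]))
  } else {
    resid0 <- pmax(y - long[["alpha"]] * exp(-t / long[["tau"]]), 0)
    headIdx <- seq_len(max(5L, floor(length(t) * 0.2)))
    short <- .tailEstimate(t[headIdx], resid0[headIdx])
    if (is.null(short))
      short <- c(alpha = max(y) * 0.3, tau = long[["tau"]] / 4)
    p0 <- c(log(long[["alpha"]]), log(short[["alpha"]]),
            log(long[["tau"]]), log(short[["tau"]]))
  }

  resFun <- function(p) {
    a <- exp(p[seq_len(nComponents)])
    tau <- exp(p[nComponents + seq_len(nComponents)])
    model <- rowSums(vapply(seq_len(nComponents),
                            function(i) a[i] * exp(-t / tau[i]),
                            numeric(length(t))))
    sqrt(wts) * (y - model)
  }
  fit <- minpack.lm::nls.lm(p0, fn = resFun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-13))
  if (fit$info %in% c(0, 5, 9))
    stop(sprintf("decay fit did not converge (nls.lm info %d: %s)",
                 fit$info, fit$message))
  a <- exp(fit$par[seq_len(nComponents)])
  tau <- exp(fit$par[nComponents + seq_len(nComponents)])
  dof <- length(t) - 2L * nComponents
  chisq <- sum(fit$fvec^2) / max(dof, 1L)
  tauSE <- rep(NA_real_, nComponents)
  cv <- tryCatch((sum(fit$fvec^2) / max(dof, 1L)) * solve(fit$hessian),
                 error = function(e) NULL)
  if (!is.null(cv))
    tauSE <- tau * sqrt(pmax(diag(cv)[nComponents + seq_len(nComponents)], 0))
  o <- order(tau, decreasing = TRUE)
  new("DecayFit", alpha = (a / sum(a))[o], tau = tau[o], tauSE = tauSE[o],
      chisqRed = chisq, nPoints = length(t))
}

#' @rdname averageLifetime
setMethod("averageLifetime", "DecayFit", function(fit) {
  if (length(fit@tau) == 1L) return(fit@tau)
  sum(fit@alpha * fit@tau^2) / sum(fit@alpha * fit@tau)
})

#' Lifetime ratios along a ligand ladder
#'
#' Computes \eqn{\tau_0 / \tau([L])} from per-concentration decay fits,
#' using intensity-weighted average lifetimes, for use with
#' [classifyMechanism()]. The zero-ligand fit is the reference.
#'
#' @param fits list of [DecayFit-class] objects.
#' @param ligandM ligand concentration per fit, mol/L; must include 0.
#' @return data.frame with columns `ligandM`, `tauAvgNs`, `tauRatio`
#'   (\eqn{\tau_0/\tau}), ordered by ligand concentration.
#' @export
lifetimeRatioSeries <- function(fits, ligandM) {
  if (!length(fits)) stop("empty decay-fit series")
  if (length(fits) != length(ligandM))
    stop("fits and ligandM must have equal length")
  if (!any(ligandM == 0))
    stop("lifetime ratios need a zero-ligand reference fit")
  o <- order(ligandM)
  fits <- fits[o]; ligandM <- ligandM[o]
  tavg <- vapply(fits, averageLifetime, numeric(1))
  data.frame(ligandM = ligandM, tauAvgNs = tavg,
             tauRatio = tavg[ligandM == 0][1L] / tavg)
}
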