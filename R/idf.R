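#' @include thermodynamics.R
NULL

#' Quench percentage
#'
#' \eqn{\Delta F = |F_{obs} - F_{free}| / F_{free} \cdot 100} — the
#' percentage loss of signal relative to the free-protein signal.
#'
#' @param Fobs observed signal in the presence of ligand.
#' @param Ffree signal of the free protein (> 0).
#' @return quench percentage.
#' @export
quenchPercentage <- function(Fobs, Ffree) {
  if (any(Ffree <= 0)) stop("free-protein signal must be positive")
  abs(Fobs - Ffree) / Ffree * 100
}

# Scalar signal per titration step (shared with buildCurve conventions).
.seriesSignals <- function(series, mode, read) {
  vapply(series@spectra, function(s) {
    if (mode == "intensity")
      stats::approx(s@wavelength, s@values, xout = read)$y
    else integrateBand(s, read[1L], read[2L])
  }, numeric(1))
}

#' Match constant-quench levels across protein concentrations (IDF)
#'
#' The interaction density function method: if two titrations at different
#' total protein concentrations reach the *same* quench percentage
#' \eqn{\Delta F}, they share the same free ligand concentration and the
#' same average binding density \eqn{\sum\nu_i}. For each horizontal
#' \eqn{\Delta F} cut, each series' monotone \eqn{\Delta F(\log_{10}
#' [L]_{total})} curve is inverted by piecewise-linear interpolation to
#' yield one total ligand concentration per protein concentration, and the
#' mass-conservation line
#' \deqn{[L]_{total} = [L]_{free} + \left(\sum\nu_i\right) [P]}
#' is fitted by ordinary least squares across protein concentrations: the
#' slope is \eqn{\sum\nu_i}, the intercept \eqn{[L]_{free}}.
#'
#' Levels are placed evenly inside the intersection of the series'
#' \eqn{\Delta F} ranges, shrunk by a relative margin at each end. A level
#' with a negative intercept (free ligand cannot be negative) or with
#' \eqn{r^2} below `r2Min` is rejected and reported via a message.
#'
#' @param seriesList list of two or more [TitrationSeries-class] objects at
#'   distinct protein concentrations, sharing temperature, kind and ladder
#'   design; all spectra must be inner-filter corrected.
#' @param nLevels number of evenly spaced quench levels (default 20).
#' @param levels explicit \eqn{\Delta F} grid (%), overriding `nLevels`.
#' @param mode scalar-signal mode, `"area"` (default) or `"intensity"`.
#' @param read read wavelength or window; defaults as in [buildCurve()].
#' @param margin relative margin trimmed from each end of the common
#'   \eqn{\Delta F} range (default 0.02).
#' @param monotoneTol largest tolerated decrease of \eqn{\Delta F} along a
#'   ladder, as a fraction of that series' \eqn{\Delta F} range. Decreases
#'   within the tolerance (counting noise near saturation) are pooled away
#'   by isotonic regression before inversion; a larger violation aborts
#'   with an error naming the series.
#' @param r2Min minimum \eqn{r^2} for a level to be accepted.
#' @return an [IDFLevels-class] object.
#' @seealso [bindingDensityCurve()], [scatchard()], [hillFit()].
#' @export
matchLevels <- function(seriesList, nLevels = 20, levels = NULL,
                        mode = c("area", "intensity"), read = NULL,
                        margin = 0.02, monotoneTol = 0.05, r2Min = 0.95) {
  mode <- match.arg(mode)
  if (is.null(read)) read <- if (mode == "intensity") 340 else c(305, 400)
  if (length(seriesList) < 2L)
    stop("IDF matching requires titrations at >= 2 protein concentrations")
  stopifnot(all(vapply(seriesList, is, logical(1), "TitrationSeries")))
  P <- vapply(seriesList, function(s) s@proteinM, numeric(1))
  if (anyNA(P) || length(unique(P)) != length(P))
    stop("series must carry distinct protein concentrations")
  temps <- vapply(seriesList, function(s) s@temperatureK, numeric(1))
  if (length(unique(temps[is.finite(temps)])) > 1L)
    stop("all series must share the same temperature")
  o <- order(P)
  seriesList <- seriesList[o]; P <- P[o]

  perSeries <- lapply(seq_along(seriesList), function(i) {
    s <- seriesList[[i]]
    if (s@ligandM[1L] != 0)
      stop(sprintf("series %d lacks a zero-ligand reference", i))
    if (any(!vapply(s@spectra, isCorrected, logical(1))))
      stop(sprintf("series %d holds uncorrected spectra", i))
    sig <- .seriesSignals(s, mode, read)
    dF <- quenchPercentage(sig, sig[1L])
    keep <- s@ligandM > 0
    dF <- dF[keep]; logL <- log10(s@ligandM[keep])
    if (any(diff(dF) < -monotoneTol * diff(range(dF))))
      stop(sprintf(
        "series %d (protein %.3g M): quench percentage is not monotone in total ligand",
        i, P[i]))
    # pool tolerated decreases (noise near saturation) into a monotone fit
    dF <- stats::isoreg(dF)$yf
    dup <- c(FALSE, diff(dF) <= 0)
    list(dF = dF[!dup], logL = logL[!dup])
  })

  loAll <- vapply(perSeries, function(z) min(z$dF), numeric(1))
  hiAll <- vapply(perSeries, function(z) max(z$dF), numeric(1))
  lo <- max(loAll); hi <- min(hiAll)
  if (hi <= lo)
    stop("quench-percentage ranges of the series do not overlap")
  if (is.null(levels)) {
    pad <- margin * (hi - lo)
    levels <- seq(lo + pad, hi - pad, length.out = nLevels)
  } else {
    levels <- sort(as.numeric(levels))
    if (any(levels <= lo) || any(levels >= hi))
      stop("explicit levels must lie strictly inside the common quench range")
  }

  totals <- matrix(NA_real_, length(levels), length(P),
                   dimnames = list(NULL, sprintf("P_%g", P)))
  for (j in seq_along(P))
    totals[, j] <- 10^stats::approx(perSeries[[j]]$dF, perSeries[[j]]$logL,
                                    xout = levels, ties = "ordered")$y

  res <- lapply(seq_along(levels), function(i) {
    fit <- stats::lm(totals[i, ] ~ P)
    cf <- stats::coef(fit)
    se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
    r2 <- suppressWarnings(summary(fit))$r.squared
    data.frame(deltaF = levels[i],
               sumNu = unname(cf[2L]), sumNuSE = unname(se[2L]),
               freeLigandM = unname(cf[1L]), freeLigandSE = unname(se[1L]),
               r2 = r2)
  })
  res <- do.call(rbind, res)
  res$accepted <- res$freeLigandM >= 0 & res$r2 >= r2Min
  res$reason <- ifelse(res$accepted, "",
                       ifelse(res$freeLigandM < 0, "negative free ligand",
                              sprintf("r2 < %g", r2Min)))
  nRej <- sum(!res$accepted)
  if (nRej > 0)
    message(sprintf("matchLevels: rejected %d of %d level(s): %s",
                    nRej, nrow(res),
                    paste(unique(res$reason[!res$accepted]), collapse = "; ")))
  new("IDFLevels", levels = res, totals = totals, proteinM = P,
      mode = mode, temperatureK = temps[which(is.finite(temps))[1L]])
}

#' Binding density curve from accepted IDF levels
#'
#' Extracts the accepted (free ligand, \eqn{\sum\nu}) pairs of an
#' [IDFLevels-class] result, ordered by ascending free ligand. A decrease
#' of binding density with free ligand violates the physics of an
#' equilibrium isotherm and is flagged with a warning.
#'
#' @param idf an [IDFLevels-class] object.
#' @return a [BindingDensityCurve-class].
#' @export
bindingDensityCurve <- function(idf) {
  stopifnot(is(idf, "IDFLevels"))
  lv <- idf@levels[idf@levels$accepted, , drop = FALSE]
  if (!nrow(lv)) stop("no accepted IDF levels")
  crv <- BindingDensityCurve(lv$freeLigandM, lv$sumNu)
  if (any(diff(crv@sumNu) < 0))
    warning("binding density is not non-decreasing in free ligand")
  crv
}

#' Scatchard transform and cooperativity diagnostic
#'
#' Transforms a binding density curve to Scatchard coordinates
#' \eqn{(\sum\nu,\ \sum\nu / [L]_{free})}. For independent identical sites
#' the Scatchard plot declines monotonically; a convex curve rising to an
#' interior maximum before falling is the signature of positive
#' cooperativity.
#'
#' @param curve a [BindingDensityCurve-class] with at least 4 points, all
#'   at positive free ligand.
#' @param tol relative tolerance (fraction of the largest transformed
#'   value) below which successive changes count as flat; guards the
#'   verdict against the level-interpolation jitter an IDF-derived curve
#'   carries.
#' @return a [ScatchardResult-class].
#' @export
scatchard <- function(curve, tol = 5e-3) {
  stopifnot(is(curve, "BindingDensityCurve"))
  if (length(curve@sumNu) < 4L)
    stop("Scatchard diagnostic requires at least 4 points")
  if (any(curve@freeLigandM <= 0))
    stop("all free ligand concentrations must be positive")
  y <- curve@sumNu / curve@freeLigandM
  d <- diff(y)
  scale <- max(abs(y))
  rising <- d > tol * scale
  falling <- d < -tol * scale
  imax <- which.max(y)
  verdict <- if (all(falling)) "non-cooperative"
  else if (imax > 1L && imax < length(y) &&
           any(rising[seq_len(imax - 1L)]) &&
           all(!rising[seq(imax, length(d))]))
    "positive-cooperative"
  else "indeterminate"
  new("ScatchardResult", sumNu = curve@sumNu, ratio = y, verdict = verdict)
}

# Multi-class Hill occupancy: sum_j n_j (k_j L)^w_j / (1 + (k_j L)^w_j).
.hillNu <- function(L, n, k, w) {
  out <- numeric(length(L))
  for (j in seq_along(k)) {
    x <- (k[j] * L)^w[j]
    term <- x / (1 + x)
    term[is.infinite(x)] <- 1  # saturated site class
    out <- out + n[j] * term
  }
  out
}

# Residuals for a log-parameterised model; p = (log k_j, log w_j) per class
# (+ log n_j when free).
.hillResiduals <- function(p, L, nu, nClasses, nFree) {
  if (nFree) {
    k <- exp(p[seq_len(nClasses)])
    w <- exp(p[nClasses + seq_len(nClasses)])
    n <- exp(p[2L * nClasses + seq_len(nClasses)])
  } else {
    k <- exp(p[seq_len(nClasses)])
    w <- exp(p[nClasses + seq_len(nClasses)])
    n <- rep(1, nClasses)
  }
  nu - .hillNu(L, n, k, w)
}

# Deterministic multi-start grid for one model size.
.hillStarts <- function(L, nClasses, nFree) {
  kDecades <- 10^seq(floor(log10(1 / max(L))) - 1,
                     ceiling(log10(1 / min(L))) + 1)
  wGrid <- c(0.5, 1, 2, 4, 8)
  if (nClasses == 1L) {
    starts <- expand.grid(k1 = kDecades, w1 = wGrid)
    plist <- lapply(seq_len(nrow(starts)), function(i)
      c(log(starts$k1[i]), log(starts$w1[i])))
  } else {
    # classes ordered by descending k: pair each decade with its neighbours
    combs <- expand.grid(i = seq_along(kDecades), j = seq_along(kDecades))
    combs <- combs[combs$i >= combs$j, , drop = FALSE]
    plist <- list()
    for (r in seq_len(nrow(combs))) for (w1 in c(1, 4)) for (w2 in c(1, 4))
      plist[[length(plist) + 1L]] <-
        c(log(kDecades[combs$i[r]]), log(kDecades[combs$j[r]]),
          log(w1), log(w2))
    if (nClasses > 2L)
      plist <- lapply(plist, function(p) {
        k <- p[1:2]; w <- p[3:4]
        c(k, rep(mean(k), nClasses - 2L), w, rep(0, nClasses - 2L))
      })
  }
  if (nFree) plist <- lapply(plist, function(p) c(p, rep(0, nClasses)))
  plist
}

.aicc <- function(rss, nObs, nPar) {
  # +1 parameter for the residual variance
  p <- nPar + 1L
  if (nObs - p - 1L <= 0L) return(Inf)
  nObs * log(rss / nObs) + 2 * p + 2 * p * (p + 1) / (nObs - p - 1L)
}

#' Fit a multi-class cooperative Hill model to a binding density curve
#'
#' Nonlinear least squares of
#' \deqn{\sum\nu = \sum_{j=1}^{J} \frac{n_j (k_j [L]_{free})^{w_j}}
#'   {1 + (k_j [L]_{free})^{w_j}}}
#' in log-parameterisation (\eqn{\log k_j}, \eqn{\log w_j}, and
#' \eqn{\log n_j} when the site counts are free), by Levenberg-Marquardt
#' from a deterministic multi-start grid (binding constants decade-spaced
#' over the range bracketing \eqn{1/[L]_{free}}, affinity indices from
#' \{0.5, 1, 2, 4, 8\}). The number of classes is selected over
#' `1..maxClasses` by the corrected Akaike information criterion with ties
#' broken toward fewer classes.
#'
#' With `njPolicy = "fixed"` (default) each class contributes a single site
#' (\eqn{n_j = 1}), the usual form when the binding density saturates near
#' an integer; `"free"` also fits the \eqn{n_j}.
#'
#' @param curve a [BindingDensityCurve-class] with positive free ligand.
#' @param maxClasses largest number of site classes scanned (>= 1).
#' @param njPolicy `"fixed"` (n_j = 1) or `"free"`.
#' @return a [HillModel-class]; classes ordered by descending `k`.
#' @examples
#' L <- 10^seq(-6.3, -4.6, length.out = 30)
#' nu <- (2.3e5 * L)^2.93 / (1 + (2.3e5 * L)^2.93) +
#'       (1.3e5 * L)^8.15 / (1 + (1.3e5 * L)^8.15)
#' hillFit(BindingDensityCurve(L, nu), maxClasses = 3)
#' @export
hillFit <- function(curve, maxClasses = 3, njPolicy = c("fixed", "free")) {
  stopifnot(is(curve, "BindingDensityCurve"))
  njPolicy <- match.arg(njPolicy)
  nFree <- njPolicy == "free"
  if (maxClasses < 1) stop("maxClasses must be >= 1")
  L <- curve@freeLigandM
  nu <- curve@sumNu
  if (any(L <= 0)) stop("free ligand concentrations must be positive")
  nObs <- length(L)

  fitOne <- function(nClasses) {
    nPar <- (if (nFree) 3L else 2L) * nClasses
    if (nObs < 2L * nPar)
      return(list(converged = FALSE, rss = Inf, aicc = Inf))
    best <- NULL
    for (p0 in .hillStarts(L, nClasses, nFree)) {
      fit <- tryCatch(
        minpack.lm::nls.lm(p0, fn = .hillResiduals, L = L, nu = nu,
                           nClasses = nClasses, nFree = nFree,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-14, ptol = 1e-12)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
    if (is.null(best))
      return(list(converged = FALSE, rss = Inf, aicc = Inf))
    p <- best$fit$par
    k <- exp(p[seq_len(nClasses)])
    w <- exp(p[nClasses + seq_len(nClasses)])
    n <- if (nFree) exp(p[2L * nClasses + seq_len(nClasses)])
    else rep(1, nClasses)
    # SEs via the Jacobian at the optimum, delta method through exp()
    dof <- nObs - nPar
    pse <- rep(NA_real_, length(p))
    if (dof > 0) {
      J <- best$fit$hessian  # nls.lm returns t(J) %*% J in $hessian
      s2 <- best$rss / dof
      cv <- tryCatch(s2 * solve(J), error = function(e) NULL)
      if (!is.null(cv)) pse <- sqrt(pmax(diag(cv), 0))
    }
    kSE <- k * pse[seq_len(nClasses)]
    wSE <- w * pse[nClasses + seq_len(nClasses)]
    o <- order(k, decreasing = TRUE)
    list(converged = TRUE, rss = best$rss,
         aicc = .aicc(best$rss, nObs, nPar),
         classes = data.frame(n = n[o], k = k[o], kSE = kSE[o],
                              w = w[o], wSE = wSE[o]))
  }

  fits <- lapply(seq_len(maxClasses), fitOne)
  scan <- data.frame(
    nClasses = seq_len(maxClasses),
    rss = vapply(fits, function(f) f$rss, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)))
  if (!any(scan$converged))
    stop("Hill fit failed to converge from every start for every model size")
  # ties toward fewer classes: strict improvement required
  sel <- 1L
  for (j in seq_len(maxClasses))
    if (scan$converged[j] && scan$aicc[j] < scan$aicc[sel] - 1e-9) sel <- j
  if (!scan$converged[sel]) sel <- which(scan$converged)[1L]
  f <- fits[[sel]]
  new("HillModel", classes = f$classes, nClasses = sel, rss = f$rss,
      aicc = f$aicc, scan = scan, nPoints = as.integer(nObs))
}

#' Predicted binding density of a Hill model
#'
#' Evaluates the fitted occupancy model at given free ligand
#' concentrations; monotone increasing and bounded by \eqn{\sum n_j}.
#'
#' @param model a [HillModel-class].
#' @param freeLigandM free ligand concentrations, mol/L.
#' @return predicted \eqn{\sum\nu}.
#' @export
predictSumNu <- function(model, freeLigandM) {
  stopifnot(is(model, "HillModel"))
  cl <- model@classes
  .hillNu(freeLigandM, cl$n, cl$k, cl$w)
}
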