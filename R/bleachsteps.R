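## Oligomeric-state inference from photobleaching step counts.

#' Conditional binomial step-count distribution
#'
#' Probability mass function of the number of observed bleaching steps for
#' an n-mer whose subunit tags fluoresce independently with probability `p`,
#' conditioned on the spot being visible (at least one fluorescent tag):
#' `pmf(k) = choose(n, k) p^k (1 - p)^(n - k) / (1 - (1 - p)^n)` for
#' `k = 1..n`.
#'
#' @param nSubunits oligomer size n (>= 1).
#' @param p per-subunit fluorescence probability, in (0, 1].
#' @return Named numeric vector of probabilities over `1..nSubunits`,
#'   summing to 1.
#' @examples
#' conditionalBinomialPmf(4, 0.776)
#' @export
conditionalBinomialPmf <- function(nSubunits, p) {
  nSubunits <- .assertCount(nSubunits, "nSubunits")
  .assertScalar(p, "p", 0, 1)
  if (p == 0)
    stop("p = 0: conditioning on >= 1 fluorescent subunit is undefined")
  k <- seq_len(nSubunits)
  pmf <- dbinom(k, nSubunits, p) / (1 - (1 - p)^nSubunits)
  setNames(pmf, k)
}

#' Detect photobleaching steps in a trace
#'
#' Fits a piecewise-constant model by binary segmentation (penalized
#' residual sum of squares; the penalty is `sensitivity * sigma^2 * log(n)`
#' with `sigma` estimated robustly from first differences), then counts
#' downward level changes. Adjacent segments whose means differ by less than
#' half the typical drop are merged back (false splits), and the remaining
#' drops are quantized as integer multiples of a unit step amplitude chosen
#' by penalized least squares -- so that two bleach events falling within
#' one frame, which appear as a single double-height drop, are still
#' counted as two steps.
#'
#' On a noiseless staircase the detected count equals the true number of
#' steps exactly.
#'
#' @param trace a [BleachTrace-class].
#' @param sensitivity positive penalty multiplier; larger values demand
#'   stronger evidence per change-point. Default 2.
#' @return Integer number of downward steps.
#' @examples
#' detectSteps(BleachTrace(rep(3:0, each = 20)))
#' @export
detectSteps <- function(trace, sensitivity = 2) {
  stopifnot(is(trace, "BleachTrace"))
  .assertScalar(sensitivity, "sensitivity", 0, strict_lower = TRUE)
  x <- intensities(trace)
  n <- length(x)
  if (n < 2L) stop("trace must have at least 2 frames")
  sigma <- mad(diff(x)) / sqrt(2)
  if (!is.finite(sigma) || sigma <= 0)
    sigma <- max(.Machine$double.eps^0.5 * max(abs(x), 1),
                 .Machine$double.xmin)
  penalty <- sensitivity * sigma^2 * log(n)
  cp <- .binseg(x, penalty)
  if (length(cp) == 0L) return(0L)
  bounds <- c(0L, sort(cp), n)
  means <- vapply(seq_len(length(bounds) - 1L), function(i)
    mean(x[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
  lens <- diff(bounds)
  down <- -diff(means)
  down <- down[down > 0]
  if (length(down) == 0L) return(0L)
  # merge away level changes below half the typical drop (false splits)
  u0 <- median(down)
  repeat {
    d <- -diff(means)
    small <- which(abs(d) < 0.5 * u0)
    if (length(small) == 0L) break
    i <- small[which.min(abs(d[small]))]
    means[i] <- (lens[i] * means[i] + lens[i + 1L] * means[i + 1L]) /
      (lens[i] + lens[i + 1L])
    lens[i] <- lens[i] + lens[i + 1L]
    means <- means[-(i + 1L)]
    lens <- lens[-(i + 1L)]
    if (length(means) == 1L) return(0L)
  }
  d <- -diff(means)
  down <- d[d > 0]
  if (length(down) == 0L) return(0L)
  # quantize drops as integer multiples of a unit amplitude: pick the unit
  # minimizing the squared quantization error, with a mild penalty per
  # extra step so multi-step readings need real evidence
  lambda <- 0.25
  cand <- unique(c(down, down / 2))
  best <- length(down)
  bestScore <- Inf
  for (u in cand) {
    m <- pmax(1L, as.integer(round(down / u)))
    score <- sum((down - m * u)^2) + lambda * u^2 * (sum(m) - length(down))
    if (score < bestScore) {
      bestScore <- score
      best <- sum(m)
    }
  }
  as.integer(best)
}

# Binary segmentation for mean shifts: recursively accept the split with the
# largest RSS reduction while it exceeds `penalty`. Returns change-point
# indices t (segment = ..t | t+1..).
.binseg <- function(x, penalty) {
  n <- length(x)
  cps <- integer()
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    l <- seg[1]; r <- seg[2]
    m <- r - l + 1L
    if (m < 2L) next
    y <- x[l:r]
    cs <- cumsum(y)
    tot <- cs[m]
    i <- seq_len(m - 1L)
    # RSS reduction of splitting after local index i
    red <- cs[i]^2 / i + (tot - cs[i])^2 / (m - i) - tot^2 / m
    best <- which.max(red)
    if (red[best] > penalty) {
      t <- l + best - 1L
      cps <- c(cps, t)
      stack[[length(stack) + 1L]] <- c(l, t)
      stack[[length(stack) + 1L]] <- c(t + 1L, r)
    }
  }
  cps
}

#' Count steps for a list of traces
#'
#' @param traces list of [BleachTrace-class] objects.
#' @param sensitivity passed to [detectSteps()].
#' @return A [StepCountHistogram-class] over the detected counts (spots
#'   with 0 detected steps are dropped, as dark/stepless spots are not
#'   scoreable).
#' @export
countSteps <- function(traces, sensitivity = 2) {
  k <- vapply(traces, detectSteps, integer(1), sensitivity = sensitivity)
  k <- k[k >= 1L]
  if (length(k) == 0L) stop("no trace yielded a positive step count")
  StepCountHistogram(setNames(tabulate(k, nbins = max(k)), seq_len(max(k))))
}

#' Maximum-likelihood fit of the per-subunit fluorescence probability
#'
#' Maximizes the multinomial log-likelihood of a step-count histogram under
#' the conditional binomial model with fixed subunit number, over
#' `p` in (0, 1]. The default is maximum likelihood; `method = "ls"`
#' minimizes the squared distance between observed and model proportions
#' instead, for comparison.
#'
#' @param hist a [StepCountHistogram-class].
#' @param nSubunits candidate oligomer size. Histogram mass above
#'   `nSubunits` lies outside the model's support; it is ignored by the fit
#'   (and condemns the model in [gofTest()], whose expected count there is
#'   zero). If *all* mass lies above `nSubunits` the fit is impossible and
#'   an error is raised.
#' @param method `"ml"` (default) or `"ls"`.
#' @return The fitted probability (scalar). The attribute `"degenerate"` is
#'   TRUE when the optimum sits at a boundary (all mass at `nSubunits`
#'   giving `pHat = 1`, or all mass at 1 driving `pHat` to 0+).
#' @examples
#' h <- StepCountHistogram(c(`1` = 35, `2` = 182, `3` = 420, `4` = 363))
#' fitP(h, 4)
#' @export
fitP <- function(hist, nSubunits, method = c("ml", "ls")) {
  stopifnot(is(hist, "StepCountHistogram"))
  nSubunits <- .assertCount(nSubunits, "nSubunits")
  method <- match.arg(method)
  cnt <- stepCounts(hist)
  k <- as.integer(names(cnt))
  if (sum(cnt[k <= nSubunits]) == 0L)
    stop("all histogram mass sits above nSubunits; the model cannot be fit")
  keep <- cnt > 0L & k <= nSubunits
  obs <- numeric(nSubunits)
  obs[k[keep]] <- cnt[keep]
  if (all(obs[-nSubunits] == 0)) {          # all mass at k = n
    return(structure(1, degenerate = TRUE))
  }
  objective <- if (method == "ml") {
    function(p) sum(obs * log(conditionalBinomialPmf(nSubunits, p)))
  } else {
    function(p) -sum((obs / sum(obs) -
                        conditionalBinomialPmf(nSubunits, p))^2)
  }
  opt <- optimize(objective, interval = c(1e-8, 1), maximum = TRUE,
                  tol = 1e-9)
  # boundary checks: optimize() never evaluates the endpoints
  cand <- c(opt$maximum, 1)
  vals <- vapply(cand, objective, numeric(1))
  pHat <- cand[which.max(vals)]
  degenerate <- pHat >= 1 - 1e-7 || pHat <= 1e-6
  structure(pHat, degenerate = degenerate)
}

#' Pearson chi-squared goodness of fit of an oligomer model
#'
#' Compares a step-count histogram with the conditional binomial expectation
#' `E_k = N * pmf(k)` over bins `k = 1..nSubunits`. Degrees of freedom
#' depend on whether `p` was fitted from the same histogram: with
#' `pFitted = TRUE` (the default, matching [selectOligomer()]),
#' `df = (bins - 1) - 1`; both conventions are returned.
#'
#' @inheritParams fitP
#' @param p per-subunit fluorescence probability at which to evaluate the
#'   expectation.
#' @param pFitted logical; was `p` estimated from this same histogram?
#' @return A list with `chisq`, `df`, `pValue`, `dfAlt`, `pValueAlt`,
#'   `expected`, `observed`, and `emptyExpected` (TRUE when an expected
#'   count of zero meets observed mass -- including any observed step count
#'   above `nSubunits`, which the model gives probability zero -- in which
#'   case `chisq = Inf` and `pValue = 0`: certain rejection).
#' @examples
#' gofTest(StepCountHistogram(c(`1` = 10, `2` = 10)), 2, p = 0.5,
#'         pFitted = FALSE)
#' @export
gofTest <- function(hist, nSubunits, p, pFitted = TRUE) {
  stopifnot(is(hist, "StepCountHistogram"))
  nSubunits <- .assertCount(nSubunits, "nSubunits")
  cnt <- stepCounts(hist)
  k <- as.integer(names(cnt))
  keep <- cnt > 0L & k <= nSubunits
  obs <- numeric(nSubunits)
  obs[k[keep]] <- cnt[keep]
  aboveSupport <- sum(cnt[k > nSubunits])
  expd <- (sum(obs) + aboveSupport) * conditionalBinomialPmf(nSubunits, p)
  emptyExpected <- aboveSupport > 0L || any(expd == 0 & obs > 0)
  chisq <- if (emptyExpected) Inf else sum((obs - expd)^2 / expd)
  df <- max(nSubunits - 2L, 0L)
  dfAlt <- nSubunits - 1L
  if (!pFitted) { tmp <- df; df <- dfAlt; dfAlt <- tmp }
  pv <- function(d) {
    if (!is.finite(chisq)) return(0)
    if (d < 1L) return(NA_real_)   # saturated model: test uninformative
    pchisq(chisq, df = d, lower.tail = FALSE)
  }
  list(chisq = chisq, df = as.integer(df), pValue = pv(df),
       dfAlt = as.integer(dfAlt), pValueAlt = pv(dfAlt),
       expected = expd, observed = setNames(obs, seq_len(nSubunits)),
       emptyExpected = emptyExpected)
}

#' Chi-squared model selection among candidate oligomeric states
#'
#' For each candidate subunit number, fits the per-subunit fluorescence
#' probability by maximum likelihood ([fitP()]) and tests goodness of fit
#' ([gofTest()], with one df subtracted for the fitted probability). A
#' candidate is retained when its p-value is at least `alpha`. All fits are
#' returned, so ambiguity (several candidates retained) is visible rather
#' than silently resolved.
#'
#' @inheritParams fitP
#' @param candidates integer vector of candidate subunit counts; default
#'   `c(4, 5, 6)` (tetramer, pentamer, hexamer).
#' @param alpha significance level in (0, 1); default 0.05.
#' @return A list of [OligomerFit-class], one per candidate, in input order.
#' @examples
#' h <- simulateStepCounts(569, 4, 0.776, seed = 7)
#' fits <- selectOligomer(h)
#' vapply(fits, isRetained, logical(1))
#' @export
selectOligomer <- function(hist, candidates = c(4L, 5L, 6L), alpha = 0.05) {
  stopifnot(is(hist, "StepCountHistogram"))
  if (length(candidates) == 0L) stop("candidate list must be nonempty")
  .assertScalar(alpha, "alpha", 0, 1, strict_lower = TRUE)
  if (alpha >= 1) stop("'alpha' must be < 1")
  lapply(candidates, function(n) {
    p <- fitP(hist, n)
    g <- gofTest(hist, n, p = as.numeric(p), pFitted = TRUE)
    retained <- if (is.na(g$pValue)) NA else g$pValue >= alpha
    new("OligomerFit", nSubunits = as.integer(n), pHat = as.numeric(p),
        chisq = g$chisq, df = g$df, pValue = g$pValue, dfAlt = g$dfAlt,
        pValueAlt = g$pValueAlt, retained = retained,
        degenerate = isTRUE(attr(p, "degenerate")))
  })
}
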