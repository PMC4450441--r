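## ON/OFF state classification, clonal-file coherence, and the
## two-reporter cis-vs-trans memory test.

## Fit a 1- vs 2-component Gaussian mixture to log intensities.
## The population is called bimodal when BIC prefers two components AND
## the fitted components are separated by at least `minSeparation` pooled
## standard deviations AND the modes differ by at least `minFold`-fold in
## intensity. EM happily splits a single Gaussian into two overlapping
## halves or shaves off a narrow tail; the SD guard rejects the former and
## the fold-change guard the latter (ON/OFF silencing contrasts are far
## larger than 2-fold).
.fitBimodal <- function(x, minSeparation = 1, minFold = 2) {
  lx <- log(pmax(x, .Machine$double.eps))
  if (length(unique(lx)) < 2L)
    return(list(bimodal = FALSE, fit = NULL))
  fit <- tryCatch(
    Mclust(lx, G = 1:2, verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || fit$G < 2L)
    return(list(bimodal = FALSE, fit = fit))
  mu <- fit$parameters$mean
  sig2 <- fit$parameters$variance$sigmasq
  if (length(sig2) == 1L) sig2 <- rep(sig2, 2L)
  pooled <- sqrt(sum(fit$parameters$pro * sig2))
  sep <- abs(diff(mu)) >= minSeparation * pooled &&
    abs(diff(mu)) >= log(minFold)
  list(bimodal = sep, fit = fit, mu = mu)
}

#' Classify cells into ON and OFF expression states
#'
#' Fits a two-component Gaussian mixture to log mean intensities and
#' assigns each cell to a component; the component with the larger mean is
#' ON. If the population is not bimodal (model selection prefers one
#' component, or the two fitted components are separated by less than
#' `minSeparation` pooled standard deviation), all cells receive the
#' single state determined by comparing the population median against
#' `fallbackThreshold`.
#'
#' @param intensity numeric vector of per-cell mean intensities (>= 20
#'   cells, one channel at a time).
#' @param fallbackThreshold absolute intensity (a.u.) separating ON from
#'   OFF populations when the distribution is unimodal. Instrument- and
#'   reporter-specific; the default suits the synthetic generator's
#'   intensity scale.
#' @param minSeparation bimodality guard in pooled standard deviations.
#' @param minFold minimum intensity fold change between the two fitted
#'   modes for the population to count as bimodal (default 2).
#' @return data.frame with `state` (`"ON"`/`"OFF"`) and `posterior` (the
#'   mixture posterior of the assigned component; 1 on the unimodal path),
#'   plus attribute `bimodal`.
#' @export
classifyStates <- function(intensity, fallbackThreshold = 10,
                           minSeparation = 1, minFold = 2) {
  if (length(intensity) < 20L)
    stop("classification requires at least 20 cells")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and non-negative")
  fb <- .fitBimodal(intensity, minSeparation, minFold)
  if (fb$bimodal) {
    fit <- fb$fit
    onComp <- which.max(fit$parameters$mean)
    state <- ifelse(fit$classification == onComp, "ON", "OFF")
    post <- fit$z[cbind(seq_along(intensity), fit$classification)]
  } else {
    state <- rep(if (median(intensity) > fallbackThreshold) "ON" else "OFF",
                 length(intensity))
    post <- rep(1, length(intensity))
  }
  out <- data.frame(state = state, posterior = post)
  attr(out, "bimodal") <- fb$bimodal
  out
}

#' Histogram summary with a bimodality flag
#'
#' Bins per-cell mean intensities and reports whether the population is
#' bimodal (two separated mixture components, i.e. coexisting ON and OFF
#' cells) together with the estimated ON fraction.
#'
#' @param intensity numeric vector of per-cell mean intensities (>= 20).
#' @param bins number of histogram bins.
#' @param fallbackThreshold,minSeparation,minFold passed to
#'   [classifyStates()].
#' @return list with `breaks`, `counts`, `mids`, `bimodal` and
#'   `onFraction`.
#' @export
histogramSummary <- function(intensity, bins = 30, fallbackThreshold = 10,
                             minSeparation = 1, minFold = 2) {
  if (length(intensity) < 20L)
    stop("histogram summary requires at least 20 cells")
  h <- graphics::hist(intensity, breaks = bins, plot = FALSE)
  cls <- classifyStates(intensity, fallbackThreshold, minSeparation, minFold)
  list(breaks = h$breaks, counts = h$counts, mids = h$mids,
       bimodal = attr(cls, "bimodal"),
       onFraction = mean(cls$state == "ON"))
}

#' Clonal cell-file coherence of state calls
#'
#' Cells in one file descend from a single stem cell, so under file-level
#' heritable states all cells of a file share a state; disagreement
#' reflects call error (or genuinely non-clonal states). The coherence
#' score is the mean, over files of length >= 2, of the fraction of cells
#' agreeing with their file's majority state; with file-level generative
#' states and i.i.d. call error e its expectation is 1 - e.
#'
#' @param states character vector of `"ON"`/`"OFF"` calls.
#' @param fileIds file assignment per cell.
#' @return list with `files` (per-file length, majority state, agreement
#'   fraction), `runs` (per-file run lengths of consecutive same-state
#'   cells, in cell order) and `coherence`.
#' @export
fileCoherence <- function(states, fileIds) {
  stopifnot(length(states) == length(fileIds),
            all(states %in% c("ON", "OFF")))
  sp <- split(states, fileIds)
  files <- data.frame(
    fileId = names(sp),
    length = lengths(sp),
    majority = vapply(sp, function(s)
      names(which.max(table(factor(s, c("OFF", "ON"))))), ""),
    agreement = vapply(sp, function(s) max(table(s)) / length(s), 1.0),
    row.names = NULL)
  runs <- lapply(sp, function(s) rle(s)$lengths)
  long <- files$length >= 2L
  if (!any(long)) stop("no files of length >= 2")
  list(files = files, runs = runs,
       coherence = mean(files$agreement[long]))
}

#' Two-reporter test of cis versus trans epigenetic memory
#'
#' Under trans memory the expression state is stored in diffusible
#' factors, so every clonal file must be ON/ON or OFF/OFF; mixed-state
#' (ON/OFF or OFF/ON) files can then arise only from per-cell call error.
#' Under cis memory each gene copy stores its own state and mixed files
#' occur at rate 2 p (1 - p). The test statistic is the observed fraction
#' of mixed-state files (file state = per-reporter majority call, ties
#' called ON); its null distribution is obtained by a parametric
#' bootstrap of the trans model: files are drawn ON/ON with the estimated
#' probability and i.i.d. per-cell call errors (estimated from within-file
#' discordance) are applied before re-taking majorities. An exact
#' two-sided binomial test of the ON/OFF vs OFF/ON count symmetry is also
#' reported: cis memory with exchangeable copies predicts equal rates.
#'
#' Both the bootstrap null and the symmetry check are formalisations
#' introduced by this package; they are not classical named tests.
#'
#' @param states1,states2 `"ON"`/`"OFF"` calls for reporter 1 and 2.
#' @param fileIds clonal file assignment per cell.
#' @param B bootstrap replicates.
#' @param seed optional seed for the bootstrap.
#' @return a [CisTransResult].
#' @export
cisTransTest <- function(states1, states2, fileIds, B = 999, seed = NULL) {
  if (missing(states2) || is.null(states2))
    stop("the cis/trans test requires two reporters")
  stopifnot(length(states1) == length(states2),
            length(states1) == length(fileIds),
            all(c(states1, states2) %in% c("ON", "OFF")))
  uf <- unique(fileIds)
  if (length(uf) < 10L) stop("at least 10 files are required")
  if (!is.null(seed)) set.seed(seed)

  s1 <- split(states1 == "ON", fileIds)
  s2 <- split(states2 == "ON", fileIds)
  lens <- lengths(s1)
  nF <- length(lens)
  majority <- function(on) sum(on) * 2L >= length(on)  # tie -> ON
  call1 <- vapply(s1, majority, TRUE)
  call2 <- vapply(s2, majority, TRUE)

  counts <- c(
    on_on = sum(call1 & call2), on_off = sum(call1 & !call2),
    off_on = sum(!call1 & call2), off_off = sum(!call1 & !call2))
  obs <- mean(call1 != call2)

  # per-cell call error: discordance with the own file's majority call
  disc <- c(unlist(s1) != rep(call1, lens), unlist(s2) != rep(call2, lens))
  eHat <- mean(disc)
  pHat <- mean(c(call1, call2))

  # bootstrap of the trans null, vectorised over replicates
  fileOn <- matrix(runif(nF * B) < pHat, nF, B)
  flips1 <- matrix(rbinom(nF * B, lens, eHat), nF, B)
  flips2 <- matrix(rbinom(nF * B, lens, eHat), nF, B)
  simCall <- function(on, flips) {
    nOn <- ifelse(on, lens - flips, flips)
    nOn * 2L >= lens
  }
  mixed <- colMeans(simCall(fileOn, flips1) != simCall(fileOn, flips2))
  pValue <- (1 + sum(mixed >= obs)) / (B + 1)

  nMixed <- counts[["on_off"]] + counts[["off_on"]]
  pSym <- if (nMixed == 0) 1 else
    binom.test(counts[["on_off"]], nMixed, 0.5)$p.value

  new("CisTransResult", counts = as.integer(counts) |>
        stats::setNames(names(counts)),
      statistic = obs, pValue = pValue, pSymmetry = pSym,
      errorRate = eHat, pOn = pHat, nFiles = as.integer(nF),
      nBoot = as.integer(B))
}
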