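#' Specification for synthetic polymer-classification data
#'
#' Describes a balanced k-class dataset with the statistical structure the
#' pipeline assumes, so every stage can be exercised without external
#' downloads. Two modes are supported:
#'
#' * `"fingerprint"`: binary features. Each informative bit is assigned one
#'   signal class (round-robin) and is set with probability `pSignal` in
#'   that class and `pOff` elsewhere; background bits are set with
#'   probability `pBackground` in every class.
#' * `"descriptor"`: continuous physical descriptors. Feature ranges cycle
#'   through typical polymer property ranges (glass transition temperature
#'   -70 to 150 degC, melting point 100 to 350 degC, viscosity 0.01 to 1000 Pa s,
#'   rheology 0.1 to 10 Pa s, elasticity 1 to 10 GPa, Young's modulus 0.5 to
#'   4 GPa, resilient modulus 1 to 5 GPa). Informative features get class
#'   means separated by `effectSize` within-class standard deviations.
#'
#' Missing values are injected completely at random at `missingRate`;
#' outliers (values at +/- 6 column sd, to exercise percentile capping)
#' only in descriptor mode at `outlierRate`.
#'
#' @param nPerClass samples per class (default 6500).
#' @param classes class names (default Plastic, Peptide, Oligosaccharide).
#' @param D number of features (default 2048).
#' @param nInformative number of class-informative features (default 32).
#' @param mode `"fingerprint"` or `"descriptor"`.
#' @param pSignal,pOff,pBackground Bernoulli rates of the fingerprint mode
#'   (defaults 0.8 / 0.2 / 0.1).
#' @param effectSize class-mean separation of the descriptor mode, in
#'   within-class sd units (default 2).
#' @param missingRate,outlierRate injection rates in `[0, 1]` (default 0).
#' @return A list of class `syntheticSpec`.
#' @export
syntheticSpec <- function(nPerClass = 6500L,
                          classes = c("Plastic", "Peptide", "Oligosaccharide"),
                          D = 2048L, nInformative = 32L,
                          mode = c("fingerprint", "descriptor"),
                          pSignal = 0.8, pOff = 0.2, pBackground = 0.1,
                          effectSize = 2, missingRate = 0, outlierRate = 0) {
  mode <- match.arg(mode)
  nPerClass <- as.integer(nPerClass); D <- as.integer(D)
  nInformative <- as.integer(nInformative)
  if (nPerClass < 1L) stop("nPerClass must be >= 1")
  if (length(classes) < 2L) stop("need at least 2 classes")
  if (nInformative > D) stop("nInformative must be <= D")
  for (r in c(missingRate, outlierRate))
    if (r < 0 || r > 1) stop("rates must be in [0, 1]")
  structure(list(nPerClass = nPerClass, classes = classes, D = D,
                 nInformative = nInformative, mode = mode,
                 pSignal = pSignal, pOff = pOff, pBackground = pBackground,
                 effectSize = effectSize, missingRate = missingRate,
                 outlierRate = outlierRate),
            class = "syntheticSpec")
}

# Typical polymer descriptor ranges the continuous mode cycles through.
descriptorRanges <- function() {
  list(glassTransition_C = c(-70, 150),
       meltingPoint_C = c(100, 350),
       viscosity_PaS = c(0.01, 1000),
       rheology_PaS = c(0.1, 10),
       elasticity_GPa = c(1, 10),
       youngsModulus_GPa = c(0.5, 4),
       resilientModulus_GPa = c(1, 5))
}

#' Generate a synthetic labeled feature matrix
#'
#' Draws a balanced dataset according to a [syntheticSpec()] and records
#' which features carry class signal, so feature-selection recovery can be
#' scored against ground truth. Two generations with the same seed are
#' identical.
#'
#' @param spec a [syntheticSpec()].
#' @param seed integer seed.
#' @return list with `fm` (a [FeatureMatrix-class]), `informative`
#'   (1-based indices of the informative features) and `spec`.
#' @examples
#' g <- generateSynthetic(syntheticSpec(nPerClass = 20, D = 30,
#'                                      nInformative = 5), seed = 1)
#' dim(g$fm)
#' @export
generateSynthetic <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "syntheticSpec"))
  k <- length(spec$classes)
  n <- spec$nPerClass * k
  D <- spec$D
  labels <- rep(spec$classes, each = spec$nPerClass)
  informative <- seq_len(spec$nInformative)
  signalClass <- rep_len(seq_len(k), length(informative))
  withLocalSeed(seed, {
    if (spec$mode == "fingerprint") {
      # background everywhere, then overwrite informative columns per class
      X <- matrix(as.numeric(stats::runif(n * D) < spec$pBackground), n, D)
      for (bi in seq_along(informative)) {
        j <- informative[bi]
        for (ci in seq_len(k)) {
          rows <- which(labels == spec$classes[ci])
          p <- if (ci == signalClass[bi]) spec$pSignal else spec$pOff
          X[rows, j] <- as.numeric(stats::runif(length(rows)) < p)
        }
      }
      featNames <- defaultFeatureNames(D)
    } else {
      ranges <- descriptorRanges()
      featNames <- character(D)
      X <- matrix(0, n, D)
      for (j in seq_len(D)) {
        rg <- ranges[[((j - 1L) %% length(ranges)) + 1L]]
        featNames[j] <- sprintf("%s_%03d",
                                names(ranges)[((j - 1L) %% length(ranges)) + 1L],
                                j)
        mid <- mean(rg)
        sdW <- diff(rg) / 10
        mu <- rep(mid, n)
        bi <- match(j, informative)
        if (!is.na(bi)) {
          # informative feature: shift the mean of its signal class only
          mu <- mid + ifelse(match(labels, spec$classes) == signalClass[bi],
                             spec$effectSize * sdW, 0)
        }
        X[, j] <- stats::rnorm(n, mu, sdW)
      }
      if (spec$outlierRate > 0) {
        hit <- which(stats::runif(n * D) < spec$outlierRate)
        if (length(hit)) {
          colIdx <- ((hit - 1L) %/% n) + 1L
          sds <- apply(X, 2L, stats::sd)
          mus <- colMeans(X)
          sign <- ifelse(stats::runif(length(hit)) < 0.5, -1, 1)
          X[hit] <- mus[colIdx] + sign * 6 * sds[colIdx]
        }
      }
    }
    if (spec$missingRate > 0) {
      miss <- stats::runif(n * D) < spec$missingRate
      X[miss] <- NA_real_
    }
    colnames(X) <- featNames
    list(fm = FeatureMatrix(X, labels), informative = informative,
         spec = spec)
  })
}
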