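# Shared small-fixture builders.

# Standardized synthetic fingerprint data ready for model fitting.
makePreprocessed <- function(nPerClass = 50, D = 30, nInformative = 6,
                             seed = 1) {
  g <- generateSynthetic(syntheticSpec(nPerClass = nPerClass, D = D,
                                       nInformative = nInformative),
                         seed = seed)
  s <- fitPreprocessor(g$fm)
  list(fm = applyPreprocessor(g$fm, s), informative = g$informative)
}

randomGruParams <- function(H, Fw, seed) {
  set.seed(seed)
  list(Wr = matrix(rnorm(H * (H + Fw)), H), Wz = matrix(rnorm(H * (H + Fw)), H),
       Wh = matrix(rnorm(H * (H + Fw)), H),
       br = rnorm(H), bz = rnorm(H), bh = rnorm(H))
}
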