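# shared fixtures: small deterministic scene configurations

# noiseless, background-free, single-slice scene: the piecewise-constant
# limit in which segmentation and the ratio are exact
noiselessConfig <- function(enrichment = 1, seed = 5L, ...) {
  sceneConfig(enrichment = enrichment, psfSigma = 0,
              backgroundAmplitude = 0, photonGain = 0,
              readNoiseSigma = 0, nSlices = 1L, seed = seed, ...)
}

# default-SNR config (the study conditions) with a chosen enrichment
snrConfig <- function(enrichment = 1, ...) {
  sceneConfig(enrichment = enrichment, ...)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

rot90mask <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# velocities straight from the Michaelis-Menten equation
mmVelocities <- function(Vmax, Km, s) Vmax * s / (Km + s)
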