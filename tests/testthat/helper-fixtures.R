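# Shared fixtures built in code at test time.

# Paper-style digestion schedule and fitted kinetic parameters used as
# generative truth throughout the tests.
paperTimepoints <- c(0, 2, 5, 10, 15, 20, 30, 50)
nucParams <- list(k = 0.012, a0 = 0.87)
tetParams <- list(k = 0.19, a0 = 1.0)

nucSpec <- function(seed = 1L, noiseSd = 0.02)
  proteolysisSpec("nucleosome", k = nucParams$k, a0 = nucParams$a0,
                  timepoints = paperTimepoints, noiseSd = noiseSd,
                  seed = seed)

tetSpec <- function(seed = 1L, noiseSd = 0.02)
  proteolysisSpec("tetrasome", k = tetParams$k, a0 = tetParams$a0,
                  timepoints = paperTimepoints, noiseSd = noiseSd,
                  seed = seed)

hexSpec <- function(seed = 1L, noiseSd = 0.02)
  proteolysisSpec("hexasome", k = c(nucParams$k, tetParams$k),
                  a0 = c(nucParams$a0, tetParams$a0),
                  weights = c(0.5, 0.5), timepoints = paperTimepoints,
                  noiseSd = noiseSd, seed = seed)

fitFromSpec <- function(spec)
  fitExposureKinetics(fractionFullLength(simulateProteolysis(spec)))

# A minimal hand-built trajectory: coordinates array plus matching topology.
makeTraj <- function(coords, chain = "A", role = "tail",
                     resno = seq_len(dim(coords)[2]), atom = "CA") {
  n <- dim(coords)[2]
  topo <- data.frame(chain = rep(chain, length.out = n),
                     resno = rep(resno, length.out = n),
                     resname = "GLY",
                     atom = rep(atom, length.out = n),
                     heavy = TRUE,
                     role = rep(role, length.out = n))
  new("TailTrajectory", coords = coords, topology = topo, dtPs = 10)
}

# Static trajectory with every frame equal to `xyz` (n x 3).
staticTraj <- function(xyz, nFrames = 2, ...) {
  coords <- array(rep(xyz, each = nFrames), c(nFrames, nrow(xyz), 3))
  makeTraj(coords, ...)
}
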