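# Shared fixtures: everything is generated in code at test time.

# binary scene list from a list of matrices
scenesFrom <- function(mats, pixelSize = 70) {
  lapply(seq_along(mats), function(i)
    presenceScene(mats[[i]], timestamp = sprintf("s%03d", i),
                  pixelSize = pixelSize))
}

# random binary scene stack
randomScenes <- function(nScenes, nr, nc, p = 0.3, seed = 1) {
  set.seed(seed)
  scenesFrom(replicate(nScenes,
                       matrix(as.numeric(runif(nr * nc) < p), nr, nc),
                       simplify = FALSE))
}

# tiny landscape config for fast simulation tests
tinyConfig <- function(...) {
  args <- list(gridWidth = 30, gridHeight = 20, nNights = 4,
               scansPerNight = 10, nPatches = 25, seed = 11,
               roosts = cbind(x = c(500, 1500), y = c(400, 1000)))
  args[names(list(...))] <- list(...)
  do.call(landscapeConfig, args)
}

# degenerate constant trait set: M = EFD*pEA*MDR / max(mu, floor)^2
constantTraits <- function(EFD = 8, pEA = 0.5, MDR = 0.1, mu = 0.2,
                           muFloor = 0.01) {
  abundanceParams(list(EFD = traitCurve("EFD", "constant", EFD),
                       pEA = traitCurve("pEA", "constant", pEA),
                       MDR = traitCurve("MDR", "constant", MDR),
                       mu = traitCurve("mu", "constant", mu)),
                  muFloor = muFloor)
}

# synthetic association-model records with known structure
makeRecords <- function(n, seed, mosquitoEffect = function(m) 0,
                        lightsBeta = 2, riceDelta = 0, noiseSd = 1) {
  set.seed(seed)
  cls <- sample(c("miscellaneous", "rice", "grassland", "urban"),
                n, replace = TRUE)
  m <- runif(n, 0, 10)
  li <- rlnorm(n, 0, 0.5)
  ir <- runif(n, 0, 100)
  data.frame(cell_id = seq_len(n),
             x = runif(n, 0, 50000), y = runif(n, 0, 40000),
             activity = mosquitoEffect(m) + lightsBeta * li +
               riceDelta * (cls == "rice") + rnorm(n, 0, noiseSd),
             mosquito = m, lights = li, irrigated_ha = ir,
             class = cls, stringsAsFactors = FALSE)
}
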