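#' Simulation configuration for synthetic fermentation proteomes
#'
#' The generator emulates a two-batch brewing time course: a first
#' fermentation from a fresh yeast pitch ("B1") and a fermentation after
#' serial repitching ("B15"), the latter followed by sampling of the
#' conditioning tank. Defaults reproduce the study design the package is
#' built around: 17 time points (7 in B1, 10 in B15), duplicate samples,
#' about 2,600 detected proteins with log-normally distributed intensities,
#' within-time-point replicate correlations near 0.89, per-time-point
#' single-replicate dropout of about 368 proteins, four planted temporal
#' trajectory classes, a batch-specific abundance shift, and planted
#' co-regulated complexes.
#'
#' @slot nProteins number of simulated proteins.
#' @slot timePoints data.frame with columns `batch`, `label`, `phase`
#'   (fermentation / post-crash / conditioning), in sampling order.
#' @slot nReplicates replicates per time point.
#' @slot baseLogMean,baseLogSd mean and sd of the per-protein baseline
#'   log2 abundance.
#' @slot replicateNoiseSd sd of per-replicate log2 noise.
#' @slot dropoutRate probability that a detected protein is missing in
#'   exactly one replicate of a time point, in `[0, 1)`.
#' @slot dropoutMode `"mcar"` (abundance-independent, default) or `"mnar"`
#'   (dropout odds tilted toward low-abundance proteins).
#' @slot trajectoryClasses data.frame with columns `shape`
#'   (one of `"early_peak"`, `"monotone_down"`, `"late_rise"`,
#'   `"late_peak"`), `n` (members) and `effect` (log2 units).
#' @slot batchShift list with `n` (proteins), `shift` (log2 offset) and
#'   `batch` (which batch receives it).
#' @slot complexPlan data.frame with one row per planted complex: `size`
#'   and `loading` (share of a latent time-course factor, in `[0, 1]`).
#' @slot trajectorySd sd (log2) of the latent complex time-course factors.
#' @slot meanProteinLength mean simulated protein length (residues).
#' @slot krFrequency combined frequency of lysine + arginine in simulated
#'   sequences; 0.1 gives tryptic peptides of mean length about 10.
#' @slot seed integer seed governing all stochastic draws.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         representation(nProteins = "integer",
                        timePoints = "data.frame",
                        nReplicates = "integer",
                        baseLogMean = "numeric",
                        baseLogSd = "numeric",
                        replicateNoiseSd = "numeric",
                        dropoutRate = "numeric",
                        dropoutMode = "character",
                        trajectoryClasses = "data.frame",
                        batchShift = "list",
                        complexPlan = "data.frame",
                        trajectorySd = "numeric",
                        meanProteinLength = "numeric",
                        krFrequency = "numeric",
                        seed = "integer"))

TRAJECTORY_SHAPES <- c("early_peak", "monotone_down", "late_rise", "late_peak")

setValidity("SimulationConfig", function(object) {
  msg <- character()
  chk <- function(cond, m) if (!isTRUE(cond)) msg <<- c(msg, m)
  chk(object@nProteins >= 1L, "nProteins must be a positive count")
  chk(object@nReplicates >= 1L, "nReplicates must be a positive count")
  chk(all(c("batch", "label", "phase") %in% colnames(object@timePoints)),
      "timePoints needs columns batch, label, phase")
  chk(nrow(object@timePoints) >= 1L, "timePoints must have at least one row")
  chk(object@replicateNoiseSd >= 0, "replicateNoiseSd must be >= 0")
  chk(object@dropoutRate >= 0 && object@dropoutRate < 1,
      "dropoutRate must be in [0, 1)")
  chk(object@dropoutMode %in% c("mcar", "mnar"),
      "dropoutMode must be 'mcar' or 'mnar'")
  tc <- object@trajectoryClasses
  chk(all(c("shape", "n", "effect") %in% colnames(tc)),
      "trajectoryClasses needs columns shape, n, effect")
  if (nrow(tc)) {
    chk(all(tc$shape %in% TRAJECTORY_SHAPES),
        paste0("trajectoryClasses$shape must be one of: ",
               paste(TRAJECTORY_SHAPES, collapse = ", ")))
    chk(all(tc$n >= 1), "trajectoryClasses$n must be positive")
  }
  cp <- object@complexPlan
  chk(all(c("size", "loading") %in% colnames(cp)),
      "complexPlan needs columns size, loading")
  if (nrow(cp)) {
    chk(all(cp$size >= 2), "complexPlan$size must be >= 2")
    chk(all(cp$loading >= 0 & cp$loading <= 1),
        "complexPlan$loading must be in [0, 1]")
  }
  planted <- sum(tc$n) + sum(cp$size) + (object@batchShift$n %||% 0)
  chk(planted <= object@nProteins,
      "planted proteins (trajectory classes + complexes + batch shift) exceed nProteins")
  chk(object@trajectorySd >= 0, "trajectorySd must be >= 0")
  chk(object@krFrequency >= 0 && object@krFrequency < 1,
      "krFrequency must be in [0, 1)")
  chk(object@meanProteinLength >= 20, "meanProteinLength must be >= 20")
  if (length(msg)) msg else TRUE
})

#' Default brewing time-point layout
#'
#' Seven fermentation-tank time points for the fresh-pitch batch and ten for
#' the repitched batch (six fermentation samples, one 24 h post-cold-crash
#' sample, and three conditioning-tank samples), 17 in total.
#'
#' @return data.frame with columns `batch`, `label`, `phase`.
#' @export
defaultTimePoints <- function() {
  rbind(
    data.frame(batch = "B1",
               label = c("6h", "24h", "48h", "72h", "96h", "120h", "24PC"),
               phase = c(rep("fermentation", 6), "post-crash")),
    data.frame(batch = "B15",
               label = c("3h", "24h", "48h", "72h", "96h", "120h", "24PC",
                         "C24", "C48", "C72"),
               phase = c(rep("fermentation", 6), "post-crash",
                         rep("conditioning", 3)))
  )
}

#' @rdname SimulationConfig-class
#' @param nProteins,timePoints,nReplicates,baseLogMean,baseLogSd see slots.
#' @param replicateNoiseSd,dropoutRate,dropoutMode,trajectoryClasses see slots.
#' @param batchShift,complexPlan,trajectorySd,meanProteinLength see slots.
#' @param krFrequency,seed see slots.
#' @return A validated `SimulationConfig`.
#' @examples
#' cfg <- simulationConfig(nProteins = 200, seed = 7)
#' sim <- simulateTimecourse(cfg)
#' sim$experiment
#' @export
simulationConfig <- function(nProteins = 2600L,
                             timePoints = defaultTimePoints(),
                             nReplicates = 2L,
                             baseLogMean = 20,
                             baseLogSd = 2,
                             replicateNoiseSd = 0.7,
                             dropoutRate = 368 / 2600,
                             dropoutMode = c("mcar", "mnar"),
                             trajectoryClasses = data.frame(
                               shape = TRAJECTORY_SHAPES,
                               n = 100L, effect = 2),
                             batchShift = list(n = 50L, shift = 1,
                                               batch = "B15"),
                             complexPlan = data.frame(size = rep(5L, 20),
                                                      loading = 0.9),
                             trajectorySd = 1.5,
                             meanProteinLength = 450,
                             krFrequency = 0.1,
                             seed = 1L) {
  dropoutMode <- match.arg(dropoutMode)
  # NULL disables a planted-structure block
  if (is.null(trajectoryClasses))
    trajectoryClasses <- data.frame(shape = character(0), n = integer(0),
                                    effect = numeric(0))
  if (is.null(batchShift)) batchShift <- list(n = 0L, shift = 0, batch = "")
  if (is.null(complexPlan))
    complexPlan <- data.frame(size = integer(0), loading = numeric(0))
  checkScalarNumber(nProteins, "nProteins", lower = 1, integer = TRUE)
  checkScalarNumber(nReplicates, "nReplicates", lower = 1, integer = TRUE)
  checkScalarNumber(seed, "seed", integer = TRUE)
  cfg <- new("SimulationConfig",
             nProteins = as.integer(nProteins),
             timePoints = timePoints,
             nReplicates = as.integer(nReplicates),
             baseLogMean = baseLogMean,
             baseLogSd = baseLogSd,
             replicateNoiseSd = replicateNoiseSd,
             dropoutRate = dropoutRate,
             dropoutMode = dropoutMode,
             trajectoryClasses = trajectoryClasses,
             batchShift = batchShift,
             complexPlan = complexPlan,
             trajectorySd = trajectorySd,
             meanProteinLength = meanProteinLength,
             krFrequency = krFrequency,
             seed = as.integer(seed))
  validObject(cfg)
  cfg
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: ", object@nProteins, " proteins, ",
      nrow(object@timePoints), " time points x ", object@nReplicates,
      " replicates (seed ", object@seed, ")\n", sep = "")
})

# Archetype trajectory value at batch-relative time t in [0, 1], scaled to
# span [0, 1] over the sampled grid.
trajectoryShape <- function(shape, t) {
  v <- switch(shape,
              early_peak    = exp(-0.5 * ((t - 0.10) / 0.15)^2),
              monotone_down = 1 - t,
              late_rise     = 1 / (1 + exp(-8 * (t - 0.65))),
              late_peak     = exp(-0.5 * ((t - 0.80) / 0.15)^2),
              stop("unknown trajectory shape: ", shape))
  rng <- range(v)
  if (diff(rng) < .Machine$double.eps) return(rep(0, length(t)))
  (v - rng[1]) / diff(rng)
}

# Planted per-protein, per-time-point mean log2 abundance surface.
plantedMeans <- function(config, ids, truth) {
  tp <- config@timePoints
  k <- nrow(tp)
  mu <- matrix(truth$baseline, length(ids), k,
               dimnames = list(ids, paste(tp$batch, tp$label, sep = ":")))
  # batch-relative normalized time
  tnorm <- numeric(k)
  for (b in unique(tp$batch)) {
    idx <- which(tp$batch == b)
    nb <- length(idx)
    tnorm[idx] <- if (nb == 1) 0.5 else (seq_along(idx) - 1) / (nb - 1)
  }
  tc <- config@trajectoryClasses
  for (i in seq_len(nrow(tc))) {
    members <- names(truth$trajectoryClass)[
      which(truth$trajectoryClass == tc$shape[i])]
    if (!length(members)) next
    for (b in unique(tp$batch)) {
      idx <- which(tp$batch == b)
      prof <- trajectoryShape(tc$shape[i], tnorm[idx]) * tc$effect[i]
      mu[members, idx] <- mu[members, idx] +
        matrix(prof, length(members), length(idx), byrow = TRUE)
    }
  }
  if (length(truth$batchShift))
    mu[truth$batchShift, tp$batch == config@batchShift$batch] <-
      mu[truth$batchShift, tp$batch == config@batchShift$batch] +
      config@batchShift$shift
  # complex members share a latent time-course factor
  if (length(truth$complexes)) {
    cp <- config@complexPlan
    for (ci in seq_along(truth$complexes)) {
      members <- truth$complexes[[ci]]
      lambda <- cp$loading[ci]
      f <- truth$complexFactors[[ci]]
      g <- truth$memberFactors[[ci]]
      for (mi in seq_along(members))
        mu[members[mi], ] <- mu[members[mi], ] +
          lambda * f + sqrt(1 - lambda^2) * g[mi, ]
    }
  }
  mu
}

#' Simulate a fermentation proteomics time course
#'
#' Draws a protein-by-sample intensity matrix with known ground truth.
#' Intensities are generated as `2^(baseline + trajectory effect +
#' batch shift + complex factor + replicate noise)`; all structure and noise
#' is additive in log2 space, matching the log-normal behaviour of
#' label-free quantification. Dropout marks a value missing (`NA`, never
#' zero) in exactly one replicate of a time point.
#'
#' @param config a [simulationConfig()].
#' @return list with elements
#'   \describe{
#'     \item{experiment}{an [AbundanceExperiment] (state `"raw"`) with
#'       `rowData(x)$uniquePeptides` simulated detection metadata,}
#'     \item{truth}{ground-truth list: `trajectoryClass` (named vector, `NA`
#'       for unplanted), `batchShift` (ids), `complexes` (named list of
#'       member ids), `plantedLog2` (proteins x time points matrix of true
#'       mean log2 abundance), `baseline`.}
#'   }
#' @seealso [trueDeps()] for the planted differential set of a time-point
#'   pair.
#' @export
simulateTimecourse <- function(config) {
  stopIfNot(is(config, "SimulationConfig"), "config must be a SimulationConfig")
  validObject(config)
  withSeed(config@seed, {
    n <- config@nProteins
    ids <- sprintf("P%04d", seq_len(n))
    tp <- config@timePoints
    k <- nrow(tp)

    # assign planted roles over disjoint protein sets
    tc <- config@trajectoryClasses
    pool <- ids
    trajClass <- setNames(rep(NA_character_, n), ids)
    for (i in seq_len(nrow(tc))) {
      members <- pool[seq_len(tc$n[i])]
      pool <- setdiff(pool, members)
      trajClass[members] <- tc$shape[i]
    }
    shiftIds <- character()
    if ((config@batchShift$n %||% 0) > 0) {
      shiftIds <- pool[seq_len(config@batchShift$n)]
      pool <- setdiff(pool, shiftIds)
    }
    cp <- config@complexPlan
    complexes <- list()
    for (i in seq_len(nrow(cp))) {
      members <- pool[seq_len(cp$size[i])]
      pool <- setdiff(pool, members)
      complexes[[sprintf("CPX%03d", i)]] <- members
    }

    truth <- list(
      trajectoryClass = trajClass,
      batchShift = shiftIds,
      complexes = complexes,
      baseline = setNames(rnorm(n, config@baseLogMean, config@baseLogSd), ids),
      complexFactors = lapply(seq_len(nrow(cp)), function(i)
        rnorm(k, 0, config@trajectorySd)),
      memberFactors = lapply(seq_len(nrow(cp)), function(i)
        matrix(rnorm(cp$size[i] * k, 0, config@trajectorySd), cp$size[i], k))
    )
    mu <- plantedMeans(config, ids, truth)
    truth$plantedLog2 <- mu
    truth$complexFactors <- NULL
    truth$memberFactors <- NULL

    nrep <- config@nReplicates
    sampleId <- paste(rep(paste(tp$batch, tp$label, sep = ":"), each = nrep),
                      paste0("r", rep(seq_len(nrep), k)), sep = ":")
    logAb <- mu[, rep(seq_len(k), each = nrep), drop = FALSE] +
      matrix(rnorm(n * k * nrep, 0, config@replicateNoiseSd), n, k * nrep)
    colnames(logAb) <- sampleId

    # dropout: with prob dropoutRate a (protein, time point) loses one
    # replicate chosen at random
    if (config@dropoutRate > 0 && nrep >= 2) {
      for (j in seq_len(k)) {
        w <- if (config@dropoutMode == "mnar") {
          z <- (mu[, j] - mean(mu[, j])) / max(sd(mu[, j]), 1e-9)
          pmin(1, config@dropoutRate * exp(-z) / mean(exp(-z)))
        } else rep(config@dropoutRate, n)
        hit <- runif(n) < w
        whichRep <- sample.int(nrep, n, replace = TRUE)
        cols <- (j - 1L) * nrep + whichRep
        logAb[cbind(which(hit), cols[hit])] <- NA
      }
    }

    cd <- data.frame(batch = rep(tp$batch, each = nrep),
                     timePoint = rep(tp$label, each = nrep),
                     phase = rep(tp$phase, each = nrep),
                     replicate = rep(seq_len(nrep), k),
                     row.names = sampleId)
    se <- AbundanceExperiment(2^logAb, cd, state = "raw",
                              uniquePeptides = 1L + rpois(n, 7))
    rownames(se) <- ids
    list(experiment = se, truth = truth)
  })
}

#' Planted differential proteins for a pair of time points
#'
#' @param truth ground-truth list from [simulateTimecourse()].
#' @param groupA,groupB time-point keys (`"batch:label"`, columns of
#'   `truth$plantedLog2`).
#' @param threshold minimum absolute planted log2 difference (default 1).
#' @return Character vector of protein ids whose planted mean log2
#'   abundance differs by at least `threshold` between the two time points.
#' @export
trueDeps <- function(truth, groupA, groupB, threshold = 1) {
  m <- truth$plantedLog2
  stopIfNot(all(c(groupA, groupB) %in% colnames(m)),
            "unknown time-point key(s)")
  d <- m[, groupA] - m[, groupB]
  rownames(m)[abs(d) >= threshold]
}

#' Simulate protein sequences
#'
#' Random sequences over the 20 standard amino acids with a controllable
#' combined lysine+arginine frequency, so that in-silico tryptic digests
#' have peptides in the detectable 7-40 residue range. With the default
#' frequency of 0.1 the cleavage-site spacing is geometric with mean about
#' 10 residues.
#'
#' @param config a [simulationConfig()]; uses `nProteins`,
#'   `meanProteinLength`, `krFrequency` and `seed`.
#' @return A [Biostrings::AAStringSet] named by protein id.
#' @importFrom Biostrings AAStringSet
#' @export
simulateProteinFasta <- function(config) {
  stopIfNot(is(config, "SimulationConfig"), "config must be a SimulationConfig")
  validObject(config)
  withSeed(config@seed + 104729L, {  # offset stream: sequences are drawn
    n <- config@nProteins            # independently of abundances
    kr <- config@krFrequency
    other <- setdiff(AA_STANDARD, c("K", "R"))
    probs <- setNames(rep((1 - kr) / length(other), length(AA_STANDARD)),
                      AA_STANDARD)
    probs[c("K", "R")] <- kr / 2
    lens <- pmax(30L, as.integer(round(rnorm(n, config@meanProteinLength,
                                             config@meanProteinLength / 5))))
    seqs <- vapply(lens, function(L)
      paste(sample(AA_STANDARD, L, replace = TRUE, prob = probs),
            collapse = ""), character(1))
    AAStringSet(setNames(seqs, sprintf("P%04d", seq_len(n))))
  })
}

#' Simulate a peptide-spectrum-match count matrix
#'
#' Inverse model of the ppm quantification: per sample, `depth` PSM events
#' are drawn multinomially over proteins with probabilities proportional to
#' abundance x detectable length (longer proteins present more detectable
#' peptides, so accrue proportionally more spectra).
#'
#' @param abundance numeric matrix of true (exp-scale) abundances,
#'   proteins x samples.
#' @param detectableLength named numeric vector: per-protein sum of in-range
#'   tryptic peptide lengths (see [detectableLengths()]).
#' @param depth total PSMs per sample.
#' @param seed integer seed.
#' @return Integer matrix of PSM counts with `colSums` equal to `depth`.
#'   Proteins with zero detectable length and non-zero abundance are
#'   excluded from sampling with a warning (their rows are all zero).
#' @export
simulatePsmCounts <- function(abundance, detectableLength, depth,
                              seed = 1L) {
  checkScalarNumber(depth, "depth", lower = 1, integer = TRUE)
  stopIfNot(is.matrix(abundance) && !is.null(rownames(abundance)),
            "abundance must be a matrix with protein-id rownames")
  stopIfNot(all(rownames(abundance) %in% names(detectableLength)),
            "detectableLength must cover all proteins in 'abundance'")
  dl <- detectableLength[rownames(abundance)]
  bad <- dl <= 0 & rowSums(abundance, na.rm = TRUE) > 0
  if (any(bad))
    warning(sum(bad), " protein(s) with zero detectable length excluded ",
            "from PSM sampling")
  withSeed(seed, {
    counts <- matrix(0L, nrow(abundance), ncol(abundance),
                     dimnames = dimnames(abundance))
    for (j in seq_len(ncol(abundance))) {
      w <- abundance[, j] * dl
      w[is.na(w) | dl <= 0] <- 0
      stopIfNot(sum(w) > 0, "sample with zero total sampling weight")
      counts[, j] <- rmultinom(1, depth, w)[, 1]
    }
    counts
  })
}
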