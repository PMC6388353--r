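## Online iterative learning: train, scan, accept, augment, repeat until the
## number of new discoveries is negligible.

#' Create the initial bootstrap state
#'
#' @param training Seed training sequences: an `AAStringSet`, a named
#'   character vector, or a FASTA path whose headers carry `locus=<LABEL>`
#'   tags (see [readLabeledFasta()]).
#' @param loci Character vector of locus labels parallel to `training`
#'   (ignored when `training` is a FASTA path with locus tags).
#' @return An [IterationState-class] at `t = 0` with empty discoveries.
#' @export
newIterationState <- function(training, loci = NULL) {
  if (is.character(training) && length(training) == 1L && file.exists(training)) {
    lab <- readLabeledFasta(training)
    training <- lab$sequences
    loci <- lab$locus
  }
  if (is.character(training)) {
    training <- Biostrings::AAStringSet(training)
  }
  stopifnot(is(training, "AAStringSet"), !is.null(loci),
            length(loci) == length(training))
  if (is.null(names(training)) || anyDuplicated(names(training))) {
    names(training) <- sprintf("seed_%04d", seq_along(training))
  }
  new("IterationState",
      t = 0L, training = training, locus = as.character(loci),
      discoveries = .emptyDiscoveries(), nAccepted = 0L, nRejected = 0L,
      scoreSamples = stats::setNames(vector("list", length(lociLabels())),
                                     lociLabels()))
}

.emptyDiscoveries <- function() {
  data.frame(aa = character(0), locus = character(0), score = numeric(0),
             mr_score = numeric(0), genome = character(0),
             contig = character(0), start = integer(0), end = integer(0),
             strand = character(0), stringsAsFactors = FALSE)
}

#' Run one bootstrap iteration
#'
#' Trains a [LocusModelSet-class] from the current training set, scans every
#' genome (chunked scan, per-candidate profiles, maximum-likelihood overlap
#' resolution), and collects the accepted candidates whose amino-acid
#' sequence is not already in the training set (exact-match deduplication,
#' also within the iteration's own discoveries).  Returns the state for
#' `t + 1` with the training set augmented by the discoveries.
#'
#' @param state An [IterationState-class].
#' @param genomes List of FASTA paths and/or named `DNAStringSet`s.
#' @param config A [vexConfig()].
#' @return The next [IterationState-class].  Its `discoveries` slot holds
#'   this iteration's newly accepted exons.
#' @export
runIteration <- function(state, genomes, config = vexConfig()) {
  stopifnot(is(state, "IterationState"), length(state@training) > 0L)
  if (!is.list(genomes)) genomes <- as.list(genomes)
  for (g in genomes) {
    if (is.character(g) && !file.exists(g)) {
      stop("genome file unreadable: ", g)
    }
  }
  mats <- buildTrainingMatrices(as.character(state@training), state@locus,
                                config, iter = state@t)
  models <- trainLocusModels(mats, config, iter = state@t)

  disc <- .emptyDiscoveries()
  nAcc <- 0L
  nRej <- 0L
  scores <- stats::setNames(vector("list", length(lociLabels())), lociLabels())
  known <- as.character(state@training)
  for (gi in seq_along(genomes)) {
    g <- genomes[[gi]]
    gname <- if (is.character(g)) basename(g) else
      names(genomes)[gi] %||% paste0("genome", gi)
    cand <- scanGenome(g, config)
    if (length(cand) == 0L) next
    prof <- assignLoci(predictProfiles(S4Vectors::mcols(cand)$aa, models), config)
    res <- resolveOverlaps(cand, prof)
    nAcc <- nAcc + length(res)
    nRej <- nRej + (length(cand) - length(res))
    if (length(res) == 0L) next
    for (k in unique(S4Vectors::mcols(res)$locus)) {
      scores[[k]] <- c(scores[[k]],
                       S4Vectors::mcols(res)$score[S4Vectors::mcols(res)$locus == k])
    }
    newRows <- data.frame(
      aa = S4Vectors::mcols(res)$aa, locus = S4Vectors::mcols(res)$locus,
      score = S4Vectors::mcols(res)$score,
      mr_score = S4Vectors::mcols(res)$mr_score,
      genome = gname,
      contig = as.character(GenomicRanges::seqnames(res)),
      start = GenomicRanges::start(res) - 1L,   # 0-based half-open
      end = GenomicRanges::end(res),
      strand = as.character(GenomicRanges::strand(res)),
      stringsAsFactors = FALSE)
    fresh <- !(newRows$aa %in% known)
    newRows <- newRows[fresh, , drop = FALSE]
    known <- c(known, newRows$aa)   # dedup across genomes and within iteration
    disc <- rbind(disc, newRows)
  }

  newTraining <- state@training
  newLoci <- state@locus
  if (nrow(disc) > 0L) {
    add <- Biostrings::AAStringSet(disc$aa)
    names(add) <- sprintf("it%d_d%04d", state@t + 1L, seq_len(nrow(disc)))
    newTraining <- c(newTraining, add)
    newLoci <- c(newLoci, disc$locus)
  }
  new("IterationState",
      t = state@t + 1L, training = newTraining, locus = newLoci,
      discoveries = disc, nAccepted = nAcc, nRejected = nRej,
      scoreSamples = scores)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1L])) b else a

#' Convergence test for the bootstrap loop
#'
#' The loop has converged when the latest iteration's discoveries are fewer
#' than `minNewFraction` of the training set they were added to, or when
#' `maxIterations` iterations have run.
#'
#' @param history Non-empty list of [IterationState-class], in order.
#' @param minNewFraction,maxIterations Convergence rule (defaults 0.01, 10).
#' @return Logical scalar.
#' @export
isConverged <- function(history, minNewFraction = 0.01, maxIterations = 10L) {
  stopifnot(length(history) > 0L)
  last <- history[[length(history)]]
  if (last@t == 0L) return(FALSE)  # nothing run yet
  nNew <- nrow(last@discoveries)
  nPrev <- length(last@training) - nNew
  (nNew / nPrev < minNewFraction) || (last@t >= maxIterations)
}

#' Run the full bootstrap loop
#'
#' Repeats [runIteration()] until [isConverged()].  Ensembles are retrained
#' from scratch each iteration, so the result depends only on the training
#' set, not on iteration history.  When `outDir` is given, each iteration
#' writes its discoveries (FASTA + annotation TSV) and the run writes the
#' final models, the iteration report and the effective configuration.
#'
#' @param genomes List of FASTA paths and/or named `DNAStringSet`s.
#' @param training,loci Seed training set (see [newIterationState()]).
#' @param config A [vexConfig()]; supplies the convergence rule and seed.
#' @param outDir Optional output directory.
#' @param verbose Print one line per iteration.
#' @return List with `history` (list of [IterationState-class]), `models`
#'   (final [LocusModelSet-class]) and `report` (the [iterationReport()]).
#' @export
runBootstrap <- function(genomes, training, loci = NULL,
                         config = vexConfig(), outDir = NULL,
                         verbose = FALSE) {
  state <- if (is(training, "IterationState")) training else
    newIterationState(training, loci)
  if (!is.null(outDir) && !dir.exists(outDir)) {
    dir.create(outDir, recursive = TRUE)
  }
  history <- list()
  repeat {
    t0 <- Sys.time()
    state <- runIteration(state, genomes, config)
    history <- c(history, state)
    if (verbose) {
      message(sprintf("[bootstrap] t=%d accepted=%d new=%d training=%d (%.1fs)",
                      state@t, state@nAccepted, nrow(state@discoveries),
                      length(state@training),
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
    if (!is.null(outDir)) .writeIterationOutputs(state, outDir)
    if (isConverged(history, config$minNewFraction, config$maxIterations)) break
  }
  ## final models reflect the converged training set
  mats <- buildTrainingMatrices(as.character(state@training), state@locus,
                                config, iter = state@t)
  models <- trainLocusModels(mats, config, iter = state@t)
  rep <- iterationReport(history)
  if (!is.null(outDir)) {
    saveLocusModels(models, file.path(outDir, "models.rds"))
    utils::write.table(rep, file.path(outDir, "iteration_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeConfig(config, file.path(outDir, "config.json"))
  }
  list(history = history, models = models, report = rep)
}

.writeIterationOutputs <- function(state, outDir) {
  d <- state@discoveries
  fa <- Biostrings::AAStringSet(d$aa)
  names(fa) <- sprintf("it%d_d%04d locus=%s score=%.6f", state@t,
                       seq_len(nrow(d)), d$locus, d$score)
  Biostrings::writeXStringSet(fa,
    file.path(outDir, sprintf("discoveries_it%02d.fasta", state@t)))
  utils::write.table(d[, c("contig", "start", "end", "strand", "locus",
                           "score", "mr_score", "genome", "aa")],
                     file.path(outDir, sprintf("discoveries_it%02d.tsv", state@t)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Gaussian kernel density of classifier scores on \[0, 1\]
#'
#' Kernel density with reflection at both boundaries, evaluated on a fixed
#' 256-point grid over \[0, 1\]; the reflection keeps all probability mass
#' inside the score range, so the trapezoid integral is 1 to within 1e-3.
#'
#' @param scores Numeric vector of scores in \[0, 1\]; needs at least 2.
#' @param bandwidth Kernel bandwidth; default is Silverman's rule
#'   (`stats::bw.nrd0`).
#' @return `data.frame` with columns `x` (grid) and `y` (density); empty
#'   (with a warning) if fewer than 2 scores.
#' @export
scoreDensity <- function(scores, bandwidth = NULL) {
  if (length(scores) < 2L) {
    warning("need at least 2 scores for a density estimate")
    return(data.frame(x = numeric(0), y = numeric(0)))
  }
  h <- if (is.null(bandwidth)) stats::bw.nrd0(scores) else bandwidth
  if (h <= 0 || stats::sd(scores) == 0) h <- 0.01  # point mass smoothing
  grid <- seq(0, 1, length.out = 256L)
  y <- vapply(grid, function(g) {
    mean(stats::dnorm(g, mean = scores, sd = h) +
         stats::dnorm(g, mean = -scores, sd = h) +        # reflect at 0
         stats::dnorm(g, mean = 2 - scores, sd = h))      # reflect at 1
  }, numeric(1))
  data.frame(x = grid, y = y)
}

#' Per-iteration bootstrap report
#'
#' @param history List of [IterationState-class] from [runBootstrap()].
#' @return `data.frame` with one row per iteration: `t`, cumulative training
#'   size `n_training`, discoveries `n_discovered`, `n_accepted`,
#'   `n_rejected`, and per-locus cumulative training counts.
#' @export
iterationReport <- function(history) {
  stopifnot(length(history) > 0L)
  rows <- lapply(history, function(s) {
    perLocus <- table(factor(s@locus, levels = lociLabels()))
    cbind(data.frame(t = s@t, n_training = length(s@training),
                     n_discovered = nrow(s@discoveries),
                     n_accepted = s@nAccepted, n_rejected = s@nRejected),
          as.data.frame(as.list(perLocus)))
  })
  do.call(rbind, rows)
}
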