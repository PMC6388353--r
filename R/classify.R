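## Per-locus, per-node binary Random Forest classification of candidate
## V-exons, with multiresolution consistency criteria and maximum-likelihood
## locus assignment.

## Subsequence of node (given by name "i.j") without building the full tree.
.nodeSubseq <- function(aa, nodeName) {
  i <- .nodeLevel(nodeName)
  j <- as.integer(sub("^.*\\.", "", nodeName))
  lo <- 1L
  hi <- nchar(aa)
  if (i > 0L) for (lv in seq_len(i)) {
    cut <- lo + ceiling((hi - lo + 1L) / 2) - 1L
    takeRight <- bitwAnd(bitwShiftR(j, i - lv), 1L) == 1L
    if (takeRight) lo <- cut + 1L else hi <- cut
  }
  substring(aa, lo, hi)
}

.shuffleResidues <- function(aa) {
  paste(sample(.splitChars(aa)), collapse = "")
}

#' Build per-locus, per-node binary training matrices
#'
#' For every locus and every multiresolution node, signal rows are the
#' featurized node subsequences of that locus's positives; background rows
#' are featurized node subsequences of residue-shuffled positives (a fresh
#' shuffle per node, preserving composition while destroying order) at one
#' background row per `ratio` signal rows (rounded up).  Row order is
#' shuffled.  All randomness derives from the config's master seed, the
#' iteration index and the (locus, node) identity, so matrices are
#' reproducible.
#'
#' @param positives Character vector of amino-acid sequences.
#' @param loci Character vector parallel to `positives` with labels from
#'   [lociLabels()].
#' @param config A [vexConfig()].
#' @param iter Iteration index mixed into the derived seeds (default 0).
#' @param table Property table for PDT featurization (defaults internally).
#' @return Nested list: `matrices[[locus]][[node]]` is a list with `x`
#'   (feature matrix) and `y` (factor `signal`/`background`).
#' @export
buildTrainingMatrices <- function(positives, loci, config = vexConfig(),
                                  iter = 0L, table = NULL) {
  stopifnot(length(positives) == length(loci),
            all(loci %in% lociLabels()))
  lm <- .levelMap(config)
  needsPdt <- any(vapply(lm, function(x) x$kind == "pdt", logical(1)))
  if (needsPdt && is.null(table)) table <- defaultPropertyTable()
  nodeNms <- .nodeNames(config$depth)
  presentLoci <- lociLabels()[lociLabels() %in% loci]
  skipped <- setdiff(lociLabels(), presentLoci)
  if (length(skipped)) {
    warning("no training positives for loci: ", paste(skipped, collapse = ", "),
            "; skipped")
  }
  featOne <- function(aa, nodeName) {
    spec <- lm[[as.character(.nodeLevel(nodeName))]]
    sub <- .nodeSubseq(aa, nodeName)
    if (spec$kind == "aa_pairs") aaPairTransform(sub)
    else pdtTransform(sub, lam = spec$lam, table = table)
  }
  out <- list()
  for (k in presentLoci) {
    pos <- positives[loci == k]
    if (length(pos) < 2L) stop("need >= 2 positives for locus ", k)
    sig <- .featurizeSet(pos, config, table = table)
    nBg <- as.integer(ceiling(length(pos) / config$ratio))
    mats <- list()
    for (nm in nodeNms) {
      set.seed(.deriveSeed(config$seed, "bg", iter, k, nm))
      bgSrc <- pos[sample.int(length(pos), nBg)]
      bgRows <- do.call(rbind, lapply(bgSrc, function(aa) {
        if (config$backgroundMode == "shuffle") {
          featOne(.shuffleResidues(aa), nm)
        } else {
          featOne(paste(sample(.AA20, nchar(aa), replace = TRUE), collapse = ""), nm)
        }
      }))
      x <- rbind(sig[[nm]], bgRows)
      y <- factor(rep(c("signal", "background"), c(length(pos), nBg)),
                  levels = c("background", "signal"))
      perm <- sample.int(nrow(x))
      mats[[nm]] <- list(x = x[perm, , drop = FALSE], y = y[perm])
    }
    out[[k]] <- mats
  }
  out
}

#' Train the per-locus, per-node Random Forest ensembles
#'
#' Fits one probability forest per (locus, node) training matrix.  The
#' returned model set carries the full featurization manifest (transform
#' configuration, AAindex accession selection, locus and node order, seed)
#' so prediction re-featurizes candidates identically; it serializes with
#' [saveLocusModels()] and reloads bit-compatibly.
#'
#' @param matrices Output of [buildTrainingMatrices()].
#' @param config The same [vexConfig()] used to build the matrices.
#' @param iter Iteration index mixed into the per-ensemble seeds.
#' @param table Property table used for featurization (for the manifest).
#' @return A [LocusModelSet-class].
#' @export
trainLocusModels <- function(matrices, config = vexConfig(), iter = 0L,
                             table = NULL) {
  lm <- .levelMap(config)
  needsPdt <- any(vapply(lm, function(x) x$kind == "pdt", logical(1)))
  if (needsPdt && is.null(table)) table <- defaultPropertyTable()
  loci <- names(matrices)
  nodeNms <- .nodeNames(config$depth)
  models <- list()
  featLen <- integer(0)
  for (k in loci) {
    for (nm in nodeNms) {
      m <- matrices[[k]][[nm]]
      if (length(unique(m$y)) < 2L) {
        stop("degenerate training matrix (single class) for ", k, " node ", nm)
      }
      fit <- ranger::ranger(
        x = m$x, y = m$y,
        num.trees = config$nTrees, probability = TRUE,
        seed = .deriveSeed(config$seed, "rf", iter, k, nm),
        num.threads = 1L, verbose = FALSE)
      models[[paste0(k, "|", nm)]] <- fit
      featLen[nm] <- ncol(m$x)
    }
  }
  manifest <- list(
    loci = loci, nodes = nodeNms, featureLengths = featLen,
    propertyAccessions = if (needsPdt) table$accessions else character(0))
  new("LocusModelSet", models = models, config = unclass(config),
      manifest = manifest, seed = config$seed)
}

#' Save / load a trained model set
#'
#' @param models A [LocusModelSet-class].
#' @param path File path for the model archive.
#' @return `saveLocusModels` returns `path` invisibly; `readLocusModels`
#'   returns the restored [LocusModelSet-class].
#' @export
saveLocusModels <- function(models, path) {
  stopifnot(is(models, "LocusModelSet"))
  saveRDS(models, path)
  invisible(path)
}

#' @rdname saveLocusModels
#' @export
readLocusModels <- function(path) {
  m <- readRDS(path)
  if (!is(m, "LocusModelSet")) stop("not a LocusModelSet archive: ", path)
  validObject(m)
  m
}

#' Predict per-node, per-locus probability profiles
#'
#' Featurizes each candidate sequence exactly as at training time and runs
#' every (locus, node) ensemble, collecting signal-class probabilities.
#' The per-locus combined statistic is the arithmetic mean over nodes (or
#' geometric mean if configured).  Locus assignment and acceptance are left
#' to [assignLoci()].
#'
#' @param aaSeqs Character vector of candidate amino-acid sequences.
#' @param models A [LocusModelSet-class].
#' @return A [PredictionProfileSet-class] with `assigned` still `NA`.
#' @export
predictProfiles <- function(aaSeqs, models) {
  stopifnot(is(models, "LocusModelSet"))
  cfg <- models@config
  class(cfg) <- "VexConfig"
  loci <- models@manifest$loci
  nodeNms <- models@manifest$nodes
  cols <- as.vector(t(outer(loci, nodeNms, function(k, n) paste0(k, "|", n))))
  n <- length(aaSeqs)
  probs <- matrix(NA_real_, nrow = n, ncol = length(cols),
                  dimnames = list(NULL, cols))
  if (n > 0L) {
    table <- if (length(models@manifest$propertyAccessions)) {
      tb <- defaultPropertyTable(length(models@manifest$propertyAccessions))
      if (!identical(tb$accessions, models@manifest$propertyAccessions)) {
        stop("AAindex property selection differs from the model manifest")
      }
      tb
    } else NULL
    feats <- .featurizeSet(aaSeqs, cfg, table = table)
    for (nm in nodeNms) {
      if (ncol(feats[[nm]]) != models@manifest$featureLengths[[nm]]) {
        stop("feature length mismatch at node ", nm, ": got ",
             ncol(feats[[nm]]), ", model expects ",
             models@manifest$featureLengths[[nm]])
      }
      for (k in loci) {
        pred <- stats::predict(models@models[[paste0(k, "|", nm)]],
                               data = feats[[nm]], num.threads = 1L)
        probs[, paste0(k, "|", nm)] <- pred$predictions[, "signal"]
      }
    }
  }
  combined <- .combineProbs(probs, loci, nodeNms, cfg$combineMethod)
  new("PredictionProfileSet",
      probs = probs, combined = combined,
      assigned = rep(NA_character_, n), accepted = rep(FALSE, n),
      mrScore = rep(NA_real_, n), ambiguous = rep(FALSE, n),
      loci = loci, nodes = nodeNms)
}

.combineProbs <- function(probs, loci, nodeNms, method = "mean") {
  combined <- matrix(NA_real_, nrow = nrow(probs), ncol = length(loci),
                     dimnames = list(NULL, loci))
  for (k in loci) {
    sub <- probs[, paste0(k, "|", nodeNms), drop = FALSE]
    combined[, k] <- if (method == "geometric") {
      exp(rowMeans(log(pmax(sub, 1e-12))))
    } else {
      rowMeans(sub)
    }
  }
  combined
}

#' Adjacent-level consistency criterion
#'
#' For the given locus, checks that the probability of every node differs
#' from each of its children by less than `eps` -- i.e., the sequence looks
#' homologous at every scale, not just on average.
#'
#' @param profiles A [PredictionProfileSet-class].
#' @param locus Locus label (scalar, recycled) or vector per candidate.
#' @param eps Consistency threshold (default 0.17).
#' @return Logical vector, one value per candidate.
#' @export
consistencyOk <- function(profiles, locus, eps = 0.17) {
  stopifnot(is(profiles, "PredictionProfileSet"))
  d <- max(.nodeLevel(profiles@nodes))
  n <- nrow(profiles@probs)
  locus <- rep_len(locus, n)
  ok <- rep(TRUE, n)
  if (d == 0L || n == 0L) return(ok)
  for (i in 0:(d - 1L)) for (j in 0:(2^i - 1L)) {
    for (child in c(2L * j, 2L * j + 1L)) {
      pp <- profiles@probs[cbind(seq_len(n),
        match(paste0(locus, "|", .nodeName(i, j)), colnames(profiles@probs)))]
      pc <- profiles@probs[cbind(seq_len(n),
        match(paste0(locus, "|", .nodeName(i + 1L, child)), colnames(profiles@probs)))]
      ok <- ok & (abs(pp - pc) < eps)
    }
  }
  ok
}

#' Terminal-subsequence criterion
#'
#' The signal probabilities of the left-most and right-most nodes of the
#' deepest level must both exceed `tau`, guaranteeing that the candidate's
#' boundaries -- where the splice acceptor and the recombination signal
#' sequence sit -- look V-like, not just its middle.
#'
#' @inheritParams consistencyOk
#' @param tau Threshold (default 0.7).
#' @return Logical vector per candidate.
#' @export
terminalOk <- function(profiles, locus, tau = 0.7) {
  stopifnot(is(profiles, "PredictionProfileSet"))
  d <- max(.nodeLevel(profiles@nodes))
  n <- nrow(profiles@probs)
  locus <- rep_len(locus, n)
  if (d == 0L) {
    warning("depth-0 decomposition: terminal criterion is vacuously true")
    return(rep(TRUE, n))
  }
  left <- .nodeName(d, 0L)
  right <- .nodeName(d, 2L^d - 1L)
  pl <- profiles@probs[cbind(seq_len(n),
    match(paste0(locus, "|", left), colnames(profiles@probs)))]
  pr <- profiles@probs[cbind(seq_len(n),
    match(paste0(locus, "|", right), colnames(profiles@probs)))]
  (pl > tau) & (pr > tau)
}

#' Multiresolution consistency score
#'
#' \deqn{s = \frac{N-1}{N}\sum_{(k,m)\neq(0,0)}
#'        \left(1 - e^{|p_{00}-p_{km}|^2/\sigma}\right)}
#' where \eqn{N} is the number of nodes.  The score is 0 when every node
#' probability equals the root probability and strictly decreases as any
#' node deviates; it ranks candidates by cross-scale homogeneity.  With
#' `sign = "negative"` the exponent is negated (scores in \eqn{[0, N-1]},
#' larger-deviation terms approaching 1).
#'
#' @inheritParams consistencyOk
#' @param sigma Width parameter (> 0), default 0.05.
#' @param sign `"as_printed"` (default) or `"negative"`.
#' @return Numeric vector per candidate.
#' @export
mrConsistencyScore <- function(profiles, locus, sigma = 0.05,
                               sign = c("as_printed", "negative")) {
  stopifnot(is(profiles, "PredictionProfileSet"))
  sign <- match.arg(sign)
  if (sigma <= 0) stop("sigma must be > 0")
  n <- nrow(profiles@probs)
  locus <- rep_len(locus, n)
  nodeNms <- profiles@nodes
  N <- length(nodeNms)
  sgn <- if (sign == "as_printed") 1 else -1
  p00 <- profiles@probs[cbind(seq_len(n),
    match(paste0(locus, "|0.0"), colnames(profiles@probs)))]
  total <- numeric(n)
  for (nm in setdiff(nodeNms, "0.0")) {
    pkm <- profiles@probs[cbind(seq_len(n),
      match(paste0(locus, "|", nm), colnames(profiles@probs)))]
    total <- total + (1 - exp(sgn * (p00 - pkm)^2 / sigma))
  }
  (N - 1) / N * total
}

#' Assign loci by maximum likelihood and apply acceptance criteria
#'
#' The assigned locus is the argmax of the combined probability (exact ties
#' break to the fixed locus order and are flagged ambiguous).  A candidate
#' is accepted iff its combined probability reaches `pMin` *and* it passes
#' the adjacent-level consistency criterion ([consistencyOk()]) *and* the
#' terminal-node criterion ([terminalOk()]) for the assigned locus.  The
#' multiresolution score is recorded for ranking and diagnostics.
#'
#' @param profiles A [PredictionProfileSet-class] from [predictProfiles()].
#' @param config A [vexConfig()] supplying `pMin`, `eps`, `terminalTau`,
#'   `sigma` and `scoreExponentSign`.
#' @return The profile set with `assigned`, `accepted`, `mrScore` and
#'   `ambiguous` filled in.
#' @export
assignLoci <- function(profiles, config = vexConfig()) {
  stopifnot(is(profiles, "PredictionProfileSet"))
  n <- nrow(profiles@probs)
  if (n == 0L) return(profiles)
  best <- apply(profiles@combined, 1L, function(r) which.max(r))
  maxed <- profiles@combined[cbind(seq_len(n), best)]
  nTied <- rowSums(profiles@combined == maxed)
  assigned <- profiles@loci[best]
  okP <- maxed >= config$pMin
  okC <- consistencyOk(profiles, assigned, eps = config$eps)
  okT <- suppressWarnings(terminalOk(profiles, assigned, tau = config$terminalTau))
  profiles@assigned <- assigned
  profiles@ambiguous <- nTied > 1L
  profiles@accepted <- okP & okC & okT
  profiles@mrScore <- mrConsistencyScore(profiles, assigned,
                                         sigma = config$sigma,
                                         sign = config$scoreExponentSign)
  validObject(profiles)
  profiles
}
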