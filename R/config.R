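#' Pipeline configuration
#'
#' Builds and validates the single configuration object used by every stage
#' of the discovery pipeline.  Unknown arguments are rejected (there are no
#' `...`), and invalid values raise immediately, so a configuration that
#' constructs is usable everywhere.
#'
#' @param chunkSize Contig chunk size in bp used when splitting large contigs
#'   for scanning.  Default 20000.
#' @param overlap Overlap between adjacent chunks in bp.  Must exceed the
#'   largest possible candidate span (`lenMax` plus motif lengths) so that a
#'   chunked scan is equivalent to an unchunked scan.  Default 1000.
#' @param lenMin,lenMax Inclusive bounds on the AG-to-CAC inner interval
#'   length in bp.  Defaults 275 and 330; V-exons are approximately 300 bp.
#' @param depth Depth of the multiresolution decomposition.  Depth 2 gives
#'   7 nodes (1 + 2 + 4); level-2 nodes of a ~100-residue exon are ~25
#'   residues, still informative for the transforms.
#' @param transform One of `"aa_pairs"` (440-dim residue + consecutive-pair
#'   histogram, applied at every level), `"pdt"` (500-dim physicochemical
#'   distance transform at every level) or `"hybrid"` (per-level mix, see
#'   `hybridLevels`).
#' @param pdtLambda Correlation lag of the PDT when `transform = "pdt"`.
#' @param hybridLevels Named list mapping level (as character `"0"`, `"1"`,
#'   ...) to either `list(kind = "aa_pairs")` or
#'   `list(kind = "pdt", lam = <lag>)`.  Must cover levels `0:depth` when
#'   `transform = "hybrid"`.
#' @param nTrees Trees per Random Forest ensemble.  Default 500.
#' @param ratio Signal-to-background row ratio of the training matrices,
#'   read as `ratio` signal rows per background row.  Default 3.
#' @param eps Consistency threshold: adjacent-level node probabilities of the
#'   assigned locus must differ by less than `eps`.  Default 0.17.
#' @param terminalTau Threshold on the signal probability of the left-most
#'   and right-most deepest nodes, guarding the exon boundaries.  Default 0.7.
#' @param sigma Width parameter of the multiresolution consistency score.
#'   Default 0.05.
#' @param pMin Minimum combined (node-mean) probability for acceptance.
#'   Default 0.7.
#' @param scoreExponentSign `"as_printed"` uses `1 - exp(+d^2/sigma)` terms
#'   (score is 0 or negative); `"negative"` uses `1 - exp(-d^2/sigma)`.
#' @param combineMethod Aggregation of per-node probabilities into the
#'   per-locus combined statistic: `"mean"` (default) or `"geometric"`.
#' @param minNewFraction Bootstrap convergence: stop when new discoveries are
#'   fewer than this fraction of the current training set.  Default 0.01.
#' @param maxIterations Hard cap on bootstrap iterations.  Default 10.
#' @param backgroundMode `"shuffle"` (residue-shuffled positives, default) or
#'   `"uniform"` (uniform random residues) for training backgrounds.
#' @param seed Master random seed; every stochastic stage derives its own
#'   seed from it deterministically.
#'
#' @return A named list of validated parameters with class `"VexConfig"`.
#' @export
#' @examples
#' cfg <- vexConfig(seed = 7)
#' cfg$eps
vexConfig <- function(chunkSize = 20000L,
                      overlap = 1000L,
                      lenMin = 275L,
                      lenMax = 330L,
                      depth = 2L,
                      transform = c("aa_pairs", "pdt", "hybrid"),
                      pdtLambda = 1L,
                      hybridLevels = list(
                        "0" = list(kind = "pdt", lam = 3L),
                        "1" = list(kind = "pdt", lam = 1L),
                        "2" = list(kind = "aa_pairs")),
                      nTrees = 500L,
                      ratio = 3L,
                      eps = 0.17,
                      terminalTau = 0.7,
                      sigma = 0.05,
                      pMin = 0.7,
                      scoreExponentSign = c("as_printed", "negative"),
                      combineMethod = c("mean", "geometric"),
                      minNewFraction = 0.01,
                      maxIterations = 10L,
                      backgroundMode = c("shuffle", "uniform"),
                      seed = 1L) {
  transform <- match.arg(transform)
  scoreExponentSign <- match.arg(scoreExponentSign)
  combineMethod <- match.arg(combineMethod)
  backgroundMode <- match.arg(backgroundMode)

  stopifnot(
    "chunkSize must be a positive integer" = chunkSize >= 1,
    "overlap must be a positive integer" = overlap >= 1,
    "overlap must be smaller than chunkSize" = overlap < chunkSize,
    "lenMin must be positive" = lenMin >= 1,
    "lenMax must be >= lenMin" = lenMax >= lenMin,
    "depth must be >= 0" = depth >= 0,
    "nTrees must be positive" = nTrees >= 1,
    "ratio must be positive" = ratio >= 1,
    "eps must be in (0, 1]" = eps > 0 && eps <= 1,
    "terminalTau must be in [0, 1]" = terminalTau >= 0 && terminalTau <= 1,
    "sigma must be > 0" = sigma > 0,
    "pMin must be in [0, 1]" = pMin >= 0 && pMin <= 1,
    "minNewFraction must be in [0, 1)" = minNewFraction >= 0 && minNewFraction < 1,
    "maxIterations must be positive" = maxIterations >= 1,
    "pdtLambda must be positive" = pdtLambda >= 1,
    "seed must be a finite number" = is.finite(seed)
  )
  ## Chunk-scan equivalence needs every candidate (inner span + AG + CAC)
  ## wholly inside at least one chunk.
  if (overlap < lenMax + 5L) {
    stop("overlap (", overlap, ") must be at least lenMax + 5 = ", lenMax + 5L,
         " so that no candidate spans more than one chunk boundary")
  }
  if (transform == "hybrid") {
    need <- as.character(0:depth)
    if (!all(need %in% names(hybridLevels))) {
      stop("hybridLevels must map every level ", paste(need, collapse = ", "))
    }
    for (lv in need) {
      hl <- hybridLevels[[lv]]
      if (!is.list(hl) || !hl$kind %in% c("aa_pairs", "pdt")) {
        stop("hybridLevels[['", lv, "']] must be list(kind='aa_pairs') or list(kind='pdt', lam=...)")
      }
    }
  }

  cfg <- list(
    chunkSize = as.integer(chunkSize), overlap = as.integer(overlap),
    lenMin = as.integer(lenMin), lenMax = as.integer(lenMax),
    depth = as.integer(depth), transform = transform,
    pdtLambda = as.integer(pdtLambda), hybridLevels = hybridLevels,
    nTrees = as.integer(nTrees), ratio = as.integer(ratio),
    eps = eps, terminalTau = terminalTau, sigma = sigma, pMin = pMin,
    scoreExponentSign = scoreExponentSign, combineMethod = combineMethod,
    minNewFraction = minNewFraction, maxIterations = as.integer(maxIterations),
    backgroundMode = backgroundMode, seed = as.integer(seed)
  )
  class(cfg) <- "VexConfig"
  cfg
}

## Per-level transform plan: list over levels "0".."depth" of
## list(kind=, lam=) resolved from the config.
.levelMap <- function(config) {
  lv <- as.character(0:config$depth)
  if (config$transform == "aa_pairs") {
    m <- rep(list(list(kind = "aa_pairs")), length(lv))
  } else if (config$transform == "pdt") {
    m <- rep(list(list(kind = "pdt", lam = config$pdtLambda)), length(lv))
  } else {
    m <- config$hybridLevels[lv]
  }
  names(m) <- lv
  m
}

#' Write the effective configuration to a JSON file
#'
#' Every output directory of a run carries its effective configuration, so
#' any run is reproducible from the directory alone.
#'
#' @param config A [vexConfig()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeConfig <- function(config, path) {
  stopifnot(inherits(config, "VexConfig"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
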