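#' Stochastic universal sampling (SUS)
#'
#' Draws `n` items from weighted categories using a single random offset
#' and `n` equally spaced pointers over the cumulative weight line. Each
#' category's count is forced to the floor or ceiling of its expectation
#' `n * w_i / sum(w)`, giving strictly lower variance than multinomial
#' sampling — the low-variance sampler used to build the acquisition null.
#'
#' @param weights positive per-category weights (e.g. gene lengths).
#' @param n number of draws.
#' @param seed optional integer seed (the caller may also manage the RNG).
#' @return integer vector of per-category counts summing to `n`.
#' @export
susSample <- function(weights, n, seed = NULL) {
  if (any(weights <= 0)) stop("all weights must be positive")
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  cum <- cumsum(as.numeric(weights))
  step <- cum[length(cum)] / n
  pointers <- stats::runif(1, 0, step) + (seq_len(n) - 1) * step
  idx <- findInterval(pointers, cum, left.open = FALSE) + 1L
  idx[idx > length(weights)] <- length(weights)  # guard fp edge
  tabulate(idx, nbins = length(weights))
}

#' Monte Carlo null envelope for spacer acquisition vs gene expression
#'
#' Repeats, `trials` times, an in-silico draw of `sampleSize` spacers from
#' all genes with probability proportional to gene length (SUS), and
#' accumulates the cumulative spacer fraction along the genes ordered by
#' descending expression (ties broken by gene id). The envelope is the
#' pointwise min/max over trials — the exact range of null relationships —
#' with an optional quantile band.
#'
#' @param geneLengths positive numeric vector of gene lengths.
#' @param expression numeric per-gene expression (for ranking only).
#' @param geneIds character gene ids.
#' @param sampleSize spacers per trial (default from `config`).
#' @param trials number of trials (default from `config`).
#' @param config a [RunConfig-class].
#' @param seed integer seed.
#' @param quantiles optional length-2 probabilities for a quantile band
#'   instead of the min/max range.
#' @return list with `order` (gene ids in envelope order), `lower`,
#'   `upper` (cumulative-fraction bounds per rank), `trials`,
#'   `sample_size`.
#' @export
nullEnvelope <- function(geneLengths, expression, geneIds,
                         sampleSize = NULL, trials = NULL,
                         config = runConfig(), seed = config@seed,
                         quantiles = NULL) {
  if (is.null(sampleSize)) sampleSize <- config@susSampleSize
  if (is.null(trials)) trials <- config@susTrials
  stopifnot(length(geneLengths) == length(expression),
            length(geneIds) == length(expression))
  ord <- order(-expression, geneIds)
  set.seed(stageSeed(seed, "null_envelope"))
  k <- length(geneLengths)
  curves <- matrix(0, nrow = trials, ncol = k)
  for (t in seq_len(trials)) {
    counts <- susSample(geneLengths, sampleSize)
    curves[t, ] <- cumsum(counts[ord]) / sampleSize
  }
  if (is.null(quantiles)) {
    lower <- apply(curves, 2, min)
    upper <- apply(curves, 2, max)
  } else {
    qs <- apply(curves, 2, stats::quantile, probs = quantiles)
    lower <- qs[1, ]; upper <- qs[2, ]
  }
  list(order = geneIds[ord], lower = lower, upper = upper,
       trials = trials, sample_size = sampleSize)
}

#' Compare observed spacer counts to a null envelope
#'
#' Positions the observed cumulative acquisition curve against the
#' envelope at every expression rank. Curves running above the envelope
#' indicate preferential acquisition from highly expressed genes; curves
#' below indicate acquisition from poorly expressed genes more often than
#' random assortment predicts.
#'
#' @param observedCounts named integer vector of spacers per gene (names
#'   are gene ids; genes absent from the names get zero).
#' @param envelope result of [nullEnvelope()].
#' @return list with `position` (factor above/within/below per rank),
#'   `observed` (cumulative fractions), and summary counts.
#' @export
envelopeTest <- function(observedCounts, envelope) {
  unknown <- setdiff(names(observedCounts), envelope$order)
  if (length(unknown))
    stop("observed counts name genes absent from the envelope: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  counts <- unname(observedCounts[match(envelope$order, names(observedCounts))])
  counts[is.na(counts)] <- 0
  total <- sum(counts)
  if (total == 0) stop("no observed spacers")
  obs <- cumsum(counts) / total
  pos <- ifelse(obs > envelope$upper, "above",
                ifelse(obs < envelope$lower, "below", "within"))
  list(position = pos, observed = unname(obs),
       n_above = sum(pos == "above"), n_within = sum(pos == "within"),
       n_below = sum(pos == "below"))
}
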