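#' Read a k-mer occurrence histogram
#'
#' Parses the common two-column whitespace-separated "histo" output of k-mer
#' counters (occurrence, number of distinct k-mers).
#'
#' @param path histo file.
#' @param k k-mer length recorded on the object (default 25).
#' @return a [KmerHistogram].
#' @export
readKmerHistogram <- function(path, k = 25L) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("occurrence", "count"))
  KmerHistogram(tab$occurrence, tab$count, k = k)
}

# Dense counts from min to max occurrence (zeros filled in), smoothed with a
# window-3 moving average.
.smoothed_spectrum <- function(hist) {
  occ <- seq.int(min(hist@occurrence), max(hist@occurrence))
  cnt <- numeric(length(occ))
  cnt[hist@occurrence - occ[1] + 1L] <- hist@count
  sm <- cnt
  if (length(cnt) >= 3L) {
    sm <- stats::filter(cnt, rep(1 / 3, 3), sides = 2)
    sm[1] <- mean(cnt[1:2]); sm[length(sm)] <- mean(cnt[(length(cnt) - 1):
                                                          length(cnt)])
    sm <- as.numeric(sm)
  }
  list(occ = occ, smoothed = sm)
}

.local_maxima <- function(x) {
  n <- length(x)
  if (n == 1L) return(1L)
  which(vapply(seq_len(n), function(i) {
    left <- if (i == 1L) -Inf else x[i - 1L]
    right <- if (i == n) -Inf else x[i + 1L]
    x[i] > left && x[i] >= right
  }, logical(1)))
}

#' Detect heterozygous and homozygous peaks in a k-mer spectrum
#'
#' Smooths the spectrum with a window-3 moving average and takes the local
#' maxima at occurrences at or above the artifact cutoff. When two maxima sit
#' in an approximate 2:1 occurrence ratio (within 25%), the larger occurrence
#' is the homozygous peak and its partner the heterozygous peak; otherwise the
#' global maximum is the homozygous peak and no heterozygous peak is reported.
#'
#' @param hist a [KmerHistogram].
#' @param cutoff artifact cutoff: occurrences below it are ignored.
#' @return list with \code{het_peak} (occurrence or NA) and \code{hom_peak}.
#' @examples
#' cfg <- syntheticConfig(seed = 1, genome_size_true = 1e6)
#' sim <- simulateKmerHistogram(cfg)
#' findPeaks(sim$histogram, cutoff = 30)
#' @export
findPeaks <- function(hist, cutoff) {
  sp <- .smoothed_spectrum(hist)
  keep <- sp$occ >= cutoff
  if (!any(keep & sp$smoothed > 0))
    stop("no k-mer mass at or above the cutoff (", cutoff, ")")
  occ <- sp$occ[keep]; sm <- sp$smoothed[keep]
  mx <- .local_maxima(sm)
  peaks <- occ[mx]
  heights <- sm[mx]
  hom <- NA_real_; het <- NA_real_
  if (length(peaks) >= 2L) {
    pairs <- expand.grid(a = seq_along(peaks), b = seq_along(peaks))
    pairs <- pairs[peaks[pairs$b] > peaks[pairs$a], , drop = FALSE]
    ok <- abs(peaks[pairs$b] - 2 * peaks[pairs$a]) <=
      0.25 * 2 * peaks[pairs$a]
    pairs <- pairs[ok, , drop = FALSE]
    if (nrow(pairs)) {
      # favour the most substantial paired peaks, then the largest occurrence
      score <- heights[pairs$a] + heights[pairs$b]
      best <- pairs[order(-score, -peaks[pairs$b])[1L], ]
      hom <- peaks[best$b]; het <- peaks[best$a]
    }
  }
  if (is.na(hom)) hom <- peaks[which.max(heights)]
  list(het_peak = het, hom_peak = hom)
}

#' Estimate genome size from a k-mer spectrum
#'
#' Genome size is the total number of genuine k-mer observations — the sum of
#' occurrence times count over the spectrum, minus the same sum below the
#' artifact cutoff — divided by the homozygous peak coverage. With a 25-mer
#' spectrum of 133e9 total observations, 18e9 of them below an artifact cutoff
#' of 30, and a homozygous peak at 136, this gives (133e9 - 18e9) / 136 =
#' 845.6 Mbp.
#'
#' @param hist a [KmerHistogram].
#' @param cutoff artifact cutoff; occurrences strictly below it are discarded
#'   as sequencing-error artifacts. \code{NULL} selects the first local
#'   minimum of the smoothed spectrum automatically.
#' @param hom_peak optional homozygous-coverage override; detected with
#'   [findPeaks()] when not supplied.
#' @return a [SpectrumEstimate].
#' @export
estimateGenomeSize <- function(hist, cutoff = NULL, hom_peak = NULL) {
  if (is.null(cutoff)) {
    sp <- .smoothed_spectrum(hist)
    n <- length(sp$smoothed)
    mins <- which(vapply(seq_len(n), function(i) {
      left <- if (i == 1L) Inf else sp$smoothed[i - 1L]
      right <- if (i == n) Inf else sp$smoothed[i + 1L]
      sp$smoothed[i] < left && sp$smoothed[i] <= right
    }, logical(1)))
    if (!length(mins)) stop("cannot auto-select a cutoff: no local minimum")
    cutoff <- sp$occ[mins[1L]]
  }
  peaks <- list(het_peak = NA_real_, hom_peak = hom_peak)
  if (is.null(hom_peak)) peaks <- findPeaks(hist, cutoff)
  if (peaks$hom_peak <= 0) stop("homozygous peak must be positive")
  total <- sum(hist@occurrence * hist@count)
  artifact <- sum(hist@occurrence[hist@occurrence < cutoff] *
                    hist@count[hist@occurrence < cutoff])
  new("SpectrumEstimate",
      hetPeak = as.numeric(peaks$het_peak),
      homPeak = as.numeric(peaks$hom_peak),
      cutoff = as.numeric(cutoff),
      totalObservations = total, artifactObservations = artifact,
      genomeSize = (total - artifact) / peaks$hom_peak)
}
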