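#' Construct an NMR spectrum
#'
#' @param ppm chemical-shift axis (ppm); stored descending.
#' @param intensity intensity series, same length.
#' @param sample_id sample identifier.
#' @param group group label.
#' @return an [NMRSpectrum-class].
#' @export
nmrSpectrum <- function(ppm, intensity, sample_id = "sample", group = "unknown") {
  if (length(ppm) >= 2 && ppm[1] < ppm[length(ppm)]) {
    ppm <- rev(ppm); intensity <- rev(intensity)
  }
  new("NMRSpectrum", ppm = as.numeric(ppm), intensity = as.numeric(intensity),
      sampleId = sample_id, group = group)
}

#' Construct a spectrum set
#'
#' @param spectra list of [NMRSpectrum-class] objects.
#' @return a [SpectrumSet-class].
#' @export
spectrumSet <- function(spectra) {
  manifest <- data.frame(
    sample_id = vapply(spectra, function(s) s@sampleId, character(1)),
    group = vapply(spectra, function(s) s@group, character(1)),
    stringsAsFactors = FALSE
  )
  new("SpectrumSet", spectra = spectra, manifest = manifest)
}

#' Construct a bucketing specification
#'
#' @param width bucket width in ppm.
#' @param region integration region `c(low, high)` in ppm.
#' @param exclusions list of excluded `c(low, high)` windows.
#' @param reference_pattern name of the calibration pattern.
#' @param reference_ppm target shift for the pattern.
#' @return a [BucketSpec-class]; defaults are the serum-study conventions
#'   (0.004-ppm buckets on 0.5-8.5 ppm, water window 4.7-5.2 excluded,
#'   lactate doublet referenced to 1.33 ppm).
#' @export
bucketSpec <- function(width = 0.004, region = c(0.5, 8.5),
                       exclusions = list(c(4.7, 5.2)),
                       reference_pattern = "lactate doublet",
                       reference_ppm = 1.33) {
  new("BucketSpec", width = width, region = region, exclusions = exclusions,
      referencePattern = reference_pattern, referencePPM = reference_ppm)
}

#' Calibrate a spectrum to its reference doublet
#'
#' Finds the two highest local maxima within +/- 0.1 ppm of the reference
#' shift, takes their midpoint as the doublet center, and shifts the whole
#' axis uniformly so the center lands on the target.
#'
#' @param spectrum an [NMRSpectrum-class].
#' @param spec a [BucketSpec-class] giving the reference pattern and target.
#' @param window half-width of the peak search window in ppm.
#' @return the shifted spectrum; the applied shift (ppm) is recorded in
#'   `attr(, "shift")`.
#' @export
calibrateSpectrum <- function(spectrum, spec = bucketSpec(), window = 0.1) {
  target <- spec@referencePPM
  ppm <- spectrum@ppm
  y <- spectrum@intensity
  sel <- which(ppm >= target - window & ppm <= target + window)
  if (length(sel) < 3)
    stop("calibration error for sample ", spectrum@sampleId,
         ": no data in the reference search window")
  idx <- sel[-c(1, length(sel))]
  ismax <- y[idx] > y[idx - 1] & y[idx] > y[idx + 1]
  peaks <- idx[ismax]
  if (length(peaks) < 2)
    stop("calibration error for sample ", spectrum@sampleId,
         ": reference doublet not found near ", target, " ppm")
  top2 <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
  center <- mean(ppm[top2])
  shift <- target - center
  out <- spectrum
  out@ppm <- ppm + shift
  attr(out, "shift") <- shift
  out
}

# Integral of the piecewise-linear interpolant of (x, y) from each lo[i] to
# hi[i], via an interpolated cumulative trapezoid. x must be ascending.
.segmentIntegrals <- function(x, y, lo, hi) {
  ct <- c(0, cumsum(diff(x) * (head(y, -1) + y[-1]) / 2))
  at <- function(p) {
    j <- findInterval(p, x, rightmost.closed = TRUE)
    j <- pmin(pmax(j, 1L), length(x) - 1L)
    frac <- (p - x[j]) / (x[j + 1L] - x[j])
    # exact trapezoid integral of the linear interpolant up to p
    yj <- y[j] + frac * (y[j + 1L] - y[j])
    ct[j] + (p - x[j]) * (y[j] + yj) / 2
  }
  at(hi) - at(lo)
}

#' Bucket boundaries for a specification
#'
#' Buckets tile `[low, high)` left-closed in steps of `width`, anchored at the
#' region's low edge; a bucket whose interval intersects any exclusion window
#' is dropped whole.
#'
#' @param spec a [BucketSpec-class].
#' @return data.frame with columns `lo`, `hi`, `center` for retained buckets.
#' @export
bucketGrid <- function(spec = bucketSpec()) {
  lo <- spec@region[1]; hi <- spec@region[2]; w <- spec@width
  n <- floor((hi - lo) / w + 1e-9)
  lows <- lo + (seq_len(n) - 1L) * w
  highs <- lows + w
  keep <- rep(TRUE, n)
  for (ex in spec@exclusions)
    keep <- keep & !(lows < ex[2] - 1e-12 & highs > ex[1] + 1e-12)
  data.frame(lo = lows[keep], hi = highs[keep],
             center = (lows[keep] + highs[keep]) / 2)
}

#' Integrate a spectrum into fixed-width buckets
#'
#' Each retained bucket's value is the trapezoidal integral of the intensity
#' over the bucket interval on the spectrum's native grid (no resampling).
#'
#' @param spectrum an [NMRSpectrum-class] covering the region.
#' @param spec a [BucketSpec-class].
#' @return named numeric vector of bucket integrals; names are bucket-center
#'   ppm to 4 decimals.
#' @export
bucketSpectrum <- function(spectrum, spec = bucketSpec()) {
  grid <- bucketGrid(spec)
  x <- spectrum@ppm; y <- spectrum@intensity
  if (x[1] > x[length(x)]) { x <- rev(x); y <- rev(y) }
  if (x[1] > spec@region[1] + 1e-9 || x[length(x)] < spec@region[2] - 1e-9)
    stop("spectrum ", spectrum@sampleId, " does not cover the region [",
         spec@region[1], ", ", spec@region[2], "] ppm")
  vals <- .segmentIntegrals(x, y, grid$lo, grid$hi)
  setNames(vals, sprintf("%.4f", grid$center))
}

#' Calibrate and bucket a whole spectrum set
#'
#' @param set a [SpectrumSet-class].
#' @param spec a [BucketSpec-class].
#' @param calibrate logical; shift each spectrum to the reference doublet
#'   before integration.
#' @return matrix of raw bucket integrals, samples in rows, buckets in
#'   columns; group labels in `attr(, "group")`, applied shifts in
#'   `attr(, "shifts")`.
#' @export
bucketSpectra <- function(set, spec = bucketSpec(), calibrate = TRUE) {
  shifts <- numeric(length(set@spectra))
  rows <- lapply(seq_along(set@spectra), function(i) {
    sp <- set@spectra[[i]]
    if (calibrate) {
      sp <- calibrateSpectrum(sp, spec)
      shifts[i] <<- attr(sp, "shift")
    }
    bucketSpectrum(sp, spec)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- set@manifest$sample_id
  attr(m, "group") <- set@manifest$group
  attr(m, "shifts") <- setNames(shifts, set@manifest$sample_id)
  m
}

#' Total-sum normalize a raw bucket matrix
#'
#' Divides each sample's bucket vector by its own total so every profile sums
#' to one; the raw totals are stored for audit.
#'
#' @param raw samples-by-buckets matrix from [bucketSpectra()]; column names
#'   are bucket-center ppm.
#' @param group group labels per sample (defaults to `attr(raw, "group")`).
#' @return an [NMRBucketMatrix-class].
#' @export
normalizeBuckets <- function(raw, group = attr(raw, "group")) {
  totals <- rowSums(raw)
  bad <- which(!(totals > 0))
  if (length(bad))
    stop("nonpositive total integral for sample(s): ",
         paste(rownames(raw)[bad], collapse = ", "))
  if (is.null(group)) group <- rep("unknown", nrow(raw))
  norm <- sweep(raw, 1, totals, "/")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(normalized = t(norm)),
    rowData = S4Vectors::DataFrame(ppm = as.numeric(colnames(raw))),
    colData = S4Vectors::DataFrame(group = group,
                                   row.names = rownames(raw)),
    metadata = list(totals = setNames(totals, rownames(raw)))
  )
  new("NMRBucketMatrix", se)
}

#' Read/write two-column spectra with a manifest
#'
#' Spectra are stored one file per sample as whitespace-delimited
#' (ppm, intensity) pairs, with a tab-separated manifest (`sample_id`,
#' `group`, `file`).
#'
#' @param set a [SpectrumSet-class].
#' @param dir directory to write into / read from.
#' @return `writeSpectra` the manifest path, invisibly; `readSpectra` a
#'   [SpectrumSet-class].
#' @export
writeSpectra <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(set@spectra))
  for (i in seq_along(set@spectra)) {
    sp <- set@spectra[[i]]
    files[i] <- paste0(sp@sampleId, ".tsv")
    write.table(
      data.frame(ppm = sp@ppm, intensity = sp@intensity),
      file.path(dir, files[i]),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  mf <- cbind(set@manifest, file = files)
  mpath <- file.path(dir, "manifest.tsv")
  write.table(mf, mpath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' @rdname writeSpectra
#' @export
readSpectra <- function(dir) {
  mf <- read.delim(file.path(dir, "manifest.tsv"), stringsAsFactors = FALSE)
  spectra <- lapply(seq_len(nrow(mf)), function(i) {
    d <- read.delim(file.path(dir, mf$file[i]), stringsAsFactors = FALSE)
    nmrSpectrum(d$ppm, d$intensity, sample_id = mf$sample_id[i],
                group = mf$group[i])
  })
  spectrumSet(spectra)
}
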