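# Reads I/O, strand shifting, bin construction and the short-bin statistic.
#
# A "bin" is the gap between two neighboring shifted 5' read positions on a
# chromosome; it is the atomic unit of the whole caller.  The optimized
# shift parameter is the strand shift that maximizes the proportion of
# short bins (it recovers half the DNA fragment size, because aligning the
# + and - strand read distributions collapses them onto fragment centers).

#' Construct a read set
#'
#' Low-level constructor; most users go through [load_reads()] or
#' [simulate_chipseq()].
#'
#' @param reads data.table with columns `chrom` (character), `pos` (integer
#'   base coordinate: 5' end of a single-end read or fragment midpoint),
#'   `strand` (`"+"`, `"-"`, or `"*"` for paired midpoints).
#' @param sample_label sample name.
#' @param layout `"single"` or `"paired"`.
#' @param fragment_hint DNA fragment size in bp (user supplied for
#'   single-end; median insert for paired-end).
#' @param chrom_sizes optional named vector used for position clipping.
#' @return object of class `read_set` with fields `reads` (sorted by
#'   chromosome and position), `total_reads`, `sample_label`, `layout`,
#'   `fragment_hint`, `shifted_by`.
#' @export
read_set <- function(reads, sample_label = "sample", layout = "single",
                     fragment_hint = NA_real_, chrom_sizes = NULL) {
  stopifnot(is.data.frame(reads), all(c("chrom", "pos", "strand") %in% names(reads)))
  dt <- data.table::as.data.table(reads)[, .(chrom = as.character(chrom),
                                             pos = as.integer(pos),
                                             strand = as.character(strand))]
  data.table::setkey(dt, chrom, pos)
  structure(list(reads = dt,
                 total_reads = nrow(dt),
                 sample_label = sample_label,
                 layout = match.arg(layout, c("single", "paired")),
                 fragment_hint = fragment_hint,
                 chrom_sizes = chrom_sizes,
                 shifted_by = 0L),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("<read_set> ", x$sample_label, ": ", format(x$total_reads, big.mark = ","),
      " ", x$layout, "-end reads on ", length(unique(x$reads$chrom)),
      " chromosome(s); shift applied = ", x$shifted_by, " bp\n", sep = "")
  invisible(x)
}

#' Load mapped reads from BED6 or BAM
#'
#' For single-end data the unshifted 5' position of each read is kept
#' (`start` for `+`, `end - 1` for `-`).  For paired-end data one record per
#' proper pair is kept and reduced to the fragment midpoint (strand `"*"`);
#' the median insert size is stored as the fragment hint.  Reads on
#' chromosomes absent from `genome` are dropped with a message.
#'
#' @param path BED6 file or coordinate-sorted indexed BAM file.
#' @param format `"bed"` or `"bam"`.
#' @param layout `"single"` or `"paired"`.
#' @param genome optional [genome_model()]; enables unknown-chromosome
#'   filtering and position clipping.
#' @param fragment_hint DNA fragment size hint in bp (single-end).
#' @param sample_label sample name.
#' @return a `read_set`.
#' @export
load_reads <- function(path, format = c("bed", "bam"),
                       layout = c("single", "paired"),
                       genome = NULL, fragment_hint = NA_real_,
                       sample_label = basename(path)) {
  format <- match.arg(format)
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (format == "bed") {
    bed <- tryCatch(read_bed(path), error = function(e)
      stop("unparseable BED file: ", path, " (", conditionMessage(e), ")"))
    if (nrow(bed) == 0L) stop("zero reads in ", path)
    if (!"strand" %in% names(bed)) bed$strand <- "+"
    if (layout == "single") {
      dt <- bed[, .(chrom, pos = ifelse(strand == "-", end - 1L, start),
                    strand)]
    } else {
      dt <- bed[, .(chrom, pos = as.integer((start + end) %/% 2L),
                    strand = "*")]
      if (is.na(fragment_hint)) fragment_hint <- stats::median(bed$end - bed$start)
    }
  } else {
    what <- c("rname", "pos", "strand", "qwidth", "isize")
    flag <- if (layout == "paired")
      Rsamtools::scanBamFlag(isProperPair = TRUE, isUnmappedQuery = FALSE)
    else Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
    res <- Rsamtools::scanBam(path,
      param = Rsamtools::ScanBamParam(what = what, flag = flag))[[1]]
    if (length(res$pos) == 0L) stop("zero reads in ", path)
    if (layout == "single") {
      start0 <- res$pos - 1L
      dt <- data.table::data.table(
        chrom = as.character(res$rname),
        pos = ifelse(res$strand == "-", start0 + res$qwidth - 1L, start0),
        strand = as.character(res$strand))
    } else {
      keep <- which(res$isize > 0L)  # one record per pair
      if (length(keep) == 0L) stop("no proper pairs with positive insert in ", path)
      start0 <- res$pos[keep] - 1L
      dt <- data.table::data.table(
        chrom = as.character(res$rname[keep]),
        pos = start0 + res$isize[keep] %/% 2L,
        strand = "*")
      if (is.na(fragment_hint)) fragment_hint <- stats::median(res$isize[keep])
    }
  }
  chrom_sizes <- NULL
  if (!is.null(genome)) {
    chrom_sizes <- genome$chrom_sizes
    known <- dt$chrom %in% names(chrom_sizes)
    if (!all(known)) {
      message(sum(!known), " read(s) on unknown chromosomes dropped")
      dt <- dt[known]
    }
    if (nrow(dt) == 0L) stop("zero reads on known chromosomes in ", path)
  }
  read_set(dt, sample_label = sample_label, layout = layout,
           fragment_hint = fragment_hint, chrom_sizes = chrom_sizes)
}

#' Shift reads towards their 3' end
#'
#' `+` strand positions move right and `-` strand positions move left by
#' `shift` bp (fragment-center alignment); `"*"` (paired midpoints) are left
#' untouched.  Positions are clipped to `[0, chrom_size)` when chromosome
#' sizes are known, and the read table is re-sorted.
#'
#' @param reads a `read_set`.
#' @param shift non-negative shift in bp.
#' @return a shifted `read_set` (`shifted_by` is incremented).
#' @export
shift_reads <- function(reads, shift) {
  stopifnot(inherits(reads, "read_set"), shift >= 0)
  shift <- as.integer(round(shift))
  dt <- data.table::copy(reads$reads)
  dt[strand == "+", pos := pos + shift]
  dt[strand == "-", pos := pos - shift]
  dt[pos < 0L, pos := 0L]
  if (!is.null(reads$chrom_sizes)) {
    for (ch in unique(dt$chrom)) {
      lim <- as.integer(reads$chrom_sizes[[ch]]) - 1L
      dt[chrom == ch & pos > lim, pos := lim]
    }
  }
  data.table::setkey(dt, chrom, pos)
  out <- reads
  out$reads <- dt
  out$shifted_by <- reads$shifted_by + shift
  out
}

#' Build bins from sorted reads
#'
#' One bin per adjacent pair of read positions per chromosome; the bin
#' length is the position difference (0 is allowed for duplicate reads at
#' identical positions).  A chromosome with fewer than two reads
#' contributes no bins.
#'
#' @param reads a `read_set` (positions already shifted as desired).
#' @return a `bin_seq`: data.table with `chrom,start,end,length`, where
#'   `start`/`end` are the flanking read positions.
#' @export
build_bins <- function(reads) {
  stopifnot(inherits(reads, "read_set"))
  dt <- reads$reads[, if (.N >= 2L)
    .(start = pos[-.N], end = pos[-1L]), by = chrom]
  if (nrow(dt) == 0L)
    dt <- data.table::data.table(chrom = character(), start = integer(),
                                 end = integer())
  dt[, length := end - start]
  data.table::setattr(dt, "class", c("bin_seq", class(dt)))
  dt[]
}

#' Short-bin fraction and cutoff
#'
#' Builds the bin-length histogram at 1-bp resolution, smooths it with a
#' centered moving average of width 5, and takes as "short bins" all bins
#' whose length does not exceed the first local maximum of the smoothed
#' histogram (plateaus resolve to their leftmost position, never below the
#' smallest observed length).  A histogram that only rises towards its
#' upper boundary is degenerate: the cutoff falls back to the smallest
#' observed length with a warning.
#'
#' @param bins a `bin_seq` from [build_bins()], or a numeric vector of bin
#'   lengths.
#' @return list with `fraction` (proportion of short bins), `cutoff` (bp).
#' @export
short_bin_fraction <- function(bins) {
  len <- if (inherits(bins, "bin_seq") || is.data.frame(bins)) bins$length else bins
  stopifnot(is.numeric(len))
  n <- length(len)
  if (n == 0L) return(list(fraction = NA_real_, cutoff = NA_real_))
  if (n < 1000L) warning("fewer than 1000 bins; short-bin fraction is noisy")
  maxl <- max(len)
  cnt <- tabulate(len + 1L, nbins = maxl + 1L)  # cnt[l+1] = #bins of length l
  # centered moving average, width 5, zero padding
  pad <- c(0, 0, cnt, 0, 0)
  sm <- (pad[1:(maxl + 1L)] + pad[2:(maxl + 2L)] + pad[3:(maxl + 3L)] +
         pad[4:(maxl + 4L)] + pad[5:(maxl + 5L)]) / 5
  l0 <- min(len)
  i0 <- l0 + 1L
  cutoff <- l0
  warn <- FALSE
  if (maxl > l0) {
    desc <- which(sm[i0:maxl] > sm[(i0 + 1L):(maxl + 1L)])
    if (length(desc) == 0L) {
      warn <- TRUE  # never descends: monotone histogram
    } else {
      i <- i0 + desc[1L] - 1L  # index of first strict descent
      if (all(diff(sm[i0:i]) >= 0) && sm[i0] < sm[i]) {
        # rose monotonically from the start: no interior peak
        warn <- TRUE
      } else {
        while (i > i0 && sm[i - 1L] == sm[i]) i <- i - 1L  # leftmost of plateau
        cutoff <- i - 1L
      }
    }
  }
  if (warn)
    warning("bin-length histogram has no interior peak; ",
            "using smallest observed length as short-bin cutoff")
  list(fraction = mean(len <= cutoff), cutoff = cutoff)
}

#' Estimate the optimized shift parameter
#'
#' For single-end data, scans candidate shifts from 0 to `max_shift` in
#' steps of `step` bp; each candidate shifts the reads, rebuilds bins and
#' records the short-bin fraction.  The candidate maximizing that fraction
#' is the optimized shift (half the DNA fragment size).  For paired-end
#' data no scan is needed: half the median insert size is returned.  When
#' the scan is uninformative (no bins, or a flat fraction profile as with
#' all-identical bin lengths) the estimate falls back to half the fragment
#' hint with a warning.
#'
#' @param reads a `read_set` (unshifted).
#' @param max_shift largest candidate shift in bp; defaults to the fragment
#'   hint.
#' @param step candidate stride in bp.
#' @return object of class `shift_estimate`: list with `optimized_shift`,
#'   `candidate_shifts`, `short_bin_fraction_by_candidate`,
#'   `short_bin_cutoff`.
#' @export
estimate_shift <- function(reads, max_shift = reads$fragment_hint, step = 5) {
  stopifnot(inherits(reads, "read_set"))
  if (reads$layout == "paired") {
    s <- reads$fragment_hint / 2
    return(structure(list(optimized_shift = s, candidate_shifts = s,
                          short_bin_fraction_by_candidate = NA_real_,
                          short_bin_cutoff = NA_real_),
                     class = "shift_estimate"))
  }
  stopifnot(!is.na(max_shift), max_shift > 0)
  cand <- seq(0, max_shift, by = step)
  frac <- numeric(length(cand))
  cuts <- numeric(length(cand))
  for (i in seq_along(cand)) {
    b <- build_bins(shift_reads(reads, cand[i]))
    if (nrow(b) == 0L) { frac[i] <- NA_real_; cuts[i] <- NA_real_; next }
    sbf <- suppressWarnings(short_bin_fraction(b))
    frac[i] <- sbf$fraction
    cuts[i] <- sbf$cutoff
  }
  fallback <- function() {
    warning("shift scan uninformative; falling back to fragment_hint/2")
    fb <- if (is.na(reads$fragment_hint)) 0 else reads$fragment_hint / 2
    structure(list(optimized_shift = fb, candidate_shifts = cand,
                   short_bin_fraction_by_candidate = frac,
                   short_bin_cutoff = NA_real_),
              class = "shift_estimate")
  }
  if (all(is.na(frac))) return(fallback())
  ok <- which(!is.na(frac))
  if (length(unique(frac[ok])) == 1L && length(ok) > 1L) return(fallback())
  best <- ok[which.max(frac[ok])]
  structure(list(optimized_shift = cand[best], candidate_shifts = cand,
                 short_bin_fraction_by_candidate = frac,
                 short_bin_cutoff = cuts[best]),
            class = "shift_estimate")
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat("<shift_estimate> optimized shift = ", x$optimized_shift, " bp",
      if (!is.na(x$short_bin_cutoff))
        paste0(" (short-bin cutoff ", x$short_bin_cutoff, " bp)"), "\n", sep = "")
  invisible(x)
}

#' Signal-to-noise ratio as the short-bin proportion of a read subsample
#'
#' Subsamples `sample_size` reads without replacement (seeded), applies the
#' data set's optimized shift, and returns the short-bin fraction.  A high
#' proportion of short bins indicates strong local read clustering, i.e.
#' high signal relative to the uniform background.
#'
#' @param reads a `read_set` (unshifted).
#' @param sample_size reads to draw; when it exceeds the library size all
#'   reads are used with a warning.
#' @param seed integer seed for the subsample.
#' @param shift optional shift to apply; defaults to [estimate_shift()] on
#'   the full read set.
#' @return the short-bin fraction of the subsample (scalar).
#' @export
snr_estimate <- function(reads, sample_size = 5e6, seed = 1L, shift = NULL) {
  stopifnot(inherits(reads, "read_set"))
  if (is.null(shift)) shift <- estimate_shift(reads)$optimized_shift
  if (sample_size >= reads$total_reads) {
    if (sample_size > reads$total_reads)
      warning("sample_size exceeds library size; using all reads")
    sub <- reads
  } else {
    idx <- withr::with_seed(seed,
      sample.int(reads$total_reads, size = sample_size, replace = FALSE))
    sub <- reads
    sub$reads <- reads$reads[sort(idx)]
    sub$total_reads <- length(idx)
  }
  suppressWarnings(
    short_bin_fraction(build_bins(shift_reads(sub, shift)))$fraction)
}
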