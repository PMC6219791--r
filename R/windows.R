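# The adaptive-window engine: initial/step/final windows, Poisson
# enrichment against a local/global background, the maximum-allowed-length
# optimizer, merging into enriched regions (ERs) and ER reporting.

#' Caller parameters
#'
#' @param maximum_allowed_length bin-length ceiling in bp; a step window
#'   containing a bin at or above it is excluded.  `NULL` lets
#'   [call_ers()] run [optimize_max_allowed_length()].
#' @param q_threshold BY q-value cutoff for reported regions.
#' @param merge_p_threshold corrected-p cutoff for merging final windows.
#' @param initial_window_bins bins per initial window (20 for ER calling).
#' @param length_criterion_fraction fraction of merged windows that must be
#'   longer than twice the shift for the optimizer to stop.
#' @return list of class `caller_params`.
#' @export
caller_params <- function(maximum_allowed_length = NULL,
                          q_threshold = 0.05,
                          merge_p_threshold = 0.05,
                          initial_window_bins = 20L,
                          length_criterion_fraction = 0.80) {
  stopifnot(q_threshold > 0, q_threshold < 1,
            merge_p_threshold > 0, merge_p_threshold < 1,
            initial_window_bins >= 2,
            is.null(maximum_allowed_length) || maximum_allowed_length > 0)
  structure(list(maximum_allowed_length = maximum_allowed_length,
                 q_threshold = q_threshold,
                 merge_p_threshold = merge_p_threshold,
                 initial_window_bins = as.integer(initial_window_bins),
                 length_criterion_fraction = length_criterion_fraction),
            class = "caller_params")
}

#' Enumerate sliding initial windows over a bin sequence
#'
#' Windows of `n_bins` consecutive bins advance one bin per step; trailing
#' windows at the chromosome end are emitted with their actual, shorter
#' span.  Chromosomes with fewer than two bins are skipped.
#'
#' @param bins a `bin_seq` from [build_bins()].
#' @param n_bins bins per full window (>= 2).
#' @return data.table `chrom, first_bin, last_bin` (1-based bin indices per
#'   chromosome) with the genomic `start`/`end` of each window.
#' @export
build_initial_windows <- function(bins, n_bins = 20L) {
  stopifnot(n_bins >= 2)
  out <- bins[, {
    B <- .N
    if (B < 2L) NULL else {
      j <- seq_len(B)
      e <- pmin(j + n_bins - 1L, B)
      .(first_bin = j, last_bin = e, start = start[j], end = end[e])
    }
  }, by = chrom]
  if (nrow(out) == 0L)
    out <- data.table::data.table(chrom = character(), first_bin = integer(),
                                  last_bin = integer(), start = integer(),
                                  end = integer())
  out[]
}

#' 3'-anchored step windows of one initial window
#'
#' Step window `k` keeps the last `k` bins of the initial window (anchored
#' at the 3' end); any step window containing a bin with length at or above
#' `max_allowed` is excluded.
#'
#' @param initial one row of [build_initial_windows()] output (list or
#'   single-row data.frame with `chrom, first_bin, last_bin`).
#' @param bins the `bin_seq` the window was built from.
#' @param max_allowed bin-length ceiling in bp.
#' @return data.table `chrom, first_bin, last_bin, start, end` of surviving
#'   step windows (possibly empty).
#' @export
step_windows <- function(initial, bins, max_allowed) {
  stopifnot(max_allowed > 0)
  b <- bins[chrom == initial$chrom]
  e <- as.integer(initial$last_bin)
  j <- as.integer(initial$first_bin)
  len <- b$length[j:e]
  badk <- which(rev(len) >= max_allowed)  # bins counted from the 3' end
  kmax <- if (length(badk)) badk[1L] - 1L else e - j + 1L
  if (kmax < 1L)
    return(data.table::data.table(chrom = character(), first_bin = integer(),
                                  last_bin = integer(), start = integer(),
                                  end = integer()))
  k <- seq_len(kmax)
  data.table::data.table(chrom = initial$chrom, first_bin = e - k + 1L,
                         last_bin = e, start = b$start[e - k + 1L],
                         end = b$end[e])
}

#' Poisson background of a window
#'
#' `max(d_genome * l_window, R_control * SF)`; without a control sample the
#' genome-density term alone is used.
#'
#' @param r_control control reads in the window (`NA` when no control).
#' @param l_window window length in bp.
#' @param dgenome genome-wide expected density, reads/bp.
#' @param sf case/control library-size scale factor (`NA` when no control).
#' @return expected background read count (vectorized).
#' @export
window_background <- function(r_control, l_window, dgenome, sf = NA_real_) {
  base <- dgenome * pmax(l_window, 1)
  ifelse(is.na(r_control) | is.na(sf), base, pmax(base, r_control * sf))
}

#' Upper-tail Poisson enrichment p-value
#'
#' `P(X >= r_case)` for `X ~ Poisson(background)`; `r_case = 0` gives 1.
#'
#' @param r_case observed case reads (vectorized).
#' @param background expected count (> 0).
#' @return p-value in (0, 1].
#' @export
poisson_p <- function(r_case, background) {
  stopifnot(all(background > 0))
  stats::ppois(r_case - 1, background, lower.tail = FALSE)
}

#' Select the final window among step windows
#'
#' Minimum p-value wins; ties prefer the longer window, then the 5'-most.
#'
#' @param steps data.table of step windows carrying a `p` column.
#' @return the selected row (single-row data.table), or `NULL` for empty
#'   input.
#' @export
select_final_window <- function(steps) {
  if (is.null(steps) || nrow(steps) == 0L) return(NULL)
  nb <- steps$last_bin - steps$first_bin + 1L
  ord <- order(steps$p, -nb, steps$first_bin)
  steps[ord[1L]]
}

#' Benjamini-Yekutieli adjusted q-values
#'
#' Step-up adjustment under arbitrary dependence, clipped at 1 and
#' order-preserving (backed by [stats::p.adjust()]).
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return adjusted q-values, `q >= p` elementwise.
#' @export
by_qvalues <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BY")
}

# --- engine -----------------------------------------------------------------

# Case/control positions for one chromosome -> unique final windows.
final_windows_chr <- function(pos, ctrl_pos, w, max_allowed, dg, sf, use_ctrl) {
  n <- length(pos)
  if (n < 3L) return(NULL)  # need >= 2 bins
  if (use_ctrl) {
    le_at <- findInterval(pos, ctrl_pos)       # control reads <= pos
    le <- findInterval(pos - 1L, ctrl_pos)     # control reads <  pos
  } else {
    le_at <- le <- integer(n)
  }
  res <- scan_final_windows(pos, as.integer(w), as.numeric(max_allowed),
                            dg, if (use_ctrl) sf else 0, le_at, le, use_ctrl)
  if (length(res$s) == 0L) return(NULL)
  dt <- data.table::data.table(s = res$s, e = res$e, p = res$p)
  dt <- unique(dt, by = c("s", "e"))
  dt[, `:=`(start = pos[s], end = pos[e + 1L])]
  dt
}

#' Merged significant windows
#'
#' Runs the full window engine over the requested chromosomes: sliding
#' initial windows of `n_bins` bins, 3'-anchored step windows with the
#' `max_allowed` bin exclusion, Poisson scoring, per-initial-window final
#' windows, genome-wide BY correction, and merging (overlapping or
#' book-ended) of significant final windows.
#'
#' @param case,control `read_set`s (shifted); `control` may be `NULL`.
#' @param genome a [genome_model()].
#' @param n_bins bins per initial window.
#' @param max_allowed bin-length ceiling in bp.
#' @param p_threshold corrected-p cutoff for keeping final windows.
#' @param chroms chromosomes to scan (default: all in `genome`).
#' @param correction multiple-testing correction for the merge step:
#'   `"bonferroni"` (family-wise, default) or `"BY"`.  Reported
#'   signal-level q-values always use BY; at the merge step a step-up FDR
#'   turns mass-significant data sets (most windows inside true signal)
#'   into a license for isolated few-read background windows, so the
#'   family-wise rule is the default here.
#' @return data.table `chrom,start,end` of merged windows, sorted.  The
#'   attribute `"final_windows"` carries the unique final windows with
#'   their `p` and BY-corrected `q`.
#' @export
merged_windows <- function(case, control, genome, n_bins, max_allowed,
                           p_threshold = 0.05, chroms = NULL,
                           correction = c("bonferroni", "BY")) {
  correction <- match.arg(correction)
  stopifnot(inherits(case, "read_set"), inherits(genome, "genome_model"))
  use_ctrl <- !is.null(control)
  sf <- if (use_ctrl) case$total_reads / control$total_reads else NA_real_
  dg <- d_genome(genome, case$total_reads)
  if (is.null(chroms)) chroms <- names(genome$chrom_sizes)
  fw <- list()
  for (ch in chroms) {
    pos <- case$reads[chrom == ch, pos]
    cpos <- if (use_ctrl) control$reads[chrom == ch, pos] else integer()
    dt <- final_windows_chr(pos, cpos, n_bins, max_allowed, dg, sf, use_ctrl)
    if (!is.null(dt)) { dt[, chrom := ch]; fw[[ch]] <- dt }
  }
  empty <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer())
  if (length(fw) == 0L) {
    data.table::setattr(empty, "final_windows", empty)
    return(empty)
  }
  fw <- data.table::rbindlist(fw)
  fw[, q := stats::p.adjust(p, method = correction)]
  sig <- fw[q < p_threshold]
  out <- if (nrow(sig)) merge_intervals(sig) else empty
  # duplicate-read stacks can yield zero-width windows (all member reads at
  # one position); such degenerate regions are dropped
  out <- out[end > start]
  data.table::setorder(out, chrom, start)
  data.table::setattr(out, "final_windows",
                      fw[, .(chrom, start, end, p, q)])
  out
}

#' Optimize the maximum-allowed-length parameter
#'
#' Sweeps ten candidates `0.2s, 0.4s, ..., 2s` (`s` = optimized shift) on
#' the training chromosomes; for each, merged significant windows are
#' called and the fraction longer than `2s` measured.  The first (smallest)
#' candidate meeting the length criterion is returned; if none qualifies,
#' `2s` with a warning.
#'
#' @param case,control shifted `read_set`s; `control` may be `NULL`.
#' @param genome a [genome_model()].
#' @param shift optimized shift parameter in bp.
#' @param params a [caller_params()].
#' @return the selected maximum-allowed-length in bp, with attribute
#'   `"sweep"`: a data.table of candidate, merged-window count and fraction
#'   longer than `2s`.
#' @export
optimize_max_allowed_length <- function(case, control, genome, shift,
                                        params = caller_params()) {
  stopifnot(shift > 0)
  cand <- pmax(1, shift * seq(0.2, 2, by = 0.2))
  tr <- training_chroms(genome)
  sweep <- data.table::data.table(max_allowed = cand, n_windows = 0L,
                                  frac_long = NA_real_)
  sel <- NA_real_
  for (i in seq_along(cand)) {
    mw <- merged_windows(case, control, genome, params$initial_window_bins,
                         cand[i], params$merge_p_threshold, chroms = tr)
    sweep[i, n_windows := nrow(mw)]
    if (nrow(mw) == 0L) next
    fl <- mean((mw$end - mw$start) > 2 * shift)
    sweep[i, frac_long := fl]
    if (is.na(sel) && fl >= params$length_criterion_fraction) sel <- cand[i]
  }
  if (all(sweep$n_windows == 0L))
    warning("no significant windows at any candidate; using 2 x shift")
  if (is.na(sel)) {
    if (any(sweep$n_windows > 0L))
      warning("length criterion never met; using 2 x shift")
    sel <- cand[length(cand)]
  }
  attr(sel, "sweep") <- sweep[]
  sel
}

# --- reporting --------------------------------------------------------------

#' Report enrichment statistics for regions
#'
#' For each region computes its length, case read count, local-control
#' density (the piecewise `max(d_ER, d_1kb, d_10kb)` rule: all three for
#' regions up to 1 kb, `d_ER` and `d_10kb` between 1 and 10 kb, `d_ER`
#' alone above 10 kb; the 1 kb / 10 kb windows are centered on the region
#' and clipped at chromosome ends), the Poisson background
#' `max(d_genome*l, d_local*l*SF)`, p-value, fold change
#' `FC = R_case / background`, and the fragment-pileup summit.
#'
#' @param regions data.table `chrom,start,end` (0-based half-open).
#' @param case,control shifted `read_set`s; `control` may be `NULL`.
#' @param genome a [genome_model()].
#' @param shift optimized shift in bp (for summit pileups).
#' @param summits compute summits (skip for speed when not needed).
#' @return `regions` with columns `length, r_case, r_control, background,
#'   p, fc, summit, summit_height` appended (no q; see [by_qvalues()]).
#' @export
report_region <- function(regions, case, control, genome, shift,
                          summits = TRUE) {
  out <- data.table::as.data.table(regions)[, .(chrom, start, end)]
  n <- nrow(out)
  out[, length := end - start]
  out[, r_case := count_reads_in(case, out)]
  dg <- d_genome(genome, case$total_reads)
  use_ctrl <- !is.null(control)
  if (use_ctrl) {
    sf <- case$total_reads / control$total_reads
    l <- pmax(out$length, 1)
    mid <- (out$start + out$end) %/% 2L
    dens_win <- function(halfw) {
      sz <- genome$chrom_sizes[out$chrom]
      a <- pmax(mid - halfw, 0)
      b <- pmin(mid + halfw, sz)
      cnt <- count_reads_in(control, data.table::data.table(
        chrom = out$chrom, start = as.integer(a), end = as.integer(b)))
      cnt / pmax(b - a, 1)
    }
    d_er <- count_reads_in(control, out) / l
    d_1kb <- dens_win(500L)
    d_10kb <- dens_win(5000L)
    d_local <- ifelse(out$length <= 1000, pmax(d_er, d_1kb, d_10kb),
               ifelse(out$length <= 10000, pmax(d_er, d_10kb), d_er))
    out[, r_control := d_local * l]
    out[, background := pmax(dg * l, r_control * sf)]
  } else {
    out[, r_control := NA_real_]
    out[, background := dg * pmax(length, 1)]
  }
  out[, p := poisson_p(r_case, background)]
  out[, fc := r_case / background]
  if (summits && n > 0L) {
    sm <- integer(n); sh <- numeric(n)
    for (i in seq_len(n)) {
      cs <- compute_summit(out[i], case, shift)
      sm[i] <- cs$summit; sh[i] <- cs$height
    }
    out[, `:=`(summit = sm, summit_height = sh)]
  } else {
    out[, `:=`(summit = NA_integer_, summit_height = NA_real_)]
  }
  out[]
}

#' Fragment-pileup summit of a region
#'
#' Case reads inside the region are extended by the optimized shift on both
#' sides of their (shifted) position; the summit is the leftmost position
#' of maximum pileup inside the region.  A region without reads falls back
#' to its midpoint with a warning.
#'
#' @param region list or single-row data.table with `chrom,start,end`.
#' @param case shifted case `read_set`.
#' @param shift optimized shift in bp.
#' @return list with `summit` (bp) and `height` (max pileup).
#' @export
compute_summit <- function(region, case, shift) {
  pos <- case$reads[chrom == region$chrom & pos >= region$start &
                      pos < region$end, pos]
  if (length(pos) == 0L) {
    warning("region without case reads; summit set to midpoint")
    return(list(summit = as.integer((region$start + region$end) %/% 2L),
                height = 0))
  }
  res <- pileup_summit(pos, as.integer(round(shift)),
                       as.integer(region$start), as.integer(region$end))
  list(summit = res$summit, height = res$height)
}

#' Call enriched regions (ERs)
#'
#' End-to-end ER calling on shifted reads: window engine over all
#' chromosomes, genome-wide BY correction of final-window p-values, merging
#' of significant windows, per-ER reporting, BY correction across reported
#' ERs and filtering at the q threshold.
#'
#' @param case,control shifted `read_set`s; `control` may be `NULL`.
#' @param genome a [genome_model()].
#' @param shift optimized shift in bp.
#' @param params a [caller_params()]; when `maximum_allowed_length` is
#'   `NULL` it is optimized on the training chromosomes first.
#' @return data.table of class `region_table`: one row per ER with
#'   `chrom,start,end,name,length,r_case,r_control,background,p,q,fc,
#'   summit,summit_height`, coordinate-sorted and pairwise disjoint.  The
#'   attributes `"max_allowed"` and `"final_windows"` record the engine
#'   state.
#' @export
call_ers <- function(case, control = NULL, genome, shift,
                     params = caller_params()) {
  if (is.null(params$maximum_allowed_length))
    params$maximum_allowed_length <-
      as.numeric(optimize_max_allowed_length(case, control, genome, shift,
                                             params))
  mw <- merged_windows(case, control, genome, params$initial_window_bins,
                       params$maximum_allowed_length,
                       params$merge_p_threshold)
  ers <- report_region(mw, case, control, genome, shift)
  if (nrow(ers)) {
    ers[, q := by_qvalues(p)]
    ers <- ers[q < params$q_threshold]
  } else ers[, q := numeric(0)]
  data.table::setorder(ers, chrom, start)
  ers[, name := sprintf("ER_%05d", seq_len(.N))]
  data.table::setcolorder(ers, c("chrom", "start", "end", "name"))
  data.table::setattr(ers, "max_allowed", params$maximum_allowed_length)
  data.table::setattr(ers, "final_windows", attr(mw, "final_windows"))
  data.table::setattr(ers, "class", c("region_table", class(ers)))
  ers[]
}

#' Export a region table as BED6+
#'
#' Score is `-10*log10(q)` (capped at 10000); extra columns carry the
#' summit offset, case reads, p, q and fold change.
#'
#' @param regions a `region_table` from [call_ers()] or the cluster
#'   callers.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_regions_bed <- function(regions, path) {
  dt <- data.table::as.data.table(regions)
  dt[, score := round(pmin(-10 * log10(pmax(q, 1e-300)), 10000), 2)]
  dt[, strand := "."]
  extras <- intersect(c("summit", "r_case", "p", "q", "fc", "n_members",
                        "members"), names(dt))
  if ("summit" %in% extras) dt[, summit := summit - start]
  write_bed(dt, path, extra = extras)
}
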