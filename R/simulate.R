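# Seeded ChIP-seq read simulator with ground truth.  Fragments of a fixed
# size are dropped uniformly in the background or inside planted features
# (narrow peaks, clustered peaks, broad domains fragmented into
# sub-regions); each fragment emits one single-end read: a + read at the
# fragment start or a - read at the fragment end, with equal probability,
# so the optimized shift recovers fragment_size/2.  PCR amplification bias
# replaces a fraction of reads with exact duplicates of others.

#' Simulation configuration
#'
#' Defaults describe a small mammalian-like test genome: five 2 Mb
#' chromosomes (so the chr1-chr5 training convention is exercised), 200 bp
#' fragments, and a case library with 60% of reads falling inside planted
#' features -- a strongly enriched TF-like data set.
#'
#' @param chrom_sizes named vector of chromosome sizes.
#' @param fragment_size DNA fragment size in bp.
#' @param case_reads,control_reads library sizes.
#' @param in_feature_fraction fraction of case reads inside peak/cluster
#'   features.
#' @param pcr_rate fraction of reads that are PCR duplicates of others.
#' @param peaks list `n, width`: isolated narrow peaks.
#' @param clusters list `n, peaks_per_cluster, peak_width, gap`: groups of
#'   closely spaced peaks (SER-like truth).
#' @param domains list `n, width, subregions, enrichment`: broad domains
#'   whose reads fall in `subregions` blocks at `enrichment` times the
#'   background density, separated by read gaps (LER-like truth).
#' @param min_feature_gap minimum distance between planted features in bp.
#'   The default, 10 kb, is the SER connecting-length cap: features closer
#'   than the clustering scale would be legitimately clustered by the
#'   method, leaving "isolated" truth labels ill-defined.  Domain worlds
#'   should raise it to ~50 kb (the LER scale) for the same reason.
#' @param seed integer seed; every draw flows from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(chrom_sizes = stats::setNames(rep(2e6, 5), paste0("chr", 1:5)),
                       fragment_size = 200L,
                       case_reads = 4e5, control_reads = 4e5,
                       in_feature_fraction = 0.6,
                       pcr_rate = 0,
                       peaks = list(n = 300L, width = 250L),
                       clusters = NULL,
                       domains = NULL,
                       min_feature_gap = 10000L,
                       seed = 1L) {
  stopifnot(in_feature_fraction >= 0, in_feature_fraction <= 1,
            pcr_rate >= 0, pcr_rate < 1, fragment_size > 0)
  structure(list(chrom_sizes = chrom_sizes, fragment_size = fragment_size,
                 case_reads = case_reads, control_reads = control_reads,
                 in_feature_fraction = in_feature_fraction,
                 pcr_rate = pcr_rate, peaks = peaks, clusters = clusters,
                 domains = domains, min_feature_gap = min_feature_gap,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Place n features of width w without overlap, with a margin between them.
place_features <- function(n, w, chrom_sizes, margin, occupied) {
  out <- vector("list", n)
  chroms <- names(chrom_sizes)
  pr <- chrom_sizes / sum(chrom_sizes)
  for (i in seq_len(n)) {
    for (att in seq_len(2000L)) {
      ch <- sample(chroms, 1L, prob = pr)
      size <- chrom_sizes[[ch]]
      if (size <= w + 2 * margin) next
      s <- floor(stats::runif(1, margin, size - w - margin))
      occ <- occupied[[ch]]
      if (is.null(occ) ||
          !any(s - margin < occ$end & s + w + margin > occ$start)) {
        occupied[[ch]] <- rbind(occ, data.frame(start = s, end = s + w))
        out[[i]] <- data.table::data.table(chrom = ch, start = as.integer(s),
                                           end = as.integer(s + w))
        break
      }
    }
    if (is.null(out[[i]])) stop("could not place all simulated features")
  }
  list(features = data.table::rbindlist(out), occupied = occupied)
}

#' Simulate case/control ChIP-seq read sets with known truth
#'
#' @param config a [sim_config()].
#' @return list with `case` and `control` (`read_set`s), `truth` (a
#'   data.table `chrom,start,end,label` where `label` is `peak`, `cluster`
#'   or `domain`; cluster member peaks are also emitted as `peak` rows and
#'   domain sub-regions as `subregion` rows), `genome`
#'   (a [genome_model()]) and `config`.
#' @export
simulate_chipseq <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cs <- config$chrom_sizes
  genome <- genome_model(cs)
  res <- withr::with_seed(config$seed, {
    occupied <- list()
    truth <- list()
    feat_intervals <- NULL   # peak/cluster-member intervals (weight by width)
    dom_intervals <- NULL    # domain sub-regions (density model)
    if (!is.null(config$peaks) && config$peaks$n > 0) {
      pf <- place_features(config$peaks$n, config$peaks$width, cs,
                           config$min_feature_gap, occupied)
      occupied <- pf$occupied
      truth$peaks <- data.table::copy(pf$features)[, label := "peak"]
      feat_intervals <- rbind(feat_intervals, pf$features)
    }
    if (!is.null(config$clusters) && config$clusters$n > 0) {
      cl <- config$clusters
      span <- cl$peaks_per_cluster * cl$peak_width +
        (cl$peaks_per_cluster - 1L) * cl$gap
      pf <- place_features(cl$n, span, cs, config$min_feature_gap, occupied)
      occupied <- pf$occupied
      env <- data.table::copy(pf$features)[, label := "cluster"]
      memb <- pf$features[, {
        off <- (seq_len(cl$peaks_per_cluster) - 1L) * (cl$peak_width + cl$gap)
        .(start = start + off, end = start + off + cl$peak_width)
      }, by = .(chrom, cstart = start)][, .(chrom, start, end)]
      memb[, label := "peak"]
      truth$clusters <- rbind(env, memb)
      feat_intervals <- rbind(feat_intervals, memb[, .(chrom, start, end)])
    }
    if (!is.null(config$domains) && config$domains$n > 0) {
      dm <- config$domains
      pf <- place_features(dm$n, dm$width, cs, config$min_feature_gap, occupied)
      occupied <- pf$occupied
      env <- data.table::copy(pf$features)[, label := "domain"]
      # split each domain into `subregions` read blocks separated by gaps
      # (gaps take ~30% of the domain and fragment the read coverage)
      k <- dm$subregions
      gap_total <- 0.3 * dm$width
      gw <- if (k > 1L) gap_total / (k - 1L) else 0
      bw <- (dm$width - gap_total * (k > 1L)) / k
      sub <- pf$features[, {
        off <- (seq_len(k) - 1L) * (bw + gw)
        .(start = as.integer(start + off), end = as.integer(start + off + bw))
      }, by = .(chrom, dstart = start)][, .(chrom, start, end)]
      sub[, label := "subregion"]
      truth$domains <- rbind(env, sub)
      dom_intervals <- sub[, .(chrom, start, end)]
    }
    truth <- data.table::rbindlist(truth)
    if (nrow(truth) == 0L)
      truth <- data.table::data.table(chrom = character(), start = integer(),
                                      end = integer(), label = character())
    # read allocation
    N <- config$case_reads
    n_feat <- if (!is.null(feat_intervals) && nrow(feat_intervals))
      round(config$in_feature_fraction * N) else 0L
    G <- sum(as.numeric(cs))
    if (!is.null(dom_intervals) && nrow(dom_intervals)) {
      Ld <- sum(as.numeric(dom_intervals$end - dom_intervals$start))
      m <- config$domains$enrichment
      # background density db solves N = n_feat + db*G + (m-1)*db*Ld
      db <- (N - n_feat) / (G + (m - 1) * Ld)
      n_dom <- round((m - 1) * db * Ld)
    } else n_dom <- 0L
    n_bg <- N - n_feat - n_dom
    case_pos <- c(
      uniform_fragment_reads(n_bg, cs, config$fragment_size),
      interval_fragment_reads(n_feat, feat_intervals, config$fragment_size),
      interval_fragment_reads(n_dom, dom_intervals, config$fragment_size))
    case_dt <- data.table::rbindlist(case_pos[!vapply(case_pos, is.null, TRUE)])
    case_dt <- apply_pcr(case_dt, config$pcr_rate)
    ctrl_dt <- data.table::rbindlist(
      uniform_fragment_reads(config$control_reads, cs, config$fragment_size))
    ctrl_dt <- apply_pcr(ctrl_dt, config$pcr_rate)
    list(case_dt = case_dt, ctrl_dt = ctrl_dt, truth = truth)
  })
  case <- read_set(res$case_dt, "sim_case", layout = "single",
                   fragment_hint = config$fragment_size, chrom_sizes = cs)
  control <- read_set(res$ctrl_dt, "sim_control", layout = "single",
                      fragment_hint = config$fragment_size, chrom_sizes = cs)
  list(case = case, control = control, truth = res$truth,
       genome = genome, config = config)
}

# n fragment centers uniform over the genome -> list of read tables.
uniform_fragment_reads <- function(n, chrom_sizes, fragment_size) {
  if (n <= 0) return(list(NULL))
  chroms <- sample(names(chrom_sizes), n, replace = TRUE,
                   prob = chrom_sizes / sum(chrom_sizes))
  centers <- floor(stats::runif(n, 0, chrom_sizes[chroms]))
  list(fragment_to_reads(chroms, centers, fragment_size, chrom_sizes))
}

# n fragments covering bound points uniform within intervals (weighted by
# width).  A fragment is captured when it overlaps the bound point, so its
# center scatters up to fragment_size/2 beyond the feature -- the standard
# pileup geometry that read-shifting methods rely on.
interval_fragment_reads <- function(n, intervals, fragment_size) {
  if (n <= 0 || is.null(intervals) || nrow(intervals) == 0L)
    return(list(NULL))
  w <- intervals$end - intervals$start
  idx <- sample.int(nrow(intervals), n, replace = TRUE, prob = w)
  points <- intervals$start[idx] + stats::runif(n, 0, w[idx])
  half <- fragment_size / 2
  centers <- floor(points + stats::runif(n, -half, half))
  list(fragment_to_reads(intervals$chrom[idx], centers, fragment_size, NULL))
}

# One read per fragment: + at the start or - at the end, equal probability.
fragment_to_reads <- function(chroms, centers, fragment_size, chrom_sizes) {
  minus <- stats::runif(length(centers)) < 0.5
  pos <- ifelse(minus, centers + fragment_size %/% 2L,
                centers - fragment_size %/% 2L)
  pos <- pmax(pos, 0L)
  if (!is.null(chrom_sizes))
    pos <- pmin(pos, chrom_sizes[chroms] - 1L)
  data.table::data.table(chrom = chroms, pos = as.integer(pos),
                         strand = ifelse(minus, "-", "+"))
}

# Replace a fraction of reads with exact duplicates of surviving reads,
# keeping the library size fixed (duplicated positions then cluster, the
# artificial-enrichment signature of over-amplification).
apply_pcr <- function(dt, rate) {
  n <- nrow(dt)
  ndup <- round(rate * n)
  if (ndup == 0L) return(dt)
  keep <- sample.int(n, n - ndup)
  dup <- sample(keep, ndup, replace = TRUE)
  dt[c(keep, dup)]
}

#' Precision/recall of calls against simulation truth
#'
#' Greedy one-to-one matching: candidate pairs meeting the reciprocal
#' overlap criterion are matched in order of decreasing overlap, each call
#' and truth interval at most once.
#'
#' @param calls data.table `chrom,start,end`.
#' @param truth data.table `chrom,start,end` (filter by `label` first).
#' @param min_reciprocal minimum reciprocal overlap fraction (both
#'   directions) for a valid match; default 0.5.
#' @return list with `precision`, `recall`, `n_matched`.
#' @export
truth_eval <- function(calls, truth, min_reciprocal = 0.5) {
  ct <- data.table::as.data.table(calls)
  tt <- data.table::as.data.table(truth)
  if (nrow(ct) == 0L)
    return(list(precision = NA_real_, recall = 0, n_matched = 0L))
  if (nrow(tt) == 0L)
    return(list(precision = 0, recall = NA_real_, n_matched = 0L))
  hits <- dt_overlaps(ct, tt)
  if (length(hits) == 0L)
    return(list(precision = 0, recall = 0, n_matched = 0L))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- pmin(ct$end[qi], tt$end[si]) - pmax(ct$start[qi], tt$start[si])
  wq <- ct$end[qi] - ct$start[qi]
  ws <- tt$end[si] - tt$start[si]
  ok <- ov >= min_reciprocal * wq & ov >= min_reciprocal * ws
  cand <- data.table::data.table(qi = qi[ok], si = si[ok], ov = ov[ok])
  data.table::setorder(cand, -ov)
  used_q <- logical(nrow(ct)); used_s <- logical(nrow(tt)); nm <- 0L
  for (i in seq_len(nrow(cand))) {
    a <- cand$qi[i]; b <- cand$si[i]
    if (!used_q[a] && !used_s[b]) {
      used_q[a] <- TRUE; used_s[b] <- TRUE; nm <- nm + 1L
    }
  }
  list(precision = nm / nrow(ct), recall = nm / nrow(tt), n_matched = nm)
}

#' Write simulated reads as BED6
#'
#' Each read becomes a 1 bp interval at its 5' position with its strand
#' (deterministic given the read set, so identical config and seed give
#' byte-identical files).
#'
#' @param reads a `read_set`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  dt <- reads$reads[, .(chrom, start = pos, end = pos + 1L,
                        name = ".", score = 0L, strand)]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
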