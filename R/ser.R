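# Short-ER clusters (SERs): the FR-D fragmentation statistic, PDNP
# connecting-length candidates from shuffled regions, and SER calling.

#' Fragment rate by distance (FR-D)
#'
#' Over all neighboring region pairs within chromosomes, the fraction whose
#' gap `d` is small relative to the regions' lengths: under the default
#' `"or"` rule a pair is fragmented when `d < l1/2` or `d < l2/2`
#' (equivalently `2d < max(l1, l2)`).  A high FR-D indicates single signals
#' split into several called regions.
#'
#' @param regions data.table `chrom,start,end`, coordinate-sorted, disjoint.
#' @param rule `"or"` (default), `"and"`, or `"min"` (`2d < min(l1,l2)`).
#' @return fragmented-pair fraction; 0 when fewer than two regions pair up.
#' @export
fr_d <- function(regions, rule = c("or", "and", "min")) {
  rule <- match.arg(rule)
  pr <- neighbor_pairs(regions)
  if (nrow(pr) == 0L) return(0)
  frag <- switch(rule,
    "or"  = pr$gap < pr$l1 / 2 | pr$gap < pr$l2 / 2,
    "and" = pr$gap < pr$l1 / 2 & pr$gap < pr$l2 / 2,
    "min" = 2 * pr$gap < pmin(pr$l1, pr$l2))
  mean(frag)
}

# Neighboring pairs within chromosomes: gap and both member spans.
neighbor_pairs <- function(regions) {
  dt <- data.table::as.data.table(regions)[, .(chrom, start, end)]
  data.table::setorder(dt, chrom, start)
  dt[, if (.N >= 2L) .(
    start1 = start[-.N], end1 = end[-.N],
    start2 = start[-1L], end2 = end[-1L],
    gap = start[-1L] - end[-.N],
    l1 = (end - start)[-.N], l2 = (end - start)[-1L]), by = chrom]
}

#' Shuffle regions uniformly within their chromosomes
#'
#' Each region keeps its length and chromosome and is placed uniformly at
#' random without overlap (rejection sampling, seeded).  Placement failure
#' after 1000 attempts for any region is fatal.
#'
#' @param regions data.table `chrom,start,end`.
#' @param genome a [genome_model()].
#' @param seed integer seed.
#' @return sorted data.table `chrom,start,end` of shuffled regions.
#' @export
shuffle_regions <- function(regions, genome, seed = 1L) {
  dt <- data.table::as.data.table(regions)[, .(chrom, start, end)]
  out <- withr::with_seed(as.integer(seed), {
    res <- list()
    for (ch in unique(dt$chrom)) {
      lens <- dt[chrom == ch, end - start]
      size <- as.numeric(genome$chrom_sizes[[ch]])
      if (sum(lens) >= size)
        stop("regions on ", ch, " exceed the chromosome length; cannot shuffle")
      ps <- numeric(0); pe <- numeric(0)
      for (len in lens) {
        placed <- FALSE
        for (att in seq_len(1000L)) {
          s <- floor(stats::runif(1, 0, size - len))
          if (!any(s < pe & s + len > ps)) {
            ps <- c(ps, s); pe <- c(pe, s + len); placed <- TRUE; break
          }
        }
        if (!placed) stop("failed to place a shuffled region on ", ch,
                          " after 1000 attempts")
      }
      res[[ch]] <- data.table::data.table(chrom = ch, start = as.integer(ps),
                                          end = as.integer(pe))
    }
    data.table::rbindlist(res)
  })
  data.table::setorder(out, chrom, start)
  out[]
}

#' PDNP connecting-length candidates
#'
#' Nearest-rank percentiles of the sorted neighbor gaps of shuffled
#' regions, at the requested percentile levels; values at or above `cap`
#' are discarded (10 kb for SER calling, 100 kb for LER calling).
#'
#' @param shuffled sorted data.table `chrom,start,end` (from
#'   [shuffle_regions()]), or a numeric vector of gaps.
#' @param levels percentile levels (1..10 for SERs; 5,10,...,50 for LERs).
#' @param cap maximum admissible connecting length in bp.
#' @return object of class `pdnp_grid`: list with `levels`, `values` (bp,
#'   non-decreasing), `cap`.  An empty grid (all values at or above the
#'   cap) triggers a warning.
#' @export
pdnp_candidates <- function(shuffled, levels = 1:10, cap = 1e4) {
  gaps <- if (is.numeric(shuffled)) shuffled
          else neighbor_pairs(shuffled)$gap
  gaps <- sort(gaps)
  n <- length(gaps)
  if (n < 100L) warning("fewer than 100 neighbor gaps; PDNP grid is noisy")
  if (n == 0L) {
    warning("no neighbor gaps; PDNP grid empty")
    return(structure(list(levels = integer(), values = numeric(), cap = cap),
                     class = "pdnp_grid"))
  }
  idx <- pmax(1L, ceiling(levels / 100 * n))  # nearest-rank
  vals <- gaps[idx]
  keep <- vals < cap
  if (!any(keep))
    warning("all PDNP values at or above the cap; grid empty")
  structure(list(levels = levels[keep], values = vals[keep], cap = cap),
            class = "pdnp_grid")
}

#' @export
print.pdnp_grid <- function(x, ...) {
  cat("<pdnp_grid> cap ", x$cap, " bp; ", length(x$values),
      " candidate(s)\n", sep = "")
  if (length(x$values))
    print(data.table::data.table(percentile = x$levels, l_pdnp = x$values))
  invisible(x)
}

#' Bins per initial window for cluster calling
#'
#' `x = min(max(floor(l_PDNP * d_genome * 5), 20), 500)`: the expected read
#' count within five connecting lengths, floored at 20 and capped at 500
#' bins.
#'
#' @param l_pdnp connecting length in bp.
#' @param dgenome genome-wide expected density, reads/bp.
#' @return integer bin count.
#' @export
ser_window_bins <- function(l_pdnp, dgenome) {
  stopifnot(l_pdnp > 0, dgenome > 0)
  as.integer(min(max(floor(l_pdnp * dgenome * 5), 20), 500))
}

# Trim merged windows to the shortest region covering their member units;
# windows covering no unit are discarded.  Each unit joins the window it
# overlaps most.  Returns list(clusters, membership).
trim_to_units <- function(windows, units) {
  empty <- list(clusters = data.table::data.table(
                  chrom = character(), start = integer(), end = integer(),
                  n_members = integer(), members = character()),
                membership = data.table::data.table(
                  cluster_idx = integer(), chrom = character(),
                  start = integer(), end = integer(), name = character()))
  if (nrow(windows) == 0L || nrow(units) == 0L) return(empty)
  w <- data.table::as.data.table(windows)[, .(chrom, start, end)]
  w[, window_id := .I]
  u <- data.table::as.data.table(units)[, .(chrom, start, end,
    name = if ("name" %in% names(units)) units$name else sprintf("u%05d", .I))]
  u[, xid := .I]
  # closed-coordinate view so book-ended half-open intervals do not touch
  wk <- w[, .(chrom, cs = start, ce = end - 1L, window_id)]
  uk <- u[, .(chrom, cs = start, ce = end - 1L, xid)]
  data.table::setkey(wk, chrom, cs, ce)
  ovl <- data.table::foverlaps(uk, wk, nomatch = NULL)
  if (nrow(ovl) == 0L) return(empty)
  ovl[, ov := pmin(ce, i.ce) - pmax(cs, i.cs) + 1L]
  ovl <- ovl[order(xid, -ov, window_id)][!duplicated(xid)]
  mem <- merge(ovl[, .(xid, window_id)], u, by = "xid")
  data.table::setorder(mem, window_id, start)
  clusters <- mem[, .(chrom = chrom[1L], start = min(start), end = max(end),
                      n_members = .N,
                      members = paste(name, collapse = ",")),
                  by = window_id]
  data.table::setorder(clusters, chrom, start)
  clusters[, cluster_idx := .I]
  membership <- merge(mem, clusters[, .(window_id, cluster_idx)],
                      by = "window_id")[, .(cluster_idx, chrom, start, end, name)]
  data.table::setorder(membership, cluster_idx, start)
  list(clusters = clusters[, .(chrom, start, end, n_members, members)],
       membership = membership)
}

#' Call short-ER clusters (SERs)
#'
#' When the genome-wide FR-D of the ERs exceeds `frd_threshold`, candidate
#' connecting lengths are drawn from the 1st-10th percentiles of shuffled
#' inter-ER distances (capped at 10 kb).  For each candidate `l_PDNP`
#' (ascending) the window engine is rerun on the training chromosomes with
#' `x`-bin initial windows ([ser_window_bins()]) and bin exclusion at
#' `l_PDNP`; merged significant windows are trimmed to the shortest region
#' covering their member ERs (windows covering no ER are discarded) and the
#' FR-D of the trimmed set is measured.  The largest candidate with FR-D
#' below the threshold wins (if none qualifies, the FR-D-minimizing
#' candidate with a warning) and is applied genome-wide.
#'
#' @param ers a `region_table` of ERs.
#' @param case,control shifted `read_set`s; `control` may be `NULL`.
#' @param genome a [genome_model()].
#' @param shift optimized shift in bp (for cluster reporting).
#' @param frd_threshold FR-D trigger and stopping threshold (default 1%).
#' @param frd_rule rule passed to [fr_d()].
#' @param grid optional precomputed [pdnp_candidates()] grid.
#' @param seed seed for the region shuffle.
#' @param merge_p_threshold corrected-p cutoff inside the window engine.
#' @return `region_table` of SERs with member bookkeeping
#'   (`n_members`, `members`) and report columns; attributes `"l_pdnp"`,
#'   `"sweep"` (candidate FR-D table), `"frd"` (FR-D of the reported set)
#'   and `"membership"`.  Empty when FR-D does not exceed the trigger.
#' @export
call_sers <- function(ers, case, control = NULL, genome, shift,
                      frd_threshold = 0.01, frd_rule = "or", grid = NULL,
                      seed = 1L, merge_p_threshold = 0.05) {
  frd0 <- fr_d(ers, rule = frd_rule)
  if (frd0 <= frd_threshold) {
    message("FR-D = ", signif(frd0, 3), " <= ", frd_threshold,
            ": no SER calling needed")
    return(empty_cluster_table("SER"))
  }
  if (is.null(grid))
    grid <- pdnp_candidates(shuffle_regions(ers, genome, seed),
                            levels = 1:10, cap = 1e4)
  if (length(grid$values) == 0L) {
    warning("empty PDNP grid; SER calling skipped")
    return(empty_cluster_table("SER"))
  }
  dg <- d_genome(genome, case$total_reads)
  tr <- training_chroms(genome)
  ers_tr <- data.table::as.data.table(ers)[chrom %in% tr]
  cand <- sort(unique(grid$values))
  sweep <- data.table::data.table(l_pdnp = cand, x_bins = NA_integer_,
                                  frd = NA_real_)
  for (i in seq_along(cand)) {
    x <- ser_window_bins(cand[i], dg)
    mw <- merged_windows(case, control, genome, x, cand[i],
                         merge_p_threshold, chroms = tr)
    tu <- trim_to_units(mw, ers_tr)
    sweep[i, `:=`(x_bins = x, frd = fr_d(tu$clusters, rule = frd_rule))]
  }
  ok <- which(sweep$frd < frd_threshold)
  if (length(ok)) {
    sel <- max(ok)
  } else {
    warning("no candidate connecting length reaches FR-D < ", frd_threshold,
            "; using the FR-D-minimizing candidate")
    sel <- which.min(sweep$frd)
  }
  l_sel <- cand[sel]
  mw <- merged_windows(case, control, genome, sweep$x_bins[sel], l_sel,
                       merge_p_threshold)
  tu <- trim_to_units(mw, ers)
  out <- finish_clusters(tu, "SER", case, control, genome, shift)
  data.table::setattr(out, "l_pdnp", l_sel)
  data.table::setattr(out, "sweep", sweep[])
  data.table::setattr(out, "frd", fr_d(out, rule = frd_rule))
  out
}

# Shared tail of SER/LER calling: report, q-values, names.
finish_clusters <- function(tu, kind, case, control, genome, shift) {
  cl <- tu$clusters
  if (nrow(cl) == 0L) return(empty_cluster_table(kind))
  rep <- report_region(cl[, .(chrom, start, end)], case, control, genome,
                       shift, summits = FALSE)
  out <- cbind(rep, cl[, .(n_members, members)])
  out[, q := by_qvalues(p)]
  data.table::setorder(out, chrom, start)
  out[, name := sprintf("%s_%05d", kind, seq_len(.N))]
  data.table::setcolorder(out, c("chrom", "start", "end", "name"))
  data.table::setattr(out, "kind", kind)
  data.table::setattr(out, "membership", tu$membership)
  data.table::setattr(out, "class", c("region_table", class(out)))
  out[]
}

empty_cluster_table <- function(kind) {
  out <- data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    name = character(), length = integer(), r_case = integer(),
    r_control = numeric(), background = numeric(), p = numeric(),
    fc = numeric(), summit = integer(), summit_height = numeric(),
    n_members = integer(), members = character(), q = numeric())
  data.table::setattr(out, "kind", kind)
  data.table::setattr(out, "class", c("region_table", class(out)))
  out
}
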