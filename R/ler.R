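# Long-ER clusters (LERs, broad enrichment signals): reads-enrichment over
# covering regions of neighboring units, the FR-RE statistic, LER calling
# and the matched-length variant used for TF clusters.

#' Case/control library scale factor
#'
#' @param case_total,control_total mapped read totals.
#' @return `case_total / control_total`.
#' @export
scale_factor <- function(case_total, control_total) {
  if (is.null(control_total) || is.na(control_total) || control_total <= 0)
    stop("LER calling requires a control sample with mapped reads")
  case_total / control_total
}

#' Reads enrichment (RE) of a region
#'
#' `RE = R_case / max(R_control * SF, d_genome * l_region)`: the control
#' count is scaled to the case library and floored by the genome-density
#' expectation so empty control stretches cannot inflate the ratio
#' (set `floor = FALSE` for the raw `R_case / (R_control * SF)` variant).
#'
#' @param r_case,r_control read counts over the region (vectorized).
#' @param sf library scale factor from [scale_factor()].
#' @param dgenome genome-wide expected density, reads/bp.
#' @param l_region region length in bp.
#' @param floor apply the genome-density floor (default `TRUE`).
#' @return unitless enrichment ratio, >= 0.
#' @export
region_re <- function(r_case, r_control, sf, dgenome, l_region, floor = TRUE) {
  stopifnot(all(l_region > 0))
  denom <- if (floor) pmax(r_control * sf, dgenome * l_region)
           else r_control * sf
  r_case / denom
}

# RE of every neighboring-unit covering region (shortest interval spanning
# both members, counts inclusive of the members).
neighbor_pair_re <- function(units, case, control, genome, floor = TRUE) {
  pr <- neighbor_pairs(units)
  if (nrow(pr) == 0L) return(pr)
  reg <- pr[, .(chrom, start = start1, end = end2)]
  sf <- scale_factor(case$total_reads, control$total_reads)
  dg <- d_genome(genome, case$total_reads)
  pr[, r_case := count_reads_in(case, reg)]
  pr[, r_control := count_reads_in(control, reg)]
  pr[, re := region_re(r_case, r_control, sf, dg, end2 - start1, floor = floor)]
  pr
}

#' Fragment rate by reads enrichment (FR-RE)
#'
#' The fraction of neighboring-unit covering regions with `RE` strictly
#' above `re_threshold`: elevated read enrichment across the gap between
#' two called regions is evidence that they fragment one broad signal.
#'
#' @param units data.table `chrom,start,end` (ERs or SERs), sorted,
#'   disjoint.
#' @param case,control shifted `read_set`s (control required).
#' @param genome a [genome_model()].
#' @param re_threshold RE cutoff (default 1.5, strict `>`).
#' @param floor see [region_re()].
#' @return fraction in `[0, 1]`; 0 when fewer than two units pair up.
#' @export
fr_re <- function(units, case, control, genome, re_threshold = 1.5,
                  floor = TRUE) {
  pr <- neighbor_pair_re(units, case, control, genome, floor = floor)
  if (nrow(pr) == 0L) return(0)
  mean(pr$re > re_threshold)
}

# FR-RE restricted to neighboring members inside clusters; NaN when no
# cluster has two members (vacuous).
frre_within <- function(membership, case, control, genome,
                        re_threshold = 1.5, floor = TRUE) {
  if (nrow(membership) == 0L) return(NaN)
  res <- membership[, if (.N >= 2L) {
    pr <- neighbor_pair_re(.SD, case, control, genome, floor = floor)
    .(re = pr$re)
  }, by = cluster_idx]
  if (nrow(res) == 0L) return(NaN)
  mean(res$re > re_threshold)
}

#' Call long-ER clusters (LERs)
#'
#' Clusters ERs (or SERs) into broad enrichment signals.  When the
#' genome-wide FR-RE of the units exceeds `frre_trigger`, candidate
#' connecting lengths are drawn from the 5th-50th percentiles (step 5) of
#' shuffled inter-unit distances, capped at 100 kb.  Each candidate reruns
#' the window engine on the training chromosomes exactly as in SER calling;
#' merged windows are trimmed to the shortest region covering their member
#' units and the FR-RE of neighboring members inside the clusters is
#' measured.  The largest candidate keeping FR-RE at or above `frre_stop`
#' wins (if none, the smallest candidate with a warning) and is applied
#' genome-wide.
#'
#' @param units `region_table` of ERs or SERs.
#' @param case,control shifted `read_set`s; a control is mandatory.
#' @param genome a [genome_model()].
#' @param shift optimized shift in bp.
#' @param frre_trigger genome-wide FR-RE needed to call LERs at all.
#' @param frre_stop FR-RE floor the reported clusters must keep (default
#'   99%).
#' @param re_threshold RE cutoff defining an enriched covering region.
#' @param grid optional precomputed [pdnp_candidates()] grid.
#' @param seed seed for the region shuffle.
#' @param merge_p_threshold corrected-p cutoff inside the window engine.
#' @param floor see [region_re()].
#' @return `region_table` of LERs (see [call_sers()] for the shape);
#'   attributes `"l_pdnp"`, `"sweep"`, `"frre"` (FR-RE inside the reported
#'   clusters) and `"membership"`.
#' @export
call_lers <- function(units, case, control, genome, shift,
                      frre_trigger = 0.01, frre_stop = 0.99,
                      re_threshold = 1.5, grid = NULL, seed = 1L,
                      merge_p_threshold = 0.05, floor = TRUE) {
  sf <- scale_factor(case$total_reads,
                     if (is.null(control)) NA_real_ else control$total_reads)
  frre0 <- fr_re(units, case, control, genome, re_threshold, floor = floor)
  if (frre0 <= frre_trigger) {
    message("FR-RE = ", signif(frre0, 3), " <= ", frre_trigger,
            ": no LER calling needed")
    return(empty_cluster_table("LER"))
  }
  if (is.null(grid))
    grid <- pdnp_candidates(shuffle_regions(units, genome, seed),
                            levels = seq(5, 50, by = 5), cap = 1e5)
  if (length(grid$values) == 0L) {
    warning("empty PDNP grid; LER calling skipped")
    return(empty_cluster_table("LER"))
  }
  sw <- ler_candidate_sweep(units, case, control, genome, grid,
                            re_threshold, merge_p_threshold, floor)
  pass <- is.nan(sw$frre) | sw$frre >= frre_stop
  if (any(pass)) {
    sel <- max(which(pass))
  } else {
    warning("no candidate keeps FR-RE >= ", frre_stop,
            "; using the smallest connecting length")
    sel <- 1L
  }
  out <- ler_call_at(sw$l_pdnp[sel], sw$x_bins[sel], units, case, control,
                     genome, shift, merge_p_threshold)
  data.table::setattr(out, "l_pdnp", sw$l_pdnp[sel])
  data.table::setattr(out, "sweep", sw[])
  data.table::setattr(out, "frre",
    frre_within(attr(out, "membership"), case, control, genome,
                re_threshold, floor))
  out
}

# Candidate sweep on the training chromosomes.
ler_candidate_sweep <- function(units, case, control, genome, grid,
                                re_threshold, merge_p_threshold, floor) {
  dg <- d_genome(genome, case$total_reads)
  tr <- training_chroms(genome)
  units_tr <- data.table::as.data.table(units)[chrom %in% tr]
  cand <- sort(unique(grid$values))
  sw <- data.table::data.table(l_pdnp = cand, x_bins = NA_integer_,
                               frre = NA_real_)
  for (i in seq_along(cand)) {
    x <- ser_window_bins(cand[i], dg)
    mw <- merged_windows(case, control, genome, x, cand[i],
                         merge_p_threshold, chroms = tr)
    tu <- trim_to_units(mw, units_tr)
    sw[i, `:=`(x_bins = x,
               frre = frre_within(tu$membership, case, control, genome,
                                  re_threshold, floor))]
  }
  sw
}

# Genome-wide LER call at a fixed connecting length.
ler_call_at <- function(l_pdnp, x_bins, units, case, control, genome, shift,
                        merge_p_threshold) {
  mw <- merged_windows(case, control, genome, x_bins, l_pdnp,
                       merge_p_threshold)
  tu <- trim_to_units(mw, data.table::as.data.table(units))
  finish_clusters(tu, "LER", case, control, genome, shift)
}

#' Area between two length distributions
#'
#' The dissimilarity of two region-length sets is the area between their
#' empirical CDFs over length, `integral |F_a - F_b| d(length)`; 0 iff the
#' distributions coincide, symmetric in its arguments.
#'
#' @param a,b numeric vectors of lengths (bp), both non-empty.
#' @return dissimilarity score in bp.
#' @export
length_dissimilarity <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  x <- sort(unique(c(a, b)))
  if (length(x) == 1L) return(0)
  fa <- stats::ecdf(a)(x)
  fb <- stats::ecdf(b)(x)
  k <- length(x)
  sum(abs(fa[-k] - fb[-k]) * diff(x))
}

#' Call LERs matched in length to a reference signal set
#'
#' Enumerates the connecting-length candidates whose training-set FR-RE
#' stays strictly above `frre_stop`, calls a genome-wide LER set for each,
#' and returns the set whose length distribution is closest (by
#' [length_dissimilarity()]) to the reference -- the procedure used to give
#' TF broad signals the length profile of an active-mark SER set.  When no
#' candidate qualifies the standard [call_lers()] result is returned with a
#' warning.
#'
#' @inheritParams call_lers
#' @param reference numeric vector of reference lengths, or a
#'   `region_table` whose `end - start` is used.
#' @return `region_table` of matched LERs; attribute `"dissimilarity"`
#'   carries the winning score.
#' @export
call_matched_lers <- function(units, case, control, genome, shift, reference,
                              frre_trigger = 0.01, frre_stop = 0.99,
                              re_threshold = 1.5, grid = NULL, seed = 1L,
                              merge_p_threshold = 0.05, floor = TRUE) {
  ref_len <- if (is.numeric(reference)) reference
             else reference$end - reference$start
  stopifnot(length(ref_len) > 0)
  frre0 <- fr_re(units, case, control, genome, re_threshold, floor = floor)
  if (frre0 <= frre_trigger) {
    message("FR-RE = ", signif(frre0, 3), " <= ", frre_trigger,
            ": no LER calling needed")
    return(empty_cluster_table("LER"))
  }
  if (is.null(grid))
    grid <- pdnp_candidates(shuffle_regions(units, genome, seed),
                            levels = seq(5, 50, by = 5), cap = 1e5)
  if (length(grid$values) == 0L) {
    warning("empty PDNP grid; LER calling skipped")
    return(empty_cluster_table("LER"))
  }
  sw <- ler_candidate_sweep(units, case, control, genome, grid,
                            re_threshold, merge_p_threshold, floor)
  qual <- which(is.nan(sw$frre) | sw$frre > frre_stop)
  if (length(qual) == 0L) {
    warning("no candidate with FR-RE > ", frre_stop,
            "; falling back to the standard LER call")
    return(call_lers(units, case, control, genome, shift,
                     frre_trigger, frre_stop, re_threshold, grid, seed,
                     merge_p_threshold, floor))
  }
  best_set <- NULL; best_score <- Inf; best_l <- NA_real_
  for (i in qual) {
    set_i <- ler_call_at(sw$l_pdnp[i], sw$x_bins[i], units, case, control,
                         genome, shift, merge_p_threshold)
    if (nrow(set_i) == 0L) next
    sc <- length_dissimilarity(set_i$end - set_i$start, ref_len)
    if (sc < best_score) {
      best_set <- set_i; best_score <- sc; best_l <- sw$l_pdnp[i]
    }
  }
  if (is.null(best_set)) {
    warning("all qualifying candidates produced empty LER sets; ",
            "falling back to the standard LER call")
    return(call_lers(units, case, control, genome, shift,
                     frre_trigger, frre_stop, re_threshold, grid, seed,
                     merge_p_threshold, floor))
  }
  data.table::setattr(best_set, "l_pdnp", best_l)
  data.table::setattr(best_set, "sweep", sw[])
  data.table::setattr(best_set, "dissimilarity", best_score)
  best_set
}
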