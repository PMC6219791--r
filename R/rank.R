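# Ranking of ERs/SERs/LERs and the motif-based reliability evaluation.

# Component rank with coordinate tie-break: position of each row in the
# ordering by `key` (ascending), then (chrom, start).
component_rank <- function(dt, key) {
  r <- integer(nrow(dt))
  r[order(key, dt$chrom, dt$start)] <- seq_len(nrow(dt))
  r
}

#' Rank ERs by q-value and summit height
#'
#' Component ranks: q ascending (`rank_qvalue`) and summit pileup height
#' descending (`rank_summit`); the final rank orders the sum of the two,
#' ties broken by coordinate.
#'
#' @param ers `region_table` with `q` and `summit_height`.
#' @return `ers` with `rank_qvalue`, `rank_summit`, `rank_final`
#'   (a permutation of 1..n) appended.
#' @export
rank_ers <- function(ers) {
  dt <- data.table::as.data.table(ers)
  dt[, rank_qvalue := component_rank(dt, dt$q)]
  dt[, rank_summit := component_rank(dt, -dt$summit_height)]
  dt[, rank_final := component_rank(dt, dt$rank_qvalue + dt$rank_summit)]
  dt[]
}

#' Rank SERs by read number
#'
#' Default descending (strongest first); `order = "asc"` gives the
#' literal ascending variant.
#'
#' @param sers `region_table` with `r_case`.
#' @param order `"desc"` (default) or `"asc"`.
#' @return `sers` with `rank_final` appended.
#' @export
rank_sers <- function(sers, order = c("desc", "asc")) {
  order <- match.arg(order)
  dt <- data.table::as.data.table(sers)
  key <- if (order == "desc") -dt$r_case else dt$r_case
  dt[, rank_final := component_rank(dt, key)]
  dt[]
}

#' Rank LERs by fold change and length
#'
#' Component ranks: fold change descending (`rank_enrichment`) and length
#' descending (`rank_length`); final rank orders their sum ascending.
#'
#' @param lers `region_table` with `fc` and `length`.
#' @return `lers` with `rank_enrichment`, `rank_length`, `rank_final`
#'   appended.
#' @export
rank_lers <- function(lers) {
  dt <- data.table::as.data.table(lers)
  dt[, rank_enrichment := component_rank(dt, -dt$fc)]
  dt[, rank_length := component_rank(dt, -as.numeric(dt$length))]
  dt[, rank_final := component_rank(dt, dt$rank_enrichment + dt$rank_length)]
  dt[]
}

#' Reliable-ER rate curve
#'
#' For each top-N cutoff (N = `step`, `2*step`, ... and finally n), the
#' fraction of the N best-ranked ERs with a motif hit within `window` bp of
#' their summit ("reliable ERs"), plus the area under the curve
#' (trapezoidal, extended flat to the y-axis).
#'
#' @param ranked output of [rank_ers()] (needs `rank_final` and `summit`).
#' @param motif_hits data.table `chrom,start,end` of motif intervals.
#' @param window half-width around the summit in bp (default 150).
#' @param step cutoff stride (default 100).
#' @return object of class `reliability_curve`: list with `cutoffs`,
#'   `rate`, `area`.
#' @export
reliability_curve <- function(ranked, motif_hits, window = 150L, step = 100L) {
  dt <- data.table::as.data.table(ranked)
  stopifnot(all(c("rank_final", "summit") %in% names(dt)))
  n <- nrow(dt)
  stopifnot(n > 0)
  dt <- dt[order(rank_final)]
  win <- dt[, .(chrom, start = pmax(summit - window, 0L),
                end = summit + window + 1L)]
  hits <- dt_overlaps(win, motif_hits)
  reliable <- logical(n)
  reliable[unique(S4Vectors::queryHits(hits))] <- TRUE
  cutoffs <- unique(c(seq(min(step, n), n, by = step), n))
  rate <- cumsum(reliable)[cutoffs] / cutoffs
  structure(list(cutoffs = cutoffs, rate = rate,
                 area = curve_area(cutoffs, rate)),
            class = "reliability_curve")
}

# Trapezoid with a flat extension from the y-axis to the first cutoff.
curve_area <- function(x, y) {
  a <- y[1L] * x[1L]
  if (length(x) > 1L)
    a <- a + sum((y[-1L] + y[-length(y)]) / 2 * diff(x))
  a
}

#' Area ratio of two reliability curves
#'
#' `ratio = area(rival) / area(ours)`; verdict `"L"` (ours has lower PPV)
#' when ratio > 1.01, `"H"` when ratio < 0.99, `"E"` otherwise.
#'
#' @param rival,ours `reliability_curve` objects on identical cutoffs.
#' @return list with `ratio` and `verdict`.
#' @export
area_ratio <- function(rival, ours) {
  stopifnot(identical(rival$cutoffs, ours$cutoffs))
  ratio <- rival$area / ours$area
  verdict <- if (ratio > 1.01) "L" else if (ratio < 0.99) "H" else "E"
  list(ratio = ratio, verdict = verdict)
}
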