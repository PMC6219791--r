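# Negative-selection CRISPR screen prioritization: sgRNA counts are
# projected onto the rank positions of a non-targeting-control pool and
# genes are scored by the largest generation-to-generation rank shift.

#' Non-targeting control pool
#'
#' Non-targeting sgRNAs with more than `min_reads` reads in generation 1
#' form the control pool; their counts are ranked descending within each
#' generation.
#'
#' @param table data.table with `sgrna, gene, is_non_targeting,
#'   count_gen1, count_gen10`.
#' @param min_reads strict lower bound on generation-1 reads (default 10).
#' @return list with `gen1` and `gen10` (descending count vectors of the
#'   same pool sgRNAs) and `size`.
#' @export
control_pool <- function(table, min_reads = 10) {
  dt <- data.table::as.data.table(table)
  nt <- dt[is_non_targeting == TRUE & count_gen1 > min_reads]
  if (nrow(nt) == 0L)
    stop("no non-targeting sgRNA passes the generation-1 read filter")
  list(gen1 = sort(nt$count_gen1, decreasing = TRUE),
       gen10 = sort(nt$count_gen10, decreasing = TRUE),
       size = nrow(nt))
}

#' Rank position of a count inside a descending control pool
#'
#' The number of pool entries strictly greater than the count, plus one
#' (descending nearest-rank insertion; ties with a pool entry share its
#' position).  A count above the whole pool gets position 1; below it,
#' pool size + 1.
#'
#' @param count read count(s), vectorized.
#' @param pool descending numeric vector of control counts.
#' @return integer position(s).
#' @export
rank_position <- function(count, pool) {
  stopifnot(length(pool) > 0)
  asc <- sort(pool)  # ascending for findInterval
  length(pool) - findInterval(count, asc) + 1L
}

#' Score and rank genes from a negative-selection screen
#'
#' Every sgRNA is projected onto the control pool in both generations;
#' its shift is `delta = position(gen10) - position(gen1)` (depleted
#' sgRNAs sink in the pool, so a large positive shift marks negative
#' selection).  A gene's score is the maximum shift over its sgRNAs; genes
#' are ranked by score descending, ties broken by gene ID.
#'
#' @param table data.table with `sgrna, gene, is_non_targeting,
#'   count_gen1, count_gen10`.
#' @param pools control pools from [control_pool()]; computed from `table`
#'   when `NULL`.
#' @return data.table `gene, score, rank` (targeting genes only), ranked.
#' @export
gene_scores <- function(table, pools = NULL) {
  dt <- data.table::as.data.table(table)
  if (is.null(pools)) pools <- control_pool(dt)
  tg <- dt[is_non_targeting == FALSE]
  stopifnot(nrow(tg) > 0, !anyNA(tg$gene))
  tg[, delta := rank_position(count_gen10, pools$gen10) -
                rank_position(count_gen1, pools$gen1)]
  out <- tg[, .(score = max(delta)), by = gene]
  data.table::setorder(out, -score, gene)
  out[, rank := .I]
  out[]
}

#' Enrichment of a candidate gene set at the top of a ranked list
#'
#' One-sided Kolmogorov-Smirnov test of the candidates' normalized rank
#' positions against the uniform null: a small p indicates the candidates
#' concentrate at the top of the prioritization.
#'
#' @param candidates character vector of gene IDs (subset of
#'   `ranked$gene`).
#' @param ranked output of [gene_scores()] (needs `gene`, `rank`).
#' @return list with `D` (KS statistic) and `p`.
#' @export
ks_enrichment <- function(candidates, ranked) {
  dt <- data.table::as.data.table(ranked)
  stopifnot(all(candidates %in% dt$gene))
  x <- dt[gene %in% candidates, rank] / nrow(dt)
  kt <- suppressWarnings(
    stats::ks.test(x, "punif", alternative = "greater"))
  p <- kt$p.value
  # R returns NA for an exact one-sided test when D+ is numerically zero;
  # no positive deviation means no enrichment
  if (!is.finite(p)) p <- 1
  list(D = unname(kt$statistic), p = p)
}

#' Read an sgRNA count table
#'
#' @param path tab-separated file with columns `sgrna, gene,
#'   is_non_targeting, count_gen1, count_gen10` (header required;
#'   `is_non_targeting` parsed as logical).
#' @return data.table in the [gene_scores()] input shape.
#' @export
read_sgrna_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("sgrna", "gene", "is_non_targeting", "count_gen1", "count_gen10")
  stopifnot(all(need %in% names(dt)))
  dt[, is_non_targeting := as.logical(is_non_targeting)]
  dt[]
}
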