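# Gene association and the bivalent-domain integration of active/repressive
# marks with TF broad signals.

#' Associate signals with genes
#'
#' Three association modes, matching how each signal class relates to
#' genes: `"ser"` -- the gene overlaps or lies within 1 kb of the signal;
#' `"ler"` -- at least 80% of the gene's length is covered by one signal;
#' `"tf_ler"` -- the gene overlaps or lies within 10 kb of the signal.
#' Many-to-many: a gene may associate with several signals and vice versa.
#'
#' @param signals data.table `chrom,start,end` with a `name` column (signal
#'   IDs; generated when absent).
#' @param genes data.table `chrom,start,end,gene_id`.
#' @param mode `"ser"`, `"ler"` or `"tf_ler"`.
#' @param max_gap override of the distance rule in bp (`ser`/`tf_ler`
#'   modes).
#' @param min_coverage override of the covered fraction (`ler` mode).
#' @return data.table `signal_id, gene_id`, one row per association.
#' @export
associate_genes <- function(signals, genes, mode = c("ser", "ler", "tf_ler"),
                            max_gap = NULL, min_coverage = 0.8) {
  mode <- match.arg(mode)
  sdt <- data.table::as.data.table(signals)
  if (!"name" %in% names(sdt)) sdt[, name := sprintf("sig_%05d", .I)]
  gdt <- data.table::as.data.table(genes)
  stopifnot("gene_id" %in% names(gdt))
  empty <- data.table::data.table(signal_id = character(),
                                  gene_id = character())
  if (nrow(sdt) == 0L || nrow(gdt) == 0L) return(empty)
  if (mode %in% c("ser", "tf_ler")) {
    if (is.null(max_gap)) max_gap <- if (mode == "ser") 1000L else 10000L
    hits <- dt_overlaps(gdt, sdt, maxgap = max_gap)
    out <- data.table::data.table(
      signal_id = sdt$name[S4Vectors::subjectHits(hits)],
      gene_id = gdt$gene_id[S4Vectors::queryHits(hits)])
  } else {
    hits <- dt_overlaps(gdt, sdt)
    if (length(hits) == 0L) return(empty)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- pmin(gdt$end[qi], sdt$end[si]) - pmax(gdt$start[qi], sdt$start[si])
    frac <- ov / (gdt$end[qi] - gdt$start[qi])
    keep <- frac >= min_coverage
    out <- data.table::data.table(
      signal_id = sdt$name[S4Vectors::subjectHits(hits)[keep]],
      gene_id = gdt$gene_id[S4Vectors::queryHits(hits)[keep]])
  }
  unique(out)[order(signal_id, gene_id)]
}

#' Bivalent-structure candidate gene filter
#'
#' Keeps genes that carry the super-enhancer-like epigenetic structure:
#' (1) within 1 kb of (or inside) one of the top `n_top_active` active-mark
#' SERs, (2) within 10 kb of (or inside) one of the top `n_top_tf` broad TF
#' signals of either factor, and (3) not overlapped by any repressive-mark
#' LER.
#'
#' @param active_sers ranked SERs (active mark, e.g. H3K4me3) with
#'   `rank_final`.
#' @param tf1_lers,tf2_lers ranked TF LER sets (e.g. Nanog, Oct4) with
#'   `rank_final`.
#' @param repressive_lers LERs of the repressive mark (e.g. H3K27me3).
#' @param genes data.table `chrom,start,end,gene_id`.
#' @param n_top_active,n_top_tf rank cutoffs (defaults 300 and 1000).
#' @param repressive_rule `"overlap"` (any overlap excludes, default) or
#'   `"coverage"` (exclude only when >= 80% covered).
#' @return character vector of qualifying gene IDs, sorted.
#' @export
bivalent_candidate_filter <- function(active_sers, tf1_lers, tf2_lers,
                                      repressive_lers, genes,
                                      n_top_active = 300L, n_top_tf = 1000L,
                                      repressive_rule = c("overlap", "coverage")) {
  repressive_rule <- match.arg(repressive_rule)
  top <- function(dt, n) data.table::as.data.table(dt)[rank_final <= n]
  g1 <- associate_genes(top(active_sers, n_top_active), genes, "ser")$gene_id
  g2 <- unique(c(
    associate_genes(top(tf1_lers, n_top_tf), genes, "tf_ler")$gene_id,
    associate_genes(top(tf2_lers, n_top_tf), genes, "tf_ler")$gene_id))
  excl <- if (repressive_rule == "overlap")
    associate_genes(repressive_lers, genes, "ser", max_gap = -1L)$gene_id
  else associate_genes(repressive_lers, genes, "ler")$gene_id
  sort(setdiff(intersect(g1, g2), excl))
}

#' Integration table of active-mark SERs with TF and repressive signals
#'
#' One row per active-mark SER: the best-ranked TF LER of each factor
#' within 10 kb (among the supplied top subsets) and whether a repressive
#' LER lies within 1 kb.
#'
#' @param active_sers `region_table` of SERs (needs `name`).
#' @param repressive_lers `region_table` of the repressive mark.
#' @param tf1_top,tf2_top ranked top TF LER subsets (need `name`,
#'   `rank_final`).
#' @return data.table `ser_id, tf1_ler, tf1_rank, tf2_ler, tf2_rank,
#'   repressive` (logical).
#' @export
integration_table <- function(active_sers, repressive_lers, tf1_top, tf2_top) {
  sdt <- data.table::as.data.table(active_sers)
  best_tf <- function(tf) {
    tfdt <- data.table::as.data.table(tf)
    out <- data.table::data.table(ler = NA_character_,
                                  rank = NA_integer_)[rep(1L, nrow(sdt))]
    if (nrow(tfdt) == 0L || nrow(sdt) == 0L) return(out)
    hits <- dt_overlaps(sdt, tfdt, maxgap = 10000L)
    if (length(hits) == 0L) return(out)
    hdt <- data.table::data.table(ser = S4Vectors::queryHits(hits),
                                  ler = S4Vectors::subjectHits(hits),
                                  rank = tfdt$rank_final[S4Vectors::subjectHits(hits)])
    hdt <- hdt[order(ser, rank)][!duplicated(ser)]
    out$ler[hdt$ser] <- tfdt$name[hdt$ler]
    out$rank[hdt$ser] <- hdt$rank
    out
  }
  t1 <- best_tf(tf1_top)
  t2 <- best_tf(tf2_top)
  rep_flag <- logical(nrow(sdt))
  rdt <- data.table::as.data.table(repressive_lers)
  if (nrow(rdt) > 0L && nrow(sdt) > 0L) {
    hits <- dt_overlaps(sdt, rdt, maxgap = 1000L)
    rep_flag[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  data.table::data.table(ser_id = sdt$name,
                         tf1_ler = t1$ler, tf1_rank = t1$rank,
                         tf2_ler = t2$ler, tf2_rank = t2$rank,
                         repressive = rep_flag)
}
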