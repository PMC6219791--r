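# Shared fixture builders.  Everything is generated in code; no data files.

library(data.table)

# read_set from explicit positions (single chromosome unless given).
rs_from_pos <- function(pos, strand = "+", chrom = "chr1",
                        chrom_sizes = c(chr1 = 1e6), ...) {
  read_set(data.table(chrom = chrom, pos = as.integer(pos), strand = strand),
           chrom_sizes = chrom_sizes, ...)
}

tiny_genome <- function(sizes = c(chr1 = 1e6)) genome_model(sizes)

# Small two-chromosome instance for oracle comparisons: a dense cluster per
# chromosome plus sparse background, <= 200 case reads in total.
oracle_instance <- function(seed) {
  withr::with_seed(seed, {
    mk <- function(n_bg, size, cl_at, cl_n, cl_span) {
      bg <- sort(sample.int(size, n_bg))
      cl <- sort(cl_at + sample.int(cl_span, cl_n, replace = TRUE))
      sort(c(bg, cl))
    }
    list(
      case = list(chr1 = mk(60, 50000L, 20000L, 25, 400L),
                  chr2 = mk(50, 40000L, 10000L, 20, 300L)),
      ctrl = list(chr1 = sort(sample.int(50000L, 70)),
                  chr2 = sort(sample.int(40000L, 60))))
  })
}

as_read_set <- function(pos_by_chrom, chrom_sizes) {
  dt <- rbindlist(lapply(names(pos_by_chrom), function(ch)
    data.table(chrom = ch, pos = pos_by_chrom[[ch]], strand = "+")))
  read_set(dt, chrom_sizes = chrom_sizes)
}

# Simulations used by several test files (small; cached per session).
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, maker) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- maker()
  .sim_cache[[key]]
}

# Synthetic negative-selection screen table.  Abundance persists across
# generations (gen10 counts are drawn conditionally on gen1), and the
# depleted genes' sgRNAs lose 10x expected abundance by gen10.
mk_acc_screen <- function(n_genes = 100, sgrna_per_gene = 3, n_nt = 100,
                          seed = 501, depleted = character()) {
  withr::with_seed(seed, {
    nt <- data.table(
      sgrna = sprintf("NT_%03d", seq_len(n_nt)), gene = NA_character_,
      is_non_targeting = TRUE,
      count_gen1 = rnbinom(n_nt, mu = 300, size = 10))
    nt[, count_gen10 := rnbinom(.N, mu = count_gen1, size = 30)]
    tg <- data.table(
      gene = rep(sprintf("G%03d", seq_len(n_genes)), each = sgrna_per_gene))
    tg[, sgrna := paste0(gene, "_", seq_len(.N)), by = gene]
    tg[, is_non_targeting := FALSE]
    tg[, count_gen1 := rnbinom(.N, mu = 300, size = 10)]
    fold <- ifelse(tg$gene %in% depleted, 0.1, 1)
    tg[, count_gen10 := rnbinom(.N, mu = count_gen1 * fold, size = 30)]
    rbind(nt, tg, fill = TRUE)[sample(.N)]
  })
}

small_peak_sim <- function() cached_sim("peaks", function() {
  sim <- simulate_chipseq(sim_config(
    chrom_sizes = stats::setNames(rep(1e6, 5), paste0("chr", 1:5)),
    case_reads = 5e4, control_reads = 5e4,
    peaks = list(n = 40, width = 250), seed = 401))
  est <- estimate_shift(sim$case)
  sim$shift <- est$optimized_shift
  sim$case_s <- shift_reads(sim$case, sim$shift)
  sim$control_s <- shift_reads(sim$control, sim$shift)
  sim
})
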