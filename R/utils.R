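# Shared small helpers: interval bookkeeping and BED-style I/O.

# data.table(chrom,start,end) [0-based half-open] -> GRanges (1-based closed)
dt2gr <- function(dt) {
  GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$start + 1L, dt$end))
}

# GRanges -> data.table(chrom,start,end), back to 0-based half-open
gr2dt <- function(gr) {
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr)
  )
}

# findOverlaps on two interval tables with harmonized sequence levels
# (avoids seqlevel-mismatch warnings when the chromosome sets differ).
dt_overlaps <- function(a, b, maxgap = -1L) {
  lev <- union(unique(a$chrom), unique(b$chrom))
  ga <- GenomicRanges::GRanges(factor(a$chrom, lev),
                               IRanges::IRanges(a$start + 1L, a$end))
  gb <- GenomicRanges::GRanges(factor(b$chrom, lev),
                               IRanges::IRanges(b$start + 1L, b$end))
  IRanges::findOverlaps(ga, gb, maxgap = maxgap)
}

# Merge intervals that overlap or are book-ended; input/output data.table.
merge_intervals <- function(dt) {
  if (nrow(dt) == 0L) return(dt[, .(chrom, start, end)])
  gr2dt(IRanges::reduce(dt2gr(dt)))
}

#' Write intervals as a BED6+ file
#'
#' Writes a tab-separated BED file (0-based half-open).  The first six
#' columns are `chrom,start,end,name,score,strand`; any further columns in
#' `dt` are appended verbatim.
#'
#' @param dt data.table with at least `chrom,start,end`.  Optional `name`,
#'   `score`, `strand` columns are used when present.
#' @param path output file path.
#' @param extra character vector of extra column names to append.
#' @return `path`, invisibly.
#' @export
write_bed <- function(dt, path, extra = character()) {
  out <- data.table::data.table(
    chrom = dt$chrom, start = dt$start, end = dt$end,
    name = if ("name" %in% names(dt)) dt$name else paste0("region_", seq_len(nrow(dt))),
    score = if ("score" %in% names(dt)) dt$score else 0,
    strand = if ("strand" %in% names(dt)) dt$strand else "."
  )
  for (cn in extra) out[[cn]] <- dt[[cn]]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, scipen = 12)
  invisible(path)
}

#' Read a BED file into a data.table
#'
#' @param path BED3+ file (tab-separated, no header).
#' @return data.table with `chrom,start,end` and, when present,
#'   `name,score,strand` plus any remaining columns `V7..`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer()))
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  base <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(dt, seq_len(min(ncol(dt), 6L)), base[seq_len(min(ncol(dt), 6L))])
  dt
}

# Count, for each query row of `regions` (chrom,start,end), the reads of a
# read_set falling in [start, end).  Vectorized per chromosome.
count_reads_in <- function(reads, regions) {
  stopifnot(inherits(reads, "read_set"))
  out <- integer(nrow(regions))
  rdt <- reads$reads
  for (ch in unique(regions$chrom)) {
    idx <- which(regions$chrom == ch)
    pos <- rdt[chrom == ch, pos]  # sorted
    if (length(pos) == 0L) next
    out[idx] <- findInterval(regions$end[idx] - 1L, pos) -
      findInterval(regions$start[idx] - 1L, pos)
  }
  out
}

# Deterministic 32-bit sub-seed derivation (for passing distinct seeds to
# nested generators while staying below 2^31).
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 9176L + 17L
}
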