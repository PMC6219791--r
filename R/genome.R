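#' Genome model: chromosome sizes and expected background density
#'
#' Holds the chromosome sizes, the mappability correction factor (MCF) and,
#' once a case library is attached, the genome-wide expected read density
#' `d_genome = R_case / (l_genome * MCF)` used as the floor of every Poisson
#' background.  MCF rescales the genome length to its effectively mappable
#' fraction; the default 0.8 is typical for short single-end reads on a
#' mammalian genome.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in bp, or a
#'   two-column file path readable by [read_chrom_sizes()].
#' @param mcf mappability correction factor in (0, 1].
#' @return object of class `genome_model` with fields `chrom_sizes`,
#'   `l_genome`, `mcf`.
#' @export
genome_model <- function(chrom_sizes, mcf = 0.8) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L)
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  stopifnot(length(chrom_sizes) > 0, !is.null(names(chrom_sizes)),
            all(chrom_sizes > 0), mcf > 0, mcf <= 1)
  structure(list(chrom_sizes = chrom_sizes,
                 l_genome = sum(as.numeric(chrom_sizes)),
                 mcf = mcf),
            class = "genome_model")
}

#' Read a chrom.sizes table
#'
#' @param path two-column tab-separated file: chromosome name, length (bp).
#' @return named numeric vector of chromosome sizes.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "size"))
  stats::setNames(as.numeric(dt$size), dt$chrom)
}

# Genome-wide expected read density (reads/bp) for a case library.
d_genome <- function(genome, total_reads) {
  total_reads / (genome$l_genome * genome$mcf)
}

# Training chromosomes: chr1..chr5 when present (any case), else the five
# longest; all chromosomes when fewer than five exist.
training_chroms <- function(genome) {
  nm <- names(genome$chrom_sizes)
  canon <- paste0("chr", 1:5)
  hit <- nm[tolower(nm) %in% canon]
  if (length(hit) == 5L) return(hit)
  if (length(nm) <= 5L) return(nm)
  nm[order(-genome$chrom_sizes)][1:5]
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", length(x$chrom_sizes), " chromosomes, ",
      format(x$l_genome, big.mark = ","), " bp, MCF = ", x$mcf, "\n", sep = "")
  invisible(x)
}
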