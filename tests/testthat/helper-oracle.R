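# Independent brute-force oracle for the window engine, written in plain
# base R with its own Poisson tail (upward pmf summation), its own BY
# step-up, and exhaustive enumeration of every initial/step window.  It
# shares no code path with the package engine.

# Upper tail P(X >= r | lambda) by summing the pmf upward from r.
oracle_ptail <- function(r, lambda) {
  if (r <= 0) return(1)
  upper <- max(r + 60, ceiling(lambda + 12 * sqrt(lambda) + 60))
  sum(stats::dpois(r:upper, lambda))
}

# BY step-up from the formula: q_(i) = min_{j>=i} p_(j) * m * c(m) / j.
oracle_by <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m * cm / seq_len(m))))
  pmin(q_sorted, 1)[order(o)]
}

# Exhaustive caller: every initial window (sliding one bin, trailing
# partials), every 3'-anchored step window, bin exclusion at max_allowed,
# min-p final window (ties: longer, then 5'-most), Bonferroni correction
# over unique final windows, merge of significant windows (overlap or
# book-ended), zero-width regions dropped.
oracle_merged_windows <- function(case_pos, ctrl_pos, chrom_sizes, mcf,
                                  n_bins, max_allowed, p_thr = 0.05) {
  total_case <- sum(lengths(case_pos))
  total_ctrl <- sum(lengths(ctrl_pos))
  dg <- total_case / (sum(chrom_sizes) * mcf)
  sf <- if (total_ctrl > 0) total_case / total_ctrl else NA_real_
  use_ctrl <- length(ctrl_pos) > 0 && total_ctrl > 0
  finals <- list()
  for (ch in names(case_pos)) {
    pos <- sort(case_pos[[ch]])
    cp <- if (use_ctrl) sort(ctrl_pos[[ch]]) else integer()
    n <- length(pos); B <- n - 1L
    if (B < 2L) next
    binlen <- diff(pos)
    for (j in seq_len(B)) {
      e <- min(j + n_bins - 1L, B)
      best <- NULL
      for (k in seq_len(e - j + 1L)) {
        s <- e - k + 1L
        if (any(binlen[s:e] >= max_allowed)) next
        l <- max(pos[e + 1L] - pos[s], 1)
        lam <- dg * l
        if (use_ctrl) {
          rc <- sum(cp >= pos[s] & cp <= pos[e + 1L])
          lam <- max(lam, rc * sf)
        }
        p <- oracle_ptail(k + 1L, lam)
        if (is.null(best) || p < best$p ||
            (p == best$p && k > best$k)) best <- list(s = s, k = k, p = p)
      }
      if (!is.null(best))
        finals[[length(finals) + 1L]] <-
          data.frame(chrom = ch, start = pos[best$s],
                     end = pos[e + 1L], p = best$p)
    }
  }
  if (length(finals) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  fw <- unique(do.call(rbind, finals))
  fw$padj <- pmin(fw$p * nrow(fw), 1)  # Bonferroni
  sig <- fw[fw$padj < p_thr, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  out <- NULL
  for (ch in unique(sig$chrom)) {
    iv <- sig[sig$chrom == ch, , drop = FALSE]
    iv <- iv[order(iv$start, iv$end), , drop = FALSE]
    ms <- iv$start[1]; me <- iv$end[1]
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv$start[i] <= me) me <- max(me, iv$end[i])
      else { out <- rbind(out, data.frame(chrom = ch, start = ms, end = me))
             ms <- iv$start[i]; me <- iv$end[i] }
    }
    out <- rbind(out, data.frame(chrom = ch, start = ms, end = me))
  }
  out <- out[out$end > out$start, , drop = FALSE]
  out[order(out$chrom, out$start), , drop = FALSE]
}
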