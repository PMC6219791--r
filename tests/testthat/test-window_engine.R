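# window_engine: window construction, Poisson scoring, selection, BY,
# reporting, summits, the optimizer, and engine/oracle agreement.

test_that("build_initial_windows slides one bin and emits trailing partials", {
  bins <- build_bins(rs_from_pos(cumsum(c(100L, rep(10L, 25)))))  # 25 bins
  w <- build_initial_windows(bins, 20L)
  expect_equal(nrow(w), 25L)
  full <- w[last_bin - first_bin + 1L == 20L]
  expect_equal(full$first_bin, 1:6)
  trail <- w[first_bin > 6L]
  expect_equal(trail$last_bin, rep(25L, 19L))
  # one bin -> no windows at all
  b1 <- build_bins(rs_from_pos(c(10L, 30L)))
  expect_equal(nrow(build_initial_windows(b1, 20L)), 0L)
})

test_that("step_windows anchor at the 3' end and apply the bin exclusion", {
  pos <- cumsum(c(1000L, rep(5L, 10)))       # 10 bins of 5 bp
  bins <- build_bins(rs_from_pos(pos))
  init <- build_initial_windows(bins, 10L)[1L]
  st <- step_windows(init, bins, max_allowed = 100)
  expect_equal(nrow(st), 10L)                 # all retained
  expect_true(all(st$last_bin == init$last_bin))
  # an interior large bin blocks every step window reaching past it
  pos2 <- cumsum(c(1000L, rep(5L, 4), 200L, rep(5L, 5)))
  bins2 <- build_bins(rs_from_pos(pos2))
  init2 <- build_initial_windows(bins2, 10L)[1L]
  st2 <- step_windows(init2, bins2, max_allowed = 100)
  expect_equal(nrow(st2), 5L)                 # only bins 6..10 survive
  expect_true(all(st2$first_bin >= 6L))
  # max_allowed at the bin size excludes (>= rule)
  st3 <- step_windows(init, bins, max_allowed = 5)
  expect_equal(nrow(st3), 0L)
})

test_that("window_background and poisson_p follow the stated formulas", {
  expect_equal(window_background(5, 1000, 0.01, 2), 10)
  expect_equal(window_background(NA, 1000, 0.01), 10)       # no control
  expect_equal(window_background(50, 1000, 0.01, 2), 100)

  expect_equal(poisson_p(0, 5), 1)
  expect_equal(poisson_p(1, 1), 1 - exp(-1))
  # dpois-sum oracle
  expect_equal(poisson_p(20, 10), oracle_ptail(20, 10), tolerance = 1e-12)
  expect_equal(poisson_p(3, 0.2), oracle_ptail(3, 0.2), tolerance = 1e-12)
})

test_that("select_final_window takes min p, ties to the longer window", {
  st <- data.table(chrom = "chr1", first_bin = c(5L, 3L, 1L),
                   last_bin = 10L, p = c(0.5, 0.01, 0.01))
  sel <- select_final_window(st)
  expect_equal(sel$first_bin, 1L)  # tie at 0.01 -> longer window
  expect_null(select_final_window(st[0]))
  one <- st[1]
  expect_equal(select_final_window(one)$first_bin, 5L)
})

test_that("by_qvalues matches the BY step-up formula and dominates p", {
  expect_equal(by_qvalues(0.01), 0.01)                   # m = 1, c(1) = 1
  expect_equal(by_qvalues(c(0.01, 0.04)), c(0.03, 0.06)) # c(2) = 1.5
  p <- withr::with_seed(3, runif(200)^2)
  q <- by_qvalues(p)
  expect_true(all(q >= p))
  expect_equal(q, oracle_by(p))
})

test_that("report_region applies the piecewise local-control density", {
  g <- tiny_genome(c(chr1 = 1e5))
  case <- rs_from_pos(c(10050L, 10060L), chrom_sizes = c(chr1 = 1e5))
  dg <- case$total_reads / (1e5 * 0.8)
  mk_ctrl <- function(pos) rs_from_pos(pos, chrom_sizes = c(chr1 = 1e5))

  # l = 100 <= 1 kb: control just outside the region but inside the 1 kb
  # window makes d_1kb the max
  ctrl <- mk_ctrl(rep(10150L, 5))
  r <- report_region(data.table(chrom = "chr1", start = 10000L, end = 10100L),
                     case, ctrl, g, shift = 50, summits = FALSE)
  sf <- case$total_reads / ctrl$total_reads
  expect_equal(r$background, max(dg * 100, (5 / 1000) * 100 * sf))

  # 1 kb < l <= 10 kb: d_1kb ignored, d_10kb used
  ctrl2 <- mk_ctrl(rep(15200L, 5))   # outside region [10000,15000)
  r2 <- report_region(data.table(chrom = "chr1", start = 10000L, end = 15000L),
                      case, ctrl2, g, shift = 50, summits = FALSE)
  expect_equal(r2$background, max(dg * 5000, (5 / 10000) * 5000 * sf))

  # l > 10 kb: only the matched-region density counts
  ctrl3 <- mk_ctrl(rep(21500L, 5))   # outside region [10000,21000)
  r3 <- report_region(data.table(chrom = "chr1", start = 10000L, end = 21000L),
                      case, ctrl3, g, shift = 50, summits = FALSE)
  expect_equal(r3$background, dg * 11000)  # d_ER = 0
  expect_equal(r3$fc, r3$r_case / r3$background)
})

test_that("compute_summit finds the leftmost maximum pileup", {
  case <- rs_from_pos(100L)
  s <- compute_summit(list(chrom = "chr1", start = 0L, end = 200L), case, 50)
  expect_equal(s$summit, 50L)   # [50,150) covered; leftmost max
  expect_equal(s$height, 1)
  # symmetric cluster peaks at its center
  case2 <- rs_from_pos(c(480L, 500L, 520L))
  s2 <- compute_summit(list(chrom = "chr1", start = 300L, end = 700L), case2, 60)
  expect_lte(abs(s2$summit - 460L), 1L)  # max overlap starts at 520-60
  expect_equal(s2$height, 3)
  expect_warning(
    s3 <- compute_summit(list(chrom = "chr1", start = 1000L, end = 2000L),
                         case, 50), "midpoint")
  expect_equal(s3$summit, 1500L)
})

test_that("engine merged windows equal the brute-force oracle on small instances", {
  sizes <- c(chr1 = 50000, chr2 = 40000)
  g <- genome_model(sizes)
  for (seed in c(11, 23, 37)) {
    inst <- oracle_instance(seed)
    case <- as_read_set(inst$case, sizes)
    ctrl <- as_read_set(inst$ctrl, sizes)
    for (ma in c(60, 250)) {
      got <- merged_windows(case, ctrl, g, n_bins = 10L, max_allowed = ma)
      want <- oracle_merged_windows(inst$case, inst$ctrl, sizes, 0.8,
                                    n_bins = 10L, max_allowed = ma)
      expect_equal(as.data.frame(got[, .(chrom, start, end)]),
                   want, ignore_attr = TRUE,
                   info = sprintf("seed %d ma %g", seed, ma))
    }
    # and without a control sample
    got0 <- merged_windows(case, NULL, g, 10L, 100)
    want0 <- oracle_merged_windows(inst$case, list(), sizes, 0.8, 10L, 100)
    expect_equal(as.data.frame(got0[, .(chrom, start, end)]), want0,
                 ignore_attr = TRUE)
  }
})

test_that("call_ers output satisfies its invariants on simulated peaks", {
  sim <- small_peak_sim()
  ers <- suppressWarnings(
    call_ers(sim$case_s, sim$control_s, sim$genome, sim$shift))
  expect_gt(nrow(ers), 0)
  expect_true(all(ers$q < 0.05))
  expect_true(all(ers$q >= ers$p))
  expect_true(all(ers$start <= ers$summit & ers$summit < ers$end))
  # pairwise disjoint and sorted per chromosome
  by_chr <- split(ers, ers$chrom)
  for (x in by_chr) {
    expect_true(all(diff(x$start) > 0))
    expect_true(all(x$start[-1] >= x$end[-nrow(x)]))
  }
  ev <- truth_eval(ers, sim$truth[label == "peak"])
  expect_gte(ev$recall, 0.9)
  expect_gte(ev$precision, 0.9)
})

test_that("adding case reads inside a region never increases its p", {
  g <- tiny_genome(c(chr1 = 1e6))
  base_pos <- sort(withr::with_seed(8, sample(5000:6000, 30, TRUE)))
  reg <- data.table(chrom = "chr1", start = 4900L, end = 6100L)
  ps <- sapply(c(0, 20, 60), function(extra) {
    pos <- sort(c(base_pos, withr::with_seed(9, sample(5000:6000, extra, TRUE))))
    case <- rs_from_pos(pos, chrom_sizes = c(chr1 = 1e6))
    report_region(reg, case, NULL, g, 50, summits = FALSE)$p
  })
  expect_true(all(diff(ps) <= 0))
})

test_that("the optimizer sweeps 0.2s..2s and returns a criterion-satisfying value", {
  sim <- small_peak_sim()
  ma <- optimize_max_allowed_length(sim$case_s, sim$control_s, sim$genome,
                                    sim$shift)
  sw <- attr(ma, "sweep")
  expect_equal(sw$max_allowed, pmax(1, sim$shift * seq(0.2, 2, 0.2)))
  expect_equal(sw$max_allowed[1L], 0.2 * sim$shift)
  # the returned candidate satisfies the criterion it was selected by
  expect_gte(sw[max_allowed == c(ma), frac_long], 0.8)
})
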