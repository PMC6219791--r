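# cluster_ler: scale factor, RE, FR-RE, LER calling, length matching.

test_that("scale_factor divides library totals and requires a control", {
  expect_equal(scale_factor(2e7, 1e7), 2)
  expect_equal(scale_factor(5e6, 5e6), 1)
  expect_error(scale_factor(1e7, 0), "control")
  expect_error(scale_factor(1e7, NA), "control")
})

test_that("region_re floors the denominator by the genome expectation", {
  expect_equal(region_re(30, 10, 2, 0.001, 1000), 1.5)   # floor smaller
  expect_equal(region_re(0, 10, 2, 0.001, 1000), 0)
  expect_equal(region_re(30, 0, 2, 0.01, 1000), 3)        # floor path
  expect_equal(region_re(30, 0, 2, 0.01, 1000, floor = FALSE), Inf)
})

test_that("fr_re counts strictly enriched covering regions", {
  g <- tiny_genome(c(chr1 = 1e6))
  units <- data.table(chrom = "chr1", start = c(1000L, 3000L, 500000L),
                      end = c(2000L, 4000L, 501000L))
  # case enriched over the units plus a uniform background; control uniform
  case <- rs_from_pos(sort(c(withr::with_seed(1, sample(1000:4000, 300, TRUE)),
                             withr::with_seed(2, sample(500000:501000, 50, TRUE)),
                             withr::with_seed(8, sample.int(1e6, 300)))),
                      chrom_sizes = c(chr1 = 1e6))
  ctrl <- rs_from_pos(sort(withr::with_seed(3, sample.int(1e6, 650))),
                      chrom_sizes = c(chr1 = 1e6))
  # pair 1 covering region is enriched; pair 2's 496 kb background gap
  # dilutes its units far below the enrichment threshold
  expect_equal(fr_re(units, case, ctrl, g), 0.5)
  expect_equal(fr_re(units[1], case, ctrl, g), 0)  # < 2 units
  # strict > at the threshold boundary
  expect_equal(region_re(15, 10, 1, 1e-9, 10) > 1.5, FALSE)
})

test_that("fr_re is invariant to duplicating both libraries", {
  g <- tiny_genome(c(chr1 = 1e6))
  units <- data.table(chrom = "chr1", start = c(1000L, 3000L, 9000L),
                      end = c(2000L, 4000L, 9500L))
  case <- rs_from_pos(sort(withr::with_seed(4, sample(500:9600, 400, TRUE))),
                      chrom_sizes = c(chr1 = 1e6))
  ctrl <- rs_from_pos(sort(withr::with_seed(5, sample.int(1e6, 500))),
                      chrom_sizes = c(chr1 = 1e6))
  dbl <- function(rs) {
    out <- rs
    out$reads <- rbind(rs$reads, rs$reads)[order(chrom, pos)]
    out$total_reads <- 2L * rs$total_reads
    out
  }
  expect_equal(fr_re(units, case, ctrl, g), fr_re(units, dbl(case), dbl(ctrl), g))
})

test_that("length_dissimilarity is the area between the length ECDFs", {
  expect_equal(length_dissimilarity(c(1, 5, 9), c(1, 5, 9)), 0)
  expect_equal(length_dissimilarity(100, 200), 100)
  a <- withr::with_seed(6, runif(40, 100, 1000))
  b <- withr::with_seed(7, runif(60, 200, 2000))
  expect_equal(length_dissimilarity(a, b), length_dissimilarity(b, a))
  expect_gt(length_dissimilarity(a, b), 0)
})

domain_sim <- function() cached_sim("domains", function() {
  s <- simulate_chipseq(sim_config(
    case_reads = 1e5, control_reads = 1e5, in_feature_fraction = 0,
    peaks = NULL, min_feature_gap = 50000L,
    domains = list(n = 10, width = 20000, subregions = 10L, enrichment = 5),
    seed = 403))
  est <- estimate_shift(s$case)
  s$shift <- est$optimized_shift
  s$case_s <- shift_reads(s$case, s$shift)
  s$control_s <- shift_reads(s$control, s$shift)
  s$ers <- suppressWarnings(call_ers(s$case_s, s$control_s, s$genome, s$shift))
  s
})

test_that("call_lers clusters fragmented broad domains", {
  sim <- domain_sim()
  expect_gt(fr_re(sim$ers, sim$case_s, sim$control_s, sim$genome), 0.01)
  lers <- call_lers(sim$ers, sim$case_s, sim$control_s, sim$genome,
                    sim$shift, seed = 403)
  expect_gt(nrow(lers), 0)
  # reported clusters keep the FR-RE floor
  expect_gte(attr(lers, "frre"), 0.99)
  # boundaries coincide with member-unit boundaries; members disjoint
  memb <- attr(lers, "membership")
  bounds <- memb[, .(start = min(start), end = max(end)), by = cluster_idx]
  expect_equal(bounds$start, lers$start)
  expect_equal(bounds$end, lers$end)
  expect_false(any(duplicated(memb$name)))
  ev <- truth_eval(lers[n_members > 1], sim$truth[label == "domain"])
  expect_gte(ev$recall, 0.9)
  expect_gte(ev$precision, 0.9)
})

test_that("call_lers returns empty on sparse isolated units", {
  sim <- domain_sim()
  iso <- data.table(chrom = "chr1",
                    start = seq(10000L, by = 150000L, length.out = 6L))
  iso[, `:=`(end = start + 400L, name = sprintf("ER_%02d", .I))]
  expect_message(
    out <- call_lers(iso, sim$control_s, sim$control_s, sim$genome, sim$shift),
    "no LER calling needed")
  expect_equal(nrow(out), 0L)
})

test_that("call_matched_lers self-match returns the standard-length solution", {
  sim <- domain_sim()
  std <- call_lers(sim$ers, sim$case_s, sim$control_s, sim$genome,
                   sim$shift, seed = 403)
  matched <- call_matched_lers(sim$ers, sim$case_s, sim$control_s, sim$genome,
                               sim$shift, reference = std, seed = 403)
  expect_equal(attr(matched, "dissimilarity"), 0)
  expect_equal(as.data.frame(matched[, .(chrom, start, end)]),
               as.data.frame(std[, .(chrom, start, end)]))
  # matched against an SER-scale reference: median length within 2x
  ref <- rep(2000, 50)
  m2 <- call_matched_lers(sim$ers, sim$case_s, sim$control_s, sim$genome,
                          sim$shift, reference = ref, seed = 403)
  expect_gt(nrow(m2), 0)
})
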