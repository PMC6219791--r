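# rank_integrate: rankings, reliability curves, gene association, the
# bivalent candidate filter and the integration table.

mk_regions <- function(n, chrom = "chr1", start0 = 0L, len = 500L,
                       gap = 10000L, ...) {
  dt <- data.table(chrom = chrom,
                   start = start0 + (seq_len(n) - 1L) * (len + gap))
  dt[, end := start + len]
  dt[, name := sprintf("R_%03d", .I)]
  extra <- list(...)
  for (nm in names(extra)) data.table::set(dt, j = nm, value = extra[[nm]])
  dt
}

test_that("rank_ers sums the q and summit-height component ranks", {
  ers <- mk_regions(3, q = c(1e-5, 1e-3, 1e-2), summit_height = c(5, 50, 20))
  r <- rank_ers(ers)
  expect_equal(r$rank_qvalue, c(1L, 2L, 3L))
  expect_equal(r$rank_summit, c(3L, 1L, 2L))
  # sums (4, 3, 5) -> final order (2nd, 1st, 3rd)
  expect_equal(r$rank_final, c(2L, 1L, 3L))
  expect_setequal(r$rank_final, seq_len(nrow(r)))
  one <- rank_ers(mk_regions(1, q = 0.01, summit_height = 3))
  expect_equal(one$rank_final, 1L)
  # dominance: best in both components is ranked first
  dom <- rank_ers(mk_regions(3, q = c(1e-6, 1e-3, 1e-2),
                             summit_height = c(90, 50, 20)))
  expect_equal(dom$rank_final[1L], 1L)
})

test_that("rank_sers orders by read number with an ascending flag", {
  sers <- mk_regions(3, r_case = c(10, 30, 20))
  expect_equal(rank_sers(sers)$rank_final, c(3L, 1L, 2L))
  expect_equal(rank_sers(sers, order = "asc")$rank_final, c(1L, 3L, 2L))
  expect_equal(rank_sers(sers[2])$rank_final, 1L)
})

test_that("rank_lers sums the fold-change and length component ranks", {
  lers <- mk_regions(3, fc = c(8, 2, 4))
  lers$length <- c(1000L, 5000L, 3000L)
  r <- rank_lers(lers)
  expect_equal(r$rank_enrichment, c(1L, 3L, 2L))
  expect_equal(r$rank_length, c(3L, 1L, 2L))
  # sums (4, 4, 4): full tie -> coordinate order
  expect_equal(r$rank_final, c(1L, 2L, 3L))
  dom <- mk_regions(2, fc = c(9, 1))
  dom$length <- c(9000L, 100L)
  expect_equal(rank_lers(dom)$rank_final, c(1L, 2L))
})

test_that("reliability_curve measures motif hits near summits by rank cutoff", {
  n <- 300L
  ers <- mk_regions(n, q = seq(1e-8, 1e-2, length.out = n),
                    summit_height = rev(seq_len(n)))
  ers[, summit := start + 250L]
  r <- rank_ers(ers)
  # motifs on every summit -> constant 1
  hits_all <- ers[, .(chrom, start = summit - 10L, end = summit + 10L)]
  c1 <- reliability_curve(r, hits_all, step = 100L)
  expect_equal(c1$cutoffs, c(100L, 200L, 300L))
  expect_equal(c1$rate, rep(1, 3))
  # no motifs -> 0
  none <- data.table(chrom = "chr2", start = 1L, end = 2L)
  expect_equal(reliability_curve(r, none, step = 100L)$rate, rep(0, 3))
  # motifs only in the top 150 -> curve decreases beyond them
  top <- r[rank_final <= 150L, .(chrom, start = summit, end = summit + 1L)]
  c2 <- reliability_curve(r, top, step = 100L)
  expect_equal(c2$rate, c(1, 0.75, 0.5))
  # window boundary: a motif 150 bp from the summit still counts
  edge <- r[rank_final == 1L, .(chrom, start = summit + 150L, end = summit + 151L)]
  c3 <- reliability_curve(r, edge, step = 100L)
  expect_equal(c3$rate[1L], 1 / 100)
})

test_that("area_ratio compares curve areas with the 0.99/1.01 bounds", {
  mk_curve <- function(y) structure(
    list(cutoffs = c(100L, 200L), rate = y,
         area = binclust:::curve_area(c(100, 200), y)),
    class = "reliability_curve")
  ours <- mk_curve(c(0.5, 0.5))
  expect_equal(area_ratio(ours, ours), list(ratio = 1, verdict = "E"))
  rival <- mk_curve(c(1, 1))
  expect_equal(area_ratio(rival, ours), list(ratio = 2, verdict = "L"))
  expect_equal(area_ratio(ours, rival)$verdict, "H")
  # bounds are strict: exactly 1.01 and 0.99 are "E"
  expect_equal(area_ratio(mk_curve(c(1.01, 1.01)), mk_curve(c(1, 1)))$verdict, "E")
  expect_equal(area_ratio(mk_curve(c(0.99, 0.99)), mk_curve(c(1, 1)))$verdict, "E")
})

test_that("associate_genes applies the ser/ler/tf_ler rules", {
  sig <- data.table(chrom = "chr1", start = 10000L, end = 20000L, name = "S1")
  genes <- data.table(chrom = "chr1",
                      start = c(12000L, 20500L, 21500L, 35000L, 14000L),
                      end = c(13000L, 21000L, 22500L, 36000L, 19000L),
                      gene_id = c("inside", "at1kb", "at1.5kb", "far", "mostly"))
  ser <- associate_genes(sig, genes, "ser")
  expect_setequal(ser$gene_id, c("inside", "at1kb", "mostly"))
  tf <- associate_genes(sig, genes, "tf_ler")
  expect_setequal(tf$gene_id, c("inside", "at1kb", "at1.5kb", "mostly"))
  # ler mode: coverage fraction, 80% boundary
  genes2 <- data.table(chrom = "chr1",
                       start = c(12000L, 19000L + 0L, 19500L),
                       end = c(13000L, 20000L + 250L, 22000L),
                       gene_id = c("g100", "g80", "g20"))
  # g80: 1000 of 1250 bp covered = 80% exactly -> associated
  # g20: 500 of 2500 = 20% -> not
  ler <- associate_genes(sig, genes2, "ler")
  expect_setequal(ler$gene_id, c("g100", "g80"))
  # 79% fails
  g79 <- data.table(chrom = "chr1", start = 19000L, end = 20266L,
                    gene_id = "g79")  # 1000/1266 = 79%
  expect_equal(nrow(associate_genes(sig, g79, "ler")), 0L)
})

test_that("bivalent_candidate_filter applies all three criteria", {
  active <- mk_regions(400, rank_final = 1:400)                # SERs
  tf1 <- copy(active)[, rank_final := 1:400]                   # co-located
  tf2 <- mk_regions(5, chrom = "chr2", rank_final = 1:5)
  genes <- data.table(
    chrom = "chr1",
    start = c(active$start[1] + 100L,   # near top SER and top tf1 -> in
              active$start[2] + 100L,   # ditto but repressed -> out
              active$start[350] + 100L, # only near rank-350 SER -> out
              990000L),                 # near nothing -> out
    gene_id = c("keep", "repressed", "lowrank", "nowhere"))
  genes[, end := start + 200L]
  repressive <- data.table(chrom = "chr1", start = genes$start[2] - 50L,
                           end = genes$end[2] + 50L, name = "K27_1")
  got <- bivalent_candidate_filter(active, tf1, tf2, repressive, genes)
  expect_equal(got, "keep")
  # without the repressive overlap the second gene also qualifies
  got2 <- bivalent_candidate_filter(active, tf1, tf2, repressive[0], genes)
  expect_equal(got2, c("keep", "repressed"))
})

test_that("integration_table picks the best-ranked TF signal within 10 kb", {
  sers <- mk_regions(2, gap = 100000L)
  tf1 <- data.table(chrom = "chr1",
                    start = c(sers$start[1] + 2000L, sers$start[1] + 5000L),
                    end = c(sers$start[1] + 2400L, sers$start[1] + 5400L),
                    name = c("N_a", "N_b"), rank_final = c(7L, 3L))
  tf2 <- tf1[0]
  rep_lers <- data.table(chrom = "chr1", start = sers$start[2] + 600L,
                         end = sers$start[2] + 900L, name = "K27")
  tab <- integration_table(sers, rep_lers, tf1, tf2)
  expect_equal(tab$tf1_ler, c("N_b", NA))   # rank 3 beats rank 7
  expect_equal(tab$tf1_rank, c(3L, NA))
  expect_true(all(is.na(tab$tf2_ler)))
  expect_equal(tab$repressive, c(FALSE, TRUE))
})
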