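depth_row <- function(start, depth, chrom = "S_chr1", sample = "s1",
                      partial = FALSE, w = 10000) {
  data.frame(chrom = chrom, start = start, end = start + ifelse(partial, w / 2, w),
             sample_id = sample, mean_depth = depth, partial = partial,
             stringsAsFactors = FALSE)
}

test_that("chromosome mean depth averages full windows only", {
  d <- depth_row(c(0, 10000, 20000), c(30, 30, 30))
  expect_equal(chromosome_mean_depth(d), 30)
  d2 <- depth_row(c(0, 10000), c(20, 40))
  expect_equal(chromosome_mean_depth(d2), 30)
  d3 <- rbind(depth_row(c(0, 10000), c(30, 30)),
              depth_row(20000, 90, partial = TRUE))
  expect_equal(chromosome_mean_depth(d3), 30)
  expect_error(chromosome_mean_depth(depth_row(0, 90, partial = TRUE)),
               "no full windows")
})

test_that("window classification applies the 1.5-5 / 0-0.5 fold thresholds inclusively", {
  d <- depth_row(seq(0, 9e4, by = 1e4),
                 c(30, 50, 10, 200, 45, 150, 15, 30, 31, 29))
  # force the chromosome mean to 30 to probe thresholds exactly
  m <- classify_windows(d, chrom_mean = 30)
  expect_equal(m$mark[m$mean_depth == 50], "DUP")    # ratio 1.67
  expect_equal(m$mark[m$mean_depth == 10], "DEL")    # ratio 0.33
  expect_equal(m$mark[m$mean_depth == 200], "HIGH")  # ratio 6.67, excluded
  expect_equal(m$mark[m$mean_depth == 45], "DUP")    # ratio 1.5: boundary in
  expect_equal(m$mark[m$mean_depth == 150], "DUP")   # ratio 5.0: boundary in
  expect_equal(m$mark[m$mean_depth == 15], "DEL")    # ratio 0.5: boundary in
  expect_equal(sum(m$mark == "NORMAL"), 4)
  # partial windows are never DUP/DEL
  dp <- rbind(depth_row(c(0, 10000), c(30, 30)),
              depth_row(20000, 90, partial = TRUE))
  expect_equal(classify_windows(dp)$mark, c("NORMAL", "NORMAL", "PARTIAL"))
  # non-positive chromosome mean is an error
  expect_error(classify_windows(depth_row(c(0, 10000), c(0, 0))),
               "positive")
  # every full window gets exactly one mark (conservation)
  expect_true(all(m$mark %in% c("DUP", "DEL", "NORMAL", "HIGH")))
})

test_that("adjacent same-mark windows merge; other marks break runs", {
  d <- depth_row(c(0, 10000, 20000), c(60, 60, 10))
  b <- merge_marked_windows(classify_windows(d, chrom_mean = 30))
  expect_equal(b$mark, c("DUP", "DEL"))
  expect_equal(b$start, c(0, 20000))
  expect_equal(b$end, c(20000, 30000))
  expect_equal(b$n_windows, c(2L, 1L))

  d2 <- depth_row(c(0, 10000, 20000), c(60, 30, 60))
  b2 <- merge_marked_windows(classify_windows(d2, chrom_mean = 30))
  expect_equal(b2$n_windows, c(1L, 1L))

  expect_equal(nrow(merge_marked_windows(
    classify_windows(depth_row(c(0, 10000), c(30, 30)), chrom_mean = 30))), 0)

  # block window counts sum to the number of DUP/DEL marks (conservation)
  set.seed(9)
  d3 <- depth_row(seq(0, 49e4, by = 1e4), sample(c(10, 30, 60), 50, TRUE))
  m3 <- classify_windows(d3, chrom_mean = 30)
  b3 <- merge_marked_windows(m3)
  expect_equal(sum(b3$n_windows), sum(m3$mark %in% c("DUP", "DEL")))
})

test_that("candidate filtering enforces span, window count and synteny rules", {
  syn <- link_anchors(data.frame(
    qchrom = "D_chr1", qstart = 0, qend = 1e6, tchrom = "S_chr1",
    tstart = 0, tend = 1e6, orientation = "same", identity = 1), 20000)
  mkblock <- function(start, n, chrom = "S_chr1") {
    data.frame(sample_id = "s1", chrom = chrom, start = start,
               end = start + n * 1e4, mark = "DEL", n_windows = as.integer(n),
               stringsAsFactors = FALSE)
  }
  expect_equal(nrow(filter_he_candidates(mkblock(0, 5), syn)), 0)    # 50 kb
  kept <- filter_he_candidates(mkblock(0, 6), syn)                   # 60 kb
  expect_equal(nrow(kept), 1)
  expect_equal(kept$synteny_covered, 1.0)
  # outside synteny -> rejected
  expect_equal(nrow(filter_he_candidates(mkblock(0, 8, chrom = "S_chr9"), syn)), 0)
})

test_that("replacement pairing is reciprocal, greedy, and oracle-optimal on tiny instances", {
  syn <- link_anchors(data.frame(
    qchrom = "S_chr1", qstart = 0, qend = 1e6, tchrom = "D_chr1",
    tstart = 0, tend = 1e6, orientation = "same", identity = 1), 20000)
  blk <- function(chrom, start, end, mark) {
    data.frame(sample_id = "s1", chrom = chrom, start = start, end = end,
               mark = mark, n_windows = as.integer((end - start) / 1e4),
               synteny_covered = 1, stringsAsFactors = FALSE)
  }
  # DEL on S lifting onto an overlapping DUP on D -> one S_replaced_by_D call
  res <- pair_replacement_events(rbind(blk("S_chr1", 100000, 200000, "DEL"),
                                       blk("D_chr1", 95000, 205000, "DUP")), syn)
  expect_equal(nrow(res$calls), 1)
  expect_equal(res$calls$direction, "S_replaced_by_D")
  expect_equal(nrow(res$unpaired), 0)

  # DEL with no DUP partner -> unpaired
  res2 <- pair_replacement_events(blk("S_chr1", 100000, 200000, "DEL"), syn)
  expect_equal(nrow(res2$calls), 0)
  expect_equal(nrow(res2$unpaired), 1)

  # two DELs competing for one DUP: higher reciprocal overlap wins, the
  # other stays unpaired; exhaustive evaluation of both pairings confirms
  # the greedy choice maximizes overlap
  dels <- rbind(blk("S_chr1", 100000, 200000, "DEL"),   # recip 0.50
                blk("S_chr1", 190000, 300000, "DEL"))   # recip 0.55
  dup <- blk("D_chr1", 100000, 300000, "DUP")
  res3 <- pair_replacement_events(rbind(dels, dup), syn)
  expect_equal(nrow(res3$calls), 1)
  expect_equal(res3$calls$lost_start, 190000)
  expect_equal(nrow(res3$unpaired), 1)
  recip <- function(del) {
    ov <- overlap_len(del$start, del$end, dup$start, dup$end)
    min(ov / (del$end - del$start), ov / (dup$end - dup$start))
  }
  expect_gt(recip(dels[2, ]), recip(dels[1, ]))  # both pairings enumerated
  # exact tie broken deterministically by the leftmost DEL
  dels_tie <- rbind(blk("S_chr1", 100000, 200000, "DEL"),
                    blk("S_chr1", 200000, 300000, "DEL"))
  res4 <- pair_replacement_events(rbind(dels_tie, dup), syn)
  expect_equal(res4$calls$lost_start, 100000)
})

test_that("multi-sample calls consolidate into events with supporting samples", {
  calls <- data.frame(
    kind = "replacement", direction = "S_replaced_by_D",
    lost_chrom = "S_chr1", lost_start = c(100000, 110000, 500000),
    lost_end = c(200000, 200000, 560000), gained_chrom = "D_chr1",
    gained_start = c(100000, 110000, 500000),
    gained_end = c(200000, 200000, 560000),
    sample_id = c("s1", "s2", "s1"), overlap_frac = 1,
    stringsAsFactors = FALSE)
  ev <- consolidate_calls(calls)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$n_samples, c(2L, 1L))
  expect_equal(ev$samples[1], "s1,s2")
})

test_that("reciprocal swap detection recovers planted swaps and nothing else", {
  ev <- data.frame(kind = "reciprocal", lost = NA, chrom = 1,
                   start = 500000, end = 600000)
  cfg <- sim_config(seed = 3, chrom_length = 1e6, n_chromosomes = 2)
  prog <- simulate_progenitors(cfg)
  atet <- simulate_allotetraploid(prog, he_events = ev)
  r <- detect_reciprocal_swaps(atet$assembly_anchors)
  expect_equal(nrow(r$calls), 1)
  tile <- cfg$assembly_anchor_tile
  expect_lte(abs(r$calls$start - 500000), tile)  # planted span +/- 1 anchor
  expect_lte(abs(r$calls$end - 600000), tile)
  expect_true(all(r$candidates$mirrored))

  # unmodified assembly: zero calls
  atet0 <- simulate_allotetraploid(prog, he_events = NULL)
  expect_equal(nrow(detect_reciprocal_swaps(atet0$assembly_anchors)$calls), 0)

  # 20 kb swap with min_span 60 kb: zero calls
  ev2 <- data.frame(kind = "reciprocal", lost = NA, chrom = 1,
                    start = 500000, end = 520000)
  atet2 <- simulate_allotetraploid(prog, he_events = ev2)
  expect_equal(nrow(detect_reciprocal_swaps(atet2$assembly_anchors)$calls), 0)

  # unlabeled chromosomes are an error
  bad <- atet$assembly_anchors
  bad$qchrom <- sub("BhD", "X", bad$qchrom)
  expect_error(detect_reciprocal_swaps(bad), "subgenome")
})

test_that("compare_references is symmetric on identical references and errors on sample mismatch", {
  cfg <- sim_config(seed = 21, chrom_length = 1e6,
                    he_events = data.frame(kind = "replacement", lost = "S",
                                           chrom = 1, start = 200000,
                                           end = 300000))
  prog <- simulate_progenitors(cfg)
  atet <- simulate_allotetraploid(prog)
  syn <- link_anchors(prog$anchors)
  d <- simulate_depth(atet, "s1")
  cmp <- compare_references(d, d, syn)
  expect_equal(cmp$dup_diff, 0L)
  expect_equal(cmp$del_diff, 0L)
  expect_equal(cmp$n_del_a, 1L)  # the planted event, against both references

  d2 <- d; d2$sample_id <- "other"
  expect_error(compare_references(d, d2, syn), "sample sets differ")

  # zero planted events, matched reference, noise-free depth -> zero blocks
  atet0 <- simulate_allotetraploid(prog, he_events = NULL)
  d0 <- simulate_depth(atet0, "s1")
  cmp0 <- compare_references(d0, d0, syn)
  expect_equal(cmp0$n_del_a + cmp0$n_dup_a, 0L)
})

test_that("HE calling is deterministic: identical inputs give identical call tables", {
  cfg <- sim_config(seed = 33, chrom_length = 1e6,
                    he_events = data.frame(kind = "replacement", lost = "D",
                                           chrom = 1, start = 100000,
                                           end = 200000),
                    depth_noise = "poisson")
  prog <- simulate_progenitors(cfg)
  atet <- simulate_allotetraploid(prog)
  syn <- link_anchors(prog$anchors)
  d <- simulate_depth(atet, "s1", seed = 99)
  r1 <- call_hes(d, syn)
  r2 <- call_hes(d, syn)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$marks, r2$marks)
})
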