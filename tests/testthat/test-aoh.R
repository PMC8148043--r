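reg <- load_region_registry()

test_that("VCF parsing yields sorted, genotype-filtered observations", {
  f <- tempfile(fileext = ".vcf")
  write_toy_vcf(f, c(
    "chr2\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1",
    "chr1\t500\t.\tC\tT\t.\tPASS\t.\tGT\t1/1",
    "chr1\t200\t.\tG\tA\t.\tPASS\t.\tGT\t0|1",
    "chr1\t300\t.\tT\tTA\t.\tPASS\t.\tGT\t1/1",
    "chr1\t400\t.\tA\tG\t.\tq10\t.\tGT\t./1",
    "chr1\t450\t.\tA\tG\t.\tPASS\t.\tGT\t./."))
  v <- read_vcf_variants(f)
  expect_equal(v$pos, c(200, 300, 500, 100))   # chr1 sorted, then chr2
  expect_equal(v$zygosity,
               c("heterozygous", "homozygous", "homozygous", "heterozygous"))
  expect_equal(v$is_snv, c(TRUE, FALSE, TRUE, TRUE))  # indel flagged

  # multi-sample requires naming
  f2 <- tempfile(fileext = ".vcf")
  write_toy_vcf(f2, "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1",
                samples = c("A", "B"))
  expect_error(read_vcf_variants(f2), "multi-sample")
  expect_equal(read_vcf_variants(f2, sample = "B")$zygosity, "homozygous")
  expect_error(read_vcf_variants(f2, sample = "C"), "not present")
  expect_error(read_vcf_variants(tempfile()), "not found")
})

test_that("variants inside the segmental-duplication mask are ignored", {
  mask <- data.frame(chrom = "chr15", start = 1000, end = 2000)
  v <- mkvars("chr15", c(500, 1500, 2500),
              c("heterozygous", "heterozygous", "homozygous"))
  obs <- categorize_variants(v, mask)
  expect_equal(obs$category, c("heterozygous", "ignored", "homozygous"))
  expect_equal(attr(obs, "counts")[["ignored"]], 1)
})

test_that("interval builder forms maximal same-zygosity runs", {
  # 10 homozygous variants, one arm -> a single interval
  obs <- categorize_variants(mkvars("chr5", seq(1e6, 10e6, by = 1e6),
                                    rep("homozygous", 10)))
  iv <- build_zygosity_intervals(obs)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$n_variants, 10)
  expect_equal(c(iv$start, iv$end), c(1e6, 10e6))

  # hom,hom,het,hom,hom -> three intervals
  obs <- categorize_variants(mkvars("chr5", 1:5 * 1e6,
                                    c("homozygous", "homozygous", "heterozygous",
                                      "homozygous", "homozygous")))
  iv <- build_zygosity_intervals(obs)
  expect_equal(iv$zygosity, c("homozygous", "heterozygous", "homozygous"))
  expect_equal(iv$n_variants, c(2, 1, 2))

  # ignored variants do not break runs but are tabulated
  v <- mkvars("chr5", 1:5 * 1e6,
              c("homozygous", "homozygous", "heterozygous", "homozygous",
                "homozygous"))
  mask <- data.frame(chrom = "chr5", start = 2.9e6, end = 3.1e6)
  iv <- build_zygosity_intervals(categorize_variants(v, mask))
  expect_equal(nrow(iv), 1)
  expect_equal(iv$n_variants, 4)
  expect_equal(iv$n_ignored, 1)

  expect_error(
    build_zygosity_intervals(
      data.frame(chrom = "chr5", pos = c(3, 1), category = "homozygous")),
    "not position-sorted")
})

test_that("runs crossing a centromere are split at the boundary", {
  cen <- data.frame(chrom = "chr5", start = 46e6, end = 51e6)
  obs <- categorize_variants(mkvars("chr5", c(40e6, 44e6, 55e6, 60e6),
                                    rep("homozygous", 4)))
  iv <- build_zygosity_intervals(obs, cen)
  expect_equal(nrow(iv), 2)
  expect_equal(iv$end[1], 44e6)
  expect_equal(iv$start[2], 55e6)
  # neither interval crosses the centromere
  expect_true(all(iv$end <= 46e6 | iv$start >= 51e6))
})

test_that("interval builder matches the brute-force run-length oracle", {
  set.seed(71)
  for (rep in 1:40) {
    n <- sample(1:50, 1)
    chrom <- sample(c("chr3", "chr8"), n, replace = TRUE)
    pos <- vapply(split(seq_len(n), chrom), length, 1L)
    v <- do.call(rbind, lapply(unique(chrom), function(ch) {
      k <- sum(chrom == ch)
      mkvars(ch, sort(sample.int(100e6, k)),
             sample(c("homozygous", "heterozygous"), k, replace = TRUE))
    }))
    mask <- if (runif(1) < 0.5) {
      s <- runif(1, 1, 90e6)
      data.frame(chrom = sample(c("chr3", "chr8"), 1), start = s, end = s + 10e6)
    } else NULL
    cen <- data.frame(chrom = c("chr3", "chr8"),
                      start = runif(2, 20e6, 60e6), end = NA)
    cen$end <- cen$start + runif(2, 1e6, 10e6)
    obs <- categorize_variants(v, mask)
    got <- build_zygosity_intervals(obs, cen)
    want <- rle_intervals_oracle(obs, cen)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got[c("chrom", "start", "end", "zygosity", "n_variants",
                       "n_ignored")], want)
  }
})

test_that("splitting observations at the centromere leaves intervals unchanged", {
  set.seed(72)
  cen <- data.frame(chrom = "chr9", start = 47.3e6, end = 50.7e6)
  pos <- sort(sample.int(120e6, 70))
  pos <- pos[pos <= cen$start | pos >= cen$end]  # no calls in the centromere gap
  v <- mkvars("chr9", pos,
              sample(c("homozygous", "heterozygous"), length(pos), replace = TRUE))
  obs <- categorize_variants(v)
  whole <- build_zygosity_intervals(obs, cen)
  p <- obs[obs$pos <= cen$start, , drop = FALSE]
  q <- obs[obs$pos > cen$start, , drop = FALSE]
  split_iv <- rbind(build_zygosity_intervals(p, cen),
                    build_zygosity_intervals(q, cen))
  rownames(whole) <- rownames(split_iv) <- NULL
  expect_equal(whole, split_iv)
})

test_that("critical-region rule is fewer-than-four heterozygous SNVs", {
  cr <- reg$critical_region
  in_cr <- function(n) seq(cr$start + 1000, cr$start + 1000 + (n - 1) * 1e5,
                           length.out = n)
  mk <- function(n_het) {
    categorize_variants(mkvars("chr15", in_cr(max(n_het, 1)),
                               c(rep("heterozygous", n_het),
                                 rep("homozygous", max(1 - n_het, 0)))))
  }
  expect_true(assess_critical_region(mk(3), reg)$positive)
  a4 <- assess_critical_region(mk(4), reg)
  expect_false(a4$positive)
  expect_equal(a4$het_count, 4)
  expect_false(assess_critical_region(mk(42), reg)$positive)
  expect_true(assess_critical_region(mk(0), reg)$positive)

  # indels and non-PASS sites do not count toward the tally
  v <- rbind(mkvars("chr15", in_cr(4), rep("heterozygous", 4)),
             mkvars("chr15", cr$start + 7e5, "heterozygous", is_snv = FALSE),
             mkvars("chr15", cr$start + 8e5, "heterozygous", filter = "q10"))
  a <- assess_critical_region(categorize_variants(v), reg)
  expect_equal(a$het_count, 4)
  expect_equal(assess_critical_region(categorize_variants(v), reg,
                                      pass_only = FALSE)$het_count, 5)
})

test_that("adding critical-region heterozygotes never turns negative positive", {
  set.seed(73)
  cr <- reg$critical_region
  for (rep in 1:20) {
    n <- sample(0:10, 1)
    pos <- sort(runif(max(n, 1), cr$start, cr$end))
    v <- mkvars("chr15", pos, sample(c("heterozygous", "homozygous"),
                                     max(n, 1), replace = TRUE))
    before <- assess_critical_region(categorize_variants(v), reg)
    v2 <- rbind(v, mkvars("chr15", runif(1, cr$start, cr$end), "heterozygous"))
    after <- assess_critical_region(categorize_variants(v2), reg)
    if (!before$positive) expect_false(after$positive)
    expect_gte(after$het_count, before$het_count)
  }
})

test_that("LOH size rules depend on methylation support", {
  q15 <- reg$centromeres$end[reg$centromeres$chrom == "chr15"]
  # 6 Mb homozygous block flanked by heterozygotes
  block <- mkvars("chr15", seq(25e6, 31e6, by = 2e5), "homozygous")
  flank <- mkvars("chr15", c(seq(q15 + 1e6, 24.5e6, by = 5e5),
                             seq(31.5e6, 60e6, by = 5e5)), "heterozygous")
  v <- rbind(block, flank)
  a_abn <- detect_aoh(v, reg, methylation = "abnormal")
  expect_true(a_abn$upd_consistent)
  a_unk <- detect_aoh(v, reg, methylation = "unknown")
  expect_false(a_unk$upd_consistent)

  # 9 Mb block qualifies even without methylation support
  block9 <- mkvars("chr15", seq(25e6, 34e6, by = 2e5), "homozygous")
  flank9 <- flank[flank$pos < 24.5e6 | flank$pos > 34.5e6, ]
  a9 <- detect_aoh(rbind(block9, flank9), reg, methylation = "unknown")
  expect_true(a9$upd_consistent)

  # the interval table round-trips through its TSV form
  f <- tempfile(fileext = ".tsv")
  write_aoh_intervals(a9, f)
  tab <- utils::read.table(f, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  expect_equal(tab$n_variants, a9$intervals$n_variants)
  expect_equal(tab$zygosity, a9$intervals$zygosity)
})

test_that("sparsely supported blocks never enter the LOH or consanguinity rules", {
  q15 <- reg$centromeres$end[reg$centromeres$chrom == "chr15"]
  flank <- mkvars("chr15", c(seq(q15 + 1e6, 24.5e6, by = 5e5),
                             seq(31.5e6, 60e6, by = 5e5)), "heterozygous")
  # 4 homozygous calls spanning 6 Mb: a chance run at thinned marker
  # density, not absence of heterozygosity
  sparse <- mkvars("chr15", seq(25e6, 31e6, length.out = 4), "homozygous")
  a <- detect_aoh(rbind(sparse, flank), reg, methylation = "abnormal")
  expect_false(a$upd_consistent)

  sparse2 <- mkvars("chr2", seq(100e6, 106e6, length.out = 4), "homozygous")
  sparse7 <- mkvars("chr7", seq(80e6, 86e6, length.out = 4), "homozygous")
  dense15 <- mkvars("chr15", seq(25e6, 31e6, by = 2e5), "homozygous")
  a2 <- detect_aoh(rbind(dense15, flank, sparse2, sparse7), reg,
                   methylation = "abnormal")
  expect_false(a2$consanguinity_flag)
  expect_true(a2$upd_consistent)
})

test_that("comparable blocks on other autosomes flag consanguinity, not UPD", {
  mk_block <- function(ch, from) {
    rbind(mkvars(ch, seq(from, from + 9e6, by = 2e5), "homozygous"),
          mkvars(ch, seq(from + 10e6, from + 30e6, by = 5e5), "heterozygous"))
  }
  v <- rbind(mk_block("chr15", 25e6), mk_block("chr2", 100e6),
             mk_block("chr7", 80e6))
  a <- detect_aoh(v, reg, methylation = "abnormal")
  expect_true(a$consanguinity_flag)
  expect_false(a$upd_consistent)

  # one extra autosome alone is an isolated event, not consanguinity
  v1 <- rbind(mk_block("chr15", 25e6), mk_block("chr2", 100e6))
  a1 <- detect_aoh(v1, reg, methylation = "abnormal")
  expect_false(a1$consanguinity_flag)
  expect_true(a1$upd_consistent)
})

test_that("chrX is excluded from AOH analysis for 46,XY specimens", {
  vx <- mkvars("chrX", seq(70e6, 90e6, by = 2e5), "homozygous")
  v15 <- mkvars("chr15", seq(23e6, 60e6, by = 3e5), "heterozygous")
  a_m <- detect_aoh(rbind(vx, v15), reg, sex_karyotype = "46,XY",
                    methylation = "abnormal")
  expect_false(a_m$upd_consistent)
  expect_false(a_m$consanguinity_flag)
  expect_equal(nrow(a_m$genomewide_blocks), 0)
  # the same block counts for a 46,XX specimen
  a_f <- detect_aoh(rbind(vx, v15), reg, sex_karyotype = "46,XX",
                    methylation = "abnormal")
  expect_gt(nrow(a_f$genomewide_blocks), 0)
})

test_that("isodisomy extent separates total from segmental by 15q coverage", {
  analyzable <- genomic_interval("chr15", 20.7e6, 102.5e6)
  full <- data.frame(chrom = "chr15", start = 20.7e6, end = 102.5e6,
                     size_mb = 81.8)
  expect_equal(classify_isodisomy_extent(full, analyzable)$extent, "total")

  seg <- data.frame(chrom = "chr15", start = 22e6, end = 29e6, size_mb = 7)
  res <- classify_isodisomy_extent(seg, analyzable)
  expect_equal(res$extent, "segmental")
  expect_equal(res$n_segments, 1)

  # 96% coverage crosses the 0.95 default boundary
  span <- analyzable$end - analyzable$start + 1
  b96 <- data.frame(chrom = "chr15", start = analyzable$start,
                    end = analyzable$start + 0.96 * span, size_mb = NA)
  expect_equal(classify_isodisomy_extent(b96, analyzable)$extent, "total")

  expect_error(classify_isodisomy_extent(full[0, ], analyzable),
               "at least one qualifying block")
})
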