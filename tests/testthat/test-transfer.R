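test_that("findHomologs recovers identical and planted fragments", {
  set.seed(61)
  shared <- randomDna(1000, 0.42)
  ga <- GenomeRecord("a", shared, circular = FALSE)
  gb <- GenomeRecord("b", shared, circular = FALSE)
  h <- findHomologs(ga, gb)
  expect_equal(nrow(h), 1L)
  expect_equal(h$length, 1000L)
  expect_equal(h$identity, 1)
  expect_equal(h$mismatches, 0L)
  expect_equal(h$gap_openings, 0L)

  # reverse-complement placement is found on the minus strand
  gb2 <- GenomeRecord("b2", paste0(randomDna(500, 0.42), revComp(shared),
                                   randomDna(500, 0.42)),
                      circular = FALSE)
  h2 <- findHomologs(ga, gb2)
  expect_equal(nrow(h2), 1L)
  expect_gt(h2$b_start, h2$b_end)  # minus strand encoded start > end
  expect_gte(h2$length, 995L)
})

test_that("a planted plastid insertion is recovered within +/- 5 bp", {
  cfg <- syntheticConfig(insertion_specs = c(3700L), seed = 13)
  gn <- makeGenomes(cfg)
  ins <- gn$manifest$insertions
  h <- findHomologs(gn$mito, gn$plastid)
  expect_gte(nrow(h), 1L)
  top <- h[1, ]  # sorted by length descending
  expect_lt(abs(top$a_start - ins$mt_start), 6)
  expect_lt(abs(top$a_end - ins$mt_end), 6)
  expect_lt(abs(top$length - ins$length), 6)
  expect_gt(top$identity, 0.999)
})

test_that("unrelated random genomes yield nothing, per exhaustive scan", {
  set.seed(62)
  a <- randomDna(2000, 0.45)
  b <- randomDna(2000, 0.45)
  h <- findHomologs(GenomeRecord("a", a, circular = FALSE),
                    GenomeRecord("b", b, circular = FALSE))
  expect_equal(nrow(h), 0L)

  # oracle: ungapped sliding 30-bp windows over every diagonal, both
  # strands; no window reaches 70% identity on this seed
  bestWindow <- function(x, y) {
    cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
    n <- length(cx); best <- 0
    for (d in (-(n - 30)):(n - 30)) {
      ix <- max(1, 1 + d):min(n, n + d)
      m <- as.integer(cx[ix] == cy[ix - d])
      if (length(m) < 30) next
      cs <- cumsum(m)
      win <- cs[30:length(m)] - c(0, cs)[seq_len(length(m) - 29)]
      best <- max(best, max(win) / 30)
    }
    best
  }
  expect_lt(bestWindow(a, b), 0.7)
  expect_lt(bestWindow(a, revComp(b)), 0.7)
})

test_that("gene coverage annotation merges fragments and flags complete", {
  frags <- data.frame(b_start = c(100, 180), b_end = c(200, 320))
  genes <- data.frame(gene = c("g_full", "g_half", "g_out"),
                      start = c(120, 281, 500), end = c(160, 360, 600))
  cov <- annotateGeneCoverage(frags, genes)
  expect_equal(nrow(cov), 2L)
  expect_equal(cov$fraction_covered[cov$gene == "g_full"], 100)
  expect_true(cov$complete[cov$gene == "g_full"])
  expect_equal(cov$fraction_covered[cov$gene == "g_half"], 50)
  expect_false(cov$complete[cov$gene == "g_half"])
})

test_that("synthetic insertion carrying annotated plastid genes", {
  # place plastid genes relative to a fixed insertion source window:
  # a whole tRNA inside it and an rRNA overlapping its tail by 40%
  cfg <- syntheticConfig(
    insertion_specs = data.frame(length = 1200L, cp_start = 5001L),
    seed = 17)
  gn <- makeGenomes(cfg)
  plastid_genes <- data.frame(gene = c("trnX", "rrnS"),
                              start = c(5101L, 6001L),
                              end = c(5170L, 6500L))
  h <- findHomologs(gn$mito, gn$plastid)
  cov <- annotateGeneCoverage(h, plastid_genes)
  expect_equal(cov$fraction_covered[cov$gene == "trnX"], 100)
  expect_true(cov$complete[cov$gene == "trnX"])
  # insertion covers 5001..6200 of the plastid: 200/500 of rrnS
  expect_lt(abs(cov$fraction_covered[cov$gene == "rrnS"] - 40), 1)
})

test_that("transferSummary arithmetic matches the published quantities", {
  tab <- read.delim(fixturePath("fsuspensa_mtpt_fragments.tsv"))
  frags <- data.frame(a_start = pmin(tab$mt_start, tab$mt_end),
                      a_end = pmax(tab$mt_start, tab$mt_end),
                      length = tab$length)
  sm <- transferSummary(frags, 535692)
  expect_equal(sm$n_fragments, 25L)
  expect_equal(sm$longest, 3704L)
  expect_equal(sm$shortest, 30L)
  expect_lte(sm$union_bp, sm$total_bp)
  # the published fraction: total length over genome length
  expect_equal(round(100 * 21037 / 535692, 2), 3.93)

  # empty input and overlap contract
  empty <- transferSummary(frags[0, ], 1000)
  expect_equal(empty$n_fragments, 0L)
  expect_equal(empty$fraction_of_genome, 0)
  two <- data.frame(a_start = c(1, 1), a_end = c(100, 100),
                    length = c(100, 100))
  sm2 <- transferSummary(two, 1000)
  expect_equal(sm2$total_bp, 200)
  expect_equal(sm2$union_bp, 100)
  expect_equal(transferSummary(two, 1000, use_union = TRUE)$
                 fraction_of_genome, 10)
  expect_error(transferSummary(two, 0), "positive")
})

test_that("union_bp equals brute-force interval union on random sets", {
  set.seed(63)
  for (rep in 1:5) {
    n <- sample(3:12, 1)
    st <- sample(1:500, n, replace = TRUE)
    en <- st + sample(10:100, n, replace = TRUE)
    frags <- data.frame(a_start = st, a_end = en, length = en - st + 1)
    sm <- transferSummary(frags, 10000)
    covered <- logical(1000)
    for (i in seq_len(n)) covered[st[i]:en[i]] <- TRUE
    expect_equal(sm$union_bp, sum(covered))
  }
})

test_that("homolog search is symmetric under genome exchange", {
  set.seed(64)
  shared1 <- randomDna(400, 0.42)
  shared2 <- randomDna(250, 0.42)
  a <- paste0(randomDna(800, 0.45), shared1, randomDna(700, 0.45),
              shared2, randomDna(500, 0.45))
  b <- paste0(randomDna(600, 0.40), shared2, randomDna(900, 0.40),
              revComp(shared1), randomDna(300, 0.40))
  ga <- GenomeRecord("a", a, circular = FALSE)
  gb <- GenomeRecord("b", b, circular = FALSE)
  hab <- findHomologs(ga, gb)
  hba <- findHomologs(gb, ga)
  expect_equal(nrow(hab), nrow(hba))
  expect_equal(sort(hab$length), sort(hba$length))
  expect_equal(sort(round(hab$identity, 3)), sort(round(hba$identity, 3)))
})
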