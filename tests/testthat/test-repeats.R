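test_that("findSsrs applies the per-unit-length copy thresholds", {
  g <- GenomeRecord("g", paste0("G", strrep("A", 12), "G",
                                strrep("C", 50), "G"), circular = FALSE)
  hits <- findSsrs(g)
  mono_a <- hits[hits$motif == "A", ]
  expect_equal(nrow(mono_a), 1L)
  expect_equal(mono_a$copies, 12L)
  expect_equal(mono_a$start, 2L)

  g9 <- GenomeRecord("g", paste0("G", strrep("A", 9), "G"),
                     circular = FALSE)
  expect_equal(nrow(findSsrs(g9)), 0L)

  # dinucleotide at exactly the threshold; motif canonicalized
  g2 <- GenomeRecord("g", paste0("CC", strrep("TA", 5), "CC"),
                     circular = FALSE)
  h2 <- findSsrs(g2)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$motif, "AT")
  expect_equal(h2$unit_length, 2L)
})

test_that("findSsrs equals the brute-force enumerator on random 5 kb", {
  for (seed in 1:3) {
    set.seed(seed)
    # AT-rich to provoke runs near the thresholds
    s <- randomDna(5000, gc = 0.25)
    got <- findSsrs(GenomeRecord("g", s, circular = FALSE))
    want <- bruteSsrs(s, circular = FALSE)
    expect_equal(got[, c("unit_length", "copies", "start", "end")],
                 want, ignore_attr = TRUE)
  }
})

test_that("SSR detection is invariant under rotation of a circular genome", {
  set.seed(41)
  backbone <- randomDna(3000, gc = 0.5)
  # plant an SSR crossing the origin after rotation
  s <- paste0(strrep("AG", 7), substr(backbone, 15, 3000))
  g <- GenomeRecord("g", s, circular = TRUE)
  L <- genomeLength(g)
  base <- findSsrs(g)
  for (off in c(7, 1500, 2995)) {
    rot <- findSsrs(rotateGenome(g, off))
    # map rotated starts back to original coordinates
    mapped <- sort(((rot$start - 1 + off) %% L) + 1)
    expect_equal(mapped, sort(base$start))
    expect_equal(sort(rot$length), sort(base$length))
  }
})

test_that("findTandems scores exact and mutated arrays as specified", {
  set.seed(42)
  unit <- randomDna(20, 0.5)
  arr <- strrep(unit, 4)
  s <- paste0(randomDna(300, 0.45), arr, randomDna(300, 0.45))
  h <- findTandems(GenomeRecord("g", s, circular = FALSE))
  expect_equal(nrow(h), 1L)
  expect_equal(h$period, 20L)
  expect_equal(h$percent_match, 100)
  expect_equal(h$score, 2 * 80)
  expect_equal(h$copies, 4)
  expect_equal(h$start, 301L)
  expect_equal(h$consensus, unit)

  # one substitution in one copy: percent_match below 100 but >= 82
  ach <- strsplit(arr, "")[[1]]
  ach[30] <- setdiff(c("A", "C", "G", "T"), ach[30])[1]
  s2 <- paste0(substr(s, 1, 300), paste(ach, collapse = ""),
               substr(s, 381, nchar(s)))
  h2 <- findTandems(GenomeRecord("g", s2, circular = FALSE))
  expect_equal(nrow(h2), 1L)
  expect_lt(h2$percent_match, 100)
  expect_gte(h2$percent_match, 82)
  expect_equal(h2$percent_match, round(100 * 79 / 80, 2))
})

test_that("non-repetitive random sequence yields no tandem hit", {
  set.seed(43)
  s <- randomDna(1500, 0.45)
  h <- findTandems(GenomeRecord("g", s, circular = FALSE))
  expect_equal(nrow(h), 0L)
  # brute-force confirmation for small periods: best possible score of
  # any window/period pair stays below the threshold
  ch <- strsplit(s, "")[[1]]
  best <- 0
  for (p in 1:25) {
    m <- ch[1:(1500 - p)] == ch[(p + 1):1500]
    r <- rle(m)
    run <- max(c(0, r$lengths[r$values]))
    best <- max(best, 2 * (run + p))  # upper bound: all-match score
  }
  expect_lt(best, 50 * 2)  # even the bound is under twice min_score
})

test_that("findDispersed recovers planted pairs with correct classes", {
  set.seed(44)
  backbone <- randomDna(4000, 0.45)
  a <- randomDna(40, 0.5)
  b <- randomDna(40, 0.5)
  ch <- strsplit(backbone, "")[[1]]
  ch[501:540] <- strsplit(a, "")[[1]]
  ch[2001:2040] <- strsplit(a, "")[[1]]           # forward copy
  ch[1001:1040] <- strsplit(b, "")[[1]]
  ch[3001:3040] <- strsplit(revComp(b), "")[[1]]  # palindromic copy
  g <- GenomeRecord("g", paste(ch, collapse = ""), circular = FALSE)
  h <- findDispersed(g)
  fwd <- h[h$class == "forward", ]
  pal <- h[h$class == "palindromic", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(nrow(pal), 1L)
  expect_equal(fwd$identity, 1)
  # boundaries may extend a base or two into chance-matching flanks
  expect_lt(max(abs(c(fwd$a_start, fwd$a_end, fwd$b_start, fwd$b_end) -
                      c(501, 540, 2001, 2040))), 4)
  expect_lt(max(abs(c(pal$a_start, pal$a_end, pal$b_start, pal$b_end) -
                      c(1001, 1040, 3001, 3040))), 4)
})

test_that("dispersed hits never sit on SSR or tandem intervals", {
  set.seed(45)
  backbone <- randomDna(3000, 0.45)
  # an SSR is itself a trivially dispersed self-similarity; it must be
  # filtered out of the dispersed table
  s <- paste0(substr(backbone, 1, 1000), strrep("AT", 30),
              substr(backbone, 1061, 3000))
  g <- GenomeRecord("g", s, circular = FALSE)
  ssrs <- findSsrs(g)
  expect_gte(nrow(ssrs), 1L)
  tand <- findTandems(g)
  disp <- findDispersed(g, ssrs = ssrs, tandems = tand)
  if (nrow(disp)) {
    for (i in seq_len(nrow(disp))) {
      ov <- min(disp$a_end[i], 1060) - max(disp$a_start[i], 1001) + 1
      expect_lt(ov / (disp$a_end[i] - disp$a_start[i] + 1), 0.5)
    }
  } else succeed()
})

test_that("generator-planted repeats are recovered with full recall", {
  cfg <- syntheticConfig(seed = 7)
  gn <- makeGenomes(cfg)
  man <- gn$manifest

  ssrs <- findSsrs(gn$mito)
  for (i in seq_len(nrow(man$ssrs))) {
    r <- man$ssrs[i, ]
    hit <- ssrs[ssrs$start == r$start & ssrs$end == r$end &
                  ssrs$motif == r$motif, ]
    expect_equal(nrow(hit), 1L, info = paste("ssr", i))
  }
  # tallies match: every found SSR is a planted one
  expect_equal(nrow(ssrs), nrow(man$ssrs))

  tands <- findTandems(gn$mito)
  for (i in seq_len(nrow(man$tandems))) {
    r <- man$tandems[i, ]
    hit <- tands[abs(tands$start - r$start) <= 2 &
                   abs(tands$end - r$end) <= 2, ]
    expect_equal(nrow(hit), 1L, info = paste("tandem", i))
    expect_equal(hit$period, r$period)
  }

  disp <- findDispersed(gn$mito)
  for (i in seq_len(nrow(man$dispersed))) {
    r <- man$dispersed[i, ]
    hit <- disp[disp$class == r$class &
                  abs(disp$a_start - r$a_start) <= 2 &
                  abs(disp$b_start - r$b_start) <= 2, ]
    expect_equal(nrow(hit), 1L, info = paste("dispersed", i))
  }
  cls_found <- table(disp$class)
  cls_want <- table(man$dispersed$class)
  expect_equal(as.integer(cls_found[names(cls_want)]),
               as.integer(cls_want))
})

test_that("repeatSummary reports totals and composition percentages", {
  ssrs <- data.frame(motif = c(rep("A", 42), rep("AG", 20),
                               rep("AT", 13), rep("AAG", 24),
                               rep("AATC", 37), rep("AACTG", 0),
                               rep("AACGTC", 1)),
                     unit_length = c(rep(1, 42), rep(2, 33), rep(3, 24),
                                     rep(4, 37), rep(6, 1)),
                     copies = 10, start = 1, end = 10, length = 10)
  tandems <- data.frame(period = rep(20, 9), copies = 3, start = 1,
                        end = 60, score = 100, percent_match = 90)
  dispersed <- data.frame(class = c(rep("palindromic", 114),
                                    rep("forward", 104)),
                          a_start = 1, a_end = 40, b_start = 100,
                          b_end = 139, length = 40, identity = 1)
  sm <- repeatSummary(ssrs, tandems, dispersed)
  expect_equal(sm$total, 364L)
  expect_equal(sm$n_ssr, 137L)
  ud <- sm$ssr_unit_distribution
  expect_equal(ud$percentage[ud$unit_length == 1], 30.66)
  expect_equal(ud$percentage[ud$unit_length == 2], 24.09)
  expect_equal(ud$percentage[ud$unit_length == 4], 27.01)
  expect_equal(ud$percentage[ud$unit_length == 6], 0.73)
  dc <- sm$dispersed_classes
  expect_equal(dc$percentage[dc$class == "palindromic"], 52.29)
  expect_equal(dc$percentage[dc$class == "forward"], 47.71)

  empty <- repeatSummary(ssrs[0, ], tandems[0, ], dispersed[0, ])
  expect_equal(empty$total, 0L)
})
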