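test_that("applyEdits changes exactly the given C positions to T", {
  expect_equal(applyEdits("CCA", integer(0)), "CCA")
  expect_equal(applyEdits("CCA", c(1, 2)), "TTA")
  expect_error(applyEdits("ACA", 1), "not C.*1")

  set.seed(21)
  cds <- paste(sample(c("GCT", "CAA", "CCT", "GAA", "TGT"), 60, TRUE),
               collapse = "")
  cpos <- which(strsplit(cds, "")[[1]] == "C")
  sites <- sort(sample(cpos, 12))
  edited <- applyEdits(cds, sites)
  diffs <- which(strsplit(cds, "")[[1]] != strsplit(edited, "")[[1]])
  expect_equal(diffs, sites)
  expect_equal(nchar(edited), nchar(cds))
})

test_that("classifyChange reproduces the published hydropathy taxonomy", {
  r <- classifyChange("TCA", "TTA")
  expect_equal(r$from_aa, "S"); expect_equal(r$to_aa, "L")
  expect_equal(r$category, "hydrophilic-hydrophobic")

  r <- classifyChange("CAA", "TAA")
  expect_equal(r$to_aa, "X")
  expect_equal(r$category, "hydrophilic-stop")

  r <- classifyChange("CCT", "TTT")
  expect_equal(r$from_aa, "P"); expect_equal(r$to_aa, "F")
  expect_equal(r$category, "hydrophobic-hydrophobic")
  expect_equal(r$positions_edited, "1,2")

  expect_error(classifyChange("TCA", "TGA"), "not pure C->T")
  expect_error(classifyChange("TCA", "TCA"), "identical")
})

test_that("classifyChange agrees with a brute-force enumeration oracle", {
  codons <- names(Biostrings::GENETIC_CODE)
  n_checked <- 0L
  for (co in codons) {
    ch <- strsplit(co, "")[[1]]
    cpos <- which(ch == "C")
    if (!length(cpos)) next
    subsets <- if (length(cpos) == 1L) list(cpos) else
      unlist(lapply(seq_along(cpos), function(m)
        utils::combn(cpos, m, simplify = FALSE)), recursive = FALSE)
    for (ss in subsets) {
      to <- ch; to[ss] <- "T"
      to <- paste(to, collapse = "")
      aa_f <- Biostrings::GENETIC_CODE[[co]]
      aa_t <- Biostrings::GENETIC_CODE[[to]]
      aa_f <- if (aa_f == "*") "X" else aa_f
      aa_t <- if (aa_t == "*") "X" else aa_t
      got <- classifyChange(co, to)
      expect_equal(got$category,
                   paste(oracleHydro(aa_f), oracleHydro(aa_t), sep = "-"),
                   info = paste(co, to))
      expect_equal(got$positions_edited, paste(ss, collapse = ","))
      n_checked <- n_checked + 1L
    }
  }
  # 27 codons with one C, 9 with two, 1 with three: 27 + 9*3 + 1*7
  expect_equal(n_checked, 61L)
})

test_that("summarizeEdits reproduces the published editing table exactly", {
  tab <- read.delim(fixturePath("fsuspensa_mt_edit_types.tsv"))
  s <- summarizeEdits(tab[, c("from_codon", "to_codon", "count")])
  expect_equal(s$total_sites, 460L)

  pc <- s$per_category
  get <- function(cat, col) pc[pc$category == cat, col]
  expect_equal(get("hydrophilic-hydrophilic", "count"), 57)
  expect_equal(get("hydrophilic-hydrophilic", "percentage"), 12.39)
  expect_equal(get("hydrophilic-hydrophobic", "count"), 217)
  expect_equal(get("hydrophilic-hydrophobic", "percentage"), 47.17)
  expect_equal(get("hydrophilic-stop", "count"), 2)
  expect_equal(get("hydrophilic-stop", "percentage"), 0.43)
  expect_equal(get("hydrophobic-hydrophilic", "count"), 35)
  expect_equal(get("hydrophobic-hydrophilic", "percentage"), 7.61)
  expect_equal(get("hydrophobic-hydrophobic", "count"), 149)
  expect_equal(get("hydrophobic-hydrophobic", "percentage"), 32.39)

  # the classifier's own categories must match the published grouping
  cls <- s$changes
  m <- merge(cls, tab, by.x = c("from_codon", "to_codon"),
             by.y = c("from_codon", "to_codon"))
  expect_equal(m$category.x, m$category.y)

  expect_equal(s$unchanged_percentage, 44.78)
  paa <- s$per_target_aa
  expect_equal(paa[paa$to_aa == "L", "percentage"], 46.52)
  expect_equal(paa[paa$to_aa == "F", "percentage"], 22.39)

  pos <- s$per_codon_position
  expect_equal(unname(pos[["dual"]]), 20)
  expect_equal(round(100 * pos[["dual"]] / s$total_sites, 2), 4.35)
  expect_equal(sum(pos), s$total_sites)
})

test_that("per-category percentages sum to 100 within rounding", {
  tab <- read.delim(fixturePath("fsuspensa_mt_edit_types.tsv"))
  s <- summarizeEdits(tab[, c("from_codon", "to_codon", "count")])
  expect_lt(abs(sum(s$per_category$percentage) - 100), 0.02)

  set.seed(5)
  rnd <- data.frame(from_codon = c("TCA", "CCA", "CGT", "CAA"),
                    to_codon = c("TTA", "CTA", "TGT", "TAA"),
                    count = sample(1:50, 4))
  s2 <- summarizeEdits(rnd)
  expect_lt(abs(sum(s2$per_category$percentage) - 100), 0.02)
})

test_that("summarizeEdits handles empty input", {
  s <- summarizeEdits(data.frame(from_codon = character(0),
                                 to_codon = character(0),
                                 count = integer(0)))
  expect_equal(s$total_sites, 0L)
  expect_null(s$per_category)
})

test_that("functional effects: stop gain and start creation", {
  # CGA -> TGA at an internal codon is a premature stop
  cds <- paste0("ATG", "CGA", "GCT", "TAA")
  fx <- detectFunctionalEffects(cds, sites = 4)
  expect_true(fx$premature_stop)
  expect_equal(fx$stop_codon_index, 2L)

  # ACG first codon edited at position 2 creates a canonical start
  cds2 <- paste0("ACG", "GCT", "TAA")
  fx2 <- detectFunctionalEffects(cds2, sites = 2)
  expect_true(fx2$start_created)
  expect_false(fx2$premature_stop)

  fx3 <- detectFunctionalEffects(cds2, sites = integer(0))
  expect_false(fx3$premature_stop)
  expect_false(fx3$start_created)
})

test_that("codonChangesFromSites counts dual edits once", {
  cds <- paste0("CCA", "TCA", "CCT", "TAA")
  sites <- c(1, 2, 5, 7)  # CCA dual, TCA pos 2, CCT pos 1
  ch <- codonChangesFromSites(cds, sites)
  expect_equal(sum(ch$count), 3L)
  expect_true(any(ch$from_codon == "CCA" & ch$to_codon == "TTA"))
  s <- summarizeEdits(ch)
  expect_equal(unname(s$per_codon_position[["dual"]]), 1)
})
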