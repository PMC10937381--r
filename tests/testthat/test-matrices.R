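shifted_pair <- function(pos1, pos2, contig = "chrS") {
  p <- data.frame(contig1 = contig, pos1 = pos1, dir1 = "downstream",
                  contig2 = contig, pos2 = pos2, dir2 = "upstream",
                  orientation = "inward", stringsAsFactors = FALSE)
  attr(p, "shifted") <- TRUE
  p
}

test_that("bp binning uses floor division and conserves counts", {
  contigs <- plasmid_contigs(400L)
  m <- bin_pairs(shifted_pair(85, 165), 80, contigs)
  expect_identical(dim(m$counts), c(5L, 5L))
  expect_identical(as.numeric(m$counts[2, 3]), 1)    # bins 1 and 2 (0-based)
  expect_identical(sum(m$counts), 1)
  # both ends in one bin increments the diagonal
  md <- bin_pairs(shifted_pair(5, 70), 80, contigs)
  expect_identical(as.numeric(md$counts[1, 1]), 1)
  expect_error(bin_pairs(shifted_pair(85, 165, contig = "chrX"), 80, contigs),
               "chrX")
  # conservation on generator output
  cfg <- generator_config(plasmid_contigs(), five_sites(), n_pairs = 1e5,
                          seed = 3)
  res <- synth_filtered_pairs(cfg)
  mm <- bin_pairs(res$flt$kept, 40, cfg$contigs)
  expect_identical(sum(mm$counts), as.numeric(res$flt$stats$n_kept))
})

test_that("nucleosome assignment takes the nearest dyad, leftmost on ties", {
  contigs <- plasmid_contigs(1000L)
  loci <- list(chrS = c(100L, 200L, 400L))
  # ends exactly on dyads
  m <- bin_to_nucleosomes(shifted_pair(100, 400), loci, contigs)
  expect_identical(as.numeric(m$counts[1, 3]), 1)
  # equidistant end (150) goes to the left dyad (100)
  m2 <- bin_to_nucleosomes(shifted_pair(150, 400), loci, contigs)
  expect_identical(as.numeric(m2$counts[1, 3]), 1)
  # ends beyond assignment_max_bp are discarded and counted
  m3 <- bin_to_nucleosomes(shifted_pair(650, 400), loci, contigs)
  expect_identical(sum(m3$counts), 0)
  expect_identical(attr(m3, "n_unassigned"), 1L)
  expect_error(bin_to_nucleosomes(shifted_pair(1, 2), list(), contigs),
               "empty")
})

test_that("jitter-free generator pairs map back to their planted nucleosomes", {
  preset <- remodeler_preset("exact", linker_bp = 41, nfr_bp = 126,
                             spacing_sd_bp = 0)
  cfg <- generator_config(plasmid_contigs(), five_sites(), preset,
                          n_pairs = 1e4, p_undigested = 0, seed = 5)
  res <- synth_filtered_pairs(cfg)
  loci <- res$gt$dyads
  m <- bin_to_nucleosomes(res$flt$kept, loci, cfg$contigs)
  # recovered assignment reproduces the truth matrix cell-for-cell
  tr <- attr(simulate_ligation_pairs(res$gt), "truth")
  tr <- tr[abs(tr$dyad2 - tr$dyad1) >= 147, ]
  i <- match(tr$dyad1, loci$chrS); j <- match(tr$dyad2, loci$chrS)
  truth_counts <- Matrix::sparseMatrix(i = pmin(i, j), j = pmax(i, j), x = 1,
                                       dims = dim(m$counts))
  frac_match <- sum(m$counts * (truth_counts > 0)) / sum(m$counts)
  expect_gte(frac_match, 0.99)
  expect_identical(sum(m$counts), sum(truth_counts))
  # maximum off-diagonal sits on adjacent nucleosomes
  tm <- as(m$counts, "TsparseMatrix")
  off <- tm@x[tm@i != tm@j]
  sep <- abs(tm@j - tm@i)[tm@i != tm@j]
  expect_identical(sep[which.max(off)], 1L)
})

test_that("pileup averages anchor snippets and is linear", {
  cfg <- generator_config(plasmid_contigs(), five_sites(), n_pairs = 2e5,
                          seed = 8)
  res <- synth_filtered_pairs(cfg)
  m <- bin_pairs(res$flt$kept, 20, cfg$contigs)
  sites <- five_sites()
  single <- pileup(m, sites[3, ], window_bp = 3000)
  expect_identical(dim(single$matrix), c(150L, 150L))
  # identity: one interior anchor equals its local snippet
  dense <- nucfold:::.dense_contig(m, "chrS")
  b <- 10000 %/% 20 + 1
  expect_identical(single$matrix, dense[(b - 75):(b + 74), (b - 75):(b + 74)])
  # two anchors average elementwise; union = weighted mean (linearity)
  a <- pileup(m, sites[1, ], window_bp = 3000)$matrix
  b2 <- pileup(m, sites[2, ], window_bp = 3000)$matrix
  both <- pileup(m, sites[1:2, ], window_bp = 3000)$matrix
  expect_equal(both, (a + b2) / 2, tolerance = 1e-12)
  # anchors too close to the contig end are skipped and counted
  edge <- anchor_set("chrS", c(500L, 10000L))
  pe <- pileup(m, edge, window_bp = 3000)
  expect_identical(pe$n_used, 1L)
  expect_identical(pe$n_skipped, 1L)
  expect_error(pileup(m, anchor_set("chrS", 100L), window_bp = 3000),
               "no usable anchors")
})

test_that("phased arrays band the pileup at the nucleosome repeat length", {
  cfg <- generator_config(plasmid_contigs(40000L),
                          anchor_set("chrS", c(10000L, 20000L, 30000L), "+"),
                          n_pairs = 5e5, seed = 10)
  res <- synth_filtered_pairs(cfg)
  m <- bin_pairs(res$flt$kept, 20, cfg$contigs)
  pu <- pileup(m, cfg$tf_sites, window_bp = 3000)
  # banding parallel to the diagonal: mean count per bin separation peaks at
  # the NRL (188 bp = 9.4 bins of 20 bp)
  band <- vapply(1:15, function(k) {
    mean(pu$matrix[cbind(1:(150 - k), (1 + k):150)])
  }, 1)
  lag_bp <- (which.max(band[5:15]) + 4) * 20    # search 100-300 bp
  expect_lt(abs(lag_bp - 188), 21)              # NRL +/- 1 bin
})

test_that("decay curves histogram distances per orientation class", {
  p <- do.call(rbind, replicate(10, shifted_pair(1000, 1200), simplify = FALSE))
  w <- testthat::capture_warnings(dc <- decay_curve(p))
  expect_match(w, "zero pairs", all = TRUE)
  expect_length(w, 3)   # one per empty orientation class
  inw <- dc[dc$class == "inward", ]
  expect_identical(sum(inw$count > 0), 1L)
  expect_equal(inw$freq[inw$count > 0], 1)
  expect_true(all(is.na(dc$freq[dc$class == "outward"])))
})

test_that("decay slope recovers the sampling exponent alpha = 1", {
  contigs <- contig_table("chrL", 100000L)
  cfg <- generator_config(contigs, NULL, alpha = 1, n_pairs = 1e6,
                          p_undigested = 0, seed = 5)
  gt <- make_ground_truth(cfg)
  fl <- filter_pairs(shift_to_dyad(classify_orientation(
    simulate_ligation_pairs(gt))))
  dc <- decay_curve(fl$kept)
  slope <- decay_slope(dc, "inward", c(2000, 20000),
                       n_loci = length(gt$dyads$chrL), nrl_bp = 188)
  expect_lt(abs(slope - (-1)), 0.1)
  # split-half consistency: two half-samples agree bin-by-bin within 3 sd
  half <- nrow(fl$kept) %/% 2
  d1 <- decay_curve(fl$kept[1:half, ])
  d2 <- decay_curve(fl$kept[(half + 1):(2 * half), ])
  i1 <- d1[d1$class == "inward", ]
  i2 <- d2[d2$class == "inward", ]
  n <- min(nrow(i1), nrow(i2))
  diff_ok <- abs(i1$count[1:n] - i2$count[1:n]) <=
    3 * sqrt(i1$count[1:n] + i2$count[1:n]) + 3
  expect_gt(mean(diff_ok), 0.99)
})

test_that("matrix correlation behaves at its fixed points", {
  cfg <- generator_config(plasmid_contigs(), five_sites(), n_pairs = 1e6,
                          seed = 1)
  gt <- make_ground_truth(cfg)
  m1 <- bin_pairs(filter_pairs(shift_to_dyad(classify_orientation(
    simulate_ligation_pairs(gt, seed = 100))))$kept, 80, cfg$contigs)
  m2 <- bin_pairs(filter_pairs(shift_to_dyad(classify_orientation(
    simulate_ligation_pairs(gt, seed = 200))))$kept, 80, cfg$contigs)
  expect_equal(matrix_correlation(m1, m1), 1)
  # independent replicates of the same chromatin correlate strongly
  expect_gt(matrix_correlation(m1, m2), 0.9)
  # cell-shuffled null decorrelates
  mp <- m2
  tm <- as(mp$counts, "TsparseMatrix")
  set.seed(99)
  tm@x <- sample(tm@x)
  perm_ij <- which(upper.tri(matrix(0, nrow(mp$counts), ncol(mp$counts))),
                   arr.ind = TRUE)
  sel <- perm_ij[sample(nrow(perm_ij), length(tm@x)), ]
  mp$counts <- Matrix::sparseMatrix(i = sel[, 1], j = sel[, 2], x = tm@x,
                                    dims = dim(mp$counts))
  expect_lt(abs(matrix_correlation(m1, mp)), 0.1)
  m3 <- bin_pairs(shifted_pair(85, 165), 80, contig_table("chrS", 400L))
  expect_error(matrix_correlation(m1, m3), "mismatched")
})
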