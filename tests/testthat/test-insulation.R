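# Independent O(n * w^2) diamond-mean oracle used against insulation_score.
diamond_oracle <- function(dense, w, circular = FALSE) {
  n <- nrow(dense)
  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!circular && (i - w < 1 || i + w > n)) next
    tot <- 0
    for (a in (i - w):(i - 1)) {
      for (b in (i + 1):(i + w)) {
        ai <- (a - 1) %% n + 1
        bi <- (b - 1) %% n + 1
        lo <- min(ai, bi); hi <- max(ai, bi)
        tot <- tot + dense[lo, hi]
      }
    }
    raw[i] <- tot / (w * w)
  }
  log2(raw / mean(raw[is.finite(raw)]))
}

random_matrix <- function(n, seed, contig_len = n * 80L, circular = FALSE) {
  set.seed(seed)
  upper <- matrix(0, n, n)
  upper[upper.tri(upper, diag = TRUE)] <-
    rpois(n * (n + 1) / 2, 3)
  contigs <- contig_table("chrT", contig_len, circular = circular)
  bins <- data.frame(contig = "chrT", start = (0:(n - 1)) * 80L,
                     end = (1:n) * 80L)
  structure(list(counts = Matrix::Matrix(upper, sparse = TRUE), bins = bins,
                 resolution = 80L, contigs = contigs),
            class = "contact_matrix")
}

test_that("insulation matches the brute-force diamond oracle to 1e-12", {
  for (seed in 1:4) {
    m <- random_matrix(30, seed)
    for (w_bp in c(400, 800)) {
      prof <- insulation_score(m, w_bp)
      dense <- as.matrix(m$counts)
      expected <- diamond_oracle(dense, w_bp / 80)
      expect_equal(prof$score, expected, tolerance = 1e-12)
    }
  }
  # circular contigs wrap the diamond: every bin is scored
  mc <- random_matrix(30, 5, circular = TRUE)
  profc <- insulation_score(mc, 400)
  expect_true(all(is.finite(profc$score)))
  expect_equal(profc$score, diamond_oracle(as.matrix(mc$counts), 5,
                                           circular = TRUE),
               tolerance = 1e-12)
})

test_that("uniform matrices score zero and split blocks dip at the split", {
  n <- 30
  uni <- random_matrix(1, 1)   # rebuilt below
  dense <- matrix(0, n, n); dense[upper.tri(dense, diag = TRUE)] <- 4
  uni <- structure(list(counts = Matrix::Matrix(dense, sparse = TRUE),
                        bins = data.frame(contig = "chrT",
                                          start = (0:(n - 1)) * 80L,
                                          end = (1:n) * 80L),
                        resolution = 80L,
                        contigs = contig_table("chrT", n * 80L)),
                   class = "contact_matrix")
  prof <- insulation_score(uni, 400)
  expect_true(all(abs(prof$score[is.finite(prof$score)]) < 1e-12))
  # two dense blocks, zero cross-block -> unique minimum at the split
  k <- 15L
  blk <- matrix(0, n, n)
  for (i in 1:n) for (j in i:n) {
    if ((i <= k && j <= k) || (i > k && j > k)) blk[i, j] <- 5
  }
  m2 <- uni; m2$counts <- Matrix::Matrix(blk, sparse = TRUE)
  prof2 <- insulation_score(m2, 400)
  # both split-adjacent bins see zero cross-block contacts; the minimum sits
  # at the split (leftmost of the tie)
  expect_identical(which.min(prof2$score), k)
  expect_true(all(which(prof2$score == min(prof2$score, na.rm = TRUE)) %in%
                    c(k, k + 1L)))
  expect_error(insulation_score(uni, 80 * 40), "window larger")
})

test_that("boundary prominences match an exhaustive oracle", {
  # oracle: for minimum m, walk to the nearest strictly deeper value on each
  # side; saddle = max in between (profile ends cap at the side maximum)
  prom_oracle <- function(s) {
    n <- length(s)
    mins <- nucfold:::.local_minima(s)
    data.frame(bin = mins, prominence = vapply(mins, function(m) {
      deeper_left <- which(s[seq_len(m - 1)] < s[m])
      from <- if (length(deeper_left)) max(deeper_left) + 1L else 1L
      lsad <- max(s[from:(m - 1)])
      deeper_right <- which(s[(m + 1):n] < s[m]) + m
      to <- if (length(deeper_right)) min(deeper_right) - 1L else n
      rsad <- max(s[(m + 1):to])
      min(lsad, rsad) - s[m]
    }, 1))
  }
  # hand example: V-shaped profile has one minimum with prominence 2
  v <- c(0, -1, -2, -1, 0)
  mins <- nucfold:::.local_minima(v)
  expect_identical(mins, 3L)
  expect_equal(nucfold:::.min_prominence(v, mins), 2)
  # monotone profile: no boundaries
  expect_identical(nucfold:::.local_minima(sort(rnorm(20))), integer(0))
  # randomized profiles vs oracle (plateaus included via rounding)
  for (seed in 1:20) {
    set.seed(seed)
    s <- round(rnorm(sample(10:50, 1)), 1)
    mins <- nucfold:::.local_minima(s)
    got <- nucfold:::.min_prominence(s, mins)
    orc <- prom_oracle(s)
    expect_identical(mins, orc$bin)
    expect_equal(got, orc$prominence)
  }
})

test_that("Li threshold fixed point, separation, and homogeneity", {
  expect_lt(abs(li_threshold(c(1, 1, 1, 1, 9, 9)) - 3.641), 1e-3)
  set.seed(42)
  v <- c(rnorm(50, 1, 0.1), rnorm(50, 10, 0.1))
  t <- li_threshold(v)
  expect_gt(t, 1.5); expect_lt(t, 9.5)
  expect_equal(li_threshold(3 * v), 3 * t, tolerance = 1e-5)
  expect_error(li_threshold(rep(2, 5)), "distinct")
  expect_error(li_threshold(c(-1, 2, 3)), "positive")
})

test_that("boundary calls are shift-invariant and carry Li strength", {
  cfg <- generator_config(plasmid_contigs(), five_sites(), n_pairs = 3e5,
                          seed = 4)
  res <- synth_filtered_pairs(cfg)
  m <- bin_pairs(res$flt$kept, 80, cfg$contigs)
  prof <- insulation_score(m, 800)
  b1 <- call_boundaries(prof)
  prof2 <- prof
  prof2$score <- prof2$score + 1.7
  b2 <- call_boundaries(prof2)
  expect_identical(b1$position, b2$position)
  expect_equal(b1$prominence, b2$prominence)
  expect_true(all(b1$prominence > 0))
  expect_true(all(b1$prominence[b1$strong] >= attr(b1, "li_threshold")))
  # planted NFRs are recovered within 2 bins by the strongest minima
  strong <- b1[b1$strong, ]
  for (c0 in cfg$tf_sites$pos) {
    expect_lte(min(abs(strong$position - c0)), 160)
  }
})

test_that("insulation composites at anchors hit their fixed points", {
  n <- 40
  prof <- structure(data.frame(contig = "chrT", start = (0:(n - 1)) * 80L,
                               end = (1:n) * 80L, score = 0),
                    class = c("insulation_profile", "data.frame"))
  attr(prof, "window_bp") <- 800; attr(prof, "resolution_bp") <- 80L
  flat <- insulation_at_anchors(prof, anchor_set("chrT", 1600L), 2000)
  expect_true(all(flat$composite == 0))
  expect_identical(flat$minimum, 0)
  # single anchor: composite equals the local profile slice
  prof$score <- sin(seq_len(n))
  one <- insulation_at_anchors(prof, anchor_set("chrT", 1600L), 2000)
  b <- 1600 %/% 80 + 1
  half <- length(one$composite) %/% 2
  expect_equal(one$composite, prof$score[(b - half):(b + half)])
  expect_error(insulation_at_anchors(prof, anchor_set("chrT", 50L), 2000),
               "interior")
})

test_that("NFR width / insulation correlation and degenerate inputs", {
  lin <- nfr_vs_insulation(c(68, 92, 126), -c(68, 92, 126) / 100)
  expect_equal(lin$r, -1)
  pts <- nfr_vs_insulation(c(68, 92, 126), c(-0.1, -0.2, -0.3))
  # hand Pearson on the listed points
  x <- c(68, 92, 126); y <- c(-0.1, -0.2, -0.3)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pts$r, r_hand, tolerance = 1e-12)
  expect_equal(pts$r, -0.99508, tolerance = 1e-4)
  expect_error(nfr_vs_insulation(c(68, 92, 126), c(-1, -1, -1)), "variance")
  expect_error(nfr_vs_insulation(c(68, 92), c(-1, -2)), ">= 3")
})

test_that("boundary/anchor overlap and its permutation null", {
  contigs <- plasmid_contigs()
  b <- data.frame(contig = "chrS", position = c(3000, 10000), bin = c(1L, 2L),
                  score = c(-1, -1), prominence = c(1, 1),
                  strong = c(TRUE, TRUE))
  anchors <- anchor_set("chrS", c(3000L, 10000L))
  hit <- boundary_anchor_overlap(b, anchors, contigs, n_perm = 20)
  expect_identical(hit$frac_boundaries, 1)
  expect_identical(hit$frac_anchors, 1)
  expect_gt(hit$enrichment, 5)
  miss <- boundary_anchor_overlap(b, anchor_set("chrX", 3000L), contigs,
                                  n_perm = 5)
  expect_identical(miss$frac_boundaries, 0)
  # shuffled boundaries are unenriched
  set.seed(7)
  bs <- data.frame(contig = "chrS", position = runif(50, 0, 20000),
                   bin = 1:50, score = -1, prominence = 1, strong = TRUE)
  null <- boundary_anchor_overlap(bs, anchors, contigs, n_perm = 200,
                                  seed = 3)
  expect_gt(null$enrichment, 0.3)
  expect_lt(null$enrichment, 3)
})
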