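test_that("wrapped-bead geometry holds at initialization to 1e-9", {
  model <- build_topology(5000L, seed = 3)
  expect_identical(nrow(model$coords), 27L)   # 23 DNA + 4 histone beads
  wr <- model$coords[model$beads$kind == "dna_wrapped", ]
  hi <- model$coords[model$beads$kind == "histone", ]
  # histone beads define the superhelical axis
  axis <- hi[4, ] - hi[1, ]
  axis <- axis / sqrt(sum(axis^2))
  center <- colMeans(hi)
  rel <- sweep(wr, 2, center)
  ax <- rel %*% axis
  radial <- sqrt(rowSums((rel - ax %*% t(axis))^2))
  expect_true(all(abs(radial - 4.18) < 1e-9))
  # axial extent = 1.65 turns x 2.39 nm pitch
  expect_equal(max(ax) - min(ax), 1.65 * 2.39, tolerance = 1e-9)
  # angular span 594 degrees, left-handed (monotone decreasing angle)
  e1 <- rel[1, ] - as.numeric(ax[1]) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  planar <- rel - ax %*% t(axis)
  ang <- atan2(planar %*% e2, planar %*% e1)
  unwrapped <- as.numeric(ang)
  for (k in 2:length(unwrapped)) {
    while (unwrapped[k] > unwrapped[k - 1]) {
      unwrapped[k] <- unwrapped[k] - 2 * pi
    }
  }
  span_deg <- abs(unwrapped[23] - unwrapped[1]) * 180 / pi
  expect_equal(span_deg, 594, tolerance = 1e-6)
})

test_that("topology counts linker beads and rejects overlapping nucleosomes", {
  m <- build_topology(c(1000L, 1000L + 147L + 41L), seed = 1)
  expect_identical(sum(m$beads$kind == "dna_linker"), 7L)  # round(41 / 5.88)
  expect_identical(sum(m$beads$kind == "dna_wrapped"), 46L)
  expect_error(build_topology(c(1000L, 1100L)), "gap < 147")
  # DNA beads form one connected chain: consecutive chain bonds exist
  chain <- which(m$beads$kind != "histone")
  bonded <- paste(m$bonds$i, m$bonds$j)
  expect_true(all(paste(chain[-length(chain)], chain[-1]) %in% bonded))
})

test_that("restraint weights are ln(1 + count) and symmetric", {
  counts <- Matrix::sparseMatrix(i = c(1, 1), j = c(2, 3),
                                 x = c(exp(1) - 1, 0), dims = c(3, 3))
  nm <- structure(list(counts = counts,
                       bins = data.frame(contig = "c", start = c(0, 188, 376),
                                         end = c(1, 189, 377)),
                       resolution = "nucleosome",
                       contigs = contig_table("c", 1000L)),
                  class = "contact_matrix")
  rs <- restraints_from_matrix(nm)
  expect_identical(nrow(rs), 1L)          # zero-count cell contributes nothing
  expect_equal(rs$weight, 1)              # ln(1 + (e - 1)) = 1
  # transposed (lower-triangular) storage yields the same restraints
  nm_t <- nm; nm_t$counts <- Matrix::t(counts)
  expect_equal(restraints_from_matrix(nm_t), rs)
  # empty matrix -> empty set
  nm0 <- nm; nm0$counts <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                                x = numeric(0), dims = c(3, 3))
  expect_identical(nrow(restraints_from_matrix(nm0)), 0L)
  bp <- nm; bp$resolution <- 80L
  expect_error(restraints_from_matrix(bp), "nucleosome-binned")
})

test_that("annealing relaxes bonds and is reproducible per seed", {
  coords <- matrix(c(0, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE)
  bonds <- data.frame(i = 1L, j = 2L, d0 = 2)
  model <- toy_bead_model(coords, bonds)
  sch <- anneal_schedule(seed = 7)
  ann <- anneal(model, NULL, sch)
  d <- sqrt(sum((ann$coords[1, ] - ann$coords[2, ])^2))
  expect_lt(abs(d - 2), 0.1)
  expect_lte(ann$final_energy, ann$initial_energy)
  # bit-identical per seed
  ann2 <- anneal(model, NULL, sch)
  expect_identical(ann$coords, ann2$coords)
  expect_identical(ann$energy_trace, ann2$energy_trace)
  expect_false(identical(ann$coords, anneal(model, NULL,
                                            anneal_schedule(seed = 8))$coords))
})

test_that("annealing reaches the independent minimizer's energy on a chain", {
  # 8-bead chain, end-to-end flat-bottom restraint active beyond 11 nm
  n <- 8
  coords <- cbind(seq(0, by = 2.5, length.out = n), 0, 0)
  bonds <- data.frame(i = 1:(n - 1), j = 2:n, d0 = 2)
  angles <- cbind(1:(n - 2), 2:(n - 1), 3:n)
  k_ang <- 12.5
  model <- toy_bead_model(coords, bonds, radii = rep(0.2, n),
                          angles = angles, k_angle = k_ang)
  rs <- structure(data.frame(i = 1L, j = 2L, weight = 2, tag = NA_character_),
                  class = c("restraint_set", "data.frame"), d_contact = 11)
  # the restraint maps beads via histone_idx in real models; for the toy,
  # restrain beads 1 and n directly through a custom energy in the oracle and
  # an equivalent restraint mapping here
  model$histone_idx <- list(c(1L, 1L, 1L, 1L), c(n, n, n, n))
  rs$i <- 1L; rs$j <- 2L   # nucleosome ids -> beads 1 and n
  k_bond <- 50; k_restr <- 3; k_rep <- 20; w <- 2; d_c <- 11
  energy_fn <- function(x) {
    xm <- matrix(x, n, 3)
    e <- 0
    for (b in 1:(n - 1)) {
      d <- sqrt(sum((xm[b, ] - xm[b + 1, ])^2))
      e <- e + k_bond * (d - 2)^2
    }
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      ov <- 0.4 - sqrt(sum((xm[a, ] - xm[b, ])^2))
      if (ov > 0) e <- e + k_rep * ov^2
    }
    for (a in 1:(n - 2)) {
      v1 <- xm[a + 1, ] - xm[a, ]; v2 <- xm[a + 2, ] - xm[a + 1, ]
      ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      e <- e + k_ang * acos(max(-1, min(1, ct)))^2
    }
    dd <- sqrt(sum((xm[1, ] - xm[n, ])^2))
    if (dd > d_c) e <- e + w * k_restr * (dd - d_c)^2
    e
  }
  # multi-start quasi-Newton oracle to approximate the global minimum
  set.seed(11)
  best <- Inf
  for (r in 1:5) {
    x0 <- as.numeric(coords) + rnorm(3 * n, 0, 0.5 * (r - 1))
    opt <- stats::optim(x0, energy_fn, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, opt$value)
  }
  # long cold tail so the annealer's thermal residue is negligible next to
  # the minimizer's optimum
  ann <- anneal(model, rs, anneal_schedule(2, 0.002, 3000, 0.2, seed = 2))
  e_ann <- energy_fn(as.numeric(ann$coords))
  # chain span 14 nm > 11 nm: restraint is active, minimum is nonzero
  expect_gt(best, 1e-3)
  expect_lt(e_ann, best * 1.05 + 1e-6)
})

test_that("a relaxed nucleosome chain settles near bond rest lengths", {
  model <- build_topology(c(2000L, 2188L, 2376L), seed = 5)
  ann <- anneal(model, NULL, anneal_schedule(t_start = 1, t_end = 0.01,
                                             n_sweeps = 600, seed = 3))
  d <- sqrt(rowSums((ann$coords[model$bonds$i, ] -
                       ann$coords[model$bonds$j, ])^2))
  rel_dev <- abs(d - model$bonds$d0) / model$bonds$d0
  expect_lt(stats::median(rel_dev), 0.05)
  expect_lte(ann$final_energy, ann$initial_energy)
})

test_that("model contact maps count close histone centers", {
  model <- build_topology(c(1000L, 1188L, 1376L), seed = 2)
  co <- model$coords
  cm_all <- model_contact_map(model, co * 0, cutoff_nm = 15)   # all collapsed
  expect_identical(sum(cm_all$counts), 3)                       # complete graph
  far <- co
  far[model$histone_idx[[2]], ] <- far[model$histone_idx[[2]], ] + 1000
  far[model$histone_idx[[3]], ] <- far[model$histone_idx[[3]], ] + 2000
  cm_far <- model_contact_map(model, far, cutoff_nm = 15)
  expect_identical(sum(cm_far$counts), 0)
})

test_that("structures round-trip through PDB-like and XYZ files", {
  model <- build_topology(c(1000L, 1188L), seed = 4)
  for (ext in c(".xyz", ".pdb")) {
    path <- withr::local_tempfile(fileext = ext)
    write_structure(model, model$coords, path)
    back <- read_structure(path)
    expect_equal(back$coords, unname(round(model$coords, 3)),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_identical(length(back$kind), nrow(model$coords))
  }
})
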