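#' Coarse-grained nucleosome bead geometry
#'
#' Geometry of the bead decomposition: a histone octamer is four histone beads
#' of 3 nm radius; one DNA bead covers 5.88 bp; 23 sequential DNA beads wrap
#' the histone particles in a left-handed superhelix of 1.65 turns with a
#' radius of 4.18 nm and a pitch of 2.39 nm. The DNA rise of 0.34 nm/bp is
#' the standard B-DNA value (an external constant, not specific to this
#' system), giving a DNA bead-to-bead bond rest length of 5.88 x 0.34 ~ 2.0
#' nm.
#'
#' @param histone_bead_radius nm, default 3.
#' @param dna_bead_radius nm, default 1 (B-DNA half-width).
#' @return object of class `bead_geometry`.
#' @export
bead_geometry <- function(histone_bead_radius = 3, dna_bead_radius = 1) {
  g <- list(histone_beads_per_nucleosome = 4L,
            histone_bead_radius = histone_bead_radius,
            bp_per_dna_bead = 5.88,
            wrapped_beads_per_nucleosome = 23L,
            wrap_turns = 1.65,
            wrap_radius = 4.18,
            wrap_pitch = 2.39,
            dna_rise = 0.34,
            dna_bead_radius = dna_bead_radius)
  g$bond_length <- g$bp_per_dna_bead * g$dna_rise
  g$wrap_height <- g$wrap_turns * g$wrap_pitch
  structure(g, class = "bead_geometry")
}

# Random orthonormal frame (u = axis, e1, e2).
.random_frame <- function() {
  repeat {
    u <- rnorm(3)
    nu <- sqrt(sum(u^2))
    if (nu > 1e-8) { u <- u / nu; break }
  }
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- c(u[2] * a[3] - u[3] * a[2],
          u[3] * a[1] - u[1] * a[3],
          u[1] * a[2] - u[2] * a[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(u = u, e1 = e1, e2 = e2)
}

#' Build the bead-model topology for a set of nucleosome loci
#'
#' Per nucleosome: 23 wrapped DNA beads on a left-handed superhelix (radius
#' 4.18 nm, total angle 1.65 x 360 = 594 degrees, axial extent 1.65 x 2.39
#' nm) and 4 histone beads equally spaced along the superhelical axis. Linker
#' DNA beads (count = round(linker_bp / 5.88)) connect each exit bead to the
#' next entry bead, so all DNA beads form a single connected chain.
#' Initialization places nucleosomes on a random walk with excluded-volume
#' retries and random superhelix orientations (seedful). Bending stiffness on
#' linker beads comes from a 50 nm (~150 bp) DNA persistence length.
#'
#' @param dyads sorted dyad coordinates (bp) of one contig; consecutive gaps
#'   must be >= 147 bp.
#' @param geometry a [bead_geometry()].
#' @param contig contig name used in outputs.
#' @param seed RNG seed for the initial configuration.
#' @return object of class `bead_model`: beads table (kind, nucleosome id),
#'   initial `coords` (nm), bonds with rest lengths, linker angle triplets,
#'   per-nucleosome entry/exit/histone bead indices.
#' @export
build_topology <- function(dyads, geometry = bead_geometry(),
                           contig = "contig1", seed = 1L) {
  dyads <- sort(dyads)
  nn <- length(dyads)
  if (nn < 1L) stop("need >= 1 nucleosome")
  if (nn > 1L) {
    gap <- diff(dyads)
    bad <- which(gap < 147)
    if (length(bad)) {
      stop("overlapping nucleosomes (gap < 147 bp) at loci ",
           paste(dyads[bad], collapse = ", "))
    }
  }
  g <- geometry
  linker_bp <- if (nn > 1L) diff(dyads) - 147 else integer(0)
  n_link <- round(linker_bp / g$bp_per_dna_bead)
  nw <- g$wrapped_beads_per_nucleosome
  nh <- g$histone_beads_per_nucleosome
  withr::with_seed(as.integer(seed), {
    # nucleosome centers: random walk with excluded-volume retries
    centers <- matrix(0, nn, 3)
    for (k in seq_len(nn)[-1]) {
      step <- 9 + 0.6 * (n_link[k - 1L] + 1L) * g$bond_length
      for (try in 1:50) {
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        cand <- centers[k - 1L, ] + dir * step
        d2 <- rowSums((centers[seq_len(k - 1L), , drop = FALSE] -
                         matrix(cand, k - 1L, 3, byrow = TRUE))^2)
        if (all(d2 > 49) || try == 50L) break
      }
      centers[k, ] <- cand
    }
    span <- g$wrap_turns * 2 * pi          # 594 degrees
    h <- g$wrap_height
    t <- seq_len(nw) - 1L
    z <- -h / 2 + t * h / (nw - 1L)
    phi <- -t * span / (nw - 1L)           # left-handed: angle decreases with z
    wrapped <- vector("list", nn)
    histones <- vector("list", nn)
    for (k in seq_len(nn)) {
      f <- .random_frame()
      ring <- outer(g$wrap_radius * cos(phi), f$e1) +
        outer(g$wrap_radius * sin(phi), f$e2) + outer(z, f$u)
      wrapped[[k]] <- sweep(ring, 2, centers[k, ], "+")
      zh <- -h / 2 + (seq_len(nh) - 0.5) * h / nh
      histones[[k]] <- sweep(outer(zh, f$u), 2, centers[k, ], "+")
    }
    # assemble chain: wrapped_k then linker_k, histones appended at the end
    kind <- character(0); nuc <- integer(0)
    coords <- matrix(numeric(0), 0, 3)
    entry <- exit <- integer(nn)
    idx <- 0L
    for (k in seq_len(nn)) {
      coords <- rbind(coords, wrapped[[k]])
      kind <- c(kind, rep("dna_wrapped", nw))
      nuc <- c(nuc, rep(k, nw))
      entry[k] <- idx + 1L
      exit[k] <- idx + nw
      idx <- idx + nw
      if (k < nn && n_link[k] > 0L) {
        a <- wrapped[[k]][nw, ]
        b <- wrapped[[k + 1L]][1L, ]
        frac <- seq_len(n_link[k]) / (n_link[k] + 1L)
        lb <- outer(frac, b - a) + matrix(a, n_link[k], 3, byrow = TRUE)
        coords <- rbind(coords, lb)
        kind <- c(kind, rep("dna_linker", n_link[k]))
        nuc <- c(nuc, rep(NA_integer_, n_link[k]))
        idx <- idx + n_link[k]
      }
    }
    hist_idx <- vector("list", nn)
    for (k in seq_len(nn)) {
      coords <- rbind(coords, histones[[k]])
      kind <- c(kind, rep("histone", nh))
      nuc <- c(nuc, rep(k, nh))
      hist_idx[[k]] <- idx + seq_len(nh)
      idx <- idx + nh
    }
    n_beads <- nrow(coords)
    # bonds: DNA chain
    chain <- which(kind != "histone")
    bi <- chain[-length(chain)]
    bj <- chain[-1L]
    d0 <- rep(g$bond_length, length(bi))
    # wrapped-wrapped bonds keep their superhelical chord length
    ww <- kind[bi] == "dna_wrapped" & kind[bj] == "dna_wrapped"
    d0[ww] <- sqrt(rowSums((coords[bi[ww], , drop = FALSE] -
                              coords[bj[ww], , drop = FALSE])^2))
    bonds <- data.frame(i = bi, j = bj, d0 = d0)
    # histone spine and wrapped-to-histone attachment bonds
    for (k in seq_len(nn)) {
      hk <- hist_idx[[k]]
      bonds <- rbind(bonds, data.frame(i = hk[-nh], j = hk[-1L], d0 = h / nh))
      wr <- entry[k]:exit[k]
      dmat <- outer(seq_along(wr), seq_along(hk),
                    function(a, b) sqrt(rowSums((coords[wr[a], , drop = FALSE] -
                                                   coords[hk[b], , drop = FALSE])^2)))
      nearest <- hk[apply(dmat, 1, which.min)]
      bonds <- rbind(bonds, data.frame(
        i = wr, j = nearest,
        d0 = sqrt(rowSums((coords[wr, , drop = FALSE] -
                             coords[nearest, , drop = FALSE])^2))))
    }
    # bending angles centered on linker beads
    linker_pos <- which(kind == "dna_linker")
    ang <- NULL
    if (length(linker_pos)) {
      pos_in_chain <- match(linker_pos, chain)
      ok <- pos_in_chain > 1L & pos_in_chain < length(chain)
      p <- pos_in_chain[ok]
      ang <- cbind(chain[p - 1L], chain[p], chain[p + 1L])
    }
    if (is.null(ang)) ang <- matrix(integer(0), 0, 3)
    radii <- ifelse(kind == "histone", g$histone_bead_radius, g$dna_bead_radius)
    structure(list(beads = data.frame(kind = kind, nucleosome = nuc),
                   coords = coords,
                   bonds = bonds,
                   angles = ang,
                   radii = radii,
                   entry = entry, exit = exit, histone_idx = hist_idx,
                   dyads = dyads, contig = contig,
                   geometry = g,
                   # persistence length 50 nm over ~2 nm segments, in kT/rad^2
                   k_angle = 50 / (2 * g$bond_length)),
              class = "bead_model")
  })
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("<bead_model> %d nucleosomes, %d beads (%d DNA, %d histone)\n",
              length(x$dyads), nrow(x$coords),
              sum(x$beads$kind != "histone"), sum(x$beads$kind == "histone")))
  invisible(x)
}

#' Restraints from a nucleosome-binned contact matrix
#'
#' One distance restraint per nonzero off-diagonal cell, with weight
#' `ln(1 + count)`. An orientation tag per restraint (the majority ligation
#' class of the contributing pairs, when available) selects which beads are
#' restrained during annealing: inward-tagged restraints act between
#' entry/exit-proximal DNA beads, all others between histone-center beads.
#'
#' @param nuc_mat a [bin_to_nucleosomes()] matrix.
#' @param d_contact target contact distance in nm, default 11.
#' @param tags optional character vector/matrix source of orientation tags.
#' @return object of class `restraint_set`: data.frame(i, j, weight, tag).
#' @export
restraints_from_matrix <- function(nuc_mat, d_contact = 11, tags = NULL) {
  if (!identical(nuc_mat$resolution, "nucleosome")) {
    stop("restraints need a nucleosome-binned matrix")
  }
  tm <- as(nuc_mat$counts, "TsparseMatrix")
  keep <- tm@i != tm@j & tm@x > 0
  i <- pmin(tm@i[keep], tm@j[keep]) + 1L
  j <- pmax(tm@i[keep], tm@j[keep]) + 1L
  r <- data.frame(i = i, j = j, weight = log1p(tm@x[keep]),
                  tag = if (is.null(tags)) rep(NA_character_, length(i))
                        else tags[keep])
  r <- r[order(r$i, r$j), ]
  rownames(r) <- NULL
  structure(r, class = c("restraint_set", "data.frame"),
            d_contact = d_contact)
}

#' Annealing schedule
#'
#' @param t_start,t_end start / end temperature in reduced units (kT); must
#'   satisfy `t_start > t_end > 0`.
#' @param n_sweeps number of whole-model sweeps (one proposed move per bead
#'   per sweep).
#' @param move_sd Gaussian displacement sd in nm.
#' @param seed RNG seed; annealing is bit-reproducible per seed.
#' @return object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(t_start = 5, t_end = 0.05, n_sweeps = 1200L,
                            move_sd = 0.3, seed = 1L) {
  if (!(t_start > t_end && t_end > 0)) stop("need t_start > t_end > 0")
  if (n_sweeps < 1) stop("n_sweeps must be >= 1")
  structure(list(t_start = t_start, t_end = t_end,
                 n_sweeps = as.integer(n_sweeps), move_sd = move_sd,
                 seed = as.integer(seed)),
            class = "anneal_schedule")
}

# Map a restraint set to bead index pairs for a model.
.restraint_beads <- function(model, restraints, use_orientation = TRUE) {
  nh_center <- vapply(model$histone_idx, function(h) as.integer(h[2L]), 1L)
  i_bead <- nh_center[restraints$i]
  j_bead <- nh_center[restraints$j]
  if (use_orientation && any(!is.na(restraints$tag))) {
    inw <- !is.na(restraints$tag) & restraints$tag == "inward"
    i_bead[inw] <- model$exit[restraints$i[inw]]
    j_bead[inw] <- model$entry[restraints$j[inw]]
  }
  cbind(i_bead, j_bead)
}

#' Anneal a bead model against contact restraints
#'
#' Metropolis simulated annealing with single-bead Gaussian moves and
#' geometric cooling. The energy is the sum of harmonic bond terms, harmonic
#' bending terms on linker beads (stiffness from the 50 nm DNA persistence
#' length), soft-core repulsion between overlapping beads, and one-sided
#' harmonic contact restraints `w_ij (|d| - d_contact)^2` active beyond
#' `d_contact`. Deterministic per `schedule$seed`.
#'
#' @param model a [build_topology()] model.
#' @param restraints a [restraints_from_matrix()] set (may be empty).
#' @param schedule an [anneal_schedule()].
#' @param k_bond,k_rep,k_restr force constants (reduced units).
#' @param use_orientation map inward-tagged restraints to entry/exit DNA
#'   beads (default TRUE).
#' @return list(coords, energy_trace, acceptance, initial_energy,
#'   final_energy) of class `anneal_result`.
#' @export
anneal <- function(model, restraints = NULL, schedule = anneal_schedule(),
                   k_bond = 50, k_rep = 20, k_restr = 3,
                   use_orientation = TRUE) {
  stopifnot(inherits(model, "bead_model"))
  if (is.null(restraints) || nrow(restraints) == 0L) {
    rb <- matrix(integer(0), 0, 2)
    rw <- numeric(0)
    d_contact <- 11
  } else {
    rb <- .restraint_beads(model, restraints, use_orientation)
    rw <- restraints$weight
    d_contact <- attr(restraints, "d_contact")
  }
  res <- withr::with_seed(schedule$seed, {
    anneal_cpp(model$coords,
               as.matrix(model$bonds[, c("i", "j")]) - 1L, model$bonds$d0,
               k_bond,
               model$angles - 1L, model$k_angle,
               model$radii, k_rep,
               rb - 1L, rw, k_restr, d_contact,
               schedule$n_sweeps, schedule$t_start, schedule$t_end,
               schedule$move_sd)
  })
  e0 <- bead_energy(model, model$coords, restraints,
                    k_bond = k_bond, k_rep = k_rep, k_restr = k_restr,
                    use_orientation = use_orientation)
  structure(list(coords = res$coords, energy_trace = res$energy_trace,
                 acceptance = res$acceptance,
                 initial_energy = e0,
                 final_energy = res$energy_trace[length(res$energy_trace)]),
            class = "anneal_result")
}

#' Total model energy of a configuration
#'
#' Same energy function as [anneal()], evaluated once; used for diagnostics
#' and independent minimizer cross-checks.
#'
#' @inheritParams anneal
#' @param coords bead coordinate matrix (n x 3, nm).
#' @return energy (numeric scalar, reduced units).
#' @export
bead_energy <- function(model, coords, restraints = NULL,
                        k_bond = 50, k_rep = 20, k_restr = 3,
                        use_orientation = TRUE) {
  if (is.null(restraints) || nrow(restraints) == 0L) {
    rb <- matrix(integer(0), 0, 2)
    rw <- numeric(0)
    d_contact <- 11
  } else {
    rb <- .restraint_beads(model, restraints, use_orientation)
    rw <- restraints$weight
    d_contact <- attr(restraints, "d_contact")
  }
  bead_energy_cpp(coords,
                  as.matrix(model$bonds[, c("i", "j")]) - 1L, model$bonds$d0,
                  k_bond,
                  model$angles - 1L, model$k_angle,
                  model$radii, k_rep,
                  rb - 1L, rw, k_restr, d_contact)
}

#' Contact map implied by a 3D configuration
#'
#' Counts a nucleosome pair as contacting when the distance between the
#' nucleosomes' histone-center positions (mean of the four histone beads) is
#' at most `cutoff_nm`. Used to check that the annealed model recapitulates
#' the input contacts.
#'
#' @param model bead model.
#' @param coords coordinates (e.g. `anneal()$coords`).
#' @param cutoff_nm contact cutoff, default 15.
#' @return a nucleosome-binned `contact_matrix` of 0/1 contacts.
#' @export
model_contact_map <- function(model, coords, cutoff_nm = 15) {
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  centers <- t(vapply(model$histone_idx,
                      function(h) colMeans(coords[h, , drop = FALSE]),
                      numeric(3)))
  d <- as.matrix(stats::dist(centers))
  adj <- d <= cutoff_nm
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  n <- length(model$dyads)
  counts <- Matrix::sparseMatrix(i = idx[, 1], j = idx[, 2], x = 1,
                                 dims = c(n, n))
  bins <- data.frame(contig = model$contig, start = model$dyads,
                     end = model$dyads + 1L)
  contigs <- contig_table(model$contig, max(model$dyads) + 147L)
  .new_contact_matrix(counts, bins, "nucleosome", contigs,
                      extra = list(loci = stats::setNames(list(model$dyads),
                                                          model$contig)))
}

#' Write / read bead-model structures
#'
#' `write_structure()` writes either a PDB-like file (one ATOM record per
#' bead, chain per contig, bead kind in the element column, coordinates in
#' nm at 3 decimals) or a plain XYZ file. `read_structure()` reads either
#' format back; coordinates round-trip exactly at 3 decimals.
#'
#' @param model bead model.
#' @param coords coordinates to write.
#' @param path output path.
#' @param format "pdb" or "xyz" (default from file extension).
#' @return `write_structure()`: the path, invisibly. `read_structure()`:
#'   list(kind, coords).
#' @export
write_structure <- function(model, coords, path,
                            format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  kind <- model$beads$kind
  elem <- c(histone = "H", dna_wrapped = "W", dna_linker = "L")[kind]
  if (format == "xyz") {
    lines <- c(as.character(nrow(coords)),
               paste0("nucfold bead model; contig ", model$contig,
                      "; coordinates in nm"),
               sprintf("%s %.3f %.3f %.3f", elem,
                       coords[, 1], coords[, 2], coords[, 3]))
  } else {
    lines <- c("REMARK nucfold bead model; coordinates in nm",
               sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                       seq_len(nrow(coords)), elem, "BED", "A",
                       ifelse(is.na(model$beads$nucleosome), 0L,
                              model$beads$nucleosome) %% 10000L,
                       coords[, 1], coords[, 2], coords[, 3], elem),
               "END")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_structure
#' @export
read_structure <- function(path) {
  lines <- readLines(path)
  if (any(grepl("^ATOM", lines))) {
    at <- grep("^ATOM", lines, value = TRUE)
    coords <- cbind(as.numeric(substr(at, 31, 38)),
                    as.numeric(substr(at, 39, 46)),
                    as.numeric(substr(at, 47, 54)))
    kind <- trimws(substr(at, 77, 78))
  } else {
    n <- as.integer(lines[1])
    body <- strsplit(lines[2 + seq_len(n)], "\\s+")
    m <- matrix(unlist(body), ncol = 4, byrow = TRUE)
    kind <- m[, 1]
    coords <- matrix(as.numeric(m[, 2:4]), ncol = 3)
  }
  list(kind = kind, coords = coords)
}
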