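#' Generator configuration for synthetic chromatin
#'
#' Bundles everything the synthetic chromatin generator needs: contig
#' geometry, planted TF sites, a remodeler preset (linker / NFR ruler), the
#' contact model (power-law distance decay with multiplicative boundary
#' attenuation at NFRs), sequencing-like sampling depths, and seeds.
#'
#' The contact model samples a nucleosome pair (i, j) with probability
#' proportional to `s^(-alpha)` where `s` is the dyad separation (shortest arc
#' on circular contigs), multiplied by `beta(w) = exp(-w / w0_bp)` for every
#' planted NFR of width `w` strictly between the two nucleosomes. Wider NFRs
#' therefore attenuate crossing contacts more strongly and produce stronger
#' insulation.
#'
#' @param contigs contig table from [contig_table()].
#' @param tf_sites anchor set of planted TF sites ([anchor_set()]) or NULL for
#'   a single uninterrupted array.
#' @param preset a [remodeler_preset()].
#' @param alpha distance-decay exponent (> 0).
#' @param w0_bp length scale of the boundary attenuation `beta(w) = exp(-w/w0)`.
#' @param beta_fun optional override: function of NFR width -> attenuation in
#'   \[0, 1\].
#' @param n_pairs number of ligation pairs to draw.
#' @param n_fragments number of MNase fragments to draw.
#' @param frag_len_mean,frag_len_sd fragment length distribution (bp), Normal
#'   truncated to \[100, 260\] so the downstream 125–205 bp filter is exercised
#'   on both sides.
#' @param midpoint_sd sd (bp) of the fragment midpoint around the true dyad.
#' @param orientation_mix probabilities of the four ligation orientation
#'   classes (inward, outward, tandem_entry, tandem_exit); must sum to 1.
#' @param p_undigested fraction of additional sub-147 bp "undigested" pairs
#'   emitted to exercise the minimum-distance filter.
#' @param cut_sites optional coordinates of restriction cut sites.
#' @param f_cut fraction of molecules in which the cut sites are severed
#'   (incomplete digestion model); pairs in severed molecules are sampled
#'   within the resulting linear segments only.
#' @param seed integer master seed; ground truth uses `seed`, fragments
#'   `seed + 1`, pairs `seed + 2`.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(contigs,
                             tf_sites = NULL,
                             preset = remodeler_preset("ino80"),
                             alpha = 1,
                             w0_bp = 150,
                             beta_fun = NULL,
                             n_pairs = 1e6,
                             n_fragments = 1e6,
                             frag_len_mean = 160,
                             frag_len_sd = 25,
                             midpoint_sd = 5,
                             orientation_mix = c(inward = 0.25, outward = 0.25,
                                                 tandem_entry = 0.25,
                                                 tandem_exit = 0.25),
                             p_undigested = 0.05,
                             cut_sites = NULL,
                             f_cut = 0,
                             seed = 42L) {
  contigs <- check_contigs(contigs)
  if (!inherits(preset, "remodeler_preset")) stop("preset must be a remodeler_preset")
  if (alpha <= 0) stop("alpha must be > 0")
  if (length(orientation_mix) != 4L ||
      abs(sum(orientation_mix) - 1) > 1e-9) {
    stop("orientation_mix must be 4 probabilities summing to 1")
  }
  cls <- c("inward", "outward", "tandem_entry", "tandem_exit")
  if (is.null(names(orientation_mix))) {
    names(orientation_mix) <- cls
  } else {
    if (!setequal(names(orientation_mix), cls)) {
      stop("orientation_mix names must be ", paste(cls, collapse = ", "))
    }
    orientation_mix <- orientation_mix[cls]
  }
  if (f_cut < 0 || f_cut > 1) stop("f_cut must be in [0, 1]")
  if (!is.null(tf_sites)) {
    bad <- !(tf_sites$contig %in% contigs$name)
    if (any(bad)) stop("tf_sites on unknown contig: ",
                       paste(unique(tf_sites$contig[bad]), collapse = ", "))
    L <- contigs$length[match(tf_sites$contig, contigs$name)]
    if (any(tf_sites$pos < 0 | tf_sites$pos >= L)) {
      stop("tf_sites coordinates outside contig bounds")
    }
  }
  if (!is.null(cut_sites)) {
    if (any(cut_sites < 0 | cut_sites >= max(contigs$length))) {
      stop("cut site outside contig bounds")
    }
  }
  bfun <- if (is.null(beta_fun)) function(w) exp(-w / w0_bp) else beta_fun
  bval <- bfun(preset$nfr_bp)
  if (!is.finite(bval) || bval < 0 || bval > 1) {
    stop("boundary attenuation beta(w) must lie in [0, 1]")
  }
  structure(list(contigs = contigs, tf_sites = tf_sites, preset = preset,
                 alpha = alpha, w0_bp = w0_bp, beta_fun = bfun,
                 n_pairs = as.integer(n_pairs),
                 n_fragments = as.integer(n_fragments),
                 frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd,
                 midpoint_sd = midpoint_sd,
                 orientation_mix = orientation_mix,
                 p_undigested = p_undigested,
                 cut_sites = cut_sites, f_cut = f_cut,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Edge margin (bp) kept free of dyads on linear contigs, so junction
# coordinates (dyad +/- 80) and fragments stay on the contig.
.edge_margin <- 147L

# One array arm: m dyads from `base` at NRL steps with cumulative Gaussian
# step noise, so consecutive gaps are NRL +/- jitter (spacing noise, which
# accumulates with distance from the phasing site).
.arm <- function(base, m, nrl, sd, sign = 1) {
  if (m < 1L) return(numeric(0))
  base + sign * (seq_len(m) - 1L) * nrl + cumsum(rnorm(m, 0, sd))
}

# Lattice + jitter for one contig; returns sorted dyad coordinates.
.contig_dyads <- function(L, circular, sites, preset) {
  nrl <- preset$nrl
  half <- preset$nfr_bp / 2
  jit <- preset$spacing_sd_bp
  margin <- .edge_margin
  pos <- numeric(0)

  if (length(sites) == 0L) {
    if (circular) {
      phase <- if (preset$phased) 0 else runif(1, 0, L)
      m <- floor(L / nrl)
      pos <- .arm(phase, m, nrl, jit) %% L
    } else {
      start <- margin + if (preset$phased) 0 else runif(1, 0, nrl)
      m <- floor((L - margin - start) / nrl) + 1L
      pos <- .arm(start, m, nrl, jit)
    }
  } else {
    sites <- sort(sites)
    ns <- length(sites)
    # sizing checks: expanded NFRs must not overlap and each inter-NFR gap
    # must fit at least one phased nucleosome per side
    gaps <- if (circular) {
      (sites[c(seq_len(ns)[-1], 1L)] - sites) %% L
    } else {
      diff(sites)
    }
    if (length(gaps)) {
      too_close <- gaps < preset$nfr_bp
      if (any(too_close)) {
        stop("expanded NFRs overlap between sites at ",
             paste(sites[which(too_close)], collapse = ", "))
      }
      too_short <- gaps < preset$nfr_bp + 2 * 73 + 2
      if (any(too_short)) {
        stop("contig too short between sites at ",
             paste(sites[which(too_short)], collapse = ", "),
             ": need room for >= 2 nucleosomes between adjacent NFRs")
      }
    }
    if (!circular && (sites[1] - half - 73 < margin ||
                      sites[ns] + half + 73 > L - margin)) {
      stop("contig too short: outermost NFR within ", margin,
           " bp of a contig end")
    }
    if (preset$phased) {
      for (k in seq_len(ns)) {
        s <- sites[k]
        # downstream arm: up to the arc midpoint toward the next site
        lim_dn <- if (circular) {
          g <- (sites[if (k == ns) 1L else k + 1L] - s) %% L
          if (g == 0) g <- L
          g / 2
        } else {
          if (k == ns) (L - margin) - s else (sites[k + 1L] - s) / 2
        }
        base <- half + 73
        if (lim_dn - 74 >= base) {
          m <- floor((lim_dn - 74 - base) / nrl) + 1L
          pos <- c(pos, .arm(s + base, m, nrl, jit, sign = 1))
        }
        # upstream arm, mirrored
        lim_up <- if (circular) {
          g <- (s - sites[if (k == 1L) ns else k - 1L]) %% L
          if (g == 0) g <- L
          g / 2
        } else {
          if (k == 1L) s - margin else (s - sites[k - 1L]) / 2
        }
        if (lim_up - 74 >= base) {
          m <- floor((lim_up - 74 - base) / nrl) + 1L
          pos <- c(pos, .arm(s - base, m, nrl, jit, sign = -1))
        }
      }
    } else {
      # unphased: independent random-phase lattice per inter-NFR segment
      edges <- sort(c(sites - half, sites + half))
      starts <- c(if (!circular) margin, edges[seq(2, length(edges), by = 2)])
      ends <- c(edges[seq(1, length(edges), by = 2)], if (!circular) L - margin)
      if (circular) {
        starts <- edges[seq(2, length(edges), by = 2)]
        ends <- c(edges[seq(1, length(edges), by = 2)][-1L],
                  edges[1L] + L)
      }
      for (seg in seq_along(starts)) {
        a <- starts[seg] + 73
        b <- ends[seg] - 73
        if (b - a < nrl) next
        phase <- runif(1, 0, nrl)
        m <- floor((b - a - phase) / nrl) + 1L
        pos <- c(pos, .arm(a + phase, m, nrl, jit))
      }
      if (circular) pos <- pos %% L
    }
  }

  if (length(pos) == 0L) {
    stop("contig too short: no nucleosome fits (length ", L, " bp)")
  }
  if (circular) {
    pos <- pos %% L
  } else {
    pos <- pos[pos >= margin & pos <= L - margin]
  }
  # no dyad center inside a planted NFR
  if (length(sites)) {
    half <- preset$nfr_bp / 2
    inside <- rep(FALSE, length(pos))
    for (s in sites) {
      d <- if (circular) pmin((pos - s) %% L, (s - pos) %% L) else abs(pos - s)
      inside <- inside | d < half
    }
    pos <- pos[!inside]
  }
  sort(round(pos))
}

#' Build synthetic chromatin ground truth
#'
#' Plants an NFR of the preset's width centered on every TF site and grows
#' phased nucleosome arrays outward from each NFR: the first dyads sit at
#' `site +/- (nfr_bp/2 + 73)` and subsequent dyads follow at NRL steps with
#' Gaussian spacing noise per step (consecutive gaps are NRL +/- jitter, so
#' positional uncertainty accumulates away from the site, as array phasing
#' decays in real chromatin). Arrays from neighbouring sites meet at the
#' midpoint between them. With `phased = FALSE` each inter-NFR segment gets a
#' uniformly random lattice phase instead. Domain labels increment at every
#' NFR.
#'
#' Deterministic per `config$seed`: regenerating with the same config is
#' bit-identical.
#'
#' @param config a [generator_config()].
#' @return object of class `ground_truth` with elements `contigs`, `dyads`
#'   (named list of sorted coordinates), `nfr` (named list of interval
#'   data.frames), `domain_ids`, `preset`, `config`.
#' @export
make_ground_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    dyads <- list(); nfr <- list(); dom <- list()
    for (ci in seq_len(nrow(config$contigs))) {
      cn <- config$contigs$name[ci]
      L <- config$contigs$length[ci]
      circ <- isTRUE(config$contigs$circular[ci])
      sites <- if (is.null(config$tf_sites)) numeric(0) else
        sort(config$tf_sites$pos[config$tf_sites$contig == cn])
      half <- config$preset$nfr_bp / 2
      d <- .contig_dyads(L, circ, sites, config$preset)
      dyads[[cn]] <- d
      nfr[[cn]] <- if (length(sites) && config$preset$nfr_bp > 0) {
        data.frame(site = sites, start = sites - half, end = sites + half,
                   center = sites, width = config$preset$nfr_bp)
      } else {
        data.frame(site = numeric(0), start = numeric(0), end = numeric(0),
                   center = numeric(0), width = numeric(0))
      }
      dom[[cn]] <- findInterval(d, sort(sites))
    }
    structure(list(contigs = config$contigs, dyads = dyads, nfr = nfr,
                   domain_ids = dom, preset = config$preset, config = config),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d contig(s), %d dyads, %d NFR(s), preset '%s'\n",
              nrow(x$contigs), sum(lengths(x$dyads)),
              sum(vapply(x$nfr, nrow, 1L)), x$preset$name))
  invisible(x)
}

#' Simulate MNase-seq fragments from planted dyads
#'
#' Each fragment midpoint is a uniformly chosen planted dyad plus
#' `Normal(0, midpoint_sd)` trimming noise; fragment lengths are Normal,
#' truncated to \[100, 260\] bp. Fragments extending beyond a contig end are
#' dropped (counted in attribute `n_dropped`). Deterministic per seed.
#'
#' @param gt a [make_ground_truth()] result.
#' @param n_fragments,frag_len_mean,frag_len_sd,midpoint_sd see
#'   [generator_config()]; default from `gt$config`.
#' @param seed RNG seed (default `gt$config$seed + 1`).
#' @return data.frame(contig, start, end), 0-based half-open.
#' @export
simulate_mnase_fragments <- function(gt,
                                     n_fragments = gt$config$n_fragments,
                                     frag_len_mean = gt$config$frag_len_mean,
                                     frag_len_sd = gt$config$frag_len_sd,
                                     midpoint_sd = gt$config$midpoint_sd,
                                     seed = gt$config$seed + 1L) {
  stopifnot(inherits(gt, "ground_truth"))
  if (n_fragments <= 0) stop("n_fragments must be > 0")
  if (sum(lengths(gt$dyads)) == 0) stop("ground truth has no dyads")
  withr::with_seed(as.integer(seed), {
    ncontig <- lengths(gt$dyads)
    cidx <- sample.int(length(ncontig), n_fragments, replace = TRUE,
                       prob = ncontig)
    out <- vector("list", length(ncontig))
    for (ci in seq_along(ncontig)) {
      n <- sum(cidx == ci)
      if (n == 0L) next
      cn <- names(gt$dyads)[ci]
      L <- gt$contigs$length[match(cn, gt$contigs$name)]
      d <- gt$dyads[[ci]][sample.int(ncontig[ci], n, replace = TRUE)]
      mid <- d + if (midpoint_sd > 0) rnorm(n, 0, midpoint_sd) else 0
      len <- round(rnorm_trunc(n, frag_len_mean, frag_len_sd, 100, 260))
      start <- round(mid - len / 2)
      end <- start + len
      keep <- start >= 0 & end <= L
      out[[ci]] <- data.frame(contig = cn, start = as.integer(start[keep]),
                              end = as.integer(end[keep]))
    }
    res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
    rownames(res) <- NULL
    attr(res, "n_dropped") <- n_fragments - nrow(res)
    res
  })
}

#' Cut-site geometry: severed linear segments of a contig
#'
#' Models restriction linearization: each cut site severs the molecule, so
#' ligation pairs can only form within the resulting linear segments and the
#' effective distance is the linear path distance within a segment. On a
#' circular contig the first cut opens the circle.
#'
#' @param gt ground truth.
#' @param cut_sites coordinates of cut sites on `contig`.
#' @param contig contig name (default: first).
#' @return list with per-dyad `segment` id, linearized `coord`, and the
#'   segment `boundaries` in linearized coordinates.
#' @export
apply_cut_sites <- function(gt, cut_sites, contig = names(gt$dyads)[1]) {
  L <- gt$contigs$length[match(contig, gt$contigs$name)]
  if (any(cut_sites < 0 | cut_sites >= L)) {
    stop("cut site outside contig ", contig, " (length ", L, ")")
  }
  circ <- isTRUE(gt$contigs$circular[match(contig, gt$contigs$name)])
  d <- gt$dyads[[contig]]
  cuts <- sort(cut_sites)
  if (circ) {
    origin <- cuts[1]
    coord <- (d - origin) %% L
    boundaries <- sort((cuts[-1] - origin) %% L)
  } else {
    coord <- d
    boundaries <- cuts
  }
  list(segment = findInterval(coord, boundaries), coord = coord,
       boundaries = boundaries, origin = if (circ) cuts[1] else NA_real_,
       circular = circ, length = L)
}

# NFR centers strictly between two linear coordinates a < b (counts).
.nfr_between <- function(a, b, centers) {
  if (length(centers) == 0L) return(rep(0L, length(a)))
  findInterval(b - 0.5, centers) - findInterval(a + 0.5, centers)
}

#' Simulate chimeric ligation pairs
#'
#' Nucleosome pairs (i, j) are sampled with probability proportional to
#' `s^(-alpha)` (s = dyad separation; shortest arc on circular contigs),
#' attenuated by `beta(w)` for every planted NFR strictly between them. With
#' cut sites, a fraction `f_cut` of molecules is severed at the cuts
#' ([apply_cut_sites()] geometry); the rest keep the original topology. An
#' orientation class is drawn per pair from `orientation_mix` and the two
#' junction coordinates are emitted at `dyad -/+ 80` with read directions
#' consistent with the class, so the downstream 80 bp dyad shift recovers the
#' planted dyads exactly. A fraction `p_undigested` of sub-147 bp pairs (both
#' sides on one dyad) is added to exercise the minimum-distance filter.
#'
#' @param gt ground truth.
#' @param config generator config (default `gt$config`).
#' @param n_pairs number of (digested) pairs; default from config.
#' @param seed RNG seed (default `gt$config$seed + 2`).
#' @return data.frame of unshifted, unclassified pairs (columns contig1, pos1,
#'   dir1, contig2, pos2, dir2, orientation = "unset"), attributes `assembly`,
#'   `shifted = FALSE` and `truth` (data.frame of the planted dyad pairs).
#' @export
simulate_ligation_pairs <- function(gt, config = gt$config,
                                    n_pairs = config$n_pairs,
                                    seed = config$seed + 2L) {
  stopifnot(inherits(gt, "ground_truth"))
  if (config$alpha <= 0) stop("alpha must be > 0")
  if (sum(lengths(gt$dyads) >= 2) == 0) stop("need >= 2 dyads to ligate")
  withr::with_seed(as.integer(seed), {
    per <- lapply(names(gt$dyads), function(cn) {
      .contig_pair_weights(gt, config, cn)
    })
    names(per) <- names(gt$dyads)
    mass <- vapply(per, function(p) p$mass, 1)
    if (sum(mass) <= 0) {
      alloc <- rep(0L, length(per))
    } else {
      alloc <- as.integer(stats::rmultinom(1, n_pairs, mass))
    }
    res <- vector("list", length(per))
    truth <- vector("list", length(per))
    for (ci in seq_along(per)) {
      n <- alloc[ci]
      if (n == 0L) next
      p <- per[[ci]]
      n_cut <- if (config$f_cut > 0 && !is.null(config$cut_sites)) {
        rbinom(1, n, config$f_cut)
      } else 0L
      idx <- integer(0)
      if (n - n_cut > 0) {
        if (sum(p$w) <= 0) stop("all intact pair weights are zero on contig ",
                                names(per)[ci])
        idx <- sample.int(length(p$w), n - n_cut, replace = TRUE, prob = p$w)
      }
      if (n_cut > 0) {
        if (sum(p$w_cut) <= 0) {
          stop("all cut-geometry pair weights are zero on contig ", names(per)[ci])
        }
        idx <- c(idx, sample.int(length(p$w_cut), n_cut, replace = TRUE,
                                 prob = p$w_cut))
      }
      d1 <- p$D[p$i[idx]]
      d2 <- p$D[p$j[idx]]
      em <- .emit_pairs(names(per)[ci], d1, d2, config$orientation_mix,
                        p$L, p$circular)
      res[[ci]] <- em
      truth[[ci]] <- data.frame(contig = names(per)[ci], dyad1 = d1, dyad2 = d2,
                                undigested = FALSE)
    }
    # undigested sub-147 bp pairs: both sides at one dyad
    n_und <- round(config$p_undigested * n_pairs)
    if (n_und > 0) {
      ncontig <- lengths(gt$dyads)
      cidx <- sample.int(length(ncontig), n_und, replace = TRUE, prob = ncontig)
      und <- lapply(seq_along(ncontig), function(ci) {
        n <- sum(cidx == ci)
        if (n == 0L) return(NULL)
        cn <- names(gt$dyads)[ci]
        L <- gt$contigs$length[match(cn, gt$contigs$name)]
        circ <- isTRUE(gt$contigs$circular[match(cn, gt$contigs$name)])
        d <- gt$dyads[[ci]][sample.int(ncontig[ci], n, replace = TRUE)]
        em <- .emit_pairs(cn, d, d, c(inward = 1, outward = 0,
                                      tandem_entry = 0, tandem_exit = 0),
                          L, circ)
        attr(em, "truth") <- data.frame(contig = cn, dyad1 = d, dyad2 = d,
                                        undigested = TRUE)
        em
      })
      und <- und[!vapply(und, is.null, TRUE)]
      res <- c(res, und)
      truth <- c(truth, lapply(und, attr, "truth"))
    }
    keep <- !vapply(res, is.null, TRUE)
    pairs <- do.call(rbind, res[keep])
    rownames(pairs) <- NULL
    attr(pairs, "assembly") <- "synthetic"
    attr(pairs, "shifted") <- FALSE
    tr <- do.call(rbind, truth[!vapply(truth, is.null, TRUE)])
    rownames(tr) <- NULL
    attr(pairs, "truth") <- tr
    pairs
  })
}

# Enumerate pair weights for one contig, for intact and (optionally) cut
# geometry. Returns dyads D, index vectors i < j, weights, circular flag.
.contig_pair_weights <- function(gt, config, cn) {
  D <- gt$dyads[[cn]]
  L <- gt$contigs$length[match(cn, gt$contigs$name)]
  circ <- isTRUE(gt$contigs$circular[match(cn, gt$contigs$name)])
  n <- length(D)
  if (n < 2L) {
    return(list(D = D, i = integer(0), j = integer(0), w = numeric(0),
                w_cut = numeric(0), mass = 0, L = L, circular = circ))
  }
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  s_lin <- D[j] - D[i]
  centers <- sort(gt$nfr[[cn]]$center)
  inner <- .nfr_between(D[i], D[j], centers)
  bw <- config$beta_fun(gt$preset$nfr_bp)
  if (!is.finite(bw) || bw < 0 || bw > 1) stop("beta(w) outside [0, 1]")
  if (circ) {
    s_out <- L - s_lin
    short_inner <- s_lin <= s_out
    s <- ifelse(short_inner, s_lin, s_out)
    natt <- ifelse(short_inner, inner, length(centers) - inner)
  } else {
    s <- s_lin
    natt <- inner
  }
  w <- s^(-config$alpha) * bw^natt
  w_cut <- numeric(0)
  if (!is.null(config$cut_sites) && config$f_cut > 0) {
    geo <- apply_cut_sites(gt, config$cut_sites, cn)
    same <- geo$segment[i] == geo$segment[j]
    s_c <- abs(geo$coord[j] - geo$coord[i])
    cc <- if (circ) sort((centers - geo$origin) %% L) else centers
    a <- pmin(geo$coord[i], geo$coord[j])
    b <- pmax(geo$coord[i], geo$coord[j])
    natt_c <- .nfr_between(a, b, cc)
    w_cut <- ifelse(same & s_c > 0, s_c^(-config$alpha) * bw^natt_c, 0)
  }
  has_cut <- length(w_cut) > 0
  mass <- if (has_cut) {
    sum(w) * (1 - config$f_cut) + sum(w_cut) * config$f_cut
  } else {
    sum(w)
  }
  list(D = D, i = i, j = j, w = w, w_cut = w_cut, mass = mass,
       L = L, circular = circ)
}

# Emit junction coordinates and read directions for sampled dyad pairs.
.emit_pairs <- function(cn, d1, d2, mix, L, circular) {
  classes <- c("inward", "outward", "tandem_entry", "tandem_exit")
  cls <- classes[sample.int(4L, length(d1), replace = TRUE, prob = mix)]
  dir1 <- c(inward = "downstream", outward = "upstream",
            tandem_entry = "downstream", tandem_exit = "upstream")[cls]
  dir2 <- c(inward = "upstream", outward = "downstream",
            tandem_entry = "downstream", tandem_exit = "upstream")[cls]
  # junction sits 80 bp outside the dyad on the side the read enters from,
  # so the downstream-side shift (+80) / upstream-side shift (-80) inverts it
  pos1 <- d1 + ifelse(dir1 == "downstream", -80, 80)
  pos2 <- d2 + ifelse(dir2 == "downstream", -80, 80)
  if (circular) {
    pos1 <- pos1 %% L
    pos2 <- pos2 %% L
  }
  data.frame(contig1 = cn, pos1 = as.integer(pos1), dir1 = unname(dir1),
             contig2 = cn, pos2 = as.integer(pos2), dir2 = unname(dir2),
             orientation = "unset", stringsAsFactors = FALSE)
}
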