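#' Contact matrices at bp or nucleosome resolution
#'
#' A `contact_matrix` holds a sparse upper-triangular count matrix over a bin
#' table that tiles the declared contigs (bp mode, `bin = floor(pos /
#' resolution)`) or lists nucleosome dyads (nucleosome mode). Counts are raw
#' pair counts; no balancing or normalization is applied (log10(1 + x) is used
#' only for display and correlation).
#'
#' @name contact_matrix
NULL

.bin_table <- function(contigs, resolution_bp) {
  contigs <- check_contigs(contigs)
  nb <- ceiling(contigs$length / resolution_bp)
  bins <- do.call(rbind, lapply(seq_len(nrow(contigs)), function(ci) {
    s <- seq_len(nb[ci]) - 1L
    data.frame(contig = contigs$name[ci],
               start = s * resolution_bp,
               end = pmin((s + 1L) * resolution_bp, contigs$length[ci]))
  }))
  rownames(bins) <- NULL
  attr(bins, "offset") <- c(0L, cumsum(nb))[seq_len(nrow(contigs))]
  bins
}

.new_contact_matrix <- function(counts, bins, resolution, contigs,
                                extra = list()) {
  structure(c(list(counts = counts, bins = bins, resolution = resolution,
                   contigs = contigs), extra),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d bins (%s), total count %g\n",
              nrow(x$bins),
              if (identical(x$resolution, "nucleosome")) "nucleosome"
              else paste0(x$resolution, " bp"),
              sum(x$counts)))
  invisible(x)
}

#' Aggregate pairs into a binned contact matrix
#'
#' Each pair increments exactly one upper-triangular cell, with
#' `bin = floor(pos / resolution_bp)` per side; the matrix total equals the
#' pair count (count conservation).
#'
#' @param pairs filtered, dyad-shifted pairs.
#' @param resolution_bp bin size in bp (the study uses 20, 40 and 80).
#' @param contigs contig table covering all pairs.
#' @return a `contact_matrix`.
#' @export
bin_pairs <- function(pairs, resolution_bp, contigs) {
  contigs <- check_contigs(contigs)
  pairs <- .check_pairs(pairs)
  bins <- .bin_table(contigs, resolution_bp)
  off <- attr(bins, "offset")
  n <- nrow(bins)
  ci1 <- match(pairs$contig1, contigs$name)
  ci2 <- match(pairs$contig2, contigs$name)
  if (anyNA(ci1) || anyNA(ci2)) {
    bad <- unique(c(pairs$contig1[is.na(ci1)], pairs$contig2[is.na(ci2)]))
    stop("pairs on undeclared contig(s): ", paste(bad, collapse = ", "))
  }
  if (any(pairs$pos1 >= contigs$length[ci1]) ||
      any(pairs$pos2 >= contigs$length[ci2])) {
    stop("pair coordinates beyond declared contig length")
  }
  b1 <- off[ci1] + pairs$pos1 %/% resolution_bp + 1L
  b2 <- off[ci2] + pairs$pos2 %/% resolution_bp + 1L
  i <- pmin(b1, b2)
  j <- pmax(b1, b2)
  counts <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  .new_contact_matrix(counts, bins, as.integer(resolution_bp), contigs)
}

#' Aggregate pairs onto nucleosome loci
#'
#' Assigns each pair end to the nearest dyad in `loci`; ends equidistant
#' between two dyads go to the leftmost (documented tie-break), and ends
#' farther than `assignment_max_bp` from any dyad are discarded and counted
#' (attribute `n_unassigned`).
#'
#' @param pairs filtered, dyad-shifted pairs.
#' @param loci named list (per contig) of sorted, unique dyad coordinates, or
#'   a data.frame with columns contig, pos.
#' @param contigs contig table.
#' @param assignment_max_bp maximum end-to-dyad distance, default 100.
#' @return a `contact_matrix` with `resolution = "nucleosome"`.
#' @export
bin_to_nucleosomes <- function(pairs, loci, contigs, assignment_max_bp = 100) {
  contigs <- check_contigs(contigs)
  pairs <- .check_pairs(pairs)
  if (is.data.frame(loci)) {
    loci <- split(loci$pos, loci$contig)
  }
  loci <- lapply(loci, function(d) sort(unique(d)))
  if (sum(lengths(loci)) == 0) stop("empty nucleosome loci")
  nl <- lengths(loci)
  off <- c(0L, cumsum(nl))[seq_along(loci)]
  names(off) <- names(loci)
  assign_end <- function(contig, pos) {
    idx <- rep(NA_integer_, length(pos))
    for (cn in unique(contig)) {
      d <- loci[[cn]]
      sel <- contig == cn
      if (is.null(d)) next
      p <- pos[sel]
      if (length(d) == 1L) {
        k <- rep(1L, length(p))
      } else {
        mids <- (d[-length(d)] + d[-1L]) / 2
        # pos exactly on a midpoint goes to the left dyad
        k <- findInterval(p - 0.5, mids) + 1L
      }
      ok <- abs(p - d[k]) <= assignment_max_bp
      idx[sel] <- ifelse(ok, off[cn] + k, NA_integer_)
    }
    idx
  }
  a1 <- assign_end(pairs$contig1, pairs$pos1)
  a2 <- assign_end(pairs$contig2, pairs$pos2)
  ok <- !is.na(a1) & !is.na(a2)
  n_unassigned <- sum(!ok)
  i <- pmin(a1[ok], a2[ok])
  j <- pmax(a1[ok], a2[ok])
  n <- sum(nl)
  counts <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  bins <- do.call(rbind, lapply(names(loci), function(cn) {
    data.frame(contig = cn, start = loci[[cn]], end = loci[[cn]] + 1L)
  }))
  rownames(bins) <- NULL
  m <- .new_contact_matrix(counts, bins, "nucleosome", contigs,
                           extra = list(loci = loci))
  attr(m, "n_unassigned") <- n_unassigned
  m
}

# Dense symmetric matrix for the bins of one contig.
.dense_contig <- function(mat, contig) {
  rows <- which(mat$bins$contig == contig)
  u <- as.matrix(mat$counts[rows, rows, drop = FALSE])
  full <- u + t(u)
  diag(full) <- diag(u)
  full
}

#' Pile-up (meta-matrix) around anchors
#'
#' Extracts a square contact-map snippet centered on each anchor's bin and
#' averages the snippets element-wise. Anchors closer than `window_bp / 2` to
#' a contig end are skipped and counted. Pile-up is linear: the pile-up over a
#' union of anchor sets equals the count-weighted mean of the individual
#' pile-ups.
#'
#' @param mat bp-resolution `contact_matrix`.
#' @param anchors anchor set.
#' @param window_bp total window, default 3000 (the study extracts 20 bp bins
#'   in a 3,000 bp window around TF binding sites).
#' @param orient_by_strand if TRUE, snippets of "-"-strand anchors are
#'   reversed along both axes before averaging (off by default).
#' @return object of class `pileup`: list(matrix, n_used, n_skipped,
#'   window_bp, resolution_bp).
#' @export
pileup <- function(mat, anchors, window_bp = 3000, orient_by_strand = FALSE) {
  res <- mat$resolution
  if (!is.numeric(res)) stop("pileup needs a bp-binned matrix")
  if (window_bp %% (2 * res) != 0) {
    stop("matrix resolution must divide window_bp / 2")
  }
  half <- window_bp %/% (2L * res)
  dense <- list()
  n_used <- 0L; n_skip <- 0L
  acc <- matrix(0, 2L * half, 2L * half)
  for (k in seq_len(nrow(anchors))) {
    cn <- anchors$contig[k]
    rows <- which(mat$bins$contig == cn)
    if (!length(rows)) { n_skip <- n_skip + 1L; next }
    b <- anchors$pos[k] %/% res + 1L     # bin index within contig
    lo <- b - half; hi <- b + half - 1L
    if (lo < 1L || hi > length(rows)) { n_skip <- n_skip + 1L; next }
    if (is.null(dense[[cn]])) dense[[cn]] <- .dense_contig(mat, cn)
    snip <- dense[[cn]][lo:hi, lo:hi]
    if (orient_by_strand && identical(anchors$strand[k], "-")) {
      snip <- snip[rev(seq_len(nrow(snip))), rev(seq_len(ncol(snip)))]
    }
    acc <- acc + snip
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no usable anchors for pileup")
  structure(list(matrix = acc / n_used, n_used = n_used, n_skipped = n_skip,
                 window_bp = window_bp, resolution_bp = res),
            class = "pileup")
}

#' Distance-decay curve per orientation class
#'
#' Histograms same-contig pair distances in log-spaced bins (default 20 bins
#' per decade) from `min_distance` bp upward, normalized to sum 1 per
#' orientation class, and reports log10 frequencies. A class with zero pairs
#' yields NaN frequencies with a warning.
#'
#' @param pairs classified, filtered pairs.
#' @param bins_per_decade log-bin density, default 20.
#' @param min_distance left edge of the first bin, default 147.
#' @return data.frame(class, lo, hi, mid, count, freq, log10_freq) of class
#'   `decay_curve`.
#' @export
decay_curve <- function(pairs, bins_per_decade = 20, min_distance = 147) {
  pairs <- .check_pairs(pairs)
  same <- pairs$contig1 == pairs$contig2
  d <- abs(pairs$pos2 - pairs$pos1)[same]
  cls <- pairs$orientation[same]
  keep <- d >= min_distance
  d <- d[keep]; cls <- cls[keep]
  if (!length(d)) stop("no same-contig pairs at or beyond min_distance")
  n_dec <- log10(max(d) / min_distance)
  n_bins <- max(1L, ceiling(bins_per_decade * n_dec))
  edges <- 10^seq(log10(min_distance), log10(max(d) + 1), length.out = n_bins + 1L)
  classes <- setdiff(.orientation_levels, "unset")
  out <- list()
  for (cl in classes) {
    dc <- d[cls == cl]
    cnt <- if (length(dc)) {
      tabulate(findInterval(dc, edges, rightmost.closed = TRUE), nbins = n_bins)
    } else {
      warning("orientation class '", cl, "' has zero pairs")
      rep(NA_real_, n_bins)
    }
    freq <- cnt / sum(cnt)
    out[[cl]] <- data.frame(class = cl,
                            lo = edges[-length(edges)], hi = edges[-1L],
                            mid = sqrt(edges[-length(edges)] * edges[-1L]),
                            count = cnt, freq = freq,
                            log10_freq = suppressWarnings(log10(freq)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("decay_curve", class(res))
  attr(res, "edges") <- edges
  res
}

#' Fit the power-law slope of a decay curve
#'
#' Linear fit of `log10(count / bin width)` against `log10(distance)` over a
#' distance range, for one orientation class. For contacts sampled with
#' probability proportional to `s^(-alpha)` the slope estimates `-alpha`.
#'
#' @param curve a [decay_curve()] result.
#' @param class orientation class to fit.
#' @param s_range distance range (bp) used for the fit. The lower edge should
#'   sit well above the nucleosome repeat length: below ~10 NRL the discrete
#'   dyad lattice aliases the log bins.
#' @param n_loci,nrl_bp optional finite-array correction: with `n_loci` dyads
#'   at repeat length `nrl_bp`, only about `n_loci - s/nrl_bp` pairs exist at
#'   separation s, so counts are divided by that availability before the fit
#'   (the per-diagonal normalization of contact-probability curves).
#' @return slope (numeric scalar).
#' @export
decay_slope <- function(curve, class = "inward", s_range = c(2000, 20000),
                        n_loci = NULL, nrl_bp = NULL) {
  cc <- curve[curve$class == class & curve$count > 0 &
                curve$mid >= s_range[1] & curve$mid <= s_range[2], ]
  if (nrow(cc) < 3L) stop("too few populated bins in s_range to fit")
  avail <- if (!is.null(n_loci) && !is.null(nrl_bp)) {
    pmax(n_loci - round(cc$mid / nrl_bp), 1)
  } else {
    rep(1, nrow(cc))
  }
  fit <- stats::lm(log10(count / ((hi - lo) * avail)) ~ log10(mid), data = cc)
  unname(stats::coef(fit)[2])
}

#' Pearson correlation of two contact matrices
#'
#' Correlation of `log10(1 + count)` over all cells with bin separation at
#' most `max_distance_bp` (same contig, diagonal included), e.g. for
#' replicate agreement.
#'
#' @param m1,m2 contact matrices with identical bin tables.
#' @param max_distance_bp maximum bin-start separation, default 5000.
#' @return Pearson r.
#' @export
matrix_correlation <- function(m1, m2, max_distance_bp = 5000) {
  if (!isTRUE(all.equal(m1$bins, m2$bins))) {
    stop("contact matrices have mismatched bin tables")
  }
  idx_i <- integer(0); idx_j <- integer(0)
  for (cn in unique(m1$bins$contig)) {
    rows <- which(m1$bins$contig == cn)
    starts <- m1$bins$start[rows]
    nb <- length(rows)
    for (w in 0:(nb - 1L)) {
      i <- seq_len(nb - w)
      sep <- starts[i + w] - starts[i]
      ok <- sep <= max_distance_bp
      if (!any(ok)) break
      idx_i <- c(idx_i, rows[i[ok]])
      idx_j <- c(idx_j, rows[i[ok] + w])
    }
  }
  x1 <- log10(1 + m1$counts[cbind(idx_i, idx_j)])
  x2 <- log10(1 + m2$counts[cbind(idx_i, idx_j)])
  stats::cor(x1, x2)
}
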