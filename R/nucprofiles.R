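#' Nucleosome dyad coverage from MNase-seq fragments
#'
#' Keeps fragments of 125–205 bp (inclusive), reduces each to a 50 bp dyad
#' footprint centered on the fragment midpoint, sums per-base coverage and
#' smooths with a centered 20 bp rolling mean (edges truncated). Away from
#' contig ends the total track mass equals `footprint * kept fragments`.
#'
#' @param fragments data.frame(contig, start, end), 0-based half-open.
#' @param contigs contig table.
#' @param min_len,max_len kept fragment-length range, default 125–205.
#' @param footprint dyad footprint width in bp, default 50.
#' @param smooth rolling-mean window in bp, default 20 (0 disables).
#' @return object of class `signal_track`: named list of per-contig numeric
#'   vectors (1 bp step; index i is coordinate i - 1), with attributes
#'   `n_kept`, `n_excluded` and the parameters.
#' @export
dyad_coverage <- function(fragments, contigs, min_len = 125, max_len = 205,
                          footprint = 50, smooth = 20) {
  contigs <- check_contigs(contigs)
  len <- fragments$end - fragments$start
  keep <- len >= min_len & len <= max_len
  kept <- fragments[keep, , drop = FALSE]
  track <- lapply(seq_len(nrow(contigs)), function(ci) {
    cn <- contigs$name[ci]
    L <- contigs$length[ci]
    f <- kept[kept$contig == cn, , drop = FALSE]
    if (nrow(f) == 0L) return(numeric(L))
    mid <- (f$start + f$end) %/% 2L
    a <- pmax(mid - footprint %/% 2L, 0L)        # [a, b) footprint
    b <- pmin(a + footprint, L)
    cov <- IRanges::coverage(IRanges::IRanges(start = a + 1L, end = b),
                             width = L)
    x <- as.numeric(cov)
    if (smooth > 1) x <- rolling_mean(x, as.integer(smooth))
    x
  })
  names(track) <- contigs$name
  structure(track, class = "signal_track",
            n_kept = nrow(kept), n_excluded = sum(!keep),
            footprint = footprint, smooth = smooth,
            contigs = contigs)
}

#' Composite signal profile around anchors
#'
#' Extracts a window of `window_bp` (odd) centered on each interior anchor,
#' flips it for "-"-strand anchors, optionally normalizes each window by its
#' own mean, and averages across anchors. Anchors at contig edges or with
#' zero-mean windows are skipped and counted.
#'
#' @param track a [dyad_coverage()] result (or compatible named list).
#' @param anchors anchor set.
#' @param window_bp odd total window width, default 2001 (3,001 for TF sites
#'   in the study's convention).
#' @param normalize_per_window divide each window by its mean (default TRUE).
#' @return object of class `composite_profile`: list(offset, signal,
#'   n_anchors, n_skipped, window_bp).
#' @export
composite_profile <- function(track, anchors, window_bp = 2001,
                              normalize_per_window = TRUE) {
  if (window_bp %% 2 == 0) stop("window_bp must be odd (symmetric window)")
  W <- (window_bp - 1L) %/% 2L
  acc <- NULL
  used <- 0L; skipped <- 0L
  for (k in seq_len(nrow(anchors))) {
    x <- track[[anchors$contig[k]]]
    if (is.null(x)) { skipped <- skipped + 1L; next }
    p <- anchors$pos[k]
    if (p - W < 0L || p + W > length(x) - 1L) { skipped <- skipped + 1L; next }
    v <- x[(p - W):(p + W) + 1L]
    if (identical(anchors$strand[k], "-")) v <- rev(v)
    if (normalize_per_window) {
      m <- mean(v)
      if (m == 0) { skipped <- skipped + 1L; next }
      v <- v / m
    }
    acc <- if (is.null(acc)) v else acc + v
    used <- used + 1L
  }
  if (used == 0L) stop("all anchors skipped (edges or zero-mean windows)")
  structure(list(offset = (-W):W, signal = acc / used, n_anchors = used,
                 n_skipped = skipped, window_bp = window_bp),
            class = "composite_profile")
}

#' Call peaks of a composite nucleosome profile
#'
#' Local maxima outside an exclusion zone around the anchor (which masks the
#' TF footprint itself), with flat-topped maxima reported at their plateau
#' center (the dyad footprint plus rolling smooth makes ideal peaks
#' trapezoidal), accepted greedily in order of decreasing height with
#' a minimum peak separation, then reported sorted by offset and split into
#' upstream (negative offset) and downstream sides. A side with no peak is
#' flagged in attribute `missing_side`.
#'
#' @param profile a [composite_profile()] result.
#' @param min_separation minimum distance between accepted peaks (bp),
#'   default 120.
#' @param exclusion_halfwidth half-width of the anchor exclusion zone (bp),
#'   default 50.
#' @return data.frame(offset, height, side) sorted by offset.
#' @export
call_profile_peaks <- function(profile, min_separation = 120,
                               exclusion_halfwidth = 50) {
  y <- profile$signal
  off <- profile$offset
  if (any(!is.finite(y))) stop("profile contains non-finite values")
  n <- length(y)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L
      # flat-topped peaks (the footprint/smoothing trapezoid) report their
      # plateau center, keeping symmetric peaks centered on the dyad
      if (j < n && y[j + 1L] < y[i]) cand <- c(cand, (i + j) %/% 2L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  cand <- cand[abs(off[cand]) > exclusion_halfwidth]
  sel <- integer(0)
  for (k in cand[order(-y[cand])]) {
    if (!length(sel) || all(abs(off[sel] - off[k]) >= min_separation)) {
      sel <- c(sel, k)
    }
  }
  sel <- sort(sel)
  res <- data.frame(offset = off[sel], height = y[sel],
                    side = ifelse(off[sel] < 0, "upstream", "downstream"))
  missing <- setdiff(c("upstream", "downstream"), res$side)
  if (length(missing)) {
    message("no peaks called on side: ", paste(missing, collapse = ", "))
  }
  attr(res, "missing_side") <- missing
  res
}

#' Linker-length, border-to-TF and NFR-width metrics from profile peaks
#'
#' Per side of the anchor: the nucleosome repeat length is the distance from
#' peak to next neighbouring peak, and 147 bp is subtracted to give the linker
#' length (first three intervals); the border-to-TF distance is the first
#' peak's distance to the alignment point minus 73 bp; the NFR width is the
#' sum of the two border-to-TF distances, so the TF footprint lies inside the
#' NFR. Negative linkers or borders (overlapping or ill-phased arrays) are
#' reported with a warning, not clamped.
#'
#' @param peaks a [call_profile_peaks()] result.
#' @return object of class `nucleosome_metrics`: per-side first-peak offsets,
#'   NRLs and linkers (up to three), border-to-TF distances, `nfr_width` and
#'   `linker_mean`.
#' @export
nucleosome_metrics <- function(peaks) {
  side_metrics <- function(side) {
    p <- peaks[peaks$side == side, ]
    if (nrow(p) == 0L) {
      return(list(first = NA_real_, nrl = numeric(0), linker = numeric(0),
                  border = NA_real_))
    }
    d <- sort(abs(p$offset))          # distance from anchor, nearest first
    nrl <- head(diff(d), 3L)
    list(first = d[1], nrl = nrl, linker = nrl - 147, border = d[1] - 73)
  }
  up <- side_metrics("upstream")
  dn <- side_metrics("downstream")
  linkers <- c(up$linker, dn$linker)
  borders <- c(up = up$border, dn = dn$border)
  if (any(linkers < 0, na.rm = TRUE) || any(borders < 0, na.rm = TRUE)) {
    warning("negative linker or border distance: overlapping or ill-phased arrays")
  }
  structure(list(upstream = up, downstream = dn,
                 nfr_width = unname(up$border + dn$border),
                 linker_mean = if (length(linkers)) mean(linkers) else NA_real_),
            class = "nucleosome_metrics")
}

#' @export
print.nucleosome_metrics <- function(x, ...) {
  cat(sprintf("<nucleosome_metrics> mean linker %.1f bp, NFR width %.1f bp\n",
              x$linker_mean, x$nfr_width))
  cat("  upstream:  first peak", x$upstream$first, "bp; linkers",
      paste(round(x$upstream$linker, 1), collapse = ", "), "\n")
  cat("  downstream: first peak", x$downstream$first, "bp; linkers",
      paste(round(x$downstream$linker, 1), collapse = ", "), "\n")
  invisible(x)
}

#' Order anchors by upstream signal strength
#'
#' For each oriented anchor, averages the signal in a window of `width` bp
#' whose near edge sits `|offset|` bp upstream of the anchor (default: a 180
#' bp window 160 bp upstream), then returns the anchors in decreasing order
#' (stable for ties) with a top-20% / bottom-80% split label.
#'
#' @param track a [dyad_coverage()]-style signal track.
#' @param anchors oriented anchor set (strand "+" or "-" required).
#' @param offset signed distance from anchor to the window's near edge,
#'   default -160 (upstream).
#' @param width window width in bp, default 180.
#' @param top_fraction fraction labelled "bound", default 0.2.
#' @return anchors in decreasing window-mean order with columns `window_mean`
#'   and `group` ("bound" for the top fraction, else "unbound").
#' @export
sort_windows_by_signal <- function(track, anchors, offset = -160, width = 180,
                                   top_fraction = 0.2) {
  if (is.null(anchors$strand) || any(!anchors$strand %in% c("+", "-"))) {
    stop("anchors must be oriented (strand '+' or '-')")
  }
  means <- vapply(seq_len(nrow(anchors)), function(k) {
    x <- track[[anchors$contig[k]]]
    p <- anchors$pos[k]
    if (anchors$strand[k] == "+") {
      a <- p + offset - width      # [a, a + width) upstream on + strand
    } else {
      a <- p - offset              # mirrored for - strand
    }
    b <- a + width
    if (a < 0L || b > length(x)) return(NA_real_)
    mean(x[(a + 1L):b])
  }, 1)
  ord <- order(-means, na.last = TRUE)
  out <- anchors[ord, , drop = FALSE]
  out$window_mean <- means[ord]
  n_top <- floor(top_fraction * nrow(out))
  out$group <- c(rep("bound", n_top), rep("unbound", nrow(out) - n_top))
  rownames(out) <- NULL
  out
}
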