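#' Diamond insulation score
#'
#' For bin `i` and window `w = window_bp / resolution`, the raw score is the
#' mean count over the diamond of cells `(a, b)` with
#' `i - w <= a < i < b <= i + w`. The reported score is
#' `log2(raw / contig-wide mean of raw)`, so a contig-wide geometric-mean bin
#' scores 0 and insulating loci are negative. Within `w` bins of a linear
#' contig end the score is NaN (the full diamond must fit); on circular
#' contigs the diamond wraps and every bin is scored.
#'
#' @param mat bp-binned `contact_matrix` (the study uses 80 bp bins).
#' @param window_bp diamond half-width in bp, a multiple of the resolution
#'   (the study uses 400, 640 and 800 bp).
#' @return object of class `insulation_profile`: data.frame(contig, start,
#'   end, score) with attributes `window_bp` and `resolution_bp`.
#' @export
insulation_score <- function(mat, window_bp) {
  res <- mat$resolution
  if (!is.numeric(res)) stop("insulation needs a bp-binned matrix")
  if (window_bp %% res != 0) stop("window_bp must be a multiple of the resolution")
  w <- window_bp %/% res
  if (w < 2L) stop("window must span >= 2 bins")
  out <- list()
  for (cn in unique(mat$bins$contig)) {
    rows <- which(mat$bins$contig == cn)
    nb <- length(rows)
    if (w >= nb) stop("window larger than contig '", cn, "'")
    circ <- isTRUE(mat$contigs$circular[match(cn, mat$contigs$name)])
    dense <- .dense_contig(mat, cn)
    raw <- rep(NA_real_, nb)
    for (i in seq_len(nb)) {
      if (!circ && (i - w < 1L || i + w > nb)) next
      a <- ((i - w):(i - 1L) - 1L) %% nb + 1L
      b <- ((i + 1L):(i + w) - 1L) %% nb + 1L
      raw[i] <- mean(dense[a, b])
    }
    mu <- mean(raw[is.finite(raw)])
    score <- log2(raw / mu)
    out[[cn]] <- data.frame(contig = cn,
                            start = mat$bins$start[rows],
                            end = mat$bins$end[rows],
                            score = score)
  }
  prof <- do.call(rbind, out)
  rownames(prof) <- NULL
  class(prof) <- c("insulation_profile", class(prof))
  attr(prof, "window_bp") <- window_bp
  attr(prof, "resolution_bp") <- res
  attr(prof, "contigs") <- mat$contigs
  prof
}

# Interior local minima of a numeric vector; a flat plateau that descends from
# the left and rises to the right reports its leftmost bin.
.local_minima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] < x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] > x[i]) out <- c(out, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# Topographic prominence of minima in a score vector: for minimum m, scan
# outward on each side until a strictly deeper value (or the end); the saddle
# on each side is the maximum in between; prominence = min(saddles) - s[m].
# Ends act as saddles of height +Inf capped at the side's maximum.
.min_prominence <- function(s, minima) {
  n <- length(s)
  vapply(minima, function(m) {
    # left
    i <- m - 1L
    left_max <- -Inf
    while (i >= 1L && s[i] >= s[m]) {
      left_max <- max(left_max, s[i])
      i <- i - 1L
    }
    # right
    i <- m + 1L
    right_max <- -Inf
    while (i <= n && s[i] >= s[m]) {
      right_max <- max(right_max, s[i])
      i <- i + 1L
    }
    min(left_max, right_max) - s[m]
  }, 1)
}

#' Call insulation boundaries by peak prominence
#'
#' Local minima of the insulation profile, ranked by topographic prominence
#' (the height from the minimum to the lower of its two enclosing key
#' saddles; profile ends act as saddles). Boundaries with prominence at or
#' above the [li_threshold()] of all prominences are flagged "strong". The
#' boundary set is invariant under adding a constant to the profile.
#'
#' @param profile an [insulation_score()] result.
#' @param li_log apply the Li threshold on a log scale (log1p of the
#'   prominences) instead of the linear scale (off by default).
#' @return data.frame(contig, position, bin, score, prominence, strong)
#'   ordered by position, with attribute `li_threshold`. All-NaN profiles
#'   yield an empty result with a warning.
#' @export
call_boundaries <- function(profile, li_log = FALSE) {
  res <- attr(profile, "resolution_bp")
  contigs <- attr(profile, "contigs")
  out <- list()
  for (cn in unique(profile$contig)) {
    p <- profile[profile$contig == cn, ]
    fin <- which(is.finite(p$score))
    if (length(fin) < 3L) next
    # contiguous finite runs (linear NaN margins split the profile)
    runs <- split(fin, cumsum(c(1L, diff(fin) != 1L)))
    circ <- !is.null(contigs) &&
      isTRUE(contigs$circular[match(cn, contigs$name)]) &&
      length(runs) == 1L && length(fin) == nrow(p)
    for (r in runs) {
      s <- p$score[r]
      if (circ) {
        # rotate so the global maximum is at the edge; then linear logic holds
        k <- which.max(s)
        rot <- c(k:length(s), seq_len(k - 1L))
        mins <- .local_minima(s[rot])
        prom <- .min_prominence(s[rot], mins)
        mins <- rot[mins]
      } else {
        mins <- .local_minima(s)
        prom <- .min_prominence(s, mins)
      }
      if (!length(mins)) next
      out[[length(out) + 1L]] <-
        data.frame(contig = cn,
                   position = p$start[r[mins]] + res / 2,
                   bin = r[mins],
                   score = s[mins],
                   prominence = prom)
    }
  }
  if (!length(out)) {
    warning("no finite insulation bins; no boundaries called")
    return(data.frame(contig = character(0), position = numeric(0),
                      bin = integer(0), score = numeric(0),
                      prominence = numeric(0), strong = logical(0)))
  }
  b <- do.call(rbind, out)
  b <- b[order(b$contig, b$position), ]
  rownames(b) <- NULL
  vals <- if (li_log) log1p(b$prominence) else b$prominence
  thr <- tryCatch(li_threshold(vals[vals > 0]),
                  error = function(e) -Inf)
  if (is.finite(thr)) {
    b$strong <- vals >= thr
  } else {
    message("Li threshold undefined (degenerate prominences); all boundaries strong")
    b$strong <- TRUE
  }
  attr(b, "li_threshold") <- thr
  b
}

#' Li minimum cross-entropy threshold
#'
#' The image-analysis "Li" threshold, computed by fixed-point iteration on the
#' class means: given a threshold t, with mu_low = mean(values <= t) and
#' mu_high = mean(values > t), the update is
#' `t' = (mu_low - mu_high) / (log(mu_low) - log(mu_high))`, iterated from
#' t0 = mean(values) to convergence. Values must be positive with at least two
#' distinct values. The threshold is homogeneous: scaling the values by c > 0
#' scales it by c.
#'
#' @param values positive numeric values (e.g. boundary prominences).
#' @param tol convergence tolerance, default 1e-6.
#' @param max_iter iteration cap.
#' @return the threshold (numeric scalar).
#' @export
#' @examples
#' li_threshold(c(1, 1, 1, 1, 9, 9))  # ~3.641
li_threshold <- function(values, tol = 1e-6, max_iter = 100L) {
  values <- values[is.finite(values)]
  if (length(values) < 2L || length(unique(values)) < 2L) {
    stop("Li threshold undefined: need >= 2 distinct values")
  }
  if (any(values <= 0)) stop("Li threshold needs positive values")
  t <- mean(values)
  for (k in seq_len(max_iter)) {
    lo <- values[values <= t]
    hi <- values[values > t]
    if (!length(lo) || !length(hi)) break
    mu_lo <- mean(lo); mu_hi <- mean(hi)
    if (mu_lo == mu_hi) break
    t_new <- (mu_lo - mu_hi) / (log(mu_lo) - log(mu_hi))
    if (abs(t_new - t) < tol) return(t_new)
    t <- t_new
  }
  t
}

#' Composite insulation around anchors
#'
#' Averages the insulation score per offset across anchors within a window
#' (default 3,000 bp) and reports the composite's minimum near the anchor
#' (within +/- 400 bp), the quantity whose relation to NFR width the analysis
#' tests.
#'
#' @param profile an [insulation_score()] result.
#' @param anchors anchor set.
#' @param window_bp total window, default 3000.
#' @return list(offset_bp, composite, minimum, n_anchors, n_skipped).
#' @export
insulation_at_anchors <- function(profile, anchors, window_bp = 3000) {
  res <- attr(profile, "resolution_bp")
  half <- (window_bp %/% 2) %/% res
  offs <- (-half):half
  rowsl <- split(seq_len(nrow(profile)), profile$contig)
  acc <- matrix(NA_real_, nrow(anchors), length(offs))
  used <- 0L
  for (k in seq_len(nrow(anchors))) {
    rows <- rowsl[[anchors$contig[k]]]
    if (is.null(rows)) next
    b <- anchors$pos[k] %/% res + 1L
    idx <- b + offs
    if (idx[1] < 1L || idx[length(idx)] > length(rows)) next
    acc[k, ] <- profile$score[rows[idx]]
    used <- used + 1L
  }
  if (used == 0L) stop("no interior anchors for insulation composite")
  comp <- colMeans(acc, na.rm = TRUE)
  near <- abs(offs * res) <= 400
  list(offset_bp = offs * res, composite = comp,
       minimum = min(comp[near], na.rm = TRUE),
       n_anchors = used, n_skipped = nrow(anchors) - used)
}

#' Boundary / anchor overlap with a permutation null
#'
#' Fraction of (strong) boundaries within `slack_bp` of an anchor, the
#' reciprocal fraction of anchors near a boundary, and an empirical enrichment
#' ratio against a null in which boundary positions are shuffled uniformly
#' within their contigs.
#'
#' @param boundaries a [call_boundaries()] result.
#' @param anchors anchor set.
#' @param contigs contig table (for shuffle bounds).
#' @param slack_bp match distance, default 200.
#' @param use_strong restrict to strong boundaries (default TRUE).
#' @param n_perm number of shuffles.
#' @param seed RNG seed for the shuffles.
#' @return list(frac_boundaries, frac_anchors, enrichment, n_boundaries).
#' @export
boundary_anchor_overlap <- function(boundaries, anchors, contigs,
                                    slack_bp = 200, use_strong = TRUE,
                                    n_perm = 100L, seed = 1L) {
  contigs <- check_contigs(contigs)
  b <- if (use_strong && any(boundaries$strong)) {
    boundaries[boundaries$strong, ]
  } else boundaries
  near_frac <- function(pos, contig, ref_pos, ref_contig) {
    if (!length(pos)) return(NA_real_)
    hit <- vapply(seq_along(pos), function(k) {
      rp <- ref_pos[ref_contig == contig[k]]
      length(rp) > 0 && min(abs(rp - pos[k])) <= slack_bp
    }, TRUE)
    mean(hit)
  }
  fb <- near_frac(b$position, b$contig, anchors$pos, anchors$contig)
  fa <- near_frac(anchors$pos, anchors$contig, b$position, b$contig)
  enr <- NA_real_
  if (nrow(b) > 0) {
    L <- contigs$length[match(b$contig, contigs$name)]
    null <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_perm), function(p) {
        near_frac(runif(nrow(b), 0, L), b$contig, anchors$pos, anchors$contig)
      }, 1)
    })
    enr <- fb / mean(null)
  }
  list(frac_boundaries = fb, frac_anchors = fa, enrichment = enr,
       n_boundaries = nrow(b))
}

#' NFR width versus insulation minimum
#'
#' Pearson correlation of composite insulation-score minima against planted or
#' measured NFR widths across conditions, with a two-sided p-value from the
#' t-distribution on n - 2 degrees of freedom.
#'
#' @param widths NFR widths (bp), one per condition (>= 3).
#' @param minima composite insulation minima, same length.
#' @return list(r, p, n).
#' @export
nfr_vs_insulation <- function(widths, minima) {
  if (length(widths) != length(minima)) stop("lengths differ")
  if (length(widths) < 3L) stop("need >= 3 conditions")
  if (sd(widths) == 0 || sd(minima) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(widths, minima, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(widths))
}
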