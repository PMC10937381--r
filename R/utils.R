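# Small shared helpers. All genomic coordinates in this package are 0-based,
# intervals half-open [start, end).

#' Centered rolling mean with truncated edges
#'
#' Window of width `k` centered on each position; for even `k` the window
#' covers `k %/% 2` positions to the left and `k - 1 - k %/% 2` to the right.
#' Edges use the available positions only (truncated, so the interior is
#' mass-preserving).
#'
#' @param x numeric vector.
#' @param k integer window width in positions.
#' @return numeric vector of `length(x)`.
#' @keywords internal
rolling_mean <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  left <- k %/% 2L
  right <- k - 1L - left
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - left, 1L)
  hi <- pmin(seq_len(n) + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Truncated normal draws by inverse-CDF; sd = 0 collapses to the clamped mean.
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(min(max(mean, lo), hi), n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Validate a contig table: data.frame(name, length, circular).
check_contigs <- function(contigs) {
  stopifnot(is.data.frame(contigs))
  req <- c("name", "length")
  if (!all(req %in% names(contigs))) {
    stop("contig table needs columns 'name' and 'length'")
  }
  if (is.null(contigs$circular)) contigs$circular <- FALSE
  if (anyDuplicated(contigs$name)) stop("duplicated contig names")
  if (any(contigs$length <= 0)) stop("contig lengths must be positive")
  contigs$name <- as.character(contigs$name)
  contigs
}

#' Define a contig table
#'
#' @param name character contig names.
#' @param length integer lengths in bp.
#' @param circular logical; circular topology (plasmids) or linear.
#' @return data.frame with columns name, length, circular.
#' @export
#' @examples
#' contig_table("plasmid", 20000, circular = TRUE)
contig_table <- function(name, length, circular = FALSE) {
  check_contigs(data.frame(name = name, length = as.integer(length),
                           circular = circular))
}

#' Define an anchor set (oriented genomic reference points)
#'
#' @param contig character contig per anchor.
#' @param pos integer 0-based coordinate.
#' @param strand "+", "-" or "*" (unoriented).
#' @return data.frame with columns contig, pos, strand.
#' @export
anchor_set <- function(contig, pos, strand = "*") {
  df <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                   strand = strand, stringsAsFactors = FALSE)
  if (!all(df$strand %in% c("+", "-", "*"))) stop("strand must be +, - or *")
  df
}
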