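#' Pair filter configuration
#'
#' Holds the processing constants for chimeric ligation pairs: minimum
#' same-contig distance (pairs less than 147 bp apart are removed; 147 itself
#' is kept, "less than" being strict), whether interchromosomal pairs are
#' dropped, and the dyad shift (the ligation junction is shifted 80 bp toward
#' the interior of the nucleosome the read enters).
#'
#' @param min_distance_bp minimum kept distance, default 147.
#' @param drop_interchromosomal drop pairs with `contig1 != contig2`.
#' @param dyad_shift_bp junction-to-dyad shift, default 80.
#' @return object of class `pair_filter_config`.
#' @export
pair_filter_config <- function(min_distance_bp = 147L,
                               drop_interchromosomal = TRUE,
                               dyad_shift_bp = 80L) {
  if (min_distance_bp < 0) stop("min_distance_bp must be >= 0")
  structure(list(min_distance_bp = as.integer(min_distance_bp),
                 drop_interchromosomal = isTRUE(drop_interchromosomal),
                 dyad_shift_bp = as.integer(dyad_shift_bp)),
            class = "pair_filter_config")
}

.dir_levels <- c("downstream", "upstream")
.orientation_levels <- c("inward", "outward", "tandem_entry", "tandem_exit",
                         "unset")

.check_pairs <- function(pairs) {
  req <- c("contig1", "pos1", "dir1", "contig2", "pos2", "dir2", "orientation")
  if (!all(req %in% names(pairs))) {
    stop("pairs need columns ", paste(req, collapse = ", "))
  }
  pairs
}

#' Canonicalize pair sides
#'
#' Orders the two sides of every pair so that `(contig1, pos1) <=
#' (contig2, pos2)`; directions travel with their side. Orientation classes
#' are defined on canonical pairs and are therefore invariant under side swap.
#'
#' @param pairs pair data.frame.
#' @return pairs with sides ordered.
#' @export
canonicalize_pairs <- function(pairs) {
  pairs <- .check_pairs(pairs)
  swap <- pairs$contig2 < pairs$contig1 |
    (pairs$contig2 == pairs$contig1 & pairs$pos2 < pairs$pos1)
  if (any(swap)) {
    tmp <- pairs[swap, c("contig1", "pos1", "dir1")]
    pairs[swap, c("contig1", "pos1", "dir1")] <-
      pairs[swap, c("contig2", "pos2", "dir2")]
    pairs[swap, c("contig2", "pos2", "dir2")] <- tmp
  }
  pairs
}

#' Classify ligation-pair orientation
#'
#' After canonicalization, the read-direction combination at the two junction
#' sides maps to one of four classes:
#' (downstream, upstream) -> inward; (upstream, downstream) -> outward;
#' (downstream, downstream) -> tandem_entry; (upstream, upstream) ->
#' tandem_exit. The mapping is exhaustive and mutually exclusive.
#'
#' @param pairs pair data.frame with dir1/dir2 set.
#' @return pairs with the `orientation` column filled.
#' @export
classify_orientation <- function(pairs) {
  pairs <- canonicalize_pairs(pairs)
  if (any(!pairs$dir1 %in% .dir_levels) || any(!pairs$dir2 %in% .dir_levels)) {
    stop("unset or unknown read direction; expected 'downstream'/'upstream'")
  }
  down1 <- pairs$dir1 == "downstream"
  down2 <- pairs$dir2 == "downstream"
  pairs$orientation <- ifelse(down1,
                              ifelse(down2, "tandem_entry", "inward"),
                              ifelse(down2, "outward", "tandem_exit"))
  pairs
}

#' Shift ligation junctions to the nucleosome dyad
#'
#' Moves each side's coordinate `dyad_shift_bp` (80 bp) toward the interior of
#' the nucleosome the read enters: a downstream-reading side moves to
#' `pos + 80`, an upstream-reading side to `pos - 80`. Inward-pair distances
#' therefore shrink by 160 bp; tandem pairs keep their distance. Pairs whose
#' shift would produce a negative coordinate are dropped and counted
#' (attribute `n_dropped_negative`). A no-op on already-shifted input (tracked
#' via the `shifted` attribute), so the classify-shift-filter pipeline is
#' idempotent.
#'
#' @param pairs classified pairs.
#' @param cfg a [pair_filter_config()].
#' @param contigs optional contig table; on circular contigs the shifted
#'   coordinate wraps around the origin instead of leaving the contig.
#' @return shifted pairs with attribute `shifted = TRUE`.
#' @export
shift_to_dyad <- function(pairs, cfg = pair_filter_config(), contigs = NULL) {
  pairs <- .check_pairs(pairs)
  if (isTRUE(attr(pairs, "shifted"))) return(pairs)
  if (any(pairs$orientation == "unset")) {
    stop("orientation must be classified before shifting")
  }
  s <- cfg$dyad_shift_bp
  sh1 <- ifelse(pairs$dir1 == "downstream", s, -s)
  sh2 <- ifelse(pairs$dir2 == "downstream", s, -s)
  pairs$pos1 <- pairs$pos1 + sh1
  pairs$pos2 <- pairs$pos2 + sh2
  if (!is.null(contigs)) {
    contigs <- check_contigs(contigs)
    circ <- contigs$name[contigs$circular]
    for (cn in circ) {
      L <- contigs$length[match(cn, contigs$name)]
      w1 <- pairs$contig1 == cn
      w2 <- pairs$contig2 == cn
      pairs$pos1[w1] <- pairs$pos1[w1] %% L
      pairs$pos2[w2] <- pairs$pos2[w2] %% L
    }
  }
  neg <- pairs$pos1 < 0 | pairs$pos2 < 0
  n_neg <- sum(neg)
  if (n_neg > 0) {
    message(n_neg, " pair(s) dropped: dyad shift produced negative coordinate")
    pairs <- pairs[!neg, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  pairs <- canonicalize_pairs(pairs)
  attr(pairs, "shifted") <- TRUE
  attr(pairs, "n_dropped_negative") <- n_neg
  pairs
}

#' Filter ligation pairs
#'
#' Removes interchromosomal pairs (optional) and same-contig pairs closer than
#' `min_distance_bp` (strictly less than; the boundary distance is kept).
#' Expects dyad-shifted input. Returns the kept pairs plus a stats list with
#' counts per removal reason and the orientation-class composition of the kept
#' pairs.
#'
#' @param pairs shifted, classified pairs.
#' @param cfg a [pair_filter_config()].
#' @return list(kept, stats); stats has `n_input`, `n_interchromosomal`,
#'   `n_close`, `n_kept`, `orientation_counts`.
#' @export
filter_pairs <- function(pairs, cfg = pair_filter_config()) {
  pairs <- .check_pairs(pairs)
  n_in <- nrow(pairs)
  inter <- pairs$contig1 != pairs$contig2
  drop_inter <- if (cfg$drop_interchromosomal) inter else rep(FALSE, n_in)
  dist <- abs(pairs$pos2 - pairs$pos1)
  close <- !inter & dist < cfg$min_distance_bp
  keep <- !drop_inter & !close
  kept <- pairs[keep, , drop = FALSE]
  rownames(kept) <- NULL
  for (a in c("assembly", "shifted")) attr(kept, a) <- attr(pairs, a)
  oc <- table(factor(kept$orientation, levels = .orientation_levels))
  list(kept = kept,
       stats = list(n_input = n_in,
                    n_interchromosomal = sum(drop_inter),
                    n_close = sum(close & !drop_inter),
                    n_kept = nrow(kept),
                    orientation_counts = oc))
}

#' Read / write pairs-text files
#'
#' Tab-separated pairs-text with `#`-prefixed header lines carrying the genome
#' assembly, the dyad-shift status and the direction-token legend
#' (`+` = downstream, `-` = upstream of the ligation junction). Columns:
#' contig1, pos1, dir1, contig2, pos2, dir2, orientation. `read_pairs()` and
#' [write_pairs()] round-trip bit-exactly.
#'
#' @param path file path.
#' @return data.frame of pairs with `assembly` and `shifted` attributes.
#' @export
read_pairs <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- lines[hdr]
  body <- lines[!hdr]
  body_lineno <- which(!hdr)
  assembly <- sub("^#assembly:\\s*", "", grep("^#assembly:", meta, value = TRUE))
  shifted <- identical(sub("^#shifted:\\s*", "",
                           grep("^#shifted:", meta, value = TRUE)), "true")
  dir_map <- c("+" = "downstream", "-" = "upstream")
  out <- data.frame(contig1 = character(0), pos1 = integer(0),
                    dir1 = character(0), contig2 = character(0),
                    pos2 = integer(0), dir2 = character(0),
                    orientation = character(0), stringsAsFactors = FALSE)
  if (length(body)) {
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 7L)) {
      bad <- which(nf != 7L)[1]
      stop("malformed pairs line ", body_lineno[bad], ": expected 7 fields, got ",
           nf[bad])
    }
    m <- matrix(unlist(fields), ncol = 7L, byrow = TRUE)
    pos1 <- suppressWarnings(as.integer(m[, 2]))
    pos2 <- suppressWarnings(as.integer(m[, 5]))
    if (anyNA(pos1) || anyNA(pos2) || any(pos1 < 0) || any(pos2 < 0)) {
      bad <- which(is.na(pos1) | is.na(pos2) | pos1 < 0 | pos2 < 0)[1]
      stop("malformed pairs line ", body_lineno[bad],
           ": coordinates must be non-negative integers")
    }
    if (any(!m[, 3] %in% names(dir_map)) || any(!m[, 6] %in% names(dir_map))) {
      bad <- which(!m[, 3] %in% names(dir_map) | !m[, 6] %in% names(dir_map))[1]
      stop("malformed pairs line ", body_lineno[bad],
           ": unknown direction token (expected '+' or '-')")
    }
    if (any(!m[, 7] %in% .orientation_levels)) {
      bad <- which(!m[, 7] %in% .orientation_levels)[1]
      stop("malformed pairs line ", body_lineno[bad],
           ": unknown orientation '", m[bad, 7], "'")
    }
    out <- data.frame(contig1 = m[, 1], pos1 = pos1,
                      dir1 = unname(dir_map[m[, 3]]),
                      contig2 = m[, 4], pos2 = pos2,
                      dir2 = unname(dir_map[m[, 6]]),
                      orientation = m[, 7], stringsAsFactors = FALSE)
  }
  attr(out, "assembly") <- if (length(assembly)) assembly[1] else "unknown"
  attr(out, "shifted") <- shifted
  out
}

#' @rdname read_pairs
#' @param pairs pair data.frame.
#' @export
write_pairs <- function(pairs, path) {
  pairs <- .check_pairs(pairs)
  assembly <- attr(pairs, "assembly")
  if (is.null(assembly)) assembly <- "unknown"
  shifted <- isTRUE(attr(pairs, "shifted"))
  tok <- c(downstream = "+", upstream = "-")
  hdr <- c("## pairs-text v1",
           paste0("#assembly: ", assembly),
           paste0("#shifted: ", if (shifted) "true" else "false"),
           "#dir: +=downstream -=upstream of ligation junction",
           "#columns: contig1 pos1 dir1 contig2 pos2 dir2 orientation")
  body <- if (nrow(pairs)) {
    paste(pairs$contig1, pairs$pos1, tok[pairs$dir1],
          pairs$contig2, pairs$pos2, tok[pairs$dir2],
          pairs$orientation, sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
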