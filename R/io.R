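# Plain-text exporters for tracks, intervals and matrices. Every artifact
# gets a machine-readable provenance header (tool version, seed, config hash)
# via .provenance_header().

.provenance_header <- function(seed = NA, config_hash = NA, comment = "#") {
  paste0(comment, "nucfold ", as.character(packageVersion("nucfold")),
         "; seed=", seed, "; config=", config_hash)
}

#' Write a signal track as bedGraph
#'
#' Consecutive equal values are collapsed into intervals. This is the
#' package's track export format (plain text).
#'
#' @param track a [dyad_coverage()]-style named list of per-contig vectors.
#' @param path output path.
#' @param name track name for the header line.
#' @param digits rounding applied before run-length collapsing.
#' @return the path, invisibly.
#' @export
write_bedgraph <- function(track, path, name = "nucfold", digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("track type=bedGraph name=", name), con)
  for (cn in names(track)) {
    x <- round(track[[cn]], digits)
    x[!is.finite(x)] <- NA
    r <- rle(x)
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    ok <- !is.na(r$values)
    if (any(ok)) {
      writeLines(paste(cn, start[ok], end[ok], r$values[ok], sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Write an insulation profile as bedGraph
#'
#' @param profile an [insulation_score()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_insulation <- function(profile, path) {
  ok <- is.finite(profile$score)
  lines <- c(paste0("track type=bedGraph name=insulation_w",
                    attr(profile, "window_bp")),
             paste(profile$contig[ok], profile$start[ok], profile$end[ok],
                   signif(profile$score[ok], 7), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write boundary calls as BED
#'
#' Prominence goes in the score column; the name field carries the
#' strong/weak flag.
#'
#' @param boundaries a [call_boundaries()] result.
#' @param path output path.
#' @param slop_bp half-width of the written interval, default 40.
#' @return the path, invisibly.
#' @export
write_boundaries_bed <- function(boundaries, path, slop_bp = 40) {
  lines <- paste(boundaries$contig,
                 pmax(0, round(boundaries$position - slop_bp)),
                 round(boundaries$position + slop_bp),
                 ifelse(boundaries$strong, "strong", "weak"),
                 signif(boundaries$prominence, 6),
                 ".", sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write fragments as BED3
#'
#' @param fragments data.frame(contig, start, end).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  writeLines(paste(fragments$contig, fragments$start, fragments$end,
                   sep = "\t"), path)
  invisible(path)
}

#' Read fragments from BED3
#'
#' @param path BED3 path.
#' @return data.frame(contig, start, end).
#' @export
read_fragments_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("contig", "start", "end"),
                          colClasses = c("character", "integer", "integer"))
  df
}

#' Write a contact matrix as sparse triplet text plus a bin table
#'
#' @param mat a `contact_matrix`.
#' @param path triplet file path; the bin table goes to `paste0(path, ".bins")`.
#' @return the path, invisibly.
#' @export
write_matrix_triplets <- function(mat, path) {
  tm <- as(mat$counts, "TsparseMatrix")
  writeLines(c("#bin1\tbin2\tcount",
               paste(tm@i + 1L, tm@j + 1L, tm@x, sep = "\t")), path)
  utils::write.table(mat$bins, paste0(path, ".bins"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
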