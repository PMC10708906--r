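# Genomic interval arithmetic.
#
# Every coordinate in this package is 0-based half-open (BED convention);
# 1-based external dialects are converted at the I/O boundary and nowhere
# else. An interval is a data.frame row with columns chrom, start, end
# (numeric, end exclusive), optionally strand.

#' Construct a table of genomic intervals
#'
#' @param chrom chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end exclusive end positions; `end > start` required.
#' @param strand optional strand, one of `"+"`, `"-"`, `"*"`.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' Validate interval invariants
#'
#' Checks `0 <= start < end` for every row; errors naming the first
#' offending row.
#'
#' @param df data.frame with `chrom`, `start`, `end` columns.
#' @param what label used in error messages.
#' @return `df`, invisibly.
#' @export
validate_intervals <- function(df, what = "interval") {
  ax_assert(all(c("chrom", "start", "end") %in% names(df)),
            sprintf("%s table must have chrom/start/end columns", what))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad) > 0) {
    stop(sprintf("invalid %s at row %d: need 0 <= start < end (got [%s, %s) on %s)",
                 what, bad[1], format(df$start[bad[1]]), format(df$end[bad[1]]),
                 df$chrom[bad[1]]), call. = FALSE)
  }
  invisible(df)
}

interval_width <- function(df) df$end - df$start

# Union of intervals, per chromosome. Returns a sorted, disjoint table.
merge_spans <- function(df) {
  if (nrow(df) == 0) return(df[, c("chrom", "start", "end")])
  pieces <- split(df[, c("chrom", "start", "end")], df$chrom)
  out <- lapply(pieces, function(p) {
    p <- p[order(p$start, p$end), , drop = FALSE]
    ns <- p$start[1]; ne <- p$end[1]
    starts <- numeric(0); ends <- numeric(0)
    if (nrow(p) > 1) {
      for (i in 2:nrow(p)) {
        if (p$start[i] <= ne) {
          ne <- max(ne, p$end[i])
        } else {
          starts <- c(starts, ns); ends <- c(ends, ne)
          ns <- p$start[i]; ne <- p$end[i]
        }
      }
    }
    data.frame(chrom = p$chrom[1], start = c(starts, ns), end = c(ends, ne),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Length of the overlap of [s1,e1) with [s2,e2); vectorised.
overlap_len <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# Bases of [start,end) on `chrom` covered by the (not necessarily disjoint)
# interval set `df`.
covered_bases <- function(df, chrom, start, end) {
  sel <- df[df$chrom == chrom, , drop = FALSE]
  if (nrow(sel) == 0) return(0)
  m <- merge_spans(sel)
  sum(overlap_len(m$start, m$end, start, end))
}

# Portions of [start,end) on `chrom` NOT covered by `df`; returns an
# interval table (possibly empty).
uncovered_portions <- function(df, chrom, start, end) {
  sel <- df[df$chrom == chrom & df$start < end & df$end > start, , drop = FALSE]
  if (nrow(sel) == 0) {
    return(data.frame(chrom = chrom, start = start, end = end,
                      stringsAsFactors = FALSE))
  }
  m <- merge_spans(sel)
  m$start <- pmax(m$start, start); m$end <- pmin(m$end, end)
  gaps_start <- c(start, m$end)
  gaps_end <- c(m$start, end)
  keep <- gaps_end > gaps_start
  data.frame(chrom = rep(chrom, sum(keep)), start = gaps_start[keep],
             end = gaps_end[keep], stringsAsFactors = FALSE)
}
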