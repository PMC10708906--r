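# Syntenic collinearity blocks: chaining of whole-genome alignment anchors
# and coordinate liftover between two genomes. Blocks gate the HE caller
# (outlier regions must lie in synteny) and carry DEL spans onto the
# homeologous coordinate system when pairing replacement events.

#' Chain alignment anchors into syntenic collinearity blocks
#'
#' Two anchors belong to the same block iff they share the
#' (query chromosome, target chromosome) pair and orientation, and the gap
#' between them is below `link_gap` (default 20 kb). Block membership is the
#' transitive closure of this pairwise relation, so blocks are maximal and
#' every anchor lands in exactly one block. Anchors overlapping on the query
#' within one chromosome pair are merged before chaining, since local
#' aligners emit overlapping hits while chaining assumes a tiling.
#'
#' @param anchors anchor table (see [read_anchors()]).
#' @param link_gap maximum linking distance in bp; default 20000.
#' @param both_sides if `TRUE` (default) the gap rule must hold on both the
#'   query side and the target side; set `FALSE` for a query-side-only rule.
#' @return block table with columns `block_id, qchrom, qstart, qend, tchrom,
#'   tstart, tend, orientation, n_anchors` and a list column `anchors`
#'   holding each block's member anchors (query-sorted).
#' @export
link_anchors <- function(anchors, link_gap = 20000, both_sides = TRUE) {
  ax_assert(link_gap > 0, "link_gap must be positive")
  empty <- data.frame(block_id = character(0), qchrom = character(0),
                      qstart = numeric(0), qend = numeric(0),
                      tchrom = character(0), tstart = numeric(0),
                      tend = numeric(0), orientation = character(0),
                      n_anchors = integer(0), stringsAsFactors = FALSE)
  empty$anchors <- list()
  if (is.null(anchors) || nrow(anchors) == 0) return(empty)
  anchors <- validate_anchors(anchors)

  key <- paste(anchors$qchrom, anchors$tchrom, anchors$orientation, sep = "\r")
  groups <- split(anchors, key)
  rows <- list()
  for (a in groups) {
    a <- a[order(a$qstart, a$qend), , drop = FALSE]
    a <- merge_query_overlaps(a)
    comp <- link_components(a, link_gap, both_sides)
    for (g in sort(unique(comp))) {
      m <- a[comp == g, , drop = FALSE]
      m <- m[order(m$qstart), , drop = FALSE]
      rows[[length(rows) + 1]] <- list(
        qchrom = m$qchrom[1], qstart = min(m$qstart), qend = max(m$qend),
        tchrom = m$tchrom[1], tstart = min(m$tstart), tend = max(m$tend),
        orientation = m$orientation[1], n_anchors = nrow(m), anchors = m)
    }
  }
  out <- data.frame(
    block_id = sprintf("blk%04d", seq_along(rows)),
    qchrom = vapply(rows, `[[`, "", "qchrom"),
    qstart = vapply(rows, `[[`, 0, "qstart"),
    qend = vapply(rows, `[[`, 0, "qend"),
    tchrom = vapply(rows, `[[`, "", "tchrom"),
    tstart = vapply(rows, `[[`, 0, "tstart"),
    tend = vapply(rows, `[[`, 0, "tend"),
    orientation = vapply(rows, `[[`, "", "orientation"),
    n_anchors = vapply(rows, function(r) as.integer(r$n_anchors), 1L),
    stringsAsFactors = FALSE)
  out$anchors <- lapply(rows, `[[`, "anchors")
  out <- out[order(out$qchrom, out$qstart), , drop = FALSE]
  out$block_id <- sprintf("blk%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  ax_log("link_anchors: %d anchors -> %d blocks (gap < %d, both_sides = %s)",
         nrow(anchors), nrow(out), link_gap, both_sides)
  out
}

# Merge anchors that overlap on the query (within one chrom pair and
# orientation); hulls are taken on both sides, identities averaged weighted
# by query length.
merge_query_overlaps <- function(a) {
  if (nrow(a) <= 1) return(a)
  grp <- integer(nrow(a)); g <- 1L; grp[1] <- g
  hi <- a$qend[1]
  for (i in 2:nrow(a)) {
    if (a$qstart[i] < hi) {
      grp[i] <- g
    } else {
      g <- g + 1L; grp[i] <- g
    }
    hi <- max(hi, a$qend[i])
  }
  if (max(grp) == nrow(a)) return(a)
  pieces <- lapply(split(a, grp), function(p) {
    if (nrow(p) == 1) return(p)
    w <- p$qend - p$qstart
    data.frame(qchrom = p$qchrom[1], qstart = min(p$qstart), qend = max(p$qend),
               tchrom = p$tchrom[1], tstart = min(p$tstart), tend = max(p$tend),
               orientation = p$orientation[1],
               identity = if (all(is.na(p$identity))) NA_real_ else
                 stats::weighted.mean(p$identity, w, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$qstart), , drop = FALSE]
}

# Connected components of the pairwise "linkable" relation (union-find).
link_components <- function(a, link_gap, both_sides) {
  n <- nrow(a)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      qgap <- max(a$qstart[j] - a$qend[i], a$qstart[i] - a$qend[j], 0)
      tgap <- max(a$tstart[j] - a$tend[i], a$tstart[i] - a$tend[j], 0)
      if (qgap < link_gap && (!both_sides || tgap < link_gap)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

#' Lift an interval through a synteny chain
#'
#' Maps the portions of a query interval covered by synteny blocks onto the
#' target genome. Coordinates are interpolated piecewise-linearly through
#' each block's anchors (and linearly across anchor gaps); inverted blocks
#' reverse the mapped interval. Portions outside every block are dropped
#' and reported. When blocks from different chromosome pairs cover the same
#' query bases, all mappings are emitted and flagged ambiguous.
#'
#' @param blocks block table from [link_anchors()].
#' @param chrom,start,end the query interval (0-based half-open).
#' @return list with `mapped` (target intervals: `chrom, start, end,
#'   block_id, qstart, qend, ambiguous`) and `dropped` (query portions not
#'   covered by any block).
#' @export
lift_interval <- function(blocks, chrom, start, end) {
  ax_assert(start >= 0 && start < end, "need 0 <= start < end")
  hit <- blocks[blocks$qchrom == chrom & blocks$qstart < end &
                  blocks$qend > start, , drop = FALSE]
  dropped <- uncovered_portions(
    data.frame(chrom = hit$qchrom, start = hit$qstart, end = hit$qend,
               stringsAsFactors = FALSE), chrom, start, end)
  if (nrow(hit) == 0) {
    warning("lift_interval: chromosome ", chrom, " not covered by any block")
    mapped <- data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0), block_id = character(0),
                         qstart = numeric(0), qend = numeric(0),
                         ambiguous = logical(0), stringsAsFactors = FALSE)
    return(list(mapped = mapped, dropped = dropped))
  }
  mapped <- do.call(rbind, lapply(seq_len(nrow(hit)), function(i) {
    b <- hit[i, ]
    s <- max(start, b$qstart); e <- min(end, b$qend)
    a <- b$anchors[[1]]
    a <- a[order(a$qstart), , drop = FALSE]
    xs <- as.vector(rbind(a$qstart, a$qend))
    ys <- if (b$orientation == "same") {
      as.vector(rbind(a$tstart, a$tend))
    } else {
      as.vector(rbind(a$tend, a$tstart))
    }
    y <- stats::approx(xs, ys, xout = c(s, e), ties = "ordered")$y
    data.frame(chrom = b$tchrom, start = round(min(y)), end = round(max(y)),
               block_id = b$block_id, qstart = s, qend = e,
               ambiguous = FALSE, stringsAsFactors = FALSE)
  }))
  # flag mappings whose query portions overlap another mapping's portion
  if (nrow(mapped) > 1) {
    for (i in seq_len(nrow(mapped))) {
      ov <- overlap_len(mapped$qstart[i], mapped$qend[i],
                        mapped$qstart[-i], mapped$qend[-i])
      if (any(ov > 0)) mapped$ambiguous[i] <- TRUE
    }
  }
  mapped <- mapped[mapped$end > mapped$start, , drop = FALSE]
  rownames(mapped) <- NULL
  list(mapped = mapped, dropped = dropped)
}

#' Fraction of an interval covered by synteny blocks
#'
#' @param blocks block table from [link_anchors()].
#' @param chrom,start,end the interval of interest.
#' @param side which block spans to use: `"query"`, `"target"`, or
#'   `"either"` (the chromosome is looked up on both sides; useful when the
#'   interval lives on one of the two genomes of a progenitor-vs-progenitor
#'   chain).
#' @return fraction in `[0, 1]` of the interval's bases covered by the
#'   union of block spans.
#' @export
overlap_fraction <- function(blocks, chrom, start, end, side = "either") {
  side <- match.arg(side, c("query", "target", "either"))
  spans <- list()
  if (side %in% c("query", "either")) {
    spans[[length(spans) + 1]] <- data.frame(
      chrom = blocks$qchrom, start = blocks$qstart, end = blocks$qend,
      stringsAsFactors = FALSE)
  }
  if (side %in% c("target", "either")) {
    spans[[length(spans) + 1]] <- data.frame(
      chrom = blocks$tchrom, start = blocks$tstart, end = blocks$tend,
      stringsAsFactors = FALSE)
  }
  spans <- do.call(rbind, spans)
  covered_bases(spans, chrom, start, end) / (end - start)
}

# Swap query and target of a block table (including member anchors), so an
# interval on the target genome can be lifted back.
invert_chain <- function(blocks) {
  out <- blocks
  out$qchrom <- blocks$tchrom; out$qstart <- blocks$tstart
  out$qend <- blocks$tend
  out$tchrom <- blocks$qchrom; out$tstart <- blocks$qstart
  out$tend <- blocks$qend
  out$anchors <- lapply(blocks$anchors, function(a) {
    data.frame(qchrom = a$tchrom, qstart = a$tstart, qend = a$tend,
               tchrom = a$qchrom, tstart = a$qstart, tend = a$qend,
               orientation = a$orientation, identity = a$identity,
               stringsAsFactors = FALSE)
  })
  out
}

#' Write synteny blocks as TSV
#' @param blocks block table.
#' @param path output TSV (the `anchors` list column is dropped).
#' @export
write_blocks <- function(blocks, path) {
  cols <- c("block_id", "qchrom", "qstart", "qend", "tchrom", "tstart",
            "tend", "orientation", "n_anchors")
  utils::write.table(blocks[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
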