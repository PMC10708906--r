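# Depth-window homeologous-exchange (HE) caller.
#
# Reads from an allotetraploid are mapped to the concatenated progenitor
# genomes; per 10 kb window the mean depth is compared with the chromosome
# average for that sample. Windows in the 1.5-5x range are duplication
# (DUP) outliers, windows at <= 0.5x are deletion (DEL) outliers. Adjacent
# same-mark windows merge into blocks; blocks spanning >= 60 kb (>= 6
# windows) inside syntenic collinearity blocks are HE candidates. A DEL on
# one subgenome paired (through synteny liftover) with a DUP on the
# homeologous chromosome is an "HE with replacement" call; syntenic swapped
# segments in an assembly-vs-progenitor alignment are "reciprocal HE"
# calls.

#' Chromosome average depth for one sample
#'
#' Plain arithmetic mean over full (non-partial) windows; a trimmed mean is
#' available because extreme windows bias the mean on small chromosomes.
#'
#' @param depth depth table rows for a single sample and chromosome.
#' @param trim fraction trimmed from each tail (default 0, the plain mean).
#' @return mean depth (numeric scalar).
#' @export
chromosome_mean_depth <- function(depth, trim = 0) {
  full <- depth$mean_depth[!depth$partial]
  if (length(full) == 0) {
    stop("no full windows: cannot compute chromosome mean depth", call. = FALSE)
  }
  mean(full, trim = trim)
}

#' Classify depth windows against the chromosome average
#'
#' Each window's ratio to its chromosome's average depth determines its
#' mark: `DUP` iff `dup_range[1] <= ratio <= dup_range[2]` (default
#' `[1.5, 5]`), `DEL` iff `ratio <= del_range[2]` (default `[0, 0.5]`),
#' `HIGH` iff ratio exceeds `dup_range[2]` (repeat-like, excluded from HE),
#' `NORMAL` otherwise. Partial windows are never DUP/DEL and are marked
#' `PARTIAL`.
#'
#' @param depth depth table (any number of samples/chromosomes; the
#'   chromosome mean is computed per (sample, chromosome) group unless
#'   `chrom_mean` is given).
#' @param dup_range,del_range inclusive ratio ranges.
#' @param chrom_mean optional precomputed mean; only valid when `depth`
#'   holds a single (sample, chromosome) group.
#' @param trim trim fraction passed to [chromosome_mean_depth()].
#' @return `depth` with added columns `ratio` and `mark`.
#' @export
classify_windows <- function(depth, dup_range = c(1.5, 5.0),
                             del_range = c(0, 0.5), chrom_mean = NULL,
                             trim = 0) {
  if (!"partial" %in% names(depth)) depth$partial <- FALSE
  key <- paste(depth$sample_id, depth$chrom, sep = "\r")
  if (!is.null(chrom_mean)) {
    ax_assert(length(unique(key)) == 1,
              "chrom_mean given but depth spans several sample/chromosome groups")
    means <- stats::setNames(chrom_mean, unique(key))
  } else {
    means <- vapply(split(depth, key), chromosome_mean_depth, 0, trim = trim)
  }
  if (any(means <= 0)) {
    stop("chromosome mean depth must be positive (got ",
         format(min(means)), ")", call. = FALSE)
  }
  depth$ratio <- depth$mean_depth / unname(means[key])
  depth$mark <- ifelse(depth$partial, "PARTIAL",
                ifelse(depth$ratio <= del_range[2], "DEL",
                ifelse(depth$ratio >= dup_range[1] & depth$ratio <= dup_range[2],
                       "DUP",
                ifelse(depth$ratio > dup_range[2], "HIGH", "NORMAL"))))
  depth <- depth[order(depth$sample_id, depth$chrom, depth$start), ,
                 drop = FALSE]
  rownames(depth) <- NULL
  depth
}

#' Merge runs of adjacent same-mark outlier windows into blocks
#'
#' Maximal runs of coordinate-adjacent windows with identical mark in
#' `{DUP, DEL}` become blocks; `NORMAL`, `HIGH` and `PARTIAL` windows break
#' runs.
#'
#' @param marks window table from [classify_windows()].
#' @return block table `sample_id, chrom, start, end, mark, n_windows`.
#' @export
merge_marked_windows <- function(marks) {
  out <- data.frame(sample_id = character(0), chrom = character(0),
                    start = numeric(0), end = numeric(0), mark = character(0),
                    n_windows = integer(0), stringsAsFactors = FALSE)
  sel <- marks[marks$mark %in% c("DUP", "DEL"), , drop = FALSE]
  if (nrow(sel) == 0) return(out)
  sel <- sel[order(sel$sample_id, sel$chrom, sel$start), , drop = FALSE]
  new_run <- c(TRUE, sel$sample_id[-1] != sel$sample_id[-nrow(sel)] |
                 sel$chrom[-1] != sel$chrom[-nrow(sel)] |
                 sel$mark[-1] != sel$mark[-nrow(sel)] |
                 sel$start[-1] != sel$end[-nrow(sel)])
  run <- cumsum(new_run)
  agg <- lapply(split(sel, run), function(p) {
    data.frame(sample_id = p$sample_id[1], chrom = p$chrom[1],
               start = min(p$start), end = max(p$end), mark = p$mark[1],
               n_windows = nrow(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Filter outlier blocks by span, window count and synteny coverage
#'
#' Implements the putative-HE-region rule: keep blocks whose span is at
#' least `min_span` (60 kb) AND which contain at least `min_windows` (6)
#' windows AND whose span is covered by progenitor-vs-progenitor syntenic
#' collinearity blocks at fraction >= `min_synteny_frac`.
#'
#' @param blocks outlier block table from [merge_marked_windows()].
#' @param synteny synteny block table from [link_anchors()] (progenitor vs
#'   progenitor); block chromosomes are matched on either side.
#' @param min_span minimum span (bp).
#' @param min_windows minimum run length.
#' @param min_synteny_frac minimum synteny coverage fraction.
#' @return filtered block table with an added `synteny_covered` column.
#' @export
filter_he_candidates <- function(blocks, synteny, min_span = 60000,
                                 min_windows = 6, min_synteny_frac = 0.5) {
  if (nrow(blocks) == 0) {
    blocks$synteny_covered <- numeric(0)
    return(blocks)
  }
  blocks$synteny_covered <- vapply(seq_len(nrow(blocks)), function(i) {
    overlap_fraction(synteny, blocks$chrom[i], blocks$start[i], blocks$end[i],
                     side = "either")
  }, 0)
  keep <- (blocks$end - blocks$start) >= min_span &
    blocks$n_windows >= min_windows &
    blocks$synteny_covered >= min_synteny_frac
  ax_log("filter_he_candidates: %d/%d blocks kept (span >= %d, windows >= %d, synteny >= %.2f)",
         sum(keep), nrow(blocks), min_span, min_windows, min_synteny_frac)
  out <- blocks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Default genome labelling: the part of the chromosome name before the
# first underscore ("S_chr1" -> "S", "BhD_1" -> "BhD").
default_genome_of <- function(chrom) sub("_.*$", "", chrom)

#' Pair DEL and DUP blocks into "HE with replacement" calls
#'
#' A deletion block on one (sub)genome and a duplication block on the
#' homeologous chromosome of the other form one replacement call iff the
#' DEL span, lifted through the synteny chain, overlaps the DUP span
#' reciprocally by at least `reciprocal_overlap_frac`. Each block is used
#' in at most one call; assignment is greedy by overlap with deterministic
#' leftmost tie-breaking. Pairing is done within each sample.
#'
#' @param blocks filtered candidate blocks (DUP and DEL together).
#' @param synteny progenitor-vs-progenitor synteny chain.
#' @param reciprocal_overlap_frac minimum reciprocal overlap (default 0.5).
#' @param genome_of function mapping a chromosome name to its genome label
#'   (used for the call direction).
#' @return list with `calls` (one row per replacement call: direction,
#'   lost/gained coordinates, sample, overlap) and `unpaired` (candidate
#'   blocks not used in any call).
#' @export
pair_replacement_events <- function(blocks, synteny,
                                    reciprocal_overlap_frac = 0.5,
                                    genome_of = default_genome_of) {
  calls <- data.frame(kind = character(0), direction = character(0),
                      lost_chrom = character(0), lost_start = numeric(0),
                      lost_end = numeric(0), gained_chrom = character(0),
                      gained_start = numeric(0), gained_end = numeric(0),
                      sample_id = character(0), overlap_frac = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(blocks) == 0) return(list(calls = calls, unpaired = blocks))
  inv <- invert_chain(synteny)
  lift_auto <- function(chrom, start, end) {
    chain <- if (chrom %in% synteny$qchrom) synteny else inv
    suppressWarnings(lift_interval(chain, chrom, start, end)$mapped)
  }
  used <- rep(FALSE, nrow(blocks))
  for (s in unique(blocks$sample_id)) {
    del_i <- which(blocks$sample_id == s & blocks$mark == "DEL")
    dup_i <- which(blocks$sample_id == s & blocks$mark == "DUP")
    if (length(del_i) == 0 || length(dup_i) == 0) next
    cand <- list()
    for (di in del_i) {
      lifted <- lift_auto(blocks$chrom[di], blocks$start[di], blocks$end[di])
      if (nrow(lifted) == 0) next
      lift_len <- sum(lifted$end - lifted$start)
      for (ui in dup_i) {
        ov <- sum(overlap_len(lifted$start, lifted$end,
                              blocks$start[ui], blocks$end[ui])[
                                lifted$chrom == blocks$chrom[ui]])
        if (ov <= 0) next
        dup_len <- blocks$end[ui] - blocks$start[ui]
        recip <- min(ov / lift_len, ov / dup_len)
        if (recip >= reciprocal_overlap_frac) {
          cand[[length(cand) + 1]] <- data.frame(
            del = di, dup = ui, recip = recip, stringsAsFactors = FALSE)
        }
      }
    }
    if (length(cand) == 0) next
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$recip, blocks$chrom[cand$del],
                       blocks$start[cand$del], blocks$chrom[cand$dup],
                       blocks$start[cand$dup]), , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      di <- cand$del[i]; ui <- cand$dup[i]
      if (used[di] || used[ui]) next
      used[di] <- TRUE; used[ui] <- TRUE
      calls <- rbind(calls, data.frame(
        kind = "replacement",
        direction = paste0(genome_of(blocks$chrom[di]), "_replaced_by_",
                           genome_of(blocks$chrom[ui])),
        lost_chrom = blocks$chrom[di], lost_start = blocks$start[di],
        lost_end = blocks$end[di], gained_chrom = blocks$chrom[ui],
        gained_start = blocks$start[ui], gained_end = blocks$end[ui],
        sample_id = s, overlap_frac = cand$recip[i],
        stringsAsFactors = FALSE))
    }
  }
  rownames(calls) <- NULL
  unpaired <- blocks[!used, , drop = FALSE]
  rownames(unpaired) <- NULL
  list(calls = calls, unpaired = unpaired)
}

#' Consolidate per-sample replacement calls into events
#'
#' Calls from different samples sharing the same direction, the same lost
#' chromosome, and >= `min_recip` reciprocal overlap of their lost regions
#' are reported as one event with a supporting-sample list.
#'
#' @param calls call table from [pair_replacement_events()].
#' @param min_recip minimum reciprocal overlap between lost regions.
#' @return event table with `n_samples` and a comma-separated `samples`
#'   column.
#' @export
consolidate_calls <- function(calls, min_recip = 0.5) {
  if (nrow(calls) == 0) {
    out <- calls[, c("kind", "direction", "lost_chrom", "lost_start",
                     "lost_end", "gained_chrom", "gained_start", "gained_end")]
    out$n_samples <- integer(0); out$samples <- character(0)
    return(out)
  }
  key <- paste(calls$direction, calls$lost_chrom, sep = "\r")
  groups <- split(calls, key)
  rows <- list()
  for (g in groups) {
    g <- g[order(g$lost_start, g$lost_end), , drop = FALSE]
    assigned <- rep(0L, nrow(g)); ev <- 0L
    for (i in seq_len(nrow(g))) {
      if (assigned[i] > 0) next
      ev <- ev + 1L; assigned[i] <- ev
      for (j in seq_len(nrow(g))) {
        if (assigned[j] > 0) next
        ov <- overlap_len(g$lost_start[i], g$lost_end[i],
                          g$lost_start[j], g$lost_end[j])
        recip <- min(ov / (g$lost_end[i] - g$lost_start[i]),
                     ov / (g$lost_end[j] - g$lost_start[j]))
        if (recip >= min_recip) assigned[j] <- ev
      }
    }
    for (e in seq_len(ev)) {
      m <- g[assigned == e, , drop = FALSE]
      rows[[length(rows) + 1]] <- data.frame(
        kind = m$kind[1], direction = m$direction[1],
        lost_chrom = m$lost_chrom[1], lost_start = min(m$lost_start),
        lost_end = max(m$lost_end), gained_chrom = m$gained_chrom[1],
        gained_start = min(m$gained_start), gained_end = max(m$gained_end),
        n_samples = length(unique(m$sample_id)),
        samples = paste(sort(unique(m$sample_id)), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$lost_chrom, out$lost_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Default subgenome labelling for allotetraploid chromosomes: "BhD_1" ->
# "D", "BhS_3" -> "S". Errors on anything else (unlabeled chromosomes).
default_subgenome_of <- function(chrom) {
  pre <- sub("_.*$", "", chrom)
  out <- c(BhD = "D", BhS = "S")[pre]
  if (anyNA(out)) {
    stop("cannot determine subgenome of chromosome(s): ",
         paste(unique(chrom[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  unname(out)
}

#' Detect reciprocal HE swaps from assembly-vs-progenitor anchors
#'
#' In an allotetraploid assembly aligned to the concatenated progenitor
#' genomes, a maximal run of anchors on a BhD chromosome whose targets lie
#' in the S progenitor (or vice versa), flanked on both sides by
#' same-subgenome anchors and spanning at least `min_span`, is a
#' swap candidate. Candidates on the two homeologous chromosomes that
#' mirror each other (each one's target region overlapping the other's
#' query region) are consolidated into one reciprocal HE call; unmirrored
#' candidates are reported separately as one-sided.
#'
#' @param anchors assembly-vs-progenitor anchor table.
#' @param min_span minimum swap span in bp (default 60000).
#' @param subgenome_of function mapping an assembly chromosome name to
#'   `"D"` or `"S"`; errors on unlabeled chromosomes.
#' @param genome_of function mapping a progenitor chromosome name to its
#'   genome label (`"D"` or `"S"`).
#' @return list with `calls` (mirrored reciprocal events, one row per
#'   mirrored pair) and `candidates` (all candidates incl. one-sided, with
#'   a `mirrored` flag).
#' @export
detect_reciprocal_swaps <- function(anchors, min_span = 60000,
                                    subgenome_of = default_subgenome_of,
                                    genome_of = default_genome_of) {
  anchors <- validate_anchors(anchors)
  empty <- data.frame(kind = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      donor_chrom = character(0), donor_start = numeric(0),
                      donor_end = numeric(0), subgenome = character(0),
                      n_anchors = integer(0), mirrored = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(anchors) == 0) return(list(calls = empty, candidates = empty))
  sg <- subgenome_of(anchors$qchrom)
  tg <- genome_of(anchors$tchrom)
  ax_assert(all(tg %in% c("D", "S")),
            "target chromosomes must be labelled D or S")
  cands <- list()
  home <- list()  # majority progenitor chromosome per assembly chromosome
  for (qc in unique(anchors$qchrom)) {
    idx <- which(anchors$qchrom == qc)
    idx <- idx[order(anchors$qstart[idx])]
    mism <- tg[idx] != sg[idx]
    matched_t <- anchors$tchrom[idx][!mism]
    home[[qc]] <- if (length(matched_t) > 0) {
      names(sort(table(matched_t), decreasing = TRUE))[1]
    } else NA_character_
    r <- rle(mism)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      if (k == 1 || k == length(r$values)) next  # not flanked on both sides
      run <- idx[starts[k]:ends[k]]
      span_s <- min(anchors$qstart[run]); span_e <- max(anchors$qend[run])
      if (span_e - span_s < min_span) next
      tc <- names(sort(table(anchors$tchrom[run]), decreasing = TRUE))[1]
      trun <- run[anchors$tchrom[run] == tc]
      cands[[length(cands) + 1]] <- data.frame(
        kind = "reciprocal", chrom = qc, start = span_s, end = span_e,
        donor_chrom = tc, donor_start = min(anchors$tstart[trun]),
        donor_end = max(anchors$tend[trun]),
        subgenome = sg[run[1]], n_anchors = length(run), mirrored = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  if (length(cands) == 0) return(list(calls = empty, candidates = empty))
  cands <- do.call(rbind, cands)
  # mirror pairing: candidate i on subgenome X donating from chromosome c
  # mirrors candidate j on subgenome Y iff i's donor region overlaps j's
  # query region (j's chromosome being homeologous to i's donor) and vice
  # versa.
  n <- nrow(cands)
  mirror_of <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || cands$subgenome[i] == cands$subgenome[j]) next
      hj <- home[[cands$chrom[j]]]; hi <- home[[cands$chrom[i]]]
      ij <- !is.na(hj) && cands$donor_chrom[i] == hj &&
        overlap_len(cands$donor_start[i], cands$donor_end[i],
                    cands$start[j], cands$end[j]) > 0
      ji <- !is.na(hi) && cands$donor_chrom[j] == hi &&
        overlap_len(cands$donor_start[j], cands$donor_end[j],
                    cands$start[i], cands$end[i]) > 0
      if (ij && ji) { mirror_of[i] <- j; cands$mirrored[i] <- TRUE }
    }
  }
  calls <- cands[cands$mirrored & seq_len(n) < mirror_of, , drop = FALSE]
  rownames(calls) <- NULL
  rownames(cands) <- NULL
  list(calls = calls, candidates = cands)
}

#' Run the window-based HE calling pipeline on one depth table
#'
#' classify -> merge -> filter -> pair -> consolidate.
#'
#' @param depth depth table (possibly several samples).
#' @param synteny progenitor-vs-progenitor synteny blocks.
#' @param config configuration list ([allohex_defaults()] overridden as
#'   needed).
#' @return list with `marks`, `blocks`, `candidates`, `calls`, `unpaired`,
#'   `events`.
#' @export
call_hes <- function(depth, synteny, config = allohex_defaults()) {
  marks <- classify_windows(depth,
                            dup_range = c(config$dup_min, config$dup_max),
                            del_range = c(0, config$del_max),
                            trim = config$trimmed_mean)
  blocks <- merge_marked_windows(marks)
  candidates <- filter_he_candidates(blocks, synteny,
                                     min_span = config$min_span,
                                     min_windows = config$min_windows,
                                     min_synteny_frac = config$min_synteny_frac)
  paired <- pair_replacement_events(candidates, synteny,
                                    reciprocal_overlap_frac =
                                      config$reciprocal_overlap_frac)
  events <- consolidate_calls(paired$calls)
  list(marks = marks, blocks = blocks, candidates = candidates,
       calls = paired$calls, unpaired = paired$unpaired, events = events)
}

#' Compare HE outlier-block counts between two candidate references
#'
#' Quantifies the reference-mismatch artifact: the same samples' depth,
#' computed against two alternative concatenated progenitor references,
#' yields more spurious outlier blocks against the more diverged reference.
#'
#' @param depth_a,depth_b depth tables for the same samples against
#'   reference A and reference B.
#' @param synteny_a,synteny_b progenitor-vs-progenitor synteny blocks in
#'   each reference's coordinates (pass the same object when coordinates
#'   coincide).
#' @param config configuration list.
#' @return data.frame sorted by sample with per-reference DUP/DEL filtered
#'   block counts and the paired differences (`A - B`).
#' @export
compare_references <- function(depth_a, depth_b, synteny_a,
                               synteny_b = synteny_a,
                               config = allohex_defaults()) {
  sa <- sort(unique(depth_a$sample_id))
  sb <- sort(unique(depth_b$sample_id))
  if (!identical(sa, sb)) {
    stop("sample sets differ between references; only in A: ",
         paste(setdiff(sa, sb), collapse = ","), "; only in B: ",
         paste(setdiff(sb, sa), collapse = ","), call. = FALSE)
  }
  count_blocks <- function(depth, synteny) {
    cand <- call_hes(depth, synteny, config)$candidates
    out <- data.frame(sample_id = sa, n_dup = 0L, n_del = 0L,
                      stringsAsFactors = FALSE)
    if (nrow(cand) > 0) {
      tab <- table(factor(cand$sample_id, levels = sa),
                   factor(cand$mark, levels = c("DUP", "DEL")))
      out$n_dup <- as.integer(tab[, "DUP"])
      out$n_del <- as.integer(tab[, "DEL"])
    }
    out
  }
  ca <- count_blocks(depth_a, synteny_a)
  cb <- count_blocks(depth_b, synteny_b)
  data.frame(sample_id = sa,
             n_dup_a = ca$n_dup, n_del_a = ca$n_del,
             n_dup_b = cb$n_dup, n_del_b = cb$n_del,
             dup_diff = ca$n_dup - cb$n_dup,
             del_diff = ca$n_del - cb$n_del,
             stringsAsFactors = FALSE)
}
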