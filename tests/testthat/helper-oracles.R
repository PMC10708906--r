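# Independent brute-force oracles used to check the package's
# implementations on small instances. These deliberately share no code
# with the package: the codon enumerator is recursive, the chaining oracle
# builds the transitive closure by boolean matrix powering.

GC_TAB <- Biostrings::GENETIC_CODE
ORACLE_BASES <- c("A", "C", "G", "T")

# synonymous site count of one codon (stop-creating changes nonsynonymous)
oracle_syn_sites <- function(codon) {
  cs <- strsplit(codon, "")[[1]]
  aa <- GC_TAB[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(ORACLE_BASES, cs[pos])) {
      alt <- cs
      alt[pos] <- b
      if (GC_TAB[[paste(alt, collapse = "")]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# pathway-averaged (synonymous, nonsynonymous) step counts between two
# codons: recursive enumeration of all minimal pathways; pathways through
# stop codons are dropped when a stop-free one exists; steps to/from a
# stop count as nonsynonymous.
oracle_path_counts <- function(from, to) {
  walk <- function(cur, tgt) {
    cv <- strsplit(cur, "")[[1]]
    tv <- strsplit(tgt, "")[[1]]
    dp <- which(cv != tv)
    if (length(dp) == 0) return(list(list(s = 0, n = 0, stop = FALSE)))
    out <- list()
    for (pos in dp) {
      nv <- cv
      nv[pos] <- tv[pos]
      nxt <- paste(nv, collapse = "")
      syn <- GC_TAB[[cur]] != "*" && GC_TAB[[nxt]] != "*" &&
        GC_TAB[[cur]] == GC_TAB[[nxt]]
      via_stop <- GC_TAB[[nxt]] == "*" && nxt != tgt
      for (r in walk(nxt, tgt)) {
        out[[length(out) + 1]] <- list(s = r$s + syn, n = r$n + !syn,
                                       stop = r$stop || via_stop)
      }
    }
    out
  }
  paths <- walk(from, to)
  ok <- !vapply(paths, `[[`, TRUE, "stop")
  use <- if (any(ok)) paths[ok] else paths
  c(s = mean(vapply(use, `[[`, 0, "s")),
    n = mean(vapply(use, `[[`, 0, "n")))
}

# block membership as the transitive closure of the pairwise "linkable"
# relation, via boolean matrix powering; returns a component id per anchor
oracle_chain_components <- function(anchors, gap, both_sides = TRUE) {
  n <- nrow(anchors)
  adj <- diag(n) > 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (anchors$qchrom[i] != anchors$qchrom[j] ||
          anchors$tchrom[i] != anchors$tchrom[j] ||
          anchors$orientation[i] != anchors$orientation[j]) next
      qgap <- max(anchors$qstart[j] - anchors$qend[i],
                  anchors$qstart[i] - anchors$qend[j], 0)
      tgap <- max(anchors$tstart[j] - anchors$tend[i],
                  anchors$tstart[i] - anchors$tend[j], 0)
      adj[i, j] <- qgap < gap && (!both_sides || tgap < gap)
    }
  }
  reach <- adj
  repeat {
    nxt <- (reach %*% reach > 0) | reach
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  first <- apply(reach, 1, function(r) min(which(r)))
  match(first, unique(first))
}

# map each input anchor to the id of the block link_anchors() placed it in
# (valid when anchors have no query overlaps, so none were merged)
blocks_membership <- function(blocks, anchors) {
  vapply(seq_len(nrow(anchors)), function(i) {
    hit <- which(vapply(seq_len(nrow(blocks)), function(b) {
      a <- blocks$anchors[[b]]
      any(a$qchrom == anchors$qchrom[i] & a$qstart == anchors$qstart[i] &
            a$qend == anchors$qend[i] & a$tchrom == anchors$tchrom[i])
    }, TRUE))
    stopifnot(length(hit) == 1)
    hit
  }, 1L)
}

# quick TSV fixture writer
write_tsv_fixture <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
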