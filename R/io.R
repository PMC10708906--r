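# Readers and writers for every on-disk format the pipeline touches.
# All tabular formats are plain TSV with a header line; coordinates are
# 0-based half-open throughout.

#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased on read and validated against the `{A,C,G,T,N}`
#' alphabet. Header lines are truncated at the first whitespace.
#'
#' @param path FASTA file (plain or gzip).
#' @return named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  dup <- unique(nm[duplicated(nm)])
  if (length(dup) > 0) {
    stop("duplicate sequence names in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  w <- Biostrings::width(seqs)
  if (any(w == 0)) {
    stop("empty sequence in ", path, ": ", nm[which(w == 0)[1]], call. = FALSE)
  }
  x <- toupper(as.character(seqs))
  names(x) <- nm
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("sequence ", nm[which(bad)[1]], " contains characters outside {A,C,G,T,N}",
         call. = FALSE)
  }
  ax_log("read_fasta: %d sequences, %d bp total from %s",
         length(x), sum(nchar(x)), path)
  x
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param path output file.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 80) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a BED3(+) file of genomic intervals
#'
#' BED is 0-based half-open, which is also the internal convention, so no
#' coordinate shift is applied. Input order is preserved.
#'
#' @param path BED file, no header.
#' @return data.frame with columns `chrom`, `start`, `end` and, when
#'   present in the file, `name`.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  ax_assert(ncol(df) >= 3, paste0(path, ": BED needs at least 3 columns"))
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.numeric(df[[2]]),
                    end = as.numeric(df[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4) out$name <- as.character(df[[4]])
  bad <- which(!(out$start >= 0 & out$start < out$end))
  if (length(bad) > 0) {
    stop(path, ": invalid interval at line ", bad[1],
         " (start must satisfy 0 <= start < end)", call. = FALSE)
  }
  out
}

#' Write intervals as BED
#' @param df interval table (`chrom`, `start`, `end`, optional `name`).
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df, "BED")
  cols <- intersect(c("chrom", "start", "end", "name"), names(df))
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-window mean depth table
#'
#' The TSV must carry the header `chrom  start  end  sample_id  mean_depth`.
#' Windows must tile each (sample, chromosome) without overlap; all full
#' windows must have width `window_size`. One trailing shorter window per
#' chromosome is accepted and flagged `partial`.
#'
#' @param path TSV file.
#' @param window_size tiling window width in bp (default 10000, i.e. the
#'   10 kb non-overlapping windows used for HE detection).
#' @return data.frame `chrom, start, end, sample_id, mean_depth, partial`,
#'   sorted by sample, chromosome, start.
#' @export
read_depth_table <- function(path, window_size = 10000) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "sample_id", "mean_depth")
  ax_assert(all(need %in% names(df)),
            paste0(path, ": depth table needs columns ",
                   paste(need, collapse = ", ")))
  df <- df[, need]
  validate_intervals(df, "depth window")
  if (any(df$mean_depth < 0)) {
    stop(path, ": negative mean_depth at row ",
         which(df$mean_depth < 0)[1], call. = FALSE)
  }
  validate_depth_windows(df, window_size, where = path)
}

# Shared window-tiling validation for depth tables (used by the reader and
# by simulated in-memory tables). Adds/normalises the `partial` flag.
validate_depth_windows <- function(df, window_size, where = "depth table") {
  key <- paste(df$sample_id, df$chrom, sep = "\r")
  ord <- order(df$sample_id, df$chrom, df$start)
  df <- df[ord, , drop = FALSE]
  df$partial <- FALSE
  for (k in unique(key[ord])) {
    idx <- which(paste(df$sample_id, df$chrom, sep = "\r") == k)
    s <- df$start[idx]; e <- df$end[idx]
    if (length(idx) > 1 && any(s[-1] < e[-length(e)])) {
      stop(where, ": overlapping windows on ", df$chrom[idx[1]],
           " for sample ", df$sample_id[idx[1]], call. = FALSE)
    }
    w <- e - s
    if (any(w > window_size)) {
      stop(where, ": window wider than window_size on ", df$chrom[idx[1]],
           call. = FALSE)
    }
    short <- which(w < window_size)
    if (length(short) > 0) {
      if (!identical(short, length(idx))) {
        stop(where, ": short window that is not the trailing window on ",
             df$chrom[idx[1]], call. = FALSE)
      }
      df$partial[idx[short]] <- TRUE
    }
  }
  rownames(df) <- NULL
  ax_log("depth table: %d windows, %d samples, %d partial",
         nrow(df), length(unique(df$sample_id)), sum(df$partial))
  df
}

#' Write a depth table
#' @param df depth table as produced by [read_depth_table()] or
#'   [simulate_depth()].
#' @param path output TSV.
#' @export
write_depth_table <- function(df, path) {
  cols <- c("chrom", "start", "end", "sample_id", "mean_depth")
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read whole-genome alignment anchors
#'
#' A PAF-compatible tabular subset with header
#' `qchrom qstart qend tchrom tstart tend orientation identity`.
#'
#' @param path TSV file.
#' @return validated anchor table.
#' @export
read_anchors <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_anchors(df)
}

#' Validate an anchor table
#' @param df anchor table.
#' @return `df`, columns coerced, invisibly usable.
#' @export
validate_anchors <- function(df) {
  need <- c("qchrom", "qstart", "qend", "tchrom", "tstart", "tend",
            "orientation")
  ax_assert(all(need %in% names(df)),
            paste0("anchor table needs columns ", paste(need, collapse = ", ")))
  if (!"identity" %in% names(df)) df$identity <- NA_real_
  for (col in c("qstart", "qend", "tstart", "tend", "identity")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  bad <- which(!(df$qstart >= 0 & df$qstart < df$qend &
                   df$tstart >= 0 & df$tstart < df$tend))
  if (length(bad) > 0) {
    stop("invalid anchor at row ", bad[1], ": spans must be non-empty",
         call. = FALSE)
  }
  ok <- df$orientation %in% c("same", "inverted")
  if (!all(ok)) {
    stop("invalid anchor orientation at row ", which(!ok)[1],
         " (must be 'same' or 'inverted')", call. = FALSE)
  }
  idok <- is.na(df$identity) | (df$identity >= 0 & df$identity <= 1)
  ax_assert(all(idok), "anchor identity must lie in [0, 1]")
  df
}

#' Write anchors as TSV
#' @param df anchor table.
#' @param path output TSV.
#' @export
write_anchors <- function(df, path) {
  cols <- c("qchrom", "qstart", "qend", "tchrom", "tstart", "tend",
            "orientation", "identity")
  utils::write.table(df[, intersect(cols, names(df))], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix (TPM)
#'
#' TSV with a `gene_id` column followed by one column per sample.
#'
#' @param path TSV file.
#' @return numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ax_assert("gene_id" %in% names(df), paste0(path, ": needs a gene_id column"))
  ax_assert(!anyDuplicated(df$gene_id), paste0(path, ": duplicate gene ids"))
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene_id
  if (any(m < 0)) stop(path, ": negative TPM values", call. = FALSE)
  m
}

#' Write an expression matrix as TSV
#' @param m numeric matrix, rownames = gene ids.
#' @param path output TSV.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with header `sample_id tissue condition replicate`. The
#' (tissue, condition, replicate) triple must be unique.
#'
#' @param path TSV file.
#' @return data.frame of sample metadata.
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "condition", "replicate")
  ax_assert(all(need %in% names(df)),
            paste0(path, ": metadata needs columns ",
                   paste(need, collapse = ", ")))
  ax_assert(!anyDuplicated(df$sample_id), "duplicate sample ids in metadata")
  trip <- paste(df$tissue, df$condition, df$replicate)
  ax_assert(!anyDuplicated(trip),
            "duplicate (tissue, condition, replicate) triple in metadata")
  ax_assert(all(df$replicate >= 1), "replicate numbers must be >= 1")
  df
}

#' Read a homeolog pair table
#'
#' TSV with at least `bhd_gene` and `bhs_gene` columns.
#'
#' @param path TSV file.
#' @return data.frame of pairs.
#' @export
read_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ax_assert(all(c("bhd_gene", "bhs_gene") %in% names(df)),
            paste0(path, ": pair table needs bhd_gene and bhs_gene columns"))
  df
}

#' Write / read a simulation truth ledger (JSON)
#' @param truth list, as emitted by the simulator.
#' @param path JSON file.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Default analysis configuration
#'
#' One flat key-value set holding every tunable threshold of the pipeline.
#' [read_config()] validates a JSON file against this schema; unknown keys
#' are errors because a silently ignored typo in a threshold would
#' invalidate HE calls.
#'
#' @return named list of defaults.
#' @export
allohex_defaults <- function() {
  list(
    window_size = 10000,        # depth window width (bp)
    link_gap = 20000,           # max gap when chaining anchors (bp)
    link_gap_both_sides = TRUE, # require the gap rule on query AND target
    dup_min = 1.5,              # duplication ratio range [dup_min, dup_max]
    dup_max = 5.0,
    del_max = 0.5,              # deletion ratio range [0, del_max]
    min_span = 60000,           # minimum HE candidate span (bp)
    min_windows = 6,            # minimum windows per HE candidate
    min_synteny_frac = 0.5,     # required synteny coverage of a candidate
    reciprocal_overlap_frac = 0.5, # DEL/DUP pairing reciprocal overlap
    trimmed_mean = 0,           # trim fraction for chromosome mean depth
    te_flank = 2000,            # flank (bp) for TE density near genes
    heb_fold = 2.0,             # >2-fold TPM rule for expression bias
    heb_eps = 0.1,              # pseudocount inside log2 ratios
    tpm_threshold = 1.0,        # low-expression filter threshold
    kaks_min_codons = 30,       # minimum alignment length for dating use
    ks_min_n = 30,              # minimum non-zero Ks values for peak fitting
    rate = 6.5e-9               # substitutions/site/year for T = Ks/(2r)
  )
}

#' Read and validate a JSON configuration file
#'
#' @param path JSON file of key-value overrides.
#' @return full configuration list (defaults overridden by the file).
#' @export
read_config <- function(path) {
  defaults <- allohex_defaults()
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration keys in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- utils::modifyList(defaults, cfg)
  ax_log("config: %s", paste(names(out), unlist(out), sep = "=", collapse = " "))
  out
}
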