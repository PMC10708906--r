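# Seeded simulator: generates every input the pipeline consumes — two
# diverged progenitor genomes, an allotetraploid with planted HE events,
# depth tables whose mean scales with copy number and decays with
# read-to-reference divergence (the mismapping artifact), codon pairs with
# controlled Ks, and replicated TPM matrices with planted bias, condition
# and TE effects — together with a ground-truth ledger emitted before any
# noise is applied.

SIM_BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Defaults describe the emulated study system: two subgenomes of a few
#' megabase-scale chromosomes, ~30x resequencing coverage, a drought
#' experiment with two tissues x two conditions x three replicates, ~10%
#' of homeolog pairs biased at 4-fold, and a Ks target at the recent-origin
#' scale (0.0035).
#'
#' @param seed integer RNG seed (mandatory; all `simulate_*` output is
#'   byte-identical for identical configurations).
#' @param n_chromosomes chromosomes per subgenome.
#' @param chrom_length chromosome length in bp (multiple of `window_size`).
#' @param window_size depth window width in bp.
#' @param progenitor_divergence total substitutions/site between the two
#'   progenitor lineages (each lineage accrues half); must be < 0.75
#'   (Jukes-Cantor saturation).
#' @param he_events data.frame of planted events (`kind` in
#'   `{"replacement","reciprocal"}`, `lost` in `{"D","S"}` for
#'   replacements, `chrom` index, `start`, `end`) or `NULL`.
#' @param coverage mean sequencing depth (x).
#' @param depth_noise `"none"`, `"poisson"` or `"negbin"`. Noise acts on
#'   the per-window read count (`expected * window_size / read_length`
#'   reads on average), the quantity a mapper actually delivers; the
#'   window mean depth is the noisy count rescaled.
#' @param negbin_theta dispersion for `"negbin"` noise.
#' @param read_length read length (bp) used to convert window depth to
#'   read counts for the noise models.
#' @param mismap_k mismapping coefficient: expected depth decays as
#'   `exp(-k * d)` with reference divergence `d`. The default 20 puts
#'   d = 0.05 at `e^-1` of nominal coverage, inside deletion-call
#'   territory.
#' @param anchor_tile tile size for emitted progenitor-vs-progenitor
#'   anchors.
#' @param assembly_anchor_tile tile size for assembly-vs-progenitor
#'   anchors.
#' @param gene_spacing,gene_length regular gene grid geometry (bp).
#' @param te_flank flank used when realising TE densities as intervals.
#' @param n_gene_pairs homeolog pairs in the expression simulation.
#' @param frac_biased fraction of pairs with planted expression bias.
#' @param bias_fold planted fold effect for biased pairs.
#' @param frac_flip fraction of biased pairs whose direction flips under
#'   the treatment condition.
#' @param expression_sd replicate noise sd on the log2 scale.
#' @param base_log2_tpm,sd_gene gene-level log2 TPM distribution.
#' @param n_replicates biological replicates per group.
#' @param tissues,conditions experimental design labels (the second
#'   condition is the treatment).
#' @param te_effect TE-density shift planted on submissive genes.
#' @param te_expr_cor planted correlation between TE density and log
#'   expression.
#' @param n_codon_pairs,n_codons,ks_target codon-pair simulation geometry
#'   and target Ks.
#' @return validated configuration list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_chromosomes = 2,
                       chrom_length = 2e6,
                       window_size = 1e4,
                       progenitor_divergence = 0.10,
                       he_events = NULL,
                       coverage = 30,
                       depth_noise = "none",
                       negbin_theta = 10,
                       read_length = 150,
                       mismap_k = 20,
                       anchor_tile = 1e5,
                       assembly_anchor_tile = 1e4,
                       gene_spacing = 1e4,
                       gene_length = 1200,
                       te_flank = 2000,
                       n_gene_pairs = 2000,
                       frac_biased = 0.1,
                       bias_fold = 4,
                       frac_flip = 0.05,
                       expression_sd = 0.2,
                       base_log2_tpm = log2(20),
                       sd_gene = 1.5,
                       n_replicates = 3,
                       tissues = c("leaf", "root"),
                       conditions = c("well_watered", "drought"),
                       te_effect = 0.1,
                       te_expr_cor = -0.3,
                       n_codon_pairs = 1000,
                       n_codons = 2000,
                       ks_target = 0.0035) {
  ax_assert(!missing(seed) && is.numeric(seed) && length(seed) == 1,
            "seed is mandatory")
  cfg <- as.list(environment())
  ax_assert(cfg$chrom_length %% cfg$window_size == 0,
            "chrom_length must be a multiple of window_size")
  ax_assert(cfg$progenitor_divergence >= 0 && cfg$progenitor_divergence < 0.75,
            "progenitor_divergence must lie in [0, 0.75) (saturation)")
  ax_assert(cfg$coverage > 0, "coverage must be positive")
  ax_assert(cfg$depth_noise %in% c("none", "poisson", "negbin"),
            "depth_noise must be none/poisson/negbin")
  for (f in c("frac_biased", "frac_flip")) {
    ax_assert(cfg[[f]] >= 0 && cfg[[f]] <= 1,
              paste(f, "must lie in [0, 1]"))
  }
  ax_assert(all(cfg$ks_target >= 0 & cfg$ks_target < 5),
            "ks_target beyond saturation")
  class(cfg) <- "sim_config"
  cfg
}

int_to_seq <- function(x) paste(SIM_BASES[x], collapse = "")

mutate_lineage <- function(x, rate) {
  if (rate <= 0) return(x)
  idx <- which(stats::runif(length(x)) < rate)
  if (length(idx) > 0) {
    shift <- sample.int(3, length(idx), replace = TRUE)
    x[idx] <- ((x[idx] - 1L + shift) %% 4L) + 1L
  }
  x
}

#' Simulate two diverged progenitor genomes
#'
#' A common ancestor sequence per chromosome is mutated independently in
#' each lineage at rate `progenitor_divergence / 2` under a uniform
#' substitution model. Emitted anchors are exact (the simulation knows the
#' true homology): one anchor per `anchor_tile`, with per-tile identity
#' measured from the realised sequences. Gene models are placed on a
#' regular grid.
#'
#' @param config a [sim_config()].
#' @return list with `seqs_d`, `seqs_s` (named sequence vectors, chroms
#'   `D_chr*` / `S_chr*`), `anchors` (D-vs-S anchor table), `genes`,
#'   `chrom_lengths`, `realized_divergence` (per chromosome), `config`.
#' @export
simulate_progenitors <- function(config) {
  set.seed(config$seed)
  L <- config$chrom_length
  nchr <- config$n_chromosomes
  d <- config$progenitor_divergence
  seqs_d <- character(nchr); seqs_s <- character(nchr)
  anchors <- list(); realized <- numeric(nchr)
  for (i in seq_len(nchr)) {
    anc <- sample.int(4L, L, replace = TRUE)
    dv <- mutate_lineage(anc, d / 2)
    sv <- mutate_lineage(anc, d / 2)
    realized[i] <- mean(dv != sv)
    seqs_d[i] <- int_to_seq(dv)
    seqs_s[i] <- int_to_seq(sv)
    starts <- seq(0, L - config$anchor_tile, by = config$anchor_tile)
    ident <- vapply(starts, function(s) {
      sel <- (s + 1):(s + config$anchor_tile)
      1 - mean(dv[sel] != sv[sel])
    }, 0)
    anchors[[i]] <- data.frame(
      qchrom = paste0("D_chr", i), qstart = starts,
      qend = starts + config$anchor_tile,
      tchrom = paste0("S_chr", i), tstart = starts,
      tend = starts + config$anchor_tile,
      orientation = "same", identity = ident, stringsAsFactors = FALSE)
  }
  names(seqs_d) <- paste0("D_chr", seq_len(nchr))
  names(seqs_s) <- paste0("S_chr", seq_len(nchr))
  gene_starts <- seq(config$te_flank,
                     L - config$gene_length - config$te_flank,
                     by = config$gene_spacing)
  genes <- do.call(rbind, lapply(c(names(seqs_d), names(seqs_s)), function(ch) {
    data.frame(chrom = ch, start = gene_starts,
               end = gene_starts + config$gene_length,
               gene_id = sprintf("%s_g%04d", ch, seq_along(gene_starts)),
               stringsAsFactors = FALSE)
  }))
  chrom_lengths <- stats::setNames(rep(L, 2 * nchr),
                                   c(names(seqs_d), names(seqs_s)))
  list(seqs_d = seqs_d, seqs_s = seqs_s,
       anchors = do.call(rbind, anchors), genes = genes,
       chrom_lengths = chrom_lengths,
       realized_divergence = realized, config = config)
}

validate_he_events <- function(events, config) {
  if (is.null(events) || nrow(events) == 0) {
    return(data.frame(kind = character(0), lost = character(0),
                      chrom = integer(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  }
  ax_assert(all(c("kind", "chrom", "start", "end") %in% names(events)),
            "he_events needs kind/chrom/start/end columns")
  if (!"lost" %in% names(events)) events$lost <- NA_character_
  ax_assert(all(events$kind %in% c("replacement", "reciprocal")),
            "he_events kind must be replacement or reciprocal")
  ax_assert(all(events$kind != "replacement" |
                  events$lost %in% c("D", "S")),
            "replacement events need lost = D or S")
  ax_assert(all(events$start >= 0 & events$end <= config$chrom_length &
                  events$start < events$end),
            "he_events out of chromosome bounds")
  repl <- events$kind == "replacement"
  ax_assert(all(events$start[repl] %% config$window_size == 0 &
                  events$end[repl] %% config$window_size == 0),
            "replacement events must start/end on window boundaries")
  # events share the homeologous coordinate frame: forbid overlap per
  # chromosome index regardless of which side is lost
  for (ch in unique(events$chrom)) {
    e <- events[events$chrom == ch, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
      stop("overlapping he_events on chromosome ", ch, call. = FALSE)
    }
  }
  events
}

#' Build the allotetraploid from the progenitors and planted HE events
#'
#' Replacement events overwrite the lost subgenome's segment with a copy of
#' the homeologous segment (donor copy number becomes 4 haploid
#' equivalents, the lost segment 0); reciprocal events exchange the
#' segments, leaving copy numbers unchanged. The truth ledger records the
#' exact breakpoints before any downstream noise.
#'
#' @param prog output of [simulate_progenitors()].
#' @param he_events planted events (see [sim_config()]); defaults to the
#'   configuration's.
#' @return list with `seqs` (BhD_*/BhS_* sequences), `cn_truth` (copy
#'   number deviations in reference coordinates), `assembly_anchors`
#'   (allotetraploid-vs-progenitors), `events`, `config`.
#' @export
simulate_allotetraploid <- function(prog, he_events = prog$config$he_events) {
  config <- prog$config
  set.seed(config$seed + 1L)
  events <- validate_he_events(he_events, config)
  nchr <- config$n_chromosomes
  L <- config$chrom_length
  seqs <- c(stats::setNames(prog$seqs_d, paste0("BhD_", seq_len(nchr))),
            stats::setNames(prog$seqs_s, paste0("BhS_", seq_len(nchr))))
  cn <- list()
  # swapped_regions: per allotetraploid chromosome, regions whose sequence
  # now originates from the other progenitor (drives assembly anchors)
  swapped <- list()
  add_swap <- function(chrom, start, end) {
    swapped[[length(swapped) + 1]] <<- data.frame(
      chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(events))) {
    ev <- events[k, ]
    bhd <- paste0("BhD_", ev$chrom); bhs <- paste0("BhS_", ev$chrom)
    dch <- paste0("D_chr", ev$chrom); sch <- paste0("S_chr", ev$chrom)
    s <- ev$start; e <- ev$end
    if (ev$kind == "replacement") {
      if (ev$lost == "S") {
        substr(seqs[[bhs]], s + 1, e) <- substr(seqs[[bhd]], s + 1, e)
        cn[[length(cn) + 1]] <- data.frame(
          chrom = c(sch, dch), start = s, end = e, copy_number = c(0, 4),
          stringsAsFactors = FALSE)
        add_swap(bhs, s, e)
      } else {
        substr(seqs[[bhd]], s + 1, e) <- substr(seqs[[bhs]], s + 1, e)
        cn[[length(cn) + 1]] <- data.frame(
          chrom = c(dch, sch), start = s, end = e, copy_number = c(0, 4),
          stringsAsFactors = FALSE)
        add_swap(bhd, s, e)
      }
    } else {  # reciprocal: exchange segments, copy numbers unchanged
      seg_d <- substr(seqs[[bhd]], s + 1, e)
      seg_s <- substr(seqs[[bhs]], s + 1, e)
      substr(seqs[[bhd]], s + 1, e) <- seg_s
      substr(seqs[[bhs]], s + 1, e) <- seg_d
      add_swap(bhd, s, e); add_swap(bhs, s, e)
    }
  }
  cn_truth <- if (length(cn) > 0) do.call(rbind, cn) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               copy_number = numeric(0), stringsAsFactors = FALSE)
  swapped <- if (length(swapped) > 0) do.call(rbind, swapped) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               stringsAsFactors = FALSE)
  # assembly anchors: tile each allotetraploid chromosome; target its home
  # progenitor chromosome, except tiles inside swapped regions, whose
  # sequence truly originates from (and therefore aligns to) the other
  # progenitor
  tile <- config$assembly_anchor_tile
  anchors <- list()
  for (i in seq_len(nchr)) {
    for (sg in c("D", "S")) {
      qc <- paste0("Bh", sg, "_", i)
      home <- paste0(sg, "_chr", i)
      other <- paste0(setdiff(c("D", "S"), sg), "_chr", i)
      starts <- seq(0, L - tile, by = tile)
      sw <- swapped[swapped$chrom == qc, , drop = FALSE]
      inside <- rep(FALSE, length(starts))
      for (r in seq_len(nrow(sw))) {
        inside <- inside | (starts >= sw$start[r] & starts + tile <= sw$end[r])
      }
      anchors[[length(anchors) + 1]] <- data.frame(
        qchrom = qc, qstart = starts, qend = starts + tile,
        tchrom = ifelse(inside, other, home), tstart = starts,
        tend = starts + tile, orientation = "same", identity = 1,
        stringsAsFactors = FALSE)
    }
  }
  list(seqs = seqs, cn_truth = cn_truth,
       assembly_anchors = do.call(rbind, anchors),
       events = events, swapped = swapped,
       chrom_lengths = prog$chrom_lengths, config = config)
}

#' Simulate a per-window depth table against a candidate reference
#'
#' Expected depth per window is
#' `coverage * (copy_number / 2) * exp(-k * d)` where `d` is the local
#' read-to-reference divergence (0 for the matched reference) and `k` the
#' mismapping coefficient; noise is then applied per the configured model.
#'
#' @param atet output of [simulate_allotetraploid()].
#' @param sample_id sample name written into the table.
#' @param divergence `NULL` (matched reference), a scalar applied
#'   everywhere, or a patch table `chrom, start, end, d`.
#' @param noise `"none"`, `"poisson"` or `"negbin"` (defaults to the
#'   configuration's `depth_noise`).
#' @param seed RNG seed for the noise draw (defaults to the configuration
#'   seed; pass distinct seeds for replicate draws).
#' @return depth table (`chrom, start, end, sample_id, mean_depth,
#'   partial`) in reference (concatenated progenitor) coordinates.
#' @export
simulate_depth <- function(atet, sample_id = "sim1", divergence = NULL,
                           noise = atet$config$depth_noise,
                           seed = atet$config$seed + 2L) {
  config <- atet$config
  ax_assert(config$coverage > 0, "coverage must be positive")
  set.seed(seed)
  W <- config$window_size
  rows <- lapply(names(atet$chrom_lengths), function(ch) {
    L <- atet$chrom_lengths[[ch]]
    starts <- seq(0, L - W, by = W)
    cn <- rep(2, length(starts))
    tr <- atet$cn_truth[atet$cn_truth$chrom == ch, , drop = FALSE]
    for (r in seq_len(nrow(tr))) {
      sel <- starts >= tr$start[r] & starts + W <= tr$end[r]
      cn[sel] <- tr$copy_number[r]
    }
    dloc <- rep(0, length(starts))
    if (!is.null(divergence)) {
      if (is.data.frame(divergence)) {
        dv <- divergence[divergence$chrom == ch, , drop = FALSE]
        for (r in seq_len(nrow(dv))) {
          mid <- starts + W / 2
          dloc[mid > dv$start[r] & mid < dv$end[r]] <- dv$d[r]
        }
      } else {
        dloc <- rep(divergence, length(starts))
      }
    }
    expected <- config$coverage * (cn / 2) * exp(-config$mismap_k * dloc)
    # noise on the per-window READ COUNT, then rescaled to mean depth: a
    # 10 kb window mean aggregates ~W/read_length reads, so its sampling
    # noise is far smaller than one Poisson draw at the depth scale
    rpw <- config$window_size / config$read_length  # reads per window per x
    depth <- switch(noise,
                    none = expected,
                    poisson = stats::rpois(length(expected),
                                           expected * rpw) / rpw,
                    negbin = stats::rnbinom(length(expected),
                                            mu = expected * rpw,
                                            size = config$negbin_theta) / rpw,
                    stop("unknown noise model: ", noise))
    data.frame(chrom = ch, start = starts, end = starts + W,
               sample_id = sample_id, mean_depth = as.numeric(depth),
               partial = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Place divergence patches on the reference, avoiding given regions
#'
#' Used to emulate a mismatched reference whose divergence from the sample
#' is concentrated in patches (creating spurious deletion blocks).
#'
#' @param atet output of [simulate_allotetraploid()].
#' @param n_patches number of patches.
#' @param patch_length patch length (bp, window-aligned).
#' @param d divergence inside the patches.
#' @param avoid interval table (e.g. the copy-number truth) that patches
#'   must not touch.
#' @param seed RNG seed for patch placement.
#' @return patch table `chrom, start, end, d`.
#' @export
divergence_patches <- function(atet, n_patches = 10, patch_length = 1e5,
                               d = 0.05, avoid = atet$cn_truth,
                               seed = atet$config$seed + 3L) {
  config <- atet$config
  set.seed(seed)
  W <- config$window_size
  cand <- do.call(rbind, lapply(names(atet$chrom_lengths), function(ch) {
    L <- atet$chrom_lengths[[ch]]
    starts <- seq(0, L - patch_length, by = W)
    data.frame(chrom = ch, start = starts, end = starts + patch_length,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(avoid) && nrow(avoid) > 0) {
    ok <- vapply(seq_len(nrow(cand)), function(i) {
      a <- avoid[avoid$chrom == cand$chrom[i], , drop = FALSE]
      nrow(a) == 0 ||
        all(overlap_len(cand$start[i] - W, cand$end[i] + W,
                        a$start, a$end) == 0)
    }, TRUE)
    cand <- cand[ok, , drop = FALSE]
  }
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  chosen <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    if (nrow(chosen) >= n_patches) break
    conflict <- any(chosen$chrom == cand$chrom[i] &
                      overlap_len(chosen$start, chosen$end,
                                  cand$start[i], cand$end[i]) > 0)
    if (!conflict) chosen <- rbind(chosen, cand[i, ])
  }
  ax_assert(nrow(chosen) == n_patches,
            "could not place the requested number of patches")
  chosen <- chosen[order(chosen$chrom, chosen$start), , drop = FALSE]
  chosen$d <- d
  rownames(chosen) <- NULL
  chosen
}

#' Simulate aligned codon pairs with controlled Ks
#'
#' Codons are drawn from fourfold-degenerate families without
#' first-position degeneracy (GGN, CCN, GCN, ACN, GTN, TCN), so every
#' third position is a synonymous site and the NG86 synonymous site count
#' equals the codon count. Per pair, the number of synonymous substitutions
#' is drawn Poisson with mean `n_codons * p`, where `p` inverts the
#' Jukes-Cantor correction of the target Ks; substitutions are placed at
#' distinct random third positions. Nonsynonymous sites are untouched.
#'
#' @param config a [sim_config()]; uses `n_codon_pairs`, `n_codons`,
#'   `ks_target` (recycled over pairs).
#' @param seed RNG seed.
#' @return list with `pairs` (`pair_id, gene_a, gene_b, true_ks, n_subs`),
#'   `seq_a`, `seq_b` (aligned CDS vectors).
#' @export
simulate_codon_pairs <- function(config, seed = config$seed + 4L) {
  set.seed(seed)
  n_pairs <- config$n_codon_pairs
  n_cod <- config$n_codons
  targets <- rep_len(config$ks_target, n_pairs)
  fam <- c("GG", "CC", "GC", "AC", "GT", "TC")
  p_target <- 0.75 * (1 - exp(-4 * targets / 3))
  ax_assert(all(p_target < 0.75), "ks_target beyond saturation")
  seq_a <- character(n_pairs); seq_b <- character(n_pairs)
  n_subs <- integer(n_pairs)
  for (i in seq_len(n_pairs)) {
    pre <- sample(fam, n_cod, replace = TRUE)
    third <- sample(SIM_BASES, n_cod, replace = TRUE)
    a3 <- third
    m <- min(stats::rpois(1, n_cod * p_target[i]), n_cod)
    b3 <- a3
    if (m > 0) {
      pos <- sample.int(n_cod, m)
      b3[pos] <- vapply(a3[pos], function(b) {
        sample(setdiff(SIM_BASES, b), 1)
      }, "")
    }
    n_subs[i] <- m
    seq_a[i] <- paste(paste0(pre, a3), collapse = "")
    seq_b[i] <- paste(paste0(pre, b3), collapse = "")
  }
  pairs <- data.frame(pair_id = sprintf("pair%05d", seq_len(n_pairs)),
                      gene_a = sprintf("gA%05d", seq_len(n_pairs)),
                      gene_b = sprintf("gB%05d", seq_len(n_pairs)),
                      true_ks = targets, n_subs = n_subs,
                      stringsAsFactors = FALSE)
  list(pairs = pairs, seq_a = seq_a, seq_b = seq_b)
}

#' Simulate a replicated homeolog expression experiment with planted bias
#'
#' Per pair, a gene-level log2 TPM is drawn; a planted fraction of pairs
#' receives a `+log2(bias_fold)` shift on one homeolog (the dominant one);
#' flip-flagged pairs reverse direction under the treatment condition.
#' Tissue and condition shifts apply to both homeologs (they move
#' expression, not the homeolog ratio). Replicates are i.i.d. around the
#' group mean with sd `expression_sd` (log2 scale). TE densities are drawn
#' from an affine Gaussian copula with the planted density-expression
#' correlation, then shifted by `te_effect` on submissive genes, and
#' realised as interval annotations that [te_flank_density()] recovers.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return list with `expr` (TPM matrix), `meta`, `pairs`, `genes` (gene
#'   intervals), `te` (TE intervals), `truth` (per-pair ledger: bias
#'   direction, flip flag, TE densities), `config`.
#' @export
simulate_expression <- function(config, seed = config$seed + 5L) {
  set.seed(seed)
  n <- config$n_gene_pairs
  bhd_gene <- sprintf("BhD_g%05d", seq_len(n))
  bhs_gene <- sprintf("BhS_g%05d", seq_len(n))
  biased <- stats::runif(n) < config$frac_biased
  direction <- ifelse(biased,
                      ifelse(stats::runif(n) < 0.5, "BhS", "BhD"),
                      NA_character_)
  flip <- biased & stats::runif(n) < config$frac_flip
  mu <- stats::rnorm(n, config$base_log2_tpm, config$sd_gene)
  eff <- log2(config$bias_fold)
  tissues <- config$tissues
  conditions <- config$conditions
  tshift <- matrix(stats::rnorm(n * length(tissues), 0, 0.3), n,
                   dimnames = list(NULL, tissues))
  cshift <- stats::rnorm(n, 0, 0.3)  # added under treatment, both homeologs
  meta <- expand.grid(replicate = seq_len(config$n_replicates),
                      condition = conditions, tissue = tissues,
                      stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s.%s.r%d", meta$tissue, meta$condition,
                            meta$replicate)
  meta <- meta[, c("sample_id", "tissue", "condition", "replicate")]
  expr <- matrix(0, 2 * n, nrow(meta),
                 dimnames = list(c(bhd_gene, bhs_gene), meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    trt <- meta$condition[j] == conditions[length(conditions)] &&
      length(conditions) > 1
    dir_now <- ifelse(flip & trt,
                      ifelse(direction == "BhS", "BhD", "BhS"), direction)
    base <- mu + tshift[, meta$tissue[j]] + if (trt) cshift else 0
    ld <- base + ifelse(!is.na(dir_now) & dir_now == "BhD", eff, 0) +
      stats::rnorm(n, 0, config$expression_sd)
    ls <- base + ifelse(!is.na(dir_now) & dir_now == "BhS", eff, 0) +
      stats::rnorm(n, 0, config$expression_sd)
    expr[, j] <- 2^c(ld, ls)
  }
  # TE densities: affine Gaussian copula against each gene's realised mean
  # log2 expression (the quantity the association test measures), then the
  # planted dominant/submissive shift
  lat <- log2(rowMeans(expr) + 0.1)
  z <- as.numeric(scale(lat))
  rho <- config$te_expr_cor
  raw <- rho * z + sqrt(1 - rho^2) * stats::rnorm(2 * n)
  dens <- pmin(1, pmax(0, 0.4 + 0.15 * raw))
  submissive <- c(!is.na(direction) & direction == "BhS",   # BhD gene is sub
                  !is.na(direction) & direction == "BhD")   # BhS gene is sub
  dens[submissive] <- pmin(1, dens[submissive] + config$te_effect)
  # realise genes + TE intervals on one chromosome per subgenome; gene
  # windows are spaced so neighbouring flanks never touch
  flank <- config$te_flank
  spacing <- 3 * (config$gene_length + 2 * flank)
  gene_tbl <- data.frame(
    chrom = rep(c("BhD_1", "BhS_1"), each = n),
    start = flank + (seq_len(n) - 1) * spacing,
    end = flank + (seq_len(n) - 1) * spacing + config$gene_length,
    gene_id = c(bhd_gene, bhs_gene), stringsAsFactors = FALSE)
  wlen <- config$gene_length + 2 * flank
  te_len <- round(dens * wlen)
  keep <- te_len > 0
  te_tbl <- data.frame(chrom = gene_tbl$chrom[keep],
                       start = gene_tbl$start[keep] - flank,
                       end = gene_tbl$start[keep] - flank + te_len[keep],
                       stringsAsFactors = FALSE)
  truth <- data.frame(pair_id = paste(bhd_gene, bhs_gene, sep = "|"),
                      bhd_gene = bhd_gene, bhs_gene = bhs_gene,
                      biased = biased, direction = direction, flip = flip,
                      mu_log2 = mu,
                      te_density_bhd = round(te_len[seq_len(n)]) / wlen,
                      te_density_bhs = round(te_len[n + seq_len(n)]) / wlen,
                      stringsAsFactors = FALSE)
  list(expr = expr, meta = meta,
       pairs = data.frame(bhd_gene = bhd_gene, bhs_gene = bhs_gene,
                          stringsAsFactors = FALSE),
       genes = gene_tbl, te = te_tbl, truth = truth, config = config)
}
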