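# Nei-Gojobori (1986) Ka/Ks estimation, zero-Ks closeness testing over
# quadruple ortho-homeologous gene chains, Ks-peak estimation and
# T = Ks/(2r) divergence dating.
#
# The NG86 counting estimator is implemented from first principles:
# per-codon synonymous site fractions averaged over the two sequences,
# pathway-averaged difference counts for codons differing at more than one
# position (minimal pathways weighted equally, pathways through stop codons
# excluded when any stop-free pathway exists), and a Jukes-Cantor
# correction applied separately to the synonymous and nonsynonymous
# proportions. Mutations creating a stop codon count as nonsynonymous, so
# synonymous + nonsynonymous sites always sum to 3 per codon.

.ng86 <- new.env(parent = emptyenv())

# Precompute the 64-codon synonymous-site vector and the 64x64 pathway-
# averaged Sd/Nd matrices; memoised for the session.
ng86_tables <- function() {
  if (!is.null(.ng86$codons)) {
    return(list(codons = .ng86$codons, syn_sites = .ng86$syn_sites,
                Sd = .ng86$Sd, Nd = .ng86$Nd))
  }
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  aa <- unname(gc_tab)
  bases <- c("A", "C", "G", "T")
  n <- length(codons)
  idx <- stats::setNames(seq_len(n), codons)

  syn_sites <- numeric(n)
  for (i in seq_len(n)) {
    if (aa[i] == "*") { syn_sites[i] <- NA_real_; next }
    cs <- strsplit(codons[i], "")[[1]]
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(bases, cs[pos])) {
        alt <- cs; alt[pos] <- b
        alt_aa <- aa[idx[paste(alt, collapse = "")]]
        # stop-creating changes count as nonsynonymous
        if (alt_aa == aa[i]) s <- s + 1 / 3
      }
    }
    syn_sites[i] <- s
  }

  Sd <- matrix(0, n, n); Nd <- matrix(0, n, n)
  step_counts <- function(from, to) {
    a1 <- aa[idx[from]]; a2 <- aa[idx[to]]
    if (a1 == "*" || a2 == "*") return(c(0, 1))  # via-stop step: nonsyn
    if (a1 == a2) c(1, 0) else c(0, 1)
  }
  for (i in seq_len(n)) {
    ci <- strsplit(codons[i], "")[[1]]
    for (j in seq_len(n)) {
      if (i == j) next
      cj <- strsplit(codons[j], "")[[1]]
      diff_pos <- which(ci != cj)
      k <- length(diff_pos)
      perms <- if (k == 1) list(diff_pos) else
        if (k == 2) list(diff_pos, rev(diff_pos)) else
          lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2),
                      c(3,2,1)), function(p) diff_pos[p])
      path_s <- numeric(0); path_n <- numeric(0); through_stop <- logical(0)
      for (p in perms) {
        cur <- ci; s <- 0; nn <- 0; stopped <- FALSE
        for (pos in p) {
          nxt <- cur; nxt[pos] <- cj[pos]
          from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
          if (aa[idx[to]] == "*" && to != codons[j]) stopped <- TRUE
          sc <- step_counts(from, to)
          s <- s + sc[1]; nn <- nn + sc[2]
          cur <- nxt
        }
        path_s <- c(path_s, s); path_n <- c(path_n, nn)
        through_stop <- c(through_stop, stopped)
      }
      use <- if (any(!through_stop)) !through_stop else rep(TRUE, length(perms))
      Sd[i, j] <- mean(path_s[use]); Nd[i, j] <- mean(path_n[use])
    }
  }
  .ng86$codons <- codons; .ng86$syn_sites <- syn_sites
  .ng86$Sd <- Sd; .ng86$Nd <- Nd
  list(codons = codons, syn_sites = syn_sites, Sd = Sd, Nd = Nd)
}

split_codons <- function(seq) {
  len <- nchar(seq)
  substring(seq, seq(1, len, 3), seq(3, len, 3))
}

jc_correct <- function(p) {
  ifelse(p == 0, 0, -0.75 * log(1 - 4 * p / 3))
}

#' NG86 Ka/Ks for one aligned codon pair
#'
#' @param seq_a,seq_b aligned coding sequences (equal length, multiple of
#'   3). Codon columns containing a gap (`-`) or `N` in either sequence are
#'   removed before counting; internal stop codons are an error.
#' @param min_codons minimum alignment length (codons) after filtering; an
#'   error below this.
#' @return one-row data.frame with `n_codons, S_sites, N_sites, Sd, Nd, pS,
#'   pN, Ka, Ks, omega, saturated`. When either proportion reaches the
#'   Jukes-Cantor saturation bound (p >= 3/4) the pair is flagged
#'   `saturated` and Ka/Ks are `NA` (such pairs are excluded from dating).
#' @export
ng86_kaks <- function(seq_a, seq_b, min_codons = 1) {
  ax_assert(nchar(seq_a) == nchar(seq_b),
            "aligned sequences must have equal length")
  ax_assert(nchar(seq_a) %% 3 == 0, "alignment length must be divisible by 3")
  tabs <- ng86_tables()
  ca <- split_codons(toupper(seq_a))
  cb <- split_codons(toupper(seq_b))
  clean <- !grepl("[-N]", ca) & !grepl("[-N]", cb)
  ca <- ca[clean]; cb <- cb[clean]
  if (length(ca) < max(min_codons, 1)) {
    stop("fewer than ", max(min_codons, 1),
         " ungapped codons in alignment", call. = FALSE)
  }
  ia <- match(ca, tabs$codons); ib <- match(cb, tabs$codons)
  if (anyNA(ia) || anyNA(ib)) {
    stop("unrecognised codon in alignment", call. = FALSE)
  }
  if (anyNA(tabs$syn_sites[ia]) || anyNA(tabs$syn_sites[ib])) {
    stop("internal stop codon in alignment", call. = FALSE)
  }
  n_codons <- length(ia)
  S <- (sum(tabs$syn_sites[ia]) + sum(tabs$syn_sites[ib])) / 2
  N <- 3 * n_codons - S
  Sd <- sum(tabs$Sd[cbind(ia, ib)])
  Nd <- sum(tabs$Nd[cbind(ia, ib)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  # saturation is per class: the Jukes-Cantor correction is undefined at
  # p >= 3/4, but an unsaturated class is still reported
  Ka <- if (pN >= 0.75) NA_real_ else jc_correct(pN)
  Ks <- if (pS >= 0.75) NA_real_ else jc_correct(pS)
  saturated <- (pS >= 0.75) || (pN >= 0.75)
  omega <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  data.frame(n_codons = n_codons, S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
             pS = pS, pN = pN, Ka = Ka, Ks = Ks, omega = omega,
             saturated = saturated)
}

#' NG86 Ka/Ks over a table of aligned pairs
#'
#' @param gene_a,gene_b gene id vectors.
#' @param seq_a,seq_b aligned CDS vectors (parallel to the ids).
#' @param min_codons minimum ungapped codons per pair.
#' @return data.frame, one row per pair, `gene_a`/`gene_b` prepended to the
#'   [ng86_kaks()] fields.
#' @export
kaks_table <- function(gene_a, gene_b, seq_a, seq_b, min_codons = 1) {
  n <- length(gene_a)
  ax_assert(length(gene_b) == n && length(seq_a) == n && length(seq_b) == n,
            "gene and sequence vectors must have equal length")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- ng86_kaks(seq_a[i], seq_b[i], min_codons = min_codons)
  }
  out <- do.call(rbind, rows)
  cbind(data.frame(gene_a = gene_a, gene_b = gene_b,
                   stringsAsFactors = FALSE), out)
}

# look up Sd for a set of (gene, gene) pairs in a kaks table, order-blind
lookup_sd <- function(kaks, ga, gb) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  stats::setNames(kaks$Sd, key(kaks$gene_a, kaks$gene_b))[key(ga, gb)]
}

#' Count zero-Ks gene pairs over quadruple gene chains
#'
#' "Zero Ks" means exactly zero synonymous differences (`Sd == 0`), not a
#' small-Ks threshold. Chains where the requested pair is missing from the
#' Ka/Ks table are excluded and counted separately.
#'
#' @param chains data.frame with a `chain_id` column and one gene-id column
#'   per genome.
#' @param kaks Ka/Ks table from [kaks_table()] covering the needed pairs.
#' @param comparisons list of length-2 character vectors naming genome
#'   column pairs to count.
#' @return data.frame `genome_a, genome_b, n_zero, n_nonzero, n_missing,
#'   n_chains`.
#' @export
zero_ks_counts <- function(chains, kaks, comparisons) {
  rows <- lapply(comparisons, function(cmp) {
    ax_assert(length(cmp) == 2, "each comparison must name two genomes")
    missing_col <- setdiff(cmp, names(chains))
    if (length(missing_col) > 0) {
      stop("comparison names genome(s) absent from chains: ",
           paste(missing_col, collapse = ", "), call. = FALSE)
    }
    sd <- lookup_sd(kaks, chains[[cmp[1]]], chains[[cmp[2]]])
    data.frame(genome_a = cmp[1], genome_b = cmp[2],
               n_zero = sum(sd == 0, na.rm = TRUE),
               n_nonzero = sum(sd > 0, na.rm = TRUE),
               n_missing = sum(is.na(sd)),
               n_chains = nrow(chains), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Zero-Ks closeness test between two candidate relatives
#'
#' Which of two candidate genomes is the focal (sub)genome closer to?
#' Discordant chains — zero-Ks with exactly one of the two candidates —
#' carry the signal: under the null of equal closeness the discordant
#' chains split 50:50 (a McNemar-style design). The two-sided p-value
#' doubles the smaller exact binomial tail, capped at 1.
#'
#' @param chains chain table (see [zero_ks_counts()]).
#' @param kaks Ka/Ks table covering the (focal, candidate) pairs.
#' @param focal genome column name of the focal (sub)genome.
#' @param candidate_a,candidate_b genome column names of the two candidate
#'   relatives.
#' @return list with `n10` (zero with A only), `n01` (zero with B only),
#'   `n_both_zero`, `n_neither`, `p_value`, `closer` (which candidate the
#'   evidence favors, or `"none"`), and `note` (`"no discordance"` when
#'   `n10 + n01 == 0`).
#' @export
closeness_test <- function(chains, kaks, focal, candidate_a, candidate_b) {
  za <- lookup_sd(kaks, chains[[focal]], chains[[candidate_a]]) == 0
  zb <- lookup_sd(kaks, chains[[focal]], chains[[candidate_b]]) == 0
  ok <- !is.na(za) & !is.na(zb)
  za <- za[ok]; zb <- zb[ok]
  n10 <- sum(za & !zb); n01 <- sum(!za & zb)
  n <- n10 + n01
  if (n == 0) {
    return(list(n10 = 0L, n01 = 0L, n_both_zero = sum(za & zb),
                n_neither = sum(!za & !zb), p_value = 1,
                closer = "none", note = "no discordance"))
  }
  p <- min(1, 2 * stats::pbinom(min(n10, n01), n, 0.5))
  closer <- if (n10 > n01) candidate_a else if (n01 > n10) candidate_b else "none"
  list(n10 = n10, n01 = n01, n_both_zero = sum(za & zb),
       n_neither = sum(!za & !zb), p_value = p, closer = closer,
       note = NA_character_)
}

#' Locate the peak of a non-zero Ks distribution
#'
#' Gaussian kernel density estimate (Silverman's rule-of-thumb bandwidth
#' unless overridden) evaluated on a grid spanning `[0, max(ks) * 1.1]`;
#' returns the grid argmax.
#'
#' @param ks numeric vector of non-zero Ks values (zeros and non-finite
#'   values are dropped).
#' @param min_n minimum number of usable values (default 30).
#' @param bw bandwidth specification passed to [stats::density()].
#' @param n_grid grid size (>= 512).
#' @return the Ks value at the density maximum.
#' @export
ks_peak <- function(ks, min_n = 30, bw = "nrd0", n_grid = 512) {
  x <- ks[is.finite(ks) & ks > 0]
  if (length(x) < min_n) {
    stop("need at least ", min_n, " non-zero Ks values (got ", length(x), ")",
         call. = FALSE)
  }
  if (stats::sd(x) == 0) return(x[1])  # degenerate distribution
  d <- stats::density(x, bw = bw, n = max(n_grid, 512), from = 0,
                      to = max(x) * 1.1)
  d$x[which.max(d$y)]
}

#' Date a divergence from a Ks peak
#'
#' `T = Ks / (2 r)` with `r` the substitution rate per site per year
#' (default `6.5e-9`). The time in Ma is kept at full precision; rounding
#' is presentation-only.
#'
#' @param ks_peak Ks at the distribution peak (>= 0).
#' @param rate substitutions/site/year (> 0).
#' @return one-row data.frame `ks_peak, rate, time_years, time_ma`.
#' @export
divergence_time <- function(ks_peak, rate = 6.5e-9) {
  ax_assert(rate > 0, "rate must be positive")
  ax_assert(ks_peak >= 0, "ks_peak must be non-negative")
  ty <- ks_peak / (2 * rate)
  data.frame(ks_peak = ks_peak, rate = rate, time_years = ty,
             time_ma = ty / 1e6)
}
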