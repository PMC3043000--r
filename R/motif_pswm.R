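# E-box weight-matrix scanning: PSWM construction, sigmoid occupancies,
# tandem-spacing autocorrelation, and site-vs-control element enrichment.

#' Build the E-box scanning PSWM
#'
#' Six columns for CACGTG; at each position the consensus letter has
#' probability 0.96875 and the three others 0.03125 each.
#'
#' @param consensus consensus word (default the canonical E-box)
#' @param p_consensus probability of the consensus letter per column
#' @param background background base probabilities (named, sums to 1)
#' @return PSWM: list(probabilities = 4 x L matrix, background, name)
#' @export
build_scan_pswm <- function(consensus = E1_CONSENSUS, p_consensus = 0.96875,
                            background = c(A = 0.25, C = 0.25, G = 0.25,
                                           T = 0.25)) {
  letters <- strsplit(consensus, "", fixed = TRUE)[[1]]
  L <- length(letters)
  M <- matrix((1 - p_consensus) / 3, nrow = 4, ncol = L,
              dimnames = list(BASES, NULL))
  for (j in seq_len(L)) M[letters[j], j] <- p_consensus
  structure(list(probabilities = M, background = background[BASES],
                 name = consensus), class = "PSWM")
}

seq_to_codes <- function(seq) {
  chartr_map <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  codes <- chartr_map[strsplit(toupper(seq), "", fixed = TRUE)[[1]]]
  codes[is.na(codes)] <- 5L    # degenerate bases
  unname(codes)
}

revcomp <- function(seq) {
  chartr("ACGTacgtN", "TGCAtgcaN", paste(rev(strsplit(seq, "",
                                                      fixed = TRUE)[[1]]),
                                         collapse = ""))
}

# Log2-odds scores of a PSWM at every start position of a coded sequence.
# Degenerate bases contribute zero bits (background emission).
pswm_scores <- function(codes, pswm) {
  M <- pswm$probabilities
  bg <- pswm$background
  L <- ncol(M)
  n <- length(codes) - L + 1
  if (n < 1) return(numeric(0))
  lo <- log2(rbind(sweep(M, 1, bg, "/"), rep(1, L)))  # 5th row: N -> 0 bits
  s <- numeric(n)
  for (j in seq_len(L)) s <- s + lo[cbind(codes[j:(j + n - 1)], j)]
  s
}

#' Scan a sequence with sigmoid occupancies
#'
#' Log-odds scores against the background are converted to occupancies with a
#' logistic transform whose threshold is the score of a single-mismatch word;
#' both strands are scanned and the per-position maximum is taken.
#'
#' @param seq DNA string
#' @param pswm PSWM from [build_scan_pswm()]
#' @param slope sigmoid slope per bit
#' @return numeric occupancy profile over motif start positions (empty for a
#'   sequence shorter than the motif)
#' @export
scan_occupancy <- function(seq, pswm = build_scan_pswm(), slope = 1) {
  L <- ncol(pswm$probabilities)
  if (nchar(seq) < L) return(numeric(0))
  theta <- one_mismatch_threshold(pswm)
  fwd <- pswm_scores(seq_to_codes(seq), pswm)
  rev_scores <- rev(pswm_scores(seq_to_codes(revcomp(seq)), pswm))
  s <- pmax(fwd, rev_scores)
  1 / (1 + exp(-slope * (s - theta)))
}

#' Log-odds score of the worst single-mismatch word
#' @param pswm a PSWM
#' @return threshold in bits
#' @export
one_mismatch_threshold <- function(pswm) {
  M <- pswm$probabilities
  bg <- pswm$background
  lo <- log2(sweep(M, 1, bg, "/"))
  best <- apply(lo, 2, max)
  drops <- vapply(seq_len(ncol(M)), function(j)
    best[j] - max(lo[-which.max(lo[, j]), j]), numeric(1))
  sum(best) - max(drops)
}

#' Positional autocorrelation of occupancy profiles
#'
#' Mean-centered autocorrelation averaged over profiles (normalized to 1 at
#' lag zero), with a null band obtained by circularly shifting each profile
#' by random offsets.
#'
#' @param profiles list of occupancy vectors (or a matrix, rows = profiles)
#' @param max_lag largest lag in bp (must be shorter than every profile)
#' @param n_perm number of random-shift permutations for the null band
#' @param conf confidence level of the null band
#' @return data.table(lag, acf, lower, upper)
#' @export
occupancy_autocorrelation <- function(profiles, max_lag = 30, n_perm = 1000,
                                      conf = 0.95) {
  if (is.matrix(profiles))
    profiles <- lapply(seq_len(nrow(profiles)), function(i) profiles[i, ])
  stop_if(length(profiles) == 0, "need at least one profile")
  lens <- vapply(profiles, length, 1L)
  stop_if(max_lag >= min(lens), "max_lag must be shorter than every profile")
  acf_one <- function(y, lmax) {
    y <- y - mean(y)
    v <- sum(y^2)
    if (v < 1e-300) return(c(1, rep(0, lmax)))
    vapply(0:lmax, function(l)
      sum(y[seq_len(length(y) - l)] * y[(l + 1):length(y)]) / v, numeric(1))
  }
  mean_acf <- function(prof) {
    rowMeans(vapply(prof, acf_one, numeric(max_lag + 1), lmax = max_lag))
  }
  obs <- mean_acf(profiles)
  null_mat <- vapply(seq_len(n_perm), function(b) {
    shifted <- lapply(profiles, function(y) {
      k <- sample.int(length(y) - 1, 1)
      c(y[(k + 1):length(y)], y[seq_len(k)])
    })
    mean_acf(shifted)
  }, numeric(max_lag + 1))
  a <- (1 - conf) / 2
  data.table(lag = 0:max_lag, acf = obs,
             lower = apply(null_mat, 1, quantile, probs = a),
             upper = apply(null_mat, 1, quantile, probs = 1 - a))
}

#' Tandem-element enrichment at sites versus downstream controls
#'
#' Counts E1-E2 element hits (spaced-matrix log-odds at or above the bit
#' threshold) in a window around each site and in a control window of the
#' same width centered 500 bp downstream, and compares the paired counts with
#' a t test.
#'
#' @param sites data.table(chrom, position)
#' @param genome named character vector of chromosome sequences
#' @param matrices list of spaced PSWMs from [extract_spaced_matrices()]
#' @param halfwidth site window half-width in bp
#' @param control_offset control center offset in bp (genome + direction)
#' @param threshold_bits hit threshold in bits
#' @return list(per_site = data.table(site_count, control_count),
#'   t_statistic, p_value, n_used, n_dropped)
#' @export
e1e2_enrichment_vs_control <- function(sites, genome, matrices,
                                       halfwidth = 50, control_offset = 500,
                                       threshold_bits = 10) {
  sites <- as.data.table(sites)
  count_hits <- function(ch, center) {
    s <- genome[[ch]]
    lo <- center - halfwidth; hi <- center + halfwidth
    if (lo < 0 || hi >= nchar(s)) return(NA_integer_)
    sub <- substr(s, lo + 1, hi + 1)
    total <- 0L
    for (m in matrices) {
      codes <- seq_to_codes(sub)
      sc <- pmax(pswm_scores(codes, m),
                 rev(pswm_scores(seq_to_codes(revcomp(sub)), m)))
      total <- total + sum(sc >= threshold_bits)
    }
    total
  }
  res <- rbindlist(lapply(seq_len(nrow(sites)), function(i) {
    data.table(
      site_count = count_hits(sites$chrom[i], sites$position[i]),
      control_count = count_hits(sites$chrom[i],
                                 sites$position[i] + control_offset))
  }))
  dropped <- !complete.cases(res)
  if (any(dropped))
    message(sum(dropped), " site(s) dropped: control window outside genome")
  used <- res[!dropped]
  tt <- if (nrow(used) >= 2 && var(used$site_count - used$control_count) > 0)
    t.test(used$site_count, used$control_count, paired = TRUE) else
      list(statistic = NA_real_, p.value = NA_real_)
  list(per_site = used, t_statistic = unname(tt$statistic),
       p_value = tt$p.value, n_used = nrow(used), n_dropped = sum(dropped))
}
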