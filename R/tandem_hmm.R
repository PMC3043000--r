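# Weighted hidden Markov model of tandem E-box (E1-E2) elements.
#
# Architecture: a background state B; a two-state filter block M that absorbs
# GT-repeat signal; an E1 block of 13 emitting positions (7 left-flank
# positions, then the canonical hexamer); an explicit-duration spacer chain
# supporting 4-20 bp; and an E2 block of 13 emitting positions (the
# non-canonical hexamer, then 7 right-flank positions). The decoded spacer
# duration therefore equals the bp gap between the two hexamers. The reverse
# strand is handled by a mirrored submodel with tied parameters, implemented
# by treating the orientation of each sequence as a latent variable.

HMM_DMIN <- 4L
HMM_DMAX <- 20L

hmm_state_layout <- function(dmin = HMM_DMIN, dmax = HMM_DMAX) {
  ndur <- dmax
  list(
    B = 1L, M1 = 2L, M2 = 3L,
    E1 = 3L + 1:13,
    SP = 16L + seq_len(ndur),        # entry at SP[ndur - d + 1] emits d bases
    E2 = 16L + ndur + 1:13,
    n_states = 16L + ndur + 13L,
    dmin = as.integer(dmin), dmax = as.integer(dmax))
}

#' Initialize a tandem E1-E2 HMM
#'
#' Emissions of the E1/E2 hexamer positions start near the canonical
#' (CACGTG) and non-canonical (AACGTG) boxes; flanks, spacer and background
#' start at the background composition; the spacer duration distribution
#' starts uniform on \[dmin, dmax\].
#'
#' @param background background base probabilities (A, C, G, T)
#' @param dmin,dmax spacer duration support in bp
#' @param single_bits,tandem_bits default classification thresholds in bits
#' @return TandemHMM object
#' @export
tandem_hmm <- function(background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       dmin = HMM_DMIN, dmax = HMM_DMAX,
                       single_bits = 7.2, tandem_bits = 10.2) {
  lay <- hmm_state_layout(dmin, dmax)
  bg <- background / sum(background)
  box_cols <- function(word) {
    letters <- strsplit(word, "", fixed = TRUE)[[1]]
    M <- matrix(0.1, 4, 6, dimnames = list(BASES, NULL))
    for (j in 1:6) M[letters[j], j] <- 0.7
    M
  }
  e1 <- cbind(matrix(bg, 4, 7, dimnames = list(BASES, NULL)),
              box_cols(E1_CONSENSUS))
  e2 <- cbind(box_cols(E2_CONSENSUS),
              matrix(bg, 4, 7, dimnames = list(BASES, NULL)))
  m_em <- cbind(c(A = 0.05, C = 0.05, G = 0.85, T = 0.05),
                c(A = 0.05, C = 0.05, G = 0.05, T = 0.85))
  rho <- rep(1 / (dmax - dmin + 1), dmax - dmin + 1)
  par <- list(bg = bg, e1 = e1, e2 = e2, m = m_em,
              a_e1 = 0.02, a_m = 0.01, p_tandem = 0.5, p_m = 0.8,
              rho = rho)
  structure(list(layout = lay, par = par,
                 thresholds = c(single = single_bits, tandem = tandem_bits),
                 trained = FALSE, loglik_trace = numeric(0)),
            class = "TandemHMM")
}

hmm_matrices <- function(model) {
  lay <- model$layout; par <- model$par
  S <- lay$n_states
  Tm <- matrix(0, S, S)
  Tm[lay$B, lay$B] <- 1 - par$a_e1 - par$a_m
  Tm[lay$B, lay$M1] <- par$a_m
  Tm[lay$B, lay$E1[1]] <- par$a_e1
  Tm[lay$M1, lay$M2] <- 1
  Tm[lay$M2, lay$M1] <- par$p_m
  Tm[lay$M2, lay$B] <- 1 - par$p_m
  for (k in 1:12) Tm[lay$E1[k], lay$E1[k + 1]] <- 1
  Tm[lay$E1[13], lay$B] <- 1 - par$p_tandem
  durs <- lay$dmin:lay$dmax
  for (i in seq_along(durs)) {
    entry <- lay$SP[lay$dmax - durs[i] + 1L]
    Tm[lay$E1[13], entry] <- par$p_tandem * par$rho[i]
  }
  nsp <- length(lay$SP)
  for (k in seq_len(nsp - 1)) Tm[lay$SP[k], lay$SP[k + 1]] <- 1
  Tm[lay$SP[nsp], lay$E2[1]] <- 1
  for (k in 1:12) Tm[lay$E2[k], lay$E2[k + 1]] <- 1
  Tm[lay$E2[13], lay$B] <- 1
  Em <- matrix(0, S, 5)
  Em[lay$B, 1:4] <- par$bg
  Em[lay$M1, 1:4] <- par$m[, 1]
  Em[lay$M2, 1:4] <- par$m[, 2]
  for (k in 1:13) Em[lay$E1[k], 1:4] <- par$e1[, k]
  for (k in seq_len(nsp)) Em[lay$SP[k], 1:4] <- par$bg
  for (k in 1:13) Em[lay$E2[k], 1:4] <- par$e2[, k]
  Em[, 5] <- 1                          # degenerate bases: neutral emission
  pi0 <- numeric(S); pi0[lay$B] <- 1
  list(Tm = Tm, Em = Em, pi0 = pi0)
}

# Batched scaled forward pass over a codes matrix (n_seq x len).
# Returns per-sequence log-likelihoods and, optionally, the alpha/scale
# history needed for the backward pass.
hmm_forward_batch <- function(codes, mats, keep = FALSE) {
  n <- nrow(codes); Tlen <- ncol(codes)
  S <- length(mats$pi0)
  emis_t <- function(t) t(mats$Em[, codes[, t], drop = FALSE])
  alpha <- matrix(mats$pi0, n, S, byrow = TRUE) * emis_t(1)
  sc <- matrix(0, n, Tlen)
  sc[, 1] <- rowSums(alpha)
  alpha <- alpha / sc[, 1]
  hist <- if (keep) vector("list", Tlen) else NULL
  if (keep) hist[[1]] <- alpha
  for (t in seq_len(Tlen - 1) + 1) {
    alpha <- (alpha %*% mats$Tm) * emis_t(t)
    sc[, t] <- rowSums(alpha)
    alpha <- alpha / sc[, t]
    if (keep) hist[[t]] <- alpha
  }
  list(loglik = rowSums(log(sc)), alpha = hist, scales = sc)
}

#' Forward log-likelihood of sequences under the HMM
#'
#' Single-orientation likelihood (no reverse-complement mixture); mainly a
#' building block and oracle hook.
#'
#' @param model TandemHMM
#' @param seqs character vector of equal-length DNA strings
#' @return numeric log-likelihoods
#' @export
hmm_forward_loglik <- function(model, seqs) {
  codes <- do.call(rbind, lapply(seqs, seq_to_codes))
  hmm_forward_batch(codes, hmm_matrices(model))$loglik
}

# Accumulate expected emission/transition counts for one orientation batch.
hmm_expected_counts <- function(codes, mats, wts) {
  n <- nrow(codes); Tlen <- ncol(codes); S <- length(mats$pi0)
  fw <- hmm_forward_batch(codes, mats, keep = TRUE)
  emis_t <- function(t) t(mats$Em[, codes[, t], drop = FALSE])
  beta <- matrix(1, n, S)
  e_counts <- matrix(0, S, 5)
  t_counts <- matrix(0, S, S)
  for (t in Tlen:1) {
    gamma <- fw$alpha[[t]] * beta
    gamma <- gamma / pmax(rowSums(gamma), 1e-300)
    gw <- gamma * wts
    for (c in unique(codes[, t])) {
      rows <- codes[, t] == c
      e_counts[, c] <- e_counts[, c] + colSums(gw[rows, , drop = FALSE])
    }
    if (t > 1) {
      eb <- emis_t(t) * beta / fw$scales[, t]
      t_counts <- t_counts +
        (t(fw$alpha[[t - 1]] * wts) %*% eb) * mats$Tm
      beta <- (eb %*% t(mats$Tm))
    }
  }
  list(e = e_counts, t = t_counts)
}

#' Train the tandem HMM by weighted Baum-Welch
#'
#' Each sequence's expected counts are multiplied by its weight (tags at peak
#' binding). The orientation of each sequence is a latent variable: forward
#' and reverse-complement readings share tied parameters and are mixed with
#' equal prior. Iterates until the weighted log-likelihood gain drops below
#' `tol`. After training, classification bit thresholds are recomputed from
#' the corpus (see [recompute_thresholds()]).
#'
#' @param seqs character vector of DNA windows (equal lengths recommended)
#' @param weights non-negative sequence weights (default all 1)
#' @param model starting TandemHMM (default [tandem_hmm()] with the corpus
#'   base composition as background)
#' @param max_iter maximum Baum-Welch iterations
#' @param tol absolute weighted log-likelihood convergence tolerance
#' @param pseudocount added to emission counts
#' @param recompute_thresholds recompute bit thresholds from the corpus
#' @return trained TandemHMM with `loglik_trace`
#' @export
train_tandem_hmm <- function(seqs, weights = NULL, model = NULL,
                             max_iter = 50, tol = 1e-3, pseudocount = 0.1,
                             recompute_thresholds = TRUE) {
  stop_if(length(seqs) < 10, "need at least 10 training sequences")
  if (is.null(weights)) weights <- rep(1, length(seqs))
  stop_if(any(weights < 0) || !any(weights > 0),
          "weights must be non-negative with positive total")
  weights <- weights / mean(weights[weights > 0])
  keep <- weights > 0
  seqs <- seqs[keep]; weights <- weights[keep]
  if (is.null(model)) {
    comp <- base_composition(seqs)
    model <- tandem_hmm(background = comp)
  }
  lay <- model$layout
  lens <- nchar(seqs)
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    mats <- hmm_matrices(model)
    total_e <- matrix(0, lay$n_states, 5)
    total_t <- matrix(0, lay$n_states, lay$n_states)
    ll_total <- 0
    for (L in unique(lens)) {
      idx <- which(lens == L)
      fwd <- do.call(rbind, lapply(seqs[idx], seq_to_codes))
      rcd <- do.call(rbind, lapply(vapply(seqs[idx], revcomp, ""),
                                   seq_to_codes))
      ll_f <- hmm_forward_batch(fwd, mats)$loglik
      ll_r <- hmm_forward_batch(rcd, mats)$loglik
      mx <- pmax(ll_f, ll_r)
      lmix <- mx + log(0.5 * exp(ll_f - mx) + 0.5 * exp(ll_r - mx))
      u_f <- 0.5 * exp(ll_f - lmix)     # posterior P(forward orientation)
      ll_total <- ll_total + sum(weights[idx] * lmix)
      cf <- hmm_expected_counts(fwd, mats, weights[idx] * u_f)
      cr <- hmm_expected_counts(rcd, mats, weights[idx] * (1 - u_f))
      total_e <- total_e + cf$e + cr$e
      total_t <- total_t + cf$t + cr$t
    }
    stop_if(!is.finite(ll_total), "non-finite training likelihood")
    trace <- c(trace, ll_total)
    model$par <- hmm_mstep(model, total_e, total_t, pseudocount)
    if (iter > 1 && trace[iter] - trace[iter - 1] < tol) break
  }
  model$loglik_trace <- trace
  model$trained <- TRUE
  if (recompute_thresholds)
    model <- recompute_thresholds(model, seqs, weights)
  model
}

base_composition <- function(seqs) {
  codes <- unlist(lapply(seqs, seq_to_codes))
  tab <- tabulate(codes[codes <= 4], 4)
  setNames((tab + 1) / sum(tab + 4), BASES)
}

hmm_mstep <- function(model, e_counts, t_counts, pseudocount) {
  lay <- model$layout; par <- model$par
  norm_emis <- function(v) {
    v <- v[1:4] + pseudocount
    v / sum(v)
  }
  bg_rows <- c(lay$B, lay$SP)            # spacer emissions tied to background
  par$bg <- setNames(norm_emis(colSums(e_counts[bg_rows, , drop = FALSE])),
                     BASES)
  for (k in 1:13) par$e1[, k] <- norm_emis(e_counts[lay$E1[k], ])
  for (k in 1:13) par$e2[, k] <- norm_emis(e_counts[lay$E2[k], ])
  par$m[, 1] <- norm_emis(e_counts[lay$M1, ])
  par$m[, 2] <- norm_emis(e_counts[lay$M2, ])
  b_out <- t_counts[lay$B, ]
  tot_b <- sum(b_out) + 3 * pseudocount
  par$a_e1 <- (b_out[lay$E1[1]] + pseudocount) / tot_b
  par$a_m <- (b_out[lay$M1] + pseudocount) / tot_b
  m2_out <- t_counts[lay$M2, ]
  par$p_m <- (m2_out[lay$M1] + pseudocount) /
    (m2_out[lay$M1] + m2_out[lay$B] + 2 * pseudocount)
  e13 <- t_counts[lay$E1[13], ]
  durs <- lay$dmin:lay$dmax
  sp_counts <- vapply(durs, function(d) e13[lay$SP[lay$dmax - d + 1L]],
                      numeric(1))
  to_b <- e13[lay$B]
  par$p_tandem <- (sum(sp_counts) + pseudocount) /
    (sum(sp_counts) + to_b + 2 * pseudocount)
  par$rho <- (sp_counts + pseudocount / length(durs)) /
    sum(sp_counts + pseudocount / length(durs))
  par
}

# Constrained Viterbi with an element-completion flag. `mode` is one of
# "any", "single" (must complete an E1 block not followed by a spacer) or
# "tandem" (must complete an E2 block). The constraint is encoded by
# duplicating the state space into "element not yet completed" and
# "completed" layers; the completing transition promotes a path to the
# second layer. Returns the best log path probability under the original
# model and the decoded state path (in original state indices).
hmm_viterbi <- function(model, seq, mode = c("any", "single", "tandem")) {
  mode <- match.arg(mode)
  mats <- hmm_matrices(model)
  lay <- model$layout
  S <- lay$n_states
  Tm <- mats$Tm
  if (mode == "single") Tm[lay$E1[13], lay$SP] <- 0
  codes <- seq_to_codes(seq)
  Tlen <- length(codes)
  if (mode == "any") {
    logT <- log(Tm)
    pi_aug <- log(mats$pi0)
    n_aug <- S
  } else {
    from <- if (mode == "single") lay$E1[13] else lay$E2[13]
    to <- lay$B
    T1 <- Tm; T1[from, to] <- 0          # stay in layer 1
    Tp <- matrix(0, S, S); Tp[from, to] <- Tm[from, to]   # promotion
    logT <- log(rbind(cbind(T1, Tp),
                      cbind(matrix(0, S, S), Tm)))
    pi_aug <- log(c(mats$pi0, numeric(S)))
    n_aug <- 2L * S
  }
  logE <- log(mats$Em)
  emis <- function(t) {
    e <- logE[, codes[t]]
    if (n_aug > S) c(e, e) else e
  }
  delta <- pi_aug + emis(1)
  back <- matrix(0L, n_aug, Tlen)
  for (t in seq_len(Tlen - 1) + 1) {
    cand <- delta + logT                 # [from, to]
    am <- max.col(t(cand), ties.method = "first")
    delta <- cand[cbind(am, seq_len(n_aug))] + emis(t)
    back[, t] <- am
  }
  if (mode == "any") {
    end <- which.max(delta)
    best <- delta[end]
  } else {
    # valid ends: completed layer, or the element finishing on the last base
    from <- if (mode == "single") lay$E1[13] else lay$E2[13]
    valid <- c(S + seq_len(S), from)
    end <- valid[which.max(delta[valid])]
    best <- delta[end]
    if (!is.finite(best)) return(list(loglik = -Inf, path = NULL))
  }
  path <- integer(Tlen)
  st <- end
  path[Tlen] <- st
  for (t in Tlen:2) {
    st <- back[st, t]
    path[t - 1] <- st
  }
  list(loglik = best, path = ((path - 1L) %% S) + 1L)
}

# Log-probability of the pure-background path.
hmm_background_loglik <- function(model, seq) {
  mats <- hmm_matrices(model)
  lay <- model$layout
  codes <- seq_to_codes(seq)
  p_bb <- mats$Tm[lay$B, lay$B]
  sum(log(mats$Em[lay$B, codes])) + (length(codes) - 1) * log(p_bb)
}

# Parse a decoded state path: locate E1/E2 blocks and the spacer duration.
hmm_parse_path <- function(model, path) {
  lay <- model$layout
  e1_start <- which(path == lay$E1[1])
  e2_start <- which(path == lay$E2[1])
  spacer <- NA_integer_
  if (length(e2_start)) {
    sp_run <- sum(path %in% lay$SP &
                    seq_along(path) < e2_start[1] &
                    seq_along(path) > ifelse(length(e1_start),
                                             e1_start[1], 0))
    spacer <- as.integer(sp_run)
  }
  list(has_e1 = length(e1_start) > 0, has_e2 = length(e2_start) > 0,
       e1_start = if (length(e1_start)) e1_start[1] else NA_integer_,
       spacer = spacer)
}

#' Recompute classification bit thresholds from a corpus
#'
#' Scores every sequence with the constrained Viterbi log-odds; the single
#' (tandem) threshold is placed midway between the lowest score among
#' sequences whose unconstrained decoding contains an E1 (E1-E2) element and
#' the highest score among sequences whose decoding does not (zero when all
#' sequences decode as hits). Falls back to the configured defaults when the
#' corpus decodes no hits.
#'
#' @param model trained TandemHMM
#' @param seqs training sequences
#' @param weights sequence weights (unused in the threshold rule, kept for
#'   interface symmetry)
#' @return model with updated `thresholds`
#' @export
recompute_thresholds <- function(model, seqs, weights = NULL) {
  singles <- tandems <- numeric(0)
  single_bg <- tandem_bg <- numeric(0)
  for (s in seqs) {
    sc <- site_scores(model, s)
    dec <- hmm_parse_path(model, hmm_viterbi(model, s, "any")$path)
    dec_rc <- hmm_parse_path(model, hmm_viterbi(model, revcomp(s),
                                                "any")$path)
    has_e2 <- dec$has_e2 || dec_rc$has_e2
    has_e1 <- dec$has_e1 || dec_rc$has_e1
    if (has_e2) tandems <- c(tandems, sc$tandem_bits) else
      tandem_bg <- c(tandem_bg, sc$tandem_bits)
    if (has_e1 && !has_e2) singles <- c(singles, sc$single_bits) else
      if (!has_e1) single_bg <- c(single_bg, sc$single_bits)
  }
  # separate decoded hits from background scores; medians keep the rule
  # robust to marginal decodes on either side
  mid <- function(hits, bg, default) {
    if (!length(hits)) return(default)
    hi <- quantile(hits, 0.5, names = FALSE)
    lo <- if (length(bg)) quantile(bg, 0.5, names = FALSE) else 0
    max((hi + min(lo, hi)) / 2, 0)
  }
  model$thresholds <- c(
    single = mid(c(singles, tandems), single_bg, model$thresholds[["single"]]),
    tandem = mid(tandems, tandem_bg, model$thresholds[["tandem"]]))
  model
}

# Constrained log-odds scores (bits) of one sequence, maximized over
# orientation. Element starts are reported as 1-based positions of the E1
# block start in the forward-orientation window (for the reverse complement
# this is the mapped block end; the *_rc flags record which).
site_scores <- function(model, seq) {
  best <- list(single_bits = -Inf, tandem_bits = -Inf,
               spacer = NA_integer_, single_e1_start = NA_integer_,
               tandem_e1_start = NA_integer_, single_rc = FALSE,
               tandem_rc = FALSE)
  n <- nchar(seq)
  for (rc in c(FALSE, TRUE)) {
    s <- if (rc) revcomp(seq) else seq
    bg <- hmm_background_loglik(model, s)
    vt_s <- hmm_viterbi(model, s, "single")
    vt_t <- hmm_viterbi(model, s, "tandem")
    sb <- (vt_s$loglik - bg) / log(2)
    tb <- (vt_t$loglik - bg) / log(2)
    if (sb > best$single_bits) {
      best$single_bits <- sb
      e1s <- hmm_parse_path(model, vt_s$path)$e1_start
      if (rc && !is.na(e1s)) e1s <- n - e1s + 1L
      best$single_e1_start <- e1s
      best$single_rc <- rc
    }
    if (tb > best$tandem_bits) {
      best$tandem_bits <- tb
      info <- hmm_parse_path(model, vt_t$path)
      e1s <- info$e1_start
      if (rc && !is.na(e1s)) e1s <- n - e1s + 1L
      best$spacer <- info$spacer
      best$tandem_e1_start <- e1s
      best$tandem_rc <- rc
    }
  }
  best
}

#' Classify a site window with the tandem HMM
#'
#' Computes best-path log-odds in bits against the background-only path for
#' the single-E-box and tandem-element constrained decodings (both strands).
#' Returns E1E2 when the tandem score reaches the tandem threshold, otherwise
#' E1 when the single score reaches the single threshold, otherwise NONE.
#'
#' @param model trained TandemHMM
#' @param seq DNA window (e.g. +/- 50 bp around a site center)
#' @return SiteMotifCall: list(class, spacer, score, offset) where offset is
#'   the decoded element midpoint minus the window center, in bp
#' @export
classify_site <- function(model, seq) {
  stop_if(!isTRUE(model$trained), "model is not trained")
  sc <- site_scores(model, seq)
  thr <- model$thresholds
  n <- nchar(seq)
  center <- (n + 1) / 2
  if (is.finite(sc$tandem_bits) && sc$tandem_bits >= thr[["tandem"]]) {
    footprint <- 26 + ifelse(is.na(sc$spacer), 0, sc$spacer)
    e1s <- sc$tandem_e1_start
    mid <- if (is.na(e1s)) NA_real_ else
      if (sc$tandem_rc) e1s - footprint / 2 else e1s + footprint / 2
    return(list(class = "E1E2", spacer = sc$spacer,
                score = sc$tandem_bits,
                offset = if (is.na(mid)) NA_real_ else mid - center))
  }
  if (is.finite(sc$single_bits) && sc$single_bits >= thr[["single"]]) {
    e1s <- sc$single_e1_start
    mid <- if (is.na(e1s)) NA_real_ else       # hexamer midpoint
      if (sc$single_rc) e1s - 9.5 else e1s + 9.5
    return(list(class = "E1", spacer = NA_integer_, score = sc$single_bits,
                offset = if (is.na(mid)) NA_real_ else mid - center))
  }
  list(class = "NONE", spacer = NA_integer_,
       score = max(sc$single_bits, sc$tandem_bits), offset = NA_real_)
}

#' Classify many site windows
#' @param model trained TandemHMM
#' @param seqs character vector of windows
#' @return data.table(class, spacer, score, offset)
#' @export
classify_sites <- function(model, seqs) {
  rbindlist(lapply(seqs, function(s) {
    cl <- classify_site(model, s)
    data.table(class = cl$class, spacer = cl$spacer, score = cl$score,
               offset = cl$offset)
  }))
}

#' Extract spaced E1-E2 weight matrices from a trained HMM
#'
#' For each requested spacer, concatenates the 13 E1 emission columns, that
#' many background columns, and the 13 E2 emission columns.
#'
#' @param model trained TandemHMM
#' @param spacers spacer lengths in bp (must lie in the model's support)
#' @return named list of PSWMs ("E1E2_sp6", ...)
#' @export
extract_spaced_matrices <- function(model, spacers = c(6, 7)) {
  lay <- model$layout
  stop_if(any(spacers < lay$dmin | spacers > lay$dmax),
          "spacer outside model support")
  out <- lapply(spacers, function(sp) {
    M <- cbind(model$par$e1,
               matrix(model$par$bg, 4, sp, dimnames = list(BASES, NULL)),
               model$par$e2)
    structure(list(probabilities = M, background = model$par$bg,
                   name = sprintf("E1E2_sp%d", sp)), class = "PSWM")
  })
  names(out) <- sprintf("E1E2_sp%d", spacers)
  out
}

#' Best spaced-matrix hit offset relative to a window center
#'
#' Scans both strands of a window with one or more spaced matrices and
#' returns the offset (bp) of the best hit's midpoint from the window center,
#' along with its score.
#'
#' @param seq DNA window
#' @param matrices list of PSWMs (e.g. from [extract_spaced_matrices()])
#' @return list(offset, score, matrix)
#' @export
best_spaced_hit <- function(seq, matrices) {
  if (inherits(matrices, "PSWM")) matrices <- list(matrices)
  center <- (nchar(seq) + 1) / 2
  best <- list(offset = NA_real_, score = -Inf, matrix = NA_character_)
  codes <- seq_to_codes(seq)
  codes_rc <- seq_to_codes(revcomp(seq))
  for (m in matrices) {
    sc <- pmax(pswm_scores(codes, m), rev(pswm_scores(codes_rc, m)))
    if (!length(sc)) next
    i <- which.max(sc)
    if (sc[i] > best$score) {
      best <- list(offset = (i + ncol(m$probabilities) / 2) - center,
                   score = sc[i], matrix = m$name %||% "")
    }
  }
  best
}

#' Serialize a TandemHMM to JSON
#' @param model TandemHMM
#' @param path output file
#' @export
write_hmm_json <- function(model, path) {
  obj <- list(layout = model$layout, par = model$par,
              thresholds = as.list(model$thresholds),
              trained = model$trained, loglik_trace = model$loglik_trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

#' Read a TandemHMM from JSON
#' @param path JSON file written by [write_hmm_json()]
#' @return TandemHMM
#' @export
read_hmm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lay <- obj$layout
  lay[c("B", "M1", "M2", "n_states", "dmin", "dmax")] <-
    lapply(lay[c("B", "M1", "M2", "n_states", "dmin", "dmax")], as.integer)
  lay$E1 <- as.integer(lay$E1); lay$SP <- as.integer(lay$SP)
  lay$E2 <- as.integer(lay$E2)
  par <- obj$par
  par$bg <- setNames(as.numeric(par$bg), BASES)
  for (nm in c("e1", "e2", "m")) {
    par[[nm]] <- as.matrix(par[[nm]])
    rownames(par[[nm]]) <- BASES
  }
  structure(list(layout = lay, par = par,
                 thresholds = unlist(obj$thresholds),
                 trained = obj$trained,
                 loglik_trace = as.numeric(obj$loglik_trace)),
            class = "TandemHMM")
}
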