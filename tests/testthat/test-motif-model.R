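test_that("the scanning PSWM matches the stated probabilities", {
  pswm <- build_scan_pswm()
  M <- pswm$probabilities
  expect_equal(dim(M), c(4, 6))
  expect_equal(unname(M["C", 1]), 0.96875)
  # non-consensus letters share the remaining 0.03125 mass equally
  expect_equal(unname(M["A", 1]), (1 - 0.96875) / 3)
  expect_equal(unname(M["G", 1]), unname(M["T", 1]))
  expect_equal(unname(colSums(M)), rep(1, 6))
  # consensus dominates every 1-mismatch word
  lo <- log2(sweep(M, 1, pswm$background, "/"))
  consensus <- sum(vapply(1:6, function(j) max(lo[, j]), numeric(1)))
  theta <- one_mismatch_threshold(pswm)
  expect_lt(theta, consensus)
})

test_that("sigmoid occupancies separate consensus from two-mismatch words", {
  pswm <- build_scan_pswm()
  occ_exact <- scan_occupancy("CACGTG", pswm)
  expect_gt(occ_exact, 0.5)
  occ_rc <- scan_occupancy("CACGTG", pswm)
  expect_equal(scan_occupancy(circaseq:::revcomp("CACGTG"), pswm), occ_rc)
  occ_2mm <- scan_occupancy("CAAATG", pswm)   # two mismatches
  expect_lt(occ_2mm, 0.5)
  expect_length(scan_occupancy("CAC", pswm), 0)
  # profile length
  expect_length(scan_occupancy(strrep("A", 20), pswm), 15)
})

test_that("occupancy autocorrelation flags a planted start-to-start lag", {
  set.seed(42)
  profiles <- lapply(1:60, function(i) {
    s <- rand_seq(101)
    at <- sample(10:70, 1)
    s <- insert_word(s, "CACGTG", at)
    s <- insert_word(s, "CACGTG", at + 13)   # 6-mer + 7 bp gap
    scan_occupancy(s)
  })
  ac <- occupancy_autocorrelation(profiles, max_lag = 25, n_perm = 300)
  expect_equal(ac$acf[ac$lag == 0], 1)
  expect_gt(ac$acf[ac$lag == 13], ac$upper[ac$lag == 13])

  # random sequences stay inside the band at positive lags almost always
  set.seed(43)
  inside <- replicate(20, {
    prof0 <- lapply(1:20, function(i) scan_occupancy(rand_seq(101)))
    ac0 <- occupancy_autocorrelation(prof0, max_lag = 10, n_perm = 100)
    mean(ac0$acf[-1] >= ac0$lower[-1] & ac0$acf[-1] <= ac0$upper[-1])
  })
  expect_gte(mean(inside), 0.9)
  expect_error(occupancy_autocorrelation(list(rep(0.5, 10)), max_lag = 10),
               "max_lag")
})

test_that("HMM forward likelihood equals brute-force path enumeration", {
  enum_ll <- function(model, seq) {
    mats <- circaseq:::hmm_matrices(model)
    codes <- circaseq:::seq_to_codes(seq)
    Tn <- length(codes)
    total <- 0
    recurse <- function(state, t, pr) {
      pr <- pr * mats$Em[state, codes[t]]
      if (pr == 0) return()
      if (t == Tn) {
        total <<- total + pr
        return()
      }
      for (s2 in which(mats$Tm[state, ] > 0))
        recurse(s2, t + 1, pr * mats$Tm[state, s2])
    }
    for (s0 in which(mats$pi0 > 0)) recurse(s0, 1, mats$pi0[s0])
    log(total)
  }
  model <- tandem_hmm()
  for (s in c("CACGTGA", "ACGTACGTAC", "GGGTGTGTGTG", "TTTTTTTT")) {
    expect_equal(hmm_forward_loglik(model, s), enum_ll(model, s),
                 tolerance = 1e-10)
  }
})

test_that("weighted Baum-Welch is monotone and reduces to unweighted", {
  set.seed(44)
  corpus <- vapply(1:20, function(i) planted_window("E1E2", len = 50),
                   character(1))
  m1 <- train_tandem_hmm(corpus, weights = rep(1, 20), max_iter = 5,
                         recompute_thresholds = FALSE)
  expect_true(all(diff(m1$loglik_trace) > -1e-6))
  # equal weights at any scale give the same fixpoint path
  m2 <- train_tandem_hmm(corpus, weights = rep(7, 20), max_iter = 5,
                         recompute_thresholds = FALSE)
  expect_equal(m1$par, m2$par, tolerance = 1e-9)
  expect_error(train_tandem_hmm(corpus, weights = rep(0, 20)),
               "positive total")
  expect_error(train_tandem_hmm(corpus[1:5]), "at least 10")
})

test_that("training recovers a planted spacer distribution", {
  set.seed(45)
  corpus <- vapply(1:120, function(i)
    if (runif(1) < 0.8) planted_window("E1E2", len = 60, spacer = 7)
    else planted_window("NONE", len = 60), character(1))
  hmm <- train_tandem_hmm(corpus, max_iter = 25)
  durs <- hmm$layout$dmin:hmm$layout$dmax
  expect_equal(durs[which.max(hmm$par$rho)], 7)
  # learned E1 hexamer emissions concentrate on CACGTG
  hex <- hmm$par$e1[, 8:13]
  expect_equal(paste(rownames(hex)[apply(hex, 2, which.max)],
                     collapse = ""), "CACGTG")
})

test_that("classification matches planted classes and is strand
           symmetric", {
  set.seed(46)
  corpus <- vapply(sample(c("NONE", "E1", "E1E2"), 150, TRUE,
                          c(0.2, 0.4, 0.4)),
                   function(k) planted_window(k, len = 60), character(1))
  hmm <- train_tandem_hmm(corpus, max_iter = 25)

  # the tandem probe: E1 + 7 nt + E2
  probe <- paste0(rand_seq(20), "CACGTG", rand_seq(7), "AACGTG",
                  rand_seq(20))
  cl <- classify_site(hmm, probe)
  expect_equal(cl$class, "E1E2")
  expect_equal(cl$spacer, 7L)
  expect_lte(abs(cl$offset), 5)

  single <- paste0(rand_seq(30), "CACGTG", rand_seq(30))
  expect_equal(classify_site(hmm, single)$class, "E1")

  # background with no word close to an E-box
  bg <- gsub("ACG", "TTT", rand_seq(80))
  expect_equal(classify_site(hmm, bg)$class, "NONE")

  # reverse complement preserves class and score
  for (s in list(probe, single)) {
    a <- classify_site(hmm, s)
    b <- classify_site(hmm, circaseq:::revcomp(s))
    expect_equal(b$class, a$class)
    expect_equal(b$score, a$score, tolerance = 1e-9)
    if (!is.na(a$offset)) expect_equal(abs(b$offset), abs(a$offset),
                                       tolerance = 1)
  }
  expect_error(classify_site(tandem_hmm(), probe), "not trained")
})

test_that("spaced matrices have the documented layout and locate planted
           elements", {
  set.seed(47)
  corpus <- vapply(1:100, function(i) planted_window("E1E2", len = 60,
                                                     spacer = 7),
                   character(1))
  hmm <- train_tandem_hmm(corpus, max_iter = 20)
  mats <- extract_spaced_matrices(hmm, spacers = c(6, 7))
  expect_named(mats, c("E1E2_sp6", "E1E2_sp7"))
  expect_equal(ncol(mats$E1E2_sp6$probabilities), 13 + 6 + 13)
  expect_equal(ncol(mats$E1E2_sp7$probabilities), 13 + 7 + 13)
  expect_equal(unname(colSums(mats$E1E2_sp7$probabilities)),
               rep(1, 33), tolerance = 1e-9)
  expect_error(extract_spaced_matrices(hmm, spacers = 99), "support")

  # scanning a window centered on a planted sp7 element
  elem <- paste0("CACGTG", rand_seq(7), "AACGTG")
  win <- paste0(rand_seq(41), elem, rand_seq(41))   # centered element
  hit <- best_spaced_hit(win, mats)
  expect_lte(abs(hit$offset), 5)
  expect_equal(hit$matrix, "E1E2_sp7")
})

test_that("HMM JSON serialization round trips", {
  set.seed(48)
  corpus <- vapply(1:30, function(i) planted_window("E1E2", len = 50),
                   character(1))
  hmm <- train_tandem_hmm(corpus, max_iter = 5,
                          recompute_thresholds = FALSE)
  path <- tempfile(fileext = ".json")
  write_hmm_json(hmm, path)
  back <- read_hmm_json(path)
  expect_equal(back$par$e1, hmm$par$e1, tolerance = 1e-12)
  expect_equal(back$thresholds, hmm$thresholds)
  s <- planted_window("E1E2", len = 50)
  expect_equal(hmm_forward_loglik(back, s), hmm_forward_loglik(hmm, s),
               tolerance = 1e-9)
  unlink(path)
})

test_that("tandem elements are enriched at sites versus controls", {
  set.seed(49)
  L <- 60000
  n_sites <- 40
  positions <- seq(2000, L - 3000, length.out = n_sites)
  g <- generate_genome(L, 0.5, seed = 49)
  # a quarter of sites carry no element so paired differences vary
  kinds <- rep(c("E1E2", "NONE"), c(30, 10))
  specs <- data.table::rbindlist(lapply(seq_along(positions), function(i)
    site_spec(kinds[i], as.integer(positions[i]),
              spacer = if (kinds[i] == "E1E2") 7 else NA_integer_)))
  pl <- plant_sites(g, specs, seed = 49)
  genome <- setNames(pl$genome, "chrS")
  corpus <- vapply(pl$truth$sites$center, function(c0)
    substr(pl$genome, c0 - 30 + 1, c0 + 30 + 1), character(1))
  hmm <- train_tandem_hmm(corpus, max_iter = 20)
  mats <- extract_spaced_matrices(hmm, spacers = 7)
  sites <- data.table::data.table(chrom = "chrS",
                                  position = pl$truth$sites$center)
  enr <- e1e2_enrichment_vs_control(sites, genome, mats, halfwidth = 50)
  expect_equal(enr$n_dropped, 0)
  expect_gt(enr$t_statistic, 2)
  expect_lt(enr$p_value, 0.01)
  expect_true(all(enr$per_site$control_count %in% 0:2))

  # identical site and control windows give zero difference
  flat <- e1e2_enrichment_vs_control(sites, genome, mats, halfwidth = 50,
                                     control_offset = 0)
  expect_true(all(flat$per_site$site_count == flat$per_site$control_count))
})
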