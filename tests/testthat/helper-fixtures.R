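# Shared fixture builders; everything is generated in code at test time.

rand_seq <- function(n) paste(sample(BASES_TEST, n, replace = TRUE),
                              collapse = "")
BASES_TEST <- c("A", "C", "G", "T")

# Insert a word at a (1-based) position of a sequence.
insert_word <- function(seq, word, at) {
  substr(seq, at, at + nchar(word) - 1) <- word
  seq
}

# A window with a planted element ("NONE", "E1" or "E1E2").
planted_window <- function(kind, len = 60, spacer = 7, margin = 8) {
  s <- rand_seq(len)
  if (kind == "NONE") return(s)
  word <- if (kind == "E1") "CACGTG" else
    paste0("CACGTG", rand_seq(spacer), "AACGTG")
  at <- sample(margin:(len - nchar(word) - margin + 1), 1)
  insert_word(s, word, at)
}

# Small single-site tag fixture: one planted point source plus uniform
# background, one library, one timepoint.
single_site_tags <- function(strength = 500, genome_length = 20000,
                             center = 10000, kernel_mu = 100,
                             kernel_sd = 25, background_fraction = 0.1,
                             seed = NULL) {
  spec <- site_spec("NONE", center, strength = strength, rel_amplitude = 0)
  bg_rate <- background_fraction / (1 - background_fraction) *
    strength / genome_length
  genome <- generate_genome(genome_length, 0.5, seed = seed)
  pl <- plant_sites(genome, spec, kernel_mu = kernel_mu,
                    kernel_sd = kernel_sd, background_rate = bg_rate,
                    timepoints = 0, libraries = "libA", seed = seed)
  tags <- simulate_chip_tags(pl$truth, depth = round(strength /
                                                       (1 - background_fraction)),
                             seed = seed)
  list(tags = tags, truth = pl$truth)
}

# von Mises sampler (Best-Fisher rejection), angles in radians.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1
    }
  }
  out
}

rvm_hours <- function(n, mu_hours, kappa)
  rvonmises(n, mu_hours * pi / 12, kappa) * 12 / pi
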