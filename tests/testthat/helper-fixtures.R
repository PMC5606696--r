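# shared fixtures and independent oracles

published_pair <- function() default_accumulibacter_params()

# closed-form Haldane evaluation, independent of specific_rate()
haldane <- function(vmax, km, ki, s) vmax * s / ((km + s) * (1 + s / ki))

# draw a random plausible parameter set
random_params <- function(label) {
  kinetic_params(label,
                 vmax = runif(1, 0.5, 1.5),
                 km = runif(1, 0.1, 2),
                 ki = runif(1, 50, 3000))
}

# brute-force crossover oracle: sign-change scan of the rate difference on an
# equally spaced grid; returns midpoints of sign-change brackets
scan_crossovers <- function(a, b, s_max = 100, step = 1e-3) {
  s <- seq(step, s_max, by = step)
  d <- haldane(a$vmax, a$km, a$ki, s) - haldane(b$vmax, b$km, b$ki, s)
  sgn <- sign(d)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  (s[flip] + s[flip + 1]) / 2
}

# hamming identity for equal-length, gap-free sequences: an independent
# route to pairwise identity for generated (indel-free) test sequences
hamming_identity <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  stopifnot(length(va) == length(vb))
  mean(va == vb)
}

# independent greedy clustering using hamming identity
oracle_greedy_otus <- function(seqs, threshold) {
  rep_seq <- character(0)
  membership <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (k in seq_along(rep_seq)) {
      if (hamming_identity(seqs[[i]], rep_seq[[k]]) >= threshold) {
        membership[i] <- k; placed <- TRUE; break
      }
    }
    if (!placed) {
      rep_seq <- c(rep_seq, seqs[[i]])
      membership[i] <- length(rep_seq)
    }
  }
  membership
}

# random clone sequences: a few founder sequences plus near-copies, so
# clustering outcomes are non-trivial
random_library <- function(n = 20, len = 120, n_founders = 4,
                           copy_mut = 0.005, run_id = "rand") {
  founders <- replicate(n_founders, paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
  seqs <- vapply(seq_len(n), function(i) {
    f <- strsplit(sample(founders, 1), "")[[1]]
    hit <- which(runif(len) < copy_mut)
    for (j in hit) f[j] <- sample(setdiff(c("A", "C", "G", "T"), f[j]), 1)
    paste(f, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("c%03d", seq_len(n))
  clone_library(run_id, seqs)
}
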