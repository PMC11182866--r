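# Independent oracles used by the unit and acceptance tests. These recompute
# the quantities by brute force, never through the package's own updates.

# a noise-free synthetic configuration (constant flux, constant sedimentation)
quiet_config <- function(seed = 1, ...) {
  synthetic_config(seed = seed, activity_cv = 0, pigment_noise_sdlog = 0,
                   spectra_noise_sd = 0, geochem_noise_sd = 0, ...)
}

# greedy stratigraphically-constrained clustering, with every merge cost
# recomputed from scratch as SS(union) - SS(a) - SS(b); ties uppermost-first
oracle_coniss <- function(m) {
  m <- as.matrix(m)
  ss <- function(idx) {
    x <- m[idx, , drop = FALSE]
    sum(sweep(x, 2, colMeans(x))^2)
  }
  clusters <- as.list(seq_len(nrow(m)))
  merges <- data.frame(step = integer(), upper_top = integer(),
                       lower_top = integer(), increase = numeric())
  s <- 0L
  while (length(clusters) > 1) {
    s <- s + 1L
    costs <- vapply(seq_len(length(clusters) - 1), function(j)
      ss(c(clusters[[j]], clusters[[j + 1]])) -
        ss(clusters[[j]]) - ss(clusters[[j + 1]]), numeric(1))
    j <- which.min(costs)
    merges <- rbind(merges, data.frame(step = s,
                                       upper_top = clusters[[j]][1],
                                       lower_top = clusters[[j + 1]][1],
                                       increase = costs[j]))
    clusters[[j]] <- c(clusters[[j]], clusters[[j + 1]])
    clusters[[j + 1]] <- NULL
  }
  merges
}

# all permutations of a vector (tiny n only), by recursion
all_permutations <- function(x) {
  n <- length(x)
  if (n <= 1) return(matrix(x, nrow = 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- all_permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

# exact two-sided permutation p-value by enumerating every ordering
oracle_ria_p <- function(values, split_index) {
  perms <- all_permutations(values)
  pre <- seq_len(split_index)
  deltas <- apply(perms, 1, function(v)
    mean(v[-pre]) - mean(v[pre]))
  obs <- mean(values[-pre]) - mean(values[pre])
  mean(abs(deltas) >= abs(obs) - 1e-12)
}
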