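#' Transform a stratigraphic matrix prior to constrained clustering
#'
#' Applies a natural-log transform to selected variables (with an optional
#' pseudo-offset for zeros), then centres every variable to mean 0, with
#' optional scaling to unit variance.
#'
#' @param x numeric matrix or data frame, samples in rows (ordered by
#'   depth), variables in columns.
#' @param log_vars character vector of column names (or logical/integer
#'   index) to log-transform.
#' @param offset pseudo-offset added before the log (0 = none; non-positive
#'   values without an offset are an error).
#' @param center centre each variable to mean 0 (default TRUE).
#' @param scale_unit_variance divide each centred variable by its standard
#'   deviation (default FALSE; constant columns are left centred).
#' @return Numeric matrix of transformed values.
#' @export
strat_transform <- function(x, log_vars = character(), offset = 0,
                            center = TRUE, scale_unit_variance = FALSE) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("`x` must be numeric", call. = FALSE)
  if (length(log_vars)) {
    cols <- if (is.character(log_vars)) match(log_vars, colnames(m)) else log_vars
    if (anyNA(cols)) stop("unknown variable in `log_vars`", call. = FALSE)
    v <- m[, cols, drop = FALSE] + offset
    if (any(v <= 0))
      stop("log of non-positive value; supply a positive `offset`",
           call. = FALSE)
    m[, cols] <- log(v)
  }
  if (center) m <- sweep(m, 2, colMeans(m))
  if (scale_unit_variance) {
    s <- apply(m, 2, stats::sd)
    s[s == 0] <- 1
    m <- sweep(m, 2, s, "/")
  }
  m
}

#' Stratigraphically constrained incremental sum-of-squares clustering (CONISS)
#'
#' Agglomerative clustering in which only stratigraphically adjacent
#' clusters may merge. At each step the adjacent pair whose fusion least
#' increases the total within-cluster (Euclidean) sum of squares is merged;
#' the increase is computed by the incremental (Ward) update
#' `n_i n_j / (n_i + n_j) * ||c_i - c_j||^2` on cluster sizes and centroids.
#' Ties are broken in favour of the stratigraphically uppermost pair, making
#' the merge sequence deterministic. The sum of all merge increments equals
#' the total sum of squares about the grand mean.
#'
#' @param x transformed sample-by-variable matrix (see [strat_transform()]),
#'   rows ordered top to bottom; >= 2 rows.
#' @param depth optional sample depths (cm) used to express zone boundaries;
#'   defaults to the row index.
#' @return An object of class `"coniss"`: a list with `merges` (data frame
#'   `step`, `upper_top`, `lower_top` — top sample indices of the two merged
#'   clusters — and `increase`), `heights` (cumulative dispersion at each
#'   merge), `total_ss`, `n`, and `depth`.
#' @seealso [broken_stick_zones()]
#' @export
coniss <- function(x, depth = NULL) {
  m <- as.matrix(x)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  if (is.null(depth)) depth <- seq_len(n)
  check_increasing(depth, "depth")

  size <- rep(1, n)
  cent <- m                      # cluster centroids, one row per cluster
  top <- seq_len(n)              # top (uppermost) sample index per cluster
  merges <- data.frame(step = integer(n - 1), upper_top = integer(n - 1),
                       lower_top = integer(n - 1), increase = numeric(n - 1))
  for (s in seq_len(n - 1)) {
    k <- length(size)
    i <- seq_len(k - 1)
    d2 <- rowSums((cent[i, , drop = FALSE] - cent[i + 1, , drop = FALSE])^2)
    cost <- size[i] * size[i + 1] / (size[i] + size[i + 1]) * d2
    j <- which.min(cost)         # first minimum = uppermost pair
    merges$step[s] <- s
    merges$upper_top[s] <- top[j]
    merges$lower_top[s] <- top[j + 1]
    merges$increase[s] <- cost[j]
    w <- size[j] + size[j + 1]
    cent[j, ] <- (size[j] * cent[j, ] + size[j + 1] * cent[j + 1, ]) / w
    size[j] <- w
    cent <- cent[-(j + 1), , drop = FALSE]
    size <- size[-(j + 1)]
    top <- top[-(j + 1)]
  }
  total_ss <- sum(sweep(m, 2, colMeans(m))^2)
  structure(list(merges = merges, heights = cumsum(merges$increase),
                 total_ss = total_ss, n = n, depth = depth),
            class = "coniss")
}

#' @export
print.coniss <- function(x, ...) {
  cat(sprintf("CONISS merge tree: %d samples, total dispersion %.4g\n",
              x$n, x$total_ss))
  invisible(x)
}

#' Number of significant stratigraphic zones by the broken-stick model
#'
#' Reads the CONISS merge tree in reverse (largest splits first). The split
#' producing k zones from k-1 explains the proportion
#' `p_k = increment_k / total dispersion`; under the broken-stick null the
#' expected proportion of the k-th largest piece of a unit stick broken into
#' n pieces is `e_k = (1/n) * sum_{j=k}^{n} 1/j`. Successive splits are
#' accepted while `p_k > e_k`; the first failure stops the scan, so the zone
#' hierarchy is contiguous. A degenerate tree with zero total dispersion
#' gives a single zone.
#'
#' @param result a [coniss()] object.
#' @return A list of class `"zonation"`: `n_zones`, `boundaries` (depths
#'   midway between the adjacent samples separating zones, uppermost first),
#'   `zone_table` (data frame `zone`, `top_depth`, `bottom_depth`), and
#'   `stick` (data frame `k`, `observed`, `expected`, `accepted`).
#' @export
broken_stick_zones <- function(result) {
  stopifnot(inherits(result, "coniss"))
  n <- result$n
  inc <- result$merges$increase
  total <- result$total_ss
  if (total <= 0) {
    return(structure(list(n_zones = 1L, boundaries = numeric(0),
                          zone_table = data.frame(zone = 1L,
                                                  top_depth = min(result$depth),
                                                  bottom_depth = max(result$depth)),
                          stick = data.frame(k = integer(0), observed = numeric(0),
                                             expected = numeric(0),
                                             accepted = logical(0))),
                     class = "zonation"))
  }
  inv <- 1 / seq_len(n)
  expected <- rev(cumsum(rev(inv))) / n      # e_k = (1/n) sum_{j=k}^n 1/j
  ks <- 2:n
  observed <- inc[n - ks + 1] / total        # split to k zones = merge n-k+1
  accepted <- logical(length(ks))
  for (i in seq_along(ks)) {
    if (observed[i] > expected[ks[i]]) accepted[i] <- TRUE else break
  }
  n_zones <- if (any(accepted)) max(ks[accepted]) else 1L
  boundaries <- zone_boundaries(result, n_zones)
  depth <- result$depth
  edges <- c(min(depth), boundaries, max(depth))
  zone_table <- data.frame(zone = seq_len(n_zones),
                           top_depth = edges[seq_len(n_zones)],
                           bottom_depth = edges[seq_len(n_zones) + 1])
  structure(list(n_zones = as.integer(n_zones), boundaries = boundaries,
                 zone_table = zone_table,
                 stick = data.frame(k = ks, observed = observed,
                                    expected = expected[ks],
                                    accepted = accepted)),
            class = "zonation")
}

#' Zone boundaries implied by cutting a CONISS tree into k zones
#'
#' Replays the merge sequence until `k` clusters remain and returns the
#' depths midway between the last sample of each zone and the first sample
#' of the next.
#'
#' @param result a [coniss()] object.
#' @param k number of zones, `1 <= k <= n`.
#' @return Numeric vector of `k - 1` boundary depths (uppermost first).
#' @export
zone_boundaries <- function(result, k) {
  stopifnot(inherits(result, "coniss"))
  n <- result$n
  if (k < 1 || k > n) stop("`k` must be between 1 and n", call. = FALSE)
  if (k == 1) return(numeric(0))
  tops <- as.list(seq_len(n))     # cluster top indices, in order
  n_merge <- n - k
  for (s in seq_len(n_merge)) {
    up <- result$merges$upper_top[s]
    j <- which(vapply(tops, `[`, integer(1), 1) == up)
    tops[[j]] <- c(tops[[j]], tops[[j + 1]])
    tops[[j + 1]] <- NULL
  }
  first <- vapply(tops, min, integer(1))
  last_above <- first[-1] - 1L
  (result$depth[last_above] + result$depth[first[-1]]) / 2
}

#' @export
print.zonation <- function(x, ...) {
  cat(sprintf("Broken-stick zonation: %d zone(s)\n", x$n_zones))
  if (length(x$boundaries))
    cat("  boundaries at depth:", paste(signif(x$boundaries, 4), collapse = ", "),
        "\n")
  invisible(x)
}
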