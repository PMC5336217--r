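#' Evanno's delta-K from clustering log-likelihoods
#'
#' Second-difference statistic on mean log-likelihoods over replicate
#' runs: deltaK(K) = |L(K+1) - 2 L(K) + L(K-1)| / sd(L(K)); the most
#' likely number of clusters is the interior K maximizing deltaK.
#'
#' @param runs data.frame with columns `K` and `lnprob` (one row per
#'   run), or a list of `list(K, lnprob)` pairs.
#' @return list with `table` (`K`, `n_runs`, `mean_L`, `sd_L`, `d2`,
#'   `deltaK`) and `best_K`.
#' @export
evanno <- function(runs) {
  if (!is.data.frame(runs))
    runs <- data.frame(K = vapply(runs, function(r) r$K, numeric(1)),
                       lnprob = vapply(runs, function(r) r$lnprob,
                                       numeric(1)))
  agg <- stats::aggregate(lnprob ~ K, data = runs,
                          FUN = function(x) c(n = length(x), m = mean(x),
                                              s = stats::sd(x)))
  tab <- data.frame(K = agg$K, n_runs = agg$lnprob[, "n"],
                    mean_L = agg$lnprob[, "m"], sd_L = agg$lnprob[, "s"])
  tab <- tab[order(tab$K), ]
  if (nrow(tab) < 3L) stop("need a contiguous K range of length >= 3")
  if (any(diff(tab$K) != 1L)) stop("K values must be contiguous")
  if (any(tab$n_runs < 2L))
    stop("need at least 2 runs per K for sd(L)")
  n <- nrow(tab)
  tab$d2 <- tab$deltaK <- NA_real_
  for (i in 2L:(n - 1L)) {
    tab$d2[i] <- abs(tab$mean_L[i + 1L] - 2 * tab$mean_L[i] +
                       tab$mean_L[i - 1L])
    if (tab$sd_L[i] == 0) {
      warning("sd(L) = 0 at K = ", tab$K[i], "; deltaK undefined there")
    } else {
      tab$deltaK[i] <- tab$d2[i] / tab$sd_L[i]
    }
  }
  best <- tab$K[which.max(tab$deltaK)]
  list(table = tab, best_K = best)
}

# all permutations of 1..k (k <= 8)
permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(k - 1L)
  out <- matrix(0L, nrow = k * nrow(sub), ncol = k)
  row <- 1L
  for (i in seq_len(k)) {
    for (s in seq_len(nrow(sub))) {
      rest <- seq_len(k)[-i]
      out[row, ] <- c(i, rest[sub[s, ]])
      row <- row + 1L
    }
  }
  out
}

#' Align replicate clustering runs and average them
#'
#' Cluster labels are arbitrary across runs; each run after the first is
#' column-permuted to minimize the summed squared difference to the first
#' run (exhaustive search over the K! permutations), then the runs are
#' averaged element-wise and rows renormalized.
#'
#' @param runs list of Q matrices with identical dimensions and row
#'   order; alternatively the output of [read_structure_runs()] (the `Q`
#'   elements are extracted).
#' @return averaged Q matrix.
#' @export
align_runs <- function(runs) {
  runs <- lapply(runs, function(r) if (is.list(r) && !is.null(r$Q)) r$Q else r)
  K <- unique(vapply(runs, ncol, integer(1)))
  if (length(K) != 1L) stop("runs disagree on K")
  if (K > 8L)
    stop("exhaustive alignment supports K <= 8 (K! permutations); ",
         "a greedy mode is not implemented")
  nr <- unique(vapply(runs, nrow, integer(1)))
  if (length(nr) != 1L) stop("runs disagree on the entities")
  ref <- runs[[1L]]
  perms <- permutations(K)
  acc <- ref
  for (i in seq_along(runs)[-1L]) {
    q <- runs[[i]]
    costs <- apply(perms, 1L, function(pm) sum((q[, pm] - ref)^2))
    best <- perms[which.min(costs), ]
    acc <- acc + q[, best]
  }
  avg <- acc / length(runs)
  avg / rowSums(avg)
}

#' Classify entities by cluster membership
#'
#' Assigns each entity (individual or population) to the cluster whose
#' membership proportion reaches the threshold, or labels it admixed.
#'
#' @param q Q matrix (rows = entities).
#' @param threshold assignment threshold in (0.5, 1] (default 0.75).
#' @return character vector: cluster index as character, or `"admixed"`.
#' @export
classify_membership <- function(q, threshold = 0.75) {
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must lie in (0.5, 1]")
  apply(q, 1L, function(row) {
    c1 <- which.max(row)
    if (row[c1] >= threshold) as.character(c1) else "admixed"
  })
}
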