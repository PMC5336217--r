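#' Nei's (1978) unbiased genetic distance between populations
#'
#' D = -ln( Jxy / sqrt(Jx Jy) ) with the within-population gene
#' identities corrected for sample size: Jx = (2N sum(x^2) - 1)/(2N - 1)
#' per locus, averaged over loci; Jxy = sum(x y) averaged over loci.
#' Small samples can push an unbiased identity to zero or below; such
#' identities are floored at 1/(allele count) and negative distances are
#' clamped to zero, both flagged.
#'
#' @param dataset a [genotype_dataset()]; every population should have at
#'   least 2 typed individuals.
#' @return symmetric distance matrix with zero diagonal; attribute
#'   `flags` lists clamped or infinite pairs.
#' @export
nei_unbiased_distance <- function(dataset) {
  pops <- dataset$populations
  k <- length(pops)
  nloc <- n_loci(dataset)
  # per locus: freq matrix + typed counts
  P <- vector("list", nloc); Nmat <- matrix(0, nloc, k)
  nal <- integer(nloc)
  for (j in seq_len(nloc)) {
    s <- locus_popsummary(dataset, j)
    if (is.null(s)) next
    P[[j]] <- s$p
    Nmat[j, ] <- s$n
    nal[j] <- length(s$alleles)
  }
  D <- matrix(0, k, k, dimnames = list(pops, pops))
  flags <- character(0)
  jwithin <- matrix(NA_real_, nloc, k)
  for (j in seq_len(nloc)) {
    if (is.null(P[[j]])) next
    for (i in seq_len(k)) {
      n <- Nmat[j, i]
      if (n < 1L) next
      jx <- (2 * n * sum(P[[j]][, i]^2) - 1) / (2 * n - 1)
      if (jx <= 0) {
        jx <- 1 / nal[j]
        flags <- c(flags, paste0("floored identity: ", pops[i], " locus ", j))
      }
      jwithin[j, i] <- jx
    }
  }
  for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
    jxy <- jx <- jy <- numeric(0)
    for (j in seq_len(nloc)) {
      if (is.null(P[[j]]) || is.na(jwithin[j, a]) || is.na(jwithin[j, b]))
        next
      jxy <- c(jxy, sum(P[[j]][, a] * P[[j]][, b]))
      jx <- c(jx, jwithin[j, a]); jy <- c(jy, jwithin[j, b])
    }
    if (length(jxy) == 0L || mean(jxy) <= 0) {
      D[a, b] <- D[b, a] <- Inf
      flags <- c(flags, paste0("infinite distance: ", pops[a], "/", pops[b]))
      next
    }
    d <- -log(mean(jxy) / sqrt(mean(jx) * mean(jy)))
    if (d < 0) {
      flags <- c(flags, paste0("negative distance clamped: ",
                               pops[a], "/", pops[b]))
      d <- 0
    }
    D[a, b] <- D[b, a] <- d
  }
  attr(D, "flags") <- unique(flags)
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via `ape::nj`). Negative branch lengths are
#' reported but flagged.
#'
#' @param distances symmetric numeric matrix with labels, zero diagonal
#'   and finite entries.
#' @return an `ape` `phylo` tree; attribute `negative_branches` gives the
#'   count of negative branch lengths.
#' @export
neighbor_joining <- function(distances) {
  distances <- as.matrix(distances)
  if (nrow(distances) < 3L) stop("need at least 3 labels")
  if (any(!is.finite(distances)))
    stop("distance matrix has non-finite entries; treat infinite ",
         "distances (e.g. clamp or drop populations) before tree building")
  if (max(abs(distances - t(distances))) > 1e-12)
    stop("distance matrix is not symmetric")
  if (is.null(rownames(distances)))
    rownames(distances) <- colnames(distances) <-
      paste0("pop", seq_len(nrow(distances)))
  tree <- ape::nj(distances)
  neg <- sum(tree$edge.length < 0)
  if (neg > 0)
    warning(neg, " negative branch length(s) in the NJ tree")
  attr(tree, "negative_branches") <- neg
  tree
}
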