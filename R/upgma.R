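#' Shared-allele genetic distance between panel lines
#'
#' Pairwise distance `1 - s`, where `s` is the shared-allele score
#' averaged over markers called in both lines (AA vs AA = 1, AA vs AB =
#' 0.5, AA vs BB = 0, AB vs AB = 1).
#'
#' @param gm a `genotype_matrix`.
#' @return symmetric numeric distance matrix.
#' @export
genotype_distance <- function(gm) {
  dosage <- matrix(c(AA = 1, AB = 0.5, BB = 0, NC = NA)[unclass(gm)],
                   nrow = nrow(gm), dimnames = dimnames(gm))
  n <- nrow(dosage)
  d <- matrix(0, n, n, dimnames = list(rownames(gm), rownames(gm)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      diff <- abs(dosage[i, ] - dosage[j, ])
      if (all(is.na(diff)))
        abort("lines '%s' and '%s' share no co-called markers",
              rownames(gm)[i], rownames(gm)[j])
      d[i, j] <- d[j, i] <- mean(diff, na.rm = TRUE)
    }
  }
  d
}

#' Distance matrix and UPGMA dendrogram of a validation panel
#'
#' Average-linkage (UPGMA) clustering of [genotype_distance()], with
#' deterministic tie-breaking by label order, producing a rooted
#' ultrametric tree in Newick format (leaf heights equal; node height =
#' half the merge distance).
#'
#' @param gm a `genotype_matrix` with at least 2 lines.
#' @return list with `distance` (matrix) and `newick` (character).
#' @export
distance_and_upgma <- function(gm) {
  if (nrow(gm) < 2L) abort("need at least 2 lines")
  d <- genotype_distance(gm)
  list(distance = d, newick = upgma_newick(d))
}

# UPGMA on a labelled distance matrix -> Newick string.
# Ties at the minimum merge distance are broken by the lexicographically
# smallest (label_i, label_j) pair, labels taken as each cluster's
# smallest member.
upgma_newick <- function(d) {
  labs <- rownames(d)
  n <- length(labs)
  clusters <- lapply(seq_len(n), function(i)
    list(newick = labs[i], height = 0, size = 1L, min_lab = labs[i]))
  dm <- d
  diag(dm) <- Inf
  while (length(clusters) > 1L) {
    idx <- which(dm == min(dm), arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    key <- vapply(seq_len(nrow(idx)), function(r) {
      a <- clusters[[idx[r, 1L]]]$min_lab
      b <- clusters[[idx[r, 2L]]]$min_lab
      paste(sort(c(a, b)), collapse = "\r")
    }, "")
    pick <- idx[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    h <- dm[i, j] / 2
    ci <- clusters[[i]]; cj <- clusters[[j]]
    # children ordered by label for a canonical string
    kids <- list(ci, cj)[order(c(ci$min_lab, cj$min_lab))]
    nw <- sprintf("(%s:%.10g,%s:%.10g)", kids[[1L]]$newick,
                  h - kids[[1L]]$height, kids[[2L]]$newick,
                  h - kids[[2L]]$height)
    merged <- list(newick = nw, height = h, size = ci$size + cj$size,
                   min_lab = min(ci$min_lab, cj$min_lab))
    # average linkage update weighted by cluster sizes
    others <- setdiff(seq_along(clusters), c(i, j))
    newrow <- vapply(others, function(o)
      (ci$size * dm[i, o] + cj$size * dm[j, o]) / (ci$size + cj$size), 0)
    keep <- others
    dm2 <- rbind(cbind(dm[keep, keep, drop = FALSE], newrow),
                 c(newrow, Inf))
    clusters <- c(clusters[keep], list(merged))
    dm <- dm2
  }
  paste0(clusters[[1L]]$newick, ";")
}
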