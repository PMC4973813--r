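calls_to_dosage <- function(calls) {
  c(AA = 0, AB = 1, BB = 2, NC = NA)[calls]
}

#' Map functions: recombination fraction to centimorgans
#'
#' Kosambi: `d = 25 ln((1 + 2r) / (1 - 2r))` (partial interference);
#' Haldane: `d = -50 ln(1 - 2r)` (no interference). `haldane_inv` is the
#' inverse of the Haldane function, used when simulating crossovers.
#'
#' @param r recombination fraction(s) in \[0, 0.5\].
#' @param d map distance(s) in cM.
#' @return numeric vector (cM, or r for the inverse).
#' @export
kosambi <- function(r) 25 * log((1 + 2 * r) / (1 - 2 * r))

#' @rdname kosambi
#' @export
haldane <- function(r) -50 * log(1 - 2 * r)

#' @rdname kosambi
#' @export
haldane_inv <- function(d) (1 - exp(-2 * d / 100)) / 2

# F2 codominant two-point EM, elementwise over matrices of 9-class
# counts. p = 1 - r; class probabilities
#   P(hom,hom parental) = p^2/4     P(single recombinant classes) = pr/2
#   P(hom,hom recomb)   = r^2/4     P(double het) = (p^2 + r^2)/2
# The double heterozygote mixes phase; EM attributes it 2 r^2/(p^2+r^2)
# expected recombinant gametes.
em_f2 <- function(n, tol = 1e-8, max_iter = 200) {
  nr1 <- n$n01 + n$n10 + n$n12 + n$n21
  nr2 <- n$n02 + n$n20
  ndh <- n$n11
  N <- nr1 + nr2 + ndh + n$n00 + n$n22
  r <- ifelse(N > 0, 0.25, NA_real_)
  for (it in seq_len(max_iter)) {
    p <- 1 - r
    r_new <- (nr1 + 2 * nr2 + ndh * 2 * r^2 / (p^2 + r^2)) / (2 * N)
    r_new <- pmin(pmax(r_new, 0), 0.5)
    if (max(abs(r_new - r), na.rm = TRUE) < tol) { r <- r_new; break }
    r <- r_new
  }
  list(r = r, lod = lod_f2(n, r), n = N)
}

log10p <- function(count, prob) ifelse(count > 0, count * log10(prob), 0)

lod_f2 <- function(n, r) {
  p <- 1 - r
  ll <- function(p, r) {
    log10p(n$n00 + n$n22, p^2 / 4) +
      log10p(n$n01 + n$n10 + n$n12 + n$n21, p * r / 2) +
      log10p(n$n02 + n$n20, r^2 / 4) +
      log10p(n$n11, (p^2 + r^2) / 2)
  }
  pmax(ll(p, r) - ll(0.5, 0.5), 0)
}

# class-count matrices for every marker pair: N_ab[j,k] with a = dosage
# of marker j, b = dosage of marker k
pair_counts <- function(dos) {
  ind <- lapply(0:2, function(g) {
    m <- (dos == g) * 1
    m[is.na(m)] <- 0
    m
  })
  out <- list()
  for (a in 0:2) for (b in 0:2)
    out[[sprintf("n%d%d", a, b)]] <- crossprod(ind[[a + 1]], ind[[b + 1]])
  out
}

#' Two-point linkage over all marker pairs of a population
#'
#' Maximum-likelihood recombination fractions by EM, vectorised over
#' every pair. For F2 codominant data the full 9-class table is used
#' with the double-heterozygote phase mixture. For inbred material
#' (F5 single-seed descent approximated as fixed, RILs) heterozygous
#' calls are uninformative and the 2x2 homozygote table is used, with
#' the observed recombinant fraction R mapped back through the
#' RIL-by-selfing correction `R = 2r / (1 + 2r)`.
#'
#' @param gm a `genotype_matrix`.
#' @param design `"f2"` or `"inbred"`.
#' @param min_n minimum jointly called individuals for a pair to be
#'   reported (default 10).
#' @param tol,max_iter EM convergence controls.
#' @return data.frame with `marker_a`, `marker_b`, `r_hat`, `lod`,
#'   `n_informative`, one row per unordered pair with enough data.
#' @export
pairwise_linkage <- function(gm, design = c("f2", "inbred"), min_n = 10,
                             tol = 1e-8, max_iter = 200) {
  design <- match.arg(design)
  dos <- matrix(calls_to_dosage(unclass(gm)), nrow = nrow(gm),
                dimnames = dimnames(gm))
  n <- pair_counts(dos)
  if (design == "f2") {
    fit <- em_f2(n, tol, max_iter)
  } else {
    par <- n$n00 + n$n22
    rec <- n$n02 + n$n20
    N <- par + rec
    R <- ifelse(N > 0, rec / N, NA_real_)
    r <- ifelse(R >= 0.5, 0.5, R / (2 * (1 - R)))
    ll <- function(R) log10p(par, (1 - R) / 2) + log10p(rec, R / 2)
    Rhat <- pmin(R, 0.5)
    fit <- list(r = r, lod = pmax(ll(Rhat) - ll(0.5), 0), n = N)
  }
  m <- ncol(dos)
  idx <- which(upper.tri(fit$n), arr.ind = TRUE)
  out <- data.frame(marker_a = colnames(dos)[idx[, 1L]],
                    marker_b = colnames(dos)[idx[, 2L]],
                    r_hat = fit$r[idx], lod = fit$lod[idx],
                    n_informative = fit$n[idx], stringsAsFactors = FALSE)
  out[out$n_informative >= min_n, , drop = FALSE]
}

#' Two-point recombination fraction for one pair of call vectors
#'
#' @param calls_a,calls_b call vectors (AA/AB/BB/NC) over the same
#'   individuals; for `design = "f2_dominant_pair"`, `calls_a` is a
#'   dominant phenotype coded "A_" (dominant) / "aa" (recessive) / "NC".
#' @param design `"f2_codominant"`, `"f2_dominant_pair"` or `"inbred"`.
#' @param tol,max_iter EM convergence controls.
#' @return one-row data.frame `r_hat`, `lod`, `n_informative`.
#' @export
estimate_rf <- function(calls_a, calls_b,
                        design = c("f2_codominant", "f2_dominant_pair",
                                   "inbred"),
                        tol = 1e-8, max_iter = 200) {
  design <- match.arg(design)
  if (design == "f2_dominant_pair")
    return(estimate_rf_dominant(calls_a, calls_b, tol, max_iter))
  gm <- genotype_matrix(matrix(c(calls_a, calls_b), ncol = 2,
                               dimnames = list(paste0("i", seq_along(calls_a)),
                                               c("a", "b"))))
  res <- pairwise_linkage(gm, if (design == "inbred") "inbred" else "f2",
                          min_n = 0, tol = tol, max_iter = max_iter)
  if (nrow(res) == 0L || res$n_informative < 10)
    abort("fewer than 10 jointly informative individuals")
  res[, c("r_hat", "lod", "n_informative")]
}

# dominant trait x codominant marker, generic EM over class coefficient
# triples (w0, w1, w2): P_c = w0 p^2 + w1 p r + w2 r^2. The phase of the
# dominant allele relative to the marker is unknown, so both phasings
# are fitted and the higher-likelihood one kept.
estimate_rf_dominant <- function(trait, marker, tol = 1e-8,
                                 max_iter = 200) {
  t <- ifelse(trait == "A_", 1L, ifelse(trait == "aa", 0L, NA_integer_))
  m <- calls_to_dosage(marker)
  ok <- !is.na(t) & !is.na(m)
  if (sum(ok) < 10) abort("fewer than 10 jointly informative individuals")
  t <- t[ok]; m <- m[ok]
  # coefficients for classes keyed "t m", coupling phase (A with marker AA)
  W <- list("1 0" = c(1 / 4, 1 / 2, 0), "1 1" = c(1 / 2, 1 / 2, 1 / 2),
            "1 2" = c(0, 1 / 2, 1 / 4), "0 0" = c(0, 0, 1 / 4),
            "0 1" = c(0, 1 / 2, 0), "0 2" = c(1 / 4, 0, 0))
  fit_phase <- function(mm) {
    key <- paste(t, mm)
    cnt <- table(factor(key, levels = names(W)))
    n <- as.numeric(cnt)
    w <- do.call(rbind, W)
    N <- sum(n)
    r <- 0.25
    for (it in seq_len(max_iter)) {
      p <- 1 - r
      Pc <- w[, 1] * p^2 + w[, 2] * p * r + w[, 3] * r^2
      Ej <- ifelse(Pc > 0, (w[, 2] * p * r + 2 * w[, 3] * r^2) / Pc, 0)
      r_new <- min(max(sum(n * Ej) / (2 * N), 0), 0.5)
      if (abs(r_new - r) < tol) { r <- r_new; break }
      r <- r_new
    }
    p <- 1 - r
    Pc <- w[, 1] * p^2 + w[, 2] * p * r + w[, 3] * r^2
    P5 <- w[, 1] * 0.25 + w[, 2] * 0.25 + w[, 3] * 0.25
    ll <- sum(log10p(n, pmax(Pc, 1e-300)))
    list(r = r, ll = ll, lod = max(ll - sum(log10p(n, P5)), 0), n = N)
  }
  f1 <- fit_phase(m)
  f2 <- fit_phase(2L - m)   # repulsion: swap marker alleles
  best <- if (f1$ll >= f2$ll) f1 else f2
  data.frame(r_hat = best$r, lod = best$lod, n_informative = best$n)
}

#' Partition markers into linkage groups
#'
#' Single-linkage transitive closure over pairs with `lod >= min_lod`
#' and `r_hat <= max_r`.
#'
#' @param linkages pair table from [pairwise_linkage()].
#' @param markers character vector of all retained markers (isolated
#'   markers become singleton groups).
#' @param min_lod LOD threshold (default 5).
#' @param max_r recombination-fraction threshold (default 0.3).
#' @return list of character vectors (groups), largest first; ties by
#'   first member.
#' @export
group_markers <- function(linkages, markers, min_lod = 5, max_r = 0.3) {
  keep <- linkages$lod >= min_lod & linkages$r_hat <= max_r
  g <- igraph::graph_from_data_frame(
    linkages[keep, c("marker_a", "marker_b"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = markers))
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(groups, sort)
  groups[order(-vapply(groups, length, 1L),
               vapply(groups, `[`, "", 1L))]
}

# symmetric r matrix for a set of markers from the pair table; missing
# pairs get r = 0.5 (unlinked)
r_matrix <- function(linkages, markers) {
  m <- length(markers)
  r <- matrix(0.5, m, m, dimnames = list(markers, markers))
  diag(r) <- 0
  sel <- linkages$marker_a %in% markers & linkages$marker_b %in% markers
  l <- linkages[sel, , drop = FALSE]
  r[cbind(l$marker_a, l$marker_b)] <- l$r_hat
  r[cbind(l$marker_b, l$marker_a)] <- l$r_hat
  r
}

sarf <- function(order, d) sum(d[cbind(order[-length(order)], order[-1L])])

#' Order the markers of one linkage group
#'
#' Co-segregating markers (pairwise `r_hat` below `bin_tol`) are binned
#' first. Bin order minimises the sum of adjacent recombination
#' fractions (SARF): greedy chaining from the closest bin pair, then
#' 2-opt segment reversals to a local optimum. Orientation is
#' normalised so the lexicographically smaller terminal marker comes
#' first.
#'
#' @param group character vector of the group's markers.
#' @param linkages pair table from [pairwise_linkage()].
#' @param bin_tol co-segregation threshold on `r_hat` (default 1e-9).
#' @return list with `bins` (ordered list of marker character vectors)
#'   and `adjacent_r` (r between consecutive bins, average linkage).
#' @export
order_markers <- function(group, linkages, bin_tol = 1e-9) {
  group <- sort(group)
  r <- r_matrix(linkages, group)
  # bin by transitive closure of r ~ 0
  adj <- r <= bin_tol
  gb <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            diag = FALSE)
  comp <- igraph::components(gb)$membership
  bins <- lapply(split(group, comp), sort)
  bins <- bins[order(vapply(bins, `[`, "", 1L))]
  nb <- length(bins)
  if (nb == 1L)
    return(list(bins = bins, adjacent_r = numeric()))
  # average-linkage distance between bins
  d <- matrix(0, nb, nb)
  for (i in seq_len(nb - 1L)) for (j in seq(i + 1L, nb)) {
    d[i, j] <- d[j, i] <- mean(r[bins[[i]], bins[[j]], drop = FALSE])
  }
  dimnames(d) <- list(seq_len(nb), seq_len(nb))
  if (nb == 2L) {
    ord <- 1:2
  } else if (nb <= 8L) {
    ord <- exhaustive_order(d)   # exact SARF minimum at small sizes
  } else {
    ord <- greedy_chain(d)
    ord <- two_opt(ord, d)
  }
  # orientation: lexicographically smallest terminal marker first
  first_lab <- bins[[ord[1L]]][1L]
  last_lab <- bins[[ord[length(ord)]]][1L]
  if (last_lab < first_lab) ord <- rev(ord)
  bins <- bins[ord]
  adj_r <- vapply(seq_len(nb - 1L), function(i)
    d[ord[i], ord[i + 1L]], 0)
  list(bins = bins, adjacent_r = adj_r)
}

exhaustive_order <- function(d) {
  n <- nrow(d)
  dimnames(d) <- NULL
  best <- seq_len(n); best_val <- Inf
  rec <- function(ord, left, val) {
    if (val >= best_val) return(invisible())
    if (length(left) == 0L) {
      best <<- ord; best_val <<- val
      return(invisible())
    }
    for (x in left)
      rec(c(ord, x), setdiff(left, x),
          val + if (length(ord)) d[ord[length(ord)], x] else 0)
  }
  # fix orientation by trying each start; pruning keeps this cheap
  rec(integer(), seq_len(n), 0)
  best
}

greedy_chain <- function(d) {
  nb <- nrow(d)
  dd <- d; diag(dd) <- Inf
  start <- which(dd == min(dd), arr.ind = TRUE)[1L, ]
  chain <- as.integer(start)
  left <- setdiff(seq_len(nb), chain)
  while (length(left) > 0L) {
    head_d <- d[chain[1L], left]
    tail_d <- d[chain[length(chain)], left]
    if (min(head_d) < min(tail_d)) {
      pick <- left[which.min(head_d)]
      chain <- c(pick, chain)
    } else {
      pick <- left[which.min(tail_d)]
      chain <- c(chain, pick)
    }
    left <- setdiff(left, pick)
  }
  chain
}

two_opt <- function(ord, d, max_sweeps = 50L) {
  n <- length(ord)
  dimnames(d) <- NULL
  best <- sum(d[cbind(ord[-n], ord[-1L])])
  for (s in seq_len(max_sweeps)) {
    improved <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        cand <- ord
        cand[i:j] <- rev(cand[i:j])
        val <- sum(d[cbind(cand[-n], cand[-1L])])
        if (val < best - 1e-12) {
          ord <- cand; best <- val; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  ord
}

#' Convert ordered loci to cumulative map positions
#'
#' Adjacent recombination fractions are transformed to cM with the
#' chosen map function and accumulated; the first locus sits at 0 cM.
#' Fractions at the 0.5 ceiling are clamped to `ceiling_cm`.
#'
#' @param ordered an [order_markers()] result.
#' @param map_function `"kosambi"` (default) or `"haldane"`.
#' @param ceiling_cm distance assigned to unresolvable (r ~ 0.5)
#'   adjacencies (default 50).
#' @param group label for the group column.
#' @return data.frame: `marker`, `group`, `position_cM`, `bin`.
#' @export
space_markers <- function(ordered, map_function = c("kosambi", "haldane"),
                          ceiling_cm = 50, group = "G1") {
  map_function <- match.arg(map_function)
  f <- if (map_function == "kosambi") kosambi else haldane
  r <- pmin(ordered$adjacent_r, 0.5)
  d <- ifelse(r >= 0.5 - 1e-9, ceiling_cm, f(r))
  pos <- c(0, cumsum(d))
  do.call(rbind, lapply(seq_along(ordered$bins), function(i) {
    data.frame(marker = ordered$bins[[i]], group = group,
               position_cM = pos[i], bin = i, stringsAsFactors = FALSE)
  }))
}

#' Build a genetic map for one population
#'
#' Full per-population pipeline: pairwise linkage, LOD/r grouping, SARF
#' ordering and map-function spacing. Groups are labelled `G1..Gn` by
#' decreasing size; markers in singleton groups are reported unplaced.
#'
#' @param gm a `genotype_matrix` (after QC/distortion filtering).
#' @param design `"f2"` or `"inbred"`.
#' @param min_lod,max_r grouping thresholds (defaults 5 and 0.3).
#' @param map_function `"kosambi"` or `"haldane"`.
#' @param min_n minimum informative individuals per pair.
#' @return object of class `genetic_map`: list with `table` (marker,
#'   group, position_cM, bin), `unplaced` (character), `linkages` (the
#'   pair table), `design`, `map_function`.
#' @export
build_map <- function(gm, design = c("f2", "inbred"), min_lod = 5,
                      max_r = 0.3, map_function = c("kosambi", "haldane"),
                      min_n = 10) {
  design <- match.arg(design)
  map_function <- match.arg(map_function)
  linkages <- pairwise_linkage(gm, design, min_n = min_n)
  groups <- group_markers(linkages, colnames(gm), min_lod, max_r)
  placed <- groups[vapply(groups, length, 1L) >= 2L]
  unplaced <- unlist(groups[vapply(groups, length, 1L) < 2L],
                     use.names = FALSE)
  tabs <- lapply(seq_along(placed), function(i) {
    ord <- order_markers(placed[[i]], linkages)
    space_markers(ord, map_function, group = paste0("G", i))
  })
  tab <- if (length(tabs)) do.call(rbind, tabs) else
    data.frame(marker = character(), group = character(),
               position_cM = numeric(), bin = integer())
  structure(list(table = tab, unplaced = unplaced %||% character(),
                 linkages = linkages, design = design,
                 map_function = map_function),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  ng <- length(unique(x$table$group))
  cat(sprintf(
    "genetic_map: %d markers in %d groups (%d unplaced), %.1f cM total\n",
    nrow(x$table), ng, length(x$unplaced),
    sum(tapply(x$table$position_cM, x$table$group, max))))
  invisible(x)
}

#' Place a dominant trait locus on a genetic map
#'
#' The trait is coded as a dominant marker; its recombination fraction
#' to every mapped locus is estimated two-point (dominant x codominant
#' EM), the best-linked group chosen, and the trait inserted at the
#' position that minimises the SARF increase. A 3:1 segregation
#' chi-square test is run first and reported.
#'
#' @param trait character vector over the population's individuals:
#'   `"A_"` (dominant phenotype), `"aa"`, or `"NC"`.
#' @param gm the population `genotype_matrix` (same individual order).
#' @param map a `genetic_map` built from `gm`.
#' @return list: `group`, `position_cM`, `flank_left`, `flank_right`
#'   (nearest codominant markers each side, equal when the trait
#'   co-segregates with a locus), `interval_cM`, `r_flanks`,
#'   `segregation` (observed counts, chi-square statistic, p-value).
#' @export
map_trait_locus <- function(trait, gm, map) {
  nd <- sum(trait == "A_"); nr <- sum(trait == "aa")
  if (nd == 0L || nr == 0L) abort("trait is monomorphic")
  chi <- sum((c(nd, nr) - c(3, 1) / 4 * (nd + nr))^2 /
               (c(3, 1) / 4 * (nd + nr)))
  seg <- list(n_dominant = nd, n_recessive = nr, chisq = chi,
              p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE))
  tab <- map$table
  rf <- do.call(rbind, lapply(unique(tab$marker), function(m) {
    fit <- estimate_rf_dominant(trait, unclass(gm)[, m])
    cbind(data.frame(marker = m), fit)
  }))
  best <- rf[which.max(rf$lod), ]
  grp <- tab$group[match(best$marker, tab$marker)]
  gt <- tab[tab$group == grp, , drop = FALSE]
  loci <- gt[!duplicated(gt$bin), , drop = FALSE]
  loci <- loci[order(loci$position_cM), , drop = FALSE]
  rr <- rf$r_hat[match(loci$marker, rf$marker)]
  # EM converges geometrically towards 0, so co-segregation is "r below
  # numerical noise", not exact zero
  if (any(rr <= 1e-6)) {
    i <- which(rr <= 1e-6)[1L]
    return(list(group = grp, position_cM = loci$position_cM[i],
                flank_left = loci$marker[i], flank_right = loci$marker[i],
                interval_cM = 0, r_flanks = c(0, 0), segregation = seg))
  }
  nl <- nrow(loci)
  # SARF increase of inserting the trait at each of the nl+1 slots
  delta <- numeric(nl + 1L)
  delta[1L] <- rr[1L]
  delta[nl + 1L] <- rr[nl]
  if (nl > 1L) {
    adj <- vapply(seq_len(nl - 1L), function(i) {
      l <- map$linkages
      hit <- (l$marker_a == loci$marker[i] & l$marker_b == loci$marker[i + 1L]) |
             (l$marker_b == loci$marker[i] & l$marker_a == loci$marker[i + 1L])
      if (any(hit)) l$r_hat[hit][1L] else 0.5
    }, 0)
    delta[2:nl] <- rr[-nl] + rr[-1L] - adj
  }
  slot <- which.min(delta)
  if (slot == 1L) {
    list(group = grp, position_cM = loci$position_cM[1L] -
           min(kosambi(min(rr[1L], 0.49)), 50),
         flank_left = NA_character_, flank_right = loci$marker[1L],
         interval_cM = NA_real_, r_flanks = c(NA, rr[1L]),
         segregation = seg)
  } else if (slot == nl + 1L) {
    list(group = grp, position_cM = loci$position_cM[nl] +
           min(kosambi(min(rr[nl], 0.49)), 50),
         flank_left = loci$marker[nl], flank_right = NA_character_,
         interval_cM = NA_real_, r_flanks = c(rr[nl], NA),
         segregation = seg)
  } else {
    i <- slot - 1L
    frac <- rr[i] / (rr[i] + rr[i + 1L])
    pos <- loci$position_cM[i] +
      frac * (loci$position_cM[i + 1L] - loci$position_cM[i])
    list(group = grp, position_cM = pos, flank_left = loci$marker[i],
         flank_right = loci$marker[i + 1L],
         interval_cM = loci$position_cM[i + 1L] - loci$position_cM[i],
         r_flanks = c(rr[i], rr[i + 1L]), segregation = seg)
  }
}
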