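# Independent oracles used to pin expected values. These deliberately use
# naive exhaustive strategies, not the package's algorithms.

# -- reciprocal best hits by direct definition over all contig pairs ----
oracle_rbh <- function(hits_ab, hits_ba, min_len = 100, max_e = 1e-30) {
  f <- function(h) h[h$alignment_length >= min_len & h$e_value <= max_e, ,
                     drop = FALSE]
  hits_ab <- f(hits_ab); hits_ba <- f(hits_ba)
  best_of <- function(h, q) {
    hh <- h[h$query_id == q, , drop = FALSE]
    if (nrow(hh) == 0L) return(NA_character_)
    # best per subject first (multi-HSP: best HSP represents the pair)
    subs <- unique(hh$subject_id)
    per <- t(vapply(subs, function(s) {
      x <- hh[hh$subject_id == s, ]
      x <- x[order(x$e_value, -x$bit_score), ]
      c(x$e_value[1L], x$bit_score[1L])
    }, c(0, 0)))
    o <- order(per[, 1L], -per[, 2L])
    if (length(subs) > 1L &&
        per[o[1L], 1L] == per[o[2L], 1L] &&
        per[o[1L], 2L] == per[o[2L], 2L]) return(NA_character_)
    subs[o[1L]]
  }
  pairs <- list()
  for (a in unique(hits_ab$query_id)) {
    b <- best_of(hits_ab, a)
    if (is.na(b)) next
    if (identical(best_of(hits_ba, b), a))
      pairs[[length(pairs) + 1L]] <- c(a, b)
  }
  if (length(pairs) == 0L)
    return(data.frame(contig_a = character(), contig_b = character(),
                      stringsAsFactors = FALSE))
  out <- as.data.frame(do.call(rbind, pairs), stringsAsFactors = FALSE)
  names(out) <- c("contig_a", "contig_b")
  out <- out[order(out$contig_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random hit table over contig sets for the RBH oracle comparison
random_hit_table <- function(queries, subjects, density = 0.6) {
  rows <- list()
  for (q in queries) for (s in subjects) {
    if (runif(1) > density) next
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = q, subject_id = s, percent_identity = 95,
      alignment_length = sample(c(50L, 150L, 300L), 1L),
      mismatches = 1L, gap_opens = 0L, query_start = 1L, query_end = 100L,
      subject_start = 1L, subject_end = 100L,
      e_value = 10^-sample(10:80, 1L),
      bit_score = sample(50:500, 1L), strand = "+",
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(fabmap::parse_hits(character()))
  do.call(rbind, rows)
}

# -- global alignment score by exhaustive enumeration ------------------
# enumerate every alignment (move strings over D/U/L), score with affine
# gaps: a run of k gap columns in one sequence costs open + (k-1)*extend
oracle_align_score <- function(a, b, match = 2, mismatch = -3,
                               gap_open = -8, gap_extend = -1) {
  ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
  best <- -Inf
  rec <- function(i, j, prev, sc) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, sc); return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1L, j + 1L, "D",
          sc + if (ca[i] == cb[j]) match else mismatch)
    if (i <= length(ca))
      rec(i + 1L, j, "U", sc + if (prev == "U") gap_extend else gap_open)
    if (j <= length(cb))
      rec(i, j + 1L, "L", sc + if (prev == "L") gap_extend else gap_open)
  }
  rec(1L, 1L, "", 0)
  best
}

# -- two-point F2 ML by grid search ------------------------------------
# counts: 3x3 matrix n[a+1, b+1] of dosage classes
oracle_grid_rf <- function(counts, step = 1e-4) {
  grid <- seq(step, 0.5, by = step)
  ll <- vapply(grid, function(r) {
    p <- 1 - r
    P <- matrix(c(p^2 / 4, p * r / 2, r^2 / 4,
                  p * r / 2, (p^2 + r^2) / 2, p * r / 2,
                  r^2 / 4, p * r / 2, p^2 / 4), 3, 3, byrow = TRUE)
    sum(ifelse(counts > 0, counts * log(P), 0))
  }, 0)
  grid[which.max(ll)]
}

# -- minimum SARF order by exhaustive permutation ----------------------
oracle_sarf_min <- function(d) {
  n <- nrow(d)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  min(vapply(perms(seq_len(n)), function(p)
    sum(d[cbind(p[-n], p[-1L])]), 0))
}

# Kendall rank correlation between two orderings of (a subset of) the
# same markers
kendall_tau_orders <- function(true_order, est_order) {
  common <- intersect(true_order, est_order)
  a <- match(common, true_order)
  b <- match(common, est_order)
  stats::cor(a, b, method = "kendall")
}
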