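#' Score KASP assay quality from 2-D fluorescence clusters
#'
#' Automates the manual I-IV quality scale: a silhouette-like
#' separation score is computed from per-call cluster centroids - for
#' each called point, (distance to the nearest other centroid minus
#' distance to its own centroid) / max(the two), clipped to \[0, 1\] and
#' averaged - then combined with the call rate as
#' `separation * call_rate^no_call_weight` and binned at
#' I >= 0.8 > II >= 0.6 > III >= 0.4 > IV.
#'
#' @param points data.frame with columns `x`, `y`, `call` (calls in
#'   AA/AB/BB/NC).
#' @param marker marker identifier carried through.
#' @param no_call_weight exponent on the call rate (default 0.5).
#' @param thresholds lower bounds of classes I-III (default
#'   `c(0.8, 0.6, 0.4)`).
#' @return one-row data.frame: `marker`, `call_rate`,
#'   `separation_score`, `composite`, `quality_class`.
#' @export
classify_quality <- function(points, marker = NA_character_,
                             no_call_weight = 0.5,
                             thresholds = c(I = 0.8, II = 0.6, III = 0.4)) {
  if (nrow(points) < 6L) abort("need at least 6 samples to score quality")
  called <- points[points$call != "NC", , drop = FALSE]
  call_rate <- nrow(called) / nrow(points)
  classes <- unique(called$call)
  if (length(classes) < 2L) {
    return(data.frame(marker = marker, call_rate = call_rate,
                      separation_score = 0, composite = 0,
                      quality_class = "IV", stringsAsFactors = FALSE))
  }
  cent <- lapply(split(called[, c("x", "y")], called$call), colMeans)
  sep <- vapply(seq_len(nrow(called)), function(i) {
    p <- c(called$x[i], called$y[i])
    own <- sqrt(sum((p - cent[[called$call[i]]])^2))
    oth <- min(vapply(cent[setdiff(names(cent), called$call[i])],
                      function(cc) sqrt(sum((p - cc)^2)), 0))
    v <- (oth - own) / max(own, oth)
    min(max(v, 0), 1)
  }, 0)
  separation <- mean(sep)
  composite <- separation * call_rate^no_call_weight
  cls <- if (composite >= thresholds[["I"]]) "I"
         else if (composite >= thresholds[["II"]]) "II"
         else if (composite >= thresholds[["III"]]) "III"
         else "IV"
  data.frame(marker = marker, call_rate = call_rate,
             separation_score = separation, composite = composite,
             quality_class = cls, stringsAsFactors = FALSE)
}

#' Iteratively remove high no-call lines and markers
#'
#' Repeatedly recomputes per-line and per-marker no-call rates and
#' removes the single worst offender (lines and markers pooled; ties
#' are broken marker-first, then lexicographically) until all rates are
#' at or below `max_nc`.
#'
#' @param gm a `genotype_matrix`.
#' @param max_nc maximum tolerated no-call fraction (default 0.06).
#' @return list with `matrix` (filtered `genotype_matrix`) and
#'   `removed` (data.frame `what` = line/marker, `id`, `nc_rate`, in
#'   removal order).
#' @export
iterative_no_call_filter <- function(gm, max_nc = 0.06) {
  removed <- data.frame(what = character(), id = character(),
                        nc_rate = numeric(), stringsAsFactors = FALSE)
  repeat {
    if (nrow(gm) == 0L || ncol(gm) == 0L) abort("matrix exhausted")
    nc <- unclass(gm) == "NC"
    line_rate <- rowMeans(nc)
    marker_rate <- colMeans(nc)
    worst <- max(c(line_rate, marker_rate))
    if (worst <= max_nc) break
    # ties: marker first, then lexicographic
    cand_m <- names(marker_rate)[marker_rate == worst]
    if (length(cand_m) > 0L) {
      id <- sort(cand_m)[1L]
      removed <- rbind(removed, data.frame(what = "marker", id = id,
                                           nc_rate = worst))
      gm <- gm[, colnames(gm) != id, drop = FALSE]
    } else {
      id <- sort(names(line_rate)[line_rate == worst])[1L]
      removed <- rbind(removed, data.frame(what = "line", id = id,
                                           nc_rate = worst))
      gm <- gm[rownames(gm) != id, , drop = FALSE]
    }
  }
  list(matrix = genotype_matrix(unclass(gm)), removed = removed)
}

#' Allele frequency, gene diversity and PIC of one marker
#'
#' Frequencies count two alleles per homozygote and one of each per
#' heterozygote; no-calls are excluded. `p` is the frequency of the
#' first (A) allele. Gene diversity (expected heterozygosity) is `2pq`;
#' `PIC = 1 - p^2 - q^2 - 2 p^2 q^2`. The minor allele is flagged
#' private when it occurs in one discovery line and in no other panel
#' line.
#'
#' @param gm a `genotype_matrix`.
#' @param marker marker identifier.
#' @param discovery_lines optional character(2) of discovery line ids.
#' @return one-row data.frame: `marker`, `n_called`, `p`, `q`,
#'   `gene_diversity`, `pic`, `private_to`.
#' @export
allele_stats <- function(gm, marker, discovery_lines = NULL) {
  if (!marker %in% colnames(gm)) abort("marker '%s' not present", marker)
  calls <- unclass(gm)[, marker]
  called <- calls[calls != "NC"]
  if (length(called) == 0L) abort("marker '%s' is all no-call", marker)
  nA <- 2 * sum(called == "AA") + sum(called == "AB")
  nB <- 2 * sum(called == "BB") + sum(called == "AB")
  p <- nA / (nA + nB); q <- 1 - p
  private <- NA_character_
  if (!is.null(discovery_lines)) {
    minor <- if (p <= q) "A" else "B"
    has_minor <- if (minor == "A") calls %in% c("AA", "AB")
                 else calls %in% c("BB", "AB")
    carriers <- names(calls)[has_minor]
    in_disc <- intersect(carriers, discovery_lines)
    if (length(carriers) > 0L && length(in_disc) == 1L &&
        all(carriers %in% discovery_lines))
      private <- in_disc
  }
  data.frame(marker = marker, n_called = length(called), p = p, q = q,
             gene_diversity = 2 * p * q,
             pic = 1 - p^2 - q^2 - 2 * p^2 * q^2,
             private_to = private, stringsAsFactors = FALSE)
}

#' Per-line heterozygosity and homozygosity percentages
#'
#' @param gm a `genotype_matrix`.
#' @param line line identifier; default all lines.
#' @return data.frame `line`, `n_called`, `pct_het`, `pct_hom`
#'   (percentages of called genotypes; they sum to 100).
#' @export
line_heterozygosity <- function(gm, line = rownames(gm)) {
  out <- do.call(rbind, lapply(line, function(l) {
    if (!l %in% rownames(gm)) abort("line '%s' not present", l)
    calls <- unclass(gm)[l, ]
    called <- calls[calls != "NC"]
    if (length(called) == 0L) abort("line '%s' is all no-call", l)
    het <- 100 * mean(called == "AB")
    data.frame(line = l, n_called = length(called), pct_het = het,
               pct_hom = 100 - het, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Audit observed discovery-line calls against sequence predictions
#'
#' A marker is concordant iff both discovery lines' observed calls are
#' homozygous and equal the alleles predicted from the discovery
#' sequences. Markers where either discovery line is no-call are
#' excluded from the denominator and logged.
#'
#' @param gm a `genotype_matrix` containing the two discovery lines.
#' @param predicted data.frame with columns `marker`, `line_a_call`,
#'   `line_b_call` (each "AA" or "BB").
#' @param discovery_lines character(2): ids of discovery lines a and b.
#' @return list with `per_marker` (marker, observed calls, `match`),
#'   `excluded` (markers skipped for no-calls), and `fraction`
#'   (matches / assessed markers).
#' @export
concordance_audit <- function(gm, predicted, discovery_lines) {
  stopifnot(length(discovery_lines) == 2L)
  obs_a <- unclass(gm)[discovery_lines[1L], predicted$marker]
  obs_b <- unclass(gm)[discovery_lines[2L], predicted$marker]
  nc <- obs_a == "NC" | obs_b == "NC"
  per <- data.frame(marker = predicted$marker, observed_a = obs_a,
                    observed_b = obs_b,
                    match = obs_a == predicted$line_a_call &
                            obs_b == predicted$line_b_call,
                    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  assessed <- per[!nc, , drop = FALSE]
  list(per_marker = assessed, excluded = predicted$marker[nc],
       fraction = if (nrow(assessed)) mean(assessed$match) else NA_real_)
}

#' Segregation-distortion screen for one marker
#'
#' A marker is removed when a homozygous parental class is absent, or
#' when its distortion ratio leaves the design's accepted band. For F2
#' populations the ratio is homozygote:heterozygote, `(AA+BB)/AB`, with
#' band (0.4, 2.1) around the Mendelian expectation 1. For inbred
#' material (F5 single-seed descent, RILs) the ratio is
#' heterozygote:homozygote, `AB/(AA+BB)`, with band (0.045, 0.25); the
#' published cut-offs can only bracket the F5 expectation of about 1/15
#' in this orientation, so that reading is adopted (see the methods
#' vignette).
#'
#' @param calls character vector of calls for one marker in one
#'   segregating population.
#' @param design `"f2"` or `"inbred"`.
#' @param bounds optional numeric(2) lower/upper ratio bounds
#'   (defaults: f2 `c(0.4, 2.1)`, inbred `c(0.045, 0.25)`).
#' @param marker marker identifier carried through.
#' @return one-row data.frame: `marker`, `rule`, `ratio`, `verdict`
#'   (`keep`/`remove`), `reason` (`skew`, `missing_parental_allele` or
#'   NA).
#' @export
distortion_filter <- function(calls, design = c("f2", "inbred"),
                              bounds = NULL, marker = NA_character_) {
  design <- match.arg(design)
  if (is.null(bounds))
    bounds <- if (design == "f2") c(0.4, 2.1) else c(0.045, 0.25)
  nAA <- sum(calls == "AA"); nBB <- sum(calls == "BB")
  nAB <- sum(calls == "AB")
  ratio <- if (design == "f2") {
    if (nAB == 0L) Inf else (nAA + nBB) / nAB
  } else {
    if (nAA + nBB == 0L) Inf else nAB / (nAA + nBB)
  }
  verdict <- "keep"; reason <- NA_character_
  if (nAA == 0L || nBB == 0L) {
    verdict <- "remove"; reason <- "missing_parental_allele"
  } else if (ratio > bounds[2L] || ratio < bounds[1L]) {
    verdict <- "remove"; reason <- "skew"
  }
  data.frame(marker = marker, rule = design, ratio = ratio,
             verdict = verdict, reason = reason, stringsAsFactors = FALSE)
}

#' Screen every marker of a population for distortion
#'
#' @param gm a `genotype_matrix` of one segregating population.
#' @inheritParams distortion_filter
#' @return data.frame, one [distortion_filter()] row per marker.
#' @export
distortion_screen <- function(gm, design = c("f2", "inbred"),
                              bounds = NULL) {
  design <- match.arg(design)
  out <- do.call(rbind, lapply(colnames(gm), function(m) {
    distortion_filter(unclass(gm)[, m], design, bounds, marker = m)
  }))
  rownames(out) <- NULL
  out
}
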