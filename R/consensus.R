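#' Bundle per-population maps with merge weights
#'
#' @param maps list of `genetic_map` objects or map tables (columns
#'   `marker`, `group`, `position_cM`).
#' @param weights positive numeric merge weights, one per map; the
#'   recommended default is the population size.
#' @param populations population identifiers (default `pop1..popN`).
#' @return object of class `weighted_map_set`.
#' @export
weighted_map_set <- function(maps, weights,
                             populations = paste0("pop", seq_along(maps))) {
  if (length(maps) != length(weights)) abort("one weight per map required")
  if (any(weights <= 0)) abort("weights must be positive")
  tabs <- lapply(maps, function(m) if (inherits(m, "genetic_map")) m$table else m)
  structure(list(tables = tabs, weights = weights,
                 populations = populations),
            class = "weighted_map_set")
}

# one input linkage group as an ordered list of position levels
# (markers sharing a position are one level) plus the positions
group_levels <- function(tab) {
  tab <- tab[order(tab$position_cM, tab$marker), , drop = FALSE]
  pos <- sort(unique(tab$position_cM))
  list(levels = lapply(pos, function(p) tab$marker[tab$position_cM == p]),
       pos = pos)
}

# directed edges (from, to, weight) implied by one map's level structure
levels_to_edges <- function(lv, weight) {
  n <- length(lv$levels)
  if (n < 2L) return(data.frame(from = character(), to = character(),
                                weight = numeric()))
  do.call(rbind, lapply(seq_len(n - 1L), function(i) {
    expand.grid(from = lv$levels[[i]], to = lv$levels[[i + 1L]],
                weight = weight, stringsAsFactors = FALSE)
  }))
}

# markers inside non-trivial strongly connected components
conflicted_markers <- function(edges) {
  if (nrow(edges) == 0L) return(character())
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")])
  sc <- igraph::components(g, mode = "strong")
  big <- which(tabulate(sc$membership) > 1L)
  names(sc$membership)[sc$membership %in% big]
}

merge_one_group <- function(inputs, weights, pops) {
  # inputs: list of level structures (one per contributing population)
  # rescale each input's positions to the longest input length
  lens <- vapply(inputs, function(lv)
    if (length(lv$pos)) max(lv$pos) - min(lv$pos) else 0, 0)
  L <- max(lens)
  if (length(inputs) > 1L && L > 0) {
    inputs <- lapply(inputs, function(lv) {
      span <- max(lv$pos) - min(lv$pos)
      if (span > 0) lv$pos <- (lv$pos - min(lv$pos)) * L / span
      lv
    })
  }
  conflicts <- data.frame(marker = character(), population = character(),
                          weight = numeric(), stringsAsFactors = FALSE)
  repeat {
    edges <- do.call(rbind, lapply(seq_along(inputs), function(k)
      levels_to_edges(inputs[[k]], weights[k])))
    bad <- conflicted_markers(edges)
    if (length(bad) == 0L) break
    # greedy weighted deletion: the (marker, map) occurrence whose
    # removal frees the most conflicted vertices per unit weight
    cand <- do.call(rbind, lapply(seq_along(inputs), function(k) {
      present <- bad[bad %in% unlist(inputs[[k]]$levels)]
      if (length(present) == 0L) return(NULL)
      data.frame(marker = present, k = k, weight = weights[k],
                 stringsAsFactors = FALSE)
    }))
    score <- vapply(seq_len(nrow(cand)), function(i) {
      trial <- inputs
      trial[[cand$k[i]]] <- drop_marker(trial[[cand$k[i]]], cand$marker[i])
      e2 <- do.call(rbind, lapply(seq_along(trial), function(k)
        levels_to_edges(trial[[k]], weights[k])))
      (length(bad) - length(conflicted_markers(e2))) / cand$weight[i]
    }, 0)
    o <- order(-score, cand$weight, cand$marker, cand$k)
    pick <- cand[o[1L], ]
    inputs[[pick$k]] <- drop_marker(inputs[[pick$k]], pick$marker)
    conflicts <- rbind(conflicts,
                       data.frame(marker = pick$marker,
                                  population = pops[pick$k],
                                  weight = pick$weight))
  }
  # weighted mean of rescaled positions per marker
  marks <- unique(unlist(lapply(inputs, function(lv) unlist(lv$levels))))
  wpos <- vapply(marks, function(m) {
    num <- 0; den <- 0
    for (k in seq_along(inputs)) {
      lv <- inputs[[k]]
      hit <- which(vapply(lv$levels, function(x) m %in% x, TRUE))
      if (length(hit)) {
        num <- num + weights[k] * lv$pos[hit]
        den <- den + weights[k]
      }
    }
    num / den
  }, 0)
  supp <- vapply(marks, function(m) {
    paste(pops[vapply(seq_along(inputs), function(k)
      m %in% unlist(inputs[[k]]$levels), TRUE)], collapse = ";")
  }, "")
  # linearise: topological order, ties by mean position then name
  edges <- do.call(rbind, lapply(seq_along(inputs), function(k)
    levels_to_edges(inputs[[k]], weights[k])))
  ord <- topo_order(marks, edges, wpos)
  pos <- cummax(wpos[ord])
  pos <- pos - pos[1L]
  out <- data.frame(marker = ord, position_cM = unname(pos),
                    supporting = unname(supp[ord]),
                    stringsAsFactors = FALSE)
  list(table = out, conflicts = conflicts)
}

drop_marker <- function(lv, m) {
  for (i in seq_along(lv$levels)) lv$levels[[i]] <- setdiff(lv$levels[[i]], m)
  keep <- vapply(lv$levels, length, 1L) > 0L
  lv$levels <- lv$levels[keep]
  lv$pos <- lv$pos[keep]
  lv
}

# Kahn's algorithm with deterministic priority (position, then name)
topo_order <- function(marks, edges, priority) {
  indeg <- setNames(integer(length(marks)), marks)
  succ <- setNames(vector("list", length(marks)), marks)
  if (nrow(edges) > 0L) {
    ek <- unique(edges[, c("from", "to")])
    for (i in seq_len(nrow(ek))) {
      indeg[[ek$to[i]]] <- indeg[[ek$to[i]]] + 1L
      succ[[ek$from[i]]] <- c(succ[[ek$from[i]]], ek$to[i])
    }
  }
  out <- character(0)
  avail <- names(indeg)[indeg == 0L]
  while (length(avail) > 0L) {
    pick <- avail[order(priority[avail], avail)][1L]
    out <- c(out, pick)
    avail <- setdiff(avail, pick)
    for (s in succ[[pick]]) {
      indeg[[s]] <- indeg[[s]] - 1L
      if (indeg[[s]] == 0L) avail <- c(avail, s)
    }
  }
  if (length(out) != length(marks)) abort("cycle survived resolution")
  out
}

#' Merge per-population maps into a consensus map
#'
#' Input linkage groups are matched across populations when they share
#' at least two markers (transitively). Within each matched set, every
#' input order contributes a directed graph (adjacent-locus edges,
#' weighted by the map's weight); the union is made acyclic by greedily
#' deleting the marker occurrence that frees the most conflicted
#' markers per unit weight (each deletion logged), then linearised in
#' topological order with positions taken as the weighted mean of
#' input positions rescaled to the longest input group.
#'
#' @param ws a [weighted_map_set()].
#' @return object of class `consensus_map`: list with `table` (`marker`,
#'   `group`, `position_cM`, `bin`, `supporting`), `conflicts` (deleted
#'   occurrences), `group_members` (input groups merged into each
#'   consensus group).
#' @export
merge_maps <- function(ws) {
  stopifnot(inherits(ws, "weighted_map_set"))
  # group-matching graph: node = (population, group)
  nodes <- do.call(rbind, lapply(seq_along(ws$tables), function(k) {
    data.frame(k = k, group = unique(ws$tables[[k]]$group),
               stringsAsFactors = FALSE)
  }))
  nodes$id <- paste(ws$populations[nodes$k], nodes$group, sep = ":")
  members <- lapply(seq_len(nrow(nodes)), function(i) {
    t <- ws$tables[[nodes$k[i]]]
    t$marker[t$group == nodes$group[i]]
  })
  el <- list()
  if (nrow(nodes) > 1L) {
    for (i in seq_len(nrow(nodes) - 1L)) for (j in seq(i + 1L, nrow(nodes))) {
      if (nodes$k[i] != nodes$k[j] &&
          length(intersect(members[[i]], members[[j]])) >= 2L)
        el[[length(el) + 1L]] <- c(nodes$id[i], nodes$id[j])
    }
  }
  g <- igraph::graph_from_data_frame(
    if (length(el)) do.call(rbind, el) else
      matrix(character(), ncol = 2), directed = FALSE,
    vertices = nodes$id)
  comp <- igraph::components(g)$membership
  merged <- list(); conflicts <- list(); gmembers <- list()
  for (cc in unique(comp)) {
    ids <- names(comp)[comp == cc]
    sel <- match(ids, nodes$id)
    inputs <- lapply(sel, function(i) {
      t <- ws$tables[[nodes$k[i]]]
      group_levels(t[t$group == nodes$group[i], , drop = FALSE])
    })
    res <- merge_one_group(inputs, ws$weights[nodes$k[sel]],
                           ws$populations[nodes$k[sel]])
    merged[[length(merged) + 1L]] <- res$table
    conflicts[[length(conflicts) + 1L]] <- res$conflicts
    gmembers[[length(gmembers) + 1L]] <- ids
  }
  o <- order(-vapply(merged, nrow, 1L),
             vapply(merged, function(t) t$marker[1L], ""))
  merged <- merged[o]; gmembers <- gmembers[o]
  tab <- do.call(rbind, lapply(seq_along(merged), function(i) {
    t <- merged[[i]]
    t$group <- paste0("G", i)
    t$bin <- match(t$position_cM, sort(unique(t$position_cM)))
    t[, c("marker", "group", "position_cM", "bin", "supporting")]
  }))
  rownames(tab) <- NULL
  structure(list(table = tab,
                 conflicts = do.call(rbind, conflicts),
                 group_members = setNames(gmembers,
                                          paste0("G", seq_along(gmembers)))),
            class = "consensus_map")
}

#' @export
print.consensus_map <- function(x, ...) {
  s <- map_stats(x)
  cat(sprintf(
    "consensus_map: %d markers, %d loci, %d groups, %.1f cM (mean gap %.1f, max %.1f)\n",
    s$n_markers, s$n_loci, s$n_groups, s$total_length_cM, s$mean_gap_cM,
    s$max_gap_cM))
  invisible(x)
}

#' Label consensus groups with chromosome names
#'
#' Each group is labelled by majority vote of its anchor markers
#' (markers with previously known chromosome assignments). A tied vote
#' leaves the group unlabelled with a warning; the same label winning
#' two groups is an error.
#'
#' @param cm a `consensus_map`.
#' @param anchors data.frame with columns `marker`, `chromosome`.
#' @return the consensus map with a `chromosome` column added to its
#'   table (NA where unlabelled).
#' @export
assign_chromosomes <- function(cm, anchors) {
  tab <- cm$table
  lab <- setNames(rep(NA_character_, length(unique(tab$group))),
                  unique(tab$group))
  tallies <- list()
  for (g in names(lab)) {
    mk <- tab$marker[tab$group == g]
    votes <- anchors$chromosome[anchors$marker %in% mk]
    if (length(votes) == 0L) next
    t <- sort(table(votes), decreasing = TRUE)
    if (length(t) > 1L && t[1L] == t[2L]) {
      warning(sprintf("group %s: tied chromosome vote, left unlabelled", g))
      next
    }
    lab[g] <- names(t)[1L]
    tallies[[g]] <- t
  }
  dup <- names(table(na.omit(lab)))[table(na.omit(lab)) > 1L]
  if (length(dup) > 0L) {
    claimers <- names(lab)[!is.na(lab) & lab == dup[1L]]
    abort("chromosome %s claimed by groups %s (votes: %s)", dup[1L],
          paste(claimers, collapse = ", "),
          paste(vapply(claimers, function(g)
            paste(names(tallies[[g]]), tallies[[g]], sep = "=",
                  collapse = "/"), ""), collapse = " vs "))
  }
  cm$table$chromosome <- lab[cm$table$group]
  cm
}

#' Summary statistics of a consensus map
#'
#' Mean adjacent gap is computed as total length / (unique loci -
#' number of groups); the marker count includes all co-segregating bin
#' members while the locus count counts bins.
#'
#' @param cm a `consensus_map` (or `genetic_map`).
#' @return list: `total_length_cM`, `group_lengths_cM`, `n_markers`,
#'   `n_loci`, `n_groups`, `mean_gap_cM`, `max_gap_cM`.
#' @export
map_stats <- function(cm) {
  tab <- if (inherits(cm, "consensus_map") || inherits(cm, "genetic_map"))
    cm$table else cm
  gl <- tapply(tab$position_cM, tab$group, function(p) max(p) - min(p))
  loci <- tapply(tab$position_cM, tab$group,
                 function(p) length(unique(p)))
  gaps <- unlist(lapply(split(tab$position_cM, tab$group),
                        function(p) diff(sort(unique(p)))))
  list(total_length_cM = sum(gl),
       group_lengths_cM = gl,
       n_markers = nrow(tab),
       n_loci = sum(loci),
       n_groups = length(gl),
       mean_gap_cM = gap_summary(sum(gl), sum(loci), length(gl)),
       max_gap_cM = if (length(gaps)) max(gaps) else 0)
}

#' Mean adjacent gap from printed map totals
#'
#' `total_length / (n_loci - n_groups)`: the denominator is the number
#' of adjacent-locus intervals in a map with `n_loci` unique loci
#' spread over `n_groups` linkage groups.
#'
#' @param total_length_cM total map length in cM.
#' @param n_loci number of unique (non-co-segregating) loci.
#' @param n_groups number of linkage groups.
#' @return mean gap in cM.
#' @export
gap_summary <- function(total_length_cM, n_loci, n_groups) {
  total_length_cM / (n_loci - n_groups)
}

#' Read / write map tables as CSV
#'
#' @param path CSV path (`marker`, `group`, `position_cM`, optionally
#'   `bin`, `supporting`).
#' @export
read_map <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_map
#' @param map a map table, `genetic_map` or `consensus_map`.
#' @export
write_map <- function(map, path) {
  tab <- if (inherits(map, "genetic_map") || inherits(map, "consensus_map"))
    map$table else map
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
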