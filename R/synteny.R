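chrom_number <- function(x) {
  n <- suppressWarnings(as.integer(sub("^[A-Za-z]*", "", x)))
  n
}

#' Link mapped markers to reference-genome gene positions
#'
#' One link per consensus-map marker with a qualifying best hit
#' (`e_value <= max_e`, best = lowest E then highest bit score) against
#' the reference CDS set. Markers named `Vf_MtXg..._ZZZ` fall back to
#' the gene id embedded in their name when no hits are available
#' (flagged `name-derived`). Links to genes absent from the gene table
#' are dropped with a warning.
#'
#' @param cm a `consensus_map` (or its table).
#' @param marker_hits hit table (query = marker id, subject = gene id),
#'   or NULL to rely on name-derived links only.
#' @param gene_coords gene table with columns `gene_id`, `chrom`,
#'   `start`, `end` (1-based inclusive), as from [read_gene_models()].
#' @param max_e E-value threshold (default 1e-37).
#' @return data.frame of links: `marker`, `vf_group`, `vf_pos`,
#'   `ref_gene`, `ref_chromosome`, `ref_pos` (gene midpoint, bp),
#'   `e_value`, `source` (`hit`/`name-derived`).
#' @export
build_links <- function(cm, marker_hits = NULL, gene_coords,
                        max_e = 1e-37) {
  tab <- if (inherits(cm, "consensus_map")) cm$table else cm
  best <- if (!is.null(marker_hits))
    unique_best_subject(qualify_hits(marker_hits, 1L, max_e))
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    mk <- tab$marker[i]
    gene <- NA_character_; e <- NA_real_; src <- NA_character_
    if (!is.null(best) && mk %in% best$query_id) {
      gene <- best$subject_id[best$query_id == mk][1L]
      h <- marker_hits[marker_hits$query_id == mk &
                         marker_hits$subject_id == gene, , drop = FALSE]
      e <- min(h$e_value)
      src <- "hit"
    } else {
      m <- regmatches(mk, regexec("^Vf_(Mt[1-8]g[0-9]+)_[0-9]+$", mk))[[1L]]
      if (length(m) == 2L) {
        gene <- m[2L]; e <- 0; src <- "name-derived"
      }
    }
    if (is.na(gene)) next
    gi <- match(gene, gene_coords$gene_id)
    if (is.na(gi)) {
      warning(sprintf("marker %s: gene %s absent from gene table; link dropped",
                      mk, gene))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      marker = mk, vf_group = tab$group[i], vf_pos = tab$position_cM[i],
      ref_gene = gene, ref_chromosome = chrom_number(gene_coords$chrom[gi]),
      ref_pos = (gene_coords$start[gi] + gene_coords$end[gi]) / 2,
      e_value = e, source = src, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(marker = character(), vf_group = character(),
               vf_pos = numeric(), ref_gene = character(),
               ref_chromosome = integer(), ref_pos = numeric(),
               e_value = numeric(), source = character())
  out[order(out$vf_group, out$vf_pos, out$marker), , drop = FALSE]
}

# longest strictly monotone (in ref_pos) subsequence of the unused
# links, with at most max_skip unused links skipped between consecutive
# members; returns indices into `sub` or NULL
best_chain <- function(ref, avail, dir, max_skip) {
  idx <- which(avail)
  m <- length(idx)
  if (m == 0L) return(NULL)
  L <- rep(1L, m); prev <- rep(0L, m)
  for (i in seq_len(m)) {
    for (j in seq_len(i - 1L)) {
      ok <- if (dir > 0) ref[idx[j]] < ref[idx[i]]
            else ref[idx[j]] > ref[idx[i]]
      if (ok && (i - j - 1L) <= max_skip && L[j] + 1L > L[i]) {
        L[i] <- L[j] + 1L; prev[i] <- j
      }
    }
  }
  e <- which.max(L)
  chain <- integer()
  while (e != 0L) { chain <- c(idx[e], chain); e <- prev[e] }
  chain
}

#' Detect colinear synteny blocks
#'
#' Chains are called per (linkage group, reference chromosome) on links
#' sorted by cM position: the longest run of links whose reference
#' positions are strictly monotone - tolerating up to `max_skip`
#' interleaved off-trend links, which are skipped, not consumed - is
#' extracted repeatedly until no run of at least `min_block` links
#' remains. A link at the pivot of an inversion fits both the ascending
#' and the descending chain; pivot links are reassigned between
#' adjacent opposite-orientation blocks to balance their sizes, which
#' makes the split deterministic. Orientation is the trend sign.
#'
#' @param links table from [build_links()].
#' @param min_block minimum links per block (default 3).
#' @param max_skip tolerated interleaved off-trend links between
#'   consecutive block members (default 2).
#' @return data.frame of blocks: `vf_group`, `ref_chromosome`,
#'   `orientation`, `n_links`, `vf_start`, `vf_end`, `ref_start`,
#'   `ref_end`, `markers` (";"-joined, in chain order).
#' @export
detect_blocks <- function(links, min_block = 3, max_skip = 2) {
  out <- list()
  for (key in unique(paste(links$vf_group, links$ref_chromosome))) {
    sub <- links[paste(links$vf_group, links$ref_chromosome) == key, ,
                 drop = FALSE]
    sub <- sub[order(sub$vf_pos, sub$marker), , drop = FALSE]
    avail <- rep(TRUE, nrow(sub))
    chains <- list()
    repeat {
      up <- best_chain(sub$ref_pos, avail, +1, max_skip)
      dn <- best_chain(sub$ref_pos, avail, -1, max_skip)
      lens <- c(length(up), length(dn))
      if (max(lens) < min_block) break
      pick <- if (lens[1L] >= lens[2L]) up else dn
      chains[[length(chains) + 1L]] <-
        list(idx = pick, dir = if (lens[1L] >= lens[2L]) 1L else -1L)
      avail[pick] <- FALSE
    }
    # pivot reassignment between adjacent opposite-orientation chains
    if (length(chains) > 1L) {
      ord <- order(vapply(chains, function(c) min(c$idx), 0L))
      chains <- chains[ord]
      changed <- TRUE
      while (changed) {
        changed <- FALSE
        for (k in seq_len(length(chains) - 1L)) {
          x <- chains[[k]]; y <- chains[[k + 1L]]
          if (x$dir == y$dir) next
          if (max(x$idx) < min(y$idx) &&
              length(x$idx) >= length(y$idx) + 2L) {
            piv <- x$idx[length(x$idx)]
            fits <- if (y$dir > 0) sub$ref_pos[piv] < sub$ref_pos[y$idx[1L]]
                    else sub$ref_pos[piv] > sub$ref_pos[y$idx[1L]]
            if (fits) {
              chains[[k]]$idx <- x$idx[-length(x$idx)]
              chains[[k + 1L]]$idx <- c(piv, y$idx)
              changed <- TRUE
            }
          } else if (max(x$idx) < min(y$idx) &&
                     length(y$idx) >= length(x$idx) + 2L) {
            piv <- y$idx[1L]
            fits <- if (x$dir > 0)
              sub$ref_pos[piv] > sub$ref_pos[x$idx[length(x$idx)]]
            else sub$ref_pos[piv] < sub$ref_pos[x$idx[length(x$idx)]]
            if (fits) {
              chains[[k + 1L]]$idx <- y$idx[-1L]
              chains[[k]]$idx <- c(x$idx, piv)
              changed <- TRUE
            }
          }
        }
      }
    }
    for (ch in chains) {
      chain <- ch$idx
      if (length(chain) < min_block) next
      out[[length(out) + 1L]] <- data.frame(
        vf_group = sub$vf_group[1L],
        ref_chromosome = sub$ref_chromosome[1L],
        orientation = if (ch$dir > 0L) "+" else "-",
        n_links = length(chain),
        vf_start = min(sub$vf_pos[chain]),
        vf_end = max(sub$vf_pos[chain]),
        ref_start = min(sub$ref_pos[chain]),
        ref_end = max(sub$ref_pos[chain]),
        markers = paste(sub$marker[chain], collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(vf_group = character(), ref_chromosome = integer(),
                      orientation = character(), n_links = integer(),
                      vf_start = numeric(), vf_end = numeric(),
                      ref_start = numeric(), ref_end = numeric(),
                      markers = character()))
  do.call(rbind, out)
}

#' List candidate genes in a trait interval via synteny
#'
#' Both flanking markers must link to the same reference chromosome;
#' the interval spans from the smaller to the larger extent of the two
#' linked genes (flanking genes included), and every gene model fully
#' inside it is returned in physical order with its annotation, ready
#' for keyword filtering.
#'
#' @param flank_a,flank_b marker identifiers of the flanking markers.
#' @param links table from [build_links()].
#' @param gene_models gene table (`gene_id`, `chrom`, `start`, `end`,
#'   `annotation`), as from [read_gene_models()].
#' @param keyword optional regular expression to filter annotations.
#' @return list: `chromosome`, `span_bp`, `genes` (ordered data.frame).
#' @export
interval_gene_content <- function(flank_a, flank_b, links, gene_models,
                                  keyword = NULL) {
  la <- links[links$marker == flank_a, , drop = FALSE]
  lb <- links[links$marker == flank_b, , drop = FALSE]
  if (nrow(la) == 0L || nrow(lb) == 0L)
    abort("flanking marker without a synteny link")
  if (la$ref_chromosome[1L] != lb$ref_chromosome[1L])
    abort("interval not syntenic: flanks link to chromosomes %d and %d",
          la$ref_chromosome[1L], lb$ref_chromosome[1L])
  ga <- gene_models[gene_models$gene_id == la$ref_gene[1L], ]
  gb <- gene_models[gene_models$gene_id == lb$ref_gene[1L], ]
  lo <- min(ga$start, gb$start)
  hi <- max(ga$end, gb$end)
  onchr <- gene_models[chrom_number(gene_models$chrom) ==
                         la$ref_chromosome[1L], , drop = FALSE]
  inside <- onchr[onchr$start >= lo & onchr$end <= hi, , drop = FALSE]
  inside <- inside[order((inside$start + inside$end) / 2), , drop = FALSE]
  if (!is.null(keyword))
    inside <- inside[grepl(keyword, inside$annotation), , drop = FALSE]
  rownames(inside) <- NULL
  list(chromosome = la$ref_chromosome[1L], span_bp = hi - lo + 1,
       genes = inside)
}
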