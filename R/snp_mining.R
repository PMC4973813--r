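# ambiguity code for an unordered base pair (secondary mismatches in the
# consensus are written as IUPAC codes, not chosen arbitrarily)
iupac_pair <- function(x, y) {
  key <- paste(sort(c(x, y)), collapse = "")
  c(AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M")[key]
}

#' Call candidate SNPs from a pairwise contig alignment
#'
#' Every substitution column (both bases present, different, and
#' unambiguous A/C/G/T) becomes one candidate. A candidate fails the
#' flank rule when either contig offset lies closer than `min_flank`
#' bases to its sequence end. Gap columns are never SNPs; substitutions
#' adjacent to indels are still reported.
#'
#' The consensus sequence takes the shared base where the lines agree,
#' the present base where one line has a gap, and an IUPAC ambiguity
#' code at other (secondary) substitution columns; the focal variant is
#' written `[X/Y]` in `consensus_flank`.
#'
#' @param aln a [global_align()] result for one anchored contig pair.
#' @param min_flank minimum flank length in bases (default 50).
#' @param contig_a,contig_b identifiers used to form `snp_id`.
#' @return data.frame, one row per substitution column: `snp_id`,
#'   `contig_a`, `contig_b`, `column`, `pos_a`, `pos_b` (0-based),
#'   `allele_a`, `allele_b`, `flank_left`, `flank_right`,
#'   `consensus_flank`, `n_secondary`, `status`, `reason`.
#' @export
call_candidate_snps <- function(aln, min_flank = 50, contig_a = "a",
                                contig_b = "b") {
  stopifnot(inherits(aln, "pairwise_alignment"))
  ca <- strsplit(aln$aligned_a, "")[[1L]]
  cb <- strsplit(aln$aligned_b, "")[[1L]]
  len_a <- sum(ca != "-"); len_b <- sum(cb != "-")
  acgt <- c("A", "C", "G", "T")
  is_sub <- ca != "-" & cb != "-" & ca != cb & ca %in% acgt & cb %in% acgt
  idx <- which(is_sub)
  if (length(idx) == 0L) return(empty_candidates())

  # consensus over all columns; substitution columns get ambiguity codes
  cons <- ifelse(ca == "-", cb, ca)
  cons[idx] <- vapply(idx, function(i) iupac_pair(ca[i], cb[i]), "")

  out <- do.call(rbind, lapply(idx, function(i) {
    pos_a <- aln$column_map$pos_a[i]
    pos_b <- aln$column_map$pos_b[i]
    left <- if (i > 1L) paste(cons[seq_len(i - 1L)], collapse = "") else ""
    right <- if (i < length(cons))
      paste(cons[seq(i + 1L, length(cons))], collapse = "") else ""
    ok <- min(pos_a, len_a - 1L - pos_a) >= min_flank &&
          min(pos_b, len_b - 1L - pos_b) >= min_flank
    data.frame(
      snp_id = sprintf("%s:%s:%d", contig_a, contig_b, pos_a),
      contig_a = contig_a, contig_b = contig_b, column = i,
      pos_a = pos_a, pos_b = pos_b, allele_a = ca[i], allele_b = cb[i],
      flank_left = left, flank_right = right,
      n_secondary = length(idx) - 1L,
      status = if (ok) "pass" else "fail",
      reason = if (ok) NA_character_ else "flank",
      stringsAsFactors = FALSE)
  }))
  out$consensus_flank <- with(out, sprintf("%s[%s/%s]%s", flank_left,
                                           allele_a, allele_b, flank_right))
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(snp_id = character(), contig_a = character(),
             contig_b = character(), column = integer(), pos_a = integer(),
             pos_b = integer(), allele_a = character(),
             allele_b = character(), flank_left = character(),
             flank_right = character(), n_secondary = integer(),
             status = character(), reason = character(),
             consensus_flank = character(), stringsAsFactors = FALSE)
}

#' Project reference-gene intron positions onto a contig
#'
#' Given the ungapped hit of a contig on a reference gene's spliced
#' transcript and the gene's exon model, maps each exon-exon boundary
#' that falls inside the aligned span to a 0-based contig offset (the
#' last contig base of the exon preceding the junction).
#'
#' @param contig_start,contig_end,transcript_start,transcript_end hit
#'   coordinates, 1-based inclusive, contig vs spliced transcript.
#' @param exon_lengths exon lengths (bases) of the gene model in
#'   transcript order.
#' @param source_gene gene identifier carried through.
#' @return list of class `gene_structure_projection` with
#'   `intron_insertion_points` (0-based contig offsets, strictly
#'   increasing) and `source_gene`.
#' @export
project_gene_structure <- function(contig_start, contig_end,
                                   transcript_start, transcript_end,
                                   exon_lengths, source_gene = NA_character_) {
  if (any(exon_lengths <= 0)) abort("exon lengths must be positive")
  n <- length(exon_lengths)
  # 0-based transcript offsets of the last base of each non-final exon
  bnd <- if (n > 1L) cumsum(exon_lengths)[-n] - 1L else integer()
  ts0 <- transcript_start - 1L
  te0 <- transcript_end - 1L
  inside <- bnd >= ts0 & bnd <= te0 - 1L
  pts <- (bnd[inside] - ts0) + (contig_start - 1L)
  if (is.unsorted(pts, strictly = TRUE)) abort("projection not increasing")
  structure(list(intron_insertion_points = as.integer(pts),
                 source_gene = source_gene),
            class = "gene_structure_projection")
}

#' Build a projection from an exon table
#'
#' Validates and converts a GFF3-style exon table (1-based inclusive
#' genomic coordinates, sorted, non-overlapping) to exon lengths, then
#' calls [project_gene_structure()].
#'
#' @param exons data.frame with columns `start`, `end` (1-based
#'   inclusive), in transcription order.
#' @inheritParams project_gene_structure
#' @return A `gene_structure_projection`.
#' @export
project_from_exons <- function(exons, contig_start, contig_end,
                               transcript_start, transcript_end,
                               source_gene = NA_character_) {
  if (nrow(exons) > 1L) {
    if (is.unsorted(exons$start, strictly = TRUE))
      abort("exons are not sorted")
    if (any(exons$start[-1L] <= exons$end[-nrow(exons)]))
      abort("exons overlap")
  }
  project_gene_structure(contig_start, contig_end, transcript_start,
                         transcript_end, exons$end - exons$start + 1L,
                         source_gene)
}

#' Apply the intron-proximity rule and truncate flanks at junctions
#'
#' A candidate SNP with an intron junction closer than `min_dist`
#' exonic bases on either side fails with reason `intron_near`.
#' Otherwise its flanks are truncated at the nearest junctions (so that
#' assay primers cannot span a splice site) and the flank rule is
#' re-checked against the truncated flanks.
#'
#' @param snps candidate table from [call_candidate_snps()].
#' @param proj a `gene_structure_projection` in the coordinate frame of
#'   contig A.
#' @param aln the alignment the candidates came from (maps contig-A
#'   offsets to consensus columns for exact truncation).
#' @param min_dist minimum SNP-to-junction distance in bases (default 50).
#' @return the candidate table with updated flanks/status.
#' @export
apply_intron_rule <- function(snps, proj, aln, min_dist = 50) {
  pts <- proj$intron_insertion_points
  if (length(pts) == 0L || nrow(snps) == 0L) return(snps)
  for (k in seq_len(nrow(snps))) {
    if (snps$status[k] != "pass") next
    pos <- snps$pos_a[k]
    # insertion point = last base of the exon left of the junction
    left_pts <- pts[pts < pos]
    right_pts <- pts[pts >= pos]
    avail_l <- if (length(left_pts)) pos - max(left_pts) - 1L else Inf
    avail_r <- if (length(right_pts)) min(right_pts) - pos else Inf
    if (avail_l < min_dist || avail_r < min_dist) {
      snps$status[k] <- "fail"; snps$reason[k] <- "intron_near"
      next
    }
    # truncate flanks at the junction columns (exact via the column map)
    col <- snps$column[k]
    if (is.finite(avail_l)) {
      cut_col <- aln$column_map$column[match(max(left_pts),
                                             aln$column_map$pos_a)]
      snps$flank_left[k] <- substr(snps$flank_left[k],
                                   nchar(snps$flank_left[k]) -
                                     (col - cut_col - 1L) + 1L,
                                   nchar(snps$flank_left[k]))
    }
    if (is.finite(avail_r)) {
      cut_col <- aln$column_map$column[match(min(right_pts),
                                             aln$column_map$pos_a)]
      snps$flank_right[k] <- substr(snps$flank_right[k], 1L,
                                    cut_col - col)
    }
    snps$consensus_flank[k] <- sprintf("%s[%s/%s]%s", snps$flank_left[k],
                                       snps$allele_a[k], snps$allele_b[k],
                                       snps$flank_right[k])
  }
  snps
}

# cluster 1-based inclusive intervals into overlapping runs; returns the
# number of distinct non-overlapping loci
count_loci <- function(start, end) {
  lo <- pmin(start, end); hi <- pmax(start, end)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  n_loci <- 1L
  reach <- hi[1L]
  for (i in seq_along(lo)[-1L]) {
    if (lo[i] > reach) n_loci <- n_loci + 1L
    reach <- max(reach, hi[i])
  }
  n_loci
}

#' Exclude multi-copy and multi-locus candidate SNPs
#'
#' A candidate whose consensus flank has qualifying hits (`e_value <=
#' max_e`) to more than one contig of either source transcriptome fails
#' with reason `paralog`; qualifying hits on more than one reference
#' chromosome, or at two non-overlapping loci of one chromosome, fail
#' with reason `multi_locus`.
#'
#' @param snps candidate table; `snp_id` must match `query_id` in the
#'   hit tables.
#' @param hits_vs_a,hits_vs_b hits of the flanks vs each transcriptome.
#' @param hits_vs_chrom optional hits of the flanks vs reference
#'   chromosomes (subject = chromosome id).
#' @param max_e E-value threshold (default 1e-30).
#' @return the candidate table with updated status.
#' @export
exclude_multilocus <- function(snps, hits_vs_a, hits_vs_b,
                               hits_vs_chrom = NULL, max_e = 1e-30) {
  qa <- qualify_hits(hits_vs_a, 1L, max_e)
  qb <- qualify_hits(hits_vs_b, 1L, max_e)
  # keep every qualifying HSP here: two HSPs on one chromosome are the
  # signature of a second locus
  qc <- if (!is.null(hits_vs_chrom))
    hits_vs_chrom[hits_vs_chrom$e_value <= max_e, , drop = FALSE]
  for (k in seq_len(nrow(snps))) {
    if (snps$status[k] != "pass") next
    id <- snps$snp_id[k]
    na <- length(unique(qa$subject_id[qa$query_id == id]))
    nb <- length(unique(qb$subject_id[qb$query_id == id]))
    if (na > 1L || nb > 1L) {
      snps$status[k] <- "fail"; snps$reason[k] <- "paralog"
      next
    }
    if (!is.null(qc)) {
      h <- qc[qc$query_id == id, , drop = FALSE]
      if (nrow(h) > 0L) {
        multi <- length(unique(h$subject_id)) > 1L
        if (!multi)
          multi <- count_loci(h$subject_start, h$subject_end) > 1L
        if (multi) {
          snps$status[k] <- "fail"; snps$reason[k] <- "multi_locus"
        }
      }
    }
  }
  snps
}

#' Format a KASP assay name
#'
#' Assays are named `Vf_MtXgYYYYYY_ZZZ`: the reference ortholog
#' identifier (whose first digit is the reference chromosome) plus a
#' zero-padded serial, unique per gene.
#'
#' @param gene_id reference gene identifier (`MtXgYYYYYY`).
#' @param serial positive integer, at most 999.
#' @return character assay name.
#' @export
name_assay <- function(gene_id, serial) {
  gene_chromosome(gene_id)  # validates the pattern
  if (any(serial < 1L) || any(serial > 999L))
    abort("assay serial must be in 1..999")
  sprintf("Vf_%s_%03d", gene_id, as.integer(serial))
}

#' Mine assay-ready SNP targets from anchored contig pairs
#'
#' Runs the full per-pair pipeline: global alignment, candidate calling
#' with the flank rule, optional intron-proximity truncation, optional
#' paralog/multi-locus exclusion (hits of the consensus flanks computed
#' with [kmer_hits()] against the two transcriptomes when not
#' supplied), and assay naming of passing candidates (serials per gene
#' in contig-offset order).
#'
#' @param seqs_a,seqs_b named character vectors of contig sequences for
#'   the two lines.
#' @param anchors accepted-anchor table from [anchor_pairs()].
#' @param projections optional named list (by `contig_a`) of
#'   `gene_structure_projection` objects.
#' @param hits_vs_a,hits_vs_b optional precomputed flank hit tables;
#'   computed internally when NULL.
#' @param hits_vs_chrom optional flank hits vs reference chromosomes.
#' @param min_flank,min_dist,max_e filter thresholds (defaults 50, 50,
#'   1e-30).
#' @return data.frame of all candidates with `assay_name` (NA for
#'   failures), anchor gene and chromosome, and filter verdicts.
#' @export
mine_snps <- function(seqs_a, seqs_b, anchors, projections = NULL,
                      hits_vs_a = NULL, hits_vs_b = NULL,
                      hits_vs_chrom = NULL, min_flank = 50, min_dist = 50,
                      max_e = 1e-30) {
  anchors <- anchors[anchors$status == "accepted", , drop = FALSE]
  all <- list()
  for (i in seq_len(nrow(anchors))) {
    a <- anchors$contig_a[i]; b <- anchors$contig_b[i]
    aln <- global_align(seqs_a[[a]], seqs_b[[b]])
    snps <- call_candidate_snps(aln, min_flank, a, b)
    if (nrow(snps) == 0L) next
    if (!is.null(projections) && !is.null(projections[[a]]))
      snps <- apply_intron_rule(snps, projections[[a]], aln, min_dist)
    snps$reference_gene_id <- anchors$reference_gene_id[i]
    snps$reference_chromosome <- anchors$reference_chromosome[i]
    all[[length(all) + 1L]] <- snps
  }
  if (length(all) == 0L) {
    out <- empty_candidates()
    out$reference_gene_id <- character()
    out$reference_chromosome <- integer()
    out$assay_name <- character()
    return(out)
  }
  snps <- do.call(rbind, all)
  # paralog / multi-locus screen on the surviving flanks
  live <- snps$status == "pass"
  if (any(live)) {
    flanks <- setNames(paste0(snps$flank_left[live], snps$allele_a[live],
                              snps$flank_right[live]), snps$snp_id[live])
    if (is.null(hits_vs_a)) hits_vs_a <- kmer_hits(flanks, seqs_a)
    if (is.null(hits_vs_b)) hits_vs_b <- kmer_hits(flanks, seqs_b)
    snps <- exclude_multilocus(snps, hits_vs_a, hits_vs_b, hits_vs_chrom,
                               max_e)
  }
  snps$assay_name <- NA_character_
  ok <- which(snps$status == "pass")
  ok <- ok[order(snps$reference_gene_id[ok], snps$pos_a[ok])]
  serial <- stats::ave(seq_along(ok), snps$reference_gene_id[ok],
                       FUN = seq_along)
  snps$assay_name[ok] <- name_assay(snps$reference_gene_id[ok], serial)
  rownames(snps) <- NULL
  snps
}
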