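random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic annotated reference genome
#'
#' Non-overlapping plus-strand gene models with exon/intron structure
#' laid out along `n_chrom` chromosomes, deterministic per seed. Gene
#' identifiers follow the `MtXgYYYYYY` convention in physical order;
#' annotations default to "hypothetical protein" and can be edited to
#' plant candidates.
#'
#' @param n_chrom number of chromosomes (2-8).
#' @param genes_per_chrom genes per chromosome.
#' @param introns_per_gene introns per gene (0-4).
#' @param seed RNG seed.
#' @param exon_range,intron_range,intergenic_range base-pair ranges for
#'   the uniform length draws.
#' @return list of class `synthetic_reference`: `sequences` (named
#'   character, one per chromosome), `genes` (gene_id, chrom, start,
#'   end, strand, annotation), `exons` (gene_id, start, end, genomic
#'   1-based inclusive), `seed`.
#' @export
make_reference <- function(n_chrom = 2, genes_per_chrom = 20,
                           introns_per_gene = 2, seed = 1,
                           exon_range = c(150, 400),
                           intron_range = c(80, 300),
                           intergenic_range = c(200, 800)) {
  if (n_chrom < 1 || n_chrom > 8) abort("n_chrom must be 1-8")
  if (introns_per_gene < 0 || introns_per_gene > 4)
    abort("introns_per_gene must be 0-4")
  set.seed(seed)
  genes <- list(); exons <- list(); seqs <- character(n_chrom)
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  for (ch in seq_len(n_chrom)) {
    pos <- 1L
    parts <- character()
    for (gi in seq_len(genes_per_chrom)) {
      gap <- sample(intergenic_range[1L]:intergenic_range[2L], 1L)
      parts <- c(parts, random_dna(gap))
      pos <- pos + gap
      ne <- introns_per_gene + 1L
      el <- sample(exon_range[1L]:exon_range[2L], ne, replace = TRUE)
      il <- if (ne > 1L)
        sample(intron_range[1L]:intron_range[2L], ne - 1L, replace = TRUE)
      else integer()
      gid <- sprintf("Mt%dg%06d", ch, gi * 10L)
      gstart <- pos
      for (e in seq_len(ne)) {
        exons[[length(exons) + 1L]] <-
          data.frame(gene_id = gid, start = pos, end = pos + el[e] - 1L)
        parts <- c(parts, random_dna(el[e]))
        pos <- pos + el[e]
        if (e < ne) {
          parts <- c(parts, random_dna(il[e]))
          pos <- pos + il[e]
        }
      }
      genes[[length(genes) + 1L]] <-
        data.frame(gene_id = gid, chrom = names(seqs)[ch], start = gstart,
                   end = pos - 1L, strand = "+",
                   annotation = "hypothetical protein",
                   stringsAsFactors = FALSE)
    }
    parts <- c(parts, random_dna(sample(intergenic_range[1L]:
                                          intergenic_range[2L], 1L)))
    seqs[ch] <- paste(parts, collapse = "")
  }
  structure(list(sequences = seqs, genes = do.call(rbind, genes),
                 exons = do.call(rbind, exons), seed = seed),
            class = "synthetic_reference")
}

# spliced transcript of one gene (plus strand only)
spliced_transcript <- function(ref, gene_id) {
  g <- ref$genes[ref$genes$gene_id == gene_id, ]
  ex <- ref$exons[ref$exons$gene_id == gene_id, , drop = FALSE]
  paste(vapply(seq_len(nrow(ex)), function(i)
    substr(ref$sequences[[g$chrom]], ex$start[i], ex$end[i]), ""),
    collapse = "")
}

mutate_at <- function(seq, pos1, new) {
  substr(seq, pos1, pos1) <- new
  seq
}

#' Generate two parental transcriptomes with planted SNPs and paralogs
#'
#' Each gene of the reference yields one spliced transcript per line;
#' line B carries biallelic substitutions planted at `snp_rate` per
#' base. A fraction of genes is additionally duplicated in line A with
#' 2-5 percent random divergence - decoy paralogs for the uniqueness
#' and paralog filters.
#'
#' @param ref a `synthetic_reference`.
#' @param snp_rate per-base substitution probability between the lines
#'   (default 0.004, about one SNP per 250 transcript bases, a typical
#'   inter-line transcript divergence for an outcrossing legume).
#' @param paralog_fraction fraction of genes duplicated as decoys
#'   (default 0.1).
#' @param seed RNG seed.
#' @return list of class `synthetic_transcriptomes`: `seqs_a`, `seqs_b`
#'   (named character; contig "ctgA_<gene>" / "ctgB_<gene>"),
#'   `variants` (contig_a, contig_b, offset 0-based, allele_a,
#'   allele_b, gene_id), `paralogs` (contig ids of planted decoys),
#'   `gene_of_contig` (named character).
#' @export
make_parental_transcriptomes <- function(ref, snp_rate = 0.004,
                                         paralog_fraction = 0.1,
                                         seed = 1) {
  set.seed(seed + 1L)
  bases <- c("A", "C", "G", "T")
  seqs_a <- character(); seqs_b <- character()
  variants <- list(); gene_of <- character(); paralogs <- character()
  for (gid in ref$genes$gene_id) {
    tx <- spliced_transcript(ref, gid)
    ca <- paste0("ctgA_", gid); cb <- paste0("ctgB_", gid)
    tb <- tx
    nsnp <- rbinom(1L, nchar(tx), snp_rate)
    if (nsnp > 0L) {
      at <- sort(sample.int(nchar(tx), nsnp))
      for (p in at) {
        old <- substr(tx, p, p)
        new <- sample(setdiff(bases, old), 1L)
        tb <- mutate_at(tb, p, new)
        variants[[length(variants) + 1L]] <- data.frame(
          contig_a = ca, contig_b = cb, offset = p - 1L, allele_a = old,
          allele_b = new, gene_id = gid, stringsAsFactors = FALSE)
      }
    }
    seqs_a[ca] <- tx; seqs_b[cb] <- tb
    gene_of[ca] <- gid; gene_of[cb] <- gid
  }
  ng <- nrow(ref$genes)
  ndup <- round(paralog_fraction * ng)
  if (ndup > 0L) {
    dup <- sample(ref$genes$gene_id, ndup)
    for (gid in dup) {
      tx <- seqs_a[[paste0("ctgA_", gid)]]
      div <- runif(1L, 0.02, 0.05)
      at <- which(runif(nchar(tx)) < div)
      for (p in at)
        tx <- mutate_at(tx, p, sample(setdiff(bases, substr(tx, p, p)), 1L))
      cid <- paste0("ctgA_", gid, "_par")
      seqs_a[cid] <- tx
      gene_of[cid] <- gid
      paralogs <- c(paralogs, cid)
    }
  }
  structure(list(seqs_a = seqs_a, seqs_b = seqs_b,
                 variants = if (length(variants)) do.call(rbind, variants)
                            else NULL,
                 paralogs = paralogs, gene_of_contig = gene_of,
                 seed = seed),
            class = "synthetic_transcriptomes")
}

# one meiosis of a phased parent: per group, crossovers ~ Poisson(len/100)
# at uniform positions, no interference (Haldane model)
meiosis <- function(hap1, hap2, positions) {
  out <- hap1
  for (g in names(positions)) {
    pos <- positions[[g]]
    len <- max(pos)
    nco <- rpois(1L, len / 100)
    start <- sample(1:2, 1L)
    if (nco == 0L) {
      out[[g]] <- if (start == 1L) hap1[[g]] else hap2[[g]]
      next
    }
    co <- sort(runif(nco, 0, len))
    k <- findInterval(pos, co)
    cur <- ((start - 1L + k) %% 2L) + 1L
    out[[g]] <- ifelse(cur == 1L, hap1[[g]], hap2[[g]])
  }
  out
}

#' Simulate a segregating population from a true map
#'
#' Gametes are produced by crossover simulation without interference
#' (crossover count per linkage group Poisson(length / 100), positions
#' uniform). Designs: `f2` (two F1 gametes per individual), `f5_ssd`
#' (F2 followed by three generations of single-seed-descent selfing),
#' `ril` (selfing to near-fixation, 20 generations). Calls are then
#' perturbed: with probability `error_rate` a call is replaced by one
#' of the two other calls, and with probability `missing_rate` it
#' becomes NC. Optional distortion applies one-locus viability
#' selection.
#'
#' @param true_map data.frame `marker`, `group`, `position_cM`.
#' @param design `"f2"`, `"f5_ssd"` or `"ril"`.
#' @param n number of individuals.
#' @param error_rate,missing_rate call perturbation rates (defaults
#'   0.01 and 0.05, typical KASP plate behaviour).
#' @param distortion optional data.frame `marker`, `w_AA`, `w_AB`,
#'   `w_BB` (relative viabilities, max 1).
#' @param seed RNG seed.
#' @return list of class `synthetic_population`: `gm`
#'   (`genotype_matrix`), `true_genotypes` (unperturbed matrix),
#'   `design`, `seed`.
#' @export
simulate_population <- function(true_map,
                                design = c("f2", "f5_ssd", "ril"),
                                n = 100, error_rate = 0.01,
                                missing_rate = 0.05, distortion = NULL,
                                seed = 1) {
  design <- match.arg(design)
  if (nrow(true_map) == 0L) abort("true map is empty")
  set.seed(seed)
  groups <- split(true_map, true_map$group)
  positions <- lapply(groups, function(g) g$position_cM)
  markers <- unlist(lapply(groups, function(g) g$marker), use.names = FALSE)
  n_self <- switch(design, f2 = 0L, f5_ssd = 3L, ril = 20L)
  make_individual <- function() {
    p1 <- lapply(positions, function(p) rep(0L, length(p)))
    p2 <- lapply(positions, function(p) rep(1L, length(p)))
    h1 <- meiosis(p1, p2, positions)
    h2 <- meiosis(p1, p2, positions)
    for (s in seq_len(n_self)) {
      n1 <- meiosis(h1, h2, positions)
      n2 <- meiosis(h1, h2, positions)
      h1 <- n1; h2 <- n2
    }
    unlist(h1, use.names = FALSE) + unlist(h2, use.names = FALSE)
  }
  fitness <- function(geno) {
    if (is.null(distortion)) return(1)
    w <- 1
    for (i in seq_len(nrow(distortion))) {
      j <- match(distortion$marker[i], markers)
      w <- w * c(distortion$w_AA[i], distortion$w_AB[i],
                 distortion$w_BB[i])[geno[j] + 1L]
    }
    w
  }
  genos <- matrix(0L, nrow = n, ncol = length(markers))
  i <- 1L
  while (i <= n) {
    g <- make_individual()
    if (runif(1L) <= fitness(g)) {
      genos[i, ] <- g
      i <- i + 1L
    }
  }
  calls <- matrix(c("AA", "AB", "BB")[genos + 1L], nrow = n,
                  dimnames = list(sprintf("ind%03d", seq_len(n)), markers))
  true_calls <- calls
  err <- matrix(runif(length(calls)) < error_rate, nrow = n)
  if (any(err)) {
    calls[err] <- vapply(calls[err], function(cl)
      sample(setdiff(c("AA", "AB", "BB"), cl), 1L), "")
  }
  miss <- matrix(runif(length(calls)) < missing_rate, nrow = n)
  calls[miss] <- "NC"
  structure(list(gm = genotype_matrix(calls),
                 true_genotypes = genotype_matrix(true_calls),
                 design = design, seed = seed),
            class = "synthetic_population")
}

FLUOR_ARCHETYPES <- data.frame(
  archetype = c("I", "II", "III", "IV"),
  cluster_sd = c(0.035, 0.11, 0.20, 0.30),
  nc_rate = c(0.01, 0.05, 0.12, 0.25),
  merged = c(FALSE, FALSE, FALSE, TRUE),
  stringsAsFactors = FALSE)

#' Simulate 2-D KASP fluorescence intensities for one marker
#'
#' Homozygote clusters sit on the two dye axes (AA at (0.9, 0.1), BB at
#' (0.1, 0.9)) with heterozygotes mixed between them at (0.5, 0.5); the
#' archetype controls cluster spread and the extra no-call fraction
#' (see `FLUOR_ARCHETYPES` in the source for the parameter table).
#' Archetype IV collapses all clusters onto one cloud. Archetype
#' parameters were chosen so that [classify_quality()] recovers the
#' matching class for the bulk of seeds.
#'
#' @param calls character vector of calls (AA/AB/BB/NC).
#' @param archetype `"I"`, `"II"`, `"III"` or `"IV"`.
#' @param seed RNG seed.
#' @return data.frame `sample`, `x`, `y`, `call`.
#' @export
simulate_fluorescence <- function(calls, archetype = c("I", "II", "III",
                                                       "IV"), seed = 1) {
  archetype <- match.arg(archetype)
  set.seed(seed)
  par <- FLUOR_ARCHETYPES[FLUOR_ARCHETYPES$archetype == archetype, ]
  n <- length(calls)
  call <- calls
  call[runif(n) < par$nc_rate] <- "NC"
  cent <- list(AA = c(0.9, 0.1), AB = c(0.5, 0.5), BB = c(0.1, 0.9),
               NC = c(0.08, 0.08))
  if (par$merged) cent[c("AA", "AB", "BB")] <-
    list(c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5))
  xy <- t(vapply(call, function(cl) {
    sd <- if (cl == "NC") 0.04 else par$cluster_sd
    cent[[cl]] + rnorm(2L, 0, sd)
  }, c(0, 0)))
  data.frame(sample = if (!is.null(names(calls))) names(calls)
             else sprintf("s%03d", seq_len(n)),
             x = xy[, 1L], y = xy[, 2L], call = call,
             stringsAsFactors = FALSE, row.names = NULL)
}
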