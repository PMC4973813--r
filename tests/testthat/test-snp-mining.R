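rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

subst <- function(s, pos1, base) { substr(s, pos1, pos1) <- base; s }

other_base <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]

test_that("call_candidate_snps applies the flank rule", {
  set.seed(21)
  a <- rand_seq(300)
  b <- subst(a, 121, other_base(substr(a, 121, 121)))  # offset 120
  snps <- call_candidate_snps(global_align(a, b))
  expect_equal(nrow(snps), 1L)
  expect_equal(snps$pos_a, 120L)
  expect_equal(snps$status, "pass")
  expect_equal(nchar(snps$flank_left), 120L)

  b2 <- subst(a, 50, other_base(substr(a, 50, 50)))    # offset 49
  snps2 <- call_candidate_snps(global_align(a, b2))
  expect_equal(snps2$status, "fail")
  expect_equal(snps2$reason, "flank")

  expect_equal(nrow(call_candidate_snps(global_align(a, a))), 0L)
})

test_that("secondary substitutions become ambiguity codes in the flank", {
  set.seed(22)
  a <- rand_seq(300)
  b <- subst(a, 150, other_base(substr(a, 150, 150)))
  b <- subst(b, 170, other_base(substr(b, 170, 170)))
  snps <- call_candidate_snps(global_align(a, b))
  expect_equal(nrow(snps), 2L)
  expect_equal(snps$n_secondary, c(1L, 1L))
  # the flank of SNP 1 carries an IUPAC code at the other SNP's position
  amb <- substr(snps$flank_right[1], 170 - 150, 170 - 150)
  expect_true(amb %in% c("R", "Y", "S", "W", "K", "M"))
})

test_that("project_gene_structure matches the coordinate conventions", {
  p1 <- project_gene_structure(1, 400, 1, 400, exon_lengths = 400)
  expect_equal(p1$intron_insertion_points, integer(0))

  p2 <- project_gene_structure(1, 400, 1, 400, exon_lengths = c(200, 200))
  expect_equal(p2$intron_insertion_points, 199L)

  expect_error(project_from_exons(
    data.frame(start = c(1, 150), end = c(200, 400)), 1, 400, 1, 400),
    "overlap")
})

test_that("projection recovers generator truth for a 3-exon model", {
  ref <- make_reference(n_chrom = 1, genes_per_chrom = 3,
                        introns_per_gene = 2, seed = 5)
  gid <- ref$genes$gene_id[2]
  ex <- ref$exons[ref$exons$gene_id == gid, ]
  el <- ex$end - ex$start + 1L
  tx_len <- sum(el)
  p <- project_from_exons(ex, 1, tx_len, 1, tx_len, source_gene = gid)
  expect_equal(p$intron_insertion_points, cumsum(el)[-3] - 1L)
})

test_that("apply_intron_rule fails near junctions and truncates flanks", {
  set.seed(23)
  a <- rand_seq(400)
  b <- subst(a, 201, other_base(substr(a, 201, 201)))  # SNP offset 200
  aln <- global_align(a, b)
  snps <- call_candidate_snps(aln)
  expect_equal(snps$status, "pass")

  near <- structure(list(intron_insertion_points = 230L, source_gene = "g"),
                    class = "gene_structure_projection")  # 30 bases right
  out <- apply_intron_rule(snps, near, aln)
  expect_equal(out$reason, "intron_near")

  both <- structure(list(intron_insertion_points = c(119L, 280L),
                         source_gene = "g"),
                    class = "gene_structure_projection")  # 80 each side
  out2 <- apply_intron_rule(snps, both, aln)
  expect_equal(out2$status, "pass")
  expect_equal(nchar(out2$flank_left), 80L)
  expect_equal(nchar(out2$flank_right), 80L)

  none <- structure(list(intron_insertion_points = integer(),
                         source_gene = "g"),
                    class = "gene_structure_projection")
  expect_equal(apply_intron_rule(snps, none, aln), snps)
})

fake_flank_hit <- function(q, s, e, sstart = 1, send = 100) {
  parse_hits(sprintf("%s\t%s\t99\t100\t0\t0\t1\t100\t%d\t%d\t%g\t200",
                     q, s, sstart, send, e))
}

test_that("exclude_multilocus flags paralogs and multi-chromosome hits", {
  snp <- data.frame(snp_id = "s1", status = "pass", reason = NA_character_,
                    stringsAsFactors = FALSE)
  ok <- exclude_multilocus(snp, fake_flank_hit("s1", "ctgA_1", 1e-50),
                           fake_flank_hit("s1", "ctgB_1", 1e-50),
                           fake_flank_hit("s1", "chr2", 1e-50))
  expect_equal(ok$status, "pass")

  par <- exclude_multilocus(snp,
                            rbind(fake_flank_hit("s1", "ctgA_1", 1e-50),
                                  fake_flank_hit("s1", "ctgA_9", 1e-40)),
                            fake_flank_hit("s1", "ctgB_1", 1e-50))
  expect_equal(par$reason, "paralog")

  chr <- exclude_multilocus(snp, fake_flank_hit("s1", "ctgA_1", 1e-50),
                            fake_flank_hit("s1", "ctgB_1", 1e-50),
                            rbind(fake_flank_hit("s1", "chr2", 1e-50),
                                  fake_flank_hit("s1", "chr6", 1e-45)))
  expect_equal(chr$reason, "multi_locus")

  two_loci <- exclude_multilocus(snp, fake_flank_hit("s1", "ctgA_1", 1e-50),
                                 fake_flank_hit("s1", "ctgB_1", 1e-50),
                                 rbind(fake_flank_hit("s1", "chr2", 1e-50,
                                                      1, 100),
                                       fake_flank_hit("s1", "chr2", 1e-45,
                                                      5000, 5100)))
  expect_equal(two_loci$reason, "multi_locus")

  # weak second hit does not qualify
  weak <- exclude_multilocus(snp,
                             rbind(fake_flank_hit("s1", "ctgA_1", 1e-50),
                                   fake_flank_hit("s1", "ctgA_9", 1e-10)),
                             fake_flank_hit("s1", "ctgB_1", 1e-50))
  expect_equal(weak$status, "pass")
})

test_that("name_assay formats, pads and overflows", {
  expect_equal(name_assay("Mt3g092810", 1), "Vf_Mt3g092810_001")
  expect_equal(name_assay("Mt3g094760", 1), "Vf_Mt3g094760_001")
  expect_equal(name_assay("Mt1g000010", 42), "Vf_Mt1g000010_042")
  expect_error(name_assay("Mt3g092810", 1000), "serial")
})

test_that("mining closed loop: precision 1 on planted variants, paralogs caught", {
  ref <- make_reference(n_chrom = 1, genes_per_chrom = 8,
                        introns_per_gene = 1, seed = 31)
  tx <- make_parental_transcriptomes(ref, snp_rate = 0.004,
                                     paralog_fraction = 0.25, seed = 31)
  hab <- kmer_hits(tx$seqs_a, tx$seqs_b)
  hba <- kmer_hits(tx$seqs_b, tx$seqs_a)
  pairs <- reciprocal_best_hits(hab, hba)
  # planted paralogs are never part of an anchored pair
  expect_false(any(tx$paralogs %in% c(pairs$contig_a, pairs$contig_b)))

  genes <- setNames(
    vapply(ref$genes$gene_id, function(g) tx$seqs_a[[paste0("ctgA_", g)]], ""),
    ref$genes$gene_id)
  h_genes <- kmer_hits(c(tx$seqs_a[pairs$contig_a], tx$seqs_b[pairs$contig_b]),
                       genes)
  anchors <- anchor_pairs(pairs, h_genes)
  expect_true(all(anchors$status == "accepted"))
  expect_equal(anchors$reference_gene_id,
               unname(tx$gene_of_contig[anchors$contig_a]))

  projections <- lapply(setNames(anchors$contig_a, anchors$contig_a),
                        function(ca) {
    gid <- tx$gene_of_contig[[ca]]
    ex <- ref$exons[ref$exons$gene_id == gid, ]
    len <- sum(ex$end - ex$start + 1L)
    project_from_exons(ex, 1, len, 1, len, source_gene = gid)
  })
  mined <- mine_snps(tx$seqs_a, tx$seqs_b, anchors, projections)

  truth <- tx$variants
  truth_key <- paste(truth$contig_a, truth$offset)
  passed <- mined[mined$status == "pass", ]
  # precision: every passing SNP is a planted variant at the right offset
  expect_true(all(paste(passed$contig_a, passed$pos_a) %in% truth_key))
  expect_true(all(grepl("^Vf_Mt1g[0-9]{6}_[0-9]{3}$", passed$assay_name)))

  # recall against the truth restricted to variants the filters allow:
  # >= 50 bases from both contig ends and from every intron junction,
  # in a gene without a planted paralog decoy
  paralog_genes <- unique(tx$gene_of_contig[tx$paralogs])
  expected <- vapply(seq_len(nrow(truth)), function(i) {
    gid <- truth$gene_id[i]
    if (gid %in% paralog_genes) return(FALSE)
    len <- nchar(tx$seqs_a[[truth$contig_a[i]]])
    pos <- truth$offset[i]
    if (min(pos, len - 1 - pos) < 50) return(FALSE)
    ex <- ref$exons[ref$exons$gene_id == gid, ]
    el <- ex$end - ex$start + 1L
    pts <- cumsum(el)[-length(el)] - 1L
    all(abs(c(pos - pts - 1L, pts - pos)[c(pts < pos, pts >= pos)]) >= 50)
  }, TRUE)
  exp_key <- truth_key[expected]
  expect_true(all(exp_key %in% paste(passed$contig_a, passed$pos_a)))

  # planted paralogs force fail(paralog) for their gene's candidates
  if (length(paralog_genes) > 0) {
    par_rows <- mined[mined$reference_gene_id %in% paralog_genes &
                        mined$reason %in% "paralog", ]
    expect_gt(nrow(par_rows), 0)
  }
})

test_that("filters are order-stable on the pass set", {
  set.seed(25)
  a <- rand_seq(400)
  b <- subst(a, 201, other_base(substr(a, 201, 201)))
  b <- subst(b, 60, other_base(substr(b, 60, 60)))
  aln <- global_align(a, b)
  snps <- call_candidate_snps(aln)
  proj <- structure(list(intron_insertion_points = 330L, source_gene = "g"),
                    class = "gene_structure_projection")
  ha <- fake_flank_hit(snps$snp_id[2], "ctg1", 1e-50)
  hb <- fake_flank_hit(snps$snp_id[2], "ctg2", 1e-50)
  r1 <- exclude_multilocus(apply_intron_rule(snps, proj, aln), ha, hb)
  r2 <- apply_intron_rule(exclude_multilocus(snps, ha, hb), proj, aln)
  expect_equal(r1$snp_id[r1$status == "pass"],
               r2$snp_id[r2$status == "pass"])
})
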