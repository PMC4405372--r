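# Fixture: a small truth set shared by the annotation tests.
annotate_fixture <- function(seed = 71) {
  cfg <- sim_config(seed = seed, n_genes = 16, n_scaffolds = 2,
                    mean_library_size = 500)
  tr <- generate_references(cfg)
  list(cfg = cfg, tr = tr)
}

test_that("translated search finds reverse-frame hits and respects e-value", {
  fx <- annotate_fixture()
  tr <- fx$tr
  gid <- names(tr$proteins)[1]
  tx <- tr$transcripts[gid]
  contigs <- tibble::tibble(
    contig_id = c("fwd", "rev", "rand"),
    seq = c(unname(tx), revcomp(unname(tx)), random_reads(1, 300)))
  tb <- translated_best_hits(contigs, tr$proteins)
  best <- tb$best
  expect_equal(best$target_id[best$query_id == "fwd"], gid)
  expect_equal(best$target_id[best$query_id == "rev"], gid)
  expect_lt(best$frame[best$query_id == "rev"], 0)
  expect_equal(best$identity[best$query_id == "rev"], 1)
  # all retained hits satisfy the e-value cutoff
  expect_true(all(tb$hits$e_value <= 1e-6))

  # empty protein set: everything unmatched
  tb0 <- translated_best_hits(contigs, character(0))
  expect_setequal(tb0$unmatched, contigs$contig_id)
})

test_that("random sequences essentially never hit a small protein set", {
  set.seed(72)
  fx <- annotate_fixture()
  contigs <- tibble::tibble(contig_id = sprintf("r%04d", 1:1000),
                            seq = random_reads(1000, 300))
  tb <- translated_best_hits(contigs, fx$tr$proteins)
  # empirical null: the 1e-6 cutoff admits at most a handful in 1000 draws
  expect_lte(nrow(tb$best), 2)
})

test_that("the chimera rule follows the printed arithmetic", {
  hit <- function(q_start, q_end, identity, target = "t1", score = NULL) {
    tibble::tibble(query_id = "c1", target_id = target,
                   identity = identity, aligned_length = q_end - q_start,
                   q_start = q_start, q_end = q_end,
                   t_start = 0L, t_end = q_end - q_start, strand = "+",
                   frame = 1L, e_value = 10^-(identity * 50),
                   bit_score = score %||% (identity * 100))
  }
  # primary 0-300 at 90%; secondary 320-520 (200 bp outside) at 75%
  # (> 0.8 * 90% = 72%) -> chimera
  h <- dplyr::bind_rows(hit(0L, 300L, 0.90), hit(320L, 520L, 0.75, "t2"))
  expect_true(detect_chimera(h)$chimeric)

  # secondary outside span only 40 bp -> not chimeric
  h2 <- dplyr::bind_rows(hit(0L, 300L, 0.90), hit(260L, 340L, 0.75, "t2"))
  expect_false(detect_chimera(h2)$chimeric)

  # secondary identity 60% (< 72%) -> not chimeric
  h3 <- dplyr::bind_rows(hit(0L, 300L, 0.90), hit(320L, 520L, 0.60, "t2"))
  expect_false(detect_chimera(h3)$chimeric)

  # absolute mode compares with the fixed 80% threshold instead
  h4 <- dplyr::bind_rows(hit(0L, 300L, 0.90), hit(320L, 520L, 0.75, "t2"))
  expect_false(detect_chimera(h4, mode = "absolute")$chimeric)

  # no hits -> nothing flagged
  expect_equal(nrow(detect_chimera(h[0, ])), 0)
})

test_that("protein re-assembly merges fragments and logs discards", {
  fx <- annotate_fixture(seed = 73)
  tr <- fx$tr
  gid <- names(tr$proteins)[2]
  tx <- unname(tr$transcripts[gid])
  L <- nchar(tx)
  contigs <- tibble::tibble(
    contig_id = c("f1", "f2", "weak"),
    seq = c(substr(tx, 1, round(L * 0.6)), substr(tx, round(L * 0.4), L),
            mutate_seq_oracle(unname(tr$transcripts[names(tr$proteins)[3]]),
                              0.02)))
  # two fragments of one gene -> one merged contig annotated to it
  pr <- protein_reassemble(contigs, tr$proteins)
  merged <- pr$retained[pr$retained$reference_id == gid, ]
  expect_equal(nrow(merged), 1)
  expect_equal(nchar(merged$seq), L)
  expect_setequal(
    pr$members$member_id[pr$members$contig_id == merged$contig_id],
    c("f1", "f2"))

  # a tightened identity rule turns the mutated contig into a
  # low_identity discard
  pr2 <- protein_reassemble(contigs, tr$proteins, identity_min = 0.995)
  expect_true("weak" %in%
                pr2$discarded$contig_id[pr2$discarded$reason == "low_identity"])

  # planted two-gene chimeras are discarded as chimeric
  g2 <- names(tr$proteins)[4]; g3 <- names(tr$proteins)[5]
  chim <- paste0(substr(tr$transcripts[g2], 1, 400),
                 substr(tr$transcripts[g3], 1, 400))
  pr3 <- protein_reassemble(
    tibble::tibble(contig_id = "chi", seq = chim), tr$proteins)
  expect_equal(pr3$discarded$reason[pr3$discarded$contig_id == "chi"],
               "chimeric")
})

test_that("genome re-assembly classifies gene-model, UTR and intergenic contigs", {
  fx <- annotate_fixture(seed = 74)
  tr <- fx$tr
  gm <- tr$gene_models[1, ]
  scaf <- tr$scaffolds[[gm$scaffold]]
  inside <- substr(scaf, gm$start + 10, gm$start + 409)
  # 400 bp contig ending 500 bp upstream of the model, fully aligned
  utr_c <- substr(scaf, gm$start - 900, gm$start - 501)
  far <- substr(scaf, nchar(scaf) - 1900, nchar(scaf) - 1501)
  contigs <- tibble::tibble(contig_id = c("in", "near", "far"),
                            seq = c(inside, utr_c, far))
  gen <- genome_reassemble(contigs, tr$scaffolds, tr$gene_models)
  got <- setNames(gen$retained$category, gen$retained$contig_id)
  expect_equal(unname(got["in"]), "gene_model_annotated")
  expect_equal(unname(got["near"]), "utr")
  expect_equal(unname(got["far"]), "unannotated_genomic")
  ref <- setNames(gen$retained$reference_id, gen$retained$contig_id)
  expect_equal(unname(ref["in"]), gm$gene_id)
  expect_equal(unname(ref["near"]), gm$gene_id)

  # contigs with no scaffold hit are dropped with a reason
  gen2 <- genome_reassemble(
    tibble::tibble(contig_id = "alien", seq = random_reads(1, 300)),
    tr$scaffolds, tr$gene_models)
  expect_equal(gen2$discarded$reason, "no_genomic_hit")
})

test_that("the percentile rule retains ceiling(0.95 n) contigs", {
  ids <- sprintf("c%02d", 1:40)
  identity <- seq(0.70, 0.999, length.out = 40)
  pr <- diapauseTx:::percentile_retain(identity, 0.95)
  expect_equal(sum(pr$keep), ceiling(0.95 * 40))
  expect_equal(pr$cutoff, sort(identity, decreasing = TRUE)[38])
  # ties at the cutoff are retained
  pr2 <- diapauseTx:::percentile_retain(c(rep(0.8, 5), rep(0.9, 15)), 0.95)
  expect_equal(sum(pr2$keep), 20)
})

test_that("spliced alignment chains across introns", {
  fx <- annotate_fixture(seed = 75)
  tr <- fx$tr
  # a spliced transcript (UTRs + CDS, introns absent) must chain to its
  # gene locus with high identity and coverage
  gid <- tr$gene_models$gene_id[3]
  contigs <- tibble::tibble(contig_id = "tx", seq = unname(
    tr$transcripts[gid]))
  ch <- spliced_align(contigs, tr$scaffolds)
  top <- ch[ch$rank == 1, ]
  expect_equal(top$scaffold, tr$gene_models$scaffold[3])
  expect_gte(top$identity, 0.99)
  expect_gte(top$coverage, 0.95)
  # the chain spans the gene model on the scaffold
  expect_lte(top$t_start + 1, tr$gene_models$start[3])
  expect_gte(top$t_end, tr$gene_models$end[3] - 5)
})

test_that("assembly statistics follow their definitions", {
  s1 <- contig_stats("ATGC")
  expect_equal(s1$n50, 4)
  expect_equal(s1$mean_gc, 0.5)
  expect_equal(s1$median_length, 4)

  lens <- c(40, 30, 20, 10)
  seqs <- vapply(lens, function(L) strrep("A", L), character(1))
  expect_equal(contig_stats(seqs)$n50, 30)
  expect_error(contig_stats(character(0)), "empty")
})

test_that("final assembly accounting matches set arithmetic", {
  p <- tibble::tibble(contig_id = c("p1", "p2", "p3"),
                      seq = c("AAA", "CCC", "GGG"),
                      reference_id = c("g1", "g2", "g3"),
                      identity = 1, e_value = 0)
  g <- tibble::tibble(contig_id = c("g1c", "g2c", "g3c", "g4c"),
                      seq = c("TTT", "AAA", "CCC", "GGG"),
                      category = c("gene_model_annotated", "utr",
                                   "gene_model_annotated",
                                   "unannotated_genomic"),
                      reference_id = c("g4", "g5", "g6", "scaf01"),
                      identity = 1, coverage = 1)
  fin <- build_final_assembly(p, g, sprintf("g%d", 1:10))
  expect_equal(fin$accounting$n_union, 6)
  expect_equal(fin$accounting$n_intersection, 0)
  expect_equal(fin$accounting$union_fraction_pct, 60)
  expect_equal(nrow(fin$unigenes), 7)

  # duplicate unigene ids are rejected
  g_bad <- g; g_bad$contig_id[1] <- "p1"
  expect_error(build_final_assembly(p, g_bad, character(0)), "duplicate")

  # pure arithmetic on path counts
  acc <- gene_model_accounting(3, 4, 7, 10)
  expect_equal(acc$n_intersection, 0)
  expect_equal(acc$union_fraction_pct, 70)
})
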