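test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(chimera_rate = 1.5), "chimera_rate")
  expect_error(sim_config(n_libraries = 10), "n_libraries")
  expect_error(sim_config(frac_de = c(photoperiod = 0.1)), "frac_de")
  expect_error(sim_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(sim_config(gene_length_range = c(100, 50)),
               "gene_length_range")
})

test_that("reference generation is seed-deterministic and empty-safe", {
  cfg <- tiny_config()
  t1 <- generate_references(cfg)
  t2 <- generate_references(cfg)
  expect_identical(t1, t2)

  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- write_truth(t1, dir1)
  p2 <- write_truth(t2, dir2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  empty <- generate_references(sim_config(n_genes = 0))
  expect_equal(nrow(empty$gene_models), 0)
  expect_length(empty$proteins, 0)
  expect_equal(nrow(empty$pathway_map), 0)
})

test_that("reference structure honours its invariants", {
  cfg <- sim_config(seed = 3, n_genes = 50, n_scaffolds = 4,
                    mean_library_size = 500)
  tr <- generate_references(cfg)
  # pathway members are a subset of the gene universe
  expect_true(all(tr$pathway_map$gene_id %in% names(tr$transcripts)))
  # gene models are non-overlapping within a scaffold
  by_scaf <- split(tr$gene_models, tr$gene_models$scaffold)
  for (g in by_scaf) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  # proteins are in-frame translations of the coding portion
  gm <- tr$gene_models[1, ]
  cds_len <- unname(nchar(tr$transcripts[gm$gene_id]) -
                      nchar(tr$utr5[gm$gene_id]) - nchar(tr$utr3[gm$gene_id]))
  expect_equal(cds_len %% 3, 0)
  cds <- substr(tr$transcripts[gm$gene_id], nchar(tr$utr5[gm$gene_id]) + 1,
                nchar(tr$utr5[gm$gene_id]) + cds_len)
  if (gm$gene_id %in% names(tr$proteins)) {
    expect_equal(
      sub("\\*$", "", as.character(
        Biostrings::translate(Biostrings::DNAString(cds)))),
      unname(tr$proteins[gm$gene_id]))
  }
  # the spliced transcript maps within its own gene model's scaffold span
  expect_true(all(tr$gene_models$end <= nchar(tr$scaffolds[
    tr$gene_models$scaffold])))
})

test_that("contig sets plant the labelled artefact classes", {
  cfg <- sim_config(seed = 5, n_genes = 60, n_scaffolds = 4,
                    mean_library_size = 500, contig_redundancy_rate = 0.5)
  tr <- generate_references(cfg)
  cs <- generate_contig_sets(tr, cfg)
  expect_setequal(cs$contigs$contig_id, cs$labels$contig_id)

  # every non-chimeric transcript-derived contig is an exact substring of
  # its source transcript (100% identity by construction)
  src <- dplyr::filter(cs$labels, .data$class %in% c("full", "fragment"))
  seqs <- setNames(cs$contigs$seq, cs$contigs$contig_id)
  hits <- vapply(seq_len(nrow(src)), function(i) {
    grepl(seqs[src$contig_id[i]], tr$transcripts[src$gene_id[i]],
          fixed = TRUE)
  }, logical(1))
  expect_true(all(hits))

  # chimeras concatenate segments of two distinct genes
  chim <- dplyr::filter(cs$labels, .data$class == "chimera")
  expect_true(all(chim$gene_id != chim$gene_id_2))

  # duplicate count within binomial 99% bounds of the configured rate
  n_base <- sum(cs$labels$class %in% c("full", "fragment"))
  n_dup <- sum(cs$labels$class == "duplicate")
  bounds <- qbinom(c(0.005, 0.995), n_base, 0.5)
  expect_gte(n_dup, bounds[1])
  expect_lte(n_dup, bounds[2])

  # zero chimera rate plants no chimeras
  cfg0 <- sim_config(seed = 5, n_genes = 30, chimera_rate = 0,
                     mean_library_size = 500)
  cs0 <- generate_contig_sets(generate_references(cfg0), cfg0)
  expect_equal(sum(cs0$labels$class == "chimera"), 0)
})

test_that("read simulation is traceable, deterministic and honours edge cases", {
  cfg <- tiny_config()
  tr <- generate_references(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- generate_reads(tr, cfg, d1)
  r2 <- generate_reads(tr, cfg, d2)
  expect_identical(unname(tools::md5sum(r1$files$fastq_1)),
                   unname(tools::md5sum(r2$files$fastq_1)))
  p <- read_fastq_pairs(r1$files$fastq_1[1], r1$files$fastq_2[1])
  # truth completeness: every read traces to a gene or a contaminant label
  src <- sub("^[^:]+:([^:]+):.*$", "\\1", p$pair_id)
  expect_true(all(src %in% c(names(tr$transcripts), "vec", "adp")))

  # empty library size gives empty but readable FASTQ files
  cfg0 <- sim_config(n_genes = 4, mean_library_size = 0)
  r0 <- generate_reads(generate_references(cfg0), cfg0,
                       withr::local_tempdir())
  expect_equal(nrow(read_fastq(r0$files$fastq_1[1])), 0)
})

test_that("planted effects and dispersion shape the true counts", {
  cfg <- sim_config(seed = 9, n_genes = 40, n_libraries = 32L,
                    mean_library_size = 4000,
                    effect_log2fc = c(photoperiod = 2, bloodmeal = 0,
                                      interaction = 0),
                    frac_de = c(photoperiod = 0.25, bloodmeal = 0,
                                interaction = 0))
  tr <- generate_references(cfg)
  rd <- generate_reads(tr, cfg, withr::local_tempdir())
  sd_cols <- rd$design$photoperiod == "SD"
  # library-size-normalized abundances; the expected ratio includes the
  # compositional shift from the planted effects (relative abundances
  # renormalize within each condition)
  cpm <- t(t(rd$true_counts) / colSums(rd$true_counts))
  w_sd <- tr$condition_means[, "SD.NB"] / sum(tr$condition_means[, "SD.NB"])
  w_ld <- tr$condition_means[, "LD.NB"] / sum(tr$condition_means[, "LD.NB"])
  eff <- dplyr::filter(tr$de_truth, .data$effect == "photoperiod")
  for (dir in c(1, -1)) {
    g <- eff$gene_id[sign(eff$log2fc) == dir]
    if (length(g) == 0) next
    obs <- log2(rowMeans(cpm[g, sd_cols, drop = FALSE]) /
                  rowMeans(cpm[g, !sd_cols, drop = FALSE]))
    expected <- log2(w_sd[g] / w_ld[g])
    expect_lt(max(abs(obs - expected)), 0.6)
    expect_lt(abs(mean(obs - expected)), 0.2)
  }
})

test_that("with all effects zero, per-gene counts differ only stochastically", {
  cfg <- sim_config(seed = 10, n_genes = 40, n_libraries = 32L,
                    mean_library_size = 4000,
                    effect_log2fc = c(photoperiod = 0, bloodmeal = 0,
                                      interaction = 0),
                    frac_de = c(photoperiod = 0, bloodmeal = 0,
                                interaction = 0))
  tr <- generate_references(cfg)
  rd <- generate_reads(tr, cfg, withr::local_tempdir())
  sd_cols <- rd$design$photoperiod == "SD"
  cpm <- t(t(rd$true_counts) / colSums(rd$true_counts)) * 1e6
  pvals <- apply(cpm, 1, function(x) {
    stats::t.test(log1p(x[sd_cols]), log1p(x[!sd_cols]))$p.value
  })
  expect_gte(mean(pvals >= 0.05), 0.94)
})

test_that("negative-binomial count moments match mu + mu^2 * dispersion", {
  # 1000 replicate libraries under identical conditions (all effects zero)
  cfg <- sim_config(seed = 2, n_genes = 8, n_scaffolds = 2,
                    n_libraries = 1000L, mean_library_size = 400,
                    nb_dispersion = 0.2,
                    effect_log2fc = c(photoperiod = 0, bloodmeal = 0,
                                      interaction = 0),
                    frac_de = c(photoperiod = 0, bloodmeal = 0,
                                interaction = 0),
                    contamination_rate = 0)
  tr <- generate_references(cfg)
  rd <- generate_reads(tr, cfg, withr::local_tempdir())
  w <- tr$condition_means[, "LD.NB"]
  mu <- cfg$mean_library_size * w / sum(w)
  keep <- mu >= 20
  v_obs <- apply(rd$true_counts[keep, , drop = FALSE], 1, var)
  v_exp <- mu[keep] + mu[keep]^2 * cfg$nb_dispersion
  # library sizes themselves vary ~10%, adding a small variance component
  expect_true(all(abs(v_obs / v_exp - 1) < 0.35))
})
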