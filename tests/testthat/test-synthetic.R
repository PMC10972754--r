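small_cfg <- function(...) {
  sim_config(n_scaffolds = 4, n_genes = 400, ...)
}

test_that("planted structure echoes the configuration", {
  cfg <- small_cfg(n_pathway_genes = 12, pathway_cluster_sizes = c(4, 4),
                   n_decoy_clustered = 0)
  sim <- simulate_genome(cfg)
  expect_equal(length(sim$truth$pathway_ids), 12)
  expect_equal(length(sim$truth$planted_cluster_members), 2)
  expect_equal(vapply(sim$truth$planted_cluster_members, length, 1L),
               c(cluster_01 = 4L, cluster_02 = 4L))
  expect_equal(nrow(sim$genes), 400)
  expect_true(sim$truth$bait_id %in% sim$truth$pathway_ids)
  expect_true(all(sim$truth$characterized_ids %in% sim$truth$pathway_ids))
  expect_equal(sum(sim$genes$characterized),
               length(sim$truth$characterized_ids))
})

test_that("identical seeds give byte-identical annotation, counts and truth", {
  cfg <- small_cfg(seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_dataset(cfg), d1)
  write_simulation(simulate_dataset(cfg), d2)
  for (f in c("genes.gff3", "counts.tsv", "lengths.tsv", "samples.tsv",
              "truth.yaml")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # and a different seed changes the data
  d3 <- withr::local_tempdir()
  write_simulation(simulate_dataset(small_cfg(seed = 100)), d3)
  expect_false(identical(readLines(file.path(d1, "counts.tsv")),
                         readLines(file.path(d3, "counts.tsv"))))
})

test_that("planted cluster members satisfy the gap bound (brute force)", {
  cfg <- small_cfg(seed = 3)
  sim <- simulate_genome(cfg)
  for (members in sim$truth$planted_cluster_members) {
    g <- sim$genes[match(members, sim$genes$gene_id), ]
    expect_equal(length(unique(g$scaffold)), 1)
    g <- g[order(g$start), ]
    for (i in seq_len(nrow(g) - 1)) {
      gap <- g$start[i + 1] - g$end[i] - 1
      expect_lte(gap, cfg$cluster_gap_bp)
    }
  }
  # non-overlap over all gene pairs per scaffold
  for (scaf in unique(sim$genes$scaffold)) {
    g <- sim$genes[sim$genes$scaffold == scaf, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
})

test_that("planted clusters carry >= 2 enzyme classes and a characterized member", {
  sim <- simulate_genome(small_cfg(seed = 12))
  for (members in sim$truth$planted_cluster_members) {
    cls <- sim$genes$enzyme_class[sim$genes$gene_id %in% members]
    expect_gte(length(unique(cls)), 2)
    expect_true(any(sim$genes$characterized[sim$genes$gene_id %in% members]))
  }
})

test_that("emitted counts recover the planted expression structure", {
  cfg <- sim_config(seed = 1)  # the validated study conditions
  sim <- simulate_dataset(cfg)
  tpm <- compute_tpm(sim$counts)
  prim <- tissue_mean_tpm(tpm, sim$counts$samples, "primordia")
  expect_gte(mean(prim[sim$truth$pathway_ids] >= 3000), 0.9)
  pcc <- bait_pcc(tpm, sim$truth$bait_id)
  pw_pcc <- pcc$pcc[match(sim$truth$pathway_ids, pcc$gene_id)]
  expect_gte(mean(pw_pcc >= 0.9), 0.9)
  # coexpression decoys share the profile too
  dx <- pcc$pcc[match(sim$truth$decoy_ids$coexpr, pcc$gene_id)]
  expect_true(all(dx >= 0.8))
})

test_that("background genes are uncorrelated with the bait across seeds", {
  # at the default conditions the planted module holds ~12% of the TPM
  # budget, so the compositional (closure) effect on background PCC is small
  means <- vapply(c(11, 12, 13), function(s) {
    sim <- simulate_dataset(sim_config(seed = s))
    tpm <- compute_tpm(sim$counts)
    pcc <- bait_pcc(tpm, sim$truth$bait_id)
    planted <- c(sim$truth$pathway_ids, unlist(sim$truth$decoy_ids))
    mean(pcc$pcc[!pcc$gene_id %in% planted], na.rm = TRUE)
  }, 1)
  expect_true(all(abs(means) <= 0.1))
})

test_that("infeasible configurations fail with explicit errors", {
  expect_error(sim_config(replicates_per_tissue = 0), "positive")
  expect_error(sim_config(n_pathway_genes = 1), "at least 2")
  expect_error(sim_config(n_genes = 10, n_pathway_genes = 12,
                          pathway_cluster_sizes = c(4, 4, 3)), "exceed")
  expect_error(sim_config(pathway_cluster_sizes = c(10, 10)),
               "exceeds n_pathway_genes")
  expect_error(simulate_genome(small_cfg(scaffold_length_bp = 50000)),
               "scaffold_length_bp")
})

test_that("counts generation rejects a mismatched gene table or truth", {
  cfg <- small_cfg(seed = 2)
  sim <- simulate_genome(cfg)
  expect_error(simulate_counts(cfg, sim$genes[-1, ], sim$truth),
               "does not match")
  other <- simulate_genome(small_cfg(seed = 5))
  expect_error(simulate_counts(cfg, sim$genes, other$truth),
               "does not match")
})

test_that("gff3 round-trip preserves the gene table", {
  sim <- simulate_genome(small_cfg(seed = 8))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_annotation(sim$genes, path)
  back <- read_gene_annotation(path)
  back <- back[match(sim$genes$gene_id, back$gene_id), ]
  rownames(back) <- NULL
  expect_equal(back[, c("gene_id", "scaffold", "start", "end", "length",
                        "enzyme_class", "characterized")],
               sim$genes[, c("gene_id", "scaffold", "start", "end", "length",
                             "enzyme_class", "characterized")])
})
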