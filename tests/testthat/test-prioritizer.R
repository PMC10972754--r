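cfg <- scoring_config()

test_that("coexpression sub-score follows the published 0.8-0.9 ramp", {
  expect_equal(coexpr_subscore(0.9, cfg), 1)
  expect_equal(coexpr_subscore(0.95, cfg), 1)
  expect_equal(coexpr_subscore(0.85, cfg), 0.5)
  expect_equal(coexpr_subscore(0.79, cfg), 0)
  expect_equal(coexpr_subscore(0.8, cfg), 0)
  expect_equal(coexpr_subscore(NA, cfg), 0)
  expect_equal(coexpr_subscore(-1, cfg), 0)
  expect_error(coexpr_subscore(1.2, cfg), "outside")
})

test_that("abundance sub-score follows the published 1,000-3,000 TPM ramp", {
  expect_equal(abundance_subscore(3000, cfg), 1)
  expect_equal(abundance_subscore(9000, cfg), 1)
  expect_equal(abundance_subscore(2000, cfg), 0.5)
  expect_equal(abundance_subscore(1000, cfg), 0)
  expect_equal(abundance_subscore(0, cfg), 0)
  expect_error(abundance_subscore(-5, cfg), "non-negative")
})

test_that("cluster sub-score gives 1 / 0.5 / 0 by membership status", {
  expect_equal(bgc_subscore("in_characterized_cluster", cfg), 1)
  expect_equal(bgc_subscore("in_other_cluster", cfg), 0.5)
  expect_equal(bgc_subscore("unclustered", cfg), 0)
  expect_error(bgc_subscore("somewhere", cfg), "invalid BGC status")
})

test_that("sub-scores are monotone and continuous at the ramp knots", {
  pgrid <- seq(-1, 1, by = 0.005)
  sc <- coexpr_subscore(pgrid, cfg)
  expect_true(all(diff(sc) >= 0))
  expect_true(all(sc >= 0 & sc <= 1))
  tgrid <- seq(0, 6000, by = 5)
  sa <- abundance_subscore(tgrid, cfg)
  expect_true(all(diff(sa) >= 0))
  expect_true(all(sa >= 0 & sa <= 1))
  eps <- 1e-9
  expect_equal(coexpr_subscore(cfg$pcc_lo + eps, cfg), 0, tolerance = 1e-6)
  expect_equal(coexpr_subscore(cfg$pcc_hi - eps, cfg), 1, tolerance = 1e-6)
  expect_equal(abundance_subscore(cfg$tpm_lo + eps, cfg), 0, tolerance = 1e-6)
  expect_equal(abundance_subscore(cfg$tpm_hi - eps, cfg), 1, tolerance = 1e-6)
})

make_scores <- function(...) {
  ev <- list(...)
  g <- do.call(rbind, lapply(seq_along(ev), function(i) {
    gene_row(names(ev)[i], i * 1000, i * 1000 + 100, "CYP")
  }))
  pcc <- data.frame(gene_id = g$gene_id,
                    pcc = vapply(ev, `[[`, 1, 1), defined = TRUE)
  tpm <- setNames(vapply(ev, `[[`, 1, 2), g$gene_id)
  status <- vapply(ev, function(x) x[[3]], "")
  clusters <- data.frame(cluster_id = c("c1", "c2"), scaffold = "sX",
                         span_start = 1L, span_end = 2L,
                         n_signature_classes = 2L,
                         contains_characterized = c(TRUE, FALSE),
                         stringsAsFactors = FALSE)
  clusters$member_ids <- list(
    g$gene_id[status == "in_characterized_cluster"],
    g$gene_id[status == "in_other_cluster"])
  score_candidates(g, pcc, tpm, clusters, cfg)
}

test_that("composite score is the exact sum with the published extremes", {
  sc <- make_scores(
    full = list(0.95, 4000, "in_characterized_cluster"),
    other = list(0.95, 4000, "in_other_cluster"),
    nothing = list(0.0, 0, "unclustered"),
    mid = list(0.85, 2000, "in_other_cluster"))
  expect_equal(sc$composite[sc$gene_id == "full"], 3.0)
  expect_equal(sc$composite[sc$gene_id == "other"], 2.5)
  expect_equal(sc$composite[sc$gene_id == "nothing"], 0)
  expect_equal(sc$composite[sc$gene_id == "mid"], 0.5 + 0.5 + 0.5)
  expect_equal(sc$composite, sc$c_coexpr + sc$c_abund + sc$c_bgc)
  expect_true(all(sc$composite >= 0 & sc$composite <= 3))
})

test_that("composite is non-decreasing in each evidence channel", {
  base <- list(0.85, 2000, "in_other_cluster")
  f <- function(ev) make_scores(g = ev)$composite
  expect_gte(f(list(0.88, 2000, "in_other_cluster")), f(base))
  expect_gte(f(list(0.85, 2600, "in_other_cluster")), f(base))
  expect_gte(f(list(0.85, 2000, "in_characterized_cluster")), f(base))
})

test_that("ranking sorts by composite with PCC, TPM and id tie-breaks", {
  sc <- make_scores(
    top = list(0.99, 5000, "in_characterized_cluster"),   # 3.0
    silver = list(0.99, 4000, "in_other_cluster"),        # 2.5, pcc 0.99
    bronze = list(0.92, 4500, "in_other_cluster"))        # 2.5, pcc 0.92
  rk <- rank_candidates(sc, cfg)
  expect_equal(rk$gene_id, c("top", "silver", "bronze"))
  expect_equal(rk$rank, 1:3)

  one <- rank_candidates(sc, scoring_config(top_n = 1))
  expect_equal(nrow(one), 1)
  expect_equal(one$gene_id, "top")

  # equal everything except id: ascending id wins
  sc2 <- make_scores(b = list(0.95, 4000, "unclustered"),
                     a = list(0.95, 4000, "unclustered"))
  expect_equal(rank_candidates(sc2, cfg)$gene_id, c("a", "b"))
})

test_that("ranks are a permutation and the class whitelist narrows the list", {
  set.seed(5)
  ev <- lapply(1:15, function(i) list(runif(1, -1, 1), runif(1, 0, 5000),
                                      sample(c("in_characterized_cluster",
                                               "in_other_cluster",
                                               "unclustered"), 1)))
  names(ev) <- sprintf("g%02d", 1:15)
  sc <- do.call(make_scores, ev)
  sc$enzyme_class <- rep(c("SDR-reductase", "CYP", "glycosyltransferase"), 5)
  rk <- rank_candidates(sc, scoring_config(top_n = NULL))
  expect_setequal(rk$rank, 1:15)

  wl <- scoring_config(top_n = NULL,
                       class_whitelist = c("SDR-reductase",
                                           "glycosyltransferase"))
  filtered <- rank_candidates(sc, wl)
  expect_equal(nrow(filtered), 10)
  expect_true(all(filtered$enzyme_class != "CYP"))
  # default timing keeps genome-wide ranks; pre-ranking filter renumbers
  refiltered <- rank_candidates(sc, wl, whitelist_timing = "before_ranking")
  expect_setequal(refiltered$rank, 1:10)
  expect_setequal(refiltered$gene_id, filtered$gene_id)
})

test_that("report rounding prints two-decimal scores without touching machine output", {
  sc <- make_scores(x = list(0.85, 2000, "in_other_cluster"))
  rk <- rank_candidates(sc, cfg)
  rep <- format_candidate_report(rk)
  expect_equal(rep$composite, 1.5)
  expect_equal(rk$composite, 1.5)
  sc2 <- make_scores(x = list(0.812, 1234, "unclustered"))
  expect_equal(format_candidate_report(rank_candidates(sc2, cfg))$composite,
               round(sc2$composite, 2))
})
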