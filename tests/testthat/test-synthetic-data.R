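test_that("configuration invariants are enforced with the field named", {
  expect_error(synth_config(n_subjects = 10,
                            profile_sizes = c(a = 3, b = 3)),
               "profile_sizes", class = "personet_config_error")
  expect_error(tiny_cfg(noise_sd = 0), "noise_sd",
               class = "personet_config_error")
  expect_error(tiny_cfg(llps_fraction = 1.2), "llps_fraction",
               class = "personet_config_error")
  expect_error(tiny_cfg(n_biclusters = 0), "n_biclusters",
               class = "personet_config_error")
  expect_error(tiny_cfg(n_genes = 20, bicluster_genes = 10),
               "bicluster_genes", class = "personet_config_error")
})

test_that("expression generator plants the advertised structure deterministically", {
  cfg <- tiny_cfg(seed = 5)
  es1 <- gen_expression(cfg)
  es2 <- gen_expression(cfg)
  expect_identical(es1$values, es2$values)  # pure function of cfg

  expect_equal(dim(es1$values), c(24, 60))
  expect_equal(nrow(es1$labels), 24)
  expect_equal(unname(table(es1$labels$profile)[c("creative", "organized",
                                                  "unregulated")]),
               c(8L, 10L, 6L), ignore_attr = TRUE)

  # planted gene blocks are disjoint and of the configured size
  sets <- lapply(es1$truth$biclusters, `[[`, "genes")
  expect_equal(lengths(sets), rep(8L, 3), ignore_attr = TRUE)
  expect_equal(anyDuplicated(unlist(sets)), 0L)

  # bicluster cells really are elevated
  b <- es1$truth$biclusters[[1]]
  inside <- mean(es1$values[b$subjects, b$genes])
  outside <- mean(es1$values[setdiff(rownames(es1$values), b$subjects),
                             b$genes])
  expect_gt(inside - outside, cfg$bicluster_effect / 2)
})

test_that("zero bicluster effect still yields a valid matrix", {
  es <- gen_expression(tiny_cfg(bicluster_effect = 0))
  expect_true(all(is.finite(es$values)))
  expect_length(es$truth$biclusters, 3)
})

test_that("paper-scale profile sizes validate and sum to 459", {
  cfg <- synth_config()
  expect_equal(sum(cfg$profile_sizes), 459L)
  expect_equal(unname(cfg$profile_sizes),
               c(125, 241, 93), ignore_attr = TRUE)
})

test_that("atlas construction elevates enriched sets and preserves gene order", {
  genes <- paste0("g", 1:40)
  sets <- list(A = genes[1:10], B = genes[11:20])
  cfg <- tiny_cfg(region_enrichment = list(A = c("R01", "R02")))
  atlas <- gen_atlas(cfg, sets, genes = genes)
  expect_identical(rownames(atlas), genes)
  expect_true(all(atlas >= 0))
  expect_gt(mean(atlas[sets$A, "R01"]), mean(atlas[genes[21:40], "R01"]))
  # non-enriched region stays exchangeable
  expect_lt(abs(mean(atlas[sets$A, "R03"]) - mean(atlas[genes[21:40], "R03"])),
            1.5)
  # degenerate 1x1 shape
  one <- gen_atlas(tiny_cfg(n_regions = 1), list(s = "g1"), genes = "g1")
  expect_equal(dim(one), c(1L, 1L))
})

test_that("atlas errors name missing genes and unknown sets", {
  cfg <- tiny_cfg()
  expect_error(gen_atlas(cfg, list(A = c("g1", "nope")), genes = "g1"),
               "nope")
  cfg2 <- tiny_cfg(region_enrichment = list(ghost = "R01"))
  expect_error(gen_atlas(cfg2, list(A = "g1"), genes = "g1"), "ghost")
})

test_that("interaction generator is deterministic and structurally sound", {
  cfg <- tiny_cfg(seed = 9)
  it1 <- gen_interactions(cfg)
  it2 <- gen_interactions(cfg)
  expect_identical(it1$edges, it2$edges)

  expect_true(all(it1$edges$layer %in% c("ppi", "tf_gene", "mirna_gene")))
  expect_true(all(it1$edges$source != it1$edges$target))
  expect_equal(anyDuplicated(it1$edges[c("source", "target", "layer")]), 0L)
  # every mirna_gene edge touches a miRNA
  types <- setNames(it1$node_types$type, it1$node_types$node)
  mg <- it1$edges[it1$edges$layer == "mirna_gene", ]
  expect_true(all(types[mg$source] == "mirna" | types[mg$target] == "mirna"))
  # both designated seed sets reach all six hub genes through the chains
  hub <- c(cfg$hub_mirnas, cfg$hub_proteins)
  expect_true(all(hub %in% it1$truth$min_networks$extrinsic))
  expect_true(all(hub %in% it1$truth$min_networks$intrinsic))
})

test_that("annotation draws follow the configured rates and determinism", {
  genes <- paste0("g", 1:4000)
  cfg <- tiny_cfg(llps_fraction = 0.157)
  ann <- gen_annotations(cfg, genes)
  expect_equal(mean(ann$llps_ht), 0.157, tolerance = 0.15)
  ann2 <- gen_annotations(cfg, genes)
  expect_identical(ann, ann2)
  none <- gen_annotations(tiny_cfg(llps_fraction = 0), genes)
  expect_equal(sum(none$llps_ht), 0)
})

test_that("planted truth survives a write/read round trip", {
  fx <- make_fixtures("small", seed = 3)
  dir <- withr::local_tempdir()
  write_fixtures(fx, dir)
  truth <- read_truth_json(file.path(dir, "truth.json"))
  expect_equal(sort(truth$seed_sets$extrinsic),
               sort(fx$truth$seed_sets$extrinsic))
  expect_equal(sort(truth$min_networks$intrinsic),
               sort(fx$truth$min_networks$intrinsic))
  m <- read_expression_tsv(file.path(dir, "expression.tsv"))
  expect_equal(m, fx$expression$values, tolerance = 1e-8)
  sets <- read_gmt(file.path(dir, "t_sets.gmt"))
  expect_identical(sets, fx$t_sets)
})

test_that("permuting subject labels destroys the planted profile effect", {
  cfg <- tiny_cfg(seed = 21, n_subjects = 90, n_genes = 200,
                  profile_sizes = c(creative = 25, organized = 40,
                                    unregulated = 25),
                  bicluster_genes = 20, responsive_frac = 0.1)
  es <- gen_expression(cfg)
  gene <- es$truth$responsive_genes[1]
  observed <- profile_anova(es$values[, gene], es$labels)$F
  perm_F <- withr::with_seed(99, vapply(seq_len(200), function(i) {
    profile_anova(es$values[, gene], sample(es$labels$profile))$F
  }, numeric(1)))
  expect_gt(observed, quantile(perm_F, 0.95))
  expect_lt(mean(perm_F), 3)  # null range
})
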