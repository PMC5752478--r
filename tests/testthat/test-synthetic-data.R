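test_that("default simulation reproduces the emulated study dimensions", {
  sim <- simulate_triomics(sim_config(seed = 1))
  expect_identical(dim(sim$matrices$mirna), c(1695L, 18L))
  expect_identical(dim(sim$matrices$protein), c(1069L, 18L))
  expect_identical(dim(sim$matrices$metabolite), c(2964L, 18L))
  expect_identical(nrow(sim$meta), 18L)
  expect_identical(as.vector(table(sim$meta$group)), rep(6L, 3))

  # truth sets carry exactly the configured cardinalities and are disjoint
  expect_identical(length(sim$truth$mirna$up), 18L)
  expect_identical(length(sim$truth$mirna$down), 10L)
  expect_identical(length(sim$truth$protein$up), 12L)
  expect_identical(length(sim$truth$protein$down), 8L)
  expect_identical(length(sim$truth$metabolite$up) +
                     length(sim$truth$metabolite$down), 9L)
  for (ly in c("mirna", "protein", "metabolite")) {
    expect_length(intersect(sim$truth[[ly]]$up, sim$truth[[ly]]$down), 0)
    expect_true(all(c(sim$truth[[ly]]$up, sim$truth[[ly]]$down) %in%
                      rownames(sim$matrices[[ly]]$values)))
  }
})

test_that("simulation is bit-identical for a fixed seed and varies across seeds", {
  cfg <- sim_config(n_features = c(mirna = 80, protein = 60, metabolite = 70),
                    annotate = FALSE, seed = 5)
  a <- simulate_triomics(cfg)
  b <- simulate_triomics(cfg)
  expect_identical(a$matrices$mirna$values, b$matrices$mirna$values)
  expect_identical(a$matrices$metabolite$values, b$matrices$metabolite$values)
  expect_identical(a$truth, b$truth)
  cfg2 <- cfg; cfg2$seed <- 6L
  expect_false(identical(a$matrices$mirna$values,
                         simulate_triomics(cfg2)$matrices$mirna$values))
})

test_that("planted effects average to delta and a null delta removes them", {
  sim <- simulate_triomics(sim_config(seed = 3))
  m <- sim$matrices$mirna
  lfc <- log2_fold_change(m, sim$meta, contrast("model", "treated"))
  up_mean <- mean(lfc[sim$truth$mirna$up])
  # mean over 18 planted-up features of a mean-difference with per-feature
  # lfc variance sigma^2 * 2/6; allow 3 sd of that average
  v_lfc <- 0.5^2 * 2 / 6
  expect_lt(abs(up_mean - 2), 3 * sqrt(v_lfc / 18))
  # the down set contains the block hub, whose latent loading inflates its
  # fold-change variance by beta^2 * 2/6 with beta = lambda * block_scale
  v_hub <- (0.95 * 3.5)^2 * 2 / 6 + v_lfc
  tol_down <- 3 * sqrt((9 * v_lfc + v_hub)) / 10
  expect_lt(abs(mean(lfc[sim$truth$mirna$down]) + 2), tol_down)

  null_sim <- simulate_triomics(sim_config(delta = 0, n_blocks = 0,
                                           annotate = FALSE, seed = 3))
  lfc0 <- log2_fold_change(null_sim$matrices$mirna, null_sim$meta,
                           contrast("model", "treated"))
  expect_identical(length(null_sim$truth$mirna$up), 18L)
  expect_lt(abs(mean(lfc0[null_sim$truth$mirna$up])), 3 * sqrt(v_lfc / 18))
})

test_that("block members are strongly mutually correlated across seeds", {
  # planted-block invariant: empirical |r| between two members exceeds 0.9
  # across the 18 samples in at least 95 of seeds 1..100
  cfg_base <- sim_config(n_features = c(mirna = 60, protein = 60,
                                        metabolite = 60),
                         annotate = FALSE, seed = 1)
  hits <- 0L
  for (s in 1:100) {
    cfg <- cfg_base; cfg$seed <- s
    sim <- simulate_triomics(cfg)
    b <- sim$truth$blocks[[1]]
    prot <- b$members$feature_id[b$members$layer == "protein"]
    x <- sim$matrices$mirna$values[b$hub, ]
    y <- sim$matrices$protein$values[prot[1], ]
    if (abs(cor(x, y)) > 0.9) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("hub and members sit in the planted-down sets with positive signs", {
  sim <- simulate_triomics(sim_config(seed = 2))
  b <- sim$truth$blocks[[1]]
  expect_true(b$hub %in% sim$truth$mirna$down)
  expect_identical(b$members$layer, c("mirna", "protein", "protein", "metabolite"))
  expect_true(all(b$members$sign == 1))
  met_member <- b$members$feature_id[b$members$layer == "metabolite"]
  expect_true(met_member %in% sim$truth$metabolite$down)
  ann <- sim$truth$annotation
  expect_identical(ann$compound[ann$feature_id == met_member],
                   "Oxoglutaric acid")
  expect_true(all(planted <- c(sim$truth$metabolite$down,
                               sim$truth$metabolite$up) %in% ann$feature_id))
})

test_that("metabolite missingness is intensity-dependent at the configured rate", {
  sim <- simulate_triomics(sim_config(seed = 4, annotate = FALSE))
  v <- sim$matrices$metabolite$values
  rate <- mean(is.na(v))
  expect_gt(rate, 0.01); expect_lt(rate, 0.03)
  expect_identical(sum(is.na(sim$matrices$mirna$values)), 0L)
  expect_identical(sum(is.na(sim$matrices$protein$values)), 0L)
  # left-censoring: features with missing cells have lower baseline intensity
  has_na <- rowSums(is.na(v)) > 0
  expect_lt(mean(rowMeans(v[has_na, ], na.rm = TRUE)),
            mean(rowMeans(v[!has_na, ])))
})

test_that("simulator rejects impossible planted counts", {
  expect_error(sim_config(n_features = c(mirna = 10, protein = 10,
                                         metabolite = 10)),
               "exceeds")
})

test_that("mito trace generator produces the implied plateaus and errors", {
  tr <- simulate_mito_trace(basal_total = 100, atp_frac = 2/3, leak_frac = 1/3,
                            nonmito = 10, max_fold = 5/3, noise_sd = 0)
  expect_equal(unique(tr$ocr), c(100, 40, 160, 10))
  expect_identical(unname(tr$injections), c(3L, 6L, 9L))
  tr2 <- simulate_mito_trace(100, 2/3, 1/3, 10, 5/3, noise_sd = 0)
  expect_identical(tr$ocr, tr2$ocr)
  tr3 <- simulate_mito_trace(100, 2/3, 1/3, 10, 5/3, noise_sd = 2, seed = 9)
  tr4 <- simulate_mito_trace(100, 2/3, 1/3, 10, 5/3, noise_sd = 2, seed = 9)
  expect_identical(tr3$ocr, tr4$ocr)
  expect_error(simulate_mito_trace(100, 2/3, 1/3, nonmito = 110, max_fold = 2),
               "nonmito")
  expect_error(simulate_mito_trace(100, 0.5, 0.3, 10, 2), "sum to 1")
})

test_that("simulated dataset writes round-trip through the readers", {
  cfg <- sim_config(n_features = c(mirna = 40, protein = 35, metabolite = 45),
                    annotate = FALSE, seed = 8)
  sim <- simulate_triomics(cfg)
  dir <- withr::local_tempdir()
  write_triomics(sim, dir)
  back <- read_feature_matrix(file.path(dir, "metabolite.csv"), "metabolite")
  expect_equal(back$values, sim$matrices$metabolite$values, tolerance = 1e-9)
  meta <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  expect_identical(meta$sample_id, sim$meta$sample_id)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_identical(sort(truth$mirna$up), sort(sim$truth$mirna$up))
})
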