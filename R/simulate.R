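# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic substream: distinct per (seed, offset) for offset < 101
substream <- function(seed, offset) {
  as.integer((as.numeric(seed) * 101 + offset) %% 2147483647)
}

#' Simulation configuration for the tri-omics generator
#'
#' Defaults reproduce the structure of the emulated study: 1695 miRNAs, 1069
#' proteins and 2964 metabolite peaks over three groups (control, model,
#' treated) of 6 replicates; 28 planted differential miRNAs (18 up / 10 down),
#' 20 proteins (12 / 8) and 9 metabolites (4 / 5) with a log2 effect of
#' `delta` in the treated group; one latent-factor correlation block tying a
#' hub miRNA to two proteins and one metabolite (the miR-144-5p /
#' IDH1 / IDH2 / oxoglutaric-acid motif).
#'
#' @param n_features Named integer vector: features per layer.
#' @param n_per_group Replicates per group.
#' @param groups Group labels; differential effects are planted in the last
#'   (treated) group, the middle group is the untreated model.
#' @param de_mirna,de_protein,de_metabolite Named vectors `c(up=, down=)` of
#'   planted differential-feature counts.
#' @param delta Planted log2 effect size in the treated group.
#' @param sigma Residual standard deviation (log2 units).
#' @param lambda Latent-factor loading of correlation blocks, in (0, 1].
#' @param block_scale Multiplier applied to `lambda` when the latent factor is
#'   added to block members. The default 3.5 puts the model-implied pairwise
#'   correlation between concordant block members near 0.98, comfortably above
#'   the 0.9 reporting threshold given sampling noise at 12-18 samples.
#' @param missing_rate Expected fraction of missing cells in the metabolite
#'   layer (missingness is intensity-dependent; see the methods vignette).
#' @param n_blocks Number of planted correlation blocks (default 1).
#' @param annotate If `TRUE`, annotate metabolite peaks with compound names
#'   from the bundled pathway library (planted peaks become TCA-cycle
#'   compounds plus cyclic AMP).
#' @param seed Integer RNG seed; all layers derive deterministic substreams.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_features = c(mirna = 1695L, protein = 1069L,
                                      metabolite = 2964L),
                       n_per_group = 6L,
                       groups = c("control", "model", "treated"),
                       de_mirna = c(up = 18L, down = 10L),
                       de_protein = c(up = 12L, down = 8L),
                       de_metabolite = c(up = 4L, down = 5L),
                       delta = 2.0, sigma = 0.5, lambda = 0.95,
                       block_scale = 3.5, missing_rate = 0.02,
                       n_blocks = 1L, annotate = TRUE, seed = 1L) {
  stopifnot(length(n_features) == 3, all(n_features >= 1),
            n_per_group >= 2, length(groups) >= 2,
            delta >= 0, sigma > 0, lambda > 0, lambda <= 1,
            block_scale > 0, missing_rate >= 0, missing_rate < 1,
            n_blocks >= 0)
  names(n_features) <- c("mirna", "protein", "metabolite")
  for (nm in c("de_mirna", "de_protein", "de_metabolite")) {
    v <- get(nm)
    if (!all(c("up", "down") %in% names(v)))
      stop(nm, " needs named elements 'up' and 'down'")
  }
  if (sum(de_mirna) > n_features["mirna"] ||
      sum(de_protein) > n_features["protein"] ||
      sum(de_metabolite) > n_features["metabolite"])
    stop("planted differential-feature count exceeds the number of features")
  structure(list(n_features = n_features, n_per_group = as.integer(n_per_group),
                 groups = groups, de_mirna = de_mirna, de_protein = de_protein,
                 de_metabolite = de_metabolite, delta = delta, sigma = sigma,
                 lambda = lambda, block_scale = block_scale,
                 missing_rate = missing_rate, n_blocks = as.integer(n_blocks),
                 annotate = isTRUE(annotate), seed = as.integer(seed)),
            class = "sim_config")
}

# compound names the simulator can hand out; the planted set mirrors the
# reported discriminant metabolites (TCA intermediates plus cyclic AMP)
planted_compounds <- function() {
  c("Oxoglutaric acid", "Citric acid", "Isocitric acid", "Malic acid",
    "Fumaric acid", "Succinic acid", "Oxaloacetic acid", "cis-Aconitic acid",
    "Cyclic AMP")
}

#' Generate a synthetic tri-omics dataset with planted ground truth
#'
#' Each feature f in sample s of group g is drawn as
#' `mu_f + Delta_f(g) + beta_f * z_s + eps` with `mu_f ~ N(8, 2^2)`,
#' `eps ~ N(0, sigma^2)`, `Delta_f(treated) = +/- delta` for planted
#' differential features (0 elsewhere), and `beta_f = sign * lambda *
#' block_scale` for correlation-block members sharing the per-sample latent
#' factor `z_s ~ N(0, 1)`. The default block plants a hub miRNA with two
#' proteins and one metabolite, all also planted as down-regulated, mirroring
#' the miR-144-5p motif. The metabolite layer receives
#' intensity-dependent missing values (left-censoring-like, logistic in
#' `mu_f`) at the configured overall rate.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `matrices` (named list of three
#'   [omics_matrix()]), `meta` (sample metadata), and `truth` (planted
#'   up/down id sets per layer, the correlation blocks, and the metabolite
#'   compound annotation).
#' @export
simulate_triomics <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  groups <- cfg$groups
  n <- cfg$n_per_group
  sample_ids <- unlist(lapply(groups, function(g) sprintf("%s_%d", g, seq_len(n))))
  meta <- sample_metadata(sample_ids, rep(groups, each = n))
  treated <- groups[length(groups)]
  S <- length(sample_ids)

  prefixes <- c(mirna = "mir", protein = "prot", metabolite = "met")
  de_counts <- list(mirna = cfg$de_mirna, protein = cfg$de_protein,
                    metabolite = cfg$de_metabolite)

  layers <- list()
  truth <- list()
  for (k in seq_along(prefixes)) {
    layer <- names(prefixes)[k]
    J <- cfg$n_features[[layer]]
    ids <- sprintf("%s_%04d", prefixes[[layer]], seq_len(J))
    cnt <- de_counts[[layer]]
    vals <- with_seed(substream(cfg$seed, k), {
      mu <- stats::rnorm(J, 8, 2)
      planted <- sample.int(J, cnt[["up"]] + cnt[["down"]])
      eps <- matrix(stats::rnorm(J * S, 0, cfg$sigma), J, S)
      v <- mu + eps
      if (cnt[["up"]] > 0) {
        up_idx <- planted[seq_len(cnt[["up"]])]
        v[up_idx, meta$group == treated] <-
          v[up_idx, meta$group == treated] + cfg$delta
      }
      if (cnt[["down"]] > 0) {
        down_idx <- planted[cnt[["up"]] + seq_len(cnt[["down"]])]
        v[down_idx, meta$group == treated] <-
          v[down_idx, meta$group == treated] - cfg$delta
      }
      list(v = v, mu = mu, planted = planted)
    })
    truth[[layer]] <- list(
      up = ids[vals$planted[seq_len(cnt[["up"]])]],
      down = ids[vals$planted[cnt[["up"]] + seq_len(cnt[["down"]])]])
    layers[[layer]] <- list(values = vals$v, mu = vals$mu, ids = ids)
  }

  # correlation blocks: hub miRNA + 2 proteins + 1 metabolite, all drawn from
  # the planted down-regulated sets so block and differential truth overlap
  blocks <- list()
  if (cfg$n_blocks > 0) {
    need <- function(layer, k) {
      ids <- truth[[layer]]$down
      if (length(ids) < k)
        stop(sprintf("need >= %d planted-down %s features for %d block(s)",
                     k, layer, cfg$n_blocks))
      ids
    }
    hub_pool <- need("mirna", cfg$n_blocks)
    prot_pool <- need("protein", 2 * cfg$n_blocks)
    met_pool <- need("metabolite", cfg$n_blocks)
    z_all <- with_seed(substream(cfg$seed, 50), {
      matrix(stats::rnorm(S * cfg$n_blocks), S, cfg$n_blocks)
    })
    for (b in seq_len(cfg$n_blocks)) {
      members <- data.frame(
        feature_id = c(hub_pool[b], prot_pool[2 * b - 1], prot_pool[2 * b],
                       met_pool[b]),
        layer = c("mirna", "protein", "protein", "metabolite"),
        sign = c(1, 1, 1, 1), stringsAsFactors = FALSE)
      beta <- cfg$lambda * cfg$block_scale
      z <- z_all[, b]
      for (i in seq_len(nrow(members))) {
        ly <- members$layer[i]
        row <- match(members$feature_id[i], layers[[ly]]$ids)
        layers[[ly]]$values[row, ] <- layers[[ly]]$values[row, ] +
          members$sign[i] * beta * z
      }
      blocks[[b]] <- list(hub = hub_pool[b], members = members,
                          lambda = cfg$lambda, scale = cfg$block_scale)
    }
  }

  # intensity-dependent missingness in the metabolite layer: logistic in mu_f,
  # location calibrated so the expected overall rate matches the config
  if (cfg$missing_rate > 0) {
    mu <- layers$metabolite$mu
    f <- function(tau) mean(stats::plogis(tau - mu)) - cfg$missing_rate
    tau <- stats::uniroot(f, c(min(mu) - 50, max(mu) + 50))$root
    p_f <- stats::plogis(tau - mu)
    layers$metabolite$values <- with_seed(substream(cfg$seed, 60), {
      v <- layers$metabolite$values
      miss <- matrix(stats::runif(length(v)) < p_f, nrow(v), ncol(v))
      v[miss] <- NA_real_
      v
    })
  }

  annotation <- NULL
  if (cfg$annotate) {
    lib <- triomix_library()
    all_compounds <- sort(unique(unlist(lapply(lib, `[[`, "members"))))
    planted_ids <- c(truth$metabolite$down, truth$metabolite$up)
    pc <- planted_compounds()
    n_pl <- min(length(planted_ids), length(pc))
    annotation <- data.frame(feature_id = planted_ids[seq_len(n_pl)],
                             compound = pc[seq_len(n_pl)],
                             stringsAsFactors = FALSE)
    rest <- setdiff(all_compounds, annotation$compound)
    free <- setdiff(layers$metabolite$ids, planted_ids)
    host <- with_seed(substream(cfg$seed, 70),
                      sample(free, min(length(rest), length(free))))
    annotation <- rbind(annotation,
                        data.frame(feature_id = host, compound = rest,
                                   stringsAsFactors = FALSE))
    annotation <- annotation[order(annotation$feature_id), , drop = FALSE]
    rownames(annotation) <- NULL
  }

  matrices <- lapply(names(prefixes), function(layer) {
    omics_matrix(layers[[layer]]$values, layer = layer,
                 feature_ids = layers[[layer]]$ids, sample_ids = sample_ids)
  })
  names(matrices) <- names(prefixes)
  list(matrices = matrices, meta = meta,
       truth = list(mirna = truth$mirna, protein = truth$protein,
                    metabolite = truth$metabolite, blocks = blocks,
                    annotation = annotation))
}

#' Write a simulated dataset to a directory
#'
#' Emits the three layer matrices (CSV), the sample metadata (TSV) and the
#' planted truth (JSON).
#'
#' @param sim Result of [simulate_triomics()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_triomics <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (layer in names(sim$matrices))
    write_feature_matrix(sim$matrices[[layer]],
                         file.path(dir, paste0(layer, ".csv")))
  writeLines(c("sample_id\tgroup",
               paste(sim$meta$sample_id, sim$meta$group, sep = "\t")),
             file.path(dir, "metadata.tsv"))
  truth <- sim$truth
  truth$blocks <- lapply(truth$blocks, function(b) {
    b$members <- as.list(b$members); b
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Generate a synthetic mito-stress-test OCR trace
#'
#' Produces the canonical four-phase oxygen-consumption-rate time series
#' (baseline, post-oligomycin, post-FCCP, post-rotenone/antimycin-A) with
#' `n_cycles` measurements per phase. Phase plateaus are implied by the
#' requested parameters: baseline = `basal_total`; post-oligomycin =
#' `nonmito + leak_frac * (basal_total - nonmito)`; post-FCCP =
#' `nonmito + max_fold * (basal_total - nonmito)`; post-rotenone = `nonmito`.
#' Gaussian noise of sd `noise_sd` is added to every measurement.
#'
#' @param basal_total Baseline OCR (pmol O2/min).
#' @param atp_frac,leak_frac Fractions of the mitochondrial (baseline minus
#'   non-mitochondrial) OCR attributed to ATP synthesis and proton leak; they
#'   must sum to 1.
#' @param nonmito Non-mitochondrial OCR; must not exceed `basal_total`.
#' @param max_fold Maximal (FCCP-uncoupled) mitochondrial OCR as a multiple of
#'   basal mitochondrial OCR; >= 1.
#' @param noise_sd Measurement noise sd (0 gives a deterministic trace).
#' @param seed RNG seed for the noise.
#' @param n_cycles Measurements per phase (>= 2; default 3).
#' @param ecar_basal If non-`NULL`, also emit a flat ECAR channel at this
#'   level (plus the same noise model).
#' @return A `mito_stress_trace`: list with `time` (min), `ocr`, optional
#'   `ecar`, and `injections` (indices of the last measurement before
#'   oligomycin, FCCP and rotenone/antimycin-A).
#' @export
simulate_mito_trace <- function(basal_total, atp_frac, leak_frac, nonmito,
                                max_fold, noise_sd = 0, seed = 1L,
                                n_cycles = 3L, ecar_basal = NULL) {
  stopifnot(atp_frac > 0, atp_frac < 1, leak_frac > 0, leak_frac < 1,
            max_fold >= 1, noise_sd >= 0, n_cycles >= 2)
  if (abs(atp_frac + leak_frac - 1) > 1e-8)
    stop("atp_frac and leak_frac must sum to 1 (they partition basal mitochondrial OCR)")
  if (nonmito > basal_total)
    stop("nonmito exceeds basal_total: no mitochondrial respiration left")
  basal_mito <- basal_total - nonmito
  plateaus <- c(basal_total,
                nonmito + leak_frac * basal_mito,
                nonmito + max_fold * basal_mito,
                nonmito)
  ocr <- rep(plateaus, each = n_cycles)
  m <- length(ocr)
  time <- seq(0, by = 6.5, length.out = m)
  if (noise_sd > 0)
    ocr <- with_seed(seed, ocr + stats::rnorm(m, 0, noise_sd))
  trace <- list(time = time, ocr = ocr,
                injections = c(oligomycin = n_cycles,
                               fccp = 2L * n_cycles,
                               rotenone = 3L * n_cycles))
  if (!is.null(ecar_basal)) {
    ecar <- rep(ecar_basal, m)
    if (noise_sd > 0)
      ecar <- with_seed(substream(seed, 1), ecar + stats::rnorm(m, 0, noise_sd))
    trace$ecar <- ecar
  }
  class(trace) <- "mito_stress_trace"
  trace
}
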