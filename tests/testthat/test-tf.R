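# TF binding-site scoring and the per-TF mutation-status model.

.tf_fixture <- function() {
  calls <- data.frame(chrom = "chr1",
                      pos = c(5L, 15L, 25L, 35L, 45L), mark = "mc",
                      sample_id = "A", timepoint_months = 0L,
                      called_sites = 10L,
                      called_modified = c(6L, 8L, 2L, 9L, 5L),
                      modified_fraction = c(0.6, 0.8, 0.2, 0.9, 0.5))
  tf <- data.frame(chrom = "chr1", start = c(0L, 30L), end = c(20L, 40L),
                   tf_name = "TFX")
  ann <- data.frame(chrom = "chr1", start = 0L, end = 30L, label = "Enh",
                    cell_type = "PBMC")
  list(calls = calls, tf = tf, ann = ann)
}

test_that("TF scores average qualifying positions unweighted", {
  fx <- .tf_fixture()
  # enhancer overlap: positions 5 and 15 (25 is enhancer but not TF-bound,
  # 35 is TF-bound but outside the enhancer)
  sc <- tf_scores(fx$calls, fx$tf, fx$ann, restriction = "all_positions",
                  universe = "enhancer_overlap")
  expect_equal(sc$mean_fraction, 0.7)
  expect_equal(sc$n_positions, 2L)
  # genome-wide universe adds position 35
  sg <- tf_scores(fx$calls, fx$tf, fx$ann, restriction = "all_positions",
                  universe = "genome_wide")
  expect_equal(sg$n_positions, 3L)
  expect_equal(sg$mean_fraction, mean(c(0.6, 0.8, 0.9)))
})

test_that("the hyper-only restriction keeps positions above the sample's enhancer mean", {
  fx <- .tf_fixture()
  # sample enhancer mean over sites 5,15,25 = (0.6+0.8+0.2)/3 = 0.5333..
  sh <- tf_scores(fx$calls, fx$tf, fx$ann, restriction = "hyper_only",
                  universe = "enhancer_overlap")
  expect_equal(sh$n_positions, 2L)
  expect_equal(sh$mean_fraction, 0.7)
  # push the enhancer mean to 0.7: only the 0.8 position stays (strict)
  fx$calls$modified_fraction[3] <- 0.7
  fx$calls$called_modified[3] <- 7L
  sh2 <- tf_scores(fx$calls, fx$tf, fx$ann, restriction = "hyper_only",
                   universe = "enhancer_overlap")
  expect_equal(sh2$n_positions, 1L)
  expect_equal(sh2$mean_fraction, 0.8)
})

test_that("TF scores match a brute-force double-membership scan", {
  set.seed(71)
  for (rep in 1:3) {
    calls <- random_site_calls(150, chroms = "chr1")
    calls$sample_id <- "A"; calls$timepoint_months <- 0L
    ann <- random_intervals(15, chroms = "chr1", labels = "Enh")
    tf <- random_intervals(10, chroms = "chr1", labels = "TFY")
    names(tf)[4] <- "tf_name"; tf$cell_type <- NULL
    got <- tf_scores(calls, tf, ann, restriction = "all_positions",
                     universe = "enhancer_overlap")
    inf <- calls$called_sites > 0L
    in_tf <- in_enh <- rep(FALSE, nrow(calls))
    for (j in seq_len(nrow(tf)))
      in_tf <- in_tf | (calls$pos >= tf$start[j] & calls$pos < tf$end[j])
    for (j in seq_len(nrow(ann)))
      in_enh <- in_enh | (calls$pos >= ann$start[j] & calls$pos < ann$end[j])
    qual <- unique(calls[inf & in_tf & in_enh,
                         c("chrom", "pos", "modified_fraction")])
    if (nrow(qual) == 0L) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$n_positions, nrow(qual))
      expect_equal(got$mean_fraction, mean(qual$modified_fraction),
                   tolerance = 1e-12)
    }
  }
})

test_that("a TF tiling the enhancer class scores the enhancer region mean", {
  set.seed(72)
  calls <- random_site_calls(200, chroms = "chr1")
  calls$sample_id <- "A"; calls$timepoint_months <- 0L
  ann <- random_intervals(10, chroms = "chr1", labels = "Enh")
  tf <- data.frame(chrom = ann$chrom, start = ann$start, end = ann$end,
                   tf_name = "TILE")
  sc <- tf_scores(calls, tf, ann, restriction = "all_positions",
                  universe = "enhancer_overlap")
  summ <- summarize_regions(calls, ann, genome_wide = FALSE)
  expect_equal(sc$mean_fraction, summ$mean_fraction[summ$label == "Enh"],
               tolerance = 1e-12)
  expect_equal(sc$n_positions, summ$n_sites[summ$label == "Enh"])
})

test_that("the hyper-only mean never falls below the all-positions mean", {
  set.seed(73)
  for (rep in 1:5) {
    calls <- random_site_calls(150, chroms = "chr1")
    calls$sample_id <- "A"; calls$timepoint_months <- 0L
    ann <- random_intervals(12, chroms = "chr1", labels = "Enh")
    tf <- random_intervals(8, chroms = "chr1", labels = "TFZ")
    names(tf)[4] <- "tf_name"; tf$cell_type <- NULL
    all_sc <- tf_scores(calls, tf, ann, "all_positions", "enhancer_overlap")
    hyp_sc <- tf_scores(calls, tf, ann, "hyper_only", "enhancer_overlap")
    if (nrow(all_sc) == 1L && nrow(hyp_sc) == 1L)
      expect_gte(hyp_sc$mean_fraction, all_sc$mean_fraction)
  }
})

test_that("exact linear TF scores identify the carrier coefficient", {
  meta <- data.frame(mutation_status = rep(c("carrier", "control"),
                                           each = 3))
  d <- data.frame(response = 0.3 +
                    0.05 * (meta$mutation_status == "carrier"),
                  mutation_status = meta$mutation_status,
                  enh_mean = 0.6)
  expect_warning(fit <- fit_tf_model(d), "constant")
  expect_equal(fit$estimate, 0.05, tolerance = 1e-12)
  # response equal to the covariate: the effect is absorbed entirely
  d2 <- data.frame(response = c(0.61, 0.62, 0.63, 0.58, 0.59, 0.60),
                   mutation_status = meta$mutation_status,
                   enh_mean = c(0.61, 0.62, 0.63, 0.58, 0.59, 0.60))
  fit2 <- fit_tf_model(d2)
  expect_equal(fit2$estimate, 0, tolerance = 1e-9)
})

test_that("TFs bound to overloaded enhancers rank top of the screen", {
  # stochastic module property: aggregated over replicate cohorts, the
  # overload-bound TFs sit in the top quarter of the hyper-only screen
  prof <- default_region_profile()
  prof <- prof[prof$label %in% c("Enh", "Tx"), ]
  ranks <- integer()
  raw_pos <- logical()
  for (sd in c(13, 5, 31, 47, 61)) {
    cfg <- sim_config(region_profile = prof, n_intervals = 150,
                      sites_per_interval = 20, timepoints = 0,
                      n_tf = 12, n_effect_tf = 3,
                      tf_intervals_per_tf = 40, seed = sd)
    co <- simulate_cohort(cfg)
    calls0 <- co$calls[co$calls$mark == "mc", ]
    sc <- tf_scores(calls0, co$tf_sites, co$annotations,
                    restriction = "hyper_only",
                    universe = "enhancer_overlap")
    s <- summarize_regions(calls0, co$annotations)
    em <- s[s$label == "Enh" & s$cell_type == "PBMC", ]
    em <- data.frame(sample_id = em$sample_id,
                     enh_mean = em$mean_fraction)
    scr <- tf_screen(sc, co$samples, em, timepoint = 0)
    expect_equal(scr$q_value, bh_oracle(scr$p_value)[order(scr$p_value)],
                 tolerance = 1e-12)
    ranks <- c(ranks, which(scr$tf_name %in% co$truth$effect_tfs))
    # the raw carrier-vs-control score difference is always positive
    meta <- co$samples[!duplicated(co$samples$sample_id), ]
    m <- merge(sc, meta, by = "sample_id")
    for (tf in co$truth$effect_tfs) {
      x <- m[m$tf_name == tf, ]
      raw_pos <- c(raw_pos,
                   mean(x$mean_fraction[x$mutation_status == "carrier"]) >
                     mean(x$mean_fraction[x$mutation_status == "control"]))
    }
  }
  expect_lte(median(ranks), 4)
  expect_true(all(raw_pos))
})
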