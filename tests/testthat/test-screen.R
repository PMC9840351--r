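# OLS screen, t-tests and FDR correction.

test_that("exact linear responses are recovered without residual error", {
  meta <- data.frame(
    mutation_status = rep(c("carrier", "control"), each = 4),
    lymphoma_status = "unaffected")
  d <- data.frame(response = 0.5 + 0.1 * (meta$mutation_status == "carrier"),
                  mutation_status = meta$mutation_status,
                  lymphoma_status = meta$lymphoma_status,
                  genomewide = 0)
  expect_warning(fit <- fit_annotation_model(d), "constant covariate")
  expect_equal(fit$estimate, 0.1, tolerance = 1e-12)
  expect_equal(fit$dropped, c("lymphoma_status", "genomewide"))

  d$response <- 0.5   # constant response: carrier effect exactly zero
  expect_warning(fit0 <- fit_annotation_model(d))
  expect_equal(fit0$estimate, 0, tolerance = 1e-12)
})

test_that("screen model needs at least 5 samples and carrier variation", {
  d <- data.frame(response = 1:4 / 10,
                  mutation_status = c("carrier", "carrier", "control",
                                      "control"))
  expect_error(fit_annotation_model(d), "at least 5")
  d <- data.frame(response = 1:6 / 10,
                  mutation_status = rep("control", 6))
  expect_error(fit_annotation_model(d), "no variation")
})

test_that("OLS estimates match the normal-equations oracle", {
  set.seed(10)
  for (rep in 1:20) {
    n <- 8L
    carrier <- rep(c(1, 0), each = 4)
    lymph <- rbinom(n, 1, 0.4)
    if (length(unique(lymph)) < 2L) lymph[1:2] <- c(0, 1)
    gw <- runif(n, 0.4, 0.6)
    y <- 0.5 + 0.02 * carrier + 0.01 * lymph + 0.3 * gw + rnorm(n, 0, 0.01)
    fit <- fit_annotation_model(data.frame(
      response = y,
      mutation_status = ifelse(carrier == 1, "carrier", "control"),
      lymphoma_status = ifelse(lymph == 1, "affected", "unaffected"),
      genomewide = gw))
    orc <- ols_oracle(cbind(1, carrier, lymph, gw), y)
    expect_equal(fit$estimate, orc$beta[2L], tolerance = 1e-9)
    expect_equal(fit$p_value, orc$p[2L], tolerance = 1e-9)
    expect_equal(fit$std_error, orc$se[2L], tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  # frozen example: family of 4 evenly spaced p-values all collapse to 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  expect_equal(p.adjust(0.03, "BH"), 0.03)       # single test: q = p
  expect_equal(p.adjust(rep(1, 5), "BH"), rep(1, 5))
  set.seed(20)
  for (rep in 1:50) {
    p <- runif(sample(2:30, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("run_screen fits every annotation and corrects over the family", {
  set.seed(5)
  n <- 6L
  samples <- sprintf("S%d", 1:n)
  meta <- data.frame(sample_id = samples,
                     mutation_status = rep(c("carrier", "control"),
                                           each = 3),
                     lymphoma_status = "unaffected",
                     timepoint_months = 0L)
  labs <- c("Enh", "TssA", "Quies")
  summ <- do.call(rbind, lapply(c(labs, "GENOME_WIDE"), function(lb)
    data.frame(sample_id = samples, timepoint_months = 0L, mark = "mc",
               cell_type = if (lb == "GENOME_WIDE") "GENOME" else "PBMC",
               label = lb,
               mean_fraction = runif(n, 0.4, 0.6) +
                 ifelse(lb == "Enh", 0.1, 0) *
                   (meta$mutation_status == "carrier"),
               n_sites = 100L)))
  scr <- run_screen(summ, meta, mark = "mc", timepoint = 0)
  expect_equal(sort(scr$label), sort(labs))       # GENOME_WIDE is covariate
  expect_true(all(scr$q_value >= scr$p_value))
  expect_equal(scr$q_value, bh_oracle(scr$p_value), tolerance = 1e-12)
  expect_gt(scr$estimate[scr$label == "Enh"], 0)
})

test_that("identical groups give t = 0 and p = 1", {
  tt <- ttest_change(c(1, 2, 3), c(1, 2, 3), variant = "welch")
  expect_equal(tt$t, 0)
  expect_equal(tt$p_value, 1)
  expect_equal(tt$mean_diff, 0)
})

test_that("Welch results match hand-computed formula values", {
  x <- c(0.1, 0.2, 0.3); y <- c(0.4, 0.5, 0.6)
  tt <- ttest_change(x, y, variant = "welch")
  # frozen values from the textbook Welch formulas:
  # t = -0.3 / sqrt(0.01/3 + 0.01/3), Welch-Satterthwaite df = 4
  expect_equal(tt$t, -3.67423461417477, tolerance = 1e-10)
  expect_equal(tt$df, 4, tolerance = 1e-10)
  expect_equal(tt$p_value, 0.0213116411287567, tolerance = 1e-10)
  orc <- welch_oracle(x, y)
  expect_equal(tt$t, orc$t)
  expect_equal(tt$p_value, orc$p)
})

test_that("confidence intervals reproduce mean diff +/- t_crit * SE", {
  set.seed(30)
  for (variant in c("welch", "student")) {
    x <- rnorm(5); y <- rnorm(7, 0.5)
    tt <- ttest_change(x, y, variant = variant)
    orc <- if (variant == "welch") welch_oracle(x, y) else
      student_oracle(x, y)
    crit <- qt(0.975, orc$df)
    expect_equal(tt$ci_low, tt$mean_diff - crit * orc$se,
                 tolerance = 1e-10)
    expect_equal(tt$ci_high, tt$mean_diff + crit * orc$se,
                 tolerance = 1e-10)
    expect_true(tt$ci_low <= tt$mean_diff & tt$mean_diff <= tt$ci_high)
    expect_equal(tt$p_value, orc$p, tolerance = 1e-10)
  }
})

test_that("Welch p-value is symmetric under group exchange", {
  set.seed(31)
  for (rep in 1:10) {
    x <- rnorm(4); y <- rnorm(6, 0.3)
    a <- ttest_change(x, y, "welch")
    b <- ttest_change(y, x, "welch")
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    expect_equal(a$t, -b$t, tolerance = 1e-12)
  }
})

test_that("zero-variance degenerate inputs follow the stated conventions", {
  eq <- ttest_change(c(1, 1, 1), c(1, 1), variant = "student")
  expect_equal(eq$p_value, 1)
  expect_false(eq$degenerate)
  ne <- ttest_change(c(2, 2, 2), c(1, 1), variant = "student")
  expect_equal(ne$p_value, 0)
  expect_true(ne$degenerate)
  expect_error(ttest_change(1, c(1, 2)), "at least 2")
})

test_that("the change screen corrects per label and counts significant ones", {
  set.seed(8)
  samples <- c(sprintf("M%d", 1:3), sprintf("C%d", 1:3), "L1")
  meta <- data.frame(sample_id = samples,
                     mutation_status = c(rep("carrier", 3),
                                         rep("control", 3), "carrier"),
                     lymphoma_status = c(rep("unaffected", 6), "affected"),
                     timepoint_months = 0L)
  mk <- function(lb, eff) data.frame(
    sample_id = samples, cell_type = "PBMC", label = lb, mark = "hmc",
    change = rnorm(7, 0, 0.0005) -
      eff * (meta$mutation_status == "carrier"))
  # one annotation family: significance count is 0 or 1
  one <- screen_hmc_change(mk("Enh", 0.01), meta)
  expect_equal(one$n_tested, 1L)
  expect_true(one$n_significant %in% c(0L, 1L))
  # lymphoma-affected samples are excluded from the groups
  expect_equal(one$results$n_x + one$results$n_y, 6L)
  two <- screen_hmc_change(rbind(mk("Enh", 0.01), mk("TssA", 0)), meta)
  expect_equal(two$n_tested, 2L)
  expect_equal(two$results$q_value, bh_oracle(two$results$p_value))
})
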