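# Annotation-level statistics: OLS screen of mutation-status effects,
# two-sample t-tests of change over time, Benjamini-Hochberg correction.

#' Fit the annotation-level mutation-status model
#'
#' Ordinary least squares of per-sample average methylation on mutation
#' status, lymphoma status and the sample's genome-wide average:
#' `response ~ mutation + lymphoma + genomewide`.  Covariates without
#' variation (e.g. all samples lymphoma-unaffected) are dropped with a
#' warning and the model refitted on the remaining terms.  The reported
#' term is the carrier indicator: its OLS estimate (on the fraction scale)
#' and two-sided t-test p-value.
#'
#' @param data Data.frame with columns `response` (numeric),
#'   `mutation_status` (`carrier`/`control`), and optionally
#'   `lymphoma_status` (`affected`/`unaffected`) and `genomewide`
#'   (numeric covariate).
#' @return List with `estimate`, `std_error`, `p_value`, `n`,
#'   `df_residual`, `dropped` (names of dropped covariates).
#' @export
fit_annotation_model <- function(data) {
  stopifnot(all(c("response", "mutation_status") %in% names(data)))
  n <- nrow(data)
  if (n < 5L)
    stop("need at least 5 samples to fit the screen model (got ", n, ")",
         call. = FALSE)
  d <- data.frame(response = as.numeric(data$response),
                  carrier = as.numeric(data$mutation_status == "carrier"))
  if (length(unique(d$carrier)) < 2L)
    stop("mutation_status has no variation; carrier effect unidentifiable",
         call. = FALSE)
  dropped <- character()
  terms <- "carrier"
  if ("lymphoma_status" %in% names(data)) {
    lym <- as.numeric(data$lymphoma_status == "affected")
    if (length(unique(lym)) > 1L) {
      d$lymphoma <- lym
      terms <- c(terms, "lymphoma")
    } else dropped <- c(dropped, "lymphoma_status")
  }
  if ("genomewide" %in% names(data)) {
    gw <- as.numeric(data$genomewide)
    if (length(unique(gw)) > 1L) {
      d$genomewide <- gw
      terms <- c(terms, "genomewide")
    } else dropped <- c(dropped, "genomewide")
  }
  if (length(dropped) > 0L)
    warning("dropped constant covariate(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  fml <- stats::as.formula(paste("response ~", paste(terms, collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  if (any(is.na(coef(fit))))
    stop("rank-deficient design after dropping constant covariates",
         call. = FALSE)
  sm <- summary(fit)$coefficients
  list(estimate = unname(sm["carrier", "Estimate"]),
       std_error = unname(sm["carrier", "Std. Error"]),
       p_value = unname(sm["carrier", "Pr(>|t|)"]),
       n = n, df_residual = fit$df.residual, dropped = dropped)
}

#' Screen all annotations for a mutation-status effect
#'
#' Fits [fit_annotation_model()] for every `(cell_type, label)` present in
#' the region summaries at one timepoint and mark, using each sample's
#' `GENOME_WIDE` mean as the genome-wide covariate, then adjusts the
#' p-value family (all fitted pairs in the run) by Benjamini-Hochberg.
#'
#' @param summaries Region summaries from [summarize_regions()] (long
#'   format, with `sample_id`, and `timepoint_months`/`mark` columns when
#'   several are present).
#' @param meta Sample sheet (see [read_sample_sheet()]).
#' @param mark Mark to screen (`"mc"` or `"hmc"`); ignored if `summaries`
#'   carries a single mark without a `mark` column.
#' @param timepoint Timepoint in months to screen.
#' @return Data.frame of screen results: `cell_type`, `label`, `mark`,
#'   `term`, `estimate`, `p_value`, `q_value`, `n_samples`.  Invariant:
#'   `q_value >= p_value`, BH-adjusted over the whole family.
#' @export
run_screen <- function(summaries, meta, mark = "mc", timepoint = 0) {
  dt <- as.data.table(summaries)
  if ("mark" %in% names(dt)) {
    keep <- dt[["mark"]] == mark
    dt <- dt[keep]
  }
  if ("timepoint_months" %in% names(dt)) {
    keep <- dt[["timepoint_months"]] == timepoint
    dt <- dt[keep]
  }
  gw <- dt[label == "GENOME_WIDE",
           list(sample_id, genomewide = mean_fraction)]
  body <- dt[label != "GENOME_WIDE"]
  meta_tp <- meta[meta$timepoint_months == timepoint |
                    !duplicated(meta$sample_id), ]
  meta_tp <- meta_tp[!duplicated(meta_tp$sample_id), ]
  pairs <- unique(body[, list(cell_type, label)])
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    sub <- body[cell_type == pairs$cell_type[i] & label == pairs$label[i]]
    d <- merge(merge(as.data.frame(sub), gw, by = "sample_id"),
               meta_tp[, c("sample_id", "mutation_status",
                           "lymphoma_status")], by = "sample_id")
    fit <- withCallingHandlers(
      fit_annotation_model(data.frame(response = d$mean_fraction,
                                      mutation_status = d$mutation_status,
                                      lymphoma_status = d$lymphoma_status,
                                      genomewide = d$genomewide)),
      warning = function(w) invokeRestart("muffleWarning"))
    res[[i]] <- data.frame(cell_type = pairs$cell_type[i],
                           label = pairs$label[i], mark = mark,
                           term = "carrier", estimate = fit$estimate,
                           p_value = fit$p_value, n_samples = fit$n,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out[order(out$p_value),
      c("cell_type", "label", "mark", "term", "estimate", "p_value",
        "q_value", "n_samples")]
}

#' Two-sample t-test of change over time
#'
#' Compares per-sample changes between two groups with either the Welch
#' unequal-variance test (Welch-Satterthwaite degrees of freedom) or the
#' Student pooled-variance test, reporting the two-sided p-value and a 95%
#' confidence interval for the difference in group means (`x` minus `y`).
#' Degenerate inputs (zero variance in both groups) yield `p = 1` when the
#' means are equal and `p = 0` flagged `degenerate` otherwise.
#'
#' @param x,y Numeric vectors of per-sample changes (>= 2 each).
#' @param variant `"welch"` or `"student"` (pooled variance).
#' @param conf_level Confidence level for the interval.
#' @return One-row data.frame: `n_x`, `n_y`, `mean_diff`, `t`, `df`,
#'   `p_value`, `ci_low`, `ci_high`, `variant`, `degenerate`.
#' @export
ttest_change <- function(x, y, variant = c("welch", "student"),
                         conf_level = 0.95) {
  variant <- match.arg(variant)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 samples per group", call. = FALSE)
  diff <- mean(x) - mean(y)
  eps <- .Machine$double.eps^0.75 * max(1, abs(mean(x)), abs(mean(y)))
  if (sd(x) < eps && sd(y) < eps) {
    degen <- abs(diff) >= eps
    return(data.frame(n_x = length(x), n_y = length(y), mean_diff = diff,
                      t = if (degen) sign(diff) * Inf else 0,
                      df = length(x) + length(y) - 2L,
                      p_value = if (degen) 0 else 1,
                      ci_low = diff, ci_high = diff, variant = variant,
                      degenerate = degen, stringsAsFactors = FALSE))
  }
  tt <- stats::t.test(x, y, var.equal = (variant == "student"),
                      conf.level = conf_level)
  data.frame(n_x = length(x), n_y = length(y), mean_diff = diff,
             t = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value, ci_low = tt$conf.int[1L],
             ci_high = tt$conf.int[2L], variant = variant,
             degenerate = FALSE, stringsAsFactors = FALSE)
}

#' Screen hydroxymethylation change over time across annotations
#'
#' For each annotation label, a Welch test of per-sample 5-hmC change in
#' unaffected mutation carriers against the change in controls
#' (lymphoma-affected samples are excluded), with Benjamini-Hochberg
#' correction over the label family and a count of labels below the FDR
#' threshold.
#'
#' @param deltas Per-sample changes from [delta_over_time()] (mark
#'   `"hmc"`).
#' @param meta Sample sheet.
#' @param fdr Significance threshold on the adjusted p-value.
#' @return List with `results` (per-label data.frame incl. `q_value`),
#'   `n_significant` and `n_tested`.
#' @export
screen_hmc_change <- function(deltas, meta, fdr = 0.1) {
  dt <- as.data.table(deltas)
  if ("mark" %in% names(dt)) dt <- dt[dt$mark == "hmc"]
  meta1 <- meta[!duplicated(meta$sample_id), ]
  keep <- meta1$sample_id[meta1$lymphoma_status == "unaffected"]
  dt <- dt[sample_id %in% keep]
  dt <- dt[label != "GENOME_WIDE"]
  if (nrow(dt) == 0L)
    stop("no unaffected samples with change records to test",
         call. = FALSE)
  carriers <- meta1$sample_id[meta1$mutation_status == "carrier" &
                                meta1$lymphoma_status == "unaffected"]
  labs <- unique(dt[, list(cell_type, label)])
  res <- vector("list", nrow(labs))
  for (i in seq_len(nrow(labs))) {
    sub <- dt[cell_type == labs$cell_type[i] & label == labs$label[i]]
    xc <- sub$change[sub$sample_id %in% carriers]
    yc <- sub$change[!sub$sample_id %in% carriers]
    tt <- ttest_change(xc, yc, variant = "welch")
    res[[i]] <- cbind(data.frame(cell_type = labs$cell_type[i],
                                 label = labs$label[i],
                                 stringsAsFactors = FALSE), tt)
  }
  out <- do.call(rbind, res)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value), ]
  list(results = out, n_significant = sum(out$q_value < fdr),
       n_tested = nrow(out))
}
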