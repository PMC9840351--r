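# Transcription-factor binding-site methylation scoring and per-TF
# mutation-status models.

#' Score TF binding sites for methylation burden
#'
#' For each (sample, timepoint, mark) group and each transcription factor,
#' the unweighted mean modified fraction over qualifying CpG sites and
#' their count.  Qualification:
#' \itemize{
#'   \item `universe = "enhancer_overlap"`: the site lies inside a binding
#'     interval of the TF \emph{and} inside an enhancer interval;
#'     `universe = "genome_wide"` (the 5-hmC analysis) requires TF
#'     membership only.
#'   \item `restriction = "hyper_only"` additionally keeps only sites whose
#'     fraction strictly exceeds the sample's own mean over the enhancer
#'     class (sample-specific hypermethylation).
#' }
#' A site inside several intervals of the same TF counts once.  TFs with
#' no qualifying position in a group are absent from the result.
#'
#' @param calls Site-call data.frame (long format).
#' @param tf_sites TF binding intervals (`chrom`, `start`, `end`,
#'   `tf_name`).
#' @param annotations Annotation intervals (for the enhancer class).
#' @param restriction `"all_positions"` or `"hyper_only"`.
#' @param universe `"enhancer_overlap"` or `"genome_wide"`.
#' @param cell_type,enh_label The enhancer region class (default PBMC
#'   `Enh`).
#' @param min_calls Minimum coverage for a site to qualify.
#' @return Data.frame with grouping columns plus `tf_name`,
#'   `mean_fraction`, `n_positions`, `restriction`, `universe`.
#' @export
tf_scores <- function(calls, tf_sites, annotations,
                      restriction = c("all_positions", "hyper_only"),
                      universe = c("enhancer_overlap", "genome_wide"),
                      cell_type = "PBMC", enh_label = "Enh",
                      min_calls = 1L) {
  restriction <- match.arg(restriction)
  universe <- match.arg(universe)
  dt <- as.data.table(calls)[called_sites >= min_calls]
  grp <- .group_cols(dt)
  enh <- annotations[annotations$cell_type == cell_type &
                       annotations$label == enh_label, ]

  # site -> TF map (unique per site and TF)
  usites <- unique(dt[, list(chrom, pos)])
  ov <- overlap_sites(as.data.frame(usites), tf_sites)
  if (nrow(ov) == 0L)
    return(data.frame())
  tf_map <- unique(data.table(chrom = usites$chrom[ov$site],
                              pos = usites$pos[ov$site],
                              tf_name = tf_sites$tf_name[ov$interval]))

  # enhancer membership flags
  ov_e <- overlap_sites(as.data.frame(usites), enh)
  enh_map <- unique(data.table(chrom = usites$chrom[ov_e$site],
                               pos = usites$pos[ov_e$site],
                               in_enh = TRUE))

  # per-group enhancer mean (reference for hyper_only)
  enh_calls <- merge(dt, enh_map, by = c("chrom", "pos"))
  enh_means <- enh_calls[, list(enh_mean = mean(modified_fraction)),
                         by = grp]

  merged <- merge(dt, tf_map, by = c("chrom", "pos"),
                  allow.cartesian = TRUE)
  if (universe == "enhancer_overlap") {
    merged <- merge(merged, enh_map, by = c("chrom", "pos"))
  }
  merged <- merge(merged, enh_means, by = grp)
  if (restriction == "hyper_only")
    merged <- merged[modified_fraction > enh_mean]
  out <- merged[, list(mean_fraction = mean(modified_fraction),
                       n_positions = .N),
                by = c(grp, "tf_name")]
  out[, `:=`(restriction = restriction, universe = universe)]
  setorderv(out, c(grp, "tf_name"))
  as.data.frame(out)
}

#' Fit the per-TF mutation-status model
#'
#' OLS of per-sample TF binding-site methylation on mutation status with
#' the sample's enhancer-class mean as covariate:
#' `score ~ mutation + enhancer_mean`.  Reports the carrier coefficient
#' and its two-sided p-value.
#'
#' @param data Data.frame with `response` (per-sample TF score),
#'   `mutation_status`, `enh_mean`.
#' @return List as from [fit_annotation_model()].
#' @export
fit_tf_model <- function(data) {
  fit_annotation_model(data.frame(response = data$response,
                                  mutation_status = data$mutation_status,
                                  genomewide = data$enh_mean))
}

#' Screen all TFs for a mutation-status methylation effect
#'
#' Fits [fit_tf_model()] per transcription factor at one timepoint,
#' excluding lymphoma-affected samples, and applies Benjamini-Hochberg
#' over the TF family (one family per restriction x universe x
#' timepoint).  TFs scored in fewer than 5 retained samples are skipped.
#'
#' @param scores TF scores from [tf_scores()].
#' @param meta Sample sheet.
#' @param enh_means Data.frame with `sample_id` (and optionally
#'   `timepoint_months`) and `enh_mean`: the per-sample enhancer-class
#'   mean used as covariate.  May be omitted if `scores` was computed with
#'   [tf_scores()] on data carrying an `enh_mean`-compatible summary; see
#'   [run_pipeline()] for the assembled path.
#' @param timepoint Timepoint in months.
#' @return Data.frame: `tf_name`, `restriction`, `universe`, `estimate`,
#'   `p_value`, `q_value`, `n_samples`.
#' @export
tf_screen <- function(scores, meta, enh_means, timepoint = 0) {
  sc <- scores
  if ("timepoint_months" %in% names(sc))
    sc <- sc[sc$timepoint_months == timepoint, ]
  em <- enh_means
  if ("timepoint_months" %in% names(em))
    em <- em[em$timepoint_months == timepoint, ]
  meta1 <- meta[!duplicated(meta$sample_id), ]
  keep <- meta1[meta1$lymphoma_status == "unaffected", ]
  sc <- merge(sc, keep[, c("sample_id", "mutation_status")],
              by = "sample_id")
  sc <- merge(sc, em[, c("sample_id", "enh_mean")], by = "sample_id")
  res <- list()
  for (tf in unique(sc$tf_name)) {
    d <- sc[sc$tf_name == tf, ]
    if (nrow(d) < 5L) next
    fit <- tryCatch(
      withCallingHandlers(
        fit_tf_model(data.frame(response = d$mean_fraction,
                                mutation_status = d$mutation_status,
                                enh_mean = d$enh_mean)),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(fit)) next
    res[[tf]] <- data.frame(tf_name = tf,
                            restriction = d$restriction[1L],
                            universe = d$universe[1L],
                            estimate = fit$estimate,
                            p_value = fit$p_value,
                            n_samples = fit$n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(data.frame())
  out$q_value <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out[order(out$p_value), ]
}
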