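# Cohort-level evaluation and the study's summary layout: for STAPLE GTVs
# the median (min, max) over patients; for individual GTVs the mean of the
# four observers' per-observer medians plus the max and min median.

#' Evaluate every GTV definition across a cohort
#'
#' Builds the STAPLE GTVs (and, optionally, each observer's individual GTVs)
#' for every patient and evaluates Dice and lesion coverage against the
#' histopathology lesion across the CTV margins.
#'
#' @param cohort List of [delineation_set()] patients.
#' @param params A [staple_params()].
#' @param margins_mm CTV margins in mm.
#' @param sources Subset of `c("staple", "individual")`.
#' @param shifts Optional named list (by patient id) of in-plane (y, x)
#'   translations in mm applied to the STAPLE GTVs before evaluation.
#' @return data.frame of overlap records (see [evaluate_case()]).
#' @export
evaluate_cohort <- function(cohort, params = staple_params(),
                            margins_mm = c(0, 1, 2, 3),
                            sources = c("staple", "individual"),
                            shifts = NULL) {
  sources <- match.arg(sources, several.ok = TRUE)
  rows <- list()
  for (dset in cohort) {
    if ("staple" %in% sources) {
      sh <- if (!is.null(shifts)) shifts[[dset$patient_id]] else NULL
      rows[[length(rows) + 1L]] <- evaluate_case(
        build_staple_gtvs(dset, params), dset$histo_lesion,
        dset$histo_support, margins_mm, patient_id = dset$patient_id,
        source = "staple", shift_mm = sh)
    }
    if ("individual" %in% sources) {
      for (obs in observers(dset)) {
        rows[[length(rows) + 1L]] <- evaluate_case(
          build_individual_gtvs(dset, obs), dset$histo_lesion,
          dset$histo_support, margins_mm, patient_id = dset$patient_id,
          source = "individual", observer = obs)
      }
    }
  }
  do.call(rbind, rows)
}

#' Cohort summary in the study's table layout
#'
#' For `source = "staple"` rows: the median, minimum and maximum of the
#' per-patient values. For `source = "individual"` rows: each observer's
#' median across patients is computed first, then the mean, maximum and
#' minimum of those observer medians. Medians use the standard midpoint
#' convention for even counts. Duplicate records are an error.
#'
#' @param records data.frame of overlap records from [evaluate_cohort()] /
#'   [evaluate_case()].
#' @return data.frame with one row per (gtv_name, source, margin_mm, metric):
#'   columns `centre` (median, or mean of observer medians), `lo`, `hi`,
#'   `n` (patients).
#' @export
summarize_cohort <- function(records) {
  if (nrow(records) == 0L) stop("`records` is empty", call. = FALSE)
  key <- paste(records$patient_id, records$gtv_name, records$source,
               records$observer, records$margin_mm)
  if (anyDuplicated(key))
    stop("duplicate overlap records for the same (patient, gtv, margin)",
         call. = FALSE)
  out <- list()
  for (metric in c("dsc", "coverage")) {
    for (src in sort(unique(records$source))) {
      sub <- records[records$source == src, , drop = FALSE]
      for (g in sort(unique(sub$gtv_name))) {
        for (mg in sort(unique(sub$margin_mm))) {
          cell <- sub[sub$gtv_name == g & sub$margin_mm == mg, , drop = FALSE]
          if (nrow(cell) == 0L) next
          v <- cell[[metric]]
          if (src == "staple") {
            centre <- stats::median(v); lo <- min(v); hi <- max(v)
          } else {
            med <- vapply(split(cell[[metric]], cell$observer),
                          stats::median, numeric(1L))
            centre <- mean(med); lo <- min(med); hi <- max(med)
          }
          out[[length(out) + 1L]] <- data.frame(
            gtv_name = g, source = src, margin_mm = mg, metric = metric,
            centre = centre, lo = lo, hi = hi,
            n = length(unique(cell$patient_id)), stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Write the cohort summary as CSV
#'
#' One row per (gtv_name, source, margin); each metric appears both as a
#' formatted `"centre (lo, hi)"` column and as raw numeric columns.
#'
#' @param summary data.frame from [summarize_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summary, path) {
  fmt <- function(c0, l0, h0) sprintf("%.2f (%.2f, %.2f)", c0, l0, h0)
  keys <- unique(summary[, c("gtv_name", "source", "margin_mm")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    row <- data.frame(gtv_name = k$gtv_name, source = k$source,
                      margin_mm = k$margin_mm, stringsAsFactors = FALSE)
    for (metric in c("dsc", "coverage")) {
      cell <- summary[summary$gtv_name == k$gtv_name &
                        summary$source == k$source &
                        summary$margin_mm == k$margin_mm &
                        summary$metric == metric, , drop = FALSE]
      if (nrow(cell) == 1L) {
        row[[metric]] <- fmt(cell$centre, cell$lo, cell$hi)
        row[[paste0(metric, "_centre")]] <- cell$centre
        row[[paste0(metric, "_lo")]] <- cell$lo
        row[[paste0(metric, "_hi")]] <- cell$hi
      }
    }
    row
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write raw overlap records as tidy CSV
#'
#' @param records data.frame of overlap records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Box plots of the metric distribution across patients
#'
#' One box per (GTV definition, margin), in the style of the study's
#' distribution figures. Base graphics; intended for quick inspection.
#'
#' @param records data.frame of overlap records (one source).
#' @param metric `"dsc"` or `"coverage"`.
#' @param main Plot title.
#' @return Invisibly, the list returned by [graphics::boxplot()].
#' @export
plot_cohort_metric <- function(records, metric = c("dsc", "coverage"),
                               main = NULL) {
  metric <- match.arg(metric)
  records$gtv_name <- factor(records$gtv_name,
                             levels = unique(records$gtv_name))
  f <- stats::as.formula(paste(metric, "~ margin_mm + gtv_name"))
  if (is.null(main))
    main <- sprintf("%s distribution by GTV and CTV margin", toupper(metric))
  bp <- graphics::boxplot(f, data = records, las = 2, cex.axis = 0.6,
                          ylab = metric, main = main,
                          col = grDevices::grey.colors(
                            length(unique(records$margin_mm))))
  invisible(bp)
}
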