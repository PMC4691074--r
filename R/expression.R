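#' Ct normalisation and relative quantification primitives
#'
#' `delta_ct()` normalises a target Ct against the reference gene measured
#' in the same reaction (`dCt = Ct_target - Ct_reference`).
#' `relative_quantification()` compares a sample's dCt to a calibrator's
#' (`ddCt = dCt_sample - dCt_calibrator`) and converts to a fold change
#' `rq = 2^-ddCt`, assuming 100% amplification efficiency.
#'
#' @param ct_target,ct_reference cycle-threshold values.
#' @return `delta_ct()`: dCt in cycles.
#' @export
delta_ct <- function(ct_target, ct_reference) {
  ct_target - ct_reference
}

#' @param sample_dct,calibrator_dct dCt values in cycles.
#' @return `relative_quantification()`: a list with `ddct` and `rq`.
#' @rdname delta_ct
#' @export
relative_quantification <- function(sample_dct, calibrator_dct) {
  ddct <- sample_dct - calibrator_dct
  list(ddct = ddct, rq = 2^(-ddct))
}

#' Relative expression analysis by the 2^-ddCt method
#'
#' Computes per-replicate dCt, per-cell (gene x condition x timepoint) mean
#' dCt, ddCt against the calibrator cell of the same gene, the fold change
#' `rq = 2^-ddCt`, a two-sided Welch t-test on replicate dCt (sample vs
#' calibrator), a differential call, and significance stars. A cell is
#' called `up` when `rq >= fold_threshold` and `p < alpha`, `down` when
#' `rq <= 1/fold_threshold` and `p < alpha`, otherwise `ns`. Stars: `*`
#' for `p < 0.05`, `**` for `p < 0.01`.
#'
#' A Benjamini-Hochberg adjusted p-value column (`p_adj`) is reported for
#' transparency but never drives the calls, which mirror per-gene testing
#' practice in qRT-PCR studies.
#'
#' @param ct a Ct tibble (see [read_ct_table()]): `gene`, `condition`,
#'   `timepoint`, `replicate`, `ct_target`, `ct_reference`.
#' @param calibrator the calibrator cell, either a single
#'   `"condition:timepoint"` string applied to every gene (e.g.
#'   `"CK:0h"`), or a data frame with columns `gene`, `condition`,
#'   `timepoint` naming a per-gene calibrator.
#' @param fold_threshold fold-change threshold for differential calls
#'   (default 2).
#' @param alpha significance level (default 0.05).
#' @param welch use Welch's t-test (default); `FALSE` pools variances.
#' @return an object of class `vq_expression`: a tibble with one row per
#'   gene x condition x timepoint: `delta_ct`, `ddct`, `rq`, `log2_rq`,
#'   `n_reps`, `p_value`, `p_adj`, `call`, `stars`, `is_calibrator`.
#' @export
analyze_expression <- function(ct, calibrator, fold_threshold = 2,
                               alpha = 0.05, welch = TRUE) {
  ct <- as_tibble(ct)
  need <- c("gene", "condition", "timepoint", "replicate",
            "ct_target", "ct_reference")
  stopifnot(all(need %in% names(ct)))
  ct <- ct %>% mutate(dct = delta_ct(.data$ct_target, .data$ct_reference))

  cal <- if (is.data.frame(calibrator)) {
    as_tibble(calibrator) %>%
      select("gene", cal_condition = "condition", cal_timepoint = "timepoint")
  } else {
    parts <- strsplit(calibrator, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      vq_abort("calibrator must be 'condition:timepoint' or a data frame")
    }
    tibble(gene = unique(ct$gene),
           cal_condition = parts[1], cal_timepoint = parts[2])
  }
  cal_dct <- ct %>%
    dplyr::inner_join(cal, by = "gene") %>%
    filter(.data$condition == .data$cal_condition,
           .data$timepoint == .data$cal_timepoint) %>%
    group_by(.data$gene) %>%
    summarise(cal_mean_dct = mean(.data$dct),
              cal_reps = list(.data$dct), .groups = "drop")
  no_cal <- setdiff(unique(ct$gene), cal_dct$gene)
  if (length(no_cal) > 0L) {
    vq_abort(paste0("missing calibrator cell for gene(s): ",
                    paste(no_cal, collapse = ", ")))
  }
  cal <- cal %>% left_join(cal_dct, by = "gene")

  out <- ct %>%
    group_by(.data$gene, .data$condition, .data$timepoint) %>%
    summarise(delta_ct = mean(.data$dct), n_reps = n(),
              reps = list(.data$dct), .groups = "drop") %>%
    left_join(cal, by = "gene") %>%
    mutate(
      is_calibrator = .data$condition == .data$cal_condition &
        .data$timepoint == .data$cal_timepoint,
      ddct = .data$delta_ct - .data$cal_mean_dct,
      rq = 2^(-.data$ddct),
      log2_rq = -.data$ddct,
      p_value = purrr::pmap_dbl(
        list(.data$reps, .data$cal_reps, .data$is_calibrator),
        function(x, y, is_cal) {
          if (is_cal || length(x) < 2L || length(y) < 2L) return(NA_real_)
          if (stats::var(x) == 0 && stats::var(y) == 0) {
            return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
          }
          stats::t.test(x, y, var.equal = !welch)$p.value
        })
    ) %>%
    mutate(
      p_adj = p.adjust(.data$p_value, method = "BH"),
      call = dplyr::case_when(
        .data$is_calibrator ~ "calibrator",
        is.na(.data$p_value) ~ NA_character_,
        .data$rq >= fold_threshold & .data$p_value < alpha ~ "up",
        .data$rq <= 1 / fold_threshold & .data$p_value < alpha ~ "down",
        TRUE ~ "ns"
      ),
      stars = dplyr::case_when(
        is.na(.data$p_value) ~ "",
        .data$p_value < 0.01 ~ "**",
        .data$p_value < 0.05 ~ "*",
        TRUE ~ ""
      )
    ) %>%
    select("gene", "condition", "timepoint", "delta_ct", "ddct", "rq",
           "log2_rq", "n_reps", "p_value", "p_adj", "call", "stars",
           "is_calibrator")
  class(out) <- c("vq_expression", class(out))
  attr(out, "fold_threshold") <- fold_threshold
  attr(out, "alpha") <- alpha
  out
}

#' @exportS3Method generics::tidy
tidy.vq_expression <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "vq_expression")
  out
}

#' @exportS3Method generics::glance
glance.vq_expression <- function(x, ...) {
  tibble(
    n_cells = nrow(x),
    n_up = sum(x$call == "up", na.rm = TRUE),
    n_down = sum(x$call == "down", na.rm = TRUE),
    n_ns = sum(x$call == "ns", na.rm = TRUE),
    fold_threshold = attr(x, "fold_threshold"),
    alpha = attr(x, "alpha")
  )
}

#' Log2 view of fold changes
#'
#' @param values a data frame with an `rq` column (all positive), e.g. a
#'   `vq_expression` result.
#' @param range_threshold genes whose rq dynamic range (max/min) exceeds
#'   this are flagged for log-scale display (default 64).
#' @return the input with `log2_rq` recomputed and a per-gene
#'   `log_display` flag appended.
#' @export
log2_report <- function(values, range_threshold = 64) {
  stopifnot("rq" %in% names(values))
  if (any(values$rq <= 0)) vq_abort("rq must be positive")
  values %>%
    mutate(log2_rq = log2(.data$rq)) %>%
    group_by(.data$gene) %>%
    mutate(log_display =
             max(.data$rq) / min(.data$rq) > range_threshold) %>%
    ungroup()
}
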