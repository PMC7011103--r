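# Differential abundance: per-lipid fold changes and t tests between salt
# treatment and control within each variety, Benjamini-Hochberg adjustment
# within each variety's contrast family, and class-level summaries.

#' Log2 fold change between two groups
#'
#' `log2(mean(treated) / mean(control))`; means, not medians, define the
#' ratio of responses.
#'
#' @param treated,control Non-empty numeric vectors of normalized abundances.
#' @return Log2 fold change; `NA` with a warning when the control mean is not
#'   positive (ratio undefined).
#' @export
log2_fold_change <- function(treated, control) {
  stopifnot(length(treated) >= 1, length(control) >= 1)
  mc <- mean(control)
  mt <- mean(treated)
  if (mc <= 0 || mt <= 0) {
    warning("fold change undefined: non-positive group mean")
    return(NA_real_)
  }
  log2(mt / mc)
}

#' Two-sample t test with degenerate-input conventions
#'
#' Two-sided Student's t test by default (equal variances), Welch by flag.
#' When both groups have zero variance: equal means give p = 1 (no evidence of
#' difference), different means give p = 0 with an infinite statistic.
#'
#' @param treated,control Numeric vectors, at least 2 values each.
#' @param var_equal Pool variances (Student) if `TRUE`, else Welch.
#' @return List with elements `t` and `p`.
#' @export
group_t_test <- function(treated, control, var_equal = TRUE) {
  if (length(treated) < 2 || length(control) < 2) {
    stop("each group needs at least two observations")
  }
  if (stats::sd(treated) == 0 && stats::sd(control) == 0) {
    if (mean(treated) == mean(control)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(treated) - mean(control)) * Inf, p = 0))
  }
  ht <- stats::t.test(treated, control, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement,
#' aligned to the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs propagate).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

.check_meta <- function(meta) {
  need <- c("sample", "variety", "treatment")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    stop("sample metadata lacks column(s): ", paste(missing, collapse = ", "))
  }
  meta
}

#' Per-lipid differential abundance across varieties
#'
#' For each variety, contrasts treated against control samples lipid by lipid
#' (log2 fold change of group means, two-sample t test) and adjusts p-values
#' by Benjamini-Hochberg within that variety's family of tests.
#'
#' @param quant Quantification table (`lipid`, optional `class`, sample
#'   columns).
#' @param meta Sample metadata: `sample`, `variety`, `treatment`, optionally
#'   `is_pbqc` (pooled-QC samples are excluded).
#' @param treatment_level,control_level Treatment labels to contrast.
#' @param var_equal Passed to [group_t_test()].
#' @return Data frame with lipid, class, variety, log2_fc, t, p, p_adj,
#'   n_treated, n_control.
#' @export
diff_abundance <- function(quant, meta, treatment_level = "salt",
                           control_level = "control", var_equal = TRUE) {
  meta <- .check_meta(meta)
  if (!is.null(meta$is_pbqc)) meta <- meta[!as.logical(meta$is_pbqc), ]
  samples <- .quant_sample_cols(quant)
  meta <- meta[meta$sample %in% samples, ]
  out <- list()
  for (v in unique(meta$variety)) {
    t_cols <- meta$sample[meta$variety == v & meta$treatment == treatment_level]
    c_cols <- meta$sample[meta$variety == v & meta$treatment == control_level]
    if (length(t_cols) == 0 || length(c_cols) == 0) next
    res <- lapply(seq_len(nrow(quant)), function(i) {
      tv <- as.numeric(quant[i, t_cols])
      cv <- as.numeric(quant[i, c_cols])
      tt <- group_t_test(tv, cv, var_equal = var_equal)
      data.frame(lipid = quant$lipid[i],
                 class = if (is.null(quant$class)) NA_character_ else
                   quant$class[i],
                 variety = v,
                 log2_fc = suppressWarnings(log2_fold_change(tv, cv)),
                 t = tt$t, p = tt$p,
                 n_treated = length(tv), n_control = length(cv),
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$p_adj <- bh_adjust(res$p)
    out[[v]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[c("lipid", "class", "variety", "log2_fc", "t", "p", "p_adj",
        "n_treated", "n_control")]
}

#' Class-level summaries and heatmap matrix
#'
#' Sums member lipids into class totals per sample (before any log
#' transform), computes the per-variety log2 fold change of each class total,
#' and builds a lipid-by-(variety x treatment) matrix of group means for
#' heatmap display, optionally row-standardized to mean 0 / sd 1.
#'
#' @param quant Quantification table with a `class` column.
#' @param meta Sample metadata (see [diff_abundance()]).
#' @param treatment_level,control_level Treatment labels to contrast.
#' @param standardize Row-standardize the heatmap matrix.
#' @return List with `class_fc` (class, variety, log2_fc) and `matrix`
#'   (lipids x group-mean columns named `variety.treatment`).
#' @export
summarize_classes <- function(quant, meta, treatment_level = "salt",
                              control_level = "control",
                              standardize = FALSE) {
  meta <- .check_meta(meta)
  if (is.null(quant$class)) stop("quant table needs a class column")
  if (!is.null(meta$is_pbqc)) meta <- meta[!as.logical(meta$is_pbqc), ]
  meta <- meta[meta$sample %in% .quant_sample_cols(quant), ]
  classes <- unique(quant$class)
  fc_rows <- list()
  for (cl in classes) {
    members <- quant[quant$class == cl, , drop = FALSE]
    if (nrow(members) == 0) next
    totals <- colSums(as.matrix(members[meta$sample]))
    for (v in unique(meta$variety)) {
      tv <- totals[meta$sample[meta$variety == v &
                                 meta$treatment == treatment_level]]
      cv <- totals[meta$sample[meta$variety == v &
                                 meta$treatment == control_level]]
      if (length(tv) == 0 || length(cv) == 0) next
      fc_rows[[length(fc_rows) + 1L]] <- data.frame(
        class = cl, variety = v,
        log2_fc = suppressWarnings(log2_fold_change(tv, cv)),
        stringsAsFactors = FALSE)
    }
  }
  class_fc <- do.call(rbind, fc_rows)
  groups <- unique(meta[c("variety", "treatment")])
  groups <- groups[order(groups$variety, groups$treatment), ]
  mat <- sapply(seq_len(nrow(groups)), function(g) {
    cols <- meta$sample[meta$variety == groups$variety[g] &
                          meta$treatment == groups$treatment[g]]
    rowMeans(as.matrix(quant[cols]))
  })
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = nrow(quant))
  rownames(mat) <- quant$lipid
  colnames(mat) <- paste(groups$variety, groups$treatment, sep = ".")
  if (standardize) {
    mat <- t(scale(t(mat)))
  }
  list(class_fc = class_fc, matrix = mat)
}
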