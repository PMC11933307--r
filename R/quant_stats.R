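# Numeric procedures for the wet-lab readouts: kinase-overexpression
# screen statistics (normality gate, Z scores, two-sided normal P,
# Benjamini-Hochberg FDR, hit calling) and the delta-delta-Ct
# translation-initiation index for harringtonine ribosome-protection
# qPCR data.

#' Two-sided normal p-value from a Z score
#'
#' `p = 2 * (1 - Phi(|z|))`, with `Phi` the standard normal CDF.
#'
#' @param z Numeric vector of Z scores.
#' @return Two-sided p-values in `(0, 1]`.
#' @examples
#' p_from_z(2.258) # ~2.39e-2
#' @export
p_from_z <- function(z) {
  if (any(!is.finite(z))) abort("z must be finite")
  2 * stats::pnorm(-abs(z))
}

#' Z scores and hit calls for a ratio screen
#'
#' Each entry's Z score is computed against the mean and sample standard
#' deviation (n - 1) of the whole screened set; control entries (e.g.
#' empty-vector wells) are excluded from the center and scale but still
#' scored. Hits are entries with two-sided `p < alpha`.
#'
#' @param table `data.frame` with columns `label` and `ratio`
#'   (positive), or a named numeric vector of ratios.
#' @param alpha Hit threshold on the two-sided p-value (default 0.05).
#' @param control_labels Labels (or a single regular prefix match via
#'   exact equality) excluded from the center/scale.
#' @return `data.frame`: `label`, `ratio`, `z`, `p`, `is_hit`,
#'   `is_control`.
#' @export
zscore_table <- function(table, alpha = 0.05, control_labels = NULL) {
  if (is.numeric(table)) {
    table <- data.frame(label = names(table) %||% as.character(seq_along(table)),
                        ratio = as.numeric(table), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(table), all(c("label", "ratio") %in% names(table)))
  if (anyDuplicated(table$label)) abort("duplicate labels in ratio table")
  if (any(!is.finite(table$ratio)) || any(table$ratio <= 0)) {
    abort("ratios must be finite and positive")
  }
  is_control <- table$label %in% (control_labels %||% character(0))
  included <- table$ratio[!is_control]
  if (length(included) < 3L) abort("need at least 3 non-control entries")
  mu <- mean(included)
  sd_ <- stats::sd(included)
  if (sd_ == 0) abort("degenerate screen: zero standard deviation")
  z <- (table$ratio - mu) / sd_
  p <- p_from_z(z)
  data.frame(label = table$label, ratio = table$ratio, z = z, p = p,
             is_hit = p < alpha & !is_control, is_control = is_control,
             stringsAsFactors = FALSE)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over the vetted routine in [stats::shapiro.test()]
#' (3 <= n <= 5000), returned as a plain list for pipeline use.
#'
#' @param values Numeric vector.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) abort("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0) abort("constant vector: normality test undefined")
  res <- stats::shapiro.test(values)
  list(W = unname(res$statistic), p = unname(res$p.value))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusted values are capped at 1 and returned in the input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  if (m == 0L) return(numeric(0))
  desc <- order(pvalues, decreasing = TRUE)
  adj <- numeric(m)
  adj[desc] <- pmin(1, cummin(m / (m:1) * pvalues[desc]))
  adj
}

#' Read a kinase-screen ratio table
#'
#' Tab-separated, header `label  ratio`.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with `label` and `ratio`.
#' @export
read_ratio_table <- function(path) {
  if (!file.exists(path)) abort("ratio table not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("label", "ratio") %in% names(df))) {
    abort("ratio table needs columns 'label' and 'ratio'")
  }
  df$ratio <- as.numeric(df$ratio)
  df
}

#' Read a Ct table for the initiation index
#'
#' Tab-separated, header `replicate  ct_target_tis  ct_target_bg
#' ct_ref_tis  ct_ref_bg`.
#'
#' @param path Path to the TSV file.
#' @return Typed `data.frame`.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) abort("Ct table not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("replicate", "ct_target_tis", "ct_target_bg",
              "ct_ref_tis", "ct_ref_bg")
  missing <- setdiff(needed, names(df))
  if (length(missing)) abort("Ct table is missing column(s): %s",
                             paste(missing, collapse = ", "))
  for (col in needed[-1L]) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Translation-initiation index by the delta-delta-Ct method
#'
#' Per replicate, the target signal (Ct at the TIS of interest) is
#' background-corrected against a non-initiating site on the same mRNA,
#' the reference signal likewise on the reference mRNA, and the index is
#' `2^-(dCt_target - dCt_ref)` where `dCt = ct_tis - ct_bg`. Equal
#' background-corrected signals give an index of 1; each cycle of extra
#' target initiation doubles it.
#'
#' @param records `data.frame` as from [read_ct_table()].
#' @return Object of class `initiation_index`: `per_replicate`, `mean`,
#'   `sd`.
#' @export
initiation_index <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  needed <- c("ct_target_tis", "ct_target_bg", "ct_ref_tis", "ct_ref_bg")
  missing <- setdiff(needed, names(records))
  if (length(missing)) abort("Ct records are missing column(s): %s",
                             paste(missing, collapse = ", "))
  for (col in needed) {
    if (any(!is.finite(records[[col]]))) {
      abort("replicate %s: missing or non-finite %s",
            format(which(!is.finite(records[[col]]))[1L]), col)
    }
  }
  dct_target <- records$ct_target_tis - records$ct_target_bg
  dct_ref <- records$ct_ref_tis - records$ct_ref_bg
  idx <- 2^(-(dct_target - dct_ref))
  structure(list(per_replicate = idx, mean = mean(idx),
                 sd = if (length(idx) > 1L) stats::sd(idx) else NA_real_),
            class = "initiation_index")
}

#' @export
print.initiation_index <- function(x, ...) {
  cat(sprintf("Initiation index: %.4g +/- %s (n = %d)\n", x$mean,
              ifelse(is.na(x$sd), "NA", sprintf("%.4g", x$sd)),
              length(x$per_replicate)))
  invisible(x)
}
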