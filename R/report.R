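#' Round half away from zero
#'
#' Presentation rounding for report tables (R's `round()` rounds half to
#' even, which does not match how published ratios are printed).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Expression fold change (case over control)
#'
#' Ratio of mean relative expression levels, rounded half-up to 3 decimals to
#' match report-table presentation. Genes below the detection line (zero or
#' missing control mean) have no defined ratio and raise an error.
#'
#' @param case_mean,ctrl_mean Mean relative expression per condition.
#' @param digits Decimal places (default 3).
#' @return The rounded ratio `case_mean / ctrl_mean`.
#' @export
fold_change <- function(case_mean, ctrl_mean, digits = 3) {
  if (any(is.na(ctrl_mean)) || any(ctrl_mean <= 0))
    stop("control mean must be positive (below-detection genes have no ratio)")
  round_half_up(case_mean / ctrl_mean, digits)
}

#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t-test computed from per-arm means, standard deviations
#' and replicate counts (raw replicate values are not needed).
#'
#' @param case_mean,case_sd,n_case Case arm summary.
#' @param ctrl_mean,ctrl_sd,n_ctrl Control arm summary.
#' @return List: `t` (case minus control), `df` (Welch-Satterthwaite),
#'   `p_value` (two-sided).
#' @export
welch_t <- function(case_mean, case_sd, n_case, ctrl_mean, ctrl_sd, n_ctrl) {
  if (n_case < 2 || n_ctrl < 2) stop("need at least 2 replicates per arm")
  if (case_sd < 0 || ctrl_sd < 0) stop("standard deviations must be >= 0")
  v1 <- case_sd^2 / n_case
  v2 <- ctrl_sd^2 / n_ctrl
  if (v1 + v2 == 0) {
    if (case_mean == ctrl_mean)
      return(list(t = 0, df = NA_real_, p_value = 1))
    return(list(t = sign(case_mean - ctrl_mean) * Inf, df = NA_real_,
                p_value = 0))
  }
  t <- (case_mean - ctrl_mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n_case - 1) + v2^2 / (n_ctrl - 1))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Read a per-gene expression summary table
#'
#' TSV with a header and columns `gene`, `category`, `ctrl_mean`, `ctrl_sd`,
#' `case_mean`, `case_sd`. Empty cells (below-detection genes) become `NA`.
#'
#' @param path File path.
#' @export
read_expression_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  needed <- c("gene", "ctrl_mean", "ctrl_sd", "case_mean", "case_sd")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0)
    stop("expression table lacks columns: ", paste(missing, collapse = ", "))
  tab
}

#' Expression fold-change report
#'
#' Adds the case/control AREL ratio per gene and, when replicate counts are
#' supplied, the Welch t statistic and two-sided p-value. Below-detection
#' genes (missing means) get `NA` throughout.
#'
#' @param tab Data frame from [read_expression_table].
#' @param n_ctrl,n_case Replicate counts per arm (optional; the t-test needs
#'   them and is skipped otherwise).
#' @return The input with columns `ratio` and, if requested, `t`, `p_value`.
#' @export
expression_report <- function(tab, n_ctrl = NULL, n_case = NULL) {
  ok <- !is.na(tab$ctrl_mean) & !is.na(tab$case_mean) & tab$ctrl_mean > 0
  tab$ratio <- NA_real_
  tab$ratio[ok] <- fold_change(tab$case_mean[ok], tab$ctrl_mean[ok])
  if (!is.null(n_ctrl) && !is.null(n_case)) {
    tab$t <- tab$p_value <- NA_real_
    for (i in which(ok)) {
      wt <- welch_t(tab$case_mean[i], tab$case_sd[i], n_case,
                    tab$ctrl_mean[i], tab$ctrl_sd[i], n_ctrl)
      tab$t[i] <- wt$t
      tab$p_value[i] <- wt$p_value
    }
  }
  tab
}
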