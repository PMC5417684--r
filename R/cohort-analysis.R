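#' Full cohort-level analysis of structure vs intraocular pressure
#'
#' Runs the complete cohort inference on a table of subject records:
#' \itemize{
#'   \item simple regressions of every macro-structural parameter (CCT, CR,
#'     AL, ACD, WTW) and every micro-structural parameter (age, GG_a, GG_v,
#'     GG_p, GG_v/p) against both the non-corrected and the corrected IOP,
#'     with \eqn{R^2}, p-value and 95% confidence band;
#'   \item cross-regressions of CCT on the GG scale and on the
#'     shape-parameter ratio (does the speckle carry information beyond
#'     thickness?);
#'   \item a median split of the cohort on IOP (both variants), per-variable
#'     group comparison by Wilcoxon rank-sum, and a two-sample KS contrast
#'     of the group-level GG densities built from the per-group mean
#'     parameters;
#'   \item forward stepwise regression of IOP_nc on all macro and micro
#'     candidates, yielding the structural pressure model.
#' }
#'
#' @param records a cohort data frame ([simulate_cohort()],
#'   [read_cohort()], or any data frame with the standard columns).
#' @param alpha_enter entry threshold of the stepwise procedure.
#' @param pdf_ks_m pseudo-sample size of the group GG-density KS contrast
#'   (default: the size of the smaller IOP group).
#' @return an object of class `"cohort_analysis"`; see the components in
#'   the examples and [write_report()].
#' @examples
#' coh <- simulate_cohort(cohort_spec(seed = 3))
#' an <- cohort_analysis(coh)
#' an$stepwise$predictors
#' an$macro_table
#' @export
cohort_analysis <- function(records, alpha_enter = 0.05, pdf_ks_m = NULL) {
  records <- as_oct_cohort(as.data.frame(records))
  if (nrow(records) < 3L)
    oct_error("need at least 3 complete records",
              "octspeckle_insufficient_sample")
  macro <- c("CCT", "CR", "AL", "ACD", "WTW")
  micro <- c("age", "GG_a", "GG_v", "GG_p", "GG_v_over_p")

  reg_block <- function(vars) {
    out <- list()
    tab <- data.frame(parameter = vars, min = NA_real_, max = NA_real_,
                      mean = NA_real_, sd = NA_real_,
                      r2_iop_nc = NA_real_, p_iop_nc = NA_real_,
                      r2_iop_c = NA_real_, p_iop_c = NA_real_)
    for (i in seq_along(vars)) {
      v <- vars[i]
      x <- records[[v]]
      rn <- simple_regression(x, records$IOP_nc)
      rc <- simple_regression(x, records$IOP_c)
      out[[v]] <- list(iop_nc = rn, iop_c = rc)
      tab[i, -1L] <- c(min(x), max(x), mean(x), stats::sd(x),
                       rn$r_squared, rn$p_value, rc$r_squared, rc$p_value)
    }
    list(regressions = out, table = tab)
  }
  mac <- reg_block(macro)
  mic <- reg_block(micro)

  cross <- list(
    GG_a = simple_regression(records$GG_a, records$CCT),
    GG_v_over_p = simple_regression(records$GG_v_over_p, records$CCT))

  split_block <- function(iop_key) {
    sp <- median_split(records, iop_key)
    vars <- c("CCT", "CR", "AL", "ACD", "WTW", "age",
              "GG_a", "GG_v", "GG_p", "GG_v_over_p")
    cmp <- lapply(vars, function(v) group_compare(sp$below, sp$above, v))
    tab <- do.call(rbind, lapply(cmp, function(cc)
      data.frame(parameter = cc$key, mean1 = cc$mean1, sd1 = cc$sd1,
                 mean2 = cc$mean2, sd2 = cc$sd2, p_value = cc$p_value)))
    iop_stats <- lapply(list(below = sp$below, above = sp$above),
                        function(g) c(mean_nc = mean(g$IOP_nc),
                                      sd_nc = stats::sd(g$IOP_nc),
                                      mean_c = mean(g$IOP_c),
                                      sd_c = stats::sd(g$IOP_c)))
    g1 <- c(a = mean(sp$below$GG_a), v = mean(sp$below$GG_v),
            p = mean(sp$below$GG_p))
    g2 <- c(a = mean(sp$above$GG_a), v = mean(sp$above$GG_v),
            p = mean(sp$above$GG_p))
    m <- if (is.null(pdf_ks_m)) max(2L, min(nrow(sp$below),
                                            nrow(sp$above))) else pdf_ks_m
    list(split = sp, table = tab, iop_stats = iop_stats,
         group_gg = list(below = g1, above = g2),
         pdf_contrast = compare_group_pdfs(g1, g2, m = m))
  }
  grp_nc <- split_block("IOP_nc")
  grp_c <- split_block("IOP_c")

  cand <- records[c(macro, micro)]
  sw <- forward_stepwise(as.list(cand), records$IOP_nc,
                         alpha_enter = alpha_enter)

  structure(list(
    n = nrow(records), records = records,
    macro_table = mac$table, macro_regressions = mac$regressions,
    micro_table = mic$table, micro_regressions = mic$regressions,
    cross_regressions = cross,
    group_nc = grp_nc, group_c = grp_c,
    stepwise = sw, alpha_enter = alpha_enter),
    class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, digits = 3, ...) {
  cat(sprintf("Cohort analysis of %d subjects\n\n", x$n))
  cat("Macro-structural parameters vs IOP:\n")
  print(format(x$macro_table, digits = digits), row.names = FALSE)
  cat("\nMicro-structural parameters vs IOP:\n")
  print(format(x$micro_table, digits = digits), row.names = FALSE)
  cat(sprintf("\nIOP_nc median: %.4g mmHg (groups of %d / %d)\n",
              x$group_nc$split$median, nrow(x$group_nc$split$below),
              nrow(x$group_nc$split$above)))
  cat(sprintf("Group GG-density KS contrast: D = %.3g, p = %.3g\n",
              x$group_nc$pdf_contrast$statistic,
              x$group_nc$pdf_contrast$p_value))
  cat("\nStepwise IOP_nc model:\n")
  print(x$stepwise, digits = digits)
  invisible(x)
}

#' Write a cohort analysis report to disk
#'
#' Writes a machine-readable JSON report plus CSV tables (macro, micro and
#' group-comparison summaries) and per-regression figure-data CSVs
#' (`x, y, fit, band_low, band_high`) into a directory.
#'
#' @param analysis a [cohort_analysis()] result.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "cohort_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fig_dir <- file.path(dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)

  utils::write.csv(analysis$macro_table,
                   file.path(dir, "macro_structure.csv"), row.names = FALSE)
  utils::write.csv(analysis$micro_table,
                   file.path(dir, "micro_structure.csv"), row.names = FALSE)
  utils::write.csv(analysis$group_nc$table,
                   file.path(dir, "group_comparison_iop_nc.csv"),
                   row.names = FALSE)
  utils::write.csv(analysis$group_c$table,
                   file.path(dir, "group_comparison_iop_c.csv"),
                   row.names = FALSE)

  write_fig <- function(reg, xvar, yvar, name) {
    d <- reg$lm_fit$model
    obs <- data.frame(x = d$x, y = d$y)
    utils::write.csv(
      data.frame(x = reg$band$x, y = NA_real_, fit = reg$band$fit,
                 band_low = reg$band$lwr, band_high = reg$band$upr),
      file.path(fig_dir, paste0(name, "_fit.csv")), row.names = FALSE)
    utils::write.csv(obs, file.path(fig_dir, paste0(name, "_points.csv")),
                     row.names = FALSE)
  }
  for (v in names(analysis$macro_regressions)) {
    write_fig(analysis$macro_regressions[[v]]$iop_nc, v, "IOP_nc",
              paste0(v, "_vs_IOP_nc"))
    write_fig(analysis$macro_regressions[[v]]$iop_c, v, "IOP_c",
              paste0(v, "_vs_IOP_c"))
  }
  for (v in names(analysis$micro_regressions)) {
    write_fig(analysis$micro_regressions[[v]]$iop_nc, v, "IOP_nc",
              paste0(v, "_vs_IOP_nc"))
    write_fig(analysis$micro_regressions[[v]]$iop_c, v, "IOP_c",
              paste0(v, "_vs_IOP_c"))
  }

  reg_json <- function(reg)
    list(slope = reg$slope, intercept = reg$intercept,
         r_squared = reg$r_squared, p_value = reg$p_value, n = reg$n)
  report <- list(
    n = analysis$n,
    macro = lapply(analysis$macro_regressions, function(rr)
      list(iop_nc = reg_json(rr$iop_nc), iop_c = reg_json(rr$iop_c))),
    micro = lapply(analysis$micro_regressions, function(rr)
      list(iop_nc = reg_json(rr$iop_nc), iop_c = reg_json(rr$iop_c))),
    cross = lapply(analysis$cross_regressions, reg_json),
    iop_nc_median = analysis$group_nc$split$median,
    iop_groups = analysis$group_nc$iop_stats,
    group_gg = analysis$group_nc$group_gg,
    pdf_contrast = analysis$group_nc$pdf_contrast[
      c("statistic", "p_value", "m", "construction")],
    pdf_contrast_corrected = analysis$group_c$pdf_contrast[
      c("statistic", "p_value", "m", "construction")],
    stepwise = list(predictors = analysis$stepwise$predictors,
                    coefficients = as.list(analysis$stepwise$coefficients),
                    r_squared = analysis$stepwise$r_squared,
                    entry_p_values = analysis$stepwise$steps$p_value,
                    alpha_enter = analysis$alpha_enter))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
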