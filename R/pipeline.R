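# Per-exposure workflow and multi-exposure screen, candidate-selection
# logic, and plot-data exports.

#' Pipeline parameters
#'
#' Bundles selection, harmonization, estimation and candidate-criteria
#' settings for [run_single()] and [mr_screen()].
#'
#' @param selection list from [selection_params()].
#' @param harmonization list from [harmonize_policy()].
#' @param ivw_p_threshold nominal IVW significance for candidacy
#'   (default 0.05).
#' @param het_p_threshold candidates require Cochran Q p above this
#'   (default 0.05: no detected heterogeneity).
#' @param pleio_p_threshold candidates require Egger intercept p above this
#'   (default 0.05: no detected directional pleiotropy).
#' @param criteria character vector of enabled candidate criteria, any of
#'   `"ivw_significant"`, `"direction_consistent"`, `"no_heterogeneity"`,
#'   `"no_pleiotropy"`, `"steiger_forward"`, `"loo_stable"`.
#' @param presso_n_sim MR-PRESSO simulation count (default 1000).
#' @param n_boot bootstrap replicates for median/mode standard errors.
#' @param phi mode bandwidth multiplier.
#' @param seed base RNG seed for bootstraps and MR-PRESSO.
#' @param p_adjust multiplicity adjustment for the screen-level IVW
#'   p-values: `"none"` (default), `"BH"` or `"bonferroni"` (reported as an
#'   extra column; candidate logic uses the nominal p).
#' @return list of parameters.
#' @export
mr_params <- function(selection = selection_params(),
                      harmonization = harmonize_policy(),
                      ivw_p_threshold = 0.05,
                      het_p_threshold = 0.05,
                      pleio_p_threshold = 0.05,
                      criteria = c("ivw_significant", "direction_consistent",
                                   "no_heterogeneity", "no_pleiotropy",
                                   "steiger_forward", "loo_stable"),
                      presso_n_sim = 1000, n_boot = 1000, phi = 1.0,
                      seed = 1L, p_adjust = c("none", "BH", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  list(selection = selection, harmonization = harmonization,
       ivw_p_threshold = ivw_p_threshold,
       het_p_threshold = het_p_threshold,
       pleio_p_threshold = pleio_p_threshold,
       criteria = criteria, presso_n_sim = presso_n_sim,
       n_boot = n_boot, phi = phi, seed = as.integer(seed),
       p_adjust = p_adjust)
}

evaluate_criteria <- function(est, sens, params) {
  ivw <- est$estimates$ivw
  trace <- list()
  crit <- params$criteria
  if ("ivw_significant" %in% crit) {
    trace$ivw_significant <- ivw$pval < params$ivw_p_threshold
  }
  if ("direction_consistent" %in% crit) {
    trace$direction_consistent <- est$direction_consistent
  }
  if ("no_heterogeneity" %in% crit) {
    trace$no_heterogeneity <- is.null(sens$q) ||
      sens$q$q_p > params$het_p_threshold
  }
  if ("no_pleiotropy" %in% crit) {
    trace$no_pleiotropy <- is.null(sens$egger_intercept) ||
      sens$egger_intercept$p > params$pleio_p_threshold
  }
  if ("steiger_forward" %in% crit) {
    trace$steiger_forward <- !is.null(sens$steiger) && sens$steiger$direction
  }
  if ("loo_stable" %in% crit) {
    trace$loo_stable <- is.null(sens$loo) || !any(sens$loo$sign_flip)
  }
  trace
}

#' Run the full workflow for one exposure
#'
#' Select instruments, harmonize, run every estimator, the sensitivity
#' battery and MR-PRESSO, then apply the candidate criteria: nominally
#' significant IVW estimate, sign agreement across the computed estimators,
#' no detected heterogeneity (Cochran Q) or directional pleiotropy (Egger
#' intercept), forward Steiger directionality, and no leave-one-out
#' sign-flipping SNP. Each criterion's pass/fail is recorded in a trace so
#' alternative candidate definitions can be replayed from the saved
#' results.
#'
#' @param exposure exposure `summary_dataset`.
#' @param outcome outcome `summary_dataset`.
#' @param ld `ld_table` used for clumping.
#' @param params list from [mr_params()].
#' @return An `exposure_result`: `exposure_id`, `analyzable` (+ `reason`),
#'   `instruments`, `harmonized`, `estimates` (from [estimate_all()]),
#'   `sensitivity`, `presso`, `criteria_trace`, `candidate`.
#' @export
run_single <- function(exposure, outcome, ld = ld_table(),
                       params = mr_params()) {
  res <- list(exposure_id = exposure$trait_id, analyzable = FALSE,
              reason = NA_character_, instruments = NULL, harmonized = NULL,
              estimates = NULL, sensitivity = NULL, presso = NULL,
              criteria_trace = NULL, candidate = FALSE)
  class(res) <- "exposure_result"
  iv <- select_instruments(exposure, outcome, ld, params$selection)
  res$instruments <- iv
  if (!iv$analyzable) {
    res$reason <- sprintf("only %d instrument(s) after selection (need %d)",
                          nrow(iv$snps), params$selection$min_snps)
    return(res)
  }
  h <- harmonize(iv, outcome, params$harmonization)
  res$harmonized <- h
  if (nrow(h$snps) < params$selection$min_snps) {
    res$reason <- sprintf("only %d instrument(s) after harmonization (need %d)",
                          nrow(h$snps), params$selection$min_snps)
    return(res)
  }
  res$analyzable <- TRUE
  res$estimates <- estimate_all(h, phi = params$phi, n_boot = params$n_boot,
                                seed = params$seed)
  res$sensitivity <- sensitivity_report(h)
  res$presso <- mr_presso(h, n_sim = params$presso_n_sim,
                          seed = params$seed + 7L)
  res$criteria_trace <- evaluate_criteria(res$estimates, res$sensitivity,
                                          params)
  res$candidate <- all(unlist(res$criteria_trace))
  res
}

#' @export
print.exposure_result <- function(x, ...) {
  cat(sprintf("<exposure_result> %s: analyzable = %s", x$exposure_id,
              x$analyzable))
  if (!x$analyzable) cat(" (", x$reason, ")", sep = "")
  cat("\n")
  if (x$analyzable) {
    ivw <- x$estimates$estimates$ivw
    cat(sprintf("  IVW: OR %.4f (95%% CI %.4f-%.4f), p = %.3g, nSNP = %d\n",
                ivw$or_point, ivw$or_low, ivw$or_high, ivw$pval, ivw$n_snp))
    cat(sprintf("  candidate = %s [%s]\n", x$candidate,
                paste(names(x$criteria_trace),
                      ifelse(unlist(x$criteria_trace), "pass", "FAIL"),
                      sep = ":", collapse = ", ")))
  }
  invisible(x)
}

result_row <- function(res, params) {
  base <- data.frame(exposure = res$exposure_id, analyzable = res$analyzable,
                     nsnp = NA_integer_, beta_ivw = NA_real_, se_ivw = NA_real_,
                     pval_ivw = NA_real_, or = NA_real_, or_low = NA_real_,
                     or_high = NA_real_, q_p = NA_real_,
                     egger_intercept_p = NA_real_, presso_global_p = NA_real_,
                     steiger_direction = NA, candidate = FALSE,
                     stringsAsFactors = FALSE)
  if (!res$analyzable) return(base)
  ivw <- res$estimates$estimates$ivw
  base$nsnp <- ivw$n_snp
  base$beta_ivw <- ivw$beta
  base$se_ivw <- ivw$se
  base$pval_ivw <- ivw$pval
  base$or <- ivw$or_point
  base$or_low <- ivw$or_low
  base$or_high <- ivw$or_high
  base$q_p <- if (!is.null(res$sensitivity$q)) res$sensitivity$q$q_p else NA_real_
  base$egger_intercept_p <- if (!is.null(res$sensitivity$egger_intercept)) {
    res$sensitivity$egger_intercept$p
  } else NA_real_
  base$presso_global_p <- if (isTRUE(res$presso$computable)) {
    res$presso$global_p
  } else NA_real_
  base$steiger_direction <- if (!is.null(res$sensitivity$steiger)) {
    res$sensitivity$steiger$direction
  } else NA
  base$candidate <- res$candidate
  base
}

#' Screen many exposures against one outcome
#'
#' Runs [run_single()] per exposure and assembles a per-exposure summary
#' table plus overall counts, splitting candidates into risk-direction
#' (OR > 1) and protective (OR < 1). The optional multiplicity-adjusted
#' IVW p-value column is reporting only; the candidate flag uses the
#' nominal threshold.
#'
#' @param exposures list of exposure `summary_dataset`s.
#' @param outcome shared outcome `summary_dataset`.
#' @param ld `ld_table`.
#' @param params list from [mr_params()].
#' @return A `screen_report`: `table` (one row per exposure), `results`
#'   (list of `exposure_result`), `summary` (counts: exposures, analyzable,
#'   candidates, risk, protective).
#' @export
mr_screen <- function(exposures, outcome, ld = ld_table(),
                      params = mr_params()) {
  stopifnot(length(exposures) >= 1)
  results <- lapply(exposures, run_single, outcome = outcome, ld = ld,
                    params = params)
  tab <- do.call(rbind, lapply(results, result_row, params = params))
  rownames(tab) <- NULL
  if (params$p_adjust != "none") {
    tab$pval_ivw_adj <- stats::p.adjust(tab$pval_ivw,
                                        method = params$p_adjust)
  }
  cand <- tab$candidate
  out <- list(
    table = tab, results = results,
    summary = list(
      exposures = nrow(tab),
      analyzable = sum(tab$analyzable),
      candidates = sum(cand),
      risk = sum(cand & tab$or > 1, na.rm = TRUE),
      protective = sum(cand & tab$or < 1, na.rm = TRUE)
    ),
    params = params
  )
  class(out) <- "screen_report"
  out
}

#' @export
print.screen_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<screen_report> %d exposures: %d analyzable, %d candidates (%d risk OR>1, %d protective OR<1)\n",
              s$exposures, s$analyzable, s$candidates, s$risk, s$protective))
  invisible(x)
}

#' Compare a screen against simulation truth
#'
#' @param report a `screen_report`.
#' @param truth truth data.frame from [simulate_metabolite_panel()]
#'   (columns `exposure_id`, `causal`).
#' @return list with `power` (candidate rate among causal exposures),
#'   `false_positives` (candidate count among null exposures),
#'   `false_positive_rate`, `n_causal`, `n_null`.
#' @export
screen_vs_truth <- function(report, truth) {
  tab <- report$table
  idx <- match(tab$exposure, truth$exposure_id)
  causal <- truth$causal[idx]
  list(
    power = if (any(causal)) mean(tab$candidate[causal]) else NA_real_,
    false_positives = sum(tab$candidate[!causal]),
    false_positive_rate = if (any(!causal)) mean(tab$candidate[!causal]) else NA_real_,
    n_causal = sum(causal), n_null = sum(!causal)
  )
}

#' Export plot-ready data tables
#'
#' Emits the numeric tables behind the standard MR figures; plotting itself
#' is out of scope. Kinds: `"forest"` (per-exposure IVW OR and CI, split by
#' direction), `"scatter"` (per-SNP effects with error bars plus per-method
#' fitted lines whose slopes equal the method estimates), `"funnel"` and
#' `"loo"` (sensitivity tables), `"circular"` (exposure x method p-value
#' matrix).
#'
#' @param result an `exposure_result` (scatter/funnel/loo) or
#'   `screen_report` (forest/circular).
#' @param kind one of `"forest"`, `"scatter"`, `"funnel"`, `"loo"`,
#'   `"circular"`.
#' @param path optional output path; when given the table is written as TSV
#'   with a commented provenance header.
#' @return the data.frame (invisibly when written to `path`).
#' @export
export_plot_data <- function(result, kind = c("forest", "scatter", "funnel",
                                              "loo", "circular"),
                             path = NULL) {
  kind <- match.arg(kind)
  df <- switch(
    kind,
    forest = {
      stopifnot(inherits(result, "screen_report"))
      tab <- result$table[result$table$analyzable, , drop = FALSE]
      data.frame(exposure = tab$exposure, nsnp = tab$nsnp, or = tab$or,
                 or_low = tab$or_low, or_high = tab$or_high,
                 pval = tab$pval_ivw,
                 direction = ifelse(tab$or > 1, "risk", "protective"),
                 candidate = tab$candidate, stringsAsFactors = FALSE)
    },
    scatter = {
      stopifnot(inherits(result, "exposure_result"), result$analyzable)
      s <- result$harmonized$snps
      pts <- data.frame(part = "point", rsid = s$rsid, beta_x = s$beta_x,
                        se_x = s$se_x, beta_y = s$beta_y, se_y = s$se_y,
                        method = NA_character_, slope = NA_real_,
                        intercept = NA_real_, stringsAsFactors = FALSE)
      ests <- result$estimates$estimates
      lines <- do.call(rbind, lapply(names(ests), function(m) {
        if (m == "egger_intercept") return(NULL)
        e <- ests[[m]]
        intercept <- if (m == "egger_slope") {
          ests$egger_intercept$beta
        } else 0
        data.frame(part = "line", rsid = NA_character_, beta_x = NA_real_,
                   se_x = NA_real_, beta_y = NA_real_, se_y = NA_real_,
                   method = m, slope = e$beta, intercept = intercept,
                   stringsAsFactors = FALSE)
      }))
      rbind(pts, lines)
    },
    funnel = {
      stopifnot(inherits(result, "exposure_result"), result$analyzable)
      f <- result$sensitivity$funnel
      f$ivw_beta <- attr(f, "ivw_beta")
      f$egger_beta <- attr(f, "egger_beta")
      f
    },
    loo = {
      stopifnot(inherits(result, "exposure_result"), result$analyzable)
      result$sensitivity$loo
    },
    circular = {
      stopifnot(inherits(result, "screen_report"))
      methods <- c("ivw", "egger_slope", "weighted_median", "weighted_mode",
                   "simple_mode")
      rows <- lapply(result$results, function(r) {
        p <- stats::setNames(rep(NA_real_, length(methods)), methods)
        if (r$analyzable) {
          for (m in methods) {
            if (!is.null(r$estimates$estimates[[m]])) {
              p[m] <- r$estimates$estimates[[m]]$pval
            }
          }
        }
        cbind(data.frame(exposure = r$exposure_id, stringsAsFactors = FALSE),
              as.data.frame(as.list(p)))
      })
      do.call(rbind, rows)
    }
  )
  rownames(df) <- NULL
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# mrscreen plot data: kind=%s generated=%s", kind,
                       format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Write a screen report table as TSV
#'
#' One row per exposure with the IVW estimate, sensitivity p-values
#' (Cochran Q, Egger intercept, MR-PRESSO global), Steiger direction and
#' the candidate flag — the shape of a per-metabolite results table. A
#' commented provenance header records the key parameters.
#'
#' @param report a `screen_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- report$params
  writeLines(c(
    "# mrscreen screen report",
    sprintf("# selection: exposure_p<%g outcome_p<%g clump_r2=%g clump_kb=%g f_min=%g min_snps=%d",
            p$selection$exposure_p_threshold, p$selection$outcome_p_threshold,
            p$selection$clump_r2, p$selection$clump_kb, p$selection$f_min,
            p$selection$min_snps),
    sprintf("# criteria: %s; seed=%d; p_adjust=%s",
            paste(p$criteria, collapse = ","), p$seed, p$p_adjust)
  ), con)
  utils::write.table(report$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
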