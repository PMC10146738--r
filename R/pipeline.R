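# Batch analysis: fit the four models to every curve, select a winner,
# classify the mechanism from the Korsmeyer-Peppas exponent, optionally
# attach solubility parameters. One failing drug is recorded, not fatal.

#' Render a fitted equation in report style
#'
#' @param model Model name.
#' @param params Parameter vector (named or canonical order).
#' @param digits Significant digits (default 5).
#' @return A string such as `"Qt=0.3556·t^0.5381"`.
#' @export
#' @examples
#' format_equation("korsmeyer_peppas", c(K = 0.3556, n = 0.5381))
#' format_equation("first_order", c(K1 = -59.78837, a = -0.00017754, b1 = 61.99435))
format_equation <- function(model, params, digits = 5) {
  model <- match_model(model)
  p <- canonical_params(model, params)
  num <- function(x) format(signif(x, digits), scientific = FALSE, trim = TRUE)
  signed <- function(x) if (x < 0) paste0("-", num(-x)) else paste0("+", num(x))
  switch(model,
    zero_order = sprintf("Qt=%s·t%s", num(p[["K0"]]), signed(p[["b0"]])),
    higuchi = sprintf("Qt=%s·t^1/2%s", num(p[["KH"]]), signed(p[["bH"]])),
    korsmeyer_peppas = sprintf("Qt=%s·t^%s", num(p[["K"]]), num(p[["n"]])),
    first_order = {
      k1 <- p[["K1"]]
      op <- if (k1 < 0) "-" else "+"
      sprintf(
        "Qt=%s%s%s·e^(%s·t)",
        num(p[["b1"]]), op, num(abs(k1)), num(p[["a"]])
      )
    }
  )
}

normalize_curve_input <- function(curves) {
  if (is.data.frame(curves)) {
    cols <- c("drug", "time_min", "Q_percent")
    if (!all(cols %in% names(curves))) {
      stop_validation("A curve table needs columns `drug`, `time_min`, `Q_percent`.")
    }
    if (nrow(curves) == 0L) stop_validation("The curve table is empty.")
    split_df <- split(as_tibble(curves)[c("time_min", "Q_percent")], curves$drug)
    return(split_df[unique(curves$drug)])
  }
  if (is.list(curves) && length(curves) > 0L) {
    if (is.null(names(curves)) || any(!nzchar(names(curves)))) {
      stop_validation("A list of curves must be named by drug.")
    }
    return(curves)
  }
  stop_validation("`curves` must be a non-empty named list or a long data frame; got an empty input.")
}

#' Analyze release curves end to end
#'
#' For each drug: fits the requested models, ranks them with
#' [rank_models()], derives the mechanism call from the Korsmeyer-Peppas
#' fit with [mechanism_call()], and (optionally) attaches
#' Hoftyzer-Van Krevelen solubility parameters for drugs with shipped
#' group multisets. A drug whose fits fail is recorded under `failures`
#' without aborting the batch.
#'
#' @param curves Either a long data frame with columns `drug`, `time_min`,
#'   `Q_percent`, or a named list of curves (each with `time_min`,
#'   `Q_percent`).
#' @param models Models to fit (default all four).
#' @inheritParams fit_release_model
#' @inheritParams rank_models
#' @inheritParams mechanism_call
#' @param solubility Attach solubility parameters for drugs among
#'   [reference_drugs()] (default `TRUE`).
#' @return An object of class `release_report`: list with `results` (one
#'   row per drug and model: parameters, equation, metrics), `selection`
#'   (one row per drug: winner, rationale, mechanism, burst flag),
#'   `solubility`, `failures`, and `fits` (nested `release_fit_set`s).
#'   [tidy()] returns `results`; [glance()] returns `selection`.
#' @export
#' @examples
#' curves <- purrr::map(
#'   setNames(nm = c("PHBA", "BPAB")),
#'   function(d) simulate_fixture(d, "korsmeyer_peppas")
#' )
#' report <- analyze_release(curves)
#' glance(report)
analyze_release <- function(curves, models = kinetic_model_names(),
                            kp_cutoff = 60,
                            adj_r2_tolerance = 0.05,
                            geometry = "cylinder",
                            n_low = 0.45, n_high = 0.89,
                            case2_tolerance = 1e-6,
                            burst_threshold = 6,
                            solubility = TRUE,
                            max_restarts = 3L, seed = 1L) {
  curve_list <- normalize_curve_input(curves)
  fits <- list()
  results <- list()
  selection <- list()
  sol <- list()
  failures <- list()
  for (drug in names(curve_list)) {
    res <- tryCatch({
      fs <- fit_release_models(
        curve_list[[drug]], models = models, kp_cutoff = kp_cutoff,
        max_restarts = max_restarts, seed = seed
      )
      cmp <- rank_models(fs, adj_r2_tolerance = adj_r2_tolerance)
      mech <- if ("korsmeyer_peppas" %in% names(fs)) {
        mechanism_call(
          fs$korsmeyer_peppas, geometry = geometry, n_low = n_low,
          n_high = n_high, case2_tolerance = case2_tolerance,
          burst_threshold = burst_threshold
        )
      } else {
        NULL
      }
      list(fits = fs, cmp = cmp, mech = mech)
    }, relkin_error = function(e) e)
    if (inherits(res, "error")) {
      failures[[drug]] <- tibble(drug = drug, error = conditionMessage(res))
      next
    }
    fits[[drug]] <- res$fits
    results[[drug]] <- dplyr::mutate(tidy_fit_set(res$fits), drug = drug, .before = 1L)
    selection[[drug]] <- tibble(
      drug = drug,
      selected = res$cmp$selected,
      rationale = paste(res$cmp$rationale, collapse = ","),
      n = if (is.null(res$mech)) NA_real_ else res$mech$n,
      K = if (is.null(res$mech)) NA_real_ else res$mech$K,
      transport_class = if (is.null(res$mech)) NA_character_ else res$mech$transport_class,
      burst_flag = if (is.null(res$mech)) NA else res$mech$burst_flag
    )
    if (isTRUE(solubility) && drug %in% reference_drugs()) {
      sol[[drug]] <- hvk_parameters(drug)
    }
  }
  if (length(results) == 0L && length(failures) > 0L) {
    warn("All drugs failed to fit; see `failures`.")
  }
  structure(
    list(
      results = dplyr::bind_rows(results),
      selection = dplyr::bind_rows(selection),
      solubility = dplyr::bind_rows(sol),
      failures = dplyr::bind_rows(failures),
      fits = fits
    ),
    class = "release_report"
  )
}

tidy_fit_set <- function(fits) {
  purrr::map_dfr(fits, function(f) {
    g <- glance(f)
    g$equation <- f$equation
    g$params <- list(f$params)
    g
  })
}

#' @export
print.release_report <- function(x, ...) {
  cat(sprintf(
    "<release_report> %d drug(s) analyzed, %d failure(s)\n",
    length(x$fits), nrow(x$failures)
  ))
  if (nrow(x$selection) > 0L) print(x$selection)
  if (nrow(x$failures) > 0L) {
    cat("failures:\n")
    print(x$failures)
  }
  invisible(x)
}

#' Render a report as human-readable text
#'
#' One block per drug mirroring a kinetics report table: fitted equation
#' and metrics per model, the selected model with its rationale, the
#' mechanism call, and solubility parameters when available.
#'
#' @param report A `release_report`.
#' @return Character vector of lines (invisibly printable with `cat`).
#' @export
report_text <- function(report) {
  stopifnot(inherits(report, "release_report"))
  lines <- character()
  for (drug in names(report$fits)) {
    lines <- c(lines, sprintf("== %s ==", drug))
    for (f in report$fits[[drug]]) {
      metric <- if (f$model == "zero_order") {
        sprintf("Pearson's r %.5f", f$pearson_r)
      } else {
        sprintf("Reduced Chi-Sqr %.5f", f$reduced_chi_sq)
      }
      lines <- c(lines, sprintf(
        "  %-17s %s  Adj. R-Square %.5f  RSS %.5f  %s",
        f$model, f$equation, f$adj_r_square, f$rss, metric
      ))
    }
    sel <- report$selection[report$selection$drug == drug, ]
    lines <- c(lines, sprintf(
      "  selected: %s (%s); mechanism: %s (n = %.4f, K = %.4f, burst: %s)",
      sel$selected, sel$rationale, sel$transport_class, sel$n, sel$K, sel$burst_flag
    ))
    if (nrow(report$solubility) > 0L && drug %in% report$solubility$drug) {
      s <- report$solubility[report$solubility$drug == drug, ]
      lines <- c(lines, sprintf(
        "  solubility parameter: delta_t = %.3f (MJ/m^3)^1/2", s$delta_t
      ))
    }
  }
  for (i in seq_len(nrow(report$failures))) {
    lines <- c(lines, sprintf(
      "== %s == FAILED: %s", report$failures$drug[i], report$failures$error[i]
    ))
  }
  lines
}

#' Write a report to disk
#'
#' Writes `results.csv` (machine-readable, full precision, one row per
#' drug and model with flattened parameter columns) and `report.txt`
#' (the [report_text()] rendering).
#'
#' @param report A `release_report`.
#' @param dir Output directory (created if missing).
#' @return Paths of the written files, invisibly.
#' @export
write_release_report <- function(report, dir) {
  stopifnot(inherits(report, "release_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- report$results
  if (nrow(flat) > 0L) {
    wide <- purrr::map_dfr(flat$params, function(p) as_tibble(as.list(p)))
    flat <- dplyr::bind_cols(flat[setdiff(names(flat), "params")], wide)
    flat <- dplyr::left_join(
      flat,
      report$selection[c("drug", "selected", "transport_class", "burst_flag")],
      by = "drug"
    )
  }
  results_path <- file.path(dir, "results.csv")
  utils::write.csv(flat, results_path, row.names = FALSE)
  report_path <- file.path(dir, "report.txt")
  writeLines(report_text(report), report_path)
  invisible(c(results_path, report_path))
}
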