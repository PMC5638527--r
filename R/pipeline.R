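#' Study pipeline: eligibility, analysis, report
#'
#' Orchestrates the full sector analysis on a cohort table: eligibility
#' filtering with an exclusion log, sector summary and all-pairs comparison,
#' the per-sector correlation/regression grid against axial length, PMP angle
#' and disc tilt, the temporal ratio analysis, the PPA subgroup comparison and
#' the sex-stratified grids with between-sex comparison of correlations.
#'
#' @name pipeline
NULL

cohort_required_cols <- function() {
  c("eye_id", "laterality", "age", "sex", "refractive_error",
    "axial_length", "pmp", "tilt", paste0("ppct_", sector_names()), "ppa")
}

cohort_numeric_cols <- function() {
  c("age", "refractive_error", "axial_length", "pmp", "tilt",
    paste0("ppct_", sector_names()), "bcva_logmar", "iop")
}

validate_cohort <- function(df, source = "cohort") {
  names(df) <- tolower(names(df))
  names(df) <- sub("^ppct_t$", "ppct_T", names(df))
  names(df) <- sub("^ppct_st$", "ppct_ST", names(df))
  names(df) <- sub("^ppct_s$", "ppct_S", names(df))
  names(df) <- sub("^ppct_sn$", "ppct_SN", names(df))
  names(df) <- sub("^ppct_n$", "ppct_N", names(df))
  names(df) <- sub("^ppct_in$", "ppct_IN", names(df))
  names(df) <- sub("^ppct_i$", "ppct_I", names(df))
  names(df) <- sub("^ppct_it$", "ppct_IT", names(df))
  missing <- setdiff(cohort_required_cols(), names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s", source,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in intersect(cohort_numeric_cols(), names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(coerced))
      if (length(bad) > 0) {
        stop(sprintf("%s: non-numeric values in column '%s' at row(s) %s",
                     source, col,
                     paste(utils::head(bad, 5), collapse = ", ")),
             call. = FALSE)
      }
      df[[col]] <- coerced
    }
  }
  if (is.character(df$ppa)) df$ppa <- toupper(df$ppa) %in% c("TRUE", "1", "YES")
  if (is.numeric(df$ppa)) df$ppa <- df$ppa != 0
  if ("exclusion_flag" %in% names(df)) {
    if (is.character(df$exclusion_flag)) {
      df$exclusion_flag <- toupper(df$exclusion_flag) %in% c("TRUE", "1", "YES")
    }
    if (is.numeric(df$exclusion_flag)) df$exclusion_flag <- df$exclusion_flag != 0
  }
  tibble::as_tibble(df)
}

#' Read a cohort table from CSV
#'
#' The schema follows the raw-data layout of the study: one row per eye with
#' identifiers, demographics, biometry, `pmp`, `tilt`, the eight `ppct_*`
#' sector columns and the `ppa` flag (column names case-insensitive).
#' Malformed rows are reported with their line numbers; missing required
#' columns are named in the error.
#'
#' @param path Path to the CSV file.
#' @return A validated cohort tibble.
#' @export
read_cohort_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  pr <- readr::problems(df)
  if (nrow(pr) > 0) {
    stop(sprintf("malformed rows in %s (line %s): %s", path,
                 paste(utils::head(pr$row, 5), collapse = ", "),
                 pr$expected[1]), call. = FALSE)
  }
  validate_cohort(df, source = path)
}

#' Read a cohort table from XLSX
#'
#' Same schema and validation as [read_cohort_csv()]; requires the readxl
#' package.
#'
#' @param path Path to the XLSX file.
#' @param sheet Sheet index or name (default first).
#' @return A validated cohort tibble.
#' @export
read_cohort_xlsx <- function(path, sheet = 1) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("the readxl package is required to read XLSX cohort tables",
         call. = FALSE)
  }
  df <- readxl::read_excel(path, sheet = sheet)
  validate_cohort(df, source = path)
}

#' Write a cohort table to CSV
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' Apply the study's eligibility criteria
#'
#' Retains right eyes of participants aged 20 to 40 years with best-corrected
#' visual acuity of at most 0.1 logMAR, intraocular pressure of at most 21
#' mmHg (inclusive), and no exclusion flag (known ocular disease, staphyloma,
#' disc anomaly, prior surgery, poor image quality). Records missing any
#' eligibility field raise a validation error.
#'
#' @param records Cohort tibble with `age`, `bcva_logmar`, `iop`,
#'   `exclusion_flag` and `laterality` columns.
#' @return List with `records` (retained rows) and `exclusions` (tibble
#'   `eye_id`, `reason`; one row per excluded record, reasons comma-joined
#'   when several rules fire).
#' @export
apply_eligibility <- function(records) {
  need <- c("eye_id", "laterality", "age", "bcva_logmar", "iop",
            "exclusion_flag")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    stop(sprintf("missing eligibility field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  rules <- list(
    laterality = records$laterality != "right",
    age = records$age < 20 | records$age > 40,
    bcva = records$bcva_logmar > 0.1,
    iop = records$iop > 21,
    exclusion_flag = records$exclusion_flag
  )
  hit <- do.call(cbind, rules)
  hit[is.na(hit)] <- TRUE
  excluded <- rowSums(hit) > 0
  reasons <- if (any(excluded)) {
    apply(hit[excluded, , drop = FALSE], 1, function(h) {
      paste(names(rules)[h], collapse = ",")
    })
  } else character(0)
  list(
    records = records[!excluded, , drop = FALSE],
    exclusions = tibble::tibble(eye_id = records$eye_id[excluded],
                                reason = reasons)
  )
}

study_predictors <- function() c(al = "axial_length", pmp = "pmp", tilt = "tilt")

# Correlation/regression grid: 8 sectors x 3 predictors x 2 methods.
analysis_grid <- function(records) {
  preds <- study_predictors()
  X <- as.matrix(records[, preds])
  colnames(X) <- names(preds)
  rows <- lapply(sector_names(), function(s) {
    y <- records[[paste0("ppct_", s)]]
    reg <- regress_standardized(y, X, outcome = s)
    dplyr::bind_rows(lapply(names(preds), function(p) {
      sp <- spearman_cor(records[[preds[[p]]]], y)
      tibble::tibble(
        sector = s, predictor = p,
        spearman_r = sp$r, spearman_p = sp$p,
        beta = reg$coefficients$beta[reg$coefficients$predictor == p],
        beta_p = reg$coefficients$p[reg$coefficients$predictor == p],
        n = sp$n
      )
    }))
  })
  dplyr::bind_rows(rows)
}

#' Run the full sector analysis
#'
#' Computes, deterministically for a given cohort: the demographic summary;
#' per-sector ppCT means and SDs with the Steel-Dwass all-pairs comparison
#' across sectors (sectors treated as independent groups, reproducing the
#' study's analysis choice); the grid of Spearman correlations and
#' standardized regression coefficients of each sector's ppCT on axial
#' length, PMP angle and disc tilt; the per-eye temporal ppCT ratio with its
#' summary and correlations (Spearman and Pearson); the per-sector
#' Mann-Whitney comparison by PPA flag; and the grid re-run within each sex
#' with a Fisher-z comparison of the Spearman correlations between sexes.
#'
#' @param records Eligible cohort tibble (>= 10 rows) with the standard
#'   columns.
#' @param alpha Two-sided significance threshold (default 0.05).
#' @param min_stratum Minimum records for a sex stratum to be analyzed.
#' @return An object of class `ppct_report`.
#' @export
run_study <- function(records, alpha = 0.05, min_stratum = 10) {
  records <- validate_cohort(records, source = "records")
  if (nrow(records) < 10) {
    stop("at least 10 eligible records are required", call. = FALSE)
  }
  sn <- sector_names()
  sector_cols <- paste0("ppct_", sn)

  demo_vars <- c("age", "refractive_error", "axial_length", "pmp", "tilt")
  demographics <- dplyr::bind_rows(lapply(demo_vars, function(v) {
    x <- records[[v]]
    tibble::tibble(variable = v, mean = mean(x), sd = stats::sd(x),
                   min = min(x), max = max(x))
  }))

  sector_summary <- tibble::tibble(
    sector = sn,
    mean = vapply(sector_cols, function(cl) mean(records[[cl]]), numeric(1)),
    sd = vapply(sector_cols, function(cl) stats::sd(records[[cl]]), numeric(1))
  )

  sector_groups <- stats::setNames(lapply(sector_cols, function(cl) {
    records[[cl]]
  }), sn)
  sector_comparison <- steel_dwass(sector_groups)

  grid <- analysis_grid(records)

  ratio <- apply(as.matrix(records[, sector_cols]), 1, function(v) {
    temporal_ratio(stats::setNames(v, sn))
  })
  preds <- study_predictors()
  ratio_cor <- dplyr::bind_rows(lapply(names(preds), function(p) {
    x <- records[[preds[[p]]]]
    sp <- spearman_cor(x, ratio)
    pe <- stats::cor.test(x, ratio, method = "pearson")
    tibble::tibble(predictor = p, spearman_r = sp$r, spearman_p = sp$p,
                   pearson_r = unname(pe$estimate), pearson_p = pe$p.value)
  }))
  ratio_summary <- tibble::tibble(mean = mean(ratio), sd = stats::sd(ratio),
                                  min = min(ratio), max = max(ratio))

  ppa_tab <- if (length(unique(records$ppa)) == 2) {
    dplyr::bind_rows(lapply(sn, function(s) {
      y <- records[[paste0("ppct_", s)]]
      tibble::tibble(
        sector = s,
        mean_ppa = mean(y[records$ppa]),
        mean_no_ppa = mean(y[!records$ppa]),
        p = mann_whitney(y[records$ppa], y[!records$ppa])
      )
    }))
  } else NULL

  by_sex <- list()
  for (sx in c("M", "F")) {
    sub <- records[records$sex == sx, , drop = FALSE]
    by_sex[[sx]] <- if (nrow(sub) >= min_stratum) analysis_grid(sub) else NULL
  }
  sex_comparison <- NULL
  if (!is.null(by_sex$M) && !is.null(by_sex$F)) {
    gm <- by_sex$M; gf <- by_sex$F
    sex_comparison <- dplyr::bind_rows(lapply(seq_len(nrow(gm)), function(i) {
      tibble::tibble(
        sector = gm$sector[i], predictor = gm$predictor[i],
        r_male = gm$spearman_r[i], n_male = gm$n[i],
        r_female = gf$spearman_r[i], n_female = gf$n[i],
        p = compare_correlations(gm$spearman_r[i], gm$n[i],
                                 gf$spearman_r[i], gf$n[i])
      )
    }))
  }

  structure(list(
    n = nrow(records),
    alpha = alpha,
    demographics = demographics,
    sector_summary = sector_summary,
    sector_comparison = sector_comparison,
    grid = grid,
    ratio = list(summary = ratio_summary, correlations = ratio_cor,
                 values = ratio),
    ppa = ppa_tab,
    by_sex = by_sex,
    sex_comparison = sex_comparison
  ), class = "ppct_report")
}

#' @export
print.ppct_report <- function(x, ...) {
  cat(sprintf("ppCT sector analysis report (n = %d eyes, alpha = %g)\n\n",
              x$n, x$alpha))
  cat("Sector ppCT (um):\n")
  print(as.data.frame(x$sector_summary), row.names = FALSE, digits = 5)
  cat(sprintf("\nTemporal ppCT ratio: %.3f +/- %.3f (range %.3f to %.3f)\n",
              x$ratio$summary$mean, x$ratio$summary$sd,
              x$ratio$summary$min, x$ratio$summary$max))
  sig <- x$grid[x$grid$spearman_p < x$alpha, ]
  cat(sprintf("\nSignificant Spearman correlations (%d of %d grid cells):\n",
              nrow(sig), nrow(x$grid)))
  print(as.data.frame(sig[, c("sector", "predictor", "spearman_r",
                              "spearman_p")]),
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a report to a directory
#'
#' Serializes the grids and tables of a `ppct_report` as tidy CSV files plus
#' a JSON summary.
#'
#' @param report A `ppct_report` from [run_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ppct_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$demographics, file.path(dir, "demographics.csv"))
  readr::write_csv(report$sector_summary, file.path(dir, "sector_summary.csv"))
  readr::write_csv(report$sector_comparison,
                   file.path(dir, "sector_comparison.csv"))
  readr::write_csv(report$grid, file.path(dir, "correlation_grid.csv"))
  readr::write_csv(report$ratio$correlations,
                   file.path(dir, "ratio_correlations.csv"))
  if (!is.null(report$ppa)) {
    readr::write_csv(report$ppa, file.path(dir, "ppa_comparison.csv"))
  }
  for (sx in names(report$by_sex)) {
    if (!is.null(report$by_sex[[sx]])) {
      readr::write_csv(report$by_sex[[sx]],
                       file.path(dir, sprintf("grid_sex_%s.csv", sx)))
    }
  }
  if (!is.null(report$sex_comparison)) {
    readr::write_csv(report$sex_comparison,
                     file.path(dir, "sex_comparison.csv"))
  }
  summary <- list(
    n = report$n,
    alpha = report$alpha,
    temporal_ratio = as.list(report$ratio$summary),
    significant_cells = sum(report$grid$spearman_p < report$alpha)
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
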