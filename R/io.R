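#' Read / write enrichment-curve tables
#'
#' Long-format CSV with header and columns `subject`, `time_min`, `source`,
#' `value` and optionally `sd` (UTF-8). Validation is strict: missing
#' columns, duplicated `(subject, time_min, source)` rows, non-positive sd
#' and unknown sources are fatal, with the offending line numbers in the
#' message. Curves without an `sd` column are accepted; weighted objectives
#' then fall back to per-curve pooled scales.
#'
#' @param path CSV file path.
#' @return `read_curves()`: an `"enrichment_curves"` data frame.
#' @export
read_curves <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "time_min", "source", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("curves file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!"sd" %in% names(df)) df$sd <- NA_real_
  bad <- which(!df$source %in% c("acetate", "propionate", "butyrate"))
  if (length(bad))
    stop("unknown source at data line(s) ", paste(bad + 1L, collapse = ", "))
  bad <- which(!is.na(df$sd) & df$sd <= 0)
  if (length(bad))
    stop("non-positive sd at data line(s) ", paste(bad + 1L, collapse = ", "))
  key <- paste(df$subject, df$time_min, df$source)
  if (anyDuplicated(key))
    stop("duplicated (subject, time_min, source) at data line(s) ",
         paste(which(duplicated(key)) + 1L, collapse = ", "))
  df <- df[order(df$subject,
                 match(df$source, c("acetate", "propionate", "butyrate")),
                 df$time_min), ]
  rownames(df) <- NULL
  class(df) <- c("enrichment_curves", "data.frame")
  df
}

#' @param curves An `"enrichment_curves"` data frame.
#' @rdname read_curves
#' @export
write_curves <- function(curves, path) {
  .check_curves(curves)
  write.csv(curves, path, row.names = FALSE)
  invisible(path)
}

#' Read / write mass-isotopologue tables
#'
#' Long-format CSV with columns `subject`, `time_min`, `metabolite`,
#' `n_carbons`, `iso_index`, `value`, `is_excess` (0/1). Each
#' `(subject, time_min, metabolite)` group must contain exactly the
#' isotopologue indices `0..n_carbons`, once each.
#'
#' @param path CSV file path.
#' @return `read_mids()`: a validated data frame.
#' @export
read_mids <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "time_min", "metabolite", "n_carbons", "iso_index",
            "value", "is_excess")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("MID file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  key <- paste(df$subject, df$time_min, df$metabolite)
  for (grp in split(df, key)) {
    if (!identical(sort(grp$iso_index), 0:grp$n_carbons[1L]))
      stop("MID group (", grp$subject[1L], ", t=", grp$time_min[1L], ", ",
           grp$metabolite[1L], ") does not cover iso_index 0..n exactly once")
  }
  df
}

#' @param mids A MID data frame in the long schema.
#' @rdname read_mids
#' @export
write_mids <- function(mids, path) {
  write.csv(mids, path, row.names = FALSE)
  invisible(path)
}

# one long-format MID group -> a mid() object
.df_to_mid <- function(grp) {
  grp <- grp[order(grp$iso_index), ]
  mid(grp$metabolite[1L], grp$value, n_carbons = grp$n_carbons[1L],
      time_min = grp$time_min[1L], subject = grp$subject[1L],
      is_excess = grp$is_excess[1L] == 1L)
}

#' Serialise a fit result to JSON
#'
#' @param fit A `"fit_result"` from [fit_rate_constants()].
#' @param path Output JSON path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  jsonlite::write_json(
    list(estimated = as.list(unclass(fit$estimated)),
         fixed = as.list(fit$fixed), se = as.list(fit$se),
         p_value = as.list(fit$p_value), sse = fit$sse, rmse = fit$rmse,
         fractions = as.list(fit$fractions), converged = fit$converged,
         n_obs = fit$n_obs),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the analysis in its natural order — correct raw MIDs for
#' natural abundance, attribute glucose/citrate labelling to the SCFA, fit
#' the compartment model to the averaged enrichment curves, run the
#' identifiability analysis, and compute fractional dose contributions —
#' writing one artifact per stage to `out_dir`. Inputs are taken from CSV
#' paths in `config`, or generated synthetically (from `config$seed`) when
#' paths are absent; either way the run is deterministic.
#'
#' Config fields (all optional except `out_dir`): `curves`, `mids` (input
#' CSV paths), `dose` ([tracer_dose()]), `subject` ([subject_profile()]),
#' `fixed` (named vector, default `c(kLa = 0.0071, k0p = 0.0109)`),
#' `threshold` (collinearity cut-off, default 20), `p13C`, `seed`,
#' `generator` (a [generator_config()] for synthetic inputs).
#'
#' @param config A named list; see Details.
#' @return Invisibly, a list with the per-stage results and artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dose <- if (is.null(config$dose)) tracer_dose() else config$dose
  subject <- if (is.null(config$subject)) subject_profile() else config$subject
  fixed <- if (is.null(config$fixed)) c(kLa = 0.0071, k0p = 0.0109) else config$fixed
  threshold <- if (is.null(config$threshold)) 20 else config$threshold
  p13C <- if (is.null(config$p13C)) 0.0107 else config$p13C

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  gen_cfg <- config$generator
  if (is.null(gen_cfg)) gen_cfg <- generator_config(seed = seed, dose = dose)

  # inputs
  curves <- stage("read-curves", {
    if (!is.null(config$curves)) read_curves(config$curves)
    else generate_enrichment_curves(gen_cfg)$curves
  })
  mids <- stage("read-mids", {
    if (!is.null(config$mids)) read_mids(config$mids)
    else generate_raw_mids(gen_cfg)$mids
  })

  # stage 1: natural-abundance correction (raw groups only)
  corrected <- stage("correct-na", {
    model <- natural_abundance_model(p13C)
    groups <- split(mids, paste(mids$subject, mids$time_min, mids$metabolite))
    do.call(rbind, lapply(groups, function(grp) {
      m <- .df_to_mid(grp)
      if (!m$is_excess) m <- correct_natural_abundance(m, model)
      data.frame(subject = grp$subject[1L], time_min = grp$time_min[1L],
                 metabolite = grp$metabolite[1L],
                 n_carbons = grp$n_carbons[1L], iso_index = 0:m$n_carbons,
                 value = m$values, is_excess = 1L)
    }))
  })
  write_mids(corrected, file.path(out_dir, "corrected_mids.csv"))

  # stage 2: source attribution for glucose and citrate
  attribution <- stage("attribute", {
    designs <- list(glucose = glucose_design(), citrate = citrate_design())
    keep <- corrected$metabolite %in% names(designs)
    groups <- split(corrected[keep, ],
                    paste(corrected$subject, corrected$time_min,
                          corrected$metabolite)[keep])
    do.call(rbind, lapply(groups, function(grp) {
      m <- .df_to_mid(grp)
      at <- attribute_sources(m, designs[[m$metabolite]], dose = dose)
      data.frame(subject = m$subject, time_min = m$time_min,
                 metabolite = m$metabolite, scfa = names(at$coefficients),
                 coefficient = unname(at$coefficients),
                 normalized_contribution = unname(at$normalized_contribution),
                 condition_number = at$condition_number)
    }))
  })
  write.csv(attribution, file.path(out_dir, "attribution.csv"),
            row.names = FALSE)

  # stage 3: averaged-data fit
  avg <- if (length(unique(curves$subject)) > 1L) average_curves(curves) else curves
  fit <- stage("fit", fit_rate_constants(avg, dose, subject, fixed = fixed))
  write_fit_json(fit, file.path(out_dir, "fit.json"))

  # stage 4: identifiability at the fitted constants
  report <- stage("identify", {
    S <- sensitivity_matrix(fit$estimated, dose, subject, observed = avg)
    identifiable_subsets(S, threshold = threshold)
  })
  write.csv(as.data.frame(report), file.path(out_dir, "collinearity.csv"),
            row.names = FALSE)

  # stage 5: fractional dose contributions
  fractions <- stage("fractions", fraction_auc(fit$estimated, dose, subject))
  write.csv(fractions, file.path(out_dir, "fractions.csv"), row.names = FALSE)

  writeLines(c(
    sprintf("gutflux %s", as.character(packageVersion("gutflux"))),
    sprintf("seed: %d", seed),
    sprintf("max identifiable subset size: %d",
            attr(report, "max_identifiable_size")),
    sprintf("fit converged: %s", fit$converged)),
    file.path(out_dir, "run_log.txt"))

  invisible(list(corrected = corrected, attribution = attribution, fit = fit,
                 collinearity = report, fractions = fractions,
                 out_dir = out_dir))
}
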