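#' Read and write assay datasets as CSV
#'
#' The CSV dialect is comma-separated UTF-8 with a mandatory header and
#' molar concentrations in scientific notation.  Columns: `replicate`,
#' `agonist`, `modulator`, `agonist_conc_M`, `modulator_conc_M`,
#' `radioligand_conc_M`, `value`; one file can hold several replicates
#' and agonists.
#'
#' @param path File path.
#' @param assay_kind Assay kind to stamp on the datasets
#'   (see [assay_dataset()]).
#' @return For `read_assay_csv`, a list of [assay_dataset()] objects
#'   (one per replicate x agonist combination).
#' @export
read_assay_csv <- function(path, assay_kind = "interaction_binding") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("replicate", "agonist_conc_M", "modulator_conc_M", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (is.null(df$agonist)) df$agonist <- "agonist"
  if (is.null(df$modulator)) df$modulator <- NA_character_
  if (is.null(df$radioligand_conc_M))
    df$radioligand_conc_M <- NA_real_
  keys <- unique(df[, c("replicate", "agonist")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$replicate == keys$replicate[i] &
                df$agonist == keys$agonist[i], ]
    assay_dataset(sub[, c("agonist_conc_M", "modulator_conc_M",
                          "radioligand_conc_M", "value")],
                  assay_kind, agonist = keys$agonist[i],
                  modulator = sub$modulator[1],
                  replicate = keys$replicate[i])
  })
}

#' @rdname read_assay_csv
#' @param datasets List of [assay_dataset()] objects.
#' @export
write_assay_csv <- function(datasets, path) {
  if (inherits(datasets, "assay_dataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(d) {
    df <- d$data
    if (is.null(df$radioligand_conc_M)) df$radioligand_conc_M <- NA_real_
    data.frame(replicate = d$replicate, agonist = d$agonist,
               modulator = d$modulator,
               agonist_conc_M = format(df$agonist_conc_M,
                                       scientific = TRUE),
               modulator_conc_M = format(df$modulator_conc_M,
                                         scientific = TRUE),
               radioligand_conc_M = format(df$radioligand_conc_M,
                                           scientific = TRUE),
               value = df$value, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fit result to JSON and back
#'
#' @param fit A [`fit_result`][parameter_spec].
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  payload <- list(
    estimates = as.list(fit$estimates),
    sems = as.list(fit$sems),
    residual_ss = fit$residual_ss,
    n_points = fit$n_points,
    converged = fit$converged,
    derived = lapply(fit$derived, function(v)
      list(value = v[1], sem = v[2])),
    flags = fit$flags,
    per_replicate = lapply(fit$per_replicate, function(f)
      list(estimates = as.list(f$estimates),
           residual_ss = f$residual_ss,
           converged = f$converged)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) {
    v <- vapply(x, function(e) if (is.null(e)) NA_real_ else
      as.numeric(e), 0)
    names(v) <- names(x)
    v
  }
  new_fit_result(
    estimates = num(j$estimates), sems = num(j$sems),
    residual_ss = as.numeric(j$residual_ss),
    n_points = as.integer(j$n_points),
    converged = isTRUE(j$converged),
    derived = lapply(j$derived, function(d)
      c(as.numeric(d$value), as.numeric(d$sem))),
    flags = unlist(j$flags))
}

#' Render a parameter summary table
#'
#' Formats fit results the way interaction studies report them: one row
#' per result, parameter columns as `"mean +/- SEM (n)"` cells, missing
#' parameters as `"N.D."`.  Replicate counts are taken from
#' `per_replicate` fits where available.
#'
#' @param results Named list of [`fit_result`][parameter_spec] objects.
#' @param parameters Optional character vector restricting/ordering the
#'   columns; default is the union over results.
#' @return A character matrix (rows = results), suitable for printing
#'   or CSV export.
#' @export
render_parameter_table <- function(results, parameters = NULL) {
  stopifnot(length(results) > 0)
  if (is.null(parameters))
    parameters <- unique(unlist(lapply(results, function(f)
      names(f$estimates))))
  out <- matrix("N.D.", length(results), length(parameters),
                dimnames = list(names(results), parameters))
  for (i in seq_along(results)) {
    f <- results[[i]]
    n <- if (length(f$per_replicate)) length(f$per_replicate) else NA
    for (p in intersect(parameters, names(f$estimates)))
      out[i, p] <- format_pm(f$estimates[[p]],
                             if (p %in% names(f$sems))
                               f$sems[[p]] else NA, n)
  }
  out
}
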