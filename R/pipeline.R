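#' Classify one specimen end to end
#'
#' Runs the streamlined workflow in clinical order: MS-MLPA interpretation
#' first (methylation status and MLPA copy number; mandatory), then the
#' exome evidence — CNV calling against batch comparators and AOH detection
#' (the AOH LOH rule uses the methylation status established in step 1) —
#' and finally the integrated mechanism classification.
#'
#' @param mlpa MLPA probe table path or data frame (required).
#' @param vcf VCF path or variant data frame, or `NULL` (caveated).
#' @param coverage Coverage table path or data frame, or `NULL` (caveated).
#' @param specimen Specimen/coverage column name; defaults to the metadata
#'   `specimen_id` when available.
#' @param meta Metadata: path to a TSV with columns
#'   `specimen_id`/`sex_karyotype`, or a list/row with those fields.
#' @param variants Optional [small_variant_finding()] data frame.
#' @param registry A `region_registry` (default if `NULL`).
#' @param out_prefix If non-`NULL`, write report JSON/text here.
#' @param ... Threshold overrides passed to [detect_aoh()] and [call_cnv()]
#'   by matching argument name.
#' @return A `mechanism_call` with module results attached as `$mlpa`,
#'   `$cnv`, `$aoh`, and `$report`.
#' @export
classify_specimen <- function(mlpa, vcf = NULL, coverage = NULL,
                              specimen = NULL, meta = NULL, variants = NULL,
                              registry = NULL, out_prefix = NULL, ...) {
  if (is.null(registry)) registry <- load_region_registry()
  if (is.null(mlpa)) {
    stop("MS-MLPA input is required: the workflow cannot start without step 1")
  }
  if (is.character(meta) && length(meta) == 1) {
    meta <- as.list(utils::read.table(meta, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE)[1, ])
  }
  if (is.null(specimen) && !is.null(meta)) specimen <- meta$specimen_id

  dots <- list(...)
  args_for <- function(fn) dots[intersect(names(dots), names(formals(fn)))]

  mlpa_res <- do.call(interpret_mlpa,
                      c(list(probes = mlpa, registry = registry),
                        args_for(interpret_mlpa)))

  cnv_res <- NULL
  if (!is.null(coverage)) {
    if (is.null(specimen)) {
      stop("specimen column name required for CNV calling (give 'specimen' or metadata)")
    }
    cnv_res <- do.call(call_cnv,
                       c(list(table = coverage, specimen = specimen,
                              registry = registry), args_for(call_cnv)))
  }

  aoh_res <- NULL
  if (!is.null(vcf)) {
    meth_status <- switch(mlpa_res$methylation_pattern,
                          loss_of_paternal = ,
                          loss_of_maternal = "abnormal",
                          normal = "normal",
                          "unknown")
    sex <- if (!is.null(meta) && !is.null(meta$sex_karyotype))
      meta$sex_karyotype else "unknown"
    aoh_res <- do.call(detect_aoh,
                       c(list(vcf = vcf, registry = registry,
                              sample = specimen, sex_karyotype = sex,
                              methylation = meth_status),
                         args_for(detect_aoh)))
  }

  call <- classify_mechanism(mlpa_res, cnv_res, aoh_res, variants,
                             meta = meta, registry = registry)
  call$mlpa <- mlpa_res
  call$cnv <- cnv_res
  call$aoh <- aoh_res
  call$report <- render_report(call, mlpa_res, cnv_res, aoh_res,
                               out_prefix = out_prefix)
  call
}

#' Classify a synthetic specimen bundle
#'
#' @param bundle A `specimen_bundle` from [generate_specimen()].
#' @param registry A `region_registry` (default if `NULL`).
#' @param ... Passed to [classify_specimen()].
#' @return A `mechanism_call`.
#' @export
classify_bundle <- function(bundle, registry = NULL, ...) {
  classify_specimen(mlpa = bundle$mlpa, vcf = bundle$vcf,
                    coverage = bundle$coverage, specimen = bundle$specimen_id,
                    meta = bundle$meta, registry = registry, ...)
}
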