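#' Render the diagnostic report
#'
#' Produces the machine-readable (JSON) and human-readable (text) report
#' for a classified specimen: the call, the per-module evidence trail, all
#' thresholds in force, and caveats. Output is deterministic for fixed
#' inputs (two runs give byte-identical JSON).
#'
#' @param call A `mechanism_call`.
#' @param mlpa,cnv,aoh The module results the call was made from (any may
#'   be `NULL`).
#' @param out_prefix If non-`NULL`, write `<out_prefix>.json` and
#'   `<out_prefix>.txt`.
#' @return List with `json` (string), `text` (character vector), `report`
#'   (the underlying list), and output paths if written.
#' @export
render_report <- function(call, mlpa = NULL, cnv = NULL, aoh = NULL,
                          out_prefix = NULL) {
  thresholds <- list()
  if (!is.null(mlpa)) thresholds$mlpa <- mlpa$params
  if (!is.null(cnv)) thresholds$cnv <- cnv$params
  if (!is.null(aoh)) thresholds$aoh <- aoh$params

  modules <- list()
  if (!is.null(mlpa)) {
    modules$mlpa <- list(
      methylation_pattern = mlpa$methylation_pattern,
      methylation_values = round(mlpa$methylation_probes$value, 2),
      cn_summary = mlpa$cn_summary,
      deleted_genes = as.list(mlpa$deleted_genes),
      duplicated_genes = as.list(mlpa$duplicated_genes))
  }
  if (!is.null(cnv)) {
    modules$cnv <- list(
      status = cnv$status,
      qc_reason = cnv$qc$reason,
      extent_class = cnv$extent_class,
      positive_segments = if (is.null(cnv$positive_segments) ||
                              nrow(cnv$positive_segments) == 0) list() else
        lapply(seq_len(nrow(cnv$positive_segments)), function(i) {
          s <- cnv$positive_segments[i, ]
          list(direction = s$direction, genes = s$genes,
               n_exons = s$n_exons,
               combined_score = round(s$combined_score, 3),
               extreme_ratio = round(s$extreme_ratio, 3),
               confirmation_required = s$confirmation_required)
        }))
  }
  if (!is.null(aoh)) {
    modules$aoh <- list(
      critical_region_het_count = aoh$critical_region_het_count,
      critical_region_positive = aoh$critical_region_positive,
      largest_block_mb = round(aoh$largest_block_mb, 3),
      n_blocks_15q = nrow(aoh$aoh_blocks_15q),
      upd_consistent = aoh$upd_consistent,
      consanguinity_flag = aoh$consanguinity_flag,
      isodisomy_extent = if (is.null(aoh$isodisomy_extent)) NULL else
        aoh$isodisomy_extent$extent)
  }

  report <- list(
    specimen_id = call$specimen_id,
    syndrome = call$syndrome,
    mechanism = call$mechanism,
    parental_origin = call$parental_origin,
    label = call$label,
    evidence = as.list(call$evidence),
    caveats = as.list(call$caveats),
    modules = modules,
    thresholds = thresholds)

  json <- jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")

  text <- c("PWS/AS streamlined molecular diagnostic report",
            strrep("=", 46),
            sprintf("Specimen:  %s", call$specimen_id),
            sprintf("Syndrome:  %s", call$syndrome),
            sprintf("Result:    %s", call$label),
            sprintf("Mechanism: %s (defective allele: %s)", call$mechanism,
                    call$parental_origin),
            "", "Evidence:",
            paste0("  - ", call$evidence))
  if (length(call$caveats) > 0) {
    text <- c(text, "", "Caveats:", paste0("  - ", call$caveats))
  }

  out <- list(json = as.character(json), text = text, report = report)
  if (!is.null(out_prefix)) {
    json_path <- paste0(out_prefix, ".json")
    txt_path <- paste0(out_prefix, ".txt")
    writeLines(out$json, json_path)
    writeLines(text, txt_path)
    out$json_path <- json_path
    out$txt_path <- txt_path
  }
  out
}

#' Validate a report against the shipped schema
#'
#' Checks the report structure against the field requirements in
#' `inst/extdata/report_schema.json` (required top-level fields and their
#' types). This is a structural checker, not a full JSON-Schema engine.
#'
#' @param report A report list (from `render_report()$report`), a JSON
#'   string, or a path to a report JSON file.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  if (is.character(report) && length(report) == 1) {
    report <- if (file.exists(report)) jsonlite::read_json(report)
              else jsonlite::fromJSON(report, simplifyVector = FALSE)
  }
  schema_path <- system.file("extdata", "report_schema.json",
                             package = "pwsasdx")
  schema <- jsonlite::read_json(schema_path)
  for (f in unlist(schema$required)) {
    if (!(f %in% names(report))) stop("report missing required field: ", f)
  }
  props <- schema$properties
  for (f in names(props)) {
    if (!(f %in% names(report))) next
    type <- props[[f]]$type
    val <- report[[f]]
    ok <- switch(type,
                 string = is.character(val) || (length(val) == 1 && is.na(val)),
                 array = is.list(val) || is.vector(val),
                 object = is.list(val),
                 TRUE)
    if (!ok) stop("report field '", f, "' is not of schema type ", type)
  }
  if (!(report$mechanism %in% MECHANISMS)) {
    stop("report mechanism not in vocabulary: ", report$mechanism)
  }
  invisible(TRUE)
}
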