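#' Read an MS-MLPA probe table
#'
#' Tab-separated with header: `probe_id`, `gene`, `chrom`, `start`, `end`,
#' `kind` (`copy_number` or `methylation`), `value`. Copy-number probe
#' values are normalized ratios (1.0 = two copies); methylation probe
#' values are intensity signals on the 0-100 scale. A synthetic panel
#' manifest mirroring the structure of the commercial PWS/AS probe mix
#' (47 copy-number probes, 5 methylation probes at SNRPN and MAGEL2) ships
#' as `inst/extdata/mlpa_panel_synthetic.tsv`.
#'
#' @param path TSV path.
#' @return Data frame as above.
#' @export
read_mlpa_table <- function(path) {
  if (!file.exists(path)) stop("MLPA probe table not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("probe_id", "gene", "chrom", "start", "end", "kind", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("MLPA table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(tab$kind %in% c("copy_number", "methylation"))) {
    stop("MLPA probe kind must be 'copy_number' or 'methylation'")
  }
  tab$chrom <- norm_chrom(tab$chrom)
  tab
}

#' Call copy-number state for MLPA probe ratios
#'
#' Standard MLPA interpretation: a heterozygous deletion halves the probe
#' ratio (expected 0.5) and a single-copy gain raises it to about 1.5.
#' Defaults follow the ubiquitous MLPA convention (not printed values) and
#' are configurable.
#'
#' @param ratio Numeric vector of normalized copy-number probe ratios.
#' @param del_threshold Deleted at or below this ratio (default 0.7).
#' @param dup_threshold Duplicated at or above this ratio (default 1.3).
#' @return Character vector: `"deleted"`, `"normal"`, or `"duplicated"`.
#' @export
call_probe_copy_number <- function(ratio, del_threshold = 0.7,
                                   dup_threshold = 1.3) {
  if (any(ratio < 0)) stop("negative MLPA copy-number ratio")
  ifelse(ratio <= del_threshold, "deleted",
         ifelse(ratio >= dup_threshold, "duplicated", "normal"))
}

#' Call the methylation pattern from MS-MLPA methylation probes
#'
#' Per-probe banding of the methylation intensity signal: PWS-consistent
#' (hypermethylation, loss of the paternal allele) between 80 and 100;
#' normal between 40 and 60; AS-consistent (hypomethylation, loss of the
#' maternal allele) at or below the low ceiling, default 20 (only the PWS
#' and control bands are established reference ranges; the AS band is a
#' configurable default). Values above 100 are clamped with a warning. The
#' pattern is the majority call across probes; no in-band probes or a tie
#' gives `uninterpretable`.
#'
#' @param values Methylation probe intensities (at least one).
#' @param pws_band,normal_band Two-element numeric ranges.
#' @param as_ceiling Upper bound of the AS band (lower bound 0).
#' @return One of `"loss_of_paternal"` (PWS-consistent),
#'   `"loss_of_maternal"` (AS-consistent), `"normal"`,
#'   `"uninterpretable"`. Attribute `bands` holds the per-probe band calls.
#' @export
call_methylation_pattern <- function(values, pws_band = c(80, 100),
                                     normal_band = c(40, 60),
                                     as_ceiling = 20) {
  if (length(values) == 0) stop("no methylation probes supplied")
  if (any(values > 100)) {
    warning("methylation intensity above 100 clamped to 100")
    values <- pmin(values, 100)
  }
  band <- ifelse(values >= pws_band[1] & values <= pws_band[2], "loss_of_paternal",
          ifelse(values >= normal_band[1] & values <= normal_band[2], "normal",
          ifelse(values <= as_ceiling, "loss_of_maternal", "out_of_band")))
  tab <- table(band[band != "out_of_band"])
  pattern <- if (length(tab) == 0) {
    "uninterpretable"
  } else {
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) "uninterpretable" else top
  }
  attr(pattern, "bands") <- band
  pattern
}

#' Summarize MLPA copy number over the 15q11-q13 region
#'
#' Region summary from the copy-number probes mapped to registry genes:
#' `deletion_multi_gene` when two or more distinct 15q11-q13 genes carry
#' deleted probes; `deletion_snrpn_only` when deleted probes are confined
#' to SNRPN (the imprinting-center microdeletion signature);
#' `deletion_single_gene` for one deleted non-SNRPN gene; `duplication`
#' when two or more region genes carry duplicated probes and none are
#' deleted; otherwise `normal`. Reference probes outside the region do not
#' contribute. The result is invariant to probe ordering.
#'
#' @param probes MLPA probe table rows of kind `copy_number`, with a
#'   `state` column (from [call_probe_copy_number()]).
#' @param registry A `region_registry`.
#' @return List with `summary`, `deleted_genes`, `duplicated_genes`.
#' @export
summarize_mlpa_copy_number <- function(probes, registry) {
  region <- probes[probes$gene %in% registry$genes$gene, , drop = FALSE]
  del_genes <- sort(unique(region$gene[region$state == "deleted"]))
  dup_genes <- sort(unique(region$gene[region$state == "duplicated"]))
  summary <- if (length(del_genes) >= 2) {
    "deletion_multi_gene"
  } else if (identical(del_genes, "SNRPN")) {
    "deletion_snrpn_only"
  } else if (length(del_genes) == 1) {
    "deletion_single_gene"
  } else if (length(dup_genes) >= 2) {
    "duplication"
  } else {
    "normal"
  }
  list(summary = summary, deleted_genes = del_genes,
       duplicated_genes = dup_genes)
}

#' Interpret an MS-MLPA probe table
#'
#' Runs the full MLPA arm: per-probe copy-number states, the 15q11-q13
#' region copy-number summary, and the methylation pattern call. Methylation
#' is derived only from methylation probes and copy number only from
#' copy-number probes.
#'
#' @param probes Probe table (path or data frame from [read_mlpa_table()]).
#' @param registry A `region_registry`.
#' @param del_threshold,dup_threshold Copy-number thresholds.
#' @param pws_band,normal_band,as_ceiling Methylation bands.
#' @return An object of class `mlpa_result` with `probe_states` (the
#'   copy-number probes with states), `cn_summary`, `deleted_genes`,
#'   `duplicated_genes`, `methylation_pattern`, `methylation_probes`, and
#'   `params`.
#' @export
interpret_mlpa <- function(probes, registry, del_threshold = 0.7,
                           dup_threshold = 1.3, pws_band = c(80, 100),
                           normal_band = c(40, 60), as_ceiling = 20) {
  if (is.character(probes)) probes <- read_mlpa_table(probes)
  cn <- probes[probes$kind == "copy_number", , drop = FALSE]
  meth <- probes[probes$kind == "methylation", , drop = FALSE]
  if (nrow(meth) == 0) stop("MLPA table has no methylation probes")
  if (nrow(cn) == 0) stop("MLPA table has no copy-number probes")
  cn$state <- call_probe_copy_number(cn$value, del_threshold, dup_threshold)
  cn_sum <- summarize_mlpa_copy_number(cn, registry)
  pattern <- call_methylation_pattern(meth$value, pws_band = pws_band,
                                      normal_band = normal_band,
                                      as_ceiling = as_ceiling)
  meth$band <- attr(pattern, "bands")
  structure(list(
    probe_states = cn,
    cn_summary = cn_sum$summary,
    deleted_genes = cn_sum$deleted_genes,
    duplicated_genes = cn_sum$duplicated_genes,
    methylation_pattern = as.character(pattern),
    methylation_probes = meth,
    params = list(del_threshold = del_threshold,
                  dup_threshold = dup_threshold, pws_band = pws_band,
                  normal_band = normal_band, as_ceiling = as_ceiling)
  ), class = "mlpa_result")
}

#' @export
print.mlpa_result <- function(x, ...) {
  cat("MS-MLPA interpretation\n")
  cat(sprintf("  methylation pattern: %s (probes: %s)\n",
              x$methylation_pattern,
              paste(sprintf("%s=%.0f", x$methylation_probes$gene,
                            x$methylation_probes$value), collapse = ", ")))
  cat(sprintf("  copy-number summary: %s", x$cn_summary))
  if (length(x$deleted_genes) > 0) {
    cat(" (deleted: ", paste(x$deleted_genes, collapse = ", "), ")", sep = "")
  }
  if (length(x$duplicated_genes) > 0) {
    cat(" (duplicated: ", paste(x$duplicated_genes, collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}
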