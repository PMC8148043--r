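#' Read a per-exon coverage table
#'
#' Tab-separated, header row required: columns `gene`, `exon`, `chrom`,
#' `start`, `end`, then one raw mean-coverage column per specimen (the test
#' specimen plus its batch comparators, co-sequenced with the same capture
#' set). Rows are in capture design order.
#'
#' @param path TSV path.
#' @return Data frame as above.
#' @export
read_coverage_table <- function(path) {
  if (!file.exists(path)) stop("coverage table not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "exon", "chrom", "start", "end")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("coverage table missing column(s): ", paste(miss, collapse = ", "))
  }
  spec_cols <- setdiff(names(tab), need)
  if (length(spec_cols) < 1) stop("coverage table has no specimen columns")
  for (s in spec_cols) {
    if (!is.numeric(tab[[s]]) || any(tab[[s]] < 0, na.rm = TRUE)) {
      stop("coverage column '", s, "' must be non-negative numeric")
    }
  }
  tab$chrom <- norm_chrom(tab$chrom)
  tab
}

#' Doubly normalize exon coverage against batch comparators
#'
#' Step one (intra-specimen): each specimen column is divided by its own
#' median across all targeted exons, removing library-size differences; the
#' median is robust to the CNVs being sought. Step two (inter-specimen):
#' the specimen's internally normalized value at each exon is compared with
#' the comparator mean and standard deviation at that exon (comparators
#' only; the test specimen never contributes to its own reference).
#'
#' @param table Coverage table from [read_coverage_table()].
#' @param specimen Name of the test-specimen column.
#' @param comparators Comparator column names (default: all other specimen
#'   columns). At least four are required.
#' @param min_comparators Minimum comparator count (default 4).
#' @return Data frame with exon keys plus `spec_norm`, `comp_mean`,
#'   `comp_sd`, `ratio` (`spec_norm / comp_mean`), `z`
#'   (`(spec_norm - comp_mean) / comp_sd`). Exons with comparator mean 0
#'   are excluded and listed in attribute `excluded`. When normalization is
#'   impossible (too few comparators, all-zero specimen) a `cnv_norm_fail`
#'   object carrying `fail_reason` is returned instead.
#' @export
normalize_coverage <- function(table, specimen, comparators = NULL,
                               min_comparators = 4) {
  key_cols <- c("gene", "exon", "chrom", "start", "end")
  spec_cols <- setdiff(names(table), key_cols)
  if (!(specimen %in% spec_cols)) {
    stop("specimen column '", specimen, "' not found in coverage table")
  }
  if (is.null(comparators)) comparators <- setdiff(spec_cols, specimen)
  fail <- function(reason) {
    structure(list(fail_reason = reason), class = "cnv_norm_fail")
  }
  if (length(comparators) < min_comparators) {
    return(fail(sprintf("only %d comparator(s); a minimum of %d is required",
                        length(comparators), min_comparators)))
  }
  spec_raw <- table[[specimen]]
  if (all(spec_raw == 0)) return(fail("specimen coverage is all zero"))

  intra <- function(col) {
    m <- stats::median(col)
    if (m == 0) return(rep(NA_real_, length(col)))
    col / m
  }
  spec_norm <- intra(spec_raw)
  comp_norm <- vapply(comparators, function(s) intra(table[[s]]),
                      numeric(nrow(table)))
  comp_mean <- rowMeans(comp_norm)
  comp_sd <- apply(comp_norm, 1, stats::sd)

  diff <- spec_norm - comp_mean
  z <- ifelse(diff == 0, 0, diff / comp_sd)  # exact agreement is 0 SD even
                                             # for degenerate comparator SD
  out <- cbind(table[key_cols],
               data.frame(spec_norm = spec_norm, comp_mean = comp_mean,
                          comp_sd = comp_sd,
                          ratio = spec_norm / comp_mean,
                          z = z))
  zero <- !is.na(comp_mean) & comp_mean == 0
  excluded <- out[zero, key_cols, drop = FALSE]
  out <- out[!zero, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "comparators") <- comparators
  out
}

#' Flag exons as potential copy-number changes
#'
#' An exon is deletion-flagged when its coverage ratio is strictly below
#' 0.8 and duplication-flagged strictly above 1.2 (ratios outside
#' `ABS(1 - N) = 0.2`; the boundary values themselves are not flagged).
#' Exons whose comparator standard deviation is zero have an undefined
#' Z score and are excluded with a warning.
#'
#' @param normalized Output of [normalize_coverage()].
#' @param del_ratio,dup_ratio Flagging thresholds (defaults 0.8 / 1.2).
#' @return The input with a `flag` column
#'   (`"deletion"`/`"duplication"`/`"none"`), undefined-Z rows removed.
#' @export
flag_exons <- function(normalized, del_ratio = 0.8, dup_ratio = 1.2) {
  bad <- !is.finite(normalized$z)
  if (any(bad)) {
    warning(sum(bad), " exon(s) with zero comparator SD excluded (Z undefined)")
    normalized <- normalized[!bad, , drop = FALSE]
  }
  normalized$flag <- ifelse(normalized$ratio < del_ratio, "deletion",
                            ifelse(normalized$ratio > dup_ratio,
                                   "duplication", "none"))
  rownames(normalized) <- NULL
  normalized
}

#' Group contiguous flagged exons into CNV segments
#'
#' Contiguous exons flagged in the same direction are grouped; their
#' Z scores are treated as independent, so the group's combined score is
#' the Stouffer combination `|sum(Z_i)| / sqrt(k)` for a k-exon group. A
#' group is potentially positive when the combined score is at least 5 SD
#' and at least one exon has a ratio at or below 0.6 (deletion) or at or
#' above 1.4 (duplication). Positive groups of fewer than 12 exons require
#' orthogonal confirmation (MLPA/qPCR); runs of 12 or more consecutive
#' exons are reliable on their own.
#'
#' @param records Flagged exon records from [flag_exons()], in capture
#'   design order.
#' @param min_combined Combined-score threshold (default 5).
#' @param extreme_del,extreme_dup Extreme-ratio requirements (0.6 / 1.4).
#' @param no_confirm_exons Exon count at which confirmation is waived (12).
#' @param break_on_gene Break contiguity at gene boundaries (default
#'   `TRUE`); `FALSE` uses pure table-row adjacency.
#' @return Data frame of segments: `direction`, `first_exon`, `last_exon`,
#'   `chrom`, `start`, `end`, `n_exons`, `combined_score`,
#'   `extreme_ratio`, `genes` (comma-joined), `positive`,
#'   `confirmation_required`.
#' @export
group_cnv_segments <- function(records, min_combined = 5,
                               extreme_del = 0.6, extreme_dup = 1.4,
                               no_confirm_exons = 12, break_on_gene = TRUE) {
  empty <- data.frame(direction = character(), first_exon = integer(),
                      last_exon = integer(), chrom = character(),
                      start = numeric(), end = numeric(), n_exons = integer(),
                      combined_score = numeric(), extreme_ratio = numeric(),
                      genes = character(), positive = logical(),
                      confirmation_required = logical(),
                      stringsAsFactors = FALSE)
  flagged <- which(records$flag != "none")
  if (length(flagged) == 0) return(empty)
  grp_key <- records$flag
  if (break_on_gene) grp_key <- paste(grp_key, records$gene)
  r <- rle(grp_key)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1
  out <- list()
  for (k in seq_along(r$lengths)) {
    rows <- records[idx_start[k]:idx_end[k], , drop = FALSE]
    dir <- rows$flag[1]
    if (dir == "none") next
    combined <- abs(sum(rows$z)) / sqrt(nrow(rows))
    extreme <- if (dir == "deletion") min(rows$ratio) else max(rows$ratio)
    extreme_ok <- if (dir == "deletion") extreme <= extreme_del else extreme >= extreme_dup
    positive <- combined >= min_combined && extreme_ok
    out[[length(out) + 1]] <- data.frame(
      direction = dir, first_exon = idx_start[k], last_exon = idx_end[k],
      chrom = rows$chrom[1], start = min(rows$start), end = max(rows$end),
      n_exons = nrow(rows), combined_score = combined,
      extreme_ratio = extreme,
      genes = paste(unique(rows$gene), collapse = ","),
      positive = positive,
      confirmation_required = nrow(rows) < no_confirm_exons,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify deletion extent within 15q11-q13
#'
#' Maps the set of deleted genes to the recurrent deletion classes: type I
#' (BP1-BP3; the BP1-BP2 genes NIPA1/NIPA2/CYFIP1/TUBGCP5 deleted together
#' with the BP2-BP3 block), type II (BP2-BP3; the BP1-BP2 genes intact),
#' SNRPN-only (deletion confined to the SNRPN/imprinting-center span, the
#' imprinting-center microdeletion signature), atypical (other multi-gene
#' 15q11-q13 deletions, larger or smaller than the typical ones), or
#' single-gene.
#'
#' @param segments Positive deletion segments from [group_cnv_segments()]
#'   (or any data frame with `genes`, `chrom`, `start`, `end`).
#' @param registry A `region_registry`.
#' @return One of `"type_I_deletion"`, `"type_II_deletion"`,
#'   `"atypical_deletion"`, `"snrpn_only_deletion"`, `"single_gene"`,
#'   `"none"`.
#' @export
classify_deletion_extent <- function(segments, registry) {
  if (is.null(segments) || nrow(segments) == 0) return("none")
  genes <- unique(unlist(strsplit(segments$genes, ",")))
  span <- genomic_interval("chr15", min(segments$start), max(segments$end))
  extent_from_genes(genes, registry, span = span)
}

# shared by the CNV caller (exon segments) and the classifier (MLPA-derived
# deleted gene sets, used when the NGS CNV arm failed QC)
extent_from_genes <- function(genes, registry, span = NULL) {
  genes <- intersect(genes, registry$genes$gene)
  if (length(genes) == 0) return("none")
  ic <- snrpn_ic_region(registry)
  if (identical(sort(genes), "SNRPN")) {
    if (is.null(span) || (span$start >= ic$start && span$end <= ic$end)) {
      return("snrpn_only_deletion")
    }
    return("single_gene")
  }
  bp12_deleted <- BP12_GENES %in% genes
  # anchors spanning the BP2-BP3 block: proximal, imprinted core, distal
  anchors <- c("MKRN3", "SNRPN", "UBE3A", "HERC2")
  bp23_through <- all(anchors %in% genes)
  if (bp23_through && all(bp12_deleted)) return("type_I_deletion")
  if (bp23_through && !any(bp12_deleted)) return("type_II_deletion")
  if (length(genes) >= 2) return("atypical_deletion")
  "single_gene"
}

#' Coverage quality-control gate
#'
#' The NGS CNV arm is sensitive to DNA quality; degraded specimens are
#' marked `cnv_fail` rather than analyzed. The gate fails when fewer than
#' four comparators are available, when the specimen's median raw coverage
#' is below the floor (default 30x), or when the robust dispersion (scaled
#' MAD) of the per-exon coverage ratios across all exons exceeds the
#' ceiling (default 0.3) — robust so that a genuine CNV over part of the
#' target does not itself trip the gate.
#'
#' @param table Coverage table.
#' @param specimen Test-specimen column name.
#' @param comparators Comparator columns (default: all others).
#' @param min_comparators,min_median_coverage,max_dispersion Gate
#'   thresholds.
#' @return List with `pass` (logical) and `reason` (string or `NA`).
#' @export
cnv_qc_gate <- function(table, specimen, comparators = NULL,
                        min_comparators = 4, min_median_coverage = 30,
                        max_dispersion = 0.3) {
  key_cols <- c("gene", "exon", "chrom", "start", "end")
  spec_cols <- setdiff(names(table), key_cols)
  if (is.null(comparators)) comparators <- setdiff(spec_cols, specimen)
  if (length(comparators) < min_comparators) {
    return(list(pass = FALSE, reason = sprintf(
      "only %d comparator(s); a minimum of %d is required",
      length(comparators), min_comparators)))
  }
  med <- stats::median(table[[specimen]])
  if (med < min_median_coverage) {
    return(list(pass = FALSE, reason = sprintf(
      "specimen median coverage %.1fx below %gx floor", med,
      min_median_coverage)))
  }
  norm <- normalize_coverage(table, specimen, comparators,
                             min_comparators = min_comparators)
  if (inherits(norm, "cnv_norm_fail")) {
    return(list(pass = FALSE, reason = norm$fail_reason))
  }
  # robust dispersion: a genuine CNV over part of the target is not noise
  # and must not trip the gate, so scaled MAD rather than SD
  disp <- stats::mad(norm$ratio, na.rm = TRUE)
  if (is.finite(disp) && disp > max_dispersion) {
    return(list(pass = FALSE, reason = sprintf(
      "specimen-vs-comparator ratio dispersion %.2f exceeds %.2f ceiling",
      disp, max_dispersion)))
  }
  list(pass = TRUE, reason = NA_character_)
}

#' Call exon-level copy-number variants for one specimen
#'
#' End-to-end CNV arm: QC gate, double normalization, ratio flagging,
#' contiguous grouping with Stouffer-combined scores, and deletion-extent
#' classification against the 15q11-q13 registry.
#'
#' @param table Coverage table (path or data frame from
#'   [read_coverage_table()]).
#' @param specimen Test-specimen column name.
#' @param registry A `region_registry`.
#' @param comparators Comparator columns (default: all other columns).
#' @param min_comparators,del_ratio,dup_ratio,extreme_del,extreme_dup
#'   Thresholds, see the step functions.
#' @param min_combined,no_confirm_exons,break_on_gene Grouping parameters.
#' @param min_median_coverage,max_dispersion QC-gate parameters.
#' @return An object of class `cnv_result` with `status`
#'   (`"completed"`/`"cnv_fail"`), `records` (per-exon), `segments` (all
#'   groups), `positive_segments`, `extent_class`, `qc`, and `params`.
#' @export
call_cnv <- function(table, specimen, registry, comparators = NULL,
                     min_comparators = 4, del_ratio = 0.8, dup_ratio = 1.2,
                     extreme_del = 0.6, extreme_dup = 1.4, min_combined = 5,
                     no_confirm_exons = 12, break_on_gene = TRUE,
                     min_median_coverage = 30, max_dispersion = 0.3) {
  if (is.character(table)) table <- read_coverage_table(table)
  params <- list(min_comparators = min_comparators, del_ratio = del_ratio,
                 dup_ratio = dup_ratio, extreme_del = extreme_del,
                 extreme_dup = extreme_dup, min_combined = min_combined,
                 no_confirm_exons = no_confirm_exons,
                 break_on_gene = break_on_gene,
                 min_median_coverage = min_median_coverage,
                 max_dispersion = max_dispersion)
  failed <- function(qc) {
    structure(list(status = "cnv_fail", records = NULL,
                   segments = NULL, positive_segments = NULL,
                   extent_class = "none", qc = qc, specimen = specimen,
                   params = params), class = "cnv_result")
  }
  qc <- cnv_qc_gate(table, specimen, comparators,
                    min_comparators = min_comparators,
                    min_median_coverage = min_median_coverage,
                    max_dispersion = max_dispersion)
  if (!qc$pass) return(failed(qc))
  norm <- normalize_coverage(table, specimen, comparators,
                             min_comparators = min_comparators)
  if (inherits(norm, "cnv_norm_fail")) {
    return(failed(list(pass = FALSE, reason = norm$fail_reason)))
  }
  records <- flag_exons(norm, del_ratio = del_ratio, dup_ratio = dup_ratio)
  segments <- group_cnv_segments(records, min_combined = min_combined,
                                 extreme_del = extreme_del,
                                 extreme_dup = extreme_dup,
                                 no_confirm_exons = no_confirm_exons,
                                 break_on_gene = break_on_gene)
  pos <- segments[segments$positive, , drop = FALSE]
  pos_del <- pos[pos$direction == "deletion", , drop = FALSE]
  extent <- classify_deletion_extent(pos_del, registry)
  if (extent == "none" && nrow(pos) > 0 &&
      all(pos$direction == "duplication")) {
    extent <- "duplication"
  }
  structure(list(status = "completed", records = records,
                 segments = segments, positive_segments = pos,
                 extent_class = extent, qc = qc, specimen = specimen,
                 params = params), class = "cnv_result")
}

#' @export
print.cnv_result <- function(x, ...) {
  cat("Exon-level CNV result for", x$specimen, "\n")
  if (x$status == "cnv_fail") {
    cat("  status: CNV FAIL -", x$qc$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  exons analyzed: %d; flagged groups: %d; positive: %d\n",
              nrow(x$records), nrow(x$segments), nrow(x$positive_segments)))
  cat("  deletion extent class:", x$extent_class, "\n")
  if (nrow(x$positive_segments) > 0) {
    p <- x$positive_segments
    for (i in seq_len(nrow(p))) {
      cat(sprintf("  %s %s (%d exon(s), combined %.1f SD, extreme ratio %.2f)%s\n",
                  p$direction[i], p$genes[i], p$n_exons[i],
                  p$combined_score[i], p$extreme_ratio[i],
                  if (p$confirmation_required[i]) " [confirmation required]" else ""))
    }
  }
  invisible(x)
}

#' Write CNV segments as TSV
#'
#' @param cnv A `cnv_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cnv_segments <- function(cnv, path) {
  seg <- cnv$segments
  if (is.null(seg)) {
    seg <- data.frame(direction = character(), genes = character())
  }
  utils::write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
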