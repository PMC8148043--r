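#' Categorize variants for AOH analysis
#'
#' Assigns each genotyped site one of three categories: `homozygous` (two
#' identical non-missing alleles), `heterozygous` (two different alleles),
#' or `ignored` (the site falls inside the segmental-duplication mask,
#' where zygosity calls are unreliable). Ignored sites take no part in
#' interval formation but are tabulated.
#'
#' @param variants Data frame from [read_vcf_variants()] (or with the same
#'   columns `chrom`, `pos`, `zygosity`, `is_snv`).
#' @param mask Segmental-duplication mask intervals (data frame
#'   `chrom`/`start`/`end`, 1-based inclusive), or `NULL` for no mask.
#' @return The input with a `category` column added, sorted by chromosome
#'   then position. Category counts are attached as attribute `counts`.
#' @export
categorize_variants <- function(variants, mask = NULL) {
  v <- variants[order(chrom_rank(variants$chrom), variants$pos), , drop = FALSE]
  rownames(v) <- NULL
  in_mask <- points_in_intervals(v$chrom, v$pos, mask)
  v$category <- ifelse(in_mask, "ignored", v$zygosity)
  attr(v, "counts") <- c(homozygous = sum(v$category == "homozygous"),
                         heterozygous = sum(v$category == "heterozygous"),
                         ignored = sum(v$category == "ignored"))
  v
}

#' Build same-zygosity intervals
#'
#' Forms maximal runs of neighboring non-ignored variants of the same
#' zygosity, per chromosome. Ignored variants have no effect on interval
#' formation but are counted inside each span. Intervals never span into or
#' across a centromere: a run with variants on both sides of the centromere
#' is split at the centromere into per-arm intervals.
#'
#' @param observations Categorized variants from [categorize_variants()],
#'   sorted by chromosome then position (contract; violating it is an error).
#' @param centromeres Data frame `chrom`/`start`/`end` of centromere
#'   intervals (may omit chromosomes; those are treated as single-arm).
#' @return Data frame with columns `chrom`, `start`, `end`, `zygosity`,
#'   `n_variants`, `n_ignored`, `size_mb`. Interval spans run from the first
#'   to the last supporting variant.
#' @export
build_zygosity_intervals <- function(observations, centromeres = NULL) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      zygosity = character(), n_variants = integer(),
                      n_ignored = integer(), size_mb = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(observations) == 0) return(empty)
  out <- list()
  for (ch in unique(observations$chrom)) {
    o <- observations[observations$chrom == ch, , drop = FALSE]
    if (is.unsorted(o$pos)) {
      stop("internal error: observations for ", ch, " are not position-sorted")
    }
    cs <- ce <- NULL
    if (!is.null(centromeres)) {
      i <- match(ch, centromeres$chrom)
      if (!is.na(i)) { cs <- centromeres$start[i]; ce <- centromeres$end[i] }
    }
    arm <- if (is.null(cs)) rep("p", nrow(o)) else centromere_arm(o$pos, cs, ce)
    supp <- o[o$category != "ignored", , drop = FALSE]
    supp_arm <- arm[o$category != "ignored"]
    ign_pos <- o$pos[o$category == "ignored"]
    for (a in unique(supp_arm)) {
      s <- supp[supp_arm == a, , drop = FALSE]
      if (nrow(s) == 0) next
      r <- rle(s$category)
      idx_end <- cumsum(r$lengths)
      idx_start <- idx_end - r$lengths + 1
      for (k in seq_along(r$lengths)) {
        span_s <- s$pos[idx_start[k]]
        span_e <- s$pos[idx_end[k]]
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = span_s, end = span_e,
          zygosity = r$values[k], n_variants = r$lengths[k],
          n_ignored = sum(ign_pos >= span_s & ign_pos <= span_e),
          size_mb = interval_length_mb(span_s, span_e),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res[order(chrom_rank(res$chrom), res$start), , drop = FALSE]
}

# assign positions to a chromosome arm; a position on the centromere
# boundary belongs to the arm containing it, positions strictly inside the
# centromere band go to the nearer arm
centromere_arm <- function(pos, cen_start, cen_end) {
  ifelse(pos <= cen_start, "p",
         ifelse(pos >= cen_end, "q",
                ifelse(pos - cen_start <= cen_end - pos, "p", "q")))
}

#' Assess the 15q11 critical region
#'
#' Counts heterozygous, non-ignored SNVs inside the 5-Mb critical region
#' (`chr15:22,892,936-27,892,936`, inclusive bounds). A specimen is
#' AOH-region positive when fewer than four such SNVs are present; control
#' exomes average 42.5 (SD 12.76) heterozygous variants here, so fewer than
#' four indicates absence of heterozygosity from hemizygosity or isodisomy.
#' Indels contribute to interval formation but not to this tally.
#'
#' @param observations Categorized variants (genome-wide or chr15 only).
#' @param registry A `region_registry`.
#' @param pass_only Count only sites whose FILTER is `PASS` or missing
#'   (default `TRUE`; set `FALSE` if the VCF carries no meaningful FILTER).
#' @return List with `het_count` and `positive` (`het_count < 4`).
#' @export
assess_critical_region <- function(observations, registry, pass_only = TRUE) {
  cr <- registry$critical_region
  o <- observations
  sel <- o$chrom == cr$chrom & o$pos >= cr$start & o$pos <= cr$end &
    o$category == "heterozygous" & o$is_snv
  if (pass_only && "filter" %in% names(o)) {
    sel <- sel & (is.na(o$filter) | o$filter %in% c("PASS", "."))
  }
  n <- sum(sel)
  list(het_count = n, positive = n < 4)
}

#' Classify isodisomy extent
#'
#' Distinguishes total from segmental isodisomy 15: total when the
#' qualifying homozygous blocks cover at least `total_fraction` of the
#' analyzable (variant-covered) 15q span, segmental otherwise (with the
#' number, sizes and locations of the segments reported).
#'
#' @param blocks_15q Data frame of homozygous 15q blocks (columns `start`,
#'   `end`, `size_mb`); must be non-empty.
#' @param analyzable A genomic interval spanning the variant-covered 15q.
#' @param total_fraction Coverage fraction at or above which the call is
#'   `total` (default 0.95; a configurable boundary, not a printed value).
#' @return List with `extent` (`"total"`/`"segmental"`), `fraction`,
#'   `n_segments`, and `segments` (the input blocks).
#' @export
classify_isodisomy_extent <- function(blocks_15q, analyzable,
                                      total_fraction = 0.95) {
  if (is.null(blocks_15q) || nrow(blocks_15q) == 0) {
    stop("classify_isodisomy_extent requires at least one qualifying block")
  }
  covered <- sum(blocks_15q$end - blocks_15q$start + 1)
  span <- analyzable$end - analyzable$start + 1
  frac <- covered / span
  list(extent = if (frac >= total_fraction) "total" else "segmental",
       fraction = frac, n_segments = nrow(blocks_15q), segments = blocks_15q)
}

#' Detect absence of heterozygosity and assess LOH/UPD consistency
#'
#' Runs the full AOH workflow on one specimen: variant categorization
#' against the segmental-duplication mask, same-zygosity interval building
#' (centromere-aware), the critical-region heterozygous-SNV rule, and the
#' LOH size rules. A 15q homozygous block qualifies as LOH consistent with
#' uniparental disomy when it exceeds 5 Mb and the methylation signal is
#' abnormal (PWS- or AS-consistent), or measures at least 8 Mb when the
#' methylation status is unknown. Comparable blocks on two or more other
#' autosomes raise the consanguinity flag instead (identity by descent),
#' which vetoes the UPD interpretation. The X chromosome is excluded for
#' 46,XY specimens.
#'
#' @param vcf Path to a VCF file, or a data frame from [read_vcf_variants()].
#' @param registry A `region_registry`.
#' @param sample Sample name for multi-sample VCFs.
#' @param sex_karyotype `"46,XX"`, `"46,XY"`, or `"unknown"`.
#' @param methylation `"abnormal"` (PWS/AS-consistent signal), `"normal"`,
#'   or `"unknown"`; controls which LOH size rule applies.
#' @param reporting_floor_mb Homozygous blocks smaller than this are not
#'   reported (default 1.5 Mb; smaller blocks are common in normal genomes).
#' @param loh_mb Strict lower bound for LOH with abnormal methylation
#'   (default 5 Mb).
#' @param loh_unknown_mb Inclusive lower bound without methylation support
#'   (default 8 Mb).
#' @param min_block_variants Minimum number of supporting variants a
#'   homozygous block needs before it can enter the LOH and consanguinity
#'   rules (default 20). A handful of consecutive homozygous calls spanning
#'   megabases is a sparse-marker artifact, not credible absence of
#'   heterozygosity; run-of-homozygosity callers apply the same kind of
#'   minimum-marker guard.
#' @param total_fraction Passed to [classify_isodisomy_extent()].
#' @param pass_only Passed to [assess_critical_region()].
#' @return An object of class `aoh_assessment`.
#' @export
detect_aoh <- function(vcf, registry, sample = NULL,
                       sex_karyotype = "unknown",
                       methylation = c("unknown", "abnormal", "normal"),
                       reporting_floor_mb = 1.5, loh_mb = 5,
                       loh_unknown_mb = 8, min_block_variants = 20,
                       total_fraction = 0.95, pass_only = TRUE) {
  methylation <- match.arg(methylation)
  variants <- if (is.character(vcf)) read_vcf_variants(vcf, sample) else vcf
  obs <- categorize_variants(variants, registry$segdup_mask)
  notes <- character()

  if (identical(sex_karyotype, "46,XY")) {
    n_x <- sum(obs$chrom == "chrX")
    if (n_x > 0) {
      obs <- obs[obs$chrom != "chrX", , drop = FALSE]
      notes <- c(notes, sprintf(
        "chrX excluded from AOH analysis for 46,XY karyotype (%d variants)", n_x))
    }
  }

  intervals <- build_zygosity_intervals(obs, registry$centromeres)
  hom <- intervals[intervals$zygosity == "homozygous" &
                     intervals$size_mb >= reporting_floor_mb, , drop = FALSE]

  cr <- assess_critical_region(obs, registry, pass_only = pass_only)
  n_chr15 <- sum(obs$chrom == "chr15")
  if (n_chr15 == 0) {
    notes <- c(notes, "low data: no chr15 variants observed; critical-region assessment is uninformative")
  }

  q15 <- q_arm_start(registry, "chr15")
  blocks_15q <- hom[hom$chrom == "chr15" & hom$start >= q15, , drop = FALSE]
  largest <- if (nrow(blocks_15q) > 0) max(blocks_15q$size_mb) else 0

  supported <- blocks_15q[blocks_15q$n_variants >= min_block_variants, ,
                          drop = FALSE]
  qualifying <- if (methylation == "abnormal") {
    supported[supported$size_mb > loh_mb, , drop = FALSE]
  } else {
    supported[supported$size_mb >= loh_unknown_mb, , drop = FALSE]
  }

  other <- hom[hom$chrom != "chr15" & hom$chrom != "chrX" &
                 hom$size_mb >= loh_mb &
                 hom$n_variants >= min_block_variants, , drop = FALSE]
  consanguinity_flag <- length(unique(other$chrom)) >= 2
  upd_consistent <- nrow(qualifying) > 0 && !consanguinity_flag
  if (consanguinity_flag) {
    notes <- c(notes, sprintf(
      "homozygous blocks >= %g Mb on %d other autosome(s) (%s): consanguinity suspected, UPD interpretation withheld",
      loh_mb, length(unique(other$chrom)),
      paste(unique(other$chrom), collapse = ", ")))
  }

  extent <- NULL
  if (upd_consistent) {
    o15q <- obs[obs$chrom == "chr15" & obs$pos >= q15 &
                  obs$category != "ignored", , drop = FALSE]
    analyzable <- genomic_interval("chr15", min(o15q$pos), max(o15q$pos))
    extent <- classify_isodisomy_extent(qualifying, analyzable,
                                        total_fraction = total_fraction)
  }

  structure(list(
    critical_region_het_count = cr$het_count,
    critical_region_positive = cr$positive,
    aoh_blocks_15q = blocks_15q,
    largest_block_mb = largest,
    genomewide_blocks = hom,
    consanguinity_flag = consanguinity_flag,
    upd_consistent = upd_consistent,
    isodisomy_extent = extent,
    intervals = intervals,
    counts = attr(obs, "counts"),
    methylation = methylation,
    notes = notes,
    params = list(reporting_floor_mb = reporting_floor_mb, loh_mb = loh_mb,
                  loh_unknown_mb = loh_unknown_mb,
                  min_block_variants = min_block_variants,
                  total_fraction = total_fraction, pass_only = pass_only)
  ), class = "aoh_assessment")
}

#' Write the per-chromosome zygosity interval table as TSV
#'
#' @param aoh An `aoh_assessment`.
#' @param path Output TSV path (columns: chrom, start, end, zygosity,
#'   n_variants, n_ignored, size_mb).
#' @return `path`, invisibly.
#' @export
write_aoh_intervals <- function(aoh, path) {
  utils::write.table(aoh$intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.aoh_assessment <- function(x, ...) {
  cat("AOH assessment\n")
  cat(sprintf("  critical-region het SNVs: %d (%s)\n",
              x$critical_region_het_count,
              if (x$critical_region_positive) "AOH POSITIVE, < 4" else "negative, >= 4"))
  cat(sprintf("  15q homozygous blocks >= %g Mb: %d (largest %.2f Mb)\n",
              x$params$reporting_floor_mb, nrow(x$aoh_blocks_15q),
              x$largest_block_mb))
  cat(sprintf("  UPD-consistent LOH: %s%s; consanguinity flag: %s\n",
              x$upd_consistent,
              if (!is.null(x$isodisomy_extent))
                sprintf(" (%s isodisomy, %d segment(s), %.0f%% of 15q)",
                        x$isodisomy_extent$extent, x$isodisomy_extent$n_segments,
                        100 * x$isodisomy_extent$fraction) else "",
              x$consanguinity_flag))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}
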