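#' Load the 15q11-q13 region registry
#'
#' The registry holds the shared genomic context the whole workflow depends
#' on: the 5-Mb critical region around SNRPN
#' (`chr15:22,892,936-27,892,936`), the imprinting-center interval, the
#' 15q11-q13 gene table with breakpoint-zone tags (BP1-BP2, BP2-BP3,
#' distal), the BP1/BP2/BP3 breakpoint positions, per-chromosome centromere
#' intervals and lengths, and a segmental-duplication mask.
#'
#' Gene, breakpoint and centromere base positions are a curated GRCh37
#' default table shipped with the package (standard annotation; the
#' classification logic depends only on gene ordering and zone tags). Users
#' can override everything via a YAML config with sections `regions`,
#' `genes`, `breakpoints`, `centromeres`, `chrom_lengths` and `masks`
#' (a BED path, resolved relative to the config file).
#'
#' @param config_path Path to a registry YAML config, or `NULL` for the
#'   built-in GRCh37 default.
#' @return An object of class `region_registry`: a list with elements
#'   `critical_region`, `imprinting_center`, `genes` (data frame in genomic
#'   order with columns `gene`, `chrom`, `start`, `end`, `zone`),
#'   `breakpoints` (named numeric: BP1, BP2, BP3), `centromeres` (data frame
#'   `chrom`, `start`, `end`), `chrom_lengths` (named numeric),
#'   `segdup_mask` (data frame, possibly zero rows).
#' @examples
#' reg <- load_region_registry()
#' interval_length_kb(reg$critical_region)  # 5000
#' @export
load_region_registry <- function(config_path = NULL) {
  if (is.null(config_path)) {
    config_path <- system.file("extdata", "registry_grch37.yaml",
                               package = "pwsasdx")
  }
  if (!file.exists(config_path)) {
    stop("registry config not found: ", config_path)
  }
  cfg <- tryCatch(yaml::read_yaml(config_path),
                  error = function(e) stop("registry config does not parse: ",
                                           conditionMessage(e)))
  need <- c("regions", "genes", "breakpoints", "centromeres", "chrom_lengths")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0) {
    stop("registry config missing section(s): ", paste(miss, collapse = ", "))
  }
  iv_from <- function(x, field) {
    if (is.null(x) || !all(c("chrom", "start", "end") %in% names(x))) {
      stop("registry config field '", field, "' must have chrom/start/end")
    }
    genomic_interval(x$chrom, x$start, x$end)
  }
  critical_region <- iv_from(cfg$regions$critical_region, "regions.critical_region")
  imprinting_center <- iv_from(cfg$regions$imprinting_center, "regions.imprinting_center")

  genes <- do.call(rbind, lapply(names(cfg$genes), function(g) {
    e <- cfg$genes[[g]]
    if (is.null(e$start) || is.null(e$end) || is.null(e$zone)) {
      stop("registry config gene '", g, "' needs start/end/zone")
    }
    data.frame(gene = g, chrom = norm_chrom(if (is.null(e$chrom)) "chr15" else e$chrom),
               start = as.numeric(e$start), end = as.numeric(e$end),
               zone = e$zone, stringsAsFactors = FALSE)
  }))
  bp <- vapply(c("BP1", "BP2", "BP3"), function(b) {
    v <- cfg$breakpoints[[b]]
    if (is.null(v)) stop("registry config missing breakpoint: ", b)
    as.numeric(v)
  }, numeric(1))
  cen <- do.call(rbind, lapply(names(cfg$centromeres), function(ch) {
    e <- cfg$centromeres[[ch]]
    data.frame(chrom = norm_chrom(ch), start = as.numeric(e$start),
               end = as.numeric(e$end), stringsAsFactors = FALSE)
  }))
  lens <- unlist(cfg$chrom_lengths)
  names(lens) <- norm_chrom(names(lens))

  mask <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                     stringsAsFactors = FALSE)
  mask_bed <- NULL
  if (!is.null(cfg$masks) && !is.null(cfg$masks$bed)) {
    p <- cfg$masks$bed
    if (!file.exists(p)) p <- file.path(dirname(config_path), cfg$masks$bed)
    mask <- read_bed_mask(p)
    mask_bed <- normalizePath(p)  # stored resolved so written configs reload
  }

  reg <- structure(list(
    critical_region = critical_region,
    imprinting_center = imprinting_center,
    genes = genes,
    breakpoints = bp,
    centromeres = cen,
    chrom_lengths = lens,
    segdup_mask = mask,
    mask_bed = mask_bed
  ), class = "region_registry")
  validate_region_registry(reg)
  reg
}

REQUIRED_GENES <- c("NIPA1", "NIPA2", "CYFIP1", "TUBGCP5", "MAGEL2", "MKRN3",
                    "NDN", "NPAP1", "SNRPN", "UBE3A", "ATP10A", "GABRA5",
                    "GABRG3", "OCA2", "HERC2", "APBA2")
BP12_GENES <- c("TUBGCP5", "CYFIP1", "NIPA2", "NIPA1")

validate_region_registry <- function(reg) {
  miss <- setdiff(REQUIRED_GENES, reg$genes$gene)
  if (length(miss) > 0) {
    stop("registry config missing gene entries: ", paste(miss, collapse = ", "))
  }
  g <- reg$genes
  if (any(g$chrom != "chr15")) stop("registry gene intervals must be on chr15")
  if (is.unsorted(g$start)) stop("registry genes must be in genomic order")
  b12 <- g[g$gene %in% BP12_GENES, ]
  if (!all(b12$zone == "BP1-BP2")) {
    stop("registry genes NIPA1/NIPA2/CYFIP1/TUBGCP5 must be tagged BP1-BP2")
  }
  bp <- reg$breakpoints
  if (!all(b12$start > bp["BP1"] & b12$end < bp["BP2"])) {
    stop("registry BP1-BP2 genes must lie between breakpoints BP1 and BP2")
  }
  cr <- reg$critical_region
  for (gg in c("SNRPN", "UBE3A")) {
    row <- g[g$gene == gg, ]
    if (!(row$start >= cr$start && row$end <= cr$end)) {
      stop("registry critical_region must contain gene ", gg)
    }
  }
  if (!("chr15" %in% reg$centromeres$chrom)) {
    stop("registry centromeres must include chr15")
  }
  invisible(reg)
}

#' Write a region registry back to its YAML config form
#'
#' Serialization is canonical: loading a config and writing it again
#' produces a byte-identical file, so configs round-trip exactly.
#'
#' @param reg A `region_registry`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_region_registry <- function(reg, path) {
  int <- function(x) as.integer(x)  # all GRCh37 coordinates fit in 32 bits
  iv_list <- function(iv) list(chrom = iv$chrom, start = int(iv$start),
                               end = int(iv$end))
  genes <- stats::setNames(lapply(seq_len(nrow(reg$genes)), function(i) {
    list(chrom = reg$genes$chrom[i], start = int(reg$genes$start[i]),
         end = int(reg$genes$end[i]), zone = reg$genes$zone[i])
  }), reg$genes$gene)
  cen <- stats::setNames(lapply(seq_len(nrow(reg$centromeres)), function(i) {
    list(start = int(reg$centromeres$start[i]),
         end = int(reg$centromeres$end[i]))
  }), reg$centromeres$chrom)
  cfg <- list(
    regions = list(critical_region = iv_list(reg$critical_region),
                   imprinting_center = iv_list(reg$imprinting_center)),
    genes = genes,
    breakpoints = lapply(as.list(reg$breakpoints), int),
    centromeres = cen,
    chrom_lengths = lapply(as.list(reg$chrom_lengths), int),
    masks = list(bed = reg$mask_bed)
  )
  txt <- yaml::as.yaml(cfg, precision = 12)
  writeLines(txt, path, sep = "")
  invisible(path)
}

#' @export
print.region_registry <- function(x, ...) {
  cat("15q11-q13 region registry (GRCh37)\n")
  cat(sprintf("  critical region:   %s:%s-%s (%d kb)\n",
              x$critical_region$chrom,
              format(x$critical_region$start, big.mark = ","),
              format(x$critical_region$end, big.mark = ","),
              interval_length_kb(x$critical_region)))
  cat(sprintf("  imprinting center: %s:%s-%s\n", x$imprinting_center$chrom,
              format(x$imprinting_center$start, big.mark = ","),
              format(x$imprinting_center$end, big.mark = ",")))
  cat(sprintf("  genes: %d (%s ... %s); breakpoints BP1=%s BP2=%s BP3=%s\n",
              nrow(x$genes), x$genes$gene[1], x$genes$gene[nrow(x$genes)],
              format(x$breakpoints[["BP1"]], big.mark = ","),
              format(x$breakpoints[["BP2"]], big.mark = ","),
              format(x$breakpoints[["BP3"]], big.mark = ",")))
  cat(sprintf("  centromeres: %d chromosomes; segdup mask: %d interval(s)\n",
              nrow(x$centromeres), nrow(x$segdup_mask)))
  invisible(x)
}

# union of the SNRPN gene interval and the imprinting-center interval;
# deletions confined to this span are "SNRPN-only" (imprinting-center class)
snrpn_ic_region <- function(reg) {
  s <- reg$genes[reg$genes$gene == "SNRPN", ]
  genomic_interval("chr15",
                   min(s$start, reg$imprinting_center$start),
                   max(s$end, reg$imprinting_center$end))
}

# q-arm start for a chromosome (centromere end); NA if unknown
q_arm_start <- function(reg, chrom) {
  chrom <- norm_chrom(chrom)
  i <- match(chrom, reg$centromeres$chrom)
  if (is.na(i)) return(NA_real_)
  reg$centromeres$end[i]
}
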