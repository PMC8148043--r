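#' Read genotyped variants from a VCF file
#'
#' Parses a VCF 4.x file (plain or bgzipped) with vcfR and returns the
#' per-site genotype observations needed by the AOH detector. Multi-sample
#' files are rejected unless `sample` names the column to use. Sites with
#' missing or half-called genotypes are excluded.
#'
#' @param path VCF file path.
#' @param sample Sample name for multi-sample files; `NULL` uses the single
#'   sample present (error if there are several).
#' @return Data frame with columns `chrom`, `pos`, `ref`, `alt`, `filter`,
#'   `gt`, `zygosity` (`"homozygous"`/`"heterozygous"`), `is_snv`, sorted by
#'   chromosome then position.
#' @export
read_vcf_variants <- function(path, sample = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("unreadable VCF: ", conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (!is.null(fix) && is.null(dim(fix))) {  # single-record files drop dims
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  if (is.null(fix) || nrow(fix) == 0) {
    return(data.frame(chrom = character(), pos = numeric(), ref = character(),
                      alt = character(), filter = character(), gt = character(),
                      zygosity = character(), is_snv = logical(),
                      stringsAsFactors = FALSE))
  }
  if (ncol(v@gt) < 2) stop("VCF has no genotype (FORMAT/sample) columns")
  samples <- colnames(v@gt)[-1]
  if (is.null(sample)) {
    if (length(samples) > 1) {
      stop("multi-sample VCF: name the sample to analyze (found: ",
           paste(samples, collapse = ", "), ")")
    }
    sample <- samples[1]
  } else if (!(sample %in% samples)) {
    stop("sample '", sample, "' not present in VCF (found: ",
         paste(samples, collapse = ", "), ")")
  }
  gt <- vcfR::extract.gt(v, element = "GT")[, sample]

  chrom <- norm_chrom(fix[, "CHROM"])
  pos <- as.numeric(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  filter <- fix[, "FILTER"]

  zyg <- gt_zygosity(gt)
  keep <- !is.na(zyg)
  out <- data.frame(chrom = chrom[keep], pos = pos[keep], ref = ref[keep],
                    alt = alt[keep], filter = filter[keep], gt = gt[keep],
                    zygosity = zyg[keep],
                    is_snv = nchar(ref[keep]) == 1 & nchar(alt[keep]) == 1 &
                      !grepl(",", alt[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(chrom_rank(out$chrom), out$pos), , drop = FALSE]
}

# genotype string -> zygosity; NA for missing / half calls
gt_zygosity <- function(gt) {
  al <- strsplit(ifelse(is.na(gt), ".", gt), "[/|]")
  vapply(al, function(a) {
    if (length(a) == 1 && a != ".") return("homozygous")  # hemizygous call
    if (length(a) != 2 || any(a == ".") || any(a == "")) return(NA_character_)
    if (a[1] == a[2]) "homozygous" else "heterozygous"
  }, character(1))
}

CHROM_ORDER <- paste0("chr", c(1:22, "X", "Y", "M"))

chrom_rank <- function(chrom) {
  r <- match(chrom, CHROM_ORDER)
  ifelse(is.na(r), length(CHROM_ORDER) + 1, r)
}

#' Write a single-sample VCF
#'
#' Emits a minimal well-formed VCF 4.2 text file (contig headers, PASS
#' filter, GT-only FORMAT) for the synthetic-specimen generator. Output is
#' readable by [read_vcf_variants()] and standard VCF tooling.
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `gt` (and optionally `filter`).
#' @param path Output path (`.vcf`).
#' @param sample Sample column name.
#' @param chrom_lengths Named numeric vector for `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_specimen_vcf <- function(variants, path, sample,
                               chrom_lengths = NULL) {
  ord <- order(chrom_rank(variants$chrom), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  filt <- if ("filter" %in% names(variants)) variants$filter else "PASS"
  hdr <- c("##fileformat=VCFv4.2",
           "##source=pwsasdx_synthetic_specimens",
           "##reference=GRCh37")
  chroms <- unique(variants$chrom)
  if (!is.null(chrom_lengths)) {
    chroms <- chroms[order(chrom_rank(chroms))]
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", chroms,
                          as.integer(chrom_lengths[chroms])))
  }
  hdr <- c(hdr,
           "##FILTER=<ID=PASS,Description=\"All filters passed\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample), collapse = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.\tGT\t%s",
                  variants$chrom, as.integer(variants$pos), variants$ref,
                  variants$alt, filt, variants$gt)
  writeLines(c(hdr, body), path)
  invisible(path)
}
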