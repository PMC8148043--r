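# Independent oracles and fixture builders. Oracles deliberately use naive
# element-by-element logic, not the implementation's vectorized paths.

# brute-force run-length scan over same-zygosity runs, splitting at the
# centromere by walking one variant at a time
rle_intervals_oracle <- function(obs, centromeres = NULL) {
  res <- list()
  for (ch in unique(obs$chrom)) {
    o <- obs[obs$chrom == ch, , drop = FALSE]
    o <- o[order(o$pos), , drop = FALSE]
    cs <- ce <- NULL
    if (!is.null(centromeres)) {
      i <- match(ch, centromeres$chrom)
      if (!is.na(i)) { cs <- centromeres$start[i]; ce <- centromeres$end[i] }
    }
    arm_of <- function(p) {
      if (is.null(cs)) return("p")
      if (p <= cs) return("p")
      if (p >= ce) return("q")
      if (p - cs <= ce - p) "p" else "q"
    }
    ign_pos <- o$pos[o$category == "ignored"]
    cur <- NULL
    flush <- function() {
      if (is.null(cur)) return()
      res[[length(res) + 1]] <<- data.frame(
        chrom = ch, start = cur$start, end = cur$end, zygosity = cur$zyg,
        n_variants = cur$n,
        n_ignored = sum(ign_pos >= cur$start & ign_pos <= cur$end),
        stringsAsFactors = FALSE)
    }
    for (j in seq_len(nrow(o))) {
      if (o$category[j] == "ignored") next
      key <- paste(o$category[j], arm_of(o$pos[j]))
      if (is.null(cur) || key != cur$key) {
        flush()
        cur <- list(key = key, start = o$pos[j], end = o$pos[j],
                    zyg = o$category[j], n = 1L)
      } else {
        cur$end <- o$pos[j]; cur$n <- cur$n + 1L
      }
    }
    flush()
  }
  if (length(res) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      zygosity = character(), n_variants = integer(),
                      n_ignored = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out[order(match(out$chrom, paste0("chr", c(1:22, "X"))), out$start), ,
      drop = FALSE]
}

stouffer_oracle <- function(z) abs(sum(z)) / sqrt(length(z))

# variant data frame in the shape read_vcf_variants() returns
mkvars <- function(chrom, pos, zygosity, is_snv = TRUE, filter = "PASS") {
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
             filter = filter, gt = ifelse(zygosity == "heterozygous", "0/1", "1/1"),
             zygosity = zygosity, is_snv = is_snv, stringsAsFactors = FALSE)
}

# hand-written VCF text fixture (independent of the package's writer)
write_toy_vcf <- function(path, rows, samples = "S1") {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  path
}

# coverage table builder: spec and comp are per-exon vectors / matrices
make_coverage <- function(spec, comp, gene = "SNRPN", chrom = "chr15",
                          start0 = 25200131, specimen = "SPEC") {
  n <- length(spec)
  comp <- as.matrix(comp)
  colnames(comp) <- sprintf("CMP%02d", seq_len(ncol(comp)))
  starts <- start0 + (seq_len(n) - 1) * 1000
  cbind(data.frame(gene = gene, exon = seq_len(n), chrom = chrom,
                   start = starts, end = starts + 149,
                   stringsAsFactors = FALSE),
        stats::setNames(data.frame(spec), specimen), as.data.frame(comp))
}

# ---- classifier stubs (module-result shaped objects for enumeration) ----
stub_mlpa <- function(pattern = "loss_of_paternal", cn_summary = "normal",
                      deleted_genes = character(),
                      duplicated_genes = character()) {
  structure(list(
    probe_states = NULL, cn_summary = cn_summary,
    deleted_genes = deleted_genes, duplicated_genes = duplicated_genes,
    methylation_pattern = pattern,
    methylation_probes = data.frame(gene = c("SNRPN", "MAGEL2"),
                                    value = c(90, 90)),
    params = list(del_threshold = 0.7, dup_threshold = 1.3)
  ), class = "mlpa_result")
}

stub_cnv <- function(status = "completed", extent = "none",
                     confirmation_required = TRUE, n_exons = 5) {
  segs <- if (extent %in% c("none", "duplication")) {
    data.frame(direction = character(), genes = character(),
               n_exons = integer(), combined_score = numeric(),
               extreme_ratio = numeric(), confirmation_required = logical())
  } else {
    data.frame(direction = "deletion", genes = "SNRPN", n_exons = n_exons,
               combined_score = 9, extreme_ratio = 0.5,
               confirmation_required = confirmation_required,
               stringsAsFactors = FALSE)
  }
  structure(list(status = status, records = NULL, segments = segs,
                 positive_segments = segs, extent_class = extent,
                 qc = list(pass = status == "completed",
                           reason = if (status == "cnv_fail")
                             "specimen median coverage 10.0x below 30x floor"
                           else NA_character_),
                 specimen = "STUB", params = list(min_combined = 5)),
            class = "cnv_result")
}

stub_aoh <- function(positive = FALSE, upd = FALSE, extent = "segmental",
                     consanguinity = FALSE, het_count = 42) {
  structure(list(
    critical_region_het_count = if (positive) 1 else het_count,
    critical_region_positive = positive,
    aoh_blocks_15q = data.frame(), largest_block_mb = if (upd) 12 else 0,
    genomewide_blocks = data.frame(),
    consanguinity_flag = consanguinity, upd_consistent = upd,
    isodisomy_extent = if (upd) list(extent = extent, fraction = 0.2,
                                     n_segments = 1) else NULL,
    intervals = NULL, counts = NULL, methylation = "abnormal",
    notes = character(),
    params = list(reporting_floor_mb = 1.5, loh_mb = 5)
  ), class = "aoh_assessment")
}
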