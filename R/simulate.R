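#' Simulation recipe for a synthetic specimen
#'
#' Defines the study conditions a synthetic specimen bundle is generated
#' under. Printed control statistics anchor the model: the critical-region
#' heterozygous-SNV count is drawn from normal(42.5, 12.76), rounded, and
#' floored at 16 (the observed control minimum); a hemizygous deletion
#' halves coverage (ratio 0.5) and a gain raises it to 1.5; methylation
#' probes emit band midpoints with +/-5 jitter (PWS 90, normal 50, AS 10);
#' per-exon coverage noise is multiplicative normal with SD 0.05. Identical
#' (recipe, seed) pairs produce byte-identical bundles.
#'
#' @param mechanism_class One of `"type_I_deletion"`, `"type_II_deletion"`,
#'   `"atypical_deletion"`, `"segmental_isodisomy_UPD"`,
#'   `"total_isodisomy_UPD"`, `"heterodisomy_UPD"`, `"epimutation"`,
#'   `"IC_microdeletion"`, `"control"`, `"consanguinity"`.
#' @param seed Integer seed.
#' @param specimen_id Specimen label (default derived from class and seed).
#' @param sex `"46,XX"`, `"46,XY"`, or `NULL` to draw one.
#' @param syndrome `"PWS"` (loss of the paternal allele) or `"AS"`; ignored
#'   for controls.
#' @param het_mean,het_sd,het_floor Critical-region heterozygous-count
#'   model.
#' @param coverage_noise_sd Multiplicative per-exon coverage noise SD.
#' @param deletion_ratio,duplication_ratio Coverage ratios emitted over
#'   deleted/duplicated spans.
#' @param meth_jitter Half-width of the uniform jitter around methylation
#'   band midpoints.
#' @param n_comparators Batch comparator count (default 8).
#' @param cnv_fail Emit degraded specimen coverage so the CNV QC gate
#'   fails (archival-DNA emulation).
#' @return An object of class `simulation_recipe`.
#' @export
simulation_recipe <- function(mechanism_class, seed, specimen_id = NULL,
                              sex = NULL, syndrome = "PWS",
                              het_mean = 42.5, het_sd = 12.76,
                              het_floor = 16, coverage_noise_sd = 0.05,
                              deletion_ratio = 0.5, duplication_ratio = 1.5,
                              meth_jitter = 5, n_comparators = 8,
                              cnv_fail = FALSE) {
  classes <- c("type_I_deletion", "type_II_deletion", "atypical_deletion",
               "segmental_isodisomy_UPD", "total_isodisomy_UPD",
               "heterodisomy_UPD", "epimutation", "IC_microdeletion",
               "control", "consanguinity")
  if (!(mechanism_class %in% classes)) {
    stop("unknown mechanism class: ", mechanism_class)
  }
  syndrome <- match.arg(syndrome, c("PWS", "AS"))
  if (is.null(specimen_id)) {
    # opaque label: the truth class is never leaked into emitted files
    specimen_id <- sprintf("SPEC%09d",
                           derive_seed(seed, match(mechanism_class, classes)))
  }
  structure(list(mechanism_class = mechanism_class, seed = as.integer(seed),
                 specimen_id = specimen_id, sex = sex, syndrome = syndrome,
                 het_mean = het_mean, het_sd = het_sd, het_floor = het_floor,
                 coverage_noise_sd = coverage_noise_sd,
                 deletion_ratio = deletion_ratio,
                 duplication_ratio = duplication_ratio,
                 meth_jitter = meth_jitter, n_comparators = n_comparators,
                 cnv_fail = cnv_fail),
            class = "simulation_recipe")
}

# mechanism the pipeline is expected to call for each truth class
#' Expected pipeline mechanism for a truth class
#'
#' Heterodisomy and epimutation specimens are molecularly distinct but are
#' both expected to yield the indeterminate heterodisomy-or-epimutation
#' disjunction (distinguishing them requires parental genotyping); controls
#' and consanguinity specimens are expected negative.
#'
#' @param mechanism_class A generator truth class.
#' @return The expected `mechanism_call` mechanism string.
#' @export
expected_mechanism <- function(mechanism_class) {
  switch(mechanism_class,
         heterodisomy_UPD = ,
         epimutation = "heterodisomy_or_IC_epimutation",
         control = ,
         consanguinity = "negative",
         mechanism_class)
}

# capture-design exon counts per registry gene (synthetic design; single-exon
# genes MKRN3/MAGEL2/NDN/NPAP1 mirror their real intronless structure)
EXON_COUNTS <- c(TUBGCP5 = 15, CYFIP1 = 17, NIPA2 = 6, NIPA1 = 5,
                 MKRN3 = 1, MAGEL2 = 1, NDN = 1, NPAP1 = 1, SNRPN = 10,
                 UBE3A = 12, ATP10A = 20, GABRA5 = 9, GABRG3 = 9,
                 OCA2 = 24, HERC2 = 30, APBA2 = 12)

# exon design table for the coverage simulator: the 15q11-q13 panel genes
# plus a whole-exome backbone of background targets on other chromosomes
# (the intra-specimen median must come from copy-neutral territory even
# when the full BP1-BP3 region is deleted, as it does in a real exome)
exon_design <- function(registry) {
  g <- registry$genes
  rows <- lapply(seq_len(nrow(g)), function(i) {
    n <- EXON_COUNTS[[g$gene[i]]]
    starts <- round(seq(g$start[i], g$end[i] - 150, length.out = n))
    data.frame(gene = g$gene[i], exon = seq_len(n), chrom = g$chrom[i],
               start = starts, end = starts + 149, stringsAsFactors = FALSE)
  })
  bg_chroms <- setdiff(names(registry$chrom_lengths), c("chr15", "chrX"))
  bg <- lapply(seq_along(bg_chroms), function(i) {
    # 60 exons per background chromosome keep the 15q panel a small
    # fraction of the design, as it is of a real exome, so the specimen
    # median stays anchored in copy-neutral territory
    starts <- 40e6 + (0:59) * 5e4
    data.frame(gene = sprintf("BG%02d", i), exon = 1:60,
               chrom = bg_chroms[i], start = starts, end = starts + 149,
               stringsAsFactors = FALSE)
  })
  rbind(do.call(rbind, rows), do.call(rbind, bg))
}

# simulated event spans (chrom/start/end + type) for a mechanism class
class_event_spans <- function(class, registry) {
  bp <- registry$breakpoints
  len15 <- registry$chrom_lengths[["chr15"]]
  q15 <- q_arm_start(registry, "chr15")
  span <- function(chrom, s, e, type) {
    data.frame(chrom = chrom, start = s, end = e, type = type,
               stringsAsFactors = FALSE)
  }
  switch(class,
    type_I_deletion = span("chr15", bp[["BP1"]], bp[["BP3"]], "deletion"),
    type_II_deletion = span("chr15", bp[["BP2"]], bp[["BP3"]], "deletion"),
    atypical_deletion = span("chr15", 23850000, 25750000, "deletion"),
    IC_microdeletion = span("chr15", 25200019, 25223890, "deletion"),
    segmental_isodisomy_UPD = span("chr15", 21200000, 33600000, "isodisomy"),
    total_isodisomy_UPD = span("chr15", q15, len15, "isodisomy"),
    consanguinity = rbind(span("chr2", 60e6, 69e6, "isodisomy"),
                          span("chr7", 80e6, 89e6, "isodisomy"),
                          span("chr15", 34e6, 43e6, "isodisomy")),
    NULL)
}

in_spans <- function(chrom, pos, spans) {
  if (is.null(spans)) return(rep(FALSE, length(pos)))
  points_in_intervals(chrom, pos, spans)
}

#' Generate one synthetic specimen bundle
#'
#' Emits a class-consistent bundle: a single-sample VCF (GRCh37,
#' genome-wide thinned variant set), a per-exon coverage table with batch
#' comparators, an MS-MLPA probe table, and a metadata file. Deletions
#' produce hemizygous coverage over the deleted span with no heterozygous
#' variants inside it; isodisomy produces copy-neutral homozygous-only
#' spans; heterodisomy/epimutation produce normal zygosity and copy number
#' with abnormal methylation; controls are normal throughout with
#' critical-region heterozygous counts from the control model.
#'
#' @param recipe A `simulation_recipe`.
#' @param dir Output directory (a per-specimen subdirectory is created).
#' @param registry A `region_registry` (default if `NULL`).
#' @return A `specimen_bundle`: list with `specimen_id`, `truth_class`,
#'   `seed`, `sex`, `syndrome` and file paths `vcf`, `coverage`, `mlpa`,
#'   `meta`.
#' @export
generate_specimen <- function(recipe, dir = tempfile("specimen_"),
                              registry = NULL) {
  stopifnot(inherits(recipe, "simulation_recipe"))
  if (is.null(registry)) registry <- load_region_registry()
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(recipe$seed)

  sex <- recipe$sex
  if (is.null(sex)) sex <- sample(c("46,XX", "46,XY"), 1)
  spans <- class_event_spans(recipe$mechanism_class, registry)
  del_spans <- spans[!is.null(spans) & spans$type == "deletion", , drop = FALSE]
  event_spans <- spans  # both deletion and isodisomy spans are het-free

  variants <- simulate_variants(recipe, registry, sex, event_spans)
  coverage <- simulate_coverage(recipe, registry, del_spans)
  mlpa <- simulate_mlpa(recipe, registry, del_spans)

  out_dir <- file.path(dir, recipe$specimen_id)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(out_dir, paste0(recipe$specimen_id, ".vcf")),
    coverage = file.path(out_dir, paste0(recipe$specimen_id, "_coverage.tsv")),
    mlpa = file.path(out_dir, paste0(recipe$specimen_id, "_mlpa.tsv")),
    meta = file.path(out_dir, paste0(recipe$specimen_id, "_meta.tsv")))
  write_specimen_vcf(variants, paths$vcf, recipe$specimen_id,
                     registry$chrom_lengths)
  utils::write.table(coverage, paths$coverage, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(mlpa, paths$mlpa, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(specimen_id = recipe$specimen_id,
                                sex_karyotype = sex,
                                stringsAsFactors = FALSE),
                     paths$meta, sep = "\t", quote = FALSE, row.names = FALSE)
  structure(c(list(specimen_id = recipe$specimen_id,
                   truth_class = recipe$mechanism_class,
                   seed = recipe$seed, sex = sex,
                   syndrome = recipe$syndrome), paths),
            class = "specimen_bundle")
}

# genome-wide thinned variant set; density and zygosity mix are invented
# (calibrated so chance runs of homozygosity >= 5 Mb stay rare at the
# thinned marker density; see the methods vignette)
simulate_variants <- function(recipe, registry, sex, event_spans) {
  cen <- registry$centromeres
  lens <- registry$chrom_lengths
  cr <- registry$critical_region
  out <- list()
  base_pair <- function(n) {
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt_shift <- sample(1:3, n, replace = TRUE)
    bases <- c("A", "C", "G", "T")
    alt <- bases[(match(ref, bases) + alt_shift - 1) %% 4 + 1]
    list(ref = ref, alt = alt)
  }
  add <- function(chrom, pos, zyg) {
    n <- length(pos)
    if (n == 0) return()
    ba <- base_pair(n)
    out[[length(out) + 1]] <<- data.frame(
      chrom = chrom, pos = pos, ref = ba$ref, alt = ba$alt,
      gt = ifelse(zyg == "het", "0/1", "1/1"), stringsAsFactors = FALSE)
  }
  draw_pos <- function(chrom, n, lo, hi, exclude = NULL) {
    pos <- sort(sample.int(hi - lo + 1, n)) + lo - 1
    i <- match(chrom, cen$chrom)
    if (!is.na(i)) pos <- pos[pos < cen$start[i] | pos > cen$end[i]]
    if (!is.null(exclude)) {
      pos <- pos[!(pos >= exclude$start & pos <= exclude$end)]
    }
    pos
  }

  for (chrom in names(lens)) {
    len <- lens[[chrom]]
    if (chrom == "chr15") {
      q15 <- q_arm_start(registry, "chr15")
      # critical-region heterozygous SNVs from the control count model
      n_het <- max(recipe$het_floor,
                   round(stats::rnorm(1, recipe$het_mean, recipe$het_sd)))
      het_pos <- sort(sample.int(cr$end - cr$start + 1, n_het)) + cr$start - 1
      hom_pos <- sort(sample.int(cr$end - cr$start + 1, 8)) + cr$start - 1
      # 15q background outside the critical region
      bg <- draw_pos("chr15", 350, q15 + 100000, len, exclude = cr)
      bg_zyg <- ifelse(stats::runif(length(bg)) < 0.8, "het", "hom")
      ev <- event_spans[!is.null(event_spans) &
                          event_spans$chrom == "chr15", , drop = FALSE]
      if (!is.null(ev) && nrow(ev) > 0) {
        het_pos <- het_pos[!in_spans("chr15", het_pos, ev)]
        hom_pos <- hom_pos[!in_spans("chr15", hom_pos, ev)]
        bg_zyg[in_spans("chr15", bg, ev)] <- "hom"
        # dense homozygous support over each simulated event span
        for (k in seq_len(nrow(ev))) {
          n_ev <- max(20, round((ev$end[k] - ev$start[k]) / 250000))
          ev_pos <- sort(sample.int(ev$end[k] - ev$start[k] + 1, n_ev)) +
            ev$start[k] - 1
          add("chr15", ev_pos, rep("hom", length(ev_pos)))
        }
      }
      add("chr15", het_pos, rep("het", length(het_pos)))
      add("chr15", hom_pos, rep("hom", length(hom_pos)))
      add("chr15", bg, bg_zyg)
      # a few variants inside the segmental-duplication mask: emitted, but
      # the detector must ignore them
      msk <- registry$segdup_mask
      if (nrow(msk) > 0) {
        for (k in seq_len(nrow(msk))) {
          mpos <- round(seq(msk$start[k], msk$end[k], length.out = 2))
          in_ev <- in_spans(msk$chrom[k], mpos, ev)
          mz <- ifelse(in_ev, "hom",
                       ifelse(stats::runif(length(mpos)) < 0.5, "het", "hom"))
          add(msk$chrom[k], mpos, mz)
        }
      }
    } else if (chrom == "chrX") {
      n <- round(len / 1e6 * 0.9)
      pos <- draw_pos(chrom, n, 1, len)
      if (identical(sex, "46,XY")) {
        add(chrom, pos, rep("hom", length(pos)))  # hemizygous calls
      } else {
        add(chrom, pos, ifelse(stats::runif(length(pos)) < 0.9, "het", "hom"))
      }
    } else {
      n <- round(len / 1e6 * 1.1)
      pos <- draw_pos(chrom, n, 1, len)
      zyg <- ifelse(stats::runif(length(pos)) < 0.9, "het", "hom")
      ev <- event_spans[!is.null(event_spans) &
                          event_spans$chrom == chrom, , drop = FALSE]
      if (!is.null(ev) && nrow(ev) > 0) {
        zyg[in_spans(chrom, pos, ev)] <- "hom"
        for (k in seq_len(nrow(ev))) {
          n_ev <- max(20, round((ev$end[k] - ev$start[k]) / 250000))
          ev_pos <- sort(sample.int(ev$end[k] - ev$start[k] + 1, n_ev)) +
            ev$start[k] - 1
          add(chrom, ev_pos, rep("hom", length(ev_pos)))
        }
      }
      add(chrom, pos, zyg)
    }
  }
  v <- do.call(rbind, out)
  v <- v[!duplicated(v[c("chrom", "pos")]), , drop = FALSE]
  v$filter <- "PASS"
  v[order(chrom_rank(v$chrom), v$pos), , drop = FALSE]
}

simulate_coverage <- function(recipe, registry, del_spans) {
  design <- exon_design(registry)
  n_ex <- nrow(design)
  baseline <- stats::rlnorm(n_ex, meanlog = log(100), sdlog = 0.25)
  mult_noise <- function() 1 + stats::rnorm(n_ex, 0, recipe$coverage_noise_sd)
  comp <- vapply(seq_len(recipe$n_comparators), function(j) {
    scale_j <- stats::runif(1, 0.8, 1.2)  # library-size differences
    pmax(0, baseline * scale_j * mult_noise())
  }, numeric(n_ex))
  colnames(comp) <- sprintf("CMP%02d", seq_len(recipe$n_comparators))

  ratio <- rep(1, n_ex)
  if (!is.null(del_spans) && nrow(del_spans) > 0) {
    deleted <- rep(FALSE, n_ex)
    for (k in seq_len(nrow(del_spans))) {
      deleted <- deleted | (design$chrom == del_spans$chrom[k] &
                              design$start >= del_spans$start[k] &
                              design$end <= del_spans$end[k])
    }
    ratio[deleted] <- recipe$deletion_ratio
  }
  spec_scale <- if (recipe$cnv_fail) 0.12 else stats::runif(1, 0.9, 1.1)
  spec <- pmax(0, baseline * ratio * spec_scale * mult_noise())

  tab <- cbind(design, stats::setNames(data.frame(spec), recipe$specimen_id),
               as.data.frame(comp))
  tab[[recipe$specimen_id]] <- round(tab[[recipe$specimen_id]], 2)
  for (s in colnames(comp)) tab[[s]] <- round(tab[[s]], 2)
  tab
}

simulate_mlpa <- function(recipe, registry, del_spans) {
  panel <- read_mlpa_table(system.file("extdata", "mlpa_panel_synthetic.tsv",
                                       package = "pwsasdx"))
  is_cn <- panel$kind == "copy_number"
  deleted <- rep(FALSE, nrow(panel))
  if (!is.null(del_spans) && nrow(del_spans) > 0) {
    for (k in seq_len(nrow(del_spans))) {
      deleted <- deleted | (panel$chrom == del_spans$chrom[k] &
                              panel$start >= del_spans$start[k] &
                              panel$end <= del_spans$end[k])
    }
  }
  cn_mid <- ifelse(deleted, 0.5, 1.0)
  value <- numeric(nrow(panel))
  value[is_cn] <- round(cn_mid[is_cn] + stats::rnorm(sum(is_cn), 0, 0.04), 3)

  abnormal <- !(recipe$mechanism_class %in% c("control", "consanguinity"))
  meth_mid <- if (!abnormal) 50 else if (recipe$syndrome == "PWS") 90 else 10
  n_meth <- sum(!is_cn)
  value[!is_cn] <- round(meth_mid + stats::runif(n_meth, -recipe$meth_jitter,
                                                 recipe$meth_jitter), 2)
  panel$value <- value
  panel
}

#' @export
print.specimen_bundle <- function(x, ...) {
  cat(sprintf("Synthetic specimen %s (truth: %s, %s, seed %d)\n",
              x$specimen_id, x$truth_class, x$sex, x$seed))
  cat("  files:", x$vcf, "\n        ", x$coverage, "\n        ", x$mlpa, "\n")
  invisible(x)
}

#' Generate the 28-specimen validation cohort
#'
#' Emits a cohort with the validation composition: 4 type I deletions,
#' 5 type II deletions, 5 segmental isodisomy 15, 5 heterodisomy 15,
#' 5 total isodisomy 15, 2 imprinting-center microdeletions, and 2
#' non-deletion (epimutation) imprinting-center specimens (4+5+5+5+5+2+2 =
#' 28, all PWS; 12 male / 16 female). Per-specimen seeds derive
#' deterministically from `base_seed`. By default five specimens (three
#' total-isodisomy, two heterodisomy) are emitted with degraded coverage so
#' the CNV QC gate fails, reproducing the archival-DNA failure pattern.
#'
#' @param base_seed Integer seed for the cohort.
#' @param dir Output directory.
#' @param registry A `region_registry` (default if `NULL`).
#' @param inject_cnv_fail Emit the 5-specimen CNV-fail pattern (default
#'   `TRUE`).
#' @return List with `bundles` (28 `specimen_bundle`s), `manifest` (data
#'   frame), `manifest_path`.
#' @export
generate_validation_cohort <- function(base_seed, dir = tempfile("cohort_"),
                                   registry = NULL, inject_cnv_fail = TRUE) {
  if (is.null(registry)) registry <- load_region_registry()
  classes <- c(rep("type_I_deletion", 4), rep("type_II_deletion", 5),
               rep("segmental_isodisomy_UPD", 5), rep("heterodisomy_UPD", 5),
               rep("total_isodisomy_UPD", 5), rep("IC_microdeletion", 2),
               rep("epimutation", 2))
  fail_idx <- integer()
  if (inject_cnv_fail) {
    tot <- which(classes == "total_isodisomy_UPD")[1:3]
    het <- which(classes == "heterodisomy_UPD")[1:2]
    fail_idx <- c(tot, het)
  }
  sexes <- rep(c("46,XY", "46,XX"), length.out = 28)
  sexes[25:28] <- "46,XX"  # 12 male / 16 female
  bundles <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    seed_i <- derive_seed(base_seed, i)
    rec <- simulation_recipe(classes[i], seed = seed_i,
                             specimen_id = sprintf("S%02d", i),
                             sex = sexes[i], cnv_fail = i %in% fail_idx)
    bundles[[i]] <- generate_specimen(rec, dir, registry)
  }
  manifest <- data.frame(
    specimen_id = vapply(bundles, `[[`, "", "specimen_id"),
    truth_class = vapply(bundles, `[[`, "", "truth_class"),
    seed = vapply(bundles, `[[`, 0L, "seed"),
    sex = vapply(bundles, `[[`, "", "sex"),
    cnv_fail = seq_along(classes) %in% fail_idx,
    stringsAsFactors = FALSE)
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(bundles = bundles, manifest = manifest, manifest_path = manifest_path)
}

#' Generate a control cohort
#'
#' @param n Number of control specimens.
#' @param seed Base seed.
#' @param dir Output directory.
#' @param registry A `region_registry` (default if `NULL`).
#' @return List with `bundles`, `manifest`, `manifest_path`.
#' @export
generate_control_cohort <- function(n, seed, dir = tempfile("controls_"),
                                    registry = NULL) {
  stopifnot(n >= 1)
  if (is.null(registry)) registry <- load_region_registry()
  bundles <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- simulation_recipe("control", seed = derive_seed(seed, i),
                             specimen_id = sprintf("CTRL%04d", i))
    bundles[[i]] <- generate_specimen(rec, dir, registry)
  }
  manifest <- data.frame(
    specimen_id = vapply(bundles, `[[`, "", "specimen_id"),
    truth_class = "control",
    seed = vapply(bundles, `[[`, 0L, "seed"),
    sex = vapply(bundles, `[[`, "", "sex"),
    stringsAsFactors = FALSE)
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(bundles = bundles, manifest = manifest, manifest_path = manifest_path)
}

# deterministic per-specimen seed below 2^31
derive_seed <- function(base_seed, i) {
  as.integer((as.numeric(base_seed) * 1009 + 7919 * as.numeric(i)) %%
               2147483629 + 1)
}
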