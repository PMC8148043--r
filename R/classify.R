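#' Construct small-variant findings
#'
#' Holds user-supplied pathogenicity assertions for sequence variants in
#' the workflow's genes (SNRPN, UBE3A, MAGEL2, ...). Classification is
#' metadata provided by upstream variant interpretation; no assertion logic
#' is performed here.
#'
#' @param gene Gene symbol(s).
#' @param classification `"pathogenic"`, `"likely_pathogenic"`, or
#'   `"other"`.
#' @param zygosity Optional zygosity annotation.
#' @return Data frame with columns `gene`, `classification`, `zygosity`.
#' @export
small_variant_finding <- function(gene, classification = "other",
                                  zygosity = NA_character_) {
  classification <- match.arg(classification,
                              c("pathogenic", "likely_pathogenic", "other"),
                              several.ok = TRUE)
  data.frame(gene = gene, classification = classification,
             zygosity = zygosity, stringsAsFactors = FALSE)
}

MECHANISMS <- c("type_I_deletion", "type_II_deletion", "atypical_deletion",
                "segmental_isodisomy_UPD", "total_isodisomy_UPD",
                "heterodisomy_or_IC_epimutation", "IC_microdeletion",
                "point_mutation", "negative")

#' Integrate module evidence into a mechanism call
#'
#' Implements the streamlined decision logic: MS-MLPA first (methylation
#' status and MLPA copy number are step 1 and mandatory), then the exome
#' evidence (CNV, AOH, small variants).
#'
#' With normal methylation, only a supplied pathogenic or likely-pathogenic
#' sequence variant makes a diagnosis (SNRPN for PWS, UBE3A for AS); a
#' pathogenic MAGEL2 variant is surfaced as a caveat (possible Schaaf-Yang
#' syndrome if paternally defective); otherwise the specimen is negative.
#'
#' With abnormal methylation the syndrome follows the parent-of-origin
#' pattern (loss of the paternal allele = PWS, maternal = AS) and the
#' mechanism is resolved in order: a multi-gene 15q11-q13 deletion (exome
#' CNV confirmed by MLPA copy number, or MLPA copy number alone when the
#' CNV arm failed QC) gives the deletion class by extent; a deletion
#' confined to SNRPN gives the imprinting-center microdeletion; with no
#' deletion, a UPD-consistent AOH signal gives segmental or total isodisomy
#' 15; with no deletion and negative AOH the call is the indeterminate
#' disjunction heterodisomy-or-epimutation (distinguishing them requires
#' parental genotyping of chromosome 15 markers, which is outside this
#' workflow and recorded as a caveat). Because MLPA is the designated
#' orthogonal confirmer and the NGS CNV arm has low positive predictive
#' value for short calls (about 45% for deletions, 34% for duplications),
#' exome CNV segments that still require confirmation and are discordant
#' with MLPA copy number are downgraded to caveats. AOH positivity inside a
#' confirmed deletion is attributed to hemizygosity, not UPD.
#'
#' @param mlpa An `mlpa_result` (mandatory; step 1 of the workflow).
#' @param cnv A `cnv_result`, or `NULL` if the exome CNV arm was not run.
#' @param aoh An `aoh_assessment`, or `NULL` (caveated).
#' @param variants A data frame from [small_variant_finding()], or `NULL`.
#' @param meta Optional list/row with `specimen_id` and `sex_karyotype`.
#' @param registry A `region_registry` (default registry if `NULL`).
#' @return An object of class `mechanism_call` with `syndrome` (`PWS`,
#'   `AS`, `none`, `indeterminate`), `mechanism`, `parental_origin` (the
#'   defective allele: `paternal` for PWS, `maternal` for AS, `n/a`),
#'   `label` (result vocabulary string), `evidence` (ordered trail), and
#'   `caveats`.
#' @export
classify_mechanism <- function(mlpa, cnv = NULL, aoh = NULL, variants = NULL,
                               meta = NULL, registry = NULL) {
  if (is.null(mlpa) || !inherits(mlpa, "mlpa_result")) {
    stop("MS-MLPA result is required: the workflow cannot start without step 1")
  }
  if (is.null(registry)) registry <- load_region_registry()

  evidence <- character()
  caveats <- character()
  ev <- function(...) evidence <<- c(evidence, sprintf(...))
  cv <- function(...) caveats <<- c(caveats, sprintf(...))

  meth <- mlpa$methylation_pattern
  ev("MS-MLPA methylation pattern: %s", meth)
  ev("MS-MLPA copy-number summary: %s%s", mlpa$cn_summary,
     if (length(mlpa$deleted_genes) > 0)
       paste0(" (deleted: ", paste(mlpa$deleted_genes, collapse = ", "), ")")
     else "")

  cnv_failed <- is.null(cnv) || cnv$status == "cnv_fail"
  if (is.null(cnv)) {
    cv("WES evidence absent: CNV arm not run")
  } else if (cnv$status == "cnv_fail") {
    cv("Not tested (CNV fail): %s", cnv$qc$reason)
    ev("WES CNV: fail (%s)", cnv$qc$reason)
  } else {
    ev("WES CNV extent class: %s (%d positive segment(s))",
       cnv$extent_class, nrow(cnv$positive_segments))
  }
  if (is.null(aoh)) {
    cv("AOH evidence absent")
  } else {
    ev("AOH: %d heterozygous SNV(s) in critical region (%s); UPD-consistent LOH: %s",
       aoh$critical_region_het_count,
       if (aoh$critical_region_positive) "positive" else "negative",
       aoh$upd_consistent)
    if (aoh$consanguinity_flag) {
      cv("Genome-wide homozygosity on multiple autosomes: consanguinity suspected")
    }
  }

  syndrome <- "none"; mechanism <- "negative"; origin <- "n/a"

  if (meth == "uninterpretable") {
    syndrome <- "indeterminate"
    cv("Methylation pattern uninterpretable; repeat MS-MLPA advised")
    if (mlpa$cn_summary != "normal") {
      cv("MLPA copy-number abnormality (%s) present but methylation is uninterpretable",
         mlpa$cn_summary)
    }
    return(finish_call(syndrome, mechanism, origin, evidence, caveats, meta))
  }

  if (meth == "normal") {
    # scenario: point mutations only; deletions with normal methylation are
    # not PWS/AS mechanisms
    if (!cnv_failed && nrow(cnv$positive_segments) > 0) {
      cv("WES CNV segment(s) with normal methylation pattern: not a PWS/AS imprinting mechanism; independent follow-up may be warranted")
    }
    if (mlpa$cn_summary != "normal") {
      cv("MLPA copy-number abnormality (%s) with normal methylation pattern",
         mlpa$cn_summary)
    }
    pg <- if (is.null(variants)) NULL else
      variants[variants$classification %in% c("pathogenic", "likely_pathogenic"), ,
               drop = FALSE]
    if (!is.null(pg) && nrow(pg) > 0) {
      if ("SNRPN" %in% pg$gene) {
        syndrome <- "PWS"; mechanism <- "point_mutation"; origin <- "paternal"
        ev("Pathogenic SNRPN sequence variant supplied")
      } else if ("UBE3A" %in% pg$gene) {
        syndrome <- "AS"; mechanism <- "point_mutation"; origin <- "maternal"
        ev("Pathogenic UBE3A sequence variant supplied")
      } else if ("MAGEL2" %in% pg$gene) {
        cv("Pathogenic MAGEL2 variant: possible Schaaf-Yang syndrome if paternally defective")
      } else {
        cv("Pathogenic variant(s) outside the PWS/AS genes supplied: %s",
           paste(unique(pg$gene), collapse = ", "))
      }
    }
    if (!is.null(variants)) {
      other <- variants[!(variants$classification %in%
                            c("pathogenic", "likely_pathogenic")), , drop = FALSE]
      if (nrow(other) > 0) {
        cv("Variant(s) of other classification not used for diagnosis: %s",
           paste(unique(other$gene), collapse = ", "))
      }
    }
    return(finish_call(syndrome, mechanism, origin, evidence, caveats, meta))
  }

  # abnormal methylation: loss_of_paternal (PWS) or loss_of_maternal (AS)
  syndrome <- if (meth == "loss_of_paternal") "PWS" else "AS"
  origin <- if (syndrome == "PWS") "paternal" else "maternal"

  # deletion evidence, MLPA copy number as the orthogonal authority
  mlpa_cn <- mlpa$cn_summary
  del <- resolve_deletion(mlpa_cn, mlpa$deleted_genes, cnv, cnv_failed,
                          registry, cv, ev)

  if (identical(del$kind, "multi")) {
    mechanism <- del$extent
    if (!is.null(aoh) && aoh$critical_region_positive) {
      ev("Critical-region AOH attributed to hemizygosity over the deletion, not UPD")
    }
  } else if (identical(del$kind, "snrpn")) {
    mechanism <- "IC_microdeletion"
  } else if (identical(del$kind, "single")) {
    mechanism <- "atypical_deletion"
    ev("Single-gene 15q11-q13 deletion (%s) with abnormal methylation",
       paste(del$genes, collapse = ", "))
  } else {
    # no confirmed deletion: AOH decides isodisomy vs the indeterminate
    # heterodisomy/epimutation disjunction
    if (mlpa_cn == "duplication") {
      cv("MLPA copy-number duplication with abnormal methylation: atypical signal, not a recognized PWS/AS deletion mechanism")
    }
    if (!is.null(aoh) && aoh$upd_consistent) {
      extent <- aoh$isodisomy_extent$extent
      mechanism <- if (extent == "total") "total_isodisomy_UPD" else "segmental_isodisomy_UPD"
      ev("LOH consistent with %s isodisomy 15 (%d segment(s), %.1f Mb largest)",
         extent, aoh$isodisomy_extent$n_segments, aoh$largest_block_mb)
    } else {
      mechanism <- "heterodisomy_or_IC_epimutation"
      cv("Heterodisomy and imprinting-center epimutation are indistinguishable without parental DNA: genotyping of chromosome 15 markers using parental DNA would determine whether biparental inheritance is present")
    }
  }
  finish_call(syndrome, mechanism, origin, evidence, caveats, meta)
}

# deletion-evidence resolution shared by the classifier; returns
# list(kind = "multi"/"snrpn"/"single"/"none", extent, genes)
resolve_deletion <- function(mlpa_cn, mlpa_del_genes, cnv, cnv_failed,
                             registry, cv, ev) {
  cnv_extent <- if (cnv_failed) "none" else cnv$extent_class
  cnv_multi <- cnv_extent %in% c("type_I_deletion", "type_II_deletion",
                                 "atypical_deletion")
  if (mlpa_cn == "deletion_multi_gene") {
    extent <- if (cnv_multi) {
      ev("Multi-gene deletion: WES CNV (%s) confirmed by MLPA copy number",
         cnv_extent)
      cnv_extent
    } else {
      e <- extent_from_genes(mlpa_del_genes, registry)
      if (cnv_failed) {
        ev("Multi-gene deletion by MLPA copy number alone (CNV arm unavailable); extent from deleted MLPA probes: %s", e)
      } else {
        ev("Multi-gene deletion by MLPA copy number; WES CNV discordant; extent from deleted MLPA probes: %s", e)
      }
      if (!(e %in% c("type_I_deletion", "type_II_deletion"))) "atypical_deletion" else e
    }
    return(list(kind = "multi", extent = extent, genes = mlpa_del_genes))
  }
  if (mlpa_cn == "deletion_snrpn_only") {
    if (identical(cnv_extent, "snrpn_only_deletion")) {
      ev("SNRPN-confined deletion: WES CNV confirmed by MLPA copy number")
    } else {
      ev("SNRPN-confined deletion by MLPA copy number")
    }
    return(list(kind = "snrpn", genes = "SNRPN"))
  }
  if (mlpa_cn == "deletion_single_gene") {
    return(list(kind = "single", genes = mlpa_del_genes))
  }
  # MLPA copy number normal (or duplication): any WES deletion claim is
  # unconfirmed; MLPA wins, per the low NGS-CNV PPV
  if (cnv_multi || identical(cnv_extent, "snrpn_only_deletion") ||
      identical(cnv_extent, "single_gene")) {
    segs <- cnv$positive_segments
    unconfirmed <- is.null(segs) || all(segs$confirmation_required)
    cv("WES CNV deletion call (%s) discordant with normal MLPA copy number: %s",
       cnv_extent,
       if (unconfirmed)
         "downgraded pending orthogonal confirmation (NGS CNV positive predictive value is low for short calls)"
       else
         "not confirmed by MLPA; MLPA copy number takes precedence")
  }
  list(kind = "none")
}

finish_call <- function(syndrome, mechanism, origin, evidence, caveats, meta) {
  structure(list(
    specimen_id = if (!is.null(meta) && !is.null(meta$specimen_id))
      meta$specimen_id else NA_character_,
    syndrome = syndrome,
    mechanism = mechanism,
    parental_origin = origin,
    label = mechanism_label(syndrome, mechanism),
    evidence = evidence,
    caveats = caveats
  ), class = "mechanism_call")
}

# result vocabulary strings matching clinical reporting usage
mechanism_label <- function(syndrome, mechanism) {
  if (mechanism == "negative") return("Negative")
  upd_parent <- if (syndrome == "PWS") "maternal" else "paternal"
  upd_prefix <- if (syndrome == "PWS") "M" else "P"
  del_parent <- if (syndrome == "PWS") "paternal" else "maternal"
  switch(mechanism,
    type_I_deletion = sprintf("Type I deletion, %s", del_parent),
    type_II_deletion = sprintf("Type II deletion, %s", del_parent),
    atypical_deletion = sprintf("Atypical 15q11-q13 deletion, %s", del_parent),
    segmental_isodisomy_UPD = sprintf("Segmental %s isodisomy 15, i-UPD", upd_parent),
    total_isodisomy_UPD = sprintf("Total %s isodisomy 15, i-UPD", upd_parent),
    heterodisomy_or_IC_epimutation = sprintf("%s-het-UPD or ICD (epimutation)", upd_prefix),
    IC_microdeletion = "ICD (deletion of SNRPN)",
    point_mutation = sprintf("Point mutation, %s", syndrome),
    mechanism)
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat("Mechanism call")
  if (!is.na(x$specimen_id)) cat(" for", x$specimen_id)
  cat("\n")
  cat(sprintf("  syndrome: %s; mechanism: %s; defective allele: %s\n",
              x$syndrome, x$mechanism, x$parental_origin))
  cat(sprintf("  result: %s\n", x$label))
  if (length(x$evidence) > 0) {
    cat("  evidence:\n")
    for (e in x$evidence) cat("    -", e, "\n")
  }
  if (length(x$caveats) > 0) {
    cat("  caveats:\n")
    for (c_ in x$caveats) cat("    -", c_, "\n")
  }
  invisible(x)
}
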