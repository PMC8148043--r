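reg <- load_region_registry()

test_that("the workflow cannot start without MS-MLPA", {
  expect_error(classify_mechanism(NULL), "step 1")
  expect_error(classify_specimen(mlpa = NULL), "step 1")
})

test_that("validation-table evidence patterns reproduce their result labels", {
  # deletion overlap + large deletion (BP1-BP2 intact) + loss of paternal
  bp23 <- setdiff(reg$genes$gene, c("TUBGCP5", "CYFIP1", "NIPA2", "NIPA1",
                                    "APBA2"))
  call <- classify_mechanism(
    stub_mlpa("loss_of_paternal", "deletion_multi_gene", bp23),
    stub_cnv("completed", "type_II_deletion"),
    stub_aoh(positive = TRUE), registry = reg)
  expect_equal(call$syndrome, "PWS")
  expect_equal(call$mechanism, "type_II_deletion")
  expect_equal(call$parental_origin, "paternal")
  expect_equal(call$label, "Type II deletion, paternal")

  # type I when the BP1-BP2 genes go too
  call1 <- classify_mechanism(
    stub_mlpa("loss_of_paternal", "deletion_multi_gene",
              setdiff(reg$genes$gene, "APBA2")),
    stub_cnv("completed", "type_I_deletion"),
    stub_aoh(positive = TRUE), registry = reg)
  expect_equal(call1$label, "Type I deletion, paternal")

  # segmental isodisomy: no deletion, UPD-consistent AOH
  call2 <- classify_mechanism(
    stub_mlpa("loss_of_paternal", "normal"),
    stub_cnv("completed", "none"),
    stub_aoh(positive = TRUE, upd = TRUE, extent = "segmental"),
    registry = reg)
  expect_equal(call2$mechanism, "segmental_isodisomy_UPD")
  expect_equal(call2$label, "Segmental maternal isodisomy 15, i-UPD")

  # total isodisomy survives a CNV fail, with the fail caveated
  call3 <- classify_mechanism(
    stub_mlpa("loss_of_paternal", "normal"),
    stub_cnv("cnv_fail", "none"),
    stub_aoh(positive = TRUE, upd = TRUE, extent = "total"),
    registry = reg)
  expect_equal(call3$mechanism, "total_isodisomy_UPD")
  expect_equal(call3$label, "Total maternal isodisomy 15, i-UPD")
  expect_true(any(grepl("CNV fail", call3$caveats)))

  # normal copy number + negative AOH: the indeterminate disjunction
  call4 <- classify_mechanism(
    stub_mlpa("loss_of_paternal", "normal"),
    stub_cnv("completed", "none"), stub_aoh(), registry = reg)
  expect_equal(call4$mechanism, "heterodisomy_or_IC_epimutation")
  expect_equal(call4$label, "M-het-UPD or ICD (epimutation)")
  expect_true(any(grepl("parental DNA", call4$caveats)))

  # SNRPN-confined deletion: imprinting-center microdeletion
  call5 <- classify_mechanism(
    stub_mlpa("loss_of_paternal", "deletion_snrpn_only", "SNRPN"),
    stub_cnv("completed", "snrpn_only_deletion"),
    stub_aoh(), registry = reg)
  expect_equal(call5$mechanism, "IC_microdeletion")
  expect_equal(call5$label, "ICD (deletion of SNRPN)")

  # AS mirror: loss of maternal allele
  call6 <- classify_mechanism(
    stub_mlpa("loss_of_maternal", "deletion_multi_gene", bp23),
    stub_cnv("completed", "type_II_deletion"), stub_aoh(positive = TRUE),
    registry = reg)
  expect_equal(call6$syndrome, "AS")
  expect_equal(call6$parental_origin, "maternal")
  expect_equal(call6$label, "Type II deletion, maternal")
})

test_that("normal methylation resolves via supplied sequence variants", {
  m <- stub_mlpa("normal")
  call_u <- classify_mechanism(m, variants = small_variant_finding("UBE3A", "pathogenic"),
                               registry = reg)
  expect_equal(call_u$syndrome, "AS")
  expect_equal(call_u$mechanism, "point_mutation")

  call_s <- classify_mechanism(m, variants = small_variant_finding("SNRPN", "likely_pathogenic"),
                               registry = reg)
  expect_equal(call_s$syndrome, "PWS")
  expect_equal(call_s$mechanism, "point_mutation")

  call_m <- classify_mechanism(m, variants = small_variant_finding("MAGEL2", "pathogenic"),
                               registry = reg)
  expect_equal(call_m$mechanism, "negative")
  expect_true(any(grepl("Schaaf-Yang", call_m$caveats)))

  # non-pathogenic variants produce caveats only
  call_o <- classify_mechanism(m, variants = small_variant_finding("UBE3A", "other"),
                               registry = reg)
  expect_equal(call_o$mechanism, "negative")
  expect_true(any(grepl("other classification", call_o$caveats)))

  expect_equal(classify_mechanism(m, registry = reg)$mechanism, "negative")
})

test_that("expected-result scenarios map to their mechanisms", {
  bp23 <- setdiff(reg$genes$gene, c("TUBGCP5", "CYFIP1", "NIPA2", "NIPA1",
                                    "APBA2"))
  scenarios <- list(
    # I: multi-gene copy-number change
    list(call = classify_mechanism(
      stub_mlpa("loss_of_paternal", "deletion_multi_gene", bp23),
      stub_cnv("completed", "type_II_deletion"), stub_aoh(positive = TRUE),
      registry = reg),
      expect = "type_II_deletion"),
    # II: single-gene copy-number change (UBE3A, AS)
    list(call = classify_mechanism(
      stub_mlpa("loss_of_maternal", "deletion_single_gene", "UBE3A"),
      stub_cnv("completed", "single_gene"), stub_aoh(), registry = reg),
      expect = "atypical_deletion"),
    # III: point mutation with a normal methylation pattern
    list(call = classify_mechanism(
      stub_mlpa("normal"), stub_cnv("completed", "none"), stub_aoh(),
      variants = small_variant_finding("UBE3A", "pathogenic"),
      registry = reg),
      expect = "point_mutation"),
    # IV: i-UPD (AOH positive, normal copy number)
    list(call = classify_mechanism(
      stub_mlpa("loss_of_paternal", "normal"), stub_cnv("completed", "none"),
      stub_aoh(positive = TRUE, upd = TRUE, extent = "total"), registry = reg),
      expect = "total_isodisomy_UPD"),
    # V: h-UPD (all negative except methylation)
    list(call = classify_mechanism(
      stub_mlpa("loss_of_paternal", "normal"), stub_cnv("completed", "none"),
      stub_aoh(), registry = reg),
      expect = "heterodisomy_or_IC_epimutation"),
    # VI: imprinting-center defect, microdeletion form
    list(call = classify_mechanism(
      stub_mlpa("loss_of_paternal", "deletion_snrpn_only", "SNRPN"),
      stub_cnv("completed", "snrpn_only_deletion"), stub_aoh(), registry = reg),
      expect = "IC_microdeletion"),
    # VI footnote: copy-number-negative imprinting-center defect falls into
    # the indeterminate disjunction
    list(call = classify_mechanism(
      stub_mlpa("loss_of_paternal", "normal"), stub_cnv("completed", "none"),
      stub_aoh(), registry = reg),
      expect = "heterodisomy_or_IC_epimutation"))
  for (s in scenarios) expect_equal(s$call$mechanism, s$expect)
})

test_that("every evidence combination yields exactly one mechanism", {
  mechanisms <- pwsasdx:::MECHANISMS
  patterns <- c("loss_of_paternal", "loss_of_maternal", "normal",
                "uninterpretable")
  cn_states <- list(
    normal = stub_mlpa(cn_summary = "normal"),
    multi = NULL, snrpn = NULL, single = NULL, dup = NULL)
  bp23 <- setdiff(reg$genes$gene, c("TUBGCP5", "CYFIP1", "NIPA2", "NIPA1",
                                    "APBA2"))
  cn_args <- list(normal = list("normal", character()),
                  multi = list("deletion_multi_gene", bp23),
                  snrpn = list("deletion_snrpn_only", "SNRPN"),
                  single = list("deletion_single_gene", "UBE3A"),
                  dup = list("duplication", character()))
  cnv_states <- list(stub_cnv("completed", "none"),
                     stub_cnv("completed", "type_I_deletion"),
                     stub_cnv("completed", "snrpn_only_deletion"),
                     stub_cnv("cnv_fail"), NULL)
  aoh_states <- list(stub_aoh(), stub_aoh(positive = TRUE),
                     stub_aoh(positive = TRUE, upd = TRUE, extent = "segmental"),
                     stub_aoh(positive = TRUE, upd = TRUE, extent = "total"),
                     stub_aoh(consanguinity = TRUE), NULL)
  var_states <- list(NULL, small_variant_finding("SNRPN", "pathogenic"),
                     small_variant_finding("UBE3A", "pathogenic"),
                     small_variant_finding("MAGEL2", "pathogenic"))
  n <- 0
  for (p in patterns) for (cn in names(cn_args)) for (cv in cnv_states)
    for (ao in aoh_states) for (va in var_states) {
      ml <- stub_mlpa(p, cn_args[[cn]][[1]], cn_args[[cn]][[2]])
      call <- classify_mechanism(ml, cv, ao, va, registry = reg)
      expect_true(call$mechanism %in% mechanisms)
      expect_true(call$syndrome %in% c("PWS", "AS", "none", "indeterminate"))
      # heterodisomy is never asserted alone
      if (grepl("het-UPD", call$label)) {
        expect_match(call$label, "or ICD")
      }
      n <- n + 1
    }
  expect_equal(n, 4 * 5 * 5 * 6 * 4)
})

test_that("unconfirmed short WES CNV calls defer to MLPA copy number", {
  call <- classify_mechanism(
    stub_mlpa("loss_of_paternal", "normal"),
    stub_cnv("completed", "atypical_deletion", confirmation_required = TRUE),
    stub_aoh(), registry = reg)
  expect_equal(call$mechanism, "heterodisomy_or_IC_epimutation")
  expect_true(any(grepl("discordant", call$caveats)))
})

test_that("reports are deterministic, schema-valid, and carry caveats", {
  call <- classify_mechanism(
    stub_mlpa("loss_of_paternal", "normal"), stub_cnv("completed", "none"),
    stub_aoh(), meta = list(specimen_id = "RPT1"), registry = reg)
  r1 <- render_report(call, stub_mlpa("loss_of_paternal", "normal"),
                      stub_cnv("completed", "none"), stub_aoh())
  r2 <- render_report(call, stub_mlpa("loss_of_paternal", "normal"),
                      stub_cnv("completed", "none"), stub_aoh())
  expect_identical(r1$json, r2$json)
  expect_true(validate_report(r1$report))
  expect_true(validate_report(r1$json))
  expect_true(any(grepl("parental DNA", unlist(r1$report$caveats))))

  # files are written when a prefix is given
  pre <- tempfile()
  r3 <- render_report(call, out_prefix = pre)
  expect_true(file.exists(paste0(pre, ".json")))
  expect_true(validate_report(paste0(pre, ".json")))
  expect_true(any(grepl("Result:", readLines(paste0(pre, ".txt")))))

  bad <- r1$report; bad$mechanism <- NULL
  expect_error(validate_report(bad), "mechanism")
})
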