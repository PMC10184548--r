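test_that("midbrain ratio matches the comparative table at 2 dp", {
  expect_equal(round_half_up(midbrain_medulla_ratio(61.6, 46.9), 2), 1.31)
  expect_equal(round_half_up(midbrain_medulla_ratio(61.1, 49.9), 2), 1.22)
  expect_equal(midbrain_medulla_ratio(33, 33), 1)
  expect_error(midbrain_medulla_ratio(0, 10), "> 0")
})

test_that("reference tables load with the expected shape", {
  hearing <- load_reference_table("hearing")
  expect_equal(nrow(hearing), 15)  # includes two Velociraptor specimens
  expect_equal(sum(hearing$taxon == "Velociraptor"), 2)
  expect_true(is.na(hearing$bcl_mm[hearing$taxon == "Phuwiangosaurus"]))

  midbrain <- load_reference_table("midbrain")
  trex <- midbrain[midbrain$taxon == "Tyrannosaurus", ]
  expect_equal(trex$ratio, 0.8)

  req_tab <- load_reference_table("req")
  allo <- req_tab[req_tab$taxon == "Allosaurus", ]
  expect_equal(c(allo$req37_min, allo$req37_max), c(1.3, 1.8))  # range kept
  expect_equal(req_tab$mbd_g_min[req_tab$taxon == "Baryonyx"], 2011000)

  metrics <- load_reference_table("metrics")
  expect_equal(metrics$endocast_volume_cm3,
               c(150.487, 185.603))
  expect_true(all(metrics$cephalic_flexure_deg > 0 &
                    metrics$cephalic_flexure_deg < 180))

  expect_error(load_reference_table("unknown"),
               "metrics, midbrain, req, hearing, olfaction")
})

test_that("every record flagged recomputable rederives at printed precision", {
  audit <- audit_reference_tables()
  expect_gt(nrow(audit), 50)
  bad <- audit[!audit$ok, ]
  expect_equal(nrow(bad), 0, info = paste(capture.output(print(bad)),
                                          collapse = "\n"))
})

test_that("a full specimen report reproduces the published quantities", {
  rep <- specimen_report(data.frame(
    taxon = "Baryonyx", specimen_id = "NHMUK PV R9951",
    endocast_volume_cm3 = 150.487, femoral_circumference_mm = 350,
    ecd_mm = 19.6, bcl_mm = 104.5,
    midbrain_length_mm = 61.6, medulla_length_mm = 46.9
  ))
  g <- glance(rep)
  expect_equal(g$body_mass_g, 2010985)
  expect_equal(g$req_37, 1.2)
  expect_equal(g$req_50, 1.6)
  expect_equal(g$best_range_hz, 2538)
  expect_equal(g$mean_freq_hz, 1594)
  expect_equal(g$midbrain_medulla_ratio, 1.31)
  # olfactory inputs were not supplied: marked not computable, not dropped
  res <- tidy(rep)
  olf <- res[res$quantity == "olfactory_ratio_pct", ]
  expect_false(olf$computable)
  expect_match(olf$inputs, "missing")
})

test_that("missing inputs are reported in-band, never dropped", {
  rep <- specimen_report(data.frame(taxon = "Mystery"))
  res <- tidy(rep)
  expect_true(all(!res$computable))
  expect_setequal(unique(res$section),
                  c("mass", "encephalization", "hearing", "olfaction",
                    "midbrain"))
  # partial inputs: hearing needs both lengths
  rep2 <- specimen_report(data.frame(taxon = "Partial", ecd_mm = 15,
                                     midbrain_length_mm = 50,
                                     medulla_length_mm = 40))
  res2 <- tidy(rep2)
  expect_false(res2$computable[res2$quantity == "best_range_hz"])
  expect_true(res2$computable[res2$quantity == "midbrain_medulla_ratio"])
})

test_that("a specimen can borrow another specimen's body mass", {
  rep <- specimen_report(data.frame(
    taxon = c("Baryonyx", "Ceratosuchops"),
    femoral_circumference_mm = c(350, NA),
    bulb_length_mm = c(NA, 26.4), cerebrum_diameter_mm = c(NA, 52.2),
    borrow_mass_from = c(NA, "Baryonyx")
  ))
  res <- tidy(rep)
  cer_mass <- res[res$taxon == "Ceratosuchops" &
                    res$quantity == "body_mass_g", ]
  expect_true(cer_mass$computable)
  expect_match(cer_mass$inputs, "borrowed from Baryonyx")
  lbm <- res[res$taxon == "Ceratosuchops" & res$quantity == "log_body_mass", ]
  expect_equal(lbm$value, log10(body_mass_bipedal(350)$mass_g))
})

test_that("report serialisation is deterministic", {
  d <- data.frame(taxon = "Baryonyx", endocast_volume_cm3 = 150.487,
                  femoral_circumference_mm = 350)
  j1 <- render_report(specimen_report(d), format = "json")
  j2 <- render_report(specimen_report(d), format = "json")
  expect_identical(j1, j2)
  md <- render_report(specimen_report(d), format = "markdown")
  expect_match(md, "not computable")
  expect_match(md, "## Baryonyx")
})

test_that("report methods expose tidy, glance and autoplot surfaces", {
  rep <- specimen_report(data.frame(taxon = "Baryonyx",
                                    ecd_mm = 19.6, bcl_mm = 104.5))
  expect_s3_class(tidy(rep), "tbl_df")
  expect_s3_class(glance(rep), "tbl_df")
  expect_s3_class(autoplot(rep), "ggplot")
})
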