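test_that("variant construction rejects meaningless field combinations", {
  expect_error(model_variant("N1", conversion = "SG"), "meaningless")
  expect_error(model_variant("N2", conversion = "I"), "meaningless")
  expect_error(model_variant("N1", resistance_origin = "both"), "meaningless")
  expect_error(model_variant("N3", conversion = "I", signal_source = "B_only"),
               "signal")
  # valid constructions fill sensible defaults
  v <- model_variant("N3")
  expect_equal(v$conversion, "SG")
  expect_equal(v$signal_source, "B_only")
  v2 <- model_variant("N2")
  expect_null(v2$conversion)
  expect_equal(v2$resistance_origin, "both")
})

test_that("active compartments reflect the variant's exclusions", {
  expect_setequal(active_compartments(model_variant("N1")),
                  c("N_S", "P", "B", "V", "I", "M"))
  expect_setequal(active_compartments(model_variant("N2")),
                  c("N_S", "N_R", "P", "B", "V", "I", "M"))
  expect_true("C" %in% active_compartments(reference_variant()))
  expect_false("C" %in% active_compartments(model_variant("N3", conversion = "IG")))
  expect_true(all(c("N_D", "C") %in%
                    active_compartments(model_variant("N4", conversion = "S"))))
})

test_that("variant labels follow the field naming scheme", {
  expect_equal(variant_label(reference_variant()), "N3-SBG-Pii-Vi")
  expect_equal(variant_label(model_variant("N3", conversion = "SG",
                                           signal_source = "both")),
               "N3-SG-Pii-Vi")
  expect_equal(variant_label(model_variant("N3", conversion = "IG",
                                           p_saturation = "Pi")),
               "N3-IG-Pi-Vi")
  expect_equal(variant_label(model_variant("N1", p_saturation = "Pi",
                                           v_saturation = "Vii")),
               "N1-Pi-Vii")
})

test_that("variants round-trip through list serialization", {
  for (v in some_variants()) {
    expect_equal(copred:::variant_from_list(copred:::variant_to_list(v)), v)
  }
})
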