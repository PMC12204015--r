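test_that("unit conversions reproduce the published factors", {
  expect_equal(convert_units(1, "insulin_uUml_to_pM_human"), 5.975)
  expect_equal(convert_units(1, "insulin_ngml_to_pM_mouse"), 1000 / 5.8,
               tolerance = 1e-12)
  expect_equal(convert_units(1, "insulin_ngml_to_pM_mouse"), 172.41,
               tolerance = 1e-4)
  expect_equal(convert_units(0, "glucose_mM_to_mgdl"), 0)
  # mM -> mg/dL -> mM round trip
  v <- c(0.3, 5.6, 11.1, 33)
  expect_equal(
    convert_units(convert_units(v, "glucose_mM_to_mgdl"),
                  "glucose_mgdl_to_mM"), v, tolerance = 1e-12)
  # ng/mL -> μU/mL chain is mouse-molar then human-unit conversion
  expect_equal(convert_units(1, "insulin_ngml_to_uUml"),
               (1000 / 5.8) / 5.975, tolerance = 1e-12)
  expect_error(convert_units(1, "furlongs"))
  expect_error(convert_units(-1, "glucose_mM_to_mgdl"), ">= 0")
})

test_that("HOMA-IR follows I0 x G0 / 22.5", {
  expect_equal(homa_ir(10, 5.625), 2.5)
  expect_equal(homa_ir(22.5, 1), 1)
  # spreadsheet-style independent recomputation on a random panel
  set.seed(31)
  I0 <- runif(50, 2, 40); G0 <- runif(50, 3, 12)
  manual <- vapply(seq_along(I0), function(i) I0[i] * G0[i] / 22.5,
                   numeric(1))
  expect_equal(homa_ir(I0, G0), manual, tolerance = 1e-12)
  expect_error(homa_ir(0, 5), "> 0")
})

test_that("QUICKI uses base-10 logs of insulin and mg/dL glucose", {
  expect_equal(quicki(10, 100), 1 / 3)
  expect_equal(quicki(1, 10), 1)
  expect_error(quicki(1, 1), "zero")    # log10 sum zero
  expect_error(quicki(-1, 100), "> 0")
})

test_that("HOMA-IR and QUICKI are antitone on any joint panel", {
  set.seed(37)
  I0 <- runif(80, 2, 40); G0 <- runif(80, 3, 12)
  h <- homa_ir(I0, G0)
  q <- quicki(I0, convert_units(G0, "glucose_mM_to_mgdl"))
  expect_lte(cor(h, q, method = "spearman"), 0)
})

test_that("status classification honours the boundary conventions", {
  panel <- glycaemic_panel(
    sprintf("m%d", 1:6),
    glucose_mm = c(5.5, 5.6, 5.9, 6.1, 4.0, 7.0),
    insulin_uUml = c(10, 10, 10, 10, 4.9, 15.1),
    postload_mm = c(7.7, 7.8, 11.0, 11.1, 5.0, 14.0))
  st <- classify_status(panel)
  expect_equal(as.character(st$fasting),
               c("normal", "IFG", "IFG", "T2DM-range", "normal",
                 "T2DM-range"))
  expect_equal(as.character(st$postload),
               c("normal", "IGT", "IGT", "T2DM-range", "normal",
                 "T2DM-range"))
  expect_equal(as.character(st$insulin),
               c("normal", "normal", "normal", "normal", "low", "high"))
  # HOMA-IR exactly 2.5 is normal; strictly above is IR
  p2 <- glycaemic_panel(c("a", "b"), c(5.625, 5.626), c(10, 10))
  st2 <- classify_status(p2)
  expect_equal(as.character(st2$homa), c("normal", "IR"))
  # QUICKI boundaries: 0.339 normal, just below is IR, below 0.300 T2DM
  p3 <- data.frame(animal_id = c("x", "y", "z"), glucose_mm = 5,
                   insulin_uUml = 10, homa_ir = 1,
                   quicki = c(0.339, 0.3389, 0.2999))
  st3 <- classify_status(p3)
  expect_equal(as.character(st3$quicki), c("normal", "IR", "T2DM-range"))
})

test_that("every panel row gets exactly one label per axis", {
  set.seed(41)
  panel <- glycaemic_panel(sprintf("m%d", 1:40),
                           glucose_mm = runif(40, 3, 13),
                           insulin_uUml = runif(40, 2, 40),
                           postload_mm = runif(40, 4, 16))
  st <- classify_status(panel)
  for (axis in c("fasting", "postload", "homa", "quicki", "insulin")) {
    expect_false(any(is.na(st[[axis]])))
  }
})

test_that("Lee index and metabolic efficiency match their formulas", {
  expect_equal(lee_index(27, 9), 1 / 3)
  expect_equal(lee_index(8, 2), 1)
  set.seed(43)
  w <- runif(20, 10, 60); l <- runif(20, 6, 12)
  expect_equal(lee_index(w, l), w^(1 / 3) * l^(-1), tolerance = 1e-12)
  expect_error(lee_index(-1, 5), "> 0")

  expect_equal(metabolic_efficiency(100, 2), 50)
  expect_true(is.na(metabolic_efficiency(100, 0)))
  expect_true(is.na(metabolic_efficiency(100, -1)))
  expect_error(metabolic_efficiency(-5, 1), ">= 0")
  # weekly series vs cumulative-difference oracle
  weight <- c(9, 11, 14, 16, 17, 17)
  intake <- rep(300, 5)
  gains <- diff(weight)
  eff <- metabolic_efficiency(intake, gains)
  expect_equal(eff[1:4], 300 / gains[1:4])
  expect_true(is.na(eff[5]))
})
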