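test_that("a symmetric triangle yields its closed-form boundaries and traits", {
  g <- 0:1200
  v <- triangleCurve(g)
  ph <- delimitPhases(g, v)
  expect_equal(ph$t_e, 1)
  expect_equal(ph$t_M, 600)
  expect_equal(ph$t_o, 631)  # first grid time strictly below 0.95 * 4
  expect_equal(ph$t_z, 1200)
  expect_false(ph$truncated)
  tr <- extractTraits(g, v, ph)
  expect_equal(length(tr), 24L)
  expect_setequal(names(tr), glaiTraitNames())
  expect_equal(unname(tr["AUC_C"]), 2400, tolerance = 0.01 * 2400)
  expect_equal(unname(tr["D_50"]), 600, tolerance = 2)
  expect_equal(unname(tr["GLAI_M"]), 4)
})

test_that("curves that never return to zero are clipped and flagged truncated", {
  g <- 0:1000
  v <- pmin(g / 200, 3)  # rises then stays flat at 3
  ph <- delimitPhases(g, v)
  expect_true(ph$truncated)
  expect_equal(ph$t_z, 1000)
  tr <- extractTraits(g, v, ph)
  expect_true(attr(tr, "truncated"))
  expect_equal(length(tr), 24L)
})

test_that("a non-positive curve is rejected", {
  expect_error(delimitPhases(0:100, rep(0, 101)), "non-positive")
})

test_that("duration and AUC additivity identities hold on random curves", {
  set.seed(31)
  for (i in 1:12) {
    tr <- extractTraits(0:2000, glaiCurve(randomCurveParams(), 0:2000))
    relTol <- function(a, b) abs(a - b) <= 1e-6 * pmax(abs(b), 1)
    expect_true(relTol(tr["D_EV"] + tr["D_LV"], tr["D_V"]))
    expect_true(relTol(tr["D_SS"] + tr["D_RS"], tr["D_S"]))
    expect_true(relTol(tr["D_V"] + tr["D_F"] + tr["D_S"], tr["D_C"]))
    expect_true(relTol(tr["AUC_EV"] + tr["AUC_LV"], tr["AUC_V"]))
    expect_true(relTol(tr["AUC_SS"] + tr["AUC_RS"], tr["AUC_S"]))
    expect_true(relTol(tr["AUC_V"] + tr["AUC_F"] + tr["AUC_S"],
                       tr["AUC_C"]))
    expect_true(tr["D_25"] >= tr["D_50"] && tr["D_50"] >= tr["D_75"] &&
                  tr["D_75"] >= 0)
    expect_true(tr["S_EV"] >= 0 && tr["S_LV"] >= 0)
    expect_true(tr["S_SS"] <= 0 && tr["S_RS"] <= 0)
  }
})

test_that("rescaling GLAI scales areas and slopes but not durations", {
  set.seed(8)
  pars <- randomCurveParams()
  g <- 0:2000
  v <- glaiCurve(pars, g)
  tr1 <- extractTraits(g, v)
  tr2 <- extractTraits(g, 3 * v)
  scaled <- c(grep("^S_", glaiTraitNames(), value = TRUE),
              grep("^AUC_", glaiTraitNames(), value = TRUE), "GLAI_M")
  durations <- grep("^D_", glaiTraitNames(), value = TRUE)
  expect_equal(unname(tr2[scaled]), unname(3 * tr1[scaled]),
               tolerance = 1e-3)
  expect_equal(unname(tr2[durations]), unname(tr1[durations]),
               tolerance = 0.02)
})

test_that("planted phase breaks are recovered at zero noise", {
  pars <- glaiCurveParams()  # tau_v = 350, tau_s = 1500
  g <- 0:2000
  ph <- delimitPhases(g, glaiCurve(pars, g))
  expect_equal(ph$t_1, 350, tolerance = 5)
  expect_equal(ph$t_2, 1500, tolerance = 5)
})

test_that("interpolated flight observations reproduce the dense-curve traits", {
  pars <- glaiCurveParams()
  ft <- round(seq(150, 1800, length.out = 10))
  obs <- data.frame(plot_id = "p1", gdd6 = ft,
                    glai = glaiCurve(pars, ft))
  tab <- extractTraitsTable(obs)
  expect_equal(nrow(tab), 1L)
  tt <- trueGlaiTraits(pars)
  expect_equal(tab$GLAI_M, unname(tt["GLAI_M"]), tolerance = 0.05)
  expect_equal(tab$AUC_C, unname(tt["AUC_C"]), tolerance = 0.1 * tt["AUC_C"])
  expect_equal(tab$D_50, unname(tt["D_50"]), tolerance = 40)
})
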